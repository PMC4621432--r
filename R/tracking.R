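#' Detect fly blobs in a grayscale frame
#'
#' Flies are dark objects on a bright background. The frame is thresholded
#' (fixed global threshold; Otsu-initialized when `threshold = NULL`),
#' connected components are labelled, and components are filtered by area and
#' reported by intensity-weighted centroid (weights are the inverted
#' intensities, so darker pixels pull harder).
#'
#' @param frame Integer/numeric matrix, gray levels 0-255 (rows = image rows).
#' @param threshold Gray level below which a pixel is foreground; NULL for
#'   Otsu on the inverted image.
#' @param min_area,max_area Component area limits in px^2.
#' @return data.frame with `x, y` (px, centroid) and `area` (px^2).
#' @export
detect_blobs <- function(frame, threshold = NULL, min_area = 1,
                         max_area = Inf) {
  if (is.null(dim(frame)) || length(dim(frame)) != 2 || !length(frame))
    stop("frame must be a non-empty 2-D image")
  stopifnot(min_area > 0, min_area <= max_area)
  img <- frame / 255
  if (is.null(threshold)) {
    inv <- 1 - img
    thr_inv <- EBImage::otsu(EBImage::Image(inv), range = c(0, 1))
    threshold <- (1 - thr_inv) * 255
  }
  binary <- img < threshold / 255
  if (!any(binary))
    return(data.frame(x = numeric(0), y = numeric(0), area = numeric(0)))
  # EBImage images are indexed [x, y]; transpose so labels match the matrix
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(binary))))
  lab <- t(lab)
  ids <- which(lab > 0)
  comp <- lab[ids]
  w <- (1 - img[ids])
  rows <- ((ids - 1) %% nrow(frame)) + 1
  cols <- ((ids - 1) %/% nrow(frame)) + 1
  sw <- tapply(w, comp, sum)
  cx <- tapply(w * cols, comp, sum) / sw
  cy <- tapply(w * rows, comp, sum) / sw
  area <- as.numeric(table(comp))
  keep <- area >= min_area & area <= max_area
  data.frame(x = as.numeric(cx)[keep], y = as.numeric(cy)[keep],
             area = area[keep])
}

#' Detect blobs across a frame stack
#'
#' @param stack A `frame_stack` or list of matrices with attribute `frames`.
#' @param ... Passed to [detect_blobs()].
#' @return data.frame with `frame, x, y, area`, ordered by frame.
#' @export
detect_blobs_stack <- function(stack, threshold = NULL, ...) {
  frames <- attr(stack, "frames")
  if (is.null(frames)) frames <- seq_along(stack) - 1L
  if (is.null(threshold) && length(stack)) {
    # fix one global Otsu threshold from the first frame (scenes are bimodal)
    inv <- 1 - stack[[1]] / 255
    threshold <- (1 - EBImage::otsu(EBImage::Image(inv), range = c(0, 1))) * 255
  }
  res <- lapply(seq_along(stack), function(k) {
    d <- detect_blobs(stack[[k]], threshold = threshold, ...)
    if (nrow(d)) d$frame <- frames[k]
    d
  })
  res <- res[vapply(res, nrow, integer(1)) > 0]
  if (!length(res))
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$frame), c("frame", "x", "y", "area")]
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbor assignment of detections to active tracks
#' within `gate_distance`. Intersecting flies terminate their tracks: a
#' detection whose area exceeds `merge_area_factor` times the running median
#' single-fly area, or that is the unique gated match of two or more active
#' tracks, is declared a merge — every involved track is terminated and the
#' merged blob contributes no position to any track (fly identity inside a
#' merge is unknown). When the blobs separate, fresh track ids are opened.
#' Detections with no gated track open new tracks; active tracks with no
#' gated detection are terminated (no gap bridging: frame indices within a
#' track are strictly consecutive). Track ids increase in order of creation.
#'
#' @param detections data.frame `frame, x, y, area` ordered by frame (px).
#' @param gate_distance Maximum displacement between consecutive frames, px.
#' @param merge_area_factor Area ratio above which a blob is a merge
#'   candidate (default 1.7).
#' @param frame_rate,arena Metadata for the output `trackset`; when `arena`
#'   is given, pixel centroids are converted to cm.
#' @return A `trackset`. The returned object also carries an element
#'   `assignment_audit`: per-frame counts of assigned, merge-flagged and
#'   new-track detections.
#' @export
link_detections <- function(detections, gate_distance, merge_area_factor = 1.7,
                            frame_rate = 30, arena = NULL) {
  d <- detections
  if (nrow(d) && is.unsorted(d$frame)) stop("detections must be ordered by frame")
  stopifnot(gate_distance > 0, merge_area_factor > 1)
  frames <- if (nrow(d)) seq(min(d$frame), max(d$frame)) else integer(0)
  det_by_frame <- if (nrow(d)) split(seq_len(nrow(d)), factor(d$frame, levels = frames))
    else list()
  aid <- integer(0); ax <- numeric(0); ay <- numeric(0)  # active tracks
  next_id <- 1L
  cap <- max(nrow(d), 1L)
  out_id <- integer(cap); out_frame <- integer(cap)
  out_x <- numeric(cap); out_y <- numeric(cap)
  n_out <- 0L
  audit <- vector("list", length(frames))
  area_hist <- numeric(0)

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det <- d[det_by_frame[[fi]], , drop = FALSE]
    nd <- nrow(det)
    area_hist <- c(utils::tail(area_hist, 499), det$area)
    med_area <- stats::median(area_hist)
    assigned_det <- rep(FALSE, nd)
    merged_det <- rep(FALSE, nd)
    det_of_track <- rep(NA_integer_, length(aid))

    if (nd) {
      # merge rule 1: oversized blob (area alone suffices)
      merged_det <- det$area > merge_area_factor * med_area
    }
    if (nd && length(aid)) {
      dist <- sqrt(outer(ax, det$x, "-")^2 +
                   outer(ay, det$y, "-")^2)
      gated <- dist <= gate_distance
      # merge rule 2: a detection that is the unique gated match of >= 2 tracks
      for (j in seq_len(nd)) {
        trks <- which(gated[, j])
        trks_unique <- trks[vapply(trks, function(i) sum(gated[i, ]) == 1L,
                                   logical(1))]
        if (length(trks_unique) >= 2) merged_det[j] <- TRUE
        if (merged_det[j]) det_of_track[trks] <- -1L  # involved tracks end
      }
      # greedy mutual nearest neighbor on the rest
      dist[, merged_det] <- Inf
      dist[!gated] <- Inf
      dist[det_of_track %in% -1L, ] <- Inf
      while (any(is.finite(dist))) {
        k <- arrayInd(which.min(dist), dim(dist))
        i <- k[1]; j <- k[2]
        if (which.min(dist[i, ]) == j && which.min(dist[, j]) == i) {
          det_of_track[i] <- j
          assigned_det[j] <- TRUE
          dist[i, ] <- Inf
          dist[, j] <- Inf
        } else {
          dist[i, j] <- Inf  # not mutual: suppress this pair and retry
        }
      }
    }

    # record assigned samples; continued tracks stay active
    cont <- which(!is.na(det_of_track) & det_of_track > 0)
    new_rows <- which(!assigned_det & !merged_det)
    k <- length(cont) + length(new_rows)
    new_ids <- if (length(new_rows))
      seq.int(next_id, length.out = length(new_rows)) else integer(0)
    if (k) {
      idx <- n_out + seq_len(k)
      js <- c(det_of_track[cont], new_rows)
      out_id[idx] <- c(aid[cont], new_ids)
      out_frame[idx] <- f
      out_x[idx] <- det$x[js]
      out_y[idx] <- det$y[js]
      n_out <- n_out + k
      aid <- out_id[idx]; ax <- out_x[idx]; ay <- out_y[idx]
    } else {
      aid <- integer(0); ax <- numeric(0); ay <- numeric(0)
    }
    next_id <- next_id + length(new_rows)
    audit[[fi]] <- c(frame = f, n_detections = nd,
                     assigned = sum(assigned_det),
                     merged = sum(merged_det),
                     new_tracks = length(new_rows))
  }

  tr <- data.frame(track_id = out_id[seq_len(n_out)],
                   frame = out_frame[seq_len(n_out)],
                   x = out_x[seq_len(n_out)], y = out_y[seq_len(n_out)])
  tr <- tr[order(tr$track_id, tr$frame), , drop = FALSE]
  rownames(tr) <- NULL
  if (!is.null(arena)) {
    cm <- px_to_cm(tr$x, tr$y, arena)
    tr$x_cm <- cm$x; tr$y_cm <- cm$y
  } else {
    tr$x_cm <- tr$x; tr$y_cm <- tr$y
  }
  tr$t_s <- tr$frame / frame_rate
  ts <- as_trackset(tr[, c("track_id", "frame", "t_s", "x_cm", "y_cm")],
                    frame_rate = frame_rate, arena = arena)
  ts$assignment_audit <- as.data.frame(do.call(rbind, audit))
  ts
}

#' Track a rendered frame stack end to end
#'
#' Convenience wrapper: [detect_blobs_stack()] then [link_detections()].
#'
#' @param stack A `frame_stack`.
#' @param frame_rate Hz.
#' @param arena `arena_geometry` for px-to-cm conversion (defaults to the
#'   stack's arena attribute).
#' @param gate_distance px; default 3 cm worth of pixels per frame interval,
#'   approximately the maximum walking displacement.
#' @param ... Passed to [detect_blobs()].
#' @return A `trackset` in cm.
#' @export
track_frames <- function(stack, frame_rate = 30, arena = attr(stack, "arena"),
                         gate_distance = NULL, ...) {
  det <- detect_blobs_stack(stack, ...)
  if (is.null(gate_distance)) {
    ppc <- if (!is.null(arena)) arena$px_per_cm else 10
    gate_distance <- max(3 * ppc / frame_rate, 3)
  }
  link_detections(det, gate_distance = gate_distance,
                  frame_rate = frame_rate, arena = arena)
}
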