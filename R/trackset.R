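#' Track sets
#'
#' A `trackset` bundles a table of frame-indexed fly positions with the
#' recording frame rate and the arena it was recorded in. It is the common
#' currency of the pipeline: both the simulator and the video tracker emit
#' the same schema, so either source feeds the behavior statistics.
#'
#' @param tracks data.frame with at least `track_id, frame, t_s, x_cm, y_cm`;
#'   `sex` is optional (NA for video-derived tracks).
#' @param frame_rate Recording rate, Hz.
#' @param arena An `arena_geometry` or NULL.
#' @return An object of class `trackset`: a list with `tracks`, `frame_rate`,
#'   `arena`.
#' @export
as_trackset <- function(tracks, frame_rate, arena = NULL) {
  need <- c("track_id", "frame", "t_s", "x_cm", "y_cm")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("track table is missing required columns: ", paste(miss, collapse = ", "))
  if (!"sex" %in% names(tracks)) tracks$sex <- NA_character_
  structure(list(tracks = tracks, frame_rate = frame_rate, arena = arena),
            class = "trackset")
}

#' @export
print.trackset <- function(x, ...) {
  nt <- length(unique(x$tracks$track_id))
  cat(sprintf("trackset: %d tracks, %d samples, %.3g Hz\n",
              nt, nrow(x$tracks), x$frame_rate))
  invisible(x)
}

#' Drop tracks shorter than a minimum length
#'
#' @param ts A `trackset`.
#' @param min_length_frames Minimum number of samples a track must have.
#' @return A `trackset` containing only the surviving tracks, their samples
#'   unchanged.
#' @export
filter_tracks <- function(ts, min_length_frames = 1L) {
  stopifnot(inherits(ts, "trackset"), min_length_frames >= 1)
  len <- table(ts$tracks$track_id)
  keep <- names(len)[len >= min_length_frames]
  ts$tracks <- ts$tracks[as.character(ts$tracks$track_id) %in% keep, ,
                         drop = FALSE]
  rownames(ts$tracks) <- NULL
  ts
}

#' Read and write the track CSV schema
#'
#' One schema regardless of origin (simulated or video-derived):
#' columns `track_id, frame, t_s, x_cm, y_cm, sex`. Floating-point columns
#' are written with 9 significant digits so re-runs are checksum-stable.
#'
#' @param ts A `trackset`.
#' @param path CSV file path.
#' @param frame_rate,arena Metadata to attach on read.
#' @return `write_tracks_csv` returns `path` invisibly; `read_tracks_csv`
#'   returns a `trackset`.
#' @export
write_tracks_csv <- function(ts, path) {
  stopifnot(inherits(ts, "trackset"))
  df <- ts$tracks[, intersect(c("track_id", "frame", "t_s", "x_cm", "y_cm", "sex"),
                              names(ts$tracks)), drop = FALSE]
  for (cn in c("t_s", "x_cm", "y_cm"))
    df[[cn]] <- signif(df[[cn]], 9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, frame_rate, arena = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_trackset(df, frame_rate = frame_rate, arena = arena)
}
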