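#' Render infrared-style frames from tracks
#'
#' Produces 8-bit grayscale frames of the arena as the infrared camera sees
#' it: bright background, dark filled discs at each fly position. The frame
#' count equals the frame range of the track set; a frame with no samples is
#' rendered blank.
#'
#' @param ts A `trackset` whose arena has `px_per_cm` set.
#' @param fly_radius_px Fly disc radius in pixels (>= 1).
#' @param bg,fg Background and fly gray levels, 0-255.
#' @return A list of integer matrices (rows = image rows, top-down), class
#'   `frame_stack`, with attributes `frames` (frame indices) and `arena`.
#' @export
render_frames <- function(ts, fly_radius_px = 3L, bg = 230L, fg = 30L) {
  stopifnot(inherits(ts, "trackset"), fly_radius_px >= 1)
  arena <- ts$arena
  if (is.null(arena)) stop("trackset has no arena; rendering needs px_per_cm")
  npx <- image_size_px(arena)
  tr <- ts$tracks
  frames <- if (nrow(tr)) seq(min(tr$frame), max(tr$frame)) else integer(0)
  px <- cm_to_px(tr$x_cm, tr$y_cm, arena)
  if (nrow(tr) && (any(px$x < 1) || any(px$x > npx) ||
                   any(px$y < 1) || any(px$y > npx)))
    stop("fly positions fall outside the image bounds")
  r <- fly_radius_px
  dy <- rep(-r:r, each = 2 * r + 1)
  dx <- rep(-r:r, times = 2 * r + 1)
  disc <- dx^2 + dy^2 <= r^2
  dx <- dx[disc]; dy <- dy[disc]
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    img <- matrix(as.integer(bg), npx, npx)
    idx <- which(tr$frame == frames[k])
    for (i in idx) {
      cx <- round(px$x[i]); cy <- round(px$y[i])
      xs <- cx + dx; ys <- cy + dy
      ok <- xs >= 1 & xs <= npx & ys >= 1 & ys <= npx
      img[cbind(ys[ok], xs[ok])] <- as.integer(fg)
    }
    out[[k]] <- img
  }
  structure(out, class = "frame_stack", frames = frames, arena = arena)
}

#' Write / read a frame stack as a PNG sequence
#'
#' Frames are written as zero-padded 8-bit grayscale PNGs
#' (`frame_000000.png`, ...).
#'
#' @param stack A `frame_stack`.
#' @param dir Output directory (created if needed).
#' @return `write_frames_png` returns the file paths invisibly;
#'   `read_frames_png` returns a list of integer matrices with attribute
#'   `frames`.
#' @export
write_frames_png <- function(stack, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG frames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames <- attr(stack, "frames")
  paths <- file.path(dir, sprintf("frame_%06d.png", frames))
  for (k in seq_along(stack))
    png::writePNG(stack[[k]] / 255, paths[k])
  invisible(paths)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read PNG frames")
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame PNGs found in ", dir)
  frames <- as.integer(sub("^frame_(\\d+)\\.png$", "\\1", basename(files)))
  out <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  })
  attr(out, "frames") <- frames
  out
}
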