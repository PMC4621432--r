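#' Arena geometry for the four-quadrant olfactometer
#'
#' Builds the star-shaped four-quadrant arena. Physical coordinates are in cm
#' with the origin at the lower-left corner of the bounding square, x rightward
#' and y upward; image pixel space (row-major, top-left origin) is converted
#' explicitly with [cm_to_px()] / [px_to_cm()]. The default walkable mask is
#' the bounding square minus four isosceles right-triangle corner notches of
#' leg `0.25 * side_length`, a simple star approximation; all quadrant
#' statistics depend only on the sign pattern about the center, so the exact
#' mask outline is configurable and not load-bearing.
#'
#' Quadrant naming at rotation 0: Q1 = (+,+), Q2 = (-,+), Q3 = (-,-),
#' Q4 = (+,-) relative to the center. The odor quadrant is an experiment
#' configuration field, not a geometry property.
#'
#' @param side_length Side of the bounding square in cm (default 19.5).
#' @param px_per_cm Pixels per cm for rendering/tracking conversion (> 0).
#' @param rotation Arena rotation in degrees counterclockwise; must be a
#'   multiple of 90.
#' @param mask_polygon Optional n x 2 matrix of vertices (cm) overriding the
#'   default star mask. Must be a simple polygon containing the center.
#' @param notch_frac Corner-notch leg as a fraction of `side_length` for the
#'   default mask (default 0.25).
#' @return An object of class `arena_geometry`.
#' @examples
#' a <- build_arena(19.5, 10, 0)
#' a$center  # (9.75, 9.75)
#' @export
build_arena <- function(side_length = 19.5, px_per_cm = 10, rotation = 0,
                        mask_polygon = NULL, notch_frac = 0.25) {
  if (!is.numeric(side_length) || length(side_length) != 1 || side_length <= 0)
    stop("side_length must be a positive scalar (cm)")
  if (!is.numeric(px_per_cm) || length(px_per_cm) != 1 || px_per_cm <= 0)
    stop("px_per_cm must be a positive scalar")
  rotation <- check_rotation(rotation)
  s <- side_length
  center <- c(s / 2, s / 2)
  if (is.null(mask_polygon)) {
    n <- notch_frac * s
    # square minus 4 corner notches, CCW from lower edge
    mask_polygon <- rbind(
      c(n, 0), c(s - n, 0), c(s, n), c(s, s - n),
      c(s - n, s), c(n, s), c(0, s - n), c(0, n)
    )
  } else {
    mask_polygon <- as.matrix(mask_polygon)
    if (ncol(mask_polygon) != 2 || nrow(mask_polygon) < 3)
      stop("mask_polygon must be an n x 2 matrix with n >= 3")
    if (!pracma::inpolygon(center[1], center[2],
                           mask_polygon[, 1], mask_polygon[, 2]))
      stop("mask_polygon must contain the arena center")
  }
  structure(list(
    side_length = s,
    center = center,
    rotation = rotation %% 360,
    mask_polygon = mask_polygon,
    px_per_cm = px_per_cm
  ), class = "arena_geometry")
}

check_rotation <- function(rotation) {
  if (!is.numeric(rotation) || length(rotation) != 1 || !is.finite(rotation) ||
      rotation %% 90 != 0)
    stop("rotation must be a finite multiple of 90 degrees")
  rotation
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf(
    "Four-quadrant arena: %.2f x %.2f cm, center (%.3f, %.3f), rotation %d deg, %.1f px/cm\n",
    x$side_length, x$side_length, x$center[1], x$center[2],
    as.integer(x$rotation), x$px_per_cm))
  invisible(x)
}

#' Rotate the arena by a multiple of 90 degrees
#'
#' Represents transferring flies to an arena rotated counterclockwise, the
#' manipulation used to dissociate residual odor from deposited pheromone in
#' the post-stimulus protocol. The quadrant label of any fixed physical point
#' is remapped consistently: one 90 degree CCW rotation maps the sector that
#' was labelled Q1 to label Q2, Q2 to Q3, Q3 to Q4 and Q4 to Q1.
#'
#' @param arena An `arena_geometry`.
#' @param degrees Rotation increment in degrees (multiple of 90, CCW).
#' @return A new `arena_geometry` with rotation incremented modulo 360.
#' @export
rotate_arena <- function(arena, degrees) {
  stopifnot(inherits(arena, "arena_geometry"))
  degrees <- check_rotation(degrees)
  arena$rotation <- (arena$rotation + degrees) %% 360
  arena
}

#' Assign positions to quadrants
#'
#' Labels each point by the sign pattern of its offset from the arena center
#' after undoing the arena rotation. Points on an axis (either coordinate
#' offset smaller than `tol` in absolute value) or outside the walkable mask
#' get `"NONE"` and are excluded from all quadrant counts downstream.
#'
#' @param x,y Point coordinates in cm (vectors of equal length).
#' @param arena An `arena_geometry`.
#' @param tol Axis tolerance in cm (default 1e-12).
#' @return Character vector in `c("Q1","Q2","Q3","Q4","NONE")`.
#' @export
assign_quadrant <- function(x, y, arena, tol = 1e-12) {
  stopifnot(inherits(arena, "arena_geometry"))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0) return(character(0))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("positions must be finite")
  dx <- x - arena$center[1]
  dy <- y - arena$center[2]
  # express the offset in the rotated arena's labeling frame: a fixed
  # physical point labelled Q1 at rotation 0 is labelled Q2 at rotation 90
  th <- arena$rotation * pi / 180
  rx <- dx * cos(th) - dy * sin(th)
  ry <- dx * sin(th) + dy * cos(th)
  lab <- rep("NONE", length(x))
  inside <- pracma::inpolygon(x, y, arena$mask_polygon[, 1], arena$mask_polygon[, 2])
  ok <- inside & abs(rx) >= tol & abs(ry) >= tol
  pos_x <- rx > 0
  pos_y <- ry > 0
  lab[ok & pos_x & pos_y] <- "Q1"
  lab[ok & !pos_x & pos_y] <- "Q2"
  lab[ok & !pos_x & !pos_y] <- "Q3"
  lab[ok & pos_x & !pos_y] <- "Q4"
  lab
}

#' Convert between physical (cm) and image (px) coordinates
#'
#' Physical space: origin lower-left, y up. Image space: origin at the top-left
#' pixel center, column x rightward, row y downward. The image is
#' `round(side_length * px_per_cm)` pixels on a side.
#'
#' @param x,y Coordinates (cm for `cm_to_px`, px for `px_to_cm`).
#' @param arena An `arena_geometry`.
#' @return A list with components `x` and `y` in the target space.
#' @export
cm_to_px <- function(x, y, arena) {
  stopifnot(inherits(arena, "arena_geometry"))
  npx <- image_size_px(arena)
  list(x = x * arena$px_per_cm + 0.5,
       y = npx - y * arena$px_per_cm + 0.5)
}

#' @rdname cm_to_px
#' @export
px_to_cm <- function(x, y, arena) {
  stopifnot(inherits(arena, "arena_geometry"))
  npx <- image_size_px(arena)
  list(x = (x - 0.5) / arena$px_per_cm,
       y = (npx - y + 0.5) / arena$px_per_cm)
}

#' @rdname cm_to_px
#' @export
image_size_px <- function(arena) {
  as.integer(round(arena$side_length * arena$px_per_cm))
}

#' Serialize / deserialize an arena as JSON
#'
#' Schema: `{side_length_cm, px_per_cm, rotation_deg, mask_polygon: [[x,y],...]}`.
#'
#' @param arena An `arena_geometry`.
#' @param path File path.
#' @return `write_arena_json` returns `path` invisibly; `read_arena_json`
#'   returns an `arena_geometry`.
#' @export
write_arena_json <- function(arena, path) {
  stopifnot(inherits(arena, "arena_geometry"))
  obj <- list(
    side_length_cm = arena$side_length,
    px_per_cm = arena$px_per_cm,
    rotation_deg = arena$rotation,
    mask_polygon = unname(apply(arena$mask_polygon, 1, function(r) r, simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_arena_json
#' @export
read_arena_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_arena(side_length = obj$side_length_cm,
              px_per_cm = obj$px_per_cm,
              rotation = obj$rotation_deg,
              mask_polygon = obj$mask_polygon)
}

#' Quadrant polygon (for sampling and plotting)
#'
#' Returns the square sector of a quadrant label at the arena's current
#' rotation, as a 4 x 2 vertex matrix in cm (intersection with the mask is
#' handled by rejection where needed).
#' @param arena An `arena_geometry`.
#' @param quadrant One of "Q1".."Q4".
#' @return 4 x 2 matrix of vertices (cm).
#' @export
quadrant_polygon <- function(arena, quadrant) {
  stopifnot(inherits(arena, "arena_geometry"))
  quadrant <- match.arg(quadrant, c("Q1", "Q2", "Q3", "Q4"))
  h <- arena$side_length / 2
  base <- switch(quadrant,
    Q1 = rbind(c(0, 0), c(h, 0), c(h, h), c(0, h)),
    Q2 = rbind(c(-h, 0), c(0, 0), c(0, h), c(-h, h)),
    Q3 = rbind(c(-h, -h), c(0, -h), c(0, 0), c(-h, 0)),
    Q4 = rbind(c(0, -h), c(h, -h), c(h, 0), c(0, 0)))
  # the sector carrying label `quadrant` at rotation theta is the base sector
  # rotated by -theta (labels advance cyclically as the arena rotates CCW)
  th <- -arena$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(base %*% t(R), 2, arena$center, "+")
}
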