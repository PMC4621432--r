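#' Deposited-pheromone field with first-order evaporation
#'
#' A gridded scalar field of deposited pheromone mass over the arena floor.
#' Males deposit while a food-odor stimulus is on and they are inside the odor
#' quadrant; every cell decays as first-order evaporation
#' `m <- m * exp(-k * temperature_factor * dt)`. `temperature_factor > 1`
#' models elevated temperature (the deposit is heat-sensitive: at high
#' temperature it evaporates away and post-stimulus aggregation is abolished).
#'
#' @param arena An `arena_geometry` the grid covers.
#' @param res Grid resolution in cells per cm (default 2).
#' @param k Evaporation rate constant, 1/s (default 0.002, giving a
#'   mass half-life of about 6 min so aggregation decays over ~25 min).
#' @param d Deposition rate, mass units per male per second (default 1).
#' @param temperature_factor Multiplier on `k` (default 1; use >> 1 for the
#'   high-temperature condition).
#' @return An object of class `pheromone_field` with elements `grid`
#'   (ny x nx matrix, row 1 = bottom of the arena), `res`, `k`, `d`,
#'   `temperature_factor`, `xc`/`yc` (cell-center coordinates, cm) and
#'   `odor_mask` (logical matrix marking deposition-eligible cells; set with
#'   [set_field_odor_quadrant()]).
#' @export
pheromone_field <- function(arena, res = 2, k = 0.002, d = 1,
                            temperature_factor = 1) {
  stopifnot(inherits(arena, "arena_geometry"), res > 0, k >= 0, d >= 0,
            temperature_factor > 0)
  n <- as.integer(ceiling(arena$side_length * res))
  h <- arena$side_length / n
  centers <- (seq_len(n) - 0.5) * h
  structure(list(
    grid = matrix(0, n, n),
    res = res, cell_cm = h,
    k = k, d = d, temperature_factor = temperature_factor,
    xc = centers, yc = centers,
    odor_mask = matrix(FALSE, n, n),
    side_length = arena$side_length
  ), class = "pheromone_field")
}

#' Mark the deposition-eligible cells of a field
#'
#' Sets the field's odor mask to the cells whose centers fall in the given
#' quadrant of the arena at its current rotation.
#' @param field A `pheromone_field`.
#' @param arena The matching `arena_geometry`.
#' @param quadrant "Q1".."Q4", or NULL to clear the mask.
#' @return The updated field.
#' @export
set_field_odor_quadrant <- function(field, arena, quadrant) {
  stopifnot(inherits(field, "pheromone_field"))
  n <- nrow(field$grid)
  if (is.null(quadrant)) {
    field$odor_mask <- matrix(FALSE, n, n)
    return(field)
  }
  xy <- expand.grid(x = field$xc, y = field$yc)
  lab <- assign_quadrant(xy$x, xy$y, arena)
  # expand.grid varies x fastest; grid is [y, x]
  field$odor_mask <- matrix(lab == quadrant, n, n, byrow = TRUE)
  field
}

#' Advance the pheromone field by one time step
#'
#' Each cell evolves as
#' `m <- m * exp(-k * temperature_factor * dt) + d * dt * males_in_cell`,
#' where deposition applies only while `odor_on` and only in cells of the
#' odor quadrant (the field's odor mask). Only male agents deposit.
#'
#' @param field A `pheromone_field`.
#' @param male_occupancy Matrix of male counts per cell (same dim as grid),
#'   e.g. from [occupancy_matrix()].
#' @param odor_on Logical: is a food-odor stimulus phase active?
#' @param dt Time step in seconds (> 0).
#' @return The updated field.
#' @export
step_pheromone <- function(field, male_occupancy, odor_on, dt) {
  stopifnot(inherits(field, "pheromone_field"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be > 0")
  if (!all(dim(male_occupancy) == dim(field$grid)))
    stop("male_occupancy does not match the field grid")
  field$grid <- field$grid * exp(-field$k * field$temperature_factor * dt)
  if (isTRUE(odor_on))
    field$grid <- field$grid + field$d * dt * male_occupancy * field$odor_mask
  field
}

#' Bin agent positions onto the field grid
#'
#' @param field A `pheromone_field`.
#' @param x,y Positions in cm.
#' @return Integer matrix of counts per cell (ny x nx, row 1 = bottom).
#' @export
occupancy_matrix <- function(field, x, y) {
  n <- nrow(field$grid)
  ix <- pmin(pmax(ceiling(x / field$cell_cm), 1L), n)
  iy <- pmin(pmax(ceiling(y / field$cell_cm), 1L), n)
  m <- matrix(0L, n, n)
  if (length(ix)) {
    tab <- table(factor(iy, levels = seq_len(n)), factor(ix, levels = seq_len(n)))
    m <- matrix(as.integer(tab), n, n)
  }
  m
}

#' Sample the field and its gradient at agent positions
#'
#' Bilinear interpolation of the mass at (x, y) and a central-difference
#' gradient with step one cell width. Positions are clamped to the grid.
#'
#' @param field A `pheromone_field`.
#' @param x,y Positions in cm.
#' @return List with `value`, `gx`, `gy` (mass and gradient components).
#' @export
field_at <- function(field, x, y) {
  n <- length(field$xc)
  h <- field$cell_cm
  lo <- field$xc[1]; hi <- field$xc[n]
  g <- field$grid
  samp <- function(px, py) {
    px <- pmin(pmax(px, lo), hi)
    py <- pmin(pmax(py, lo), hi)
    fx <- (px - lo) / h; fy <- (py - lo) / h
    i0 <- pmin(floor(fy), n - 2) + 1L   # row index (y)
    j0 <- pmin(floor(fx), n - 2) + 1L   # col index (x)
    tx <- fx - (j0 - 1L); ty <- fy - (i0 - 1L)
    g[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
      g[cbind(i0, j0 + 1L)] * tx * (1 - ty) +
      g[cbind(i0 + 1L, j0)] * (1 - tx) * ty +
      g[cbind(i0 + 1L, j0 + 1L)] * tx * ty
  }
  list(value = samp(x, y),
       gx = (samp(x + h, y) - samp(x - h, y)) / (2 * h),
       gy = (samp(x, y + h) - samp(x, y - h)) / (2 * h))
}

#' Rotate the field grid with the arena
#'
#' The deposit sits on the arena floor, so an arena rotation carries the field
#' with it. Rotates the grid (and odor mask) counterclockwise by a multiple of
#' 90 degrees.
#' @param field A `pheromone_field`.
#' @param degrees Multiple of 90 (CCW).
#' @return The rotated field.
#' @export
rotate_field <- function(field, degrees) {
  stopifnot(inherits(field, "pheromone_field"))
  degrees <- check_rotation(degrees) %% 360
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  for (i in seq_len(degrees / 90)) {
    field$grid <- rot90(field$grid)
    field$odor_mask <- rot90(field$odor_mask)
  }
  field
}

#' Total deposited mass
#' @param field A `pheromone_field`.
#' @return Sum of all cell masses.
#' @export
total_mass <- function(field) sum(field$grid)
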