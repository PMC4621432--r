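#' Attraction Index over a time window
#'
#' The Attraction Index is AI = (O - C_avg) / (O + C_avg), where O is the
#' number of tracked positional samples in the odor quadrant over the window
#' and C_avg is the mean number of samples per non-odor (control) quadrant.
#' AI = 1 means every sample was in the odor quadrant; AI = 0 means samples
#' were spread equally over the four quadrants; AI = -1 means none were in
#' the odor quadrant. Samples labelled NONE (on an axis or outside the mask)
#' are excluded from both O and C_avg. All flies' samples are pooled; set
#' `per_fly = TRUE` to average per-track AIs instead.
#'
#' @param ts A `trackset` with an arena.
#' @param odor_quadrant "Q1".."Q4".
#' @param window Numeric length-2 `(t_start, t_end)` in seconds; samples with
#'   `t_start <= t_s < t_end` are used. Default 0-300 s (the 5-min testing
#'   period).
#' @param per_fly Average per-track AIs instead of pooling samples.
#' @return An `attraction_result`: list with `O`, `C_avg`, `AI`, `window`,
#'   `n_samples_total` and `per_quadrant` counts.
#' @export
attraction_index <- function(ts, odor_quadrant, window = c(0, 300),
                             per_fly = FALSE) {
  stopifnot(inherits(ts, "trackset"))
  odor_quadrant <- match.arg(odor_quadrant, c("Q1", "Q2", "Q3", "Q4"))
  if (is.null(ts$arena)) stop("trackset has no arena")
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be (t_start, t_end) with t_end > t_start")
  tr <- ts$tracks[ts$tracks$t_s >= window[1] & ts$tracks$t_s < window[2], ,
                  drop = FALSE]
  lab <- assign_quadrant(tr$x_cm, tr$y_cm, ts$arena)
  qs <- c("Q1", "Q2", "Q3", "Q4")
  counts <- vapply(qs, function(q) sum(lab == q), numeric(1))
  if (per_fly) {
    ids <- unique(tr$track_id)
    ai <- vapply(ids, function(id) {
      l <- lab[tr$track_id == id]
      o <- sum(l == odor_quadrant)
      ca <- sum(l %in% setdiff(qs, odor_quadrant)) / 3
      if (o + ca == 0) NA_real_ else (o - ca) / (o + ca)
    }, numeric(1))
    AI <- mean(ai, na.rm = TRUE)
    O <- counts[[odor_quadrant]]
    C_avg <- sum(counts[setdiff(qs, odor_quadrant)]) / 3
  } else {
    O <- counts[[odor_quadrant]]
    C_avg <- sum(counts[setdiff(qs, odor_quadrant)]) / 3
    if (O + C_avg == 0)
      stop("undefined statistic: no quadrant-labelled samples in the window")
    AI <- (O - C_avg) / (O + C_avg)
  }
  structure(list(O = O, C_avg = C_avg, AI = AI, window = window,
                 n_samples_total = nrow(tr), per_quadrant = counts,
                 odor_quadrant = odor_quadrant),
            class = "attraction_result")
}

#' @export
print.attraction_result <- function(x, ...) {
  cat(sprintf("AI = %.4f  (O = %d, C_avg = %.2f, window %g-%g s, odor %s)\n",
              x$AI, x$O, x$C_avg, x$window[1], x$window[2], x$odor_quadrant))
  invisible(x)
}

#' Sliding-window Attraction Index time course
#'
#' @param ts A `trackset`.
#' @param odor_quadrant "Q1".."Q4".
#' @param window_len Window length, s (default 300: 5-min windows).
#' @param stride Window start spacing, s (default `window_len`:
#'   non-overlapping windows).
#' @param per_fly See [attraction_index()].
#' @return data.frame with `t_start, t_end, O, C_avg, AI, n_samples,
#'   undefined` (TRUE where the window held no quadrant-labelled samples;
#'   flagged, not dropped).
#' @export
ai_timecourse <- function(ts, odor_quadrant, window_len = 300,
                          stride = window_len, per_fly = FALSE) {
  stopifnot(inherits(ts, "trackset"), window_len > 0, stride > 0)
  t_max <- max(ts$tracks$t_s) + 1 / ts$frame_rate
  if (window_len > t_max) stop("window_len exceeds the recording duration")
  starts <- seq(0, t_max - window_len, by = stride)
  rows <- lapply(starts, function(t0) {
    res <- tryCatch(
      attraction_index(ts, odor_quadrant, c(t0, t0 + window_len), per_fly),
      error = function(e) NULL)
    if (is.null(res))
      data.frame(t_start = t0, t_end = t0 + window_len, O = NA_real_,
                 C_avg = NA_real_, AI = NA_real_, n_samples = 0L,
                 undefined = TRUE)
    else
      data.frame(t_start = t0, t_end = t0 + window_len, O = res$O,
                 C_avg = res$C_avg, AI = res$AI,
                 n_samples = res$n_samples_total, undefined = FALSE)
  })
  do.call(rbind, rows)
}

#' Stimulus vs post-stimulus attraction under arena rotation
#'
#' Computes the stimulus-phase AI against the odor quadrant and the
#' post-stimulus AI against the rotated position of that quadrant: after a
#' counterclockwise arena rotation the deposited material moves with the
#' arena floor, so the original odor quadrant's label is remapped (one 90
#' degree CCW step maps Q1 to Q2, Q2 to Q3, Q3 to Q4, Q4 to Q1). This
#' dissociates residual odor in the room frame from deposited-pheromone
#' attraction in the arena frame.
#'
#' @param pre_ts `trackset` of the stimulus phase (arena at rotation r).
#' @param post_ts `trackset` of the post-stimulus phase (arena at rotation
#'   r + `rotation_applied`).
#' @param odor_quadrant_at_stimulus "Q1".."Q4" in the stimulus-phase frame.
#' @param rotation_applied Degrees (multiple of 90, CCW) the arena was
#'   rotated between phases.
#' @param window_pre,window_post Analysis windows (s) within each trackset.
#' @return list with `stimulus` and `post` `attraction_result`s and
#'   `post_quadrant`, the remapped label.
#' @export
post_stimulus_analysis <- function(pre_ts, post_ts, odor_quadrant_at_stimulus,
                                   rotation_applied = 90,
                                   window_pre = c(0, 300),
                                   window_post = c(0, 300)) {
  rotation_applied <- check_rotation(rotation_applied)
  q <- match.arg(odor_quadrant_at_stimulus, c("Q1", "Q2", "Q3", "Q4"))
  post_q <- remap_quadrant(q, rotation_applied)
  list(stimulus = attraction_index(pre_ts, q, window_pre),
       post = attraction_index(post_ts, post_q, window_post),
       post_quadrant = post_q)
}

#' Remap a quadrant label under arena rotation
#'
#' @param quadrant "Q1".."Q4".
#' @param degrees Multiple of 90 (CCW).
#' @return The label of the sector the physical quadrant occupies after the
#'   rotation.
#' @export
remap_quadrant <- function(quadrant, degrees) {
  degrees <- check_rotation(degrees) %% 360
  qs <- c("Q1", "Q2", "Q3", "Q4")
  i <- match(match.arg(quadrant, qs), qs)
  qs[((i - 1 + degrees / 90) %% 4) + 1]
}

#' Egg counts per quadrant and the odor-quadrant preference
#'
#' Assigns egg positions to quadrants and summarizes them against a
#' designated odor quadrant using the oviposition preference formula
#' (E_o - E_avg) / (E_o + E_avg) with E_avg the mean count per control
#' quadrant.
#'
#' @param eggs data.frame with `x_cm, y_cm` (e.g. from [simulate_eggs()]).
#' @param arena An `arena_geometry`.
#' @param odor_quadrant "Q1".."Q4".
#' @return An `oviposition_result`: list with `per_region_counts`, `E_o`,
#'   `E_avg`, `OPI`, `fold_enrichment`, `total_eggs`.
#' @export
egg_quadrant_counts <- function(eggs, arena, odor_quadrant = "Q1") {
  stopifnot(inherits(arena, "arena_geometry"))
  odor_quadrant <- match.arg(odor_quadrant, c("Q1", "Q2", "Q3", "Q4"))
  if (nrow(eggs) && (any(!is.finite(eggs$x_cm)) || any(!is.finite(eggs$y_cm))))
    stop("egg coordinates must be finite")
  lab <- assign_quadrant(eggs$x_cm, eggs$y_cm, arena)
  qs <- c("Q1", "Q2", "Q3", "Q4")
  counts <- vapply(qs, function(q) sum(lab == q), numeric(1))
  E_o <- counts[[odor_quadrant]]
  E_avg <- sum(counts[setdiff(qs, odor_quadrant)]) / 3
  opi <- if (E_o + E_avg > 0) (E_o - E_avg) / (E_o + E_avg) else NA_real_
  structure(list(per_region_counts = counts, E_o = E_o, E_avg = E_avg,
                 OPI = opi,
                 fold_enrichment = if (E_avg > 0) E_o / E_avg else NA_real_,
                 total_eggs = nrow(eggs), odor_region = odor_quadrant),
            class = "oviposition_result")
}

#' Oviposition Preference Index for the 3-well assay
#'
#' OPI = (E_o - E_avg) / (E_o + E_avg), where E_o is the egg count in the
#' odor well and E_avg the mean count of the two non-odor wells. OPI = 1:
#' all eggs in the odor well; OPI = 0: eggs equally distributed over the 3
#' wells; OPI = -1: all eggs in the non-odor wells.
#'
#' @param per_well_counts Nonnegative integer vector of length 3.
#' @param odor_well Index (1-3) of the odor well.
#' @return An `oviposition_result`.
#' @export
oviposition_preference_index <- function(per_well_counts, odor_well = 1L) {
  if (length(per_well_counts) != 3 || any(per_well_counts < 0))
    stop("per_well_counts must be 3 nonnegative counts")
  stopifnot(odor_well %in% 1:3)
  per_well_counts <- unname(per_well_counts)
  E_o <- per_well_counts[odor_well]
  E_avg <- mean(per_well_counts[-odor_well])
  if (E_o + E_avg == 0)
    stop("undefined statistic: no eggs in any well")
  structure(list(per_region_counts = per_well_counts, E_o = E_o,
                 E_avg = E_avg, OPI = (E_o - E_avg) / (E_o + E_avg),
                 fold_enrichment = if (E_avg > 0) E_o / E_avg else NA_real_,
                 total_eggs = sum(per_well_counts),
                 odor_region = paste0("W", odor_well)),
            class = "oviposition_result")
}

#' @export
print.oviposition_result <- function(x, ...) {
  cat(sprintf("OPI = %.4f  (E_o = %g, E_avg = %.2f, total %d eggs, odor %s)\n",
              x$OPI, x$E_o, x$E_avg, x$total_eggs, x$odor_region))
  invisible(x)
}

#' 2-D occupancy histogram of tracked positions
#'
#' Bins in-mask samples on a square grid over the arena. The sum of counts
#' equals the number of in-mask samples binned.
#'
#' @param ts A `trackset` with an arena.
#' @param bin_size_cm Bin edge length, cm (default 0.5).
#' @return An `occupancy_map`: list with `counts` (ny x nx, row 1 = bottom),
#'   `xedges`, `yedges`, `n_binned`.
#' @export
occupancy_heatmap <- function(ts, bin_size_cm = 0.5) {
  stopifnot(inherits(ts, "trackset"), bin_size_cm > 0)
  arena <- ts$arena
  if (is.null(arena)) stop("trackset has no arena")
  s <- arena$side_length
  edges <- seq(0, s + bin_size_cm * 0.999, by = bin_size_cm)
  tr <- ts$tracks
  inside <- pracma::inpolygon(tr$x_cm, tr$y_cm,
                              arena$mask_polygon[, 1], arena$mask_polygon[, 2])
  x <- tr$x_cm[inside]; y <- tr$y_cm[inside]
  nb <- length(edges) - 1
  ix <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), nb)
  iy <- pmin(pmax(findInterval(y, edges, rightmost.closed = TRUE), 1L), nb)
  counts <- matrix(0L, nb, nb)
  if (length(ix)) {
    tab <- table(factor(iy, levels = seq_len(nb)),
                 factor(ix, levels = seq_len(nb)))
    counts <- matrix(as.integer(tab), nb, nb)
  }
  structure(list(counts = counts, xedges = edges, yedges = edges,
                 n_binned = length(x)),
            class = "occupancy_map")
}

#' @export
plot.occupancy_map <- function(x, ...) {
  graphics::image(x = x$xedges, y = x$yedges, z = t(x$counts),
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "x (cm)", ylab = "y (cm)", useRaster = TRUE, ...)
  invisible(x)
}

#' Compare trial-level statistics between groups
#'
#' Two groups: two-sample t test (Student's equal-variance by default, the
#' paper-style "t-test"; `welch = TRUE` selects Welch). More than two groups:
#' one-way ANOVA. The sampling unit is the trial (one AI or OPI per replicate
#' arena run). P values are reported raw, with no multiple-testing
#' correction.
#'
#' @param values_by_group Named list of numeric vectors, each length >= 2.
#' @param welch Use Welch's unequal-variance t test for two groups.
#' @return list with `statistic`, `p_value`, `test_name`, `df`.
#' @export
compare_groups <- function(values_by_group, welch = FALSE) {
  if (!is.list(values_by_group) || length(values_by_group) < 2)
    stop("need at least two groups")
  n <- vapply(values_by_group, length, integer(1))
  if (any(n < 2)) stop("each group needs at least two values")
  if (all(vapply(values_by_group, stats::var, numeric(1)) == 0) &&
      length(unique(unlist(lapply(values_by_group, unique)))) == 1 &&
      length(values_by_group) == 2) {
    # identical constant groups: t = 0, p = 1 (t.test errors on zero variance)
    return(list(statistic = 0, p_value = 1,
                test_name = if (welch) "Welch t-test" else "Student t-test",
                df = sum(n) - 2))
  }
  if (length(values_by_group) == 2) {
    ht <- stats::t.test(values_by_group[[1]], values_by_group[[2]],
                        var.equal = !welch)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test_name = if (welch) "Welch t-test" else "Student t-test",
         df = unname(ht$parameter))
  } else {
    g <- factor(rep(seq_along(values_by_group), n))
    v <- unlist(values_by_group)
    fit <- stats::aov(v ~ g)
    sm <- summary(fit)[[1]]
    list(statistic = sm$`F value`[1], p_value = sm$`Pr(>F)`[1],
         test_name = "one-way ANOVA", df = sm$Df)
  }
}
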