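#' Egg-laying simulation configuration
#'
#' Region weights are the ground truth the downstream OPI / quadrant
#' statistics must recover: the total egg count is Poisson(`n_eggs_mean`),
#' each egg falls in region i with probability `region_weights[i] /
#' sum(region_weights)`, uniformly within the region.
#'
#' @param region_weights Nonnegative weights, one per quadrant (length 4) or
#'   per well (length 3); at least one must be positive.
#' @param n_eggs_mean Expected total egg count.
#' @param seed Integer seed.
#' @return An `egg_config`.
#' @export
egg_config <- function(region_weights, n_eggs_mean = 100, seed = 1L) {
  if (!is.numeric(region_weights) || any(region_weights < 0) ||
      sum(region_weights) <= 0)
    stop("region_weights must be nonnegative with at least one positive entry")
  stopifnot(n_eggs_mean >= 0)
  structure(list(region_weights = region_weights,
                 n_eggs_mean = n_eggs_mean, seed = as.integer(seed)),
            class = "egg_config")
}

#' Default 3-well egg-laying plate
#'
#' Three agarose wells along a 34 x 85 mm plate; well 1 is conventionally the
#' odor (pheromone gel) well, wells 2-3 the plain-agarose controls.
#' @return data.frame with `well, x_cm, y_cm, radius_cm`.
#' @export
default_wells <- function() {
  data.frame(well = c("W1", "W2", "W3"),
             x_cm = c(1.7, 1.7, 1.7),
             y_cm = c(1.7, 4.25, 6.8),
             radius_cm = 0.8,
             stringsAsFactors = FALSE)
}

#' Simulate egg positions
#'
#' Draws a Poisson total egg count, assigns eggs to regions with probability
#' proportional to the configured weights, and places each egg uniformly
#' within its region: within a quadrant sector of the arena mask (4-quadrant
#' mode, `arena` given) or within a circular well (3-well mode, `wells`
#' given).
#'
#' @param cfg An `egg_config`.
#' @param arena An `arena_geometry` (4-quadrant mode; weights ordered
#'   Q1..Q4) or NULL.
#' @param wells A wells data.frame as [default_wells()] (3-well mode) or NULL.
#' @return data.frame with `egg_id, x_cm, y_cm, region`.
#' @export
simulate_eggs <- function(cfg, arena = NULL, wells = NULL) {
  stopifnot(inherits(cfg, "egg_config"))
  if (is.null(arena) == is.null(wells))
    stop("give exactly one of arena (4-quadrant mode) or wells (3-well mode)")
  set.seed(cfg$seed)
  n_regions <- if (!is.null(arena)) 4L else nrow(wells)
  if (length(cfg$region_weights) != n_regions)
    stop("region_weights length must match the number of regions (", n_regions, ")")
  n <- stats::rpois(1, cfg$n_eggs_mean)
  labels <- if (!is.null(arena)) c("Q1", "Q2", "Q3", "Q4") else wells$well
  if (n == 0)
    return(data.frame(egg_id = integer(0), x_cm = numeric(0),
                      y_cm = numeric(0), region = character(0),
                      stringsAsFactors = FALSE))
  region <- sample(labels, n, replace = TRUE,
                   prob = cfg$region_weights / sum(cfg$region_weights))
  x <- numeric(n); y <- numeric(n)
  if (!is.null(arena)) {
    for (q in labels) {
      idx <- which(region == q)
      if (!length(idx)) next
      qp <- quadrant_polygon(arena, q)
      xr <- range(qp[, 1]); yr <- range(qp[, 2])
      got <- 0L
      while (got < length(idx)) {
        m <- (length(idx) - got) * 2 + 4
        cx <- stats::runif(m, xr[1], xr[2])
        cy <- stats::runif(m, yr[1], yr[2])
        ok <- assign_quadrant(cx, cy, arena) == q
        take <- utils::head(which(ok), length(idx) - got)
        x[idx[got + seq_along(take)]] <- cx[take]
        y[idx[got + seq_along(take)]] <- cy[take]
        got <- got + length(take)
      }
    }
  } else {
    for (i in seq_len(n_regions)) {
      idx <- which(region == wells$well[i])
      if (!length(idx)) next
      r <- wells$radius_cm[i] * sqrt(stats::runif(length(idx)))
      th <- stats::runif(length(idx), 0, 2 * pi)
      x[idx] <- wells$x_cm[i] + r * cos(th)
      y[idx] <- wells$y_cm[i] + r * sin(th)
    }
  }
  data.frame(egg_id = seq_len(n), x_cm = x, y_cm = y, region = region,
             stringsAsFactors = FALSE)
}

#' Spike-train simulation configuration
#'
#' Inhomogeneous Poisson model of a single-sensillum recording trial: rate
#' `baseline_rate` everywhere except the evoked window
#' `[stim_onset + latency, stim_onset + latency + stim_duration)`, where the
#' rate is `evoked_rate`. The default latency of 0.5 s mirrors the analysis
#' window offset of the response quantification.
#'
#' @param baseline_rate,evoked_rate Spikes/s, >= 0.
#' @param stim_onset Stimulus onset, s.
#' @param stim_duration Stimulus (and evoked-window) length, s (default 1).
#' @param latency Response latency after onset, s (default 0.5).
#' @param trial_duration Trial length, s.
#' @param seed Integer seed.
#' @return A `spike_config`.
#' @export
spike_config <- function(baseline_rate = 10, evoked_rate = 40,
                         stim_onset = 2, stim_duration = 1, latency = 0.5,
                         trial_duration = 5, seed = 1L) {
  stopifnot(baseline_rate >= 0, evoked_rate >= 0, stim_onset >= 0,
            stim_duration > 0, latency >= 0,
            stim_onset + latency + stim_duration <= trial_duration)
  structure(list(baseline_rate = baseline_rate, evoked_rate = evoked_rate,
                 stim_onset = stim_onset, stim_duration = stim_duration,
                 latency = latency, trial_duration = trial_duration,
                 seed = as.integer(seed)),
            class = "spike_config")
}

#' Simulate one spike train
#'
#' @param cfg A `spike_config`.
#' @param label Trial label, one of "odor", "solvent", "none".
#' @return A `spike_train` (see [spike_train()]).
#' @export
simulate_spike_train <- function(cfg, label = "odor") {
  stopifnot(inherits(cfg, "spike_config"))
  set.seed(cfg$seed)
  a <- cfg$stim_onset + cfg$latency
  b <- a + cfg$stim_duration
  segs <- rbind(c(0, a, cfg$baseline_rate),
                c(a, b, cfg$evoked_rate),
                c(b, cfg$trial_duration, cfg$baseline_rate))
  times <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    len <- segs[i, 2] - segs[i, 1]
    if (len <= 0 || segs[i, 3] <= 0) next
    k <- stats::rpois(1, segs[i, 3] * len)
    if (k > 0) times <- c(times, stats::runif(k, segs[i, 1], segs[i, 2]))
  }
  spike_train(sort(times), stim_onset = cfg$stim_onset,
              trial_duration = cfg$trial_duration, label = label)
}

#' Simulate an EAG-like voltage trace
#'
#' A baseline-zero trace with a smooth negative deflection after `onset`
#' (alpha-function time course, peak magnitude `amplitude`) plus Gaussian
#' noise.
#'
#' @param amplitude Peak deflection magnitude, mV (>= 0).
#' @param onset Deflection onset, s.
#' @param noise_sd Gaussian noise SD, mV.
#' @param fs Sampling rate, Hz.
#' @param duration Trace length, s.
#' @param tau Alpha-function time constant, s (peak occurs `tau` after onset).
#' @param seed Integer seed.
#' @return data.frame with `t_s, mV`; attributes `fs` and `onset`.
#' @export
simulate_eag_trace <- function(amplitude, onset = 1, noise_sd = 0, fs = 1000,
                               duration = 5, tau = 0.3, seed = 1L) {
  stopifnot(fs > 0, amplitude >= 0, noise_sd >= 0, duration > onset)
  set.seed(seed)
  t <- seq(0, duration, by = 1 / fs)
  s <- pmax(t - onset, 0)
  v <- -amplitude * (s / tau) * exp(1 - s / tau)
  v <- v + stats::rnorm(length(t), sd = noise_sd)
  out <- data.frame(t_s = t, mV = v)
  attr(out, "fs") <- fs
  attr(out, "onset") <- onset
  out
}
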