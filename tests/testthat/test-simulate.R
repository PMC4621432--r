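test_that("simulation sampling contract and determinism hold", {
  a <- default_arena()
  cfg <- sim_config(n_flies = 4, frame_rate = 10,
                    phases = list(list(name = "pre", duration = 7.3,
                                       odor_quadrant = NULL,
                                       odor_is_food = FALSE)),
                    seed = 21)
  ts <- simulate_flies(cfg, a)
  n_frames <- round(10 * 7.3)
  expect_equal(unname(table(ts$tracks$track_id)),
               rep(n_frames, 4), ignore_attr = TRUE)
  expect_equal(ts$tracks$t_s, ts$tracks$frame / 10)
  # positions confined to the mask
  inside <- pracma::inpolygon(ts$tracks$x_cm, ts$tracks$y_cm,
                              a$mask_polygon[, 1], a$mask_polygon[, 2])
  expect_true(all(inside))
  # bitwise determinism under the same config and seed
  ts2 <- simulate_flies(cfg, a)
  expect_identical(ts$tracks, ts2$tracks)
  expect_identical(ts$field$grid, ts2$field$grid)
})

test_that("unbiased walks give AI near zero; stronger bias gives larger AI", {
  a <- default_arena()
  mk <- function(beta, seed) {
    cfg <- sim_config(n_flies = 10, frame_rate = 5,
                      phases = list(list(name = "stimulus", duration = 60,
                                         odor_quadrant = "Q1",
                                         odor_is_food = FALSE)),
                      bias_strength = beta, seed = seed)
    attraction_index(simulate_flies(cfg, a), "Q1", c(0, 60))$AI
  }
  seeds <- 1:20
  ai0 <- vapply(seeds, function(s) mk(0, s), numeric(1))
  expect_lt(abs(mean(ai0)), 3 * sd(ai0) / sqrt(length(ai0)))
  ai1 <- vapply(seeds, function(s) mk(1, s), numeric(1))
  ai5 <- vapply(seeds, function(s) mk(5, s), numeric(1))
  expect_gt(mean(ai5), mean(ai1))
  expect_gt(mean(ai1), mean(ai0))
})

test_that("egg simulation honors degenerate, uniform and biased weights", {
  # all weight on well 1: every egg there, OPI = 1
  e1 <- simulate_eggs(egg_config(c(1, 0, 0), 60, seed = 2),
                      wells = default_wells())
  expect_true(all(e1$region == "W1"))
  counts <- vapply(c("W1", "W2", "W3"),
                   function(w) sum(e1$region == w), numeric(1))
  expect_equal(oviposition_preference_index(counts, 1)$OPI, 1)
  # uniform quadrant weights: per-quadrant counts within multinomial 99% CI
  a <- default_arena()
  e2 <- simulate_eggs(egg_config(c(1, 1, 1, 1), 400, seed = 3), arena = a)
  n <- nrow(e2)
  tab <- table(factor(e2$region, levels = c("Q1", "Q2", "Q3", "Q4")))
  ci <- qbinom(c(0.005, 0.995), n, 0.25)
  expect_true(all(tab >= ci[1] & tab <= ci[2]))
  # positions fall in their assigned quadrant
  expect_equal(assign_quadrant(e2$x_cm, e2$y_cm, a), as.character(e2$region))
  # 5:1:1:1 weights: odor fraction near 5/8 within the binomial 99% CI
  e3 <- simulate_eggs(egg_config(c(5, 1, 1, 1), 800, seed = 4), arena = a)
  n3 <- nrow(e3)
  k <- sum(e3$region == "Q1")
  ci3 <- qbinom(c(0.005, 0.995), n3, 5 / 8)
  expect_true(k >= ci3[1] && k <= ci3[2])
  # all-zero weights rejected
  expect_error(egg_config(c(0, 0, 0), 10), "positive")
})

test_that("spike-train generator matches Poisson expectations", {
  # zero rates: empty train
  t0 <- simulate_spike_train(spike_config(0, 0, stim_onset = 2,
                                          trial_duration = 5, seed = 1))
  expect_length(t0$spike_times, 0)
  # r1 = r0: mean delta over 1000 trains within 3 SE of 0
  d_eq <- vapply(1:1000, function(s)
    delta_spikes(simulate_spike_train(
      spike_config(15, 15, stim_onset = 2, trial_duration = 5,
                   seed = s)))$delta, numeric(1))
  expect_lt(abs(mean(d_eq)), 3 * sd(d_eq) / sqrt(1000))
  # r0 = 10, r1 = 40, latency 0.5: mean delta near 30 within 3 SE
  d <- vapply(1:1000, function(s)
    delta_spikes(simulate_spike_train(
      spike_config(10, 40, stim_onset = 2, latency = 0.5,
                   trial_duration = 5, seed = s)))$delta, numeric(1))
  expect_lt(abs(mean(d) - 30), 3 * sd(d) / sqrt(1000))
  # determinism
  s1 <- simulate_spike_train(spike_config(seed = 33))
  s2 <- simulate_spike_train(spike_config(seed = 33))
  expect_identical(s1$spike_times, s2$spike_times)
})

test_that("EAG trace generator produces the requested deflection", {
  tr <- simulate_eag_trace(2, onset = 1, noise_sd = 0, fs = 1000, seed = 1)
  expect_equal(eag_peak(tr)$peak_deflection_mV, 2, tolerance = 1e-9)
  tr0 <- simulate_eag_trace(0, onset = 1, noise_sd = 0, fs = 1000, seed = 1)
  expect_equal(eag_peak(tr0)$peak_deflection_mV, 0, tolerance = 1e-12)
  # the deflection is negative-going
  expect_lt(min(tr$mV), -1.9)
  # noisy estimate stays within [1.8, 2.2] over 100 seeds
  peaks <- vapply(1:100, function(s)
    eag_peak(simulate_eag_trace(2, onset = 1, noise_sd = 0.05, fs = 1000,
                                seed = s))$peak_deflection_mV, numeric(1))
  expect_true(all(peaks >= 1.8 & peaks <= 2.2))
})

test_that("rendered frames match fly positions and overlaps merge", {
  a <- default_arena(px_per_cm = 5)
  ts <- lane_tracks(1, 10, a, seed = 2)
  st <- render_frames(ts, fly_radius_px = 2)
  expect_length(st, 10)
  # one fly: exactly one dark component per frame
  for (k in c(1, 5, 10)) {
    d <- detect_blobs(st[[k]])
    expect_equal(nrow(d), 1)
  }
  # round-trip centroid within 0.5 px of ground truth
  d1 <- detect_blobs(st[[1]])
  gt <- cm_to_px(ts$tracks$x_cm[1], ts$tracks$y_cm[1], a)
  expect_lt(abs(d1$x - gt$x), 0.5)
  expect_lt(abs(d1$y - gt$y), 0.5)
  # two flies closer than 2 x radius: one connected component
  tr2 <- data.frame(track_id = 1:2, frame = 0L, t_s = 0,
                    x_cm = c(10, 10.5), y_cm = 10, sex = NA)
  st2 <- render_frames(as_trackset(tr2, 30, a), fly_radius_px = 2)
  expect_equal(nrow(detect_blobs(st2[[1]])), 1)
  # out-of-bounds positions are rejected
  tr3 <- data.frame(track_id = 1, frame = 0L, t_s = 0,
                    x_cm = 25, y_cm = 10, sex = NA)
  expect_error(render_frames(as_trackset(tr3, 30, a)), "bounds")
})
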