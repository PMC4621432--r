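test_that("windowed spike counting follows the half-open convention", {
  on <- 2
  # a spike exactly at onset + 0.5 counts; exactly at onset + 1.5 does not
  tr <- spike_train(c(on + 0.5, on + 1.5), on, 5)
  r <- delta_spikes(tr)
  expect_equal(r$post_count, 1)
  # left edge of the pre window counts, right edge (onset itself) does not
  tr2 <- spike_train(c(on - 1, on), on, 5)
  expect_equal(delta_spikes(tr2)$pre_count, 1)
  # spikes only outside both windows: delta = 0
  tr3 <- spike_train(c(0.1, 0.5, 4.9), on, 5)
  expect_equal(delta_spikes(tr3)$delta, 0)
  # windows must fit in the trial
  expect_error(delta_spikes(spike_train(1, stim_onset = 0.5,
                                        trial_duration = 5)), "window")
  expect_error(delta_spikes(spike_train(1, stim_onset = 4,
                                        trial_duration = 5)), "window")
})

test_that("delta and solvent correction reproduce constructed counts", {
  on <- 2
  mk <- function(pre_n, post_n, label = "odor")
    spike_train(sort(c(seq(on - 0.95, on - 0.05, length.out = pre_n),
                       seq(on + 0.55, on + 1.45, length.out = post_n))),
                on, 5, label = label)
  odor <- mk(10, 40)
  solvent <- mk(10, 12, "solvent")
  expect_equal(delta_spikes(odor)$delta, 30)
  r <- solvent_corrected_response(odor, solvent)
  expect_equal(r$solvent_corrected, (40 - 10) - (12 - 10))
  # self-correction gives zero
  expect_equal(solvent_corrected_response(odor, odor)$solvent_corrected, 0)
  # no solvent trial: solvent_corrected stays NULL, never assumed zero
  expect_null(delta_spikes(odor)$solvent_corrected)
})

test_that("delta_spikes agrees with brute-force counting on random trains", {
  set.seed(31)
  for (i in 1:200) {
    on <- runif(1, 1, 3)
    times <- sort(runif(rpois(1, 30), 0, 5))
    tr <- spike_train(times, on, 5)
    expect_equal(delta_spikes(tr)$delta, brute_delta(times, on))
  }
})

test_that("delta is additive over disjoint subsets and shift-invariant", {
  set.seed(17)
  on <- 2.2
  times <- sort(runif(60, 0, 6))
  split_idx <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  tA <- spike_train(times[split_idx], on, 6)
  tB <- spike_train(times[!split_idx], on, 6)
  tAll <- spike_train(times, on, 6)
  expect_equal(delta_spikes(tAll)$delta,
               delta_spikes(tA)$delta + delta_spikes(tB)$delta)
  # time shift of all spikes and the onset leaves the result unchanged
  sh <- 1.3
  t_shift <- spike_train(times + sh, on + sh, 6 + sh)
  expect_equal(delta_spikes(t_shift)$delta, delta_spikes(tAll)$delta)
})

test_that("Monte-Carlo corrected response matches the Poisson expectation", {
  n <- 1000
  corrected <- vapply(seq_len(n), function(s) {
    odor <- simulate_spike_train(spike_config(10, 40, stim_onset = 2,
                                              trial_duration = 5, seed = s))
    solv <- simulate_spike_train(spike_config(10, 12, stim_onset = 2,
                                              trial_duration = 5,
                                              seed = s + n), label = "solvent")
    solvent_corrected_response(odor, solv)$solvent_corrected
  }, numeric(1))
  expect_lt(abs(mean(corrected) - 28), 3 * sd(corrected) / sqrt(n))
})

test_that("EAG peak is the greatest deflection from the baseline mean", {
  # flat trace: 0 mV
  flat <- data.frame(t_s = seq(0, 4, by = 0.001), mV = 0)
  attr(flat, "fs") <- 1000; attr(flat, "onset") <- 1
  expect_equal(eag_peak(flat)$peak_deflection_mV, 0)
  # a nonzero baseline is subtracted before measuring the deflection
  offs <- simulate_eag_trace(2, onset = 1, noise_sd = 0, fs = 1000, seed = 1)
  offs$mV <- offs$mV + 0.7
  expect_equal(eag_peak(offs)$peak_deflection_mV, 2, tolerance = 1e-9)
  expect_error(eag_peak(flat, response_window = c(10, 12)), "empty")
})

test_that("dose-response table summarizes replicates per dilution", {
  df <- data.frame(dilution = c("1e-2", "1e-2", "1e-2", "1e-1"),
                   response = c(1, 2, 3, 5))
  out <- dose_response_table(df)
  r2 <- out[out$dilution == "1e-2", ]
  expect_equal(r2$mean, 2)
  expect_equal(r2$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(r2$n, 3L)
  # single replicate: SEM flagged NA
  expect_true(is.na(out$sem[out$dilution == "1e-1"]))
  # a monotone simulated dose series keeps its ordering in the means
  set.seed(3)
  sim <- do.call(rbind, lapply(1:4, function(i)
    data.frame(dilution = sprintf("d%d", i),
               response = rnorm(6, mean = 10 * i, sd = 0.5))))
  means <- dose_response_table(sim)$mean
  expect_true(all(diff(means) > 0))
})
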