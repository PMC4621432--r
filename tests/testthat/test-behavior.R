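test_that("AI boundary semantics and arithmetic match the definition", {
  a <- default_arena()
  # all samples in the odor quadrant
  all_in <- quadrant_tracks(a, list(Q1 = 900))
  expect_equal(attraction_index(all_in, "Q1", c(0, 300))$AI, 1)
  # equal distribution over the four quadrants
  uniform <- quadrant_tracks(a, list(Q1 = 250, Q2 = 250, Q3 = 250, Q4 = 250))
  expect_equal(attraction_index(uniform, "Q1", c(0, 300))$AI, 0)
  # O = 300 against (100, 100, 100): C_avg = 100, AI = 0.5
  r <- attraction_index(
    quadrant_tracks(a, list(Q1 = 300, Q2 = 100, Q3 = 100, Q4 = 100)),
    "Q1", c(0, 300))
  expect_equal(r$O, 300)
  expect_equal(r$C_avg, 100)
  expect_equal(r$AI, 0.5)
  # zero in odor, positive elsewhere: AI = -1
  none_in <- quadrant_tracks(a, list(Q2 = 40, Q3 = 80, Q4 = 20))
  # against Q2: controls are Q1 (0), Q3 (80), Q4 (20), so C_avg = 100/3
  expect_equal(attraction_index(none_in, "Q2", c(0, 300))$AI,
               (40 - 100 / 3) / (40 + 100 / 3))
  expect_equal(attraction_index(none_in, "Q1", c(0, 300))$AI, -1)
  # no labelled samples at all: undefined, not zero
  empty <- quadrant_tracks(a, list(Q1 = 10))
  expect_error(attraction_index(empty, "Q1", c(200, 300)), "undefined")
})

test_that("AI is antisymmetric under swapping odor and pooled control", {
  ai <- function(o, c_avg) (o - c_avg) / (o + c_avg)
  for (p in list(c(10, 40), c(300, 100), c(7, 7))) {
    expect_equal(ai(p[1], p[2]), -ai(p[2], p[1]))
  }
  # and via the full pipeline: per-quadrant counts swapped
  a <- default_arena()
  t1 <- quadrant_tracks(a, list(Q1 = 60, Q2 = 20, Q3 = 20, Q4 = 20))
  t2 <- quadrant_tracks(a, list(Q1 = 20, Q2 = 60, Q3 = 60, Q4 = 60))
  expect_equal(attraction_index(t1, "Q1", c(0, 300))$AI,
               -attraction_index(t2, "Q1", c(0, 300))$AI)
})

test_that("AI is stable under uniform temporal subsampling", {
  a <- default_arena()
  cfg <- sim_config(n_flies = 8, frame_rate = 10,
                    phases = list(list(name = "stimulus", duration = 60,
                                       odor_quadrant = "Q1",
                                       odor_is_food = FALSE)),
                    bias_strength = 2, seed = 12)
  ts <- simulate_flies(cfg, a)
  full <- attraction_index(ts, "Q1", c(0, 60))$AI
  sub <- ts
  sub$tracks <- sub$tracks[sub$tracks$frame %% 5 == 0, ]
  expect_equal(attraction_index(sub, "Q1", c(0, 60))$AI, full,
               tolerance = 0.05)
})

test_that("the AI time course flags undefined windows and peaks in-stimulus", {
  a <- default_arena()
  uniform <- quadrant_tracks(a, list(Q1 = 300, Q2 = 300, Q3 = 300, Q4 = 300),
                             frame_rate = 1)
  tc <- ai_timecourse(uniform, "Q1", window_len = 100, stride = 100)
  expect_equal(nrow(tc), 3)
  expect_true(all(abs(tc$AI) < 1e-12))
  expect_false(any(tc$undefined))
  # simulated stimulus then unbiased decay: max AI in the stimulus epoch
  cfg <- sim_config(n_flies = 12, frame_rate = 5,
                    phases = list(
                      list(name = "stimulus", duration = 120,
                           odor_quadrant = "Q1", odor_is_food = FALSE),
                      list(name = "clean_air", duration = 240,
                           odor_quadrant = NULL, odor_is_food = FALSE)),
                    bias_strength = 4, seed = 5)
  ts <- simulate_flies(cfg, a)
  tc2 <- ai_timecourse(ts, "Q1", window_len = 60, stride = 60)
  expect_lte(tc2$t_end[which.max(tc2$AI)], 120)
})

test_that("post-stimulus analysis targets the rotated quadrant", {
  a <- default_arena()
  pre <- quadrant_tracks(a, list(Q1 = 400, Q2 = 100, Q3 = 100, Q4 = 100))
  # rotation 0: identical to two independent attraction_index calls
  res0 <- post_stimulus_analysis(pre, pre, "Q1", 0)
  expect_equal(res0$post_quadrant, "Q1")
  expect_equal(res0$post$AI, attraction_index(pre, "Q1", c(0, 300))$AI)
  # rotation 90: the same physical points score against the remapped label
  a90 <- rotate_arena(a, 90)
  post <- pre
  post$arena <- a90
  res <- post_stimulus_analysis(pre, post, "Q1", 90)
  expect_equal(res$post_quadrant, "Q2")
  expect_equal(res$post$AI, res$stimulus$AI)
})

test_that("egg quadrant counts recover weights and fold enrichment", {
  a <- default_arena()
  # all eggs in the odor quadrant
  e <- simulate_eggs(egg_config(c(1, 0, 0, 0), 80, seed = 6), arena = a)
  r <- egg_quadrant_counts(e, a, "Q1")
  expect_equal(sum(r$per_region_counts > 0), 1)
  expect_equal(r$OPI, 1)
  expect_equal(sum(r$per_region_counts), r$total_eggs)
  # counts (50, 10, 10, 10): E_avg = 10, fold enrichment 5
  pts <- lapply(list(c("Q1", 50), c("Q2", 10), c("Q3", 10), c("Q4", 10)),
                function(q) {
                  cen <- colMeans(quadrant_polygon(a, q[1]))
                  data.frame(x_cm = rep(cen[1], as.integer(q[2])),
                             y_cm = rep(cen[2], as.integer(q[2])))
                })
  r2 <- egg_quadrant_counts(do.call(rbind, pts), a, "Q1")
  expect_equal(r2$E_avg, 10)
  expect_equal(r2$fold_enrichment, 5)
  # weights (5,1,1,1) at large n: measured fold change near 5
  e3 <- simulate_eggs(egg_config(c(5, 1, 1, 1), 4000, seed = 7), arena = a)
  r3 <- egg_quadrant_counts(e3, a, "Q1")
  # binomial CI on the odor fraction translated to fold enrichment
  n <- r3$total_eggs
  ci <- qbinom(c(0.005, 0.995), n, 5 / 8) / n
  fold_ci <- 3 * ci / (1 - ci)
  expect_gte(r3$fold_enrichment, fold_ci[1])
  expect_lte(r3$fold_enrichment, fold_ci[2])
})

test_that("OPI boundary semantics match the definition", {
  expect_equal(oviposition_preference_index(c(37, 0, 0), 1)$OPI, 1)
  expect_equal(oviposition_preference_index(c(12, 12, 12), 1)$OPI, 0)
  expect_equal(oviposition_preference_index(c(0, 30, 10), 1)$OPI, -1)
  r <- oviposition_preference_index(c(20, 10, 4), 1)
  expect_equal(r$E_avg, 7)
  expect_equal(r$OPI, (20 - 7) / (20 + 7))
  expect_error(oviposition_preference_index(c(0, 0, 0), 1), "undefined")
  expect_error(oviposition_preference_index(c(1, 2), 1), "3 nonnegative")
})

test_that("OPI from simulated eggs converges to (w-1)/(w+1)", {
  for (w in c(3, 9)) {
    e <- simulate_eggs(egg_config(c(w, 1, 1), 10000, seed = w),
                       wells = default_wells())
    counts <- vapply(c("W1", "W2", "W3"),
                     function(x) sum(e$region == x), numeric(1))
    opi <- oviposition_preference_index(counts, 1)$OPI
    expect_equal(opi, (w - 1) / (w + 1), tolerance = 0.02)
  }
})

test_that("occupancy heatmap conserves in-mask samples", {
  a <- default_arena()
  # single stationary fly: one bin holds all samples
  still <- as_trackset(data.frame(track_id = 1, frame = 0:99,
                                  t_s = (0:99) / 30, x_cm = 5.2, y_cm = 13.7,
                                  sex = NA), 30, a)
  hm <- occupancy_heatmap(still, 0.5)
  expect_equal(max(hm$counts), 100)
  expect_equal(sum(hm$counts), 100)
  # conservation on a simulation
  cfg <- sim_config(n_flies = 6, frame_rate = 5,
                    phases = list(list(name = "pre", duration = 30,
                                       odor_quadrant = NULL,
                                       odor_is_food = FALSE)), seed = 2)
  ts <- simulate_flies(cfg, a)
  hm2 <- occupancy_heatmap(ts, 1)
  expect_equal(sum(hm2$counts), hm2$n_binned)
  expect_equal(hm2$n_binned, nrow(ts$tracks))
})

test_that("group comparisons match closed-form statistics", {
  # identical constant groups: t = 0, p = 1
  r0 <- compare_groups(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # textbook fixture vs the pooled-variance formula
  g1 <- c(1, 2, 3, 4, 5); g2 <- c(2, 3, 4, 5, 6)
  r <- compare_groups(list(g1 = g1, g2 = g2))
  sp2 <- (4 * var(g1) + 4 * var(g2)) / 8
  t_manual <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_manual <- 2 * pt(-abs(t_manual), 8)
  expect_equal(r$statistic, t_manual, tolerance = 1e-9)
  expect_equal(r$p_value, p_manual, tolerance = 1e-9)
  expect_equal(r$test_name, "Student t-test")
  expect_equal(compare_groups(list(g1 = g1, g2 = g2), welch = TRUE)$test_name,
               "Welch t-test")
  # three groups: one-way ANOVA F matches the closed form
  g3 <- c(1, 3, 5, 7)
  r3 <- compare_groups(list(g1 = g1, g2 = g2, g3 = g3))
  expect_equal(r3$test_name, "one-way ANOVA")
  fit <- stats::oneway.test(v ~ g,
    data = data.frame(v = c(g1, g2, g3),
                      g = rep(1:3, c(5, 5, 4))), var.equal = TRUE)
  expect_equal(r3$statistic, unname(fit$statistic), tolerance = 1e-9)
  expect_equal(r3$p_value, fit$p.value, tolerance = 1e-9)
  # degenerate input flagged
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "at least two values")
  expect_error(compare_groups(list(a = c(1, 2))), "two groups")
})

test_that("the ANOVA keeps its nominal type-I error on equal means", {
  set.seed(99)
  n_rep <- 3000
  rej <- vapply(seq_len(n_rep), function(i) {
    g <- lapply(1:3, function(j) rnorm(5))
    compare_groups(g)$p_value < 0.05
  }, logical(1))
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 4 * se)
})
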