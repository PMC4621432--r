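#!/usr/bin/env Rscript
# Post-stimulus aggregation protocol: 5-min food-odor stimulus with male
# depositors, then clean air with the arena rotated 90 degrees. The AI is
# scored against the rotated label of the original odor quadrant, so any
# post-stimulus attraction reflects the deposited pheromone, not the odor.
# Three conditions: male depositors, female-only (no deposition), and male
# depositors at high temperature (deposit evaporates quickly).

suppressMessages(library(quadfly))
dir.create("results", showWarnings = FALSE)

arena <- build_arena(19.5, 10, 0)
run_condition <- function(label, sex, temperature_factor, seed) {
  cfg <- sim_config(
    n_flies = 30, sex = sex, frame_rate = 5,
    phases = list(
      list(name = "stimulus", duration = 300, odor_quadrant = "Q1",
           odor_is_food = TRUE),
      list(name = "clean_air", duration = 1500, odor_quadrant = NULL,
           odor_is_food = FALSE)),
    bias_strength = 3, rotate_after_stimulus_deg = 90, seed = seed)
  field <- pheromone_field(arena, temperature_factor = temperature_factor)
  ts <- simulate_flies(cfg, arena, field)
  stim <- phase_trackset(ts, "stimulus")
  post <- phase_trackset(ts, "clean_air")
  res <- post_stimulus_analysis(stim, post, "Q1", 90)
  tc <- ai_timecourse(post, res$post_quadrant, window_len = 300)
  data.frame(condition = label, seed = seed,
             window = sprintf("%d-%d min", tc$t_start / 60, tc$t_end / 60),
             t_mid_min = (tc$t_start + tc$t_end) / 120,
             AI = tc$AI, stimulus_AI = res$stimulus$AI,
             final_mass = total_mass(ts$field))
}

out <- rbind(
  run_condition("male_depositors", "male", 1, 11),
  run_condition("female_only", "female", 1, 11),
  run_condition("male_32C", "male", 100, 11))
write_results(out, csv_path = "results/04_post_stimulus.csv")

cat("Post-stimulus AI toward the rotated odor quadrant (5-min windows):\n")
for (cond in unique(out$condition)) {
  sub <- out[out$condition == cond, ]
  cat(sprintf("  %-16s stimulus AI %.2f | post: %s | residual deposit %.1f\n",
              cond, sub$stimulus_AI[1],
              paste(sprintf("%.2f", sub$AI), collapse = " "),
              sub$final_mass[1]))
}
cat("Male depositors show aggregation decaying over ~25 min;\n")
cat("female-only and heated runs stay near zero.\n")
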