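#!/usr/bin/env Rscript
# Simulate a four-quadrant stimulus trial and write the track CSV + manifest.
# The config mirrors the live assay: 45 flies, 5-min odor stimulus, 30 fps.
# (Downstream scripts re-simulate at lower frame rates where only window
# statistics are needed.)

suppressMessages(library(quadfly))
dir.create("results", showWarnings = FALSE)

arena <- build_arena(19.5, 10, 0)
config <- list(
  arena = list(side_length_cm = 19.5, px_per_cm = 10, rotation_deg = 0),
  simulation = list(
    n_flies = 45, sex = "female", frame_rate = 30,
    phases = list(list(name = "stimulus", duration = 300,
                       odor_quadrant = "Q1", odor_is_food = FALSE)),
    bias_strength = 2, seed = 1))
write_experiment_config(config, "results/01_config.yaml")

obj <- config_to_objects(config)
ts <- simulate_flies(obj$sim, obj$arena)
write_tracks_csv(ts, "results/01_tracks.csv")
write_manifest(config, seed = obj$sim$seed,
               files = c("results/01_tracks.csv"),
               path = "results/01_manifest.json")

res <- attraction_index(ts, "Q1", c(0, 300))
cat(sprintf("Simulated %d flies for 5 min at 30 fps: %d positional samples\n",
            obj$sim$n_flies, nrow(ts$tracks)))
cat(sprintf("Samples per fly per minute: %.0f\n",
            nrow(ts$tracks) / obj$sim$n_flies / 5))
print(res)
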