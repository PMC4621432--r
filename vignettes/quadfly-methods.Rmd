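---
title: "Models and methods behind quadfly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quadfly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

quadfly quantifies four-quadrant olfactometer behavior, egg-laying
preference, and sensillum/antennal electrophysiology, and ships an
agent-based generator that produces every input the pipeline consumes. This
vignette explains the models, the parameters that matter, the numerical
conventions, and what validation on synthetic data does and does not show.

## Arena geometry and quadrant semantics

The arena is a 19.5 × 19.5 cm square with a star-shaped walkable region;
positions are physical cm (origin lower-left, y up) and are converted to
image pixels (top-left origin, row-major) only at the rendering/tracking
boundary. The published assay does not specify the star outline, so the
default mask is the bounding square minus four isosceles right-triangle
corner notches with legs of 0.25 × side. This choice is declared, not
inferred — and it is not load-bearing: every statistic in the package
depends only on which quadrant a point falls in, i.e. on the sign pattern of
its offset from the center, never on the mask outline. The mask is
overridable for users who measure their own arena.

Quadrants are named Q1 = (+,+), Q2 = (−,+), Q3 = (−,−), Q4 = (+,−) at
rotation 0. Which quadrant carries odor is an experiment-config field, not a
geometry property. Points exactly on an axis (offset below 1e−12 cm) or
outside the mask are labelled NONE and excluded from quadrant counts: for
continuous positions the axes are a measure-zero set, and excluding them
avoids biased tie-breaking.

`rotate_arena()` models the 90° rotation used in the post-stimulus protocol
as a relabeling of the analysis frame: a fixed physical point labelled Q1 at
rotation 0 is labelled Q2 after one 90° counterclockwise step (the cyclic
permutation Q1→Q2→Q3→Q4). Deposited material therefore keeps its physical
coordinates across a rotation while its quadrant label is remapped by
`remap_quadrant()`; `post_stimulus_analysis()` scores the post-phase AI
against the remapped label, which is exactly what dissociates
deposit-following from residual room-frame odor.

## Behavioral statistics

The Attraction Index over a window is AI = (O − C_avg)/(O + C_avg), with O
the pooled count of positional samples in the odor quadrant and C_avg the
mean count per control quadrant. Pooling all flies' samples follows the
"tracked positional data points" reading of the definition; a per-fly
average is available behind `per_fly = TRUE` but is not the default. A
window with no quadrant-labelled samples raises an undefined-statistic error
rather than returning 0 — AI = 0 is a meaningful value (uniform occupancy)
and must not be conflated with "no data". Windows are half-open in time
(`t_start <= t < t_end`); post-stimulus windows start at the first frame
after the clean-air switch.

The Oviposition Preference Index uses the same contrast on egg counts, with
E_avg the mean of the two control wells (3-well mode) or three control
quadrants (4-quadrant mode).

Group comparisons take the trial (one replicate arena run) as the sampling
unit: two groups get a Student's equal-variance t test by default (a flag
selects Welch) and more than two get a one-way ANOVA, both via the standard
stats routines; p values are reported raw, with no multiple-testing
correction, and labelled as such.

## Tracking

Flies are dark blobs on a bright infrared background. Detection thresholds
the inverted image with a fixed global threshold (Otsu-initialized on the
first frame — the synthetic scenes are strongly bimodal — and overridable),
labels connected components (EBImage), filters them by area and reports
intensity-weighted centroids.

Linking is greedy mutual-nearest-neighbor within a gate distance, default
3 cm worth of pixels per frame interval (roughly the maximum walking
displacement), rather than a global assignment: at the assay's densities the
mutual-NN solution almost always coincides with the global one and is far
easier to reason about. The intersection rule is enforced by two merge
tests, either of which suffices: a blob whose area exceeds 1.7× the running
median single-fly area, or a blob that is the unique gated match of two or
more active tracks. All tracks involved in a merge are terminated, and the
merged blob contributes no position to any track — identity inside a merge
is unknown, so a strict reading of "tracks are considered completed" keeps
it out of every track. Fresh ids open when the blobs separate. Tracks never
bridge gaps: an unmatched track terminates, so frame indices within a track
are strictly consecutive.

## The synthetic-data generator

`simulate_flies()` is a discrete-time correlated random walk. Each frame,
agent heading is the direction of the vector sum of (persistence ×
previous-heading unit vector) and a unit vector drawn from a von Mises
distribution whose mean points at the attractant and whose concentration is
β × s, where s ∈ [0,1] is the normalized local stimulus strength. With
β = 0 the von Mises component is uniform and the walk is isotropic — the
zero-symmetry that makes β a clean ground-truth dial for parameter-recovery
tests. During a stimulus phase the attractant is the odor-quadrant centroid
with s = 1; during clean air it is the local pheromone gradient (bilinear
interpolation of the gridded field; central differences at one cell width)
with s = |∇m|/(|∇m| + g½), saturating at the `grad_half_sat` parameter
(default 5 mass units/cm). Speeds are gamma-distributed (shape 4) around
`step_speed_mean` (default 1 cm/s); boundaries reflect specularly off the
mask polygon, preserving the speed distribution.

The pheromone field evolves per frame as m ← m·exp(−k·τ·dt) + d·dt·(males
in cell), with deposition only while a food-odor phase is on and only in
odor-quadrant cells, and τ the temperature factor (τ ≫ 1 models the heated
condition, which strips the deposit and abolishes post-stimulus
aggregation). No quantitative deposition or evaporation rates are published,
so k and d are free parameters; the defaults (k = 0.002 s⁻¹, d = 1
unit·male⁻¹·s⁻¹, grid at 2 cells/cm) were chosen once so that a 5-min
stimulus with ~15 males yields post-stimulus aggregation decaying on the
~25-minute scale the assay reports, and are not tuned per run.

Randomness: one generator seeded per simulation, with draws ordered by
(frame, agent). Agent order is fixed by the config, so identical config +
seed gives bitwise-identical output; this vectorized single-stream design
was preferred over per-agent sub-streams because it keeps 30-fps multi-fly
simulation tractable in R while losing nothing given deterministic agent
ordering.

Egg positions are drawn uniformly within regions whose weights are the
analytic ground truth (total count Poisson), deliberately not from a
pheromone field, so OPI recovery has a closed-form target (w−1)/(w+1).
Spike trains are piecewise-homogeneous Poisson (baseline r0, evoked r1 in a
latency-shifted window); EAG traces are a negative alpha-function deflection
(time constant 0.3 s) plus Gaussian noise.

What the generator does *not* emulate: courtship/feeding interactions,
airflow and plume structure, body shape and orientation in rendering,
illumination drift, and per-fly behavioral heterogeneity. Passing tests
therefore certify the statistics, the tracker's contract and the pipeline's
plumbing on idealized scenes — they do not certify detection robustness on
real infrared video.

## Electrophysiology

`delta_spikes()` uses half-open windows [a, b): the 1000-ms response window
starts 500 ms after stimulus onset, the 1000-ms spontaneous window ends at
onset. A spike exactly on a left edge counts; on a right edge it does not —
the standard histogram convention, declared and tested (additivity over
disjoint spike sets and time-shift invariance are property-tested).
`solvent_corrected_response()` subtracts the solvent trial's delta; when no
solvent trial exists the corrected value is NULL, never assumed 0, because
the protocol always subtracts a measured solvent response. The EAG peak
search window is not published; the default is onset to onset + 3 s,
configurable. Spike sorting from raw voltage is out of scope — the module
consumes spike times.

## Numerical choices and test scale

Simulation-based tests run at reduced frame rates (2–5 Hz) and modest agent
counts: the AI is a ratio of occupancy counts, so its expectation is
invariant to uniform temporal subsampling (verified within Monte-Carlo error),
and these sizes keep the full suite within minutes. The sampling-arithmetic
checks (1800 samples/fly/min at 30 frames/s; 16,560 samples per 23-hr
egg-laying recording at 1 frame/5 s) run at the full rates, where they are
exact integer contracts. Tracker validation uses 20 synthetic 30-s videos at
30 fps with lane-separated trajectories (pairwise separation always above
3× fly radius) plus an engineered crossing fixture for the
intersection-termination rule.

## Known limitations

- The AI is a nonlinear ratio, so its finite-sample expectation under an
  unbiased walk is not exactly zero: slow, autocorrelated walkers produce
  clumped occupancy, and a clump is three times more likely to sit in a
  control quadrant than in the odor quadrant, pulling single-trial AIs
  slightly negative (in the degenerate limit of one clump, AI is +1 with
  probability 1/4 and −1 with probability 3/4). The effect shrinks with
  flies × recording length; trial-level replication absorbs it, but very
  short recordings of few flies should not be read at the second decimal.
- The greedy linker can mislabel during dense multi-fly pileups faster than
  the gate; the assay's own rule (terminate on intersection) bounds the
  damage, but heavy crowding shortens tracks.
- The star mask is an approximation; statistics are mask-independent but
  rendered videos are not photorealistic.
- The deposition–evaporation model is first-order and well-mixed per cell;
  it reproduces the qualitative decay, not measured kinetics.
- Group tests assume exchangeable trials; no hierarchical modeling of
  within-trial correlation is attempted.
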