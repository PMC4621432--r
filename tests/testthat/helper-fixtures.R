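# Shared fixtures, all built in code.

default_arena <- function(px_per_cm = 10) build_arena(19.5, px_per_cm, 0)

# A track table with n_per samples placed at the centroid of each listed
# quadrant (one synthetic "fly" per quadrant), sampled at frame_rate.
quadrant_tracks <- function(arena, n_per_quadrant, frame_rate = 30) {
  qs <- names(n_per_quadrant)
  rows <- lapply(seq_along(qs), function(i) {
    n <- n_per_quadrant[[i]]
    if (n == 0) return(NULL)
    cen <- colMeans(quadrant_polygon(arena, qs[i]))
    data.frame(track_id = i, frame = seq_len(n) - 1L,
               t_s = (seq_len(n) - 1L) / frame_rate,
               x_cm = cen[1], y_cm = cen[2], sex = NA_character_)
  })
  as_trackset(do.call(rbind, rows), frame_rate = frame_rate, arena = arena)
}

# Ground-truth "lane" trajectories: each fly random-walks in x within its own
# horizontal lane, so pairwise distance never drops below the lane spacing.
lane_tracks <- function(n_flies, n_frames, arena, frame_rate = 30,
                        seed = 1, step_sd_cm = 0.05) {
  set.seed(seed)
  lane_y <- seq(2.5, arena$side_length - 2.5, length.out = max(n_flies, 2))
  rows <- lapply(seq_len(n_flies), function(i) {
    x <- numeric(n_frames)
    x[1] <- runif(1, 4, arena$side_length - 4)
    for (f in 2:n_frames)
      x[f] <- min(max(x[f - 1] + rnorm(1, 0, step_sd_cm), 2.5),
                  arena$side_length - 2.5)
    data.frame(track_id = i, frame = seq_len(n_frames) - 1L,
               t_s = (seq_len(n_frames) - 1L) / frame_rate,
               x_cm = x, y_cm = lane_y[i], sex = NA_character_)
  })
  as_trackset(do.call(rbind, rows), frame_rate = frame_rate, arena = arena)
}

# Two flies on a head-on collision course (cross at the midpoint), same y.
crossing_tracks <- function(arena, n_frames = 40, frame_rate = 30) {
  x1 <- seq(5, 13, length.out = n_frames)
  x2 <- rev(x1)
  tr <- rbind(
    data.frame(track_id = 1, frame = seq_len(n_frames) - 1L,
               t_s = (seq_len(n_frames) - 1L) / frame_rate,
               x_cm = x1, y_cm = 10, sex = NA_character_),
    data.frame(track_id = 2, frame = seq_len(n_frames) - 1L,
               t_s = (seq_len(n_frames) - 1L) / frame_rate,
               x_cm = x2, y_cm = 10, sex = NA_character_))
  as_trackset(tr, frame_rate = frame_rate, arena = arena)
}

# Brute-force oracle for the windowed spike-count response.
brute_delta <- function(times, onset, post_offset = 0.5, window_len = 1) {
  pre <- 0; post <- 0
  for (s in times) {
    if (s >= onset - window_len && s < onset) pre <- pre + 1
    if (s >= onset + post_offset && s < onset + post_offset + window_len)
      post <- post + 1
  }
  (post - pre) / window_len
}
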