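#' Spike trains
#'
#' @param spike_times Sorted nonnegative spike times (s), within
#'   `[0, trial_duration]`.
#' @param stim_onset Stimulus onset, s.
#' @param trial_duration Trial length, s.
#' @param label One of "odor", "solvent", "none".
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, stim_onset, trial_duration,
                        label = "none") {
  label <- match.arg(label, c("odor", "solvent", "none"))
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) stop("spike_times must be sorted ascending")
  if (length(spike_times) &&
      (min(spike_times) < 0 || max(spike_times) > trial_duration))
    stop("spike times must lie within [0, trial_duration]")
  structure(list(spike_times = spike_times, stim_onset = stim_onset,
                 trial_duration = trial_duration, label = label),
            class = "spike_train")
}

#' Windowed spike-count response (delta spikes/s)
#'
#' Counts spikes in a 1000 ms response window starting 500 ms after stimulus
#' onset and subtracts the count in the 1000 ms window immediately before
#' onset. Both windows are half-open `[a, b)`: a spike exactly at the left
#' edge counts, one at the right edge does not. With 1 s windows the counts
#' are rates, so delta is in spikes/s.
#'
#' @param train A `spike_train`.
#' @param post_offset Start of the response window after onset, s (default
#'   0.5).
#' @param window_len Window length, s (default 1).
#' @return An `ssr_response`: list with `pre_count`, `post_count`, `delta`
#'   (spikes/s) and `solvent_corrected` (NULL until a solvent trial is
#'   subtracted; never assumed 0).
#' @export
delta_spikes <- function(train, post_offset = 0.5, window_len = 1) {
  stopifnot(inherits(train, "spike_train"))
  on <- train$stim_onset
  if (on < window_len)
    stop("pre-stimulus window does not fit before onset")
  if (on + post_offset + window_len > train$trial_duration)
    stop("response window exceeds the trial duration")
  st <- train$spike_times
  pre <- sum(st >= on - window_len & st < on)
  post <- sum(st >= on + post_offset & st < on + post_offset + window_len)
  structure(list(pre_count = pre, post_count = post,
                 delta = (post - pre) / window_len,
                 solvent_corrected = NULL, label = train$label),
            class = "ssr_response")
}

#' Solvent-corrected spike response
#'
#' (odor response - spontaneous response) - (solvent response - spontaneous
#' response): the windowed delta of the odor trial minus the windowed delta
#' of the solvent trial.
#'
#' @param odor,solvent `spike_train`s.
#' @param ... Passed to [delta_spikes()].
#' @return An `ssr_response` for the odor trial with `solvent_corrected` set
#'   (spikes/s).
#' @export
solvent_corrected_response <- function(odor, solvent, ...) {
  r_odor <- delta_spikes(odor, ...)
  r_solv <- delta_spikes(solvent, ...)
  r_odor$solvent_corrected <- r_odor$delta - r_solv$delta
  r_odor
}

#' @export
print.ssr_response <- function(x, ...) {
  cat(sprintf("SSR response: pre %d, post %d, delta %.1f spikes/s%s\n",
              x$pre_count, x$post_count, x$delta,
              if (!is.null(x$solvent_corrected))
                sprintf(", solvent-corrected %.1f spikes/s",
                        x$solvent_corrected) else ""))
  invisible(x)
}

#' EAG peak deflection
#'
#' Quantifies an electroantennogram trace by the greatest deflection: the
#' maximum absolute deviation from the baseline mean within the response
#' window. EAG responses are negative-going; the magnitude is reported in mV.
#'
#' @param trace data.frame with `t_s, mV` (e.g. from [simulate_eag_trace()]
#'   or [read_eag_csv()]).
#' @param fs Sampling rate, Hz (defaults to the trace's `fs` attribute).
#' @param baseline_window `(t0, t1)` s used for the baseline mean; default
#'   everything before `response_window[1]`.
#' @param response_window `(t0, t1)` s searched for the peak; default from
#'   the trace's onset attribute to onset + 3 s.
#' @return An `eag_measurement`: list with `peak_deflection_mV` (>= 0),
#'   `t_peak`, `baseline_mV`, and the windows used.
#' @export
eag_peak <- function(trace, fs = attr(trace, "fs"),
                     baseline_window = NULL, response_window = NULL) {
  stopifnot(is.data.frame(trace), all(c("t_s", "mV") %in% names(trace)))
  if (is.null(response_window)) {
    onset <- attr(trace, "onset")
    if (is.null(onset)) stop("give response_window or a trace with an onset attribute")
    response_window <- c(onset, min(onset + 3, max(trace$t_s)))
  }
  if (is.null(baseline_window))
    baseline_window <- c(min(trace$t_s), response_window[1])
  bl <- trace$mV[trace$t_s >= baseline_window[1] &
                 trace$t_s < baseline_window[2]]
  rs <- trace$t_s >= response_window[1] & trace$t_s <= response_window[2]
  if (!length(bl) || !any(rs)) stop("empty baseline or response window")
  base <- mean(bl)
  dev <- abs(trace$mV[rs] - base)
  i <- which.max(dev)
  structure(list(peak_deflection_mV = dev[i],
                 t_peak = trace$t_s[rs][i], baseline_mV = base,
                 baseline_window = baseline_window,
                 response_window = response_window),
            class = "eag_measurement")
}

#' Summarize responses per stimulus dilution
#'
#' @param responses data.frame with columns `dilution` and `response`.
#' @return data.frame with per-dilution `mean`, `sem` (NA for a single
#'   replicate) and `n`, ordered by dilution.
#' @export
dose_response_table <- function(responses) {
  stopifnot(is.data.frame(responses),
            all(c("dilution", "response") %in% names(responses)),
            nrow(responses) >= 1)
  sp <- split(responses$response, responses$dilution)
  out <- data.frame(
    dilution = names(sp),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    n = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$dilution), , drop = FALSE]
}
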