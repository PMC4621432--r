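#' Read and write experiment configuration (YAML or JSON)
#'
#' The configuration mirrors the domain types: an `arena` block
#' (side_length_cm, px_per_cm, rotation_deg), a `simulation` block
#' (fields of [sim_config()]), a `tracking` block (threshold, min_area,
#' max_area, gate_distance, merge_area_factor) and an `analysis` block
#' (odor_quadrant or odor_well, window_s, rotation_deg). Unknown blocks are
#' preserved.
#'
#' @param path File path ending in .yaml/.yml or .json.
#' @param config A named list.
#' @return `read_experiment_config` returns the named list;
#'   `write_experiment_config` returns `path` invisibly.
#' @export
read_experiment_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
}

#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(config, path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else stop("config must be .yaml/.yml or .json")
  invisible(path)
}

#' Build the simulation objects described by a config list
#'
#' @param config A list as returned by [read_experiment_config()].
#' @return list with `arena` (`arena_geometry`) and `sim` (`sim_config`).
#' @export
config_to_objects <- function(config) {
  a <- config$arena
  arena <- build_arena(
    side_length = a$side_length_cm %||% 19.5,
    px_per_cm = a$px_per_cm %||% 10,
    rotation = a$rotation_deg %||% 0)
  s <- config$simulation
  if (!is.null(s$phases)) {
    # JSON readers may simplify the phase list into a data.frame; normalize
    # back to one list per phase
    if (is.data.frame(s$phases))
      s$phases <- lapply(seq_len(nrow(s$phases)),
                         function(i) as.list(s$phases[i, ]))
    s$phases <- lapply(s$phases, function(ph) {
      if (!is.null(ph$odor_quadrant) && all(is.na(ph$odor_quadrant)))
        ph$odor_quadrant <- NULL
      ph
    })
  }
  sim <- if (is.null(s)) NULL else do.call(sim_config, s)
  list(arena = arena, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest for reproducibility auditing
#'
#' Records the config hash, package version, timestamp, seed and the MD5
#' checksums of the listed files. Re-running with the same config hash and
#' seed reproduces identical outputs (all floating output is written with 9
#' significant digits).
#'
#' @param config The config list used.
#' @param seed The seed used.
#' @param files Character vector of input/output file paths to checksum.
#' @param path Where to write the manifest JSON; NULL to only return it.
#' @return The manifest list, invisibly if written.
#' @export
write_manifest <- function(config, seed, files = character(0), path = NULL) {
  man <- list(
    config_hash = unname(tools::md5sum(
      textConnection_md5(jsonlite::toJSON(config, auto_unbox = TRUE)))),
    package_version = as.character(utils::packageVersion("quadfly")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    files = lapply(files[file.exists(files)], function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}

# md5 of a string via a temp file (tools::md5sum is file-based)
textConnection_md5 <- function(s) {
  tf <- tempfile()
  writeLines(as.character(s), tf)
  tf
}

#' Read and write egg-position CSVs
#'
#' Schema: `egg_id, x_cm, y_cm, region`.
#' @param eggs data.frame from [simulate_eggs()].
#' @param path CSV path.
#' @return The data.frame (read) or `path` invisibly (write).
#' @export
write_eggs_csv <- function(eggs, path) {
  df <- eggs
  for (cn in c("x_cm", "y_cm")) df[[cn]] <- signif(df[[cn]], 9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eggs_csv
#' @export
read_eggs_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Read and write spike-time CSVs with trial metadata
#'
#' Spike CSV schema: `trial_id, spike_time_s`; the JSON sidecar holds one
#' record per trial: `trial_id, stim_onset, trial_duration, label`.
#'
#' @param trains Named list of `spike_train`s (names are trial ids).
#' @param csv_path,meta_path Output paths.
#' @return `write_spikes_csv` returns `csv_path` invisibly; `read_spikes_csv`
#'   returns the named list of `spike_train`s.
#' @export
write_spikes_csv <- function(trains, csv_path, meta_path) {
  rows <- lapply(names(trains), function(id)
    if (length(trains[[id]]$spike_times))
      data.frame(trial_id = id,
                 spike_time_s = signif(trains[[id]]$spike_times, 9))
    else NULL)
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(trial_id = character(0), spike_time_s = numeric(0))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  meta <- lapply(names(trains), function(id)
    list(trial_id = id, stim_onset = trains[[id]]$stim_onset,
         trial_duration = trains[[id]]$trial_duration,
         label = trains[[id]]$label))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(csv_path, meta_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  out <- lapply(meta, function(m) {
    st <- sort(df$spike_time_s[df$trial_id == m$trial_id])
    spike_train(st, stim_onset = m$stim_onset,
                trial_duration = m$trial_duration, label = m$label)
  })
  names(out) <- vapply(meta, `[[`, character(1), "trial_id")
  out
}

#' Read and write EAG traces
#'
#' Two-column CSV `(t_s, mV)` with a JSON sidecar `(fs, onset)`.
#' @param trace data.frame with `t_s, mV` and attributes `fs`, `onset`.
#' @param csv_path,meta_path Paths.
#' @return `read_eag_csv` returns the trace with attributes restored.
#' @export
write_eag_csv <- function(trace, csv_path, meta_path) {
  df <- data.frame(t_s = signif(trace$t_s, 9), mV = signif(trace$mV, 9))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = attr(trace, "fs"),
                            onset = attr(trace, "onset")),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_eag_csv
#' @export
read_eag_csv <- function(csv_path, meta_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  attr(df, "fs") <- meta$fs
  attr(df, "onset") <- meta$onset
  df
}

#' Write analysis results as tidy CSV and a JSON summary
#'
#' @param results data.frame (one row per trial x window x statistic).
#' @param csv_path,json_path Output paths (either may be NULL).
#' @return Invisibly, the results.
#' @export
write_results <- function(results, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- results
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 9)
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = NA)
  invisible(results)
}
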