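# Run configuration and run reports: every analysis run is described by a
# config (preset, seed, thresholds) that round-trips to YAML, and produces a
# JSON report with all materialized parameters and per-trace exclusions, so
# results are self-describing and exactly reproducible.

default_thresholds <- function() {
  list(detection_mads = 6,
       particle_mads = 5,
       ramp_window_points = 60,
       amplitude_window_s = c(5, 8),
       scission_hi = 0.5,
       scission_lo = 0.2,
       scission_max_drop_s = 1,
       max_displacement_um = 0.3,
       max_gap_frames = 1,
       msd_lags = 4,
       min_dwell_frames = 2)
}

#' Build a run configuration
#'
#' All defaults are materialized into the config so that the resulting run
#' report fully describes the analysis.
#'
#' @param preset preset name driving the run.
#' @param seed integer seed for every stochastic step.
#' @param output_dir directory for run outputs.
#' @param overrides named list overriding entries of the default thresholds.
#' @return List of class `run_config`.
#' @export
run_config <- function(preset, seed, output_dir = ".", overrides = list()) {
  thr <- default_thresholds()
  bad <- setdiff(names(overrides), names(thr))
  if (length(bad))
    stop("unknown config overrides: ", paste(bad, collapse = ", "))
  thr[names(overrides)] <- overrides
  if (is.null(seed) || !is.finite(seed))
    stop("every run must carry an explicit seed")
  structure(list(preset = preset, seed = as.integer(seed),
                 output_dir = output_dir, thresholds = thr,
                 package_version = as.character(utils::packageVersion("endotrace"))),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a [run_config()] (read); round-trips losslessly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Write a JSON run report
#'
#' @param config the [run_config()] of the run.
#' @param results named list of summary results (numbers, tables).
#' @param exclusions optional data.frame of excluded traces/events with
#'   machine-readable reasons.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(config, results, exclusions = NULL, path) {
  rep <- list(config = unclass(config), results = results,
              exclusions = exclusions)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
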