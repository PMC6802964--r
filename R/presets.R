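.preset_cache <- new.env(parent = emptyenv())

presets_file <- function() {
  system.file("extdata", "presets.json", package = "endotrace")
}

load_presets <- function() {
  if (is.null(.preset_cache$presets)) {
    .preset_cache$presets <- jsonlite::read_json(presets_file(),
                                                 simplifyVector = TRUE)
  }
  .preset_cache$presets
}

#' List shipped preset names
#'
#' Presets are named parameter sets (kinetics, cameras, binding models,
#' transients) stored as data in `inst/extdata/presets.json`. Event presets
#' are calibrated so that the analysis pipeline recovers the summary numbers
#' reported for the corresponding in vivo / in vitro experiments.
#'
#' @return Named list of character vectors of preset names by category.
#' @export
list_presets <- function() {
  p <- load_presets()
  list(events = names(p$events),
       two_color = names(p$two_color),
       cameras = names(p$cameras),
       titrations = names(p$titrations),
       transients = names(p$transients))
}

#' Retrieve an event kinetics preset
#'
#' @param name one of `list_presets()$events`.
#' @return List with `kinetics` ([event_kinetics()]), `camera`
#'   ([camera_model()]), `jitter` (event-to-event variability parameters) and
#'   `trace` (baseline padding) components.
#' @export
event_preset <- function(name) {
  p <- load_presets()
  if (!name %in% names(p$events))
    stop(sprintf("unknown event preset '%s'; available: %s", name,
                 paste(names(p$events), collapse = ", ")))
  e <- p$events[[name]]
  k <- e$kinetics
  list(name = name,
       kinetics = event_kinetics(k$rise_rate, k$peak_molecules,
                                 k$plateau_duration, k$fall_rate,
                                 k$scission_mode,
                                 scission_offset = k$scission_offset),
       camera = camera_preset(e$camera),
       jitter = e$jitter,
       trace = e$trace)
}

#' Retrieve a camera preset
#'
#' @param name one of `list_presets()$cameras`.
#' @return A [camera_model()].
#' @export
camera_preset <- function(name) {
  p <- load_presets()
  if (!name %in% names(p$cameras))
    stop(sprintf("unknown camera preset '%s'", name))
  cc <- p$cameras[[name]]
  camera_model(pixel_size = cc$pixel_size,
               frame_interval = cc$frame_interval,
               psf_sigma = cc$psf_sigma,
               single_fluorophore_intensity = cc$single_fluorophore_intensity,
               read_noise_sd = cc$read_noise_sd,
               shot_noise = cc$shot_noise,
               baseline_offset = cc$baseline_offset)
}

#' Retrieve a two-colour event preset
#'
#' @param name one of `list_presets()$two_color`.
#' @return List with channel-a and channel-b event presets plus the mean and
#'   SD of the channel-b start offset (positive: channel b starts later).
#' @export
two_color_preset <- function(name) {
  p <- load_presets()
  if (!name %in% names(p$two_color))
    stop(sprintf("unknown two-colour preset '%s'", name))
  tc <- p$two_color[[name]]
  list(name = name,
       a = event_preset(tc$channel_a),
       b = event_preset(tc$channel_b),
       offset_b = tc$offset_b,
       offset_b_sd = tc$offset_b_sd)
}

#' Retrieve the single-molecule scene preset
#'
#' @return List with [single_molecule_kinetics()], [camera_model()], field
#'   size (um) and duration (s).
#' @export
single_molecule_preset <- function() {
  p <- load_presets()
  s <- p$single_molecule
  list(kinetics = single_molecule_kinetics(s$on_rate_density, s$off_rate,
                                           s$diffusion_coefficient),
       camera = camera_preset(s$camera),
       field_um = s$field_um,
       duration_s = s$duration_s)
}

#' Retrieve a titration preset
#'
#' @param name one of `list_presets()$titrations`.
#' @return For binding titrations, a list with a
#'   [sequential_binding_model()], ligand concentrations and noise CV; for
#'   the pCa preset, the Hill model parameters, pCa grid and noise CV.
#' @export
titration_preset <- function(name) {
  p <- load_presets()
  if (!name %in% names(p$titrations))
    stop(sprintf("unknown titration preset '%s'", name))
  tp <- p$titrations[[name]]
  if (!is.null(tp$model$pCa50)) {
    list(name = name, model = tp$model, pca = tp$pca, noise_cv = tp$noise_cv)
  } else {
    m <- tp$model
    list(name = name,
         model = sequential_binding_model(m$K1, m$K2, m$dF1, m$dF2, m$F0,
                                          m$reporter_total),
         ligand_uM = tp$ligand_uM,
         noise_cv = tp$noise_cv)
  }
}

#' Retrieve a transient (stopped-flow) preset
#'
#' @param name one of `list_presets()$transients`.
#' @return List of amplitudes, rates, offset, timebase and noise SD.
#' @export
transient_preset <- function(name = "ca_release") {
  p <- load_presets()
  if (!name %in% names(p$transients))
    stop(sprintf("unknown transient preset '%s'", name))
  p$transients[[name]]
}

#' Default excitation scale between calibration and measurement illumination
#'
#' @return Scalar illumination ratio (measurement / calibration).
#' @export
default_excitation_scale <- function() {
  load_presets()$calibration$excitation_scale
}
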