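#' Endocytic event kinetics
#'
#' Parameterises the trapezoidal accumulation/disassembly of fluorophores at
#' an immobile endocytic site: a linear rise to `peak_molecules`, a plateau,
#' and a linear fall. With `scission_mode = "abrupt"` the fluorophore
#' population is removed within one frame at `scission_offset` seconds after
#' the event start, emulating vesicle scission and departure from the TIRF
#' evanescent field.
#'
#' @param rise_rate assembly rate, molecules/s (> 0).
#' @param peak_molecules plateau copy number (> 0).
#' @param plateau_duration plateau length, s (>= 0).
#' @param fall_rate disassembly rate, molecules/s (> 0).
#' @param scission_mode `"none"` or `"abrupt"`.
#' @param scission_offset time of abrupt scission relative to the event
#'   start, s; required when `scission_mode = "abrupt"`.
#' @return An object of class `event_kinetics`.
#' @export
event_kinetics <- function(rise_rate, peak_molecules, plateau_duration,
                           fall_rate, scission_mode = c("none", "abrupt"),
                           scission_offset = NULL) {
  scission_mode <- match.arg(scission_mode)
  stopifnot(is.numeric(rise_rate), is.numeric(peak_molecules),
            is.numeric(plateau_duration), is.numeric(fall_rate))
  if (!is.finite(rise_rate) || rise_rate <= 0)
    stop("`rise_rate` must be a positive finite rate (molecules/s)")
  if (!is.finite(fall_rate) || fall_rate <= 0)
    stop("`fall_rate` must be a positive finite rate (molecules/s)")
  if (!is.finite(peak_molecules) || peak_molecules <= 0)
    stop("`peak_molecules` must be > 0")
  if (!is.finite(plateau_duration) || plateau_duration < 0)
    stop("`plateau_duration` must be >= 0")
  if (scission_mode == "abrupt") {
    if (is.null(scission_offset) || !is.finite(scission_offset) ||
        scission_offset <= 0)
      stop("abrupt scission requires a positive `scission_offset`")
  }
  structure(list(rise_rate = rise_rate,
                 peak_molecules = peak_molecules,
                 plateau_duration = plateau_duration,
                 fall_rate = fall_rate,
                 scission_mode = scission_mode,
                 scission_offset = scission_offset),
            class = "event_kinetics")
}

#' Total duration of a noiseless event
#'
#' Closed-form phase sum `peak/rise + plateau + peak/fall`, truncated at the
#' scission time for abrupt-scission kinetics.
#'
#' @param kinetics an [event_kinetics()] object.
#' @return Duration in seconds.
#' @export
event_duration <- function(kinetics) {
  full <- kinetics$peak_molecules / kinetics$rise_rate +
    kinetics$plateau_duration +
    kinetics$peak_molecules / kinetics$fall_rate
  if (identical(kinetics$scission_mode, "abrupt"))
    min(full, kinetics$scission_offset) else full
}

#' Camera and optics model
#'
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval s per frame (> 0).
#' @param psf_sigma isotropic Gaussian PSF sigma, um (>= pixel_size/2).
#' @param single_fluorophore_intensity mean integrated counts per fluorophore
#'   per frame, AU (> 0), at the illumination used for this movie.
#' @param read_noise_sd additive Gaussian read noise per pixel, AU.
#' @param shot_noise logical; Poisson shot noise on expected counts.
#' @param baseline_offset camera offset per pixel, AU.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pixel_size = 0.1, frame_interval = 0.05,
                         psf_sigma = 0.09,
                         single_fluorophore_intensity = 52.7333333,
                         read_noise_sd = 2, shot_noise = TRUE,
                         baseline_offset = 20) {
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be > 0")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be > 0")
  if (!is.finite(psf_sigma) || psf_sigma < pixel_size / 2)
    stop("`psf_sigma` must be >= pixel_size/2")
  if (!is.finite(single_fluorophore_intensity) ||
      single_fluorophore_intensity <= 0)
    stop("`single_fluorophore_intensity` must be > 0")
  if (read_noise_sd < 0) stop("`read_noise_sd` must be >= 0")
  structure(list(pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 psf_sigma = psf_sigma,
                 single_fluorophore_intensity = single_fluorophore_intensity,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 baseline_offset = baseline_offset),
            class = "camera_model")
}

#' Single-molecule membrane-binding kinetics
#'
#' @param on_rate_density Poisson arrival density of membrane-binding events,
#'   events/um^2/s.
#' @param off_rate exponential detachment rate, 1/s (> 0).
#' @param diffusion_coefficient lateral diffusion coefficient, um^2/s (>= 0).
#' @return An object of class `single_molecule_kinetics`.
#' @export
single_molecule_kinetics <- function(on_rate_density, off_rate,
                                     diffusion_coefficient) {
  if (!is.finite(on_rate_density) || on_rate_density < 0)
    stop("`on_rate_density` must be >= 0")
  if (!is.finite(off_rate) || off_rate <= 0)
    stop("`off_rate` must be > 0")
  if (!is.finite(diffusion_coefficient) || diffusion_coefficient < 0)
    stop("`diffusion_coefficient` must be >= 0")
  structure(list(on_rate_density = on_rate_density, off_rate = off_rate,
                 diffusion_coefficient = diffusion_coefficient),
            class = "single_molecule_kinetics")
}

#' Background-corrected intensity trace
#'
#' @param time sample times, s (uniform spacing).
#' @param intensity background-corrected intensity, AU.
#' @param frame_interval s per frame.
#' @param channel optional channel label.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(time, intensity, frame_interval,
                            channel = NA_character_) {
  if (length(time) != length(intensity))
    stop("`time` and `intensity` must have the same length")
  if (length(time) < 2) stop("a trace needs at least two samples")
  if (!all(is.finite(intensity))) stop("trace intensities must be finite")
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 frame_interval = frame_interval, channel = channel),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d frames @ %.4g s/frame, range [%.4g, %.4g] AU\n",
              length(x$time), x$frame_interval,
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Single-fluorophore intensity calibration
#'
#' Converts measured amplitudes (AU) into fluorophore counts. Calibration
#' movies are typically acquired at full laser power while endocytosis movies
#' use attenuated illumination; `excitation_scale` is the measurement/
#' calibration illumination ratio (default 0.2 for 20% laser power, assuming
#' linear excitation).
#'
#' @param single_fluorophore_intensity AU per molecule per frame at the
#'   calibration illumination (> 0).
#' @param excitation_scale illumination ratio (> 0).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(single_fluorophore_intensity,
                              excitation_scale = 1) {
  if (!is.finite(single_fluorophore_intensity) ||
      single_fluorophore_intensity <= 0)
    stop("`single_fluorophore_intensity` must be > 0")
  if (!is.finite(excitation_scale) || excitation_scale <= 0)
    stop("`excitation_scale` must be > 0")
  structure(list(single_fluorophore_intensity = single_fluorophore_intensity,
                 excitation_scale = excitation_scale),
            class = "calibration_model")
}

#' TIRF movie container
#'
#' @param frames numeric array `[row, col, frame]` of pixel intensities (AU).
#' @param pixel_size um per pixel.
#' @param frame_interval s per frame.
#' @param channel optional channel label.
#' @return An object of class `tirf_movie`.
#' @export
tirf_movie <- function(frames, pixel_size, frame_interval,
                       channel = NA_character_) {
  if (length(dim(frames)) != 3) stop("`frames` must be a 3D array")
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("`pixel_size` and `frame_interval` must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, channel = channel),
            class = "tirf_movie")
}

#' @export
print.tirf_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<tirf_movie> %dx%d px, %d frames, %.3g um/px, %.4g s/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}
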