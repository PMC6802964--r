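# Event quantification: background correction, maximum-gradient ramp
# fitting, zero-intercept event timing, plateau amplitude, abrupt-scission
# detection, synchronized averaging, and molecule-count conversion.

#' Background-correct a raw ROI trace
#'
#' Subtracts the per-pixel background (mean over the 1.5-um region excluding
#' the core) scaled by the number of core pixels from the core sum, so a
#' no-event trace has baseline ~0.
#'
#' @param core per-frame core sums, AU.
#' @param background per-frame background means per pixel, AU.
#' @param core_pixel_count number of pixels summed in the core (default 25).
#' @param frame_interval s per frame.
#' @param channel optional label.
#' @return An [intensity_trace()].
#' @export
correct_background <- function(core, background, core_pixel_count = 25,
                               frame_interval, channel = NA_character_) {
  if (is.list(core) && !is.null(core$core)) {
    roi <- core
    if (missing(frame_interval)) frame_interval <- roi$frame_interval
    background <- roi$background
    core_pixel_count <- roi$n_core_px
    core <- roi$core
  }
  if (length(core) != length(background))
    stop("core and background traces must have the same length")
  if (!length(background) || all(!is.finite(background)))
    stop("background trace is empty; trace uncorrectable")
  intensity_trace((seq_along(core) - 1) * frame_interval,
                  core - core_pixel_count * background,
                  frame_interval, channel)
}

#' Maximum-gradient linear ramp fit
#'
#' Fits a least-squares line in every contiguous window of `window_points`
#' samples (stride 1) and returns the window with the maximum slope
#' (`direction = "rising"`) or minimum slope (`"falling"`); ties are broken
#' by the earliest window.
#'
#' @param trace an [intensity_trace()].
#' @param window_points window length in samples (default 60; 3 s at 20 fps).
#' @param direction `"rising"` or `"falling"`.
#' @return List with `slope` (AU/s), `intercept` (AU at t = 0),
#'   `window_start` (index), `window_time` (s) and `r_squared`.
#' @export
fit_ramp <- function(trace, window_points = 60,
                     direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  y <- trace$intensity; t <- trace$time
  n <- length(y); w <- window_points
  if (n < w) stop(sprintf("trace too short (%d) for a %d-point window", n, w))
  cy <- c(0, cumsum(y)); ct <- c(0, cumsum(t))
  cty <- c(0, cumsum(t * y)); ct2 <- c(0, cumsum(t * t))
  cy2 <- c(0, cumsum(y * y))
  j <- seq_len(n - w + 1)
  Sy <- cy[j + w] - cy[j]; St <- ct[j + w] - ct[j]
  Sty <- cty[j + w] - cty[j]; St2 <- ct2[j + w] - ct2[j]
  Sy2 <- cy2[j + w] - cy2[j]
  sxx <- St2 - St * St / w
  sxy <- Sty - St * Sy / w
  syy <- Sy2 - Sy * Sy / w
  slope <- sxy / sxx
  # ties (within numerical noise) break to the earliest window
  if (direction == "rising") {
    mx <- max(slope)
    best <- which(slope >= mx - 1e-9 * max(abs(mx), 1))[1]
  } else {
    mn <- min(slope)
    best <- which(slope <= mn + 1e-9 * max(abs(mn), 1))[1]
  }
  r2 <- if (syy[best] > 0) (sxy[best]^2) / (sxx[best] * syy[best]) else NA_real_
  list(slope = slope[best],
       intercept = (Sy[best] - slope[best] * St[best]) / w,
       window_start = best, window_time = t[best],
       r_squared = r2)
}

#' Detect abrupt vesicle scission in a trace
#'
#' Scission is the first transition where the (3-point median filtered)
#' intensity falls from above `hi` x plateau to below `lo` x plateau within
#' `max_drop_s` seconds; a gradual decay produces no scission time.
#'
#' @param trace an [intensity_trace()].
#' @param plateau plateau amplitude, AU (> 0).
#' @param hi,lo fractional thresholds (defaults 0.5 and 0.2).
#' @param max_drop_s maximum duration of the drop, s (default 1).
#' @return Scission time in seconds, or `NA_real_` when absent.
#' @export
detect_scission <- function(trace, plateau, hi = 0.5, lo = 0.2,
                            max_drop_s = 1) {
  if (!is.finite(plateau) || plateau <= 0) stop("`plateau` must be > 0")
  y <- runmed(trace$intensity, 3)
  n <- length(y)
  K <- max(1, floor(max_drop_s / trace$frame_interval))
  above <- which(y > hi * plateau)
  for (i in above) {
    jmax <- min(n, i + K)
    if (jmax <= i) next
    j <- which(y[(i + 1):jmax] < lo * plateau)
    if (length(j)) return(trace$time[i + j[1]])
  }
  NA_real_
}

# centred boxcar mean with full windows only
smooth_boxcar <- function(y, w) {
  if (w <= 1) return(y)
  as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
}

#' Measure one endocytic event from a background-corrected trace
#'
#' The rising and falling phases are fitted with 60-point maximum-gradient
#' lines ([fit_ramp()]); the intercepts of those lines with the baseline
#' (zero after background correction) give `t_start` and `t_end`, and
#' `t_dur = t_end - t_start`. The amplitude `a_av` is the mean intensity
#' from the 5th to the 8th second after `t_start` (60 points at 20 fps,
#' half-open window, truncated with a flag for short traces). `a_peak` is
#' the maximum of the 1-s boxcar-smoothed trace — a plateau estimate that is
#' robust for events whose plateau does not span the fixed a_av window — and
#' is used for molecule counting and scission detection.
#'
#' The ramp-fit window defaults to the fixed 60 points; with
#' `adaptive_window = TRUE` (default) a ramp that is briefer than the window
#' is refitted with a window matched to its estimated duration (from the
#' 10-90% crossing times), since a zero-intercept from a line fitted mostly
#' to baseline and plateau would be biased. Events whose ramps last at least
#' the window duration are unaffected.
#'
#' @param trace an [intensity_trace()].
#' @param window_points ramp-fit window (default 60).
#' @param amplitude_window seconds after `t_start` over which `a_av` is
#'   averaged (default `c(5, 8)`).
#' @param peak_smooth_s boxcar width for the plateau estimate, s.
#' @param baseline baseline intensity for the intercepts (default 0).
#' @param calibration optional [calibration_model()]; adds `molecules_peak`.
#' @param adaptive_window shrink the ramp window for ramps briefer than it.
#' @return List of class `event_measurement`: `t_start`, `t_end`, `t_dur`,
#'   `a_av`, `a_peak`, `rise_gradient`, `fall_gradient`, `t_scis`,
#'   `molecules_peak`, fit diagnostics and flags.
#' @export
measure_event <- function(trace, window_points = 60,
                          amplitude_window = c(5, 8), peak_smooth_s = 1,
                          baseline = 0, calibration = NULL,
                          adaptive_window = TRUE) {
  dt <- trace$frame_interval
  w_peak <- max(1, round(peak_smooth_s / dt))
  smoothed <- smooth_boxcar(trace$intensity, w_peak)
  a_peak <- max(smoothed, na.rm = TRUE) - baseline
  w_rise <- w_fall <- window_points
  if (adaptive_window && a_peak > 0) {
    med <- runmed(trace$intensity, 5) - baseline
    hi <- which(med >= 0.9 * a_peak)
    lo <- which(med >= 0.1 * a_peak)
    if (length(hi) && length(lo)) {
      wr <- round((trace$time[hi[1]] - trace$time[lo[1]]) / 0.8 / dt)
      wf <- round((trace$time[lo[length(lo)]] -
                     trace$time[hi[length(hi)]]) / 0.8 / dt)
      w_rise <- max(10, min(window_points, wr))
      w_fall <- max(10, min(window_points, wf))
    }
  }
  rise <- fit_ramp(trace, w_rise, "rising")
  fall <- fit_ramp(trace, w_fall, "falling")
  if (!is.finite(rise$slope) || rise$slope <= 0)
    stop("malformed event: no rising phase found")
  if (!is.finite(fall$slope) || fall$slope >= 0)
    stop("malformed event: no falling phase found")
  t_start <- (baseline - rise$intercept) / rise$slope
  t_end <- (baseline - fall$intercept) / fall$slope
  if (t_end <= t_start)
    stop("malformed event: falling intercept precedes rising intercept")
  # a_av over [t_start + 5, t_start + 8), truncated at the trace end
  lo <- t_start + amplitude_window[1]
  hi <- t_start + amplitude_window[2]
  in_win <- trace$time >= lo & trace$time < hi
  truncated <- hi > max(trace$time) + dt / 2
  a_av <- if (any(in_win)) mean(trace$intensity[in_win]) - baseline
          else NA_real_
  t_scis <- if (a_peak > 0)
    detect_scission(trace, plateau = a_peak) else NA_real_
  out <- list(t_start = t_start, t_end = t_end, t_dur = t_end - t_start,
              a_av = a_av, a_peak = a_peak,
              rise_gradient = rise$slope, fall_gradient = fall$slope,
              t_scis = t_scis,
              molecules_peak = if (is.null(calibration)) NA_real_
                               else to_molecules(a_peak, calibration),
              rise_r2 = rise$r_squared, fall_r2 = fall$r_squared,
              rise_window_time = rise$window_time,
              fall_window_time = fall$window_time,
              a_av_truncated = truncated)
  class(out) <- "event_measurement"
  out
}

#' Measure a list of traces, collecting results in a table
#'
#' Traces for which [measure_event()] fails (malformed events) are excluded
#' and reported in the `excluded` attribute.
#'
#' @param traces list of [intensity_trace()].
#' @param ... passed to [measure_event()].
#' @return data.frame, one row per successfully measured trace, with a
#'   `trace_id` column; excluded ids and reasons in `attr(, "excluded")`.
#' @export
measure_events <- function(traces, ...) {
  rows <- vector("list", length(traces))
  excl <- list()
  for (i in seq_along(traces)) {
    m <- tryCatch(measure_event(traces[[i]], ...), error = function(e) e)
    if (inherits(m, "error")) {
      excl[[length(excl) + 1]] <- data.frame(trace_id = i,
                                             reason = conditionMessage(m))
    } else {
      rows[[i]] <- data.frame(trace_id = i, t_start = m$t_start,
                              t_end = m$t_end, t_dur = m$t_dur,
                              a_av = m$a_av, a_peak = m$a_peak,
                              rise_gradient = m$rise_gradient,
                              fall_gradient = m$fall_gradient,
                              t_scis = m$t_scis,
                              molecules_peak = m$molecules_peak,
                              a_av_truncated = m$a_av_truncated)
    }
  }
  keep <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(keep)) do.call(rbind, keep) else
    data.frame(trace_id = integer(), t_start = numeric(), t_end = numeric(),
               t_dur = numeric(), a_av = numeric(), a_peak = numeric(),
               rise_gradient = numeric(), fall_gradient = numeric(),
               t_scis = numeric(), molecules_peak = numeric(),
               a_av_truncated = logical())
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else NULL
  out
}

#' Synchronize traces on an anchor and average them
#'
#' Shifts each trace so that its anchor (e.g. measured `t_start` or `t_end`,
#' or an externally supplied time such as the partner-channel `t_start` for
#' Cam2) aligns at t = 0, resamples on a common frame-interval grid by
#' nearest-frame alignment (no interpolation), and averages pointwise.
#'
#' @param traces list of [intensity_trace()] (>= 2).
#' @param anchors numeric vector of anchor times, one per trace; traces with
#'   missing anchors are excluded and reported.
#' @param mean_t_dur optional mean event duration to record on the profile.
#' @return data.frame of class `averaged_profile` with `time_s` (relative to
#'   the anchor), `mean_au`, `sem_au`, `n`; excluded trace ids in
#'   `attr(, "excluded")`, `mean_t_dur` in `attr(, "mean_t_dur")`.
#' @export
synchronize_and_average <- function(traces, anchors, mean_t_dur = NULL) {
  if (length(traces) < 2) stop("need at least 2 traces to average")
  if (length(anchors) != length(traces))
    stop("one anchor per trace required")
  ok <- is.finite(anchors)
  excluded <- which(!ok)
  traces <- traces[ok]; anchors <- anchors[ok]
  if (length(traces) < 2) stop("fewer than 2 traces have usable anchors")
  dt <- traces[[1]]$frame_interval
  rel <- lapply(seq_along(traces), function(i)
    round((traces[[i]]$time - anchors[i]) / dt))
  kmin <- min(vapply(rel, min, numeric(1)))
  kmax <- max(vapply(rel, max, numeric(1)))
  nk <- kmax - kmin + 1
  s1 <- numeric(nk); s2 <- numeric(nk); nn <- integer(nk)
  for (i in seq_along(traces)) {
    idx <- rel[[i]] - kmin + 1
    y <- traces[[i]]$intensity
    s1[idx] <- s1[idx] + y
    s2[idx] <- s2[idx] + y^2
    nn[idx] <- nn[idx] + 1L
  }
  keep <- nn >= 1
  mu <- s1[keep] / nn[keep]
  vv <- pmax(s2[keep] / nn[keep] - mu^2, 0) * nn[keep] / pmax(nn[keep] - 1, 1)
  out <- data.frame(time_s = (seq_len(nk)[keep] + kmin - 1) * dt,
                    mean_au = mu,
                    sem_au = ifelse(nn[keep] > 1, sqrt(vv / nn[keep]),
                                    NA_real_),
                    n = nn[keep])
  class(out) <- c("averaged_profile", "data.frame")
  attr(out, "excluded") <- excluded
  attr(out, "mean_t_dur") <- mean_t_dur
  out
}

#' Convert an amplitude to a fluorophore count
#'
#' `count = amplitude / (single_fluorophore_intensity * excitation_scale)`;
#' returned as a real number (rounding is left to callers).
#'
#' @param amplitude AU.
#' @param calibration a [calibration_model()].
#' @return Estimated number of fluorophores.
#' @export
to_molecules <- function(amplitude, calibration) {
  stopifnot(inherits(calibration, "calibration_model"))
  amplitude / (calibration$single_fluorophore_intensity *
                 calibration$excitation_scale)
}

#' Estimate the single-fluorophore intensity from single-molecule tracks
#'
#' Robust mean (median over tracks of the per-track mean spot intensity),
#' insensitive to the occasional mislinked or overlapping track.
#'
#' @param tracks data.frame with `track_id` and `intensity_au` columns (as
#'   from [track_movie()]).
#' @param excitation_scale illumination ratio between measurement and
#'   calibration movies (see [calibration_model()]).
#' @param min_frames minimum track length in frames for inclusion.
#' @param min_tracks minimum number of qualifying tracks (default 20).
#' @return A [calibration_model()].
#' @export
estimate_single_fluorophore_intensity <- function(tracks,
                                                  excitation_scale = 1,
                                                  min_frames = 3,
                                                  min_tracks = 20) {
  if (!all(c("track_id", "intensity_au") %in% names(tracks)))
    stop("`tracks` must have track_id and intensity_au columns")
  len <- table(tracks$track_id)
  keep <- names(len)[len >= min_frames]
  if (length(keep) < min_tracks)
    stop(sprintf("only %d tracks with >= %d frames; need >= %d",
                 length(keep), min_frames, min_tracks))
  sub <- tracks[tracks$track_id %in% keep, ]
  per_track <- tapply(sub$intensity_au, sub$track_id, mean)
  calibration_model(median(per_track), excitation_scale)
}

#' Analyze an endocytosis movie end to end
#'
#' Standard-deviation projection, site detection, ROI trace extraction,
#' background correction and per-event measurement. Overlap- or edge-flagged
#' sites are dropped (the automated counterpart of manual exclusion of
#' contaminated events); malformed traces are excluded with reasons.
#'
#' @param movie a [tirf_movie()].
#' @param calibration optional [calibration_model()] for molecule counts.
#' @param threshold_mads detection threshold (see [detect_event_sites()]).
#' @param drop_flagged drop overlap/edge-flagged ROIs (default TRUE).
#' @param ... passed to [measure_event()].
#' @return List with `sites` (detection table), `measurements` (data.frame
#'   as [measure_events()]) and `traces` (the corrected traces).
#' @export
analyze_event_movie <- function(movie, calibration = NULL,
                                threshold_mads = 6, drop_flagged = TRUE,
                                ...) {
  proj <- std_projection(movie)
  sites <- detect_event_sites(proj, threshold_mads = threshold_mads,
                              pixel_size = movie$pixel_size)
  use <- if (drop_flagged) sites[!sites$overlap & !sites$edge, ] else sites
  traces <- lapply(seq_len(nrow(use)), function(i) {
    roi <- extract_roi_trace(movie, use$x_px[i], use$y_px[i])
    correct_background(roi)
  })
  meas <- measure_events(traces, calibration = calibration, ...)
  list(sites = sites, measurements = meas, traces = traces)
}
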