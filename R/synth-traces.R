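# Synthetic background-corrected intensity traces with exported ground truth.

# Symmetric truncated normal (+/- trunc SDs). Symmetric truncation keeps the
# mean exactly at `mean`, so jittered cohorts are unbiased by construction.
rtnorm_sym <- function(n, mean = 0, sd = 1, trunc = 1.7) {
  lo <- pnorm(-trunc)
  mean + sd * qnorm(runif(n, lo, 1 - lo))
}

# Expected molecule count at times `t_rel` (s, relative to event start).
molecules_at <- function(t_rel, kinetics) {
  k <- kinetics
  t_rise <- k$peak_molecules / k$rise_rate
  t_fall <- k$peak_molecules / k$fall_rate
  m <- numeric(length(t_rel))
  i <- t_rel >= 0 & t_rel < t_rise
  m[i] <- k$rise_rate * t_rel[i]
  i <- t_rel >= t_rise & t_rel < t_rise + k$plateau_duration
  m[i] <- k$peak_molecules
  i <- t_rel >= t_rise + k$plateau_duration
  m[i] <- pmax(k$peak_molecules -
                 k$fall_rate * (t_rel[i] - t_rise - k$plateau_duration), 0)
  if (identical(k$scission_mode, "abrupt"))
    m[t_rel >= k$scission_offset] <- 0
  m
}

# Core-summed noise for a 5x5 ROI after background correction: Poisson shot
# noise on (signal + background counts) recentred, plus Gaussian read noise
# summed over the core pixels.
add_trace_noise <- function(expected, camera, core_px = 25) {
  bg <- core_px * camera$baseline_offset
  y <- expected
  if (camera$shot_noise)
    y <- rpois(length(expected), lambda = pmax(expected + bg, 0)) - bg
  if (camera$read_noise_sd > 0)
    y <- y + rnorm(length(expected), 0, camera$read_noise_sd * sqrt(core_px))
  y
}

#' Simulate one background-corrected endocytic event trace
#'
#' Samples the trapezoidal (or scission-truncated) molecule count at the
#' camera frame rate, scales by the single-fluorophore intensity, and adds
#' per-frame shot and read noise appropriate to a background-corrected 5x5
#' ROI sum. The returned ground truth records the true event timings.
#'
#' @param kinetics an [event_kinetics()].
#' @param camera a [camera_model()].
#' @param seed optional integer seed (omit to continue the current RNG
#'   stream).
#' @param pre_pad_s,post_pad_s baseline padding before the event start and
#'   after the event end, s.
#' @param start_time event start relative to trace start, s (default
#'   `pre_pad_s`).
#' @param noise logical; set `FALSE` for a noiseless trace regardless of the
#'   camera noise settings.
#' @return List with `trace` ([intensity_trace()]) and `truth` (list of
#'   `t_start`, `t_end`, `t_scis`, `duration`, `peak_molecules`,
#'   `rise_rate`, `fall_rate`).
#' @export
generate_event_trace <- function(kinetics, camera, seed = NULL,
                                 pre_pad_s = 4, post_pad_s = 5,
                                 start_time = pre_pad_s, noise = TRUE) {
  stopifnot(inherits(kinetics, "event_kinetics"),
            inherits(camera, "camera_model"))
  if (!is.null(seed)) set.seed(seed)
  dur <- event_duration(kinetics)
  total <- start_time + dur + post_pad_s
  dt <- camera$frame_interval
  n <- ceiling(total / dt)
  if (n < 2) stop("trace would have fewer than 2 frames; enlarge padding")
  tt <- (seq_len(n) - 1) * dt
  m <- molecules_at(tt - start_time, kinetics)
  expected <- m * camera$single_fluorophore_intensity
  y <- if (noise) add_trace_noise(expected, camera) else expected
  t_scis <- if (identical(kinetics$scission_mode, "abrupt"))
    start_time + kinetics$scission_offset else NA_real_
  list(trace = intensity_trace(tt, y, dt),
       truth = list(t_start = start_time,
                    t_end = start_time + dur,
                    t_scis = t_scis,
                    duration = dur,
                    peak_molecules = kinetics$peak_molecules,
                    rise_rate = kinetics$rise_rate,
                    fall_rate = kinetics$fall_rate))
}

# Scale an event's phase durations by `s` (peak optionally rescaled by `pf`):
# rates change, the trapezoid shape is preserved, total duration scales by s.
scale_kinetics <- function(kinetics, s, pf = 1) {
  k <- kinetics
  t_rise <- k$peak_molecules / k$rise_rate * s
  t_fall <- k$peak_molecules / k$fall_rate * s
  peak <- k$peak_molecules * pf
  event_kinetics(rise_rate = peak / t_rise,
                 peak_molecules = peak,
                 plateau_duration = k$plateau_duration * s,
                 fall_rate = peak / t_fall,
                 scission_mode = k$scission_mode,
                 scission_offset = if (is.null(k$scission_offset)) NULL
                                   else k$scission_offset * s)
}

#' Simulate a cohort of endocytic event traces from a preset
#'
#' Event-to-event variability follows the preset's jitter parameters: phase
#' durations are scaled by a symmetric truncated-normal factor
#' (`duration_cv`), peak copy number by an independent factor (`peak_cv`),
#' and the event start is jittered (`start_sd`). All traces share a common
#' length so they can be stacked for synchronized averaging.
#'
#' @param preset an event preset name (see [list_presets()]) or the list
#'   returned by [event_preset()].
#' @param n number of traces.
#' @param seed integer seed.
#' @param noise logical; disable all noise and jitter for oracle checks.
#' @return List with `traces` (list of [intensity_trace()]), `truth`
#'   (data.frame, one row per trace) and `camera`.
#' @export
generate_event_cohort <- function(preset = "myo1", n, seed = NULL,
                                  noise = TRUE) {
  if (is.character(preset)) preset <- event_preset(preset)
  if (!is.null(seed)) set.seed(seed)
  jit <- preset$jitter
  if (noise) {
    s <- rtnorm_sym(n, 1, jit$duration_cv)
    pf <- rtnorm_sym(n, 1, jit$peak_cv)
    st <- rtnorm_sym(n, 0, jit$start_sd)
  } else {
    s <- rep(1, n); pf <- rep(1, n); st <- rep(0, n)
  }
  base_dur <- event_duration(preset$kinetics)
  max_dur <- base_dur * (1 + 1.7 * jit$duration_cv) + 1.7 * jit$start_sd
  total <- preset$trace$pre_pad_s + max_dur + preset$trace$post_pad_s
  dt <- preset$camera$frame_interval
  n_frames <- ceiling(total / dt)
  tt <- (seq_len(n_frames) - 1) * dt
  traces <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ki <- scale_kinetics(preset$kinetics, s[i], pf[i])
    t0 <- preset$trace$pre_pad_s + st[i]
    m <- molecules_at(tt - t0, ki)
    expected <- m * preset$camera$single_fluorophore_intensity
    y <- if (noise) add_trace_noise(expected, preset$camera) else expected
    traces[[i]] <- intensity_trace(tt, y, dt)
    dur <- event_duration(ki)
    truth[[i]] <- data.frame(
      event_id = i, t_start = t0, t_end = t0 + dur,
      t_scis = if (identical(ki$scission_mode, "abrupt"))
        t0 + ki$scission_offset else NA_real_,
      duration = dur, peak_molecules = ki$peak_molecules,
      rise_rate = ki$rise_rate, fall_rate = ki$fall_rate)
  }
  list(traces = traces, truth = do.call(rbind, truth),
       camera = preset$camera)
}

#' Simulate a two-colour endocytic event (one site, two channels)
#'
#' Channel b shares the site with channel a; its event start is shifted by
#' `offset_b` seconds (positive: channel b starts later). Presets cover the
#' Myo1/Cam1 pairing (simultaneous start, Cam1 ends ~3 s earlier) and the
#' Cam1/Cam2 pairing (late Cam2 start, abrupt Cam2 scission).
#'
#' @param kinetics_a,kinetics_b [event_kinetics()] for the two channels.
#' @param offset_b channel-b start minus channel-a start, s.
#' @param camera shared [camera_model()].
#' @param seed optional integer seed.
#' @param pre_pad_s,post_pad_s baseline padding, s.
#' @param noise logical.
#' @return List with `a`, `b` ([intensity_trace()]) and `truth` (timings of
#'   both channels on the common clock).
#' @export
generate_two_color_event <- function(kinetics_a, kinetics_b, offset_b,
                                     camera, seed = NULL, pre_pad_s = 4,
                                     post_pad_s = 5, noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  t0a <- pre_pad_s
  t0b <- pre_pad_s + offset_b
  if (t0b < 0) stop("`offset_b` places channel b before the trace start")
  end_a <- t0a + event_duration(kinetics_a)
  end_b <- t0b + event_duration(kinetics_b)
  total <- max(end_a, end_b) + post_pad_s
  dt <- camera$frame_interval
  tt <- (seq_len(ceiling(total / dt)) - 1) * dt
  make <- function(kin, t0) {
    expected <- molecules_at(tt - t0, kin) * camera$single_fluorophore_intensity
    y <- if (noise) add_trace_noise(expected, camera) else expected
    intensity_trace(tt, y, dt)
  }
  scis_b <- if (identical(kinetics_b$scission_mode, "abrupt"))
    t0b + kinetics_b$scission_offset else NA_real_
  scis_a <- if (identical(kinetics_a$scission_mode, "abrupt"))
    t0a + kinetics_a$scission_offset else NA_real_
  list(a = make(kinetics_a, t0a), b = make(kinetics_b, t0b),
       truth = list(t_start_a = t0a, t_end_a = end_a, t_scis_a = scis_a,
                    t_start_b = t0b, t_end_b = end_b, t_scis_b = scis_b,
                    offset_b = offset_b))
}

#' Simulate a cohort of two-colour event pairs from a preset
#'
#' Per-pair jitter scales each channel's phase durations independently and
#' jitters the channel-b start offset (all symmetric truncated normal, hence
#' unbiased means).
#'
#' @param preset a two-colour preset name or [two_color_preset()] list.
#' @param n number of pairs.
#' @param seed integer seed.
#' @param noise logical.
#' @return List with `pairs` (list as from [generate_two_color_event()]) and
#'   `truth` data.frame.
#' @export
generate_two_color_cohort <- function(preset = "cam1_cam2", n, seed = NULL,
                                      noise = TRUE) {
  if (is.character(preset)) preset <- two_color_preset(preset)
  if (!is.null(seed)) set.seed(seed)
  camera <- preset$a$camera
  pairs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    if (noise) {
      sa <- rtnorm_sym(1, 1, preset$a$jitter$duration_cv)
      sb <- rtnorm_sym(1, 1, preset$b$jitter$duration_cv)
      off <- preset$offset_b + rtnorm_sym(1, 0, preset$offset_b_sd)
    } else {
      sa <- sb <- 1
      off <- preset$offset_b
    }
    ka <- scale_kinetics(preset$a$kinetics, sa)
    kb <- scale_kinetics(preset$b$kinetics, sb)
    pairs[[i]] <- generate_two_color_event(
      ka, kb, off, camera,
      pre_pad_s = preset$a$trace$pre_pad_s,
      post_pad_s = max(preset$a$trace$post_pad_s, preset$b$trace$post_pad_s),
      noise = noise)
    truth[[i]] <- data.frame(pair_id = i,
                             as.data.frame(pairs[[i]]$truth))
  }
  list(pairs = pairs, truth = do.call(rbind, truth), camera = camera)
}
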