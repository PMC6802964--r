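# Rendering of synthetic TIRF movies: immobile endocytic sites plus
# transiently bound, diffusing single molecules, as pixel-integrated 2D
# Gaussian PSFs with Poisson shot noise and Gaussian read noise.

# Pixel-integrated Gaussian weights along one axis. Pixel j (0-based) covers
# [j*ps, (j+1)*ps) um; `center_um` is the emitter position.
psf_weights_1d <- function(idx, center_um, pixel_size, sigma_um) {
  pnorm(((idx + 1) * pixel_size - center_um) / sigma_um) -
    pnorm((idx * pixel_size - center_um) / sigma_um)
}

# Add `flux` AU at (x_um, y_um) to matrix `frame` (rows = y). Returns frame.
render_spot <- function(frame, x_um, y_um, flux, pixel_size, sigma_um,
                        half_width_px = NULL) {
  if (is.null(half_width_px))
    half_width_px <- ceiling(4 * sigma_um / pixel_size)
  nx <- ncol(frame); ny <- nrow(frame)
  cx <- floor(x_um / pixel_size); cy <- floor(y_um / pixel_size)
  jx <- max(0, cx - half_width_px):min(nx - 1, cx + half_width_px)
  jy <- max(0, cy - half_width_px):min(ny - 1, cy + half_width_px)
  if (!length(jx) || !length(jy)) return(frame)
  wx <- psf_weights_1d(jx, x_um, pixel_size, sigma_um)
  wy <- psf_weights_1d(jy, y_um, pixel_size, sigma_um)
  frame[jy + 1, jx + 1] <- frame[jy + 1, jx + 1] + flux * outer(wy, wx)
  frame
}

#' Simulate a TIRF movie of endocytic events and single molecules
#'
#' Endocytic sites are immobile; each site's fluorophore count follows its
#' [event_kinetics()]. Single molecules appear as a spatial Poisson process,
#' diffuse with coefficient D and detach with exponential dwell times.
#' Every fluorophore population is rendered as a pixel-integrated isotropic
#' 2D Gaussian PSF; the camera adds a constant baseline, Poisson shot noise
#' on expected counts and Gaussian read noise. Frames are sampled at frame
#' midpoints.
#'
#' @param events list of events, each a list with `x_um`, `y_um`, `t_start`
#'   and `kinetics` ([event_kinetics()]); may be empty.
#' @param singles a [single_molecule_kinetics()] or `NULL`.
#' @param camera a [camera_model()].
#' @param field_um field edge length, um (square field).
#' @param duration_s movie duration, s.
#' @param seed optional integer seed.
#' @param noise logical; `FALSE` renders the noiseless expectation.
#' @return List with `movie` ([tirf_movie()]) and `truth`: `events`
#'   (data.frame with timings, positions and an overlap flag for sites whose
#'   1.5-um background regions touch), `tracks` (per-frame true single-
#'   molecule coordinates) and `dwells` (true dwell times).
#' @export
generate_movie <- function(events = list(), singles = NULL, camera,
                           field_um, duration_s, seed = NULL, noise = TRUE) {
  stopifnot(inherits(camera, "camera_model"))
  if (!is.null(seed)) set.seed(seed)
  ps <- camera$pixel_size
  dt <- camera$frame_interval
  npx <- round(field_um / ps)
  nt <- ceiling(duration_s / dt)
  t_frames <- (seq_len(nt) - 0.5) * dt
  for (ev in events) {
    if (ev$x_um < 0 || ev$x_um > field_um || ev$y_um < 0 || ev$y_um > field_um)
      stop("event position outside the field")
    if (ev$t_start + event_duration(ev$kinetics) > duration_s)
      stop("movie duration does not cover the longest event")
  }

  expected <- array(camera$baseline_offset, dim = c(npx, npx, nt))

  # --- endocytic sites (immobile; fixed PSF patch scaled per frame)
  ev_truth <- NULL
  if (length(events)) {
    rows <- vector("list", length(events))
    for (e in seq_along(events)) {
      ev <- events[[e]]
      amp <- molecules_at(t_frames - ev$t_start, ev$kinetics) *
        camera$single_fluorophore_intensity
      hw <- ceiling(4 * camera$psf_sigma / ps)
      cx <- floor(ev$x_um / ps); cy <- floor(ev$y_um / ps)
      jx <- max(0, cx - hw):min(npx - 1, cx + hw)
      jy <- max(0, cy - hw):min(npx - 1, cy + hw)
      patch <- outer(psf_weights_1d(jy, ev$y_um, ps, camera$psf_sigma),
                     psf_weights_1d(jx, ev$x_um, ps, camera$psf_sigma))
      for (f in which(amp > 0))
        expected[jy + 1, jx + 1, f] <- expected[jy + 1, jx + 1, f] +
          amp[f] * patch
      dur <- event_duration(ev$kinetics)
      rows[[e]] <- data.frame(
        event_id = e, x_um = ev$x_um, y_um = ev$y_um,
        t_start = ev$t_start, t_end = ev$t_start + dur, duration = dur,
        t_scis = if (identical(ev$kinetics$scission_mode, "abrupt"))
          ev$t_start + ev$kinetics$scission_offset else NA_real_,
        peak_molecules = ev$kinetics$peak_molecules,
        rise_rate = ev$kinetics$rise_rate,
        fall_rate = ev$kinetics$fall_rate)
    }
    ev_truth <- do.call(rbind, rows)
    # flag sites whose 1.5-um background regions contain another site
    if (nrow(ev_truth) > 1) {
      d <- as.matrix(dist(ev_truth[, c("x_um", "y_um")]))
      diag(d) <- Inf
      ev_truth$overlap <- apply(d, 1, min) < 1.5
    } else ev_truth$overlap <- FALSE
  }

  # --- single molecules
  tracks <- NULL; dwells <- NULL
  if (!is.null(singles) && singles$on_rate_density > 0) {
    area <- field_um^2
    n_mol <- rpois(1, singles$on_rate_density * area * duration_s)
    trk <- vector("list", n_mol)
    dwl <- vector("list", n_mol)
    step_sd <- sqrt(2 * singles$diffusion_coefficient * dt)
    for (m in seq_len(n_mol)) {
      t_on <- runif(1, 0, duration_s)
      dwell <- rexp(1, singles$off_rate)
      frames <- which(t_frames >= t_on & t_frames < t_on + dwell)
      x0 <- runif(1, 0, field_um); y0 <- runif(1, 0, field_um)
      dwl[[m]] <- data.frame(track_id = m, t_on = t_on, dwell_s = dwell,
                             n_frames = length(frames))
      if (!length(frames)) next
      nf <- length(frames)
      xs <- x0 + c(0, cumsum(rnorm(nf - 1, 0, step_sd)))
      ys <- y0 + c(0, cumsum(rnorm(nf - 1, 0, step_sd)))
      for (j in seq_len(nf)) {
        expected[, , frames[j]] <- render_spot(
          expected[, , frames[j]], xs[j], ys[j],
          camera$single_fluorophore_intensity, ps, camera$psf_sigma)
      }
      trk[[m]] <- data.frame(track_id = m, frame = frames,
                             x_um = xs, y_um = ys)
    }
    tracks <- do.call(rbind, trk)
    dwells <- do.call(rbind, dwl)
  }

  # --- camera noise
  if (noise) {
    for (f in seq_len(nt)) {
      fr <- expected[, , f]
      if (camera$shot_noise)
        fr <- matrix(rpois(length(fr), pmax(fr, 0)), nrow = npx)
      if (camera$read_noise_sd > 0)
        fr <- fr + rnorm(length(fr), 0, camera$read_noise_sd)
      expected[, , f] <- fr
    }
  }

  list(movie = tirf_movie(expected, ps, dt),
       truth = list(events = ev_truth, tracks = tracks, dwells = dwells))
}

#' Simulate an endocytosis movie from an event preset
#'
#' Places `n_events` jittered copies of the preset event on a regular grid
#' (well separated so that measurement and background regions do not
#' overlap), with jittered start times around the baseline padding.
#'
#' @param preset event preset name or [event_preset()] list.
#' @param n_events number of endocytic sites.
#' @param seed integer seed.
#' @param spacing_um grid spacing, um.
#' @param margin_um margin between the grid and the field edge, um.
#' @param noise logical.
#' @return As [generate_movie()].
#' @export
generate_event_movie <- function(preset = "myo1", n_events = 36, seed = NULL,
                                 spacing_um = 3.2, margin_um = 1.6,
                                 noise = TRUE) {
  if (is.character(preset)) preset <- event_preset(preset)
  if (!is.null(seed)) set.seed(seed)
  jit <- preset$jitter
  n_side <- ceiling(sqrt(n_events))
  field <- 2 * margin_um + (n_side - 1) * spacing_um
  pos <- expand.grid(ix = seq_len(n_side) - 1, iy = seq_len(n_side) - 1)
  pos <- pos[seq_len(n_events), ]
  base_dur <- event_duration(preset$kinetics)
  max_dur <- base_dur * (1 + 1.7 * jit$duration_cv) + 1.7 * jit$start_sd
  duration <- preset$trace$pre_pad_s + max_dur + preset$trace$post_pad_s
  events <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    s <- if (noise) rtnorm_sym(1, 1, jit$duration_cv) else 1
    pf <- if (noise) rtnorm_sym(1, 1, jit$peak_cv) else 1
    st <- if (noise) rtnorm_sym(1, 0, jit$start_sd) else 0
    # snap sites to pixel centres so the 5x5 measurement core is symmetric
    ps <- preset$camera$pixel_size
    x <- round((margin_um + pos$ix[i] * spacing_um) / ps - 0.5) * ps + ps / 2
    y <- round((margin_um + pos$iy[i] * spacing_um) / ps - 0.5) * ps + ps / 2
    events[[i]] <- list(x_um = x, y_um = y,
                        t_start = preset$trace$pre_pad_s + st,
                        kinetics = scale_kinetics(preset$kinetics, s, pf))
  }
  generate_movie(events = events, singles = NULL, camera = preset$camera,
                 field_um = field, duration_s = duration, noise = noise)
}

#' Simulate a single-molecule membrane-binding scene
#'
#' @param preset defaults to [single_molecule_preset()].
#' @param seed integer seed.
#' @param duration_s,field_um optional overrides of the preset scene.
#' @param noise logical.
#' @return As [generate_movie()].
#' @export
generate_single_molecule_movie <- function(preset = single_molecule_preset(),
                                           seed = NULL, duration_s = NULL,
                                           field_um = NULL, noise = TRUE) {
  if (is.null(duration_s)) duration_s <- preset$duration_s
  if (is.null(field_um)) field_um <- preset$field_um
  generate_movie(events = list(), singles = preset$kinetics,
                 camera = preset$camera, field_um = field_um,
                 duration_s = duration_s, seed = seed, noise = noise)
}

#' Simulate Brownian trajectories directly (no rendering)
#'
#' Convenience generator for estimator checks: 2D Brownian tracks at fixed
#' length with optional Gaussian localization noise.
#'
#' @param n_tracks number of trajectories.
#' @param n_frames frames per trajectory.
#' @param D diffusion coefficient, um^2/s.
#' @param frame_interval s per frame.
#' @param loc_noise_sd localization noise SD per axis, um.
#' @param seed integer seed.
#' @return data.frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @export
simulate_brownian_tracks <- function(n_tracks, n_frames, D, frame_interval,
                                     loc_noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  step_sd <- sqrt(2 * D * frame_interval)
  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    x <- cumsum(c(0, rnorm(n_frames - 1, 0, step_sd)))
    y <- cumsum(c(0, rnorm(n_frames - 1, 0, step_sd)))
    if (loc_noise_sd > 0) {
      x <- x + rnorm(n_frames, 0, loc_noise_sd)
      y <- y + rnorm(n_frames, 0, loc_noise_sd)
    }
    out[[i]] <- data.frame(track_id = i, frame = seq_len(n_frames),
                           x_um = x, y_um = y)
  }
  do.call(rbind, out)
}
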