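test_that("noiseless event traces follow the closed-form trapezoid", {
  # worked example: rise 13 mol/s to 45, 6 s plateau, fall 14 mol/s
  k <- event_kinetics(13, 45, 6, 14)
  expect_equal(event_duration(k), 45 / 13 + 6 + 45 / 14, tolerance = 1e-12)

  shapes <- expand.grid(rise = c(5, 13, 30), fall = c(7, 14, 25),
                        plateau = c(0.5, 2, 6))
  cam <- quiet_camera()
  for (i in seq_len(nrow(shapes))) {
    k <- event_kinetics(shapes$rise[i], 45, shapes$plateau[i],
                        shapes$fall[i])
    g <- generate_event_trace(k, cam, noise = FALSE)
    expect_equal(g$truth$duration,
                 trapezoid_duration_oracle(shapes$rise[i], 45,
                                           shapes$plateau[i],
                                           shapes$fall[i]),
                 tolerance = 1e-12)
    # noiseless maximum is exactly peak x single-fluorophore intensity
    expect_equal(max(g$trace$intensity),
                 45 * cam$single_fluorophore_intensity, tolerance = 1e-12)
  }
})

test_that("kinetics invariants are enforced", {
  expect_error(event_kinetics(13, 0, 6, 14), "peak_molecules")
  expect_error(event_kinetics(-1, 45, 6, 14), "rise_rate")
  expect_error(event_kinetics(13, 45, 6, 14, "abrupt"), "scission")
  expect_error(camera_model(pixel_size = 0.1, psf_sigma = 0.01), "psf_sigma")
  expect_error(single_molecule_kinetics(0.1, -1, 0.03), "off_rate")
})

test_that("generators are bitwise reproducible under a fixed seed", {
  k <- event_preset("myo1")
  a <- generate_event_cohort(k, 5, seed = 7)
  b <- generate_event_cohort(k, 5, seed = 7)
  expect_identical(a, b)

  tp <- titration_preset("cam1_titration")
  expect_identical(
    generate_titration(tp$model, tp$ligand_uM, tp$noise_cv, seed = 3),
    generate_titration(tp$model, tp$ligand_uM, tp$noise_cv, seed = 3))

  expect_identical(generate_ca_release_transient(seed = 5),
                   generate_ca_release_transient(seed = 5))

  sm <- single_molecule_preset()
  m1 <- generate_movie(camera = sm$camera, singles = sm$kinetics,
                       field_um = 3.2, duration_s = 1, seed = 9)
  m2 <- generate_movie(camera = sm$camera, singles = sm$kinetics,
                       field_um = 3.2, duration_s = 1, seed = 9)
  expect_identical(m1$movie$frames, m2$movie$frames)
})

test_that("two-colour events share one clock with the configured offsets", {
  tc <- two_color_preset("myo1_cam1")
  ev <- generate_two_color_event(tc$a$kinetics, tc$b$kinetics, 0,
                                 tc$a$camera, noise = FALSE)
  # Myo1 outlives Cam1 by the difference of the preset durations (~2.9 s)
  gap <- event_duration(tc$a$kinetics) - event_duration(tc$b$kinetics)
  expect_equal(ev$truth$t_end_a - ev$truth$t_end_b, gap, tolerance = 1e-12)
  expect_gt(gap, 2.5)
  expect_lt(gap, 3.5)

  # identical kinetics, zero offset: the channels are identical frame by frame
  ev2 <- generate_two_color_event(tc$a$kinetics, tc$a$kinetics, 0,
                                  tc$a$camera, noise = FALSE)
  expect_identical(ev2$a$intensity, ev2$b$intensity)
})

test_that("abrupt scission drops the channel-b trace within one frame", {
  tc <- two_color_preset("cam1_cam2")
  ev <- generate_two_color_event(tc$a$kinetics, tc$b$kinetics, tc$offset_b,
                                 tc$a$camera, noise = FALSE)
  y <- ev$b$intensity
  plateau <- max(y)
  drops <- which(diff(y) < -0.5 * plateau)
  expect_length(drops, 1)
  expect_equal(ev$b$time[drops + 1], ev$truth$t_scis_b,
               tolerance = ev$b$frame_interval)
})

test_that("empty noiseless movies are the constant baseline image", {
  cam <- camera_model(frame_interval = 0.05, read_noise_sd = 0,
                      shot_noise = FALSE, baseline_offset = 17,
                      single_fluorophore_intensity = 50, psf_sigma = 0.09)
  m <- generate_movie(camera = cam, field_um = 3.2, duration_s = 0.5,
                      noise = FALSE)
  expect_true(all(m$movie$frames == 17))
})

test_that("noiseless movie ROI intensity conserves the trace to within PSF truncation", {
  p <- event_preset("myo1")
  cam <- quiet_camera()
  ev <- list(x_um = 3.25, y_um = 3.25, t_start = 2, kinetics = p$kinetics)
  m <- generate_movie(events = list(ev), camera = cam, field_um = 6.4,
                      duration_s = 18, noise = FALSE)
  roi <- extract_roi_trace(m$movie, x_px = 32, y_px = 32)
  corr <- correct_background(roi)
  ref <- generate_event_trace(p$kinetics, cam, pre_pad_s = 2,
                              post_pad_s = 18 - 2 - event_duration(p$kinetics),
                              noise = FALSE)
  n <- min(length(corr$intensity), length(ref$trace$intensity))
  peak <- max(ref$trace$intensity)
  # movie samples at frame midpoints, the trace generator at frame starts;
  # compare away from the ramps' half-frame offset by checking the plateau
  expect_equal(max(corr$intensity), peak, tolerance = 0.02)
  # total above-baseline flux conservation at the plateau frame
  plateau_frame <- which.max(corr$intensity)
  expect_equal(sum(m$movie$frames[, , plateau_frame]),
               45 * cam$single_fluorophore_intensity, tolerance = 0.02)
})

test_that("immobile single molecules yield zero-displacement ground truth", {
  kin <- single_molecule_kinetics(0.3, 2, 0)
  cam <- camera_preset("single_molecule")
  m <- generate_movie(singles = kin, camera = cam, field_um = 3.2,
                      duration_s = 3, seed = 4)
  disp <- tapply(seq_len(nrow(m$truth$tracks)), m$truth$tracks$track_id,
                 function(i) {
                   tr <- m$truth$tracks[i, ]
                   max(abs(tr$x_um - tr$x_um[1]), abs(tr$y_um - tr$y_um[1]))
                 })
  expect_true(all(disp == 0))
})

test_that("ground truth is complete: one record per rendered object", {
  p <- event_preset("myo1")
  m <- generate_event_movie(p, n_events = 4, seed = 2)
  expect_identical(nrow(m$truth$events), 4L)
  expect_identical(anyDuplicated(m$truth$events$event_id), 0L)
  sm <- single_molecule_preset()
  mv <- generate_movie(singles = sm$kinetics, camera = sm$camera,
                       field_um = 4.8, duration_s = 3, seed = 6)
  rendered <- unique(mv$truth$tracks$track_id)
  listed <- mv$truth$dwells$track_id[mv$truth$dwells$n_frames > 0]
  expect_setequal(rendered, listed)
})

test_that("titration generator obeys baseline and saturation limits", {
  tp <- titration_preset("cam1_titration")
  m <- tp$model
  noiseless <- generate_titration(m, c(0, 1e4 * max(m$K1, m$K2)), 0)
  expect_identical(noiseless$signal_au[1], m$F0)
  expect_equal(noiseless$signal_au[2], m$F0 + m$dF1 + m$dF2,
               tolerance = 1e-3)
})

test_that("transient generator matches the closed form and covers the slow phase", {
  tr <- generate_transient(1, 1, duration_s = 2, sample_rate = 100,
                           noise_sd = 0)
  expect_equal(tr$signal_au[tr$time_s == 1], exp(-1), tolerance = 1e-12)
  expect_error(generate_transient(c(1, 1), c(2, 2), 1, 100), "distinct")

  p <- transient_preset("ca_release")
  k_slow <- min(p$rates)
  expect_gte(p$duration_s, 5 / k_slow)  # slow phase >= 99% complete
})
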