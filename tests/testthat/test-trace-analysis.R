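test_that("background correction zeroes a uniform field and rejects bad input", {
  corr <- correct_background(rep(75, 20), rep(3, 20), 25,
                             frame_interval = 0.05)
  expect_true(all(corr$intensity == 0))
  expect_error(correct_background(rep(1, 5), rep(1, 4), 25,
                                  frame_interval = 0.05), "length")
})

test_that("ramp fitting recovers exact lines and breaks ties at the earliest window", {
  tt <- seq(0, 10, by = 0.05)
  tr <- intensity_trace(tt, 100 * tt, 0.05)
  r <- fit_ramp(tr, 60, "rising")
  expect_equal(r$slope, 100, tolerance = 1e-9)
  expect_identical(r$window_start, 1L)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)

  flat <- intensity_trace(tt, rep(2, length(tt)), 0.05)
  expect_equal(fit_ramp(flat, 60, "rising")$slope, 0, tolerance = 1e-12)
  expect_equal(fit_ramp(flat, 60, "falling")$slope, 0, tolerance = 1e-12)
  expect_error(fit_ramp(intensity_trace(1:10 * 0.05, 1:10, 0.05), 60),
               "too short")
})

test_that("ramp-intercept timing matches the trapezoid oracle within one frame", {
  cam <- quiet_camera()
  for (t_rise in c(1, 2, 3.46, 5, 10)) {
    for (plateau in c(2, 6)) {
      k <- event_kinetics(45 / t_rise, 45, plateau, 45 / 3.21)
      g <- generate_event_trace(k, cam, pre_pad_s = 4, post_pad_s = 5,
                                noise = FALSE)
      m <- measure_event(g$trace)
      oracle <- trapezoid_duration_oracle(45 / t_rise, 45, plateau,
                                          45 / 3.21)
      expect_lte(abs(m$t_dur - oracle), cam$frame_interval)
      expect_lte(abs(m$t_start - g$truth$t_start), cam$frame_interval)
    }
  }
})

test_that("worked example: trapezoid with 3.46 s rise and 3.21 s fall lasts 12.68 s", {
  cam <- quiet_camera()
  k <- event_kinetics(45 / 3.46, 45, 6, 45 / 3.21)
  g <- generate_event_trace(k, cam, start_time = 2, pre_pad_s = 2,
                            noise = FALSE)
  m <- measure_event(g$trace)
  expect_equal(m$t_dur, 3.46 + 6 + 3.21, tolerance = 0.05)
})

test_that("event timing is invariant to intensity rescaling", {
  coh <- generate_event_cohort("myo1", 1, seed = 5)
  tr <- coh$traces[[1]]
  m1 <- measure_event(tr)
  tr2 <- intensity_trace(tr$time, tr$intensity * 7.3, tr$frame_interval)
  m2 <- measure_event(tr2)
  expect_equal(m2$t_dur, m1$t_dur, tolerance = 1e-9)
  expect_equal(m2$t_start, m1$t_start, tolerance = 1e-9)
  expect_equal(m2$a_av, 7.3 * m1$a_av, tolerance = 1e-9)
})

test_that("traces without an event are rejected as malformed", {
  flat <- intensity_trace(seq(0, 10, 0.05), rep(0, 201), 0.05)
  expect_error(measure_event(flat), "malformed")
  meas <- measure_events(list(flat))
  expect_identical(nrow(meas), 0L)
  expect_identical(nrow(attr(meas, "excluded")), 1L)
})

test_that("scission detection flags abrupt drops and ignores gradual decay", {
  # constant-then-zero step
  y <- c(rep(100, 50), rep(0, 50))
  tr <- intensity_trace(seq_along(y) * 0.05, y, 0.05)
  expect_equal(detect_scission(tr, plateau = 100), 51 * 0.05,
               tolerance = 1e-9)

  cam <- quiet_camera()
  p <- event_preset("cam2")
  g <- generate_event_trace(p$kinetics, cam, noise = FALSE)
  ts <- detect_scission(g$trace, plateau = max(g$trace$intensity))
  expect_lte(abs(ts - g$truth$t_scis), cam$frame_interval)

  myo <- generate_event_trace(event_preset("myo1")$kinetics, cam,
                              noise = FALSE)
  expect_true(is.na(detect_scission(myo$trace,
                                    plateau = max(myo$trace$intensity))))
})

test_that("synchronized averaging aligns anchors and scales SEM as 1/sqrt(n)", {
  cam <- quiet_camera()
  k <- event_preset("myo1")$kinetics
  g1 <- generate_event_trace(k, cam, start_time = 3, pre_pad_s = 3,
                             noise = FALSE)
  g2 <- generate_event_trace(k, cam, start_time = 6, pre_pad_s = 6,
                             noise = FALSE)
  prof <- synchronize_and_average(list(g1$trace, g2$trace),
                                  anchors = c(3, 6))
  both <- prof[prof$n == 2, ]
  ref <- g1$trace$intensity[round(g1$trace$time / 0.05) %in%
                              round((both$time_s + 3) / 0.05)]
  expect_equal(both$mean_au, ref, tolerance = 1e-9)

  set.seed(42)
  noise_traces <- function(n) lapply(seq_len(n), function(i)
    intensity_trace(seq(0, 5, 0.05), rnorm(101), 0.05))
  p8 <- synchronize_and_average(noise_traces(8), anchors = rep(0, 8))
  p32 <- synchronize_and_average(noise_traces(32), anchors = rep(0, 32))
  ratio <- mean(p32$sem_au) / mean(p8$sem_au)
  expect_equal(ratio, 0.5, tolerance = 0.2)

  # missing anchors are excluded and reported
  p2 <- synchronize_and_average(noise_traces(3), anchors = c(0, NA, 0))
  expect_identical(attr(p2, "excluded"), 2L)
})

test_that("molecule conversion and calibration recover generator truth", {
  cal <- calibration_model(260, 1)
  expect_identical(to_molecules(260, cal), 1)
  expect_error(calibration_model(-5, 1), "single_fluorophore")

  # noiseless constant emitters: exact recovery of the per-molecule intensity
  tracks <- data.frame(track_id = rep(1:25, each = 4),
                       intensity_au = rep(260, 100))
  est <- estimate_single_fluorophore_intensity(tracks)
  expect_identical(est$single_fluorophore_intensity, 260)
  expect_error(estimate_single_fluorophore_intensity(tracks[1:20, ]),
               "tracks")
})

test_that("recovered cohort statistics match generator truth across presets", {
  cal <- calibration_model(263.6666667, 0.2)
  stats <- lapply(c(myo1 = "myo1", cam1 = "cam1", s742a = "myo1_S742A"),
                  function(p) {
    coh <- generate_event_cohort(p, 40, seed = 97)
    mm <- measure_events(coh$traces, calibration = cal)
    list(t_dur = mean(mm$t_dur), truth_dur = mean(coh$truth$duration),
         mol = mean(mm$molecules_peak),
         truth_mol = mean(coh$truth$peak_molecules),
         rise = median(mm$rise_gradient),
         truth_rise = median(coh$truth$rise_rate) * 52.7333333)
  })
  for (s in stats) {
    expect_equal(s$t_dur, s$truth_dur, tolerance = 0.03)
    expect_equal(s$mol, s$truth_mol, tolerance = 0.05)
    expect_equal(s$rise, s$truth_rise, tolerance = 0.10)
  }
  # ordering: Cam1 events are shorter than Myo1 events
  expect_lt(stats$cam1$t_dur, stats$myo1$t_dur)
})
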