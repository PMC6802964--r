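make_movie_array <- function(frames, pixel_size = 0.1, dt = 0.05) {
  tirf_movie(frames, pixel_size, dt)
}

test_that("std projection is the per-pixel sample SD and ignores frame order", {
  const <- make_movie_array(array(7, dim = c(8, 8, 20)))
  expect_true(all(std_projection(const) == 0))
  expect_error(std_projection(make_movie_array(array(0, dim = c(4, 4, 1)))),
               "2 frames")

  fr <- array(0, dim = c(6, 6, 100))
  fr[3, 4, ] <- rep(c(0, 100), 50)
  proj <- std_projection(make_movie_array(fr))
  expect_equal(proj[3, 4], sd(rep(c(0, 100), 50)), tolerance = 1e-10)
  expect_equal(proj[3, 4], 50.2519, tolerance = 1e-4)
  expect_true(all(proj[-(3 + (4 - 1) * 6)] == 0))

  set.seed(1)
  fr2 <- array(rnorm(6 * 6 * 30), dim = c(6, 6, 30))
  perm <- sample(30)
  expect_equal(std_projection(make_movie_array(fr2)),
               std_projection(make_movie_array(fr2[, , perm])))
})

test_that("detection recovers synthetic endocytic sites within one pixel", {
  m <- generate_event_movie("myo1", n_events = 9, seed = 31)
  proj <- std_projection(m$movie)
  # global maximum near a true site
  mx <- which(proj == max(proj), arr.ind = TRUE)
  d_min <- min(sqrt((m$truth$events$x_um / 0.1 - 0.5 - (mx[2] - 1))^2 +
                    (m$truth$events$y_um / 0.1 - 0.5 - (mx[1] - 1))^2))
  expect_lte(d_min, 1)
  sites <- detect_event_sites(proj, pixel_size = m$movie$pixel_size)
  expect_identical(nrow(sites), 9L)
  expect_false(any(sites$overlap | sites$edge))
  for (i in seq_len(nrow(m$truth$events))) {
    tx <- m$truth$events$x_um[i] / 0.1 - 0.5
    ty <- m$truth$events$y_um[i] / 0.1 - 0.5
    dd <- sqrt((sites$x_px - tx)^2 + (sites$y_px - ty)^2)
    expect_lte(min(dd), 1)
  }
})

test_that("thresholding yields no false positives on pure-noise movies", {
  cam <- camera_model(frame_interval = 0.05, read_noise_sd = 2,
                      shot_noise = TRUE, baseline_offset = 20,
                      single_fluorophore_intensity = 50, psf_sigma = 0.09)
  m <- generate_movie(camera = cam, field_um = 5, duration_s = 10,
                      seed = 17)
  sites <- detect_event_sites(std_projection(m$movie),
                              pixel_size = cam$pixel_size)
  expect_lt(nrow(sites), 1)
  expect_identical(nrow(detect_event_sites(matrix(0, 32, 32))), 0L)
})

test_that("close site pairs are flagged overlap-contaminated, distant ones are not", {
  p <- event_preset("myo1")
  cam <- quiet_camera()
  mk <- function(sep_um) {
    evs <- list(list(x_um = 2.05, y_um = 3.05, t_start = 2,
                     kinetics = p$kinetics),
                list(x_um = 2.05 + sep_um, y_um = 3.05, t_start = 2,
                     kinetics = p$kinetics))
    generate_movie(events = evs, camera = cam, field_um = 6.4,
                   duration_s = 18, noise = FALSE)
  }
  far <- detect_event_sites(std_projection(mk(3)$movie), pixel_size = 0.1)
  expect_identical(nrow(far), 2L)
  expect_false(any(far$overlap))
  near <- detect_event_sites(std_projection(mk(0.8)$movie),
                             pixel_size = 0.1, min_separation_um = 0.5)
  expect_identical(nrow(near), 2L)
  expect_true(all(near$overlap))
})

test_that("ROI extraction separates core sums from per-pixel background", {
  uni <- make_movie_array(array(3, dim = c(32, 32, 10)))
  roi <- extract_roi_trace(uni, x_px = 15, y_px = 15)
  expect_equal(roi$core, rep(75, 10))
  expect_equal(roi$background, rep(3, 10))
  expect_identical(roi$n_core_px, 25L)
  expect_false(roi$edge_clipped)

  edge <- extract_roi_trace(uni, x_px = 1, y_px = 15)
  expect_true(edge$edge_clipped)

  tiny <- make_movie_array(array(1, dim = c(5, 5, 4)))
  expect_error(extract_roi_trace(tiny, x_px = 2, y_px = 2), "uncorrectable")
})
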