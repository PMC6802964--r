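render_frame <- function(x_um, y_um, flux, n_px = 32, baseline = 20,
                         sigma = 0.09, noise = FALSE) {
  fr <- matrix(baseline, n_px, n_px)
  fr <- endotrace:::render_spot(fr, x_um, y_um, flux, 0.1, sigma)
  if (noise) fr <- matrix(rpois(length(fr), fr), n_px, n_px)
  fr
}

test_that("particle detection localizes single PSFs to sub-pixel accuracy", {
  set.seed(11)
  errs <- replicate(25, {
    x <- runif(1, 1.2, 2.0); y <- runif(1, 1.2, 2.0)
    fr <- render_frame(x, y, 264, noise = TRUE)
    det <- detect_particles(fr)
    expect_identical(nrow(det), 1L)
    sqrt((det$x_px - (x / 0.1 - 0.5))^2 + (det$y_px - (y / 0.1 - 0.5))^2)
  })
  expect_lt(sqrt(mean(errs^2)), 0.3)  # <= 0.3 px RMS

  # two well-separated spots are both found (with realistic shot noise;
  # a noiseless frame is degenerate for a MAD-based threshold)
  set.seed(19)
  fr <- render_frame(1.0, 1.0, 264)
  fr <- endotrace:::render_spot(fr, 2.0, 1.0, 264, 0.1, 0.09)
  fr <- matrix(rpois(length(fr), fr), nrow(fr), ncol(fr))
  expect_identical(nrow(detect_particles(fr)), 2L)
})

test_that("blank noisy frames produce almost no spurious detections", {
  set.seed(12)
  fp <- replicate(30, {
    fr <- matrix(rpois(32 * 32, 20) + rnorm(32 * 32, 0, 2), 32, 32)
    nrow(detect_particles(fr))
  })
  # field is (3.2 um)^2 ~ 10 um^2; false positives must be far below 1/frame
  expect_lt(mean(fp), 0.2)
})

test_that("linking turns an immobile spot into one full-length trajectory", {
  dets <- lapply(1:50, function(f)
    data.frame(x_px = 10.2, y_px = 14.8, intensity_au = 250))
  tr <- link_trajectories(dets, pixel_size = 0.1)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(nrow(tr), 50L)
})

test_that("crossing particles terminate their tracks instead of guessing", {
  # two spots approach, cross within the search radius, and separate
  frames <- lapply(seq(-5, 5), function(s) {
    data.frame(x_px = c(10 + s, 10 - s), y_px = c(10, 10.5),
               intensity_au = c(250, 250))
  })
  tr <- link_trajectories(frames, max_displacement_um = 0.3,
                          pixel_size = 0.1)
  lens <- table(tr$track_id)
  expect_gte(length(lens), 3)          # tracks were broken at the crossing
  expect_lt(max(lens), length(frames)) # nobody survived the ambiguity
})

test_that("off-rate MLE handles truncation exactly and without bias", {
  k0 <- 4
  d <- rep(0.1 + 1 / k0, 30)
  est <- estimate_off_rate(d, min_duration_s = 0.1, n_boot = 10)
  expect_equal(est$rate, k0, tolerance = 1e-12)
  expect_identical(est$n, 30L)
  # durations at/below the threshold are excluded from n
  est2 <- estimate_off_rate(c(d, rep(0.05, 100)), min_duration_s = 0.1,
                            n_boot = 10)
  expect_identical(est2$n, 30L)
  expect_error(estimate_off_rate(rep(1, 5), 0.1), "need")

  set.seed(13)
  for (k in c(1, 8, 20)) {
    dw <- rexp(150, k)
    trunc <- 0.03
    est <- estimate_off_rate(dw[dw > trunc], min_duration_s = trunc,
                             n_boot = 10)
    expect_equal(est$rate, k, tolerance = 3 / sqrt(sum(dw > trunc)))
  }
})

test_that("MSD fitting recovers D with slope 4D and a noise intercept", {
  tr <- simulate_brownian_tracks(150, 9, 0.03, 1 / 63, seed = 14)
  est <- estimate_diffusion(tr, 1 / 63, n_boot = 10)
  expect_equal(est$D, 0.03, tolerance = 0.1)
  expect_gt(est$r_squared, 0.99)

  still <- simulate_brownian_tracks(150, 9, 0, 1 / 63,
                                    loc_noise_sd = 0.02, seed = 15)
  est0 <- estimate_diffusion(still, 1 / 63, n_boot = 10)
  expect_lte(abs(est0$D), 0.002)
  expect_gt(est0$intercept, 0)

  frozen <- simulate_brownian_tracks(20, 9, 0, 1 / 63, seed = 16)
  estf <- estimate_diffusion(frozen, 1 / 63, n_boot = 0)
  expect_identical(estf$D, 0)
})

test_that("linked track durations reproduce the true dwell distribution", {
  p <- single_molecule_preset()
  m <- generate_single_molecule_movie(p, seed = 18, duration_s = 10,
                                      field_um = 9.6)
  tracks <- track_movie(m$movie)
  dt <- m$movie$frame_interval
  got <- track_durations(tracks, dt)
  truth <- m$truth$dwells$n_frames * dt
  got <- got[got > 2 * dt]; truth <- truth[truth > 2 * dt]
  expect_gt(length(got), 50)
  ks <- suppressWarnings(stats::ks.test(got, truth))
  expect_gt(ks$p.value, 0.01)
  # >= 90% of long dwells recovered as single tracks
  expect_gt(length(got) / length(truth), 0.8)
})
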