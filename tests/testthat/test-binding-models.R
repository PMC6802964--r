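test_that("depletion solver matches the independent root-finder oracle", {
  m <- sequential_binding_model(0.1, 0.68, 1, 1, 0, 0.5)
  expect_identical(free_ligand(0, m), 0)
  # worked example from the scheme: K1 = 0.1, K2 = 0.68, 0.5 uM reporter
  expect_equal(free_ligand(1, m), depletion_oracle(1, 0.1, 0.68, 0.5),
               tolerance = 1e-8)
  # no-binding limit
  m_inf <- sequential_binding_model(1e6, 1e6, 1, 1, 0, 0.5)
  expect_equal(free_ligand(2, m_inf), 2, tolerance = 1e-6)
  # grid agreement to 1e-8 uM
  for (K1 in c(0.01, 0.1, 1)) for (K2 in c(0.1, 1, 10)) {
    mm <- sequential_binding_model(K1, K2, 1, 1, 0, 0.5)
    for (tot in c(0.05, 0.3, 1, 3, 10)) {
      expect_equal(free_ligand(tot, mm),
                   depletion_oracle(tot, K1, K2, 0.5), tolerance = 1e-8)
    }
  }
})

test_that("occupancies obey limits, ordering and monotonicity", {
  m <- sequential_binding_model(0.2, 1.5, 1, 1, 0, 0.5)
  o0 <- occupancy(0, m)
  expect_identical(c(o0$f1, o0$f2), c(0, 0))
  oi <- occupancy(1e9, m)
  expect_equal(c(oi$f1, oi$f2), c(1, 1), tolerance = 1e-6)
  # single-site half saturation when the second site is inaccessible
  m1 <- sequential_binding_model(0.2, 1e9, 1, 1, 0, 0.5)
  oh <- occupancy(0.2, m1)
  expect_equal(oh$f1, 0.5, tolerance = 1e-6)
  expect_lt(oh$f2, 1e-6)

  L <- 10^seq(-3, 2, length.out = 60)
  oc <- occupancy(L, m)
  expect_true(all(oc$f2 <= oc$f1 + 1e-12))
  expect_true(all(diff(oc$f1) > -1e-12))
  expect_true(all(diff(oc$f2) > -1e-12))
})

test_that("predicted signal satisfies its limits and the no-depletion regime", {
  m <- sequential_binding_model(0.1, 0.68, 11, 11, 3, 0.5)
  expect_equal(predict_signal(1e5, m), 3 + 22, tolerance = 1e-3)
  m0 <- sequential_binding_model(0.1, 0.68, 0, 0, 3, 0.5)
  expect_true(all(predict_signal(c(0, 1, 5), m0) == 3))
  # reporter << K1: depletion-corrected curve matches the free-ligand form
  mt <- sequential_binding_model(1, 3, 10, 10, 0, 0.01)
  L <- c(0.3, 1, 3, 10)
  occ <- occupancy(L, mt)
  expect_equal(predict_signal(L, mt), 10 * occ$f1 + 10 * occ$f2,
               tolerance = 0.01)
})

test_that("titration fitting is self-consistent and invariant to affine rescaling", {
  m <- sequential_binding_model(0.3, 3, 12, 20, 1, 0.05)
  conc <- c(0, 0.1, 0.25, 0.5, 1, 2, 4, 8, 16, 30)
  clean <- generate_titration(m, conc, 0)
  fit <- fit_titration(clean, 0.05, seed = 2, n_boot = 0)
  expect_false(fit$k1_bound)
  expect_equal(fit$K1, 0.3, tolerance = 1e-3)
  expect_equal(fit$K2, 3, tolerance = 1e-3)

  resc <- clean
  resc$signal_au <- 5 * resc$signal_au + 40
  fit2 <- fit_titration(resc, 0.05, seed = 2, n_boot = 0,
                        weighting = "none")
  fit1 <- fit_titration(clean, 0.05, seed = 2, n_boot = 0,
                        weighting = "none")
  expect_equal(fit2$K2, fit1$K2, tolerance = 1e-6)

  expect_error(fit_titration(clean[1:5, ], 0.05), "8 concentration")
})

test_that("stoichiometric first sites are reported as bounds, not points", {
  tp <- titration_preset("cam1_titration")
  curve <- generate_titration(tp$model, tp$ligand_uM, tp$noise_cv,
                              seed = 21)
  fit <- fit_titration(curve, tp$model$reporter_total, seed = 22,
                       n_boot = 0)
  expect_true(fit$k1_bound)
  expect_match(fit$k1_report, "K1 <")
})

test_that("pCa Hill fitting recovers exact curves and rejects bad data", {
  truth <- list(pCa50 = 5.87, hill_n = 2, Ymin = 5, Ymax = 46.05)
  pca <- seq(4.5, 7.5, length.out = 10)
  clean <- generate_pca_titration(truth, pca, 0)
  fit <- fit_pca(clean, seed = 4, n_boot = 0)
  expect_equal(fit$pCa50, 5.87, tolerance = 1e-6)
  expect_equal(fit$hill_n, 2, tolerance = 1e-5)

  onesided <- generate_pca_titration(truth, seq(7.2, 9, length.out = 8), 0)
  expect_error(fit_pca(onesided, seed = 4, n_boot = 0), "bracket")
  expect_error(fit_pca(clean[1:4, ]), "6 pCa")
})

test_that("Forster conversions obey the defining identities", {
  pair <- forster_pair(5.301)
  expect_equal(efficiency_to_distance(0.5, pair), 5.301, tolerance = 1e-12)
  # neck-length worked example: 4.6 nm corresponds to E ~ 0.701
  expect_equal(distance_to_efficiency(4.6, pair), 0.701, tolerance = 1e-3)
  E <- c(0.05, 0.3, 0.7, 0.95)
  expect_equal(distance_to_efficiency(efficiency_to_distance(E, pair),
                                      pair), E, tolerance = 1e-12)
  expect_error(efficiency_to_distance(1.2), "between 0 and 1")
  expect_error(distance_to_efficiency(-1), "R must")
})
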