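# Sequential two-site calmodulin-IQ binding with ligand depletion, FRET
# observable prediction, titration and pCa (Hill) fitting, and Forster
# efficiency <-> distance conversion.
#
# The binding scheme is strictly sequential (IQ1 then IQ2): species R, RL
# (IQ1 occupied) and RL2 (both occupied) with statistical weights
# 1, L/K1, L^2/(K1 K2); there is no IQ2-only species, encoding the
# observation that calmodulin cannot occupy IQ2 unless IQ1 is occupied.

#' Sequential two-site binding model
#'
#' @param K1 first-site dissociation constant, uM (> 0).
#' @param K2 second-site dissociation constant (accessible only after the
#'   first site is occupied), uM (> 0).
#' @param dF1,dF2 signal change per binding step, AU.
#' @param F0 baseline signal, AU.
#' @param reporter_total reporter (IQ construct) concentration, uM (> 0).
#' @return An object of class `sequential_binding_model`.
#' @export
sequential_binding_model <- function(K1, K2, dF1, dF2, F0 = 0,
                                     reporter_total) {
  if (!is.finite(K1) || K1 <= 0 || !is.finite(K2) || K2 <= 0)
    stop("K1 and K2 must be positive")
  if (!is.finite(reporter_total) || reporter_total <= 0)
    stop("reporter_total must be positive")
  structure(list(K1 = K1, K2 = K2, dF1 = dF1, dF2 = dF2, F0 = F0,
                 reporter_total = reporter_total),
            class = "sequential_binding_model")
}

#' Free ligand concentration under depletion
#'
#' Solves the mass-conservation closure
#' `L + R (L/K1 + 2 L^2/(K1 K2)) / (1 + L/K1 + L^2/(K1 K2)) = L_total`
#' for the free ligand `L` by bracketed bisection on `[0, L_total]` to a
#' relative tolerance of 1e-10. The left side is strictly increasing in L,
#' so the root is unique.
#'
#' @param ligand_total total ligand, uM (vectorised, >= 0).
#' @param model a [sequential_binding_model()].
#' @return Free ligand concentrations, uM.
#' @export
free_ligand <- function(ligand_total, model) {
  stopifnot(inherits(model, "sequential_binding_model"))
  if (any(ligand_total < 0)) stop("ligand_total must be >= 0")
  R <- model$reporter_total; K1 <- model$K1; K2 <- model$K2
  vapply(ligand_total, function(tot) {
    if (tot == 0) return(0)
    g <- function(L) {
      z1 <- L / K1; z2 <- L * L / (K1 * K2)
      L + R * (z1 + 2 * z2) / (1 + z1 + z2) - tot
    }
    lo <- 0; hi <- tot
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (mid <= lo || mid >= hi) break   # float resolution reached
      if (g(mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) <= 1e-10 * tot) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Fractional occupancies of the sequential scheme
#'
#' `f1` is the fraction of reporter with at least one site occupied, `f2`
#' the fraction with both; `0 <= f2 <= f1 <= 1` always.
#'
#' @param free free ligand concentration, uM (vectorised).
#' @param model a [sequential_binding_model()].
#' @return List with numeric vectors `f1` and `f2`.
#' @export
occupancy <- function(free, model) {
  z1 <- free / model$K1
  z2 <- free^2 / (model$K1 * model$K2)
  Z <- 1 + z1 + z2
  list(f1 = (z1 + z2) / Z, f2 = z2 / Z)
}

#' Predicted titration signal at total ligand concentrations
#'
#' `F = F0 + dF1 * f1 + dF2 * f2` evaluated at the depletion-corrected free
#' ligand.
#'
#' @param ligand_total total ligand, uM (vectorised).
#' @param model a [sequential_binding_model()].
#' @return Signal, AU.
#' @export
predict_signal <- function(ligand_total, model) {
  occ <- occupancy(free_ligand(ligand_total, model), model)
  model$F0 + model$dF1 * occ$f1 + model$dF2 * occ$f2
}

# one-site depletion closed form: L + R L/(K+L) = tot
free_ligand_one_site <- function(tot, K, R) {
  b <- K + R - tot
  (-b + sqrt(b^2 + 4 * K * tot)) / 2
}

#' Fit an equilibrium titration
#'
#' Weighted least-squares fit of the depletion-corrected sequential two-site
#' model (parameters K1, K2, dF1, dF2, F0) or a one-site model (K1, dF1,
#' F0), with seeded log-uniform multistart over the dissociation constants.
#' With the default `weighting = "multiplicative"` the residuals are scaled
#' by the model prediction, the maximum-likelihood weighting for the
#' constant-CV noise of fluorescence titrations.
#'
#' Tight-site handling: when the free fit places K1 below
#' `reporter_total / 5` the titration is stoichiometric in the first site —
#' binding is too tight for the data to determine K1 — so the fit is
#' repeated with K1 profiled at a representative tight value
#' (`reporter_total / 100`; any sufficiently tight value predicts the same
#' curve) and K1 is reported as the upper bound `reporter_total / 5`
#' (`k1_bound = TRUE`). This decorrelates the otherwise strongly coupled
#' (K1, K2) pair. Confidence intervals by residual bootstrap.
#'
#' @param curve data.frame with `concentration_uM` and `signal_au` (as from
#'   [generate_titration()]).
#' @param reporter_total reporter concentration, uM.
#' @param model_spec `"two_site"` or `"one_site"`.
#' @param multistart number of random starts (default 32).
#' @param seed seed for the multistart draws and bootstrap.
#' @param n_boot bootstrap replicates (default 100; 0 to skip).
#' @param k_bounds log10 bounds on the dissociation constants, uM.
#' @param weighting `"multiplicative"` (constant-CV noise) or `"none"`.
#' @return List of class `titration_fit` with `K1`, `K2`, `k1_bound`,
#'   `k1_report`, `amplitude_fraction2` (dF2 / (dF1 + dF2)), the fitted
#'   `model`, `rss`, `ci` and `fitted` values (two-site), or `K1`, `dF1`,
#'   `F0` etc. (one-site).
#' @export
fit_titration <- function(curve, reporter_total,
                          model_spec = c("two_site", "one_site"),
                          multistart = 32, seed = 1, n_boot = 100,
                          k_bounds = c(-3, 2.5),
                          weighting = c("multiplicative", "none")) {
  model_spec <- match.arg(model_spec)
  weighting <- match.arg(weighting)
  conc <- curve$concentration_uM
  y_obs <- curve$signal_au
  if (length(conc) < 8)
    stop("need at least 8 concentration points spanning the transition")
  set.seed(seed)
  two <- model_spec == "two_site"
  scale_floor <- 0.02 * max(abs(y_obs))
  predict_par <- function(par, k1_fix = NULL) {
    if (two) {
      K1 <- if (is.null(k1_fix)) 10^par[length(par)] else k1_fix
      m <- sequential_binding_model(K1, 10^par[1], par[2], par[3],
                                    par[4], reporter_total)
      predict_signal(conc, m)
    } else {
      K <- 10^par[1]
      L <- free_ligand_one_site(conc, K, reporter_total)
      par[3] + par[2] * L / (K + L)
    }
  }
  resid_par <- function(par, y, k1_fix = NULL) {
    mu <- predict_par(par, k1_fix)
    r <- mu - y
    if (weighting == "multiplicative") r / pmax(abs(mu), scale_floor) else r
  }
  run_fit <- function(start, y, k1_fix = NULL) {
    free_k1 <- two && is.null(k1_fix)
    lower <- c(k_bounds[1], rep(-Inf, length(start) - 1 - free_k1),
               if (free_k1) k_bounds[1])
    upper <- c(k_bounds[2], rep(Inf, length(start) - 1 - free_k1),
               if (free_k1) k_bounds[2])
    tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_par, y = y,
                         k1_fix = k1_fix, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  f0_0 <- y_obs[which.min(conc)]
  span <- diff(range(y_obs))
  dir <- sign(y_obs[which.max(conc)] - f0_0); if (dir == 0) dir <- 1
  multi_fit <- function(y, k1_fix = NULL) {
    best <- NULL
    for (s in seq_len(multistart)) {
      lk2 <- runif(1, k_bounds[1], k_bounds[2])
      start <- if (two) {
        st <- c(lk2, dir * span / 2, dir * span / 2, f0_0)
        if (is.null(k1_fix)) c(st, runif(1, k_bounds[1], 0.5)) else st
      } else c(lk2, dir * span, f0_0)
      fit <- run_fit(start, y, k1_fix)
      if (is.null(fit)) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    best
  }
  best <- multi_fit(y_obs)
  if (is.null(best))
    stop("titration fit failed to converge from any start")
  k1_fix <- NULL
  k1_bound <- FALSE
  if (two && 10^best$par[5] < reporter_total / 5) {
    k1_bound <- TRUE
    k1_fix <- reporter_total / 100
    best2 <- multi_fit(y_obs, k1_fix)
    if (!is.null(best2)) best <- best2
  }
  par <- best$par
  refit_value <- function(y) {
    fb <- run_fit(par, y, k1_fix)
    if (is.null(fb)) NA_real_ else 10^fb$par[1]
  }
  ci <- NULL
  if (n_boot > 0) {
    fitted0 <- predict_par(par, k1_fix)
    res <- fitted0 - y_obs
    boots <- vapply(seq_len(n_boot), function(b)
      refit_value(fitted0 + sample(res, replace = TRUE)), numeric(1))
    ci <- data.frame(parameter = if (two) "K2" else "K1",
                     lower = quantile(boots, 0.025, na.rm = TRUE),
                     upper = quantile(boots, 0.975, na.rm = TRUE),
                     row.names = NULL)
  }
  if (two) {
    K1_hat <- if (k1_bound) k1_fix else 10^par[5]
    m <- sequential_binding_model(K1_hat, 10^par[1], par[2], par[3],
                                  par[4], reporter_total)
    out <- list(model = m, K1 = K1_hat, K2 = m$K2, k1_bound = k1_bound,
                k1_report = if (k1_bound)
                  sprintf("K1 < %.3g uM (too tight to determine)",
                          reporter_total / 5)
                else sprintf("K1 = %.3g uM", K1_hat),
                amplitude_fraction2 = m$dF2 / (m$dF1 + m$dF2),
                rss = best$deviance, ci = ci,
                fitted = predict_par(par, k1_fix))
  } else {
    K <- 10^par[1]
    out <- list(K1 = K, dF1 = par[2], F0 = par[3],
                k1_bound = K < reporter_total / 5,
                rss = best$deviance, ci = ci,
                fitted = predict_par(par))
  }
  class(out) <- "titration_fit"
  out
}

#' @export
print.titration_fit <- function(x, ...) {
  if (!is.null(x$K2)) {
    cat(sprintf("<titration_fit two-site> %s; K2 = %.3g uM; dF2 fraction %.2f; rss %.4g\n",
                x$k1_report, x$K2, x$amplitude_fraction2, x$rss))
  } else {
    cat(sprintf("<titration_fit one-site> K1 = %.3g uM; rss %.4g\n",
                x$K1, x$rss))
  }
  invisible(x)
}

#' Fit a pCa (Hill) titration
#'
#' `Y(pCa) = Ymin + (Ymax - Ymin) / (1 + 10^(hill_n (pCa50 - pCa)))`; the
#' direction of the transition is inferred from the data via the fitted
#' Ymin/Ymax. Errors when the data do not bracket the midpoint.
#'
#' @param curve data.frame with `pCa` and `signal_au`.
#' @param multistart random starts (default 16).
#' @param seed seed for multistart and bootstrap.
#' @param n_boot residual-bootstrap replicates for the pCa50 CI.
#' @return List of class `pca_fit`: `pCa50`, `hill_n`, `Ymin`, `Ymax`,
#'   `rss`, `ci`, `fitted`.
#' @export
fit_pca <- function(curve, multistart = 16, seed = 1, n_boot = 100) {
  pca <- curve$pCa
  y_obs <- curve$signal_au
  if (length(pca) < 6) stop("need at least 6 pCa points")
  set.seed(seed)
  run_fit <- function(start, y) {
    tryCatch(minpack.lm::nls.lm(
      par = start,
      fn = function(p) hill_pca(pca, p[1], exp(p[2]), p[3], p[4]) - y,
      lower = c(min(pca) - 2, log(0.1), -Inf, -Inf),
      upper = c(max(pca) + 2, log(10), Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  o <- order(pca)
  y_lo <- mean(y_obs[o][seq_len(2)])        # low-pCa end
  y_hi <- mean(rev(y_obs[o])[seq_len(2)])   # high-pCa end
  best <- NULL
  for (s in seq_len(multistart)) {
    start <- c(runif(1, min(pca), max(pca)), log(runif(1, 0.5, 4)),
               y_lo, y_hi)
    fit <- run_fit(start, y_obs)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("pCa fit failed to converge")
  par <- best$par
  if (par[1] <= min(pca) || par[1] >= max(pca))
    stop("pCa data do not bracket the transition midpoint")
  ci <- NULL
  if (n_boot > 0) {
    fitted0 <- hill_pca(pca, par[1], exp(par[2]), par[3], par[4])
    res <- fitted0 - y_obs
    boots <- vapply(seq_len(n_boot), function(b) {
      fb <- run_fit(par, fitted0 + sample(res, replace = TRUE))
      if (is.null(fb)) NA_real_ else fb$par[1]
    }, numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(pCa50 = par[1], hill_n = exp(par[2]),
                 Ymin = par[3], Ymax = par[4], rss = best$deviance,
                 ci = ci,
                 fitted = hill_pca(pca, par[1], exp(par[2]), par[3],
                                   par[4])),
            class = "pca_fit")
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("<pca_fit> pCa50 = %.3f, hill_n = %.2f, range [%.3g, %.3g]\n",
              x$pCa50, x$hill_n, x$Ymin, x$Ymax))
  invisible(x)
}

#' Forster pair
#'
#' @param R0 Forster radius, nm. Default 5.301 nm for the CyPet-YPet pair.
#' @return An object of class `forster_pair`.
#' @export
forster_pair <- function(R0 = 5.301) {
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be > 0")
  structure(list(R0 = R0), class = "forster_pair")
}

#' Convert FRET efficiency to donor-acceptor distance (and back)
#'
#' `R = R0 (1/E - 1)^(1/6)` and `E = 1 / (1 + (R/R0)^6)`.
#'
#' @param E transfer efficiency, in (0, 1).
#' @param pair a [forster_pair()].
#' @return Distance in nm.
#' @export
efficiency_to_distance <- function(E, pair = forster_pair()) {
  if (any(E <= 0 | E >= 1)) stop("E must lie strictly between 0 and 1")
  pair$R0 * (1 / E - 1)^(1 / 6)
}

#' @rdname efficiency_to_distance
#' @param R distance, nm (> 0).
#' @export
distance_to_efficiency <- function(R, pair = forster_pair()) {
  if (any(R <= 0)) stop("R must be > 0")
  1 / (1 + (R / pair$R0)^6)
}
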