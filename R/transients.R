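# Multi-exponential fitting of stopped-flow transients with sequential
# F-test phase-count selection.

multiexp_eval <- function(time, offset, amplitudes, rates) {
  offset + as.vector(exp(-outer(time, rates)) %*% amplitudes)
}

# Given trial rates, solve offset and amplitudes by linear least squares;
# used to seed the nonlinear refinement (variable projection style).
linear_amplitudes <- function(time, signal, rates) {
  X <- cbind(1, exp(-outer(time, rates)))
  qr.coef(qr(X), signal)
}

#' Fit an N-exponential decay to a transient
#'
#' Nonlinear least squares on `y(t) = offset + sum_i A_i exp(-k_i t)` with
#' seeded multistart: trial rate sets are drawn log-uniformly over the
#' resolvable range, amplitudes and offset are first solved linearly for
#' each trial, then all parameters are refined with Levenberg-Marquardt.
#' Amplitude signs are unconstrained (transients may rise or fall). Rates
#' are returned in strictly descending order.
#'
#' @param trace data.frame with `time_s` and `signal_au` (as from
#'   [generate_transient()]).
#' @param n_phases number of exponential phases (1-4).
#' @param multistart random starts (default 32).
#' @param seed seed for the multistart draws.
#' @return List of class `transient_fit`: `n_phases`, `amplitudes`,
#'   `rates` (descending), `offset`, `rss`, `aic`, `fitted`, `n_obs`.
#' @export
fit_multiexp <- function(trace, n_phases, multistart = 32, seed = 1) {
  time <- trace$time_s; y <- trace$signal_au
  if (!(n_phases %in% 1:4)) stop("n_phases must be in 1..4")
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing")
  set.seed(seed)
  lk_range <- c(log10(0.5 / max(time)), log10(0.5 / min(diff(time))))
  resid_fn <- function(p) {
    k <- exp(p[seq_len(n_phases)])
    A <- p[n_phases + seq_len(n_phases)]
    off <- p[2 * n_phases + 1]
    multiexp_eval(time, off, A, k) - y
  }
  best <- NULL
  for (s in seq_len(multistart)) {
    lk <- sort(runif(n_phases, lk_range[1], lk_range[2]), decreasing = TRUE)
    k0 <- 10^lk
    lin <- linear_amplitudes(time, y, k0)
    if (any(!is.finite(lin))) next
    start <- c(log(k0), lin[-1], lin[1])
    bound <- log(10) * lk_range
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         lower = c(rep(bound[1], n_phases),
                                   rep(-Inf, n_phases + 1)),
                         upper = c(rep(bound[2], n_phases),
                                   rep(Inf, n_phases + 1)),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("multi-exponential fit failed to converge; residual diagnostics: ",
         "check that the record covers the slowest phase")
  p <- best$par
  k <- exp(p[seq_len(n_phases)])
  A <- p[n_phases + seq_len(n_phases)]
  off <- p[2 * n_phases + 1]
  o <- order(k, decreasing = TRUE)
  n <- length(y)
  rss <- best$deviance
  aic <- n * log(rss / n) + 2 * (2 * n_phases + 1)
  structure(list(n_phases = n_phases, amplitudes = A[o], rates = k[o],
                 offset = off, rss = rss, aic = aic,
                 fitted = multiexp_eval(time, off, A, k), n_obs = n),
            class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  cat(sprintf("<transient_fit> %d phases; rates (1/s): %s; amplitudes: %s; offset %.4g\n",
              x$n_phases, paste(signif(x$rates, 4), collapse = ", "),
              paste(signif(x$amplitudes, 4), collapse = ", "), x$offset))
  invisible(x)
}

#' Select the number of exponential phases
#'
#' Fits 1..`max_n` phases and recommends the smallest n that is not rejected
#' against n+1 by a sequential extra-sum-of-squares F-test at level `alpha`;
#' AIC values are reported alongside.
#'
#' @param trace data.frame with `time_s`, `signal_au`.
#' @param max_n largest candidate phase count (1-4).
#' @param alpha F-test level (default 0.01).
#' @param multistart,seed passed to [fit_multiexp()].
#' @return List with `recommended_n`, `criteria` (data.frame of n, rss, aic
#'   and the p-value of n vs n+1) and `fits` (list of `transient_fit`).
#' @export
select_n_phases <- function(trace, max_n = 4, alpha = 0.01,
                            multistart = 32, seed = 1) {
  if (!(max_n %in% 1:4)) stop("max_n must be in 1..4")
  fits <- lapply(seq_len(max_n), function(n)
    fit_multiexp(trace, n, multistart = multistart, seed = seed + n))
  n_obs <- fits[[1]]$n_obs
  pvals <- rep(NA_real_, max_n)
  for (n in seq_len(max_n - 1)) {
    rss1 <- fits[[n]]$rss; rss2 <- fits[[n + 1]]$rss
    df_extra <- 2
    df_resid <- n_obs - (2 * (n + 1) + 1)
    Fstat <- ((rss1 - rss2) / df_extra) / (rss2 / df_resid)
    pvals[n] <- pf(Fstat, df_extra, df_resid, lower.tail = FALSE)
  }
  rec <- max_n
  for (n in seq_len(max_n - 1)) {
    if (is.na(pvals[n]) || pvals[n] > alpha) { rec <- n; break }
  }
  list(recommended_n = rec,
       criteria = data.frame(n = seq_len(max_n),
                             rss = vapply(fits, `[[`, numeric(1), "rss"),
                             aic = vapply(fits, `[[`, numeric(1), "aic"),
                             p_vs_next = pvals),
       fits = fits)
}
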