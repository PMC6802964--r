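# Synthetic equilibrium titrations and stopped-flow transients.

#' Simulate a ligand titration from a sequential two-site binding model
#'
#' Signal is computed from the depletion-corrected sequential binding model
#' (see [predict_signal()]) and perturbed with multiplicative Gaussian noise.
#'
#' @param model a [sequential_binding_model()].
#' @param ligand_uM total ligand concentrations, uM (>= 0).
#' @param noise_cv multiplicative noise CV (0 for noiseless).
#' @param seed optional integer seed.
#' @return data.frame with `concentration_uM` and `signal_au`, with the true
#'   model attached as attribute `truth`.
#' @export
generate_titration <- function(model, ligand_uM, noise_cv = 0.02,
                               seed = NULL) {
  stopifnot(inherits(model, "sequential_binding_model"))
  if (any(ligand_uM < 0)) stop("ligand concentrations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  y <- predict_signal(ligand_uM, model)
  if (noise_cv > 0)
    y <- y * (1 + rnorm(length(y), 0, noise_cv))
  structure(data.frame(concentration_uM = ligand_uM, signal_au = y),
            truth = model)
}

# Hill curve in pCa units: rises towards Ymax at high pCa (low Ca2+) for
# hill_n > 0 with Ymax > Ymin; direction is encoded by the Ymax/Ymin order.
hill_pca <- function(pca, pCa50, hill_n, Ymin, Ymax) {
  Ymin + (Ymax - Ymin) / (1 + 10^(hill_n * (pCa50 - pca)))
}

#' Simulate a calcium (pCa) titration
#'
#' @param model list with `pCa50`, `hill_n`, `Ymin`, `Ymax`.
#' @param pca pCa values (-log10 free Ca2+).
#' @param noise_cv multiplicative noise CV.
#' @param seed optional integer seed.
#' @return data.frame with `pCa` and `signal_au`; truth attached.
#' @export
generate_pca_titration <- function(model, pca, noise_cv = 0.02,
                                   seed = NULL) {
  stopifnot(is.numeric(pca), length(pca) >= 2)
  if (!is.null(seed)) set.seed(seed)
  y <- hill_pca(pca, model$pCa50, model$hill_n, model$Ymin, model$Ymax)
  if (noise_cv > 0)
    y <- y * (1 + rnorm(length(y), 0, noise_cv))
  structure(data.frame(pCa = pca, signal_au = y), truth = model)
}

#' Simulate a multi-exponential stopped-flow transient
#'
#' `y(t) = offset + sum_i A_i exp(-k_i t)` plus additive Gaussian noise.
#' Either a uniform timebase (`sample_rate`) or an explicit `times` vector
#' (e.g. the two-regime stopped-flow timebase of [transient_timebase()]) can
#' be used.
#'
#' @param amplitudes phase amplitudes, AU.
#' @param rates phase rate constants, 1/s (positive, distinct).
#' @param duration_s record length, s.
#' @param sample_rate samples per second (ignored when `times` is given).
#' @param noise_sd additive noise SD, AU.
#' @param seed optional integer seed.
#' @param offset baseline offset, AU.
#' @param times optional explicit sample times, s.
#' @return data.frame with `time_s` and `signal_au`; truth attached.
#' @export
generate_transient <- function(amplitudes, rates, duration_s = NULL,
                               sample_rate = NULL, noise_sd = 0,
                               seed = NULL, offset = 0, times = NULL) {
  if (length(amplitudes) != length(rates))
    stop("`amplitudes` and `rates` must have the same length")
  if (any(rates <= 0)) stop("rates must be positive")
  if (anyDuplicated(rates))
    stop("duplicate rates are not identifiable; rates must be distinct")
  if (is.null(times)) {
    if (is.null(duration_s) || is.null(sample_rate))
      stop("either `times` or both `duration_s` and `sample_rate` required")
    times <- seq(1 / sample_rate, duration_s, by = 1 / sample_rate)
  }
  if (!is.null(seed)) set.seed(seed)
  y <- offset + as.vector(exp(-outer(times, rates)) %*% amplitudes)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  structure(data.frame(time_s = times, signal_au = y),
            truth = list(amplitudes = amplitudes, rates = rates,
                         offset = offset))
}

#' Two-regime stopped-flow timebase
#'
#' Dense sampling early (to resolve the fastest phase) and sparse sampling
#' late (to cover the slowest), mimicking split-timebase acquisition.
#'
#' @param duration_s total record, s.
#' @param dense_until_s end of the dense regime, s.
#' @param dense_dt_s,sparse_dt_s sampling intervals in the two regimes, s.
#' @return Numeric vector of sample times.
#' @export
transient_timebase <- function(duration_s = 2.5, dense_until_s = 0.12,
                               dense_dt_s = 2e-4, sparse_dt_s = 5e-3) {
  c(seq(dense_dt_s, dense_until_s, by = dense_dt_s),
    seq(dense_until_s + sparse_dt_s, duration_s, by = sparse_dt_s))
}

#' Simulate the calcium-release transient preset
#'
#' Three-phase Quin-2 calcium-release transient (fast, medium, slow phases of
#' equal amplitude) on the split stopped-flow timebase.
#'
#' @param seed optional integer seed.
#' @param noise logical.
#' @return As [generate_transient()].
#' @export
generate_ca_release_transient <- function(seed = NULL, noise = TRUE) {
  p <- transient_preset("ca_release")
  generate_transient(
    amplitudes = p$amplitudes, rates = p$rates,
    noise_sd = if (noise) p$noise_sd else 0, seed = seed,
    offset = p$offset,
    times = transient_timebase(p$duration_s, p$dense_until_s,
                               p$dense_dt_s, p$sparse_dt_s))
}
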