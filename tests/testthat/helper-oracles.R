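# Independent oracles used by the tests. These are deliberately written
# against the underlying mathematics (closed forms, stats::uniroot), not
# against the package implementation they check.

# Closed-form trapezoid duration: rise + plateau + fall phase times.
trapezoid_duration_oracle <- function(rise_rate, peak, plateau, fall_rate) {
  peak / rise_rate + plateau + peak / fall_rate
}

# Depletion-corrected free ligand by stats::uniroot on the mass balance.
depletion_oracle <- function(total, K1, K2, R) {
  if (total == 0) return(0)
  f <- function(L) {
    z1 <- L / K1; z2 <- L^2 / (K1 * K2)
    L + R * (z1 + 2 * z2) / (1 + z1 + z2) - total
  }
  stats::uniroot(f, c(0, total), tol = 1e-14)$root
}

# A minimal noiseless camera for deterministic checks.
quiet_camera <- function(frame_interval = 0.05, sfi = 52.7333333,
                         psf_sigma = 0.09) {
  camera_model(pixel_size = 0.1, frame_interval = frame_interval,
               psf_sigma = psf_sigma, single_fluorophore_intensity = sfi,
               read_noise_sd = 0, shot_noise = FALSE, baseline_offset = 0)
}
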