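# Independent oracles used across the suite. These reimplement the physics
# from first principles (numerical integration, direct summation, grid
# search) so the package code is checked against a second route.

# Phasor of a periodically excited mono-exponential decay by brute-force
# numerical integration over one period (trapezoid on a fine grid).
oracle_phasor_numint <- function(tau, period, harmonic = 1, npts = 2e5) {
  t <- seq(0, period, length.out = npts)
  # wrapped decay: sum over periodic images
  I <- exp(-t / tau) / (1 - exp(-period / tau))
  w <- 2 * pi / period * harmonic
  tot <- pracma_trapz(t, I)
  c(g = pracma_trapz(t, I * cos(w * t)) / tot,
    s = pracma_trapz(t, I * sin(w * t)) / tot)
}

pracma_trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Expected bin probabilities of a wrapped mono-exponential decay,
# independent of the package implementation.
oracle_bin_probs <- function(tau, nbins, period) {
  edges <- seq(0, period, length.out = nbins + 1)
  p <- (exp(-edges[-(nbins + 1)] / tau) - exp(-edges[-1] / tau)) /
    (1 - exp(-period / tau))
  p / sum(p)
}

# Maximum-likelihood single-exponential refit by grid search over tau.
oracle_grid_refit <- function(counts, period, taus) {
  ll <- vapply(taus, function(tau) {
    p <- oracle_bin_probs(tau, length(counts), period)
    sum(counts * log(p))
  }, numeric(1))
  taus[which.max(ll)]
}

# Count-weighted mean wavelength by direct summation.
oracle_com_wavelength <- function(counts, lambda_min, channel_width) {
  lc <- lambda_min + (seq_along(counts) - 0.5) * channel_width
  sum(lc * counts) / sum(counts)
}

# Exact two-sided permutation test on the difference of means, enumerating
# all label assignments (small n only).
oracle_permutation_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  obs <- abs(mean(a) - mean(b))
  combs <- utils::combn(length(pool), n)
  diffs <- apply(combs, 2, function(ix)
    abs(mean(pool[ix]) - mean(pool[-ix])))
  mean(diffs >= obs - 1e-12)
}

# Small acquisition used widely in tests.
test_acq <- function(...) {
  acquisition_config(image_shape = c(16L, 16L), n_time_bins = 128L, ...)
}

single_tau_endmember <- function(tau, peak = 589, fwhm = 30, brightness = 100) {
  endmember_spec(paste0("tau", tau), lifetimes = tau, amplitudes = 1,
                 spectrum_peak = peak, spectrum_fwhm = fwhm,
                 brightness = brightness)
}
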