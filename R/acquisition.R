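#' Acquisition configuration
#'
#' Describes the time and wavelength axes of a two-photon FLIM + spectral
#' acquisition. Defaults follow a typical 80 MHz Ti:Sapphire TCSPC setup with a
#' 32-channel spectral detector covering 410--696 nm in 8.9 nm bins.
#'
#' The TCSPC time axis always spans exactly one laser period `1/rep_rate`
#' divided into `n_time_bins` equal bins; the spectral axis must cover
#' `[lambda_min, lambda_max]` to within one channel width. Channel `c`
#' (0-based) is centred at `lambda_min + (c + 0.5) * channel_width`.
#'
#' @param rep_rate laser repetition rate in Hz.
#' @param n_time_bins number of TCSPC time bins per period.
#' @param image_shape integer vector `c(rows, cols)`.
#' @param lambda_min,lambda_max spectral range in nm.
#' @param n_channels number of spectral detector channels.
#' @param channel_width spectral bin width in nm.
#' @param harmonic Fourier harmonic used by the phasor transforms.
#' @param irf_fwhm full width at half maximum of the Gaussian instrument
#'   response in ps; 0 disables IRF convolution.
#' @return An object of class `acq_config`.
#' @export
#' @examples
#' acq <- acquisition_config()
#' acq$period_ns   # 12.5 ns at 80 MHz
acquisition_config <- function(rep_rate = 80e6, n_time_bins = 256L,
                               image_shape = c(64L, 64L),
                               lambda_min = 410, lambda_max = 696,
                               n_channels = 32L, channel_width = 8.9,
                               harmonic = 1L, irf_fwhm = 0) {
  stopifnot(rep_rate > 0, n_time_bins >= 2, length(image_shape) == 2,
            all(image_shape >= 1), lambda_max > lambda_min,
            n_channels >= 1, channel_width > 0, harmonic >= 1, irf_fwhm >= 0)
  span <- n_channels * channel_width
  rng <- lambda_max - lambda_min
  if (abs(span - rng) > channel_width + 1e-9)
    stop("spectral channels (", span, " nm) must cover the range (",
         rng, " nm) to within one channel width")
  period_ns <- 1e9 / rep_rate
  obj <- list(
    rep_rate = rep_rate,
    n_time_bins = as.integer(n_time_bins),
    image_shape = as.integer(image_shape),
    lambda_min = lambda_min, lambda_max = lambda_max,
    n_channels = as.integer(n_channels), channel_width = channel_width,
    harmonic = as.integer(harmonic), irf_fwhm = irf_fwhm,
    period_ns = period_ns,
    bin_width_ns = period_ns / n_time_bins,
    omega = 2 * pi * rep_rate * 1e-9  # rad/ns, fundamental
  )
  class(obj) <- "acq_config"
  obj
}

#' @export
print.acq_config <- function(x, ...) {
  cat("Acquisition config\n")
  cat(sprintf("  rep rate      : %.3g MHz (period %.4g ns, %d bins of %.4g ps)\n",
              x$rep_rate / 1e6, x$period_ns, x$n_time_bins,
              1e3 * x$bin_width_ns))
  cat(sprintf("  spectral axis : %d channels x %.3g nm over %g-%g nm\n",
              x$n_channels, x$channel_width, x$lambda_min, x$lambda_max))
  cat(sprintf("  image         : %d x %d px, harmonic %d, IRF fwhm %g ps\n",
              x$image_shape[1], x$image_shape[2], x$harmonic, x$irf_fwhm))
  invisible(x)
}

#' Time-bin centres of an acquisition, in ns
#' @param acq an `acq_config`.
#' @return numeric vector of length `n_time_bins`.
#' @export
time_bin_centers <- function(acq) {
  (seq_len(acq$n_time_bins) - 0.5) * acq$bin_width_ns
}

#' Spectral channel centres of an acquisition, in nm
#' @param acq an `acq_config`.
#' @return numeric vector of length `n_channels`.
#' @export
channel_centers <- function(acq) {
  acq$lambda_min + (seq_len(acq$n_channels) - 0.5) * acq$channel_width
}

#' Fluorophore endmember specification
#'
#' A pure species is described by its (multi-exponential) fluorescence decay,
#' a Gaussian emission spectrum, and a mean brightness. Mixture scenes place
#' pixels on the line between two endmember phasors, which is what the
#' downstream fraction decomposition recovers.
#'
#' @param name species label.
#' @param lifetimes decay times in ns, one per exponential component.
#' @param amplitudes pre-exponential amplitude fractions; must be positive and
#'   sum to 1. Recycled to `1` for a single component.
#' @param spectrum_peak emission peak in nm.
#' @param spectrum_fwhm emission full width at half maximum in nm; 0 gives a
#'   delta-like single-channel spectrum.
#' @param brightness mean photons per pixel contributed by this species.
#' @return An object of class `endmember_spec`.
#' @export
#' @examples
#' endmember_eumelanin()
#' endmember_spec("dye", lifetimes = 4.1, spectrum_peak = 520,
#'                spectrum_fwhm = 35, brightness = 500)
endmember_spec <- function(name, lifetimes, amplitudes = NULL,
                          spectrum_peak, spectrum_fwhm, brightness = 100) {
  if (is.null(amplitudes)) amplitudes <- rep(1 / length(lifetimes), length(lifetimes))
  stopifnot(length(lifetimes) == length(amplitudes))
  if (any(lifetimes <= 0)) stop("lifetimes must be > 0 (ns)")
  if (any(amplitudes <= 0) || abs(sum(amplitudes) - 1) > 1e-9)
    stop("amplitudes must be positive and sum to 1")
  if (spectrum_fwhm < 0) stop("spectrum_fwhm must be >= 0")
  if (brightness < 0) stop("brightness must be >= 0")
  obj <- list(name = name, lifetimes = lifetimes, amplitudes = amplitudes,
              spectrum_peak = spectrum_peak, spectrum_fwhm = spectrum_fwhm,
              brightness = brightness)
  class(obj) <- "endmember_spec"
  obj
}

#' @export
print.endmember_spec <- function(x, ...) {
  cat(sprintf("Endmember '%s': tau = {%s} ns (a = {%s}), tau_avg(int) = %.3g ns\n",
              x$name, paste(signif(x$lifetimes, 3), collapse = ", "),
              paste(signif(x$amplitudes, 3), collapse = ", "),
              intensity_avg_lifetime(x$lifetimes, x$amplitudes)))
  cat(sprintf("  emission peak %g nm (fwhm %g nm), brightness %g photons/px\n",
              x$spectrum_peak, x$spectrum_fwhm, x$brightness))
  invisible(x)
}

#' Intensity-weighted average lifetime
#'
#' For a multi-exponential decay with amplitudes `a_i` and lifetimes `tau_i`,
#' the intensity-weighted average lifetime is
#' `sum(a_i * tau_i^2) / sum(a_i * tau_i)`.
#'
#' @param lifetimes decay times in ns.
#' @param amplitudes amplitude fractions.
#' @return average lifetime in ns.
#' @export
intensity_avg_lifetime <- function(lifetimes, amplitudes) {
  sum(amplitudes * lifetimes^2) / sum(amplitudes * lifetimes)
}

#' Default melanin endmembers
#'
#' Eumelanin-like species: short lifetime, red-shifted emission (610 nm, the
#' dark-hair control value); intensity-averaged lifetime about 1.7 ns.
#' Pheomelanin-like species: long lifetime, blue-shifted emission (589 nm, the
#' red-hair control value); intensity-averaged lifetime about 2.4 ns.
#' Both are biexponential, so their phasors sit inside the universal circle as
#' real melanin phasors do. Emission widths are illustrative (60 nm).
#'
#' @param brightness mean photons per pixel.
#' @return An `endmember_spec`.
#' @export
endmember_eumelanin <- function(brightness = 200) {
  endmember_spec("eumelanin", lifetimes = c(0.7, 2.3),
                 amplitudes = c(0.65, 0.35),
                 spectrum_peak = 610, spectrum_fwhm = 60,
                 brightness = brightness)
}

#' @rdname endmember_eumelanin
#' @export
endmember_pheomelanin <- function(brightness = 200) {
  endmember_spec("pheomelanin", lifetimes = c(1.2, 2.95),
                 amplitudes = c(0.5, 0.5),
                 spectrum_peak = 589, spectrum_fwhm = 60,
                 brightness = brightness)
}

#' Optional confounder species
#'
#' NADH-like: short-lived, blue emission, as found in cytoplasm/mitochondria.
#' ECM-like (collagen/elastin): long-lived, blue-green.  Heme-like (porphyrin
#' in red blood cells): red emission near 612 nm.
#'
#' @param brightness mean photons per pixel.
#' @return An `endmember_spec`.
#' @export
endmember_nadh <- function(brightness = 100) {
  endmember_spec("NADH", lifetimes = c(0.4, 2.5), amplitudes = c(0.8, 0.2),
                 spectrum_peak = 460, spectrum_fwhm = 70,
                 brightness = brightness)
}

#' @rdname endmember_nadh
#' @export
endmember_ecm <- function(brightness = 100) {
  endmember_spec("ECM", lifetimes = c(0.3, 3.5), amplitudes = c(0.5, 0.5),
                 spectrum_peak = 480, spectrum_fwhm = 80,
                 brightness = brightness)
}

#' @rdname endmember_nadh
#' @export
endmember_heme <- function(brightness = 100) {
  endmember_spec("heme", lifetimes = c(0.2, 1.5), amplitudes = c(0.85, 0.15),
                 spectrum_peak = 612, spectrum_fwhm = 45,
                 brightness = brightness)
}
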