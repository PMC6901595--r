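#' FLIM image stack
#'
#' Per-pixel TCSPC photon-count histograms. The time axis spans exactly one
#' laser period: `n_time_bins * bin_width_ns = 1e9 / rep_rate`.
#'
#' @param counts rows x cols x n_time_bins array of non-negative counts.
#' @param bin_width_ns TCSPC bin width in ns.
#' @param rep_rate laser repetition rate in Hz.
#' @return An object of class `flim_stack`.
#' @export
flim_stack <- function(counts, bin_width_ns, rep_rate) {
  stopifnot(length(dim(counts)) == 3)
  if (any(counts < 0)) stop("counts must be non-negative")
  period <- 1e9 / rep_rate
  nb <- dim(counts)[3]
  if (abs(nb * bin_width_ns - period) > 1e-9 * period)
    stop("n_time_bins * bin_width (", nb * bin_width_ns,
         " ns) must equal one laser period (", period, " ns)")
  structure(list(counts = counts, bin_width_ns = bin_width_ns,
                 rep_rate = rep_rate,
                 omega = 2 * pi * rep_rate * 1e-9),
            class = "flim_stack")
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("FLIM stack %d x %d px, %d time bins (%.4g ps), %.3g MHz, %.4g total photons\n",
              d[1], d[2], d[3], 1e3 * x$bin_width_ns, x$rep_rate / 1e6,
              sum(x$counts)))
  invisible(x)
}

#' Spectral image stack
#'
#' Per-pixel emission-channel photon counts on a linear wavelength axis.
#'
#' @param counts rows x cols x n_channels array of non-negative counts.
#' @param lambda_min,lambda_max wavelength range in nm.
#' @param channel_width channel width in nm.
#' @param lambda_i initial wavelength of the phasor transform (default
#'   `lambda_min`).
#' @return An object of class `spectral_stack`.
#' @export
spectral_stack <- function(counts, lambda_min, lambda_max, channel_width,
                           lambda_i = lambda_min) {
  stopifnot(length(dim(counts)) == 3)
  if (any(counts < 0)) stop("counts must be non-negative")
  nch <- dim(counts)[3]
  if (abs(nch * channel_width - (lambda_max - lambda_min)) >
      channel_width + 1e-9)
    stop("channels must cover [lambda_min, lambda_max] within one width")
  structure(list(counts = counts, lambda_min = lambda_min,
                 lambda_max = lambda_max, channel_width = channel_width,
                 lambda_i = lambda_i),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Spectral stack %d x %d px, %d channels x %.3g nm over %g-%g nm, %.4g total photons\n",
              d[1], d[2], d[3], x$channel_width, x$lambda_min, x$lambda_max,
              sum(x$counts)))
  invisible(x)
}

#' Phasor field
#'
#' Per-pixel phasor coordinates for either modality, with the total intensity
#' image and a validity mask. Masked-out pixels carry `NA` coordinates.
#'
#' @param g,s numeric matrices of phasor coordinates.
#' @param intensity matrix of per-pixel total counts.
#' @param mask logical matrix: `TRUE` where the phasor is valid.
#' @param harmonic Fourier harmonic used.
#' @param modality `"flim"` or `"spectral"`.
#' @param meta list of axis metadata (omega for FLIM; wavelength axis for
#'   spectral).
#' @return An object of class `phasor_field`.
#' @export
phasor_field <- function(g, s, intensity, mask, harmonic, modality,
                         meta = list()) {
  stopifnot(all(dim(g) == dim(s)), all(dim(g) == dim(intensity)),
            all(dim(g) == dim(mask)))
  modality <- match.arg(modality, c("flim", "spectral"))
  g[!mask] <- NA_real_; s[!mask] <- NA_real_
  structure(list(g = g, s = s, intensity = intensity, mask = mask,
                 harmonic = as.integer(harmonic), modality = modality,
                 meta = meta),
            class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("Phasor field (%s, harmonic %d): %d x %d px, %d unmasked (%.1f%%)\n",
              x$modality, x$harmonic, nrow(x$g), ncol(x$g), sum(x$mask),
              100 * mean(x$mask)))
  if (any(x$mask))
    cat(sprintf("  mean g = %.4f, mean s = %.4f\n",
                mean(x$g[x$mask]), mean(x$s[x$mask])))
  invisible(x)
}

#' Plot a phasor field
#'
#' Scatter of per-pixel (g, s) phasors. For FLIM fields the universal
#' semicircle (radius 1/2 centred at (1/2, 0), on which all single-exponential
#' phasors lie) is overlaid; spectral fields get the unit circle and
#' four-quadrant axes.
#'
#' @param x a `phasor_field`.
#' @param max_points subsample cap for large images.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phasor_field <- function(x, max_points = 20000, ...) {
  gv <- x$g[x$mask]; sv <- x$s[x$mask]
  if (length(gv) > max_points) {
    keep <- seq(1, length(gv), length.out = max_points)
    gv <- gv[keep]; sv <- sv[keep]
  }
  if (x$modality == "flim") {
    graphics::plot(gv, sv, pch = ".", col = grDevices::rgb(0, 0, 0, 0.3),
                   xlim = c(0, 1), ylim = c(0, 0.6), xlab = "g", ylab = "s",
                   ...)
    th <- seq(0, pi, length.out = 200)
    graphics::lines(0.5 + 0.5 * cos(th), 0.5 * sin(th), col = "red")
  } else {
    graphics::plot(gv, sv, pch = ".", col = grDevices::rgb(0, 0, 0, 0.3),
                   xlim = c(-1, 1), ylim = c(-1, 1), xlab = "g", ylab = "s",
                   ...)
    th <- seq(0, 2 * pi, length.out = 400)
    graphics::lines(cos(th), sin(th), col = "red")
    graphics::abline(h = 0, v = 0, col = "grey70")
  }
  invisible(x)
}
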