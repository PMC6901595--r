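# Spectral phasor transform: emission spectra to four-quadrant phasors,
# phase/modulus, and the angle -> peak-wavelength inversion.

spectral_args <- function(stack, harmonic) {
  lc <- stack$lambda_min + (seq_len(dim(stack$counts)[3]) - 0.5) *
    stack$channel_width
  2 * pi * harmonic * (lc - stack$lambda_i) /
    (stack$lambda_max - stack$lambda_min)
}

#' Spectral phasor transform
#'
#' Transforms a spectral stack to per-pixel phasors: with channel-centre
#' wavelengths `lambda_c`,
#' `g = sum(I cos(2 pi n (lambda_c - lambda_i) / (lambda_max - lambda_min))) / sum(I)`
#' and likewise with `sin` for `s`. The plot is four-quadrant with origin
#' (0, 0); a spectrally flat (infinite-width) background lands at the origin,
#' and a red shift moves the phasor counter-clockwise from (1, 0).
#' Zero-count pixels are always masked.
#'
#' @param stack a [spectral_stack()].
#' @param harmonic harmonic number `n >= 1`.
#' @param threshold minimum total counts per pixel (default 1, i.e. only
#'   zero-count pixels masked).
#' @return A [phasor_field()] with `modality = "spectral"`.
#' @export
spectral_phasor <- function(stack, harmonic = 1L, threshold = 1) {
  stopifnot(inherits(stack, "spectral_stack"))
  if (harmonic < 1) stop("harmonic must be >= 1")
  d <- dim(stack$counts)
  npx <- d[1] * d[2]
  arg <- spectral_args(stack, harmonic)
  M <- matrix(stack$counts, nrow = npx, ncol = d[3])
  tot <- rowSums(M)
  ok <- tot >= max(threshold, 1)
  g <- ifelse(ok, as.vector(M %*% cos(arg)) / tot, NA_real_)
  s <- ifelse(ok, as.vector(M %*% sin(arg)) / tot, NA_real_)
  phasor_field(matrix(g, d[1], d[2]), matrix(s, d[1], d[2]),
               matrix(tot, d[1], d[2]), matrix(ok, d[1], d[2]),
               harmonic, "spectral",
               meta = list(lambda_min = stack$lambda_min,
                           lambda_max = stack$lambda_max,
                           lambda_i = stack$lambda_i,
                           channel_width = stack$channel_width))
}

#' Phasor of a single spectrum
#'
#' @param spectrum a `spectrum_vector`.
#' @param harmonic harmonic number.
#' @param lambda_i initial wavelength (default `lambda_min`).
#' @return named vector `c(g, s)`.
#' @export
spectrum_phasor <- function(spectrum, harmonic = 1L, lambda_i = NULL) {
  if (is.null(lambda_i)) lambda_i <- spectrum$lambda_min
  n <- length(spectrum$counts)
  lc <- spectrum$lambda_min + (seq_len(n) - 0.5) * spectrum$channel_width
  arg <- 2 * pi * harmonic * (lc - lambda_i) /
    (spectrum$lambda_max - spectrum$lambda_min)
  tot <- sum(spectrum$counts)
  if (tot <= 0) stop("spectrum has no counts")
  c(g = sum(spectrum$counts * cos(arg)) / tot,
    s = sum(spectrum$counts * sin(arg)) / tot)
}

#' Phase and modulus of a phasor
#'
#' `phi = atan2(s, g)` mapped to `[0, 2 pi)` (counter-clockwise from (1, 0)),
#' `M = sqrt(g^2 + s^2)`. The origin, where the phase is undefined, returns
#' `phi = 0` with `degenerate = TRUE`.
#'
#' @param g,s phasor coordinates (`g` may be a length-2 vector `c(g, s)`).
#' @return list with `phi`, `M`, `degenerate`.
#' @export
#' @examples
#' phase_modulus(0, 1)  # phi = pi/2, M = 1
phase_modulus <- function(g, s = NULL) {
  if (is.null(s)) { s <- g[2]; g <- g[1] }
  M <- sqrt(g^2 + s^2)
  degenerate <- M == 0
  phi <- ifelse(degenerate, 0, atan2(s, g) %% (2 * pi))
  list(phi = phi, M = M, degenerate = degenerate)
}

#' Peak emission wavelength from a spectral phasor angle
#'
#' The angular position of a spectral phasor encodes the centre of mass of
#' the emission spectrum:
#' `lambda = lambda_i + phi (lambda_max - lambda_min) / (2 pi n)`.
#' For a narrow symmetric spectrum this equals its peak wavelength. Angles
#' mapping outside the acquisition range are flagged as aliased but the value
#' is still returned.
#'
#' @param phi phase angle(s) in `[0, 2 pi)`.
#' @param field a spectral [phasor_field()], or a list carrying `lambda_min`,
#'   `lambda_max`, `lambda_i`.
#' @param harmonic harmonic number; defaults to the field's.
#' @return list with `lambda` (nm) and logical `aliased`.
#' @export
peak_wavelength <- function(phi, field, harmonic = NULL) {
  meta <- if (inherits(field, "phasor_field")) field$meta else field
  if (is.null(harmonic))
    harmonic <- if (inherits(field, "phasor_field")) field$harmonic else 1L
  if (any(phi < 0 | phi >= 2 * pi)) stop("phi must lie in [0, 2 pi)")
  li <- if (is.null(meta$lambda_i)) meta$lambda_min else meta$lambda_i
  lambda <- li + unname(phi) * (meta$lambda_max - meta$lambda_min) /
    (2 * pi * harmonic)
  list(lambda = lambda,
       aliased = lambda < meta$lambda_min | lambda > meta$lambda_max)
}
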