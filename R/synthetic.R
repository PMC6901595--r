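# Synthetic TCSPC / spectral data with known ground truth.
#
# Decays are wrapped modulo the laser period (incomplete-decay effect at
# 80 MHz); the per-bin expectation of a unit-area wrapped exponential over
# bin [t0, t1] is (exp(-t0/tau) - exp(-t1/tau)) / (1 - exp(-T/tau)).

# Expected (noiseless) unit-area decay curve of one endmember on the binned
# time axis: amplitude-weighted sum of wrapped exponentials; within a species
# the photon share of component j is a_j*tau_j / sum(a*tau).
decay_shape <- function(spec, acq) {
  edges <- (0:acq$n_time_bins) * acq$bin_width_ns
  Tp <- acq$period_ns
  shape <- numeric(acq$n_time_bins)
  w <- spec$amplitudes * spec$lifetimes
  w <- w / sum(w)
  for (j in seq_along(spec$lifetimes)) {
    tau <- spec$lifetimes[j]
    binint <- (exp(-edges[-length(edges)] / tau) - exp(-edges[-1] / tau)) /
      (1 - exp(-Tp / tau))
    shape <- shape + w[j] * binint
  }
  if (acq$irf_fwhm > 0) shape <- irf_convolve(shape, acq)
  shape
}

# Circular convolution with a period-wrapped Gaussian IRF centred at t = 0.
irf_convolve <- function(shape, acq) {
  n <- length(shape)
  sd_ns <- acq$irf_fwhm / 1000 / (2 * sqrt(2 * log(2)))
  t <- (seq_len(n) - 1) * acq$bin_width_ns
  # wrap distances to the nearest period image
  d <- pmin(t, acq$period_ns - t)
  k <- exp(-d^2 / (2 * sd_ns^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(shape) * stats::fft(k), inverse = TRUE)) / n
}

# Expected unit-area emission spectrum of one endmember on the channel axis.
spectrum_shape <- function(spec, acq) {
  if (spec$spectrum_peak < acq$lambda_min || spec$spectrum_peak > acq$lambda_max)
    stop("spectrum_peak ", spec$spectrum_peak, " nm outside acquisition range [",
         acq$lambda_min, ", ", acq$lambda_max, "] nm")
  edges <- acq$lambda_min + (0:acq$n_channels) * acq$channel_width
  if (spec$spectrum_fwhm <= 0) {
    # delta-like: all counts in the channel containing the peak
    ch <- findInterval(spec$spectrum_peak, edges, rightmost.closed = TRUE)
    ch <- min(max(ch, 1L), acq$n_channels)
    shape <- numeric(acq$n_channels)
    shape[ch] <- 1
    return(shape)
  }
  sd <- spec$spectrum_fwhm / (2 * sqrt(2 * log(2)))
  p <- stats::pnorm(edges, spec$spectrum_peak, sd)
  shape <- diff(p)
  tot <- sum(shape)
  if (tot <= 0) stop("spectrum has no mass inside the acquisition range")
  shape / tot
}

validate_mixture <- function(fractions, total_photons) {
  if (total_photons < 0) stop("total_photons must be >= 0")
  if (any(fractions < 0)) stop("photon fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9) stop("photon fractions must sum to 1")
}

#' Simulate one TCSPC decay histogram
#'
#' Draws a photon-count decay histogram for a mixture of endmember species
#' under periodic excitation. Mixing is by photon (intensity) fraction; the
#' expectation is the fraction-weighted sum of unit-area wrapped exponential
#' decays scaled to `total_photons`, optionally convolved with a Gaussian
#' instrument response, with independent Poisson noise per bin.
#'
#' @param endmembers list of `endmember_spec` objects.
#' @param fractions photon fractions, one per endmember; non-negative, sum 1.
#' @param total_photons expected total photon count.
#' @param acq an [acquisition_config()].
#' @param seed integer seed; identical inputs give bit-identical histograms.
#' @param noiseless if `TRUE`, return the (real-valued) expectation instead of
#'   Poisson counts.
#' @return An object of class `decay_histogram`: list with `counts`,
#'   `bin_width_ns`, `rep_rate`.
#' @export
#' @examples
#' acq <- acquisition_config(n_time_bins = 64)
#' d <- generate_decay(list(endmember_eumelanin()), 1, 1e4, acq, seed = 1)
#' sum(d$counts)
generate_decay <- function(endmembers, fractions, total_photons, acq,
                           seed = 1L, noiseless = FALSE) {
  if (inherits(endmembers, "endmember_spec")) endmembers <- list(endmembers)
  stopifnot(length(endmembers) == length(fractions))
  validate_mixture(fractions, total_photons)
  mu <- numeric(acq$n_time_bins)
  for (i in seq_along(endmembers))
    if (fractions[i] > 0)
      mu <- mu + fractions[i] * decay_shape(endmembers[[i]], acq)
  mu <- mu * total_photons
  counts <- if (noiseless) mu else {
    set.seed(as.integer(seed))
    stats::rpois(length(mu), mu)
  }
  structure(list(counts = counts, bin_width_ns = acq$bin_width_ns,
                 rep_rate = acq$rep_rate),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("TCSPC decay: %d bins of %.4g ps, %.4g total counts\n",
              length(x$counts), 1e3 * x$bin_width_ns, sum(x$counts)))
  invisible(x)
}

#' Simulate one emission spectrum
#'
#' Spectral twin of [generate_decay()]: the expectation is the mixture of
#' channel-integrated Gaussian emission spectra scaled to `total_photons`,
#' with Poisson noise.
#'
#' @inheritParams generate_decay
#' @return An object of class `spectrum_vector`: list with `counts` and the
#'   wavelength-axis metadata.
#' @export
generate_spectrum <- function(endmembers, fractions, total_photons, acq,
                              seed = 1L, noiseless = FALSE) {
  if (inherits(endmembers, "endmember_spec")) endmembers <- list(endmembers)
  stopifnot(length(endmembers) == length(fractions))
  validate_mixture(fractions, total_photons)
  mu <- numeric(acq$n_channels)
  for (i in seq_along(endmembers))
    if (fractions[i] > 0)
      mu <- mu + fractions[i] * spectrum_shape(endmembers[[i]], acq)
  mu <- mu * total_photons
  counts <- if (noiseless) mu else {
    set.seed(as.integer(seed))
    stats::rpois(length(mu), mu)
  }
  structure(list(counts = counts, lambda_min = acq$lambda_min,
                 lambda_max = acq$lambda_max,
                 channel_width = acq$channel_width),
            class = "spectrum_vector")
}

#' Scene layout for synthetic melanocyte images
#'
#' Low-level constructor: a labelled cell mask, a per-pixel eumelanin photon
#' fraction map, and a per-pixel brightness map. Pixels with label 0 are
#' tissue background.
#'
#' @param cell_masks integer matrix of cell labels (0 = background).
#' @param f_eu numeric matrix in `[0, 1]`, eumelanin photon fraction per pixel.
#' @param brightness numeric matrix of expected photons per pixel.
#' @param background optional background `endmember_spec` (e.g. ECM-like);
#'   `NULL` means background pixels are dark.
#' @param background_photons expected photons per background pixel.
#' @return An object of class `scene_layout`.
#' @export
scene_layout <- function(cell_masks, f_eu, brightness,
                         background = NULL, background_photons = 0) {
  stopifnot(is.matrix(cell_masks), all(dim(f_eu) == dim(cell_masks)),
            all(dim(brightness) == dim(cell_masks)))
  if (any(f_eu < 0 | f_eu > 1)) stop("f_eu must lie in [0, 1] everywhere")
  if (any(brightness < 0)) stop("brightness must be >= 0")
  structure(list(cell_masks = cell_masks, f_eu = f_eu, brightness = brightness,
                 background = background,
                 background_photons = background_photons),
            class = "scene_layout")
}

#' Generate a melanocyte-like scene layout
#'
#' Emulates heterogeneously pigmented choroidal melanocytes: each cell is a
#' disk-shaped body with a nuclear void, dense perinuclear melanosome granules,
#' and sparse granules along a few radiating peripheral processes. Each cell
#' carries one eumelanin/pheomelanin photon-fraction ratio; granule pixels are
#' bright, residual cytoplasm is dim.
#'
#' Melanosome size/density statistics are not constrained by published values;
#' the defaults are illustrative and exposed here.
#'
#' @param shape image shape `c(rows, cols)`.
#' @param n_cells number of cells.
#' @param f_eu per-cell eumelanin photon fractions, recycled; default spreads
#'   cells evenly from 0 to 1 (very light to very dark pigmentation).
#' @param granule_photons expected photons per granule pixel.
#' @param cytoplasm_photons expected photons per non-granule cytoplasm pixel.
#' @param cell_radius,nucleus_radius,granule_radius geometry in pixels.
#' @param n_granules perinuclear granules per cell.
#' @param n_processes radiating processes per cell.
#' @param background,background_photons as in [scene_layout()].
#' @param seed integer seed for the layout randomness.
#' @return A `scene_layout`.
#' @export
melanocyte_scene <- function(shape = c(64L, 64L), n_cells = 4L,
                             f_eu = NULL,
                             granule_photons = 300, cytoplasm_photons = 30,
                             cell_radius = NULL, nucleus_radius = NULL,
                             granule_radius = 1.2, n_granules = 25L,
                             n_processes = 3L,
                             background = NULL, background_photons = 0,
                             seed = 1L) {
  rows <- shape[1]; cols <- shape[2]
  if (is.null(f_eu)) f_eu <- seq(0, 1, length.out = n_cells)
  f_eu <- rep_len(f_eu, n_cells)
  if (is.null(cell_radius)) cell_radius <- max(4, round(min(rows, cols) / (2 * ceiling(sqrt(n_cells)) + 1)))
  if (is.null(nucleus_radius)) nucleus_radius <- max(1.5, cell_radius / 3)

  set.seed(as.integer(seed))
  labels <- matrix(0L, rows, cols)
  fmap <- matrix(0, rows, cols)
  bright <- matrix(0, rows, cols)
  rr <- row(labels); cc <- col(labels)

  # cell centres on a jittered grid so bodies rarely overlap
  k <- ceiling(sqrt(n_cells))
  centers <- expand.grid(
    r = seq(cell_radius + 1, rows - cell_radius, length.out = k),
    c = seq(cell_radius + 1, cols - cell_radius, length.out = k))
  centers <- centers[seq_len(n_cells), , drop = FALSE]
  centers$r <- centers$r + stats::runif(n_cells, -2, 2)
  centers$c <- centers$c + stats::runif(n_cells, -2, 2)

  for (i in seq_len(n_cells)) {
    cr <- centers$r[i]; cxy <- centers$c[i]
    d2 <- (rr - cr)^2 + (cc - cxy)^2
    body <- d2 <= cell_radius^2
    nucleus <- d2 <= nucleus_radius^2
    cyto <- body & !nucleus
    labels[cyto] <- i
    fmap[cyto] <- f_eu[i]
    bright[cyto] <- cytoplasm_photons
    # perinuclear granules
    ang <- stats::runif(n_granules, 0, 2 * pi)
    rad <- nucleus_radius + stats::runif(n_granules, 0.5, cell_radius - nucleus_radius - 0.5)
    gr <- cbind(cr + rad * sin(ang), cxy + rad * cos(ang))
    # peripheral processes with sparse granules
    pang <- stats::runif(n_processes, 0, 2 * pi)
    for (p in seq_len(n_processes)) {
      steps <- seq(cell_radius, cell_radius * 1.8, by = 1.5)
      gr <- rbind(gr, cbind(cr + steps * sin(pang[p]), cxy + steps * cos(pang[p])))
    }
    for (gidx in seq_len(nrow(gr))) {
      g2 <- (rr - gr[gidx, 1])^2 + (cc - gr[gidx, 2])^2
      hit <- g2 <= granule_radius^2 & !nucleus
      hit <- hit & rr >= 1 & cc >= 1
      labels[hit] <- i
      fmap[hit] <- f_eu[i]
      bright[hit] <- granule_photons
    }
  }
  scene_layout(labels, fmap, bright, background = background,
               background_photons = background_photons)
}

#' @export
print.scene_layout <- function(x, ...) {
  cat(sprintf("Scene layout %d x %d px, %d cells, %d lit pixels\n",
              nrow(x$cell_masks), ncol(x$cell_masks),
              length(setdiff(unique(as.vector(x$cell_masks)), 0L)),
              sum(x$brightness > 0)))
  invisible(x)
}

# Shared workhorse: per-pixel expectation cube for either modality, plus the
# ground truth. Pixels are grouped by unique (f_eu, brightness) to avoid
# recomputing mixture shapes.
scene_expectation <- function(layout, endA, endB, acq, modality,
                              snr_scale = 1) {
  shapeA <- if (modality == "flim") decay_shape(endA, acq) else spectrum_shape(endA, acq)
  shapeB <- if (modality == "flim") decay_shape(endB, acq) else spectrum_shape(endB, acq)
  nbin <- length(shapeA)
  rows <- nrow(layout$cell_masks); cols <- ncol(layout$cell_masks)
  mu <- array(0, dim = c(rows, cols, nbin))
  lit <- layout$brightness > 0
  if (any(lit)) {
    key <- paste(layout$f_eu[lit], layout$brightness[lit])
    idx <- which(lit)
    for (k in unique(key)) {
      sel <- idx[key == k]
      f <- layout$f_eu[sel[1]]; b <- layout$brightness[sel[1]]
      curve <- snr_scale * b * (f * shapeA + (1 - f) * shapeB)
      for (j in seq_len(nbin)) mu[sel + (j - 1) * rows * cols] <- curve[j]
    }
  }
  if (!is.null(layout$background) && layout$background_photons > 0) {
    bg <- layout$cell_masks == 0 & !lit
    if (any(bg)) {
      shapeBG <- if (modality == "flim") decay_shape(layout$background, acq)
                 else spectrum_shape(layout$background, acq)
      curve <- snr_scale * layout$background_photons * shapeBG
      selbg <- which(bg)
      for (j in seq_len(nbin)) mu[selbg + (j - 1) * rows * cols] <- curve[j]
    }
  }
  mu
}

ground_truth <- function(layout, acq, mu, seed) {
  structure(list(f_eu = layout$f_eu,
                 species = layout$cell_masks,
                 expected_photons = apply(mu, c(1, 2), sum),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate a synthetic FLIM image stack
#'
#' Assembles per-pixel decay histograms for a scene: each lit pixel mixes the
#' two endmember decays by its eumelanin photon fraction, scaled to its
#' brightness, with Poisson noise. Returns the stack together with the ground
#' truth (fraction map, species labels, expected photons, seed).
#'
#' @param layout a [scene_layout()] / [melanocyte_scene()].
#' @param endA,endB endmember specs; `f_eu` is the photon fraction of `endA`.
#' @param acq an [acquisition_config()].
#' @param seed integer seed; (layout, endmembers, acq, seed) determine the
#'   stack bit-exactly.
#' @param noiseless if `TRUE`, counts are the real-valued expectation.
#' @return list with elements `stack` (a `flim_stack`) and `truth`
#'   (a `ground_truth`).
#' @export
generate_flim_stack <- function(layout, endA = endmember_eumelanin(),
                                endB = endmember_pheomelanin(), acq,
                                seed = 1L, noiseless = FALSE) {
  if (!all(dim(layout$cell_masks) == acq$image_shape))
    stop("layout shape ", paste(dim(layout$cell_masks), collapse = "x"),
         " does not match acq image_shape ",
         paste(acq$image_shape, collapse = "x"))
  mu <- scene_expectation(layout, endA, endB, acq, "flim")
  counts <- mu
  if (!noiseless) {
    set.seed(as.integer(seed))
    counts <- array(stats::rpois(length(mu), mu), dim = dim(mu))
  }
  stack <- flim_stack(counts, bin_width_ns = acq$bin_width_ns,
                      rep_rate = acq$rep_rate)
  list(stack = stack, truth = ground_truth(layout, acq, mu, seed))
}

#' Generate a synthetic spectral image stack
#'
#' Spectral twin of [generate_flim_stack()]; the same layout yields the same
#' ground-truth fraction map, so matched FLIM/spectral segmentations can be
#' compared. `snr_scale < 1` emulates the poorer photon budget of descanned
#' spectral detection by scaling every pixel's expected photons.
#'
#' @inheritParams generate_flim_stack
#' @param snr_scale multiplicative photon-budget factor in `(0, 1]`.
#' @return list with elements `stack` (a `spectral_stack`) and `truth`.
#' @export
generate_spectral_stack <- function(layout, endA = endmember_eumelanin(),
                                    endB = endmember_pheomelanin(), acq,
                                    seed = 1L, noiseless = FALSE,
                                    snr_scale = 1) {
  if (!all(dim(layout$cell_masks) == acq$image_shape))
    stop("layout shape does not match acq image_shape")
  stopifnot(snr_scale > 0, snr_scale <= 1)
  mu <- scene_expectation(layout, endA, endB, acq, "spectral", snr_scale)
  counts <- mu
  if (!noiseless) {
    set.seed(as.integer(seed))
    counts <- array(stats::rpois(length(mu), mu), dim = dim(mu))
  }
  stack <- spectral_stack(counts, lambda_min = acq$lambda_min,
                          lambda_max = acq$lambda_max,
                          channel_width = acq$channel_width)
  list(stack = stack, truth = ground_truth(layout, acq, mu, seed))
}
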