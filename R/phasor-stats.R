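# Region-level phasor statistics: average points, population SDs, s-value
# t tests, linearity scoring, and the shot-noise scaling check.

region_indices <- function(regions, dim_field) {
  if (is.matrix(regions) && !is.list(regions)) {
    # label-mask form: one region per nonzero label
    labs <- sort(setdiff(unique(as.vector(regions)), c(0, NA)))
    out <- lapply(labs, function(l) which(regions == l))
    names(out) <- as.character(labs)
    return(out)
  }
  if (!is.list(regions)) stop("regions must be a label matrix or a list of pixel index vectors")
  if (is.null(names(regions))) names(regions) <- as.character(seq_along(regions))
  regions
}

#' Average phasor points of image regions
#'
#' For each region (a set of pixel indices, or one label of a label mask),
#' computes the photon-weighted mean (g, s) over its unmasked pixels --- the
#' "average point" of the region's phasor cluster. Set `weighted = FALSE`
#' for the unweighted pixel mean.
#'
#' @param field a [phasor_field()].
#' @param regions label matrix (0 = outside) or named list of pixel index
#'   vectors (linear indices into the image).
#' @param weighted photon-weighted (default) or plain mean.
#' @return data frame with one row per region: `region`, `g`, `s`,
#'   `photons`, `n_pixels`.
#' @export
region_average_points <- function(field, regions, weighted = TRUE) {
  stopifnot(inherits(field, "phasor_field"))
  idx <- region_indices(regions, dim(field$g))
  if (length(idx) < 1) stop("need at least one region")
  rows <- lapply(names(idx), function(nm) {
    px <- idx[[nm]]
    if (length(px) == 0) stop("region '", nm, "' is empty")
    px <- px[field$mask[px]]
    if (length(px) == 0) stop("region '", nm, "' contains no unmasked pixels")
    w <- if (weighted) field$intensity[px] else rep(1, length(px))
    data.frame(region = nm,
               g = sum(w * field$g[px]) / sum(w),
               s = sum(w * field$s[px]) / sum(w),
               photons = sum(field$intensity[px]),
               n_pixels = length(px))
  })
  do.call(rbind, rows)
}

#' Summary of a population of average points
#'
#' Sample standard deviations (n - 1 denominator) of the g and s coordinates
#' across a group of average points.
#'
#' @param points data frame with `g` and `s` columns (as returned by
#'   [region_average_points()]).
#' @return list with `n`, `mean_g`, `mean_s`, `sd_g`, `sd_s`.
#' @export
population_summary <- function(points) {
  if (nrow(points) < 2) stop("need at least 2 average points")
  list(n = nrow(points),
       mean_g = mean(points$g), mean_s = mean(points$s),
       sd_g = stats::sd(points$g), sd_s = stats::sd(points$s))
}

#' Two-sample t test on s values of average-point populations
#'
#' Tests whether two populations of phasor average points differ in their
#' s coordinate (two-sided). Welch's unequal-variance form is the default;
#' `var.equal = TRUE` gives the pooled Student form. Two identical
#' zero-variance populations return `p = 1` with a degenerate flag rather
#' than an error.
#'
#' @param popA,popB data frames with an `s` column, or plain numeric vectors
#'   of s values; each of length `>= 2`.
#' @param alpha significance level (default 0.05).
#' @param var.equal use pooled-variance Student's t.
#' @return list with `t`, `df`, `p_value`, `significant`, `alpha`,
#'   `degenerate`.
#' @export
s_value_ttest <- function(popA, popB, alpha = 0.05, var.equal = FALSE) {
  sA <- if (is.data.frame(popA)) popA$s else as.numeric(popA)
  sB <- if (is.data.frame(popB)) popB$s else as.numeric(popB)
  if (length(sA) < 2 || length(sB) < 2)
    stop("each population needs at least 2 points")
  if (stats::sd(sA) == 0 && stats::sd(sB) == 0) {
    if (mean(sA) == mean(sB))
      return(list(t = 0, df = NA_real_, p_value = 1, significant = FALSE,
                  alpha = alpha, degenerate = TRUE))
    return(list(t = sign(mean(sA) - mean(sB)) * Inf, df = NA_real_,
                p_value = 0, significant = TRUE, alpha = alpha,
                degenerate = TRUE))
  }
  tt <- stats::t.test(sA, sB, var.equal = var.equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       alpha = alpha, degenerate = FALSE)
}

#' Linearity of a phasor point cloud
#'
#' Total-least-squares line through a set of (g, s) points (first principal
#' direction through the centroid); reports the perpendicular RMS residual
#' and the fraction of variance captured by the line. A linear distribution
#' is the phasor signature of a two-fluorophore mixture series.
#'
#' @param points data frame with `g`, `s` columns, or a 2-column matrix.
#' @return An object of class `linearity_report`: `direction`, `centroid`,
#'   `rms_residual`, `r_squared`, `degenerate`.
#' @export
linearity_score <- function(points) {
  P <- if (is.data.frame(points)) cbind(points$g, points$s) else as.matrix(points)
  if (nrow(P) < 3) stop("need at least 3 points")
  ctr <- colMeans(P)
  X <- sweep(P, 2, ctr)
  if (all(abs(X) < 1e-15))
    return(structure(list(direction = c(1, 0), centroid = ctr,
                          rms_residual = 0, r_squared = NA_real_,
                          degenerate = TRUE),
                     class = "linearity_report"))
  sv <- svd(X)
  resid <- X %*% sv$v[, 2]
  structure(list(direction = sv$v[, 1], centroid = ctr,
                 rms_residual = sqrt(mean(resid^2)),
                 r_squared = sv$d[1]^2 / sum(sv$d^2),
                 degenerate = FALSE),
            class = "linearity_report")
}

#' @export
print.linearity_report <- function(x, ...) {
  if (x$degenerate) {
    cat("Linearity: degenerate (all points identical)\n")
  } else {
    cat(sprintf("Linearity: perpendicular RMS %.4g, R^2 = %.5f\n",
                x$rms_residual, x$r_squared))
  }
  invisible(x)
}

#' Shot-noise scaling of phasor scatter
#'
#' Simulates repeated single-pixel decays of one endmember at several photon
#' counts and measures the spread of the phasor position,
#' `SD = sqrt(var(g) + var(s))`, at each level, plus the fitted log-log
#' slope of SD versus N. Phasor scatter follows shot noise: SD is
#' proportional to `1 / sqrt(N)`, so the slope is -1/2.
#'
#' @param spec an [endmember_spec()] to simulate.
#' @param acq an [acquisition_config()].
#' @param photon_levels vector of expected photon counts (`>= 2` levels).
#' @param replicates reseeded replicates per level.
#' @param seed master seed.
#' @param harmonic phasor harmonic.
#' @return list with `table` (data frame `N`, `sd`) and `slope`.
#' @export
photon_scaling_check <- function(spec, acq, photon_levels = c(100, 400, 1600, 6400),
                                 replicates = 500, seed = 1L, harmonic = 1L) {
  if (length(photon_levels) < 2) stop("need at least 2 photon levels")
  shape <- decay_shape(spec, acq)
  tk <- time_bin_centers(acq)
  arg <- harmonic * acq$omega * tk
  cw <- cos(arg); sw <- sin(arg)
  set.seed(as.integer(seed))
  sds <- vapply(photon_levels, function(N) {
    mu <- N * shape
    gs <- vapply(seq_len(replicates), function(r) {
      y <- stats::rpois(length(mu), mu)
      tot <- sum(y)
      if (tot == 0) return(c(NA_real_, NA_real_))
      c(sum(y * cw) / tot, sum(y * sw) / tot)
    }, numeric(2))
    sqrt(stats::var(gs[1, ], na.rm = TRUE) + stats::var(gs[2, ], na.rm = TRUE))
  }, numeric(1))
  tab <- data.frame(N = photon_levels, sd = sds)
  slope <- unname(stats::coef(stats::lm(log(sd) ~ log(N), data = tab))[2])
  list(table = tab, slope = slope)
}
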