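# Cursor-based segmentation of phasor plots back onto image pixels, and the
# quantitative melanin ratio-fraction profile.

#' Circular phasor cursor
#'
#' A colored circular selection region on the phasor plot; pixels whose
#' phasor falls inside the disk are mapped back to the image with the
#' cursor's label. Cursor size and position are free parameters chosen to
#' match the phasor distribution under study.
#'
#' @param id unique integer id.
#' @param g,s centre coordinates in phasor space.
#' @param radius disk radius, `> 0`.
#' @param color display color label.
#' @return An object of class `cursor`.
#' @export
cursor <- function(id, g, s, radius, color = NA_character_) {
  if (radius <= 0) stop("cursor radius must be > 0")
  structure(list(id = as.integer(id), g = g, s = s, radius = radius,
                 color = color),
            class = "cursor")
}

#' Ordered set of cursors
#'
#' @param ... `cursor` objects, or a single list of them.
#' @return An object of class `cursor_set`.
#' @export
cursor_set <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && !inherits(cs[[1]], "cursor")) cs <- cs[[1]]
  ids <- vapply(cs, function(x) x$id, integer(1))
  if (anyDuplicated(ids)) stop("cursor ids must be unique")
  structure(cs, class = "cursor_set")
}

#' @export
print.cursor_set <- function(x, ...) {
  cat(sprintf("Cursor set: %d cursors\n", length(x)))
  for (cu in x)
    cat(sprintf("  #%d at (%.4f, %.4f) r = %.3g [%s]\n",
                cu$id, cu$g, cu$s, cu$radius, cu$color))
  invisible(x)
}

#' @export
as.data.frame.cursor_set <- function(x, ...) {
  data.frame(id = vapply(x, `[[`, integer(1), "id"),
             g = vapply(x, `[[`, numeric(1), "g"),
             s = vapply(x, `[[`, numeric(1), "s"),
             radius = vapply(x, `[[`, numeric(1), "radius"),
             color = vapply(x, `[[`, character(1), "color"))
}

#' Place cursors evenly along an endmember segment
#'
#' Programmatic stand-in for manual cursor placement: `k` cursors with
#' centres evenly spaced on the segment from endmember A to endmember B
#' (consecutive spacing `|AB| / (k - 1)`), ids ordered `1..k` from A to B.
#' With `k = 7` this reproduces the seven-cluster eumelanin-to-pheomelanin
#' segmentation scheme.
#'
#' @param pair an [endmember_pair()].
#' @param k number of cursors, `>= 2`.
#' @param radius common cursor radius.
#' @param colors optional color labels, recycled.
#' @return A [cursor_set()].
#' @export
place_cursors_on_segment <- function(pair, k = 7L, radius,
                                     colors = grDevices::hcl.colors(k, "Zissou 1")) {
  stopifnot(inherits(pair, "endmember_pair"), k >= 2)
  tt <- seq(0, 1, length.out = k)
  colors <- rep_len(colors, k)
  cursor_set(lapply(seq_len(k), function(i) {
    cursor(i, pair$A[1] + tt[i] * (pair$B[1] - pair$A[1]),
           pair$A[2] + tt[i] * (pair$B[2] - pair$A[2]),
           radius, colors[i])
  }))
}

#' Assign image pixels to phasor cursors
#'
#' Each unmasked pixel is assigned to the cursor whose disk contains its
#' (g, s) phasor; pixels inside several disks go to the nearest cursor centre
#' (Euclidean distance in phasor space), exact ties to the lowest cursor id;
#' pixels in no disk stay unlabelled (`NA`). Pure function: the same field
#' and cursors always yield the identical map.
#'
#' @param field a [phasor_field()].
#' @param cursors a [cursor_set()].
#' @return An object of class `segmentation_map`: integer label matrix
#'   (`NA` = unlabelled) plus the cursors.
#' @export
assign_pixels <- function(field, cursors) {
  stopifnot(inherits(field, "phasor_field"), inherits(cursors, "cursor_set"))
  labels <- matrix(NA_integer_, nrow(field$g), ncol(field$g))
  best <- matrix(Inf, nrow(field$g), ncol(field$g))
  ids <- vapply(cursors, `[[`, integer(1), "id")
  for (ci in order(ids)) {
    cu <- cursors[[ci]]
    d2 <- (field$g - cu$g)^2 + (field$s - cu$s)^2
    hit <- field$mask & !is.na(d2) & d2 <= cu$radius^2 & d2 < best
    labels[hit] <- cu$id
    best[hit] <- d2[hit]
  }
  structure(list(labels = labels, cursors = cursors),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  tab <- table(x$labels, useNA = "no")
  cat(sprintf("Segmentation map %d x %d px, %d labelled\n",
              nrow(x$labels), ncol(x$labels), sum(!is.na(x$labels))))
  for (id in names(tab)) cat(sprintf("  cursor %s: %d px\n", id, tab[[id]]))
  invisible(x)
}

#' Ratio fraction of a phasor cluster
#'
#' The melanin-profile statistic: number of image pixels mapped to the
#' cursor's phasor cluster divided by the total pixels of the sampled image
#' field. The denominator is the full image (masked pixels included), so
#' fractions over all cursors sum to at most 1.
#'
#' @param segmap a [assign_pixels()] result.
#' @param id cursor id.
#' @return fraction in `[0, 1]`.
#' @export
ratio_fraction <- function(segmap, id) {
  stopifnot(inherits(segmap, "segmentation_map"))
  ids <- vapply(segmap$cursors, `[[`, integer(1), "id")
  if (!id %in% ids) stop("unknown cursor id: ", id)
  sum(segmap$labels == id, na.rm = TRUE) / length(segmap$labels)
}

# Order cursors along the eumelanin -> pheomelanin direction: by projection
# onto the principal axis of the cursor centres, oriented so that phase angle
# increases (FLIM: longer lifetime) or decreases (spectral: blue shift).
order_cursors <- function(cursors, modality) {
  df <- as.data.frame(cursors)
  if (nrow(unique(df[, c("g", "s")])) < 2)
    stop("cursor set not orderable: identical centres")
  ctr <- cbind(df$g - mean(df$g), df$s - mean(df$s))
  dir <- svd(ctr)$v[, 1]
  proj <- ctr %*% dir
  ang <- atan2(df$s, df$g)
  or <- as.numeric(stats::cor(proj[, 1], ang))
  sgn <- if (modality == "flim") sign(or) else -sign(or)
  if (is.na(sgn) || sgn == 0) sgn <- 1
  df$order_key <- sgn * proj[, 1]
  df[order(df$order_key), ]
}

#' Quantitative melanin profile
#'
#' The melanin histogram: per-cursor ratio fractions ordered along the
#' eumelanin-to-pheomelanin axis (FLIM: increasing phase angle from (1, 0),
#' i.e. lengthening lifetime; spectral: decreasing angle, i.e. blue shift),
#' with each cluster's mean phasor and, for spectral fields, the peak
#' emission wavelength of its centre of mass.
#'
#' @param segmap a segmentation map from [assign_pixels()].
#' @param field the [phasor_field()] that was segmented.
#' @param cursors optional cursor set (defaults to the one in `segmap`).
#' @return An object of class `melanin_profile`: a data frame with one row
#'   per cursor in profile order: `rank`, `id`, `fraction`, `n_pixels`,
#'   `mean_g`, `mean_s`, and `peak_lambda` for spectral fields.
#' @export
melanin_profile <- function(segmap, field, cursors = NULL) {
  stopifnot(inherits(segmap, "segmentation_map"),
            inherits(field, "phasor_field"))
  if (is.null(cursors)) cursors <- segmap$cursors
  if (length(cursors) < 2) stop("need at least 2 cursors for a profile")
  df <- order_cursors(cursors, field$modality)
  df$rank <- seq_len(nrow(df))
  df$fraction <- vapply(df$id, function(i) ratio_fraction(segmap, i), numeric(1))
  df$n_pixels <- vapply(df$id, function(i)
    sum(segmap$labels == i, na.rm = TRUE), numeric(1))
  df$mean_g <- NA_real_; df$mean_s <- NA_real_
  for (r in seq_len(nrow(df))) {
    in_cl <- !is.na(segmap$labels) & segmap$labels == df$id[r]
    if (any(in_cl)) {
      w <- field$intensity[in_cl]
      df$mean_g[r] <- sum(w * field$g[in_cl]) / sum(w)
      df$mean_s[r] <- sum(w * field$s[in_cl]) / sum(w)
    }
  }
  if (field$modality == "spectral") {
    pm <- phase_modulus(df$mean_g, df$mean_s)
    df$peak_lambda <- ifelse(is.na(df$mean_g), NA_real_,
                             peak_wavelength(ifelse(is.na(pm$phi), 0, pm$phi),
                                             field)$lambda)
  }
  rownames(df) <- NULL
  cols <- c("rank", "id", "fraction", "n_pixels", "mean_g", "mean_s",
            intersect("peak_lambda", names(df)))
  structure(df[, cols], class = c("melanin_profile", "data.frame"),
            modality = field$modality, total_pixels = length(segmap$labels))
}

#' @export
print.melanin_profile <- function(x, ...) {
  cat(sprintf("Melanin profile (%s), %d clusters over %d px:\n",
              attr(x, "modality"), nrow(x), attr(x, "total_pixels")))
  print.data.frame(cbind(cluster = tolower(utils::as.roman(x$rank)),
                         x[, -1]), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Bar-plot of a melanin profile
#'
#' @param x a `melanin_profile`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.melanin_profile <- function(x, ...) {
  graphics::barplot(x$fraction,
                    names.arg = tolower(utils::as.roman(x$rank)),
                    xlab = "phasor cluster (eumelanin -> pheomelanin)",
                    ylab = "ratio fraction", ...)
  invisible(x)
}
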