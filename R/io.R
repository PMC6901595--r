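# On-disk artifacts: multi-page TIFF (one page per time bin / channel) with a
# JSON sidecar carrying the axis metadata, plus cursor JSON and CSV outputs.
# 16-bit unsigned pages for counts; promoted to scaled 32-bit samples when a
# count exceeds 65535 (noted in the sidecar).

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Write an image stack as multi-page TIFF + JSON sidecar
#'
#' One grayscale page per time bin (FLIM) or spectral channel; 16-bit unsigned
#' counts, promoted to scaled 32-bit samples with a sidecar note if any count
#' exceeds 65535 or is non-integer. The sidecar records the modality and axis
#' metadata so [read_stack()] can rebuild the object exactly.
#'
#' @param stack a [flim_stack()] or [spectral_stack()].
#' @param path output TIFF path; the sidecar goes next to it as `.json`.
#' @param seed optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, seed = NULL) {
  counts <- stack$counts
  d <- dim(counts)
  integer_counts <- all(counts == round(counts))
  wide <- max(counts) > 65535 || !integer_counts
  # wide pages go out as 32-bit samples scaled into [0, 1) by a power of two;
  # the scale lives in the sidecar and integer counts round-trip exactly
  scale <- if (wide) 2^ceiling(log2(max(counts, 1) + 1)) else 65535
  pages <- lapply(seq_len(d[3]), function(k) counts[, , k] / scale)
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (wide) 32L else 16L,
                  compression = "none", reduce = FALSE)
  meta <- if (inherits(stack, "flim_stack")) {
    list(modality = "flim", bin_width_ns = stack$bin_width_ns,
         rep_rate = stack$rep_rate)
  } else {
    list(modality = "spectral", lambda_min = stack$lambda_min,
         lambda_max = stack$lambda_max, channel_width = stack$channel_width,
         lambda_i = stack$lambda_i)
  }
  meta$shape <- d
  meta$pixel_format <- if (wide) "uint32_scaled" else "uint16"
  meta$integer_counts <- integer_counts
  if (wide) {
    meta$scale <- scale
    meta$note <- "counts exceed the 16-bit range; promoted to scaled 32-bit"
  }
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Modality is inferred from the sidecar; counts and metadata round-trip
#' bit-exactly. Inconsistent sidecars (page-count mismatch, negative counts)
#' raise descriptive errors.
#'
#' @param path TIFF path with its `.json` sidecar alongside.
#' @return A `flim_stack` or `spectral_stack`.
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  wide <- identical(meta$pixel_format, "uint32_scaled")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !wide)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$shape[3])
    stop("sidecar declares ", meta$shape[3], " pages but TIFF holds ",
         length(pages))
  counts <- array(0, dim = meta$shape)
  for (k in seq_along(pages)) counts[, , k] <- pages[[k]]
  if (wide) {
    counts <- counts * meta$scale
    if (isTRUE(meta$integer_counts)) counts <- round(counts)
  }
  if (any(counts < 0)) stop("negative counts in ", path)
  if (identical(meta$modality, "flim")) {
    flim_stack(counts, bin_width_ns = meta$bin_width_ns,
               rep_rate = meta$rep_rate)
  } else if (identical(meta$modality, "spectral")) {
    spectral_stack(counts, lambda_min = meta$lambda_min,
                   lambda_max = meta$lambda_max,
                   channel_width = meta$channel_width,
                   lambda_i = meta$lambda_i)
  } else stop("sidecar has unknown modality: ", meta$modality)
}

#' Write a phasor field as 32-bit TIFF + JSON sidecar
#'
#' Four pages: g, s, intensity, mask (masked-out g/s stored as 0).
#'
#' @param field a [phasor_field()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_phasor_field <- function(field, path) {
  z <- function(m) { m[is.na(m)] <- 0; m }
  # 32-bit pages must lie in [0, 1]: g and s are mapped from [-1, 1] via
  # (x + 1) / 2, intensity scaled by a power of two; recorded in the sidecar
  iscale <- 2^ceiling(log2(max(field$intensity, 1)))
  pages <- list((z(field$g) + 1) / 2, (z(field$s) + 1) / 2,
                field$intensity / iscale, field$mask + 0)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(type = "phasor_field", modality = field$modality,
               harmonic = field$harmonic,
               pages = c("g", "s", "intensity", "mask"),
               intensity_scale = iscale,
               meta = field$meta)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a phasor field written by [write_phasor_field()]
#' @param path TIFF path.
#' @return A [phasor_field()].
#' @export
read_phasor_field <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  mask <- pages[[4]] > 0.5
  phasor_field(2 * pages[[1]] - 1, 2 * pages[[2]] - 1,
               pages[[3]] * meta$intensity_scale, mask,
               harmonic = meta$harmonic, modality = meta$modality,
               meta = as.list(meta$meta))
}

#' Write / read cursors as JSON
#'
#' Cursors are stored as a JSON list of `{id, g, s, radius, color}`.
#'
#' @param cursors a [cursor_set()].
#' @param path JSON path.
#' @return `path` invisibly (write); a `cursor_set` (read).
#' @export
write_cursors <- function(cursors, path) {
  jsonlite::write_json(as.data.frame(cursors), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cursors
#' @export
read_cursors <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  cursor_set(lapply(seq_len(nrow(df)), function(i)
    cursor(df$id[i], df$g[i], df$s[i], df$radius[i],
           if ("color" %in% names(df)) df$color[i] else NA_character_)))
}

pipeline_config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    acquisition = list(rep_rate = 80e6, n_time_bins = 256L,
                       image_shape = c(64L, 64L), lambda_min = 410,
                       lambda_max = 696, n_channels = 32L,
                       channel_width = 8.9, harmonic = 1L, irf_fwhm = 0),
    scene = list(n_cells = 4L, f_eu = NULL, granule_photons = 300,
                 cytoplasm_photons = 30, granule_radius = 1.2,
                 n_granules = 25L, n_processes = 3L),
    analysis = list(harmonic = 1L, threshold = 20, calibration_tau = 4.1,
                    efilter_passes = 1L, efilter_kernel = 3L,
                    n_cursors = 7L, cursor_radius = 0.04, alpha = 0.05,
                    modality = "flim")
  )
}

validate_config <- function(config) {
  def <- pipeline_config_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (blk in c("acquisition", "scene", "analysis")) {
    bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
    if (length(bad))
      stop("unknown keys in '", blk, "' block: ", paste(bad, collapse = ", "))
    def[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  for (k in c("seed", "out_dir")) if (!is.null(config[[k]])) def[[k]] <- config[[k]]
  def
}

log_stage <- function(stage, cfg_hash, seed, t0) {
  message(sprintf("[melphasor] stage=%s config=%s seed=%d elapsed=%.2fs",
                  stage, cfg_hash, seed,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the end-to-end melanin profiling pipeline
#'
#' Simulate a melanocyte scene, transform to phasors, E-filter, calibrate,
#' place seven cursors on the eumelanin--pheomelanin segment, segment the
#' image, and write the melanin ratio-fraction profile plus region-level
#' phasor statistics. Every output is listed (with its MD5 hash) in a
#' manifest, so two runs with the same config and seed produce byte-identical
#' manifests.
#'
#' @param config a config list, or path to a JSON config file. Recognized
#'   blocks: `acquisition`, `scene`, `analysis`, plus `seed` and `out_dir`;
#'   unknown keys are rejected. See `inst/extdata/demo_config.json`.
#' @param out_dir output directory; overrides the config's.
#' @return Invisibly, the manifest (named list of file MD5 hashes, plus the
#'   profile as a data frame).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  t0 <- proc.time()[3]
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- validate_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- substr(digest_obj(cfg[setdiff(names(cfg), "out_dir")]), 1, 12)
  seed <- as.integer(cfg$seed)

  acq <- do.call(acquisition_config, cfg$acquisition)
  scene_args <- cfg$scene
  scene_args$shape <- acq$image_shape
  scene_args$seed <- seed
  scene <- do.call(melanocyte_scene, scene_args)
  log_stage("scene", cfg_hash, seed, t0)

  endA <- endmember_eumelanin(); endB <- endmember_pheomelanin()
  sim <- generate_flim_stack(scene, endA, endB, acq, seed = seed + 1L)
  f_stack <- file.path(cfg$out_dir, "flim_stack.tif")
  write_stack(sim$stack, f_stack, seed = seed + 1L)
  log_stage("simulate", cfg_hash, seed, t0)

  an <- cfg$analysis
  field <- flim_phasor(sim$stack, harmonic = an$harmonic,
                       threshold = an$threshold)
  if (!is.null(an$calibration_tau)) {
    ref_decay <- generate_decay(
      list(endmember_spec("ref", an$calibration_tau, 1, 520, 35)), 1,
      1e7, acq, seed = seed + 2L)
    field <- calibrate(field, calibration_ref(ref_decay,
                                              tau_ref = an$calibration_tau,
                                              harmonic = an$harmonic))
  }
  if (an$efilter_passes >= 1)
    field <- efilter(field, passes = an$efilter_passes,
                     kernel = an$efilter_kernel)
  f_field <- file.path(cfg$out_dir, "phasor_field.tif")
  write_phasor_field(field, f_field)
  log_stage("phasor", cfg_hash, seed, t0)

  pair <- endmember_pair(endmember_phasor(endA, acq$omega, an$harmonic),
                         endmember_phasor(endB, acq$omega, an$harmonic),
                         labels = c(endA$name, endB$name))
  cursors <- place_cursors_on_segment(pair, k = an$n_cursors,
                                      radius = an$cursor_radius)
  f_cur <- file.path(cfg$out_dir, "cursors.json")
  write_cursors(cursors, f_cur)
  seg <- assign_pixels(field, cursors)
  prof <- melanin_profile(seg, field)
  f_prof <- file.path(cfg$out_dir, "melanin_profile.csv")
  utils::write.csv(as.data.frame(prof), f_prof, row.names = FALSE)
  log_stage("segment+profile", cfg_hash, seed, t0)

  # region statistics: each cell is a region; populations split by ground
  # truth pigmentation (dark: f_eu > 0.5)
  pts <- region_average_points(field, sim$truth$species)
  stats_out <- list(n_regions = nrow(pts))
  cell_f <- vapply(pts$region, function(l)
    mean(scene$f_eu[scene$cell_masks == as.integer(l)]), numeric(1))
  dark <- pts[cell_f > 0.5, , drop = FALSE]
  light <- pts[cell_f <= 0.5, , drop = FALSE]
  if (nrow(dark) >= 2 && nrow(light) >= 2) {
    tt <- s_value_ttest(dark, light, alpha = an$alpha)
    stats_out$s_ttest_dark_vs_light <- tt
    stats_out$dark <- population_summary(dark)
    stats_out$light <- population_summary(light)
  }
  keep <- !is.na(prof$mean_g)
  lin <- linearity_score(cbind(prof$mean_g[keep], prof$mean_s[keep]))
  stats_out$cluster_linearity <- list(rms_residual = lin$rms_residual,
                                      r_squared = lin$r_squared)
  f_stats <- file.path(cfg$out_dir, "stats.json")
  jsonlite::write_json(stats_out, f_stats, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_stage("stats", cfg_hash, seed, t0)

  files <- c(f_stack, sidecar_path(f_stack), f_field, sidecar_path(f_field),
             f_cur, f_prof, f_stats)
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(files)
  manifest <- list(config_hash = cfg_hash, seed = seed, files = hashes)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("manifest", cfg_hash, seed, t0)
  invisible(c(manifest, list(profile = as.data.frame(prof))))
}

# Stable content hash of an R object (md5 of its serialization, version-fixed).
digest_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
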