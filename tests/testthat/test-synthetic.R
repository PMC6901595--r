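# Synthetic TCSPC / spectral generator: zero cases, determinism, refit and
# centre-of-mass oracles, Poisson noise law, fraction bookkeeping.

test_that("generate_decay handles zero photons, rejects bad input, is deterministic", {
  acq <- test_acq()
  em <- single_tau_endmember(2)
  d0 <- generate_decay(em, 1, 0, acq, seed = 3)
  expect_equal(d0$counts, rep(0L, acq$n_time_bins), ignore_attr = TRUE)

  expect_error(generate_decay(em, 1, -5, acq), "total_photons")
  expect_error(generate_decay(list(em, em), c(0.7, 0.7), 10, acq), "sum to 1")
  expect_error(generate_decay(list(em, em), c(1.3, -0.3), 10, acq), ">= 0")

  d1 <- generate_decay(em, 1, 1e4, acq, seed = 11)
  d2 <- generate_decay(em, 1, 1e4, acq, seed = 11)
  expect_identical(d1$counts, d2$counts)
  d3 <- generate_decay(em, 1, 1e4, acq, seed = 12)
  expect_false(identical(d1$counts, d3$counts))
})

test_that("single-exponential decay refits to its tau (grid-search ML oracle)", {
  acq <- acquisition_config(image_shape = c(1, 1), n_time_bins = 256)
  tau <- 2.0
  d <- generate_decay(single_tau_endmember(tau), 1, 1e7, acq, seed = 42)
  tau_hat <- oracle_grid_refit(d$counts, acq$period_ns,
                               seq(1.9, 2.1, by = 5e-4))
  expect_lt(abs(tau_hat - tau) / tau, 0.005)
})

test_that("decay expectation wraps the incomplete decay over the laser period", {
  acq <- test_acq()
  d <- generate_decay(single_tau_endmember(4), 1, 1e6, acq, noiseless = TRUE)
  # last/first bin ratio follows the exponential across one period
  expect_equal(d$counts[acq$n_time_bins] / d$counts[1],
               exp(-(acq$period_ns - acq$bin_width_ns) / 4), tolerance = 1e-9)
  # expectation matches the analytic wrapped-exponential bin integrals,
  # including the 1 - exp(-T/tau) incomplete-decay normalization
  expect_equal(d$counts / sum(d$counts),
               oracle_bin_probs(4, acq$n_time_bins, acq$period_ns),
               tolerance = 1e-12)
  expect_equal(sum(d$counts), 1e6, tolerance = 1e-9)
})

test_that("generate_spectrum: zero case, delta spectrum, COM oracle, errors", {
  acq <- test_acq()
  em <- single_tau_endmember(2, peak = 589, fwhm = 30)
  s0 <- generate_spectrum(em, 1, 0, acq, seed = 1)
  expect_equal(sum(s0$counts), 0)

  # delta-like spectrum at a channel centre -> all counts in that channel
  ch_centers <- channel_centers(acq)
  emd <- single_tau_endmember(2, peak = ch_centers[12], fwhm = 0)
  sd <- generate_spectrum(emd, 1, 1e4, acq, seed = 1, noiseless = TRUE)
  expect_equal(which(sd$counts > 0), 12L)

  # count-weighted mean wavelength within 1 nm of direct-summation oracle
  sn <- generate_spectrum(em, 1, 1e6, acq, seed = 5)
  com_noisy <- oracle_com_wavelength(sn$counts, acq$lambda_min, acq$channel_width)
  sm <- generate_spectrum(em, 1, 1e6, acq, noiseless = TRUE)
  com_exact <- oracle_com_wavelength(sm$counts, acq$lambda_min, acq$channel_width)
  expect_lt(abs(com_noisy - com_exact), 1)

  bad <- endmember_spec("uv", 2, 1, spectrum_peak = 300, spectrum_fwhm = 20)
  expect_error(generate_spectrum(bad, 1, 100, acq), "outside")
})

test_that("flim stack generation respects layout, ground truth and determinism", {
  acq <- test_acq()
  # single 1-pixel granule, zero elsewhere -> exactly one nonzero pixel
  lay <- scene_layout(cell_masks = matrix(0L, 16, 16),
                      f_eu = matrix(0.5, 16, 16),
                      brightness = {
                        b <- matrix(0, 16, 16); b[7, 9] <- 500; b
                      })
  sim <- generate_flim_stack(lay, acq = acq, seed = 2)
  tot <- apply(sim$stack$counts, c(1, 2), sum)
  expect_equal(which(tot > 0), which(lay$brightness > 0))
  expect_equal(sim$truth$f_eu, lay$f_eu)

  sim2 <- generate_flim_stack(lay, acq = acq, seed = 2)
  expect_identical(sim$stack$counts, sim2$stack$counts)

  bad_acq <- acquisition_config(image_shape = c(8, 8), n_time_bins = 128)
  expect_error(generate_flim_stack(lay, acq = bad_acq, seed = 1), "shape")
})

test_that("pure-endmember scene decays match a fresh pure simulation (mean arrival time)", {
  acq <- test_acq()
  endA <- endmember_eumelanin()
  lay <- scene_layout(matrix(1L, 16, 16), matrix(1, 16, 16),
                      matrix(200, 16, 16))
  sim <- generate_flim_stack(lay, endA = endA, acq = acq, seed = 9)
  tk <- time_bin_centers(acq)
  mean_arrival <- function(cube) {
    m <- matrix(cube, ncol = length(tk))
    rowSums(sweep(m, 2, tk, `*`)) / rowSums(m)
  }
  tbar_scene <- mean_arrival(sim$stack$counts)
  # independent pure-endA pixels
  pure <- vapply(1:256, function(i) {
    d <- generate_decay(endA, 1, 200, acq, seed = 10000 + i)
    sum(d$counts * tk) / sum(d$counts)
  }, numeric(1))
  tt <- t.test(tbar_scene, pure)
  expect_gt(tt$p.value, 0.01)
})

test_that("spectral stack shares ground truth with the FLIM stack and obeys the SNR scale", {
  acq <- test_acq()
  lay <- melanocyte_scene(c(16, 16), n_cells = 2, seed = 4)
  fs <- generate_flim_stack(lay, acq = acq, seed = 5)
  ss <- generate_spectral_stack(lay, acq = acq, seed = 5)
  expect_identical(fs$truth$f_eu, ss$truth$f_eu)

  # zero-brightness scene -> all-zero stack
  lay0 <- scene_layout(matrix(0L, 16, 16), matrix(0, 16, 16), matrix(0, 16, 16))
  s0 <- generate_spectral_stack(lay0, acq = acq, seed = 1)
  expect_equal(sum(s0$stack$counts), 0)

  # descanned scale 0.25 -> ~25% photons within 3 sigma Poisson
  full <- generate_spectral_stack(lay, acq = acq, seed = 6)
  quarter <- generate_spectral_stack(lay, acq = acq, seed = 6, snr_scale = 0.25)
  expected <- 0.25 * sum(full$truth$expected_photons)
  expect_lt(abs(sum(quarter$stack$counts) - expected), 3 * sqrt(expected))
})

test_that("per-bin counts are Poisson: variance matches mean across reseeded replicates", {
  acq <- acquisition_config(image_shape = c(1, 1), n_time_bins = 32)
  em <- single_tau_endmember(3)
  reps <- vapply(seq_len(1000), function(r)
    generate_decay(em, 1, 5e4, acq, seed = r)$counts, numeric(32))
  m <- rowMeans(reps); v <- apply(reps, 1, var)
  big <- m > 500
  expect_true(any(big))
  ratio <- v[big] / m[big]
  # variance tracks the mean: Poisson dispersion 1 (sampling error on a
  # 1000-replicate variance is ~4.5%, so the mean ratio is tight)
  expect_lt(abs(mean(ratio) - 1), 0.10)
  expect_true(all(abs(ratio - 1) < 0.25))
})

test_that("noiseless expectation mode makes photon-fraction bookkeeping exact", {
  acq <- test_acq()
  emA <- single_tau_endmember(1); emB <- single_tau_endmember(3)
  dA <- generate_decay(list(emA, emB), c(1, 0), 1000, acq, noiseless = TRUE)
  dmix <- generate_decay(list(emA, emB), c(0.3, 0.7), 1000, acq, noiseless = TRUE)
  # expected photons from A = 0.3 * 1000 exactly
  expect_equal(sum(dmix$counts - 0.7 * generate_decay(list(emA, emB), c(0, 1),
                                                      1000, acq,
                                                      noiseless = TRUE)$counts),
               300, tolerance = 1e-9)
  expect_equal(sum(dA$counts), 1000, tolerance = 1e-9)
})

test_that("endmember and layout validation rejects inconsistent specs", {
  expect_error(endmember_spec("x", c(1, -2), c(0.5, 0.5), 589, 30), "lifetimes")
  expect_error(endmember_spec("x", c(1, 2), c(0.6, 0.6), 589, 30), "sum to 1")
  expect_error(scene_layout(matrix(0L, 4, 4), matrix(1.5, 4, 4),
                            matrix(1, 4, 4)), "f_eu")
})
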