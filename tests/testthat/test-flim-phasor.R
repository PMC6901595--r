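# Lifetime phasor transform, universal circle, calibration, E-filter and
# two-component fraction decomposition.

test_that("delta decay maps to (1, 0) and uniform decay to (0, 0)", {
  acq <- test_acq()
  cube <- array(0, dim = c(16, 16, acq$n_time_bins))
  cube[, , 1] <- 1000   # all photons in the first bin
  st <- flim_stack(cube, acq$bin_width_ns, acq$rep_rate)
  f <- flim_phasor(st, threshold = 1)
  # first bin centre is at dt/2, not exactly 0; converges to (1,0) as dt -> 0
  expect_equal(unname(f$g[1, 1]), cos(acq$omega * acq$bin_width_ns / 2),
               tolerance = 1e-12)
  fine <- acquisition_config(image_shape = c(1, 1), n_time_bins = 4096)
  cube2 <- array(0, dim = c(1, 1, 4096)); cube2[1, 1, 1] <- 1000
  f2 <- flim_phasor(flim_stack(cube2, fine$bin_width_ns, fine$rep_rate),
                    threshold = 1)
  expect_equal(unname(c(f2$g[1, 1], f2$s[1, 1])), c(1, 0), tolerance = 1e-3)

  cube[, , ] <- 7  # uniform over the full period -> exactly (0, 0)
  fu <- flim_phasor(flim_stack(cube, acq$bin_width_ns, acq$rep_rate),
                    threshold = 1)
  expect_equal(unname(fu$g[3, 3]), 0, tolerance = 1e-12)
  expect_equal(unname(fu$s[3, 3]), 0, tolerance = 1e-12)
})

test_that("discrete transform matches the periodic closed form (numerical-integration oracle)", {
  acq <- acquisition_config(image_shape = c(1, 1), n_time_bins = 4096)
  w <- acq$omega
  for (tau in c(0.5, 1 / w, 2, 4)) {
    d <- generate_decay(single_tau_endmember(tau), 1, 1e6, acq, noiseless = TRUE)
    p <- decay_phasor(d)
    a <- single_exp_phasor(tau, w)
    o <- oracle_phasor_numint(tau, acq$period_ns)
    expect_lt(sqrt(sum((p - a)^2)), 2e-3)
    expect_lt(sqrt(sum((p - o)^2)), 2e-3)
    # the closed form itself agrees with brute-force integration
    expect_lt(sqrt(sum((a - o)^2)), 1e-4)
  }
})

test_that("single_exp_phasor: limits, symmetry point, universal circle, monotonicity", {
  w <- 2 * pi * 80e6 * 1e-9
  expect_equal(unname(single_exp_phasor(1e-9, w)), c(1, 0), tolerance = 1e-6)
  expect_equal(unname(single_exp_phasor(1e9, w)), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(single_exp_phasor(1 / w, w)), c(0.5, 0.5))
  expect_error(single_exp_phasor(-1, w), "tau")

  taus <- 10^seq(-2, 2, length.out = 41)
  ang_prev <- -Inf
  for (tau in taus) {
    p <- single_exp_phasor(tau, w)
    expect_equal((p["g"] - 0.5)^2 + p["s"]^2, c(g = 0.25), tolerance = 1e-14)
    ang <- atan2(p["s"], p["g"])
    expect_gt(ang, ang_prev)  # phase angle strictly increasing in tau
    ang_prev <- ang
  }
})

test_that("transform is intensity-normalized and masks low-count pixels", {
  acq <- test_acq()
  sim <- generate_flim_stack(melanocyte_scene(c(16, 16), n_cells = 2, seed = 1),
                             acq = acq, seed = 1, noiseless = TRUE)
  f1 <- flim_phasor(sim$stack, threshold = 5)
  scaled <- sim$stack
  scaled$counts <- scaled$counts * 10
  f10 <- flim_phasor(scaled, threshold = 5)
  expect_equal(f1$g[f1$mask], f10$g[f1$mask], tolerance = 1e-12)

  empty <- sim$stack
  empty$counts <- empty$counts * 0
  expect_warning(fe <- flim_phasor(empty), "threshold")
  expect_false(any(fe$mask))
  # masked pixels carry NA coordinates; intensity equals per-pixel count sums
  expect_true(all(is.na(f1$g[!f1$mask])))
  expect_equal(f1$intensity, apply(sim$stack$counts, c(1, 2), sum))
})

test_that("calibration maps the measured reference onto the analytic reference", {
  acq <- test_acq()
  w <- acq$omega
  a <- single_exp_phasor(4.1, w)
  # identity when already calibrated
  ref <- calibration_ref(a, tau_ref = 4.1, omega = w)
  expect_equal(ref$rotation, 0, tolerance = 1e-12)
  expect_equal(ref$scale, 1, tolerance = 1e-12)

  # measured = analytic rotated by +0.1 rad -> field rotated by -0.1 rad
  rot <- function(p, th) c(cos(th) * p[1] - sin(th) * p[2],
                           sin(th) * p[1] + cos(th) * p[2])
  ref2 <- calibration_ref(rot(a, 0.1), tau_ref = 4.1, omega = w)
  expect_equal(ref2$rotation, -0.1, tolerance = 1e-12)
  sim <- generate_flim_stack(melanocyte_scene(c(16, 16), seed = 2), acq = acq,
                             seed = 3)
  f <- flim_phasor(sim$stack)
  fc <- calibrate(f, ref2)
  i <- which(f$mask)[1]
  expect_equal(unname(rot(c(f$g[i], f$s[i]), -0.1)),
               c(fc$g[i], fc$s[i]), tolerance = 1e-12)
  # applying the calibration to the measured reference gives the analytic one
  mref <- rot(a, 0.1)
  z <- complex(modulus = ref2$scale, argument = ref2$rotation) *
    complex(real = mref[1], imaginary = mref[2])
  expect_equal(c(Re(z), Im(z)), unname(a), tolerance = 1e-12)

  expect_error(calibration_ref(c(0, 0), omega = w), "zero modulus")
})

test_that("E-filter: constants unchanged, outliers removed, borders untouched, variance reduced", {
  acq <- test_acq()
  g <- matrix(0.4, 16, 16); s <- matrix(0.3, 16, 16)
  fld <- phasor_field(g, s, matrix(100, 16, 16), matrix(TRUE, 16, 16),
                      1L, "flim")
  expect_equal(efilter(fld)$g, fld$g)

  g2 <- g; g2[8, 8] <- 0.9
  fld2 <- phasor_field(g2, s, matrix(100, 16, 16), matrix(TRUE, 16, 16),
                       1L, "flim")
  filt <- efilter(fld2, passes = 1, kernel = 3)
  expect_equal(filt$g[8, 8], 0.4)
  expect_equal(filt$g[1, ], fld2$g[1, ])          # border rows untouched
  expect_equal(filt$g[, 16], fld2$g[, 16])
  expect_error(efilter(fld, kernel = 4), "odd")

  # variance reduction on noisy fields (interior pixels), 100 replicates
  em <- single_tau_endmember(2)
  sd_before <- sd_after <- numeric(100)
  lay <- scene_layout(matrix(1L, 8, 8), matrix(1, 8, 8), matrix(150, 8, 8))
  acq8 <- acquisition_config(image_shape = c(8, 8), n_time_bins = 64)
  for (r in 1:100) {
    sim <- generate_flim_stack(lay, endA = em, endB = em, acq = acq8, seed = r)
    f <- flim_phasor(sim$stack, threshold = 1)
    ff <- efilter(f)
    inn <- 2:7
    sd_before[r] <- sd(f$g[inn, inn])
    sd_after[r] <- sd(ff$g[inn, inn])
  }
  expect_lt(mean(sd_after), mean(sd_before))
})

test_that("fraction decomposition: endpoints, midpoint, and parameter recovery", {
  A <- c(0.7, 0.35); B <- c(0.3, 0.45)
  pair <- endmember_pair(A, B)
  mk <- function(g, s) phasor_field(matrix(g), matrix(s), matrix(100),
                                    matrix(TRUE), 1L, "flim")
  expect_equal(fraction_decompose(mk(A[1], A[2]), pair)$f_A[1, 1], 1)
  expect_equal(fraction_decompose(mk(A[1], A[2]), pair)$residual[1, 1], 0)
  expect_equal(fraction_decompose(mk(mean(c(A[1], B[1])), mean(c(A[2], B[2]))),
                                  pair)$f_A[1, 1], 0.5)
  expect_error(endmember_pair(A, A), "distinct")

  # recovery of a 0.7 photon fraction at 5000 photons/pixel over 1024 pixels
  acq <- acquisition_config(image_shape = c(32, 32), n_time_bins = 128)
  emA <- endmember_eumelanin(); emB <- endmember_pheomelanin()
  lay <- scene_layout(matrix(1L, 32, 32), matrix(0.7, 32, 32),
                      matrix(5000, 32, 32))
  sim <- generate_flim_stack(lay, emA, emB, acq, seed = 17)
  f <- flim_phasor(sim$stack)
  truth_pair <- endmember_pair(endmember_phasor(emA, acq$omega),
                               endmember_phasor(emB, acq$omega))
  fm <- fraction_decompose(f, truth_pair)
  expect_lt(abs(mean(fm$f_A, na.rm = TRUE) - 0.7), 0.02)
})

test_that("mixture phasors are linear in the photon fraction (vector addition)", {
  acq <- test_acq()
  emA <- single_tau_endmember(0.8); emB <- single_tau_endmember(3.2)
  pA <- decay_phasor(generate_decay(emA, 1, 1e6, acq, noiseless = TRUE))
  pB <- decay_phasor(generate_decay(emB, 1, 1e6, acq, noiseless = TRUE))
  for (fr in c(0.2, 0.5, 0.8)) {
    pm <- decay_phasor(generate_decay(list(emA, emB), c(fr, 1 - fr), 1e6, acq,
                                      noiseless = TRUE))
    expect_equal(unname(pm), unname(fr * pA + (1 - fr) * pB), tolerance = 1e-12)
  }
})

test_that("IRF convolution preserves the phasor up to the IRF's own phasor factor", {
  # circular convolution multiplies Fourier coefficients; a centred Gaussian
  # IRF mainly demodulates, so |phasor| shrinks but the decay stays valid
  acq_irf <- acquisition_config(image_shape = c(1, 1), n_time_bins = 512,
                                irf_fwhm = 300)
  acq0 <- acquisition_config(image_shape = c(1, 1), n_time_bins = 512)
  d0 <- generate_decay(single_tau_endmember(2), 1, 1e6, acq0, noiseless = TRUE)
  di <- generate_decay(single_tau_endmember(2), 1, 1e6, acq_irf, noiseless = TRUE)
  expect_equal(sum(di$counts), sum(d0$counts), tolerance = 1e-6)
  p0 <- phase_modulus(decay_phasor(d0)); pi_ <- phase_modulus(decay_phasor(di))
  expect_lt(pi_$M, p0$M)
})
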