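test_that("gaussian_area matches the closed form and quadrature", {
  expect_equal(gaussian_area(1, 1), sqrt(2 * pi))
  expect_equal(gaussian_area(2, 0.05), 0.2506628, tolerance = 1e-6)
  grid <- seq(-8 * 0.05, 8 * 0.05, length.out = 20001)
  g <- 2 * gauss_abs(grid, 0, 0.05)
  quad <- sum((g[-1] + g[-length(g)]) / 2) * diff(grid[1:2])
  expect_equal(gaussian_area(2, 0.05), quad, tolerance = 1e-6)
  expect_error(gaussian_area(1, 0), "sigma")
})

test_that("the Dawson evaluator matches direct numerical integration", {
  dawson_ref <- function(x) {
    exp(-x^2) * stats::integrate(function(u) exp(u^2), 0, x,
                                 rel.tol = 1e-12)$value
  }
  xs <- c(0.1, 0.4, 1, 2, 3.7, 6, 10, -1.5)
  got <- as.vector(editmrs:::dawson_cpp(xs))
  ref <- vapply(xs, dawson_ref, numeric(1))
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("gauss_disp is the Hilbert partner of the Gaussian absorption", {
  # FFT-based discrete Hilbert transform as the independent oracle
  n <- 2^16
  f <- seq(-200, 200, length.out = n)
  g <- gauss_abs(f, 0, 1)
  G <- stats::fft(g)
  h <- rep(0, n); h[1] <- 1
  h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  analytic <- stats::fft(G * h, inverse = TRUE) / n
  hilb <- -Im(analytic)              # quadrature component
  mid <- abs(f) < 5
  expect_equal(gauss_disp(f[mid], 0, 1), -hilb[mid], tolerance = 2e-3)
})

test_that("peak fitting recovers its own model exactly", {
  acq <- acq_h
  zf <- 8192
  base <- fid(complex(real = rep(0, acq$n_points)), acq)
  sp <- to_spectrum(base, zf, 0)
  sp$intensities <- complex(real = gauss_abs(sp$ppm, 3.02, 0.04))
  pf <- fit_gaba_glx(sp)
  expect_false(pf$flagged)
  expect_equal(pf$peaks$amplitude[1], 1, tolerance = 1e-6)
  expect_equal(pf$peaks$center_ppm[1], 3.02, tolerance = 1e-6)
  expect_equal(pf$peaks$sigma_ppm[1], 0.04, tolerance = 1e-6)
  expect_equal(pf$target_area, 0.04 * sqrt(2 * pi), tolerance = 1e-5)

  # a constant offset is absorbed by the baseline
  sp2 <- sp
  sp2$intensities <- sp$intensities + 0.5
  pf2 <- fit_gaba_glx(sp2)
  expect_equal(pf2$target_area, pf$target_area, tolerance = 1e-3)

  # amplitude linearity
  sp3 <- sp
  sp3$intensities <- 3.7 * sp$intensities
  pf3 <- fit_gaba_glx(sp3)
  expect_equal(pf3$target_area, 3.7 * pf$target_area, tolerance = 1e-3)
})

test_that("a lone 2.95-ppm Gaussian yields an exact GSH area", {
  acq <- acq_h
  sp <- to_spectrum(fid(complex(real = rep(0, acq$n_points)), acq), 8192, 0)
  sp$intensities <- complex(real = 2 * gauss_abs(sp$ppm, 2.95, 0.035))
  pf <- fit_gsh_peaks(sp, peak_fit_config("GSH80"))
  expect_equal(pf$target_area, gaussian_area(2, 0.035), tolerance = 1e-5)
  expect_lt(max(abs(pf$peaks$amplitude[-1])), 1e-3)
})

test_that("absorptive TE-120 spectra are quantified close to the GSH-only reference", {
  catal <- default_catalog("MEGA120")
  ref <- fit_gsh_peaks(to_spectrum(diff_fid_of(catal, "GSH", truth_default,
                                               acq_m), 8192, 3),
                       peak_fit_config("GSH120"))$target_area
  full <- fit_gsh_peaks(to_spectrum(diff_fid_of(catal, c("GSH", "Asp", "MM12",
                                                         "MM14"),
                                                truth_default, acq_m),
                                    8192, 3),
                        peak_fit_config("GSH120"))$target_area
  expect_equal(full, ref, tolerance = 0.05)
})

test_that("the Glx doublet does not perturb the phase-model GABA+ area", {
  # the phase-rotated Gaussian model absorbs the Glx doublet cleanly; the
  # default cubic-baseline model trades that robustness for baseline
  # flexibility and is held to a looser band
  catal <- default_catalog("HERMES80")
  mk <- function(nms) to_spectrum(diff_fid_of(catal, nms, truth_default,
                                              acq_h, "GABA"), 8192, 3)
  cfg_ph <- peak_fit_config("GABAGLX", phase = TRUE)
  a_ref <- fit_gaba_glx(mk("GABA"), cfg_ph)$target_area
  a_full <- fit_gaba_glx(mk(c("GABA", "Glx")), cfg_ph)$target_area
  expect_equal(a_full, a_ref, tolerance = 0.02)

  b_ref <- fit_gaba_glx(mk("GABA"))$target_area
  b_full <- fit_gaba_glx(mk(c("GABA", "Glx")))$target_area
  expect_equal(b_full, b_ref, tolerance = 0.15)
})

test_that("Gaussian-Lorentzian water fitting matches analytic limit cases", {
  acq <- acq_h
  sp <- to_spectrum(fid(complex(real = rep(0, acq$n_points)), acq), 8192, 0)
  # pure Lorentzian: area pi * A * gamma
  A <- 5; gam <- 0.03
  sp$intensities <- complex(real = A / (1 + ((sp$ppm - 4.68) / gam)^2))
  wl <- fit_water_gl(sp)
  # analytic Lorentzian area over the finite fit window
  expect_equal(wl$area, A * gam * 2 * atan(0.5 / gam), tolerance = 0.01)
  # pure Gaussian: area A * sqrt(pi) / s
  s <- 1 / (2 * 0.04)
  sp$intensities <- complex(real = A * exp(-s^2 * (sp$ppm - 4.68)^2))
  wg <- fit_water_gl(sp)
  expect_equal(wg$area, A * sqrt(pi) / s, tolerance = 0.01 * A * sqrt(pi) / s)
})

test_that("water area scales linearly with the reference amplitude", {
  catal <- default_catalog("HERMES80")
  unit <- water_basis_fid(catal, acq_h)
  a1 <- fit_water_gl(to_spectrum(unit, 8192, 3))$area
  big <- unit
  big$samples <- big$samples * 30000
  a2 <- fit_water_gl(to_spectrum(big, 8192, 3))$area
  expect_equal(a2, 30000 * a1, tolerance = 0.02 * 30000 * a1)
})

test_that("mixed-phase TE-80 spectra destabilize the GSH peak fit", {
  # paired fixtures on common seeds: per-seed test-retest pairs for both TE
  # styles; the TE-80 pair discrepancy should exceed the TE-120 one, and the
  # LCM engine should beat the peak fit on the same TE-80 spectra
  n_seeds <- 50
  means <- default_truth_means()
  bas <- exact_basis("HERMES80")
  bcfg <- lcm_config(target = "GSH", max_iter = 50, ftol = 1e-7,
                     soft_constraints = NULL)
  p80 <- peak_fit_config("GSH80", max_iter = 80)
  p120 <- peak_fit_config("GSH120", max_iter = 80)
  d80 <- numeric(n_seeds); d120 <- numeric(n_seeds); dl80 <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    truth <- with_seed(4000 + i,
                       means * stats::rlnorm(length(means), -0.005, 0.0995))
    # identical noise level for both TE styles isolates the lineshape effect
    pair <- function(seqtag, scan_seed) {
      fixture_diff_spectrum(seqtag, truth, scan_seed, noise_sd = 0.35)
    }
    rel_diff <- function(x) abs(diff(x)) / mean(x)
    a80 <- vapply(1:2, function(j) {
      fit_gsh_peaks(pair("HERMES80", 100 * i + j), p80)$target_area
    }, numeric(1))
    a120 <- vapply(1:2, function(j) {
      fit_gsh_peaks(pair("MEGA120", 100 * i + j), p120)$target_area
    }, numeric(1))
    l80 <- vapply(1:2, function(j) {
      sp <- fixture_diff_spectrum("HERMES80", truth, 100 * i + j,
                                  noise_sd = 0.35, truncate = 1024)
      lcm_fit(sp, bas, bcfg)$amplitudes["GSH"]
    }, numeric(1))
    d80[i] <- rel_diff(a80); d120[i] <- rel_diff(a120); dl80[i] <- rel_diff(l80)
  }
  expect_gt(median(d80), median(d120))
  p_te <- stats::binom.test(sum(d80 > d120), n_seeds, alternative = "greater")
  expect_lt(p_te$p.value, 0.05)
  expect_gt(median(d80), median(dl80))
  p_eng <- stats::binom.test(sum(d80 > dl80), n_seeds, alternative = "greater")
  expect_lt(p_eng$p.value, 0.05)
})
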