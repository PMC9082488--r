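test_that("compiled NNLS agrees with the reference active-set solver", {
  skip_if_not_installed("pracma")
  set.seed(12)
  for (i in 1:20) {
    A <- matrix(rnorm(60 * 8), 60, 8)
    b <- rnorm(60)
    got <- as.vector(editmrs:::nnls_lh(A, b))
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("spline baseline regressors follow the construction rule", {
  grid <- seq(0.6, 4.1, length.out = 400)
  B <- spline_basis(c(0.5, 4.2), 0.4, grid)
  expect_equal(ncol(B), ceiling(3.7 / 0.4) + 3)       # 13 regressors
  expect_equal(rowSums(B), rep(1, length(grid)), tolerance = 1e-9)
  line <- 2 - 0.7 * grid
  coef <- qr.solve(B, line)
  expect_lt(max(abs(B %*% coef - line)), 1e-9)
  expect_error(spline_basis(c(3, 3.1), 0.4, grid), "narrower")
})

test_that("MM basis functions are added per target with unit area", {
  bas <- exact_basis("HERMES80", target = "GSH",
                     exclude = c("H2O", "H2Oresid", "MM09", "MM30",
                                 "MM12", "MM14"))
  bas_gsh <- add_mm_basis(bas)
  expect_setequal(setdiff(bas_gsh$names, bas$names), c("MM12", "MM14"))
  bas_gaba <- exact_basis("HERMES80", target = "GABA",
                          exclude = c("H2O", "H2Oresid", "MM09", "MM30",
                                      "MM12", "MM14"))
  bas_gaba <- add_mm_basis(bas_gaba)
  expect_true(all(c("MM093", "MM30") %in% bas_gaba$names))
  expect_error(add_mm_basis(bas_gsh), "duplicate")

  # unit integrated area over the fit window (ppm x intensity units)
  acq1 <- bas_gsh$acq
  sp <- to_spectrum(fid(bas_gsh$fids[, "MM12"], acq1), acq1$n_points, 0)
  sel <- sp$ppm > 0.5 & sp$ppm < 4.2
  area <- -sum(diff(sp$ppm[sel]) *
                 (Re(sp$intensities[sel])[-1] +
                    Re(sp$intensities[sel])[-sum(sel)]) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
})

test_that("exact-basis noiseless fits recover amplitudes, phases and shifts", {
  bas <- exact_basis("HERMES80")
  acq1 <- bas$acq
  cfg <- lcm_config(target = "GSH", soft_constraints = NULL)
  truth <- c(GSH = 2, Asp = 1, MM12 = 0.8, MM14 = 0.5)
  f <- fid(as.vector(bas$fids %*% truth[bas$names]), acq1)
  lf <- lcm_fit(to_spectrum(f, acq1$n_points, 3), bas, cfg)
  expect_true(lf$converged)
  expect_equal(unname(lf$amplitudes[names(truth)]), unname(truth),
               tolerance = 1e-3)
  expect_lt(abs(lf$phi0_deg), 0.5)
  expect_lt(max(abs(lf$delta_ppm)), 0.005)

  # a known zero-order phase on the data is recovered
  fr <- f
  fr$samples <- fr$samples * exp(1i * 15 * pi / 180)
  lfr <- lcm_fit(to_spectrum(fr, acq1$n_points, 3), bas, cfg)
  expect_equal(lfr$phi0_deg, -15, tolerance = 0.5)
  expect_equal(unname(lfr$amplitudes["GSH"]), 2, tolerance = 5e-3)
})

test_that("a pure spline-shaped baseline attracts no metabolite amplitude", {
  bas <- exact_basis("HERMES80")
  acq1 <- bas$acq
  sp <- to_spectrum(fid(complex(real = rep(0, acq1$n_points)), acq1),
                    acq1$n_points, 3)
  B <- spline_basis(c(0.5, 4.2), 0.4, sp$ppm)
  set.seed(31)
  sp$intensities <- complex(real = as.vector(B %*% rnorm(ncol(B), 0, 100)))
  lf <- lcm_fit(sp, bas, lcm_config(target = "GSH", soft_constraints = NULL))
  expect_lt(max(lf$amplitudes), 1e-6 * 100)
})

test_that("spline-representable distortion barely moves the TE-120 GSH amplitude", {
  bas <- exact_basis("MEGA120")
  acq1 <- bas$acq
  truth <- c(GSH = 2, Asp = 2.5, MM12 = 2, MM14 = 1)
  f <- fid(as.vector(bas$fids %*% truth[bas$names]), acq1)
  cfg <- lcm_config(target = "GSH")
  sp0 <- to_spectrum(f, acq1$n_points, 3)
  a0 <- lcm_fit(sp0, bas, cfg)$amplitudes["GSH"]
  B <- spline_basis(c(0.5, 4.2), 0.4, sp0$ppm)
  set.seed(41)
  sp1 <- sp0
  sp1$intensities <- sp0$intensities +
    complex(real = as.vector(B %*% rnorm(ncol(B), 0, 30)))
  a1 <- lcm_fit(sp1, bas, cfg)$amplitudes["GSH"]
  expect_equal(unname(a1), unname(a0), tolerance = 0.05)
})

test_that("amplitude estimates are unbiased under complex white noise", {
  # the data carry genuine extra broadening so the broadening parameters sit
  # in the interior of their one-sided ranges (on the boundary, any
  # implementation of the model has an O(noise) positive bias); priors are
  # relaxed so the check isolates the estimator's noise behavior
  bas <- exact_basis("HERMES80")
  acq1 <- bas$acq
  truth <- c(GSH = 2, Asp = 2.5, MM12 = 2, MM14 = 1)
  t <- time_axis(acq1)
  broadened <- (bas$fids * exp(-3 * t - (4 * t)^2)) %*% truth[bas$names]
  cfg <- lcm_config(target = "GSH", max_iter = 50, ftol = 1e-7,
                    soft_constraints = NULL, lorentz_prior_sd_hz = 50,
                    gauss_prior_sd_hz = 50)
  n_rep <- 100
  est <- with_seed(77, vapply(seq_len(n_rep), function(i) {
    f <- fid(as.vector(broadened) +
               complex(real = rnorm(acq1$n_points, 0, 0.15),
                       imaginary = rnorm(acq1$n_points, 0, 0.15)), acq1)
    lcm_fit(to_spectrum(f, acq1$n_points, 3), bas, cfg)$amplitudes["GSH"]
  }, numeric(1)))
  se <- stats::sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - 2), 2 * se + 1e-6)
})

test_that("a basis species absent from the data fits to roughly zero", {
  bas <- exact_basis("HERMES80")
  acq1 <- bas$acq
  truth <- c(GSH = 2, Asp = 2.5, MM12 = 0, MM14 = 0)   # MMs absent
  f <- fid(as.vector(bas$fids %*% truth[bas$names]), acq1)
  lf <- lcm_fit(to_spectrum(f, acq1$n_points, 3), bas,
                lcm_config(target = "GSH", soft_constraints = NULL))
  expect_lt(max(lf$amplitudes[c("MM12", "MM14")]), 1e-3 * max(truth))
})

test_that("rank-deficient designs are rejected with the offending names", {
  bas <- exact_basis("HERMES80")
  dup <- basis_set(c(bas$names, "GSHcopy"),
                   cbind(bas$fids, bas$fids[, "GSH"]), bas$acq, "GSH")
  f <- fid(as.vector(bas$fids[, "GSH"] * 2), bas$acq)
  expect_error(lcm_fit(to_spectrum(f, bas$acq$n_points, 3), dup,
                       lcm_config(target = "GSH")), "collinear")
})

test_that("gaba_plus combines the GABA and 3-ppm MM amplitudes", {
  res <- structure(list(amplitudes = c(GABA = 1.2, MM30 = 0.9)),
                   class = "lcm_fit_result")
  expect_equal(gaba_plus(res), 2.1)
  res$amplitudes["MM30"] <- 0
  expect_equal(gaba_plus(res), 1.2)
  expect_gte(gaba_plus(res), res$amplitudes[["GABA"]])
  res2 <- structure(list(amplitudes = c(GABA = 1)), class = "lcm_fit_result")
  expect_error(gaba_plus(res2), "MM30")
})

test_that("the six-parameter water model is exact on itself and linear", {
  catal <- default_catalog("HERMES80")
  wb <- water_basis_fid(catal, acq_h)
  wsp <- to_spectrum(wb, acq_h$n_points, 3)
  self <- fit_water_lcm(wsp, wb)
  expect_equal(self$amplitude, 1, tolerance = 1e-6)
  expect_lt(abs(self$params["phi0_deg"]), 1e-3)
  expect_lt(abs(self$params["delta_ppm"]), 1e-5)

  scaled <- wb
  scaled$samples <- scaled$samples * 3.5
  sc <- fit_water_lcm(to_spectrum(scaled, acq_h$n_points, 3), wb)
  expect_equal(sc$amplitude, 3.5, tolerance = 3.5e-3)

  # broadening and shift recovery
  t <- time_axis(acq_h)
  mod <- wb
  mod$samples <- 2 * wb$samples * exp(-8 * t) *
    exp(2i * pi * 0.04 * acq_h$transmitter_mhz * t)
  rec <- fit_water_lcm(to_spectrum(mod, acq_h$n_points, 3), wb)
  expect_equal(unname(rec$params["gamma_hz"]), 8, tolerance = 0.4)
  expect_equal(unname(rec$params["delta_ppm"]), 0.04, tolerance = 0.002)
  expect_equal(rec$amplitude, 2, tolerance = 0.1)
})
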