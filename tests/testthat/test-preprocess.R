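test_that("eddy-current correction inverts a known phase exactly", {
  catal <- default_catalog("HERMES80")
  base <- synth_fid(catalog_multiplets(catal, "A"), truth_default, acq_h)
  t <- time_axis(acq_h)
  phi <- 0.4 * exp(-t / 0.05)
  water <- water_basis_fid(catal, acq_h)
  water$samples <- water$samples * exp(1i * phi)
  distorted <- base
  distorted$samples <- distorted$samples * exp(1i * phi)
  fixed <- eddy_correct(distorted, water)
  # water phase = eddy phase (water line is on-resonance), so correction
  # recovers the undistorted FID to machine precision
  expect_equal(fixed$samples, base$samples, tolerance = 1e-12)

  # zero-phase water leaves the input unchanged
  wat0 <- water_basis_fid(catal, acq_h)
  expect_equal(eddy_correct(base, wat0)$samples, base$samples,
               tolerance = 1e-12)

  # water corrected by itself becomes purely real
  wcorr <- eddy_correct(water, water)
  expect_lt(sum(Im(wcorr$samples)^2) / sum(Mod(wcorr$samples)^2), 1e-6)
  expect_true(all(Re(wcorr$samples) >= -1e-9))
})

test_that("registration recovers known displacements and stays put otherwise", {
  catal <- default_catalog("HERMES80")
  base <- synth_fid(catalog_multiplets(catal, "A"), truth_default, acq_h)
  aligned <- lapply(1:6, function(i) base)
  r0 <- register_transients(aligned)
  expect_lt(max(abs(r0$result$df_hz)), 0.01)

  displaced <- aligned
  displaced[[3]] <- shift_phase_fid(displaced[[3]], 3, 20 * pi / 180)
  r <- register_transients(displaced)
  expect_equal(r$result$df_hz[3], -3, tolerance = 0.05)
  expect_equal(r$result$phase_deg[3], -20, tolerance = 1)
  expect_equal(r$transients[[3]]$samples, base$samples, tolerance = 1e-3)
})

test_that("profiled registration matches the 2-D simplex optimum", {
  catal <- default_catalog("HERMES80")
  base <- synth_fid(catalog_multiplets(catal, "A"), truth_default, acq_h)
  t <- time_axis(acq_h)
  win <- which(t < 0.2)
  set.seed(8)
  s <- base$samples * exp(1i * (2 * pi * 1.7 * t + 0.3)) +
    complex(real = rnorm(acq_h$n_points, 0, 2),
            imaginary = rnorm(acq_h$n_points, 0, 2))
  ref <- base$samples[win]
  prof <- editmrs:::register_profiled(s[win] * Conj(ref), t[win], 0)
  nm <- editmrs:::register_nm(s[win], ref, t[win], c(0, 0), maxit = 500, reltol = 1e-12)
  expect_equal(prof[1], nm[1], tolerance = 0.01)
  ang <- (prof[2] - nm[2] + pi) %% (2 * pi) - pi
  expect_lt(abs(ang), 0.01)
})

test_that("registration + weighted averaging reduce variance without inflating noise", {
  catal <- default_catalog("HERMES80")
  nz <- noise_config(noise_sd = 4)
  raw <- simulate_scan(truth_default, acq_h, catal, nz, seed = 21)
  tl <- raw$transients$A
  spec_of <- function(f) Re(to_spectrum(f, 2048, 3)$intensities)
  before <- apply(vapply(tl, spec_of, numeric(2048)), 1, stats::var)
  r <- register_transients(tl)
  after <- apply(vapply(r$transients, spec_of, numeric(2048)), 1, stats::var)
  expect_lt(mean(after), mean(before))

  # drift-free data: robust chain no worse than the naive mean by > 5%
  nz0 <- noise_config(noise_sd = 4, drift_hz_per_transient = 0,
                      jitter_hz_sd = 0, phase_jitter_deg_sd = 0,
                      baseline_wobble = 0, eddy_phase_amp_rad = 0,
                      shim_hz = 0, shim_hz_sd = 0)
  raw0 <- simulate_scan(truth_default, acq_h, catal, nz0, seed = 22)
  tl0 <- raw0$transients$A
  naive <- Reduce(`+`, lapply(tl0, function(f) f$samples)) / length(tl0)
  r0 <- register_transients(tl0)
  robust <- weighted_average(r0$transients)$fid$samples
  floor_of <- function(s) {
    sp <- to_spectrum(fid(s, acq_h), 2048, 3)
    stats::sd(Re(sp$intensities[sp$ppm > 0 & sp$ppm < 0.5]))
  }
  expect_lt(floor_of(robust), floor_of(naive) * 1.05)
})

test_that("weighted averaging down-weights a gross outlier", {
  catal <- default_catalog("HERMES80")
  base <- synth_fid(catalog_multiplets(catal, "A"), truth_default, acq_h)
  set.seed(7)
  tl <- lapply(1:8, function(i) {
    f <- base
    f$samples <- f$samples + complex(real = rnorm(acq_h$n_points, 0, 1),
                                     imaginary = rnorm(acq_h$n_points, 0, 1))
    f
  })
  tl[[5]]$samples <- tl[[5]]$samples + 50      # gross DC corruption
  wa <- weighted_average(tl)
  expect_equal(sum(wa$weights), 1)
  expect_true(all(wa$weights >= 0))
  expect_equal(which.min(wa$weights), 5)

  same <- lapply(1:4, function(i) base)
  expect_equal(weighted_average(same)$fid$samples, base$samples)
  expect_equal(weighted_average(same)$weights, rep(0.25, 4))
})

test_that("sub-spectrum alignment stays put on an aligned clean quartet", {
  # quartet without co-edited 3-ppm content so the target regions are clean
  catal <- default_catalog("HERMES80")
  catal$entries <- catal$entries[c("GSH", "Asp", "NAA", "tCr", "tCho")]
  catal$entries$H2Oresid <- default_catalog("HERMES80")$entries$H2Oresid
  catal$entries$H2Oresid$lines <- catal$entries$H2Oresid$lines[1, ]
  subs <- lapply(stats::setNames(subexp_labels("HERMES80"),
                                 subexp_labels("HERMES80")), function(lab) {
    synth_fid(catalog_multiplets(catal, lab), truth_default, acq_h, lab)
  })
  al <- align_subspectra(subs, "HERMES")
  expect_lt(max(abs(al$adjustments$df_hz)), 0.02)
  expect_lt(max(abs(al$adjustments$phase_deg)), 0.2)
})

test_that("sub-spectrum alignment recovers a known displacement of C", {
  catal <- default_catalog("HERMES80")
  subs <- lapply(stats::setNames(subexp_labels("HERMES80"),
                                 subexp_labels("HERMES80")), function(lab) {
    synth_fid(catalog_multiplets(catal, lab), truth_default, acq_h, lab)
  })
  subs$C <- shift_phase_fid(subs$C, 2, 0)
  al <- align_subspectra(subs, "HERMES")
  expect_equal(al$adjustments$df_hz[al$adjustments$label == "C"], -2,
               tolerance = 0.1)
})

test_that("after alignment the 2-ppm residual in the GSH difference is small", {
  catal <- default_catalog("HERMES80")
  raw <- simulate_scan(truth_default, acq_h, catal, noise_off, seed = 1)
  ps <- preprocess_scan(raw, pp_study)
  sp <- to_spectrum(ps$diff_fids$GSH, 2048, 3)
  res2 <- max(Mod(sp$intensities[sp$ppm > 1.95 & sp$ppm < 2.07]))
  subA <- to_spectrum(weighted_average(raw$transients$A)$fid, 2048, 3)
  naa <- max(Mod(subA$intensities[subA$ppm > 1.95 & subA$ppm < 2.07]))
  expect_lt(res2 / naa, 0.01)
})

test_that("HSVD removes in-band components and preserves out-of-band ones", {
  acq <- acq_h
  t <- time_axis(acq)
  f_in <- ppm_to_hz(4.7, acq)
  f_out <- ppm_to_hz(2.0, acq)
  one <- fid(exp((-12 + 2i * pi * f_in) * t), acq)
  filt <- hsvd_filter(one, rank = 5, model_points = 512)
  expect_lt(sum(Mod(filt$samples)^2) / sum(Mod(one$samples)^2), 1e-8)

  outside <- fid(0.7 * exp((-9 + 2i * pi * f_out) * t), acq)
  pass <- hsvd_filter(outside, rank = 5, model_points = 512)
  expect_equal(pass$samples, outside$samples, tolerance = 1e-6)

  two <- fid(one$samples + outside$samples, acq)
  filt2 <- hsvd_filter(two, rank = 6, model_points = 512)
  # brute-force least squares of the two known decaying sinusoids
  V <- cbind(exp((-12 + 2i * pi * f_in) * t), exp((-9 + 2i * pi * f_out) * t))
  amps <- qr.solve(V, filt2$samples)
  expect_lt(Mod(amps[1]), 1e-3)
  expect_equal(Mod(amps[2]), 0.7, tolerance = 7e-4)

  expect_error(hsvd_filter(one, rank = 300, model_points = 512), "rank")
})

test_that("HSVD leaves the cohort difference spectra nearly water-free", {
  catal <- default_catalog("HERMES80")
  raw <- simulate_scan(truth_default, acq_h, catal, noise_config(), seed = 13)
  cfg_off <- preprocess_config(hsvd = FALSE, zerofill_to = 2048)
  cfg_on <- preprocess_config(zerofill_to = 2048)  # default 1024/25 HSVD
  before <- preprocess_scan(raw, cfg_off)
  after <- preprocess_scan(raw, cfg_on)
  wband <- function(ps) {
    sp <- ps$diff_spectra$GSH
    max(Mod(sp$intensities[sp$ppm > 4.4 & sp$ppm < 5.0]))
  }
  expect_lt(wband(after) / wband(before), 0.05)
})

test_that("the noiseless distortion-free chain is an identity", {
  catal <- default_catalog("HERMES80")
  raw <- simulate_scan(truth_default, acq_h, catal, noise_off, seed = 1)
  ps <- preprocess_scan(raw, preprocess_config(hsvd = FALSE, align = FALSE,
                                               zerofill_to = 2048))
  pred <- diff_fid_of(default_catalog("HERMES80"),
                      c("GSH", "Asp", "MM12", "MM14", "H2Oresid"),
                      truth_default, acq_h)
  expect_lt(max(Mod(ps$diff_fids$GSH$samples - pred$samples)) /
              max(Mod(pred$samples)), 1e-6)
  expect_true(length(ps$provenance) > 0)
})

test_that("preprocessing is deterministic and label-equivariant", {
  catal <- default_catalog("HERMES80")
  raw <- simulate_scan(truth_default, acq_h, catal, noise_config(), seed = 17)
  p1 <- preprocess_scan(raw, pp_study)
  p2 <- preprocess_scan(raw, pp_study)
  expect_identical(p1$diff_fids$GSH$samples, p2$diff_fids$GSH$samples)

  raw_perm <- raw
  raw_perm$transients <- lapply(raw$transients, function(tl) rev(tl))
  p3 <- preprocess_scan(raw_perm, pp_study)
  expect_equal(p3$diff_fids$GSH$samples, p1$diff_fids$GSH$samples,
               tolerance = 1e-9)
})
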