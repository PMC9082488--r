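test_that("ppm axis spans the spectral width symmetrically about the carrier", {
  acq <- acq_params(sw_hz = 2500, transmitter_mhz = 127.7, center_ppm = 4.68)
  ends <- ppm_axis(acq, 2)
  expect_equal(ends, 4.68 + c(1, -1) * 1250 / 127.7, tolerance = 1e-12)
  ax <- ppm_axis(acq, 257)
  expect_equal(ax[129], 4.68)                       # midpoint for odd n
  expect_equal(diff(range(ax)) * acq$transmitter_mhz, 2500)
  ax2 <- ppm_axis(acq, 33)
  expect_equal(diff(range(ax2)) * acq$transmitter_mhz, 2500)
  expect_error(ppm_axis(acq, 1), "n")
})

test_that("ppm/Hz conversion is a bijection", {
  acq <- acq_hermes80()
  ppm <- runif(200, -2, 11)
  expect_equal(hz_to_ppm(ppm_to_hz(ppm, acq), acq), ppm, tolerance = 1e-9)
  hz <- runif(200, -1250, 1250)
  expect_equal(ppm_to_hz(hz_to_ppm(hz, acq), acq), hz, tolerance = 1e-9)
})

test_that("synth_fid realizes the forward model", {
  acq <- acq_hermes80()
  # single on-resonance line: pure T2 decay of the magnitude
  m <- multiplet("x", data.frame(offset_ppm = acq$center_ppm, amplitude = 1,
                                 phase_deg = 0), t2_ms = 100)
  f <- synth_fid(list(m), c(x = 1), acq)
  expect_equal(Mod(f$samples), exp(-time_axis(acq) / 0.1), tolerance = 1e-12)
  # antiphase doublet: zero real part at t = 0
  j <- 7 / acq$transmitter_mhz
  m2 <- multiplet("d", data.frame(offset_ppm = acq$center_ppm + c(-j, j) / 2,
                                  amplitude = 0.5,
                                  phase_deg = c(90, -90)), t2_ms = 100)
  f2 <- synth_fid(list(m2), c(d = 1), acq)
  expect_equal(Re(f2$samples[1]), 0, tolerance = 1e-12)
  # linearity in concentration
  f1 <- synth_fid(list(m), c(x = 1.3), acq)
  f2x <- synth_fid(list(m), c(x = 2.6), acq)
  expect_equal(f2x$samples, 2 * f1$samples, tolerance = 1e-12)
  expect_error(synth_fid(list(m), c(y = 1), acq), "missing concentration")
})

test_that("synthesis and transform are linear in amplitudes", {
  acq <- acq_hermes80()
  set.seed(5)
  ms <- lapply(1:3, function(i) {
    multiplet(paste0("m", i),
              data.frame(offset_ppm = runif(2, 1, 4), amplitude = runif(2),
                         phase_deg = runif(2, -180, 180)),
              t2_ms = runif(1, 50, 200), gaussian_hz = runif(1, 0, 10))
  })
  cs <- c(m1 = 0.7, m2 = 1.9, m3 = 0.4)
  together <- synth_fid(ms, cs, acq)
  apart <- Reduce(`+`, lapply(1:3, function(i) {
    cs[i] * synth_fid(ms[i], stats::setNames(1, paste0("m", i)), acq)$samples
  }))
  expect_equal(together$samples, apart, tolerance = 1e-12)
  sp_sum <- to_spectrum(together, 4096, 2)
  sp_parts <- Reduce(`+`, lapply(1:3, function(i) {
    to_spectrum(fid(cs[i] * synth_fid(ms[i], stats::setNames(1, paste0("m", i)),
                                      acq)$samples, acq), 4096, 2)$intensities
  }))
  expect_equal(sp_sum$intensities, sp_parts, tolerance = 1e-10)
})

test_that("to_spectrum round-trips and reproduces the Lorentzian width", {
  acq <- acq_hermes80()
  m <- multiplet("x", data.frame(offset_ppm = 2.9, amplitude = 1,
                                 phase_deg = 0), t2_ms = 120)
  f <- synth_fid(list(m), c(x = 2), acq)
  rt <- from_spectrum(to_spectrum(f, acq$n_points, 0))
  expect_equal(rt$samples, f$samples, tolerance = 1e-10)
  # FWHM of the absorption line = 1/(pi T2) + lb
  for (lb in c(0, 3)) {
    sp <- to_spectrum(f, 65536, lb)
    mag <- Re(sp$intensities)
    half <- max(mag) / 2
    above <- range(which(mag >= half))
    fwhm_hz <- abs(diff(sp$ppm[above])) * acq$transmitter_mhz
    expect_equal(fwhm_hz, 1 / (pi * 0.12) + lb, tolerance = 0.05)
  }
  expect_error(to_spectrum(f, 1024, 0), "zerofill_to")
  expect_s3_class(to_spectrum(f, 32768, 3), "spectrum")  # defaults accepted
})

test_that("Hadamard combination isolates the targeted sign patterns", {
  acq <- acq_hermes80()
  mk <- function(v) fid(complex(real = rep(v, acq$n_points)), acq)
  same <- list(A = mk(1), B = mk(1), C = mk(1), D = mk(1))
  expect_equal(max(Mod(hadamard_combine(same, "GSH")$samples)), 0)
  expect_equal(max(Mod(hadamard_combine(same, "GABA")$samples)), 0)

  only_a <- list(A = mk(4), B = mk(0), C = mk(0), D = mk(0))
  expect_equal(hadamard_combine(only_a, "GSH")$samples,
               only_a$A$samples / 4)
  expect_equal(hadamard_combine(only_a, "GABA")$samples,
               only_a$A$samples / 4)

  # expected value computed by direct evaluation of the combination formula
  set.seed(2)
  comp <- complex(real = rnorm(acq$n_points), imaginary = rnorm(acq$n_points))
  sgn_gsh <- c(A = 1, B = -1, C = 1, D = -1)
  quartet <- lapply(sgn_gsh, function(s) fid(s * comp, acq))
  expected_gsh <- Reduce(`+`, Map(function(s, f) s * f$samples,
                                  sgn_gsh, quartet)) / 4
  expect_equal(hadamard_combine(quartet, "GSH")$samples, expected_gsh)
  expect_equal(expected_gsh, comp)   # magnitude-1 pattern -> amplitude 1
  expect_equal(max(Mod(hadamard_combine(quartet, "GABA")$samples)), 0)
})

test_that("Hadamard combination inverts on an orthogonal 4-component toy", {
  acq <- acq_hermes80()
  set.seed(3)
  comp_gsh <- complex(real = rnorm(acq$n_points), imaginary = rnorm(acq$n_points))
  comp_gaba <- complex(real = rnorm(acq$n_points), imaginary = rnorm(acq$n_points))
  comp_mean <- complex(real = rnorm(acq$n_points), imaginary = rnorm(acq$n_points))
  sg <- c(A = 1, B = -1, C = 1, D = -1)
  sb <- c(A = 1, B = 1, C = -1, D = -1)
  quartet <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(l) {
    fid(comp_mean + sg[l] * comp_gsh + sb[l] * comp_gaba, acq)
  })
  expect_equal(hadamard_combine(quartet, "GSH")$samples, comp_gsh,
               tolerance = 1e-12)
  expect_equal(hadamard_combine(quartet, "GABA")$samples, comp_gaba,
               tolerance = 1e-12)
})

test_that("MEGA difference is (ON - OFF)/2 and linear", {
  acq <- acq_mega120()
  set.seed(4)
  a <- complex(real = rnorm(acq$n_points)); b <- complex(real = rnorm(acq$n_points))
  on <- fid(a, acq, "ON"); off <- fid(b, acq, "OFF")
  expect_equal(mega_difference(on, on)$samples,
               complex(real = rep(0, acq$n_points)))
  zero <- fid(complex(real = rep(0, acq$n_points)), acq, "OFF")
  expect_equal(mega_difference(on, zero)$samples, a / 2)
  d12 <- mega_difference(fid(a + b, acq), zero)$samples
  expect_equal(d12, mega_difference(on, zero)$samples +
                 mega_difference(fid(b, acq), zero)$samples)
  bad <- fid(complex(real = rnorm(64)), acq_params(n_points = 64))
  expect_error(mega_difference(on, bad), "mismatch")
})
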