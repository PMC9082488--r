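#' Cubic B-spline baseline regressors
#'
#' Builds cubic B-spline regressors on evenly spaced knots spanning the fit
#' range. The number of regressors is `ceiling(span / knot_spacing) + 3`, and
#' the regressors form a partition of unity on the interior of the range, so
#' any straight line on the range is represented exactly.
#'
#' @param fit_range_ppm Length-2 interval.
#' @param knot_spacing_ppm Nominal knot spacing (default 0.4 ppm).
#' @param grid Frequency grid (ppm) to evaluate on.
#' @return Matrix `length(grid) x n_regressors`.
#' @export
spline_basis <- function(fit_range_ppm, knot_spacing_ppm = 0.4, grid) {
  lo <- min(fit_range_ppm); hi <- max(fit_range_ppm)
  span <- hi - lo
  if (span < knot_spacing_ppm) stop("fit range narrower than knot spacing")
  n_int <- ceiling(span / knot_spacing_ppm)
  breaks <- seq(lo, hi, length.out = n_int + 1)
  h <- breaks[2] - breaks[1]
  knots <- c(lo - h * (3:1), breaks, hi + h * (1:3))
  splines::splineDesign(knots, grid, ord = 4, outer.ok = TRUE)
}

#' Configuration for linear-combination modeling
#'
#' @param fit_range_ppm Modeled interval (default 0.5-4.2 ppm).
#' @param knot_spacing_ppm Baseline knot spacing (default 0.4 ppm).
#' @param soft_constraints Data frame with columns `name_p`, `name_q`,
#'   `ratio`, `sd`: quadratic penalties `((A_p - ratio * A_q) / sd)^2`
#'   applied when both names are in the basis. Default constrains the
#'   parametrized MM pair MM12:MM14 to ratio 2 (sd 0.2).
#' @param shift_prior_sd_ppm Gaussian prior SD on per-basis shifts
#'   (default 0.02 ppm; shifts bounded to +/- 0.05 ppm).
#' @param lorentz_prior_sd_hz Gaussian prior SD on per-basis Lorentzian
#'   broadening (default 2 Hz; gamma >= 0).
#' @param gauss_prior_sd_hz Gaussian prior SD on the global Gaussian
#'   broadening (default 3 Hz; the one-sided sigma_G >= 0 bound would
#'   otherwise let noise-driven broadening bias amplitudes upward).
#' @param max_iter Maximum outer Levenberg-Marquardt iterations.
#' @param ftol Relative residual-change convergence tolerance of the outer
#'   loop (default 1e-8).
#' @param target `"GSH"` or `"GABA"`.
#' @export
lcm_config <- function(fit_range_ppm = c(0.5, 4.2), knot_spacing_ppm = 0.4,
                       soft_constraints = data.frame(
                         name_p = "MM12", name_q = "MM14",
                         ratio = 2.0, sd = 0.2),
                       shift_prior_sd_ppm = 0.02, lorentz_prior_sd_hz = 2,
                       gauss_prior_sd_hz = 3, max_iter = 200, ftol = 1e-8,
                       target = c("GSH", "GABA")) {
  stopifnot(knot_spacing_ppm > 0)
  list(fit_range_ppm = fit_range_ppm, knot_spacing_ppm = knot_spacing_ppm,
       soft_constraints = soft_constraints,
       shift_prior_sd_ppm = shift_prior_sd_ppm,
       lorentz_prior_sd_hz = lorentz_prior_sd_hz,
       gauss_prior_sd_hz = gauss_prior_sd_hz,
       max_iter = max_iter, ftol = ftol, target = match.arg(target))
}

#' Linear-combination fit of a difference spectrum
#'
#' Models the real part of the spectrum over the fit range as a non-negative
#' linear combination of phase-rotated, broadened and shifted basis spectra
#' plus a free-signed cubic-spline baseline:
#' the objective is
#' `|| Re{e^{-i(phi0 + phi1 (f - fbar))} sum_m A_m B_m(f)} + sum_k beta_k
#' S_k(f) - Re S(f) ||^2` plus soft-constraint and prior penalties, where
#' `B_m` is the transform of `b_m(t) e^{-gamma_m t} e^{-(sigma_G t)^2}
#' e^{i 2 pi delta_m nu0 t}`. The linear coefficients (`A_m >= 0` by
#' non-negative least squares, `beta` free) are re-solved at every outer
#' iteration (variable projection); the outer parameters
#' `(phi0, phi1, sigma_G, gamma_m, delta_m)` move by Levenberg-Marquardt.
#' Deterministic given its inputs.
#'
#' @param spec A `spectrum` produced by [to_spectrum] (its recorded zero-fill
#'   and line broadening are applied to the basis).
#' @param basis A [basis_set] sharing the spectrum's acquisition.
#' @param cfg An [lcm_config].
#' @return An `lcm_fit_result` with amplitudes, phases (deg, deg/ppm),
#'   broadenings, shifts, spline coefficients, model/baseline/residual
#'   curves, and `gaba_plus` when the target is GABA.
#' @export
lcm_fit <- function(spec, basis, cfg = lcm_config()) {
  acq <- spec$acq
  stopifnot(inherits(basis, "basis_set"),
            abs(basis$acq$sw_hz - acq$sw_hz) < 1e-9,
            abs(basis$acq$transmitter_mhz - acq$transmitter_mhz) < 1e-9)
  M <- length(basis$names)
  zf <- spec$proc$zerofill_to %||% length(spec$intensities)
  lb <- spec$proc$lb_hz %||% 0
  n0 <- nrow(basis$fids)
  t <- time_axis(acq, n0)
  basis_apod <- basis$fids * exp(-pi * lb * t)

  fit_sel <- which(spec$ppm >= min(cfg$fit_range_ppm) &
                     spec$ppm <= max(cfg$fit_range_ppm))
  if (length(fit_sel) < 10) stop("fit range not covered by spectrum")
  fppm <- spec$ppm[fit_sel]
  ord <- fft_desc_order(zf)
  idx0 <- ord$order[fit_sel] - 1L       # 0-based bins in raw FFT order
  y <- Re(spec$intensities[fit_sel])
  fbar <- mean(cfg$fit_range_ppm)
  B <- spline_basis(cfg$fit_range_ppm, cfg$knot_spacing_ppm, fppm)
  nb <- ncol(B)

  # soft-constraint penalty rows over [A, beta+, beta-]
  sc <- cfg$soft_constraints
  pen_rows <- NULL
  if (!is.null(sc) && nrow(sc) > 0) {
    for (i in seq_len(nrow(sc))) {
      if (sc$name_p[i] %in% basis$names && sc$name_q[i] %in% basis$names) {
        row <- numeric(M + 2 * nb)
        row[match(sc$name_p[i], basis$names)] <- 1 / sc$sd[i]
        row[match(sc$name_q[i], basis$names)] <- -sc$ratio[i] / sc$sd[i]
        pen_rows <- rbind(pen_rows, row)
      }
    }
  }

  # rank check at the unmodified basis
  D0 <- lcm_design_cpp(basis_apod, t, zf, rep(0, M), 0, rep(0, M), idx0,
                       rep(1 + 0i, length(idx0)))
  qr0 <- qr(D0)
  if (qr0$rank < M) {
    bad <- basis$names[qr0$pivot[(qr0$rank + 1):M]]
    stop("rank-deficient design; collinear basis entries: ",
         paste(bad, collapse = ", "))
  }

  pen_mat <- if (is.null(pen_rows)) {
    matrix(0, 0, M + 2 * nb)
  } else {
    unname(pen_rows)
  }
  solve_inner <- function(theta, want_design = FALSE) {
    phasor <- exp(-1i * (theta[1] + theta[2] * (fppm - fbar)))
    lcm_inner_cpp(basis_apod, t, zf, theta[3 + seq_len(M)], theta[3],
                  theta[3 + M + seq_len(M)] * acq$transmitter_mhz,
                  idx0, phasor, B, pen_mat, y, want_design)
  }

  resid_fn <- function(theta) {
    inner <- solve_inner(theta)
    gamma <- theta[3 + seq_len(M)]
    delta <- theta[3 + M + seq_len(M)]
    c(as.vector(inner$resid), delta / cfg$shift_prior_sd_ppm,
      gamma / cfg$lorentz_prior_sd_hz,
      theta[3] / (cfg$gauss_prior_sd_hz %||% 3))
  }

  theta0 <- c(0, 0, 0.1, rep(0.05, M), rep(0, M))
  lower <- c(-pi, -pi, 0, rep(0, M), rep(-0.05, M))
  upper <- c(pi, pi, 30, rep(20, M), rep(0.05, M))
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    theta0, lower, upper, resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = cfg$max_iter,
                                         ftol = cfg$ftol %||% 1e-8,
                                         ptol = cfg$ftol %||% 1e-8,
                                         maxfev = 20000))), silent = TRUE)
  flagged <- inherits(fit, "try-error")
  theta <- if (flagged) theta0 else fit$par
  inner <- solve_inner(theta, want_design = TRUE)
  xsol <- as.vector(inner$x)
  amp <- stats::setNames(xsol[seq_len(M)], basis$names)
  beta <- xsol[M + seq_len(nb)] - xsol[M + nb + seq_len(nb)]
  model <- as.vector(inner$Dmet %*% amp) + as.vector(B %*% beta)
  baseline <- as.vector(B %*% beta)
  res <- structure(list(
    amplitudes = amp,
    phi0_deg = theta[1] * 180 / pi,
    phi1_deg_per_ppm = theta[2] * 180 / pi,
    sigma_g_hz = theta[3],
    gamma_hz = stats::setNames(theta[3 + seq_len(M)], basis$names),
    delta_ppm = stats::setNames(theta[3 + M + seq_len(M)], basis$names),
    beta = beta, ppm = fppm, data = y, model = model, baseline = baseline,
    residual = y - model, target = cfg$target,
    converged = if (flagged) FALSE else fit$info %in% 1:4,
    flagged = if (flagged) TRUE else !(fit$info %in% 1:4)
  ), class = "lcm_fit_result")
  if (cfg$target == "GABA" && "MM30" %in% basis$names) {
    res$gaba_plus <- gaba_plus(res)
  }
  res
}

#' @export
print.lcm_fit_result <- function(x, ...) {
  cat(sprintf("<lcm_fit_result> target %s%s\n", x$target,
              if (x$flagged) " [flagged]" else ""))
  print(round(x$amplitudes, 4))
  invisible(x)
}

#' Combined GABA+ amount from an LCM fit
#'
#' The reported GABA+ value combines the GABA basis amplitude and the
#' co-edited 3-ppm macromolecule basis amplitude.
#'
#' @param result An `lcm_fit_result` with target GABA.
#' @export
gaba_plus <- function(result) {
  if (!"MM30" %in% names(result$amplitudes)) {
    stop("no MM30 entry in the fitted basis")
  }
  unname(result$amplitudes["GABA"] + result$amplitudes["MM30"])
}

#' Unit-concentration water basis FID from a catalog
#' @param catalog A `metabolite_catalog`.
#' @param acq An [acq_params].
#' @export
water_basis_fid <- function(catalog, acq) {
  lab <- subexp_labels(acq$sequence_tag)[1]
  synth_fid(list(resolve_entry(catalog$entries$H2O,
                               subexp_state(acq$sequence_tag, lab))),
            c(H2O = 1), acq, label = "WATER")
}

#' Six-parameter water fit against a simulated water basis function
#'
#' Frequency-domain model with exactly six free parameters: amplitude,
#' zero- and first-order phase, Gaussian and Lorentzian line broadening, and
#' frequency shift. The amplitude is profiled out by exact least squares at
#' each outer step.
#'
#' @param water_spec Water-reference `spectrum`.
#' @param water_basis A [fid] holding the unit-amplitude water basis.
#' @param window_ppm Fit window (default 4.2-5.2 ppm).
#' @return List with `amplitude`, `params`, `converged`, `flagged`.
#' @export
fit_water_lcm <- function(water_spec, water_basis, window_ppm = c(4.2, 5.2)) {
  acq <- water_spec$acq
  zf <- water_spec$proc$zerofill_to %||% length(water_spec$intensities)
  lb <- water_spec$proc$lb_hz %||% 0
  n0 <- length(water_basis$samples)
  t <- time_axis(acq, n0)
  bas <- matrix(water_basis$samples * exp(-pi * lb * t), ncol = 1)
  sel <- which(water_spec$ppm >= min(window_ppm) &
                 water_spec$ppm <= max(window_ppm))
  fppm <- water_spec$ppm[sel]
  ord <- fft_desc_order(zf)
  idx0 <- ord$order[sel] - 1L
  y <- Re(water_spec$intensities[sel])
  fbar <- mean(window_ppm)

  inner <- function(th) {
    phasor <- exp(-1i * (th[1] + th[2] * (fppm - fbar)))
    col <- lcm_design_cpp(bas, t, zf, th[4], th[3],
                          th[5] * acq$transmitter_mhz, idx0, phasor)[, 1]
    A <- sum(col * y) / sum(col * col)
    list(A = A, resid = A * col - y)
  }
  # starts covering Gaussian-dominant and Lorentzian-dominant broadening
  starts <- list(c(0, 0, 0.1, 0.05, 0), c(0, 0, 0.1, 8, 0),
                 c(0, 0, 8, 0.1, 0))
  fit <- NULL
  for (th0 in starts) {
    cand <- try(suppressWarnings(minpack.lm::nls.lm(
      th0, c(-pi, -pi, 0, 0, -0.3), c(pi, pi, 50, 30, 0.3),
      function(th) inner(th)$resid,
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-9,
                                           ptol = 1e-9))), silent = TRUE)
    if (inherits(cand, "try-error")) next
    if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
  }
  if (is.null(fit)) {
    return(list(amplitude = NA_real_, params = NULL, converged = FALSE,
                flagged = TRUE))
  }
  th <- fit$par
  list(amplitude = inner(th)$A,
       params = stats::setNames(
         c(th[1] * 180 / pi, th[2] * 180 / pi, th[3], th[4], th[5]),
         c("phi0_deg", "phi1_deg_per_ppm", "sigma_g_hz", "gamma_hz",
           "delta_ppm")),
       converged = fit$info %in% 1:4, flagged = !(fit$info %in% 1:4))
}
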