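#' Eddy-current correction against the water reference
#'
#' Removes the time-dependent phase of the water FID from a metabolite FID:
#' `out(t) = fid(t) * exp(-i phi_w(t))` where `phi_w` is the unwrapped phase
#' of the water samples. Samples where the water magnitude vanishes carry the
#' previous phase forward (with a warning).
#'
#' @param fid_obj Metabolite [fid].
#' @param water Water-reference [fid] of equal length.
#' @export
eddy_correct <- function(fid_obj, water) {
  if (length(fid_obj$samples) != length(water$samples)) {
    stop("fid and water reference have different lengths")
  }
  mag <- Mod(water$samples)
  ph <- unwrap_phase(Arg(water$samples))
  if (any(mag == 0)) {
    warning("zero-magnitude water samples: carrying previous phase forward")
    bad <- which(mag == 0)
    for (i in bad) ph[i] <- if (i == 1) 0 else ph[i - 1]
  }
  fid_obj$samples <- fid_obj$samples * exp(-1i * ph)
  fid_obj
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  jumps <- round(dp / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

# Pointwise complex median of transients (columns); compiled kernel.
median_reference <- function(samples_mat) as.vector(row_median_cx(samples_mat))

# Closed-form first guess for (df, phi): weighted linear fit of the unwrapped
# phase of ref * conj(s) over the window.
register_guess <- function(s, ref, t) {
  q <- ref * Conj(s)
  w <- Mod(q)
  if (sum(w) == 0) return(c(0, 0))
  ph <- unwrap_phase(Arg(q))
  W <- sum(w); tw <- sum(w * t) / W; pw <- sum(w * ph) / W
  denom <- sum(w * (t - tw)^2)
  slope <- if (denom > 0) sum(w * (t - tw) * (ph - pw)) / denom else 0
  c(slope / (2 * pi), pw - slope * tw)
}

#' Frequency-and-phase registration of transients
#'
#' Aligns each transient to a robust reference (the pointwise median across
#' transients) by finding the frequency shift and zero-order phase that
#' minimize the time-domain squared distance over the first `fit_window_ms`.
#' For fixed frequency the optimal phase is available in closed form (the
#' argument of the windowed cross-correlation), so the search is a profiled
#' 1-D optimization in frequency -- a coarse grid over +/- `search_half_hz`
#' around a phase-slope initial estimate (wide enough to avoid 2*pi phase
#' ambiguity) followed by golden-section refinement. The whole procedure is
#' iterated with the reference rebuilt from the corrected transients.
#'
#' The window is subsampled with `stride` (default 3: every third sample),
#' which loses essentially nothing at these linewidths.
#'
#' @param transients List of [fid] objects (>= 2).
#' @param cfg List of options: `fit_window_ms` (default 200), `max_iter`
#'   (reference rebuilds, default 2), `search_half_hz` (default 6),
#'   `stride` (default 3).
#' @return List with `transients` (corrected) and `result`, a
#'   `registration_result` holding per-transient cumulative shifts (Hz) and
#'   phases (deg) and a reference description.
#' @export
register_transients <- function(transients, cfg = list()) {
  if (length(transients) < 2) stop("need at least 2 transients")
  fit_window_ms <- cfg$fit_window_ms %||% 200
  max_iter <- cfg$max_iter %||% 2
  half_hz <- cfg$search_half_hz %||% 6
  stride <- cfg$stride %||% 3
  acq <- transients[[1]]$acq
  t_full <- time_axis(acq)
  win <- which(t_full < fit_window_ms / 1000)
  tw <- t_full[win]
  S <- vapply(transients, function(f) f$samples, complex(acq$n_points))
  if (any(!is.finite(Re(S))) || any(!is.finite(Im(S)))) {
    stop("non-finite samples in transients")
  }
  n_tr <- ncol(S)
  tot_df <- numeric(n_tr); tot_ph <- numeric(n_tr)

  reg <- register_all_cpp(S, t_full, length(win), iters = max_iter,
                          half_hz = half_hz, stride = stride)
  S <- reg$S
  tot_df <- as.vector(reg$df_hz)
  tot_ph <- as.vector(reg$phase)
  out <- lapply(seq_len(n_tr), function(j) fid(S[, j], acq,
                                               transients[[j]]$label))
  res <- structure(list(df_hz = tot_df,
                        phase_deg = tot_ph * 180 / pi,
                        reference = sprintf(
                          "pointwise median, %d iterations, %g-ms window",
                          max_iter, fit_window_ms),
                        weights = NULL),
                   class = "registration_result")
  list(transients = out, result = res)
}

#' Weighted averaging of aligned transients
#'
#' Weights are inversely proportional to the squared deviation from the
#' pointwise median: `w_n` proportional to `1 / d_n^2` with
#' `d_n = sum_t |s_n(t) - median(t)|^2`; weights are normalized to sum to 1,
#' so a gross outlier is strongly down-weighted.
#'
#' @param transients List of aligned [fid] objects.
#' @return List with `fid` (the weighted average) and `weights`.
#' @export
weighted_average <- function(transients) {
  acq <- transients[[1]]$acq
  if (length(transients) == 1) {
    return(list(fid = transients[[1]], weights = 1))
  }
  S <- vapply(transients, function(f) f$samples, complex(acq$n_points))
  med <- median_reference(S)
  d <- colSums(abs(S - med)^2)
  if (max(d) == 0) {                    # identical transients: plain mean
    w <- rep(1 / ncol(S), ncol(S))
  } else {
    d <- pmax(d, max(d) * 1e-12)
    w <- 1 / d^2
    w <- w / sum(w)
  }
  avg <- as.vector(S %*% w)
  list(fid = fid(avg, acq, transients[[1]]$label), weights = w)
}

# Residual power of the difference spectrum of (moving - fixed) restricted to
# a ppm region, after projecting out a complex linear trend across the
# region, as a function of (df, phi) applied to `moving`. The linear nuisance
# absorbs smooth baseline differences and the slowly varying tails of
# co-edited signal that legitimately survives the pair difference, so an
# already-aligned pair stays (nearly) stationary while misalignment of the
# targeted unedited singlet produces a strong structured residual.
align_objective <- function(par, moving, fixed, t, acq, region_idx, proj) {
  m <- moving * exp(1i * (2 * pi * par[1] * t + par[2]))
  d <- m - fixed
  d[1] <- d[1] / 2                     # first-point pedestal removal
  d <- stats::fft(d)[region_idx]
  sum(Mod(d - proj %*% d)^2)
}

# Projection onto a quadratic trend across `n` equispaced points.
trend_projector <- function(n) {
  u <- seq_len(n) - (n + 1) / 2
  X <- cbind(1, u, u^2)
  X %*% solve(crossprod(X), t(X))
}

region_bins <- function(acq, region_ppm) {
  n <- acq$n_points
  ord <- fft_desc_order(n)
  ppm <- hz_to_ppm(ord$k * acq$sw_hz / n, acq)
  keep <- ppm >= min(region_ppm) & ppm <= max(region_ppm)
  ord$order[keep]
}

#' Align averaged sub-spectra before recombination
#'
#' HERMES: three sequential pairwise frequency/phase optimizations, each
#' minimizing the integrated magnitude of the pair difference over a target
#' region -- residual water (4.2-5.2 ppm) to align B to D, the 2-ppm tNAA
#' signal (1.9-2.1 ppm) to align C to D, then the 3.2-ppm tCho signal
#' (3.1-3.3 ppm) to align A to C. MEGA: one optimization minimizing the
#' 1.9-2.1-ppm tNAA region of the ON-OFF difference.
#'
#' The (df, phi) estimation runs on line-broadened copies of the averaged
#' FIDs (matched filtering against late-FID noise); the corrections are then
#' applied to the unapodized FIDs.
#'
#' @param averaged Named list of averaged [fid] objects (A/B/C/D or ON/OFF).
#' @param scheme `"HERMES"` or `"MEGA"`.
#' @param lb_hz Line broadening used inside the estimation objective only.
#' @return List with `fids` (aligned) and `adjustments` (per-label df/phase).
#' @export
align_subspectra <- function(averaged, scheme = c("HERMES", "MEGA"),
                             lb_hz = 3) {
  scheme <- match.arg(scheme)
  steps <- if (scheme == "HERMES") {
    if (!all(c("A", "B", "C", "D") %in% names(averaged))) {
      stop("HERMES alignment needs labels A, B, C, D")
    }
    list(list(move = "B", fix = "D", region = c(4.2, 5.2)),
         list(move = "C", fix = "D", region = c(1.9, 2.1)),
         # the tCho window starts at 3.12 ppm: below that the envelope of the
         # co-edited 3-ppm signals leaks into the pair difference and would
         # bias the optimum
         list(move = "A", fix = "C", region = c(3.12, 3.32)))
  } else {
    if (!all(c("ON", "OFF") %in% names(averaged))) {
      stop("MEGA alignment needs labels ON, OFF")
    }
    list(list(move = "ON", fix = "OFF", region = c(1.9, 2.1)))
  }
  acq <- averaged[[1]]$acq
  t <- time_axis(acq)
  apod <- exp(-pi * lb_hz * t)
  adj <- data.frame(label = names(averaged), df_hz = 0, phase_deg = 0)
  for (st in steps) {
    idx <- region_bins(acq, st$region)
    proj <- trend_projector(length(idx))
    opt <- stats::optim(c(0, 0), align_objective,
                        moving = averaged[[st$move]]$samples * apod,
                        fixed = averaged[[st$fix]]$samples * apod,
                        t = t, acq = acq, region_idx = idx, proj = proj,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-9, maxit = 300))
    averaged[[st$move]]$samples <- averaged[[st$move]]$samples *
      exp(1i * (2 * pi * opt$par[1] * t + opt$par[2]))
    k <- adj$label == st$move
    adj$df_hz[k] <- opt$par[1]
    adj$phase_deg[k] <- opt$par[2] * 180 / pi
  }
  list(fids = averaged, adjustments = adj)
}
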