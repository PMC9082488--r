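#' HSVD filtering of residual water
#'
#' Decomposes the leading `model_points` samples of an FID into damped complex
#' sinusoids via a Hankel-matrix singular value decomposition: the signal
#' subspace is the span of the leading `rank` left singular vectors, the
#' component poles come from the shift-invariance least-squares eigenproblem
#' of that subspace, and amplitudes follow by linear least squares.
#' Components whose frequency falls inside `remove_band_ppm` are reconstructed
#' over the full FID length and subtracted.
#'
#' @param fid_obj An [fid].
#' @param remove_band_ppm Interval of ppm values to remove (default
#'   `c(4.4, 5.0)`, the residual-water band).
#' @param rank Truncation rank of the SVD (default 25).
#' @param model_points Number of leading samples used to build the Hankel
#'   matrix (default 1024); `rank < model_points / 2` is required.
#' @return The filtered [fid]; attributes `hsvd_components` (data frame of
#'   all estimated components) and `hsvd_removed` (logical) record the model.
#' @export
hsvd_filter <- function(fid_obj, remove_band_ppm = c(4.4, 5.0), rank = 25,
                        model_points = 1024) {
  acq <- fid_obj$acq
  n <- length(fid_obj$samples)
  model_points <- min(model_points, n)
  if (rank >= model_points / 2) stop("rank must be < model_points / 2")
  x <- fid_obj$samples[seq_len(model_points)]
  L <- floor(model_points / 2)
  Mcol <- model_points - L + 1
  H <- matrix(x[outer(seq_len(L), seq_len(Mcol) - 1L, `+`)], L, Mcol)
  sv <- svd(H, nu = rank, nv = 0)
  U <- sv$u
  # shift invariance: U_bottom ~= U_top %*% Z, poles = eigenvalues of Z
  Ut <- U[-L, , drop = FALSE]
  Ub <- U[-1, , drop = FALSE]
  Z <- qr.solve(Ut, Ub)
  ev <- eigen(Z, only.values = TRUE)$values
  if (any(!is.finite(ev))) stop("degenerate input: eigenproblem did not converge")
  dt <- dwell_time(acq)
  f_hz <- Arg(ev) / (2 * pi * dt)
  damp <- log(Mod(ev)) / dt          # 1/s (negative for decaying components)
  # amplitudes on the modeled points
  tm <- (seq_len(model_points) - 1) * dt
  V <- exp(outer(tm, damp + 2i * pi * f_hz))
  amp <- qr.solve(V, x)
  band_hz <- ppm_to_hz(sort(remove_band_ppm), acq)
  # exclude (numerically) growing poles from subtraction
  inband <- f_hz >= band_hz[1] & f_hz <= band_hz[2] & Mod(ev) <= 1.001
  comp <- data.frame(f_hz = f_hz, ppm = hz_to_ppm(f_hz, acq), damping = damp,
                     amplitude = Mod(amp), phase_deg = Arg(amp) * 180 / pi,
                     removed = inband)
  if (any(inband)) {
    tf <- time_axis(acq, n)
    recon <- exp(outer(tf, damp[inband] + 2i * pi * f_hz[inband])) %*%
      amp[inband]
    fid_obj$samples <- fid_obj$samples - as.vector(recon)
  }
  attr(fid_obj, "hsvd_components") <- comp
  attr(fid_obj, "hsvd_removed") <- any(inband)
  fid_obj
}
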