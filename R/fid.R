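#' Construct an FID (complex time-domain signal)
#'
#' @param samples Complex vector of time-domain samples.
#' @param acq An [acq_params] object; `length(samples)` must equal
#'   `acq$n_points` (zero-filling happens only inside [to_spectrum]).
#' @param label Sub-experiment tag: one of A, B, C, D, ON, OFF, WATER, or a
#'   difference-target tag such as GSH/GABA after recombination.
#' @export
fid <- function(samples, acq, label = "A") {
  stopifnot(inherits(acq, "acq_params"))
  if (length(samples) != acq$n_points) {
    stop(sprintf("FID has %d samples but acq$n_points is %d",
                 length(samples), acq$n_points))
  }
  structure(list(samples = as.complex(samples), acq = acq, label = label),
            class = "fid")
}

#' @export
print.fid <- function(x, ...) {
  cat(sprintf("<fid> label=%s, %d points, |s(0)|=%.4g\n",
              x$label, length(x$samples), Mod(x$samples[1])))
  invisible(x)
}

#' Construct a frequency-domain spectrum
#'
#' @param intensities Complex spectral intensities, ordered to match `ppm`.
#' @param ppm Strictly descending ppm axis (NMR convention, high field right).
#' @param acq The [acq_params] the spectrum derives from.
#' @param proc Optional list of processing metadata (zero-fill length,
#'   line broadening) recorded by [to_spectrum].
#' @export
new_spectrum <- function(intensities, ppm, acq, proc = list()) {
  stopifnot(length(intensities) == length(ppm))
  if (any(diff(ppm) >= 0)) stop("ppm axis must be strictly descending")
  structure(list(intensities = as.complex(intensities), ppm = ppm, acq = acq,
                 proc = proc), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.2f..%.2f ppm\n",
              length(x$ppm), max(x$ppm), min(x$ppm)))
  invisible(x)
}

# Descending-ppm ordering of raw FFT output of length n (Nyquist bin assigned
# to +sw/2). Returns 1-based indices into the FFT output and the bin numbers k
# such that f_k = k * sw / n.
fft_desc_order <- function(n) {
  k <- c(seq(n / 2, 0), seq(-1, -n / 2 + 1))
  list(order = ifelse(k >= 0, k, k + n) + 1L, k = k)
}

#' Fourier transform an FID with apodization and zero-filling
#'
#' Applies exponential line broadening `exp(-pi * lb_hz * t)` followed by
#' zero-filling and a discrete Fourier transform. The returned ppm axis is
#' descending and derives from the exact DFT bin frequencies
#' (`f = k * sw / zerofill_to`), so line positions are bin-accurate.
#'
#' @param fid_obj An [fid].
#' @param zerofill_to Transform length; must be at least the FID length.
#'   Default 32768 with 3-Hz broadening, the conventional display/peak-fit
#'   processing of edited difference spectra.
#' @param lb_hz Exponential line broadening in Hz (>= 0).
#' @return A `spectrum` object.
#' @export
to_spectrum <- function(fid_obj, zerofill_to = 32768, lb_hz = 3) {
  stopifnot(inherits(fid_obj, "fid"), lb_hz >= 0)
  n0 <- length(fid_obj$samples)
  if (zerofill_to < n0) stop("zerofill_to must be >= the number of FID points")
  acq <- fid_obj$acq
  t <- time_axis(acq, n0)
  s <- fid_obj$samples * exp(-pi * lb_hz * t)
  # halve the first point: removes the constant real pedestal (s(0)/2) that
  # the one-sided DFT of a causal signal otherwise adds to every bin
  s[1] <- s[1] / 2
  s <- c(s, complex(real = rep(0, zerofill_to - n0)))
  sp <- stats::fft(s)
  ord <- fft_desc_order(zerofill_to)
  ppm <- hz_to_ppm(ord$k * acq$sw_hz / zerofill_to, acq)
  new_spectrum(sp[ord$order], ppm, acq,
               proc = list(zerofill_to = zerofill_to, lb_hz = lb_hz,
                           n_points = n0))
}

#' Inverse transform of a spectrum back to an FID (no apodization removal)
#'
#' Mainly for testing round-trip identities; truncates back to the original
#' FID length recorded in `proc` when available.
#' @param spec A `spectrum` produced by [to_spectrum].
#' @export
from_spectrum <- function(spec) {
  n <- length(spec$intensities)
  ord <- fft_desc_order(n)
  raw <- complex(real = rep(0, n))
  raw[ord$order] <- spec$intensities
  s <- stats::fft(raw, inverse = TRUE) / n
  s[1] <- s[1] * 2                     # undo first-point halving
  n0 <- spec$proc$n_points %||% n
  fid(s[seq_len(n0)], replace_npoints(spec$acq, n0), label = "IFFT")
}

replace_npoints <- function(acq, n) {
  acq$n_points <- as.integer(n)
  acq
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Truncate an FID to its first `n` points
#'
#' Late FID samples of a decayed signal carry noise only; truncating before
#' transformation trades a coarser (but still line-width-resolving) spectral
#' grid for faster model evaluation.
#' @param fid_obj An [fid].
#' @param n Number of leading samples to keep.
#' @export
truncate_fid <- function(fid_obj, n) {
  stopifnot(n >= 2, n <= length(fid_obj$samples))
  fid(fid_obj$samples[seq_len(n)], replace_npoints(fid_obj$acq, n),
      fid_obj$label)
}

#' Restrict a spectrum to a ppm interval
#' @param spec A `spectrum`.
#' @param range_ppm Length-2 numeric interval (any order).
#' @export
crop_spectrum <- function(spec, range_ppm) {
  lo <- min(range_ppm); hi <- max(range_ppm)
  keep <- spec$ppm >= lo & spec$ppm <= hi
  if (!any(keep)) stop("spectrum does not cover the requested ppm range")
  new_spectrum(spec$intensities[keep], spec$ppm[keep], spec$acq, spec$proc)
}
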