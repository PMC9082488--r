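# Recombination arithmetic for edited experiments. Both operations accept
# either `fid` or `spectrum` objects (the combination is linear, so it commutes
# with the Fourier transform) and normalize by the number of summed
# sub-spectra so difference amplitudes are per-average comparable.

combine_payload <- function(x) if (inherits(x, "fid")) x$samples else x$intensities

combine_rebuild <- function(template, values, label) {
  if (inherits(template, "fid")) {
    out <- template
    out$samples <- values
    out$label <- label
    out
  } else {
    out <- template
    out$intensities <- values
    out
  }
}

check_matching <- function(xs) {
  n <- vapply(xs, function(x) length(combine_payload(x)), integer(1))
  if (length(unique(n)) != 1) stop("inputs have mismatched lengths")
  sw <- vapply(xs, function(x) x$acq$sw_hz, numeric(1))
  f0 <- vapply(xs, function(x) x$acq$transmitter_mhz, numeric(1))
  if (length(unique(sw)) != 1 || length(unique(f0)) != 1) {
    stop("inputs have mismatched acquisition parameters")
  }
}

#' Hadamard combination of the four HERMES sub-experiments
#'
#' With sub-experiments A = (GABA-ON, GSH-ON), B = (GABA-ON, GSH-OFF),
#' C = (GABA-OFF, GSH-ON), D = (GABA-OFF, GSH-OFF):
#' the GSH difference is `(A - B + C - D) / 4` and the GABA difference is
#' `(A + B - C - D) / 4`.
#'
#' @param quartet Named list with elements A, B, C, D, all [fid] or all
#'   `spectrum` with matching acquisitions.
#' @param target `"GSH"` or `"GABA"`.
#' @return Same kind of object as the inputs.
#' @export
hadamard_combine <- function(quartet, target = c("GSH", "GABA")) {
  target <- match.arg(target)
  if (!all(c("A", "B", "C", "D") %in% names(quartet))) {
    stop("quartet must have entries A, B, C, D")
  }
  quartet <- quartet[c("A", "B", "C", "D")]
  check_matching(quartet)
  sgn <- if (target == "GSH") c(1, -1, 1, -1) else c(1, 1, -1, -1)
  vals <- Reduce(`+`, Map(function(x, s) s * combine_payload(x), quartet, sgn)) / 4
  combine_rebuild(quartet$A, vals, paste0("DIFF_", target))
}

#' MEGA-PRESS difference: (ON - OFF) / 2
#'
#' @param on,off [fid] or `spectrum` objects with matching acquisitions.
#' @export
mega_difference <- function(on, off) {
  check_matching(list(on, off))
  vals <- (combine_payload(on) - combine_payload(off)) / 2
  combine_rebuild(on, vals, "DIFF_GSH")
}
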