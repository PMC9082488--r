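#' Basis set for linear-combination modeling
#'
#' A basis set holds noiseless unit-concentration difference-spectrum FIDs for
#' a set of names, all sharing one acquisition. Columns of `fids` are complex
#' time-domain responses.
#'
#' @param names Character vector of basis names (unique).
#' @param fids Complex matrix, `n_points x length(names)`.
#' @param acq An [acq_params].
#' @param target Difference target the basis models: `"GSH"` or `"GABA"`.
#' @param mm_names Subset of `names` flagged as parametrized macromolecule
#'   functions.
#' @export
basis_set <- function(names, fids, acq, target, mm_names = character()) {
  stopifnot(!anyDuplicated(names), ncol(fids) == length(names),
            nrow(fids) == acq$n_points, all(mm_names %in% names))
  colnames(fids) <- names
  structure(list(names = names, fids = fids, acq = acq, target = target,
                 mm_names = mm_names), class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> target %s: %s\n", x$target,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Build a matched basis set from a catalog
#'
#' For every catalog entry with a non-vanishing response in the targeted
#' difference spectrum, synthesizes the noiseless unit-concentration
#' difference FID via the same combination arithmetic used on the data. With
#' `mismatch = NULL` the basis is exact, enabling exact-recovery tests;
#' `mismatch` perturbs decay constants and line positions to emulate
#' basis/in-vivo discrepancy.
#'
#' @param catalog A `metabolite_catalog`.
#' @param acq An [acq_params] (same sequence as the catalog).
#' @param target `"GSH"` or `"GABA"`.
#' @param exclude Entry names never included (default: water entries, which
#'   the HSVD filter removes from the data, and -- when
#'   `parametrized_mm = TRUE` is intended downstream -- the catalog MM
#'   entries can be excluded here by the caller).
#' @param mismatch Optional list with elements `t2_scale` (multiplies every
#'   T2), `shift_ppm_sd` (SD of random line-position shifts) and `seed`.
#' @export
make_basis <- function(catalog, acq, target = c("GSH", "GABA"),
                       exclude = c("H2O", "H2Oresid"), mismatch = NULL) {
  target <- match.arg(target)
  stopifnot(catalog$te_preset == acq$sequence_tag)
  cand <- setdiff(names(catalog$entries), exclude)
  mults <- lapply(cand, function(nm) difference_multiplet(catalog, nm, target))
  keep <- vapply(mults, function(m) nrow(m$lines) > 0, logical(1))
  mults <- mults[keep]
  nms <- cand[keep]
  if (!is.null(mismatch)) {
    t2s <- mismatch$t2_scale %||% 1
    ssd <- mismatch$shift_ppm_sd %||% 0
    mults <- with_seed(mismatch$seed %||% 1, lapply(mults, function(m) {
      m$t2_ms <- m$t2_ms * t2s
      m$lines$offset_ppm <- m$lines$offset_ppm +
        stats::rnorm(nrow(m$lines), 0, ssd)
      m
    }))
  }
  fids <- vapply(seq_along(mults), function(i) {
    synth_fid(mults[i], stats::setNames(1, nms[i]), acq)$samples
  }, complex(acq$n_points))
  basis_set(nms, fids, acq, target)
}

#' Add parametrized macromolecule basis functions
#'
#' Adds Gaussian MM basis functions as time-domain entries: MM12 and MM14
#' (1.2 / 1.4 ppm) for the GSH-targeted difference, MM093 and MM30
#' (0.93 / 3.0 ppm) for the GABA-targeted difference. Each is a 14-Hz-FWHM
#' Gaussian scaled to unit integrated area (in ppm x intensity units) over
#' the fit window.
#'
#' @param basis A [basis_set].
#' @param target `"GSH"` or `"GABA"` (defaults to the basis target).
#' @param fwhm_hz Spectral FWHM of the MM Gaussians (default 14 Hz).
#' @export
add_mm_basis <- function(basis, target = basis$target, fwhm_hz = 14) {
  mm <- if (target == "GSH") {
    c(MM12 = 1.2, MM14 = 1.4)
  } else {
    c(MM093 = 0.93, MM30 = 3.0)
  }
  if (any(names(mm) %in% basis$names)) {
    stop("duplicate MM names: ",
         paste(intersect(names(mm), basis$names), collapse = ", "))
  }
  acq <- basis$acq
  t <- time_axis(acq)
  g <- fwhm_hz * pi / (2 * sqrt(log(2)))  # time-domain Gaussian rate
  # unit area on the ppm scale: with first-point halving in the transform the
  # spectral area is s(0)/2 * sw / f0, so s(0) = 2 f0 / sw
  amp0 <- 2 * acq$transmitter_mhz / acq$sw_hz
  cols <- vapply(mm, function(pos) {
    amp0 * exp(-(g * t)^2) * exp(2i * pi * ppm_to_hz(pos, acq) * t)
  }, complex(acq$n_points))
  basis_set(c(basis$names, names(mm)), cbind(basis$fids, cols), acq,
            basis$target, mm_names = c(basis$mm_names, names(mm)))
}
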