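#' Water-scaled quantification in institutional units
#'
#' Scales a fitted metabolite amplitude by the unsuppressed-water amplitude:
#' `estimate = kappa * met_amplitude / water_amplitude`. No relaxation or
#' tissue-segmentation corrections are applied anywhere in the pipeline; the
#' scale constant `kappa` is an arbitrary institutional-unit factor.
#'
#' @param met_amplitude Fitted metabolite amplitude (area or basis amplitude).
#' @param water_amplitude Fitted water amplitude (> 0).
#' @param kappa Scale constant (default 1000).
#' @export
water_scaled <- function(met_amplitude, water_amplitude, kappa = 1000) {
  if (any(!is.finite(water_amplitude)) || any(water_amplitude <= 0)) {
    stop("water amplitude must be positive")
  }
  kappa * met_amplitude / water_amplitude
}

#' Quantify a processed scan with one or both modeling engines
#'
#' Runs simple peak fitting and/or linear-combination modeling on the
#' difference spectra of a [preprocess_scan] output, fits the water reference
#' with the engine-matched water model, and returns water-scaled estimates.
#'
#' For peak fitting, the difference spectra are re-transformed at
#' `peak_zerofill` points; the GSH model is `GSH80` for HERMES and `GSH120`
#' for MEGA-PRESS. For LCM, spectra are re-transformed at `lcm_zerofill`
#' points and fitted with a catalog-matched basis plus parametrized MM
#' functions.
#'
#' @param ps A `processed_scan`.
#' @param methods Subset of `c("PEAK", "LCM")`.
#' @param bases Named list of [basis_set] per target (`GSH`, `GABA`) for the
#'   LCM engine; built from `catalog` when NULL.
#' @param catalog Catalog used to build default bases and the water basis.
#' @param peak_zerofill,lcm_zerofill,lb_hz Spectrum processing per engine.
#' @param kappa Institutional-unit scale.
#' @param lcm_cfgs Optional named list of [lcm_config] per target.
#' @return Data frame with columns subject, scan, sequence, method,
#'   metabolite, estimate_iu, flagged.
#' @export
quantify_scan <- function(ps, methods = c("PEAK", "LCM"), bases = NULL,
                          catalog = NULL, peak_zerofill = 32768,
                          lcm_zerofill = NULL, lb_hz = 3, kappa = 1000,
                          lcm_cfgs = NULL, lcm_truncate = NULL,
                          peak_cfgs = NULL, include_gaba = TRUE) {
  stopifnot(inherits(ps, "processed_scan"))
  if (is.null(catalog)) catalog <- default_catalog(ps$sequence_tag)
  is_hermes <- ps$sequence_tag == "HERMES80"
  rows <- list()
  add_row <- function(method, metabolite, est, flagged) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = ps$subject_id, scan = ps$scan_id, sequence = ps$sequence_tag,
      method = method, metabolite = metabolite, estimate_iu = est,
      flagged = flagged)
  }

  if ("PEAK" %in% methods) {
    wsp <- to_spectrum(ps$water_fid, peak_zerofill, lb_hz)
    wat <- fit_water_gl(wsp)
    gsh_spec <- to_spectrum(ps$diff_fids$GSH, peak_zerofill, lb_hz)
    gsh_tag <- if (is_hermes) "GSH80" else "GSH120"
    gcfg <- if (!is.null(peak_cfgs) && gsh_tag %in% names(peak_cfgs)) {
      peak_cfgs[[gsh_tag]]
    } else peak_fit_config(gsh_tag)
    gf <- fit_gsh_peaks(gsh_spec, gcfg)
    add_row("PEAK", "GSH",
            water_scaled(gf$target_area, wat$area, kappa),
            isTRUE(gf$flagged) || isTRUE(wat$flagged))
    if (is_hermes && include_gaba) {
      gaba_spec <- to_spectrum(ps$diff_fids$GABA, peak_zerofill, lb_hz)
      bf <- fit_gaba_glx(gaba_spec)
      add_row("PEAK", "GABA+",
              water_scaled(bf$target_area, wat$area, kappa),
              isTRUE(bf$flagged) || isTRUE(wat$flagged))
    }
  }

  if ("LCM" %in% methods) {
    acq_l <- ps$acq
    dfids <- ps$diff_fids
    wfid <- ps$water_fid
    if (!is.null(lcm_truncate) && lcm_truncate < acq_l$n_points) {
      dfids <- lapply(dfids, truncate_fid, n = lcm_truncate)
      wfid <- truncate_fid(wfid, lcm_truncate)
      acq_l <- replace_npoints(acq_l, lcm_truncate)
    }
    zf <- lcm_zerofill %||% acq_l$n_points
    wsp <- to_spectrum(wfid, zf, lb_hz)
    wat <- fit_water_lcm(wsp, water_basis_fid(catalog, acq_l))
    targets <- if (is_hermes && include_gaba) c("GSH", "GABA") else "GSH"
    for (tg in targets) {
      bs <- if (!is.null(bases) && tg %in% names(bases)) bases[[tg]] else {
        add_mm_basis(make_basis(catalog, acq_l, tg,
                                exclude = c("H2O", "H2Oresid", "MM09",
                                            "MM30", "MM12", "MM14")))
      }
      cfg <- if (!is.null(lcm_cfgs) && tg %in% names(lcm_cfgs)) {
        lcm_cfgs[[tg]]
      } else lcm_config(target = tg)
      sp <- to_spectrum(dfids[[tg]], zf, lb_hz)
      lf <- lcm_fit(sp, bs, cfg)
      est <- if (tg == "GABA") lf$gaba_plus else unname(lf$amplitudes["GSH"])
      add_row("LCM", if (tg == "GABA") "GABA+" else "GSH",
              water_scaled(est, wat$amplitude, kappa),
              isTRUE(lf$flagged) || isTRUE(wat$flagged))
    }
  }
  do.call(rbind, rows)
}
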