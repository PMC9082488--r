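#' Pipeline configuration
#'
#' Bundles every stage's options; a configuration plus its seed reproduces
#' all outputs bit-for-bit through the deterministic stages.
#'
#' @param cohort A [cohort_config].
#' @param transients_per_subexp Transients acquired per sub-experiment
#'   (HERMES uses 4 sub-experiments, MEGA 2).
#' @param noise A [noise_config].
#' @param preprocess A [preprocess_config].
#' @param methods Quantification engines to run.
#' @param peak_zerofill,lcm_truncate,lb_hz,kappa Engine options passed to
#'   [quantify_scan].
#' @param lcm_max_iter,lcm_ftol Outer-loop budget of the LCM engine.
#' @param peak_max_iter Iteration budget per peak-fit start.
#' @param include_gaba Quantify the GABA+ target as well as GSH.
#' @param max_flagged_fraction Abort threshold for the fraction of flagged
#'   fits in [run_all].
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            transients_per_subexp = 32,
                            noise = noise_config(),
                            preprocess = preprocess_config(
                              hsvd_model_points = 256, hsvd_rank = 15,
                              zerofill_to = 2048),
                            methods = c("PEAK", "LCM"),
                            peak_zerofill = 4096, lcm_truncate = 1024,
                            lb_hz = 3, kappa = 1000,
                            lcm_max_iter = 30, lcm_ftol = 1e-6,
                            peak_max_iter = 80, include_gaba = TRUE,
                            max_flagged_fraction = 0.2) {
  list(cohort = cohort, transients_per_subexp = transients_per_subexp,
       noise = noise, preprocess = preprocess, methods = methods,
       peak_zerofill = peak_zerofill, lcm_truncate = lcm_truncate,
       lb_hz = lb_hz, kappa = kappa, lcm_max_iter = lcm_max_iter,
       lcm_ftol = lcm_ftol, peak_max_iter = peak_max_iter,
       include_gaba = include_gaba,
       max_flagged_fraction = max_flagged_fraction)
}

#' Acquisition parameters for both sequences of the study design
#'
#' @param transients_per_subexp Transients per sub-experiment (HERMES
#'   acquires 4 sub-experiments, MEGA 2).
#' @return Named list of [acq_params] for HERMES80 and MEGA120.
#' @export
study_acq_map <- function(transients_per_subexp = 32) {
  list(HERMES80 = acq_hermes80(4 * transients_per_subexp),
       MEGA120 = acq_mega120(2 * transients_per_subexp))
}

# Precompute per-sequence engine inputs (bases, configs) once per run.
engine_setup <- function(config) {
  n_lcm <- config$lcm_truncate %||% 2048
  setup <- list()
  for (seqtag in c("HERMES80", "MEGA120")) {
    catal <- default_catalog(seqtag)
    acq_l <- replace_npoints(study_acq_map(config$transients_per_subexp)[[
      seqtag]], n_lcm)
    targets <- if (seqtag == "HERMES80" && config$include_gaba) {
      c("GSH", "GABA")
    } else "GSH"
    bases <- lapply(setNames(targets, targets), function(tg) {
      add_mm_basis(make_basis(catal, acq_l, tg,
                              exclude = c("H2O", "H2Oresid", "MM09", "MM30",
                                          "MM12", "MM14")))
    })
    lcm_cfgs <- lapply(setNames(targets, targets), function(tg) {
      lcm_config(target = tg, max_iter = config$lcm_max_iter,
                 ftol = config$lcm_ftol)
    })
    gsh_tag <- if (seqtag == "HERMES80") "GSH80" else "GSH120"
    peak_cfgs <- setNames(list(peak_fit_config(
      gsh_tag, max_iter = config$peak_max_iter)), gsh_tag)
    setup[[seqtag]] <- list(catalog = catal, bases = bases,
                            lcm_cfgs = lcm_cfgs, peak_cfgs = peak_cfgs)
  }
  setup
}

#' Quantify every scan of a simulated cohort
#'
#' Preprocesses each raw scan and runs the configured engines, returning the
#' tidy cohort table (one row per subject, scan, sequence, method,
#' metabolite).
#'
#' @param scans List of `raw_scan` objects from [simulate_cohort].
#' @param config A [pipeline_config].
#' @param setup Optional precomputed [engine_setup] output.
#' @export
quantify_cohort <- function(scans, config = pipeline_config(), setup = NULL) {
  if (is.null(setup)) setup <- engine_setup(config)
  rows <- lapply(scans, function(raw) {
    pp <- config$preprocess
    if (is.null(pp$targets) && !config$include_gaba) pp$targets <- "GSH"
    ps <- preprocess_scan(raw, pp)
    su <- setup[[raw$sequence_tag]]
    methods <- config$methods
    if (raw$sequence_tag == "MEGA120" && !is.null(config$mega_methods)) {
      methods <- config$mega_methods
    }
    quantify_scan(ps, methods = methods, bases = su$bases,
                  catalog = su$catalog, peak_zerofill = config$peak_zerofill,
                  lb_hz = config$lb_hz, kappa = config$kappa,
                  lcm_cfgs = su$lcm_cfgs, lcm_truncate = config$lcm_truncate,
                  peak_cfgs = su$peak_cfgs,
                  include_gaba = config$include_gaba)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline: simulate, preprocess, fit, quantify, report
#'
#' Simulates a test-retest cohort, quantifies every scan with both engines,
#' and writes `quant.csv`, `table1.csv`, `table2.csv`, `ftests.json` and
#' `bland_altman.csv` to `out_dir`. Errors if the fraction of flagged fits
#' exceeds `config$max_flagged_fraction`. Per-stage timings are logged via
#' `message()`.
#'
#' @param config A [pipeline_config].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the cohort table and the [cohort_stats]
#'   report.
#' @export
run_all <- function(config = pipeline_config(), out_dir = tempfile("editmrs"),
                    quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]
  scans <- simulate_cohort(config$cohort,
                           study_acq_map(config$transients_per_subexp),
                           config$noise)
  say("simulate: %d scans [%.1f s]", length(scans), proc.time()[3] - t0)
  t1 <- proc.time()[3]
  tab <- quantify_cohort(scans, config)
  say("preprocess + fit + quantify: %d estimates [%.1f s]", nrow(tab),
      proc.time()[3] - t1)
  fl <- mean(tab$flagged)
  if (fl > config$max_flagged_fraction) {
    stop(sprintf("flagged-fit fraction %.2f exceeds threshold %.2f", fl,
                 config$max_flagged_fraction))
  }
  rep <- cohort_stats(tab)
  num <- function(d) {
    d[] <- lapply(d, function(x) if (is.numeric(x)) round(x, 6) else x)
    d
  }
  utils::write.csv(num(tab), file.path(out_dir, "quant.csv"),
                   row.names = FALSE)
  utils::write.csv(num(rep$table1), file.path(out_dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(num(rep$table2), file.path(out_dir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(num(rep$bland_altman),
                   file.path(out_dir, "bland_altman.csv"), row.names = FALSE)
  jsonlite::write_json(rep$ftests, file.path(out_dir, "ftests.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  say("report written to %s", out_dir)
  invisible(list(table = tab, report = rep, out_dir = out_dir))
}

#' Multi-seed test-retest reproducibility study
#'
#' Repeats the whole pipeline over `n_seeds` independently seeded cohorts and
#' collects, per seed, the within-subject CVs of the GSH estimates:
#' simple peak fitting on the HERMES (TE 80 ms) spectra, LCM on the same
#' spectra, and LCM on the MEGA-PRESS (TE 120 ms) spectra (plus the GABA+
#' and MEGA peak-fit CVs when `config$include_gaba` is TRUE).
#'
#' @param n_seeds Number of cohort replicates (default 50).
#' @param seed Master seed from which per-cohort seeds derive.
#' @param config A [pipeline_config].
#' @param quiet Suppress per-seed progress messages.
#' @param mega_lcm_only Quantify the MEGA-PRESS scans with the LCM engine
#'   only (the peak engine on MEGA is not part of the study's primary
#'   comparison; [run_all] still runs both engines everywhere).
#' @return Data frame with one row per seed.
#' @export
run_retest_study <- function(n_seeds = 50, seed = 1,
                             config = pipeline_config(include_gaba = FALSE),
                             quiet = FALSE, mega_lcm_only = TRUE) {
  if (mega_lcm_only && is.null(config$mega_methods)) {
    config$mega_methods <- "LCM"
  }
  seeds <- derive_seeds(seed, n_seeds)
  setup <- engine_setup(config)
  acq_map <- study_acq_map(config$transients_per_subexp)
  out <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    t0 <- proc.time()[3]
    cfg_i <- config
    cfg_i$cohort$seed <- seeds[i]
    scans <- simulate_cohort(cfg_i$cohort, acq_map, cfg_i$noise)
    tab <- quantify_cohort(scans, cfg_i, setup)
    rep <- cohort_stats(tab)
    t2 <- rep$table2
    cvof <- function(seqtag, method, metab) {
      v <- t2$cv_percent[t2$sequence == seqtag & t2$method == method &
                           t2$metabolite == metab]
      if (length(v) == 1) v else NA_real_
    }
    out[[i]] <- data.frame(
      seed = seeds[i],
      cv_peak_hermes_gsh = cvof("HERMES80", "PEAK", "GSH"),
      cv_lcm_hermes_gsh = cvof("HERMES80", "LCM", "GSH"),
      cv_peak_mega_gsh = cvof("MEGA120", "PEAK", "GSH"),
      cv_lcm_mega_gsh = cvof("MEGA120", "LCM", "GSH"),
      cv_peak_hermes_gaba = cvof("HERMES80", "PEAK", "GABA+"),
      cv_lcm_hermes_gaba = cvof("HERMES80", "LCM", "GABA+"),
      flagged_fraction = mean(tab$flagged))
    if (!quiet) {
      message(sprintf(
        "seed %d/%d: CV peak/LCM HERMES GSH %.1f%% / %.1f%% [%.1f s]",
        i, n_seeds, out[[i]]$cv_peak_hermes_gsh,
        out[[i]]$cv_lcm_hermes_gsh, proc.time()[3] - t0))
    }
  }
  do.call(rbind, out)
}
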