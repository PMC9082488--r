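#' Instrumental-instability configuration for the synthetic scanner
#'
#' Emulates the instabilities that motivate frequency-and-phase correction and
#' water filtering: per-transient complex white noise, a slow linear frequency
#' drift, random frequency/phase jitter, a smooth random additive baseline
#' distortion per sub-experiment, and an exponential eddy-current phase shared
#' by all FIDs of a scan.
#'
#' @param noise_sd SD of the real and imaginary parts of the per-transient
#'   complex noise (intensity units).
#' @param drift_hz_per_transient Linear frequency drift per transient, Hz.
#' @param jitter_hz_sd SD of the random per-transient frequency offset, Hz.
#' @param phase_jitter_deg_sd SD of the random per-transient phase, degrees.
#' @param baseline_wobble SD (intensity units) of the slow spline-shaped
#'   spectral distortion added independently to each sub-experiment.
#' @param eddy_phase_amp_rad,eddy_tau_ms Amplitude (rad) and decay constant
#'   (ms) of the eddy-current phase `phi(t) = amp * exp(-t / tau)` applied to
#'   all FIDs including the water reference.
#' @param shim_hz,shim_hz_sd Session linewidth: every scan draws one extra
#'   Gaussian broadening (Hz) log-normally with this mean and SD, applied to
#'   all FIDs of the scan. Emulates shim differences between sessions after
#'   subject repositioning -- the dominant scan-to-scan lineshape change in
#'   a test-retest design.
#' @export
noise_config <- function(noise_sd = 4, drift_hz_per_transient = 0.015,
                         jitter_hz_sd = 0.3, phase_jitter_deg_sd = 2,
                         baseline_wobble = 50, eddy_phase_amp_rad = 0.3,
                         eddy_tau_ms = 50, shim_hz = 3, shim_hz_sd = 1.5) {
  vals <- c(noise_sd, drift_hz_per_transient, jitter_hz_sd,
            phase_jitter_deg_sd, baseline_wobble, eddy_phase_amp_rad,
            eddy_tau_ms, shim_hz, shim_hz_sd)
  stopifnot(all(vals >= 0))
  structure(list(noise_sd = noise_sd,
                 drift_hz_per_transient = drift_hz_per_transient,
                 jitter_hz_sd = jitter_hz_sd,
                 phase_jitter_deg_sd = phase_jitter_deg_sd,
                 baseline_wobble = baseline_wobble,
                 eddy_phase_amp_rad = eddy_phase_amp_rad,
                 eddy_tau_ms = eddy_tau_ms,
                 shim_hz = shim_hz, shim_hz_sd = shim_hz_sd),
            class = "noise_config")
}

#' Test-retest cohort configuration
#'
#' Defaults follow the study design the generator emulates: twelve subjects,
#' two consecutive scans each. Subject-level true concentrations are drawn
#' log-normally around `truth_means` with coefficient of variation
#' `between_subject_cv`; scan-level values are jittered log-normally with
#' `within_subject_cv` (CVs are SD/mean of the log-normal).
#'
#' @param n_subjects Number of subjects (default 12).
#' @param n_scans Scans per subject (default 2; >= 2 for test-retest).
#' @param truth_means Named concentration means, see [default_truth_means].
#' @param between_subject_cv,within_subject_cv CVs as fractions (default 0.10
#'   and 0.05).
#' @param seed Master seed for the cohort.
#' @export
cohort_config <- function(n_subjects = 12, n_scans = 2,
                          truth_means = default_truth_means(),
                          between_subject_cv = 0.10, within_subject_cv = 0.05,
                          seed = 1) {
  stopifnot(n_subjects >= 2, n_scans >= 2,
            between_subject_cv >= 0, within_subject_cv >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_scans = as.integer(n_scans), truth_means = truth_means,
                 between_subject_cv = between_subject_cv,
                 within_subject_cv = within_subject_cv, seed = seed),
            class = "cohort_config")
}

# Smooth random complex spectral distortion returned as a time-domain signal.
# The default coefficient count gives baseline features of roughly 0.5 ppm --
# broad enough to be "baseline", too structured for a quadratic to follow.
wobble_signal <- function(acq, amp, n_coef = 40) {
  if (amp == 0) return(complex(real = rep(0, acq$n_points)))
  n <- acq$n_points
  grid <- seq(0, 1, length.out = n)
  knots <- seq(-3, n_coef + 2) / (n_coef - 1)
  B <- splines::splineDesign(knots, grid, ord = 4, outer.ok = TRUE)
  curve <- as.vector(B %*% stats::rnorm(ncol(B), 0, amp)) +
    1i * as.vector(B %*% stats::rnorm(ncol(B), 0, amp))
  # curve lives on the descending-ppm grid; map back to raw FFT order, then to
  # the time domain
  ord <- fft_desc_order(n)
  raw <- complex(real = rep(0, n))
  raw[ord$order] <- curve
  stats::fft(raw, inverse = TRUE) / n
}

#' Simulate one raw scan (all sub-experiment transients plus water reference)
#'
#' Per-transient FIDs are the noiseless sub-experiment signal, frequency
#' shifted by drift + jitter, phase jittered, with added complex white noise.
#' Sub-experiments are interleaved in acquisition order, so drift is shared
#' across them. All FIDs (including water) carry the eddy-current phase.
#' Deterministic for a fixed seed.
#'
#' @param truth Named concentrations covering the catalog entries.
#' @param acq An [acq_params].
#' @param catalog A `metabolite_catalog` matching `acq$sequence_tag`.
#' @param noise A [noise_config].
#' @param seed Integer seed.
#' @param subject_id,scan_id Identifiers recorded in the scan.
#' @return An object of class `raw_scan`.
#' @export
simulate_scan <- function(truth, acq, catalog, noise = noise_config(),
                          seed = 1, subject_id = 1L, scan_id = 1L) {
  stopifnot(inherits(catalog, "metabolite_catalog"),
            catalog$te_preset == acq$sequence_tag)
  missing_names <- setdiff(names(catalog$entries), names(truth))
  if (length(missing_names) > 0) {
    stop("missing truth entries: ", paste(missing_names, collapse = ", "))
  }
  labels <- subexp_labels(acq$sequence_tag)
  n_per <- acq$n_transients / length(labels)
  if (n_per != round(n_per)) {
    stop("n_transients must be divisible by the number of sub-experiments")
  }
  n_per <- as.integer(n_per)
  t <- time_axis(acq)
  eddy <- exp(1i * noise$eddy_phase_amp_rad * exp(-t / (noise$eddy_tau_ms / 1000)))

  with_seed(seed, {
    shim <- if (noise$shim_hz > 0 && noise$shim_hz_sd > 0) {
      sl <- sqrt(log(1 + (noise$shim_hz_sd / noise$shim_hz)^2))
      stats::rlnorm(1, log(noise$shim_hz) - sl^2 / 2, sl)
    } else noise$shim_hz
    shim_decay <- exp(-(shim * t)^2)
    base <- lapply(labels, function(lab) {
      f <- synth_fid(catalog_multiplets(catalog, lab), truth, acq, label = lab)
      f$samples <- f$samples * shim_decay +
        wobble_signal(acq, noise$baseline_wobble)
      f$samples <- f$samples * eddy
      f
    })
    names(base) <- labels

    n_tot <- n_per * length(labels)
    sched <- rep(labels, times = n_per)            # interleaved A B C D A B ...
    df_all <- noise$drift_hz_per_transient * (seq_len(n_tot) - 1) +
      stats::rnorm(n_tot, 0, noise$jitter_hz_sd)
    ph_all <- stats::rnorm(n_tot, 0, noise$phase_jitter_deg_sd) * pi / 180

    transients <- stats::setNames(vector("list", length(labels)), labels)
    for (lab in labels) {
      sel <- which(sched == lab)
      # all transients of one sub-experiment in a single matrix operation
      ph_mat <- exp(1i * (outer(2 * pi * t, df_all[sel]) +
                            rep(ph_all[sel], each = acq$n_points)))
      S <- base[[lab]]$samples * ph_mat +
        matrix(complex_noise(acq$n_points * length(sel), noise$noise_sd),
               acq$n_points)
      transients[[lab]] <- lapply(seq_along(sel), function(j) {
        fid(S[, j], acq, lab)
      })
    }

    water_acq <- acq
    w <- synth_fid(list(resolve_entry(catalog$entries$H2O,
                                      subexp_state(acq$sequence_tag, labels[1]))),
                   truth["H2O"], water_acq, label = "WATER")
    w$samples <- w$samples * shim_decay * eddy +
      complex_noise(acq$n_points, noise$noise_sd / sqrt(acq$n_transients))

    structure(list(transients = transients, water = w, truth = truth,
                   subject_id = subject_id, scan_id = scan_id,
                   sequence_tag = acq$sequence_tag, acq = acq, seed = seed),
              class = "raw_scan")
  })
}

#' @export
print.raw_scan <- function(x, ...) {
  cat(sprintf("<raw_scan> subject %s scan %s %s: %s x %d transients + water\n",
              x$subject_id, x$scan_id, x$sequence_tag,
              paste(names(x$transients), collapse = "/"),
              length(x$transients[[1]])))
  invisible(x)
}

#' Simulate a full test-retest cohort
#'
#' Draws subject- and scan-level true concentrations (log-normal), then
#' simulates, for every subject and scan, one scan per sequence in `acq_map`.
#'
#' @param cfg A [cohort_config].
#' @param acq_map Named list of [acq_params], e.g.
#'   `list(HERMES80 = acq_hermes80(), MEGA120 = acq_mega120())`.
#' @param noise A [noise_config].
#' @param catalogs Optional named list of catalogs per sequence tag; defaults
#'   to [default_catalog] of each.
#' @return List of `raw_scan` objects (subjects x scans x sequences).
#' @export
simulate_cohort <- function(cfg, acq_map = list(HERMES80 = acq_hermes80(),
                                                MEGA120 = acq_mega120()),
                            noise = noise_config(), catalogs = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.null(catalogs)) {
    catalogs <- lapply(stats::setNames(names(acq_map), names(acq_map)),
                       default_catalog)
  }
  sdlog_b <- sqrt(log(1 + cfg$between_subject_cv^2))
  sdlog_w <- sqrt(log(1 + cfg$within_subject_cv^2))
  n_names <- length(cfg$truth_means)

  seeds <- derive_seeds(cfg$seed, cfg$n_subjects * cfg$n_scans *
                          length(acq_map) + 1)
  truths <- with_seed(seeds[1], {
    lapply(seq_len(cfg$n_subjects), function(s) {
      subj <- cfg$truth_means *
        stats::rlnorm(n_names, -sdlog_b^2 / 2, sdlog_b)
      lapply(seq_len(cfg$n_scans), function(k) {
        subj * stats::rlnorm(n_names, -sdlog_w^2 / 2, sdlog_w)
      })
    })
  })

  scans <- list()
  idx <- 1L
  for (s in seq_len(cfg$n_subjects)) {
    for (k in seq_len(cfg$n_scans)) {
      for (seqtag in names(acq_map)) {
        scans[[length(scans) + 1L]] <- simulate_scan(
          truths[[s]][[k]], acq_map[[seqtag]], catalogs[[seqtag]],
          noise = noise, seed = seeds[idx + 1L],
          subject_id = s, scan_id = k)
        idx <- idx + 1L
      }
    }
  }
  scans
}
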