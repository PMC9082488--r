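# Shared fixtures: everything is generated in code at test time.

acq_h <- acq_hermes80(128)    # 32 transients per sub-experiment
acq_m <- acq_mega120(64)

truth_default <- default_truth_means()

# Noiseless difference-spectrum FID of selected catalog entries.
diff_fid_of <- function(catalog, names, truth, acq, target = "GSH") {
  synth_fid(lapply(names, function(n) difference_multiplet(catalog, n, target)),
            truth, acq, label = paste0("DIFF_", target))
}

# A fully quiet instability configuration.
noise_off <- noise_config(noise_sd = 0, drift_hz_per_transient = 0,
                          jitter_hz_sd = 0, phase_jitter_deg_sd = 0,
                          baseline_wobble = 0, eddy_phase_amp_rad = 0,
                          shim_hz = 0, shim_hz_sd = 0)

# Study-grade preprocessing configuration (reduced HSVD model size).
pp_study <- preprocess_config(hsvd_model_points = 256, hsvd_rank = 15,
                              zerofill_to = 2048)

# Spectrum-level test-retest fixture: one difference spectrum with wobble,
# session-linewidth and complex noise applied directly at the difference
# level (no transient chain), for fast paired-engine comparisons.
fixture_diff_spectrum <- function(seqtag, truth, seed, zerofill = 4096,
                                  lb = 3, noise_sd = 0.4, wobble = 25,
                                  target = "GSH", truncate = NULL) {
  catal <- default_catalog(seqtag)
  acq <- if (seqtag == "HERMES80") acq_h else acq_m
  nms <- if (target == "GSH") c("GSH", "Asp", "MM12", "MM14") else
    c("GABA", "MM30", "Glx", "MM09")
  f <- diff_fid_of(catal, nms, truth, acq, target)
  with_seed(seed, {
    t <- time_axis(acq)
    shim <- stats::rlnorm(1, log(3) - 0.111, 0.472)   # ~3 +/- 1.5 Hz
    f$samples <- f$samples * exp(-(shim * t)^2) +
      editmrs:::wobble_signal(acq, wobble) +
      complex(real = stats::rnorm(acq$n_points, 0, noise_sd),
              imaginary = stats::rnorm(acq$n_points, 0, noise_sd))
  })
  if (!is.null(truncate)) {
    f <- truncate_fid(f, truncate)
    zerofill <- max(truncate, min(zerofill, truncate))
  }
  to_spectrum(f, zerofill, lb)
}

# Exact catalog basis (truncated acquisition) for LCM recovery tests.
exact_basis <- function(seqtag, n_points = 1024, target = "GSH",
                        exclude = c("H2O", "H2Oresid")) {
  acq <- if (seqtag == "HERMES80") acq_h else acq_m
  make_basis(default_catalog(seqtag),
             editmrs:::replace_npoints(acq, n_points), target,
             exclude = exclude)
}
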