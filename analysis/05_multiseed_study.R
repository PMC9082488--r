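#!/usr/bin/env Rscript
# The headline experiment: repeat the whole pipeline over 50 independently
# seeded test-retest cohorts and compare the within-subject CV of GSH
# between simple peak fitting and linear-combination modeling, on HERMES
# (TE 80 ms) and MEGA-PRESS (TE 120 ms) spectra. Expect the peak-fit CV at
# TE 80 to sit well above the LCM CV, and the LCM CVs of the two sequences
# to be comparable. Runs in roughly a quarter of an hour on one CPU.

library(editmrs)

dir.create("results", showWarnings = FALSE)
study <- run_retest_study(n_seeds = 50, seed = 1)
write.csv(study, "results/multiseed_cvs.csv", row.names = FALSE)

med <- vapply(study[, c("cv_peak_hermes_gsh", "cv_lcm_hermes_gsh",
                        "cv_lcm_mega_gsh")], median, numeric(1))
wins <- sum(study$cv_peak_hermes_gsh > study$cv_lcm_hermes_gsh)
p <- stats::binom.test(wins, nrow(study), alternative = "greater")$p.value

message(sprintf("median within-subject GSH CV, HERMES-80: %.1f%% (peak fit) vs %.1f%% (LCM)",
                med[1], med[2]))
message(sprintf("median within-subject GSH CV, LCM: %.1f%% (TE 80) vs %.1f%% (TE 120); ratio %.2f",
                med[2], med[3], med[2] / med[3]))
message(sprintf("peak > LCM on HERMES in %d / %d cohorts (sign test p = %.2g)",
                wins, nrow(study), p))
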