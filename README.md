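# editmrs

Simple peak fitting versus linear-combination modeling for
J-difference-edited MRS of glutathione (GSH) and GABA+, evaluated on a
fully synthetic test–retest cohort.

## The problem

Edited <sup>1</sup>H-MRS isolates low-concentration metabolites by
subtracting sub-spectra acquired with editing pulses on and off: MEGA-PRESS
targets one metabolite per experiment, while Hadamard-encoded HERMES
acquires four sub-spectra (A–D) whose ± combinations yield GSH- and
GABA-edited difference spectra from a single scan. The edited GSH signal at
2.95 ppm sits next to co-edited aspartyl multiplets at ~2.6 ppm that are
near-absorptive at TE = 120 ms but strongly mixed-phase at the TE = 80 ms
Hadamard compromise — a known hazard for simple peak fitting, which models
the difference spectrum as a handful of Gaussians over a low-order
polynomial baseline. Linear-combination modeling (LCM) instead fits a
non-negative superposition of exact metabolite responses plus a cubic-spline
baseline:

    min over (A_m >= 0, beta, phi0, phi1, sigma_G, gamma_m, delta_m) of
    || Re{ e^{-i(phi0 + phi1 (f - fbar))} * sum_m A_m B_m(f) }
       + sum_k beta_k S_k(f)  -  Re S(f) ||^2  + soft-constraint penalties

with `B_m` the transform of the basis FID `b_m(t)` after per-basis
Lorentzian broadening `gamma_m`, global Gaussian broadening `sigma_G` and
shift `delta_m`, and `S_k` cubic B-splines on 0.4-ppm knots.

The package asks, on synthetic data with known ground truth: does LCM
improve the test–retest reproducibility (within-subject coefficient of
variation, CV) of GSH quantification for HERMES at TE 80 ms, while the two
approaches remain comparable for MEGA-PRESS at TE 120 ms?

Everything runs from code: a metabolite catalog with encoded editing
behavior generates raw transients for 12 subjects × 2 scans; a
preprocessing chain (eddy-current correction, robust frequency-and-phase
registration, weighted averaging, pairwise sub-spectrum alignment, Hadamard
recombination, HSVD water removal) produces difference spectra; both
engines quantify GSH and GABA+ against the unsuppressed water reference;
and the statistics layer computes within-subject CVs, variance-ratio
(F) tests with confidence intervals, and Bland–Altman summaries.

## Worked example

```r
library(editmrs)

# one synthetic HERMES session (32 transients per sub-experiment)
catal <- default_catalog("HERMES80")
raw <- simulate_scan(default_truth_means(), acq_hermes80(128), catal,
                     noise_config(), seed = 7)
ps <- preprocess_scan(raw, preprocess_config(hsvd_model_points = 256,
                                             hsvd_rank = 15,
                                             zerofill_to = 2048))
quantify_scan(ps, peak_zerofill = 4096, lcm_truncate = 1024)
```

```
  subject scan sequence method metabolite estimate_iu flagged
1       1    1 HERMES80   PEAK        GSH  0.04663812   FALSE
2       1    1 HERMES80   PEAK      GABA+  0.08143512   FALSE
3       1    1 HERMES80    LCM        GSH  0.07051374   FALSE
4       1    1 HERMES80    LCM      GABA+  0.30908213   FALSE
```

Estimates are water-scaled institutional units (metabolite amplitude over
the fitted unsuppressed-water amplitude, times a global constant); they are
internally consistent but arbitrary in absolute value, and the two engines
use different amplitude conventions (Gaussian peak areas versus basis
amplitudes), so only within-engine comparisons are meaningful. The true GSH
concentration here is 2.0 mM-equivalents; the LCM basis amplitude behind
the LCM row recovers it to a few percent, while the peak-fit row reflects
the smaller share of the GSH signal that a Gaussian-plus-baseline model
captures at TE 80 ms.

The full analysis lives in `analysis/01_simulate_cohort.R` through
`analysis/05_multiseed_study.R`: cohort simulation with an on-disk FID
bundle export, preprocessing, both engines with exported fit curves,
test–retest statistics shaped like the study's tables, and the 50-cohort
reproducibility experiment. A typical run of the final driver prints

```
median within-subject GSH CV, HERMES-80: 18.4% (peak fit) vs 11.1% (LCM)
median within-subject GSH CV, LCM: 11.1% (TE 80) vs 8.4% (TE 120); ratio 1.32
peak > LCM on HERMES in 49 / 50 cohorts (sign test p = 4.5e-14)
```

— the qualitative pattern of the in vivo comparison this design emulates:
LCM roughly halves the HERMES-80 GSH CV and brings it in line with
MEGA-120, while simple peak fitting struggles with the mixed-phase
aspartyl background.

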