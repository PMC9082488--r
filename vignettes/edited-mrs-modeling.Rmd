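---
title: "Modeling J-difference-edited spectra: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling J-difference-edited spectra: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the forward
model behind the synthetic cohort, the preprocessing chain, the two
quantification engines, the reproducibility statistics, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## What the package studies

J-difference editing isolates overlapped, low-concentration metabolites by
subtracting sub-spectra acquired with a frequency-selective editing pulse
on and off the coupling partner of the target. MEGA-PRESS edits one
metabolite per experiment; HERMES interleaves four sub-experiments (A–D)
whose Hadamard combinations yield two difference spectra — here GSH-edited
and GABA-edited — from one acquisition at a shared echo time of 80 ms,
versus 120 ms for the MEGA-PRESS GSH reference experiment.

The scientific question is a methods comparison: how reproducibly do two
standard modeling families quantify the edited GSH signal across a
test–retest pair of sessions? *Simple peak fitting* models the difference
spectrum with a handful of Gaussians over a curved polynomial baseline;
*linear-combination modeling* (LCM) fits exact metabolite responses with a
cubic-spline baseline. The TE-80 GSH difference spectrum carries a
co-edited aspartyl multiplet at ~2.6 ppm with strongly mixed-phase lines,
which a sum of absorptive Gaussians cannot represent — the fitted baseline
then becomes ill-determined under the 2.95-ppm GSH peak, and the GSH
estimate inherits that instability. At TE 120 the multiplet has refocused
to near-absorptive lines and the simple model works well. LCM, knowing the
exact multiplet shapes, is insensitive to this hazard at either TE.

## The forward model and metabolite catalog

Every signal is a sum of damped complex sinusoids,

$$ s(t) \;=\; \sum_m c_m \sum_l a_l e^{i\varphi_l}\,
   e^{2\pi i f_l t}\, e^{-t/T_{2,m}}\, e^{-(g_m t)^2}, $$

with line offsets in ppm relative to the 4.68-ppm water carrier at a
transmitter frequency of 127.7 MHz (a 3-T default; the field strength is a
configuration assumption). Editing physics is *encoded, not simulated*:
each catalog line stores its (signed amplitude, phase) under edit-ON and
edit-OFF of the dimension it responds to, so difference behavior is exact
by construction — unedited singlets (NAA, tCr, tCho) cancel identically in
every combination, the GSH doublet at 2.93/2.97 ppm inverts between GSH-ON
and GSH-OFF, and the aspartyl, Glx and macromolecule entries co-edit with
their respective pulses.

Catalog parameters that matter, with the reasoning behind them:

* **Aspartyl presets.** These are versioned fixtures chosen to reproduce
  the qualitative TE contrast, not spin physics. The TE-120 preset is five
  near-absorptive lines (phases within ±15°). The TE-80 preset is an
  8-line "two doublets of doublets" spanning 2.44–2.84 ppm with phases
  {+40, −65, +120, −150, −140, +160, −170, +175}°. Two properties were
  deliberate: the multiplet is dense enough that four or five free
  Gaussians plus a cubic baseline cannot model it cleanly, and the lines
  adjacent to GSH are near-antiphase, leaving a negative shoulder that
  makes baseline placement under the GSH peak ill-determined. A sparser
  4-line variant was tried first and proved too easy for the Gaussian
  model: the TE contrast that motivates the whole comparison did not
  emerge, and the fitted TE-80 GSH area was *larger* than at TE-120,
  opposite to the in vivo pattern of a suppressed peak-fit HERMES GSH
  estimate.
* **GSH editing efficiency 0.75 at TE 80.** The GSH doublet refocuses
  optimally near TE 120 ms; at the Hadamard compromise the edited signal is
  weaker while the co-edited aspartyl response is not.
* **Proton-weighted amplitudes.** tCho's nine choline protons give it
  amplitude 3 against the 3-proton methyl reference of NAA/tCr — this also
  makes tCho a usable anchor for sub-spectrum alignment.
* **Macromolecules** (0.93/1.2/1.4/3.0 ppm) are Gaussian-dominated humps
  (T2 200 ms, 24-Hz Gaussian width): broad, but without the slow Lorentzian
  tails that would otherwise leak into the alignment windows. The 3-ppm MM
  co-edits with GABA such that it carries ~45% of the GABA+ 3-ppm area,
  making "GABA+" meaningfully composite.
* **Residual water** survives each difference at ~5× the GSH peak (a mild
  editing-dependence of the suppression residue), so the HSVD filter has
  real work to do. The unsuppressed water reference is 30000 concentration
  units — an arbitrary but realistic four orders of magnitude above the
  metabolites.

## The cohort generator

Twelve subjects × two scans, with both sequences per session. Subject
concentrations are log-normal around plausible brain values
(between-subject CV 10%), scan values are jittered log-normally
(within-subject CV 5%); CVs are interpreted as SD/mean of the log-normal,
which keeps concentrations positive.

The instability model carries what frequency-and-phase correction and
water filtering exist to fix, each with a default chosen once as realistic:

* complex white noise per transient (`noise_sd = 4`, calibrated so that a
  single scan's GSH fit CV lands at roughly 5–10%, the flagged-as-arbitrary
  convention for the missing in vivo SNR figure);
* linear frequency drift (0.015 Hz/transient) plus per-transient frequency
  jitter (0.3 Hz SD) and phase jitter (2° SD), on an interleaved
  sub-experiment schedule so drift is shared across sub-experiments;
* a smooth random complex baseline distortion per sub-experiment
  (spline-shaped, ~0.5-ppm features, SD 50): broad enough to read as
  "baseline", too structured for a quadratic to follow, representable by
  the LCM's 0.4-ppm-knot spline — the operative difference between the two
  engines' baseline models;
* an eddy-current phase $\varphi(t) = 0.3\,e^{-t/50\,\mathrm{ms}}$ on all
  FIDs including water;
* a per-scan session linewidth: one log-normal draw of extra Gaussian
  broadening (mean 3 Hz, SD 1.5 Hz) applied to all FIDs of the scan.
  Test–retest sessions involve repositioning and re-shimming, so
  between-session lineshape change is first-order real. LCM absorbs it
  through its global Gaussian broadening parameter; simple peak fitting
  has no lineshape parameter and must re-negotiate its Gaussians and
  baseline — without this term, the basin a peak fit settles into is
  almost a deterministic function of the subject's spectrum and its
  instability cancels out of the within-subject CV entirely.

What the generator does *not* emulate: phase cycling, spatial localization
and chemical-shift displacement, vendor raw formats, relaxation differences
between scans, and any non-Gaussian artifact population (motion spikes,
lipid contamination). Passing tests therefore show that the pipeline and
the engine comparison behave correctly under these idealized instabilities
— not that either engine is robust to everything real data does.

## Preprocessing chain

`preprocess_scan` runs, in order: eddy-current correction (the unwrapped
water phase removed from every FID), frequency-and-phase registration of
the transients separately within each sub-spectrum, weighted averaging,
pairwise sub-spectrum alignment, Hadamard combination or MEGA subtraction
(normalized by the number of summed sub-spectra, a convention that cancels
in water-scaled ratios), HSVD water filtering of the difference FIDs, and
Fourier transformation. Numerical choices worth knowing:

* **First-point halving.** The one-sided DFT of a causal FID adds a flat
  real pedestal of $s(0)/2$ to every bin. The package halves the first
  sample before every transform (and doubles it back on inversion), the
  classic remedy. This matters more than cosmetics: sub-spectra with
  different $s(0)$ would otherwise bias the alignment optimum by several
  degrees.
* **Registration** minimizes the time-domain squared distance to a
  pointwise-median reference over the first 200 ms. For fixed frequency
  the optimal phase is the argument of the windowed cross-correlation, so
  the search is a profiled one-dimensional optimization in frequency:
  coarse grid over ±6 Hz (wide enough to avoid 2π ambiguity around the
  phase-slope initial estimate), golden-section refinement, then parabolic
  interpolation of the correlation peak. Two passes with the reference
  rebuilt. The window is subsampled (every third point) with no practical
  accuracy loss at these linewidths. A full two-parameter simplex is kept
  in the package and tested to agree with the profiled search.
* **Weighted averaging** uses $w_n \propto 1/d_n^2$ with $d_n$ the squared
  deviation from the pointwise median — a strong but simple down-weighting
  of outlier transients; the weighting rule behind "weighted averaging" in
  the emulated processing chains is not public, and this is our choice.
* **Sub-spectrum alignment** performs the conventional pairwise sequence:
  B→D on the residual-water window (4.2–5.2 ppm), C→D on tNAA
  (1.9–2.1 ppm), A→C on tCho, and ON→OFF on tNAA for MEGA. The objective
  is the *residual power after projecting out a quadratic trend* across
  the window, computed on 3-Hz-apodized copies (matched filtering); the
  corrections are applied to the raw FIDs. The nuisance projection is the
  result of a concrete failure mode: dispersive $1/\Delta$ tails of the
  legitimately co-edited 3-ppm signals leak into the tCho window, and a
  plain magnitude objective rotates an already-aligned pair by several
  degrees, which in turn makes the unedited singlets (NAA at 2.0, tCr at
  3.03, tCho at 3.2 ppm) stop cancelling in the Hadamard difference — a
  quadrature leakage proportional to the phase error times their full
  concentrations. The tCho window is 3.12–3.32 ppm; below 3.12 the
  co-edited envelope still contaminates the pair difference.
* **HSVD** decomposes the first `model_points` samples via a Hankel-matrix
  SVD (defaults 1024 points, rank 25; the cohort study uses 256/15 — the
  water pole is heavily over-resolved either way), takes poles from the
  shift-invariance eigenproblem of the signal subspace, amplitudes by
  least squares, and subtracts the full-length reconstruction of
  components inside 4.4–5.0 ppm. Growing poles (|z| > 1.001) are never
  subtracted.

## The two engines

**Peak fitting.** Nonlinear least squares of 3 (GABA+/Glx, 2.79–4.10 ppm),
5 (GSH at TE 80) or 6 (GSH at TE 120) Gaussians over 2.25–3.50 ppm, plus a
curved 4-parameter baseline, on the real part. The published description
of the emulated tool does not enumerate the four baseline parameters; this
package reads them as a cubic polynomial (constant + linear + quadratic +
cubic) with purely absorptive Gaussians and no model phase, which matches
the parsimonious character of the approach. A variant with three
polynomial terms plus a global zero-order phase (rotating each Gaussian
into its Dawson-function dispersion partner) is available via
`peak_fit_config(phase = TRUE)`; it is substantially more capable on
mixed-phase multiplets — capable enough, in fact, that the TE-80
instability this comparison exists to measure largely disappears, which is
the reason it is not the default. Widths are bounded to [0.01, 0.2] ppm,
centers to ±0.1 ppm of their initialization (preventing peak swapping),
amplitudes to ±10× the data range (preventing unbounded canceling pairs on
mixed-phase data); three deterministically jittered starts, best residual
wins, with a stationarity polish that accepts an iteration-capped fit
whose residual has stopped improving. The reported quantity is the
analytic area $A\sigma\sqrt{2\pi}$ of the designated Gaussian.

**LCM.** Variable projection: at each outer step the non-negative
amplitudes (and free-signed spline coefficients, handled as differences of
non-negative pairs) are re-solved by Lawson–Hanson non-negative least
squares on normal equations; the outer parameters — zero- and first-order
phase, global Gaussian broadening, per-basis Lorentzian broadening and
shift — move by Levenberg–Marquardt. The basis is generated by the same
forward model through the same difference arithmetic as the data (exact by
construction, which enables exact-recovery tests; `make_basis(mismatch =
...)` perturbs T2 and line positions to emulate basis/in-vivo
discrepancy). Parametrized macromolecule Gaussians (14-Hz FWHM, unit
spectral area) are added per target: 1.2/1.4 ppm for GSH, 0.93/3.0 ppm for
GABA+, with a soft amplitude-ratio constraint MM1.2:MM1.4 = 2.0 (SD 0.2)
as a quadratic penalty. Priors: shifts ±0.05 ppm with SD 0.02 ppm,
Lorentzian broadenings ≥ 0 with SD 2 Hz, and the global Gaussian
broadening with SD 3 Hz — the last because a one-sided broadening
parameter with no prior lets noise-driven broadening bias amplitudes
upward. GABA+ is reported as the GABA basis amplitude plus the 3-ppm MM
amplitude (their units differ — concentration-like versus area-like — so
the composite is dominated by the MM term; it is internally consistent,
which is all the scale-free statistics require). The water reference is
fitted with a six-parameter frequency-domain model (amplitude, two phases,
two broadenings, shift) against the simulated water basis function, with
starts covering Gaussian- and Lorentzian-dominant broadening.

Quantification divides the metabolite amplitude by the engine-matched
water amplitude and multiplies by a global constant (1000); no relaxation
or tissue corrections exist anywhere in the path, and a test asserts that
from the recorded provenance.

## Statistics

Within-subject CV uses the RMS-of-paired-differences estimator
$100\,\sqrt{\sum_i d_i^2 / 2n}\,/\,\bar{x}$ (the cited reliability
literature gives no formula; this is the standard choice and is
scale-invariant). The engine comparison is the classic two-sample
variance-ratio test on unit-mean-normalized per-subject means — the cited
routine is a variance-ratio test, not a paired procedure — with two-sided
p by doubling the smaller tail and the 95% CI $(F/q_{0.975},
F/q_{0.025})$. The implementation is by the formulas; `stats::var.test`
and numerical F-density integration serve as independent oracles in the
tests. Bland–Altman summaries use mean difference ± 1.96 SD.

## Problem sizes and degenerate inputs

The multi-seed study runs 50 cohorts at 32 transients per sub-experiment,
with the LCM fitted on the leading 1024 FID samples at the native grid
(the discarded tail is noise only) and peak fitting on a 4096-point
zero-fill; `to_spectrum` defaults remain 32768 points with 3-Hz broadening
for display-grade spectra. These sizes are the package's chosen operating
point for a study that repeats the full pipeline 2400 times; all spectral
quantities that matter (linewidths ≥ 5 Hz against ≤ 2.4-Hz grids) stay
comfortably resolved. Degenerate inputs are handled explicitly: identical
transients average with equal weights, a variation-free cohort reports
F = 1 with p = 1 rather than a zero-variance error, zero-magnitude water
samples carry the previous phase forward with a warning, growing HSVD
poles are excluded from subtraction, and non-convergent fits return
flagged results rather than exceptions.

## Known limitations

The catalog is a parametric stand-in, not a density-matrix simulation: its
aspartyl presets reproduce the qualitative TE contrast by construction,
and conclusions about the *magnitude* of the engine gap transfer to real
data only directionally. The full 19-metabolite basis of in vivo LCM
collapses here to the handful of species with non-vanishing difference
responses, so the baseline burden on the spline is lighter than in vivo.
Subtraction artifacts arise only through the modeled instabilities;
bad-average rejection, tissue corrections and fit-quality filters are out
of scope. The interface is the package's functions plus the numbered
analysis drivers — the workflow is a sequence of analyses over generated
data, and a shell tool would add nothing the drivers do not already do.
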