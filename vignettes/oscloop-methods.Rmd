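---
title: "Source-localized EEG oscillatory connectivity: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-localized EEG oscillatory connectivity: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscloop)
```

# What this package computes

`oscloop` implements a resting-state EEG analysis chain entirely in source
space: scalp recordings are band-passed to 2–44 Hz and resampled to 128 Hz,
re-referenced to the common average, inverted with sLORETA on a three-shell
spherical head model, and summarized at seven single-voxel regions of
interest (left/right auditory cortex AUD, left/right somatosensory cortex
SOM, left/right parahippocampus PHC, and a single midline pregenual anterior
cingulate pgACC — laterality so close to the midline is not resolvable under
volume conduction). On the ROI summaries it computes four families of
statistics:

* **log relative band power** — per band, voxel power is normalized across
  the whole grid to sum to one at every time step, averaged over time, and
  natural-log transformed; an ROI value is the log fraction of overall power
  at its voxel;
* **lagged phase coherence (LPC)** — the part of coherence attributable only
  to non-instantaneous dependence, `LC = Im(c)^2 / (1 - Re(c)^2)` for a
  complex coherency `c`; instantaneous (volume-conducted) dependence is
  purely real and contributes nothing;
* **theta-band Granger causality (GC)** — `ln(sigma2_reduced /
  sigma2_full)` from bivariate autoregressive fits, band-restricted through
  the Geweke spectral decomposition;
* **theta–gamma phase–amplitude coupling (PAC)** — the normalized mean
  vector length `|mean(a e^{i theta})| / mean(a)` of the gamma analytic
  envelope against the theta phase.

Group inference uses the max-statistic permutation test (familywise-error
control over all features and bands jointly), minimum-statistic conjunction
of patient-minus-control Z maps, and a MANOVA → ANOVA → pairwise step-down
with Holm–Bonferroni correction and eta-squared effect sizes.

Because no public recordings accompany the design this package emulates, a
first-class synthetic-cohort generator plants the full effect structure —
control, tinnitus and pain groups with directed parahippocampal–sensory
theta loops, pgACC theta and sensory gamma power elevations, and theta–gamma
nesting — and exposes the ground truth, so every stage is validated by
parameter recovery rather than by inspection.

# The generative model

Each ROI current is a sum of three components at 128 Hz:

1. a **theta process**: Gaussian white noise filtered into 4–7.5 Hz with a
   zero-phase (real, symmetric frequency response) filter, unit RMS, scaled
   by the template's theta amplitude. Narrowband noise rather than a
   sinusoid is used so that coherence and autoregressive estimators face
   realistic spectra — pure tones make MVAR fits degenerate;
2. a **gamma carrier** (30.5–44 Hz narrowband noise) whose envelope is
   modulated as `(1 + m cos theta_phase) / sqrt(1 + m^2/2)` with modulation
   depth `m` in [0, 1]. Because the modulator's spectrum lies entirely below
   the carrier band, the analytic envelope of the product factorizes
   (Bedrosian's condition), which gives the closed-form expectation
   `MVL -> m/2` used as the PAC oracle;
3. a small **1/f background** (2–44 Hz, amplitude 0.3) that keeps the
   autoregressive designs well conditioned.

Directed influences are lagged linear couplings on the theta components:
`x_target(t) += strength * x_source(t - lag)`, solved by Neumann iteration
of `x = b + A(L) x`. Lags are integer samples (default 3 at 128 Hz ≈ 23 ms,
near the quarter-cycle theta delay that lagged coherence is built to
detect). A configuration is refused, naming its strongest edge, when the
companion spectral radius of the coupling operator reaches 1; subject-level
jitter is additionally clamped so the radius stays below 0.9.

The condition templates plant the directed-loop difference between the two
patient groups: in the tinnitus template the parahippocampus and the
auditory cortex are coupled **bidirectionally** while PHC drives SOM
**unidirectionally**; the pain template is the mirror image. Both patient
templates couple the two parahippocampi bidirectionally, raise pgACC theta
amplitude (×1.8), sensory gamma amplitude (×2) and modulation depth (0.45
vs 0.10). The control template has no pathological edges. Between-subject
variability is log-normal multiplicative jitter with coefficient of
variation 0.2 on amplitudes and coupling strengths. No effect-size-
calibrated parameters exist to copy from real cohorts, so these magnitudes
were chosen once to be detectable at 25 subjects per group — the scale at
which the recovery analyses are run — and are documented here as such.

Scalp data are the lead-field projection of the ROI currents (each ROI
radiates along a fixed radial orientation — the orientation EEG sees best,
fixed across subjects as cortical anatomy is), **plus 60 background brain
sources** at random non-ROI voxels with 1/f spectra and random orientations,
plus independent 1 µV sensor noise. The background sources matter more than
they may seem: relative power is a ratio measure, and in an "empty brain"
the six jointly elevated sensory-gamma ROIs dominate their own
normalization denominator, cancelling the planted effect. Whole-brain
background activity — present in any real recording — stabilizes the
denominator, and without it the generator would misrepresent what relative
power can detect.

# Forward and inverse model

The forward model is the closed-form series solution for a dipole in three
concentric spheres (brain/skull/scalp radii 78/86/92 mm, conductivities
1 : 1/80 : 1). Per spherical-harmonic degree the five boundary conditions
give a linear system solved once (radii normalized to the scalp radius for
conditioning); with equal conductivities the solution collapses to the
homogeneous-sphere series `t_n = (2n+1)/n · R^-(n+1)`, which the tests
verify to machine precision, and the source term reproduces the
infinite-medium dipole potential exactly.

The solution space is a half-spacing-offset cubic lattice inside a 78 mm
sphere; presets `mini` (160 voxels), `test` (500) and `paper6239` (6239, the
paper-scale count) keep the innermost points of progressively finer
lattices. ROI coordinates on this phantom are declared approximations of
the anatomical targets, not atlas reproductions, and can be overridden.

The inverse is sLORETA: minimum-norm operator `T = L'(L L' + alpha H)^+`
with `H` the average-reference centering matrix, standardized by the 3×3
diagonal blocks of the resolution matrix `T L`. Standardized power of a
noise-free point source is maximal exactly at the source voxel for any
`alpha >= 0`; the acceptance suite verifies this zero-localization-error
property exhaustively over all 500 voxels of the test grid. The default
`alpha` is 1e-2 times the mean eigenvalue of `L L'`.

# Estimator design choices

**Cross-spectra.** Four-second non-overlapping Hanning-tapered epochs
(0.25 Hz resolution, so the theta band spans ≥ 2 Fourier bins); band value =
mean of per-bin cross-spectra over the half-open band interval; per-epoch
coefficients are retained so that surrogate tests can permute epoch
pairings. Amplitude-threshold epoch rejection (default ±100 µV for scalp
data) stands in for manual artifact review.

**LPC.** Both the coherence form (raw coefficients) and the
phase-synchronization form (unit-modulus coefficients) are implemented; the
phase form is the default. Significance is assessed by epoch-pairing
surrogates by default; the asymptotic chi-square route is available but the
surrogate is exact at the epoch counts used here.

**GC.** The band value is the Geweke spectral decomposition of the fitted
bivariate model averaged over the band — the series are *not* band-pass
filtered before fitting, which is known to distort autoregressive causality.
The default order is 12: the ROI series superimpose theta, gamma and 1/f
components, and an under-parameterized model (order ~5) leaves structure in
the residuals that shows up as spurious *reverse* causality — at order 12
the planted unidirectional couplings recover with a ~10:1 forward/reverse
ratio on source series. Negative estimates are floored at zero and flagged.

**ROI series for directed connectivity.** This is the one place where the
package deviates from the naive chain, and the reason is quantitative. With
19 upper-hemisphere electrodes, the raw sLORETA series at a deep
parahippocampal voxel is heavily contaminated by the superficial temporal
sources: the ROI-level mixing matrix (`roiMixingMatrix()`) shows leakage
coefficients up to ~0.9–1.2 between PHC and AUD/SOM estimates, at which
point pairwise GC becomes symmetric regardless of the true direction —
controlled mixing experiments show the asymmetry is destroyed once mixing
exceeds ~0.7. The pipeline therefore estimates GC on **crosstalk-corrected
series**: scalar radial extractions multiplied by the inverse of the
operator-derived mixing matrix (`crosstalkCorrectedSeries()`). The
correction needs no ground truth — it is computed from the forward and
inverse operators alone — and makes the corrected mixing exactly the
identity on the atlas ROIs, at the price of amplified sensor noise.
Pairwise symmetric (Löwdin) orthogonalization is also implemented
(`leakage_correction` flag) but is off by default: it removes the shared
zero-lag component, and a genuinely bidirectional theta coupling at a
quarter-cycle lag has a large zero-lag correlation, so orthogonalization
suppresses exactly the couplings of interest.

**PAC.** Within-ROI, so leakage is less corrosive: the three orientation
series are band-passed, projected on their first principal component per
band (sign fixed by positive correlation with the largest-variance raw
component), and the normalized mean vector length is compared against
circular time-shift surrogates (shifts ≥ 1 s, 200 by default, evaluated in
one FFT pass; 1 s is trimmed at each end after the Hilbert transforms to
suppress edge artifacts). MVL was chosen over the modulation index because
it has the closed-form `m/2` oracle that makes the module testable; phase 0
is at the theta peak.

**Group inference.** The max statistic is taken over all features *and*
bands jointly. Patient-minus-control contrasts are converted to Z through
the permutation null of the two-group F statistic, signed by the direction
of the mean difference; the conjunction statistic is the elementwise
minimum of the two Z maps at the 1.96 two-sided cutoff. The multivariate
gate of the step-down is Pillai's trace (robust to covariance
heterogeneity; Wilks' lambda behind a flag); families are declarative and
nestable, e.g. the 12-link pgACC family with per-pair 2-link subfamilies,
and a family whose multivariate test would need more subjects per group
than it has features must be declared as subfamilies instead (the pipeline
does this collapse automatically).

# What the synthetic cohort does and does not show

The generator emulates: band-limited oscillatory sources with planted
directed lagged couplings, theta–gamma nesting, group-specific power and
connectivity differences, instantaneous volume-conduction mixing through a
physical forward model, whole-brain background activity and sensor noise.
It does **not** emulate realistic cortical geometry or orientation maps,
non-stationarity (drowsiness, artifacts — rejection is exercised by
amplitude thresholds only), alpha-rhythm structure beyond 1/f background,
or any biophysical neural-mass dynamics. Passing recovery tests therefore
demonstrates that the estimators are correct and that the chain detects the
planted structure through a physically plausible mixing process; it does
not guarantee comparable sensitivity on real recordings.

The scaled-down study conditions used by the recovery analyses are 25
subjects per group, 90-second recordings at 128 Hz on the 500-voxel grid
with 500 label permutations; at these sizes a full recovery run completes
in minutes on one CPU. Spatial resolution, not estimator validity, is the
binding constraint at this scale: the source-level tests recover the
planted loop pattern cleanly, while through the 19-channel scalp chain the
bidirectional arm of the pain loop (PHC→SOM in the presence of SOM→PHC) is
attenuated by the deep PHC estimate's noise amplification and sits at the
edge of detectability. This is reported as measured; generator parameters
are not adjusted to force it over a threshold.

# Numerical conventions

* Zero-phase filtering is frequency-domain multiplication with raised-cosine
  transitions (0.5 Hz wide); circular edge effects are accepted for
  multi-minute records. Resampling is Fourier truncation (band-limited).
* Coordinates are head-frame millimetres, origin at the sphere centre;
  grids are 1-indexed; ROI voxels are nearest-lattice-point snaps of the
  requested coordinates, required to be distinct.
* Half-open band intervals [lo, hi) avoid double counting at shared edges.
* Permutation p-values use the add-one rule `(1 + #{null >= obs}) / (n + 1)`
  and are therefore never zero; corrected thresholds are empirical
  quantiles of the max-statistic null.
* All randomness is seeded: cohorts derive per-subject seeds
  deterministically from one master seed, and rerunning any pipeline
  configuration reproduces byte-identical tables.
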