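---
title: "Methods: amplitude mapping, cluster correction and marker evaluation in perafr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplitude mapping, cluster correction and marker evaluation in perafr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `perafr`, the
choices that were genuinely open when the package was designed, and
what its validation on synthetic cohorts does and does not establish
about real data.

## The PerAF metric

For a voxel's BOLD series $x_1,\dots,x_n$ with mean
$\mu = \frac{1}{n}\sum_i x_i$, the percent amplitude of fluctuation is

$$\mathrm{PerAF} \;=\; \frac{1}{n}\sum_{i=1}^n
  \left|\frac{x_i-\mu}{\mu}\right| \times 100\%.$$

Three properties matter in practice and are enforced as tested
invariants:

* **Scale invariance.** $\mathrm{PerAF}(cx) = \mathrm{PerAF}(x)$ for any
  $c>0$: the metric is a percentage of the voxel's own mean signal, so
  scanner gain and global intensity normalisation drop out. ALFF, by
  contrast, is homogeneous of degree one ($\mathrm{ALFF}(cx) =
  c\,\mathrm{ALFF}(x)$); both behaviours are asserted in the test
  suite.
* **Offset sensitivity.** An additive offset changes $\mu$ and
  therefore PerAF. This is deliberate and intrinsic to a
  percent-of-mean metric; it is why the preprocessing steps below are
  careful never to move the voxel mean.
* **Gaussian limit.** For an i.i.d. Gaussian series
  $N(\mu,\sigma^2)$, $E|x-\mu| = \sigma\sqrt{2/\pi}$, so sample PerAF
  converges to $100\,\sqrt{2/\pi}\,\sigma/\mu$ — the closed form the
  test suite checks at $n = 10{,}000$ within three Monte-Carlo standard
  errors. With $\sigma/\mu = 0.02$ this is $\approx 1.596\%$, a
  realistic cortical value.

Because $\mu$ appears in a denominator, PerAF is only defined for
series with strictly positive mean. Voxels whose mean is non-positive,
or below $10^{-6}$ of the within-mask grand mean, are dropped from the
map's mask and counted in its metadata rather than producing huge
percentages.

ALFF is computed from the plain (untapered) periodogram — the mean of
the single-sided amplitude spectrum over the 0.01–0.08 Hz band — and
fALFF as the in-band fraction of total amplitude. The plain periodogram
was chosen over tapered estimators for transparency: pure sinusoids on
grid frequencies give exactly recoverable amplitudes, which the tests
exploit.

## Temporal preprocessing

The pipeline operates on spatially aligned 4D volumes and performs, in
a fixed order: initial-volume discard → motion QC → nuisance
regression → linear detrend → amplitude maps → map smoothing.

* **Volume discard, default 15.** The first volumes of a resting
  acquisition are acquired before magnetisation reaches steady state
  and are dropped. With the default 245-volume simulation, 230 remain.
* **Motion exclusion, 1.5 mm / 1.5°.** A subject is excluded when any
  translation exceeds 1.5 mm on any axis at any timepoint — a strict
  inequality, so exactly 1.5 mm is kept. Rotations use 1.5° by
  analogy; rotation limits for "excessive angular movement" vary across
  studies and 1.5° is the common companion to a 1.5 mm rule. Excluded
  subjects propagate into reports but never into statistics.
* **Nuisance regression.** Each voxel series is regressed on an
  intercept plus the mean series of a central white-matter mask and a
  ventricle mask (no motion-parameter regressors). The residuals are
  returned **with the voxel's original mean added back**: regression
  centres residuals near zero, which would destroy the PerAF
  denominator, and restoring the pre-regression mean keeps the metric's
  meaning as percent of baseline signal. The de-meaned output is
  orthogonal to every regressor to $10^{-8}$, and the mean is preserved
  to $10^{-10}$ (both tested against an independent normal-equations
  solver).
* **Detrending** removes a least-squares line per voxel and restores
  the mean, for the same reason.
* **Smoothing is applied to the amplitude maps, not the 4D series**
  (6 mm FWHM default, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$,
  separable kernel, reflective boundaries). Map-level smoothing is the
  common choice for amplitude analyses: smoothing the series first
  would mix time courses before the nonlinear $|x-\mu|$ step.
  Reflective boundaries leave constant maps fixed and conserve the mass
  of interior impulses, both asserted against a direct-convolution
  oracle. Series-level smoothing is available through the simulator's
  `spatial_fwhm_mm` if wanted.

## Group statistics and cluster-extent correction

Group difference maps use the pooled-variance two-sample t-statistic
(patient − control), $df = n_1+n_2-2$, vectorised over voxels and
cross-checked against `stats::t.test` on extracted voxel vectors.
Testing is two-tailed with the positive and negative tails clustered
separately; direction is recorded per cluster, so a study expecting
only decreases can simply read the negative-direction rows.

Suprathreshold voxels (default voxelwise $p = 0.01$, two-tailed) are
grouped into connected components under 18-connectivity by default
(faces + edges; 6 and 26 are available). 18 is a middle ground: 6 is
conservative about bridging, 26 merges aggressively through corners.

Two cluster-extent rules are provided:

* **Fixed rule:** a cluster is significant iff its size strictly
  exceeds a given count (the "> 40 voxels" convention) — the
  replication preset.
* **Monte-Carlo rule (primary):** simulate null fields, threshold at
  the same voxelwise $p$, record the maximum cluster size per
  iteration, and return the smallest integer $m$ such that
  $P(\max \ge m) \le \alpha$ (default $\alpha = 0.05$); clusters of
  size $\ge m$ are significant. The simulation is deterministic given
  its seed.

The null fields are Gaussian white noise smoothed at the same FWHM as
the analysis maps. Two null modes exist: a single smoothed z-field per
iteration (fast, classic), and — when the group sizes are supplied, as
`run_pipeline()` does — a simulation of the actual two-group t-field
from $n_1+n_2$ smoothed noise volumes. The t-field mode is the more
accurate null at small degrees of freedom: the voxelwise variance
estimate in the t denominator is spatially rougher than the smoothed
means, so extreme t voxels cluster less than a z-field of the same
nominal smoothness, and a z-field threshold is slightly conservative.
The family-wise error calibration test (500 null cohorts of 10 + 10 on
a 20³ grid, FWHM 2 voxels) checks that the achieved rate of any
significant cluster lies within the 95% binomial interval around 0.05;
an integer size threshold is necessarily a little conservative (the
attained level is the largest tail probability not exceeding
$\alpha$), which the interval accommodates. Data-driven smoothness
estimation is out of scope; the null smoothness defaults to the map
smoothing FWHM.

Peak coordinates are reported in reference-space mm through the image
affine (grid indices are 1-based internally; the affine maps 0-based
indices with the origin at the volume centre). Anatomical labelling
requires an atlas and is not bundled.

## Marker evaluation

Mean amplitude over each significant cluster gives one feature per
region per subject.

* **ROC.** Empirical curve over all thresholds; the trapezoid AUC
  equals the normalised Mann–Whitney U (ties one half), verified to
  $10^{-12}$ against exhaustive pair counting. The curve is oriented so
  AUC ≥ 0.5 and the direction (lower-indicates-patient for an
  amplitude reduction) is reported rather than hidden. Confidence
  intervals are DeLong's, truncated to $[0,1]$; the operating point is
  the Youden-optimal cutoff with ties broken toward higher
  specificity.
* **Leave-one-out SVM.** Linear kernel, $C = 1$ — the standard choice
  for a handful of neuroimaging features, where nonlinear kernels
  mainly add variance. For each fold the features are z-scored using
  the training subjects only (the held-out subject never influences
  its own scaler — asserted directly), a soft-margin SVM is fit on the
  other $N-1$ subjects, and the held-out subject is predicted.
  Sensitivity, specificity and accuracy recompute exactly from the
  stored confusion counts, and every reported metric carries its $N$.
* **Permutation test.** Each permutation shuffles the labels and
  reruns the *entire* leave-one-out procedure, z-scoring included;
  $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + B)$, so the
  smallest attainable p is $1/(B+1)$ and p is never zero. The suite
  checks super-uniformity under label-shuffled truth
  ($P(p \le 0.05) \le 0.08$ over 200 reduced replicates). The
  replication preset uses $B = 10{,}000$; tests use 1000 (and 59 for
  the validity sweep), trading resolution for runtime.

## The synthetic cohort generator

Each subject's image is `baseline + band-limited Gaussian signal +
white noise`. The signal is synthesised in the frequency domain:
independent complex-Gaussian coefficients on the grid frequencies
inside the band (default 0.01–0.08 Hz, the resting-state convention),
Hermitian-symmetrised and inverse-transformed, then scaled so the
population SD is exactly `fluct_amplitude`. This gives exact band
control — fALFF of a noiseless subject is ≈ 1 by construction — at the
cost of a stationary, periodic process. The group effect multiplies the
signal amplitude by `effect_factor` inside spherical ROIs for patients
only; `effect_factor = 1` makes the groups exchangeable, which the
tests use as a null.

Defaults emulate a typical 3 T resting scan at desk scale: 24³ voxels
of 3 mm, TR 2 s, 245 timepoints, 18 subjects per group, baseline 1000,
fluctuation SD 20, noise SD 10, effect factor 0.5. Baseline ≥
10 × (amplitude + noise) keeps intensities positive by construction
rather than by clipping (clipping would bias $\mu$); if a configuration
ever produces non-positive values the image is shifted and the shift
recorded in metadata. Per-subject seeds derive deterministically from
the master seed, so cohorts are bit-reproducible and subjects
independent.

What the generator does **not** emulate: hemodynamic response shapes,
cardiac/respiratory noise, scanner drift beyond a linear trend, EPI
distortion, motion *corruption* of the images (motion exists only as a
trace for the exclusion rule), spatial heterogeneity of baseline or
noise, and anatomical structure. Passing the recovery tests therefore
shows the pipeline's statistics behave correctly under the stated
model — correct false-positive control, recovery of genuine amplitude
reductions, valid permutation inference — not that any particular
clinical effect is detectable in real scans.

## Problem sizes and numerical choices

The test suite runs at deliberately small scales chosen to keep the
statistics stable: recovery uses 20 cohorts of 18 + 18 subjects on a
16³ grid with 115 timepoints (100 after discard); false-positive
calibration uses 500 null cohorts of 10 + 10 on a 20³ grid with the
cluster threshold from 1000 Monte-Carlo iterations; permutation
validity uses 200 cohorts of 5 + 5. The acceptance script runs one
full-default cohort (24³, 245 timepoints, 18 + 18).

Numerical policies, in one place: exact-arithmetic identities (group
swap antisymmetry, confusion-count consistency) are asserted as
identical; oracle comparisons at $10^{-10}$–$10^{-12}$; Monte-Carlo
comparisons at 3 standard errors or a 95% binomial interval. Zero
variance in a t-test voxel yields t = 0 plus a flag, never ±∞. A
constant ROC feature returns AUC 0.5 with a warning; a constant fALFF
series is an error (0/0). Gaussian kernels truncate at 4σ. Empty
suprathreshold sets produce empty cluster tables, and a run with no
significant clusters marks the discrimination stages "not applicable"
instead of failing.

## Interface note

The package's stages are exported R functions consumed by
`run_pipeline()`; this is the primary interface, with
`inst/scripts/run_pipeline.R` as a thin command-line wrapper for
shell-driven use. Each stage reads and writes ordinary containers
(arrays, data frames) plus NIfTI/TSV/JSON on request, so stages are
independently scriptable and testable.

## Known limitations

* No spatial preprocessing (realignment, normalisation, slice timing):
  inputs are assumed aligned, as the simulator produces them.
* Cluster-level inference assumes stationary smoothness equal to the
  applied map smoothing; no data-driven smoothness estimation.
* No covariate adjustment in the group model (two-sample t only), no
  paired designs, no voxelwise permutation inference.
* The SVM route uses the significant-cluster mean features; voxelwise
  feature sets and nested model selection are out of scope.
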