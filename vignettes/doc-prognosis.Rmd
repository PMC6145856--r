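---
title: "Multidomain prognosis for chronic disorders of consciousness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidomain prognosis for chronic disorders of consciousness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docprog)
```

## The modelling problem

A patient in a chronic disorder of consciousness (DOC) is scanned with
resting-state fMRI and assessed clinically at a baseline time point; at
least a year later the outcome is recorded as the CRS-R total score
(0–23) and a GOS grade, with GOS ≥ 3 defined as recovery of
consciousness. `docprog` fits a regression of the follow-up CRS-R on
baseline imaging and clinical features, then thresholds the predicted
score to classify recovery at the single-subject level. Regressing the
graded CRS-R rather than classifying directly keeps the model
interpretable (each predictor has a weight on the CRS-R scale) and lets
one cutoff trade sensitivity against specificity transparently.

The model assumes (a) the follow-up CRS-R is approximately linear in a
small number of z-scored predictors, (b) predictors are heavily collinear
— which is why partial least squares (PLS1) rather than ordinary least
squares carries the fit — and (c) the selection step, not the fit, is
where overfitting concentrates, which is why every internal-validation
routine re-runs selection inside the resampling loop.

## Preprocessing

Per subject, on a 4D BOLD run with its 6-parameter motion trace:

1. **Initial discard** — the first `drop_k = 5` volumes (scanner
   equilibration).
2. **Smoothing** — separable Gaussian kernel, `fwhm_mm = 6` mm; per-axis
   sigma in voxels is `fwhm / (2 sqrt(2 log 2)) / voxel_size`. The kernel
   is truncated at 3 sigma and renormalized, so a spatially constant
   volume is reproduced exactly, including at the edges.
3. **Nuisance regression** — per in-mask voxel, least-squares residuals on
   the 6 motion parameters, their first backward differences, the global
   mean over the brain mask (computed after smoothing, i.e. in pipeline
   order), a linear trend, and an intercept. Aliased columns are dropped
   with a warning. Residual orthogonality to the design is asserted in the
   tests at 1e-8 relative to the vector norms.
4. **Censoring** — framewise displacement
   `FD_t = Σ|Δtranslations| + 50 mm · Σ|Δrotations|` (rotations in
   radians converted to arc length at a 50 mm head radius; `FD_1 = 0`).
   `FD_t` describes the transition from volume *t−1* to *t*, so when it
   exceeds `fd_threshold_mm = 1.5` both bracketing volumes are removed —
   both endpoints of a contaminated transition are contaminated. A wider
   margin is available via `censor_margin` for users who read
   "preceded or followed" as a full volume on each side. Runs retaining
   fewer than `min_volumes = 50` volumes yield an exclusion signal
   (a value, not an error, so cohort-level code can count exclusions).
5. **Band-pass** — 0.01–0.08 Hz, realized as a second-order Butterworth
   band-pass applied forward and backward (`signal::filtfilt`, zero
   phase) per voxel on the *concatenated* retained series; gaps left by
   censoring are ignored rather than modelled. Each series is demeaned
   first, which removes the DC edge transients of forward–backward
   filtering. The contract is the amplitude response, not the kernel: at
   TR = 2 s a 0.04 Hz component retains ≥ 90% amplitude and a 0.2 Hz
   component ≤ 10%; both bounds are asserted in the tests.

## Imaging features

22 spherical seeds (radius 6 mm by default; the radius is a configuration
parameter because only the coordinates of such seed sets are conventionally
published) in six networks give `22·21/2 = 231` pairwise Fisher-z
connectivities, ordered canonically (upper triangle, row-major, in
ROI-configuration order — the ordering is part of the model contract since
coefficients attach to names).

The 22 template-resemblance features need healthy-control templates: per
network, member-ROI series are averaged, correlated with every in-mask
voxel, Fisher-z transformed, and the per-voxel one-sample t across
controls (`t = mean/(sd/√n)`, signed, unthresholded) is the template. A
subject's resemblance feature for seed *i* is the spatial Pearson
correlation between the subject's seed-*i* z-map and the template of seed
*i*'s network. Correlation makes the feature invariant to affine
intensity differences between scanners — the property that justifies
comparing patients against a control-group template at all.

Degenerate cases are pinned down: correlations of ±1 are clipped at
`|r| = 1 − 1e−7` before `atanh`; zero-variance template voxels get the
capped value `±100` (resemblance only uses the template through a spatial
correlation, which is insensitive to the cap); zero-variance subject
voxels propagate as `NA` and are excluded voxelwise.

Clinical covariates enter as `age` (years), `duration` (months) and two
etiology dummies with traumatic injury as the reference level — the
standard coding when one level is the clinically favourable reference.

## Selection and fit

**Stage 1** keeps imaging features significantly correlated with the
follow-up CRS-R (two-sided p < `alpha = 0.05`, uncorrected). Uncorrected
is deliberate: the stage is a permissive screen ahead of the subset
search, and both feature families are screened identically.

**Stage 2 (CARS-PLSR)** runs `N = 50` iterations. Iteration *i* fits a
PLS1 model on a random 80% of rows using the retained variables, keeps the
top `⌈p·a·e^(−k i)⌉` variables by |coefficient| (the schedule decays from
*p* at *i* = 1 to 2 at *i* = N, i.e. `a = (p/2)^{1/(N−1)}`,
`k = log(p/2)/(N−1)`), resamples *p* candidates with probability
proportional to the normalized |coefficients| and retains the unique set,
then records 5-fold cross-validated RMSE of a refit on that set. The
minimal-RMSECV set wins. The starting set is also evaluated (an
"iteration 0"), so a retained set that collapses below two variables
still returns a best-so-far subset instead of failing. Run count,
sampling fraction and CV scheme are conventional defaults — none are
published for this design — and all are exposed in `pipeline_config()`.
Columns are standardized inside CARS so coefficient magnitudes are
comparable across features.

**PLS1** is NIPALS on centred data with `n_latent = 3` components (the
published choice; `n_latent = "cv"` re-derives it by 5-fold CV, with a
one-part-in-1e6 plateau tolerance so that components adding nothing
resolve to the smaller model). With as many components as the predictor
rank the fit equals the normal-equations solution — asserted at 1e-8 in
the tests — and extraction stops at rank exhaustion with a warning.
Only predictors are z-scored; the response stays on its natural 0–23
CRS-R scale so the cutoff is interpretable as a CRS-R-like score.

**sMC importance**: each centred predictor is regressed on the fitted
direction `ŷ = Xb`; `F_j = SSR_j / (SSE_j/(n−2))` with df (1, n−2).
Predictors collinear with ŷ report `Inf` (flagged, not capped);
an all-zero coefficient vector reports all-zero F. Passing `yhat`
directly lets unselected features be ranked against the model too.

**Cutoff**: threshold candidates are ±∞ and midpoints between consecutive
sorted unique scores — this makes exhaustive search exact, and the test
suite compares against brute force on 200 random instances. The criterion
is maximal sensitivity + specificity (Youden's J; the phrase "sum of true
positive and false negative rates" sums to 1 for every threshold and was
read as Youden), ties resolved to higher specificity then lower
threshold. A score exactly at the cutoff classifies as recovery. R²
throughout is the squared Pearson correlation between predicted and
observed scores.

## Internal validation

- **Optimism bootstrap** (B = 1000 by default): per replicate, resample
  rows with replacement, re-run *the whole pipeline* (screen, CARS, fit),
  and record R²(bootstrap sample) − R²(original data); the corrected
  estimate is apparent R² minus the mean optimism. Freezing selection
  outside the loop (`refit_selection = FALSE`) exists purely as a
  diagnostic: on null data it understates optimism by a wide margin, and a
  regression test guards that difference.
- **Out-of-bag voting**: per held-out subject, B bootstrap learning sets
  of size n−1 from the remaining rows each fit the full pipeline + cutoff
  and vote; ties and all-abstain default to non-recovery (the
  conservative clinical call, and deterministic). Degenerate resamples
  (one outcome class) abstain and are counted.
- **Permutation test**: permute the response, re-run the full pipeline per
  permutation, `p = (1 + #{perm ≥ obs})/(1 + B)` — the add-one form keeps
  p in (0, 1] with floor 1/(1+B).
- **Bland–Altman**: mean difference ± 1.96 SD and a one-sample t of the
  differences; zero-variance differences report p = 1 with a note.
- **Model comparison**: per bootstrap resample, clinical-only,
  imaging-only and combined models are re-fit and their accuracies
  recorded on each test table; reported are means ± SD,
  repeated-measures ANOVA across the three models, pairwise paired t, and
  Ψ — implemented as the RMS of per-replicate accuracy differences
  standardized by the pooled SD, carrying the sign of the mean difference
  (Ψ is named but not defined in the source literature; the signed form
  reports direction).

Every stochastic routine draws replicate seeds through `derive_seed()`
from one master seed, so any single replicate can be reproduced in
isolation and whole reports are byte-identical under the same seed.

## What the synthetic data emulates — and what it does not

`gen_cohort()` plants the structure the analysis assumes: a latent
recovery capacity `c ~ U(0,1)` per patient (controls: 1) drives the
resemblance features (loading 0.5 each), the default-mode × executive
connectivity (`atanh(strength · c)` with `strength = −0.3`: low-capacity
patients lose the anti-correlation), and — through a sparse linear model
with Gaussian noise, rounded and clipped to 3–23 — the follow-up CRS-R.
GOS is thresholded on that score (3 from CRS-R 14, 4 from 18), giving
roughly a quarter recoveries at the defaults, in line with reported DOC
cohorts. Default block covariance for ROI series is `ρ_within = 0.4`,
zero between networks, −0.3 for the default-mode × executive block at
full capacity — values that put pairwise correlations in the plausible
fMRI range. Clinical covariates are drawn uniformly/categorically within
reported cohort bands (age 18–71, trauma/stroke/anoxia ≈ 17/21/25,
log-normal duration clipped to 1–77 months), since only ranges, not
distributions, are published. Motion traces are a low-amplitude random
walk plus Bernoulli spikes with alternating sign (so consecutive spiked
volumes still produce super-threshold displacement).

Not emulated: scanner physics, slice-timing effects, lesioned anatomy,
spatial normalization error, physiological noise spectra, or site
effects. Passing tests therefore demonstrate that the *statistical
machinery* is correct and calibrated — not that the model generalizes to
real patients; external validity can only come from real multi-site data.

## Problem sizes and calibration checks

The test and acceptance suites size their simulations for tight feedback:
planted-subset recovery uses 5 informative of 50 features at n = 100
(noise SD 0.5) over 20 seeds; the null calibration of the optimism
bootstrap uses n = 60 cohorts at the study's imaging dimension (253 null
features) with B = 100, averaged over three independent cohorts — across
ten such cohorts the corrected R² is centred near zero (mean ≈ −0.02)
while apparent post-selection R² averages ≈ 0.48, but any single draw
scatters by ±0.2, which is why the check averages. Permutation-p
uniformity is checked at B = 99 over 200 repeats with a cheap statistic;
out-of-bag runs use B = 11–25. The full-volume imaging route is exercised
on small grids (16 × 16 × 8 voxels of 3 mm) with 4–8 ROIs; the shipped
22-ROI default set uses synthetic literature-inspired coordinates and is
an example — real studies supply their own coordinates via
`read_roi_config()`.

## Known limitations

- The band-pass ignores censoring gaps (concatenated filtering); a
  gap-aware filter is out of scope.
- CARS hyperparameters are conventions, not published values; conclusions
  that depend on them should be checked across settings.
- The optimism bootstrap is conservative under aggressive selection
  (bootstrap samples contain duplicated rows, overstating overfitting
  slightly); its corrected R² can undershoot zero on null data in any
  single draw.
- `run_pipeline()` orchestrates single-site runs; multi-site calibration
  and DICOM ingestion are out of scope.
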