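# docprog

Prognostic modelling for chronic disorders of consciousness (DOC) from
resting-state fMRI functional networks and clinical characteristics.

## The problem

After severe brain injury some patients remain in a vegetative state /
unresponsive wakefulness syndrome (VS/UWS) or a minimally conscious state
(MCS). Whether such a patient will regain consciousness within a year is a
central question for treatment and ethical decisions, and no single
behavioural or imaging marker answers it reliably. `docprog` implements a
multidomain approach: resting-state functional-network features and a small
set of clinical characteristics are combined in a regression of the
follow-up Coma Recovery Scale–Revised (CRS-R) total score, and the
predicted score is thresholded to classify each patient as *recovery*
(Glasgow Outcome Scale, GOS ≥ 3) or *non-recovery* (GOS ≤ 2) — at the
single-subject level.

## The model

For each patient, 22 spherical seed regions spanning six resting-state
networks (default-mode, executive control, salience, sensorimotor,
auditory, visual) yield **253 imaging features**:

- **231 functional connectivities** `z_ij = atanh(r_ij)`, the Fisher-z
  transformed Pearson correlations between all 22·21/2 pairs of seed time
  series, after preprocessing (initial-volume discard, 6 mm FWHM Gaussian
  smoothing, nuisance regression of 12 motion parameters + global signal +
  trend, censoring of volumes bracketing any framewise displacement
  FD > 1.5 mm, and 0.01–0.08 Hz band-pass on the surviving volumes);
- **22 template-resemblance features**, the spatial correlation between each
  seed's whole-brain connectivity z-map and the healthy-control group
  template (voxelwise one-sample t-map) of that seed's network.

These are combined with age, DOC duration and two etiology dummies
(stroke, anoxia; trauma as reference). The modelling chain is

1. **screen** — keep imaging features whose Pearson correlation with the
   follow-up CRS-R is significant (two-sided p < 0.05);
2. **subset** — competitive adaptive reweighted sampling with PLS
   regression (CARS-PLSR): variables are pruned along an exponentially
   decreasing retention schedule with weight-proportional resampling, and
   the subset with minimal cross-validated RMSE wins;
3. **fit** — PLS1 regression (3 latent variables, z-scored predictors) of
   the CRS-R score at follow-up, `score = b0 + Σ_j b_j (x_j − m_j)/s_j`;
4. **interpret** — significant multivariate correlation (sMC) F-values
   rank each predictor's variance along the prediction direction;
5. **classify** — an ROC cutoff maximizing sensitivity + specificity turns
   the predicted score into recovery / non-recovery (`score ≥ cutoff` ⇒
   recovery).

Validation utilities implement the full machinery around this model:
optimism-corrected bootstrap of R² with selection re-run inside every
replicate, out-of-bag majority voting, permutation tests, Bland–Altman
agreement, and bootstrap comparison of clinical-only vs imaging-only vs
combined models (paired t, repeated-measures ANOVA, Ψ effect sizes).

A first-class synthetic-data module generates cohorts, ROI time series with
six-network block covariance (including the default-mode × executive
anti-correlation that collapses with a latent "recovery capacity"), 4D BOLD
volumes and motion traces, so the whole chain is testable without any
patient data.

## Worked example

```r
library(docprog)

spec    <- cohort_spec(n_patients = 63, n_controls = 30, seed = 42)
cohort  <- gen_cohort(spec)
patients <- subset(cohort$subjects, group == "patient")
imaging  <- cohort$features[, 1:253]
clinical <- cohort$features[, 254:257]

model <- fit_prognostic_pipeline(imaging, clinical,
                                 y        = patients$crsr_t1,
                                 recovery = patients$gos_t1 >= 3,
                                 seed = 7)
model
#> <prognostic_model> 10 predictors (6 imaging), 3 latent variables
#>   apparent R2 0.925 | AUC 0.989 | cutoff 12.9

predict_score(model, cohort$features[1:3, ])
#>     id predicted_score imaging_subscore        label
#> 1 P001        17.91606         7.305817     recovery
#> 2 P002        16.81108         6.219775     recovery
#> 3 P003         8.88420        -2.215171 non_recovery
```

The selected imaging features include the anterior-medial-prefrontal and
dorsomedial-prefrontal resemblance features and the default-mode ×
executive connectivity `fc_DMN.aMPFC__ExecuContr.DMPFC` — which carries a
*negative* weight: patients who re-acquire that anti-correlation (a more
negative z) are predicted to score higher. Its sMC F-value (127) is among
the largest in the model; on this seed the top importances are the
salience/default-mode resemblance features (F = 305, 196, 128). Training
classification of this synthetic cohort: accuracy 0.921, sensitivity 1.00,
specificity 0.896.

Internal validation on the same cohort (see `optimism_bootstrap`,
`oob_accuracy`, `permutation_test`, `bland_altman`) shows the familiar
pattern: a high apparent R² shrinks after optimism correction, and on a
*null* cohort the corrected R² is centred near zero even though
post-selection apparent R² is large — the leakage the correction exists to
remove.

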