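# dysmetrix

Detection of oculomotor dysmetria from horizontal-saccade eye tracking.

Oculomotor dysmetria — hypometric (undershooting, with a same-direction
corrective saccade) and hypermetric (overshooting, returning to target)
saccades — is a hallmark of cerebellar ataxia. `dysmetrix` takes binocular
horizontal gaze-position time series recorded during the standard
horizontal saccade task (target stepping centre → ±16° → centre; both
eyes' normalized iris-centre X coordinate sampled at 240 Hz for 42 s) and
quantifies dysmetria with five families of signal statistics, then
classifies subjects with a PCA + linear-SVM model:

* **preprocessing** — scaling to [-0.5, +0.5], 200th-order FIR (Hamming)
  band-passes into 0.08–5 Hz and 5–25 Hz, order-200 median-filter blink
  removal (only excursions that return to their starting level are
  excised — overshoots and undershoots are preserved), relative PSD;
* **template matching** — zero-normalized cross-correlation with an ideal
  saccade pulse; score = mean of the first four correlation peaks and
  first four absolute troughs;
* **threshold surface** — area of the normalized trace beyond ±0.35
  (∫ max(x − 0.35, 0) dt + ∫ max(−0.35 − x, 0) dt); small for the sharp
  peaks of hypermetric saccades;
* **irregularity** — SampEn, local fuzzy entropy, dispersion entropy
  (DispEn), fluctuation DispEn, Higuchi fractal dimension, Lempel-Ziv
  complexity;
* **multiscale complexity** — MDE / MFE / MFDE over coarse-graining
  scales τ = 1..10 (`y_j = mean(x[(j−1)τ+1 .. jτ]`);
* **connectivity** — left↔right Pearson correlation, nonlinear
  correlation h², band coherence (Welch), Granger causality
  (ln(σ²_restricted / σ²_full), BIC order selection);
* **statistics** — two-sided Mann-Whitney U (exact for pooled n ≤ 12
  without ties), Hedges' g with small-sample correction, test-retest
  Pearson correlation;
* **classifier** — 14 features (template score, surface, DispEn, h²,
  MDE scales 1–10) → fold-internal standardization + PCA to ≥ 95%
  cumulative variance → linear SVM, stratified 10-fold CV, sensitivity
  defined with dysmetria positive.

Because no clinical recordings are deposited, the package includes a
synthetic saccade-task simulator (`generate_schedule()`,
`simulate_recording()`, `generate_cohort()`) that reproduces the task
structure — pseudorandom balanced left/right trials, dwell durations
uniform on 1.3–2 s, main-sequence saccade kinematics, corrective
saccades, conjugate binocular commands with per-eye gain asymmetry,
blinks, drift and noise — so every stage is testable end to end. See the
methods vignette (`vignettes/dysmetria-detection.Rmd`) for the model and
all parameter choices.

## Worked example

```r
library(dysmetrix)

sched <- generate_schedule(n_trials = 20, amplitude_deg = 16, seed = 1)
sched
#> <target_schedule> 20 trials, 16 deg, 67.2 s total

rec <- simulate_recording(sched, dysmetric_profile("hypermetric"), seed = 1)
rec
#> <gaze_recording> dysmetric, 240 Hz, 42.0 s (10080 samples/channel)

round(unclass(extract_features(rec))[1:6], 3)
#>    template_score threshold_surface            dispen                h2
#>             0.703             0.279             1.590             0.996
#>            mde_s1            mde_s2
#>             1.593             1.665
```

The template score (0.70) says this recording's excursions correlate
imperfectly with the ideal saccade pulse; the small threshold surface
(0.28 amplitude·s) reflects sharp overshoot peaks rather than sustained
plateaus; DispEn 1.59 and the rising MDE profile quantify the extra
irregularity that corrective saccades inject.

On a small synthetic cohort, the per-feature group table and classifier:

```r
recs <- generate_cohort(n_dysmetric = 12, n_control = 12, seed = 42)
feats <- feature_table(recs)
compare_groups(feats)[1:4, c("feature", "mean_pos", "mean_neg", "p_value", "hedges_g")]
#>             feature mean_pos mean_neg  p_value hedges_g
#> 1    template_score    0.684    0.709 1.41e-01   -0.579
#> 2 threshold_surface    1.011    1.624 7.83e-02   -0.874
#> 3            dispen    1.519    1.446 1.94e-02    0.829
#> 4                h2    0.996    0.999 3.66e-05   -1.461

X <- as.matrix(feats[, -(1:2)])
fit_evaluate(X, feats$label, k_folds = 5, seed = 42)
#> <classifier_report> n = 24 | accuracy 83.3% (sensitivity 75.0%, specificity 91.7%)
#>   components kept per fold: 3 3 3 3 3
```

`mean_pos` / `mean_neg` are the dysmetric / non-dysmetric group means:
dysmetric subjects show lower template similarity and surface area,
higher dispersion entropy, and weaker inter-eye coupling — the clinical
pattern. At n = 12 + 12 only the stronger features reach p < 0.05; the
full-size 72 + 80 cohort used by the test suite separates on every
feature family.

A command-line front end over the same functions is installed at
`inst/cli/dysmetrix`
(`dysmetrix simulate|features|compare|classify|all`).

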