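---
title: "Detecting oculomotor dysmetria from horizontal-saccade eye tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting oculomotor dysmetria from horizontal-saccade eye tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysmetrix)
```

## The problem

Oculomotor dysmetria — saccades that undershoot (hypometric) or overshoot
(hypermetric) the fixation target — is a hallmark of cerebellar ataxia.
During a horizontal saccade task the target steps from screen centre to a
peripheral location (16 degrees of visual angle) and back, and the
subject's horizontal gaze position is recorded for both eyes as the
normalized iris centre (NIC) X coordinate, the iris centre expressed
relative to the midpoint of the two eye-corner landmarks so that head
motion is largely compensated. A healthy trace is a clean staircase; a
dysmetric trace carries overshoot spikes, undershoot plateaus with
same-direction corrective saccades, or both.

`dysmetrix` implements the full signal-processing and machine-learning
chain for detecting dysmetria from such two-channel traces:
preprocessing, a matched-filter template score, a threshold-based surface
area, single-scale irregularity measures, multiscale complexity profiles,
left–right functional connectivity, non-parametric group statistics, and
a PCA + linear-SVM classifier — plus a synthetic saccade-task simulator
that makes every stage testable without clinical recordings.

## The synthetic task and cohort

Clinical recordings of this task are not publicly deposited, so the
package ships a generative stand-in whose defaults are the study
conditions used throughout the tests:

* task: 20 trials of centre → periphery → centre jumps, left/right order
  pseudorandom with balanced counts, dwell durations i.i.d. uniform on
  1.3–2 s, amplitude 16 degrees;
* recording: 42 s at 240 Hz, both eyes. A 20-trial task with these
  dwells lasts about 66 s on average, so a 42-s recording is necessarily
  an excerpt of the task; `simulate_recording()` therefore truncates by
  default (`on_overrun = "error"` instead demands that the schedule fit,
  and names the required duration);
* eye kinematics: each target jump elicits, after a 200 ms reaction
  latency, a sigmoidal (raised-cosine) position step whose duration
  follows a main-sequence rule (2.2 ms/deg + 21 ms). The raised cosine
  is used rather than a logistic because its compact support keeps
  fixation segments exactly flat, which makes the generator's own
  invariants (plateau flatness, gain recovery) exactly testable; any
  smooth monotone transition is equivalent for the downstream features;
* gains: the primary saccade covers `gain ×` the remaining target step.
  Controls draw their per-saccade gain from roughly N(0.94, 0.02) —
  healthy saccades slightly undershoot — with the subject-level mean
  drawn from U(0.91, 0.97). Hypometric subjects centre near 0.72,
  hypermetric near 1.25, and mixed subjects draw each saccade from a
  50/50 hypo/hyper mixture; dysmetric subjects follow the command with a
  corrective saccade (gain 0.85 of the residual error) after about
  150 ms;
* binocular coupling: saccadic commands are conjugate (Hering's law).
  The command is computed from the left (reference) eye's error and
  executed by both eyes; the right eye's primary amplitude is perturbed
  multiplicatively per saccade (SD `left_right_asymmetry`, about 0.02
  for controls and 0.06 for dysmetric subjects, echoing the greater
  binocular dysconjugacy of cerebellar disease) plus a partial (k = 0.5)
  vergence re-alignment so the inter-eye offset is stationary rather
  than a random walk. Corrective commands are shared verbatim — this
  matters: if each eye re-converged on the target independently,
  correction would *erase* the dysmetric asymmetry and invert the
  synchrony contrast between groups;
* nuisances: blinks are Poisson events (about 2–6 per minute) rendered
  as brief (100–200 ms) large excursions that return exactly to the
  pre-blink level; slow sinusoidal drift (< 0.08 Hz, amplitude 0.02 NIC
  units) models residual head-motion compensation error and is common
  mode across the two eyes; white measurement noise (SD 0.01 NIC) is
  independent per eye. Degrees map linearly to raw NIC units
  (16° = 0.4), a scale that the downstream range normalization removes.

What the simulator does *not* emulate: video processing and iris-tracking
artefacts other than blinks (dropouts, quantization), vertical eye
movements, pursuit intrusions, age effects, and the heterogeneity of real
cerebellar disease. Passing the direction-of-effect tests on this cohort
shows that the implemented statistics respond to over/undershoot
dynamics, corrective saccades and binocular dysconjugacy in the expected
directions — not that the classifier's synthetic accuracy transfers to
clinical data.

```{r simulate}
sched <- generate_schedule(n_trials = 20, seed = 1)
rec <- simulate_recording(sched, dysmetric_profile("hypermetric"), seed = 1)
rec
```

## Preprocessing

Each channel is scaled so its range is exactly [-0.5, +0.5] (the
amplitude convention every amplitude-sensitive statistic assumes), then
band-pass filtered with 200th-order windowed-sinc (Hamming) FIR filters
into 0.08–5 Hz and 5–25 Hz bands (plus 0.08–25 Hz for the multiscale
features), applied single-pass with group-delay compensation and reflect
padding. At 240 Hz a 201-tap filter cannot realize a sharp 0.08 Hz edge —
its transition band is a few hertz wide — so the low cutoff mainly
attenuates rather than removes the slowest drift; the order is
configurable for users with longer filters in mind.

Blink removal compares the signal with an order-200 running median:
samples deviating by more than 5 robust SDs are grouped into events
(hysteresis grows each event outward until the deviation falls below one
robust SD, so the whole excursion is covered, not just its tip), and an
event is excised — replaced by the running median — only if it is
shorter than 500 ms *and* the signal level after it returns to within
tolerance (0.1 × the robust signal range) of the level before it. That
return-to-baseline condition is what distinguishes a blink from an
overshoot or undershoot, which must be preserved for the analysis.
The band signal is then re-normalized to [-0.5, +0.5], matching the
convention under which the ±0.35 surface thresholds are defined.

## The two bespoke saccade statistics

**Template score.** An ideal saccade is a pulse: baseline, smooth rise
(50 ms) to +0.5, a 1.5 s hold (a typical target dwell), and a smooth
return. The trace is compared with this template by zero-normalized
cross-correlation (each window is Pearson-correlated with the template),
which makes the score unitless in [-1, 1] and invariant to local offset
and scale. Correlation peaks mark rightward excursions and troughs mark
leftward ones; after non-maximum suppression at 1.3 s (the shortest
dwell) and a detection floor at half the strongest same-sign extremum
(sub-threshold local maxima are noise, not saccades), the score averages
the first four peaks and first four absolute troughs in temporal order —
every 42-s recording contains at least four excursions per side. Taking
the four *largest* extrema instead is available via
`select = "largest"`, but it scores best-case matches and in simulation
is dominated by task luck rather than subject behaviour.

**Threshold surface.** The area of the band-passed, normalized trace
above +0.35 plus the area below -0.35 (trapezoidal integration,
amplitude·seconds). Accurate saccades hold sustained plateaus beyond the
thresholds and accumulate area; hypermetric saccades produce sharp peaks
that cross briefly, and variable dysmetric gains leave many plateaus
short of the thresholds — so dysmetric recordings score smaller areas.
The group ordering is stable across thresholds ±0.2 … ±0.4. By design
this statistic sees overshoots much more clearly than undershoots, which
is why it is one feature among fourteen rather than a classifier on its
own.

## Irregularity and complexity measures

Six single-scale measures quantify how irregular a band-limited trace
is; dysmetric traces, with their corrective saccades and variable
plateau levels, are more irregular in the 0.08–5 Hz band:

* **SampEn(m, r)** — negative log conditional probability that
  subsequences similar for m points (Chebyshev distance < r × SD) stay
  similar at the next point, self-matches excluded;
* **LocFuzEn** — the fuzzy variant: locally centred embedding vectors
  and membership `exp(-(d/r)^p)` instead of the hard threshold;
* **DispEn / FDispEn** — Shannon entropy of dispersion patterns: the
  signal is mapped through the normal CDF (fitted mean/SD) into c
  classes and m-length (or (m-1)-difference) class patterns are tallied;
* **Higuchi FD** — fractal dimension from the log-log slope of the
  Higuchi curve length over lags 1..kmax;
* **LZ76** — normalized Lempel-Ziv complexity of the median-binarized
  trace.

Defaults (m = 2, c = 6, d = 1, r = 0.2 SD, fuzzy power 2, kmax = 10) are
the customary choices in the respective method literature; all are
exposed in `default_config()$entropy`. Numerical conventions worth
knowing: the NCDF class mapping rounds half-up and clamps to [1, c];
SampEn on a constant series is 0 by definition (perfect predictability),
and when no template matches exist at all the estimate is undefined —
the function returns `NA` with a warning and downstream code treats the
slot as flagged-missing rather than imputing.

Multiscale profiles (MDE, MFE, MFDE) repeat DispEn / LocFuzEn / FDispEn
on coarse-grained versions of the 0.08–25 Hz band signal: scale τ
replaces the series by means of non-overlapping τ-windows, acting as a
low-pass at about fs/(2τ). The NCDF parameters (and the fuzzy tolerance)
are fitted at scale 1 and reused at every scale, so the profile reflects
changing dynamics rather than changing normalization; refitting per
scale is available. Scales 1–10 of MDE are the ten multiscale features
of the classifier.

## Left–right connectivity

Because both eyes execute nearly the same motor commands, their traces
are strongly coupled; dysmetria loosens the coupling. Four indices are
computed on band-filtered channel pairs:

* Pearson correlation;
* nonlinear correlation h² — variance fraction of one channel explained
  by a piecewise-linear regression on the other (a least-squares line
  per equal-count bin, 10 bins; the maximum over both directions).
  Per-bin least squares, rather than interpolation through bin means, is
  used because the latter leaves curvature bias inside bins and visibly
  under-scores smooth deterministic relations such as a cubic;
* band-averaged magnitude-squared coherence (Welch estimator: 4-s
  Hamming segments, 50% overlap). No installed package provides
  Welch-averaged cross-spectra, so the estimator is built directly on
  the FFT;
* Granger causality — log ratio of restricted to full residual variance
  of least-squares AR models (order by BIC up to 20, both models on a
  common sample), averaged over the two directions; both directions and
  the chosen orders ride along as attributes. Identical channels give
  index 0: the statistic measures *incremental* predictability.

## Group statistics

Two-group comparisons use the two-sided Mann-Whitney U test (exact null
distribution of U when the pooled sample is ≤ 12 without ties; otherwise
the normal approximation with midrank tie correction and continuity
correction) and Hedges' g (pooled-SD standardized mean difference with
the small-sample correction J = 1 - 3/(4N - 9)). Test-retest reliability
across two recording sessions is summarized by the Pearson correlation
over subjects. No multiple-testing correction is applied to the
per-feature table — the p-values are per-feature and should be read as
such. The exact/approximate switch at pooled n = 12 follows the smallest
cohort the package is expected to compare; the approximation agrees with
the exact enumeration to about 0.01 in p at pooled n = 16.

## The classifier

Each subject contributes 14 features: template score, threshold surface,
DispEn (0.08–5 Hz), h² (0.08–5 Hz), and MDE scales 1–10 (0.08–25 Hz) —
the best-performing technique from each family, with MDE contributing
its ten scales. Single-channel features are the mean of the two eyes
(configurable). Evaluation is stratified 10-fold cross-validation with
seeded shuffling; *within every training fold* the features are
standardized, PCA is fitted and truncated at the smallest component
count reaching 95% cumulative explained variance, and a linear SVM
(cost 1) is trained; the held-out fold is projected through the
training-fold transforms only. Fitting the scaler and PCA inside the
folds is the statistically sound choice (the alternative — global PCA —
leaks test-fold statistics into training and is deliberately not
offered as a default); metrics are reported on the pooled held-out
predictions, with dysmetria as the positive class, alongside per-fold
accuracies. Age and sex are not model inputs; on clinical data this
means group demographics can confound the features, a limitation to keep
in mind when interpreting any real-data result.

```{r classify}
recs <- generate_cohort(n_dysmetric = 12, n_control = 12, seed = 42)
feats <- feature_table(recs)
X <- as.matrix(feats[, -(1:2)])
fit_evaluate(X, feats$label, k_folds = 5, seed = 42)
```

## Problem sizes used by the test suite

The package's own checks run at deliberately chosen sizes: oracle
equivalence on ≥ 25 random short series (n ≤ 50) per estimator against
brute-force double-loop implementations; analytic-limit checks at
n = 5,000–50,000; direction-of-effect on a seeded 20 + 20 cohort at the
full 42 s × 240 Hz recording size; and the end-to-end classifier on the
full 72 + 80 cohort. On this synthetic cohort every feature family
separates the groups in the clinically reported direction (entropies and
MDE higher with dysmetria; template score, surface area, correlation and
h² higher in controls), and the classifier sits well above chance while
permuted labels collapse it to chance.

## Known limitations

* The synthetic cohort is far cleaner than clinical video-derived gaze
  data; its classification accuracy is an upper bound, not a forecast.
* The 201-tap FIR cannot realize the nominal 0.08 Hz edge at 240 Hz
  (documented above); results at the band edges reflect the realized
  response.
* The threshold surface is blind to undershoot by construction.
* Granger causality is computed in the time domain on band-filtered
  signals; a spectral decomposition of causality is out of scope.
* SampEn/LocFuzEn kernels are O(n²) (compiled); at 42 s × 240 Hz a call
  takes well under a second, but much longer recordings will feel it.
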