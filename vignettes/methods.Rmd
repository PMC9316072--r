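---
title: "Methods: simulating and detecting compensated shock from electrical cardiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting compensated shock from electrical cardiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecshock)
```

## The problem

Compensated shock is a circulating-volume deficit in which stroke volume
and cardiac output are already substantially reduced while the routinely
monitored vital signs — heart rate (HR) and arterial pressures — remain
within normal limits. A decrease of the echocardiographic stroke-volume
index of 20% or more is the accepted marker of that state. Electrical
cardiometry (EC, thoracic bioimpedance) measures stroke volume and a panel
of related indices (pre-ejection period PEP, left-ventricular ejection
time LVET, systolic time ratio STR = PEP/LVET, contractility index ICON,
stroke-volume and heart-rate variability, and several complexity
channels) non-invasively and beat-to-beat. Individually these channels
track hypovolaemia only moderately well; the question this package
addresses is whether a classifier combining many weak EC features can
detect the ≥ 20% stroke-volume decrease reliably, and how to evaluate such
a claim without leaking information across subjects.

`ecshock` implements the full analysis chain: a synthetic cohort
generator for graded lower-body negative pressure (LBNP) experiments,
end-of-stage window feature engineering, within-subject relational
observations, grey-zone ROC diagnostics, stage-wise nonparametric
statistics, and subject-grouped leave-two-out nested cross-validation of
five classifier families.

## The LBNP protocol and analysis windows

An LBNP chamber pools blood into the legs under sub-atmospheric pressure,
reversibly simulating graded central blood loss. The default
`lbnp_protocol()` is: baseline (0 mmHg, 600 s), three LBNP stages (−15,
−30, −45 mmHg, 420 s each), recovery (0 mmHg, 600 s). The first 120 s of
every LBNP stage and the first 420 s of recovery are excluded as
pressure-transition settling; all analysis uses the final 120 s window of
each stage. With these defaults a window can never overlap an excluded
interval; protocols that would violate this are rejected at construction.

## The synthetic cohort generator

No public data sets exist for this design, so the generator is a
first-class, tested component rather than a fixture. It emulates the
statistical structure the downstream analysis assumes:

* **Multiplicative stage responses.** Every generated parameter has a
  median level per stage relative to baseline (`stage_multipliers`).
  Entries for which published stage medians exist are set to them:
  SV-TTE 0.657, SV-EC 0.799, ICON 0.704 at −45 mmHg; the full HR profile
  (0.969, 1.022, 1.095, 0.92); SBP 0.953/0.948 at −30/−45; DBP
  1.027/1.038 at −45/recovery. The remaining entries (e.g. SV-TTE at
  −15/−30, the PEP/LVET/SVV/HRV profiles) are package defaults chosen for
  physiological plausibility and monotone progression with chamber
  pressure; they are explicit in `generator_config()` and can be
  overridden. SV-TTE recovery is set to 0.95, which makes roughly 3 of
  the 11 relational observations of a median subject positive (≈ 27%
  prevalence), matching the prevalence regime the analysis targets.
* **Subject heterogeneity.** A shared log-normal responsiveness effect
  (`between_subject_sd = 0.35`) scales each subject's log stage response,
  with small parameter-specific jitter (`response_jitter_sd = 0.10`).
  This reproduces the wide interquartile ranges of the relative changes
  and makes the ≥ 20% label genuinely subject-dependent near the decision
  boundary.
* **Correlation structure.** All volume-responsive parameters are driven
  by one latent per-(subject, stage) central-volume fluctuation
  (`latent_stage_sd = 0.04`), with signs reflecting physiology (PEP, SVV,
  HR, DBP move against volume). Parameter-specific stage-level log-noise
  (`stage_noise`) was calibrated once, by large-`n` simulation, so that
  the median intra-subject Pearson correlations with SV-TTE match the
  eight target values (SV-EC 0.856, ICON 0.806, PEP −0.839, STR −0.902,
  SVV −0.706, HRV 0.797, SBP 0.624, HR −0.576). The calibrated constants
  are the package defaults; `correlation_targets` documents the intent
  and is what validation tests compare against.
* **Beats.** Records are emitted beat-to-beat at heart-rate-determined
  intervals (RR jitter log-SD 0.03); each beat carries log-normal noise
  with parameter-specific coefficients of variation (1–20%). Values are
  stationary within a stage — the settling dynamics after a pressure
  change are not modelled, which is precisely why the protocol excludes
  the settling interval. Derived identities hold exactly per beat:
  SI = SV/BSA, CO = SV·HR/1000 (L·min⁻¹), CI = CO/BSA, STR = PEP/LVET,
  FTC = LVET/√RR (Bazett), MAP = (SBP + 2·DBP)/3. BSA uses the DuBois
  formula. Cardiac output is derived as the product SV·HR even though
  monitor documentation sometimes prints "SV/HR": only the product is
  dimensionally consistent with L·min⁻¹.
* **Echo reference.** Per (subject, stage), nine Doppler velocity-time
  integral samples are drawn around the latent target and
  SV-TTE = π(d/2)² · median(VTI) with the baseline LVOT diameter reused
  at every stage.
* **Missingness.** Echo acquisitions go missing independently per
  (subject, stage) with probability 0.055 by default, chosen so the
  expected share of relational observations invalid at one or both
  endpoints is ≈ 11% (1 − (1 − q)²). A second mechanism can drop whole EC
  recordings (`missingness_rate_absolute`, default 0 so that the
  330-observation count structure of a fully observed cohort holds
  exactly).

What the generator does **not** emulate: raw 200 Hz waveforms (the
complexity channels HRC/MSE/PNN/STAT are weakly-informative noise with
unit multipliers, since no stage-response values are available for them),
within-stage drift, baroreflex dynamics, or any neuro-humoral variables.
Passing tests therefore demonstrate correctness of the analysis machinery
and recoverability of the configured statistical structure — not that the
classifiers would reach the same accuracy on real recordings.

## Features and standardization

Each (subject, stage) window yields seven descriptors per parameter:
mean, median, SD (n−1), variance, moment skewness g1, excess kurtosis g2
and IQR (type-7 linear-interpolation quantiles). Zero-variance windows
return skew = kurt = 0 rather than NaN. With the default roster of 17
parameters (the development-only cycle counter is dropped) this gives
119 features. Standardization is a z-score scaler fitted on a reference
set; zero-variance features are recorded and dropped consistently at
apply time. Inside the cross-validation the scaler is always fitted on
training subjects only — the original description does not state whether
standardization was fold-local, and the leakage-safe choice is the
defensible one.

## Relational observations

Each timepoint is related to every earlier timepoint of the same subject;
the baseline enters once as a self-relation. A subject observed at all 5
timepoints contributes 1 + 5·4/2 = 11 observations; 30 subjects give 330,
29 give 319. The "relation" is the element-wise difference of
standardized features (target − reference): differences of z-scores are
scale-free, antisymmetric, and embed the baseline singleton naturally as
the zero vector (labelled negative). For single-marker diagnostics the
package additionally carries raw ratio markers (target window mean /
reference window mean), because cutoffs for quantities like relative HR
change are naturally read on the ratio scale. The label is positive when
the echo stroke volume at the target is ≤ 0.8 × the reference value
(boundary inclusive); observations missing the echo value at either
endpoint are emitted with `valid = FALSE` and excluded from modelling but
kept in the counts.

## Grey-zone ROC

`roc_auc()` builds the full ROC curve over candidate thresholds (midpoints
of adjacent sorted unique scores plus ±∞) and integrates trapezoidally;
with ties counted ½ this equals the Mann–Whitney rank statistic, which is
the identity the test suite enforces to 1e−12. `youden_best_cutoff()`
maximizes J = sensitivity + specificity − 1 with ties broken toward the
smaller threshold. `grey_zone()` recomputes the best cutoff on each of
B = 1000 bootstrap resamples of the observations and reports the mean and
the percentile 2.5/97.5% interval — the grey zone within which the marker
can neither rule the stroke-volume decrease in nor out. Percentile (not
BCa) intervals are used, and resampling is at the observation level by
default with a class-stratified option; replicates that degenerate to a
single class are skipped. Marker orientation is auto-detected as the
direction giving AUC ≥ 0.5 and recorded; inside the cross-validation,
marker orientation is learned on the training split and applied to the
held-out data.

## Stage statistics

Relative changes are per-subject ratios to baseline (baseline exactly 1;
zero/missing baselines excluded with a warning). Stage-versus-baseline
comparisons use the paired Wilcoxon signed-rank test via
`stats::wilcox.test` (zero differences dropped, exact distribution for
small tie-free samples, normal approximation with continuity correction
otherwise); an exhaustive sign-flip enumeration serves as the test
oracle, and a 10⁴-replicate null simulation checks the empirical type-I
rate at α = 0.05. Correlations are Pearson on raw values and Spearman on
average ranks, population-wide and per subject (≥ 3 points required),
with Cohen strength classes stepping at |ρ| = 0.1/0.3/0.5 (inclusive
lower edges).

## Nested cross-validation

The outer loop holds out two randomly selected subjects (without
duplicate pairs across repetitions while possible) and trains on the
rest, 29 times by default; all relational observations follow their
subject. Within each repetition, scaler fitting, feature selection and
hyperparameter tuning see training subjects only. The inner loop is
10-fold stratified cross-validation at the observation level (the outer
loop alone is subject-grouped), maximizing AUC.

Five algorithms are supported, with default selection methods per
algorithm: KNN uses all features; naive Bayes uses recursive elimination
(features ranked by symmetrical uncertainty, nested subset sizes
evaluated by inner-CV AUC); the radial SVM uses the gain-ratio filter;
the linear SVM and the random forest use the union of the three
entropy filters (information gain, gain ratio, symmetrical uncertainty,
computed after equal-frequency 5-bin discretization; features scored
positive by any filter are kept). A greedy forward wrapper (stop when no
candidate improves inner-CV AUC by > 0.01, cap 15 features) is available
for every algorithm. Cuff-pressure channels are excluded from model
features; they serve as the vital-sign comparators.

Grid search ties break toward the first point in ascending grid order.
When the optimum sits on a grid edge, the axis is extended past that edge
following its own step pattern (multiplicative for geometric grids such
as the radial-SVM sigma, additive otherwise), at most twice per axis;
bandwidths, costs and counts are kept positive. The naive Bayes
implementation models continuous features with Gaussian or kernel-density
class conditionals (`adjust` multiplies the bandwidth, `fL` smooths the
class priors); it is written in-package and cross-checked against an
independent Gaussian implementation in the tests.

Per repetition the tuned model's AUC on the held-out observations is
recorded (NA, not imputed, if the held-out split is single-class), along
with single-marker AUCs on the same observations. Model-versus-marker
comparison uses the two-sided unpaired rank-sum test.

## Problem sizes and numerical choices

The validation suite exercises the pipeline at the study's own scale
(29–30 subjects, 5 stages) and uses 200 subjects for generator-recovery
checks, 1000 bootstrap replicates for grey zones, and a benchmark
cross-validation configuration of a reduced random-forest grid
(mtry ∈ {2, 5, 8}, 120–150 trees) with 5 inner folds — enough to separate
signal (median test AUC ≥ 0.9 on a low-noise cohort) from the
within-subject permutation null (mean test AUC ≈ 0.5) while keeping a
full run in minutes on one core. The permutation-null diagnostic is built
into `run_nested_cv(permute_labels = TRUE)` so the leakage guarantee is
continuously assertable. All randomness is seed-controlled; identical
configuration and seed reproduce cohorts, bootstrap results and
cross-validation bit-identically.

## Known limitations

* The exact roster behind a specific published feature count cannot be
  reconstructed from monitor documentation; the roster here is explicit
  and configurable, and feature counts are data-dependent after
  zero-variance dropping.
* Stage medians not published anywhere are modelling choices; only the
  published entries should be read as empirically anchored.
* The generator's stationarity and log-normal noise assumptions are
  simplifications; classifier accuracies obtained on synthetic cohorts
  bound the machinery's correctness, not clinical performance.
* Entropy-filter "keep if score > 0" is permissive on continuous
  features (finite-sample information gain is almost surely positive),
  so the union filter mainly removes constant or near-constant channels;
  the wrapper and recursive-elimination methods provide aggressive
  alternatives.

## Worked example

```{r example}
cfg <- run_config(n_subjects = 30, seed = 7,
                  models = list(model_spec("rf", grid = list(mtry = c(2, 5, 8)),
                                           ntree = 150, inner_folds = 5)),
                  bootstrap_B = 1000)
report <- run_pipeline(cfg, out_dir = "ecshock-out")
print(report)
```
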