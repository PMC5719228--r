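---
title: "Modelling unplanned ICU transfers from ward event streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling unplanned ICU transfers from ward event streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Children who deteriorate on a general inpatient floor and require an
unplanned transfer to the intensive care unit have markedly worse outcomes
than children admitted to the ICU directly. Early-warning scores flag some of
these deteriorations, but they use a handful of manually charted inputs and
rarely exploit trends. `wardwatch` implements a full retrospective modelling
pipeline for this problem: it identifies unplanned floor-to-ICU transfers
from admission–discharge–transfer (ADT) records, assembles a matched control
group, converts the irregular clinical event stream of each encounter into a
sparse feature vector at a chosen *prediction horizon*, fits heavily
regularized classifiers, and evaluates how discrimination behaves as the
horizon grows.

Because the clinical data such a study uses are private, the package ships a
seeded synthetic EHR generator with a known ground-truth deterioration
process. Every stage of the pipeline is exercised and tested against that
generator; nothing in the package depends on access to real data.

## Cohort construction

**Cases.** Candidate transfers are floor segments immediately followed by an
ICU segment in the ADT stream. Transfers out of the emergency department,
operating room or post-anesthesia care unit, transfers from ICU to ICU, and
transfers into the NICU are excluded. A candidate becomes a *case* when at
least one of five configurable criteria fires in a window around the
transfer (default 2 h before to 12 h after, closed on both ends): initiation
of CPAP/BiPAP or invasive ventilation; vasopressor administration; an NS/LR
fluid bolus of at least 20 mL/kg; an emergent procedure or resuscitation
event; or an ICU-only medication on the medication administration record.
The criteria are plain data (`default_criteria()`, or YAML via
`read_criteria()`): the attribute lists, the volume threshold and the window
are configuration, not constants. A case additionally carries a *critical
deterioration event* (CDE) flag when positive-pressure ventilation,
vasopressors, fluid resuscitation or an emergent procedure occurs in
[transfer − 2 h, transfer + 12 h]; ICU-only medications deliberately do not
qualify, so the CDE set is a strict subset of the case set. The unit of
analysis is the transfer: an encounter with two qualifying transfers
contributes two case records.

**Controls** are encounters with at least 24 hours of floor time and no ICU
segment, sampled stratified over (age bin × diagnosis group) cells so the
control distribution tracks the case distribution, at roughly `ratio`
controls per case (largest-remainder allocation of the control budget across
cells; an exhausted cell falls back to the nearest age bin within the same
diagnosis group, with a message). A control's event time is its floor
departure. Finally, any record — case or control — with fewer than 8 hours
of floor time before its event is removed; the 8-hour boundary is inclusive,
and floor hours are the summed durations of all floor segments before the
event time.

Age bins are `<1`, `1–4`, `5–11`, `12–17`, `≥18` years; diagnosis groups are
opaque strings. Both are matching strata only — the package makes no claims
about them clinically.

## Feature extraction

A prediction instance is a cohort record plus a horizon *h*: the prediction
time is the event time minus *h* hours, and only events strictly before that
time may contribute. Records whose prediction time precedes floor arrival
are dropped. Per element type, lookback windows end at the prediction time:
24 h for vitals, 72 h for labs, acuity scores and nursing assessments, with
a nested 6 h sub-window for acuity recency features. All windows are open
intervals `(t_pred − w, t_pred)`: an observation charted exactly at or after
the prediction time never enters a feature. This is the stricter of the two
defensible boundary conventions and is what the leakage tests enforce —
perturbing every event at or after the prediction time must leave every
feature vector bit-identical.

The operator families, per element type:

* **Vitals** — least-squares slope in units/hour (time origin at the window
  start; any affine choice works, one must be fixed), its magnitude, a
  sign-of-slope indicator; the risk category (C1–C4, age-stratified
  boundaries) of the maximum, minimum, average, newest and oldest value
  (the average is binned after averaging); and a category histogram
  normalized to sum to 1.
* **Labs** — each value is binned Low/Normal/High by reference range;
  features are the (2nd-newest → newest) category pair, a category
  changed/unchanged indicator, ratio bins for newest/oldest and
  newest/2nd-newest at the thresholds >{1.25, 1.5, 2, 3} and
  <{0.8, 0.67, 0.5, 0.33} (omitted when the reference value is 0), a
  presence indicator, and the last category.
* **Acuity scores** — indicators "minimum/maximum/newest is 0" or "> k" for
  k = 0…9; full-window and 6 h sub-window slopes with magnitudes; and
  overlapping count indicators "number of measurements in the last 6 h >
  {0, 1, 2, 4, 6, 10}".
* **Nursing assessments** — one 0/1 indicator per distinct attribute–value
  pair observed in the window plus a newest-value indicator per attribute.
  Multiplicity is ignored (presence only); counting occurrences would be a
  straightforward sensitivity analysis.

Missing data are never imputed: an element type with no observations simply
contributes no features, and a type with a single observation contributes no
trend features. Ties in time are resolved by stable (timestamp, arrival)
order, which fixes "newest" and "2nd newest" deterministically. Scalar
features (slopes and magnitudes) enter the design matrix as real values,
everything else as 0/1 indicators.

The C1–C4 vital boundaries and lab reference ranges are an editable YAML
table (`inst/extdata/binning.yaml`). They are configuration: the tests
establish the correctness of the operators given a table, not the clinical
validity of any particular table. The shipped defaults are synthetic,
age-stratified values centered on the generator's baselines.

The feature *vocabulary* (name → column index) is fit on training instances
only and then frozen; names that first appear at evaluation time are
silently dropped. Instances serialize to SVMlight sparse format with a TSV
vocabulary.

## Models

Both model families maximize the penalized log-likelihood

$$L(D, W) = \sum_i \log p(y^{(i)} \mid x^{(i)}) \;-\; a_1 \lVert W \rVert_1
\;-\; a_2 \lVert W \rVert_2^2$$

over all layer weights *W* (biases unpenalized, which preserves
calibration), by minibatch stochastic gradient ascent. With no hidden layers
this is elastic-net logistic regression,
$p(y{=}1\mid x) = 1/(1+e^{-wx})$; with hidden layers each layer applies a
rectified-linear activation $g(x) = \max(0, x)$ and the output layer is a
single logistic unit. The same code path serves both, so the degenerate MLP
*is* logistic regression, bit for bit.

Numerical choices worth stating:

* The L1 term is applied as a proximal soft-threshold after each gradient
  step rather than as a raw subgradient, so weights reach exact zeros and the
  penalty performs genuine feature selection. The analytic gradient (used in
  the tests' finite-difference check) uses the sign subgradient and is exact
  away from zeros.
* The L2 term is read as the conventional squared elastic-net penalty
  $a_2 \sum W^2$; an unsquared-norm variant is available via
  `l2_squared = FALSE`.
* Dropout is inverted dropout on hidden activations during training only;
  prediction uses the full network unscaled. Default rate 0 (0.5 is the
  conventional choice for the MLP architecture of 60–40–40 hidden units with
  `a1 = 0.0003`).
* Defaults `a1 = 0.001`, `a2 = 0.01`, minibatch 32, 30 epochs, step-decay
  learning rate (0.05 × 0.9 per epoch). The schedule and epoch count are
  tunables exposed in `model_hyperparams()`, meant to be tuned by
  cross-validation rather than trusted; `cross_validate()` performs
  stratified k-fold selection by mean fold auROC, breaking ties toward
  stronger regularization (larger `a1`, then `a2`) and refolding with a new
  seed if a fold ends up single-class.
* Logistic models start from zero weights (the uninformative model); MLP
  layers use scaled normal initialisation. Training is deterministic under a
  fixed seed, covering initialisation, shuffling and dropout masks.

## Evaluation

`auroc()` is the Mann–Whitney statistic — the probability a random case
outscores a random control, ties counting ½ — computed via ranks and tested
against exhaustive pair counting. Confidence intervals and model
comparisons use the DeLong structural-components variance via pROC; the
paired test assumes both models were scored on the identical instance set,
which is how the experiment harness produces scores. A degenerate
zero-variance input collapses the interval to a flagged point.

The operating point is the largest threshold whose sensitivity still reaches
the target (default 0.80); specificity is read there, and the positive
predictive value follows the closed form
$\mathrm{PPV} = s\,p / (s\,p + (1-s_p)(1-p))$ at an assumed prevalence
(default 1.3%, interpreted as instance-level prevalence). The threshold is
chosen on the evaluation scores, mirroring a post-hoc operating point; a
train-derived threshold is a one-line variant since `spec_at_sensitivity()`
accepts any score vectors.

Experiments split the cohort temporally by encounter admission date
(default 75/25), mirroring a calendar-year evaluation design, and subsample
training controls to roughly 1:5 cases:controls; the test split is never
subsampled. The harness runs single, additive (vitals → +labs → +acuity →
+assessments), ablation (All−X) and full feature-set configurations at a
shared horizon, per-horizon sweeps, and the full train-by-eval cross-horizon
grid, reusing one featurization of each evaluation horizon across all
trained models.

## The synthetic generator

The generator is the package's substitute for private hospital extracts, and
its defaults define the study conditions the tests assert under. Each
encounter has an admission date (uniform over four simulated years, so the
temporal split is meaningful), an age drawn from binned distributions and a
diagnosis group. Cases hold a floor stay (log-normal, median 48 h, minimum
20 h) followed by an ICU stay; controls a floor stay only (median 60 h,
minimum 26 h ≥ the 24 h pool rule). About 30% of encounters have a
preceding ED segment.

Observations arrive as homogeneous Poisson processes per element type —
vitals every 2 h on average, labs once per analyte-day, acuity scores and
assessments four per type-day — with 10% of observations dropped at random
as missingness. A latent severity ramp is 0 until 8 h before the transfer
and rises linearly to `effect_size` (default 2, in within-type standard
deviations) at the transfer; it shifts vitals and labs toward their abnormal
direction, inflates acuity scores, and moves assessment values down their
ordered vocabularies toward abnormal. Controls carry no signal
(`effect_size = 0` reduces cases to the same null, which is how the
chance-level test works). Cases receive one or two intervention events in
[transfer − 1 h, transfer + 8 h], drawn from the same vocabulary the cohort
criteria match on; 20% of the draws are ICU-only medications, producing
cases that are not CDEs.

The linear ramp is the simplest monotone signal that makes horizon
degradation testable: a model predicting at horizon *h* sees at most the
first `8 − h` hours of drift, so discrimination must fall as *h* grows and
vanish for `h ≥ 8`, and a model trained at one horizon is best matched to
evaluation at the same horizon — the diagonal-dominance pattern the grid
tests assert. What the generator does **not** emulate is equally important
for interpreting green tests: real physiology (no circadian structure, no
autocorrelation beyond the ramp, no age-dependent baselines), informative
sampling (charting frequency does not rise with acuity), inter-feature
correlation, vocabulary drift across institutions, or free-text content.
Passing tests demonstrate the pipeline's correctness and the qualitative
horizon behaviour under a known signal, not clinical performance.

## Problem sizes and determinism

The test suite runs the full horizon grid on a cohort of 320 cases and
1,600 controls (16 trained models, a 16×16 evaluation grid) and the weight
recovery check at 5,000 instances × 500 features; the acceptance script uses
160 cases and 800 controls for its end-to-end run. These sizes were chosen
so the qualitative assertions (horizon decay, diagonal dominance, sign
recovery) sit far from their thresholds while the whole pipeline remains
comfortable on a single CPU. Every stochastic step — generation, control
sampling, subsampling, fold assignment, initialisation, shuffling, dropout —
is seeded, and identical inputs plus seeds reproduce byte-identical outputs
end to end.

## Known limitations

* The five case criteria and the binning tables are synthetic defaults;
  using the pipeline on real extracts requires institution-specific
  configuration of both.
* The severity model is a single shared ramp; it cannot represent
  heterogeneous deterioration trajectories or relapsing courses.
* `spec_at_sensitivity()` picks the operating threshold on the evaluation
  scores; for prospective use a threshold must be frozen on training data.
* The MLP is a plain feed-forward network trained by SGD; no early stopping,
  momentum or adaptive step sizes are implemented.
* Repeated transfers of one patient are treated as independent records;
  no within-patient clustering is attempted.
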