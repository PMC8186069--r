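---
title: "Classifying Caprid behaviour from collar accelerometry and magnetometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Caprid behaviour from collar accelerometry and magnetometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprax)
```

## The problem

Collar-mounted biologgers record tri-axial acceleration (surge *x*, sway
*y*, heave *z*, in g) and tri-axial magnetometry at tens of hertz. Given a
span of recording annotated with observed behaviours, a classifier can be
trained to translate the raw signal into an ethogram — and then applied to
animals that cannot be observed. `caprax` implements that workflow for
Caprids (ibex, goats and relatives), including the questions that decide
whether such a model is usable in practice:

* how far can the sampling frequency be lowered before accuracy suffers;
* which of the many candidate signal variables are worth keeping;
* how much is accuracy inflated by validating on windows from the same
  individuals that trained the model (random split) rather than on
  held-out animals (individual split);
* whether a model trained on one species (a domestic surrogate) can
  predict another, and whether matching sex helps in dimorphic species;
* whether the slope of terrain (flat / uphill / downhill) can be read off
  the posture signal during locomotion.

The observational data such a study uses are rarely redistributable, so
the package ships a synthetic cohort generator with the statistical
structure the classifier relies on. Every stage of the pipeline is
exercised end to end on simulated cohorts whose ground truth is known.

## Signal model

The device orientation is modelled as intrinsic heading (about the world
vertical), then pitch (about sway), then roll (about surge). With pitch
$p$ and roll $r$ the gravity vector in the device frame is

$$ g = (\sin p,\; \cos p \sin r,\; \cos p \cos r), $$

so pitch is recoverable as $\arcsin$ of the static surge component and
heading leaves the accelerometer untouched — heading dynamics are
observable only through the magnetometer, which reads the local field
vector rotated by the same orientation. This is what makes "do
magnetometry variables help?" a well-posed question for the simulator:
behaviours that differ only in how fast the animal turns are
indistinguishable by accelerometry.

Each behaviour bout contributes:

* a posture (behaviour pitch/roll, plus the individual's collar offset,
  plus the terrain slope angle for locomotion — uphill positive);
* a gait oscillation: fundamental sinusoid at the stride frequency with
  one harmonic, per-axis amplitudes, heave leading surge by 90°;
* a bounded heading random walk with behaviour-specific volatility;
* additive Gaussian sensor noise (defaults: 0.02 g, 0.01 field units).

Slope categories follow the field convention: flat within ±2.5°, uphill
above, downhill below. Uphill/downhill bout angles are drawn from 5–15°
and scale gait amplitude by 1.1/0.9 (effort). A `slope_pitch_effect`
switch removes the postural tilt while keeping the labels, which is how
the package demonstrates that slope classification rests entirely on the
posture cue.

### The default cohort

The defaults emulate a two-species zoo deployment: 6 ibex-like (2 male, 4
female) and 9 goat-like (all female) individuals, 30 minutes of labelled
recording each at 40 Hz. Behaviour bout probabilities follow the duration
shares of the reference ethogram (`caprid_ethogram()`), so eating and
standing dominate and shaking is rare — the class-imbalance regime the
down-sampling stage exists for. Bout durations are log-normal (median
18 s, log-sd 0.6). The ibex-like species strides at 0.6× the goat-like
frequency (longer legs), individual animals get log-normal stride and
amplitude scales (sd `individual_sd`, default 0.15) and Gaussian posture
offsets with sd `30 × individual_sd` degrees — one knob controls all
individual variation, which is what the individual-split experiments
vary. Males are modelled as larger animals: stride ×0.7, amplitude ×1.5
and a systematic +8° collar-pitch shift. Those dimorphism defaults were
set so that male morphology visibly degrades cross-species prediction,
the mechanism the sex-specific transfer variant probes; they are
stipulations, not fitted values, as are all per-behaviour amplitudes and
stride frequencies — the study this package operationalises reports
durations, not signal parameters.

What the simulator does *not* emulate: biomechanically realistic gait
waveforms, collar swing, transitional ambiguity between behaviours, and
observer mislabelling. Passing tests on synthetic cohorts therefore show
that the pipeline recovers structure that is present by construction;
they do not certify accuracy levels on real deployments.

## Windowed variables

Features are computed per non-overlapping 2 s window, labelled by the
behaviour interval containing the window midpoint; windows straddling an
interval boundary are dropped rather than given mixed labels. The static
component of acceleration is a centred 2 s running mean per axis
(shrinking at the edges); dynamic acceleration is raw minus static, so
the decomposition reconstructs the raw signal exactly in its defining
subtraction form. VeDBA is the Euclidean norm of the three dynamic axes,
smoothed VeDBA its 2 s running mean; pitch and roll are arcsines of the
normalised static surge and sway. The oscillation-amplitude variables
(PSD1X/Y/Z) take the dominant non-zero-frequency periodogram amplitude of
the window. Five magnetometry variables summarise per-axis variability,
field-norm variability and the mean angular change of the normalised
field vector. The full registry (`feature_registry()`) holds 39 named
variables, 34 without magnetometry.

Numerical edge cases are pinned down deliberately: the running-mean
half-width is floored at one sample so the 1 Hz pipeline cell stays
defined; oscillation amplitudes are computed for any window of ≥ 2
samples (at 1 Hz a 2 s window has exactly 2); constant features enter
correlation pruning as $r = 0$ with a warning; undefined precision or
recall (empty classes) is reported as 0 and flagged rather than dropped
silently.

Lowering the sampling frequency is decimation — every $k$-th sample —
applied *before* decomposition; the two operations do not commute and the
pipeline fixes this order.

## Model and refinement

The classifier is a 500-tree random forest (Gini splitting, √p variables
per split, bootstrap per tree), exposing per-feature mean Gini decrease
and the out-of-bag error trace. Feature refinement has two stages:

1. **Correlation pruning** — repeatedly remove the less important member
   of the most correlated pair with $|r| \ge 0.70$, until no pair
   remains; deterministic (pairs by descending $|r|$, importance ties by
   name) and idempotent.
2. **Recursive feature elimination** — walk a size grid from large to
   small, keeping the top-size features by importance *recomputed at each
   step*, scoring each size by stratified k-fold cross-validation, and
   selecting the size that maximises CV accuracy with ties to the
   smaller set.

Class balancing down-samples, whole windows at a time, any class whose
labelled duration exceeds the pooled median class duration of the
reference ethogram (560.4 s); behaviour reduction drops aggression,
grooming and shaking, the classes least relevant to downstream ecology.

## Validation designs

`split_random()` is stratified by class at a 60/40 train/validation
fraction; because consecutive 2 s windows are autocorrelated and every
individual appears on both sides, it estimates performance on *observed*
animals and flatters the model. `split_by_individual()` enumerates all
subsets of individuals whose row share lies within ±10 percentage points
of the 60% target and emits one fold per subset (capped, seeded),
estimating performance on *unobserved* animals. The gap between the two
is a finding, not a flaw, and the package keeps it visible rather than
"correcting" it. Metrics are the standard confusion-matrix set: overall
accuracy (trace over total — the one-vs-rest aggregate form some sources
print is available behind `accuracy_form = "printed"` for audits),
per-class precision, recall and F1, and fold means ± sd.

Cross-species transfer trains on one species' full table and evaluates on
the other, restricted to shared behaviours (climbing and browsing are
species-specific and excluded); a sex filter gives the sex-specific
variant. The chance floor comes from retraining on labels redrawn i.i.d.
with the empirical class proportions.

## Problem sizes and determinism

Simulation, splitting, training and label redraws are all seeded; one
master seed fans out to per-individual and per-stage child seeds, so any
cohort, fold or report is reproducible in isolation. The shipped
experiment sizes — the 15-individual default cohort for the split-design
comparison, a 12-individual 10-minute cohort for transfer, 300-tree
forests for grid cells and 500 for headline fits, three-fold caps on
individual splits — were chosen so the full suite runs comfortably on a
single CPU while leaving every compared effect (frequency degradation,
split-design gap, transfer loss, null floor) far larger than its
seed-to-seed variability.

## Known limitations

* Simulator parameters are stipulated, not estimated from recordings;
  absolute accuracies on synthetic cohorts say nothing about absolute
  accuracies on real collars.
* The generator emits clean bout boundaries; real transitions smear
  labels across windows and would lower all accuracies.
* Statistical comparison of pipeline variants is descriptive (tables and
  ordered effects); formal significance tests on simulated cells would
  test the simulator, not the method.
* The RFE stage is the slow path (k-fold CV per candidate size); the
  sweep stage therefore refines by correlation pruning only, with full
  RFE available through `refine_features()`.

## A worked example

```{r, eval = FALSE}
library(caprax)
cfg <- simulation_config(n_individuals = c(ibex = 3, goat = 3),
                         total_duration_s = 300, seed = 42)
cohort <- generate_cohort(cfg)
ft <- cohort_features(cohort, target_hz = 10)
res <- evaluate_design(ft, "random", n_trees = 200, seed = 1)
res$summary
```

The README shows the same pipeline with the numbers it prints and the
`scripts/acceptance.R` entry point that recomputes every headline
quantity from scratch.
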