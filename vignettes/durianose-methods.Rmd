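---
title: "Methods: e-nose signal processing for durian pest and ripeness detection"
author: "durianose maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: e-nose signal processing for durian pest and ripeness detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durianose)
```

## The measurement problem

Mealybug infestation changes the volatile-organic-compound (VOC) profile a
durian fruit emits, and so does ripening. An electronic nose — an array of
partially selective metal-oxide-semiconductor (MOS) gas sensors — can
fingerprint those changes cheaply, but the raw signal of a MOS element is
dominated by nuisance structure: heating transients after switching the air
path, slow resistance drift, and strong temperature/humidity response. The
package implements the full chain that turns per-second multichannel sensor
streams into statistical answers about infestation status and ripeness
stage, together with a seeded simulator of such streams so every stage can
be validated against known ground truth.

Two acquisition designs are supported as presets of one code path
(`phaseSchedule()`):

* **survey** — a 13-sensor array (nine MQ-series elements and the four
  channels of a Grove Multichannel Gas Sensor v2: GM102B, GM302B, GM502B,
  GM702B) measures room air for 100 s and then sample air for 100 s;
* **prototype** — the 4-channel GM module runs relay-controlled cycles of
  reset (charcoal-filtered air, 300 s), sampling (100 s) and rest (200 s).

## The slope statistic and its extraction

The survey's per-sensor odor statistic is a *net emission rate*: medians are
taken over consecutive 10-s windows of each 100-s phase
(`windowMedians()`), an ordinary-least-squares slope is fitted through the
ten medians (`olsSlope()`), and the room-air slope is subtracted from the
sample-air slope (`netOdorSlope()`). Median prefiltering rejects spikes;
the room-air subtraction cancels whatever contaminates both phases alike —
sensor drift and, to first order, the heating transient.

Numerical conventions worth stating:

* Windows are half-open `[kw, (k+1)w)` over 0-based 1-s sample indices;
  even-count windows use the mean of the two central order statistics.
* The regression abscissa is the *window midpoint in seconds* (5, 15, …,
  95 for the default 100 s / 10 s), so slopes are per second. An
  index-based abscissa would scale every slope by the window width; this
  choice must be kept in mind when comparing against externally computed
  slopes.
* On a noise-free linear ramp the median of a window equals the ramp value
  at the window's centre, so the extracted slope is exact to floating-point
  precision for any window width that divides the series length. The
  warm-up transient breaks this exactness (medians are not additive): with
  the transient on, the room-air subtraction cancels it only to about
  1e-4 relative, which is one of the reasons the prototype discards early
  sampling readings instead.
* Up to 5 % of dropped seconds per phase are linearly interpolated during
  cycle segmentation (serial links lose lines in practice); more is an
  error, as is any phase sequence violating the schedule grammar.

The survey instrument logs a *normalized* signal, so its slopes are
relative rates of signal change per second — that is the only scale on
which net slopes of order 1e-6 to 1e-4 per second are resolvable, and it is
the scale of the package's survey effect-size table
(`surveyEffectSizes()`). The prototype, by contrast, streams raw ADC counts
(baselines of a few thousand), and its preprocessing handles the scale
explicitly, as follows.

## Prototype preprocessing: trim, correct, normalize

Each prototype sampling phase yields 100 readings; the first 70 are
discarded and the last 30 retained (`trimSampling()`), because the
transition from control to sample air leaves a warm-up/equilibration
transient on the early readings. The retained readings are corrected for
environment and normalized (`cycleFeatureSet()`):

1. **Environmental correction** (`fitEnvCalibration()`,
   `applyEnvCorrection()`). A per-sensor multiple OLS of 24 h of
   charcoal-filtered control-air readings on temperature and relative
   humidity gives `beta_T` (a.u./°C) and `beta_H` (a.u./%RH);
   corrected = raw − beta_T (T − T_ref) − beta_H (RH − H_ref), with the
   reference points being the calibration means. The two regressors are fit
   *jointly*: T and RH covary diurnally, so marginal fits would be biased.
   A constant or collinear T/RH profile is rejected as a calibration error.
2. **Two-step normalization** (`normalizeCycle()`). Each reading is divided
   by the anchor value and then re-expressed as a relative change
   (`x/anchor − 1`; a log-ratio variant is available). The anchor is the
   *initial value of the sampling phase* (captured before the trim). This
   choice is load-bearing: anchoring at the first *retained* reading would
   divide out the response amplitude itself — every measurement's feature
   cloud would collapse onto the within-measurement residual dynamics and
   class/day information would be destroyed. The trimmed-first variant is
   kept behind a switch for sensitivity analyses.

The resulting feature table (an `OdorFeatureSet`, a
`SummarizedExperiment` with one row per channel and one column per retained
reading) is dimensionless, scale-invariant in the raw units, and carries
class/fruit/day labels in its `colData`.

## Statistical inference

**Per-sensor screening** uses the Brunner–Munzel test
(`brunnerMunzel()`): a midrank-based estimate of the relative effect
P(X < Y) + ½P(X = Y), studentized with the Welch–Satterthwaite-type degrees
of freedom of the original test and referred to a t distribution,
two-sided. It tolerates unequal variances and distributions — the actual
situation at five fruits per group with wildly different per-group spreads.
At n = 5 + 5 the statistic is a function of the rank configuration only and
takes a small discrete set of values, so identical statistics for different
sensors are expected rank coincidences, not errors. No multiple-testing
correction is applied across the 13 sensors (raw p-values are reported, as
is conventional for a screening table); `screenSensors()` documents this
caveat. Completely separated samples leave the variance estimator undefined;
`brunnerMunzel()` raises an informative error, while the screening report
records the limiting behaviour (infinite statistic, p = 0).

**Group structure** is tested with ANOSIM (`anosimTest()`): with midranks
of all pairwise distances, R = (mean between-group rank − mean within-group
rank)/(M/2), M = n(n−1)/2, so R = 1 exactly when every between-group
distance outranks every within-group distance and R ≈ 0 under exchangeable
labels. The p-value is by relabeling — exact enumeration of all distinct
label permutations when there are at most 20 000 of them, otherwise seeded
Monte-Carlo with p = (#{R* ≥ R} + 1)/(B + 1). Distances are Euclidean on
the corrected, normalized features by default (Bray–Curtis behind a
switch); since ANOSIM is rank-based, any monotone transform of the
distances leaves R unchanged.

**Ripeness staging** (`pcaFit()`, `assignRipenessStages()`): per fruit,
daily score clouds in PC1–PC2 (channels centered and unit-variance scaled:
they share units but differ in dynamic range) are summarized by mean and
covariance; a day *overlaps* the cracking day when the two 95 %
coverage ellipses (Mahalanobis radius √χ²₀.₉₅(2 df)) intersect. Days before
the cracking day that do not overlap it are `before_ripening`, overlapping
days `ripened`, later non-overlapping days `after_ripening`. Ellipse
intersection is decided by testing the centers and 360 boundary points of
each ellipse against the other — deterministic and robust for the
2-D case; degenerate (collinear) day clouds receive a tiny ridge. Days with
fewer than three readings have no covariance and are left `unassigned` with
a warning.

**Classification** (`ldaFit()`, `ldaPredict()`, `classConfusion()`): linear
discriminant axes are eigenvectors of the pooled within-class covariance
inverse times the between-class scatter, obtained through a symmetric
Cholesky reduction. Axes are L2-normalized and sign-canonicalized (largest
coefficient positive) because LDA sign/scale is convention; comparisons
against externally stored discriminant functions should be made after the
same canonicalization. A near-singular within-class covariance receives a
ridge of 1e-8·trace(S_w)/p (logged; disable to get a hard error instead).
Prediction is nearest class mean in discriminant space under log priors.
Confusion matrices follow the predicted-rows × true-columns orientation
with per-class accuracy = diagonal/column total; a class trained but never
observed in testing keeps its (empty) row.

## What the simulator emulates — and what it does not

`simulateControlAir()`, `simulateCycle()` and the three experiment
generators produce streams with the statistical structure the pipeline
assumes: per-sensor baseline, linear drift, linear T/RH response, additive
Gaussian read noise, a warm-up transient `warmup_amp·exp(−t/warmup_tau)` at
the start of each measured phase, and an odor term. All randomness derives
from one integer seed; identical seed and configuration give bit-identical
streams, and generators restore the caller's RNG state.

Two odor response models are provided:

* **ramp** (default in `simulateCycle()` and the survey generator): the
  noise-free sampling-phase reading rises linearly at the configured
  per-sensor slope — the slope *is* the statistic of interest.
* **saturating** (used by the outdoor/indoor generators): the reading rises
  with time constant 20 s towards a class-/day-specific amplitude. This is
  the physically sensible model for the prototype — MOS responses
  equilibrate, which is exactly why the last 30 readings are the stable
  ones — and it is also necessary: under the per-cycle anchor
  normalization, a pure ramp reduces every measurement to a ray through the
  origin, and amplitude-coded classes are the only way the trimmed,
  normalized features can form the separated clusters the downstream
  analyses operate on.

Generator defaults are the study conditions: 5 + 5 fruits with one paired
room/sample measurement each (survey, with per-fruit net slopes drawn from
the per-sensor Gaussian group distributions of `surveyEffectSizes()`, or
placed at deterministic equal-probability quantiles for noise-free runs);
10 training fruits × 3 measurements + 3 air measurements and 10 test
fruits × 1 measurement (outdoor; 900 + 90 training and 300 testing
readings); 6 fruits × 7 days × 30 retained readings (indoor; 210 readings
per fruit), with each fruit's daily 4-channel amplitude following a
directed trajectory whose displacement direction reverses at the fruit's
cracking day and whose daily step doubles under infestation. Environment
defaults to a sinusoidal diel cycle, 25 ± 5 °C and 60 ± 15 %RH, with the
humidity phase-shifted so the calibration design is full rank.

Quantities the sources do not specify were fixed once at field-plausible
values and are documented in the design objects: prototype amplitudes of a
few hundred ADC counts against ~3000-count baselines; outdoor
class-amplitude separation and between-fruit/between-measurement spread
chosen so pure air is perfectly separable while the two fruit groups
overlap to roughly 60 % per-class test accuracy; indoor daily step 20 a.u.
against 1.5-count read noise, giving by-day ANOSIM R around 0.9–1.0 and a
ripened block of the cracking day ± about one day; warm-up amplitude and
the 20-s time constant sized so the first ~70 s of a sampling phase are
visibly contaminated (the rationale for the 70/30 trim).

The simulator does *not* model electrochemical sensor physics (no Langmuir
adsorption or resistance-ratio curves), airflow actuation beyond phase
labels, cross-sensitivities between channels, non-Gaussian noise, or
long-horizon aging. Passing tests on simulated data therefore demonstrate
the correctness and statistical behaviour of the processing chain under
its stated assumptions — not field performance of any physical device. One
known consequence: Gaussian group distributions matched to reported
mean ± SD summaries do not reproduce rank-based significance patterns that
arose from heavy-tailed or near-separated real samples, so rank tests on
simulated surveys are systematically *less* decisive than the field data
that motivated them.

## Problem sizes and numerical tolerances used in validation

The shipped test-suite and the acceptance script size their simulations for
desk-scale runs: 500 replicate cycles for slope bias, 1 000 random
instances against the O(n²) pair-enumeration oracle and 5 000 null
simulations for the Brunner–Munzel size, 2 000 null ANOSIM datasets at 199
permutations for p-value uniformity, 200 random problems for the LDA–Fisher
comparison, 24 h (86 400 s) of control air for the decorrelation check, and
100 seeded indoor trajectories for staging. Key tolerances: noise-free
slope recovery to 1e-10 relative (with the warm-up transient off, the
condition under which exactness is defined); relative-effect agreement with
the enumeration oracle to 1e-12; empirical test size within [0.03, 0.08] at
α = 0.05; |r| < 0.05 between corrected control air and T/RH.

## Configuration and outputs

All tabular artifacts are CSV with documented headers; nested results are
JSON; run configuration is a flat YAML file with unknown keys rejected.
Every artifact embeds the package version and a 32-bit FNV-1a fingerprint
of the analysis-relevant configuration plus the seed, so re-running a
command with the same configuration and seed yields byte-identical files
(an optional timestamp stamp line is off by default). A thin command-line
wrapper (`exec/durianose`) exposes the stages as subcommands
(`simulate`, `extract`, `calibrate`, `correct`, `screen`, `anosim`,
`classify`, `stage`, `run`).

## Known limitations

* The Brunner–Munzel t-approximation is anticonservative at very small
  samples; at n = 5 + 5 its size is near nominal but its discrete rank
  support makes p-values lumpy. No permutation variant is provided.
* ANOSIM Monte-Carlo p-values at 990 readings cost O(B·n²) rank
  comparisons; the default permutation count in the bundled pipeline is
  therefore modest (199) and should be raised for publication-grade
  p-values.
* Ellipse-overlap staging operationalizes a judgment originally made by
  eye; the coverage level (default 0.95) is a tunable with no ground truth.
* The confusion-matrix accuracy of a class with zero true-column total is
  undefined and reported as `NA`.

## A worked end-to-end example

```{r pipeline, eval = FALSE}
cfg <- readRunConfig(overrides = list(mode = "indoor", seed = 11L,
                                      out_dir = tempfile()))
res <- runPipeline(cfg)
res$stages          # per fruit-day ripeness stages
res$per_fruit[[1]]$anosim
```
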