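---
title: "Methods: predicting single-cell division from kinase activity dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting single-cell division from kinase activity dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfate)
```

## Overview

`kinfate` classifies single cells as *divided* or *undivided* from their
ERK and Akt activity time courses (C/N reporter ratios on a regular
sampling grid) and interprets which parts of the time course the
classifier relies on. This vignette documents the model assumptions, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, the numerical choices, and known limitations.

## The data model

A *cell time course* is one cell's per-modality series of positive C/N
ratios sampled every `sampling_interval` minutes, starting at
`start_h` hours relative to treatment (a pre-treatment baseline hour gives
`start_h = -1`). A divided cell's series ends at the grid point at or just
before its division time, because the mother cell ceases to exist. A
*cohort* is a set of cells sharing grid conventions; the canonical design
is 49 h at 15-min intervals, i.e. a 197-point full-length grid.

### The length artifact

Because imaging stops at division, series length alone separates the
classes almost perfectly. Any classifier trained on naively padded data
would learn this artifact instead of biology. The preprocessing pipeline
therefore:

1. truncates divided cells at division (`truncate_at_division`);
2. truncates every undivided cell to a length drawn with replacement,
   seeded, from the divided class's empirical length distribution
   (`match_length_distributions`);
3. pads every series back to the full grid with that cell's own retained
   mean (`pad_with_mean`), which preserves the cell's mean exactly.

I.i.d. sampling from the empirical length distribution was chosen over
quantile matching because it is the simplest scheme that makes the two
length distributions equal in distribution; the per-cohort
Kolmogorov–Smirnov statistic of the matched lengths is reported in the
preprocessing record so the match can be audited. The package's test suite
verifies the intended consequence directly: on a cohort with *no* class
signal, a classifier given only the retained length scores AUC > 0.9
before matching and within [0.45, 0.55] after.

### Cross-context adapters

For cohorts from a different experimental context (finer sampling, longer
courses, asynchronously cycling cells, a different reporter chemistry),
three adapters bring data onto the training conventions:

- `resample_to_grid`: linear interpolation onto the target interval,
  never extrapolating. The interpolation error obeys the usual
  h²·max|f″|/8 bound, negligible relative to reporter noise at these
  sampling rates.
- `relabel_last_window`: for cells with recorded division events rather
  than labels, a cell is *divided* if any event falls in the trailing
  window (49 h by default), *undivided* if it has no events, and
  *excluded* if it divided only before the window — such cells were
  committed to division before the treatment under study and would
  confound the labels.
- `rescale_to_reference`: a per-modality affine map matching the pooled
  median and IQR of the training cohort. Robust location/scale matching
  was chosen over z-scoring (config-switchable) because reporter
  distributions are skewed and occasionally heavy-tailed; the fitted
  (scale, offset) is recorded in provenance.

## Feature extraction

The level-`L` Haar approximation cascade applies the orthonormal low-pass
step (a, b) → (a + b)/√2 `L` times, halving the series length (with
ceiling) at each level. At the default `level = 3`, a 197-point course
yields 99 → 50 → 25 coefficients, each summarizing a ~2-h window; feature
matrices carry a `time_h` attribute anchoring each coefficient to its
window center so importance scores map back to time. Level 3 is the
default because the division-fate signal is a slow trend: coarser levels
discard too much temporal resolution and finer levels keep noise.

Numerical notes, decided once and tested:

- **Odd-length boundary**: symmetric (half-point) extension — the common
  wavelet-toolkit default — replicates the edge sample before pairing;
  `zero` and `periodic` modes are available in `transform_spec`. The
  cascade's length arithmetic (ceiling halving) is what produces exactly
  25 coefficients from 197 points.
- **Energy**: the orthonormal analysis discards detail energy, so the sum
  of squared approximation coefficients never exceeds the input energy on
  even-length cascades. Boundary extension duplicates one sample at odd
  lengths and can add energy there; the property is therefore asserted on
  lengths divisible by 2^level.
- The DFT alternative reports half-spectrum amplitudes (indices
  0…⌊n/2⌋). MiniRocket- or tsfresh-style featurizers can be plugged in
  via `transform_spec("external_adapter", fn = ...)`; they are not
  re-implemented here.

## Ensemble Integration

Per modality, a roster of heterogeneous base classifiers — ridge logistic
regression, k-nearest neighbors, radial SVM with probability calibration,
random forest, naive Bayes, a decision tree, and optionally gradient
boosting — is trained on the DWT features. Class imbalance is addressed by
undersampling the majority class *inside each training fold only*; the
test suite includes a canary that audits the recorded training indices of
every inner fit against its test fold.

Stacking hygiene follows the standard pattern: the stacker (meta-model) is
trained on *out-of-fold* base predictions from an inner stratified
cross-validation (`inner_folds = 5` by default), never on resubstitution
predictions. The stacker itself — probability averaging, ridge logistic
regression, or random forest — is selected by inner-CV F<sub>max</sub> of
the minority class, with ties broken in roster order; by construction the
selected stacker's inner-CV F<sub>max</sub> is at least that of plain
averaging. The selected stacker's out-of-fold scores are retained in the
model, so a nested-CV performance estimate is available without refitting.

The logistic learners are ridge-penalized (glmnet, fixed λ = 1/n, the
glmnet-scale analog of the conventional unit-C default). This matters
beyond numerical stability: the 25 approximation coefficients are strongly
collinear (they share each cell's baseline level), and unpenalized
maximum-likelihood fits drift to enormous level-cancelling contrast
coefficients whose permutation importance no longer reflects
time-localized signal. The fixed penalty also keeps the fit fully
deterministic.

## Evaluation

F<sub>max</sub> is the maximum, over all decision thresholds, of the
F-measure (harmonic mean of precision and recall) of the *divided*
(minority) class. Candidate thresholds are the observed unique scores —
the F-measure is piecewise constant between them — plus an all-negative
sentinel; ties are resolved toward the lowest threshold. The maximizing
threshold learned on training data is transferred unchanged to test data
(`f_measure` at that threshold); test labels never influence threshold
selection. Ranking quality is the Mann–Whitney AUC with ties counted ½.
Both statistics are pinned to brute-force oracles (exhaustive threshold
enumeration; all-pairs counting) in the test suite.

`cross_validate` runs stratified k-fold CV (default k = 10) with the
whole fitting procedure — undersampling, base layer, stacker selection,
threshold — repeated inside every fold, and reports per-fold metrics with
median and quartile aggregation (medians are robust to the occasional
hard fold at these cohort sizes). `comparison_grid` crosses transforms ×
EI configurations × modality sets ({ERK}, {Akt}, {ERK, Akt}) to select the
best combination per modality set; a failing grid cell is flagged in the
output rather than aborting the grid.

## Interpretation

For a model with a linear stacker, `ei_importance` computes, per base
classifier, the mean drop in training F<sub>max</sub> when one feature
column is randomly permuted (`n_repeats` independent seeded permutations,
default 10 as a stability/cost compromise), converts drops to fractional
ranks in [0, 1] (largest drop → 1), and averages the rank vectors with
weights proportional to the absolute stacker coefficients of that
modality's base columns, renormalized within the modality. Permutation was
chosen over column *removal* because it preserves the model's input
contract — the fitted model is interrogated unchanged; the magnitude of a
ridge-stacker coefficient is used as the reliance weight because its sign
only encodes direction. Each modality's profile is min-max normalized to
[0, 1] separately so ERK and Akt profiles are displayed on a common axis.

The companion descriptive statistic, `median_class_difference`, is the
absolute difference of per-class medians of each transformed coefficient;
`importance_concordance` reports the Spearman correlation between the two
per modality. On cohorts with a *localized* class effect the ERK
concordance is strongly positive; when the effect is spread over the whole
course the difference profile is nearly flat and the rank correlation is
small and unstable — a flat profile has no rank structure to recover.

## The synthetic cohort generator

`generate_cohort` emulates the statistical structure of a growth-factor
stimulation experiment, on the log scale (exponentiated, so C/N ratios are
positive):

log x(t) = cell baseline + step response + class effect + AR(1) noise.

| parameter | default | meaning |
|---|---|---|
| `n_cells` | 1002 | cohort size |
| `divided_fraction` | 0.246 | divided-class probability (binomial, or exact with `exact_counts`) |
| `sampling_interval`, `duration`, `baseline_hours` | 15 min, 49 h, 1 h | the 197-point grid from −1 h to 48 h |
| `erk_effect`, `akt_effect` | 0.10, 0.05 | peak log-scale amplitude of the divided-class trend |
| `effect_window` | full post-treatment course | support of the class effect |
| `cross_corr` | 0.4 | ERK–Akt noise correlation |
| `noise_sd`, `ar_coef` | 0.15, 0.8 | marginal SD and autocorrelation of the noise |
| `baseline_sd` | 0.1 | SD of the per-cell baseline level |
| `step_amp` | ERK 0.3, Akt 0.2 | label-independent treatment step |
| `division_time_mean/sd/window` | 40 h, 3 h, [24, 48] h | truncated-normal division times |

Design choices: the class effect is a smooth mixture of a half-sine and a
half-cosine ramp, peak-normalized, so the injected signal lives exactly
where level-3 approximation coefficients look; division times are
truncated-normal late in the window, reflecting that most divisions
cluster near the end of a 48-h observation in this kind of experiment (the
exact empirical distribution is not published, so these are exposed,
documented stand-ins); cross-modality correlation is induced by mixing a
shared AR(1) latent series into both modalities with weight
√`cross_corr`, which makes the per-timepoint noise correlation equal
`cross_corr` analytically — with the deterministic trend shared between
modalities, the mean per-cell series correlation lands in the intended
0.3–0.5 band at the 0.4 default. The effect amplitudes were fixed once so
that nested-CV AUC of the default multi-modal model sits near 0.75–0.80,
with ERK ≈ 0.75–0.79 and Akt ≈ 0.58–0.65 — the separability regime typical
of published division-fate classification — rather than in a trivially
separable one.

`generate_rpe_like` emulates a chronically cycling population measured
with a differently scaled reporter: 96 h at 10-min sampling (577 points),
no pre-assigned labels, multiple division events per cell recorded in
metadata (cycling cells divide roughly every 18 ± 2 h from a uniform
phase; a configurable fraction arrest), and an affine reporter transform.
Labels are derived by `relabel_last_window` and scales harmonized by
`rescale_to_reference`.

What the generator deliberately does **not** emulate: mechanistic ERK/Akt
pathway dynamics (no ODEs), reporter saturation, imaging artifacts
(mitosis dips, tracking errors, flatfield residue), apoptosis and other
fates, batch effects, or pulsatile signaling. Consequently, passing tests
demonstrate that the pipeline recovers the *kind* of structure it assumes
(low-frequency class-dependent trends under autocorrelated noise and
truncation); they do not certify performance on real reporter data, where
mis-tracking, non-stationary noise and unmodeled biology can dominate.

## Problem sizes and determinism

The test suite's statistical properties use the cohort sizes at which each
effect is reliably detectable at its stated acceptance margin: n = 600 for
the length-artifact property, n = 1000 across 10 generator seeds for
modality-ordering and planted-window recovery, n = 1000 for chance-level
behavior of zero-effect cohorts (pooled out-of-fold AUC, null SD ≈ 0.02).
Unit tests use 40–300 cells. Every stochastic step — generation, length
matching, fold assignment, undersampling, stochastic learners,
permutations — is driven by explicit seeds derived from a single master
seed, and identical (config, seed) reproduce artifacts byte-for-byte.

## Known limitations

- The interpretation algorithm requires a linear stacker; with
  random-forest stacking it refuses rather than approximates.
- Permutation importance is computed on training data; heavily
  memorizing base learners (deep forests on tiny cohorts) dilute its
  contrast, which the rank conversion only partly restores.
- Length matching discards observed data from undivided cells by design;
  with very few divided cells the matched cohort can become short-biased.
- The AdaBoost-style member of the classical heterogeneous roster is not
  implemented; the roster is config-overridable and the stacker treats
  any probability-emitting base uniformly.
- Real multi-day reporter experiments drift; the generator's AR(1)
  stationary noise does not model slow drift, so drift-robustness is
  untested here.
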