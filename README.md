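# kinfate

Predicting single-cell division events from ERK and Akt kinase-activity
time courses.

## The problem

Live-cell reporters (kinase translocation reporters, FRET sensors) read out
the activity of the ERK and Akt pathways in individual cells as a
cytoplasmic-to-nuclear fluorescence ratio (C/N ratio) sampled every 10–15
minutes over days. Clonal cells under identical growth-factor treatment
nevertheless diverge: some divide within the observation window, most do
not. `kinfate` asks whether the *dynamics* of ERK and Akt activity in a
single cell predict that cell's division fate, and which parts of the time
course carry the signal.

The package is aimed at computational biologists working with single-cell
signaling time courses who want a tested, reproducible reference pipeline
for fate classification — including an honest treatment of the two pitfalls
that dominate this problem: the *length artifact* (divided cells have
shorter series, because imaging stops at division) and severe *class
imbalance* (typically ~25% divided).

## The method

1. **Anti-artifact preprocessing.** Divided cells' series are truncated at
   division; every undivided cell is then truncated to a length drawn from
   the divided class's empirical length distribution; all series are padded
   back to the full grid with the cell's own mean. After this, series
   length carries no class information (a length-only classifier drops
   from AUC ≈ 1 to AUC ≈ 0.5).
2. **Low-frequency features.** Each padded course is reduced by a level-3
   Haar discrete wavelet transform, keeping only approximation
   coefficients: the orthonormal cascade x → (a+b)/√2 applied three times,
   mapping a 197-point course (49 h at 15 min) to 25 coefficients, one per
   ~2-h window. Discrete Fourier amplitudes and external adapters are
   available behind the same interface.
3. **Ensemble Integration (EI).** Per modality (ERK, Akt), a roster of
   heterogeneous base classifiers is trained with majority-class
   undersampling inside stratified folds; their out-of-fold probability
   predictions feed a stacker (mean, logistic regression, or random
   forest) selected by nested cross-validation on the minority-class
   F<sub>max</sub>.
4. **F<sub>max</sub> evaluation with threshold transfer.** F<sub>max</sub> =
   max over thresholds of the divided-class F-measure. The maximizing
   threshold is learned on training data only and *transferred* to test
   data; ranking quality is reported as the Mann–Whitney AUC.
5. **Interpretation.** Per-feature permutation importance of every base
   classifier, rank-normalized to [0, 1] and averaged with weights
   proportional to the absolute logistic-stacker coefficients, yields an
   importance score per (modality, time window), comparable against the
   per-window median C/N difference between fate classes.

A seeded synthetic-cohort generator reproduces the statistical structure
the pipeline assumes (AR(1) noise, correlated modalities, class-dependent
low-frequency trends, late division times, configurable imbalance), so
every stage is testable without any external data.

## Worked example

```r
library(kinfate)

res <- run_pipeline(
  generator = generator_config(n_cells = 300, seed = 42),
  out_dir   = "kinfate_run",
  ei        = ei_config(base_roster = c("lr", "rf", "nb"),
                        stacker_roster = c("mean", "lr"),
                        inner_folds = 5, seed = 42),
  k = 5, n_repeats = 5, seed = 42)
```

```
[kinfate] simulate: n_cells = 300, seed = 42
[kinfate] classes: 79 divided / 221 undivided
[kinfate] preprocess: class length KS = 0.0274
[kinfate] evaluate: 5-fold stratified CV
[kinfate] train final model on full cohort
[kinfate] selected stacker: lr; training F_max = 0.579 at threshold 0.172
[kinfate] interpret: permutation importance, 5 repeats
[kinfate] importance-vs-median-difference Spearman: ERK = -0.174, Akt = 0.339
```

```r
res$evaluation$summary
#>        metric    median        q1        q3
#> 1 f_max_train 0.5696203 0.5324675 0.5960265
#> 2   f_measure 0.5789474 0.5116279 0.6470588
#> 3         auc 0.8096591 0.7357955 0.8148148
```

Reading the output: the simulated cohort has 26% divided cells; after
length matching the class length distributions are statistically
indistinguishable (Kolmogorov–Smirnov statistic 0.027). Five-fold
cross-validation of the multi-modal DWT+EI model gives a median held-out
F-measure of 0.58 at the transferred training threshold and a median AUC of
0.81. The logistic-regression stacker was selected over plain probability
averaging by inner-CV F<sub>max</sub>. With the default generator the class
effect is spread over the whole course, so the per-window difference
profile is nearly flat and its rank correlation with importance is weak at
this cohort size — localized effects (see the vignette) produce strongly
positive ERK concordance.

All artifacts (cohort CSVs, preprocessing report, feature matrices,
per-fold metrics, model summary, importance profile, provenance with all
seeds) are written under `out_dir`.

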