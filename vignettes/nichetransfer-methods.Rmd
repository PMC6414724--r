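---
title: "Models and methods behind nichetransfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nichetransfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nichetransfer` is an in-silico test bench for the temporal transferability
of ecological niche models (ENMs). This vignette documents the models and
procedures it implements, the synthetic data they are exercised on, the
numerical conventions, and the design choices made where the design was
genuinely open.

## The experimental design being emulated

The framework reproduces a classic two-epoch survey design from a dynamic
Atlantic–Mediterranean transition landscape: a fine-resolution "local" study
area (230-m cells) nested in a coarse "regional" window (≈10-km cells over a
10× wider extent); a calibration survey of 344 points at the first epoch
(t0); a revisit of 204 of those points at the second epoch (t1, the
*internal* temporal-transferability test); and 384 fresh, spatially distinct
points at t1 (the *external* test). Species enter the analysis only with
strictly more than 15 calibration presences — the rule that guarantees at
least five occurrences per predictor in a trivariate model. Those constants
are the package defaults (`survey_design()`, `experiment_config()`); reduced
settings used in tests are always passed explicitly.

## Synthetic worlds

`make_world()` builds epoch t0. Climate is smooth by construction — a
seasonal cycle plus a north–south gradient plus Gaussian-filtered white
noise (`smoothing_sigma`, in cells, is the spatial autocorrelation length;
real climate surfaces are smooth, and smoothing filtered noise is the
simplest process with that property). Monthly minimum temperature is the
maximum minus a strictly positive diurnal-range field, so `tmax ≥ tmin`
holds cell-wise by construction; precipitation is winter-peaked and floored
at zero. Land cover is a single smoothed field thresholded at the class
proportions' quantiles, which yields patch structure with realized
fractions within rasterization error of the targets (defaults: 62%
scrubland, 21% forest, 10% cropland, 7% other — a shrubland-dominated
mosaic). The vegetation-index year is 23 sixteen-day composites following a
per-class seasonal curve (forest: high level, low amplitude, late peak;
cropland: high amplitude, early peak), clamped to [−1, 1].

`apply_change()` derives epoch t1: additive climate deltas; a fraction
`encroachment_rate` of cropland converts to scrubland and of scrubland to
forest (land abandonment); then `n_fires` disc patches convert forest to
scrubland and scrubland to "other". Conversions only move cells between the
four classes. The vegetation-index year is regenerated from the t1 land
cover when any cell changed class, and left untouched otherwise — so an
all-zero scenario leaves every t1 layer identical to t0, which the test
suite asserts.

**The unobserved-driver field.** If a virtual species' occupancy at t1 were
exactly the same logistic function of the same mapped predictors, any model
that learned the function at t0 would transfer essentially perfectly — the
phenomenon under study could never appear. Real systems do not behave that
way: between-epoch community change is also driven by disturbance history,
post-fire resource dynamics and distributional disequilibrium that no
predictor layer carries. The change scenario therefore includes
`niche_shift_sd`, the logit-scale SD of a smooth per-species random field
added to the t1 linear predictor (`disturbance_field()`). Its default of 3
places the synthetic system in the empirically observed regime for this
kind of landscape — within-epoch AUC far above temporal-transfer AUC, the
latter near 0.6–0.7 — and was fixed once as part of the scenario
definition. `no_change()` sets it to zero, which is what makes the
zero-change null test meaningful.

## Virtual species and surveys

`make_virtual_species()` assigns the four binary traits (balanced by
default) and wires them into the coefficients of the true suitability
`S*(x) = logistic(β₀ + Σ βⱼ zⱼ(x))` over the nine standardized local
predictors: forest-preferring species load positively on forest fraction,
open-habitat species on scrubland; Mediterranean species positively on
warm-month maximum temperature, Eurosiberian negatively; migrants on
vegetation-index seasonality; specialists carry twice the coefficient scale
of generalists (a linear-predictor proxy for narrower niches). Coefficient
magnitudes are drawn from `beta_ranges` (default 0.6–1.4 on the
standardized scale) and intercepts from ±0.4, giving mid-range prevalences.

Surveys share locations across species (one field campaign, many species),
and detection equals occurrence: every detection is a Bernoulli draw from
the species' true suitability at the survey cell. Imperfect detection is
deliberately not simulated — the design being emulated lacks the repeated
visits needed to correct for it, and the framework mirrors the design
rather than fixing it. Internal-test points are a random subset of the
calibration points by default (`internal_subset = "stratified"` is
available; the original design does not say which was used).

## Predictor derivations

* **Bioclim.** All 19 variables from the standard definitions. Quarters are
  running 3-month windows with December–January wrap-around; "warmest
  quarter" ties break to the earliest starting month. The sample (n−1) SD
  is used throughout, and BIO15 is `100 · SD / (1 + BIO12/12)` — the
  convention of the canonical implementations, which keeps the coefficient
  of variation finite in arid cells. Only BIO5, BIO12 and BIO15 enter
  models by default (the trivariate climate set); all 19 are computed,
  tested against an independent direct-from-definition oracle, and
  exported.
* **EFAs.** Mean, sample SD and 1-based arg-max (earliest composite on
  ties) of the 23-composite year. The peak is reported as a composite index
  rather than a calendar date — the unit-safe choice.
* **Fractional cover.** Exact block counting; partial edge blocks use only
  covered cells; class mass is conserved exactly (tested). The target cell
  size must be an integer multiple of the fine cell — no fractional-block
  interpolation.
* **Resampling.** Bilinear for continuous layers, nearest for categorical,
  block mean for aggregation; nodata propagates through any contributing
  cell. The original design resampled climate 200 m → 230 m without naming
  a method; bilinear is the default here, switchable.
* **Standardization.** Layers are standardized on t0 statistics; t1 layers
  reuse those statistics (never recomputed), so both epochs live on one
  scale and projection is meaningful. A zero-variance layer is an error
  naming the layer.

## Ensemble machinery

Every single model sees at most three predictors. Partitions are stratified
by presence/absence (the design description says only "randomly"; the
stratified version preserves prevalence and avoids degenerate test folds).
All algorithm × replicate members are pooled into one consensus — the
pooling order is not specified in the design being emulated, so the choice
is documented here and fixed. Members with holdout AUC strictly above 0.65
enter with weight equal to their raw AUC (an `(AUC − 0.5)` rescaling exists
behind a configuration switch, default off). When no member qualifies the
single best member is used alone, with a warning, so every species obtains
an ensemble. Final projections use the consensus of split-sample members;
there is no refit on 100% of the data.

The learner registry maps the seven-algorithm family of the classic
ensemble platforms onto installed implementations: `stats::glm`, `glmnet`
(ridge logistic), `mgcv` GAM, `ranger` random forest, `xgboost` boosting,
`MASS::lda` posterior, `nnet`. Multivariate adaptive regression splines has
no installed equivalent and is omitted; the registry is the contract, and
the default experiment uses `glm`, `rf`, `gbm`.

Single-class training folds are skipped and logged rather than fatal
(possible at very low prevalence).

**Hierarchical integration.** The regional climate ensemble is fitted on
coarse-grid occurrences and projected *directly* onto fine-resolution
climate standardized with the regional training statistics — the literal
"direct downscaling" reading; no cell-area weighting is attempted. The
projection becomes the climate component of combined models under the
hierarchical approach. Predictor sets with no climate component are
identical under the two approaches; they are fitted once and reported under
both labels.

## Evaluation conventions

Cross-validation AUC is the mean over replicates of the *per-replicate*
consensus on that replicate's held-out fold (only members trained on the
same fold contribute, so the held-out points are never seen by any
contributing fit). For the projection-only hierarchical climate model the
regional fit never saw local data, so its plain map AUC at the calibration
points is already out-of-sample. Transferability AUCs score the t1
suitability map at the t1 points.

Sensitivity needs a threshold the emulated design never states: the
calibration-data max-TSS threshold is the declared default (smallest
candidate score on ties), frozen at t0 and reused for both transferability
regimes — the freeze is asserted by the tests. TSS and kappa are computed
but secondary. Schoener's D is computed on continuous suitability surfaces
normalized over shared unmasked cells, per epoch (not pooled), and the
package reports both epochs. The transferability head-count uses a strict
AUC > 0.7.

## Multimodel inference

The accuracy GLMs are ordinary least squares with the maximum-likelihood
variance `σ̂² = RSS/n` in the likelihood and `k` counting the variance
parameter — exactly the `stats::logLik`/`AIC` conventions — so AIC is
comparable across fixed-effect structures. All 2^m main-effects subsets are
fitted (interactions excluded by design); ΔAIC < 7 defines the support set,
Akaike weights are `exp(−Δᵢ/2)` normalized, and a factor is consequential
when its summed weight exceeds 0.5. Near-perfect fits floor the variance at
1e−12 and are flagged degenerate.

The TRAIT term is one trait column per run; the pipeline cycles over all
four traits and reports each dredge (a single combined "TRAIT" factor would
be ambiguous). Because trait levels partition species, a species-level
paired test is impossible; the Wilcoxon signed-rank pairing unit is the
model-configuration cell (predictor set × approach), with group means per
cell, and an unpaired rank-sum alternative behind `paired = FALSE`. The
signed-rank test drops zero differences, midranks ties, enumerates the
exact sign-assignment distribution up to n = 25 pairs (by convolution) and
uses the continuity-corrected normal approximation above. Significance
follows the conservative p < 0.001 rule, with no further multiplicity
correction — matching the emulated analysis rather than silently improving
it.

## Problem sizes

The package defaults are the full emulated design (27 species, 344/204/384
points, 30 replicates). The test suite and the acceptance script run
reduced settings chosen as the smallest sizes at which every qualitative
contrast is stable across seeds: 30–40-cell grids, 3–6 species, 1–2
learners, 4–8 replicates, and ten-seed loops for the stochastic recovery
checks (transferability gap, combined-model gain, planted-effect
inference). The planted-effect harness (`simulate_planted_auc()`) bypasses
model fitting entirely and feeds a known additive AUC model straight into
the inference machinery.

## File formats

Rasters are written as single-band ESRI ASCII grids (`.asc`, plain text,
nodata −9999) with a JSON layer manifest — a deliberately dependency-free
choice that any GIS reads. Occurrences and traits are CSV with validated
schemas (errors name the offending column and row); the experiment
configuration round-trips losslessly through YAML; every result table
carries the run's configuration hash, and the inference stage refuses to
mix tables from different runs.

## What passing tests do and do not show

The synthetic landscapes are smooth, stationary Gaussian-filtered fields
with exactly aligned epochs; real predictor stacks carry sensor noise,
classification error, temporal misalignment (e.g. a vegetation-index year
adjacent to the survey year) and projection artefacts, none of which are
simulated. Detection is perfect, occurrences are independent Bernoulli
draws (no spatial autocorrelation in the residual, no biotic interactions),
and fire geometry is circular. Consequently the tests validate the
*machinery* — derivations, ensemble algebra, evaluation statistics,
inference — and the *qualitative* behaviour of the design (transferability
degrades under change; combining predictor families helps; planted effects
are recovered), not quantitative accuracy on any real system. Known further
limitations: no presence-background learners, no hyperparameter tuning, no
spatial-block cross-validation, no occupancy-style detection correction.
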