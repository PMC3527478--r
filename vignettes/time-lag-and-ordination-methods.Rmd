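---
title: "Methods: time-lag analysis and constrained ordination for community fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-lag analysis and constrained ordination for community fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagbeta)
```

`lagbeta` analyses community fingerprint time series — band-intensity
matrices of the kind produced by gel fingerprinting (DGGE and relatives),
where each band approximates a dominant taxon and its intensity approximates
relative abundance. The package asks two questions about such series:

1. **Is the community changing directionally over time, or just
   fluctuating?** (time-lag analysis, temporal β-diversity)
2. **Which measured soil variables explain the compositional variation?**
   (constrained ordination, permutation tests, forward selection, variance
   partitioning)

This vignette documents the statistical model behind each tool, the default
parameter choices and why they were made, what the bundled simulator does
and does not establish, and the numerical decisions that matter for
reproducing results.

## Data model

A *fingerprint* is a tibble with a `sample_id` column and one numeric column
per band. Intensities are non-negative; rows are normalized to relative
abundance (sum 1) on import by default, because gel band intensities are
only meaningful within a lane. *Metadata* attaches `site_id`, `date`,
`replicate`, and `texture` to each sample. *Chemistry* holds soil variables
(pH, NH4, NO3, organic matter, clay, moisture) either per sample or per
`(site, date)`.

Replicates of one sampling are collapsed to a *composite profile* (the mean
of the replicate relative-abundance vectors, renormalized) before any
between-date comparison, so that replicate-level noise does not masquerade
as temporal turnover.

## Diversity and turnover

- **Shannon diversity** H′ = −Σ pᵢ log pᵢ, natural log by default (the
  convention in the soil-ecology literature this package serves); the base
  is a parameter.
- **Band richness** counts bands above a detection epsilon (default 0:
  every positive band counts, since censoring already happened on the gel).
- **Temporal β-diversity** of a site is the mean of all pairwise
  Bray–Curtis dissimilarities (Σ|aᵢ−bᵢ| / Σ(aᵢ+bᵢ), on relative
  abundances) between its composite profiles. It is a single-number summary
  of how much a community moves around its own centroid over the study.

## Time-lag analysis (TLA)

For every pair of dates within a site, compute a community distance and
regress it on the **square root of the time lag**:

> distance = β₀ + β₁ √lag + ε

The √ scale linearizes the saturating rise of ecological distance with time:
distances are bounded (Bray–Curtis by 1, Hellinger by √2), so a straight
line on the raw lag scale cannot hold for long series. A significantly
positive slope β₁ indicates *directional* change; a flat slope indicates
*stochastic* fluctuation around a stable composition. Lags are measured in
months (1 month = 30.44 days) by default, matching multi-year seasonal
sampling designs; days and years are options.

The default distance for TLA is the **Hellinger distance** (Euclidean
distance between square-rooted relative-abundance vectors), which is less
dominated by a few strong bands than Bray–Curtis and is the standard choice
before linear ordination methods. Bray–Curtis is available as an option.

`tla()` fits one regression per site and one pooled regression over all
sites' pairs (`"overall"`), reporting slope, intercept, R², a parametric
t-test p-value, and (optionally) a permutation p-value.

### Permutation scheme: why dates are relabeled, not pairs shuffled

Distances on pairs of dates are not independent observations: the 15 pairs
of a 6-date series share only 6 underlying communities. Two permutation
null schemes are implemented:

- **`"relabel"` (default):** permute the *date labels* within each site and
  recompute every pairwise lag, keeping the distance matrix fixed — the
  Mantel-style scheme. Under the null hypothesis that community composition
  is exchangeable across dates, this is exact: each permutation is a
  draw from the null distribution of the slope.
- **`"shuffle"`:** permute the distance values across the lag multiset
  directly. This treats pairs as exchangeable units, which they are not;
  in simulation it is *conservative* (it rejects a true null at ~2% when
  nominal α is 5%, versus ~5–6% for relabeling).

Both are offered because the shuffle scheme appears in applied work, but
relabeling is the default because it is the scheme whose assumptions match
the data structure, and the one that is calibrated in the package's own
null simulations. The permutation p-value uses the standard +1 correction,
p = (1 + #{|β₁*| ≥ |β₁|}) / (1 + n_perm), so it can never be zero.

## Constrained ordination (CCA)

`cca_fit()` implements canonical correspondence analysis from its
definition rather than wrapping an existing implementation, so that every
numerical step is visible and testable:

1. Scale the community matrix to proportions P; let r and c be row and
   column mass vectors.
2. Form the chi-square standardized matrix Q = (P − r cᵀ) / √(r cᵀ).
   Total inertia is ΣQ².
3. Weight-standardize the predictors (center and scale with row-mass
   weights) and multiply rows by √r.
4. Project Q onto the column space of the weighted predictors (QR
   decomposition); the squared singular values of the projection are the
   constrained eigenvalues.

**Partial CCA** first residualizes both Q and the weighted focus predictors
on the weighted covariables, then proceeds as above; the unique fraction is
reported against the *original* total inertia so that fractions from
different focus sets are comparable. A focus variable that is fully
absorbed by the covariables (e.g. a duplicate) has, correctly, nothing left
to explain: columns whose residual norm falls below 1e-8 of their original
norm are dropped, and a fully-absorbed focus returns a zero-eigenvalue fit
rather than projecting onto round-off noise.

**Permutation test.** The statistic is the pseudo-F ratio
(constrained inertia / q) / (residual inertia / (n − q − c − 1)), where q
and c are the focus and covariable ranks. The null distribution permutes
*reduced-model residuals*: the focus predictors are residualized on the
covariables in sample space, rows are permuted, re-weighted, re-residualized,
and the statistic recomputed. The +1-corrected p-value is reported.

**Forward selection** adds variables greedily: at each step the candidate
with the largest conditional (partial) explained fraction is tested by
permutation given the already-selected set, and retained only if its
p-value is below `alpha` (default 0.05 with 999 permutations, the customary
operating point for Monte Carlo selection in ordination). Selection stops
at the first non-significant candidate.

**Variance partitioning** reports, for each variable, its *unique*
fraction — the partial CCA fraction given all other variables as
covariables — alongside the joint explained fraction and the residual.
Unique fractions do not generally sum to the joint fraction (shared
fractions are not displayed), except for orthogonal designs.

## Association screen

`pearson_screen()` correlates biotic summaries (diversity, turnover)
against soil variables in bulk. All variables are transformed log(x+1)
*except pH* (pH is already a log scale), the standard normalization for
right-skewed soil chemistry. Each pair yields Pearson r, a t-test p-value,
and a Benjamini–Hochberg q-value across the whole screen, so users read one
multiplicity-corrected table instead of eyeballing dozens of raw p-values.

## The simulator, and what passing its tests means

`simulate_dataset()` generates fingerprint series with known ground truth:

- Each site has a *resident* and an *incoming* lognormal community profile
  (log-sd `abundance_sd = 1.2`, giving realistic dominance structure where
  a minority of taxa carry most of the mass).
- **Directional drift** mixes the two with weight w = min(1, θ·months),
  so `drift_rate` θ is interpretable as fraction-replaced-per-month and the
  community at time t is a known mixture.
- **Seasonality** is a per-taxon sinusoid on the log scale with random
  phase (`seasonal_amplitude`).
- **Chemistry linkage** shifts log-abundances by fixed per-taxon loadings
  times the standardized soil variable (`chemistry_linkage`, effect size in
  log-units per sd).
- Date-level (`temporal_sd = 0.3`) and replicate-level (`noise_sd = 0.3`)
  lognormal noise create exchangeable scatter; these defaults put the
  null-model temporal β in the 0.2–0.6 range typical of published soil
  fingerprint series.
- **Detection censoring** zeroes taxa below `detection_fraction = 0.01` of
  the community, emulating the limited sensitivity of gel fingerprints
  (which resolve only taxa above roughly 0.1–1% of the community).

The test suite uses this simulator for calibration (null rejection rates,
uniform p-values), parameter recovery (mean TLA slope strictly increasing
in θ), and selection (a linked variable found among noise variables).
Passing these tests demonstrates that the *estimators are faithful to the
generative model they assume*: exchangeable noise, mixture drift, monotone
chemistry effects. It does **not** demonstrate robustness to everything
real gels do — co-migrating taxa sharing one band, gel-to-gel alignment
error, intensity saturation, or compositional artifacts are outside the
simulator's scope and must be handled upstream.

## Problem sizes and test design

The package's own test and demonstration sizes are chosen to keep the full
suite in minutes on one CPU while retaining statistical resolution:

- `desk_small` (3 sites × 6 dates × 2 replicates, 80 taxa) for
  calibration loops (hundreds of replicate simulations);
- `paper_scale` (8 sites × 11 dates × 4 replicates, 150 taxa, 352 samples)
  for full-design checks and examples;
- permutation counts of 99–199 inside replicated calibration loops, 999
  for single decisions (forward selection), with fixed seeds throughout.

## Numerical choices

- All randomized procedures take explicit seeds; the pipeline derives one
  seed per stage from the configured seed, so whole runs are byte-identical
  given the same inputs and configuration.
- Permutation p-values always use the +1 correction; ties count against
  the alternative (≥ with a 1e-12 slack), which is conservative.
- Relative abundances are compared at 1e-8 tolerances in validators to
  tolerate accumulated floating-point error in long pipelines.
- CSV artifacts embed their provenance (package version, configuration) as
  a JSON comment header and contain no timestamps, so determinism is
  testable at the byte level.

## Limitations

- Band identity is positional: the package assumes bands are already
  aligned across samples. It does not align gels.
- TLA's parametric p-value treats pairs as independent; it is reported for
  comparability with common practice but the permutation p-value is the
  defensible one.
- CCA inherits chi-square distance's sensitivity to rare bands; the
  Hellinger-transform pathway (`cca_fingerprint(transform = TRUE)` for
  predictors, `hellinger_transform()` for communities) mitigates but does
  not remove this.
- The simulator's drift is monotone replacement; cyclic or regime-shift
  dynamics would need a custom scenario.
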