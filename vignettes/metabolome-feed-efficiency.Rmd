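---
title: "Blood metabolome association and co-abundance networks for feed efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood metabolome association and co-abundance networks for feed efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedomics)
options(feedomics.verbose = FALSE)
```

## The problem

Feed is the dominant cost of pig production, and feed efficiency (FE) is a
complex trait whose molecular background is poorly resolved. Blood plasma is
the transport medium for absorbed nutrients, so untargeted plasma
metabolomics — hundreds of annotated and unannotated ion intensities per
animal — is a natural window onto the physiology of efficient growth.
`feedomics` implements a complete analysis chain for such studies: it takes
a samples × metabolites intensity table from two breeds sampled at two time
points, derives growth and efficiency phenotypes, removes design nuisance
effects per metabolite, screens metabolite–trait associations with a global
signal test, builds a signed weighted co-abundance network per breed and
time point, screens network modules against the phenotypes, intersects the
two lines of evidence into candidate sets, and finishes with pathway
over-representation and compound–gene hub analysis.

The package also ships a synthetic-study generator with complete ground
truth. Every stage of the pipeline is therefore testable as a
parameter-recovery problem, which is how the test suite and the acceptance
script exercise it.

## Phenotypes

For each animal in a test phase of 41–70 days starting near 28 kg live
weight:

* `DW = end_weight − start_weight` (kg), `FE = DW / FC` where FC is feed
  consumed (kg); FE·FC = DW holds by construction.
* Daily gains over three windows: `EDG = start_weight / age_at_start`
  (birth weight taken as 0 when absent), `TDG = DW / test_days`,
  `DG = end_weight / age_at_end`.
* `DFI = FC / test_days`; predicted intake `pDFI` is the within-breed OLS
  prediction of DFI from TDG and mean metabolic weight
  `((start + end)/2)^0.75`; residual feed intake `RFI = DFI − pDFI`.
  By the OLS residual property RFI averages exactly zero within breed, so it
  measures metabolic efficiency orthogonal to growth. Both pDFI predictors
  can be toggled (`use_tdg`, `use_metabolic_weight`).

## Preprocessing

Intensities are total-ion-intensity normalized (each sample scaled so all
totals equal the grand mean; idempotent), and the relative-standard-deviation
filter keeps metabolites with sd/mean strictly above 0.15 *computed on the
raw counts within each analysis group* — six groups: each breed at time
point 1, time point 2, and combined. Log transformation uses a half-minimum
offset only when zeros are present. A PCA overview (deterministic sign
convention: the largest-magnitude loading of each component is positive) and
a per-metabolite TP2-on-TP1 stability regression summarize global structure.

## Per-metabolite adjustment

Within a group, each metabolite's log concentration is modeled with breed
(only when the group contains both breeds) and instrument batch as fixed
effects and pen as a random intercept, fitted by REML through `lme4` (one
model per metabolite, `refit()` for speed; sum-to-zero contrasts). Pen falls
back to a fixed effect when it has fewer than three levels, is unique per
sample, or REML fails; the path taken is recorded per metabolite. The
adjusted value is the observation minus all estimated effects — intercept
plus residual. Combined-time-point groups add time point as a fixed effect;
repeated measures per animal are not modeled beyond that, matching the
group-wise cross-sectional analysis the pipeline performs.

Sampling age is deliberately **not** removed here: slower-growing animals
reach the test-start weight later, so age is correlated with the growth
phenotypes themselves, and adjusting it out of the metabolites would bias
the downstream associations. Age enters only as a covariate of the
association model. `check_effect_removal()` provides one-way F-scans of any
factor on the adjusted matrix as a QC; note that for factors removed as
fixed effects the in-sample scan is degenerate (p ≈ 1 — the effect is
removed exactly), so residual-confounding QC on genuinely new data should
use `adjust_new_samples()` on a held-out cohort, where approximate
uniformity of the F-test p-values is the expected behavior. We validate
that design with a training cohort of 100 samples and a held-out cohort of
20: the held-out noncentrality from estimation error is then
n_test/n_train ≈ 0.2, small enough that the Kolmogorov–Smirnov check reads
the p-values as uniform; with equally sized cohorts it is ≈ 1 and the check
would flag the (real, but second-order) estimation error instead.

## Association and the global KS test

Per metabolite and trait (FE, EDG, TDG, DG, RFI), the phenotype is regressed
on an intercept, the adjusted metabolite, and sampling age; the two-sided
t-test on the metabolite slope is the association p-value (intercept and
error term are included even though compact model notations omit them — a
no-intercept regression of a raw phenotype would be meaningless). Because
hundreds of models are fitted per trait, the pipeline first asks a global
question: *is there any overall relation at all?* The one-sample two-sided
Kolmogorov–Smirnov test compares the per-trait p-value distribution with
Uniform(0,1) (exact null distribution for n ≤ 50, asymptotic beyond — exact
where cheap, standard asymptotics elsewhere). Benjamini–Hochberg q-values
(via `p.adjust`) accompany each table, and `significant_set()` applies the
inclusive threshold p ≤ 0.05. The threshold is inclusive because that is the
convention of the tabulated counts this layout mirrors.

## The co-abundance network

Built per breed × time point on the adjusted matrix:

1. **Spearman correlation** between all metabolite pairs (constant columns
   excluded with a flag).
2. **Signed adjacency** `a = ((1 + r)/2)^β`, preserving sign information.
3. **Soft threshold selection**: β scans 12–22; connectivity is binned into
   10 equal-width bins and OLS of log₁₀(frequency) on log₁₀(mean k) gives a
   signed R²; the smallest β with R² > 0.8 wins, otherwise the argmax is
   used and flagged.
4. **Topological overlap**:
   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` — the
   unsigned TOM on the signed adjacency, the standard default of the
   framework this follows.
5. **Module detection**: average-linkage clustering of `1 − TOM`, then an
   adaptive cut: merges above the 0.99 quantile of merge heights always
   split; below it a branch is decomposed whenever both children hold at
   least `min_module_size` (default 30) leaves; surviving branches must pass
   a density check — mean within-branch TOM at least `min_density_ratio`
   (default 10) times the mean TOM from the branch to everything else.
   The decomposition peels apart loosely joined branches (background noise
   chained onto a tight module); the density check is what keeps pure-noise
   agglomerations grey: on the generator, genuine modules score ≈ 130 while
   noise clusters score ≈ 2–5, so 10 separates both by an order of
   magnitude. Modules take the conventional color names in size order, ties
   broken by lowest member index; "grey" is the unassigned background.
6. **Eigen-metabolites**: per module, the first principal component of the
   standardized member columns, unit variance, sign aligned with the module
   (mean member correlation ≥ 0).
7. **Module–trait screen**: Spearman correlation of each eigen-profile with
   each phenotype, p from the t-approximation on n − 2 df; a module is
   selected at |r| ≥ 0.2 and p ≤ 0.1. The absolute value is used because
   negative module–trait correlations are equally interpretable candidates.

## Candidate integration

For every selected (module, trait) pair, candidates are metabolites that are
both association-significant for that trait (p ≤ 0.05) and members of that
module; the per-group unique union removes metabolites picked by several
traits. Overlap bookkeeping intersects candidate sets across time points
within breed and across breeds. Metabolites significant for RFI in the
combined-time-point groups are additionally clustered for a heatmap view:
rows z-scored, Euclidean distance, complete linkage on rows and columns, row
dendrogram cut into k = 4 clusters (k is a parameter mirroring the observed
cluster count, not a discovery claim).

## Enrichment and hubs

Over-representation uses a user-supplied GMT pathway database and an
upper-tail hypergeometric test. The universe is the annotated,
filter-surviving metabolites of the group — over-representation must
condition on what was measurable; pathway membership is restricted to that
universe first, and BH q-values are computed across tested pathways (the
raw-p ≤ 0.05 criterion is also reported, since that is the convention of
the table this layout mirrors). The compound–gene bipartite network links
candidate compounds to genes via a user-supplied mapping (igraph; GraphML
export); a **hub** is a compound linked to more than one gene, ranked by
degree with ID tie-breaks, and `shared_hubs()` reports hubs recurring
across groups. Hosted pathway web services are deliberately replaced by
these local, auditable statistics; database content is an input, not a
claim.

## The synthetic-study generator

`simulate_study()` emulates the study design: two breeds (59 + 50 animals),
729 metabolites, two time points 45 days apart, pens of ~10 nested in breed,
four instrument batches per time point.

* **Modules**: one latent factor per module; member loadings are drawn
  U(loading·0.5, loading·1.5) (default mean 0.8). Heterogeneous loadings are
  deliberate: with identical loadings every member has the same
  connectivity, the degree distribution is multimodal, and no soft threshold
  can make it look scale-free; real co-abundance modules have hubs and
  peripheries. Background metabolites load weakly (U(0, 0.5)) on 15 minor
  factors — small clumps far below any sensible minimum module size — which
  gives the background the weak-correlation continuum real data shows.
* **In-sample orthogonal factors**: all latent factors (module, minor, and
  the efficiency factor u) are drawn jointly and QR-orthogonalized over the
  realized animals whenever the sample size allows. With ~50 animals,
  independently drawn factors would correlate at |r| up to ≈ 0.3 by chance,
  which merges planted modules and makes "the planted partition" an
  ill-defined recovery target. Orthogonalization makes the documented truth
  true in the realized sample.
* **Time**: TP2 factors are `ρ·TP1 + √(1−ρ²)·innovation` (default ρ = 0.6).
* **Traits**: 10% of metabolites carry an animal-level efficiency factor u;
  u adds `trait_effect` kg to test-phase gain and `trait_effect/100` kg/day
  to daily feed intake, so FE, TDG and RFI all inherit signal. Sampling age
  is planted as `78 − 4·u + noise` days (r ≈ −0.5): slower animals are
  sampled older, reproducing the confounding that motivates keeping age out
  of the adjustment model.
* **Nuisance**: per-metabolite breed/batch/pen effect vectors (sd 0.5 /
  0.5 / 0.3 log units, centered per level), and ~5% near-constant
  metabolites whose total variation straddles the RSD threshold, so each
  group's filter removes a slightly different two-to-three percent
  (729 → ~705, echoing the survivor counts such studies report).
* Raw intensities are `exp` of the log signal around a baseline of
  log(1e4), so the table is positive and right-skewed like real ion counts.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: mass-spectral artifacts (drift, batch-varying
detection limits, isotopes), missingness beyond optional zero dropout,
heavy-tailed intensity noise, metabolite-specific temporal dynamics, and —
important for interpretation — any *sample-loading/dilution* component.
Because the generator plants no dilution, total-ion-intensity normalization
has nothing to correct in simulated data; worse, with most metabolites in
modules the sample total tracks a weighted mix of the module factors, and
dividing by it injects a common-mode component that caps eigen-profile
fidelity around 0.83. The recovery benchmarks and calibration experiments
therefore run on log intensities directly, isolating the stage they
measure, while the pipeline keeps TII normalization as a stage because real
intensity tables need it. On real data TII removes genuine dilution, and
the common-mode side effect is shared with every analysis of compositional
intensity data.

## Numerical and design choices

* REML per metabolite with `calc.derivs = FALSE`; singular or non-convergent
  fits fall back to the fixed-pen path and are flagged, never dropped.
* Batch is fixed (only pen is treated as random); switchable by fitting pen
  fixed via `pen_method = "fixed"`.
* The association stage drops rows with missing phenotypes per trait
  (listwise, with counts); metabolites collinear with age (|r| > 0.999) get
  NA p-values and a flag.
* KS exact/asymptotic switch at n = 50; module–trait p via Spearman's
  t-approximation (Pearson mode available).
* Hierarchical-clustering label ties broken by smallest member index;
  permuting metabolite order permutes the partition identically.
* Heatmap defaults (row z-score, Euclidean, complete linkage) mirror the
  defaults of the plotting tool such figures are usually made with; all are
  arguments.
* All pipeline randomness flows through one integer seed; identical config
  and seed give byte-identical output files.

## Problem sizes used in the shipped checks

The test suite and acceptance script run, by choice, at the study's own
scale: the full pipeline on 109 animals × 729 metabolites × 2 time points
(six groups × five traits, ~1 minute); the network benchmark on 100
samples × 500 metabolites with planted modules of 150/130/100/80 at mean
loading 0.8 and unit noise (seed 7) — module recovery ARI ≈ 0.91, scale-free
R² met within the 12–22 scan, eigen-profile fidelity ≥ 0.9 per module; null
calibration on 200 replicates of 200 metabolites × 100 animals (KS
rejection ≈ 5%, per-metabolite rejection ≈ 0.05); FDR on 50 replicates with
10% planted effects (realized FDP ≈ 0.05); and design-effect recovery with
planted batch/breed shifts of 1 and 0.5 log units on 100 samples (mean
absolute error ≈ 0.07–0.11, hold-out uniformity KS p ≫ 0.01).

## Known limitations

* Combined-time-point groups treat repeated measures as independent beyond
  the time-point fixed effect — the same simplification the tabulated
  group-wise analysis implies; a repeated-measures extension would need an
  animal random effect in both the adjustment and association stages.
* No module merging by eigen-profile similarity and no block-wise
  decomposition for very large metabolomes (>10k features).
* The ORA background is the measured universe; results are conditional on
  the annotation supplied and are not comparable across different GMT
  versions.
* No multi-metabolite joint phenotype models — associations are marginal by
  design.
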