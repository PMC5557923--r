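---
title: "Scale-dependent functional dispersion: models, null models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-dependent functional dispersion: models, null models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundisp)
```

## The question the package addresses

Communities assemble from a regional species pool through filters that act
on functional traits. Deterministic abiotic filtering leaves co-occurring
species more similar in trait space than chance would predict
(under-dispersion, or clustering); competitive niche differentiation can
leave them more dissimilar (over-dispersion). Whether a survey detects one
or the other depends on the spatial grain of the "community": the same
data can show clustering at the regional grain and randomness among
neighbouring quadrats. `fundisp` implements the full chain needed to ask
this question with lake macrophyte surveys in mind: plots nested in 0.5 m
water-depth strata, strata in lakes, lakes in regions, with one dominant
environmental gradient per scale (water depth, water transparency,
elevation).

## Trait space

Five traits drive the analysis: life history (annual vs perennial,
categorical), shoot height (cm), specific leaf area, leaf dry mass content
and flowering duration (months, treated as continuous). Inter-species
distances are

* **Gower** for categorical or mixed data: per-trait contributions are
  range-normalized absolute differences (continuous) or 0/1 mismatches
  (categorical), averaged with equal weights. Entries live in [0, 1] and
  are invariant to affine rescaling of any continuous trait. A trait with
  zero range contributes nothing and is reported with a warning; the
  distance is only refused when every requested trait is constant.
* **Euclidean on the z-standardized trait** for single continuous traits.
  Standardization is a deliberate choice the source analyses leave
  unstated: it puts all single-trait dendrograms on a common scale so that
  standardized effect sizes are comparable across traits.

`build_all_dendrograms()` produces six trees: one per trait and one
multi-trait Gower tree. Clustering is UPGMA (average linkage) — the default
in trait-dendrogram ecology; complete and single linkage remain available
for sensitivity analysis. All downstream metrics use the **cophenetic**
distance implied by the tree, which is ultrametric by construction (the
test suite checks the triple inequality on every matrix it builds).

## Dispersion metrics

With `f` the relative abundances of the species present in a community and
`d` cophenetic distances, the alpha metrics are

$$\mathrm{PW} = \frac{\sum_{i \ne j} f_i f_j d_{ij}}{\sum_{i \ne j} f_i f_j},
\qquad
\mathrm{NN} = \sum_i f_i \min_{j \ne i} d_{ij},$$

the abundance-weighted mean pairwise and nearest-neighbour trait distances
(dendrogram analogues of MPD and MNTD). Between two communities,

$$\mathrm{D_{pw}} = \sum_{i \in A}\sum_{j \in B} f_{iA} f_{jB} d_{ij},
\qquad
\mathrm{D_{nn}} = \tfrac12\Big(\sum_{i \in A} f_{iA}\min_{j \in B} d_{ij}
 + \sum_{j \in B} f_{jB}\min_{i \in A} d_{ij}\Big).$$

The exact weighting formulas are not printed in the source metric family;
these relative-abundance forms are frozen here as the reference
definitions, each backed by an independent brute-force loop in the test
suite, and `Dnn` is symmetrized as the mean of its two directions (the
one-directional variant is not pair-symmetric). They agree numerically
with `picante`'s abundance-weighted `mntd`, `comdist` and `comdistnt`;
`picante`'s weighted `mpd` differs by including self-pairs in the weights,
which is why PW is validated against the explicit loop instead.

Communities with a single species have no within-community trait spread:
alpha metrics are *undefined* there (`NA`, with a `defined` flag) rather
than zero, which would masquerade as extreme clustering and bias the SES
aggregation. Pooling up the hierarchy (`pool_to_scale()`) sums abundances,
conserving totals exactly — the natural reading of quadrats "pooled" into
plots.

## Null model and SES

The taxa-shuffle null (`taxa_shuffle()`, 999 iterations by default)
randomly reassigns species names to dendrogram tips. Community matrices
are untouched, so richness, occupancy, abundances and spatial structure
are preserved exactly; only the mapping from species to trait positions is
randomized. Each observed metric is standardized as

$$\mathrm{SES} = \frac{\mathrm{Metric}_{obs} - \mathrm{Metric}_{null}}
{\mathrm{Metric}_{SD}},$$

negative meaning under-dispersion. Three implementation decisions worth
knowing:

* the observed value is **not** included in the null sample;
* within one iteration a **single pool-wide shuffle is shared by all
  communities and pairs**, preserving cross-community structure for the
  beta metrics (independent per-community shuffles would break the fixed
  spatial-distribution constraint);
* a null SD at floating-point noise level (a community holding the whole
  pool with equal abundances makes every shuffle equivalent) marks the SES
  undefined instead of astronomically large.

Group-level departure from zero uses the two-sided Wilcoxon signed-rank
test (`wilcoxon_departure()`), exact for small samples without ties, with
the usual 0.05/0.01/0.001 star convention and no multiple-testing
correction by default (a Benjamini–Hochberg option exists but is off, to
match the reporting convention of the field).

### A calibration caveat that matters

SES values of communities drawn from the *same* survey share one observed
trait-to-species assignment and overlap in composition, so they are
positively dependent under neutrality. A signed-rank test across them is
therefore anticonservative: in our neutral simulations, groups of 12 plots
sharing a 50-species pool rejected at roughly 10–12% instead of 5%,
whereas SES values from independently generated neutral communities
rejected at the nominal rate. This dependence is intrinsic to combining
taxa-shuffle SES with group-level tests — field studies using this design
inherit it — and it is why the package's calibration checks draw each
neutral community from an independent generator realization, isolating the
machinery itself. Interpret small p-values from many overlapping
communities with corresponding caution.

## Scale and gradient analysis

`variance_partition()` fits the nested random-effects-only model (region,
lake-in-region, depth-in-lake, plot-in-depth, residual = within-plot) by
REML via `lme4`, whose non-negativity constraint replaces negative
method-of-moments components by zero; shares are reported as percentages
summing to 100. With a single SES value per plot the plot and within-plot
components are confounded and the fit splits them; supplying replicate
values per plot (e.g. quadrat-level SES) identifies both.

`pca_environment()` log-transforms all six water parameters (Secchi depth,
total N, total P, chlorophyll-a, pH, temperature — the source describes
log-transforming all six, so pH and temperature are included, with a
`log_transform` switch), standardizes to mean 0 / SD 1, and orients axis 1
so Secchi depth loads positively: high scores mean clear, nutrient-poor
water. `bin_gradient()` splits a gradient into equal-width levels;
assignment uses unrounded boundaries while the display rounds half-up to
two decimals, reproducing the published level-2 upper boundary (2.06) of
the log-transparency range [1.47, 2.95].

`gradient_trend()` fits SES ~ gradient with a random intercept for the
enclosing spatial unit, and tests the fixed effect with a likelihood-ratio
test between ML fits (the reported slope comes from the REML refit,
following the convention of presenting final mixed models under REML). The
full top-down model-selection workflow is deliberately reduced to one
fixed, documented structure per scale — random intercept for the
immediately enclosing unit — because the source does not report its
selected structures: depth-scale trends use lake intercepts; lake-scale
trends (against log Secchi depth) use region intercepts; the regional
contrast (two elevation levels, 16.3 vs 1967.4 m a.s.l.) is evaluated on
lake-scale SES values, where the grouping coincides with the contrast and
the model honestly degrades to ordinary least squares. Beta-metric pairs
receive the mean gradient value of their two units (for plot-scale pairs
within a stratum this is exactly the stratum depth). Degenerate inputs
(constant SES) return slope 0 with p = 1 and direction "none"; singular
mixed fits are flagged, not raised. The chi-square reference for the LRT
is known to be slightly anticonservative with few groups; our
model-matched simulations put the type-I error near 5% (roughly 5–9%
across seed sets at 36 lakes).

## The synthetic survey generator

`scenario()` + `generate_traits()` + `generate_survey()` emulate the
survey that motivated the package: 2 regions (16.3 and 1967.4 m
elevation), 12 lakes per region, six 0.5 m depth strata per lake, 7 plots
per stratum — 1008 plots — and a 50-species pool with plot richness
constrained to 1–18 (median ~5 at the defaults). Traits follow field-like
distributions: lognormal shoot height, a negatively correlated
(log-scale, r = −0.6) SLA–LDMC pair for the leaf-economics trade-off, 30%
annuals, integer flowering months. Lake environments are organised around
a latent trophic axis so transparency rises as N, P and chlorophyll fall;
the generator's PCA axis 1 typically explains well over half the
variance, like real lake sets.

Filtering: each site has an optimum `opt` on the standardized trait axes,
a weighted combination of its three scale-specific gradients (weights 0.5
depth, 0.35 transparency, 0.35 elevation). A species' occurrence weight
multiplies a trait-independent base occupancy (Beta(1.2, 12) — a realistic
dominance structure) by `exp(-(lambda/K) * sum_k (z_ik - opt)^2)`; weights
are rescaled to an expected richness of 5 and occurrences drawn Bernoulli,
with rejection sampling (capped, then a deterministic top-probability
fill, which slightly biases composition at extreme `lambda`) enforcing the
richness range. Abundances are a lognormal lottery conditional on
occurrence. `lambda = 0` is exactly neutral; mean SES PW falls steeply
over `lambda` in 0–4 and saturates beyond (assembly becomes effectively
deterministic), which is why monotonicity checks probe 0/1/4 rather than
larger values.

What the generator does *not* emulate: intraspecific trait variation,
mechanistic light/depth physiology, spatial autocorrelation within
strata, unequal stratum counts per lake (the real survey's 135 strata
arise from unequal depth ranges; the balanced default gives 144), or
realistic biomass units. Passing recovery tests therefore demonstrate
correctness of the statistical machinery under a plausible assembly model,
not ecological realism of any particular lake.

`simulate_ses_table()` bypasses community assembly entirely and draws SES
values as sums of independent normal effects at the five levels, with
optional replicates per plot and an optional fixed depth slope — the
ground truth for variance-partition and trend-recovery tests.

## Problem sizes and numerical choices in the shipped checks

The test suite and `scripts/acceptance.R` use sizes chosen to make
Monte-Carlo error small relative to each tolerance: exhaustive-enumeration
comparisons on pools of 5–6 species against 4000 sampled shuffles (3
Monte-Carlo SEs); ~2000 independent neutral communities for the
bias check (|mean SES| < 0.1) and 200 groups of 10 for the rejection-rate
band; the filtering scenario on a reduced 2 x 4 x 4 x 4 design at
`lambda = 8` with 999 iterations; 50 replicates for variance-component
recovery (each share within 10 points of 20%) and slope recovery
(coverage >= 90%); 200 replicates for type-I rates. At the region scale
the filtering check pools the six trait metrics (2 communities each) into
one signed-rank test of n = 12, whose smallest attainable two-sided exact
p is 0.00049 — any single near-zero value (the binary life-history
dendrogram produces one by construction) lifts p above 0.001, so that
sub-check sits at the edge of what the design can resolve.

## Known limitations

* The group-level Wilcoxon dependence described above.
* Dendrogram-based distances coarsen raw trait differences; two species
  merged low in the tree are equidistant from everything else regardless
  of their raw trait gap.
* The fixed random-effect structures are a modelling convention, not a
  data-driven selection; with very few groups the regional contrast is an
  OLS comparison and should be read descriptively.
* No multiple-testing correction is applied by default across the many
  scale x trait x metric combinations the pipeline reports.
```{r example, eval = FALSE}
# a complete miniature analysis
res <- run_pipeline(list(
  seed = 1, n_iter = 999,
  simulate = list(lakes_per_region = 4, strata_per_lake = 4,
                  plots_per_stratum = 4, lambda = 8)
))
dplyr::filter(res$departure, trait_metric == "multi_trait", metric == "PW")
autoplot(res$ses)
```
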