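# fundisp

Scale-dependent functional dispersion analysis for nested community
surveys, built around the workflow used in lake macrophyte ecology.

## The problem

Community assembly leaves signatures in trait space. If abiotic filters
dominate, the species that co-occur are more functionally similar than a
random draw from the pool (**under-dispersion / clustering**); if niche
differentiation dominates, they are more dissimilar (**over-dispersion**).
Both the sign and the strength of the signal depend on the spatial grain
at which a "community" is defined and on which environmental gradient
operates at that grain. `fundisp` is for ecologists who have (or want to
simulate) surveys with a nested design — plots within water-depth strata
within lakes within regions — and want to quantify functional alpha and
beta dispersion across those scales and along scale-specific gradients.

## The statistics at the core

Inter-species functional distances come from trait dendrograms (UPGMA on
Gower distances for mixed/categorical traits, Euclidean on z-standardized
values for single continuous traits; cophenetic distances feed all
metrics). For a community with relative abundances `f` and distances `d`:

- alpha: `PW = Σ_{i≠j} f_i f_j d_ij / Σ_{i≠j} f_i f_j` (mean pairwise) and
  `NN = Σ_i f_i min_{j≠i} d_ij` (nearest neighbour);
- beta, between communities A and B: `Dpw = Σ_{i∈A} Σ_{j∈B} f_iA f_jB d_ij`
  and the symmetrized nearest-neighbour dissimilarity `Dnn`.

Observed values are standardized against a **taxa-shuffle null model**
(999 random reassignments of species names to dendrogram tips; richness,
abundances, occupancy and spatial structure all fixed):

```
SES = (Metric_obs − Metric_null) / Metric_SD
```

SES < 0 means clustering. Group-level departure from zero is tested with
Wilcoxon signed-rank tests; SES variance is decomposed over the spatial
hierarchy with nested random effects (REML); and SES trends along water
depth, water transparency (PCA axis 1 of six water parameters, equal-width
binnable into levels) and elevation are estimated with linear mixed models
and likelihood-ratio tests. A synthetic survey generator with known
filtering strength `lambda` provides ground truth for every stage.

## Worked example

Simulate a reduced survey (2 regions x 4 lakes x 4 depth strata x 4
plots, 50-species pool) under strong environmental filtering, then ask
whether multi-trait dispersion departs from the null at the plot and lake
scales:

```r
library(fundisp)

scen    <- scenario(seed = 2024, lakes_per_region = 4, strata_per_lake = 4,
                    plots_per_stratum = 4, lambda = 6)
traits  <- generate_traits(scen)
survey  <- generate_survey(scen, traits)
dendros <- build_all_dendrograms(traits)

ses_tbl <- ses_dispersion(survey$community, survey$hier, dendros,
                          scales = c("plot", "lake"),
                          metrics = c("PW", "Dpw"),
                          n_iter = 999, seed = 2024)
dplyr::filter(summarize_departure(ses_tbl), trait_metric == "multi_trait")
#> # A tibble: 4 × 10
#>   scale trait_metric metric     n mean_ses median_ses statistic  p_value direction stars
#>   <chr> <chr>        <chr>  <int>    <dbl>      <dbl>     <dbl>    <dbl> <chr>     <chr>
#> 1 lake  multi_trait  Dpw       12    -3.46      -3.79         0 4.88e- 4 clustered ***
#> 2 lake  multi_trait  PW         8    -3.18      -3.44         0 7.81e- 3 clustered **
#> 3 plot  multi_trait  Dpw      192    -1.76      -2.05      1027 1.22e-26 clustered ***
#> 4 plot  multi_trait  PW       128    -1.55      -1.88       449 2.17e-18 clustered ***
```

Every mean SES is negative and every signed-rank test rejects: the
generator's filtering is detected as functional clustering within
communities (PW) and reduced functional turnover between them (Dpw), at
both grains. The lake-scale transparency trend for the same table:

```r
trend <- scale_gradient_trends(ses_tbl, survey$hier, survey$env, scale = "lake")
dplyr::select(dplyr::filter(trend, trait_metric == "multi_trait"),
              scale, metric, slope, p_value, direction, method)
#> # A tibble: 2 × 6
#>   scale metric slope p_value direction      method
#>   <chr> <chr>  <dbl>   <dbl> <chr>          <chr>
#> 1 lake  Dpw    -6.41  0.0385 more clustered lmm
#> 2 lake  PW     -5.60  0.165  none           lmm
```

Beta dispersion grows more clustered toward clearer lakes (negative slope
per unit log Secchi depth, p < 0.05 by likelihood-ratio test); the alpha
trend points the same way but is not significant at these sizes. An
end-to-end run — dendrograms, all four scales, all four metrics, Wilcoxon
summaries, variance components, gradient trends, CSV + Newick + manifest
outputs — is one call: `run_pipeline(list(seed = 1, simulate = list(...)))`.

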