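# reefsucc

Coral-reef succession analysis from line-intercept benthic transects and
belt-transect fish counts: diversity, multivariate assemblage tests, coral
trait-space metrics, and mixed-model tests of coral–fish relationships.

## Who this is for

Reef ecologists tracking how coral assemblages change through cycles of
degradation and recovery — and how those changes propagate to reef fish.
Repeated bleaching and coastal disturbance can leave species richness rising
while *trait* diversity stays depressed, because the species that return
(encrusting and massive forms) are functionally redundant with survivors
while the lost corymbose and branching corals, with their high surface area
and fine fractal structure, do not come back. Separating those two signals
requires trait-space metrics alongside the classical diversity and
ordination toolkit, in one reproducible pipeline.

## What it computes

**Cover.** Line Intercept Transect (LIT) cover is a length ratio, so
transects of unequal length (one 50-m tape in the first survey, six 10-m
replicates later) pool by length:
`cover = 100 · Σ intercepts / Σ tape length`. Unclassified tape is reported
explicitly, never renormalised away.

**Diversity.** Hill numbers `^qD = (Σ pᵢ^q)^(1/(1−q))` for q = 0 (richness),
q = 1 (exponential Shannon, as the analytic limit) and q = 2 (inverse
Simpson); Chao–Jost sample coverage
`Ĉ = 1 − (f₁/n)·(n−1)f₁ / ((n−1)f₁ + 2f₂)` from singletons/doubletons; exact
hypergeometric rarefaction with extrapolation capped at 2n. Cover-based
assemblages are discretised to pseudo-counts at a declared tape resolution
(default 1 cm).

**Multivariate.** Bray–Curtis dissimilarity, principal coordinates analysis,
PERMANOVA with crossed fixed factors (year, protection, interaction;
sequential sums of squares, 999 permutations, `(b+1)/(B+1)` p-values), and
distance-based RDA with AIC forward selection over the 12 benthos/substrate
cover types, using `AIC = n·ln(residual inertia/n) + 2(k+1)`.

**Trait space.** Seven coral traits (growth rate, skeletal density, colony
size, colony height, corallite width, intra-colony space,
surface-area:volume), hierarchically imputed, binned to ordinal 1–5 scores,
Gower distance, and a fixed 4-axis PCoA reference frame in which every
yearly meta-assemblage is measured: occupied volume as a convex-hull
fraction (general-dimension hull computed in-package), functional redundancy
as the mean summed distance to the five nearest neighbours, abundance-
weighted functional dispersion (FDis), and Gaussian-KDE occupancy maps with
50%/95% contours.

**Fish.** Belt-transect counts standardised to individuals per 60 m²,
partitioned into coral dwellers (CD) and non-coral dwellers (NCD) with four
body-size classes, plus PERMANOVA/db-RDA of fish composition.

**Inference.** Random-intercept linear mixed models (REML) with Satterthwaite
Wald tests — cover vs protection × year with a site intercept, fish abundance
vs coral cover with crossed site and year intercepts — and one-way ANOVA with
Fisher's LSD letters.

A synthetic-data module generates complete survey scenarios (8 sites, 4
protected, three surveys, ~90-taxon trait pool, fish coupled to cover) with
known ground truth, so the full pipeline is testable without field data.

## Worked example

```r
library(reefsucc)

scenario <- simulate_scenario(seed = 7)
compute_cover(scenario$transects, by = "year")[, c("year", "tape_m",
    "reef-building coral", "bare reef", "sand")]
#>    year tape_m `reef-building coral` `bare reef`  sand
#> 1  2006    400                  26.4       12.8   7.63
#> 2  2010    480                  13.9       30.1  10.6
#> 3  2018    480                  23.0        8.11 24.4
```

Total coral cover collapses between the first two surveys and partially
recovers, while the dominant non-living substrate shifts from bare reef
(post-disturbance) to sand. The trait-space metrics, measured in the pooled
reference frame:

```r
ordinal <- bin_traits(impute_traits(scenario$traits))
pooled  <- coral_abundance_matrix(scenario$transects, "pooled-year")
space   <- build_trait_space(gower_distance(
             ordinal[ordinal$taxon %in% names(pooled), ]))
functional_metrics(space, pooled)
#>   unit  year n_taxa volume_fraction degenerate redundancy_5nn dispersion
#> 1 2006  2006     48           0.728 FALSE               0.451      0.303
#> 2 2010  2010     50           0.202 FALSE               0.297      0.176
#> 3 2018  2018     78           0.321 FALSE               0.236      0.184
```

Richness rises monotonically (48 → 50 → 78) yet the occupied trait volume is
V-shaped and ends far below its start — the newly arrived taxa pack into
already-occupied regions, which is also why the 5-NN redundancy statistic
falls every year (smaller = more redundant). The full pipeline adds the
assemblage tests and the coral–fish models:

```r
res <- run_pipeline(scenario, seed = 7)
tidy(res$permanova)
#>   term           df    ss      r2     f     p
#> 1 year            2 1.89  0.255   3.59  0.001
#> 2 protected       1 0.290 0.0392  1.10  0.299
#> 3 year:protected  2 0.481 0.0651  0.915 0.625
#> ...
dplyr::filter(res$fish_lmm, model == "total_gt20", term == "coral_cover")
#>   model      term        estimate std_error     t    df           p
#> 1 total_gt20 coral_cover    0.223    0.0194  11.5  11.0 0.000000181
```

Assemblage composition differs among years but not with protection status,
and large-fish (>20 cm) abundance increases with coral cover (Satterthwaite
t-test on the mixed-model slope).

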