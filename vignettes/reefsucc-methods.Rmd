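---
title: "Methods: coral-reef succession analysis in reefsucc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coral-reef succession analysis in reefsucc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods in `reefsucc`, the
assumptions behind them, the tunable parameters, the design decisions taken
where more than one construction was defensible, and the limits of what the
synthetic-data tests can show.

## Survey model

A benthic survey unit is a site visited in a survey year. Cover comes from
the Line Intercept Transect (LIT) method: a category's cover is the length
of tape it intercepts divided by tape length. Because LIT cover is a length
ratio, transects of unequal length are pooled by summing intercepts and
summing tape — the estimator consistent with the definition — rather than by
averaging per-transect percentages. This matters because the emulated survey
design mixes one 50-m transect per site in the first year with six 10-m
replicates afterwards; how a lone long transect should be weighted against
short replicates is not a settled convention, and length weighting is our
declared choice.

Tape not accounted for by any segment is assigned to an explicit
`unclassified` pseudo-category. This keeps the row-sum-to-100 invariant
testable and flags incomplete field sheets instead of silently renormalising
them. Category labels pass through a dialect map
(`default_dialect()`) because field sheets name the same categories
inconsistently.

## Diversity

Hill numbers are used at q = 0, 1, 2. The q = 1 case is computed as the
analytic exponential-Shannon limit, never by numerically approaching q = 1.
Sample coverage uses the singleton/doubleton estimator
`Ĉ = 1 − (f₁/n)·(n−1)f₁/((n−1)f₁ + 2f₂)`; rarefaction interpolates with the
exact hypergeometric expectation (for q = 1, the exact expected subsample
entropy), anchors at the observed value at `m = n`, and extrapolates at most
to `2n`, past which the asymptotics are unstable. Extrapolation uses the
Chao1 estimate of undetected species for q = 0, the unbiased Simpson
continuation for q = 2 (valid at any m), and for q = 1 a sample-size-weighted
blend of the observed exponential Shannon with the Chao–Wang–Jost asymptotic
entropy estimator — the blend is anchored exactly at the observed value and
approaches the asymptote as m grows.

LIT "abundance" is percent cover, not individuals, while coverage and
rarefaction are defined on counts. We convert cover to pseudo-counts by
discretising the intercepted tape at a declared resolution
(`resolution_cm`, default 1 cm — the finest length a field observer
realistically resolves). The conversion is surfaced in the pipeline
configuration because published analyses of cover data rarely state it; at
1 cm the pooled assemblages sit in the >99% coverage regime, so the
rarefaction curves are essentially flat at the observed values and the
choice is not load-bearing.

## Multivariate analyses

Assemblage dissimilarity is Bray–Curtis on percent cover. PCoA retains axes
with positive eigenvalues; explained variance is computed over positive
eigenvalues only. Bray–Curtis matrices are generally non-Euclidean, so some
eigenvalues are negative; by default no correction is applied (negative axes
are simply dropped), with the Cailliez constant-shift available via
`correction = "cailliez"` for users who need a full embedding.

PERMANOVA enters terms sequentially (Type-I) in the declared order — year,
protection, interaction — permutes raw unit rows freely (no strata), and
reports `(b+1)/(B+1)` p-values at 999 permutations by default. The seed is a
required argument: a permutation p-value without its seed is not
reproducible. The unit of replication is the site-year assemblage; with 8
sites and 3 years that gives 24 units, enough for the crossed two-factor
design but leaving modest power for the interaction.

Distance-based RDA works in the positive-eigenvalue principal-coordinate
representation. Forward selection adds, at each step, the candidate that
most lowers `AIC = n·ln(residual inertia/n) + 2(k+1)` and stops when no
addition lowers it. This residual-deviance analogue is stated explicitly
because "AIC for a constrained ordination" has no single canonical form; the
constant 2(k+1) treats each added predictor as one parameter plus one for
the implicit scale. Candidates perfectly collinear with the selected set are
skipped and logged. The AIC penalty is intentionally mild: with a
low-dimensional response cloud, the best of many pure-noise candidates can
absorb enough inertia to be admitted, whereas on community-shaped data
(many species, Bray–Curtis) selection on pure noise retains the null model
— the acceptance tests exercise exactly that contrast.

## Coral trait space

Seven habitat-forming traits are used: growth rate (mm/yr), skeletal density
(g/cm³), colony size (cm), colony height (cm), corallite width (mm),
intra-colony space (mm), and surface-area:volume ratio (1/cm). Missing raw
values are filled by hierarchical geometric means — genus, then growth form,
then global, on the log scale, since all seven traits are positive and
right-skewed. This deliberately simplifies the published
regression-plus-phylogeny imputation approaches: the fixture scale (a few
masked cells per trait) does not support fitting a hierarchical regression,
and the provenance of every imputed cell is recorded per-cell so downstream
users can drop imputed values.

Raw values are binned to ordinal 1–5 categories with declared per-trait
breaks; a value exactly on a cut point takes the lower category (a
deterministic tie rule). Gower distance is the unweighted mean over traits
of `|x−y|/range`, with zero-range traits dropped (they carry no
information). The trait space is the PCoA of this matrix over the *pooled*
taxon set of all years; the first 4 axes (config-overridable) form a fixed
reference frame. A fixed frame is the only construction under which per-year
occupied-volume percentages are comparable — re-ordinating each year
separately would change the denominator geometry each time.

Three per-assemblage metrics are computed in that frame:

* **Occupied volume fraction** — exact convex-hull volume of the
  assemblage's taxa divided by the pooled hull volume. Hulls are computed by
  an in-package incremental (beneath-beyond) algorithm that works in any
  dimension; it is cross-checked in the tests against planar closed forms
  and an independent computational-geometry library. We read the
  four-dimensional "volume of trait space" as a convex hull rather than a
  kernel hypervolume: the hull is parameter-free, exactly monotone under
  supersets, and equals 1 for the full set by construction, which is what
  makes the per-year percentages interpretable. Subsets with fewer than five
  affinely independent taxa return 0 with a degeneracy flag instead of
  failing the pipeline.
* **Functional redundancy (5-NN)** — the mean over taxa of the summed
  Euclidean distances to the five nearest other taxa; smaller values mean
  denser packing, i.e. more redundancy. The statistic is purely geometric
  (presence-based, no cover weighting); neighbour ties break by taxon label
  for determinism.
* **Functional dispersion (FDis)** — the cover-weighted mean distance to the
  cover-weighted centroid. Whether the original formulation weights by
  abundance or presence is ambiguous in parts of the literature; cover
  weighting is our declared choice, and FDis is computed on the same 4-axis
  coordinates as the other two metrics so all three share one geometry.

KDE occupancy maps use a Gaussian kernel with the normal-reference plug-in
bandwidth per axis on an axis pair ((1,2) or (3,4)), a grid extended three
bandwidths past the data range so the density integrates to 1 within 2%,
and contour levels chosen so the enclosed mass is 50% and 95%.

## Fish

Counts standardise to individuals per 60 m² (`count/area × 60`) because the
emulated design changes transect length across years (150 m, 150 m, 60 m at
a 2-m belt). Size classes (<5, 5–10, 10–20, >20 cm) remain an ordered
categorical axis; converting them to midpoint lengths would fabricate
precision. The coral-dweller (CD) classification is a lookup table with a
genus-level fallback; strict mode errors on unmatched taxa, lenient mode
defaults them to NCD with a warning. PERMANOVA and db-RDA of fish
composition run on the standardised abundances (standardised vs raw counts
is a declared choice; totals are conserved either way).

## Mixed models and post hoc tests

All mixed models are random-intercept models — cover vs protection × year
with a site intercept, fish abundance vs coral cover with crossed site and
year intercepts — fitted by REML with Satterthwaite degrees of freedom for
the Wald t-tests (via lme4/lmerTest). Random slopes are deliberately
unsupported: the analyses this package implements never use them, and
rejecting them early gives clearer errors than a silently overparameterised
fit. Boundary fits (a variance component estimated at zero) are legitimate —
in that limit the fixed effects coincide with ordinary least squares and the
Satterthwaite df approach N − p, which the tests assert — and are flagged
rather than hidden. Year enters the cover model as a categorical factor:
three unevenly spaced surveys give no basis for a linear year trend. Cover
is modelled untransformed (declared; a transformation can be applied to the
response column upstream).

The ANOVA post hoc uses Fisher's LSD: all pairwise t-tests on the pooled
residual mean square, run only after a significant omnibus F, with **no**
multiplicity correction — that is what the LSD procedure is, and the output
metadata says so. Compact letters are assigned to the maximal cliques of the
pairwise non-significance graph in descending-mean order, so groups share a
letter exactly when they are pairwise non-significant and the labelling is
deterministic.

## The synthetic scenario

The generator emulates a three-survey monitoring design: 8 sites, 4
protected;
surveys in 2006, 2010, 2018; one 50-m LIT then six 10-m replicates; ~90
coral taxa with genus and growth form; fish surveys at 5 of the sites.
Its defaults are the study conditions:

* Mean total coral cover 27.87 → 12.94 → 22.76%, with a
  10-percentage-point protected-vs-unprotected difference in year-3
  recovery. Site-level multipliers are lognormal with σ = 0.8, giving an
  among-site CV near 0.9, the dispersion scale reported for the real sites
  (which ranged from under 5% to large covers).
* Per-year richness 48/50/78 by cohort construction: 12 corymbose/branching
  taxa present only in year 1; a 36-taxon core; 14 near-duplicate additions
  by year 2; 28 more by year 3, of which 8 "edge" variants extend the
  colony-size/skeletal-density region of trait space and 20 are
  near-duplicates of core encrusting/massive taxa. Corymbose and branching
  archetypes occupy an extreme region (fast growth, high intra-colony space
  and surface-area:volume) that no other growth form reaches, so the taxa
  deleted after year 1 are hull vertices by construction and their loss must
  shrink the occupied volume; the year-3 near-duplicates drive the 5-NN
  redundancy statistic down.
* Transect noise is Dirichlet over category shares (concentration
  1/`cover_noise`, default 0.02), which respects the 100% constraint exactly
  and degenerates to the targets as the noise goes to zero. Fish counts are
  Poisson around `intercept + slope × cover` per coral-dweller flag and size
  class, with positive slopes only for >20 cm non-coral dwellers (0.16
  ind./60 m² per % cover) and 5–10 cm coral dwellers (0.12) — the classes
  the emulated study found associated with cover — and intercepts per class
  *and year* so NCD abundance declines monotonically across surveys (a
  fishing-pressure signature that cover cannot produce, since cover is
  V-shaped). Effect sizes were fixed once so that, at the study's own sample
  size (5 sites × 3 years), the mixed model recovers a positive, significant
  slope in ≥95% of seeds, as the recovery properties demand; the Poisson
  noise and site spread are not tuned per test.
* About 12% of raw trait cells are masked missing, the proportion the
  emulated study had to impute (11 of 91 species).

All randomness flows from one master seed through named substreams
(traits, benthic, fish), so any stage can be regenerated alone.

What the generator does **not** emulate: spatial autocorrelation among
sites, within-site depth structure, observer error in taxon identification,
size-dependent detectability of fish, and taxon-level temporal persistence
beyond the cohort design. Passing tests therefore show that the estimators
and the pipeline recover known structure of this kind; they do not validate
ecological conclusions on field data, and the absolute magnitudes of the
synthetic trait metrics (e.g. occupied-volume percentages) track the
qualitative trajectory of the real system rather than its exact values,
which depend on a pinned trait-database snapshot we do not ship.

## Numerical choices

* Hull tolerance: points within `1e-9 ×` the coordinate range of a facet are
  treated as on it; degenerate inputs (fewer than d+1 affinely independent
  points) return volume 0 with a flag.
* PCoA keeps eigenvalues above `1e-9 ×` the largest magnitude; an all-zero
  distance matrix yields a 0-axis ordination rather than an error, and
  PERMANOVA on it reports residual R² = 1 with no test.
* Gower range is computed over the supplied table (4 when both extreme
  ordinal categories occur); zero-range traits are dropped with a warning.
* LSD declares "zero within-group variance" via a relative threshold
  (`eps^0.75 ×` the response variance) so perfect fits error out instead of
  producing unreliable F statistics.
* Nearest-neighbour and genus-mode ties break by label order; forward
  selection breaks exact AIC ties by candidate order. All tie rules are
  deterministic.

## Problem sizes

The test suite and acceptance checks run at the scale of the emulated study:
24 benthic site-year units, 15 fish site-year units, 90-taxon trait pools,
999 permutations per test, 1000 replicates for the PERMANOVA type-I-error
study, 100 seeds for the selection studies, 200 replicates at 20 groups × 10
observations for mixed-model recovery, and 20 scenario seeds for the
qualitative signature. These sizes make the whole suite run in a couple of
minutes on a single core while keeping every Monte-Carlo margin interpretable.

## Known limitations

* The hull-volume metric is sensitive to single extreme taxa (a hull is an
  extreme-value geometry); the KDE maps are the complementary, mass-based
  view.
* The q = 1 extrapolation blend is one defensible interpolation between the
  observed entropy and its asymptotic estimate; alternatives differ in the
  second order in m/n.
* db-RDA forward selection inherits the usual greedy-selection caveats:
  correlated true drivers can mask each other, and the declared AIC is mild
  on low-dimensional responses.
* With three year levels, the crossed year intercept in the fish models is
  estimated from very little information; boundary fits there are common and
  expected.
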