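---
title: "Evaluating plant functional groups against trait-based clustering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating plant functional groups against trait-based clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitgroups)
```

## The question and the model

A priori functional groups (evergreen shrubs, deciduous shrubs, graminoids,
forbs; optionally finer schemes splitting graminoids into grasses, sedges
and rushes, or shrubs into dwarf and tall) are a categorical model of plant
form and function. `traitgroups` treats that model as a testable hypothesis:
if the groups are real trait syndromes, a grouping factor should explain a
large share of the multivariate variation in species-level traits, and
unsupervised clustering of the same traits should rediscover approximately
the same species sets. The package quantifies both halves — variance
explained (PERMANOVA $R^2$) and species-level correspondence (an optimal
label-matching consistency statistic) — plus the sensitivity of $R^2$ to
which traits are measured (the trait-subset resampling analysis).

## From records to a trait matrix

Trait databases compiled from many sources carry duplicates, transcription
errors, and unit-scale outliers. `clean_dataset()` applies, in order: exact
duplicate collapse (same species, trait, value, unit, source — fuzzier
matching would need a rule we cannot justify, so near-duplicates are kept);
removal of values $\le 0$ (all traits handled here are strictly positive);
and a per species-by-trait outlier filter at 4 sample standard deviations.
Because every trait here is approximately log-normal, the filter operates on
$\log_{10}$ values; it runs in a single pass with each point included in its
own cell mean and SD, and is skipped for cells with fewer than 3 records,
where a sample SD is too unstable to trust. Seed mass is especially prone to
measurement error, so records beyond 3 SDs are *flagged* in the provenance
report for manual review rather than silently dropped. Cleaning is
idempotent, and the record count before cleaning always equals the count
after plus the itemized removals.

`build_trait_matrix()` then log10-transforms each record, aggregates per
species and trait (the aggregation statistic is computed over log values, so
the mean behaves like a geometric mean on the raw scale), and scales each
trait column. Species lacking any requested trait are excluded (complete
case): imputation is out of scope, and the excluded species are typically
the rarely measured ones. "Standardized between 0 and 1 using variance
scaling" admits two readings, so both are implemented and recorded in the
scaling metadata: the default z-scores each trait then min-max rescales to
$[0,1]$; plain min-max is a switch; `"none"` keeps aggregated log values
(useful when traits are already on comparable, known scales, as in
simulations). The two $[0,1]$ modes differ by a per-trait affine map, which
*does* change Euclidean distances — hence the explicit switch rather than a
hidden choice. Quantile aggregation (`q = 0.25` / `q = 0.75`) supports the
within-species robustness variants; quantiles interpolate linearly at index
$(n-1)q$ (R type 7). The metadata make the aggregated log values exactly
recoverable, so no information is destroyed by scaling.

Site-restricted or north-of-60°N analyses rescale within the analyzed
species set by default (each analysis sees a well-spread $[0,1]$ space);
reusing the global scaling is possible by subsetting the matrix instead of
the dataset.

## Variance partitioning

`trait_permanova()` implements one-way PERMANOVA from the squared
Euclidean distance matrix:
$SS_T = \frac1n \sum_{i<j} d_{ij}^2$,
$SS_W = \sum_g \frac1{n_g}\sum_{i<j\in g} d_{ij}^2$,
$SS_A = SS_T - SS_W$,
$F = \frac{SS_A/(a-1)}{SS_W/(n-a)}$, $R^2 = SS_A/SS_T$.
For a single variable this is algebraically identical to classical one-way
ANOVA (the identity $\sum_{i<j} d_{ij}^2 = n\sum_i (x_i-\bar x)^2$), which
the test suite verifies against `stats::aov` to $10^{-9}$ on random
datasets, and against `vegan::adonis2` in the multivariate case.

Inference permutes group labels over species with the distance matrix held
fixed. The p-value estimator includes the observed statistic,
$p = (1 + \#\{F^* \ge F\})/(1 + B)$, so $p \ge 1/(B+1) > 0$ — with $B = 999$
the smallest reportable value is 0.001. When the number of distinct label
assignments $n!/\prod_g n_g!$ is at most 10,000 the full set is enumerated
and $p$ is exact. Degenerate inputs are flagged rather than fudged: all
points identical gives $R^2 = 0$ with undefined $F$; perfectly separated
identical groups give $R^2 = 1$, $F = \infty$. Under label exchangeability
the permutation distribution of $R^2$ has mean exactly $(a-1)/(n-1)$ — a
sharp identity the suite checks by full enumeration — and the test is
calibrated: the fraction of null p-values at or below 0.05 stays within
$0.05 \pm 0.02$ over 2,000 simulated null datasets.

Multi-factor designs, strata, and dispersion tests are deliberately absent:
the study design is strictly one-way.

PCA (`trait_pca()`) decomposes the covariance of the centered matrix —
columns are already on a common $[0,1]$ scale, so re-standardizing to
correlation would double-weight low-variance traits; it remains available
via `scale.`. Component signs are fixed by making each loading's
largest-magnitude entry positive, removing the eigenvector sign ambiguity
from serialized output. Per-trait group differences use a rank-sum test
(groups are independent samples, so the signed-rank variant for paired data
does not apply); with both groups at 10 or fewer species the two-sided
p-value comes from full enumeration of label assignments using midranks,
which remains exact under ties, otherwise from the tie-corrected normal
approximation with continuity correction.

## Post hoc classification

`trait_kmeans()` is Lloyd's algorithm with k-means++ seeding, 100 restarts
by default (the best inertia wins), convergence when assignments stop
changing, and empty-cluster repair by re-seeding with the point farthest
from its centroid. Restart count matters more than iteration count for
avoiding poor local optima at these problem sizes (tens to hundreds of
species, $k \le 7$); 100 restarts makes distinct seeds agree on the toy
problems and planted benchmarks in the suite. Inertia is asserted
non-increasing within each run.

`ward_linkage()` merges, at each step, the pair of clusters minimizing the
increase in total within-cluster sum of squares, via the Lance–Williams
update on the $\Delta SS$ cost matrix initialized at half the squared
Euclidean distances. This is the "Ward.D2-equivalent" objective: heights on
the `ward.D2` scale are $\sqrt{2\,\Delta SS}$, and the suite checks exact
height and cut agreement with `stats::hclust`. Ties (exactly equal merge
costs happen in regular or degenerate data) break deterministically toward
the lexicographically smallest pair of smallest original member indices, so
the tree is reproducible to the byte. Merge costs are non-decreasing and
sum to the total SS of the centered matrix. `cut_tree(k)` returns the
clusters existing after $n-k$ merges; $k$ is always fixed to the group
scheme being compared (4, 6 or 7) — data-driven selection of $k$ is a
non-goal.

## The consistency statistic

`confusion()` cross-tabulates two partitions over their shared species;
`optimal_matching()` solves the assignment problem of matching cluster
labels one-to-one to reference groups so that the count of co-classified
species is maximal — exhaustively (lexicographic order, first optimum) up
to 8 labels, by the Hungarian/Jonker–Volgenant algorithm beyond; both routes
are oracle-checked against brute force. A species is *consistent* under a
comparison when its matched cluster equals its reference group; with more
clusters than reference groups, unmatched clusters contribute nothing.

The "all methods" figure is reference-anchored: a species counts when
*every* comparison partition maps it to its reference group under that
partition's own optimal matching — the intersection of the pairwise
consistent sets, so it can never exceed the smallest pairwise proportion.
(A three-way simultaneous matching could be defined instead; the anchored
definition is the one that yields a per-reference-group breakdown.)

Abundance weighting asks whether the inconsistently classified species are
rare: per plot only the most recent survey year is kept, cover is summed to
site level by species and restricted to species with trait data, and each
site contributes the cover share of the consistent set. Sites are then
averaged without weighting — "aggregating at the site level" does not
specify a weighting rule, and equal site weights avoid letting a
densely-plotted site dominate; pooling cover across sites first is available
as `mode = "pooled"`.

## Trait-subset resampling

Because different traits are measured for very different numbers of
species, raw $R^2$ values across trait subsets confound trait identity with
sample size. `resampled_group_r2()` therefore fixes the species count: per
subset, the complete-case matrix is built once (standardization on the full
pool — per-draw re-standardization is a switch, off by default for
stability), and each of the replications draws that fixed number of species
without replacement and records the group $R^2$. Only $R^2$ is computed per
draw (no permutations — the mean-$R^2$ surface needs no p-values), via the
classical sums-of-squares route that the PERMANOVA identity tests guarantee
equals the distance computation. Draws are independent across subsets (a
per-subset seed offset). If the pool is not larger than the requested draw,
every replication is the full pool, flagged degenerate, with SD exactly 0.
Subsets are enumerated from singletons up (`min_size = 1`), and
`combo_summary()` averages by subset class — economic-only
$\{SLA, LDMC, leaf\ N\}$, size-only $\{height, seed\ mass, leaf\ area\}$,
mixed — and by LDMC / height-or-seed-mass membership.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the pipeline
assumes, with known ground truth: species nested in groups; species true
log10 trait means = group archetype + Normal between-species offset;
records = species mean + Normal within-species noise, exponentiated to the
raw scale; species-by-trait cells dropped whole with a per-trait missing
probability (matching how real databases lack a trait for a species, and
making complete-case counts binomial); cover allocated by a per-site
symmetric Dirichlet draw (concentration 0.5 by default — strongly skewed,
the simplest skew-controllable choice) jittered per plot and year.

Defaults describe a small tundra-like study: 4 groups x 25 species, the six
focal traits with archetypes ordered like real functional groups (evergreen
shrubs lowest SLA and leaf N, highest LDMC; shrubs taller and
heavier-seeded than forbs — orderings only, no values copied from any
source), between-species SD 0.25 and within-species SD 0.15 log10 units, 5
records per cell, 10% missing cells, 3 sites x 5 plots x 3 years. With 10%
missingness per trait, about $0.9^6 \approx 53\%$ of species are
complete-case for all six traits — the same order of attrition real
compilations show.

`expected_separation_r2()` gives the analytic large-sample $R^2$ on the
unscaled log matrix: summed over traits, archetype variance over archetype
+ between-species + within-species/record-count variance. It is exact for
`scaling = "none"` and approximate under $[0,1]$ rescaling (rescaling
reweights traits); the suite verifies empirical agreement within $\pm 0.05$
at 1,000 species for targets 0.1, 0.3 and 0.6.

What the generator does *not* emulate — phylogenetic signal, spatial and
trait–environment structure, non-normal tails, correlated missingness —
bounds what green tests mean: they certify the statistical machinery, not
any ecological conclusion about real tundra data, which require the real
trait compilation and cover archives as inputs.

## Orchestration, determinism and problem sizes

`run_full_analysis()` chains every stage from one config (YAML or list) and
writes each result table as CSV plus a JSON summary; any stage failure
aborts with a stage-tagged message, retaining tables already written. One
global seed expands into fixed per-stage offsets (simulation +0,
permutations +1, k-means +2, resampling +3), so any stage can be reproduced
in isolation and full reruns are byte-identical. No randomness escapes the
seed: permutations, restarts, draws and simulation all flow through it.

The test suite and the acceptance script run their simulations at moderate
sizes chosen to make Monte-Carlo tolerances sharp while keeping the whole
suite fast — e.g. 2,000 null datasets of 20 species for calibration, 1,000
species for generator recovery, 199 replications where the SE bound is
what matters, 999 permutations where a p-value floor of 0.001 is quoted.
These sizes are stated in the tests themselves; all checks are
property-based (identities, oracles, calibration bands), not comparisons to
any archived dataset.

## Known limitations

Only one-way designs; no unit conversion beyond trusting the declared
units; no imputation; complete-case bias toward well-measured species is
inherited, not corrected; the Hungarian route returns one optimum when
several matchings tie (the optimum value is unique, the matching need not
be); and k-means results for weakly separated data can vary across seeds —
consistency percentages involving k-means should be read as stochastic to a
few species.
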