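---
title: "Methods behind poolgp: population-level genomic analysis of genebank collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind poolgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`poolgp` analyses collections of natural populations genotyped by pooled
sequencing, where the data unit is an allele *frequency* per population and
marker rather than a genotype per individual. This vignette is the
package's own account of its models, the choices that were genuinely open,
and what the synthetic-data validation does and does not establish.

## The data and their quirks

A pooled frequency matrix behaves like a very accurate "average genotype":
frequencies are continuous in `[0, 1]`, missing calls are common (on the
order of 8% per marker, with some markers missing up to a third of
populations), and linkage disequilibrium between markers is *not*
observable — only the between-population correlation of frequency columns
is. All methods in the package are phrased directly on this matrix; nothing
ever requires individual genotypes.

Quality control keeps a marker when its per-population minor allele
frequency `min(x, 1 − x)` strictly exceeds 5% in at least 10 populations
(both thresholds are arguments), counting only non-missing calls — the
filter deliberately precedes imputation, so imputed values can never
qualify a marker. Missing calls are then replaced by the marker's mean
frequency, which preserves every column mean and therefore the kinship
scaling below.

## Trial analysis and heritability indicators

Phenotypes enter as plot-level records of a balanced complete-block design.
The within-environment model is `Y_ij = µ + g_i + b_j + E_ij`; across
environments, `Y_ijr = µ + g_i + env_j + (g×env)_ij + b/env_jr + E_ijr`.
Variance components are estimated by expected mean squares on the
random-population reading of these models:

* `σ̂²_g = max(0, (MS_g − MS_e)/R)` (one environment),
* `σ̂²_g = max(0, (MS_g − MS_g×e)/(J·R))`,
  `σ̂²_ge = max(0, (MS_g×e − MS_e)/R)` (J environments),

with the population F statistic tested against `MS_g×e` in the
multi-environment model, consistent with random environment and
interaction effects. The package supports *only* balanced data and raises
a clear error otherwise: on balance the EMS estimators are exact (the test
suite checks agreement with an REML oracle to 1e-3), and the generator
produces balanced designs by construction. Unbalanced or spatially
trended trials are out of scope. Negative component estimates are
truncated at zero — standard EMS practice.

Heritability indicators of population means follow directly:
`H² = σ²_g/(σ²_g + σ²_e/R)` or
`H² = σ²_g/(σ²_g + σ²_ge/J + σ²_e/(J·R))`. These are indicators analogous
to broad-sense heritability, not narrow-sense estimates — with pooled
natural populations the distinction matters and the package keeps the
modest name.

Adjusted means are least-squares means from the fixed-effect fit,
evaluated by averaging model predictions over the nuisance levels. For
balanced data they equal raw population means; the multi-environment mean
carries an `_avg` suffix on the trait label. Whether across-environment
means should come from the fixed or the mixed reading of the model is
genuinely undecidable on balanced data (they coincide), so the fixed fit
is used.

## Kinship and correlation decay

The genomic relationship matrix is `G = M M′/K` with columns of the
frequency matrix centered by their means and
`K = 0.5 Σ_j x̄_j(1 − x̄_j)`. `K` is the natural sum-of-genetic-variance
scale for frequencies of outbreeding diploid pools; the factor 0.5 makes
the diagonal comparable to an individual-genotype relationship matrix.
Two exact invariants are tested: duplicating every marker leaves `G`
unchanged, and `trace(G) = Σ_i ‖M_i‖²/K`.

As an LD surrogate, squared Pearson correlations between same-scaffold
frequency columns are binned by bp distance (pairs subsampled per scaffold
under a seed). Both squared and absolute correlation are exposed, since
redundancy pruning of significant markers is phrased in `|r|` while decay
summaries are phrased in `r²`.

## Spatial statistics

Geographic distances are haversine great circles on the mean Earth radius
6,371,008.8 m; the sub-0.5% discrepancy to ellipsoidal geodesics is
irrelevant to any rank-based use here. Moran's I is computed from the raw
textbook formula `I = (n/S0) Σ w_ij z_i z_j / Σ z_i²` with the Cliff–Ord
randomization variance; weights default to inverse distance and are
applied exactly as supplied — deliberately *not* row-normalized, so the
two-population symmetric case gives exactly −1 and a definitional oracle
can be matched at machine precision. The nominal range [−1, 1] is not
enforced: some weight matrices push I outside it and the raw statistic is
reported.

The Mantel correlation is the Pearson correlation of strictly-lower
triangles, with a one-tailed (greater) permutation test,
`p = (1 + #{r* ≥ r_obs})/(n_perm + 1)` over seeded joint row/column
permutations (500 by default). The add-one correction keeps the test valid
at any permutation count; the suite verifies the permutation p against
exhaustive enumeration at n = 5 and the empirical size against the nominal
5% level.

## Mixed-model GWAS

The kinship scan fits the null `y = Xβ + u + e`, `u ~ N(0, σ²_g G)`, by
spectral REML: the covariate-projected `G` is eigendecomposed once and the
restricted likelihood, profiled to `δ = σ²_e/σ²_g`, is maximised on a
100-point log grid on `[1e−5, 1e5]` followed by golden-section refinement
to 1e-6. Grid-plus-refinement is deliberate: the profile can be flat or
bimodal near boundaries, and the suite asserts the returned δ̂ beats a
1000-point brute-force grid. Markers are then tested by GLS with the null
components held fixed (the P3D shortcut); `p3d = FALSE` refits every
marker exactly and agrees in rank (Spearman > 0.99) at desk scale.
Constant markers are reported with `β = 0`, `p = 1` and flagged rather
than dropped, keeping output rows aligned with the input map.

Multiple testing uses Benjamini–Hochberg q-values with a strict `q < 0.10`
significance rule. BH was chosen over Storey-type q-values as the
procedure is fully deterministic and assumption-light; the choice is a
strategy switch in spirit and the suite pins BH to its O(m²) definitional
oracle.

Per-marker variance explained is reported twice: `r²_ols`, the squared
correlation of trait and frequency, and `r²_kinship`, the partial
R-squared of the marker on data whitened by the null `H^{−1/2}`. The
whitened partial R² is a defensible but not uniquely determined reading of
"variance explained with kinship taken into account"; its two desirable
limits are tested (it converges to `r²_ols` as the kinship signal
vanishes, and it is never larger for structure-confounded markers).

The multi-marker summary is a forward stepwise regression over significant
markers in p-value order, admitting a marker only if it lowers AIC, with
candidates truncated to `n − 2` to keep the fit estimable.

## RR-BLUP prediction

Genomic prediction uses RR-BLUP on centered frequencies, fitted with the
same spectral REML machinery on `ZZ′` and therefore numerically identical
to GBLUP through `G` (asserted to 1e-8). New populations are centered by
the *training* column means — the model stores them — so cross-validation
cannot leak holdout information through centering. Cross-validation
follows the repeated-holdout protocol (default 100 repeats, 50 held-out
populations, Pearson r per repeat); one master seed spawns per-repeat
subset seeds, making every split reproducible and independent of marker
subset choices.

Geographic-origin prediction treats longitude and latitude as traits under
leave-one-out RR-BLUP. One numerical subtlety is handled explicitly: the
fold-specific intercept of a leave-one-out model equals
`(Σy − y_i)/(n − 1)`, which is perfectly anti-correlated with the held-out
value, so pooling predictions that include it drives the evaluation
correlation to −1 whenever the markers carry no signal. The assembled
predictions therefore use each fold's marker-effect deviation around the
grand coordinate mean — a constant shift that cannot manufacture signal —
and the no-structure control in the suite stays near zero as it should.

## Calibration-set optimization

Procedures 1–2 cluster the collection with Ward linkage (`ward.D2`) on the
genetic or spatial distance matrix and take, per cluster, the member with
the smallest mean distance to its cluster mates (ties broken by population
id). Ward is a choice, not a given: it matches the pseudo-inertia
criterion of the constrained variant and yields compact strata; the
linkage is an argument. Procedure 3 blends the two max-normalized
dissimilarities through their pseudo-inertias with mixing parameter α
(default 0.5); because Ward's criterion is additive in squared
dissimilarities this is implemented exactly as Ward clustering of
`d = sqrt((1−α)d*²_gen + α d*²_geo)`, and α = 0 or 1 reduces *identically*
to the unconstrained procedures. Procedure 4 maximises CDmean — the mean
coefficient of determination of the genotypic BLUPs of non-selected
populations,
`CD_i = [G − λ(Z′PZ + λG⁻)⁻¹]_ii / G_ii` — by seeded random exchanges that
are accepted only when the criterion improves (1000 iterations by
default). The pooled `G` is typically rank-deficient, so its inverse is
ridge-stabilized with `1e-6 × mean(diag(G))`. λ defaults to 1, i.e. an
assumed heritability of one half, and is always reported alongside the
result; nothing in the method pins it.

A selected set is scored against the envelope of 100 random same-size
sets trained and evaluated identically:
`score = (OptPA − MinPA)/(MaxPA − MinPA)`. The score may exceed 1 or fall
below 0 and is reported unclamped.

GWAS-informed marker selection first builds the "GWAS set" strictly on
calibration data (kinship-only scan, markers admitted in p-order when a
nested-model F test improves at 5%, capped at the calibration size), then
traces validation predictive ability as markers enter one by one —
GWAS-set first, then random markers, against a random-from-the-start
control — and reports the smallest count reaching 95% of each curve's
maximum. The 95% threshold is applied to the raw (unsmoothed) curve.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not the biology that produced it:

* **Isolation by distance** — a Gaussian process on the logit scale with
  exponential covariance `exp(−d_km/range)` plus a 15% nugget, marginal SD
  1.1. The default range of 250 km was fixed once by bisection so that the
  genetic-vs-geographic Mantel correlation of a 200-population, 2000-marker
  Europe-like panel falls near 0.44, the level typical of continuous
  spatial differentiation in outbreeding grassland collections.
* **Rare-allele skew** — ancestral frequencies `Beta(0.35, 1)` folded to
  the minor allele (alternative-allele labels flipped at random), giving a
  frequency spectrum dominated by low-MAF markers.
* **Within-scaffold correlation** — a latent field that evolves along each
  scaffold as an exponentially decaying (AR(1)-in-position) process with
  decay length 10 kb, so the correlation of two markers' fields is exactly
  `exp(−d_bp/L)`. Marker positions are drawn in twin pairs around shared
  sites (offsets up to 80 bp), mimicking the read-stack clustering of
  reduced-representation genotyping and guaranteeing both sub-100-bp and
  multi-kb pairs on 100-kb scaffolds.
* **Phenotypes** — `n_qtl` markers drawn as additive QTL (Gaussian effects
  for polygenic architectures, exponential for few-large-effect ones), the
  genetic value standardized, and interaction/residual variances solved
  from the target `H²` and an interaction share: with
  `T = (1 − h²)/h²`, `σ²_ge = gxe_share·T·J` and
  `σ²_e = (1 − gxe_share)·T·J·R`. Balanced complete blocks only.

What passing tests on this generator show: the estimators recover the
quantities they claim (H² within ±0.1 across a grid, planted QTL found at
`q < 0.10`, inflation controlled by the kinship model, predictive ability
rising with heritability and calibration size, optimized calibration sets
beating the random-envelope midpoint). What they do not show: robustness
to unbalanced trials, genotyping error, selection, admixture pulses,
non-equilibrium demography, or LD patterns beyond an exponential decay —
none of which the generator produces.

## Problem sizes and numerical conventions

The validation suite runs at desk scale, chosen as the package's own
testing conditions: panels of 100–300 populations with 600–5000 markers,
20-replicate recovery grids, 200-trait inflation contrasts, and marker
curves a few hundred markers long. Tolerances are set by the nature of
each check — machine-precision (1e-8 to 1e-12) for the closed-form and
oracle identities, ±0.1-type bands for stochastic recovery. Degenerate
inputs have defined behaviour throughout: constant traits refuse Moran's I,
constant markers are flagged rather than tested, all-missing markers abort
imputation by name, `K = 0` aborts kinship, and an empty significant set is
a legal GWAS-set result.
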