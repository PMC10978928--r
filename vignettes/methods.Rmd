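---
title: "Continuous biogeographic isolation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous biogeographic isolation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `biogeodiv`, the
assumptions behind it, and the places where the design was genuinely open
and a choice had to be made.

## 1. Biogeographic distance from branch lengths

Two assemblages are compared through their *branch sets*: the union of
root-to-tip paths of their species on a shared rooted phylogeny. With
shared length $a$ and unique lengths $b$ and $c$,

$$\beta_{sim} = \frac{\min(b,c)}{a + \min(b,c)}, \qquad
  \beta_{sor} = \frac{b + c}{2a + b + c}, \qquad
  \beta_{sne} = \beta_{sor} - \beta_{sim}.$$

$\beta_{sim}$ (turnover) discounts nestedness — one assemblage being a
richness-reduced subset of another contributes nothing — which is what
makes it usable as a *biogeographic* distance: it responds to the
replacement of evolutionary lineages, not to diversity gradients.

**Rooted convention.** Branch sets run to the tree root, not to the
most recent common ancestor of the subset. Consequences: the
phylogenetic diversity (PD) of the full pool equals the total tree
length, single-species assemblages have positive PD, and results match
the common `include.root = TRUE` behaviour of established PD
implementations (the test suite cross-checks against `picante`). The
alternative MRCA convention would shrink every branch set by the stem to
the root; for turnover this mostly cancels between assemblages, but we
fix one convention and state it rather than mixing the two.

Zero-length edges are kept as set members (membership is by edge
identity, not length) so they can never change totals. Cells with no
species are refused by the metric functions; the matrix builder can drop
them with a logged warning, because downstream regression needs complete
rows. The all-pairs matrix is three matrix products over a cell-by-edge
incidence, so its cost is independent of the number of pairs.

## 2. Functional space and convex-hull geometry

Traits are mixed-type: continuous (optionally log- or sqrt-transformed
first; body mass is the log case), percentages on 0–100 (rescaled to
[0, 1] and treated as continuous), and categorical (0/1 mismatch). The
Gower dissimilarity is the weighted mean of per-trait dissimilarities
with equal weights by default. Whether trait *blocks* (e.g. the diet
percentages) should share one weight is not settled usage; equal
per-column weights are the default and block weighting is available
through the `weights` argument.

The trait space is a principal-coordinates embedding of the Gower
matrix. Negative eigenvalues (non-Euclidean input) are truncated by
default — reproducible and simple — with a Lingoes correction available
as `correction = "lingoes"`. Axes with zero eigenvalue are legitimate
(zero-variance) coordinates; only materially negative eigenvalues bound
the usable dimensionality. Four axes are the default, matching common
practice for rich vertebrate assemblages; sparse pools (a bat-only
analysis, say) usually justify three.

Functional richness is the convex-hull volume of an assemblage divided
by the pool hull volume. Functional beta diversity applies the Sorensen
partition to hull volumes, with $a$ the volume of the hull
*intersection*: turnover is the replacement of functional space, zero
when one hull nests inside the other.

**Geometry implementation.** Hulls are built by the incremental
(beneath-beyond) algorithm in 2–4 dimensions; the triangulated boundary
gives volume (fan from an interior point) and half-space form. The
intersection volume is exact: pool both half-space systems, locate a
strictly interior point as the Chebyshev centre (a small linear program),
enumerate the intersection's vertices by point–hyperplane duality, and
take the volume of their hull. A seeded rejection-sampling estimator is
kept in the test suite as an independent oracle; the two agree to within
the oracle's sampling error on random 3-D hull pairs.

Polytope vertex sets are massively degenerate (every facet's vertices
are coplanar), and a triangulated boundary built under floating-point
tolerances can come out combinatorially closed yet self-overlapping,
which silently inflates a fan volume. Every hull therefore verifies two
invariants — each ridge shared by exactly two facets, and the Euler
characteristic of the boundary complex ($V - E + F = 2$ in 3-D,
$V - E + F - C = 0$ in 4-D) — plus containment of all input points; on
failure the points are re-hulled after a deterministic sub-tolerance
"joggle" (amplitude $10^{-8}$–$10^{-6}$ of the coordinate scale), the
standard remedy for degenerate inputs in computational geometry. The
joggle perturbs volumes by at most surface area × amplitude, orders of
magnitude below every tolerance used downstream.

Assemblages with fewer than $m + 1$ species, or whose points span no
$m$-volume, have undefined functional richness; they yield `NA` with a
reason code and are excluded (and counted) downstream, rather than being
silently imputed.

## 3. Ordination

NMDS minimises Kruskal stress-1,

$$\sigma_1 = \sqrt{\frac{\sum_{i<j} (d_{ij} - \hat d_{ij})^2}
                        {\sum_{i<j} d_{ij}^2}},$$

where $\hat d$ is the least-squares non-decreasing (isotonic) fit of the
configuration distances on the dissimilarity order. Tied dissimilarities
are averaged within tie blocks, which reduces the weighted
pool-adjacent-violators problem to an unweighted isotonic fit on
block-mean-expanded values (delegated to `stats::isoreg`). Optimisation
alternates isotonic fits with Guttman majorisation steps; a backtracking
line search toward the Guttman target guarantees the recorded stress
trace never increases even though the stress normaliser shifts between
iterations. The first start is the classical metric-scaling
configuration, the rest are seeded random configurations; defaults are
20 starts, 500 iterations, and a tolerance of $10^{-7}$ on the stress
decrease. The best solution is centred, rotated to principal axes, and
sign-fixed (largest-magnitude score positive), so axis labels are
deterministic.

Because NMDS coordinates are meaningful only up to similarity
transforms, "biogeographic isolation" enters regressions as a
second-order trend surface — all axes, squares and pairwise products
(9 terms for k = 3) — never as raw axis values.

## 4. Regression and variance partitioning

The environment design is fixed at 12 predictors: four climate principal
components (computed on the correlation matrix after sqrt-transforming
the flagged skewed variables) with quadratics, mean elevation with a
quadratic, elevation range, and log landmass area. Model quality is
adjusted R², and all partition fractions are differences of adjusted
R² values; they can be slightly negative, which is a standard property
of this partition and is reported unmodified. Within each fit the
partition identity
`unique_env + unique_iso + shared = adjR2_global`
holds to machine precision by construction.

Each predictor block must be full rank on its own (rank deficiency is an
error naming the aliased columns). In the *combined* model, columns that
are exactly aliased across the two blocks are dropped with a warning
instead of failing: removing exact redundancies leaves the global fit's
explanatory content unchanged, and it makes degenerate comparisons (the
same block entered twice collapses to pure shared variance) behave
sensibly.

The residual-difference map is `|resid_env| − |resid_global|` per cell:
positive where adding isolation moved the fit toward the observation. No
spatial-autocorrelation machinery beyond the trend surface is applied;
the trend surface itself is the spatial-structure control. A helper
(`delta_r2_screen`) expresses candidate-variable screening as an
adjusted-R² gain over a base model, threshold 0.01 by default.

## 5. Phylogenetic signal

Blomberg's K is computed from the tip variance–covariance matrix
(1 under Brownian motion, 0 with no signal). Fritz–Purvis D places the
observed sum of sister-clade differences between a tip-shuffle null
(D = 1) and a Brownian-threshold null matched to the observed prevalence
(D = 0), 1000 simulations each by default, seeded. Two choices the
literature leaves open:

- **Rescaling.** D is oriented oppositely to K, so the reported
  `rescaled` value is `1 − D`: orientation, not range, is matched
  (D is unbounded below for hyper-conserved traits, so no affine map
  can match K's range).
- **Multi-state traits.** Categorical traits with more than two states
  are decomposed into one-versus-rest binary traits, each scored with
  its own D; the decomposition is explicit in the output rather than
  hidden behind a single pooled number.

Note that a perfectly monophyletic (clade-membership) trait is *more*
conserved than Brownian clumping and has D at or below 0; only
Brownian-threshold traits are expected to centre on 0. The calibration
tests check exactly that.

## 6. What the synthetic world does and does not emulate

The generator exists so the full pipeline — including the headline
variance partition — can be validated against known truth at desk scale.
Defaults: a 12 × 18 grid (216 cells), three realms spanning 8/8/2
columns, 320 species per realm (960 total), tree depth 1 with per-realm
clades of height 0.7 on stems of 0.3, Brownian trait rate 1 per unit
depth, categorical transition rate 2, niche breadth 0.25 on the unit
latitude scale, occupancy ceiling 0.85, climate noise 0.05.

Two kinds of isolation are injected *independently*: clade endemism (the
`mixing` fraction controls how much of the pool is cosmopolitan) and
diversity depression (`isolation_factor` = ρ multiplies occupancy in one
realm). This separation is deliberate: it lets the tests confirm that
the turnover-based isolation surface predicts diversity only when a true
diversity effect exists, and finds nothing when composition structure is
present but diversity is environmentally determined.

**Occupancy is range-map-like, not cell-wise random.** Each species
draws one uniform threshold against its niche curve, so it occupies a
contiguous block of cells with exactly the specified marginal
probability. This matters: with independent per-cell draws, the shared
branch length between two cells scales with the product of their
richnesses, so the turnover matrix acquires a spurious richness gradient
and the ordination "discovers" isolation structure that is nothing but
sampling noise — an artifact real range maps do not have. A second,
weakly selective niche axis on elevation (σ = 0.5 on its unit scale)
varies composition between same-latitude cells without adding richness
structure that the environment design cannot represent. The species-rich
pool keeps the residual compositional wiggle (which scales as
$1/\sqrt{S}$) well below the variance-partition tolerances.

Not emulated: dispersal limitation within realms, speciation–extinction
dynamics in space, range-size heterogeneity beyond niche breadth,
climate change, coastlines or projections (cells are abstract row/column
positions with a pseudo-latitude). Passing tests on these worlds
therefore demonstrate the *statistical machinery* — they do not show
that real diversity is governed by these processes.

## 7. Problem sizes and numerical settings

The validation studies use 216-cell worlds with 960 species for the
variance-partition recovery (NMDS with 2–4 starts there, since the
turnover structure is strong), a 36-cell demonstration world for the
all-response pipeline and the k = 2 versus k = 3 stress comparison, 200
random tree/assemblage pairs (≤ 12 tips) against the brute-force
branch-set oracle at $10^{-12}$, 50 random 3-D hull pairs against a
$10^6$-point Monte-Carlo oracle, 500 Brownian simulations for the K
calibration and 1000-draw null ensembles for D. Geometry tolerance is
$10^{-9}$ of the coordinate scale throughout; partition identities are
asserted at $10^{-12}$; functional-beta identities at $10^{-9}$
(volumes pass through the LP and duality steps).

## 8. Known limitations

- The hull machinery targets 2–4 dimensions; higher-dimensional trait
  spaces would need a compiled qhull-style backend.
- `boot::simplex` is a dense tableau LP solver; fine for the few hundred
  constraints arising here, not for much larger systems.
- NMDS is O(n²) per iteration in the number of cells; global grids in
  the thousands of cells are feasible but slow in pure R.
- The D statistic requires a binary (fully bifurcating) tree; resolve
  polytomies first (`ape::multi2di`).
- Adjusted-R² partitions can return small negative fractions; this is
  reported, not clipped, and should be read as "indistinguishable from
  zero".
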