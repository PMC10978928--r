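# biogeodiv

Biogeographic analyses usually treat regions (realms, continents) as
discrete units, yet assemblages differ *continuously* in how much
evolutionary history they share. `biogeodiv` implements a continuous
alternative: the phylogenetic beta-diversity turnover between grid-cell
assemblages is used as a biogeographic distance, embedded by non-metric
multidimensional scaling (NMDS), and entered into regressions as a
second-order trend surface, so that the variance in diversity can be
partitioned between **environment** and **biogeographic isolation**. The
package is aimed at macroecologists and biogeographers who want to ask:
how much of the global variation in species richness, phylogenetic
diversity, or functional richness is explained by where an assemblage sits
in "biogeographic space", beyond what climate and topography predict?

## The method

For two assemblages with branch sets on a shared rooted phylogeny, let
*a* be the shared branch length and *b*, *c* the branch lengths unique to
each side. The package computes the branch-length Sorensen family

- turnover (Simpson): `pbeta_sim = min(b, c) / (a + min(b, c))`
- total: `pbeta_sor = (b + c) / (2a + b + c)`
- nestedness: `pbeta_sne = pbeta_sor − pbeta_sim`

`pbeta_sim` is insensitive to differences in phylogenetic alpha diversity,
which makes it the standard biogeographic distance. The cell-by-cell
`pbeta_sim` matrix is embedded in k = 3 dimensions by Kruskal NMDS
(isotonic regression + majorisation, stress-1), and the axes enter an OLS
model as `x1, x2, x3, x1^2, x2^2, x3^2, x1x2, x1x3, x2x3`. The environment
model uses four climate principal components (with quadratics), mean
elevation (with quadratic), elevation range and log landmass area. For a
response *y* (species richness, Faith's PD, convex-hull functional
richness, or mean functional turnover), the adjusted R² of the
environment-only, isolation-only and combined fits give the partition

```
unique_iso = adjR2_global − adjR2_env
unique_env = adjR2_global − adjR2_iso
shared     = adjR2_env + adjR2_iso − adjR2_global
```

and the per-cell residual difference `|resid_env| − |resid_global|` maps
where isolation improves the fit. Functional diversity is measured in a
Gower/PCoA trait space with exact convex-hull volumes and hull-overlap
beta diversity; phylogenetic signal of traits is quantified by Blomberg's
K (continuous) and Fritz–Purvis D (binary).

Because the global range-map, climate and phylogeny inputs of a real
analysis are large and restricted, the package ships a synthetic-world
generator (`build_world()`) with known ground truth: realm-structured
phylogenies, range-map-like niche-driven occupancy on a latitudinal grid,
Brownian/Markov trait evolution, and an isolation effect (`rho`) that
thins richness in one realm independently of environment.

## Worked example

A 216-cell world whose third realm is thinned to half its environmental
expectation (`rho = 0.5`), analysed with the package's own pipeline
pieces:

```r
library(biogeodiv)

w   <- build_world(world_config(seed = 1, isolation_factor = 0.5,
                                mixing = 0.1))
y   <- setNames(rowSums(w$occurrence), rownames(w$occurrence))
pb  <- phylobeta_matrix(w$tree, w$occurrence)
ord <- nmds(pb$sim, k = 3, n_starts = 4, seed = 1)
pca <- climate_pca(w$env[, c("temp1","temp2","temp3","temp4",
                             "precip1","precip2")],
                   sqrt_vars = c("precip1", "precip2"))
vp  <- variance_partition(y, build_env_design(w$env, pca$scores),
                          build_isolation_design(ord))
vp
#> variance partition (adjusted R2):
#>   environment only:  0.3813
#>   isolation only:    0.2756
#>   shared:            0.3131
#>   global:            0.9700

rd <- residual_difference(vp$fit_env, vp$fit_global)
ps <- prediction_summary(vp$fit_env, y, w$truth$isolated_cells)
```

The partition says that 28% of the richness variance is explained by
biogeographic isolation *only* — the environment model cannot account for
it. The residual-difference map is positive in 100% of the isolated
realm's cells (isolation improves the fit exactly where the effect was
injected), and the environment model over-predicts richness there:
observed median 80 against a predicted 130.3, i.e. 39% below prediction —
the signature of an isolation-depressed biota. Re-running with
`isolation_factor = 1, mixing = 1` (no isolation effect to find) drives
`unique_iso` to ~0.01.

The same analysis runs end-to-end with `run_pipeline()` (all four
response variables, realm-mode comparison, JSON/CSV outputs), or from a
shell via `inst/cli/biogeodiv.R simulate | pipeline`.

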