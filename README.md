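# stemspat

Spatial structure analysis of forest stem maps: marked point patterns of
tree stems (x, y, species, DBH) in a rectangular, fully mapped plot.

The package is aimed at forest ecologists analysing census plots in which
every stem above a diameter threshold has been mapped. It covers both of
the standard methodological families:

* **Distance-independent structural indices** computed from each tree's
  four nearest neighbours: the uniform angle index
  `U_i = (1/4) Σ_j 1(α_j < α_0)` (local regularity vs clumping, with the
  standard angle α₀ = 72°), the mingling index
  `M_i = (1/4) Σ_j 1(sp_j ≠ sp_i)` (species isolation), and the
  neighbourhood comparison index
  `N_i = (1/4) Σ_j 1(dbh_j ≥ dbh_i)` (size dominance).
* **Second-order spatial statistics** with translation edge correction:
  the univariate and bivariate pair correlation g(r), the bivariate
  Ripley K₁₂(r) and nearest-neighbour distribution D₁₂(r), the two-axis
  association classification (Types 0–IV from the standardised axes
  `P(r) = (D₁₂ − E[D₁₂])/SD[D₁₂]`, `M(r) = (K₁₂ − E[K₁₂])/SD[K₁₂]`
  against a ±2.33 acceptance box), and the normalised mark variogram
  `γ_m(r) = E[½(m(x) − m(x+r))²]/σ_m²` for diameter autocorrelation
  (1 = independence, < 1 similar neighbours, > 1 segregation).
* **Null models and Monte Carlo envelopes**: conditioned CSR, Thomas
  cluster processes (simulation and minimum-contrast fitting from K),
  antecedent-pattern independence nulls, random labelling, and pointwise
  rank envelopes (e.g. rank 13 of 499 simulations ≈ 95% coverage).
* **A synthetic stem-map generator** with presets emulating a disturbed
  secondary stand and an undisturbed old-growth stand, so the complete
  pipeline can be exercised and calibrated without field data.

## Worked example

```r
library(stemspat)

map <- generate_stem_map(preset_undisturbed(), seed = 42)
map
#> Stem map: 1074 trees, 4 species, window [0, 100] x [0, 100] m
#> Species counts:
#>  Pk  Bp  Am  Ta
#> 571 214 168 121

head(species_summary(map)[, c("species", "mean_dbh", "sd_dbh",
                              "basal_area", "density", "gini")], 2)
#>   species mean_dbh   sd_dbh basal_area density      gini
#> 3      Pk 19.57147 8.868035  20.698639     571 0.4533465
#> 2      Bp 14.61774 5.462639   4.090601     214 0.3869572

tab <- structural_indices(map)          # per-tree U, M, N
index_distribution(tab, "M", "Pk")$mean # mingling of the dominant conifer
#> [1] 0.2787846

g <- pair_correlation(map, "Pk")        # univariate g(r), translation corr.
round(g$value[1:5], 2)                  # > 1: clustering at short range
#> [1] 2.23 1.94 2.01 1.95 1.86

mv <- mark_variogram(map, "Pk")
round(mv$gamma[1:5], 2)                 # < 1: similar diameters up close
#> [1] 0.92 0.92 0.97 0.92 0.97

tr <- run_scheme(map, "Pk", "Bp", null = "thomas", nsim = 199, seed = 1)
table(tr$type)                          # association types across scales
#>   0   I  II III  IV
#>  19   0   0   0   0
```

The summary says the dominant conifer (571 stems/ha) holds most of the
basal area with moderate size inequality (Gini 0.45); its pair
correlation near 2 at 1–5 m shows small-scale clustering, the mark
variogram below 1 shows mild positive diameter autocorrelation among
near neighbours, and the low mingling mean (0.28) shows mostly
conspecific surroundings. The association trajectory is Type 0 at every
distance where the axes are defined (19 of 30 here — the
nearest-neighbour axis saturates at these densities beyond ~15 m, so its
null SD is zero there): no detectable association between the two
species once the second species' own clustering is built into the null.

`run_full_analysis(map, out_dir, seed = 1)` runs every stage (summary,
indices, CSR envelopes for g, all pairwise association schemes, mark
variograms with random-labelling envelopes) and writes one CSV + JSON
metadata pair per stage.

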