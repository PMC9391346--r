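---
title: "Methods: spatial structure analysis of stem maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial structure analysis of stem maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical methods implemented in
`stemspat`, the conventions and defaults chosen where the literature
leaves room, and the limits of what the package's synthetic validation
can show about real stands.

## The data model

A stem map is a marked point pattern: stem coordinates $(x, y)$ in
metres inside a rectangular window $W$, a species label and a diameter
at breast height (DBH, cm) per tree, optionally a height. Coordinates
are continuous, with the origin at the plot's lower-left corner; there
is no geodesy. The census convention assumed throughout is a fully
mapped plot with a lower DBH threshold: `read_stem_map()` drops stems
below `min_dbh` (default 5 cm) at read time and reports the count.
Boundary trees are kept; subplot cells are half-open with a closed top
edge so each tree belongs to exactly one cell.

## Stand-level summaries

Basal area uses the cross-sectional area $\pi (d/200)^2$ m² for a stem
of $d$ cm; standard deviations are sample ($n-1$) values. The Gini index
$G = \sum_i \sum_j |v_i - v_j| / (2 n^2 \bar v)$ is computed on per-tree
basal areas by default — the usual convention in the forest-structure
literature, and the one consistent with typical published magnitudes —
with DBH available as an option; the choice matters because area is a
convex transform of diameter, so area-based Gini runs higher. The
importance value is the mean of relative density, relative frequency and
relative dominance; occurrence frequencies are normalised across species
(the classical convention) since only the one-third-sum structure is
fixed by the definition.

## Nearest-neighbour structural indices

All three indices use the four nearest neighbours of each reference
tree, ties broken by tree index so results are deterministic.

* **Uniform angle index** $U_i$: the four neighbours are sorted by
  azimuth, the four circular gaps formed, and each reference angle taken
  as the smaller angle between adjacent rays, $\min(g, 360° - g)$.
  $U_i$ is the fraction of angles *below* the standard angle
  $\alpha_0$ (default 72°, the conventional $360°/(k+1)$ for $k = 4$).
  With this orientation clumped neighbourhoods give high $U$ and the CSR
  expectation is just below 0.5 (the gap of four uniform directions is
  $360° \times \mathrm{Beta}(1,3)$, giving
  $P(\alpha < 72°) \approx 0.496$) — the reading under which observed
  means near 0.5 are interpreted as random. The opposite indicator
  orientation appears in some typeset formulas but contradicts both the
  verbal definition and that interpretation, so it is not used.
* **Mingling** $M_i$: fraction of heterospecific neighbours.
* **Neighbourhood comparison** $N_i$: fraction of neighbours with DBH
  $\geq$ the reference ($N_i = 0$ means full local dominance); equal
  diameters count as "not smaller", as the definition's *otherwise*
  branch requires.

Edge handling: the literature rarely states any for these indices. The
default flags trees within a 5 m buffer of the window edge and excludes
them as references only (they remain neighbours); `buffer = 0`
reproduces an uncorrected analysis.

## Second-order statistics

All pair-based estimators use ordered pairs and the translation edge
correction $w_{ij} = |W| / ((L_x - |\Delta x|)(L_y - |\Delta y|))$, the
reciprocal fraction of window translations keeping both endpoints inside.

* **Pair correlation** $g(r)$: ring (box-kernel) estimator,
  $$\hat g(r) = \frac{\sum w_{ij}\,\mathbf 1(|d_{ij} - r| \le h/2)}
  {2\pi r\, h\, \hat\lambda_a \hat\lambda_b\, |W|},$$
  with ring width $h$ = 1 m and a 1 m grid by default. Intensities are
  $n/|W|$, so the univariate CSR expectation is $(n-1)/n$ rather than
  exactly 1 — negligible at census sizes. Values at $r < h/2$ are
  reported `NA`: there the ring overlaps zero distance and the $1/2\pi r$
  normalisation is unstable below stem scale.
* **Bivariate Ripley** $K_{12}(r)$: cumulative analogue, expectation
  $\pi r^2$ under independence.
* **Nearest-neighbour distribution** $D_{12}(r)$: empirical CDF of the
  distance from each pattern-1 tree to its nearest pattern-2 tree, with
  the reduced-sample border correction (only trees at least $r$ from
  every edge contribute at $r$). The uncorrected CDF is available; note
  the reduced-sample estimator is not guaranteed monotone because its
  denominator shrinks with $r$ (the uncorrected mode is, by
  construction). Closed CSR form: $1 - \exp(-\lambda_2 \pi r^2)$ with
  $\lambda_2$ the intensity of the second pattern.

Scale ranges default to 0–25 m univariate and 0–30 m bivariate on a
100 m plot; a warning is issued beyond one quarter of the smaller window
dimension, where edge-corrected estimates grow unreliable.

## Association scheme

The two axes standardise the bivariate statistics against a simulated
independence null: $P(r) = (D_{12} - E[D_{12}])/SD[D_{12}]$ and
$M(r) = (K_{12} - E[K_{12}])/SD[K_{12}]$, with $E$ and $SD$ estimated
from the same simulation set used for envelopes (499 draws by default) —
the scheme's Monte Carlo construction, not a closed form. Classification
per distance: Type 0 inside the box $[-c, c]$ on both axes, otherwise
Type I ($M<0, P<0$, segregation), II ($M>0, P<0$, partial overlap),
III ($M>0, P>0$, mixing), IV ($M<0, P>0$); an axis exactly 0 outside the
box counts as positive. The default box half-width is $c = 2.33$, the
value conventionally printed for this scheme; note it is described there
as a two-sided $p = 0.025$ bound although the matching normal quantile
would be 1.96 — the package keeps the printed 2.33 and leaves the
threshold configurable rather than silently resolving the discrepancy.
Where a null SD is zero (typically $D_{12}$ saturated at 1 at larger
distances) the axis is undefined; such distances are excluded from type
summaries and reported as `NA`.

The null for a species pair is asymmetric ("antecedent"): the pattern
regarded as established (e.g. an upper height class that constrains
recruitment beneath it, while the reverse influence is implausible) is
held fixed, and the other is redrawn — by default from a Thomas cluster
process fitted to it, so the null keeps the species' own aggregation and
only breaks the cross-species dependence; conditioned CSR is the
simpler option.

## Mark variogram

The normalised mark variogram is
$\gamma_m(r) = E[\tfrac12 (m(x) - m(x+r))^2]/\sigma_m^2$, estimated with
the same rings and translation weights as $g(r)$ and the sample ($n-1$)
mark variance. Calibration: independent marks give 1; positive
autocorrelation (similar diameters among near neighbours) gives values
below 1; size segregation gives values above 1. Garbled typeset variants
of this definition circulate; only this form matches that calibration,
so it is the one implemented. The null is random labelling: marks
permuted over fixed locations, with the pair structure computed once and
reused across permutations.

## Null models and envelopes

* **CSR** is conditioned on the observed count (binomial process), since
  observed patterns have fixed size; unconditioned Poisson is not
  offered.
* **Thomas process**: Poisson parents of intensity $\kappa$ simulated on
  the window extended by $4\sigma$ (avoiding cluster edge deficits),
  Poisson($\mu$) offspring per parent with isotropic Gaussian($\sigma$)
  displacement, offspring clipped to the window. Exact-count
  conditioning, needed for the synthetic generator and the antecedent
  null, accumulates offspring over repeated realisations and subsamples
  uniformly to $n$ — an independent thinning that preserves the cluster
  geometry.
* **Fitting** is by minimum contrast on
  $K_\theta(r) = \pi r^2 + (1 - e^{-r^2/4\sigma^2})/\kappa$ with the
  variance-stabilising $K^{1/4}$ transform over $r \in [1, 25]$ m by
  default, Nelder–Mead over $(\log\kappa, \log\sigma)$ from a 3×3 start
  grid; $\mu$ is set from the observed intensity. A CSR-like input drives
  $1/\kappa \to 0$ or $\sigma$ to the scale ceiling; the fit is then
  flagged degenerate rather than failing.
* **Envelopes** are pointwise $k$-th extremes of the simulated statistic;
  nominal two-sided coverage $1 - 2k/(n_{sim}+1)$ is explicit metadata.
  For the customary 499 simulations the default rank 13 gives ~95%;
  rank 3 gives the ~99% preset. Published analyses quote both levels for
  the same 499 draws, so the level is never implicit here. Pointwise
  envelopes control the error rate per distance, not globally — a curve
  escaping somewhere along 30 distances is expected under the null at
  roughly the pointwise rate times an effective number of independent
  scales.

## Synthetic stem maps

The generator draws, per species, an exact tree count (conditioned, not
Poisson, so calibration experiments are sharp), locations from CSR or a
Thomas model, and diameters from a truncated exponential (reverse-J),
truncated normal (unimodal/bell) or two-component normal mixture
(bimodal), all truncated at the 5 cm census threshold. Optional mark
smoothing mixes each diameter with a Gaussian-kernel average of its
neighbours within $\sim 3\rho$ and rescales to the original mean and
variance, inducing positive short-range autocorrelation without changing
the marginal moments the variogram normalises by.

Two presets emulate the structure of a disturbed secondary stand
(densities 664/401/175/117 per ha; bimodal pioneer cohort, two reverse-J
species, one unimodal) and an undisturbed old-growth stand
(571/214/168/121 per ha; all bell-shaped). Diameter-model parameters are
documented constants set to the published summary moments of those stand
types; for the bell-shaped species the printed mean/SD pairs are used
directly as the underlying normal parameters, because exact moment
matching under 5 cm truncation would force the mode to the threshold and
destroy the bell shape — the realised moments therefore sit slightly
above the nominal ones, a deliberate shape-over-moments choice. Cluster
parameters (10–40 parents per species per ha, $\sigma$ = 3–5 m) give the
short-range aggregation typical of such stands, and mark smoothing
($\rho$ = 5 m, weight 0.3) a mild positive diameter autocorrelation.

What the synthetic data do *not* emulate: environmental heterogeneity
(all intensities are homogeneous), inter-species dependence (species are
generated independently — the null case), height structure, and any
plot-specific spatial detail. Passing calibration tests therefore shows
the estimators are correct and unbiased under known conditions, not that
any particular field result would be reproduced.

## Validation problem sizes

The package's statistical calibration (in the test suite and
`scripts/acceptance.R`) uses: 50 replicates of $n = 500$ CSR patterns on
1 ha for the $g$ and $\gamma_m$ calibrations (means over 5–20 m within
±0.05 of 1); 20 replicates of two independent $n = 300$ patterns with a
199-simulation null for the scheme-axis calibration (mean of $P$ and $M$
within ±0.15 of 0 — the per-replicate axis means retain substantial
variance because $K$-based z-scores are strongly correlated across
distances, so this band is a few standard errors wide, not tight);
100 replicates against the closed-form Thomas pair correlation
$1 + e^{-r^2/4\sigma^2}/(4\pi\sigma^2\kappa)$ and 20 replicate
minimum-contrast fits (medians within ±30%); 20 replicates of
199-simulation envelopes for the escape-rate check; and exhaustive
brute-force oracle comparisons on maps of up to 50 trees. These sizes
keep every experiment sharp enough to detect estimator bias of a few
percent while completing in minutes on one core.

## Known limitations

Rectangular windows only; no inhomogeneous second-order statistics; no
replicated-plot pooling; the neighbourhood indices are fixed at four
neighbours (the conventional choice) apart from the standard angle being
configurable; DBH is the only mark analysed. The Thomas fit inherits the
usual minimum-contrast caveats: parameters are weakly identified when
clusters overlap heavily, and intensity estimated from a clustered
realisation correlates with the pattern, biasing $\hat\kappa$ slightly
upward at these plot sizes.
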