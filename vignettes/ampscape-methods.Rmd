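---
title: "Methods: species-agnostic connectivity and its uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-agnostic connectivity and its uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampscape)
```

## The model

`ampscape` models structural landscape connectivity without species-specific
movement parameters. The premise is that human modification is the dominant,
measurable constraint on ecological flow at regional scales, so a resistance
surface can be built from mapped human footprints alone and connectivity can
be summarized as electrical current density on the resulting resistor
network.

### From footprints to modification

Every footprint category $j$ present in a cell contributes a modification
value $h_j \in [0, 1]$, taken from an expert catalog that distinguishes a
physical-footprint score $h_F$, an intensity-of-use score $h_U$, and (for the
averaged index $H_{FU}$) their mean, and that may assign different values in
the forest- and agriculture-dominated regions. Per cell the values combine by
the fuzzy algebraic sum

$$H = 1 - \prod_j (1 - h_j),$$

so multiple overlapping footprints increase modification, the combined value
never falls below its largest term, and it never exceeds 1. Cells with no
footprint have $H = 0$.

Because the catalog defines $H_{FU}$ at the category level, the package
averages $h_F$ and $h_U$ *per category before* the fuzzy sum
(`fu_average = "category"`). The alternative — averaging the finished $H_F$
and $H_U$ surfaces — is exposed as `fu_average = "surface"`; the two agree
exactly wherever at most one footprint is present and differ only through the
nonlinearity of the product on multiply-impacted cells.

### From modification to resistance

$$R = f(H) + s/4 + w_{\mathrm{res}} \cdot w$$

with percent slope $s \in [0, 100]$ and water flag $w$. Two scalings bracket
the plausible contrast between natural and modified land:

* high contrast: $f(H) = (H + 1)^{10}$, giving $\{1, 57.7, 1024\}$ at
  $H = \{0, 0.5, 1\}$;
* low contrast: $f(H) = 1 + 1000 H$, giving $\{1, 501, 1001\}$.

Both have $f(0) = 1$, the resistance floor. The slope divisor 4 makes a 100%
slope cost 25 resistance units and is not varied. Water resistance takes
three levels: 0 (water is no barrier), 1000 (near-absolute barrier,
comparable to complete modification), and the main-map value 57.7 — the
high-contrast scaling of an intermediate modification of 0.5, stored as the
printed constant `round(1.5^10, 1)` while the scaling function itself uses
the exact power. The water term is additive on top of $f(H)$ and water cells
keep their footprint-derived $H$, so a fully modified water cell can
technically reach $1024 + 1000 = 2024$.

Resistance is computed at fine resolution (to limit rasterization artefacts
on one-cell-wide linear features) and then block-averaged to the analysis
resolution with `aggregate_raster()`. Partial edge blocks average over the
available cells, and a coarse cell is NoData only if all its fine cells are.
Exact-division aggregation preserves the global mean.

### Current density

`build_graph()` turns the raster into a graph: nodes are valid cells, edges
join 8-neighbours (4-neighbourhood available), and edge conductance is the
inverse of the mean of the two cell resistances — each cell contributes half
its resistance in series — with diagonal edges divided by $\sqrt{2}$ for the
longer centre distance. The mean-of-conductances alternative is exposed but
not default. Water cells are ordinary high-resistance cells, never removed.

`place_boundary_nodes()` spaces nodes at equal arc length around the
outermost ring of the buffered extent from a seeded offset. Boundary (rather
than interior) sources remove node-placement bias from the interior once the
buffer — at least 20% of the study-area width — is clipped away after
solving.

`solve_pair()` injects a unit current, grounds the sink, and solves the
reduced symmetric positive-definite Laplacian system by sparse Cholesky
factorization. Per-cell current density is half the sum of absolute currents
on incident edges, with the terminals set to the injected magnitude, so every
cell of a uniform chain registers exactly 1. `accumulate()` samples distinct
node pairs uniformly at random without replacement and sums the per-pair
densities; because per-edge currents are invariant to the choice of ground,
it factorizes the reduced system once for a fixed reference node and reuses
the factor for every pair, which is algebraically identical to per-pair sink
grounding and roughly an order of magnitude faster.

Convergence follows a "three nines" rule: after each solve beyond
`min_pairs = 10`, the Pearson correlation between the cumulative map before
and after the latest solve is computed, and accumulation stops at
$r \ge 0.999$ (or when all pairs are exhausted). What exactly the original
GFlow convergence function correlates is not documented; this implementation
makes one concrete, reproducible choice and records the full trace in the
result rather than claiming bit-compatibility. Per-pair maps are accumulated
as raw sums — any normalization would be absorbed by the downstream
z-standardization anyway.

### Map comparison and variance partitioning

Clipped maps are standardized to $z = (x - \bar{x})/sd$ using the population
standard deviation (divide by $n$); at raster cell counts the distinction
from the sample convention is far below any decision threshold. Cells are
classified important at $z \ge$ 0, 1, or 2; the $\ge$ convention is applied
uniformly at all three cutoffs, so classifications are nested by
construction. Constant maps cannot be standardized and raise an error.

The eight factorial maps (H index × water resistance × scaling, the main
$H_{FU}$ map excluded) are compared by cell-wise Pearson correlation and, per
cutoff, by the proportion of cells classified identically. Similarities
convert to dissimilarities, and `varpart_dbrda()` partitions the between-map
variance: principal coordinates of the Gower-centred $-D^2/2$ matrix, axes
with positive eigenvalues retained (no Lingoes/Cailliez correction, matching
default db-RDA behaviour; a negative-eigenvalue-free transform is preferred
instead, below), redundancy-analysis $R^2$ of the retained coordinates on
every subset of the dummy-coded factors, and each factor's unique fraction as
the drop from the full model when that factor is removed. The Ezekiel
adjustment $R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-1-p)$ is available
(`adjust = TRUE`); unexplained variance is 100% minus the sum of the unique
fractions. Negative fractions, where they arise, are reported as-is, and an
all-zero dissimilarity matrix is flagged degenerate rather than partitioned.

Two conventions deserve their own paragraph because the literature leaves
them open. First, the dissimilarity transform of a correlation matrix:
$D = 1 - r$ is the simplest choice but is strongly non-Euclidean, forcing the
PCoA step to discard negative eigenvalues and making fractions depend on that
discard; $D = \sqrt{1 - r}$ embeds exactly in Euclidean space (it is what
`sqrt.dist = TRUE` does in vegan's distance-based tools), so nothing is
discarded. Second, with only $n = 8$ maps and $p = 3$ regressors, the Ezekiel
adjustment is aggressive ($\times 7/4$ on the unexplained share) and can push
fraction sums past 100%; unadjusted fractions remain interpretable shares of
total variance that, for an orthogonal factorial, sum with the residual to
exactly 100%. `reanalyze_map_correlations()` therefore defaults to
$\sqrt{1 - r}$ with unadjusted fractions — the convention that, applied to
the shipped published correlation matrix, reproduces the published
partitioning most closely (to within about 3 percentage points, with the
factor ranking water > scaling > H index preserved exactly). Both defaults
can be overridden.

## The synthetic generator

`generate_landscape()` produces the data structures the analysis assumes, not
a faithful land-cover model. Footprint patches are thresholded smoothed
Gaussian noise (threshold chosen by quantile, so realized coverage tracks the
requested fraction); the first category is drawn as one-cell-wide straight
segments between random border points, because linear features and their
rasterization artefacts are the main reason the resistance stage works at
fine resolution; water is a thresholded smooth field, giving contiguous
patches; slope is smoothed noise rescaled to $[0, 45]$ percent — a
field-realistic upper bound for terrain that still matters next to the
1–1024 modification term, since slope is deliberately a minor additive
penalty (at most 25); the region mask splits the grid along a wavy boundary.
An `overlap` parameter mixes a shared latent field into every patch category
(default 0 = independent), since real footprint co-occurrence rates are not
something the generator should silently assume. Catalog values are uniform
on $[0, 1]$ per category and region.

What the generator does *not* emulate: real land-cover class semantics,
footprint size/shape distributions, spatial correlation between footprints
and terrain, vector-polygon geometry, and realistic proportions between
region types. Tests passing on these landscapes therefore demonstrate the
correctness and stability of the algorithms — conservation laws, oracle
equivalence, design-factor recovery — not that any particular real landscape
would yield similar maps.

## Numerical choices and degenerate inputs

* Laplacian solves: sparse Cholesky with permutation on the
  ground-node-reduced system; solutions match a dense pseudo-inverse oracle
  to $10^{-8}$ and satisfy Kirchhoff's law at non-terminal nodes to
  $10^{-8}$ (tested on random grids up to 12×12).
* Disconnected rasters, non-positive resistances, and sub-2-cell rasters are
  rejected at graph construction.
* PCoA eigenvalues are retained above a $10^{-9}$ relative tolerance.
* Boundary-node snapping walks the perimeter ring in both directions to the
  nearest valid, unused cell; ties resolve in ring order.
* Classification ties ($z$ exactly at a cutoff) count as important.
* Fuzzy-sum products are computed in double precision directly; with
  $h \le 1$ and realistic layer counts no log-space evaluation is needed.

## Interfaces and problem sizes

The package surface is R functions plus `run_all()` for orchestration and
`scripts/acceptance.R` for headline numbers; no shell CLI is shipped, in line
with comparable R analysis packages. Rasters interchange as ESRI ASCII grids
(`read_asc()`/`write_asc()`), catalogs and matrices as CSV, configurations as
YAML, reports as JSON.

The test suite exercises the full factorial pipeline on a 300×300 buffered
fine grid (200×200 study area, 25% buffer) aggregated ×3 to a 10,000-node
circuit with 20 boundary nodes — a size chosen so the whole ensemble of nine
maps completes in seconds while still separating fine and analysis
resolutions; solver oracles run on 5×5–12×12 grids where dense pseudo-inverse
computation is exact and cheap.

## Limitations

* Current density is a structural connectivity proxy; no validation against
  movement or biodiversity data is attempted here.
* The two scalings bracket contrast but do not explore intermediate
  exponents; slope and its divisor are fixed.
* The db-RDA partitioning deliberately omits interaction terms (eight maps
  cannot support them), so "unexplained" variance includes any interactions.
* Only omnidirectional boundary-to-boundary flow is modelled; least-cost
  paths and patch-based network metrics are out of scope.
* GeoTIFF I/O is not provided; ESRI ASCII grids are the interchange format.
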