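# ampscape

Species-agnostic landscape-connectivity modelling with circuit theory, plus a
factorial uncertainty analysis of the modelling decisions involved.

Connectivity planning at regional scales often cannot commit to a focal
species. A species-agnostic alternative models "ecological flow" directly
from human landscape modification: the more modified a cell, the more it
resists movement. `ampscape` implements that pipeline end to end and — just as
importantly — quantifies how sensitive the resulting maps are to the three
big modelling decisions: how human modification is defined, whether water is
a barrier, and how modification is scaled into resistance.

The pipeline:

1. **Human modification.** Each binary footprint layer *j* (roads, crops,
   wells, ...) carries an expert score *h<sub>j</sub>* ∈ [0, 1], possibly
   different between a forest- and an agriculture-dominated region. Layers
   are combined per cell with the fuzzy algebraic sum

   *H* = 1 − ∏<sub>j</sub> (1 − *h<sub>j</sub>*),

   which is at least as large as its largest term, additive in spirit, and
   bounded by 1. Variants: *H<sub>F</sub>* (physical footprint),
   *H<sub>U</sub>* (intensity of use), *H<sub>FU</sub>* (their mean).
2. **Resistance.** *R* = *f*(*H*) + *s*/4 + *w*<sub>res</sub>·*w*, with
   percent slope *s*, water flag *w*, and a scaling function *f* that is
   either high-contrast, *f*(*H*) = (*H* + 1)<sup>10</sup> (range 1–1024), or
   low-contrast, *f*(*H*) = 1 + 1000·*H* (range 1–1001). Fine-resolution
   resistance is aggregated to the analysis resolution by block means.
3. **Current density.** The raster becomes a resistor network (edge
   conductance = inverse mean resistance of the two cells, diagonals
   distance-weighted). Unit current is injected between random pairs of
   boundary nodes spaced evenly around a buffered extent, each pair solved
   through the sparse graph Laplacian; accumulation stops when successive
   cumulative maps correlate at ≥ 0.999. The buffer is then clipped off.
4. **Uncertainty analysis.** Eight maps from the 2×2×2 factorial (H index ×
   water resistance × scaling) are z-standardized, classified at cutoffs
   z ≥ 0/1/2, compared by Pearson correlation and classification agreement,
   and the between-map dissimilarity is partitioned among the three factors
   with distance-based RDA.

A synthetic-landscape generator (autocorrelated patches, one-cell-wide
linear features, smooth slope, water bodies, two-region mask) makes the whole
analysis runnable and testable without any external data.

## Worked example

```r
library(ampscape)

cfg     <- landscape_config(nrow = 60, ncol = 60, n_categories = 5, seed = 42)
bundle  <- generate_landscape(cfg)
catalog <- generate_catalog(5, seed = 42)

H <- modification_surface(bundle, catalog, index = "H_FU")
R <- resistance_map(H, bundle, contrast = "high")   # water at 57.7
print(R)
#> <grid_raster> 90 x 90 cells, cellsize 100, origin (0, 0)
#>   values: min 1, mean 61.71, max 943.4 (8100 valid, 0 NoData)

cmp <- run_uncertainty_analysis(bundle, catalog, agg_factor = 3,
                                n_nodes = 12, seed = 42)
print(cmp)
#> <connectivity_comparison> 8 factorial maps + main map
#>   pairs solved per map: 44, 44, 44, 50, 40, 40, 40, 44
#>   correlation-based variance partitioning:
#> db-RDA variance partitioning (unadjusted unique fractions)
#>   water            42.5 %
#>   scaling          22.1 %
#>   h_index          23.5 %
#>   unexplained      11.9 %
```

The resistance summary says the synthetic landscape spans nearly the full
1–1024 high-contrast range. Each factorial map converged after 40–50 random
node pairs. On this landscape the water-resistance decision dominates the
between-map variance (42.5%), i.e. whether lakes and rivers are treated as
barriers changes the connectivity map more than the choice of modification
index or scaling — the same qualitative conclusion the method reaches on real
provincial data.

A published 8×8 correlation matrix between the factorial maps of a
province-wide (Alberta) analysis ships as a fixture and can be re-analyzed
directly:

```r
print(reanalyze_map_correlations())
#> db-RDA variance partitioning (unadjusted unique fractions)
#>   water            39.5 %
#>   scaling          25.5 %
#>   h_index          15.3 %
#>   unexplained      19.7 %
```

`run_all(run_config(...), out_dir)` drives the full pipeline and writes the
maps (ESRI ASCII grids), matrices (CSV) and a JSON run report; every artefact
is re-derivable from the configuration seeds.

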