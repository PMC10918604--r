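# seascapeConnect

Combined seascape-connectivity analysis for sessile marine invertebrates with
pelagic larvae — corals, gorgonians, and similar broadcast spawners whose only
mobile stage drifts with the surface currents. The package asks, end to end,
the question such studies pose: *do ocean currents and geography explain the
spatial genetic structure of the populations?*

It provides three layers that are usually scattered across different tools:

1. **Larval dispersal physics.** A passive Lagrangian particle tracker (RK4
   over bilinearly interpolated gridded currents read from NetCDF) releases
   thousands of particles per site and year, kills particles that strand on
   land or leave the domain, and reduces the trajectories to buffer-zone
   connectivity matrices `P[i,j]` (the proportion of site-*i* particles inside
   a 20 km source zone of site *j* at the end of a pelagic larval duration),
   self-recruitment, displacement summaries and rare long-distance-dispersal
   flags across years.

2. **Population genetics.** Genotype I/O (VCF), an auditable SNP filtering
   ledger (site presence, MAF, maximum heterozygosity, missingness, greedy
   LD pruning), per-site diversity (Ho, sample-size-corrected Hs, FIS =
   1 − Ho/Hs), Weir–Cockerham FST from variance components

   θ̂ = Σₗ aₗ / Σₗ (aₗ + bₗ + cₗ)

   (ratio of sums across loci, never a mean of ratios), and two outlier scans
   — a trimmed chi-square fit to a non-negative per-locus differentiation
   ratio, and a PCA z-score/Mahalanobis scan — whose joint neutral set defines
   the analysis panel.

3. **Spatial inference.** Marine least-cost distances (Dijkstra over the
   ocean-cell graph), one-sided Mantel tests of isolation by distance,
   distance-based Moran eigenvector maps (dbMEM: MST-threshold truncation,
   Gower-centred PCoA), asymmetric eigenvector maps (AEM) built from the
   directed dispersal graph, and redundancy analysis (RDA) on
   Hellinger-transformed allele frequencies with Ezekiel-adjusted R²,
   permutation ANOVA, variance partitioning and forward selection.

A synthetic-data module generates every input — coastal ocean fields with
interannual variability and rare strong-advection years, site transects, and
stepping-stone Wright–Fisher genotypes with known migration and selfing — so
the full pipeline runs and is tested without any external download.

## Worked example

The reference synthetic study — ten coastal sites in a northward jet with
eddies, three years (2012 a rare strong-advection year, multiplier 3), 500
particles per site-year, and 1000-locus stepping-stone genotypes — runs in
about a minute:

```r
library(seascapeConnect)
res <- runPipeline(defaultPipelineConfig(seed = 1, outDir = "run1"))

res$mantel
#> $r        0.9867
#> $r2       0.9736
#> $p        0.001
res$globalFst
#> [1] 0.0778
res$interannual$flagged      # rare-advection years detected per site
#>   site year
#>    S01 2012  ... (2012 flagged at several sites)
head(res$diversity, 3)
#>   site  n     Ho     Hs    Fis
#>    S01 15  0.315  0.334  0.055
#>    S02 15  0.300  0.339  0.113
#>    S03 15  0.345  0.355  0.027
```

Reading the output: genetic distance grows tightly with marine least-cost
distance (Mantel r² = 0.97, p = 0.001 — the synthetic stepping-stone chain is
a textbook isolation-by-distance system), global FST ≈ 0.08 reflects the
migration rate between neighbouring demes, FIS > 0 reflects the simulated
10% selfing, and the 3× advection year is flagged because its maximum
particle displacement exceeds twice the other years' maxima. `run1/` holds
the site table, yearly and mean connectivity matrices, a dispersal summary
table, the filter ledger, diversity and pairwise-FST tables, dbMEM/AEM
scores, an RDA report and a JSON manifest of every parameter, seed and file
hash.

Individual stages are ordinary functions (`makeVelocityField`, `advect`,
`dispersalMatrix`, `filterChain`, `wcFst`, `detectOutliers`,
`leastCostDistance`, `mantelTest`, `dbMem`, `aem`, `rdaFit`, ...) and a thin
wrapper for shell use lives at `inst/scripts/run_pipeline.R`.

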