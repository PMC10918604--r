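---
title: "Methods: larval dispersal simulation and spatial population genetics"
author: "seascapeConnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: larval dispersal simulation and spatial population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models, their
assumptions, the parameters that matter, the numerical choices, and what the
synthetic tests do and do not demonstrate about real data.

# The scientific setting

Sessile marine invertebrates with pelagic larvae connect their populations
only through larval drift. Two observable layers describe that connectivity:
a *physical* layer — where do passively drifting larvae actually go, given
the surface currents of a particular year? — and a *genetic* layer — how much
allele-frequency differentiation has accumulated among sites, and does it
follow geography? The package implements both layers and the statistical
bridge between them, so that a single configured run produces dispersal
probabilities, diversity and differentiation tables, isolation-by-distance
tests, spatial eigenvector bases and a redundancy analysis.

# Larval dispersal model

## Velocity fields and interpolation

Currents are gridded surface velocities `u(t, lat, lon)`, `v(t, lat, lon)`
in m/s on a regular lon/lat grid with a cell-level land mask, read from and
written to CF-style NetCDF (`uo`/`vo`, land as fill values). Only one depth
is modelled: larvae are treated as passive surface drifters with no
buoyancy, swimming, or vertical behaviour. Velocity at an arbitrary point
and time is bilinear in space and linear in time. Land cells among the four
spatial neighbours contribute zero velocity and the remaining weights are
renormalized; if all four neighbours are land the query signals "on land",
which is distinct from the out-of-domain error. Land itself follows a
nearest-cell rule (a point belongs to the grid cell whose centre is
nearest; exact midpoints round to the east/north cell). There is no
sub-cell coastline.

All metric conversions use the local-tangent approximation 1° lat =
111.32 km, 1° lon = 111.32·cos(lat) km, which matches the haversine radius
used throughout to better than 0.01% and is standard for regional
Lagrangian work.

## Integration

Particles advance by classical 4th-order Runge–Kutta on the interpolated
velocity, default step 60 minutes (tests needing precision use 15). The
step is internally adjusted so a whole number of steps spans one day, and
positions are snapshotted at release and every whole day, so the 14- and
21-day marks used for connectivity are always stored exactly. A step that
ends on a land cell or outside the domain kills the particle at that step;
dead particles carry no further positions, and alive + dead = released at
every snapshot. Release geometry is a uniform 1 km disc around the site
(a point release is available); the scatter draw is keyed by site and seed
only, so years with identical fields produce identical trajectories and all
interannual variation is oceanographic. Horizontal diffusion is off by
default — the model is deliberately purely advective — and step-halving
convergence (< 0.5 km over 21 days in the eddy field) plus a time-reversal
check (negated field returns survivors to < 1 km of their origin) are part
of the test suite.

## Connectivity statistics

For a pelagic larval duration (PLD) of `d` days, `P[i, j]` is the
proportion of site-i particles credited to site j's *source zone*, a
great-circle disc of 20 km radius about the site. The default membership
convention is the **final snapshot**: a particle counts for zone j if it is
inside that zone at the `d`-day snapshot, among particles still alive then;
the denominator is the number alive at `d` days. The wording "entered the
zone" is ambiguous between final position and any-time entry, so the
any-time convention is available behind a flag (`convention = "any_time"`);
on identical trajectories it can only increase entries, which is asserted
as a property. Yearly matrices are computed first and averaged afterwards
(normalize per year, then average). Rows with zero survivors are NaN with a
warning, not an error. Percent-remaining denominators are per release.

The interannual report gives, per site, the year-to-year range of mean
displacement, the ratio of overall maximum to overall mean displacement,
and flags *rare long-distance dispersal years*: years whose maximum
displacement exceeds `factor` (default 2) times the mean of the **other**
years' maxima. The leave-one-out baseline matters: typical years already
have max ≈ 3 × mean displacement, so comparing a year's maximum against a
baseline that includes itself would either flag everything or nothing.

# Synthetic ocean generator

The generator emulates a regional coastal analysis-and-forecast product: a
rectangular domain with a rasterized land strip, a mean alongshore jet, and
a field of ten rotational Gaussian eddies (velocity scale `eddyAmp`,
e-folding scale `eddyScaleKm`) whose centres, signs and strengths depend
only on the spec's seed. Interannual structure is explicit in the spec:
per-year multipliers, a list of rare strong-advection years with a boosted
multiplier (default 3), and optional per-year jet-direction offsets. A
rare-event year is therefore *exactly* the base pattern scaled, which makes
the flagging contract constructive: the tests verify that max |u| in a
multiplier-3 year is exactly three times the reference year's. Speeds are
capped at 2 m/s.

The reference configuration (`defaultPipelineConfig()`) uses a 0.03 m/s jet
and 0.06 m/s eddies on a 0.1° grid with sites 30 km offshore, chosen so
that 14-day displacements fall in the tens-of-kilometres range typical of
passive coastal larval dispersal and so that site-level outcomes span the
realistic spectrum — some sites retain most particles, some lose all to
stranding — rather than all behaving identically. What the generator does
*not* emulate: realistic bathymetry or coastline shape, tides, Stokes
drift, sub-daily variability, and vertical structure. Tests passing on this
substrate validate the machinery (interpolation, integration, accounting,
statistics), not any particular real ocean.

# Stepping-stone genotype generator

Diploid biallelic genotypes come from a forward Wright–Fisher simulation:
`d` demes of `N` diploids, non-overlapping generations; each offspring
draws its parent deme from a row-stochastic backward migration matrix
(adjacent-neighbour rate `m`, or a custom matrix, e.g. derived from a
connectivity matrix), then with probability `s` (the selfing rate) both
gametes come from a single uniformly drawn parent, otherwise from two
uniformly drawn parents. Initial allele frequencies are uniform on
[0.1, 0.9] to avoid immediate fixation; there is no mutation or
recombination (loci are unlinked by construction). This mixed-mating model
has the classical equilibrium FIS = s/(2−s), which the estimators must
recover within ±0.03, and the two-deme island case anchors FST near
1/(1+4Nm).

Two statistical facts shape the tests here. First, all loci share one
pedigree, so the realized multilocus FST of a single run carries
demographic noise that more loci cannot remove — at Nm = 1 the run-to-run
spread is substantial. Second, without mutation, heterozygosity decays with
effective size, and after 2000 generations at N = 100 only a small fraction
of loci still segregate. The island-model recovery check therefore pools
Weir–Cockerham variance components over three replicate runs of the
implementation and three of an independently coded brute-force two-deme
simulator (ratio of pooled sums, the same convention as the multilocus
estimator) before applying its ±0.05 band, rather than trusting one noisy
realization of either route.

# Genetic estimators

## Filtering ledger

Filters (site presence, minor allele frequency, maximum observed locus
heterozygosity, individual and locus missingness, monomorphic removal, and
greedy LD pruning) are applied in the configured order, each appending one
accounting row: loci in, removed, out; individuals in, removed, out. The
ledger is validated for exact conservation at every step — the arithmetic
that, at published scale, takes 8906 loci, removes 1256 in LD and leaves
7650. LD pruning is a deterministic greedy scan in locus order: locus j is
removed when its squared genotype correlation with any earlier *kept* locus
exceeds 0.7, so of every flagged pair the later locus is dropped.
Read-depth filters are declared unsupported: no depth information is in
scope.

## Diversity and F-statistics

Per locus and site, Ho is the heterozygote proportion and the gene
diversity uses the small-sample correction
Hs = n/(n−1)·(1 − Σp² − Ho/2n) — the `basic.stats` convention, so users
expecting the uncorrected 1 − Σp² will see slightly larger values. Site
summaries are means over loci and FIS = 1 − mean(Ho)/mean(Hs); the
per-locus-FIS-then-average alternative exists in the literature but is not
used here. A site with only monomorphic loci has Hs = 0 and *missing* FIS,
never zero. Weir–Cockerham variance components a, b, c are computed per
locus from genotype counts (sample sizes, allele frequencies, heterozygote
frequencies per population); loci informative in fewer than two populations
are skipped; the multilocus estimate is Σa/Σ(a+b+c) and negative estimates
are reported as computed, not clamped. The implementation is verified
against an independently coded mean-squares formulation to 1e-12 and is
invariant to allele-label swaps and locus order.

## Outlier scans and the neutral panel

The differentiation-outlier scan fits a scaled chi-square null by maximum
likelihood over (df, scale) to the trimmed (5% each tail) distribution of a
per-locus statistic, then flags two-sided Benjamini–Hochberg q-values
below 0.05. The statistic is the non-negative Lewontin–Krakauer-style ratio
s²/(p̄(1−p̄)) from the among-population variance — *not* the sample-size
corrected per-locus WC ratio, which is negative for a large share of null
loci and would make any two-sided parametric p-value meaningless on the
low side. Truncation is ignored in the likelihood; with 5% trimming this
biases df slightly but leaves the Benjamini–Hochberg behaviour on null data
intact, which is what the ≤ 7% false-flag calibration checks. Fewer than 50
loci are refused (the fit is unstable).

The structure-outlier scan mean-imputes and standardizes the genotype
matrix (loci under 1% minor allele frequency are left unscanned), regresses
each SNP on the first K principal components, forms per-SNP z-score
vectors, and converts Mahalanobis distances to chi-square(K) p-values after
dividing by the genomic inflation factor (median d²/χ²₀.₅). The cutoff is a
configured *quantile* of the p-value distribution (default 1%), exposed
rather than interpreted, because the source convention ("a 1% lower
quantile to select the p-value cut-off") is ambiguous as an FDR rule. The
neutral panel keeps only loci flagged by *neither* scan.

# Spatial statistics

## Marine least-cost distances

The ocean cells of the velocity grid form an 8-connected graph; horizontal
and vertical steps use latitude-corrected cell lengths, diagonals their
Euclidean combination, and Dijkstra gives shortest ocean-only paths between
sites (igraph). Because an 8-connected lattice overestimates free-water
distances by up to ~8% (octile metric), any site pair whose straight
segment crosses no land cell gets the great-circle distance directly; the
grid path is used only where land actually intervenes. Pairs with no ocean
path are Inf and flagged. Sites on land are an error, not snapped.

## Mantel tests

Pearson correlation over upper-triangle pairs; significance by simultaneous
row/column permutation of the second matrix, one-sided for positive
association (the isolation-by-distance hypothesis); p-values always use the
+1 correction and an exact enumeration mode exists for n ≤ 8. The reported
"r²" is the squared Mantel r, labelled as such, since a regression-R²
reading of published values cannot be excluded. A calibration test holds
the empirical size within [0.03, 0.07] over 1000 null replicates.

## dbMEM

The truncation threshold t is the longest edge of the minimum spanning tree
of the distance matrix (vegan's `spantree`); distances beyond t are
replaced by 4t; −D²/2 is Gower double-centred and eigen-decomposed; all
eigenvectors with eigenvalue > 1e-10 are retained in descending order, with
no Moran's-I screen — the variant that yields the maximum n−1 vectors from
n sites. This construction is identical to vegan's `pcnm` (the test suite
asserts score-by-score agreement), which matters for one honest caveat: on
an *exactly equidistant* transect the leading vector of this construction
is a centred sine whose correlation with position plateaus around
|r| ≈ 0.8–0.88 regardless of n, so a "monotone gradient, |r| > 0.9"
expectation is unattainable there — for every retained vector, not just the
first. On transects with regional clusters or gaps (the geometry of real
coastal surveys, where the truncation threshold spans the gap) the leading
vector is a clean gradient with |r| > 0.99, and that is the configuration
on which the gradient contract is tested.

## AEM

Directed edges are taken wherever dispersal probability is positive, one
per site pair, oriented toward the larger of the two directed
probabilities (ties by site order) and weighted by it. Directed cycles —
possible because the orientation rule is local — are broken at their
weakest edge, logged. The sites-by-edges matrix carries the edge weight
wherever the edge lies on a directed path reaching the site; it is
column-centred and SVD-decomposed, left singular vectors scaled by singular
values giving the scores. The orientation rule is a declared choice: the
source literature does not specify how to orient edges derived from an
asymmetric dispersal matrix.

## RDA, partial RDA, forward selection

The response is Hellinger-transformed site-by-allele frequencies (each
entry √(x/row sum)), summarized by the principal components that pass the
Kaiser–Guttman rule. The RDA itself is multivariate least squares of the
centred (optionally condition-residualized) response on the predictors;
canonical axes are the principal components of fitted values; R² =
SS(fit)/SS(total) with Ezekiel's adjustment (n−1)/(n−p−1); global and
per-axis significance come from permuting rows of the residualized
response with the +1 rule (per-axis tests are marginal comparisons of the
k-th eigenvalue, a documented simplification of sequential axis testing).
Collinear predictors are an error naming the dependent columns; VIFs come
from regressing each predictor on the rest. With conditioning variables,
the conditioned fraction (R² of the response on the condition alone) plus
the semi-partial constrained fraction equals the joint model's R² to
1e-10 by least-squares algebra, and the test suite asserts exactly that.
Forward selection adds, per round, the smallest-p candidate whose marginal
partial-RDA permutation p-value is below alpha, skips candidates collinear
with the current selection, caps the selection at n−3 predictors to keep
residual degrees of freedom, and is deterministic for a fixed seed. The
implementation is cross-checked against vegan's `rda` (R², adjusted R²,
VIF) on shared inputs; vegan is never the computation path.

# Reference problem sizes and reproducibility

The reference synthetic study uses 10 sites × 3 years × 500 particles at a
60-minute step, 1000 loci in 10 demes of 100 diploids for 300 generations,
999 Mantel/RDA permutations and 499 forward-selection permutations — sizes
chosen so a complete run takes about a minute on one core while leaving
every statistic well inside its asymptotic regime for the contracts tested.
Every function that consumes randomness derives sub-seeds deterministically
from one master seed and restores the caller's RNG state on exit, so reruns
are byte-identical and replicate loops in the tests are undisturbed. The
pipeline writes a JSON manifest of all parameters, seeds, stage timings and
output-file hashes.

# Limitations

Physical realism is intentionally minimal: no larval behaviour, mortality
other than stranding, diffusion, tides, or multi-depth flow, and the
synthetic coastline is rectangular. The genetic model has no mutation,
recombination map, or coalescent machinery, so very long mutation-free runs
lose polymorphism (quantified above). Dispersal probabilities are
single-generation, not multigenerational matrix powers. Passing the suite
therefore demonstrates correct implementations of the declared models and
estimators, not oceanographic or demographic realism for any particular
species or region.
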