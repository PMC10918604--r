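Package: seascapeConnect
Title: Seascape Connectivity: Larval Dispersal Simulation and Spatial
    Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for combined seascape-connectivity analysis of benthic
    marine invertebrates with pelagic larvae. Provides a passive Lagrangian
    particle tracker driven by gridded surface-current fields (NetCDF),
    buffer-zone dispersal connectivity matrices and interannual dispersal
    summaries; SNP genotype filtering with a full accounting ledger,
    per-site diversity statistics (Ho, Hs, FIS), Weir-Cockerham
    F-statistics and two outlier scans defining a neutral panel; and the
    spatial inference chain linking the two: marine least-cost distances,
    Mantel isolation-by-distance tests, distance-based Moran and asymmetric
    eigenvector maps, and redundancy analysis with permutation tests and
    forward selection. A synthetic-data module generates ocean fields with
    interannual variability, coastal site layouts and stepping-stone
    genotypes with known migration and selfing, so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ncdf4,
    vcfR,
    geosphere,
    igraph,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ade4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
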