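#' Default synthetic pipeline configuration
#'
#' The reference synthetic study: a 10-site coastal transect in a jet+eddy
#' ocean over three years, one of which is a rare strong-advection year
#' (multiplier 3), 500 particles per site-year, and stepping-stone genotypes
#' (1000 loci) whose demes sit at the sites, with mild selfing. All
#' randomness derives from \code{seed}.
#'
#' @param seed integer master seed.
#' @param outDir output directory.
#' @return nested config list understood by \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(seed = 1L, outDir = "seascape_run") {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    # jet + eddy magnitudes chosen so 14-day displacements sit in the
    # tens-of-km range typical of passive coastal larval dispersal
    ocean = list(nSites = 10, years = c("2010", "2011", "2012"),
                 rareYears = "2012", rareMultiplier = 3,
                 lonMin = -11, lonMax = -7, latMin = 40, latMax = 44.5,
                 dLon = 0.1, dLat = 0.1, days = 22,
                 jetSpeed = 0.03, jetDirection = 90,
                 eddyAmp = 0.06, eddyScaleKm = 35, offshoreKm = 30),
    release = list(nParticles = 500L, stepMinutes = 60, duration = 21,
                   startDay = 0.5, scatterKm = 1),
    connectivity = list(plds = c(14, 21), radiusKm = 20, rareFactor = 2),
    genetics = list(N = 100, m = 0.05, selfing = 0.1, L = 1000,
                    generations = 300, sampleSize = 15),
    filters = list(monomorphic = TRUE, maf = 0.05, max_het = 0.6,
                   indiv_missing = 0.10),
    ldPruneR2 = 0.7,
    outliers = list(qThreshold = 0.05, K = 2, mafMin = 0.01,
                    cutoffQuantile = 0.01),
    mantel = list(nPerm = 999),
    rda = list(nPerm = 999, forwardAlpha = 0.05, forwardPerm = 499)
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-or-configured seascape analysis
#'
#' Generates (or loads) velocity fields and genotypes, runs the tracking
#' campaign, computes connectivity and dispersal summaries, the genetic
#' filtering/outlier/diversity/FST chain, then least-cost distances, Mantel
#' isolation-by-distance, dbMEM/AEM bases and the RDA. Every stage's outputs
#' are written under \code{config$outDir} as labelled CSV/VCF/NetCDF plus a
#' JSON manifest with all parameters and seeds; identical config and seed
#' give identical outputs. A stage failure halts the pipeline naming the
#' stage; outputs of completed stages are retained.
#'
#' @param config a config list (see \code{\link{defaultPipelineConfig}}) or
#'   the path of a YAML file holding one.
#' @return (invisibly) list of key results: site table, connectivity,
#'   dispersal summaries, interannual report, filter ledger, neutral-panel
#'   retention, diversity table, global/pairwise FST, Mantel result, bases,
#'   RDA result and the manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaultPipelineConfig(), config)

  # validation before any compute
  if (length(cfg$connectivity$plds) == 0)
    stop("config validation: at least one PLD required")
  if (any(cfg$connectivity$plds > cfg$release$duration))
    stop("config validation: PLD exceeds drift duration")
  if (any(cfg$connectivity$plds <= 0))
    stop("config validation: PLDs must be positive")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }

  oceanSpec <- .stage("ocean_spec", do.call(syntheticOceanSpec, c(
    cfg$ocean[setdiff(names(cfg$ocean), c("nSites", "years", "offshoreKm"))],
    list(seed = .subSeed(cfg$seed, "ocean")))))
  years <- as.character(cfg$ocean$years)
  fields <- .stage("velocity_fields", {
    fl <- lapply(years, function(y) makeVelocityField(oceanSpec, y))
    names(fl) <- years
    dir.create(file.path(cfg$outDir, "fields"), showWarnings = FALSE)
    for (y in years)
      writeVelocityField(fl[[y]], file.path(cfg$outDir, "fields",
                                            paste0("field_", y, ".nc")))
    fl
  })
  tick("fields")

  sites <- .stage("site_layout", {
    s <- makeSiteLayout(cfg$ocean$nSites, "coastal", fields[[1]],
                        sampleSizes = cfg$genetics$sampleSize,
                        offshoreKm = cfg$ocean$offshoreKm)
    utils::write.csv(s, file.path(cfg$outDir, "sites.csv"), row.names = FALSE)
    s
  })
  tick("sites")

  trajectories <- .stage("tracking_campaign", runCampaign(
    fields, sites, years,
    config = list(nParticles = cfg$release$nParticles,
                  stepMinutes = cfg$release$stepMinutes,
                  duration = cfg$release$duration,
                  startDay = cfg$release$startDay,
                  scatterKm = cfg$release$scatterKm,
                  seed = .subSeed(cfg$seed, "release"))))
  tick("tracking")

  conn <- list(); summaries <- list()
  .stage("connectivity", {
    for (pld in cfg$connectivity$plds) {
      cm <- dispersalMatrix(trajectories, sites, pld,
                            radiusKm = cfg$connectivity$radiusKm)
      conn[[as.character(pld)]] <- cm
      for (y in names(connYearly(cm)))
        utils::write.csv(connYearly(cm)[[y]],
                         file.path(cfg$outDir, sprintf("connectivity_pld%d_%s.csv", pld, y)))
      utils::write.csv(connMean(cm),
                       file.path(cfg$outDir, sprintf("connectivity_pld%d_mean.csv", pld)))
      summaries[[as.character(pld)]] <-
        dispersalSummary(trajectories, sites, pld,
                         radiusKm = cfg$connectivity$radiusKm)
    }
    utils::write.csv(do.call(rbind, summaries),
                     file.path(cfg$outDir, "dispersal_summary.csv"),
                     row.names = FALSE)
  })
  interannual <- .stage("interannual_report", {
    rep1 <- interannualReport(trajectories, sites, cfg$connectivity$plds[1],
                              factor = cfg$connectivity$rareFactor)
    utils::write.csv(rep1$perSite, file.path(cfg$outDir, "interannual_per_site.csv"),
                     row.names = FALSE)
    utils::write.csv(rep1$perSiteYear,
                     file.path(cfg$outDir, "interannual_per_site_year.csv"),
                     row.names = FALSE)
    rep1
  })
  tick("connectivity")

  genotypes <- .stage("genotype_simulation", {
    spec <- steppingStoneSpec(d = nrow(sites), N = cfg$genetics$N,
                              m = cfg$genetics$m,
                              selfing = cfg$genetics$selfing,
                              L = cfg$genetics$L,
                              generations = cfg$genetics$generations,
                              sampleSize = cfg$genetics$sampleSize,
                              seed = .subSeed(cfg$seed, "genotypes"))
    g <- simulateSteppingStone(spec)
    # demes sit at the coastal sites, in order
    lab <- sites$site[match(siteLabels(g), sprintf("D%02d", seq_len(nrow(sites))))]
    g <- genotypeMatrix(genotypeCalls(g), lab,
                        lociInfo(g)$chrom, lociInfo(g)$pos)
    writeGenotypeVcf(g, file.path(cfg$outDir, "genotypes.vcf.gz"))
    g
  })
  tick("genotypes")

  filtered <- .stage("snp_filtering", {
    fc <- filterChain(genotypes, cfg$filters)
    lp <- ldPrune(fc$genotypes, cfg$ldPruneR2)
    ledger <- rbind(fc$ledger, lp$ledger)
    validateLedger(ledger)
    utils::write.csv(ledger, file.path(cfg$outDir, "filter_ledger.csv"),
                     row.names = FALSE)
    list(genotypes = lp$genotypes, ledger = ledger)
  })
  tick("filtering")

  panel <- .stage("outlier_scans", {
    oF <- detectOutliers(filtered$genotypes, "fst_trim",
                         qThreshold = cfg$outliers$qThreshold)
    oP <- detectOutliers(filtered$genotypes, "pc_regression",
                         K = cfg$outliers$K, mafMin = cfg$outliers$mafMin,
                         cutoffQuantile = cfg$outliers$cutoffQuantile)
    np <- neutralPanel(filtered$genotypes, oF, oP)
    np$flagsFst <- oF; np$flagsPc <- oP
    np
  })
  tick("outliers")

  genetics <- .stage("diversity_and_fst", {
    div <- diversityStats(panel$genotypes)
    utils::write.csv(div, file.path(cfg$outDir, "diversity_table.csv"),
                     row.names = FALSE)
    fstAll <- wcFst(panel$genotypes)
    pw <- pairwiseFst(panel$genotypes, siteOrder = sites$site)
    utils::write.csv(pw, file.path(cfg$outDir, "pairwise_fst.csv"))
    list(diversity = div, globalFst = fstAll$fst, pairwiseFst = pw)
  })
  tick("genetics")

  spatial <- .stage("spatial_chain", {
    D <- leastCostDistance(fields[[1]], sites)
    utils::write.csv(D, file.path(cfg$outDir, "least_cost_km.csv"))
    mt <- mantelTest(genetics$pairwiseFst, D, nPerm = cfg$mantel$nPerm,
                     seed = .subSeed(cfg$seed, "mantel"))
    mem <- dbMem(D)
    utils::write.csv(basisScores(mem), file.path(cfg$outDir, "dbmem_scores.csv"))
    ae <- aem(conn[[1]])
    utils::write.csv(basisScores(ae), file.path(cfg$outDir, "aem_scores.csv"))
    list(distances = D, mantel = mt, dbmem = mem, aem = ae)
  })
  tick("spatial")

  rdaRes <- .stage("rda", {
    geno <- genotypeCalls(panel$genotypes)
    lab <- siteLabels(panel$genotypes)
    pMat <- do.call(rbind, lapply(sites$site, function(s)
      colMeans(geno[lab == s, , drop = FALSE], na.rm = TRUE) / 2))
    rownames(pMat) <- sites$site
    freq <- cbind(pMat, 1 - pMat)
    H <- hellingerTransform(freq)
    pca <- stats::prcomp(H, center = TRUE, scale. = FALSE)
    eigv <- pca$sdev^2
    keep <- which(eigv > mean(eigv))            # Kaiser-Guttman
    Y <- pca$x[, keep, drop = FALSE]
    restoreRng <- .localSeed(.subSeed(cfg$seed, "env"))
    on.exit(restoreRng(), add = TRUE)
    env <- data.frame(sstHottest = 14 + 0.6 * (max(sites$lat) - sites$lat) +
                        rnorm(nrow(sites), 0, 0.3))
    utils::write.csv(cbind(site = sites$site, env),
                     file.path(cfg$outDir, "env_table.csv"), row.names = FALSE)
    Xc <- cbind(basisScores(spatial$dbmem), basisScores(spatial$aem),
                sstHottest = env$sstHottest)
    fs <- forwardSelect(Y, Xc, alpha = cfg$rda$forwardAlpha,
                        nPerm = cfg$rda$forwardPerm,
                        seed = .subSeed(cfg$seed, "ordistep"),
                        maxSelect = nrow(sites) - 3L)
    sel <- fs$selected
    final <- NULL; fractions <- NULL
    if (length(sel)) {
      final <- rdaFit(Y, Xc[, sel, drop = FALSE], nPerm = cfg$rda$nPerm,
                      seed = .subSeed(cfg$seed, "rda"))
      spatialSel <- sel[!sel %in% "sstHottest"]
      envSel <- sel[sel %in% "sstHottest"]
      if (length(spatialSel) && length(envSel)) {
        fsp <- rdaFit(Y, Xc[, spatialSel, drop = FALSE],
                      condition = Xc[, envSel, drop = FALSE],
                      nPerm = cfg$rda$nPerm, seed = .subSeed(cfg$seed, "prda1"))
        fen <- rdaFit(Y, Xc[, envSel, drop = FALSE],
                      condition = Xc[, spatialSel, drop = FALSE],
                      nPerm = cfg$rda$nPerm, seed = .subSeed(cfg$seed, "prda2"))
        fractions <- list(spatialGivenEnv = fsp@r2, envGivenSpatial = fen@r2)
      }
    }
    rj <- list(selected = sel,
               r2 = if (!is.null(final)) final@r2 else NA,
               adjR2 = if (!is.null(final)) final@adjR2 else NA,
               globalP = if (!is.null(final)) final@globalP else NA,
               axisP = if (!is.null(final)) final@axisP else NA,
               vif = if (!is.null(final)) as.list(final@vif) else NULL,
               fractions = fractions, retainedPCs = length(keep))
    jsonlite::write_json(rj, file.path(cfg$outDir, "rda_report.json"),
                         auto_unbox = TRUE, digits = NA)
    c(rj, list(final = final, forward = fs))
  })
  tick("rda")

  manifest <- .stage("manifest", {
    outFiles <- setdiff(list.files(cfg$outDir, recursive = TRUE),
                        "manifest.json")
    m <- list(package = as.character(utils::packageVersion("seascapeConnect")),
              seed = cfg$seed, config = cfg,
              files = lapply(stats::setNames(outFiles, outFiles), function(f)
                unname(tools::md5sum(file.path(cfg$outDir, f)))),
              timingsSec = timings)
    jsonlite::write_json(m, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  invisible(list(sites = sites, connectivity = conn, summaries = summaries,
                 interannual = interannual, ledger = filtered$ledger,
                 neutralRetention = panel$retention,
                 neutralRetained = panel$retained,
                 diversity = genetics$diversity,
                 globalFst = genetics$globalFst,
                 pairwiseFst = genetics$pairwiseFst,
                 distances = spatial$distances, mantel = spatial$mantel,
                 dbmem = spatial$dbmem, aem = spatial$aem,
                 rda = rdaRes, manifest = manifest, outDir = cfg$outDir))
}
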