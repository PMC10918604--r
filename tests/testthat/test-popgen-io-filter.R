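test_that("VCF write/read round-trips genotypes, sites and missing calls", {
  sp <- steppingStoneSpec(d = 3, N = 20, m = 0.05, L = 60, generations = 10,
                          sampleSize = 8, seed = 2)
  g <- simulateSteppingStone(sp)
  geno <- genotypeCalls(g)
  geno[2, 5] <- NA; geno[7, 1] <- NA
  g <- genotypeMatrix(geno, siteLabels(g), lociInfo(g)$chrom, lociInfo(g)$pos)
  tf <- tempfile(fileext = ".vcf.gz")
  writeGenotypeVcf(g, tf)
  g2 <- readGenotypeVcf(tf)
  expect_equal(unname(genotypeCalls(g2)), unname(genotypeCalls(g)))
  expect_identical(siteLabels(g2), siteLabels(g))
  expect_true(is.na(genotypeCalls(g2)[2, 5]))
})

test_that("multiallelic rows are dropped with a count and mismatches error", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A_1", "A_2", sep = "\t"),
    paste("1", "100", "snp1", "A", "C", ".", "PASS", ".", "GT",
          "0/0", "0|1", sep = "\t"),
    paste("1", "200", "tri1", "A", "C,G", ".", "PASS", ".", "GT",
          "0/1", "1/2", sep = "\t"),
    paste("1", "300", "snp2", "A", "C", ".", "PASS", ".", "GT",
          "./.", "1/1", sep = "\t")), tf)
  expect_message(g <- readGenotypeVcf(tf), "1 non-biallelic")
  expect_equal(ncol(genotypeCalls(g)), 2)
  expect_equal(attr(g, "droppedMultiallelic"), 1)
  expect_true(is.na(genotypeCalls(g)["A_1", "snp2"]))
  expect_equal(unname(genotypeCalls(g)["A_2", "snp1"]), 1L)  # phased == unphased

  st <- data.frame(id = c("A_1"), site = "A")
  expect_error(readGenotypeVcf(tf, siteTable = st), "A_2")
})

test_that("each filter removes exactly the offending loci/individuals", {
  # 20 individuals, 2 sites, constructed loci
  set.seed(4)
  n <- 20
  loc_ok <- rbinom(n, 2, 0.4)
  loc_maf04 <- c(rep(1L, 2), rep(0L, n - 2)) [sample(n)]   # maf = 0.05 kept
  loc_maf03 <- c(1L, rep(0L, n - 1))                       # maf = 0.025 < 0.05
  loc_het07 <- c(rep(1L, 14), rep(0L, 6))                  # het 0.7 > 0.6
  geno <- cbind(ok = loc_ok, borderline = loc_maf04, rare = loc_maf03,
                het = loc_het07)
  site <- rep(c("A", "B"), each = 10)
  g <- genotypeMatrix(geno, site)
  res <- filterChain(g, list(maf = 0.05, max_het = 0.6))
  kept <- colnames(genotypeCalls(res$genotypes))
  expect_false("rare" %in% kept)
  expect_false("het" %in% kept)
  expect_true(all(c("ok", "borderline") %in% kept))
  expect_equal(res$ledger$lociOut[nrow(res$ledger)], length(kept))

  # individual with 12% missing removed under a 10% ceiling
  geno2 <- matrix(rbinom(25 * 20, 2, 0.5), 25, 20)
  geno2[1, 1:3] <- NA                      # 15% missing
  g2 <- genotypeMatrix(geno2, rep(c("A", "B"), length.out = 25))
  res2 <- filterChain(g2, list(indiv_missing = 0.10))
  expect_equal(res2$ledger$indRemoved, 1L)
  expect_equal(nrow(genotypeCalls(res2$genotypes)), 24)

  # site-presence rule
  geno3 <- matrix(rbinom(30 * 4, 2, 0.5), 30, 4)
  geno3[11:30, 2] <- NA                    # locus 2 typed in 1 of 3 sites
  g3 <- genotypeMatrix(geno3, rep(c("A", "B", "C"), each = 10))
  res3 <- filterChain(g3, list(site_presence = 2))
  expect_equal(res3$ledger$lociRemoved, 1L)

  expect_error(filterChain(g, list(depth = 9)), "unknown filter")
})

test_that("ledger counts are conserved through chains", {
  l1 <- filterLedgerRow("populations", "initial", 23111, 14205, 285, 39)
  l2 <- filterLedgerRow("ld_prune", "r2>0.7", l1$lociOut, 1256, l1$indOut, 0)
  expect_true(validateLedger(rbind(l1, l2)))
  bad <- l2; bad$lociIn <- 9000
  expect_error(validateLedger(rbind(l1, bad)), "broken")
  expect_error(filterLedgerRow("x", "", 10, 11))
})

test_that("LD pruning removes the later member of duplicated loci only", {
  set.seed(8)
  base <- matrix(rbinom(40 * 30, 2, 0.5), 40, 30)
  geno <- cbind(base, dup = base[, 3])
  colnames(geno) <- c(paste0("L", 1:30), "dup")
  g <- genotypeMatrix(geno, rep(c("A", "B"), each = 20))
  res <- ldPrune(g, 0.7)
  kept <- colnames(genotypeCalls(res$genotypes))
  expect_true("L3" %in% kept)       # earlier member kept
  expect_false("dup" %in% kept)     # later removed
  expect_equal(res$removed, sum(!colnames(geno) %in% kept))

  # independent random loci: no removals expected
  set.seed(9)
  indep <- matrix(rbinom(200 * 60, 2, 0.5), 200, 60)
  gI <- genotypeMatrix(indep, rep(c("A", "B"), each = 100))
  expect_equal(ldPrune(gI, 0.7)$removed, 0)
  expect_error(ldPrune(genotypeMatrix(indep[, 1, drop = FALSE],
                                      rep(c("A", "B"), each = 100))),
               "2 loci")
})
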