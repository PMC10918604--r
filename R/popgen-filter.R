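# per-locus summaries used by several filters
.locusStats <- function(geno) {
  nTyped <- colSums(!is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  het <- colMeans(geno == 1L, na.rm = TRUE)
  list(nTyped = nTyped, p = p, maf = pmin(p, 1 - p), het = het)
}

#' One accounting row of a filter ledger
#'
#' The ledger's arithmetic is strict: loci out = loci in - loci removed and
#' likewise for individuals, so counts are conserved through a chain.
#'
#' @param filter filter name.
#' @param params parameter string.
#' @param lociIn,lociRemoved,indIn,indRemoved integer counts.
#' @return one-row data.frame with \code{lociOut}/\code{indOut} computed.
#' @export
filterLedgerRow <- function(filter, params, lociIn, lociRemoved,
                            indIn = NA_integer_, indRemoved = 0L) {
  stopifnot(lociRemoved >= 0, lociRemoved <= lociIn)
  data.frame(filter = filter, params = params,
             lociIn = as.integer(lociIn),
             lociRemoved = as.integer(lociRemoved),
             lociOut = as.integer(lociIn - lociRemoved),
             indIn = as.integer(indIn),
             indRemoved = as.integer(indRemoved),
             indOut = as.integer(indIn - indRemoved),
             stringsAsFactors = FALSE)
}

#' Check ledger count conservation
#'
#' @param ledger a filter ledger (rbind of \code{\link{filterLedgerRow}}).
#' @return \code{TRUE}, or an error describing the broken step.
#' @export
validateLedger <- function(ledger) {
  if (nrow(ledger) < 2) return(TRUE)
  for (k in 2:nrow(ledger)) {
    if (ledger$lociIn[k] != ledger$lociOut[k - 1])
      stop("ledger broken at step ", k, ": loci in != previous loci out")
    if (!is.na(ledger$indIn[k]) && !is.na(ledger$indOut[k - 1]) &&
        ledger$indIn[k] != ledger$indOut[k - 1])
      stop("ledger broken at step ", k, ": individuals in != previous out")
  }
  TRUE
}

#' Apply a chain of genotype filters with full accounting
#'
#' Rules are applied in the order given. Supported rules:
#' \describe{
#'   \item{site_presence}{locus must be genotyped in at least this many sites}
#'   \item{maf}{minor allele frequency must be >= the threshold}
#'   \item{max_het}{observed locus heterozygosity must be <= the threshold}
#'   \item{indiv_missing}{individual removed when its missing-call fraction
#'     exceeds the ceiling}
#'   \item{locus_missing}{locus removed when its missing fraction exceeds the
#'     ceiling}
#'   \item{monomorphic}{(logical) remove loci with no variation}
#' }
#' Read-depth rules are unsupported: no depth information is carried.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param rules named list in application order, e.g.
#'   \code{list(site_presence = 16, maf = 0.05, max_het = 0.6,
#'   indiv_missing = 0.10)}.
#' @return list with \code{genotypes} (filtered \linkS4class{GenotypeMatrix})
#'   and \code{ledger} (data.frame).
#' @export
filterChain <- function(g, rules) {
  known <- c("site_presence", "maf", "max_het", "indiv_missing",
             "locus_missing", "monomorphic")
  bad <- setdiff(names(rules), known)
  if (length(bad)) stop("unknown filter rule(s): ", paste(bad, collapse = ", "))
  geno <- genotypeCalls(g)
  site <- siteLabels(g)
  info <- lociInfo(g)
  ledger <- NULL
  for (rn in names(rules)) {
    val <- rules[[rn]]
    lociIn <- ncol(geno); indIn <- nrow(geno)
    keepL <- rep(TRUE, lociIn); keepI <- rep(TRUE, indIn)
    st <- .locusStats(geno)
    if (rn == "site_presence") {
      nSitesTyped <- vapply(seq_len(lociIn), function(l) {
        length(unique(site[!is.na(geno[, l])]))
      }, integer(1))
      keepL <- nSitesTyped >= val
    } else if (rn == "maf") {
      keepL <- !is.na(st$maf) & st$maf >= val
    } else if (rn == "max_het") {
      keepL <- !is.na(st$het) & st$het <= val
    } else if (rn == "indiv_missing") {
      keepI <- rowMeans(is.na(geno)) <= val
    } else if (rn == "locus_missing") {
      keepL <- colMeans(is.na(geno)) <= val
    } else if (rn == "monomorphic") {
      if (isTRUE(val)) keepL <- !is.na(st$maf) & st$maf > 0
    }
    row <- filterLedgerRow(rn, paste(val, collapse = ","),
                           lociIn, sum(!keepL), indIn, sum(!keepI))
    ledger <- if (is.null(ledger)) row else rbind(ledger, row)
    geno <- geno[keepI, keepL, drop = FALSE]
    site <- site[keepI]
    info <- info[keepL, , drop = FALSE]
  }
  validateLedger(ledger)
  list(genotypes = genotypeMatrix(geno, site, info$chrom, info$pos),
       ledger = ledger)
}

#' Prune loci in linkage disequilibrium
#'
#' Greedy scan in locus order: locus j is removed when its squared genotype
#' correlation with any earlier \emph{kept} locus exceeds the threshold, so
#' of every flagged pair the later locus is dropped. Deterministic.
#'
#' @param g a \linkS4class{GenotypeMatrix} with >= 2 loci.
#' @param r2Threshold squared-correlation threshold (default 0.7).
#' @return list: \code{genotypes} (pruned), \code{removed} (count), and
#'   \code{ledger} (one accounting row).
#' @export
ldPrune <- function(g, r2Threshold = 0.7) {
  geno <- genotypeCalls(g)
  L <- ncol(geno)
  if (L < 2) stop("ld_prune needs at least 2 loci")
  removed <- logical(L)
  blk <- 2000L
  C2 <- NULL
  if (L <= blk) {
    C2 <- suppressWarnings(stats::cor(geno, use = "pairwise.complete.obs"))^2
  }
  for (j in 2:L) {
    earlier <- which(!removed[seq_len(j - 1L)])
    if (!length(earlier)) next
    r2 <- if (!is.null(C2)) C2[earlier, j] else
      suppressWarnings(stats::cor(geno[, earlier, drop = FALSE], geno[, j],
                                  use = "pairwise.complete.obs"))^2
    if (any(!is.na(r2) & r2 > r2Threshold)) removed[j] <- TRUE
  }
  info <- lociInfo(g)
  keep <- !removed
  list(genotypes = genotypeMatrix(geno[, keep, drop = FALSE], siteLabels(g),
                                  info$chrom[keep], info$pos[keep]),
       removed = sum(removed),
       ledger = filterLedgerRow("ld_prune", paste0("r2>", r2Threshold),
                                L, sum(removed), nrow(geno), 0L))
}
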