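#' Per-site diversity statistics (Ho, Hs, FIS)
#'
#' Per locus and site with sample size \code{n} (genotyped individuals),
#' observed heterozygosity \code{Ho} is the heterozygote proportion and the
#' gene diversity \code{Hs} uses the small-sample correction
#' \deqn{Hs = n/(n-1) (1 - p^2 - q^2 - Ho/(2n)),}
#' the convention of hierfstat's \code{basic.stats} (so values differ from
#' the uncorrected \eqn{1 - \sum p^2}). Site values are means over loci with
#' >= 2 genotyped individuals and \eqn{FIS = 1 - mean(Ho)/mean(Hs)}; a site
#' with only monomorphic loci has \code{Hs = 0} and missing FIS.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @return data.frame \code{site, n, Ho, Hs, Fis}, with attribute
#'   \code{"global"}: the across-site means and the FIS computed from them.
#' @export
diversityStats <- function(g) {
  geno <- genotypeCalls(g)
  site <- siteLabels(g)
  sitesU <- unique(site)
  out <- data.frame(site = sitesU, n = NA_integer_,
                    Ho = NA_real_, Hs = NA_real_, Fis = NA_real_)
  for (k in seq_along(sitesU)) {
    sub <- geno[site == sitesU[k], , drop = FALSE]
    n <- colSums(!is.na(sub))
    use <- n >= 2
    ho <- colMeans(sub == 1L, na.rm = TRUE)
    p <- colMeans(sub, na.rm = TRUE) / 2
    hs <- (n / (n - 1)) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
    mHo <- mean(ho[use]); mHs <- mean(hs[use])
    out$n[k] <- nrow(sub)
    out$Ho[k] <- mHo
    out$Hs[k] <- mHs
    out$Fis[k] <- if (is.finite(mHs) && mHs > 0) 1 - mHo / mHs else NA_real_
  }
  gHo <- mean(out$Ho); gHs <- mean(out$Hs)
  attr(out, "global") <- list(Ho = gHo, Hs = gHs,
                              Fis = if (gHs > 0) 1 - gHo / gHs else NA_real_)
  out
}

# Weir-Cockerham (1984) variance components per locus for the given
# genotype submatrix and site labels; returns a data.frame(locus, a, b, c)
# with NA rows for loci informative in < 2 populations.
.wcComponents <- function(geno, site) {
  sitesU <- unique(site)
  L <- ncol(geno)
  nMat <- pMat <- hMat <- matrix(NA_real_, length(sitesU), L)
  for (k in seq_along(sitesU)) {
    sub <- geno[site == sitesU[k], , drop = FALSE]
    nMat[k, ] <- colSums(!is.na(sub))
    pMat[k, ] <- colMeans(sub, na.rm = TRUE) / 2
    hMat[k, ] <- colMeans(sub == 1L, na.rm = TRUE)
  }
  a <- b <- cc <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    ok <- which(nMat[, l] > 0)
    r <- length(ok)
    if (r < 2) next
    ni <- nMat[ok, l]; pi <- pMat[ok, l]; hi <- hMat[ok, l]
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a[l] <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc[l] <- hbar / 2
  }
  data.frame(locus = colnames(geno), a = a, b = b, c = cc,
             stringsAsFactors = FALSE)
}

#' Weir-Cockerham FST
#'
#' Per-locus variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) from genotype counts, and
#' the multilocus estimate as the ratio of sums
#' \eqn{\hat\theta = \sum a / \sum (a+b+c)} (never a mean of per-locus
#' ratios). Loci genotyped in fewer than two of the requested populations are
#' skipped. Negative estimates are reported as computed.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param sites optional character vector: restrict to these site labels
#'   (e.g. a pair for pairwise FST). Default: all sites.
#' @return list with \code{components} (per-locus data.frame with a, b, c and
#'   \code{fst = a/(a+b+c)}) and \code{fst} (multilocus).
#' @export
wcFst <- function(g, sites = NULL) {
  geno <- genotypeCalls(g)
  lab <- siteLabels(g)
  if (!is.null(sites)) {
    keep <- lab %in% sites
    if (length(unique(lab[keep])) < 2)
      stop("need >= 2 sites with data")
    geno <- geno[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  if (length(unique(lab)) < 2) stop("need >= 2 sites with data")
  comp <- .wcComponents(geno, lab)
  tot <- comp$a + comp$b + comp$c
  comp$fst <- ifelse(is.na(tot) | tot == 0, NA_real_, comp$a / tot)
  ok <- !is.na(tot)
  fst <- sum(comp$a[ok]) / sum(tot[ok])
  list(components = comp, fst = fst)
}

#' Pairwise Weir-Cockerham FST matrix
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param siteOrder optional ordering of site labels for the matrix.
#' @return symmetric matrix of multilocus pairwise FST, zero diagonal.
#' @export
pairwiseFst <- function(g, siteOrder = NULL) {
  sitesU <- if (is.null(siteOrder)) unique(siteLabels(g)) else siteOrder
  ns <- length(sitesU)
  M <- matrix(0, ns, ns, dimnames = list(sitesU, sitesU))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    M[i, j] <- M[j, i] <- wcFst(g, sites = c(sitesU[i], sitesU[j]))$fst
  }
  M
}
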