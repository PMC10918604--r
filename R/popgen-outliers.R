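#' Outlier-locus scans
#'
#' Two scans for loci departing from the genome-wide pattern of population
#' differentiation; their complement defines the putatively neutral panel.
#'
#' \strong{fst_trim} computes a non-negative per-locus differentiation ratio
#' (the Lewontin-Krakauer-style \eqn{s^2 / \bar p (1-\bar p)} from the
#' Weir-Cockerham among-population variance, which unlike the sample-size
#' corrected per-locus FST is never negative under drift noise), trims the
#' top and bottom \code{trim} fraction, fits a scaled chi-square null by
#' maximum likelihood over (df, scale), converts every locus to a two-sided
#' p-value under the fit and flags Benjamini-Hochberg q-values below
#' \code{qThreshold}.
#'
#' \strong{pc_regression} mean-imputes and standardizes the genotype matrix
#' (loci below \code{mafMin} minor allele frequency are left unscanned),
#' regresses each SNP on the first \code{K} principal components, forms
#' per-SNP z-score vectors, converts their Mahalanobis distances into
#' chi-square p-values after genomic-inflation rescaling, and flags loci with
#' p-values at or below the \code{cutoffQuantile} quantile of the p-value
#' distribution.
#'
#' @param g a \linkS4class{GenotypeMatrix} (>= 2 sites; >= 50 loci for
#'   \code{fst_trim}).
#' @param method \code{"fst_trim"} or \code{"pc_regression"}.
#' @param qThreshold BH q-value threshold for \code{fst_trim}.
#' @param trim trimmed fraction at each tail for the null fit.
#' @param K number of retained principal components.
#' @param mafMin minor-allele-frequency floor for \code{pc_regression}.
#' @param cutoffQuantile p-value quantile defining the
#'   \code{pc_regression} cutoff.
#' @return list: \code{flag} (logical per locus; \code{NA}-p loci are never
#'   flagged), \code{p}, \code{q} (fst_trim only), \code{stat},
#'   \code{method}, \code{params}.
#' @export
detectOutliers <- function(g, method = c("fst_trim", "pc_regression"),
                           qThreshold = 0.05, trim = 0.05,
                           K = 2, mafMin = 0.01, cutoffQuantile = 0.01) {
  method <- match.arg(method)
  geno <- genotypeCalls(g)
  L <- ncol(geno)
  if (method == "fst_trim") {
    if (L < 50) stop("fst_trim needs >= 50 loci (distribution fit unstable)")
    if (length(unique(siteLabels(g))) < 2) stop("fst_trim needs >= 2 sites")
    x <- .lkStat(geno, siteLabels(g))
    ok <- which(is.finite(x))
    xs <- sort(x[ok])
    lo <- floor(length(xs) * trim); hi <- ceiling(length(xs) * (1 - trim))
    xt <- xs[(lo + 1):hi]
    fit <- .fitScaledChisq(xt)
    pUp <- stats::pchisq(x / fit$scale, fit$df, lower.tail = FALSE)
    pLo <- stats::pchisq(x / fit$scale, fit$df, lower.tail = TRUE)
    p <- pmin(1, 2 * pmin(pUp, pLo))
    q <- rep(NA_real_, L)
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    flag <- !is.na(q) & q < qThreshold
    list(flag = stats::setNames(flag, colnames(geno)), p = p, q = q, stat = x,
         method = method,
         params = list(qThreshold = qThreshold, trim = trim,
                       df = fit$df, scale = fit$scale))
  } else {
    n <- nrow(geno)
    if (n <= K + 2) stop("pc_regression needs n > K + 2 individuals")
    if (K < 2) stop("pc_regression needs >= 2 retained PCs")
    imp <- geno
    mu <- colMeans(imp, na.rm = TRUE)
    idx <- which(is.na(imp), arr.ind = TRUE)
    if (nrow(idx)) imp[idx] <- mu[idx[, 2]]
    p0 <- mu / 2
    maf <- pmin(p0, 1 - p0)
    sdv <- apply(imp, 2, stats::sd)
    scan <- which(maf >= mafMin & sdv > 0)
    X <- scale(imp[, scan, drop = FALSE])
    U <- svd(X, nu = K, nv = 0)$u
    B <- crossprod(U, X)                       # K x L'
    ss <- colSums(X^2)
    rv <- pmax(ss - colSums(B^2), 0) / (n - K - 1)
    Z <- t(B) / sqrt(pmax(rv, .Machine$double.eps))   # L' x K
    d2 <- stats::mahalanobis(Z, colMeans(Z), stats::cov(Z))
    gif <- stats::median(d2) / stats::qchisq(0.5, df = K)
    pv <- stats::pchisq(d2 / gif, df = K, lower.tail = FALSE)
    p <- rep(NA_real_, L)
    p[scan] <- pv
    cut <- stats::quantile(pv, cutoffQuantile, names = FALSE)
    flag <- !is.na(p) & p <= cut
    list(flag = stats::setNames(flag, colnames(geno)), p = p, q = NULL,
         stat = p, method = method,
         params = list(K = K, mafMin = mafMin,
                       cutoffQuantile = cutoffQuantile, gif = gif))
  }
}

# Lewontin-Krakauer-style non-negative differentiation ratio per locus
.lkStat <- function(geno, site) {
  sitesU <- unique(site)
  L <- ncol(geno)
  nMat <- pMat <- matrix(NA_real_, length(sitesU), L)
  for (k in seq_along(sitesU)) {
    sub <- geno[site == sitesU[k], , drop = FALSE]
    nMat[k, ] <- colSums(!is.na(sub))
    pMat[k, ] <- colMeans(sub, na.rm = TRUE) / 2
  }
  x <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    ok <- which(nMat[, l] > 0)
    r <- length(ok)
    if (r < 2) next
    ni <- nMat[ok, l]; pi <- pMat[ok, l]
    nbar <- mean(ni)
    pbar <- sum(ni * pi) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    x[l] <- s2 / (pbar * (1 - pbar))
  }
  x
}

# ML fit of x ~ scale * chisq(df) on a (trimmed) sample
.fitScaledChisq <- function(x) {
  x <- x[x > 0]
  nll <- function(par) {
    df <- exp(par[1]); sc <- exp(par[2])
    -sum(stats::dchisq(x / sc, df, log = TRUE) - log(sc))
  }
  init <- c(log(max(2 * mean(x)^2 / max(stats::var(x), 1e-12), 0.1)),
            log(mean(x)))
  opt <- stats::optim(init, nll, method = "Nelder-Mead")
  list(df = exp(opt$par[1]), scale = exp(opt$par[2]) , nll = opt$value)
}

#' Neutral panel from two outlier scans
#'
#' A locus is neutral only when flagged by \emph{neither} method
#' (intersection-of-neutral convention).
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param flagsA,flagsB logical flag vectors from \code{\link{detectOutliers}}
#'   (or the result lists themselves).
#' @return list: \code{genotypes} (neutral-panel subset), \code{neutral}
#'   (logical), \code{retained} (count) and \code{retention} (fraction).
#' @export
neutralPanel <- function(g, flagsA, flagsB) {
  if (is.list(flagsA)) flagsA <- flagsA$flag
  if (is.list(flagsB)) flagsB <- flagsB$flag
  neutral <- !flagsA & !flagsB
  geno <- genotypeCalls(g)
  info <- lociInfo(g)
  list(genotypes = genotypeMatrix(geno[, neutral, drop = FALSE],
                                  siteLabels(g),
                                  info$chrom[neutral], info$pos[neutral]),
       neutral = neutral, retained = sum(neutral),
       retention = sum(neutral) / length(neutral))
}
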