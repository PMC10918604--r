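#' Hellinger transform of a site-by-allele frequency table
#'
#' Each entry becomes the square root of its row-relative value,
#' \eqn{\sqrt{x_{ij} / \sum_j x_{ij}}}, so transformed rows have unit
#' Euclidean norm and Euclidean distances between them equal Hellinger
#' distances of the originals.
#'
#' @param x non-negative matrix/data.frame with positive row sums.
#' @return transformed matrix.
#' @export
hellingerTransform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative values in frequency table")
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("zero-sum row(s): ", paste(which(rs <= 0), collapse = ", "))
  as.matrix(vegan::decostand(x, method = "hellinger"))
}

.centre <- function(M) {
  M <- as.matrix(M)
  sweep(M, 2, colMeans(M))
}

# residuals of (already centred) M on centred predictors Z
.residOn <- function(M, Z) {
  if (is.null(Z)) return(M)
  qz <- qr(cbind(1, as.matrix(Z)))
  qr.resid(qz, M)
}

.checkCollinear <- function(X) {
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  q <- qr(Xm)
  if (q$rank < ncol(Xm)) {
    dep <- colnames(Xm)[q$pivot[(q$rank + 1):ncol(Xm)]]
    stop("collinear predictors: ", paste(dep, collapse = ", "))
  }
}

#' Redundancy analysis with permutation tests
#'
#' Multivariate least squares of the (optionally conditioned) response on the
#' predictors; canonical axes are the principal components of the fitted
#' values. R^2 is SS(fitted)/SS(total centred response); the adjustment is
#' Ezekiel's \eqn{1-(1-R^2)(n-1)/(n-p-1)}. Significance (global and per
#' axis) comes from permutation of the residualized response rows with the
#' +1 rule; with conditioning predictors the residuals of the response on
#' the conditioning set are permuted. With conditioning, \code{fractions}
#' reports the conditioned fraction (R^2 of the response on the condition
#' alone), the conditional (semi-partial) fraction and their sum, which
#' equals the R^2 of the full joint model.
#'
#' @param Y response matrix (sites x variables).
#' @param X predictor matrix/data.frame (numeric).
#' @param condition optional conditioning predictors (partial RDA).
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed.
#' @return an \linkS4class{RdaResult}.
#' @export
rdaFit <- function(Y, X, condition = NULL, nPerm = 999, seed = 1L) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  p <- ncol(X)
  pz <- if (is.null(condition)) 0L else ncol(as.matrix(condition))
  if (n <= p + pz + 1) stop("need n_sites > n_predictors + 1")
  if (!is.null(condition)) .checkCollinear(cbind(as.matrix(condition), X))
  else .checkCollinear(X)

  Yc <- .centre(Y)
  ssTot <- sum(Yc^2)
  if (ssTot <= 0) stop("response has no variance")
  Zc <- if (is.null(condition)) NULL else .centre(condition)
  Yr <- .residOn(Yc, Zc)
  Xr <- .residOn(.centre(X), Zc)

  qx <- qr(Xr)
  fit <- qr.fitted(qx, Yr)
  res <- Yr - fit
  ssFit <- sum(fit^2)
  ssRes <- sum(res^2)
  r2 <- ssFit / ssTot
  adjR2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)

  sv <- svd(fit)
  eig <- sv$d^2
  eig <- eig[eig > max(eig) * 1e-12]

  dfRes <- n - p - pz - 1
  fObs <- (ssFit / p) / (ssRes / dfRes)
  fAxis <- eig / (ssRes / dfRes)

  restoreRng <- .localSeed(.subSeed(seed, "rda"))
  on.exit(restoreRng(), add = TRUE)
  hitG <- 0L
  hitA <- rep(0L, length(eig))
  for (k in seq_len(nPerm)) {
    Yp <- Yr[sample.int(n), , drop = FALSE]
    fitP <- qr.fitted(qx, Yp)
    ssFitP <- sum(fitP^2)
    ssResP <- sum(Yp^2) - ssFitP
    fP <- (ssFitP / p) / (ssResP / dfRes)
    if (fP >= fObs - 1e-12) hitG <- hitG + 1L
    dP <- svd(fitP, nu = 0, nv = 0)$d^2
    fAxP <- dP[seq_along(eig)] / (ssResP / dfRes)
    hitA <- hitA + as.integer(!is.na(fAxP) & fAxP >= fAxis - 1e-12)
  }
  globalP <- (hitG + 1) / (nPerm + 1)
  axisP <- (hitA + 1) / (nPerm + 1)

  # VIFs over the full predictor set (condition included)
  XA <- if (is.null(condition)) X else cbind(as.matrix(condition), X)
  vif <- vapply(seq_len(ncol(XA)), function(j) {
    if (ncol(XA) == 1L) return(1)
    r2j <- summary(stats::lm(XA[, j] ~ XA[, -j, drop = FALSE]))$r.squared
    1 / max(1 - r2j, .Machine$double.eps)
  }, numeric(1))
  names(vif) <- colnames(XA)

  fractions <- list()
  if (!is.null(condition)) {
    qz2 <- qr(cbind(1, Zc))
    ssCond <- sum(qr.fitted(qz2, Yc)^2)
    fractions <- list(conditioned = ssCond / ssTot,
                      conditional = r2,
                      joint = ssCond / ssTot + r2)
  }
  new("RdaResult", r2 = r2, adjR2 = adjR2, eig = eig, axisP = axisP,
      globalP = globalP, vif = vif, fractions = fractions,
      details = list(fitted = fit, nPerm = nPerm, F = fObs,
                     eigProp = eig / ssTot, ssTot = ssTot, ssRes = ssRes))
}

#' Forward selection of RDA predictors by permutation tests
#'
#' Stepwise addition: at each round every remaining candidate is tested
#' marginally (partial RDA conditioned on the current selection); the
#' smallest-p candidate enters if its permutation p-value is below
#' \code{alpha}; selection stops when none qualifies. Candidates collinear
#' with the current selection are skipped (never enter). Deterministic for a
#' fixed seed.
#'
#' @param Y response matrix.
#' @param X candidate predictor matrix/data.frame (>= 1 column).
#' @param alpha entry threshold (default 0.05).
#' @param nPerm permutations per test (default 10000).
#' @param seed integer seed.
#' @param maxSelect cap on the number of selected predictors; default
#'   \code{nrow(Y) - 3} so the final model keeps residual degrees of freedom.
#' @return list: \code{selected} (character), \code{trace} (data.frame of
#'   candidate tests per round).
#' @export
forwardSelect <- function(Y, X, alpha = 0.05, nPerm = 10000, seed = 1L,
                          maxSelect = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (ncol(X) < 1) stop("need >= 1 candidate")
  if (is.null(maxSelect)) maxSelect <- max(1L, nrow(as.matrix(Y)) - 3L)
  selected <- character()
  trace <- NULL
  round <- 0L
  repeat {
    round <- round + 1L
    remaining <- setdiff(colnames(X), selected)
    if (!length(remaining) || length(selected) >= maxSelect) break
    ps <- rep(NA_real_, length(remaining)); names(ps) <- remaining
    r2s <- ps
    cond <- if (length(selected)) X[, selected, drop = FALSE] else NULL
    for (cand in remaining) {
      fullSet <- cbind(cond, X[, cand, drop = FALSE])
      ok <- tryCatch({ .checkCollinear(fullSet); TRUE },
                     error = function(e) FALSE)
      if (!ok) next   # collinearity guard: duplicates never enter
      ft <- tryCatch(
        rdaFit(Y, X[, cand, drop = FALSE], condition = cond,
               nPerm = nPerm, seed = .subSeed(seed, round, cand)),
        error = function(e) NULL)
      if (is.null(ft)) next
      ps[cand] <- ft@globalP
      r2s[cand] <- ft@r2
    }
    trace <- rbind(trace, data.frame(round = round, candidate = remaining,
                                     p = ps, r2 = r2s, row.names = NULL))
    if (all(is.na(ps))) break
    best <- remaining[order(ps, -r2s)][1]
    if (is.na(ps[best]) || ps[best] >= alpha) break
    selected <- c(selected, best)
  }
  list(selected = selected, trace = trace)
}
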