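#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper-triangle pairs, with
#' significance from simultaneous row/column permutations of \code{B}.
#' One-sided (positive association) by default, matching the
#' isolation-by-distance hypothesis; the permutation p-value always uses the
#' +1 correction so p is never zero. With \code{exact = TRUE} all \code{n!}
#' relabelings are enumerated instead (small n only) and
#' p = #\{permuted r >= observed r\} / n! (the identity permutation counts).
#'
#' @param A,B square symmetric matrices over the same ordered site set.
#' @param nPerm number of random permutations.
#' @param seed integer seed.
#' @param exact enumerate all permutations (requires n <= 8).
#' @return list: \code{r}, \code{r2}, \code{p}, \code{nPerm}.
#' @export
mantelTest <- function(A, B, nPerm = 9999, seed = 1L, exact = FALSE) {
  stopifnot(identical(dim(A), dim(B)), nrow(A) == ncol(A))
  n <- nrow(A)
  if (n < 4) stop("mantel test needs n >= 4")
  ut <- upper.tri(A)
  a <- A[ut]
  if (stats::sd(a) == 0 || stats::sd(B[ut]) == 0)
    stop("constant distance matrix: correlation undefined")
  robs <- stats::cor(a, B[ut])
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- .allPerms(n)
    rs <- vapply(seq_len(nrow(perms)), function(k) {
      idx <- perms[k, ]
      stats::cor(a, B[idx, idx][ut])
    }, numeric(1))
    p <- sum(rs >= robs - 1e-12) / nrow(perms)
    return(list(r = robs, r2 = robs^2, p = p, nPerm = nrow(perms)))
  }
  restoreRng <- .localSeed(.subSeed(seed, "mantel"))
  on.exit(restoreRng(), add = TRUE)
  hits <- 0L
  for (k in seq_len(nPerm)) {
    idx <- sample.int(n)
    if (stats::cor(a, B[idx, idx][ut]) >= robs - 1e-12) hits <- hits + 1L
  }
  list(r = robs, r2 = robs^2, p = (hits + 1) / (nPerm + 1), nPerm = nPerm)
}

.allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}
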