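#' Migration matrix for a 1-D stepping-stone chain
#'
#' Each deme sends rate \code{m} to each adjacent neighbour and retains the
#' rest (so interior demes emigrate \code{2m}, end demes \code{m}; for
#' \code{d = 2} this is the classical two-island exchange at rate \code{m}).
#'
#' @param d number of demes.
#' @param m per-neighbour migration rate (0 <= m <= 0.5).
#' @return row-stochastic \code{d x d} matrix; \code{M[i, j]} is the
#'   probability that an offspring born in deme i has parents from deme j.
#' @export
steppingStoneMigration <- function(d, m) {
  stopifnot(d >= 1, m >= 0, m <= 0.5)
  M <- matrix(0, d, d)
  for (i in seq_len(d)) {
    if (i > 1) M[i, i - 1] <- m
    if (i < d) M[i, i + 1] <- m
    M[i, i] <- 1 - sum(M[i, ])
  }
  M
}

#' Specification of a stepping-stone genotype simulation
#'
#' Forward-time Wright-Fisher reproduction with partial selfing and
#' neighbour migration, producing diploid biallelic genotypes with known
#' demographic parameters (used to validate the genetic estimators against
#' the classical equilibria FIS = s/(2-s) and island-model FST).
#'
#' @param d number of demes.
#' @param N diploid deme size.
#' @param m per-neighbour migration rate (ignored when
#'   \code{migrationMatrix} is given).
#' @param migrationMatrix optional row-stochastic \code{d x d} backward
#'   migration matrix (e.g. derived from a connectivity matrix).
#' @param selfing probability that an offspring's two gametes come from a
#'   single parent (mixed-mating model), in [0, 1].
#' @param L number of unlinked biallelic loci.
#' @param generations number of non-overlapping generations to simulate.
#' @param sampleSize individuals sampled per deme (<= N).
#' @param initFreqRange range of the uniform initial allele frequencies.
#' @param seed integer seed.
#' @return a \code{SteppingStoneSpec} (list).
#' @export
steppingStoneSpec <- function(d = 10, N = 100, m = 0.05,
                              migrationMatrix = NULL, selfing = 0,
                              L = 1000, generations = 200, sampleSize = 20,
                              initFreqRange = c(0.1, 0.9), seed = 1L) {
  stopifnot(d >= 1, N >= 2, L >= 1, generations >= 1,
            selfing >= 0, selfing <= 1)
  if (sampleSize > N) stop("sampleSize must be <= deme size N")
  if (!is.null(migrationMatrix)) {
    stopifnot(identical(dim(migrationMatrix), c(as.integer(d), as.integer(d))) ||
              identical(dim(migrationMatrix), c(d, d)))
    if (any(migrationMatrix < 0) ||
        any(abs(rowSums(migrationMatrix) - 1) > 1e-8))
      stop("migrationMatrix rows must be non-negative and sum to 1")
  }
  structure(list(d = as.integer(d), N = as.integer(N), m = m,
                 migrationMatrix = migrationMatrix, selfing = selfing,
                 L = as.integer(L), generations = as.integer(generations),
                 sampleSize = as.integer(sampleSize),
                 initFreqRange = initFreqRange, seed = as.integer(seed)),
            class = "SteppingStoneSpec")
}

#' Simulate stepping-stone genotypes
#'
#' Wright-Fisher forward simulation: each generation every deme is replaced
#' by \code{N} offspring; an offspring draws its parent deme from the
#' backward migration matrix, then with probability \code{selfing} both
#' gametes come from one uniformly drawn parent, otherwise from two
#' uniformly drawn parents. Gametes segregate one allele per locus. After
#' \code{generations} generations, \code{sampleSize} individuals per deme
#' are sampled without replacement.
#'
#' @param spec a \code{\link{steppingStoneSpec}}.
#' @return a \linkS4class{GenotypeMatrix} with deme labels
#'   \code{D01, D02, ...} as sites.
#' @export
simulateSteppingStone <- function(spec) {
  stopifnot(inherits(spec, "SteppingStoneSpec"))
  d <- spec$d; N <- spec$N; L <- spec$L
  M <- if (!is.null(spec$migrationMatrix)) spec$migrationMatrix
       else steppingStoneMigration(d, spec$m)
  restoreRng <- .localSeed(.subSeed(spec$seed, "stepping-stone"))
  on.exit(restoreRng(), add = TRUE)
  p0 <- runif(L, spec$initFreqRange[1], spec$initFreqRange[2])
  # population as a single (d*N) x L matrix of 0/1/2; deme i occupies rows
  # (i-1)*N + 1 .. i*N
  P <- matrix(rbinom(d * N * L, 2L, rep(p0, each = d * N)), d * N, L)

  gamete <- function(rows) {
    gm <- P[rows, , drop = FALSE]
    (matrix(runif(length(gm)), nrow(gm)) < gm / 2) + 0L
  }
  s <- spec$selfing
  for (gen in seq_len(spec$generations)) {
    newP <- P
    for (i in seq_len(d)) {
      src <- if (d == 1L) rep(1L, N) else
        sample.int(d, N, replace = TRUE, prob = M[i, ])
      par1 <- (src - 1L) * N + sample.int(N, N, replace = TRUE)
      par2 <- (src - 1L) * N + sample.int(N, N, replace = TRUE)
      if (s > 0) {
        selfed <- runif(N) < s
        par2[selfed] <- par1[selfed]
      }
      newP[((i - 1L) * N + 1L):(i * N), ] <- gamete(par1) + gamete(par2)
    }
    P <- newP
  }

  idx <- unlist(lapply(seq_len(d), function(i)
    (i - 1L) * N + sample.int(N, spec$sampleSize)))
  geno <- P[idx, , drop = FALSE]
  storage.mode(geno) <- "integer"
  site <- rep(sprintf("D%02d", seq_len(d)), each = spec$sampleSize)
  rownames(geno) <- paste0(site, "_", sequence(rep(spec$sampleSize, d)))
  colnames(geno) <- sprintf("L%05d", seq_len(L))
  new("GenotypeMatrix", geno = geno, site = site,
      chrom = rep("1", L), pos = seq_len(L) * 100L)
}
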