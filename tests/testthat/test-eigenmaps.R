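test_that("dbMEM matches the canonical truncated-PCoA construction on an
           equidistant transect", {
  pos <- seq(0, 90, by = 10)                  # 10 equidistant collinear sites
  D <- abs(outer(pos, pos, "-"))
  mem <- dbMem(D)
  expect_lte(ncol(basisScores(mem)), 9)
  # independent oracle: vegan's pcnm implements the same recipe
  p <- vegan::pcnm(as.dist(D))
  expect_equal(mem@meta$truncation, p$threshold)
  k <- min(ncol(basisScores(mem)), ncol(p$vectors))
  for (j in seq_len(k))
    expect_gt(abs(cor(basisScores(mem)[, j], p$vectors[, j])), 1 - 1e-8)
  # the leading vector carries the broadest scale; on an exactly equidistant
  # transect it is a centred sine whose gradient correlation plateaus ~0.85
  expect_gt(abs(cor(basisScores(mem)[, 1], pos)), 0.8)
})

test_that("dbMEM recovers a monotone leading gradient on a clustered
           transect", {
  # two regional clusters along one line, as real coastal surveys have
  pos <- c(seq(0, 40, by = 10), seq(200, 240, by = 10))
  mem <- dbMem(abs(outer(pos, pos, "-")))
  expect_gt(abs(cor(basisScores(mem)[, 1], pos)), 0.9)
})

test_that("dbMEM eigenvalues match an independent principal-coordinates
           oracle on the truncated matrix", {
  set.seed(20)
  xy <- cbind(runif(5, 0, 100), runif(5, 0, 100))
  D <- as.matrix(dist(xy))
  mem <- dbMem(D)
  thr <- mem@meta$truncation
  Dt <- D; Dt[Dt > thr] <- 4 * thr; diag(Dt) <- 0
  pcoa <- cmdscale(Dt, k = 4, eig = TRUE)     # independent Gower-centred route
  want <- pcoa$eig[pcoa$eig > 1e-8]
  got <- basisValues(mem)[basisValues(mem) > 1e-8]
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("dbMEM bases are orthogonal, centred, and capped at n - 1", {
  spec <- syntheticOceanSpec(seed = 5)
  f <- makeVelocityField(spec, "2010")
  sites <- makeSiteLayout(20, "coastal", f)
  D <- leastCostDistance(f, sites)
  mem <- dbMem(D)
  S <- basisScores(mem)
  expect_lte(ncol(S), 19)
  expect_lt(max(abs(crossprod(S) - diag(ncol(S)))), 1e-8)
  expect_lt(max(abs(colMeans(S))), 1e-10)
  expect_error(dbMem(D[1:2, 1:2]), "n >= 3")
})

test_that("AEM site-by-edge matrix matches hand enumeration on a toy graph", {
  # 4 nodes: 1->2 (0.4), 2->3 (0.3), 2->4 (0.2); node 1 upstream of all
  P <- matrix(0, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  P[1, 2] <- 0.4; P[2, 3] <- 0.3; P[2, 4] <- 0.2
  ae <- aem(P)
  E <- ae@meta$siteByEdge
  # edges ordered (1->2), (2->3), (2->4); rows = sites
  want <- rbind(c(0, 0, 0),
                c(0.4, 0, 0),
                c(0.4, 0.3, 0),
                c(0.4, 0, 0.2))
  expect_equal(unname(E), want)
  expect_lte(ncol(basisScores(ae)), 3)
  # centred and orthogonal columns
  S <- basisScores(ae)
  expect_lt(max(abs(colMeans(S))), 1e-10)
  ip <- crossprod(S)
  expect_lt(max(abs(ip - diag(diag(ip)))), 1e-8)
})

test_that("a downstream chain yields a monotone first AEM vector", {
  P <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  P[1, 2] <- 0.5; P[2, 3] <- 0.5
  ae <- aem(P)
  v1 <- basisScores(ae)[, 1]
  expect_true(all(diff(v1) > 0) || all(diff(v1) < 0))
  expect_error(aem(matrix(0, 3, 3)), "positive off-diagonal")
})

test_that("ties are broken by site order and cycles at the weakest edge", {
  # symmetric pair: orientation must be low index -> high index
  P <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  P[1, 2] <- 0.5; P[2, 1] <- 0.5; P[2, 3] <- 0.4
  ae <- aem(P)
  e <- ae@meta$edges
  expect_equal(e$from[1], 1); expect_equal(e$to[1], 2)

  # directed 3-cycle: weakest edge (0.1) dropped
  Pc <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  Pc[1, 2] <- 0.5; Pc[2, 3] <- 0.3; Pc[3, 1] <- 0.1
  expect_message(aeC <- aem(Pc), "cycle broken")
  expect_equal(nrow(aeC@meta$edges), 2)
  expect_false(any(aeC@meta$edges$from == 3 & aeC@meta$edges$to == 1))
})
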