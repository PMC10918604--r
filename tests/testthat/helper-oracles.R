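# Independent oracle implementations kept deliberately separate from the
# package's code paths.

# Weir-Cockerham (1984) components written from the estimator's published
# algebra, one locus at a time, scalar arithmetic only.
oracleWc <- function(geno, site) {
  sitesU <- unique(site)
  L <- ncol(geno)
  a <- b <- cc <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    ni <- c(); pi <- c(); hi <- c()
    for (s in sitesU) {
      gl <- geno[site == s, l]
      gl <- gl[!is.na(gl)]
      if (length(gl) == 0) next
      ni <- c(ni, length(gl))
      pi <- c(pi, sum(gl) / (2 * length(gl)))
      hi <- c(hi, mean(gl == 1))
    }
    r <- length(ni)
    if (r < 2) next
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a[l] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[l] <- hbar / 2
  }
  ok <- !is.na(a)
  list(a = a, b = b, c = cc, fst = sum(a[ok]) / sum(a[ok] + b[ok] + cc[ok]))
}

# per-site diversity by direct evaluation of the corrected gene diversity
oracleDiversity <- function(geno, site) {
  out <- NULL
  for (s in unique(site)) {
    sub <- geno[site == s, , drop = FALSE]
    hoL <- hsL <- c()
    for (l in seq_len(ncol(sub))) {
      gl <- sub[!is.na(sub[, l]), l]
      n <- length(gl)
      if (n < 2) next
      ho <- mean(gl == 1)
      p <- sum(gl) / (2 * n)
      hs <- n / (n - 1) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
      hoL <- c(hoL, ho); hsL <- c(hsL, hs)
    }
    out <- rbind(out, data.frame(site = s, Ho = mean(hoL), Hs = mean(hsL),
                                 Fis = 1 - mean(hoL) / mean(hsL)))
  }
  out
}

# brute-force two-deme Wright-Fisher simulator (individual-based, shared
# pedigree across loci), written as explicit per-deme matrices with rbinom
# gamete draws -- an independent route to the same demographic model
oracleTwoDemeSim <- function(N, m, L, generations, sampleSize, seed) {
  set.seed(seed)
  p0 <- runif(L, 0.1, 0.9)
  deme1 <- matrix(rbinom(N * L, 2, rep(p0, each = N)), N, L)
  deme2 <- matrix(rbinom(N * L, 2, rep(p0, each = N)), N, L)
  drawGamete <- function(pool, parents)
    matrix(rbinom(length(parents) * L, 1, pool[parents, ] / 2),
           length(parents), L)
  for (g in seq_len(generations)) {
    new1 <- matrix(0L, N, L); new2 <- matrix(0L, N, L)
    for (target in 1:2) {
      fromOther <- runif(N) < m   # both parents share the migrant's deme
      srcPool <- if (target == 1) list(deme1, deme2) else list(deme2, deme1)
      idxHome <- which(!fromOther); idxAway <- which(fromOther)
      res <- matrix(0L, N, L)
      if (length(idxHome)) {
        pa <- sample.int(N, length(idxHome), TRUE)
        pb <- sample.int(N, length(idxHome), TRUE)
        res[idxHome, ] <- drawGamete(srcPool[[1]], pa) + drawGamete(srcPool[[1]], pb)
      }
      if (length(idxAway)) {
        pa <- sample.int(N, length(idxAway), TRUE)
        pb <- sample.int(N, length(idxAway), TRUE)
        res[idxAway, ] <- drawGamete(srcPool[[2]], pa) + drawGamete(srcPool[[2]], pb)
      }
      if (target == 1) new1 <- res else new2 <- res
    }
    deme1 <- new1; deme2 <- new2
  }
  g1 <- deme1[sample.int(N, sampleSize), , drop = FALSE]
  g2 <- deme2[sample.int(N, sampleSize), , drop = FALSE]
  list(geno = rbind(g1, g2),
       site = rep(c("A", "B"), each = sampleSize))
}

# direct bilinear + linear-time weighted average at one point
oracleSampleVelocity <- function(field, x, y, t) {
  gx <- field@lon; gy <- field@lat; gt <- field@time
  i <- max(which(gx <= x + 1e-12)); i <- min(i, length(gx) - 1)
  j <- max(which(gy <= y + 1e-12)); j <- min(j, length(gy) - 1)
  k <- max(which(gt <= t + 1e-12)); k <- min(k, max(length(gt) - 1, 1))
  wx <- (x - gx[i]) / (gx[i + 1] - gx[i])
  wy <- (y - gy[j]) / (gy[j + 1] - gy[j])
  one <- function(slice) {
    vals <- c(slice[i, j], slice[i + 1, j], slice[i, j + 1], slice[i + 1, j + 1])
    wts <- c((1 - wx) * (1 - wy), wx * (1 - wy), (1 - wx) * wy, wx * wy)
    wts[is.na(vals)] <- 0
    vals[is.na(vals)] <- 0
    if (sum(wts) <= 0) return(NA_real_)
    sum(wts * vals) / sum(wts)
  }
  if (length(gt) == 1) return(c(one(field@u[, , 1]), one(field@v[, , 1])))
  wt <- (t - gt[k]) / (gt[k + 1] - gt[k])
  c((1 - wt) * one(field@u[, , k]) + wt * one(field@u[, , k + 1]),
    (1 - wt) * one(field@v[, , k]) + wt * one(field@v[, , k + 1]))
}

# exhaustive breadth-first / Dijkstra over an explicit adjacency list,
# implemented with a simple O(V^2) scan (no igraph)
oracleGridShortestPath <- function(land, lon, lat, from, to) {
  nx <- length(lon); ny <- length(lat)
  id <- function(i, j) (j - 1L) * nx + i
  dist <- rep(Inf, nx * ny)
  visited <- rep(FALSE, nx * ny)
  dist[id(from[1], from[2])] <- 0
  kmLat <- 111.32 * mean(diff(lat))
  repeat {
    u <- which.min(ifelse(visited, Inf, dist))
    if (!is.finite(dist[u])) break
    if (u == id(to[1], to[2])) break
    visited[u] <- TRUE
    iu <- (u - 1L) %% nx + 1L; ju <- (u - 1L) %/% nx + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- iu + di; j2 <- ju + dj
      if (i2 < 1 || i2 > nx || j2 < 1 || j2 > ny) next
      if (land[i2, j2]) next
      latMid <- (lat[ju] + lat[j2]) / 2
      kmLon <- 111.32 * cos(latMid * pi / 180) * mean(diff(lon))
      step <- sqrt((abs(di) * kmLon)^2 + (abs(dj) * kmLat)^2)
      v <- id(i2, j2)
      if (dist[u] + step < dist[v]) dist[v] <- dist[u] + step
    }
  }
  dist[id(to[1], to[2])]
}

# all permutations of 1..n, constructed iteratively (independent of the
# package's recursive generator)
oracleAllPerms <- function(n) {
  perms <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- NULL
    for (r in seq_len(nrow(perms))) {
      for (pos in 0:(k - 1)) {
        out <- rbind(out, append(perms[r, ], k, after = pos))
      }
    }
    perms <- out
  }
  perms
}
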