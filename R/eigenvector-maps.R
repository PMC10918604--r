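#' Distance-based Moran's eigenvector maps (dbMEM)
#'
#' Classical construction: the truncation threshold is the longest edge of
#' the minimum spanning tree of \code{D}; distances above it are replaced by
#' four times the threshold; the truncated matrix is converted to a Gower
#' double-centred form \eqn{-D^2/2} and eigen-decomposed; all eigenvectors
#' with eigenvalue above 1e-10 are retained in descending eigenvalue order
#' (no Moran's-I significance screen, so 20 sites yield up to 19 vectors).
#'
#' @param D symmetric matrix of finite distances (km), n >= 3.
#' @return an \linkS4class{EigenbasisSet} of kind \code{"dbMEM"}; vector
#'   names MEM1, MEM2, ...
#' @export
dbMem <- function(D) {
  n <- nrow(D)
  if (n < 3) stop("dbMEM needs n >= 3 sites")
  if (any(!is.finite(D))) stop("dbMEM needs finite distances")
  thr <- max(vegan::spantree(stats::as.dist(D))$dist)
  Dt <- D
  Dt[Dt > thr] <- 4 * thr
  diag(Dt) <- 0
  A <- -0.5 * Dt^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- which(ev$values > 1e-10)
  sc <- ev$vectors[, keep, drop = FALSE]
  colnames(sc) <- paste0("MEM", seq_along(keep))
  rownames(sc) <- rownames(D)
  new("EigenbasisSet", kind = "dbMEM", scores = sc, values = ev$values[keep],
      meta = list(truncation = thr, replacement = 4 * thr))
}

# orient every connected pair by the larger dispersal probability and break
# any directed cycles at their weakest edge
.aemEdges <- function(P) {
  ns <- nrow(P)
  from <- to <- integer(); wt <- numeric()
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    pij <- P[i, j]; pji <- P[j, i]
    if (is.na(pij)) pij <- 0
    if (is.na(pji)) pji <- 0
    if (pij <= 0 && pji <= 0) next
    if (pij >= pji) { from <- c(from, i); to <- c(to, j); wt <- c(wt, pij) }
    else { from <- c(from, j); to <- c(to, i); wt <- c(wt, pji) }
  }
  if (!length(from)) stop("no positive off-diagonal dispersal probabilities")
  repeat {
    gr <- igraph::graph_from_edgelist(cbind(from, to))
    if (igraph::is_dag(gr)) break
    comp <- igraph::components(gr, mode = "strong")
    cyc <- which(comp$csize > 1)[1]
    nodes <- which(comp$membership == cyc)
    inCyc <- which(from %in% nodes & to %in% nodes)
    drop <- inCyc[which.min(wt[inCyc])]
    message("AEM: cycle broken at edge ", from[drop], "->", to[drop],
            " (weight ", signif(wt[drop], 3), ")")
    from <- from[-drop]; to <- to[-drop]; wt <- wt[-drop]
  }
  data.frame(from = from, to = to, weight = wt)
}

#' Asymmetric eigenvector maps (AEM)
#'
#' Directional spatial basis from a dispersal-probability matrix. Edges are
#' taken where dispersal probability is positive, oriented by the larger of
#' the two directed probabilities (ties broken by site order; directed
#' cycles broken at their weakest edge, logged). The site-by-edge matrix
#' carries the edge weight wherever the edge lies on a directed path
#' reaching the site; it is column-centred and decomposed by SVD, the left
#' singular vectors scaled by their singular values giving the AEM scores.
#'
#' @param C a \linkS4class{ConnectivityMatrix} (its across-year mean is
#'   used) or a plain site-by-site probability matrix.
#' @return an \linkS4class{EigenbasisSet} of kind \code{"AEM"} with the
#'   oriented edge list and the site-by-edge matrix in \code{meta}.
#' @export
aem <- function(C) {
  P <- if (is(C, "ConnectivityMatrix")) connMean(C) else as.matrix(C)
  siteNm <- rownames(P)
  ns <- nrow(P)
  diag(P) <- 0
  edges <- .aemEdges(P)
  ne <- nrow(edges)
  gr <- igraph::graph_from_edgelist(cbind(edges$from, edges$to))
  if (igraph::vcount(gr) < ns) gr <- igraph::add_vertices(gr, ns - igraph::vcount(gr))
  reach <- igraph::distances(gr, mode = "out")   # finite = reachable
  E <- matrix(0, ns, ne)
  for (e in seq_len(ne)) {
    onPath <- is.finite(reach[edges$to[e], ])
    E[onPath, e] <- edges$weight[e]
  }
  Ec <- scale(E, center = TRUE, scale = FALSE)
  sv <- svd(Ec)
  keep <- which(sv$d > 1e-8)
  sc <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  colnames(sc) <- paste0("AEM", seq_along(keep))
  rownames(sc) <- siteNm
  new("EigenbasisSet", kind = "AEM", scores = sc, values = sv$d[keep]^2,
      meta = list(edges = edges, siteByEdge = E))
}
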