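#' Markov clustering of a weighted network
#'
#' Deterministic Markov Cluster (MCL) algorithm on the positive-weight part
#' of a network. The transition matrix is built from the edge weights with
#' each node's self-loop set to its maximum incident weight, then column
#' normalized. Iteration alternates expansion (matrix power) and inflation
#' (entrywise power followed by column renormalization), pruning entries
#' below `pruneTol`, until the matrix changes by less than `1e-6`
#' (max-norm) or `maxIter` rounds are reached (the latter returns the
#' current clustering with a warning). Clusters are read off the attractor
#' rows of the converged matrix; overlapping attractor systems are merged,
#' so the result is a partition of all nodes incident to a positive-weight
#' edge.
#'
#' @param x a [ConditionalNetwork-class] (clustered on `clusterWeight`), a
#'   data.frame with columns `from`, `to`, `weight`, or a symmetric
#'   nonnegative weight matrix with dimnames.
#' @param inflation inflation exponent (> 1); conventionally 2.3.
#' @param expansion expansion power (integer >= 2).
#' @param maxIter maximum number of expansion/inflation rounds.
#' @param pruneTol entries below this are set to zero after each inflation.
#' @return named list of character vectors (the clusters), ordered by
#'   decreasing size then lexicographically; attribute `converged` is
#'   `FALSE` if `maxIter` was hit.
#' @export
mclCluster <- function(x, inflation = 2.3, expansion = 2L, maxIter = 100L,
                       pruneTol = 1e-5) {
  stopifnot(inflation > 1, expansion >= 2, maxIter >= 1)
  W <- .mclWeightMatrix(x)
  n <- nrow(W)
  if (n == 0L) stop("no positive-weight edges to cluster")
  nodes <- rownames(W)
  # self-loops: each node's maximum incident weight
  diag(W) <- apply(W, 1L, max)
  M <- sweep(W, 2L, colSums(W), "/")
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    Mexp <- M
    for (p in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < pruneTol] <- 0
    cs <- colSums(Minf)
    dead <- cs == 0                       # fully pruned column: restore self
    if (any(dead)) {
      Minf[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Minf <- sweep(Minf, 2L, cs, "/")
    if (max(abs(Minf - M)) < 1e-6) { M <- Minf; converged <- TRUE; break }
    M <- Minf
  }
  if (!converged)
    warning("MCL did not converge within ", maxIter, " iterations")
  clusters <- .mclReadClusters(M, nodes, pruneTol)
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1), 1L))
  clusters <- clusters[ord]
  names(clusters) <- sprintf("mcl%03d", seq_along(clusters))
  attr(clusters, "converged") <- converged
  clusters
}

# dense symmetric weight matrix over positive-weight nodes
.mclWeightMatrix <- function(x) {
  if (is(x, "ConditionalNetwork")) {
    e <- networkEdges(x)
    x <- data.frame(from = e$from, to = e$to, weight = e$clusterWeight,
                    stringsAsFactors = FALSE)
  }
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("weight matrix needs dimnames")
    if (any(x < 0)) stop("weights must be nonnegative")
    keep <- rowSums(x > 0) > 0
    return(x[keep, keep, drop = FALSE])
  }
  stopifnot(all(c("from", "to", "weight") %in% names(x)))
  e <- x[x$weight > 0, , drop = FALSE]
  if (!nrow(e)) stop("no positive-weight edges to cluster")
  nodes <- sort(unique(c(e$from, e$to)))
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  i <- match(e$from, nodes); j <- match(e$to, nodes)
  W[cbind(i, j)] <- pmax(W[cbind(i, j)], e$weight)
  W[cbind(j, i)] <- W[cbind(i, j)]
  W
}

# attractor-row interpretation, merging overlapping attractor systems
.mclReadClusters <- function(M, nodes, tol) {
  n <- length(nodes)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  for (r in seq_len(n)) {
    cols <- which(M[r, ] > tol)
    if (length(cols) > 1L)
      g <- igraph::add_edges(g, rbind(cols[1L], cols[-1L]))
    if (length(cols))                      # tie node r to its attractor
      g <- igraph::add_edges(g, rbind(r, cols[1L]))
  }
  comp <- igraph::components(g)$membership
  unname(split(nodes, comp))
}
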