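#' Jaccard similarity of two member sets
#'
#' @param a,b character vectors (at least one non-empty).
#' @return `|a n b| / |a u b|`.
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("jaccard undefined for two empty sets")
  length(intersect(a, b)) / u
}

#' Match complexes across two conditions
#'
#' Pairs complexes from the first-condition set `S` with complexes from the
#' second-condition set `T` when their Jaccard similarity is at least `tJ`
#' and their absolute co-expression change is at least `delta`. Matching is
#' one-to-one and greedy: candidate pairs are taken in order of descending
#' Jaccard, ties broken by larger co-expression change, then
#' lexicographically by the two ids; each complex is used at most once.
#'
#' @param S,T [ProteinComplexSet-class] objects with co-expression computed.
#' @param tJ minimum Jaccard similarity; conventionally 0.67.
#' @param delta minimum absolute co-expression change; conventionally 0.10.
#' @return data.frame with one row per matched pair: `s_id`, `t_id`,
#'   `jaccard`, `C_s`, `C_t`, `delta_c` (= `|C_s - C_t|`) and `direction`
#'   (`"decrease"` when the first condition's co-expression is higher,
#'   `"increase"` otherwise). Zero rows when nothing matches.
#' @export
matchComplexes <- function(S, T, tJ = 0.67, delta = 0.10) {
  stopifnot(is(S, "ProteinComplexSet"), is(T, "ProteinComplexSet"))
  empty <- data.frame(s_id = character(), t_id = character(),
                      jaccard = numeric(), C_s = numeric(), C_t = numeric(),
                      delta_c = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (!length(S@members) || !length(T@members)) return(empty)
  cand <- expand.grid(s = names(S@members), t = names(T@members),
                      stringsAsFactors = FALSE)
  cand$jaccard <- mapply(function(s, t)
    jaccardIndex(S@members[[s]], T@members[[t]]), cand$s, cand$t)
  cand$C_s <- S@coexpression[cand$s]
  cand$C_t <- T@coexpression[cand$t]
  cand$delta_c <- abs(cand$C_s - cand$C_t)
  cand <- cand[!is.na(cand$delta_c) & cand$jaccard >= tJ &
                 cand$delta_c >= delta, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(-cand$jaccard, -cand$delta_c, cand$s, cand$t), ,
               drop = FALSE]
  usedS <- character(); usedT <- character(); take <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (cand$s[r] %in% usedS || cand$t[r] %in% usedT) next
    take[r] <- TRUE
    usedS <- c(usedS, cand$s[r]); usedT <- c(usedT, cand$t[r])
  }
  cand <- cand[take, , drop = FALSE]
  data.frame(s_id = cand$s, t_id = cand$t, jaccard = cand$jaccard,
             C_s = unname(cand$C_s), C_t = unname(cand$C_t),
             delta_c = cand$delta_c,
             direction = ifelse(cand$C_s > cand$C_t, "decrease", "increase"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition matched pairs by direction of co-expression change
#'
#' Splits the matched set into the pairs whose co-expression is higher in
#' the first condition (direction `"decrease"`, usually written M') and
#' those where it is lower (`"increase"`, M''), reporting per-subset size,
#' maximum and mean co-expression change.
#'
#' @param matched data.frame from [matchComplexes()].
#' @return data.frame with rows `Mprime` and `Mdprime` and columns
#'   `subset`, `direction`, `n`, `max_delta_c`, `mean_delta_c` (the last
#'   two `NA` for an empty subset).
#' @export
partitionMatched <- function(matched) {
  stat <- function(dir) {
    d <- matched$delta_c[matched$direction == dir]
    c(n = length(d),
      max = if (length(d)) max(d) else NA_real_,
      mean = if (length(d)) mean(d) else NA_real_)
  }
  a <- stat("decrease"); b <- stat("increase")
  data.frame(subset = c("Mprime", "Mdprime"),
             direction = c("decrease", "increase"),
             n = c(a["n"], b["n"]),
             max_delta_c = c(a["max"], b["max"]),
             mean_delta_c = c(a["mean"], b["mean"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Random-complex null model for a co-expression statistic
#'
#' Draws `nComplexes` random node sets, size-matched to `sizes`, from the
#' supplied node universe (uniformly, without replacement within a set),
#' computes each set's absolute co-expression change between the two
#' conditions, summarizes them with `statistic`, and repeats `reps` times.
#' The empirical p-value is `(1 + #{null >= observed}) / (1 + reps)`.
#'
#' @param observed observed value of the statistic.
#' @param exprA,exprB the two conditions' expression data.
#' @param nodes node universe to sample from (e.g. network nodes with
#'   expression).
#' @param sizes integer vector of complex sizes to match (recycled to
#'   `nComplexes`).
#' @param nComplexes random complexes per replicate; conventionally 500.
#' @param reps number of replicates; conventionally 1000.
#' @param statistic function reducing the vector of per-complex
#'   co-expression changes to one number (default: mean).
#' @param seed optional integer seed.
#' @param transformBase passed to [fisherTransform()].
#' @return list with `p`, the `null` vector of replicate statistics, and
#'   `observed`.
#' @export
randomComplexNull <- function(observed, exprA, exprB, nodes, sizes,
                              nComplexes = 500L, reps = 1000L,
                              statistic = function(d) mean(d, na.rm = TRUE),
                              seed = NULL,
                              transformBase = c("paper", "e")) {
  transformBase <- match.arg(transformBase)
  .checkSeed(seed)
  mA <- .exprMatrix(exprA); mB <- .exprMatrix(exprB)
  nodes <- nodes[nodes %in% rownames(mA) & nodes %in% rownames(mB)]
  if (max(sizes) > length(nodes))
    stop("requested complex size exceeds the node universe")
  sizes <- rep_len(as.integer(sizes), nComplexes)
  # precompute transformed correlation matrices once
  zA <- suppressWarnings(fisherTransform(cor(t(mA[nodes, , drop = FALSE]),
                                             use = "pairwise.complete.obs"),
                                         base = transformBase))
  zB <- suppressWarnings(fisherTransform(cor(t(mB[nodes, , drop = FALSE]),
                                             use = "pairwise.complete.obs"),
                                         base = transformBase))
  dim(zA) <- dim(zB) <- c(length(nodes), length(nodes))
  null <- numeric(reps)
  for (r in seq_len(reps)) {
    dC <- vapply(sizes, function(k) {
      idx <- sample.int(length(nodes), k)
      abs(mean(.upperTri(zA[idx, idx, drop = FALSE]), na.rm = TRUE) -
            mean(.upperTri(zB[idx, idx, drop = FALSE]), na.rm = TRUE))
    }, numeric(1))
    null[r] <- statistic(dC)
  }
  list(p = (1 + sum(null >= observed)) / (1 + reps),
       null = null, observed = observed)
}

#' Two-sample Kolmogorov-Smirnov comparison with scaled statistic
#'
#' Computes the sup-difference `D` of the two empirical CDFs, the scaled
#' statistic `D * sqrt(n*m/(n+m))` and the large-sample critical value
#' `c(alpha) = sqrt(-log(alpha/2)/2)` (1.36 at alpha = 0.05); the
#' difference is called significant when the scaled statistic exceeds the
#' critical value.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param alpha significance level.
#' @return list with `statistic` (D), `scaled`, `critical`, `reject`,
#'   `alpha`, `n`, `m`.
#' @export
ksCompare <- function(x, y, alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  stopifnot(n >= 2L, m >= 2L)
  pts <- sort(unique(c(x, y)))
  Fx <- findInterval(pts, sort(x)) / n
  Fy <- findInterval(pts, sort(y)) / m
  D <- max(abs(Fx - Fy))
  scaled <- D * sqrt(n * m / (n + m))
  critical <- sqrt(-log(alpha / 2) / 2)
  list(statistic = D, scaled = scaled, critical = critical,
       reject = scaled > critical, alpha = alpha, n = n, m = m)
}

#' Coverage of a gene list by differentially co-expressed complexes
#'
#' Fraction of the gene list appearing in at least one matched complex
#' (either side of the pair) whose co-expression change meets the
#' threshold. When `networkNodes` is supplied, a second fraction restricted
#' to the genes present in the network is also reported.
#'
#' @param matched data.frame from [matchComplexes()].
#' @param S,T the matched [ProteinComplexSet-class] objects.
#' @param geneList character vector of genes of interest (non-empty).
#' @param threshold minimum `delta_c`; conventionally 0.10.
#' @param networkNodes optional node universe for the restricted
#'   denominator.
#' @return list with `coverage`, `nCovered`, `nGenes`, and (when
#'   `networkNodes` is given) `coverageInNetwork`, `nGenesInNetwork`.
#' @export
cancerGeneCoverage <- function(matched, S, T, geneList, threshold = 0.10,
                               networkNodes = NULL) {
  geneList <- unique(toupper(geneList))
  if (!length(geneList)) stop("geneList must be non-empty")
  sel <- matched[matched$delta_c >= threshold, , drop = FALSE]
  covered <- unique(c(unlist(S@members[sel$s_id], use.names = FALSE),
                      unlist(T@members[sel$t_id], use.names = FALSE)))
  out <- list(coverage = mean(geneList %in% covered),
              nCovered = sum(geneList %in% covered),
              nGenes = length(geneList))
  if (!is.null(networkNodes)) {
    inNet <- geneList[geneList %in% networkNodes]
    out$coverageInNetwork <- if (length(inNet)) mean(inNet %in% covered)
                             else NA_real_
    out$nGenesInNetwork <- length(inNet)
  }
  out
}

#' Differential co-expression network between two conditions
#'
#' Restricts both conditional networks to their shared edges and weights
#' each edge by `delta`, the transformed-correlation difference (first
#' condition minus second). Edges with `abs(delta)` at or above
#' `minAbsDelta` form the rewired view, on which connected components are
#' computed and Markov clusters (weight `abs(delta)`) are labelled:
#' `"decrease"` if at least two-thirds of a cluster's rewired edges have
#' positive delta (co-expression drops from the first to the second
#' condition), `"increase"` if at least two-thirds have negative delta,
#' `"mixed"` otherwise. Exactly two-thirds counts as directional.
#'
#' @param netA,netB [ConditionalNetwork-class] objects for the two
#'   conditions.
#' @param minAbsDelta rewiring cutoff; conventionally 0.50.
#' @param inflation MCL inflation for cluster labelling.
#' @return A [DifferentialNetwork-class].
#' @export
differentialNetwork <- function(netA, netB, minAbsDelta = 0.50,
                                inflation = 2.3) {
  stopifnot(is(netA, "ConditionalNetwork"), is(netB, "ConditionalNetwork"))
  ea <- networkEdges(netA); eb <- networkEdges(netB)
  key <- function(e) paste(e$from, e$to, sep = "\r")
  shared <- intersect(key(ea), key(eb))
  if (!length(shared)) stop("the two networks share no edges")
  ia <- match(shared, key(ea)); ib <- match(shared, key(eb))
  edges <- data.frame(from = ea$from[ia], to = ea$to[ia],
                      delta = ea$z[ia] - eb$z[ib],
                      stringsAsFactors = FALSE)
  edges$rewired <- abs(edges$delta) >= minAbsDelta
  rew <- edges[edges$rewired, , drop = FALSE]
  clusters <- list(); labels <- character(0); largest <- character(0)
  if (nrow(rew)) {
    g <- igraph::graph_from_data_frame(rew[, c("from", "to")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    largest <- sort(names(comp$membership)[comp$membership ==
                                             which.max(comp$csize)])
    clusters <- mclCluster(data.frame(from = rew$from, to = rew$to,
                                      weight = abs(rew$delta)),
                           inflation = inflation)
    attr(clusters, "converged") <- NULL
    labels <- vapply(clusters, function(memb) {
      sel <- rew$from %in% memb & rew$to %in% memb
      if (!any(sel)) return("mixed")
      fracDec <- mean(rew$delta[sel] > 0)
      fracInc <- mean(rew$delta[sel] < 0)
      if (fracDec >= 2 / 3) "decrease"
      else if (fracInc >= 2 / 3) "increase"
      else "mixed"
    }, character(1))
  }
  new("DifferentialNetwork", edges = edges, clusters = clusters,
      clusterLabels = labels, largestComponent = largest,
      conditionLabels = c(conditionLabel(netA), conditionLabel(netB)))
}
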