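#' Iterated Czekanowski-Dice reliability scoring
#'
#' Assigns each interaction a reliability score in \[0, 1\] by iterating the
#' degree-adjusted Czekanowski-Dice neighbourhood similarity. Closed
#' neighbourhoods are used (a protein belongs to its own neighbourhood) and
#' each round re-weights neighbourhoods by the previous round's scores:
#'
#' \deqn{w_k(u,v) = \frac{\sum_{x \in N_u \cap N_v} (w_{k-1}(u,x) + w_{k-1}(v,x))}
#'   {\lambda_u + S_u + \lambda_v + S_v}}
#'
#' with \eqn{S_u = \sum_{x \in N_u} w_{k-1}(u,x)} and the degree penalty
#' \eqn{\lambda_u = \max(0, \bar S - S_u)} (\eqn{\bar S} the network-wide
#' mean of \eqn{S}). Round 1 (all weights 1) is the classical adjusted CD
#' score. The computation is deterministic.
#'
#' @param net a [ReliabilityNetwork-class]; prior reliability values are
#'   ignored, only the topology matters.
#' @param iterations number of scoring rounds (>= 1); conventionally 40.
#' @return The network with `reliability` replaced by the iterated scores.
#' @export
iterativeCDScore <- function(net, iterations = 40) {
  stopifnot(is(net, "ReliabilityNetwork"))
  if (iterations < 1) stop("iterations must be >= 1")
  e <- networkEdges(net)
  if (!nrow(e)) stop("cannot score an empty network")
  nodes <- networkNodes(net)
  n <- length(nodes)
  i <- match(e$from, nodes)
  j <- match(e$to, nodes)
  # closed-neighbourhood support: edges both ways plus the diagonal
  A <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)), j = c(j, i, seq_len(n)),
                            x = 1, dims = c(n, n))
  W <- A                                   # w_0 = 1 on the support
  sup <- cbind(c(i, j, seq_len(n)), c(j, i, seq_len(n)))
  for (k in seq_len(iterations)) {
    S <- Matrix::rowSums(W)
    lambda <- pmax(0, mean(S) - S)
    M <- W %*% A                           # M[u,v] = sum_{x in Nu&Nv} w(u,x)
    num <- M + Matrix::t(M)
    ls <- lambda + S
    vals <- as.numeric(num[sup]) / (ls[sup[, 1]] + ls[sup[, 2]])
    W <- Matrix::sparseMatrix(i = sup[, 1], j = sup[, 2], x = vals,
                              dims = c(n, n))
  }
  e$reliability <- as.numeric(W[cbind(i, j)])
  out <- net
  out@edges <- e
  validObject(out)
  out
}

#' Drop low-reliability interactions
#'
#' Removes edges whose reliability is strictly below `minScore` (the
#' boundary is kept); nodes left without edges disappear from the network.
#'
#' @param net a [ReliabilityNetwork-class] with scores assigned.
#' @param minScore reliability cutoff; conventionally 0.20.
#' @return The filtered network.
#' @export
filterByReliability <- function(net, minScore = 0.20) {
  stopifnot(is(net, "ReliabilityNetwork"))
  e <- networkEdges(net)
  keep <- e$reliability >= minScore
  removed <- sum(!keep)
  if (removed) message(removed, " edge(s) below reliability ", minScore,
                       " removed")
  out <- net
  out@edges <- e[keep, , drop = FALSE]
  rownames(out@edges) <- NULL
  out
}

#' Variance-emphasizing transform of a Pearson correlation
#'
#' Maps \eqn{\rho \in (-1, 1)} to \eqn{z = \frac{1}{2}\log\frac{1+\rho}{1-\rho}}.
#' In the default `"paper"` mode the logarithm is base 10 (so
#' \eqn{\rho = 0.10 \to z = 0.043} and \eqn{\rho = 0.99 \to z = 1.149});
#' `base = "e"` gives the natural-log variant, identical to `atanh`. The
#' map is odd and strictly increasing. Inputs at or beyond \eqn{\pm 1} are
#' clamped to \eqn{\pm 0.999999} with a warning.
#'
#' @param rho numeric vector of correlations.
#' @param base `"paper"` (base-10, default) or `"e"`.
#' @return numeric vector of transformed values.
#' @examples
#' fisherTransform(c(0.10, 0.99))   # 0.043, 1.149
#' @export
fisherTransform <- function(rho, base = c("paper", "e")) {
  base <- match.arg(base)
  out <- rep(NA_real_, length(rho))
  ok <- !is.na(rho)
  r <- rho[ok]
  if (any(abs(r) >= 1)) {
    warning("correlations at or beyond +/-1 clamped to +/-0.999999")
    r <- pmin(pmax(r, -0.999999), 0.999999)
  }
  z <- 0.5 * log((1 + r) / (1 - r))
  if (base == "paper") z <- z / log(10)
  out[ok] <- z
  out
}

#' @rdname fisherTransform
#' @param z numeric vector of transformed values to map back to
#'   correlations.
#' @export
inverseFisherTransform <- function(z, base = c("paper", "e")) {
  base <- match.arg(base)
  if (base == "paper") z <- z * log(10)
  tanh(z)
}

#' Overlay one condition's expression onto a PPI network
#'
#' For every edge whose two genes are measured, computes the Pearson
#' correlation `rho` across the condition's samples (missing cells excluded
#' pairwise), its transform `z = fisherTransform(rho)`, and the clustering
#' weight. Edges with a gene absent from the expression data are dropped
#' (count reported via `message`). Correlations that are undefined (zero
#' variance, or fewer than 3 complete sample pairs) become 0 and are
#' flagged in `rhoUndefined`.
#'
#' @param net a [ReliabilityNetwork-class].
#' @param expr a [ConditionExpression-class] or genes-x-samples matrix.
#' @param negativeMode how negative co-expression enters the clustering
#'   weight: `"positive"` (default) uses
#'   `reliability * max(rho, 0)` so anti-correlated pairs are treated as
#'   absent; `"abs"` uses `reliability * abs(rho)`.
#' @param transformBase passed to [fisherTransform()].
#' @return A [ConditionalNetwork-class] labelled with the condition of
#'   `expr`.
#' @export
conditionNetwork <- function(net, expr, negativeMode = c("positive", "abs"),
                             transformBase = c("paper", "e")) {
  stopifnot(is(net, "ReliabilityNetwork"))
  negativeMode <- match.arg(negativeMode)
  transformBase <- match.arg(transformBase)
  m <- .exprMatrix(expr)
  label <- if (is(expr, "ConditionExpression")) conditionLabel(expr) else "?"
  e <- networkEdges(net)
  present <- e$from %in% rownames(m) & e$to %in% rownames(m)
  if (!any(present)) stop("no network edge has both genes in the expression data")
  dropped <- sum(!present)
  if (dropped) message(dropped, " edge(s) without expression data dropped")
  e <- e[present, , drop = FALSE]
  rho <- mapply(function(a, b) .pairRho(m[a, ], m[b, ]), e$from, e$to,
                USE.NAMES = FALSE)
  undef <- is.na(rho)
  rho[undef] <- 0
  rho[abs(rho) < 1e-12] <- 0       # floating-point noise is not co-expression
  e$rho <- rho
  e$z <- suppressWarnings(fisherTransform(rho, base = transformBase))
  e$clusterWeight <- e$reliability *
    if (negativeMode == "positive") pmax(rho, 0) else abs(rho)
  e$rhoUndefined <- undef
  rownames(e) <- NULL
  new("ConditionalNetwork", edges = e, conditionLabel = label)
}
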