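#' Filter clusters to complex candidates
#'
#' Drops clusters below the minimum size and assigns deterministic ids
#' derived from a hash of the sorted member list, so the same member set
#' always receives the same id regardless of input order.
#'
#' @param clusters list of character vectors (e.g. from [mclCluster()]).
#' @param minSize minimum number of members; conventionally 4.
#' @return named list of member vectors (sorted members, ids as names).
#' @export
filterComplexes <- function(clusters, minSize = 4L) {
  clusters <- lapply(clusters, function(s) sort(unique(as.character(s))))
  keep <- lengths(clusters) >= minSize
  out <- clusters[keep]
  ids <- vapply(out, function(s) paste0("cpx", .stableHash(paste(s, collapse = "|"))),
                character(1))
  # disambiguate in the (unlikely) event of a hash collision
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  names(out) <- ids
  out[order(names(out))]
}

#' Co-expression score of one complex
#'
#' The co-expression C of a member set is the aggregate of the transformed
#' pairwise Pearson correlations of its members' expression profiles.
#' Mode `"pairs"` (default) averages `fisherTransform(rho(p, q))` over all
#' unordered distinct member pairs with measured expression. Mode
#' `"literal"` sums over ordered pairs (each unordered pair counted twice,
#' self-pairs excluded) and divides by the squared member count; it differs
#' from `"pairs"` only by the positive factor `(m-1)/m`, so signs and
#' orderings agree between modes at a fixed size.
#'
#' @param members character vector of member identifiers.
#' @param expr a [ConditionExpression-class] or genes-x-samples matrix.
#' @param mode `"pairs"` or `"literal"`.
#' @param transformBase passed to [fisherTransform()].
#' @return A single numeric score; `NA` (flagged via attribute
#'   `"undefined"`) when fewer than two members have expression rows.
#'   Attribute `"nMissing"` counts members without expression data.
#' @examples
#' m <- matrix(rnorm(40), 4, 10, dimnames = list(c("A","B","C","D"), NULL))
#' complexCoexpression(c("A", "B", "C", "D"), m)
#' @export
complexCoexpression <- function(members, expr, mode = c("pairs", "literal"),
                                transformBase = c("paper", "e")) {
  mode <- match.arg(mode)
  transformBase <- match.arg(transformBase)
  m <- .exprMatrix(expr)
  members <- unique(toupper(as.character(members)))
  measured <- members[members %in% rownames(m)]
  nMissing <- length(members) - length(measured)
  if (nMissing) message(nMissing, " member(s) without expression data excluded")
  if (length(measured) < 2L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    attr(out, "nMissing") <- nMissing
    return(out)
  }
  k <- length(measured)
  sub <- m[measured, , drop = FALSE]
  if (!anyNA(sub) && ncol(sub) >= 3L) {
    rho <- suppressWarnings(cor(t(sub)))
    rho <- .upperTri(rho)
    rho <- rho[!is.na(rho)]                 # zero-variance rows give NA
  } else {
    rho <- numeric(0)
    for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
      r <- .pairRho(sub[a, ], sub[b, ])
      if (!is.na(r)) rho <- c(rho, r)
    }
  }
  z <- suppressWarnings(fisherTransform(rho, base = transformBase))
  if (!length(z)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    attr(out, "nMissing") <- nMissing
    return(out)
  }
  out <- switch(mode,
                pairs = mean(z),
                literal = 2 * sum(z) / k^2)
  attr(out, "nMissing") <- nMissing
  out
}

#' Extract scored complexes from a conditional network
#'
#' Convenience pipeline stage: Markov clustering of the conditional
#' network's clustering weights, size filtering, and per-complex
#' co-expression scoring against the condition's expression data.
#'
#' @param net a [ConditionalNetwork-class].
#' @param expr the same condition's expression
#'   ([ConditionExpression-class] or matrix).
#' @param inflation,minSize,expansion,maxIter,pruneTol see [mclCluster()]
#'   and [filterComplexes()].
#' @param mode,transformBase see [complexCoexpression()].
#' @return A [ProteinComplexSet-class].
#' @export
extractComplexes <- function(net, expr, inflation = 2.3, minSize = 4L,
                             expansion = 2L, maxIter = 100L, pruneTol = 1e-5,
                             mode = c("pairs", "literal"),
                             transformBase = c("paper", "e")) {
  stopifnot(is(net, "ConditionalNetwork"))
  mode <- match.arg(mode)
  transformBase <- match.arg(transformBase)
  clusters <- mclCluster(net, inflation = inflation, expansion = expansion,
                         maxIter = maxIter, pruneTol = pruneTol)
  proteinComplexSet(filterComplexes(clusters, minSize = minSize), expr,
                    conditionLabel = conditionLabel(net), mode = mode,
                    transformBase = transformBase)
}

#' Build a ProteinComplexSet from member lists and expression data
#'
#' @param members named list of member vectors (ids assigned via
#'   [filterComplexes()] when names are missing).
#' @param expr expression data used to score each complex.
#' @param conditionLabel condition label for the set.
#' @inheritParams complexCoexpression
#' @return A [ProteinComplexSet-class].
#' @export
proteinComplexSet <- function(members, expr, conditionLabel,
                              mode = c("pairs", "literal"),
                              transformBase = c("paper", "e")) {
  mode <- match.arg(mode)
  transformBase <- match.arg(transformBase)
  if (is.null(names(members)))
    members <- filterComplexes(members, minSize = 2L)
  C <- vapply(members, function(s)
    as.numeric(suppressMessages(
      complexCoexpression(s, expr, mode = mode, transformBase = transformBase))),
    numeric(1))
  new("ProteinComplexSet", members = members, coexpression = C,
      conditionLabel = as.character(conditionLabel))
}
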