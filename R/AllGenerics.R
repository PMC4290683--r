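#' Construct a ReliabilityNetwork from endpoint vectors
#'
#' Canonicalizes identifiers to uppercase, drops self-loops and merges
#' duplicate undirected edges keeping the maximum reliability.
#'
#' @param from,to character vectors of interacting protein identifiers.
#' @param reliability numeric vector of per-edge scores in \[0, 1\]
#'   (recycled; defaults to 1).
#' @return A [ReliabilityNetwork-class] object.
#' @examples
#' net <- ReliabilityNetwork(c("a", "B", "c"), c("b", "A", "C"),
#'                           c(0.9, 0.4, 1))
#' networkEdges(net)  # one A-B edge at 0.9; the C-C self-loop is gone
#' @export
ReliabilityNetwork <- function(from, to, reliability = 1) {
  stopifnot(length(from) == length(to))
  from <- toupper(as.character(from))
  to <- toupper(as.character(to))
  reliability <- rep_len(as.numeric(reliability), length(from))
  keep <- from != to
  from <- from[keep]; to <- to[keep]; reliability <- reliability[keep]
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  if (length(from)) {
    key <- paste(from, to, sep = "\r")
    ord <- order(key, -reliability)
    first <- !duplicated(key[ord])
    idx <- ord[first]
    edges <- data.frame(from = from[idx], to = to[idx],
                        reliability = reliability[idx],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        reliability = numeric(), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  new("ReliabilityNetwork", edges = edges)
}

#' Construct a ConditionExpression object
#'
#' @param values numeric matrix, genes as rows (rownames required), samples
#'   as columns.
#' @param conditionLabel single character label for the condition.
#' @return A [ConditionExpression-class] object.
#' @export
ConditionExpression <- function(values, conditionLabel) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("expression matrix needs gene identifiers as rownames")
  rownames(values) <- toupper(rownames(values))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  new("ConditionExpression", se, conditionLabel = as.character(conditionLabel))
}

## ---- generics ------------------------------------------------------------

#' Edge table of a network
#' @param x a network object.
#' @return data.frame of edges.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Node identifiers of a network
#' @param x a network object.
#' @return character vector of node identifiers (sorted).
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Condition label of an object
#' @param x object carrying a condition label.
#' @return single character.
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' Member sets of a complex collection
#' @param x a [ProteinComplexSet-class] or [SyntheticTruth-class].
#' @return named list of character vectors.
#' @export
setGeneric("complexMembers", function(x) standardGeneric("complexMembers"))

#' Per-complex co-expression scores
#' @param x a [ProteinComplexSet-class].
#' @return named numeric vector.
#' @export
setGeneric("coexpression", function(x) standardGeneric("coexpression"))

#' Differential-regulation matrix
#' @param x a [RegulationMatrix-class].
#' @return numeric matrix of `|R_s - R_t|` values (NA where undefined).
#' @export
setGeneric("deltaRegulation", function(x) standardGeneric("deltaRegulation"))

#' Influence table
#' @param x an [InfluenceResult-class].
#' @return data.frame with per-TF coefficients.
#' @export
setGeneric("influenceTable", function(x) standardGeneric("influenceTable"))

## ---- methods -------------------------------------------------------------

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "ReliabilityNetwork", function(x) x@edges)

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "ReliabilityNetwork", function(x)
  sort(unique(c(x@edges$from, x@edges$to))))

#' @rdname conditionLabel
#' @export
setMethod("conditionLabel", "ConditionalNetwork", function(x) x@conditionLabel)

#' @rdname conditionLabel
#' @export
setMethod("conditionLabel", "ConditionExpression", function(x) x@conditionLabel)

#' @rdname conditionLabel
#' @export
setMethod("conditionLabel", "ProteinComplexSet", function(x) x@conditionLabel)

#' @rdname complexMembers
#' @export
setMethod("complexMembers", "ProteinComplexSet", function(x) x@members)

#' @rdname complexMembers
#' @export
setMethod("complexMembers", "SyntheticTruth", function(x) x@plantedComplexes)

#' @rdname coexpression
#' @export
setMethod("coexpression", "ProteinComplexSet", function(x) x@coexpression)

#' @rdname deltaRegulation
#' @export
setMethod("deltaRegulation", "RegulationMatrix", function(x) {
  m <- x@deltaR
  dimnames(m) <- list(x@pairIds, x@tfIds)
  m
})

#' @rdname influenceTable
#' @export
setMethod("influenceTable", "InfluenceResult", function(x) x@table)

setMethod("show", "ReliabilityNetwork", function(object) {
  e <- object@edges
  cat(sprintf("%s with %d nodes and %d edges\n", class(object),
              length(networkNodes(object)), nrow(e)))
  if (nrow(e))
    cat(sprintf("  reliability: [%.3g, %.3g]\n",
                min(e$reliability), max(e$reliability)))
  invisible(NULL)
})

setMethod("show", "ConditionalNetwork", function(object) {
  e <- object@edges
  cat(sprintf("ConditionalNetwork '%s': %d nodes, %d edges\n",
              object@conditionLabel, length(networkNodes(object)), nrow(e)))
  if (nrow(e))
    cat(sprintf("  rho: [%.3f, %.3f] (%d undefined), clusterWeight max %.3f\n",
                min(e$rho), max(e$rho), sum(e$rhoUndefined),
                max(e$clusterWeight)))
  invisible(NULL)
})

setMethod("show", "ProteinComplexSet", function(object) {
  n <- length(object@members)
  cat(sprintf("ProteinComplexSet '%s': %d complexes\n",
              object@conditionLabel, n))
  if (n) {
    sz <- lengths(object@members)
    cat(sprintf("  sizes: %d-%d (mean %.2f); C: [%.3f, %.3f]\n",
                min(sz), max(sz), mean(sz),
                suppressWarnings(min(object@coexpression, na.rm = TRUE)),
                suppressWarnings(max(object@coexpression, na.rm = TRUE))))
  }
  invisible(NULL)
})

setMethod("show", "RegulationMatrix", function(object) {
  cat(sprintf("RegulationMatrix: %d matched pairs x %d TFs (%d defined deltaR)\n",
              length(object@pairIds), length(object@tfIds),
              sum(!is.na(object@deltaR))))
  invisible(NULL)
})

setMethod("show", "InfluenceResult", function(object) {
  cat(sprintf("InfluenceResult over %d matched pairs (residual %.4g)\n",
              object@nPairs, object@residual))
  tb <- object@table
  print(head(tb[order(-abs(tb$gamma)), ], 10), row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "DifferentialNetwork", function(object) {
  e <- object@edges
  cat(sprintf("DifferentialNetwork %s vs %s: %d shared edges, %d rewired\n",
              object@conditionLabels[1], object@conditionLabels[2],
              nrow(e), sum(e$rewired)))
  if (length(object@clusterLabels))
    cat("  cluster directions:",
        paste(sprintf("%s=%d", names(table(object@clusterLabels)),
                      as.integer(table(object@clusterLabels))),
              collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth (seed %d): %d planted complexes, %d TFs, sigma %.3g\n",
              object@seed, length(object@plantedComplexes),
              length(object@plantedGamma), object@noiseSigma))
  invisible(NULL)
})
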