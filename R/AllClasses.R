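#' @import methods
#' @importFrom stats cor cov sd quantile rnorm runif setNames
#' @importFrom utils read.table write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
NULL

#' ReliabilityNetwork: an undirected PPI network with per-edge reliability
#'
#' Holds an undirected protein-protein interaction graph. Edges are stored
#' in canonical form (endpoint identifiers uppercased, `from < to`
#' lexicographically), self-loops are forbidden and every edge carries a
#' reliability score in \[0, 1\].
#'
#' @slot edges data.frame with character columns `from`, `to` and numeric
#'   column `reliability`, one row per undirected edge.
#' @seealso [ReliabilityNetwork()] for the user constructor,
#'   [readPPIEdgelist()] to build one from a tab-delimited edge list.
#' @exportClass ReliabilityNetwork
setClass("ReliabilityNetwork", slots = c(edges = "data.frame"))

setValidity("ReliabilityNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("from", "to", "reliability")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be canonical (from < to)")
    if (anyDuplicated(paste(e$from, e$to)))
      msg <- c(msg, "duplicate edges are not allowed")
    r <- e$reliability
    if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
      msg <- c(msg, "reliability must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' ConditionalNetwork: a PPI network weighted by one condition's co-expression
#'
#' Extends [ReliabilityNetwork-class] with per-edge Pearson correlations
#' computed from one condition's expression data, their transformed values
#' and the nonnegative clustering weight used for complex extraction.
#' Edges whose correlation was undefined (zero variance or fewer than three
#' shared samples) carry `rho = 0` and `rhoUndefined = TRUE`.
#'
#' @slot conditionLabel single character, the condition this network
#'   describes.
#' @seealso [conditionNetwork()]
#' @exportClass ConditionalNetwork
setClass("ConditionalNetwork",
         contains = "ReliabilityNetwork",
         slots = c(conditionLabel = "character"))

setValidity("ConditionalNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("rho", "z", "clusterWeight", "rhoUndefined")
  if (!all(need %in% names(e)))
    return(paste("edges must also have columns:", paste(need, collapse = ", ")))
  if (length(object@conditionLabel) != 1L)
    msg <- c(msg, "conditionLabel must be a single string")
  if (nrow(e)) {
    if (any(abs(e$rho) > 1 + 1e-12)) msg <- c(msg, "rho must lie in [-1, 1]")
    if (any(e$clusterWeight < 0)) msg <- c(msg, "clusterWeight must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' ConditionExpression: one condition's expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] (assay `"exprs"`,
#' genes as rows, samples as columns) tagged with the condition it was
#' measured under. Gene identifiers are canonicalized to uppercase and must
#' be unique; missing measurements are kept as `NA` and later excluded
#' pairwise from correlation computations.
#'
#' @slot conditionLabel single character condition label.
#' @seealso [ConditionExpression()], [readExpression()]
#' @exportClass ConditionExpression
setClass("ConditionExpression",
         contains = "SummarizedExperiment",
         slots = c(conditionLabel = "character"))

setValidity("ConditionExpression", function(object) {
  msg <- character()
  if (length(object@conditionLabel) != 1L)
    msg <- c(msg, "conditionLabel must be a single string")
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (length(msg)) msg else TRUE
})

#' ProteinComplexSet: extracted complexes of one condition, with co-expression
#'
#' @slot members named list of character vectors; each element is the member
#'   set of one complex (>= 2 members), names are the deterministic complex
#'   ids.
#' @slot coexpression named numeric vector parallel to `members`; the
#'   per-complex co-expression score C (mean transformed pairwise
#'   correlation), `NA` when fewer than two members had expression data.
#' @slot conditionLabel single character condition label.
#' @exportClass ProteinComplexSet
setClass("ProteinComplexSet",
         slots = c(members = "list",
                   coexpression = "numeric",
                   conditionLabel = "character"))

setValidity("ProteinComplexSet", function(object) {
  msg <- character()
  m <- object@members
  if (length(m)) {
    if (is.null(names(m)) || anyDuplicated(names(m)))
      msg <- c(msg, "complexes must carry unique ids")
    if (any(vapply(m, function(s) length(unique(s)) < 2L, logical(1))))
      msg <- c(msg, "every complex needs >= 2 distinct members")
    if (length(object@coexpression) != length(m))
      msg <- c(msg, "coexpression must be parallel to members")
  }
  if (length(object@conditionLabel) != 1L)
    msg <- c(msg, "conditionLabel must be a single string")
  if (length(msg)) msg else TRUE
})

#' RegulationMatrix: TF regulation scores for matched complex pairs
#'
#' For every matched complex pair and TF, holds the regulation score of the
#' first-condition complex (`Rs`), of the second-condition complex (`Rt`),
#' their absolute difference (`deltaR`) and the number of complex members
#' the TF physically interacts with under each condition. A regulation
#' score is defined only when the TF interacts with at least one member;
#' undefined entries are `NA` and `deltaR` is defined only where both sides
#' are.
#'
#' @slot pairIds character, `"s_id|t_id"` ids of the matched pairs (rows).
#' @slot tfIds character, TF identifiers (columns).
#' @slot Rs,Rt,deltaR numeric matrices `length(pairIds) x length(tfIds)`.
#' @slot nInteractorsS,nInteractorsT integer matrices of interactor counts.
#' @exportClass RegulationMatrix
setClass("RegulationMatrix",
         slots = c(pairIds = "character", tfIds = "character",
                   Rs = "matrix", Rt = "matrix", deltaR = "matrix",
                   nInteractorsS = "matrix", nInteractorsT = "matrix"))

setValidity("RegulationMatrix", function(object) {
  dims <- c(length(object@pairIds), length(object@tfIds))
  for (s in c("Rs", "Rt", "deltaR", "nInteractorsS", "nInteractorsT"))
    if (!identical(dim(slot(object, s)), as.integer(dims)))
      return(sprintf("slot %s must be a %d x %d matrix", s, dims[1], dims[2]))
  d <- object@deltaR
  if (any(d[!is.na(d)] < 0)) return("deltaR must be >= 0 where defined")
  TRUE
})

#' InfluenceResult: per-TF influence coefficients with significance
#'
#' @slot table data.frame with one row per TF: `tf`, `gamma` (influence
#'   coefficient), `normGamma` (gamma scaled by the maximum absolute
#'   gamma), `nComplexes` (matched pairs with defined nonzero differential
#'   regulation for that TF) and `pValue` (permutation p-value, `NA` if not
#'   computed).
#' @slot residual numeric(1), Euclidean norm of the least-squares residual.
#' @slot nPairs integer(1), number of matched pairs in the solved system.
#' @exportClass InfluenceResult
setClass("InfluenceResult",
         slots = c(table = "data.frame", residual = "numeric",
                   nPairs = "integer"))

#' DifferentialNetwork: edgewise co-expression change between two conditions
#'
#' Built on the edge intersection of two conditional networks. Each edge
#' carries `delta`, the transformed-correlation difference (first condition
#' minus second); edges with `abs(delta)` at or above the rewiring cutoff
#' form the rewired view, whose Markov clusters are labelled by the
#' two-thirds direction rule.
#'
#' @slot edges data.frame: `from`, `to`, `delta`, logical `rewired`.
#' @slot clusters named list of node sets (Markov clusters of the rewired
#'   view).
#' @slot clusterLabels named character vector: `"decrease"`, `"increase"`
#'   or `"mixed"` per cluster.
#' @slot largestComponent character vector of nodes in the largest connected
#'   component of the rewired view.
#' @slot conditionLabels character(2), the two condition labels.
#' @exportClass DifferentialNetwork
setClass("DifferentialNetwork",
         slots = c(edges = "data.frame", clusters = "list",
                   clusterLabels = "character",
                   largestComponent = "character",
                   conditionLabels = "character"))

#' SyntheticTruth: planted ground truth of a generated study
#'
#' @slot plantedComplexes named list of member sets embedded as cliques.
#' @slot plantedC numeric matrix (complexes x 2 conditions) of planted
#'   co-expression scores on the transformed scale, or a 0-row matrix when
#'   not applicable.
#' @slot plantedGamma named numeric vector of planted TF influence
#'   coefficients (may be empty).
#' @slot noiseSigma numeric(1), standard deviation of the multiplicative
#'   (log-scale) noise.
#' @slot blockDirections character, planted per-complex direction
#'   (`"decrease"`/`"increase"`), possibly empty.
#' @slot seed integer(1) seed the study was generated under.
#' @slot extra list of generator-specific extras (e.g. planted deltaR).
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         slots = c(plantedComplexes = "list", plantedC = "matrix",
                   plantedGamma = "numeric", noiseSigma = "numeric",
                   blockDirections = "character", seed = "integer",
                   extra = "list"))
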