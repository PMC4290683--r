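#' Regulation of a complex by a transcription factor
#'
#' A TF is taken to regulate a complex only if it physically interacts with
#' at least one member in the PPI network. The regulation score is the
#' mean Pearson correlation (untransformed) between the TF's expression
#' profile and the profiles of the members it interacts with; the TF never
#' counts as its own interactor.
#'
#' @param members character vector of complex member identifiers.
#' @param tf TF identifier (must be a node of `net`).
#' @param net the [ReliabilityNetwork-class] defining physical interaction.
#' @param expr the condition's expression data.
#' @return numeric score with attribute `nInteractors`; `NA` (with
#'   `nInteractors = 0`) when the TF interacts with no member, which is an
#'   "absent" score rather than an error.
#' @export
regulationScore <- function(members, tf, net, expr) {
  stopifnot(is(net, "ReliabilityNetwork"))
  tf <- toupper(tf)
  e <- networkEdges(net)
  if (!(tf %in% c(e$from, e$to)))
    stop("TF ", tf, " is not a node of the PPI network")
  nbrs <- c(e$to[e$from == tf], e$from[e$to == tf])
  m <- .exprMatrix(expr)
  members <- setdiff(unique(toupper(members)), tf)
  sel <- intersect(members, nbrs)
  sel <- sel[sel %in% rownames(m)]
  if (!length(sel) || !(tf %in% rownames(m))) {
    out <- NA_real_
    attr(out, "nInteractors") <- 0L
    return(out)
  }
  rhos <- vapply(sel, function(p) .pairRho(m[p, ], m[tf, ]), numeric(1))
  rhos <- rhos[!is.na(rhos)]
  if (!length(rhos)) {
    out <- NA_real_
    attr(out, "nInteractors") <- 0L
    return(out)
  }
  out <- mean(rhos)
  attr(out, "nInteractors") <- length(rhos)
  out
}

#' Regulation scores for all matched pairs and TFs
#'
#' Evaluates [regulationScore()] for both sides of every matched complex
#' pair against every TF and records the absolute differential regulation
#' `deltaR = |R_s - R_t|`, defined only where both sides are.
#'
#' @param matched data.frame from [matchComplexes()].
#' @param S,T the matched [ProteinComplexSet-class] objects.
#' @param tfs character vector of TF identifiers (must be network nodes).
#' @param net the [ReliabilityNetwork-class] of physical interactions.
#' @param exprA,exprB expression data of the first and second condition.
#' @return A [RegulationMatrix-class].
#' @export
regulationMatrix <- function(matched, S, T, tfs, net, exprA, exprB) {
  tfs <- unique(toupper(tfs))
  npair <- nrow(matched); ntf <- length(tfs)
  pairIds <- paste(matched$s_id, matched$t_id, sep = "|")
  mk <- function() matrix(NA_real_, npair, ntf)
  Rs <- mk(); Rt <- mk()
  nS <- matrix(0L, npair, ntf); nT <- matrix(0L, npair, ntf)
  for (f in seq_len(ntf)) for (p in seq_len(npair)) {
    rs <- regulationScore(S@members[[matched$s_id[p]]], tfs[f], net, exprA)
    rt <- regulationScore(T@members[[matched$t_id[p]]], tfs[f], net, exprB)
    Rs[p, f] <- as.numeric(rs); Rt[p, f] <- as.numeric(rt)
    nS[p, f] <- attr(rs, "nInteractors")
    nT[p, f] <- attr(rt, "nInteractors")
  }
  dR <- abs(Rs - Rt)
  new("RegulationMatrix", pairIds = pairIds, tfIds = tfs,
      Rs = Rs, Rt = Rt, deltaR = dR, nInteractorsS = nS, nInteractorsT = nT)
}

#' Assemble the log-linear influence system
#'
#' Turns per-pair co-expression changes and the per-pair/per-TF
#' differential-regulation matrix into the base-10 log system
#' `log10(deltaC) = log10(deltaR) . gamma`. Pairs with zero or undefined
#' `deltaC` are always dropped. Zero or undefined `deltaR` entries are
#' handled per `zeroPolicy`: `"drop"` removes the pair from the system,
#' `"floor"` replaces the entry with `floorEps`.
#'
#' @param deltaC numeric vector of co-expression changes (optionally
#'   named), or a data.frame from [matchComplexes()] (its `delta_c` is
#'   used).
#' @param deltaR numeric matrix (pairs x TFs) of differential-regulation
#'   values, or a [RegulationMatrix-class].
#' @param zeroPolicy `"drop"` (default) or `"floor"`.
#' @param floorEps replacement value under the floor policy.
#' @return list with `logDC` (vector), `logDR` (matrix), `keptPairs`
#'   (indices into the input), `nDropped`, and `tfIds`.
#' @examples
#' # the two-complex, two-TF demonstration system
#' m <- assembleModel(c(0.50, 0.60), rbind(c(5, 10), c(6, 20)))
#' m$logDR   # 0.699 1 / 0.778 1.301
#' @export
assembleModel <- function(deltaC, deltaR, zeroPolicy = c("drop", "floor"),
                          floorEps = 1e-6) {
  zeroPolicy <- match.arg(zeroPolicy)
  if (is.data.frame(deltaC)) {
    nm <- paste(deltaC$s_id, deltaC$t_id, sep = "|")
    deltaC <- setNames(deltaC$delta_c, nm)
  }
  if (is(deltaR, "RegulationMatrix")) deltaR <- deltaRegulation(deltaR)
  deltaR <- as.matrix(deltaR)
  stopifnot(length(deltaC) == nrow(deltaR))
  tfIds <- colnames(deltaR)
  if (is.null(tfIds)) tfIds <- paste0("TF", seq_len(ncol(deltaR)))
  keep <- !is.na(deltaC) & deltaC > 0
  bad <- is.na(deltaR) | deltaR <= 0
  if (zeroPolicy == "drop") {
    keep <- keep & rowSums(bad) == 0L
  } else {
    deltaR[bad] <- floorEps
  }
  kept <- which(keep)
  nDropped <- length(deltaC) - length(kept)
  if (length(kept) < ncol(deltaR))
    stop(sprintf(paste0("underdetermined influence system: %d usable pairs",
                        " for %d TFs after filtering (%d dropped)"),
                 length(kept), ncol(deltaR), nDropped))
  logDC <- log10(unname(deltaC[kept]))
  logDR <- log10(deltaR[kept, , drop = FALSE])
  dimnames(logDR) <- list(names(deltaC)[kept], tfIds)
  list(logDC = logDC, logDR = logDR, keptPairs = kept,
       nDropped = nDropped, tfIds = tfIds)
}

#' Solve the influence system by SVD least squares
#'
#' Minimum-norm least-squares solution of `logDC ~ logDR . gamma` via
#' singular value decomposition; singular values below `tol` times the
#' largest are treated as zero. On a square full-rank system the solution
#' is exact.
#'
#' @param logDC numeric response vector (base-10 log co-expression
#'   changes), or the list returned by [assembleModel()].
#' @param logDR design matrix of base-10 log differential regulation (not
#'   needed when `logDC` is an assembled model).
#' @param tol relative singular-value cutoff.
#' @return list with `gamma` (named), `residual` (Euclidean norm), `rank`,
#'   and `fitted`.
#' @examples
#' m <- assembleModel(c(0.50, 0.60), rbind(c(5, 10), c(6, 20)))
#' solveInfluence(m)$gamma     # -1.293, 0.603
#' @export
solveInfluence <- function(logDC, logDR = NULL, tol = 1e-10) {
  if (is.list(logDC) && is.null(logDR)) {
    logDR <- logDC$logDR; logDC <- logDC$logDC
  }
  logDR <- as.matrix(logDR)
  stopifnot(length(logDC) == nrow(logDR), ncol(logDR) >= 1L)
  if (all(logDR == 0)) stop("design matrix is identically zero")
  sv <- svd(logDR)
  d <- sv$d
  pos <- d > tol * max(d)
  dinv <- ifelse(pos, 1 / d, 0)
  gamma <- as.numeric(sv$v %*% (dinv * crossprod(sv$u, logDC)))
  names(gamma) <- colnames(logDR)
  fitted <- as.numeric(logDR %*% gamma)
  list(gamma = gamma, residual = sqrt(sum((logDC - fitted)^2)),
       rank = sum(pos), fitted = fitted)
}

#' Scale influence coefficients to the maximum absolute influence
#'
#' @param gammas numeric vector of influence coefficients.
#' @return `gammas / max(abs(gammas))`, signs preserved, so the most
#'   influential TF gets +/-1. An all-zero input is returned unchanged with
#'   attribute `allZero = TRUE` and a warning.
#' @export
normalizeInfluence <- function(gammas) {
  mx <- max(abs(gammas))
  if (mx == 0) {
    warning("all influence coefficients are zero; nothing to normalize")
    attr(gammas, "allZero") <- TRUE
    return(gammas)
  }
  gammas / mx
}

#' Permutation p-values for influence coefficients
#'
#' Permutes the assignment of log co-expression changes across matched
#' pairs, re-solves the system each time, and reports per TF
#' `p = (1 + #{ |gamma_perm| >= |gamma_obs| }) / (1 + nPerm)`. The
#' permutation preserves the regulation design while breaking its relation
#' to the co-expression changes.
#'
#' @param model list from [assembleModel()] (or any list with `logDC` and
#'   `logDR`).
#' @param nPerm number of permutations (>= 1).
#' @param seed optional integer seed.
#' @return named numeric vector of p-values in (0, 1\].
#' @export
influencePValues <- function(model, nPerm = 1000L, seed = NULL) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  .checkSeed(seed)
  obs <- solveInfluence(model)$gamma
  k <- length(obs)
  count <- integer(k)
  y <- model$logDC
  X <- model$logDR
  for (b in seq_len(nPerm)) {
    gb <- solveInfluence(sample(y), X)$gamma
    count <- count + (abs(gb) >= abs(obs))
  }
  setNames((1 + count) / (1 + nPerm), names(obs))
}

#' Influence solve restricted to a TF subset
#'
#' Restricts the system to the matched pairs for which every TF in the
#' subset has a defined, nonzero differential regulation (their shared
#' complexes), then solves as usual. With the full TF set and drop policy
#' this reproduces the joint solve.
#'
#' @param deltaC,deltaR as in [assembleModel()].
#' @param tfSubset character vector of TF ids (columns of `deltaR`) or
#'   column indices.
#' @return list from [solveInfluence()] plus `nPairs`, the shared-complex
#'   count.
#' @export
subsetInfluence <- function(deltaC, deltaR, tfSubset) {
  if (is.data.frame(deltaC)) {
    nm <- paste(deltaC$s_id, deltaC$t_id, sep = "|")
    deltaC <- setNames(deltaC$delta_c, nm)
  }
  if (is(deltaR, "RegulationMatrix")) deltaR <- deltaRegulation(deltaR)
  deltaR <- as.matrix(deltaR)
  if (is.null(colnames(deltaR)))
    colnames(deltaR) <- paste0("TF", seq_len(ncol(deltaR)))
  if (is.character(tfSubset)) {
    miss <- setdiff(tfSubset, colnames(deltaR))
    if (length(miss)) stop("unknown TFs: ", paste(miss, collapse = ", "))
  }
  sub <- deltaR[, tfSubset, drop = FALSE]
  ok <- !is.na(deltaC) & deltaC > 0 &
    rowSums(is.na(sub) | sub <= 0) == 0L
  if (!any(ok)) stop("the TF subset shares no usable complexes")
  model <- assembleModel(deltaC[ok], sub[ok, , drop = FALSE],
                         zeroPolicy = "drop")
  out <- solveInfluence(model)
  out$nPairs <- sum(ok)
  out
}

#' Correlation between co-expression change and total regulation change
#'
#' For each matched pair, the total regulation change is the sum of its
#' defined differential-regulation values across TFs. Reports the Pearson
#' and Spearman correlation between the co-expression changes and these
#' sums, over the pairs with at least one defined entry.
#'
#' @param matched data.frame from [matchComplexes()] (or numeric deltaC
#'   vector).
#' @param reg a [RegulationMatrix-class] (or deltaR matrix).
#' @return list with `pearson`, `spearman`, `nPairs`; coefficients are
#'   `NA` (flagged via `undefined`) when either vector has zero variance.
#' @export
coexprRegulationCorrelation <- function(matched, reg) {
  dC <- if (is.data.frame(matched)) matched$delta_c else as.numeric(matched)
  dR <- if (is(reg, "RegulationMatrix")) deltaRegulation(reg) else
    as.matrix(reg)
  stopifnot(length(dC) == nrow(dR))
  defined <- rowSums(!is.na(dR)) > 0L
  ok <- defined & !is.na(dC)
  if (sum(ok) < 3L) stop("need at least 3 pairs with defined regulation sums")
  sdr <- rowSums(dR[ok, , drop = FALSE], na.rm = TRUE)
  dc <- dC[ok]
  if (sd(dc) == 0 || sd(sdr) == 0) {
    return(list(pearson = NA_real_, spearman = NA_real_, nPairs = sum(ok),
                undefined = TRUE))
  }
  list(pearson = cor(dc, sdr),
       spearman = cor(dc, sdr, method = "spearman"),
       nPairs = sum(ok))
}

#' Full TF-influence analysis of a matched study
#'
#' Wrapper running [regulationMatrix()], [assembleModel()],
#' [solveInfluence()], [normalizeInfluence()] and (optionally)
#' [influencePValues()] and returning a Table-style summary.
#'
#' @inheritParams regulationMatrix
#' @inheritParams assembleModel
#' @param nPerm permutations for p-values; 0 skips them.
#' @param seed optional integer seed for the permutations.
#' @return An [InfluenceResult-class]. Per TF, `nComplexes` counts the
#'   matched pairs with defined nonzero differential regulation for that
#'   TF.
#' @export
tfInfluence <- function(matched, S, T, tfs, net, exprA, exprB,
                        zeroPolicy = c("drop", "floor"), floorEps = 1e-6,
                        nPerm = 1000L, seed = NULL) {
  zeroPolicy <- match.arg(zeroPolicy)
  reg <- regulationMatrix(matched, S, T, tfs, net, exprA, exprB)
  dR <- deltaRegulation(reg)
  model <- assembleModel(matched, reg, zeroPolicy = zeroPolicy,
                         floorEps = floorEps)
  fit <- solveInfluence(model)
  pv <- if (nPerm > 0) influencePValues(model, nPerm = nPerm, seed = seed)
        else setNames(rep(NA_real_, length(fit$gamma)), names(fit$gamma))
  tb <- data.frame(tf = names(fit$gamma),
                   gamma = unname(fit$gamma),
                   normGamma = unname(normalizeInfluence(fit$gamma)),
                   nComplexes = colSums(!is.na(dR) & dR > 0),
                   pValue = unname(pv),
                   stringsAsFactors = FALSE, row.names = NULL)
  new("InfluenceResult", table = tb, residual = fit$residual,
      nPairs = length(model$logDC))
}
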