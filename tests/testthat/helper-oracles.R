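# Independent oracles, deliberately written with plain loops so they share
# no code path with the package implementations they check.

# iterated adjusted Czekanowski-Dice score, closed neighbourhoods,
# re-weighted by the previous round; returns the full weight matrix
refAdjustCD <- function(edges, iterations) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  nb <- lapply(nodes, function(u)
    sort(unique(c(u, edges$to[edges$from == u], edges$from[edges$to == u]))))
  names(nb) <- nodes
  w <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (u in nodes) for (v in nb[[u]]) w[u, v] <- 1
  for (k in seq_len(iterations)) {
    S <- vapply(nodes, function(u) sum(w[u, nb[[u]]]), numeric(1))
    lam <- setNames(pmax(0, mean(S) - S), nodes)
    w2 <- matrix(0, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
    for (u in nodes) for (v in nb[[u]]) {
      common <- intersect(nb[[u]], nb[[v]])
      num <- sum(w[u, common]) + sum(w[v, common])
      w2[u, v] <- num / (lam[u] + S[u] + lam[v] + S[v])
    }
    w <- w2
  }
  w
}

# textbook Pearson correlation: covariance over the product of standard
# deviations, written out longhand
refPearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force one-to-one matching: enumerate every candidate pair, then
# repeatedly pick the best remaining by (jaccard desc, deltaC desc, ids)
refMatch <- function(membersS, Cs, membersT, Ct, tJ, delta) {
  cand <- NULL
  for (s in names(membersS)) for (t in names(membersT)) {
    j <- length(intersect(membersS[[s]], membersT[[t]])) /
      length(union(membersS[[s]], membersT[[t]]))
    dc <- abs(Cs[[s]] - Ct[[t]])
    if (j >= tJ && dc >= delta)
      cand <- rbind(cand, data.frame(s = s, t = t, j = j, dc = dc,
                                     stringsAsFactors = FALSE))
  }
  out <- NULL
  while (!is.null(cand) && nrow(cand)) {
    best <- cand[order(-cand$j, -cand$dc, cand$s, cand$t), ][1, ]
    out <- rbind(out, best)
    cand <- cand[cand$s != best$s & cand$t != best$t, , drop = FALSE]
  }
  out
}

# least squares through the normal equations (full-column-rank designs)
refNormalEquations <- function(X, y) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# expression fixture whose sample correlations are exact by construction:
# mean-zero mutually orthogonal contrast vectors combined with unit-norm
# loadings
orthoBasis4 <- function() {
  rbind(u = c(1, -1, 1, -1), v = c(1, 1, -1, -1), w = c(1, -1, -1, 1))
}
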