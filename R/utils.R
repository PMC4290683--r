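# internal helpers

# Pearson correlation of two vectors over pairwise-complete samples.
# Returns NA when fewer than 3 complete pairs remain or either side has
# zero variance.
.pairRho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# expression matrix (genes x samples) out of the supported containers
.exprMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(expr, 1L))
  if (is.matrix(expr)) {
    if (is.null(rownames(expr)))
      stop("expression matrix needs gene identifiers as rownames")
    return(expr)
  }
  stop("expression must be a ConditionExpression or a matrix with rownames")
}

# deterministic 32-bit string hash (polynomial, FNV-ish), for complex ids
.stableHash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# upper-triangle values of a square matrix (excluding the diagonal)
.upperTri <- function(m) m[upper.tri(m)]

# check a seed is usable with set.seed
.checkSeed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  invisible(NULL)
}
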