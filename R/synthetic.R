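#' Generate a two-condition expression study with planted co-expressed modules
#'
#' Samples two genes-x-samples matrices in which each planted module is
#' drawn from a multivariate normal with exchangeable (compound-symmetry)
#' within-module correlation -- one correlation per module per condition --
#' while background genes are independent standard normals. This emulates
#' the statistical structure of a two-cohort tumour study: two conditions
#' of a few dozen arrays whose module-level co-expression differs by known
#' amounts.
#'
#' `method = "exact"` additionally recolours the draws so the *sample*
#' correlation matrix equals the target exactly (requires
#' `nSamples > nGenes + 1` and `sigma = 0`); useful when downstream tests
#' must see planted effects unobscured by sampling noise.
#'
#' @param nGenes total number of genes.
#' @param nSamples integer vector of length 2: samples per condition
#'   (default 39 and 39, matched-cohort sized).
#' @param modules list; each element a list with `members` (gene indices
#'   or ids), `rhoA` and `rhoB` (within-module correlation per condition,
#'   each in (-1/(m-1), 1) for module size m). Modules may not overlap.
#' @param sigma standard deviation of additive measurement noise (>= 0).
#' @param seed optional integer seed; same seed, same matrices.
#' @param method `"population"` (default) or `"exact"`.
#' @param conditionLabels labels of the two conditions.
#' @return list with `exprA`, `exprB` ([ConditionExpression-class]) and
#'   `truth` ([SyntheticTruth-class]) whose `plantedC` holds the
#'   transformed within-module correlations per condition.
#' @export
generateExpressionPair <- function(nGenes, nSamples = c(39L, 39L), modules,
                                   sigma = 0, seed = NULL,
                                   method = c("population", "exact"),
                                   conditionLabels = c("A", "B")) {
  method <- match.arg(method)
  if (sigma < 0) stop("sigma must be >= 0")
  if (method == "exact" && sigma > 0)
    stop("exact method requires sigma = 0")
  .checkSeed(seed)
  genes <- sprintf("G%04d", seq_len(nGenes))
  memb <- lapply(modules, function(mod) {
    m <- mod$members
    if (is.numeric(m)) genes[m] else toupper(as.character(m))
  })
  if (length(memb)) {
    all <- unlist(memb)
    if (anyDuplicated(all)) stop("modules may not overlap")
    if (!all(all %in% genes)) stop("module members outside the gene set")
  }
  for (i in seq_along(modules)) {
    m <- length(memb[[i]])
    for (rho in c(modules[[i]]$rhoA, modules[[i]]$rhoB)) {
      if (abs(rho) >= 1) stop("module correlations must satisfy |rho| < 1")
      if (rho <= -1 / (m - 1))
        stop(sprintf("rho = %.3f is not positive definite for module size %d",
                     rho, m))
    }
  }
  draw <- function(n, which) {
    sigmaMat <- diag(nGenes)
    dimnames(sigmaMat) <- list(genes, genes)
    for (i in seq_along(modules)) {
      rho <- if (which == 1L) modules[[i]]$rhoA else modules[[i]]$rhoB
      idx <- match(memb[[i]], genes)
      sigmaMat[idx, idx] <- rho
      diag(sigmaMat)[idx] <- 1
    }
    Z <- matrix(rnorm(n * nGenes), n, nGenes)
    if (method == "exact") {
      if (n < nGenes + 2L)
        stop("exact method needs nSamples > nGenes + 1")
      Z <- scale(Z, center = TRUE, scale = FALSE)
      Z <- Z %*% solve(chol(stats::cov(Z)))
    }
    X <- Z %*% chol(sigmaMat)
    if (sigma > 0) X <- X + matrix(rnorm(length(X), sd = sigma), nrow(X))
    t(X)                              # genes x samples
  }
  A <- draw(nSamples[1L], 1L)
  B <- draw(nSamples[2L], 2L)
  rownames(A) <- rownames(B) <- genes
  colnames(A) <- sprintf("%s_s%02d", conditionLabels[1L], seq_len(nSamples[1L]))
  colnames(B) <- sprintf("%s_s%02d", conditionLabels[2L], seq_len(nSamples[2L]))
  zA <- vapply(modules, function(m) fisherTransform(m$rhoA), numeric(1))
  zB <- vapply(modules, function(m) fisherTransform(m$rhoB), numeric(1))
  plantedC <- cbind(A = zA, B = zB)
  names(memb) <- sprintf("planted%02d", seq_along(memb))
  if (length(memb)) rownames(plantedC) <- names(memb)
  truth <- new("SyntheticTruth", plantedComplexes = memb,
               plantedC = plantedC, plantedGamma = numeric(0),
               noiseSigma = sigma,
               blockDirections = ifelse(zA > zB, "decrease", "increase"),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
               extra = list())
  list(exprA = ConditionExpression(A, conditionLabels[1L]),
       exprB = ConditionExpression(B, conditionLabels[2L]),
       truth = truth)
}

#' Generate a PPI network embedding planted complexes
#'
#' Planted complexes become cliques with a fixed high reliability;
#' background edges are random pairs (uniform reliability in
#' `backgroundReliability`) that avoid within-complex pairs; optional TF
#' attachment edges link TF nodes to chosen complex members.
#'
#' @param truth a [SyntheticTruth-class] (its planted complexes are used),
#'   or a plain list of member vectors.
#' @param backgroundEdges number of random background edges.
#' @param seed optional integer seed.
#' @param extraNodes additional nodes available for background edges.
#' @param tfEdges optional data.frame with columns `tf`, `protein` giving
#'   TF attachment edges.
#' @param cliqueReliability reliability of within-complex edges.
#' @param backgroundReliability range of background reliabilities.
#' @param tfReliability reliability of TF attachment edges.
#' @return A [ReliabilityNetwork-class].
#' @export
generatePPIWithComplexes <- function(truth, backgroundEdges = 0L, seed = NULL,
                                     extraNodes = character(),
                                     tfEdges = NULL,
                                     cliqueReliability = 0.9,
                                     backgroundReliability = c(0.2, 0.6),
                                     tfReliability = 0.3) {
  .checkSeed(seed)
  complexes <- if (is(truth, "SyntheticTruth")) truth@plantedComplexes
               else truth
  from <- character(); to <- character(); rel <- numeric()
  for (s in complexes) {
    s <- sort(unique(toupper(s)))
    if (length(s) < 2L) next
    pr <- utils::combn(s, 2L)
    from <- c(from, pr[1L, ]); to <- c(to, pr[2L, ])
    rel <- c(rel, rep(cliqueReliability, ncol(pr)))
  }
  if (!is.null(tfEdges)) {
    from <- c(from, toupper(tfEdges$tf))
    to <- c(to, toupper(tfEdges$protein))
    rel <- c(rel, rep(tfReliability, nrow(tfEdges)))
  }
  if (backgroundEdges > 0L) {
    nodes <- sort(unique(c(unlist(complexes), toupper(extraNodes),
                           if (!is.null(tfEdges)) toupper(tfEdges$tf))))
    pairs <- utils::combn(nodes, 2L)
    cx <- rep(NA_integer_, length(nodes))
    names(cx) <- nodes
    for (i in seq_along(complexes)) cx[toupper(complexes[[i]])] <- i
    cx1 <- cx[pairs[1L, ]]; cx2 <- cx[pairs[2L, ]]
    sameComplex <- !is.na(cx1) & !is.na(cx2) & cx1 == cx2
    existing <- paste(pmin(from, to), pmax(from, to))
    isExisting <- paste(pairs[1L, ], pairs[2L, ]) %in% existing
    avail <- which(!sameComplex & !isExisting)
    if (backgroundEdges > length(avail))
      stop(sprintf("requested %d background edges but only %d pairs available",
                   backgroundEdges, length(avail)))
    pick <- sample(avail, backgroundEdges)
    from <- c(from, pairs[1L, pick]); to <- c(to, pairs[2L, pick])
    rel <- c(rel, runif(backgroundEdges, backgroundReliability[1L],
                        backgroundReliability[2L]))
  }
  if (!length(from)) stop("nothing to embed: no complexes, TF edges or background")
  ReliabilityNetwork(from, to, rel)
}

#' Simulate the log-linear influence system directly
#'
#' Forward simulation of the influence model: differential-regulation
#' values are drawn log-uniformly in `dRRange` (or supplied), and each
#' pair's co-expression change is the product of its regulation values
#' raised to the planted influence coefficients, times multiplicative
#' lognormal noise `10^eps`, `eps ~ N(0, sigma)`.
#'
#' @param nPairs number of matched complex pairs (rows); must exceed the
#'   TF count when `deltaR` is sampled.
#' @param gammas numeric vector of planted influence coefficients.
#' @param dRRange positive range for the log-uniform deltaR draw.
#' @param sigma log10-scale noise standard deviation (>= 0).
#' @param seed optional integer seed.
#' @param deltaR optional explicit matrix (`nPairs` x `length(gammas)`),
#'   bypassing the draw -- handy for pinning a known system.
#' @return list with `deltaC`, `deltaR` and `truth`
#'   ([SyntheticTruth-class] with `plantedGamma`).
#' @examples
#' sys <- generateInfluenceSystem(2, c(-1.293, 0.603), sigma = 0,
#'                                deltaR = rbind(c(5, 10), c(6, 20)))
#' round(sys$deltaC, 2)   # 0.50 0.60
#' @export
generateInfluenceSystem <- function(nPairs, gammas, dRRange = c(0.1, 10),
                                    sigma = 0, seed = NULL, deltaR = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  .checkSeed(seed)
  k <- length(gammas)
  if (is.null(deltaR)) {
    if (nPairs <= k)
      stop("nPairs must exceed the number of TFs when deltaR is sampled")
    if (any(dRRange <= 0)) stop("dRRange must be positive")
    deltaR <- matrix(10^runif(nPairs * k, log10(dRRange[1L]),
                              log10(dRRange[2L])), nPairs, k)
  } else {
    deltaR <- as.matrix(deltaR)
    stopifnot(nrow(deltaR) == nPairs, ncol(deltaR) == k)
  }
  colnames(deltaR) <- if (!is.null(names(gammas))) names(gammas)
                      else paste0("TF", seq_len(k))
  eps <- if (sigma > 0) rnorm(nPairs, 0, sigma) else numeric(nPairs)
  deltaC <- as.numeric(10^(log10(deltaR) %*% gammas + eps))
  truth <- new("SyntheticTruth", plantedComplexes = list(),
               plantedC = matrix(numeric(0), 0, 2),
               plantedGamma = setNames(as.numeric(gammas),
                                       colnames(deltaR)),
               noiseSigma = sigma, blockDirections = character(0),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
               extra = list(deltaR = deltaR, deltaC = deltaC))
  list(deltaC = deltaC, deltaR = deltaR, truth = truth)
}

#' Generate a complete recovery study with planted TF influence
#'
#' Builds a two-condition study in which every pipeline stage has known
#' ground truth: complexes are embedded as cliques, their co-expression
#' shift between conditions follows the log-linear influence model with
#' the planted coefficients, and TF nodes attain the planted
#' member-correlations by construction. Expression is generated with the
#' exact-correlation colouring (sample correlations equal their targets),
#' so the realized co-expression changes and regulation changes match the
#' planted model up to the multiplicative noise `sigma`; the study thereby
#' isolates the pipeline's algebra (clustering, matching, model assembly,
#' solving) from correlation-estimation noise, which
#' [generateExpressionPair()]'s cohort-sized default exercises separately.
#'
#' Half the complexes are planted with decreasing, half with increasing
#' co-expression (first relative to second condition). Per-pair
#' differential-regulation values are drawn log-uniformly in
#' \[0.08, 0.28\] with rejection so the implied co-expression change stays
#' within what correlations can realize (about 0.125 to 0.38 on the
#' transformed scale above a floor of 0.20).
#'
#' @param seed integer seed (required; the study is fully reproducible).
#' @param nComplexes number of planted complexes (even).
#' @param complexSize members per complex.
#' @param gammas named or unnamed planted influence coefficients (one per
#'   TF; not all zero).
#' @param sigma log10-scale noise on the planted co-expression changes.
#' @param nSamples samples per condition; must exceed the total gene count
#'   plus one (exact colouring).
#' @param nBackgroundGenes independent background genes.
#' @param backgroundEdges random PPI edges touching the background genes.
#' @param tfDegPerComplex complex members each TF attaches to.
#' @param tfReliability,cliqueReliability PPI edge reliabilities.
#' @return list with `exprA`, `exprB`, `net`, `tfs` (TF ids) and `truth`;
#'   `truth@extra` holds the planted `deltaR` matrix and `deltaC` vector.
#' @export
generateRecoveryStudy <- function(seed, nComplexes = 8L, complexSize = 8L,
                                  gammas = c(2, -1, 0), sigma = 0.02,
                                  nSamples = 120L, nBackgroundGenes = 12L,
                                  backgroundEdges = 30L,
                                  tfDegPerComplex = 4L,
                                  tfReliability = 0.15,
                                  cliqueReliability = 0.9) {
  stopifnot(nComplexes %% 2L == 0L, complexSize >= 3L,
            tfDegPerComplex <= complexSize)
  if (all(gammas == 0)) stop("at least one planted gamma must be nonzero")
  .checkSeed(seed)
  k <- length(gammas)
  tfs <- if (!is.null(names(gammas))) toupper(names(gammas))
         else sprintf("TF%d", seq_len(k))
  names(gammas) <- tfs
  # planted differential regulation, rejected into the feasible dC band
  dRlog <- matrix(NA_real_, nComplexes, k)
  tTarget <- numeric(nComplexes)
  band <- log10(c(0.125, 0.38))
  for (i in seq_len(nComplexes)) {
    for (try in seq_len(5000L)) {
      l <- runif(k, log10(0.08), log10(0.24))
      tt <- sum(gammas * l)
      if (tt >= band[1L] && tt <= band[2L]) break
      if (try == 5000L) stop("could not sample a feasible regulation profile")
    }
    dRlog[i, ] <- l
    tTarget[i] <- tt
  }
  deltaR <- 10^dRlog
  colnames(deltaR) <- tfs
  eps <- rnorm(nComplexes, 0, sigma)
  deltaC <- 10^(tTarget + eps)
  deltaC <- pmin(deltaC, 0.45)           # stay inside the realizable range
  # planted module correlations realizing deltaC
  zLo <- 0.25
  directions <- rep(c("decrease", "increase"), each = nComplexes / 2L)
  zA <- ifelse(directions == "decrease", zLo + deltaC, zLo)
  zB <- ifelse(directions == "decrease", zLo, zLo + deltaC)
  rhoA <- inverseFisherTransform(zA)
  rhoB <- inverseFisherTransform(zB)
  # TF-member target correlations: |rA - rB| = deltaR. The high side is
  # balanced across conditions and across the decrease/increase halves so
  # no single condition concentrates the TF's correlation budget.
  rLow <- 0.04
  dec <- which(directions == "decrease"); inc <- which(directions == "increase")
  rA <- rB <- matrix(rLow, nComplexes, k)
  for (f in seq_len(k)) {
    highA <- c(sample(dec, length(dec) %/% 2L),
               sample(inc, length(inc) %/% 2L))
    rA[highA, f] <- rLow + deltaR[highA, f]
    rB[-highA, f] <- rLow + deltaR[-highA, f]
  }
  # gene inventory: planted complex members, TFs with three dedicated
  # anchor partners each (the anchor module keeps the TF hub from being
  # pulled into a planted clique during clustering), background genes
  members <- lapply(seq_len(nComplexes), function(i)
    sprintf("C%02dP%02d", i, seq_len(complexSize)))
  names(members) <- sprintf("planted%02d", seq_len(nComplexes))
  partners <- lapply(seq_len(k), function(f) sprintf("%sAP%d", tfs[f], 1:3))
  bg <- sprintf("BG%02d", seq_len(nBackgroundGenes))
  genes <- c(unlist(members), tfs, unlist(partners), bg)
  nGenes <- length(genes)
  rhoAnchor <- 0.45
  if (nSamples < nGenes + 2L)
    stop("nSamples must exceed the gene count + 1 for exact colouring")
  latentDim <- nComplexes + nComplexes * complexSize +
    k +                       # anchor factors
    k + 3L * k +              # TF and partner private dimensions
    nBackgroundGenes
  buildLoadings <- function(rho, r) {
    L <- matrix(0, nGenes, latentDim, dimnames = list(genes, NULL))
    anchorDim <- nComplexes + nComplexes * complexSize + seq_len(k)
    own <- nComplexes                       # next free latent dimension
    for (i in seq_len(nComplexes)) for (p in members[[i]]) {
      own <- own + 1L
      L[p, i] <- sqrt(rho[i])
      L[p, own] <- sqrt(1 - rho[i])
    }
    own <- max(anchorDim)
    for (f in seq_len(k)) {
      alpha <- r[, f] / sqrt(rho)
      s2 <- sum(alpha^2) + rhoAnchor
      if (s2 >= 0.98)
        stop("planted TF correlations too strong to be jointly realizable")
      L[tfs[f], seq_len(nComplexes)] <- alpha
      L[tfs[f], anchorDim[f]] <- sqrt(rhoAnchor)
      own <- own + 1L
      L[tfs[f], own] <- sqrt(1 - s2)
      for (p in partners[[f]]) {
        own <- own + 1L
        L[p, anchorDim[f]] <- sqrt(rhoAnchor)
        L[p, own] <- sqrt(1 - rhoAnchor)
      }
    }
    for (b in bg) {
      own <- own + 1L
      L[b, own] <- 1
    }
    L
  }
  drawExact <- function(L, label) {
    Z <- matrix(rnorm(nSamples * latentDim), nSamples, latentDim)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    Z <- Z %*% solve(chol(stats::cov(Z)))
    X <- t(Z %*% t(L))
    colnames(X) <- sprintf("%s_s%03d", label, seq_len(nSamples))
    ConditionExpression(X, label)
  }
  exprA <- drawExact(buildLoadings(rhoA, rA), "A")
  exprB <- drawExact(buildLoadings(rhoB, rB), "B")
  # PPI: cliques + TF attachments + TF anchor cliques + background
  tfEdges <- do.call(rbind, lapply(seq_len(k), function(f)
    do.call(rbind, lapply(seq_len(nComplexes), function(i)
      data.frame(tf = tfs[f],
                 protein = members[[i]][seq_len(tfDegPerComplex)],
                 stringsAsFactors = FALSE)))))
  anchors <- lapply(seq_len(k), function(f) c(tfs[f], partners[[f]]))
  net <- generatePPIWithComplexes(c(members, anchors),
                                  backgroundEdges = backgroundEdges,
                                  extraNodes = bg, tfEdges = tfEdges,
                                  cliqueReliability = cliqueReliability,
                                  tfReliability = tfReliability)
  plantedC <- cbind(A = zA, B = zB)
  rownames(plantedC) <- names(members)
  truth <- new("SyntheticTruth", plantedComplexes = members,
               plantedC = plantedC, plantedGamma = gammas,
               noiseSigma = sigma, blockDirections = directions,
               seed = as.integer(seed),
               extra = list(deltaR = deltaR, deltaC = deltaC,
                            rA = rA, rB = rB, tfs = tfs))
  list(exprA = exprA, exprB = exprB, net = net, tfs = tfs, truth = truth)
}
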