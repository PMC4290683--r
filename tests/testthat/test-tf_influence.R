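test_that("regulation is the mean TF correlation over interacting members", {
  # exact-by-construction correlations: tf~m1 = 0.8, tf~m2 = 0.4
  B <- orthoBasis4()
  m <- rbind(TF = B["u", ],
             M1 = 0.8 * B["u", ] + 0.6 * B["v", ],
             M2 = 0.4 * B["u", ] + sqrt(0.84) * B["w", ],
             M3 = B["v", ], M4 = B["w", ])
  net <- ReliabilityNetwork(c("TF", "TF", "M3"), c("M1", "M2", "M4"), 0.9)
  r <- regulationScore(c("M1", "M2", "M3", "M4"), "TF", net, m)
  expect_equal(as.numeric(r), 0.6, tolerance = 1e-12)
  expect_equal(attr(r, "nInteractors"), 2L)
  # adjacent to no member: absent score, not an error
  r0 <- regulationScore(c("M3", "M4"), "TF", net, m)
  expect_true(is.na(r0))
  expect_equal(attr(r0, "nInteractors"), 0L)
  # unknown TF: a real error, distinct from absence
  expect_error(regulationScore(c("M1"), "NOPE", net, m), "not a node")
  # the TF never counts as its own interactor
  rSelf <- regulationScore(c("TF", "M1"), "TF", net, m)
  expect_equal(as.numeric(rSelf), 0.8, tolerance = 1e-12)
})

test_that("regulation matches a brute-force loop on a random fixture", {
  set.seed(61)
  genes <- c("TF", paste0("P", 1:6))
  m <- matrix(rnorm(7 * 20), 7, 20, dimnames = list(genes, NULL))
  adj <- c("P1", "P3", "P4")
  net <- ReliabilityNetwork(rep("TF", 3), adj, 1)
  got <- regulationScore(paste0("P", 1:6), "TF", net, m)
  ref <- mean(vapply(adj, function(p) refPearson(m[p, ], m["TF", ]),
                     numeric(1)))
  expect_equal(as.numeric(got), ref, tolerance = 1e-12)
})

test_that("model assembly reproduces the demonstration system's logs", {
  m <- assembleModel(c(0.50, 0.60), rbind(c(5, 10), c(6, 20)))
  expect_lte(max(abs(as.numeric(m$logDR) - c(0.699, 0.778, 1, 1.301))),
             1e-3)
  expect_lte(max(abs(m$logDC - c(-0.301, -0.221))), 1e-3)
  # a deltaR of exactly 1 contributes log 0
  m1 <- assembleModel(c(0.5, 0.5, 0.5), cbind(c(1, 2, 4)))
  expect_equal(unname(m1$logDR[1, 1]), 0)
})

test_that("zero policies drop or floor undefined regulation entries", {
  dC <- c(0.5, 0.6, 0.7, 0.8)
  dR <- rbind(c(5, 10), c(0, 20), c(6, NA), c(7, 8))
  m <- assembleModel(dC, dR, zeroPolicy = "drop")
  expect_equal(m$keptPairs, c(1L, 4L))
  expect_equal(m$nDropped, 2L)
  m <- assembleModel(dC, dR, zeroPolicy = "floor", floorEps = 1e-6)
  expect_equal(length(m$logDC), 4L)
  expect_equal(unname(m$logDR[2, 1]), -6)
  expect_equal(unname(m$logDR[3, 2]), -6)
  # zero deltaC rows always go; underdetermined systems are refused
  m <- assembleModel(c(0, 0.6, 0.7), rbind(c(5, 10), c(6, 20), c(7, 8)),
                     zeroPolicy = "floor")
  expect_equal(length(m$logDC), 2L)
  expect_error(assembleModel(c(0.5, 0), rbind(c(5, 10), c(6, 20))),
               "underdetermined")
})

test_that("SVD least squares solves the demonstration system", {
  fit <- solveInfluence(assembleModel(c(0.50, 0.60),
                                      rbind(c(5, 10), c(6, 20))))
  expect_equal(unname(fit$gamma), c(-1.293, 0.603), tolerance = 1e-3)
  expect_lt(fit$residual, 1e-12)
  # opposite signs: the two TFs act counteractively
  expect_equal(sign(fit$gamma[1]) * sign(fit$gamma[2]), -1, ignore_attr = TRUE)
  # consistent single-TF system: deltaC = deltaR^2 gives gamma = 2 exactly
  fit <- solveInfluence(assembleModel(c(4, 9, 16), cbind(c(2, 3, 4))))
  expect_equal(unname(fit$gamma), 2, tolerance = 1e-12)
  expect_error(solveInfluence(c(1, 2), matrix(0, 2, 1)), "zero")
})

test_that("SVD least squares equals the normal equations on full-rank systems", {
  set.seed(62)
  for (i in 1:100) {
    n <- sample(6:20, 1); k <- sample(1:5, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n)
    expect_equal(unname(solveInfluence(y, X)$gamma),
                 refNormalEquations(X, y), tolerance = 1e-8)
  }
  # noiseless planted system: recovery to numerical precision
  set.seed(63)
  X <- matrix(rnorm(20 * 5), 20, 5)
  gamma <- c(2, -1, 0.5, 0, 1.5)
  y <- as.numeric(X %*% gamma)
  expect_equal(unname(solveInfluence(y, X)$gamma), gamma, tolerance = 1e-8)
  # rank-deficient design: minimum-norm solution, not an error
  Xd <- cbind(X[, 1], X[, 1])
  fit <- solveInfluence(as.numeric(X[, 1] * 2), Xd)
  expect_equal(fit$rank, 1L)
  expect_equal(unname(fit$gamma), c(1, 1), tolerance = 1e-8)
})

test_that("influence normalization scales by the largest magnitude", {
  pancreatic <- c(STAT5B = 2.911, RREB1 = -2.606, BACH1 = -1.592,
                  SRF = 1.522, TBP = -0.944, JUNB = 0.219)
  norm <- normalizeInfluence(pancreatic)
  expect_equal(unname(norm["STAT5B"]), 1)
  expect_equal(unname(norm["RREB1"]), -0.895, tolerance = 1e-3)
  expect_equal(unname(norm["TBP"]), -0.324, tolerance = 1e-3)
  expect_equal(normalizeInfluence(-0.4), -1)
  expect_equal(normalizeInfluence(pancreatic * 10), norm)
  expect_warning(z <- normalizeInfluence(c(0, 0)), "zero")
  expect_true(attr(z, "allZero"))
})

test_that("permutation p-values flag planted TFs and spare null ones", {
  # a TF with zero coefficient ties every permutation: p = 1
  model <- list(logDC = c(1, 2, 3, 1.5),
                logDR = cbind(c(1, 2, 3, 1.5), c(0, 0, 0, 0)))
  p <- influencePValues(model, nPerm = 50, seed = 1)
  expect_equal(unname(p[2]), 1)
  # strongly planted TF at 200 permutations: p at the resolution floor
  set.seed(64)
  sys <- generateInfluenceSystem(40, c(2, -2), sigma = 0.01, seed = 65)
  model <- assembleModel(sys$deltaC, sys$deltaR)
  p <- influencePValues(model, nPerm = 200, seed = 66)
  expect_lte(p[[1]], 0.01)
  expect_lte(p[[2]], 0.01)
  expect_error(influencePValues(model, nPerm = 0), "nPerm")
  # reproducible under seed
  expect_identical(influencePValues(model, nPerm = 50, seed = 9),
                   influencePValues(model, nPerm = 50, seed = 9))
})

test_that("subset solves restrict to shared complexes and match full solves", {
  sys <- generateInfluenceSystem(15, c(1.2, -0.8, 0.4), sigma = 0, seed = 67)
  full <- solveInfluence(assembleModel(sys$deltaC, sys$deltaR))
  sub <- subsetInfluence(sys$deltaC, sys$deltaR, c("TF1", "TF2", "TF3"))
  expect_equal(sub$gamma, full$gamma, tolerance = 1e-10)
  expect_equal(sub$nPairs, 15L)
  # the demonstration pair as a two-TF shared system
  sub <- subsetInfluence(c(0.50, 0.60), rbind(c(5, 10), c(6, 20)),
                         c("TF1", "TF2"))
  expect_equal(unname(sub$gamma), c(-1.293, 0.603), tolerance = 1e-3)
  # counteractive plant: opposite signs recovered
  sys <- generateInfluenceSystem(20, c(1.5, -1.5), sigma = 0, seed = 68)
  sub <- subsetInfluence(sys$deltaC, sys$deltaR, c("TF1", "TF2"))
  expect_lt(sub$gamma[["TF1"]] * sub$gamma[["TF2"]], 0)
  expect_error(subsetInfluence(c(0.5), cbind(TF1 = 0), "TF1"), "no usable")
})

test_that("co-expression change correlates with summed regulation change", {
  dR <- matrix(runif(60, 0.1, 2), 20, 3)
  sdr <- rowSums(dR)
  r <- coexprRegulationCorrelation(0.3 * sdr, dR)
  expect_equal(r$pearson, 1, tolerance = 1e-12)
  expect_equal(r$spearman, 1, tolerance = 1e-12)
  expect_equal(r$nPairs, 20L)
  # independence: both coefficients near zero at n = 200
  set.seed(69)
  dR <- matrix(runif(600, 0.1, 2), 200, 3)
  r <- coexprRegulationCorrelation(sample(rowSums(dR)), dR)
  expect_lt(abs(r$pearson), 0.2)
  expect_lt(abs(r$spearman), 0.2)
  # monotone nonlinear relation: rank correlation outruns linear
  dR <- matrix(runif(60, 0.1, 2), 20, 3)
  r <- coexprRegulationCorrelation(rowSums(dR)^3, dR)
  expect_equal(r$spearman, 1, tolerance = 1e-12)
  expect_lt(r$pearson, r$spearman)
  expect_error(coexprRegulationCorrelation(c(1, 2), matrix(1, 2, 1)),
               "at least 3")
})

test_that("rescaling one TF's regulation shifts predictions by the power law", {
  sys <- generateInfluenceSystem(12, c(1.5, -0.5), sigma = 0, seed = 70)
  cc <- 3.7
  dR2 <- sys$deltaR
  dR2[, 1] <- dR2[, 1] * cc
  dC2 <- sys$deltaC * cc^1.5
  fit2 <- solveInfluence(assembleModel(dC2, dR2))
  expect_equal(unname(fit2$gamma), c(1.5, -0.5), tolerance = 1e-8)
  expect_lt(fit2$residual, 1e-10)
})

test_that("the full influence wrapper reports a Table-style summary", {
  study <- generateRecoveryStudy(3, nComplexes = 6, complexSize = 6,
                                 nSamples = 100)
  cnA <- suppressMessages(conditionNetwork(study$net, study$exprA))
  cnB <- suppressMessages(conditionNetwork(study$net, study$exprB))
  SA <- suppressMessages(extractComplexes(cnA, study$exprA))
  SB <- suppressMessages(extractComplexes(cnB, study$exprB))
  matched <- matchComplexes(SA, SB)
  res <- suppressWarnings(suppressMessages(
    tfInfluence(matched, SA, SB, study$tfs, study$net,
                study$exprA, study$exprB, nPerm = 50, seed = 4)))
  tb <- influenceTable(res)
  expect_named(tb, c("tf", "gamma", "normGamma", "nComplexes", "pValue"))
  expect_equal(nrow(tb), 3L)
  expect_equal(max(abs(tb$normGamma)), 1)
  expect_true(all(tb$pValue > 0 & tb$pValue <= 1))
  expect_true(all(tb$nComplexes <= nrow(matched)))
})
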