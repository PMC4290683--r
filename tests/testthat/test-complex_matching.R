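mkSet <- function(members, C, label = "X") {
  new("ProteinComplexSet", members = members,
      coexpression = setNames(C, names(members)), conditionLabel = label)
}

test_that("jaccard similarity follows its set-theoretic definition", {
  expect_equal(jaccardIndex(c("A", "B"), c("B", "A")), 1)
  expect_equal(jaccardIndex(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccardIndex(c("A", "B", "C", "D"), c("A", "B", "C", "E")), 0.6)
  expect_error(jaccardIndex(character(), character()), "empty")
  # symmetry and the equality criterion on random sets
  set.seed(41)
  for (i in 1:20) {
    a <- sample(LETTERS, sample(1:6, 1)); b <- sample(LETTERS, sample(1:6, 1))
    expect_equal(jaccardIndex(a, b), jaccardIndex(b, a))
    expect_equal(jaccardIndex(a, b) == 1, setequal(a, b))
  }
})

test_that("matching requires both thresholds and a real change", {
  S <- mkSet(list(c1 = c("A", "B", "C", "D")), 0.5)
  # identical composition and identical C: deltaC = 0 < delta, no match
  expect_equal(nrow(matchComplexes(S, S)), 0L)
  T2 <- mkSet(list(d1 = c("A", "B", "C", "E")), 0.2, "Y")
  m <- matchComplexes(S, T2)    # J = 0.6 < 0.67
  expect_equal(nrow(m), 0L)
  m <- matchComplexes(S, T2, tJ = 0.5)
  expect_equal(nrow(m), 1L)
  expect_equal(m$jaccard, 0.6)
  expect_equal(m$delta_c, 0.3)
  expect_equal(m$direction, "decrease")
})

test_that("greedy one-to-one matching equals brute-force enumeration", {
  set.seed(42)
  for (rep in 1:10) {
    mkMembers <- function(p) {
      out <- lapply(1:5, function(i) sample(LETTERS[1:10], sample(3:6, 1)))
      names(out) <- paste0(p, 1:5)
      out
    }
    mS <- mkMembers("s"); mT <- mkMembers("t")
    Cs <- setNames(round(runif(5, -0.2, 0.8), 2), names(mS))
    Ct <- setNames(round(runif(5, -0.2, 0.8), 2), names(mT))
    got <- matchComplexes(mkSet(mS, Cs), mkSet(mT, Ct, "Y"),
                          tJ = 0.3, delta = 0.05)
    ref <- refMatch(mS, Cs, mT, Ct, tJ = 0.3, delta = 0.05)
    if (is.null(ref)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$s_id, ref$s)
      expect_equal(got$t_id, ref$t)
      expect_equal(got$delta_c, ref$dc, tolerance = 1e-12)
    }
    # contract: thresholds hold and no id repeats
    expect_true(all(got$jaccard >= 0.3) && all(got$delta_c >= 0.05))
    expect_false(anyDuplicated(got$s_id) > 0 || anyDuplicated(got$t_id) > 0)
  }
})

test_that("the direction partition reports sizes, max and mean change", {
  m <- data.frame(delta_c = c(0.2, 0.4, 0.15),
                  direction = c("decrease", "decrease", "increase"))
  p <- partitionMatched(m)
  expect_equal(p$n, c(2L, 1L))
  expect_equal(p$max_delta_c[1], 0.4)
  expect_equal(p$mean_delta_c[1], 0.3)
  expect_equal(sum(p$n), nrow(m))
  # one-sided input leaves the other subset empty
  onlyDec <- m[m$direction == "decrease", ]
  p <- partitionMatched(onlyDec)
  expect_equal(p$n[p$subset == "Mdprime"], 0L)
  expect_true(is.na(p$max_delta_c[p$subset == "Mdprime"]))
  # random input agrees with direct recomputation
  set.seed(43)
  m <- data.frame(delta_c = runif(30),
                  direction = sample(c("decrease", "increase"), 30, TRUE))
  p <- partitionMatched(m)
  expect_equal(p$mean_delta_c[1], mean(m$delta_c[m$direction == "decrease"]))
  expect_equal(p$max_delta_c[2], max(m$delta_c[m$direction == "increase"]))
})

test_that("random-complex empirical p-values follow their definition", {
  set.seed(44)
  mA <- matrix(rnorm(20 * 12), 20, 12,
               dimnames = list(sprintf("G%02d", 1:20), NULL))
  mB <- matrix(rnorm(20 * 12), 20, 12, dimnames = dimnames(mA))
  nodes <- rownames(mA)
  # observed below every draw (the statistic is nonnegative): p = 1
  r <- randomComplexNull(-1, mA, mB, nodes, sizes = c(4, 5),
                         nComplexes = 3, reps = 25, seed = 1)
  expect_equal(r$p, 1)
  # observed above every draw at 99 replicates: p = (1+0)/(1+99)
  r <- randomComplexNull(1e9, mA, mB, nodes, sizes = c(4, 5),
                         nComplexes = 3, reps = 99, seed = 1)
  expect_equal(r$p, 0.01)
  expect_error(randomComplexNull(0, mA, mB, nodes, sizes = 50,
                                 nComplexes = 2, reps = 5),
               "exceeds")
  # reproducible under seed
  r2 <- randomComplexNull(0.05, mA, mB, nodes, sizes = c(4, 5),
                          nComplexes = 3, reps = 25, seed = 7)
  r3 <- randomComplexNull(0.05, mA, mB, nodes, sizes = c(4, 5),
                          nComplexes = 3, reps = 25, seed = 7)
  expect_identical(r2$null, r3$null)
})

test_that("a planted co-expression shift beats the random-complex null", {
  sim <- generateExpressionPair(24, nSamples = c(30, 30),
                                modules = list(
                                  list(members = 1:5, rhoA = 0.8, rhoB = 0.1),
                                  list(members = 6:10, rhoA = 0.75, rhoB = 0.05)),
                                seed = 45, method = "exact")
  planted <- complexMembers(sim$truth)
  dC <- vapply(planted, function(s)
    abs(as.numeric(complexCoexpression(s, sim$exprA)) -
          as.numeric(complexCoexpression(s, sim$exprB))), numeric(1))
  r <- randomComplexNull(mean(dC), sim$exprA, sim$exprB,
                         rownames(sim$exprA), sizes = lengths(planted),
                         nComplexes = 20, reps = 200, seed = 46)
  expect_lte(r$p, 0.05)
})

test_that("random-complex p-values are uniform when the observed value is null", {
  set.seed(47)
  ps <- replicate(100, {
    mA <- matrix(rnorm(15 * 10), 15, 10,
                 dimnames = list(sprintf("G%02d", 1:15), NULL))
    mB <- matrix(rnorm(15 * 10), 15, 10, dimnames = dimnames(mA))
    nodes <- rownames(mA)
    zd <- function(idx, m) mean(fisherTransform(
      cor(t(m[idx, ]))[upper.tri(diag(length(idx)))]))
    obs <- mean(vapply(1:4, function(i) {
      idx <- sample(nodes, 4)
      abs(zd(idx, mA) - zd(idx, mB))
    }, numeric(1)))
    randomComplexNull(obs, mA, mB, nodes, sizes = 4, nComplexes = 4,
                      reps = 200)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("the KS comparison matches the reference implementation exactly", {
  r <- ksCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_false(r$reject)
  r <- ksCompare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 1)
  expect_equal(r$scaled, sqrt(1.5), tolerance = 1e-12)
  expect_false(r$reject)          # 1.22 < 1.36
  expect_equal(r$critical, 1.36, tolerance = 0.002)
  set.seed(48)
  r <- ksCompare(rnorm(200), rnorm(200, 2))
  expect_true(r$reject)
  for (i in 1:50) {
    x <- rnorm(sample(10:80, 1)); y <- rnorm(sample(10:80, 1), sd = 2)
    ref <- suppressWarnings(ks.test(x, y)$statistic)
    got <- ksCompare(x, y)
    expect_equal(got$statistic, unname(ref), tolerance = 1e-9)
    expect_equal(got$scaled,
                 unname(ref) * sqrt(length(x) * length(y) /
                                      (length(x) + length(y))),
                 tolerance = 1e-9)
  }
})

test_that("gene coverage by changed complexes is exact set arithmetic", {
  S <- mkSet(list(s1 = c("A", "B", "C", "D"), s2 = c("E", "F", "G", "H")),
             c(0.6, 0.5))
  T2 <- mkSet(list(t1 = c("A", "B", "C", "D"), t2 = c("E", "F", "G", "H")),
              c(0.2, 0.45), "Y")
  matched <- matchComplexes(S, T2, tJ = 0.5, delta = 0.05)
  # s1 changes by 0.4, s2 by 0.05
  expect_equal(cancerGeneCoverage(matched, S, T2, c("A", "B"))$coverage, 1)
  expect_equal(cancerGeneCoverage(matched, S, T2, c("X", "Y"))$coverage, 0)
  cov <- cancerGeneCoverage(matched, S, T2, c("A", "E", "X"),
                            threshold = 0.10,
                            networkNodes = c("A", "E", LETTERS[2:8]))
  expect_equal(cov$coverage, 1 / 3)            # only A is in a >=0.10 pair
  expect_equal(cov$coverageInNetwork, 1 / 2)   # X is outside the network
  set.seed(49)
  genes <- sample(LETTERS, 20)
  direct <- mean(genes %in% unlist(S@members[matched$s_id[
    matched$delta_c >= 0.1]]) |
      genes %in% unlist(T2@members[matched$t_id[matched$delta_c >= 0.1]]))
  expect_equal(cancerGeneCoverage(matched, S, T2, genes)$coverage, direct)
})

mkCondNet <- function(from, to, z, label) {
  n <- length(from)
  rho <- inverseFisherTransform(z)
  new("ConditionalNetwork",
      edges = data.frame(from = pmin(from, to), to = pmax(from, to),
                         reliability = 1, rho = rho, z = z,
                         clusterWeight = pmax(rho, 0),
                         rhoUndefined = FALSE, stringsAsFactors = FALSE),
      conditionLabel = label)
}

test_that("the differential network applies the two-thirds direction rule", {
  # identical networks: all deltas zero, rewired view empty
  f <- c("A", "A", "B"); t <- c("B", "C", "C")
  nA <- mkCondNet(f, t, c(0.3, 0.4, 0.5), "A")
  d <- differentialNetwork(nA, nA)
  expect_equal(d@edges$delta, c(0, 0, 0))
  expect_equal(sum(d@edges$rewired), 0L)
  expect_length(d@clusters, 0L)

  # 4-clique, six edges: four drop (delta > 0), two rise -> "decrease"
  pr <- t(combn(c("P", "Q", "R", "S"), 2))
  zA <- c(0.6, 0.6, 0.6, 0.6, 0, 0)
  zB <- c(0, 0, 0, 0, 0.6, 0.6)
  d <- differentialNetwork(mkCondNet(pr[, 1], pr[, 2], zA, "A"),
                           mkCondNet(pr[, 1], pr[, 2], zB, "B"),
                           minAbsDelta = 0.5)
  expect_equal(unname(d@clusterLabels), "decrease")
  expect_setequal(d@largestComponent, c("P", "Q", "R", "S"))
  expect_error(differentialNetwork(nA, mkCondNet("X", "Y", 0.2, "B")),
               "share no edges")
})

test_that("opposite planted shifts give two opposite-direction clusters", {
  sim <- generateExpressionPair(14, nSamples = c(20, 20),
                                modules = list(
                                  list(members = 1:5, rhoA = 0.85, rhoB = 0.2),
                                  list(members = 6:10, rhoA = 0.2, rhoB = 0.85)),
                                seed = 50, method = "exact")
  net <- generatePPIWithComplexes(sim$truth, backgroundEdges = 0)
  dn <- differentialNetwork(conditionNetwork(net, sim$exprA),
                            conditionNetwork(net, sim$exprB),
                            minAbsDelta = 0.3)
  expect_length(dn@clusters, 2L)
  lab <- dn@clusterLabels
  first <- vapply(dn@clusters, function(s) "G0001" %in% s, logical(1))
  expect_equal(unname(lab[first]), "decrease")
  expect_equal(unname(lab[!first]), "increase")
})
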