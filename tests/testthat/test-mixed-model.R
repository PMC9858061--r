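test_that("variance components follow the fixed 0.3/0.7 split", {
  spec <- estimateVariances(c(0, 0, 1, 1))
  expect_equal(spec@sigmaY2, 1 / 3)
  expect_equal(spec@sigmaG2, 0.1)
  expect_equal(spec@sigmaE2, 0.7 / 3)
  expect_equal(spec@lambda, 7 / 3)
  # literal lambda is the share ratio regardless of the data
  set.seed(1)
  for (y in list(rbinom(50, 1, 0.3), rnorm(20))) {
    if (var(y) > 0)
      expect_equal(estimateVariances(y)@lambda, 7 / 3, tolerance = 1e-12)
  }
  y541 <- c(rep(1, 235), rep(0, 306))
  m <- 235 / 541
  expect_equal(estimateVariances(y541)@sigmaY2,
               (235 * (1 - m)^2 + 306 * m^2) / 540, tolerance = 1e-12)
  expect_error(estimateVariances(rep(1, 10)), "constant")
  expect_error(estimateVariances(c(0, 1)), "at least 3")
})

test_that("scaled mode divides the genetic share by the heterozygosity sum", {
  gm <- makeGenotypes(cbind(c(0, 1, 2, 1), c(0, 0, 1, 1)))
  y <- c(0, 0, 1, 1)
  spec <- estimateVariances(y, gm, varianceMode = "scaled")
  p <- c(4 / 8, 2 / 8)
  denom <- 2 * sum(p * (1 - p))
  expect_equal(spec@sigmaG2, 0.3 * var(y) / denom, tolerance = 1e-12)
  expect_equal(spec@lambda, spec@sigmaE2 / spec@sigmaG2, tolerance = 1e-12)
  expect_error(estimateVariances(y, varianceMode = "scaled"), "genotype")
})

test_that("the Henderson coefficient matrix has the documented structure", {
  spec <- estimateVariances(c(0, 0, 1, 1))
  lam <- spec@lambda
  sys1 <- buildMME(y = 1, X = matrix(1, 1, 1), Z = matrix(2, 1, 1), spec)
  C1 <- mmeCoefficientMatrix(sys1)$C
  expect_equal(unname(C1), rbind(c(1, 2), c(2, 4 + lam)))
  sysZ <- buildMME(c(0, 1, 1), matrix(1, 3, 1),
                   cbind(c(1, 0, 2), c(0, 0, 0)), spec)
  CZ <- mmeCoefficientMatrix(sysZ)$C
  expect_equal(unname(CZ[3, 3]), lam)
  inst <- randomInstance(25, 8, seed = 44)
  sys <- buildMME(inst$y, inst$X, inst$Z, spec)
  got <- mmeCoefficientMatrix(sys)
  Cref <- rbind(cbind(t(inst$X) %*% inst$X, t(inst$X) %*% inst$Z),
                cbind(t(inst$Z) %*% inst$X,
                      t(inst$Z) %*% inst$Z + lam * diag(8)))
  expect_equal(unname(got$C), unname(Cref), tolerance = 1e-12)
  expect_equal(unname(got$rhs),
               unname(drop(rbind(t(inst$X), t(inst$Z)) %*% inst$y)),
               tolerance = 1e-12)
})

test_that("a rank-deficient fixed design is rejected with the offending column", {
  spec <- estimateVariances(c(0, 0, 1, 1))
  X <- cbind(intercept = rep(1, 4), age = rep(50, 4))
  expect_error(buildMME(c(0, 0, 1, 1), X, matrix(rbinom(8, 2, 0.4), 4, 2),
                        spec), "age")
  Zna <- matrix(c(1, NA, 0, 1), 2, 2)
  expect_error(buildMME(c(0, 1), matrix(1, 2, 1), Zna, spec), "missing")
})

test_that("the fixed 4-sample instance matches the dense ridge oracle", {
  X <- matrix(1, 4, 1)
  Z <- rbind(c(0, 1), c(1, 0), c(2, 1), c(1, 2))
  y <- c(0, 0, 1, 1)
  spec <- estimateVariances(y)     # lambda = 7/3
  fit <- solveMME(buildMME(y, X, Z, spec), method = "direct")
  ref <- oracleRidge(X, Z, y, 7 / 3)
  expect_equal(unname(c(fit@betaHat, fit@gHat)), unname(ref),
               tolerance = 1e-10)
})

test_that("a zero response yields exactly zero effects", {
  spec <- new("MixedModelSpec", geneticShare = 0.3, residualShare = 0.7,
              sigmaY2 = 1, sigmaG2 = 0.3, sigmaE2 = 0.7,
              lambda = 0.7 / 0.3, varianceMode = "literal")
  inst <- randomInstance(30, 10, seed = 3)
  sys <- buildMME(rep(0, 30), inst$X, inst$Z, spec)
  for (m in c("direct", "pcg")) {
    fit <- solveMME(sys, method = m)
    expect_equal(unname(fit@betaHat), rep(0, 3))
    expect_equal(unname(fit@gHat), rep(0, 10))
  }
})

test_that("infinite shrinkage recovers the ordinary least-squares fixed effects", {
  inst <- randomInstance(60, 15, seed = 5)
  spec <- new("MixedModelSpec", geneticShare = 0.3, residualShare = 0.7,
              sigmaY2 = 1, sigmaG2 = 1e-12, sigmaE2 = 1, lambda = 1e12,
              varianceMode = "literal")
  fit <- solveMME(buildMME(inst$y, inst$X, inst$Z, spec), method = "direct")
  expect_lt(max(abs(fit@gHat)), 1e-6 * sd(inst$y))
  ols <- qr.coef(qr(inst$X), inst$y)
  expect_equal(unname(fit@betaHat), unname(ols), tolerance = 1e-6)
})

test_that("both solvers match the generalized-ridge oracle on random instances", {
  spec <- estimateVariances(c(0, 1, 0, 1))
  for (s in 1:12) {
    n <- sample(15:80, 1)
    q <- sample(c(4:30, 90), 1)  # exercises both q <= n and q > n branches
    inst <- randomInstance(n, q, seed = 500 + s)
    sys <- buildMME(inst$y, inst$X, inst$Z, spec)
    ref <- oracleRidge(inst$X, inst$Z, inst$y, spec@lambda)
    dir <- solveMME(sys, method = "direct")
    got <- c(dir@betaHat, dir@gHat)
    expect_lt(max(abs(got - ref)) / max(1, max(abs(ref))), 1e-8)
    pcg <- solveMME(sys, method = "pcg", tol = 1e-10)
    expect_lt(max(abs(c(pcg@betaHat, pcg@gHat) - got)), 1e-6)
    expect_lte(pcg@relResidual, 1e-10)
  }
})

test_that("PCG reports non-convergence with the achieved residual", {
  inst <- randomInstance(40, 12, seed = 9)
  spec <- estimateVariances(inst$y)
  sys <- buildMME(inst$y, inst$X, inst$Z, spec)
  expect_error(solveMME(sys, method = "pcg", tol = 1e-14, maxIter = 2L),
               "did not converge")
})

test_that("the SNP-effect norm shrinks monotonically in lambda", {
  inst <- randomInstance(50, 20, seed = 11)
  norms <- vapply(c(0.1, 1, 10, 100, 1000), function(lam) {
    spec <- new("MixedModelSpec", geneticShare = 0.3, residualShare = 0.7,
                sigmaY2 = 1, sigmaG2 = 1 / lam, sigmaE2 = 1, lambda = lam,
                varianceMode = "literal")
    fit <- solveMME(buildMME(inst$y, inst$X, inst$Z, spec), "direct")
    sqrt(sum(fit@gHat^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("permuting SNP columns permutes the effects and fixes the fixed effects", {
  inst <- randomInstance(40, 12, seed = 13)
  spec <- estimateVariances(inst$y)
  base <- solveMME(buildMME(inst$y, inst$X, inst$Z, spec,
                            snpIDs = sprintf("s%02d", 1:12)), "direct")
  set.seed(2)
  perm <- sample(12)
  permuted <- solveMME(buildMME(inst$y, inst$X, inst$Z[, perm], spec,
                                snpIDs = sprintf("s%02d", (1:12)[perm])),
                       "direct")
  expect_equal(unname(permuted@gHat), unname(base@gHat[perm]),
               tolerance = 1e-10)
  expect_equal(permuted@betaHat, base@betaHat, tolerance = 1e-10)
})

test_that("Wald statistics refer effects to the prior SD and the standard normal", {
  spec <- new("MixedModelSpec", geneticShare = 0.3, residualShare = 0.7,
              sigmaY2 = 1, sigmaG2 = 0.25, sigmaE2 = 0.7, lambda = 2.8,
              varianceMode = "literal")
  sg <- 0.5
  fit <- new("ModelFit",
             betaHat = c(intercept = 0),
             gHat = c(a = 0, b = 1.959964 * sg, c = 0.5 * sg, d = -2 * sg,
                      e = 3 * sg),
             solver = "direct", iterations = 0L, relResidual = 0)
  res <- waldTest(fit, spec)
  tab <- resultTable(res)[match(letters[1:5], resultTable(res)$snp_id), ]
  expect_equal(tab$W, c(0, 1.959964, 0.5, -2, 3), tolerance = 1e-12)
  expect_equal(tab$p[1], 1)
  expect_equal(tab$p[2], 0.05, tolerance = 1e-6)
  expect_equal(tab$p[3:5], c(0.6171, 0.0455, 0.0027), tolerance = 1e-4)
  # p-values are floored, never zero
  fitBig <- new("ModelFit", betaHat = c(i = 0), gHat = c(z = 60 * sg),
                solver = "direct", iterations = 0L, relResidual = 0)
  expect_gt(min(resultTable(waldTest(fitBig, spec))$p), 0)
})

test_that("Bonferroni control uses alpha over the number of tests, strictly", {
  res <- makeAssociation(c(0.04, 0.2))
  one <- makeAssociation(0.04)
  expect_equal(bonferroniCorrect(one, 0.05)@threshold, 0.05)
  expect_false(resultTable(bonferroniCorrect(one, 0.04))$significant)
  m <- 15489173
  big <- makeAssociation(rep(0.5, 5))
  big@mTests <- as.integer(m)
  big@threshold <- 0.05 / m
  expect_equal(bonferroniCorrect(big, 0.05)@threshold, 0.05 / 15489173,
               tolerance = 1e-15)
  allOne <- makeAssociation(rep(1, 10))
  expect_identical(sum(resultTable(bonferroniCorrect(allOne))$significant),
                   0L)
  expect_error(bonferroniCorrect(res, 0), "alpha")
  expect_error(bonferroniCorrect(res, 1), "alpha")
})

test_that("hits rank by p-value with positional tie-breaking", {
  res <- makeAssociation(c(0.5, 0.001, 0.03))
  expect_identical(rankHits(res)$snp_id, c("s002", "s003", "s001"))
  tied <- makeAssociation(c(0.01, 0.01, 0.5), chrom = c("2", "1", "1"),
                          pos = c(5, 9, 1))
  expect_identical(rankHits(tied)$snp_id[1:2], c("s002", "s001"))
  set.seed(33)
  p <- round(runif(40), 2)  # many ties
  rnd <- makeAssociation(p, chrom = sample(1:3, 40, TRUE),
                         pos = sample(1000, 40))
  ref <- with(resultTable(rnd), order(p, as.numeric(chrom), pos))
  expect_identical(rankHits(rnd)$snp_id, resultTable(rnd)$snp_id[ref])
})
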