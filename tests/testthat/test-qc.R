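test_that("call rate counts non-missing genotypes", {
  expect_equal(callRate(c(0, 1, 2, NA)), 0.75)
  expect_equal(callRate(c(0, 1, 2)), 1)
  expect_equal(callRate(c(rep(1, 19), NA)), 0.95)
  expect_error(callRate(numeric(0)), "empty")
})

test_that("MAF is computed over observed alleles and folded", {
  expect_equal(maf(c(0, 0, 1, 2)), 0.375)
  expect_equal(maf(c(2, 2, 2)), 0)
  expect_equal(maf(c(0, NA, 2)), 0.5)
  expect_error(maf(c(NA_real_, NA_real_)), "missing")
})

test_that("the exact Hardy-Weinberg test matches direct enumeration", {
  expect_equal(hweExactP(0, 0, 100), 1)
  expect_equal(hweExactP(1, 0, 1), oracleHweP(1, 0, 1), tolerance = 1e-12)
  expect_equal(hweExactP(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hweExactP(57, 14, 50), oracleHweP(57, 14, 50),
               tolerance = 1e-12)
  # all configurations with modest totals (full sweep to 50 runs in the
  # acceptance suite)
  for (n in c(1:12, 30)) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hweExactP(nAA, nAa, naa), oracleHweP(nAA, nAa, naa),
                   tolerance = 1e-12)
    }
  }
  expect_error(hweExactP(-1, 2, 3), "nonnegative")
})

test_that("Hardy-Weinberg conditional probabilities sum to one and the test is stable at scale", {
  for (n in c(10, 25, 40)) for (nA in c(1, 5, n)) {
    expect_equal(sum(oracleHweProbs(n, nA)), 1, tolerance = 1e-12)
  }
  p <- hweExactP(30000, 30000, 40000)
  expect_gt(p, 0)
  expect_lte(p, 1)
  pEq <- hweExactP(25000, 50000, 25000)  # perfect equilibrium at n = 1e5
  expect_gt(pEq, 0.5)
})

test_that("the mid-p variant is smaller than the plain exact p", {
  expect_lt(hweExactP(57, 14, 50, midp = TRUE), hweExactP(57, 14, 50))
})

test_that("the QC cascade removes one variant per reason on the toy fixture", {
  n <- 1000
  mkCol <- function(nAA, nAa, naa, nMiss = 0) {
    c(rep(0, nAA), rep(1, nAa), rep(2, naa), rep(NA_real_, nMiss))
  }
  d <- cbind(
    multi = mkCol(500, 400, 100),          # fails: multi-allelic
    lowcr = mkCol(450, 360, 90, 100),      # call rate 0.90 < 0.95
    hwefail = mkCol(900, 0, 100),          # massive heterozygote deficit
    lowmaf = mkCol(999, 1, 0),             # alt frequency 0.0005 < 0.001
    clean1 = mkCol(490, 420, 90),
    clean2 = mkCol(640, 320, 40)
  )
  gm <- makeGenotypes(d, multiallelic = c(TRUE, rep(FALSE, 5)))
  out <- applyQC(gm, qcThresholds(0.95, 1e-4, 0.001))
  rep_ <- out$report
  expect_identical(rep_@nInput, 6L)
  expect_identical(rep_@nPass, 2L)
  expect_identical(rep_@nRemovedMultiallelic, 1L)
  expect_identical(rep_@nRemovedCallrate, 1L)
  expect_identical(rep_@nRemovedHwe, 1L)
  expect_identical(rep_@nRemovedMaf, 1L)
  tab <- resultTable(rep_)
  expect_identical(tab$fail_reason[1:4],
                   c("multiallelic", "callrate", "hwe", "maf"))
  expect_equal(tab$call_rate[2], 0.90)
  expect_equal(tab$maf[4], 0.0005)
  expect_lt(tab$hwe_p[3], 1e-4)
  expect_identical(ncol(dosages(out$genotypes)), 2L)
})

test_that("thresholds are strict and zero thresholds pass everything", {
  # a variant sitting exactly on the call-rate threshold survives
  borderCr <- c(rep(0, 5), rep(1, 10), rep(2, 4), NA)  # call rate = 0.95
  gm <- makeGenotypes(cbind(borderCr))
  out <- applyQC(gm, qcThresholds(0.95, 1e-4, 0.001))
  expect_identical(out$report@nPass, 1L)
  d <- dosages(simulateGenotypes(simulationConfig(nSamples = 80, nSnps = 20,
                                                  seed = 6)))
  out0 <- applyQC(makeGenotypes(d), qcThresholds(0, 0, 0))
  expect_identical(out0$report@nPass, 20L)
})

test_that("applyQC is idempotent and conserves its ledger", {
  cfg <- simulationConfig(nSamples = 200, nSnps = 80, missingRate = 0.04,
                          mafRange = c(0.005, 0.5), seed = 17)
  gm <- simulateGenotypes(cfg)
  out1 <- applyQC(gm)
  expect_identical(
    out1$report@nInput,
    out1$report@nPass + out1$report@nRemovedMultiallelic +
      out1$report@nRemovedCallrate + out1$report@nRemovedHwe +
      out1$report@nRemovedMaf)
  out2 <- applyQC(out1$genotypes)
  expect_identical(out2$report@nPass, out1$report@nPass)
  expect_identical(dosages(out2$genotypes), dosages(out1$genotypes))
})

test_that("raising any threshold never increases the number of passing variants", {
  cfg <- simulationConfig(nSamples = 150, nSnps = 60, missingRate = 0.05,
                          mafRange = c(0.005, 0.5), seed = 23)
  gm <- simulateGenotypes(cfg)
  base <- applyQC(gm, qcThresholds(0.9, 1e-5, 0.001))$report@nPass
  for (thr in list(qcThresholds(0.97, 1e-5, 0.001),
                   qcThresholds(0.9, 1e-2, 0.001),
                   qcThresholds(0.9, 1e-5, 0.05))) {
    expect_lte(applyQC(gm, thr)$report@nPass, base)
  }
})

test_that("HWE can be restricted to a sample subset", {
  d <- rbind(matrix(rep(c(0, 1), each = 25), 25),    # equilibrium-ish block
             matrix(2, 25, 2))
  gm <- makeGenotypes(d)
  full <- applyQC(gm)$report
  sub <- applyQC(gm, hweSampleIDs = sampleIDs(gm)[1:25])$report
  expect_false(identical(resultTable(full)$hwe_p, resultTable(sub)$hwe_p))
  expect_error(applyQC(gm, hweSampleIDs = "nobody"), "none of")
})

test_that("mean imputation fills only missing entries and preserves SNP means", {
  gm <- makeGenotypes(cbind(c(0, 2, NA), c(1, 1, 1)))
  imp <- dosages(imputeMissingMean(gm))
  expect_equal(unname(imp[, 1]), c(0, 2, 1))
  expect_equal(unname(imp[, 2]), c(1, 1, 1))
  cfg <- simulationConfig(nSamples = 120, nSnps = 40, missingRate = 0.1,
                          seed = 19)
  gm2 <- simulateGenotypes(cfg)
  imp2 <- imputeMissingMean(gm2)
  expect_equal(colMeans(dosages(imp2)),
               colMeans(dosages(gm2), na.rm = TRUE), tolerance = 1e-12)
  obs <- !is.na(dosages(gm2))
  expect_identical(dosages(imp2)[obs], dosages(gm2)[obs])
  expect_identical(imputeMissingMean(imp2), imp2)
  allMiss <- makeGenotypes(cbind(c(NA_real_, NA_real_)))
  expect_error(imputeMissingMean(allMiss), "no observed")
})
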