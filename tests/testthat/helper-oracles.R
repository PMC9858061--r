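# Independent oracles used across the suite. These deliberately take
# different computational routes from the package code they check.

# Hardy-Weinberg exact test by direct enumeration: log-factorial formula for
# the conditional probability of every attainable heterozygote count.
oracleHweP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nAlt <- 2 * naa + nAa
  nA <- min(nAlt, 2 * n - nAlt)
  if (nA == 0) return(1)
  hets <- seq.int(nA %% 2, nA, by = 2)
  lp <- vapply(hets, function(h) {
    homRare <- (nA - h) / 2
    homCommon <- n - h - homRare
    lfactorial(n) - lfactorial(homRare) - lfactorial(h) -
      lfactorial(homCommon) + h * log(2) +
      lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp)
  pr <- pr / sum(pr)
  pObs <- pr[hets == nAa]
  sum(pr[pr <= pObs * (1 + 1e-12)])
}

# Conditional probabilities of the enumeration (for the sum-to-one
# self-check).
oracleHweProbs <- function(n, nA) {
  hets <- seq.int(nA %% 2, nA, by = 2)
  lp <- vapply(hets, function(h) {
    homRare <- (nA - h) / 2
    homCommon <- n - h - homRare
    lfactorial(n) - lfactorial(homRare) - lfactorial(h) -
      lfactorial(homCommon) + h * log(2) +
      lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  exp(lp)
}

# Generalized-ridge oracle: solve min ||y - Xb - Zg||^2 + lambda ||g||^2
# through the QR factorisation of the augmented least-squares system —
# a different route from Henderson's equations.
oracleRidge <- function(X, Z, y, lambda) {
  p <- ncol(X)
  q <- ncol(Z)
  Xaug <- rbind(cbind(X, Z),
                cbind(matrix(0, q, p), sqrt(lambda) * diag(q)))
  yaug <- c(y, rep(0, q))
  qr.coef(qr(Xaug), yaug)
}

# Random mixed-model instance with intercept/age/sex covariates.
randomInstance <- function(n, q, seed) {
  set.seed(seed)
  X <- cbind(intercept = 1, age = runif(n, 20, 80),
             sex_code = rbinom(n, 1, 0.5))
  Z <- matrix(rbinom(n * q, 2, runif(q, 0.1, 0.5)[rep(seq_len(q), each = n)]),
              n, q)
  y <- rbinom(n, 1, 0.4)
  if (var(y) == 0) y[1] <- 1 - y[1]
  list(X = X, Z = Z, y = as.numeric(y))
}

# A BinaryPhenotype built directly from raw vectors (bypasses encoding).
makePhenotype <- function(y, age = NULL, sex = NULL,
                          contrast = "severe") {
  n <- length(y)
  if (is.null(age)) age <- round(seq(20, 80, length.out = n))
  if (is.null(sex)) sex <- rep_len(c(0, 1), n)
  new("BinaryPhenotype", y = as.integer(y),
      sampleIDs = sprintf("S%05d", seq_len(n)), age = as.numeric(age),
      sexCode = as.numeric(sex), contrast = contrast)
}

# GenotypeMatrix from a plain dosage matrix with generated metadata.
makeGenotypes <- function(d, chrom = NULL, multiallelic = NULL) {
  p <- ncol(d)
  if (is.null(chrom)) chrom <- rep("1", p)
  v <- data.frame(chrom = chrom, pos = seq_len(p) * 100L,
                  id = sprintf("snp%05d", seq_len(p)),
                  ref = "A", alt = "G",
                  multiallelic = if (is.null(multiallelic)) FALSE
                                 else multiallelic,
                  stringsAsFactors = FALSE)
  GenotypeMatrix(d, v, samples = sprintf("S%05d", seq_len(nrow(d))))
}

# SingleSnpResult assembled from explicit p-values.
singleFromP <- function(p, alpha = 0.05) {
  m <- length(p)
  df <- 30
  tstat <- -qt(p / 2, df)
  tab <- data.frame(snp_id = sprintf("s%03d", seq_len(m)), chrom = "1",
                    pos = seq_len(m), ref = "A", alt = "G", beta = tstat,
                    se = 1, t = tstat, p = p, degenerate = FALSE,
                    significant = p < alpha / m, stringsAsFactors = FALSE)
  new("SingleSnpResult", table = tab, mTests = m, alpha = alpha,
      threshold = alpha / m)
}

# AssociationResult assembled from explicit p-values (for sort/summary
# oracles); g_hat/W back-computed to keep the object self-consistent.
makeAssociation <- function(p, chrom = NULL, pos = NULL, alpha = 0.05,
                            snpID = NULL) {
  m <- length(p)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m)
  if (is.null(snpID)) snpID <- sprintf("s%03d", seq_len(m))
  W <- -qnorm(p / 2)
  tab <- data.frame(snp_id = snpID, chrom = as.character(chrom), pos = pos,
                    ref = "A", alt = "G", g_hat = W, W = W, p = p,
                    significant = p < alpha / m, stringsAsFactors = FALSE)
  new("AssociationResult", table = tab, mTests = m, alpha = alpha,
      threshold = alpha / m)
}
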