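#' Configure the synthetic cohort generator
#'
#' The generator emulates the data structure the association model assumes:
#' unrelated individuals, bi-allelic SNPs organised in linkage-disequilibrium
#' (LD) blocks, an oligogenic latent liability with a configurable genetic
#' variance share, five ordered disease categories assigned by liability
#' quantiles, and age/sex covariates. Defaults describe a cohort of 1076
#' individuals with 306 resistant and 235 severe samples, the group sizes of
#' the study design this package targets; the control/benign/mild split is a
#' free choice (see the methods vignette).
#'
#' @param nSamples number of individuals (default 1076).
#' @param nSnps number of bi-allelic SNPs (default 5000).
#' @param ldBlockSize SNPs per LD block (default 10); SNPs in different
#'   blocks are independent.
#' @param withinBlockR target pairwise dosage correlation within a block, in
#'   \eqn{[0,1)} (default 0.6).
#' @param mafRange interval within (0, 0.5] from which per-SNP alternate
#'   allele frequencies are drawn uniformly (default `c(0.05, 0.5)`).
#' @param nCausal number of causal SNPs (default 10).
#' @param causalEffectSD standard deviation of causal effects on the
#'   liability scale, before heritability rescaling (default 1).
#' @param effectDistribution `"fixed"` (default): every causal effect has
#'   magnitude `causalEffectSD` with an independent random sign, so all
#'   causal SNPs carry comparably large effects; `"gaussian"`: effects are
#'   drawn `N(0, causalEffectSD^2)`.
#' @param heritability genetic share of liability variance, in \eqn{[0,1)}
#'   (default 0.3).
#' @param categoryProportions five nonnegative proportions summing to 1, named
#'   or given in `categoryOrder`; default
#'   `c(306, 200, 180, 155, 235)/1076`.
#' @param categoryOrder category labels from lowest to highest liability;
#'   default `c("resistant","control","benign","mild","severe")`.
#' @param ageRange age interval in years (default `c(18, 85)`).
#' @param ageEffect liability-scale coefficient of standardized age; 0 (the
#'   default) keeps covariates independent of liability.
#' @param missingRate completely-at-random genotype missingness (default 0;
#'   useful for exercising QC).
#' @param seed integer RNG seed.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(nSamples = 200, nSnps = 100, seed = 7)
#' cohort <- simulateCohort(cfg)
#' table(cohortTable(cohort)$category)
#' @export
simulationConfig <- function(nSamples = 1076L, nSnps = 5000L,
                             ldBlockSize = 10L, withinBlockR = 0.6,
                             mafRange = c(0.05, 0.5), nCausal = 10L,
                             causalEffectSD = 1,
                             effectDistribution = c("fixed", "gaussian"),
                             heritability = 0.3,
                             categoryProportions =
                               c(resistant = 306, control = 200, benign = 180,
                                 mild = 155, severe = 235) / 1076,
                             categoryOrder = c("resistant", "control",
                                               "benign", "mild", "severe"),
                             ageRange = c(18, 85), ageEffect = 0,
                             missingRate = 0, seed = 1L) {
  if (!is.null(names(categoryProportions)))
    categoryProportions <- categoryProportions[categoryOrder]
  if (anyNA(categoryProportions))
    stop("categoryProportions names must match categoryOrder")
  new("SimulationConfig",
      nSamples = as.integer(nSamples), nSnps = as.integer(nSnps),
      ldBlockSize = as.integer(ldBlockSize), withinBlockR = withinBlockR,
      mafRange = as.numeric(mafRange), nCausal = as.integer(nCausal),
      causalEffectSD = causalEffectSD,
      effectDistribution = match.arg(effectDistribution),
      heritability = heritability,
      categoryProportions = unname(as.numeric(categoryProportions)),
      categoryOrder = categoryOrder, ageRange = as.numeric(ageRange),
      ageEffect = ageEffect, missingRate = missingRate,
      seed = as.integer(seed))
}

# Derive an independent child RNG seed from the configured one; keeps the
# streams of the genotype and phenotype stages decoupled and < 2^31.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) + 779230947 * k) %% 2147483647)
}

# P(Z1 < q, Z2 < q) for a standard bivariate normal with correlation rho,
# by 1-D quadrature (no bivariate-CDF dependency needed).
bivariateLowerProb <- function(q, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(q)^2)
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((q - rho * x) / s)
  stats::integrate(f, -Inf, q, rel.tol = 1e-10)$value
}

# Latent Gaussian correlation that yields a target correlation r between
# allele indicators thresholded at frequency f (and hence between dosages,
# which are sums of two independent haplotypes).
latentRho <- function(f, r) {
  if (r <= 0) return(0)
  q <- stats::qnorm(f)
  target <- function(rho) {
    p11 <- bivariateLowerProb(q, rho)
    (p11 - f^2) / (f * (1 - f)) - r
  }
  stats::uniroot(target, c(0, 1 - 1e-9), tol = 1e-9)$root
}

snpBlocks <- function(nSnps, blockSize) {
  split(seq_len(nSnps), ceiling(seq_len(nSnps) / blockSize))
}

variantFrame <- function(nSnps, blockSize) {
  nBlocks <- ceiling(nSnps / blockSize)
  nChrom <- min(22L, nBlocks)
  blockChrom <- ceiling(seq_len(nBlocks) / ceiling(nBlocks / nChrom))
  chrom <- blockChrom[ceiling(seq_len(nSnps) / blockSize)]
  idxWithin <- stats::ave(seq_len(nSnps), chrom, FUN = seq_along)
  data.frame(
    chrom = as.character(chrom),
    pos = 1000L * idxWithin,
    id = sprintf("snp%05d", seq_len(nSnps)),
    ref = rep(c("A", "C"), length.out = nSnps),
    alt = rep(c("G", "T"), length.out = nSnps),
    multiallelic = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Simulate LD-block genotypes
#'
#' Genotypes are built from a latent Gaussian copula: for each of the two
#' haplotypes of an individual, a latent vector with block-constant
#' correlation is drawn and thresholded at the per-SNP allele-frequency
#' quantile; the two haplotypes are summed to a 0/1/2 dosage. The latent
#' correlation of each block is calibrated numerically so the *dosage*
#' correlation matches `withinBlockR` (at the block's mean allele frequency);
#' SNPs in different blocks are independent. Per-SNP alternate allele
#' frequencies are drawn uniformly from `mafRange`. With `missingRate > 0`
#' genotypes are masked missing completely at random.
#'
#' The same `config` (including its seed) always yields the same matrix.
#'
#' @param config a [SimulationConfig-class].
#' @return A [GenotypeMatrix-class] of dimension `nSamples x nSnps`.
#' @export
simulateGenotypes <- function(config) {
  validObject(config)
  n <- config@nSamples
  p <- config@nSnps
  set.seed(config@seed)
  freq <- stats::runif(p, config@mafRange[1], config@mafRange[2])
  blocks <- snpBlocks(p, config@ldBlockSize)

  rhoCache <- new.env(parent = emptyenv())
  blockRho <- vapply(blocks, function(idx) {
    if (config@withinBlockR <= 0 || length(idx) < 2L) return(0)
    fbar <- mean(freq[idx])
    key <- sprintf("%.4f", fbar)
    if (is.null(rhoCache[[key]]))
      rhoCache[[key]] <- latentRho(fbar, config@withinBlockR)
    rhoCache[[key]]
  }, numeric(1))

  qthr <- stats::qnorm(freq)
  dos <- matrix(0, n, p)
  for (hap in 1:2) {
    latent <- matrix(stats::rnorm(n * p), n, p)
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      rho <- blockRho[b]
      if (rho > 0 && length(idx) > 1L) {
        shared <- stats::rnorm(n)
        latent[, idx] <- sqrt(rho) * shared +
          sqrt(1 - rho) * latent[, idx, drop = FALSE]
      }
    }
    dos <- dos + (latent < rep(qthr, each = n))
  }
  if (config@missingRate > 0)
    dos[stats::runif(n * p) < config@missingRate] <- NA_real_

  GenotypeMatrix(dos, variantFrame(p, config@ldBlockSize),
                 samples = sprintf("S%05d", seq_len(n)))
}

categoryCounts <- function(proportions, n) {
  diff(c(0L, round(cumsum(proportions) * n)))
}

#' Simulate a liability-threshold phenotype over given genotypes
#'
#' A latent liability is formed as the standardized-genotype score of
#' `nCausal` randomly chosen causal SNPs (effects drawn
#' `N(0, causalEffectSD^2)`) plus Gaussian noise, with the two parts rescaled
#' so the genetic share of liability variance equals `heritability`
#' (`heritability = 0` gives pure noise). Samples are then partitioned into
#' the five categories by empirical liability quantiles: category counts are
#' the rounded cumulative-proportion partition of `nSamples`, assigned along
#' increasing liability in `categoryOrder`. Ages are uniform over `ageRange`
#' (rounded to whole years) and sex is Bernoulli(0.5); by default both are
#' independent of liability (`ageEffect = 0`).
#'
#' @param genotypes a complete (no missing) [GenotypeMatrix-class].
#' @param config the [SimulationConfig-class] (its seed drives a stream
#'   independent of the genotype stage, so the same config reproduces the
#'   same cohort bit-for-bit).
#' @return A [SimulatedCohort-class].
#' @export
simulatePhenotype <- function(genotypes, config) {
  validObject(config)
  d <- dosages(genotypes)
  if (anyNA(d))
    stop("genotypes must be complete (no missing) to simulate a phenotype")
  n <- nrow(d)
  p <- ncol(d)
  if (config@nCausal > p)
    stop("nCausal exceeds the number of SNPs in the genotype matrix")
  set.seed(childSeed(config@seed, 1L))

  causalIdx <- sort(sample.int(p, config@nCausal))
  effects <- if (config@effectDistribution == "gaussian") {
    stats::rnorm(config@nCausal, 0, config@causalEffectSD)
  } else {
    config@causalEffectSD * sample(c(-1, 1), config@nCausal, replace = TRUE)
  }
  age <- round(stats::runif(n, config@ageRange[1], config@ageRange[2]))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  noise <- stats::rnorm(n)

  h2 <- config@heritability
  score <- rep(0, n)
  if (config@nCausal > 0L && h2 > 0) {
    f <- colMeans(d[, causalIdx, drop = FALSE]) / 2
    sdv <- sqrt(2 * f * (1 - f))
    Xs <- sweep(d[, causalIdx, drop = FALSE], 2, 2 * f, "-")
    ok <- sdv > 0
    Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2, sdv[ok], "/")
    Xs[, !ok] <- 0
    score <- drop(Xs %*% effects)
  }
  genetic <- if (h2 > 0 && stats::sd(score) > 0) {
    sqrt(h2) * scale(score)[, 1]
  } else {
    if (h2 > 0)
      warning("causal score has zero variance; liability is noise only")
    rep(0, n)
  }
  envShare <- if (all(genetic == 0)) 1 else 1 - h2
  liability <- genetic + sqrt(envShare) * scale(noise)[, 1]
  if (config@ageEffect != 0)
    liability <- liability + config@ageEffect * scale(age)[, 1]

  counts <- categoryCounts(config@categoryProportions, n)
  category <- character(n)
  category[order(liability)] <- rep(config@categoryOrder, counts)

  truth <- data.frame(
    snp_id = variants(genotypes)$id,
    is_causal = seq_len(p) %in% causalIdx,
    effect = 0,
    stringsAsFactors = FALSE
  )
  truth$effect[causalIdx] <- effects

  cohort <- data.frame(
    sample_id = sampleIDs(genotypes),
    category = category,
    age = age,
    sex = sex,
    stringsAsFactors = FALSE
  )
  new("SimulatedCohort", genotypes = genotypes, truth = truth,
      cohortTable = cohort, liability = as.numeric(liability),
      config = config)
}

#' Simulate a full cohort (genotypes + phenotype) in one call
#'
#' The liability is always computed from the complete genotypes; with
#' `missingRate > 0` the missingness mask is applied to the returned
#' genotype matrix afterwards, so missing data never distort the simulated
#' phenotype.
#'
#' @param config a [SimulationConfig-class].
#' @return A [SimulatedCohort-class].
#' @export
simulateCohort <- function(config) {
  completeCfg <- config
  completeCfg@missingRate <- 0
  cohort <- simulatePhenotype(simulateGenotypes(completeCfg), completeCfg)
  if (config@missingRate > 0) {
    gm <- cohort@genotypes
    d <- dosages(gm)
    set.seed(childSeed(config@seed, 2L))
    d[stats::runif(length(d)) < config@missingRate] <- NA_real_
    cohort@genotypes <- GenotypeMatrix(d, variants(gm),
                                       samples = sampleIDs(gm))
    cohort@config <- config
  }
  cohort
}

#' Write a simulated cohort in the pipeline's input formats
#'
#' Emits `<prefix>.vcf` (VCF v4.2, GT-only FORMAT, unphased genotypes),
#' `<prefix>.pheno.tsv` (`sample_id`, `category`, `age`, `sex`) and
#' `<prefix>.truth.tsv` (`snp_id`, `is_causal`, `effect`). Reading the VCF
#' back with [readVCF()] reproduces the dosage matrix exactly.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param outPrefix path prefix for the three files.
#' @return Invisibly, a named character vector of the written paths.
#' @export
writeCohort <- function(cohort, outPrefix) {
  stopifnot(is(cohort, "SimulatedCohort"))
  dir <- dirname(outPrefix)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir)
  paths <- c(vcf = paste0(outPrefix, ".vcf"),
             pheno = paste0(outPrefix, ".pheno.tsv"),
             truth = paste0(outPrefix, ".truth.tsv"))
  writeVCFFile(cohort@genotypes, paths[["vcf"]])
  utils::write.table(cohort@cohortTable, paths[["pheno"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort@truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
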