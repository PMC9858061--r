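#' @import methods
NULL

CATEGORY_LEVELS <- c("control", "resistant", "benign", "mild", "severe")
CONSEQUENCE_CLASSES <- c("intron", "intergenic", "regulatory", "coding", "other")
CODING_SUBCLASSES <- c("synonymous", "missense", "other", "n/a")

#' GenotypeMatrix: samples-by-SNPs dosage matrix with variant metadata
#'
#' Container for bi-allelic SNP genotypes coded as alternate-allele dosages
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing). Rows are samples, columns are variants. After mean
#' imputation (see [imputeMissingMean()]) entries may be fractional in
#' \eqn{[0, 2]}. Variant metadata carries chromosome, 1-based position, id,
#' reference and alternate alleles, and a flag marking records that were
#' multi-allelic in the source VCF (such records are kept intact here and
#' removed by [applyQC()]).
#'
#' @slot dosages numeric matrix, samples x SNPs, values in \eqn{[0,2]} or `NA`.
#' @slot variants `data.frame` with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `multiallelic`; one row per matrix column.
#' @slot samples character vector of sample identifiers (row order).
#'
#' @seealso [readVCF()], [simulateGenotypes()], [applyQC()]
#' @export
setClass("GenotypeMatrix",
  representation(
    dosages  = "matrix",
    variants = "data.frame",
    samples  = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosages
  v <- object@variants
  if (!is.numeric(d) && !(is.logical(d) && length(d) == 0L))
    msg <- c(msg, "dosages must be a numeric matrix")
  if (nrow(v) != ncol(d))
    msg <- c(msg, sprintf("variant rows (%d) != dosage columns (%d)",
                          nrow(v), ncol(d)))
  if (length(object@samples) != nrow(d))
    msg <- c(msg, sprintf("sample ids (%d) != dosage rows (%d)",
                          length(object@samples), nrow(d)))
  need <- c("chrom", "pos", "id", "ref", "alt", "multiallelic")
  if (!all(need %in% names(v)))
    msg <- c(msg, paste0("variants must have columns: ",
                         paste(need, collapse = ", ")))
  if (anyDuplicated(object@samples))
    msg <- c(msg, "sample ids must be unique")
  if (all(need %in% names(v)) && nrow(v) > 0L) {
    key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "(chrom, pos, ref, alt) must be unique")
  }
  dd <- d[!is.na(d)]
  if (length(dd) && (min(dd) < 0 || max(dd) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric samples x SNPs matrix over `{0, 1, 2, NA}` (fractional
#'   values in \eqn{[0,2]} are allowed for imputed data).
#' @param variants `data.frame` with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt` and optionally `multiallelic` (defaults to `FALSE`).
#' @param samples character vector of sample ids; defaults to
#'   `rownames(dosages)` or `sample1..sampleN`.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosages, variants, samples = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(samples)) {
    samples <- rownames(dosages)
    if (is.null(samples))
      samples <- sprintf("sample%d", seq_len(nrow(dosages)))
  }
  if (is.null(variants$multiallelic))
    variants$multiallelic <- rep(FALSE, nrow(variants))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  new("GenotypeMatrix", dosages = dosages, variants = variants,
      samples = as.character(samples))
}

#' SimulationConfig: parameters of the synthetic cohort generator
#'
#' Describes a cohort with linkage-disequilibrium (LD) block genotypes and an
#' oligogenic liability-threshold phenotype mapped to the five disease
#' categories `resistant`, `control`, `benign`, `mild`, `severe` (ordered
#' along increasing liability by default). See [simulationConfig()] for field
#' semantics and defaults.
#'
#' @slot nSamples,nSnps cohort and marker dimensions.
#' @slot ldBlockSize SNPs per LD block.
#' @slot withinBlockR target pairwise dosage correlation within a block.
#' @slot mafRange alternate-allele frequency interval, within (0, 0.5].
#' @slot nCausal number of causal SNPs.
#' @slot causalEffectSD standard deviation of causal effects on the liability
#'   scale (before heritability rescaling).
#' @slot effectDistribution `"fixed"` (magnitude `causalEffectSD`, random
#'   sign) or `"gaussian"`.
#' @slot heritability genetic share of liability variance, in \eqn{[0, 1)}.
#' @slot categoryProportions five proportions (sum 1) in liability order.
#' @slot categoryOrder category labels from lowest to highest liability.
#' @slot ageRange age interval in years.
#' @slot ageEffect liability-scale coefficient of standardized age (0 = no
#'   confounding).
#' @slot missingRate probability a genotype is masked missing-at-random.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nSamples = "integer", nSnps = "integer", ldBlockSize = "integer",
    withinBlockR = "numeric", mafRange = "numeric", nCausal = "integer",
    causalEffectSD = "numeric", effectDistribution = "character",
    heritability = "numeric",
    categoryProportions = "numeric", categoryOrder = "character",
    ageRange = "numeric", ageEffect = "numeric", missingRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSamples < 1L || object@nSnps < 1L)
    msg <- c(msg, "nSamples and nSnps must be positive")
  if (object@ldBlockSize < 1L)
    msg <- c(msg, "ldBlockSize must be positive")
  if (object@withinBlockR < 0 || object@withinBlockR >= 1)
    msg <- c(msg, "withinBlockR must lie in [0, 1)")
  if (length(object@mafRange) != 2L || object@mafRange[1] > object@mafRange[2] ||
      object@mafRange[1] <= 0 || object@mafRange[2] > 0.5)
    msg <- c(msg, "mafRange must be an interval within (0, 0.5]")
  if (object@nCausal < 0L || object@nCausal > object@nSnps)
    msg <- c(msg, "nCausal must lie in [0, nSnps]")
  if (object@heritability < 0 || object@heritability >= 1)
    msg <- c(msg, "heritability must lie in [0, 1)")
  if (!object@effectDistribution %in% c("fixed", "gaussian"))
    msg <- c(msg, "effectDistribution must be 'fixed' or 'gaussian'")
  pr <- object@categoryProportions
  if (length(pr) != 5L || any(pr < 0) || abs(sum(pr) - 1) > 1e-12)
    msg <- c(msg, "categoryProportions must be 5 nonnegative values summing to 1")
  if (!setequal(object@categoryOrder, CATEGORY_LEVELS) ||
      length(object@categoryOrder) != 5L)
    msg <- c(msg, "categoryOrder must be a permutation of the five categories")
  if (length(object@ageRange) != 2L || object@ageRange[1] > object@ageRange[2])
    msg <- c(msg, "ageRange must be an increasing interval")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' SimulatedCohort: genotypes, truth and phenotype table of one simulation
#'
#' @slot genotypes a [GenotypeMatrix-class].
#' @slot truth per-SNP `data.frame` (`snp_id`, `is_causal`, `effect`): the
#'   liability-scale effect of each SNP (0 for non-causal SNPs).
#' @slot cohortTable per-sample `data.frame` (`sample_id`, `category`, `age`,
#'   `sex`), in sample order.
#' @slot liability per-sample latent liability.
#' @slot config the generating [SimulationConfig-class].
#' @export
setClass("SimulatedCohort",
  representation(
    genotypes = "GenotypeMatrix", truth = "data.frame",
    cohortTable = "data.frame", liability = "numeric",
    config = "SimulationConfig"
  )
)

setValidity("SimulatedCohort", function(object) {
  msg <- character()
  if (sum(object@truth$is_causal) != object@config@nCausal)
    msg <- c(msg, "truth must mark exactly nCausal causal SNPs")
  if (!all(object@cohortTable$category %in% CATEGORY_LEVELS))
    msg <- c(msg, "every sample must carry one of the five categories")
  if (nrow(object@cohortTable) != length(object@liability))
    msg <- c(msg, "cohort table and liability lengths differ")
  if (length(msg)) msg else TRUE
})

#' QCThresholds: variant-filter thresholds
#'
#' All removals are strict: a variant is removed when its call rate is
#' *below* `minCallRate`, its Hardy-Weinberg exact-test p-value is *below*
#' `hwePMin`, or its minor allele frequency is *below* `mafMin`; boundary
#' values survive.
#'
#' @slot minCallRate minimum fraction of non-missing genotypes (default 0.95).
#' @slot hwePMin minimum Hardy-Weinberg exact p-value (default 1e-4).
#' @slot mafMin minimum minor allele frequency (default 0.001).
#' @export
setClass("QCThresholds",
  representation(minCallRate = "numeric", hwePMin = "numeric",
                 mafMin = "numeric")
)

setValidity("QCThresholds", function(object) {
  v <- c(object@minCallRate, object@hwePMin, object@mafMin)
  if (length(v) != 3L || any(v < 0) || any(v > 1))
    "all thresholds must lie in [0, 1]" else TRUE
})

#' @describeIn QCThresholds-class Constructor with the standard defaults.
#' @param minCallRate,hwePMin,mafMin see slot documentation.
#' @export
qcThresholds <- function(minCallRate = 0.95, hwePMin = 1e-4, mafMin = 0.001) {
  new("QCThresholds", minCallRate = minCallRate, hwePMin = hwePMin,
      mafMin = mafMin)
}

#' QCReport: auditable record of the variant-filter cascade
#'
#' The filters are applied in a fixed order (multi-allelic, call rate,
#' Hardy-Weinberg, minor allele frequency) and each removed variant is
#' attributed to the first filter it fails; the counts reconcile:
#' `nInput = nPass + sum(removals)`.
#'
#' @slot table per-variant `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `status` (`pass`/`fail`), `fail_reason` (`multiallelic`, `callrate`,
#'   `hwe`, `maf` or `NA`), `call_rate`, `maf`, `hwe_p`.
#' @slot nInput,nRemovedMultiallelic,nRemovedCallrate,nRemovedHwe,nRemovedMaf,nPass
#'   integer tallies.
#' @slot thresholds the [QCThresholds-class] used.
#' @export
setClass("QCReport",
  representation(
    table = "data.frame", nInput = "integer",
    nRemovedMultiallelic = "integer", nRemovedCallrate = "integer",
    nRemovedHwe = "integer", nRemovedMaf = "integer", nPass = "integer",
    thresholds = "QCThresholds"
  )
)

setValidity("QCReport", function(object) {
  removed <- object@nRemovedMultiallelic + object@nRemovedCallrate +
    object@nRemovedHwe + object@nRemovedMaf
  if (object@nInput != object@nPass + removed)
    return("nInput must equal nPass + total removals")
  if (nrow(object@table) != object@nInput)
    return("per-variant table must have nInput rows")
  TRUE
})

#' BinaryPhenotype: binarised response with covariates
#'
#' One of the two case/rest contrasts of the five-category cohort after
#' removal of the control group: under the `severe` contrast severe samples
#' are coded 1 and resistant/benign/mild 0; under the `resistant` contrast
#' resistant samples are coded 1 and benign/mild/severe 0. Controls never
#' enter either analysis. Sex is coded 0/1 (reference level configurable at
#' encoding).
#'
#' @slot y integer 0/1 response vector.
#' @slot sampleIDs retained sample ids, in input order.
#' @slot age,sexCode numeric covariates aligned with `y`.
#' @slot contrast `"severe"` or `"resistant"`.
#' @export
setClass("BinaryPhenotype",
  representation(y = "integer", sampleIDs = "character", age = "numeric",
                 sexCode = "numeric", contrast = "character")
)

setValidity("BinaryPhenotype", function(object) {
  msg <- character()
  n <- length(object@y)
  if (!all(object@y %in% c(0L, 1L)))
    msg <- c(msg, "y must be 0/1")
  if (length(object@sampleIDs) != n || length(object@age) != n ||
      length(object@sexCode) != n)
    msg <- c(msg, "sampleIDs, age and sexCode must align with y")
  if (n > 0L && (sum(object@y) == 0L || sum(object@y) == n))
    msg <- c(msg, "both response classes must be non-empty")
  if (!object@contrast %in% c("severe", "resistant"))
    msg <- c(msg, "contrast must be 'severe' or 'resistant'")
  if (length(msg)) msg else TRUE
})

#' MixedModelSpec: fixed variance components of the all-SNP model
#'
#' The model treats the variance components as known: the phenotypic variance
#' \eqn{\sigma_y^2} is estimated from the response and split into a genetic
#' share (default 0.3) and a residual share (default 0.7), giving
#' \eqn{\sigma_g^2}, \eqn{\sigma_\epsilon^2} and the ridge parameter
#' \eqn{\lambda = \sigma_\epsilon^2 / \sigma_g^2}. In `literal` mode the
#' full genetic share is assigned to each SNP effect
#' (\eqn{\sigma_g^2 = 0.3\,\sigma_y^2}); in `scaled` mode the share is divided
#' by \eqn{2\sum_j p_j(1-p_j)} as is conventional for whole-genome SNP-BLUP.
#'
#' @slot geneticShare,residualShare shares of \eqn{\sigma_y^2}, summing to 1.
#' @slot sigmaY2,sigmaG2,sigmaE2 variances.
#' @slot lambda ridge parameter \eqn{\sigma_\epsilon^2/\sigma_g^2}.
#' @slot varianceMode `"literal"` or `"scaled"`.
#' @export
setClass("MixedModelSpec",
  representation(geneticShare = "numeric", residualShare = "numeric",
                 sigmaY2 = "numeric", sigmaG2 = "numeric", sigmaE2 = "numeric",
                 lambda = "numeric", varianceMode = "character")
)

setValidity("MixedModelSpec", function(object) {
  msg <- character()
  if (abs(object@geneticShare + object@residualShare - 1) > 1e-12)
    msg <- c(msg, "variance shares must sum to 1")
  if (object@sigmaY2 <= 0 || object@sigmaG2 <= 0 || object@sigmaE2 <= 0)
    msg <- c(msg, "all variances must be positive")
  if (abs(object@lambda - object@sigmaE2 / object@sigmaG2) >
      1e-12 * max(1, object@lambda))
    msg <- c(msg, "lambda must equal sigmaE2/sigmaG2")
  if (!object@varianceMode %in% c("literal", "scaled"))
    msg <- c(msg, "varianceMode must be 'literal' or 'scaled'")
  if (length(msg)) msg else TRUE
})

#' MMESystem: assembled mixed-model equations
#'
#' Henderson's equations for \eqn{y = X\beta + Zg + \epsilon} with
#' \eqn{g \sim N(0, I\sigma_g^2)} and \eqn{\epsilon \sim N(0, I\sigma_\epsilon^2)}:
#' \deqn{\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda I \end{pmatrix}
#'       \begin{pmatrix} \hat\beta \\ \hat g \end{pmatrix} =
#'       \begin{pmatrix} X'y \\ Z'y \end{pmatrix}}
#' The system is stored through its components (`X`, `Z`, `y`, `lambda`); the
#' dense coefficient matrix can be materialised with
#' [mmeCoefficientMatrix()].
#'
#' @slot X fixed-effects design (intercept, age, sex code), full column rank.
#' @slot Z samples x SNPs genotype design with complete 0/1/2 (or imputed)
#'   dosages.
#' @slot y response vector.
#' @slot lambda ridge parameter applied to the SNP block only.
#' @slot fixedNames,snpIDs coefficient labels.
#' @export
setClass("MMESystem",
  representation(X = "matrix", Z = "matrix", y = "numeric", lambda = "numeric",
                 fixedNames = "character", snpIDs = "character")
)

setValidity("MMESystem", function(object) {
  msg <- character()
  n <- length(object@y)
  if (nrow(object@X) != n || nrow(object@Z) != n)
    msg <- c(msg, "X, Z and y must have conformable sample dimension")
  if (anyNA(object@Z))
    msg <- c(msg, "Z must be complete (impute missing genotypes first)")
  if (object@lambda <= 0)
    msg <- c(msg, "lambda must be positive")
  if (length(object@fixedNames) != ncol(object@X) ||
      length(object@snpIDs) != ncol(object@Z))
    msg <- c(msg, "coefficient labels must match design dimensions")
  if (length(msg)) msg else TRUE
})

#' ModelFit: solved effects of the mixed-model equations
#'
#' @slot betaHat named fixed-effect estimates.
#' @slot gHat named per-SNP effect estimates (BLUPs).
#' @slot solver `"direct"` or `"pcg"`.
#' @slot iterations iteration count (0 for the direct solver).
#' @slot relResidual achieved relative residual of the normal equations.
#' @export
setClass("ModelFit",
  representation(betaHat = "numeric", gHat = "numeric", solver = "character",
                 iterations = "integer", relResidual = "numeric")
)

#' AssociationResult: per-SNP Wald tests of the all-SNP model
#'
#' For each SNP the Wald statistic \eqn{W_i = \hat g_i / \sigma_g} is referred
#' to the standard normal; Bonferroni control compares each two-sided p-value
#' with `alpha / mTests`. `significant` is strict: `p < threshold`.
#'
#' @slot table `data.frame` (`snp_id`, `chrom`, `pos`, `ref`, `alt`, `g_hat`,
#'   `W`, `p`, `significant`), ordered by (chrom, pos).
#' @slot mTests number of tests used for the correction.
#' @slot alpha family-wise error level (default 0.05).
#' @slot threshold `alpha / mTests`.
#' @export
setClass("AssociationResult",
  representation(table = "data.frame", mTests = "integer", alpha = "numeric",
                 threshold = "numeric")
)

setValidity("AssociationResult", function(object) {
  msg <- character()
  tb <- object@table
  need <- c("snp_id", "chrom", "pos", "g_hat", "W", "p", "significant")
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste0("table must have columns: ",
                         paste(need, collapse = ", ")))
  else {
    if (nrow(tb) && (min(tb$p) <= 0 || max(tb$p) > 1))
      msg <- c(msg, "p-values must lie in (0, 1]")
    if (nrow(tb) && !identical(tb$significant, tb$p < object@threshold))
      msg <- c(msg, "significant flag must equal p < threshold")
  }
  if (object@mTests < 1L)
    msg <- c(msg, "mTests must be at least 1")
  if (abs(object@threshold - object@alpha / object@mTests) > 1e-15)
    msg <- c(msg, "threshold must equal alpha/mTests")
  if (length(msg)) msg else TRUE
})

#' SingleSnpResult: covariate-adjusted one-SNP-at-a-time scan
#'
#' Ordinary least squares of the binarised response on (intercept, age, sex,
#' dosage) per SNP; the dosage coefficient is tested two-sided against a
#' t distribution with `n - 4` degrees of freedom. SNPs collinear with the
#' covariates (including monomorphic SNPs) are flagged `degenerate` and
#' assigned p = 1.
#'
#' @slot table `data.frame` (`snp_id`, `chrom`, `pos`, `ref`, `alt`, `beta`,
#'   `se`, `t`, `p`, `degenerate`, `significant`).
#' @slot mTests,alpha,threshold Bonferroni bookkeeping as in
#'   [AssociationResult-class].
#' @export
setClass("SingleSnpResult",
  representation(table = "data.frame", mTests = "integer", alpha = "numeric",
                 threshold = "numeric")
)

#' ConsequenceSummary: two-level functional-class tally of significant SNPs
#'
#' Class percentages are computed over all significant *annotated* SNPs;
#' coding-subclass percentages over coding SNPs only. Percentages at each
#' level sum to 100 (within numerical tolerance) whenever the level is
#' non-empty.
#'
#' @slot classTable `data.frame` (`consequence_class`, `n`, `pct`).
#' @slot codingTable `data.frame` (`coding_subclass`, `n`, `pct`).
#' @slot nSignificant,nAnnotated,nUnannotated integer tallies.
#' @export
setClass("ConsequenceSummary",
  representation(classTable = "data.frame", codingTable = "data.frame",
                 nSignificant = "integer", nAnnotated = "integer",
                 nUnannotated = "integer")
)
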