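#' Per-SNP call rate
#'
#' Fraction of samples with a non-missing genotype.
#'
#' @param x a numeric dosage vector for one SNP, or a
#'   [GenotypeMatrix-class] (one value per SNP).
#' @return Fraction in \eqn{[0, 1]}.
#' @export
setGeneric("callRate", function(x) standardGeneric("callRate"))

#' @rdname callRate
#' @export
setMethod("callRate", "numeric", function(x) {
  if (!length(x)) stop("call rate of an empty genotype column is undefined")
  mean(!is.na(x))
})

#' @rdname callRate
#' @export
setMethod("callRate", "GenotypeMatrix", function(x) {
  d <- dosages(x)
  if (!ncol(d)) return(numeric(0))
  stats::setNames(colMeans(!is.na(d)), variants(x)$id)
})

#' Minor allele frequency
#'
#' The alternate-allele frequency is computed over observed alleles (two per
#' non-missing genotype); the MAF is the smaller of the two allele
#' frequencies.
#'
#' @param x a numeric dosage vector for one SNP, or a
#'   [GenotypeMatrix-class] (one value per SNP).
#' @return Frequency in \eqn{[0, 0.5]}.
#' @export
setGeneric("maf", function(x) standardGeneric("maf"))

#' @rdname maf
#' @export
setMethod("maf", "numeric", function(x) {
  obs <- x[!is.na(x)]
  if (!length(obs)) stop("MAF is undefined when all genotypes are missing")
  p <- sum(obs) / (2 * length(obs))
  min(p, 1 - p)
})

#' @rdname maf
#' @export
setMethod("maf", "GenotypeMatrix", function(x) {
  d <- dosages(x)
  nObs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nObs)
  stats::setNames(pmin(p, 1 - p), variants(x)$id)
})

altFreq <- function(d) {
  nObs <- colSums(!is.na(d))
  colSums(d, na.rm = TRUE) / (2 * nObs)
}

#' Apply the four-filter variant QC cascade
#'
#' Filters are applied in a fixed order — multi-allelic records, call rate,
#' Hardy-Weinberg exact test, minor allele frequency — and a variant removed
#' at one stage is attributed to that stage only (first-failing reason).
#' Removal is strict: `call_rate < minCallRate`, `hwe_p < hwePMin`,
#' `maf < mafMin`; variants sitting exactly on a threshold survive. The
#' Hardy-Weinberg test is computed on all retained samples jointly by
#' default; pass `hweSampleIDs` to restrict it (e.g. to controls only).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param thresholds a [QCThresholds-class] (defaults: call rate 0.95,
#'   HWE p 1e-4, MAF 0.001).
#' @param hweSampleIDs optional character vector of sample ids on which to
#'   compute the Hardy-Weinberg test.
#' @param hweMidp logical; use the mid-p Hardy-Weinberg variant.
#' @return A list with elements `genotypes` (the filtered
#'   [GenotypeMatrix-class]) and `report` (a [QCReport-class]).
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 100, nSnps = 50,
#'                                           seed = 3))
#' qc <- applyQC(genotypes(cohort), qcThresholds())
#' qc$report
#' @export
applyQC <- function(gm, thresholds = qcThresholds(), hweSampleIDs = NULL,
                    hweMidp = FALSE) {
  validObject(thresholds)
  d <- dosages(gm)
  v <- variants(gm)
  p <- ncol(d)

  cr <- if (p) colMeans(!is.na(d)) else numeric(0)
  mafv <- {
    nObs <- colSums(!is.na(d))
    af <- colSums(d, na.rm = TRUE) / (2 * nObs)
    pmin(af, 1 - af)  # NaN when a column is entirely missing
  }
  dh <- d
  if (!is.null(hweSampleIDs)) {
    keep <- sampleIDs(gm) %in% hweSampleIDs
    if (!any(keep))
      stop("none of hweSampleIDs are present in the genotype matrix")
    dh <- d[keep, , drop = FALSE]
  }
  # genotype counts on integer dosages; fractional (imputed) entries would be
  # a user error here and are counted as their rounded genotype
  nAA <- colSums(dh == 0, na.rm = TRUE)
  nAa <- colSums(dh == 1, na.rm = TRUE)
  naa <- colSums(dh == 2, na.rm = TRUE)
  hwe <- rep(NA_real_, p)
  tested <- (nAA + nAa + naa) > 0
  hwe[tested] <- hweExactP(nAA[tested], nAa[tested], naa[tested],
                           midp = hweMidp)

  failsStrict <- function(value, threshold) !is.na(value) & value < threshold
  reason <- rep(NA_character_, p)
  reason[v$multiallelic] <- "multiallelic"
  idx <- is.na(reason) & failsStrict(cr, thresholds@minCallRate)
  reason[idx] <- "callrate"
  idx <- is.na(reason) & failsStrict(hwe, thresholds@hwePMin)
  reason[idx] <- "hwe"
  idx <- is.na(reason) & failsStrict(mafv, thresholds@mafMin)
  reason[idx] <- "maf"

  pass <- is.na(reason)
  tab <- data.frame(
    snp_id = v$id, chrom = v$chrom, pos = v$pos,
    status = ifelse(pass, "pass", "fail"),
    fail_reason = reason,
    call_rate = cr, maf = ifelse(is.nan(mafv), NA_real_, mafv), hwe_p = hwe,
    stringsAsFactors = FALSE
  )
  report <- new("QCReport", table = tab, nInput = p,
                nRemovedMultiallelic = sum(reason == "multiallelic", na.rm = TRUE),
                nRemovedCallrate = sum(reason == "callrate", na.rm = TRUE),
                nRemovedHwe = sum(reason == "hwe", na.rm = TRUE),
                nRemovedMaf = sum(reason == "maf", na.rm = TRUE),
                nPass = sum(pass), thresholds = thresholds)
  filtered <- GenotypeMatrix(d[, pass, drop = FALSE],
                             v[pass, , drop = FALSE], samples = sampleIDs(gm))
  list(genotypes = filtered, report = report)
}

#' Replace missing genotypes by the SNP's mean observed dosage
#'
#' The all-SNP model requires a complete genotype design; residual
#' missingness after QC is filled with each SNP's mean observed dosage,
#' which leaves the per-SNP mean unchanged. Entries that are observed are
#' never modified.
#'
#' @param gm a [GenotypeMatrix-class] in which every SNP has at least one
#'   observed genotype.
#' @return A complete [GenotypeMatrix-class].
#' @export
imputeMissingMean <- function(gm) {
  d <- dosages(gm)
  if (!anyNA(d)) return(gm)
  nObs <- colSums(!is.na(d))
  if (any(nObs == 0L))
    stop("cannot impute SNPs with no observed genotypes: ",
         paste(utils::head(variants(gm)$id[nObs == 0L], 5), collapse = ", "))
  mu <- colSums(d, na.rm = TRUE) / nObs
  miss <- which(is.na(d), arr.ind = TRUE)
  d[miss] <- mu[miss[, 2]]
  GenotypeMatrix(d, variants(gm), samples = sampleIDs(gm))
}

#' Write a QC report as TSV
#'
#' One row per input variant:
#' `snp_id  chrom  pos  status  fail_reason  call_rate  maf  hwe_p`.
#'
#' @param report a [QCReport-class].
#' @param path output path.
#' @param headerLines optional `##`-prefixed comment lines to prepend.
#' @return Invisibly, `path`.
#' @export
writeQCReport <- function(report, path, headerLines = character()) {
  writeTSV(resultTable(report), path, headerLines)
}

writeTSV <- function(df, path, headerLines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(headerLines))
    writeLines(headerLines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
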