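#' Accessors for blupgwas containers
#'
#' `dosages()` returns the samples x SNPs dosage matrix, `variants()` the
#' per-SNP metadata, `sampleIDs()` the ordered sample identifiers,
#' `resultTable()` the per-SNP table of an association result, and
#' `phenotypeVector()` the 0/1 response of a [BinaryPhenotype-class].
#'
#' @param x a blupgwas object.
#' @return The slot contents, never the raw slot (use these rather than `@`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname accessors
#' @export
setMethod("dosages", "SimulatedCohort", function(x) x@genotypes@dosages)

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname accessors
#' @export
setMethod("variants", "GenotypeMatrix", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("variants", "SimulatedCohort", function(x) x@genotypes@variants)

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "GenotypeMatrix", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "BinaryPhenotype", function(x) x@sampleIDs)

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setMethod("resultTable", "AssociationResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("resultTable", "SingleSnpResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("resultTable", "QCReport", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("phenotypeVector", function(x) standardGeneric("phenotypeVector"))

#' @rdname accessors
#' @export
setMethod("phenotypeVector", "BinaryPhenotype", function(x) x@y)

#' Genotypes of a simulated cohort
#' @param x a [SimulatedCohort-class].
#' @return The embedded [GenotypeMatrix-class].
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname genotypes
#' @export
setMethod("genotypes", "SimulatedCohort", function(x) x@genotypes)

#' Cohort phenotype table of a simulated cohort
#' @param x a [SimulatedCohort-class].
#' @return `data.frame` (`sample_id`, `category`, `age`, `sex`).
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))

#' @rdname cohortTable
#' @export
setMethod("cohortTable", "SimulatedCohort", function(x) x@cohortTable)

#' Per-SNP simulation truth
#' @param x a [SimulatedCohort-class].
#' @return `data.frame` (`snp_id`, `is_causal`, `effect`).
#' @export
setGeneric("simulationTruth", function(x) standardGeneric("simulationTruth"))

#' @rdname simulationTruth
#' @export
setMethod("simulationTruth", "SimulatedCohort", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosages))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dim(object@dosages)
  cat(sprintf("GenotypeMatrix: %d samples x %d SNPs\n", d[1], d[2]))
  nMiss <- sum(is.na(object@dosages))
  cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nMiss,
              if (prod(d) > 0) 100 * nMiss / prod(d) else 0))
  if (d[2] > 0)
    cat("  chromosomes:", paste(unique(object@variants$chrom)[1:min(8, d[2])],
                                collapse = ", "),
        if (length(unique(object@variants$chrom)) > 8) "..." else "", "\n")
})

setMethod("show", "SimulatedCohort", function(object) {
  cat(sprintf("SimulatedCohort: %d samples x %d SNPs, %d causal\n",
              nrow(object@cohortTable), nrow(object@truth),
              sum(object@truth$is_causal)))
  print(table(factor(object@cohortTable$category, levels = CATEGORY_LEVELS)))
})

setMethod("show", "QCReport", function(object) {
  cat("QC report\n")
  cat(sprintf("  input variants:        %d\n", object@nInput))
  cat(sprintf("  removed multi-allelic: %d\n", object@nRemovedMultiallelic))
  cat(sprintf("  removed call rate:     %d (< %.4g)\n",
              object@nRemovedCallrate, object@thresholds@minCallRate))
  cat(sprintf("  removed HWE:           %d (p < %.4g)\n",
              object@nRemovedHwe, object@thresholds@hwePMin))
  cat(sprintf("  removed MAF:           %d (< %.4g)\n",
              object@nRemovedMaf, object@thresholds@mafMin))
  cat(sprintf("  passing:               %d\n", object@nPass))
})

setMethod("show", "BinaryPhenotype", function(object) {
  cat(sprintf("BinaryPhenotype (contrast = %s): %d samples, %d cases, %d non-cases\n",
              object@contrast, length(object@y), sum(object@y),
              sum(object@y == 0L)))
})

setMethod("show", "MixedModelSpec", function(object) {
  cat(sprintf("MixedModelSpec (%s mode)\n", object@varianceMode))
  cat(sprintf("  sigma_y^2 = %.6g\n", object@sigmaY2))
  cat(sprintf("  sigma_g^2 = %.6g (share %.2f)\n", object@sigmaG2,
              object@geneticShare))
  cat(sprintf("  sigma_e^2 = %.6g (share %.2f)\n", object@sigmaE2,
              object@residualShare))
  cat(sprintf("  lambda    = %.6g\n", object@lambda))
})

setMethod("show", "MMESystem", function(object) {
  cat(sprintf("MMESystem: n = %d, fixed effects = %d, SNPs = %d, lambda = %.6g\n",
              length(object@y), ncol(object@X), ncol(object@Z), object@lambda))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit (%s solver): %d fixed effects, %d SNP effects\n",
              object@solver, length(object@betaHat), length(object@gHat)))
  cat(sprintf("  iterations = %d, relative residual = %.3g\n",
              object@iterations, object@relResidual))
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult: %d SNPs tested\n", object@mTests))
  cat(sprintf("  Bonferroni: alpha = %g, threshold = %.4g, significant = %d\n",
              object@alpha, object@threshold, sum(object@table$significant)))
})

setMethod("show", "SingleSnpResult", function(object) {
  cat(sprintf("SingleSnpResult: %d SNPs tested (%d degenerate)\n",
              object@mTests, sum(object@table$degenerate)))
  cat(sprintf("  Bonferroni: alpha = %g, threshold = %.4g, significant = %d\n",
              object@alpha, object@threshold, sum(object@table$significant)))
})

setMethod("show", "ConsequenceSummary", function(object) {
  cat(sprintf("ConsequenceSummary: %d significant SNPs (%d annotated, %d unannotated)\n",
              object@nSignificant, object@nAnnotated, object@nUnannotated))
  if (nrow(object@classTable)) {
    tb <- object@classTable
    cat(paste(sprintf("  %-11s %6d  %6.2f%%", tb$consequence_class, tb$n,
                      tb$pct), collapse = "\n"), "\n")
  }
  if (nrow(object@codingTable)) {
    cat("  among coding:\n")
    tb <- object@codingTable
    cat(paste(sprintf("    %-11s %6d  %6.2f%%", tb$coding_subclass, tb$n,
                      tb$pct), collapse = "\n"), "\n")
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d samples x %d SNPs (LD blocks of %d, r = %.2f)\n",
              object@nSamples, object@nSnps, object@ldBlockSize,
              object@withinBlockR))
  cat(sprintf("  MAF in [%.3g, %.3g]; %d causal SNPs, heritability %.2f, seed %d\n",
              object@mafRange[1], object@mafRange[2], object@nCausal,
              object@heritability, object@seed))
  cat("  category proportions:",
      paste(sprintf("%s=%.3f", object@categoryOrder,
                    object@categoryProportions), collapse = ", "), "\n")
})
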