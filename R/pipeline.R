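#' Build a pipeline run configuration
#'
#' A flat, YAML-serialisable set of every knob of the pipeline: input paths,
#' QC thresholds, contrast, variance mode, test level, solver settings and
#' the seed, plus the synthetic-cohort parameters used by the `simulate`
#' stage. Every field has a default and the object round-trips losslessly
#' through [writeRunConfig()] / [readRunConfig()].
#'
#' @param vcf,pheno,annotation input paths (`annotation` optional).
#' @param outDir output directory for [runPipeline()].
#' @param contrast `"severe"` or `"resistant"`.
#' @param mode association modes to run: subset of `c("multi", "single")`.
#' @param varianceMode `"literal"` or `"scaled"`.
#' @param alpha family-wise error level.
#' @param solver,tol solver settings (see [solveMME()]).
#' @param minCallRate,hwePMin,mafMin QC thresholds (see
#'   [QCThresholds-class]).
#' @param seed integer seed recorded in the run (and used by `simulate`).
#' @param sim named list overriding [simulationConfig()] defaults for the
#'   `simulate` stage.
#' @return A named list of class `RunConfig`.
#' @export
runConfig <- function(vcf = NULL, pheno = NULL, annotation = NULL,
                      outDir = "blupgwas_run",
                      contrast = "severe", mode = c("multi", "single"),
                      varianceMode = "literal", alpha = 0.05,
                      solver = "auto", tol = 1e-8,
                      minCallRate = 0.95, hwePMin = 1e-4, mafMin = 0.001,
                      seed = 1L, sim = list()) {
  cfg <- list(vcf = vcf, pheno = pheno, annotation = annotation,
              outDir = outDir, contrast = contrast, mode = mode,
              varianceMode = varianceMode, alpha = alpha, solver = solver,
              tol = tol, minCallRate = minCallRate, hwePMin = hwePMin,
              mafMin = mafMin, seed = as.integer(seed), sim = sim)
  class(cfg) <- "RunConfig"
  cfg
}

#' @describeIn runConfig Serialise a configuration to YAML.
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @describeIn runConfig Read a YAML configuration, filling defaults.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, raw)
}

configHeaderLines <- function(config) {
  c(sprintf("## blupgwas %s",
            as.character(utils::packageVersion("blupgwas"))),
    paste0("## ", strsplit(yaml::as.yaml(unclass(config)), "\n")[[1]]))
}

runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full association pipeline
#'
#' Composes the stages QC, phenotype encoding, association (all-SNP mixed
#' model and/or single-SNP baseline), model comparison and, when an
#' annotation table is supplied, consequence summarisation. All outputs are
#' written under `config$outDir` with the configuration echoed verbatim as
#' `##` header lines, plus a JSON manifest with input checksums and
#' per-stage row counts. Identical configuration and inputs produce
#' byte-identical association tables; only the manifest carries a
#' timestamp. Any stage failure aborts with the stage name and cause.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return Invisibly, a list with the written `paths`, per-stage `counts`
#'   and the in-memory stage results.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  for (f in c("vcf", "pheno")) {
    if (is.null(config[[f]]))
      stop("config field '", f, "' is required")
    if (!file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ", config[[f]])
  }
  if (!is.null(config$annotation) && !file.exists(config$annotation))
    stop("annotation file not found: ", config$annotation)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- configHeaderLines(config)
  paths <- list()
  counts <- list()

  gm <- runStage("read_vcf", readVCF(config$vcf))
  counts$n_snps_input <- ncol(dosages(gm))
  counts$n_samples_vcf <- length(sampleIDs(gm))

  qc <- runStage("qc", applyQC(gm, qcThresholds(config$minCallRate,
                                                config$hwePMin,
                                                config$mafMin)))
  paths$qc_report <- file.path(config$outDir, "qc_report.tsv")
  writeQCReport(qc$report, paths$qc_report, hdr)
  counts$n_snps_pass_qc <- qc$report@nPass

  pheno <- runStage("encode", {
    cohort <- readCohortTable(config$pheno)
    encodePhenotype(cohort, config$contrast)
  })
  paths$phenotype <- file.path(config$outDir, "phenotype_encoded.tsv")
  writePhenotype(pheno, paths$phenotype, hdr)
  counts$n_samples_encoded <- length(pheno@y)
  counts$n_cases <- sum(pheno@y)

  multi <- single <- NULL
  if ("multi" %in% config$mode) {
    multi <- runStage("assoc_multi",
      multiSnpGWAS(qc$genotypes, pheno, varianceMode = config$varianceMode,
                   alpha = config$alpha, solver = config$solver,
                   tol = config$tol))
    paths$assoc_multi <- file.path(config$outDir, "assoc_multi.tsv")
    writeAssociation(multi$result, paths$assoc_multi, hdr)
    counts$n_snps_tested_multi <- multi$result@mTests
    counts$n_significant_multi <- sum(resultTable(multi$result)$significant)
  }
  if ("single" %in% config$mode) {
    single <- runStage("assoc_single",
      singleSnpScan(qc$genotypes, pheno, alpha = config$alpha))
    paths$assoc_single <- file.path(config$outDir, "assoc_single.tsv")
    writeAssociation(single, paths$assoc_single, hdr)
    counts$n_snps_tested_single <- single@mTests
    counts$n_significant_single <- sum(resultTable(single)$significant)
  }
  comparison <- NULL
  if (!is.null(multi) && !is.null(single)) {
    comparison <- runStage("compare", compareModels(multi$result, single))
    paths$comparison <- file.path(config$outDir, "comparison.tsv")
    writeTSV(comparison$table, paths$comparison, hdr)
    paths$comparison_summary <- file.path(config$outDir,
                                          "comparison_summary.tsv")
    writeTSV(comparison$summary, paths$comparison_summary, hdr)
  }
  summaryObj <- NULL
  if (!is.null(config$annotation)) {
    result <- if (!is.null(multi)) multi$result else single
    ann <- runStage("summarize", readAnnotation(config$annotation))
    summaryObj <- runStage("summarize",
                           suppressWarnings(consequenceSummary(result, ann)))
    paths$consequence_summary <- writeConsequenceSummary(
      summaryObj, file.path(config$outDir, "consequence_summary"))
    paths$gene_hits <- file.path(config$outDir, "gene_hits.tsv")
    writeTSV(geneHitList(result, ann), paths$gene_hits, hdr)
    paths$manhattan <- file.path(config$outDir, "manhattan.tsv")
    writeTSV(manhattanExport(result, ann), paths$manhattan, hdr)
  }

  manifest <- list(
    package = "blupgwas",
    version = as.character(utils::packageVersion("blupgwas")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(
      Filter(Negate(is.null),
             config[c("vcf", "pheno", "annotation")])))),
    counts = counts
  )
  paths$manifest <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(paths = paths, counts = counts, qc = qc, phenotype = pheno,
                 multi = multi, single = single, comparison = comparison,
                 consequence = summaryObj))
}
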