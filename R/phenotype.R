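#' Read a cohort phenotype table
#'
#' Expects a TSV with header `sample_id  category  age  sex`, categories in
#' `{control, resistant, benign, mild, severe}` and sex in `{M, F}`.
#'
#' @param path path to the TSV.
#' @return A validated `data.frame`.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path))
    stop("phenotype table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "category", "age", "sex")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  validateCohortTable(df)
  df
}

validateCohortTable <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample ids in the cohort table")
  bad <- setdiff(unique(df$category), CATEGORY_LEVELS)
  if (length(bad))
    stop("unknown category literal(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(CATEGORY_LEVELS, collapse = "|"), ")")
  badSex <- setdiff(unique(df$sex[!is.na(df$sex)]), c("M", "F"))
  if (length(badSex))
    stop("unknown sex literal(s): ", paste(badSex, collapse = ", "),
         " (expected M|F)")
  invisible(df)
}

#' Encode the five-category cohort into a binary phenotype
#'
#' Builds the response vector of one of the two analyses. Under
#' `contrast = "resistant"` the resistant group is coded 1, the control group
#' is removed, and all other groups are coded 0; under `contrast = "severe"`
#' the severe group is coded 1, the control group is removed, and all other
#' groups are coded 0. Sample order is preserved. Sex is coded 0 for the
#' reference level (`M` by default) and 1 otherwise; flipping the reference
#' only changes the sign of the fitted sex effect.
#'
#' Missing age or sex raises an error unless `imputeCovariates = TRUE`, in
#' which case age is mean-imputed and sex is set to the majority level.
#'
#' @param cohort a cohort `data.frame` as returned by [readCohortTable()] or
#'   [cohortTable()], or a [SimulatedCohort-class].
#' @param contrast `"severe"` or `"resistant"`.
#' @param sexReference the sex level coded 0 (default `"M"`).
#' @param imputeCovariates impute missing age/sex instead of failing.
#' @return A [BinaryPhenotype-class].
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 300, nSnps = 20,
#'                                           seed = 11))
#' ph <- encodePhenotype(cohort, "severe")
#' sum(phenotypeVector(ph))
#' @export
encodePhenotype <- function(cohort, contrast = c("severe", "resistant"),
                            sexReference = "M", imputeCovariates = FALSE) {
  contrast <- match.arg(contrast)
  if (is(cohort, "SimulatedCohort"))
    cohort <- cohortTable(cohort)
  if (!nrow(cohort))
    stop("cohort table is empty")
  validateCohortTable(cohort)
  stopifnot(sexReference %in% c("M", "F"))

  kept <- cohort[cohort$category != "control", , drop = FALSE]
  if (!nrow(kept))
    stop("degenerate phenotype: no samples remain after removing controls")
  y <- as.integer(kept$category == contrast)
  if (sum(y) == 0L || sum(y) == length(y))
    stop("degenerate phenotype: response is constant under the ", contrast,
         " contrast")

  age <- as.numeric(kept$age)
  sex <- kept$sex
  if (anyNA(age) || anyNA(sex)) {
    if (!imputeCovariates)
      stop("missing age or sex; set imputeCovariates = TRUE to impute")
    age[is.na(age)] <- mean(age, na.rm = TRUE)
    sexTab <- table(sex[!is.na(sex)])
    sex[is.na(sex)] <- names(sexTab)[which.max(sexTab)]
  }
  sexCode <- as.numeric(sex != sexReference)
  new("BinaryPhenotype", y = y, sampleIDs = as.character(kept$sample_id),
      age = age, sexCode = sexCode, contrast = contrast)
}

#' Write an encoded phenotype as TSV
#'
#' Columns: `sample_id  y  age  sex_code`.
#'
#' @param pheno a [BinaryPhenotype-class].
#' @param path output path.
#' @param headerLines optional `##`-prefixed comment lines to prepend.
#' @return Invisibly, `path`.
#' @export
writePhenotype <- function(pheno, path, headerLines = character()) {
  df <- data.frame(sample_id = pheno@sampleIDs, y = pheno@y, age = pheno@age,
                   sex_code = pheno@sexCode, stringsAsFactors = FALSE)
  writeTSV(df, path, headerLines)
}

#' Read an encoded phenotype TSV back into a BinaryPhenotype
#'
#' @param path path to a TSV written by [writePhenotype()].
#' @param contrast the contrast label to attach.
#' @return A [BinaryPhenotype-class].
#' @export
readPhenotype <- function(path, contrast = c("severe", "resistant")) {
  contrast <- match.arg(contrast)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "y", "age", "sex_code")
  if (!all(need %in% names(df)))
    stop("encoded phenotype must have columns: ", paste(need, collapse = ", "))
  new("BinaryPhenotype", y = as.integer(df$y),
      sampleIDs = as.character(df$sample_id), age = as.numeric(df$age),
      sexCode = as.numeric(df$sex_code), contrast = contrast)
}
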