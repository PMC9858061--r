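#' Read a variant consequence-annotation table
#'
#' A TSV with columns `snp_id`, `consequence_class` (one of `intron`,
#' `intergenic`, `regulatory`, `coding`, `other`), `coding_subclass`
#' (`synonymous`, `missense`, `other`, or `n/a` for non-coding SNPs),
#' `gene_id`, `gene_name`. The table is consumed, never computed: functional
#' annotation comes from an external annotator. A SNP may appear on several
#' rows when it is annotated to several genes, but its consequence class
#' must be consistent; SNP-level summaries count such SNPs once, per-gene
#' summaries once per gene.
#'
#' @param path path to the TSV.
#' @return A validated `data.frame`.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path))
    stop("annotation table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "", na.strings = "NA")
  validateAnnotation(df)
}

validateAnnotation <- function(df) {
  need <- c("snp_id", "consequence_class", "coding_subclass", "gene_id",
            "gene_name")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$consequence_class), CONSEQUENCE_CLASSES)
  if (length(bad))
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  badSub <- setdiff(unique(df$coding_subclass), CODING_SUBCLASSES)
  if (length(badSub))
    stop("unknown coding subclass(es): ", paste(badSub, collapse = ", "))
  mismatch <- xor(df$consequence_class == "coding",
                  df$coding_subclass != "n/a")
  if (any(mismatch))
    stop("coding_subclass must be 'n/a' exactly for non-coding SNPs (",
         sum(mismatch), " offending rows)")
  if (anyDuplicated(df[, c("snp_id", "gene_id")]))
    stop("duplicated (snp_id, gene_id) rows in the annotation")
  classPerSnp <- tapply(df$consequence_class, df$snp_id,
                        function(x) length(unique(x)))
  if (any(classPerSnp > 1))
    stop("a SNP carries conflicting consequence classes")
  df
}

#' Generate a synthetic annotation table for testing
#'
#' Produces a fixture with configurable class proportions, mirroring the
#' two-level vocabulary expected by [consequenceSummary()]. Intron, coding
#' and regulatory SNPs are assigned to genes laid out as consecutive blocks
#' along each chromosome; intergenic and other SNPs carry no gene. This is a
#' synthetic stand-in for an external functional annotator, intended for
#' tests and examples.
#'
#' @param variantInfo a variant `data.frame` (needs `id`; e.g.
#'   `variants(gm)`).
#' @param classProportions named proportions over the five consequence
#'   classes (need not be normalised).
#' @param codingSubclassProportions named proportions over
#'   `synonymous`/`missense`/`other`.
#' @param snpsPerGene gene size in SNPs (default 25).
#' @param seed integer RNG seed.
#' @return An annotation `data.frame`.
#' @export
simulateAnnotation <- function(variantInfo,
                               classProportions = c(intron = 0.5577,
                                                    intergenic = 0.3655,
                                                    regulatory = 0.0541,
                                                    coding = 0.0177,
                                                    other = 0.005),
                               codingSubclassProportions = c(synonymous = 0.6,
                                                             missense = 0.39,
                                                             other = 0.01),
                               snpsPerGene = 25L, seed = 1L) {
  stopifnot(all(names(classProportions) %in% CONSEQUENCE_CLASSES))
  set.seed(seed)
  n <- nrow(variantInfo)
  cls <- sample(names(classProportions), n, replace = TRUE,
                prob = classProportions)
  sub <- rep("n/a", n)
  coding <- cls == "coding"
  if (any(coding))
    sub[coding] <- sample(names(codingSubclassProportions), sum(coding),
                          replace = TRUE, prob = codingSubclassProportions)
  geneIdx <- ceiling(seq_len(n) / snpsPerGene)
  hasGene <- cls %in% c("intron", "coding", "regulatory")
  data.frame(
    snp_id = variantInfo$id,
    consequence_class = cls,
    coding_subclass = sub,
    gene_id = ifelse(hasGene, sprintf("GENE%04d", geneIdx), NA_character_),
    gene_name = ifelse(hasGene, sprintf("Gene%d", geneIdx), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Two-level consequence-class summary of significant SNPs
#'
#' Restricted to Bonferroni-significant SNPs: consequence-class counts and
#' percentages over all significant annotated SNPs, and coding-subclass
#' counts and percentages over coding SNPs only. Significant SNPs absent
#' from the annotation are tallied as unannotated (and excluded from the
#' percentages). An empty significant set yields an empty summary with a
#' warning rather than an error.
#'
#' @param result an [AssociationResult-class] (or [SingleSnpResult-class]).
#' @param annotation an annotation `data.frame` (see [readAnnotation()]).
#' @return A [ConsequenceSummary-class].
#' @export
consequenceSummary <- function(result, annotation) {
  annotation <- validateAnnotation(annotation)
  tab <- resultTable(result)
  sig <- unique(tab$snp_id[tab$significant])
  if (!length(sig)) {
    warning("no significant SNPs; consequence summary is empty")
    return(new("ConsequenceSummary",
               classTable = data.frame(consequence_class = character(),
                                       n = integer(), pct = numeric()),
               codingTable = data.frame(coding_subclass = character(),
                                        n = integer(), pct = numeric()),
               nSignificant = 0L, nAnnotated = 0L, nUnannotated = 0L))
  }
  # one row per SNP (multi-gene SNPs counted once at this level)
  snpClass <- annotation[!duplicated(annotation$snp_id),
                         c("snp_id", "consequence_class", "coding_subclass")]
  idx <- match(sig, snpClass$snp_id)
  annotated <- !is.na(idx)
  cls <- snpClass$consequence_class[idx[annotated]]
  sub <- snpClass$coding_subclass[idx[annotated]]

  clsCount <- table(factor(cls, levels = CONSEQUENCE_CLASSES))
  clsCount <- clsCount[clsCount > 0]
  classTable <- data.frame(
    consequence_class = names(clsCount),
    n = as.integer(clsCount),
    pct = 100 * as.integer(clsCount) / sum(clsCount),
    stringsAsFactors = FALSE
  )
  subCount <- table(factor(sub[cls == "coding"],
                           levels = setdiff(CODING_SUBCLASSES, "n/a")))
  subCount <- subCount[subCount > 0]
  codingTable <- data.frame(
    coding_subclass = names(subCount),
    n = as.integer(subCount),
    pct = if (length(subCount)) 100 * as.integer(subCount) / sum(subCount)
          else numeric(0),
    stringsAsFactors = FALSE
  )
  new("ConsequenceSummary", classTable = classTable,
      codingTable = codingTable, nSignificant = length(sig),
      nAnnotated = sum(annotated), nUnannotated = sum(!annotated))
}

#' Write a consequence summary as TSV
#'
#' Emits `<prefix>.classes.tsv` and `<prefix>.coding.tsv` with percentages
#' rounded to two decimals, plus a small human-readable `<prefix>.txt`.
#'
#' @param summary a [ConsequenceSummary-class].
#' @param outPrefix output path prefix.
#' @return Invisibly, the written paths.
#' @export
writeConsequenceSummary <- function(summary, outPrefix) {
  cls <- summary@classTable
  sub <- summary@codingTable
  cls$pct <- round(cls$pct, 2)
  sub$pct <- round(sub$pct, 2)
  paths <- c(classes = paste0(outPrefix, ".classes.tsv"),
             coding = paste0(outPrefix, ".coding.tsv"),
             text = paste0(outPrefix, ".txt"))
  writeTSV(cls, paths[["classes"]])
  writeTSV(sub, paths[["coding"]])
  txt <- c(sprintf("significant SNPs: %d (annotated %d, unannotated %d)",
                   summary@nSignificant, summary@nAnnotated,
                   summary@nUnannotated),
           sprintf("  %s: %d (%.2f%%)", cls$consequence_class, cls$n, cls$pct),
           if (nrow(sub)) "  among coding:",
           sprintf("    %s: %d (%.2f%%)", sub$coding_subclass, sub$n, sub$pct))
  writeLines(txt, paths[["text"]])
  invisible(paths)
}

#' Export Manhattan-plot data
#'
#' Per SNP: chromosome, position, a cumulative genome coordinate for
#' plotting (per-chromosome offsets are the running sums of preceding
#' chromosome lengths), -log10 p, the Bonferroni significance flag and,
#' when an annotation is supplied, an `exon` flag marking coding SNPs. Rows
#' are ordered by (chrom, pos).
#'
#' @param result an [AssociationResult-class] or [SingleSnpResult-class].
#' @param annotation optional annotation `data.frame`.
#' @return A `data.frame` ready for plotting.
#' @export
manhattanExport <- function(result, annotation = NULL) {
  tab <- resultTable(result)
  if (!nrow(tab))
    stop("cannot export an empty association result")
  tab <- tab[chromOrder(tab$chrom, tab$pos), , drop = FALSE]
  chromLevels <- unique(tab$chrom)
  chromLen <- vapply(chromLevels,
                     function(ch) max(tab$pos[tab$chrom == ch]), numeric(1))
  offset <- stats::setNames(cumsum(c(0, chromLen[-length(chromLen)])),
                            chromLevels)
  out <- data.frame(
    snp_id = tab$snp_id, chrom = tab$chrom, pos = tab$pos,
    cum_pos = tab$pos + offset[tab$chrom],
    neglog10_p = -log10(tab$p),
    significant = tab$significant,
    stringsAsFactors = FALSE
  )
  if (!is.null(annotation)) {
    annotation <- validateAnnotation(annotation)
    snpClass <- annotation[!duplicated(annotation$snp_id), ]
    out$exon <- snpClass$consequence_class[
      match(out$snp_id, snpClass$snp_id)] == "coding"
    out$exon[is.na(out$exon)] <- FALSE
  }
  rownames(out) <- NULL
  out
}

#' Per-gene table of significant SNPs
#'
#' Joins significant SNPs to their gene annotations and reports, per gene:
#' the number of significant SNPs, the minimum p-value and the consequence
#' classes present, sorted by minimum p. A SNP annotated to several genes
#' contributes to each gene's row.
#'
#' @param result an [AssociationResult-class] or [SingleSnpResult-class].
#' @param annotation an annotation `data.frame` with gene assignments.
#' @return A `data.frame` (`gene_id`, `gene_name`, `n_significant`, `min_p`,
#'   `classes`), possibly empty.
#' @export
geneHitList <- function(result, annotation) {
  annotation <- validateAnnotation(annotation)
  tab <- resultTable(result)
  sig <- tab[tab$significant, c("snp_id", "p"), drop = FALSE]
  ann <- annotation[!is.na(annotation$gene_id), , drop = FALSE]
  hits <- merge(sig, ann, by = "snp_id")
  if (!nrow(hits))
    return(data.frame(gene_id = character(), gene_name = character(),
                      n_significant = integer(), min_p = numeric(),
                      classes = character(), stringsAsFactors = FALSE))
  parts <- split(hits, hits$gene_id)
  out <- do.call(rbind, lapply(parts, function(h) data.frame(
    gene_id = h$gene_id[1],
    gene_name = h$gene_name[1],
    n_significant = length(unique(h$snp_id)),
    min_p = min(h$p),
    classes = paste(sort(unique(h$consequence_class)), collapse = ","),
    stringsAsFactors = FALSE
  )))
  out <- out[order(out$min_p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
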