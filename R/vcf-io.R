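#' Read bi-allelic SNP genotypes from a VCF
#'
#' Parses a VCF v4.2 (plain or bgzipped) with GT fields into a
#' [GenotypeMatrix-class]. Dosage is the count of alternate alleles in the
#' genotype; `./.` and half-calls such as `0/.` are treated as missing;
#' phased separators (`|`) are accepted. Multi-allelic records (ALT with a
#' comma) are carried through with their `multiallelic` flag set — they are
#' not split — and are removed later by [applyQC()]. Sample order is
#' preserved.
#'
#' @param path path to a VCF file.
#' @return A [GenotypeMatrix-class].
#' @export
readVCF <- function(path) {
  if (!file.exists(path))
    stop("VCF file not found: ", path)
  firstLine <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path,
                         n = 1L)
  if (!length(firstLine) || !grepl("^##fileformat=VCF", firstLine))
    stop("parse error at line 1 of ", path,
         ": missing ##fileformat=VCF header")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  nVar <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]
  if (length(samples) == 0L && nVar == 0L) {
    # header-only file: vcfR drops the sample columns, recover them from the
    # #CHROM line
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    hdr <- grep("^#CHROM", readLines(con), value = TRUE)
    if (length(hdr)) {
      fields <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]]
      if (length(fields) > 9L) samples <- fields[-(1:9)]
    }
  }
  if (length(samples) == 0L)
    stop("empty cohort: VCF contains no sample columns")

  if (nVar == 0L) {
    return(GenotypeMatrix(
      matrix(numeric(0), nrow = length(samples), ncol = 0),
      data.frame(chrom = character(), pos = integer(), id = character(),
                 ref = character(), alt = character(),
                 multiallelic = logical(), stringsAsFactors = FALSE),
      samples = samples))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt[is.na(gt)] <- "./."
  dict <- unique(as.vector(gt))
  dictDosage <- vapply(dict, gtToDosage, numeric(1))
  dos <- matrix(dictDosage[match(gt, dict)], nrow = nVar, ncol = length(samples))
  variantsDf <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    ref = fix$REF,
    alt = ifelse(is.na(fix$ALT), ".", fix$ALT),
    multiallelic = grepl(",", fix$ALT),
    stringsAsFactors = FALSE
  )
  GenotypeMatrix(t(dos), variantsDf, samples = samples)
}

# One GT string -> alternate-allele dosage; any "." allele makes it missing.
gtToDosage <- function(gt) {
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)[[1]]
  if (any(alleles == ".") || !length(alleles)) return(NA_real_)
  sum(alleles != "0")
}

#' Write a GenotypeMatrix as a VCF v4.2
#'
#' Writes a GT-only, unphased VCF (one sample column per individual, 1-based
#' positions). Dosages must be integer 0/1/2 or missing; imputed fractional
#' dosages cannot be represented as genotypes and raise an error.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeVCFFile <- function(gm, path) {
  d <- dosages(gm)
  v <- variants(gm)
  dd <- d[!is.na(d)]
  if (length(dd) && any(dd != round(dd)))
    stop("dosages contain fractional (imputed) values; cannot write GT")
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=blupgwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIDs(gm)), collapse = "\t")
  )
  writeLines(header, con)
  if (nrow(v) > 0L) {
    gtCodes <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    obs <- !is.na(d)
    gt[obs] <- gtCodes[d[obs] + 1L]
    lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                   sep = "\t")
    body <- apply(gt, 2, paste, collapse = "\t")
    writeLines(paste(lines, body, sep = "\t"), con)
  }
  invisible(path)
}
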