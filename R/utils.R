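# Sort key for chromosome labels: numeric labels in numeric order first,
# then X/Y/MT and anything else lexicographically after them.
chromKey <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  special <- match(toupper(chrom), c("X", "Y", "MT", "M"))
  key <- ifelse(!is.na(num), num,
                ifelse(!is.na(special), 1e6 + special, 2e6))
  # distinguish unknown non-numeric labels deterministically
  key + ifelse(is.na(num) & is.na(special),
               match(chrom, sort(unique(chrom))) * 1e-3, 0)
}

chromOrder <- function(chrom, pos) {
  order(chromKey(chrom), pos)
}
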