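toyAnnotation <- function(ids, classes, subclasses = NULL, genes = NULL) {
  n <- length(ids)
  if (is.null(subclasses))
    subclasses <- ifelse(classes == "coding", "missense", "n/a")
  if (is.null(genes))
    genes <- ifelse(classes == "intergenic", NA_character_,
                    sprintf("GENE%02d", seq_len(n)))
  data.frame(snp_id = ids, consequence_class = classes,
             coding_subclass = subclasses, gene_id = genes,
             gene_name = genes, stringsAsFactors = FALSE)
}

test_that("consequence tallies reproduce a hand count at two levels", {
  p <- c(rep(1e-9, 10), rep(0.9, 2))  # 10 significant of 12
  res <- makeAssociation(p)
  ids <- resultTable(res)$snp_id
  ann <- toyAnnotation(ids,
                       c(rep("intron", 4), rep("intergenic", 3),
                         rep("regulatory", 2), "coding", "intron", "other"))
  cs <- consequenceSummary(res, ann)
  tab <- cs@classTable
  expect_equal(tab$pct[match(c("intron", "intergenic", "regulatory",
                               "coding"), tab$consequence_class)],
               c(40, 30, 20, 10))
  expect_equal(sum(tab$pct), 100, tolerance = 1e-9)
  expect_identical(sum(tab$n), 10L)
  expect_identical(cs@codingTable$coding_subclass, "missense")
  expect_equal(cs@codingTable$pct, 100)
})

test_that("unannotated and degenerate significant sets are handled", {
  res <- makeAssociation(c(1e-9, 1e-9, 0.9))
  ids <- resultTable(res)$snp_id
  noAnn <- toyAnnotation("unrelated", "intron")
  cs <- consequenceSummary(res, noAnn)
  expect_identical(cs@nUnannotated, 2L)
  expect_identical(nrow(cs@classTable), 0L)
  one <- toyAnnotation(ids[1], "regulatory")
  cs1 <- consequenceSummary(res, one)
  expect_equal(cs1@classTable$pct, 100)
  none <- makeAssociation(rep(0.9, 3))
  expect_warning(cs0 <- consequenceSummary(none, noAnn), "no significant")
  expect_identical(cs0@nSignificant, 0L)
})

test_that("the summary is invariant to row order of both inputs", {
  set.seed(91)
  res <- makeAssociation(runif(30)^3)
  ids <- resultTable(res)$snp_id
  ann <- toyAnnotation(ids, sample(c("intron", "intergenic", "coding"), 30,
                                   TRUE))
  a <- consequenceSummary(res, ann)
  res2 <- res
  perm <- sample(30)
  res2@table <- res2@table[perm, ]
  b <- consequenceSummary(res2, ann[sample(30), ])
  expect_identical(a@classTable, b@classTable)
  expect_identical(a@codingTable, b@codingTable)
})

test_that("annotation validation enforces the two-level vocabulary", {
  bad <- toyAnnotation("s1", "exotic")
  expect_error(consequenceSummary(makeAssociation(0.5), bad),
               "unknown consequence class")
  inconsistent <- toyAnnotation("s1", "intron")
  inconsistent$coding_subclass <- "missense"
  expect_error(consequenceSummary(makeAssociation(0.5), inconsistent),
               "coding_subclass")
})

test_that("Manhattan export transforms p-values and offsets chromosomes", {
  res <- makeAssociation(c(0.01, 0.5, 0.2), chrom = c("1", "1", "2"),
                         pos = c(100, 900, 50))
  out <- manhattanExport(res)
  expect_equal(out$neglog10_p[1], 2)
  expect_identical(nrow(out), 3L)
  expect_gte(out$cum_pos[out$chrom == "2"][1], 900)
  # ordering and row preservation on a random result
  set.seed(92)
  rnd <- makeAssociation(runif(50), chrom = sample(1:4, 50, TRUE),
                         pos = sample(1e5, 50))
  got <- manhattanExport(rnd)
  expect_identical(nrow(got), 50L)
  expect_false(is.unsorted(got$cum_pos))
  ann <- toyAnnotation(got$snp_id, rep(c("coding", "intron"), 25))
  withExon <- manhattanExport(rnd, ann)
  expect_identical(sum(withExon$exon), 25L)
})

test_that("gene hit lists aggregate significant SNPs per gene", {
  res <- makeAssociation(c(1e-8, 0.2, 1e-9, 1e-7))
  ids <- resultTable(res)$snp_id
  ann <- toyAnnotation(ids, rep("intron", 4),
                       genes = c("GENE1", "GENE1", "GENE2", "GENE2"))
  hits <- geneHitList(res, ann)
  expect_identical(hits$gene_id, c("GENE2", "GENE1"))
  expect_identical(hits$n_significant, c(2L, 1L))
  expect_equal(hits$min_p, c(1e-9, 1e-8))
  empty <- geneHitList(makeAssociation(rep(0.9, 4)), ann)
  expect_identical(nrow(empty), 0L)
  # group-by oracle on a simulated annotation
  set.seed(93)
  rnd <- makeAssociation(runif(200)^4)
  rann <- simulateAnnotation(data.frame(id = resultTable(rnd)$snp_id),
                             seed = 7)
  got <- geneHitList(rnd, rann)
  sig <- resultTable(rnd)[resultTable(rnd)$significant, ]
  joined <- merge(sig, rann[!is.na(rann$gene_id), ], by = "snp_id")
  ref <- tapply(joined$snp_id, joined$gene_id, function(x)
    length(unique(x)))
  expect_identical(sum(got$n_significant), sum(ref[got$gene_id]))
  expect_identical(sort(got$gene_id), sort(names(ref)))
})

test_that("a multi-gene SNP counts once overall but once per gene", {
  res <- makeAssociation(c(1e-9, 0.9))
  ids <- resultTable(res)$snp_id
  ann <- data.frame(snp_id = c(ids[1], ids[1]),
                    consequence_class = "intron", coding_subclass = "n/a",
                    gene_id = c("GENEA", "GENEB"),
                    gene_name = c("GeneA", "GeneB"),
                    stringsAsFactors = FALSE)
  cs <- consequenceSummary(res, ann)
  expect_identical(sum(cs@classTable$n), 1L)
  hits <- geneHitList(res, ann)
  expect_identical(nrow(hits), 2L)
})

test_that("written consequence summaries round percentages to two decimals", {
  res <- makeAssociation(c(rep(1e-9, 3), 0.9))
  ids <- resultTable(res)$snp_id
  ann <- toyAnnotation(ids, c("intron", "intron", "intergenic", "other"))
  cs <- consequenceSummary(res, ann)
  prefix <- file.path(tempdir(), "cons")
  paths <- writeConsequenceSummary(cs, prefix)
  cls <- utils::read.table(paths[["classes"]], header = TRUE, sep = "\t")
  expect_equal(cls$pct[cls$consequence_class == "intron"], 66.67)
})
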