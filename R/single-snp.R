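#' Conventional single-SNP association scan
#'
#' The textbook baseline the all-SNP model is compared against: for each SNP
#' j, the binarised response is regressed by ordinary least squares on
#' (intercept, age, sex code, dosage_j) and the dosage coefficient is tested
#' two-sided against a t distribution with n - 4 degrees of freedom. A
#' linear (not logistic) model is used deliberately so that the comparison
#' with the all-SNP linear mixed model is like-for-like. SNPs whose dosage
#' is collinear with the covariates — monomorphic SNPs in particular — are
#' flagged `degenerate` and assigned an effect of 0 and p = 1.
#'
#' @param gm a complete [GenotypeMatrix-class] (impute first if needed).
#' @param pheno a [BinaryPhenotype-class]; samples are aligned by id.
#' @param alpha family-wise level for the Bonferroni threshold.
#' @return A [SingleSnpResult-class].
#' @export
singleSnpScan <- function(gm, pheno, alpha = 0.05) {
  gm <- alignGenotypes(gm, pheno)
  gm <- imputeMissingMean(gm)
  Z <- dosages(gm)
  y <- as.numeric(pheno@y)
  X <- designMatrix(pheno)
  n <- length(y)
  k <- ncol(X) + 1L
  if (n <= k)
    stop("insufficient sample size: need more than ", k, " samples")
  if (stats::var(y) == 0)
    stop("degenerate phenotype: response is constant")

  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  rZ <- qr.resid(qrX, Z)
  den <- colSums(rZ^2)
  num <- colSums(rZ * ry)
  df <- n - k
  tss <- sum(ry^2)

  degenerate <- den <= n * .Machine$double.eps * 100
  beta <- ifelse(degenerate, 0, num / den)
  rss <- pmax(tss - beta^2 * den, 0)
  se <- ifelse(degenerate, NA_real_, sqrt(rss / df / den))
  tstat <- ifelse(degenerate, 0, beta / se)
  pval <- ifelse(degenerate, 1,
                 pmax(2 * stats::pt(-abs(tstat), df), .Machine$double.xmin))

  v <- variants(gm)
  tab <- data.frame(
    snp_id = v$id, chrom = as.character(v$chrom), pos = v$pos, ref = v$ref,
    alt = v$alt, beta = beta, se = se, t = tstat, p = pval,
    degenerate = degenerate, significant = FALSE, stringsAsFactors = FALSE
  )
  tab <- tab[chromOrder(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  m <- nrow(tab)
  res <- new("SingleSnpResult", table = tab, mTests = m, alpha = alpha,
             threshold = alpha / m)
  res@table$significant <- res@table$p < res@threshold
  res
}

#' Compare the all-SNP and single-SNP association results
#'
#' Pairs the two scans over the same SNP universe: per SNP the two p-values,
#' their -log10 transforms, the within-scan ranks (ties to the minimum) and
#' the rank difference (`rank_single - rank_multi`; positive means the SNP
#' ranks better, i.e. earlier, in the multi-SNP scan). The summary counts
#' SNPs significant under both approaches, under exactly one, and under
#' neither.
#'
#' @param multi an [AssociationResult-class].
#' @param single a [SingleSnpResult-class].
#' @return A list with `table` (per-SNP comparison, in (chrom, pos) order)
#'   and `summary` (one-row `data.frame` of counts).
#' @export
compareModels <- function(multi, single) {
  mt <- resultTable(multi)
  st <- resultTable(single)
  onlyM <- setdiff(mt$snp_id, st$snp_id)
  onlyS <- setdiff(st$snp_id, mt$snp_id)
  if (length(onlyM) || length(onlyS))
    stop("SNP universes differ; multi-only: ",
         paste(utils::head(onlyM, 5), collapse = ", "),
         "; single-only: ", paste(utils::head(onlyS, 5), collapse = ", "))
  idx <- match(mt$snp_id, st$snp_id)
  tab <- data.frame(
    snp_id = mt$snp_id, chrom = mt$chrom, pos = mt$pos,
    p_multi = mt$p, p_single = st$p[idx],
    neglog10_p_multi = -log10(mt$p),
    neglog10_p_single = -log10(st$p[idx]),
    sig_multi = mt$significant, sig_single = st$significant[idx],
    stringsAsFactors = FALSE
  )
  tab$rank_multi <- rank(tab$p_multi, ties.method = "min")
  tab$rank_single <- rank(tab$p_single, ties.method = "min")
  tab$rank_diff <- tab$rank_single - tab$rank_multi
  summary <- data.frame(
    n_snps = nrow(tab),
    sig_both = sum(tab$sig_multi & tab$sig_single),
    sig_multi_only = sum(tab$sig_multi & !tab$sig_single),
    sig_single_only = sum(!tab$sig_multi & tab$sig_single),
    sig_neither = sum(!tab$sig_multi & !tab$sig_single)
  )
  list(table = tab, summary = summary)
}
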