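#' Fixed-effects design matrix for the association models
#'
#' Intercept (general mean), age in years and sex code, in that order.
#'
#' @param pheno a [BinaryPhenotype-class].
#' @return Numeric matrix with columns `intercept`, `age`, `sex_code`.
#' @export
designMatrix <- function(pheno) {
  cbind(intercept = rep(1, length(pheno@y)), age = pheno@age,
        sex_code = pheno@sexCode)
}

#' Set the variance components of the all-SNP model
#'
#' The variance components are treated as known: the phenotypic variance
#' \eqn{\sigma_y^2} is the unbiased sample variance of the binarised
#' response, and the genetic and residual components are fixed shares of it
#' (defaults 0.3 and 0.7). In `literal` mode
#' \eqn{\sigma_g^2 = geneticShare \cdot \sigma_y^2} is assigned to each SNP
#' effect directly, so \eqn{\lambda = \sigma_\epsilon^2/\sigma_g^2} equals
#' `residualShare/geneticShare` (7/3 at the defaults) regardless of the data.
#' In `scaled` mode the genetic share is divided by
#' \eqn{2\sum_j p_j (1-p_j)} (the conventional per-SNP scaling for
#' whole-genome SNP-BLUP), which requires the genotype matrix for the allele
#' frequencies \eqn{p_j}.
#'
#' @param y a numeric response vector or a [BinaryPhenotype-class].
#' @param genotypes a [GenotypeMatrix-class]; required for `scaled` mode.
#' @param geneticShare,residualShare shares of \eqn{\sigma_y^2}; must sum
#'   to 1.
#' @param varianceMode `"literal"` (default) or `"scaled"`.
#' @return A [MixedModelSpec-class].
#' @examples
#' estimateVariances(c(0, 0, 1, 1))  # sigma_y^2 = 1/3, lambda = 7/3
#' @export
estimateVariances <- function(y, genotypes = NULL, geneticShare = 0.3,
                              residualShare = 0.7,
                              varianceMode = c("literal", "scaled")) {
  varianceMode <- match.arg(varianceMode)
  if (is(y, "BinaryPhenotype")) y <- y@y
  y <- as.numeric(y)
  if (length(y) < 3L)
    stop("at least 3 observations are required to estimate sigma_y^2")
  sy2 <- stats::var(y)
  if (sy2 == 0)
    stop("degenerate phenotype: response is constant")
  if (abs(geneticShare + residualShare - 1) > 1e-12)
    stop("geneticShare and residualShare must sum to 1")
  se2 <- residualShare * sy2
  sg2 <- geneticShare * sy2
  if (varianceMode == "scaled") {
    if (is.null(genotypes))
      stop("scaled variance mode requires the genotype matrix")
    p <- altFreq(dosages(genotypes))
    denom <- 2 * sum(p * (1 - p), na.rm = TRUE)
    if (denom <= 0)
      stop("all SNPs are monomorphic; scaled variance mode is undefined")
    sg2 <- sg2 / denom
  }
  new("MixedModelSpec", geneticShare = geneticShare,
      residualShare = residualShare, sigmaY2 = sy2, sigmaG2 = sg2,
      sigmaE2 = se2, lambda = se2 / sg2, varianceMode = varianceMode)
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the system for \eqn{y = X\beta + Zg + \epsilon} with
#' \eqn{G = I\sigma_g^2} and \eqn{R = I\sigma_\epsilon^2}: the symmetric
#' coefficient matrix \eqn{[X'X\; X'Z;\; Z'X\; Z'Z + \lambda I]} with
#' \eqn{\lambda = \sigma_\epsilon^2/\sigma_g^2} augmenting the SNP block
#' only, and right-hand side \eqn{[X'y;\; Z'y]}. `X` must have full column
#' rank and `Z` must be complete (see [imputeMissingMean()]).
#'
#' @param y numeric response.
#' @param X fixed-effects design matrix.
#' @param Z samples x SNPs genotype design (raw 0/1/2 dosages by default;
#'   centring is a modelling choice left to the caller).
#' @param spec a [MixedModelSpec-class] (only `lambda` enters the system).
#' @param snpIDs optional SNP labels (default `colnames(Z)`).
#' @return An [MMESystem-class].
#' @export
buildMME <- function(y, X, Z, spec, snpIDs = NULL) {
  X <- as.matrix(X); Z <- as.matrix(Z); y <- as.numeric(y)
  if (nrow(X) != length(y) || nrow(Z) != length(y))
    stop("X, Z and y must have the same number of rows")
  if (anyNA(Z))
    stop("Z contains missing genotypes; impute before assembling the system")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("X", seq_len(ncol(X)))
    stop("fixed-effects design is rank deficient; collinear column(s): ",
         paste(nm[dropped], collapse = ", "))
  }
  if (is.null(snpIDs)) snpIDs <- colnames(Z)
  if (is.null(snpIDs)) snpIDs <- sprintf("snp%d", seq_len(ncol(Z)))
  fixedNames <- colnames(X)
  if (is.null(fixedNames)) fixedNames <- paste0("X", seq_len(ncol(X)))
  new("MMESystem", X = X, Z = Z, y = y, lambda = spec@lambda,
      fixedNames = fixedNames, snpIDs = snpIDs)
}

#' Materialise the dense Henderson coefficient matrix and right-hand side
#'
#' Mostly useful for inspection and for small systems; the solvers work from
#' the factored components.
#'
#' @param system an [MMESystem-class].
#' @return A list with `C` (the symmetric coefficient matrix) and `rhs`.
#' @export
mmeCoefficientMatrix <- function(system) {
  X <- system@X; Z <- system@Z
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) +
                     diag(system@lambda, ncol(Z))))
  labels <- c(system@fixedNames, system@snpIDs)
  dimnames(C) <- list(labels, labels)
  list(C = C, rhs = stats::setNames(c(crossprod(X, system@y),
                                      crossprod(Z, system@y)), labels))
}

#' Solve the mixed-model equations
#'
#' Two routes are provided. The `direct` solver factorises the symmetric
#' positive-definite system: for SNP counts up to the sample size it uses a
#' Cholesky factorisation of the Henderson coefficient matrix; when there are
#' more SNPs than samples it solves the algebraically identical
#' variance-form \eqn{V = ZZ'/\lambda + I} system of dimension n and recovers
#' \eqn{\hat g = Z'V^{-1}(y - X\hat\beta)/\lambda}, which is exact to
#' machine precision and far cheaper. The `pcg` solver runs
#' Jacobi-preconditioned conjugate gradients on the full Henderson system
#' through matrix-free products, from a zero start, to a relative residual
#' of `tol`. `auto` picks `direct` for up to 5000 SNPs and `pcg` above.
#'
#' @param system an [MMESystem-class].
#' @param method `"auto"`, `"direct"` or `"pcg"`.
#' @param tol relative residual tolerance for PCG (default 1e-8).
#' @param maxIter maximum PCG iterations (default `10 * (p + q)`).
#' @return A [ModelFit-class].
#' @export
solveMME <- function(system, method = c("auto", "direct", "pcg"),
                     tol = 1e-8, maxIter = NULL) {
  method <- match.arg(method)
  q <- ncol(system@Z)
  if (method == "auto")
    method <- if (q <= 5000L) "direct" else "pcg"
  sol <- if (method == "direct") solveMMEDirect(system)
         else solveMMEPCG(system, tol, maxIter)
  p <- ncol(system@X)
  new("ModelFit",
      betaHat = stats::setNames(sol$theta[seq_len(p)], system@fixedNames),
      gHat = stats::setNames(sol$theta[p + seq_len(q)], system@snpIDs),
      solver = method, iterations = as.integer(sol$iterations),
      relResidual = sol$relResidual)
}

mmeMultiply <- function(system, v) {
  p <- ncol(system@X); q <- ncol(system@Z)
  v1 <- v[seq_len(p)]; v2 <- v[p + seq_len(q)]
  w <- drop(system@X %*% v1 + system@Z %*% v2)
  c(drop(crossprod(system@X, w)),
    drop(crossprod(system@Z, w)) + system@lambda * v2)
}

mmeRhs <- function(system) {
  c(drop(crossprod(system@X, system@y)),
    drop(crossprod(system@Z, system@y)))
}

mmeRelResidual <- function(system, theta) {
  b <- mmeRhs(system)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(0)
  sqrt(sum((b - mmeMultiply(system, theta))^2)) / nb
}

solveMMEDirect <- function(system) {
  X <- system@X; Z <- system@Z; y <- system@y
  n <- length(y); q <- ncol(Z); lambda <- system@lambda
  theta <- if (q <= n) {
    sys <- mmeCoefficientMatrix(system)
    R <- tryCatch(chol(sys$C),
                  error = function(e) stop("singular mixed-model system: ",
                                           conditionMessage(e)))
    backsolve(R, forwardsolve(t(R), sys$rhs))
  } else {
    Vs <- tcrossprod(Z) / lambda
    diag(Vs) <- diag(Vs) + 1
    R <- tryCatch(chol(Vs),
                  error = function(e) stop("singular mixed-model system: ",
                                           conditionMessage(e)))
    ViX <- backsolve(R, forwardsolve(t(R), X))
    Viy <- backsolve(R, forwardsolve(t(R), y))
    beta <- solve(crossprod(X, ViX), crossprod(X, Viy))
    resid <- Viy - ViX %*% beta
    g <- drop(crossprod(Z, resid)) / lambda
    c(drop(beta), g)
  }
  list(theta = theta, iterations = 0L,
       relResidual = mmeRelResidual(system, theta))
}

solveMMEPCG <- function(system, tol = 1e-8, maxIter = NULL) {
  p <- ncol(system@X); q <- ncol(system@Z)
  if (is.null(maxIter)) maxIter <- 10L * (p + q)
  b <- mmeRhs(system)
  nb <- sqrt(sum(b^2))
  if (nb == 0)
    return(list(theta = rep(0, p + q), iterations = 0L, relResidual = 0))
  # Jacobi preconditioner: the diagonal of the Henderson coefficient matrix
  d <- c(colSums(system@X^2), colSums(system@Z^2) + system@lambda)
  d[d <= 0] <- 1
  x <- rep(0, p + q)
  r <- b
  z <- r / d
  s <- z
  rz <- sum(r * z)
  for (it in seq_len(maxIter)) {
    As <- mmeMultiply(system, s)
    alpha <- rz / sum(s * As)
    x <- x + alpha * s
    r <- r - alpha * As
    rel <- sqrt(sum(r^2)) / nb
    if (rel <= tol)
      return(list(theta = x, iterations = it, relResidual = rel))
    z <- r / d
    rzNew <- sum(r * z)
    s <- z + (rzNew / rz) * s
    rz <- rzNew
  }
  stop(sprintf(
    "PCG did not converge in %d iterations (achieved relative residual %.3g, tolerance %.3g)",
    maxIter, sqrt(sum(r^2)) / nb, tol))
}

#' Wald tests of all SNP effects
#'
#' For each SNP the hypothesis \eqn{H_0: g_i = 0} is tested with
#' \eqn{W_i = \hat g_i / \sigma_g}, where \eqn{\sigma_g} is the prior
#' standard deviation of SNP effects from the model specification (not a
#' standard error of \eqn{\hat g_i}); under \eqn{H_0} the statistic is
#' referred to the standard normal, giving the two-sided p-value
#' \eqn{2(1 - \Phi(|W_i|))}. Because ridge shrinkage makes
#' \eqn{|\hat g_i| \ll \sigma_g} under the null, the test is conservative;
#' this is a property of the published procedure and is reproduced as such.
#' P-values are floored at the smallest positive double so log-scale
#' reporting is always defined. Bonferroni significance at level `alpha` is
#' attached via [bonferroniCorrect()].
#'
#' @param fit a [ModelFit-class].
#' @param spec the [MixedModelSpec-class] the fit was produced with.
#' @param variantInfo optional `data.frame` with columns `id`, `chrom`,
#'   `pos`, `ref`, `alt` aligned with the fitted SNPs (e.g.
#'   `variants(genotypes)`).
#' @param alpha family-wise error level (default 0.05).
#' @return An [AssociationResult-class], ordered by (chrom, pos).
#' @export
waldTest <- function(fit, spec, variantInfo = NULL, alpha = 0.05) {
  if (spec@sigmaG2 <= 0)
    stop("sigma_g^2 must be positive")
  g <- fit@gHat
  W <- g / sqrt(spec@sigmaG2)
  pval <- pmax(2 * stats::pnorm(-abs(W)), .Machine$double.xmin)
  if (is.null(variantInfo)) {
    variantInfo <- data.frame(id = names(g), chrom = "0",
                              pos = seq_along(g), ref = NA_character_,
                              alt = NA_character_, stringsAsFactors = FALSE)
  }
  if (nrow(variantInfo) != length(g))
    stop("variantInfo must have one row per fitted SNP")
  tab <- data.frame(
    snp_id = variantInfo$id, chrom = as.character(variantInfo$chrom),
    pos = variantInfo$pos, ref = variantInfo$ref, alt = variantInfo$alt,
    g_hat = unname(g), W = unname(W), p = unname(pval),
    significant = FALSE, stringsAsFactors = FALSE
  )
  tab <- tab[chromOrder(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  tab$significant <- tab$p < alpha / length(g)
  new("AssociationResult", table = tab, mTests = length(g), alpha = alpha,
      threshold = alpha / length(g))
}

#' Bonferroni family-wise error control
#'
#' Sets `threshold = alpha / mTests` and flags `significant` strictly
#' (`p < threshold`).
#'
#' @param result an [AssociationResult-class] or [SingleSnpResult-class].
#' @param alpha family-wise error level in (0, 1).
#' @return The result with updated `alpha`, `threshold` and `significant`.
#' @export
bonferroniCorrect <- function(result, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (result@mTests < 1L)
    stop("mTests must be at least 1")
  result@alpha <- alpha
  result@threshold <- alpha / result@mTests
  result@table$significant <- result@table$p < result@threshold
  validObject(result)
  result
}

#' Rank SNPs by association strength
#'
#' Stable sort ascending by p-value with ties broken by (chrom, pos).
#'
#' @param result an [AssociationResult-class] or [SingleSnpResult-class].
#' @return The per-SNP table sorted by significance, with a `rank` column.
#' @export
rankHits <- function(result) {
  tab <- resultTable(result)
  if (!nrow(tab))
    stop("cannot rank an empty association result")
  ord <- order(tab$p, chromKey(tab$chrom), tab$pos)
  out <- tab[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full all-SNP mixed-model association analysis
#'
#' Convenience wrapper: aligns genotypes to the encoded phenotype, imputes
#' residual missingness by SNP means, fixes the variance components, builds
#' and solves Henderson's equations, and Wald-tests every SNP with
#' Bonferroni control.
#'
#' @param gm a post-QC [GenotypeMatrix-class].
#' @param pheno a [BinaryPhenotype-class].
#' @param varianceMode `"literal"` or `"scaled"` (see [estimateVariances()]).
#' @param alpha family-wise error level.
#' @param solver,tol,maxIter passed to [solveMME()].
#' @param geneticShare,residualShare passed to [estimateVariances()].
#' @return A list with `spec` ([MixedModelSpec-class]), `fit`
#'   ([ModelFit-class]) and `result` ([AssociationResult-class]).
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 150, nSnps = 60,
#'                                           heritability = 0.5, seed = 5))
#' ph <- encodePhenotype(cohort, "severe")
#' ans <- multiSnpGWAS(genotypes(cohort), ph)
#' head(rankHits(ans$result), 3)
#' @export
multiSnpGWAS <- function(gm, pheno, varianceMode = c("literal", "scaled"),
                         alpha = 0.05, solver = c("auto", "direct", "pcg"),
                         tol = 1e-8, maxIter = NULL, geneticShare = 0.3,
                         residualShare = 0.7) {
  varianceMode <- match.arg(varianceMode)
  solver <- match.arg(solver)
  gm <- alignGenotypes(gm, pheno)
  gm <- imputeMissingMean(gm)
  spec <- estimateVariances(pheno, genotypes = gm,
                            geneticShare = geneticShare,
                            residualShare = residualShare,
                            varianceMode = varianceMode)
  system <- buildMME(pheno@y, designMatrix(pheno), dosages(gm), spec,
                     snpIDs = variants(gm)$id)
  fit <- solveMME(system, method = solver, tol = tol, maxIter = maxIter)
  vi <- variants(gm)
  result <- waldTest(fit, spec,
                     variantInfo = vi[, c("id", "chrom", "pos", "ref", "alt")],
                     alpha = alpha)
  list(spec = spec, fit = fit, result = result)
}

alignGenotypes <- function(gm, pheno) {
  idx <- match(pheno@sampleIDs, sampleIDs(gm))
  if (anyNA(idx))
    stop("phenotype samples missing from the genotype matrix: ",
         paste(utils::head(pheno@sampleIDs[is.na(idx)], 5), collapse = ", "))
  GenotypeMatrix(dosages(gm)[idx, , drop = FALSE], variants(gm),
                 samples = pheno@sampleIDs)
}

#' Write an association result as TSV
#'
#' Columns: `snp_id chrom pos ref alt g_hat W p significant` (plus `se`, `t`
#' and `degenerate` for a single-SNP result), one row per tested SNP in
#' (chrom, pos) order.
#'
#' @param result an [AssociationResult-class] or [SingleSnpResult-class].
#' @param path output path.
#' @param headerLines optional `##`-prefixed comment lines to prepend.
#' @return Invisibly, `path`.
#' @export
writeAssociation <- function(result, path, headerLines = character()) {
  writeTSV(resultTable(result), path, headerLines)
}
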