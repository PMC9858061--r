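#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a bi-allelic SNP: conditional on the observed
#' allele counts, the probability of every attainable heterozygote count is
#' evaluated and those no more probable than the observed count are summed.
#' Probabilities are computed through the standard ratio recurrence in log
#' space, so the test is numerically stable for sample totals well beyond
#' 1e5. The returned p-value lies in (0, 1]; when one allele is absent there
#' is a single attainable configuration and p = 1.
#'
#' With `midp = TRUE` the mid-p variant is returned (half the probability of
#' the observed configuration is counted), as offered by common GWAS
#' toolkits; the plain exact test is the default.
#'
#' @param nAA,nAa,naa nonnegative integer genotype counts (reference
#'   homozygote, heterozygote, alternate homozygote); vectors are recycled to
#'   a common length and tested element-wise.
#' @param midp logical; use the mid-p correction.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' hweExactP(57, 14, 50)    # strong heterozygote deficit
#' hweExactP(25, 50, 25)    # perfect equilibrium, p = 1
#' @export
hweExactP <- function(nAA, nAa, naa, midp = FALSE) {
  m <- max(length(nAA), length(nAa), length(naa))
  nAA <- rep_len(nAA, m); nAa <- rep_len(nAa, m); naa <- rep_len(naa, m)
  vapply(seq_len(m), function(i) hweExactP1(nAA[i], nAa[i], naa[i], midp),
         numeric(1))
}

hweExactP1 <- function(nAA, nAa, naa, midp = FALSE) {
  if (anyNA(c(nAA, nAa, naa)))
    return(NA_real_)
  if (any(c(nAA, nAa, naa) < 0) || any(c(nAA, nAa, naa) != round(c(nAA, nAa, naa))))
    stop("genotype counts must be nonnegative integers")
  n <- nAA + nAa + naa
  if (n < 1L)
    stop("at least one genotype is required")
  nAlt <- 2 * naa + nAa
  nRare <- min(nAlt, 2L * n - nAlt)
  if (nRare == 0L)
    return(1)

  # attainable heterozygote counts share the parity of the rare allele count
  hets <- seq.int(nRare %% 2L, nRare, by = 2L)
  # log-probability recurrence: moving h -> h+2 multiplies the conditional
  # probability by 4*homRare*homCommon / ((h+2)*(h+1))
  lp <- numeric(length(hets))
  for (k in seq_len(length(hets) - 1L)) {
    h <- hets[k]
    homRare <- (nRare - h) / 2
    homCommon <- n - h - homRare
    lp[k + 1L] <- lp[k] + log(4 * homRare * homCommon) -
      log((h + 2) * (h + 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)

  obs <- which(hets == nAa)
  if (!length(obs))
    stop("observed heterozygote count is not attainable for these allele counts")
  pObs <- pr[obs]
  p <- sum(pr[pr <= pObs * (1 + 1e-12)])
  if (midp)
    p <- p - 0.5 * pObs
  min(max(p, .Machine$double.xmin), 1)
}
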