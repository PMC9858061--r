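---
title: "Methods: all-SNP mixed-model association for binarised phenotypes"
author: "blupgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: all-SNP mixed-model association for binarised phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blupgwas)
```

## The model

Conventional GWAS tests one SNP at a time and pays for it twice: the
Bonferroni correction assumes independent tests, which linkage
disequilibrium (LD) between nearby variants violates, and a single-marker
model forces the rest of the genetic background into the residual, where
moderate effects are lost. For oligogenic binary phenotypes, this package
implements the alternative: a linear mixed model fitting additive effects of
**all** SNPs simultaneously,

$$y = X\beta + Zg + \varepsilon, \qquad
  g \sim N(0, I\sigma_g^2), \qquad \varepsilon \sim N(0, I\sigma_\varepsilon^2),$$

where $y$ is the binarised disease status, $X$ carries the fixed effects
(general mean, age in years, sex code), and $Z$ holds raw SNP genotype
dosages coded 0/1/2 (homozygous reference, heterozygous, homozygous
alternate). The correlation structure among SNPs induced by LD enters the
model through $Z$ itself. A binary response is deliberately modelled with a
*linear* (not logistic) mixed model: the SNP effects are then on the risk
scale and the all-SNP system stays a single sparse-free linear solve.

The variance components are treated as **known**: the phenotypic variance
$\sigma_y^2$ is the unbiased sample variance of $y$, and fixed shares split
it into $\sigma_g^2 = 0.3\,\sigma_y^2$ and
$\sigma_\varepsilon^2 = 0.7\,\sigma_y^2$. No REML or Bayesian estimation is
performed (a non-goal of this package).

Estimates come from Henderson's mixed-model equations,

$$\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda I \end{pmatrix}
  \begin{pmatrix} \hat\beta \\ \hat g \end{pmatrix} =
  \begin{pmatrix} X'y \\ Z'y \end{pmatrix},
  \qquad \lambda = \sigma_\varepsilon^2 / \sigma_g^2,$$

which is exactly a generalized ridge regression (SNP-BLUP): only the SNP
block is $\lambda$-augmented.

### The two variance modes

`varianceMode = "literal"` assigns the full genetic share to *each* SNP
effect, so $\lambda = 0.7/0.3 = 7/3$ regardless of the data. This is the
procedure as published for the analysis this package reproduces, and it is
the package default. It is, however, unconventional for whole-genome models:
with thousands of SNPs, $\lambda = 7/3$ is tiny relative to the $Z'Z$
diagonal (order $n/2$), so the fit is barely regularised and, when the SNP
count exceeds the sample size, close to an interpolating minimum-norm
solution. `varianceMode = "scaled"` divides the genetic share by
$2\sum_j p_j(1-p_j)$ (with $p_j$ the alternate allele frequency), the
standard per-SNP calibration for SNP-BLUP/GBLUP software. Both modes are
implemented and tested; the signal-recovery property below uses the scaled
mode because it is the setting under which per-SNP effect ranking is
well-posed at $q > n$, while the null error-control property uses the
literal mode, matching the published configuration.

### Testing

Each SNP is tested with the Wald statistic
$W_i = \hat g_i / \sigma_g$ referred to the standard normal,
$p_i = 2(1-\Phi(|W_i|))$. The denominator is the **prior** standard
deviation of SNP effects, not a standard error of $\hat g_i$; because ridge
shrinkage keeps $|\hat g_i|$ well below $\sigma_g$ under the null, the test
is conservative. That conservatism is a property of the published procedure;
the package reproduces it literally and verifies empirically that the
family-wise error rate after Bonferroni correction
($p_i < \alpha/m$, strictly) stays below its nominal level. P-values are
floored at the smallest positive double so $-\log_{10} p$ is always finite.
$\alpha$ defaults to 0.05 and $m$ defaults to the number of SNPs actually
tested.

## Solvers

Two routes solve the mixed-model equations, both deterministic:

* **direct** — for $q \le n$ SNPs, a Cholesky factorisation of the dense
  Henderson coefficient matrix. For $q > n$ the solver switches to the
  algebraically identical variance form: with
  $V^\ast = ZZ'/\lambda + I_n$, generalized least squares gives $\hat\beta$,
  and $\hat g = Z'V^{\ast-1}(y - X\hat\beta)/\lambda$. This is exact (it is
  the same linear system after block elimination), and reduces the cost
  from $O((p+q)^3)$ to $O(n^2 q)$ — the difference between minutes and
  seconds on the default cohort (1076 samples, 5000 SNPs).
* **pcg** — Jacobi-preconditioned conjugate gradients on the full Henderson
  system through matrix-free products $v \mapsto X'(Xv_1+Zv_2)$, from a zero
  start, to a relative residual of `tol` (default 1e-8, `maxIter` default
  $10(p+q)$). Non-convergence is an error carrying the achieved residual,
  never a silent partial answer.

`solver = "auto"` uses the direct route up to 5000 SNPs and PCG above. The
test suite requires both routes to agree with an independent augmented-QR
generalized-ridge solve to 1e-8 relative error on random instances.

## Pre-model steps

**QC cascade.** Four variant filters in a fixed order: multi-allelic records
(dropped whole, never decomposed), call rate, Hardy-Weinberg equilibrium,
minor allele frequency. Thresholds default to the published values (call
rate 0.95, HWE p 1e-4, MAF 0.001) and all removals are *strict*
inequalities, read literally from "less than 95%", "below 0.0001", "under
0.001" — boundary variants survive. Each removed variant is attributed to
the first filter it fails, so the report's ledger reconciles exactly. The
HWE p-value is a two-sided exact conditional test (summing probabilities of
heterozygote counts no more likely than the observed one), computed through
the standard log-space ratio recurrence; it matches full enumeration to
1e-12 for every table with up to 50 samples and is stable to $10^5$
samples. The test is computed on all retained samples jointly by default —
the published pre-processing does not restrict it to controls — with
`hweSampleIDs` available to restrict it, and a mid-p variant behind a flag.

**Phenotype encoding.** The five-category cohort (control, resistant,
benign, mild, severe) yields two binary analyses: *severe* (severe = 1,
controls removed, everything else 0) and *resistant* (resistant = 1,
controls removed, everything else 0). Sample order is preserved. Sex is
coded M = 0 / F = 1 by default; the reference level only flips the sign of
the sex effect and is configurable. Missing age or sex is a hard error by
default — silently imputing covariates is rarely what one wants — with an
explicit opt-in (`imputeCovariates`) for robustness testing.

**Residual missingness.** The model needs a complete $Z$; genotypes still
missing after QC are replaced by the SNP's mean observed dosage, which
leaves allele-frequency estimates unchanged.

## The synthetic cohort generator

The generator exists so every statistical guarantee of the pipeline can be
exercised end-to-end on data whose truth is known. It emulates the
*structure* the analysis assumes — unrelated individuals, LD-blocked
bi-allelic SNPs, an oligogenic latent liability, five ordered outcome
categories, age/sex covariates — at the scale of a cohort of 1076
individuals with 306 resistant and 235 severe members.

* **Genotypes** come from a latent Gaussian copula: per haplotype, a latent
  normal vector with block-constant correlation is thresholded at the
  per-SNP allele-frequency quantile, and the two haplotypes are summed.
  The latent correlation is calibrated numerically (one-dimensional
  quadrature plus root finding) so that the realised *dosage* correlation
  matches `withinBlockR` at the block's mean allele frequency; blocks are
  independent. Defaults: blocks of 10 SNPs, target dosage correlation 0.6,
  allele frequencies uniform on [0.05, 0.5] — moderate, realistic LD that
  neither trivialises nor swamps the multi-SNP model.
* **Phenotype** follows a liability-threshold model: liability is the
  standardized-genotype score of `nCausal` causal SNPs plus Gaussian noise,
  rescaled so the genetic share equals `heritability` exactly in-sample.
  Causal effects default to *fixed magnitude* `causalEffectSD` with random
  sign: the package's recovery guarantees are stated for causal SNPs of
  large effect, and Gaussian draws would routinely produce near-null
  "causal" SNPs (the heritability rescaling cancels any overall scale, so
  shape is the only thing the distribution controls). A `gaussian` option
  exists for heterogeneous-effect simulations.
* **Categories** are assigned by empirical liability quantiles with exact
  counts (the rounded cumulative partition of `categoryProportions`),
  ordered resistant < control < benign < mild < severe along liability.
  Exact counts rather than fixed thresholds guarantee the group sizes that
  downstream contrasts rely on; the ordering is a modelling choice and is
  configurable. The study design fixes only 306 resistant and 235 severe of
  1076; the control/benign/mild split (200/180/155) is a free parameter
  chosen once to give a sizeable removed-control group and a realistic
  middle mass.
* **Covariates** are independent of liability by default (ages uniform on
  18–85 years, sex Bernoulli(0.5)); `ageEffect` can inject age confounding.
  Missingness is off by default and available as `missingRate` for QC
  testing.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: coalescent-realistic haplotype structure and
allele-frequency spectra, population stratification and admixture,
relatedness, genotyping-error patterns, informative missingness, and
covariate distributions of a real cohort.

## Numerical and design choices

* Seeds: every stochastic operation is driven by the configuration seed;
  genotype and phenotype stages use decoupled derived streams, so the same
  configuration is bit-reproducible and changing only `nSnps` does not
  reshuffle the phenotype.
* Z columns are raw 0/1/2 dosages, not centred or standardized, matching
  the published parameterisation (a centring choice would change
  $\hat\beta$, not the SNP ranking).
* Rank deficiency of $X$ is an error naming the offending column rather
  than a silent drop; a constant SNP column simply receives maximal
  shrinkage ($\hat g_i \to 0$).
* Ties in hit ranking break by (chromosome, position), so reports are
  stable across runs and platforms.
* The single-SNP baseline is the textbook covariate-adjusted OLS scan with
  a $t_{n-4}$ reference — linear, like the multi-SNP model, so the
  comparison is like-for-like; monomorphic or covariate-collinear SNPs are
  flagged degenerate with p = 1 rather than dropped.
* Functional annotation is consumed, never computed: consequence classes
  come from an external annotator's table, and the package only tallies
  them (two-level percentages: classes over significant annotated SNPs,
  coding subclasses over coding SNPs), reporting to two decimals.

## Problem sizes used by the test suite

The suite validates the pipeline at the scales it targets: oracle
equivalence of the solvers on 100 random instances up to 200 samples x 500
SNPs; Hardy-Weinberg enumeration up to 50 samples (23,425 genotype
configurations); family-wise error over 500 null cohorts of 300 samples x
1000 SNPs; signal recovery over 50 cohorts of 1076 samples x 2000 SNPs with
10 causal SNPs at heritability 0.5; and byte-level determinism of the full
pipeline on the default 1076 x 5000 cohort. These sizes are the package's
own validation choices: large enough that the asymptotic claims
(conservative FWER, top-5% causal ranking, null-uniform baseline p-values)
are meaningfully exercised, small enough to run routinely.

## Known limitations

* The Wald test inherits the conservatism of its prior-SD denominator;
  with the literal variance mode and genome-scale $m$, significant calls
  require very large effects. This is faithful to the published procedure,
  not a recommendation.
* Fixed 0.3/0.7 variance shares are an assumption, not an estimate; no
  uncertainty propagates from them.
* The linear model on a binary response ignores the mean-variance
  relationship; at cohort scale this mainly affects efficiency, not
  validity of the permutation-style guarantees tested here.
* No GRM/kinship correction, dominance, epistasis, or X-dosage handling;
  samples are assumed unrelated, as in the study design this mirrors.
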