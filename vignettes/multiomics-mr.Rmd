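---
title: "Multi-omics Mendelian randomization: models, combination tests and the simulation benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics Mendelian randomization: models, combination tests and the simulation benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momr)
```

## The problem

A gene is rarely observed through a single molecular readout. Expression,
protein abundance, methylation and metabolite levels each come with their
own QTL summary statistics, and each can be treated as an exposure in a
two-sample Mendelian randomization (MR) analysis against a disease GWAS.
`momr` addresses the resulting inference problem at the *gene* level: test
whether **any** omics biomarker annotated to a gene has a (pleiotropic)
effect on the outcome, using only summary statistics — per-SNP effect
sizes $\hat\beta$, standard errors $\hat\sigma$, and an unsquared LD
correlation matrix $R$ for the cis-SNPs used as instruments.

Two sources of dependence make this hard:

1. **LD between instruments.** Cis-QTL SNPs are physically close and
   correlated; estimators that assume independent instruments inflate the
   type I error.
2. **Correlation between exposures.** The omics layers of one gene are
   biologically coupled, so the per-exposure MR P-values are themselves
   dependent, and naive combination rules (Fisher's chi-squared
   calibration, minimum P) are invalid.

## Per-exposure engines

For exposure $k$ with instrument effects $\hat\beta_{Xk}$, outcome effects
$\hat\beta_Y$ and outcome standard errors $\hat\sigma_Y$:

* **IVW** (`mr_ivw`): $\hat\theta = (\hat\beta_X^\top W \hat\beta_X)^{-1}
  \hat\beta_X^\top W \hat\beta_Y$ with $W = \mathrm{diag}(\hat\sigma_Y^{-2})$ —
  the no-intercept weighted-least-squares slope. Valid only for
  uncorrelated instruments.
* **GLS** (`mr_gls`): replaces $W^{-1}$ by
  $\Omega = \mathrm{diag}(\hat\sigma_Y) R\, \mathrm{diag}(\hat\sigma_Y)$,
  accounting for residual LD after clumping. `mr_gls` with $R = I$ is
  algebraically identical to `mr_ivw`.
* **SMR** (`mr_smr`): the single-SNP statistic
  $T = z_Y^2 z_X^2 / (z_Y^2 + z_X^2) \sim \chi^2_1$. `mr_smr_multi`
  either takes the strongest QTL per exposure (`singleSNP`) or every
  SNP-exposure pair (`allSNPs`).
* **GSMR** (`mr_gsmr`): per-SNP Wald ratios pooled by GLS under a
  second-order covariance matrix built from both sets of sampling
  variances and the LD correlations. Default filters follow the method's
  own recommendations ($r^2 < 0.95$, $z_X^2 > 10$, at least 10 surviving
  SNPs); `min_snps` and `chi2_filter` are exposed because designs with
  five instruments — as in our benchmark — cannot meet the defaults.
* **Multivariable MR** (`mr_mvmr`): joint regression
  $\hat\beta_{Yj} = \sum_k \theta_k \hat\beta_{Xkj} + \epsilon$ with
  weights $\hat\sigma_{Yj}^{-2}$ (GLS form when $R$ is supplied) and an
  $m$-df Wald test of $\theta_1 = \dots = \theta_m = 0$. It needs more
  instruments than exposures; otherwise the result is flagged
  `insufficient_ivs` rather than silently extrapolated.

A note on the IVW normalization: the estimator is implemented with
$\hat\beta_X$ in the quadratic form of the denominator, which is the form
consistent with its GLS generalization and with the weighted-regression
view of multivariable MR (one sometimes sees $\hat\beta_Y^2$ printed in
the IVW denominator; that form is not self-consistent with either
reduction and is not used here).

## Gene-level combination tests

Given per-exposure P-values $p_1,\dots,p_m$ (equal weights $w_k = 1/m$ by
default):

* **Cauchy combination / ACAT** (`combine_cauchy`):
  $T = \sum_k w_k \tan\{(0.5 - p_k)\pi\}$, $P = 0.5 -
  \arctan(T/\sum w_k)/\pi$. Valid under arbitrary dependence. For
  $p < 10^{-16}$ the tangent is replaced by its tail expansion
  $1/(p\pi)$, and for extreme $T$ the combined P-value uses
  $(\sum w_k)/(\pi T)$, so the map stays monotone and positive over the
  full double range.
* **Harmonic mean P-value** (`combine_hmp`):
  $T = \sum w_k / \sum (w_k/p_k)$, calibrated against the one-sided
  stable (Landau-type) law with tail index 1 — location
  $\log m + 1 - \gamma + \log(\pi/2)$, scale $\pi/2$ — the
  asymptotically exact calibration. No stable-distribution package is
  required: the upper tail is computed by Gil-Pelaez inversion of the
  characteristic function, switching to the regularly-varying tail
  $2/(\pi z)$ for standardized quantiles above 500 (the two branches
  agree to about 1% at the switch point, in a region where the combined
  P-value is already below 0.002). The implementation is validated in the
  test suite against a Chambers–Mallows–Stuck Monte-Carlo sampler and an
  independent Zolotarev-type quadrature of the distribution function.
* **Minimum P** (`combine_minp`): reports $\min_k p_k$ unadjusted —
  intentionally anti-conservative, retained because the benchmark uses it
  as a negative control.
* **Fisher, chi-squared calibration** (`combine_fisher_chisq`):
  $T = -2\sum \ln p_k \sim \chi^2_{2m}$, exact only under independence —
  the second negative control.
* **Fisher, gamma calibration** (`combine_fisher_gamma`): matches the
  first two null moments of $T$ given the correlation matrix of the
  underlying GLS z-statistics: $E[T] = 2m$,
  $\mathrm{Var}[T] = 4m + 2\sum_{i<j} c(\rho_{ij})$ with the Brown/Kost
  cubic $c(\rho) = 3.263|\rho| + 0.710\rho^2 + 0.027|\rho|^3$, and
  compares $T$ with a gamma(shape $E^2/\mathrm{Var}$, scale
  $\mathrm{Var}/E$). $c(0) = 0$ recovers the chi-squared calibration
  exactly; $c(1) = 4$ makes the $m = 2$, $\rho = 1$ case collapse to an
  exponential under which the combined P equals the (common) input P.

The z-statistic correlation itself (`gls_z_correlation`) uses the
first-order ("strong instrument") approximation: treating
$\gamma_{Xk} = \hat\beta_{Xk}/\hat\sigma_Y$ as fixed and
$\mathrm{cov}(z_Y) = R$, the covariance of two GLS z-statistics is the
sandwich $a_{k_1}^\top R\, a_{k_2}$ with
$a_k = R_k^{-1}\gamma_{Xk} / (\gamma_{Xk}^\top R_k^{-1}\gamma_{Xk})^{1/2}$,
computed on the union of the two exposures' (clumped) SNP sets only.
Estimates that exceed $\pm 1$ by numerical error are clamped with a
warning.

Two caveats we consider worth stating plainly:

* The cubic kernel was fitted for one-sided tests; applied to $|\rho|$
  with two-sided P-values it overstates the variance contribution
  (at $|\rho| = 0.5$, $m = 3$, the exact variance of $T$ is about 17.8
  versus the kernel's 22.9). The effect is a mildly *conservative*
  combined P-value, which is the safe direction for type I error; the
  $\rho \in \{0, 1\}$ endpoints are exact.
* Any moment-matched gamma is a tail approximation. In the test suite it
  reproduces a $10^6$-draw Monte-Carlo null P-value of $\approx 0.005$
  within a factor of 1.4 (and never anti-conservatively), but it should
  not be read as exact beyond the first couple of significant digits deep
  in the tail.

* The Cauchy combination itself is exact only as the significance level
  tends to zero; at an operating point of 0.05 with $m = 3$ strongly
  correlated inputs its true level is near 0.053. The calibration tests
  therefore check a ±0.01 band around the nominal level rather than pure
  Monte-Carlo error.

## The simulation benchmark

`sim_config` + `simulate_replicate` + `compute_summary` generate
summary-statistic studies under two pleiotropy models over three omics
exposures $X_1, X_2, X_3$, a shared confounder $U \sim N(0,1)$ and i.i.d.
$N(0,1)$ noise:

* **vertical** (series): $X_1 = \frac{\alpha}{p}\sum_j Z_j + U +
  \epsilon_1$, $X_2 = 2X_1 - U + \epsilon_2$, $X_3 = -0.5X_2 + U +
  \epsilon_3$, outcome $Y_C = \beta_X X_3 - U + \epsilon_Y$ or
  $\mathrm{logit}(\tau) = -2 + \beta_X X_3 - U$;
* **horizontal** (parallel): $X_1$ loads on all $p$ SNPs, $X_2$ on the
  first $\lfloor p/2\rfloor$ with loading $-\alpha/p$, $X_3$ on the rest,
  and $Y$ depends on $\sum_k X_k$ with confounder $+U$.

Dosages are $\mathrm{Binom}(2, 0.3)$ with equicorrelated pairwise LD: each
haplotype is a thresholded one-factor Gaussian copula whose latent
correlation is calibrated by quadrature so the realized dosage correlation
is exactly $\sqrt{r^2}$, keeping the binomial marginals exact. Studies
have 500 subjects each (250 cases + 250 controls for binary outcomes,
drawn from an oversampled population of 5000, QTLs on controls by
default), with the QTL/GWAS sample overlap configurable in $[0, 1]$;
per-omic QTL samples are shared by default or drawn disjointly when
configured as independent. Per-SNP summary statistics come from simple
linear regressions (closed form, vectorized) or logistic fits
(`glm.fit`, i.e. binomial IRLS), and the empirical LD matrix is taken
from the GWAS-sample dosages, since $\Omega$ approximates the covariance
of the GWAS z-errors.

`run_benchmark` repeats simulate → summarize → analyze over a grid and
reports empirical rejection rates at 0.05 with Monte-Carlo standard
errors. Replicate-level seeds are derived from the master seed, the
setting index and the replicate index, so any cell is reproducible in
isolation and results do not depend on worker scheduling. Failed
replicates (singular covariance, insufficient instruments) are counted
separately and excluded from the rate denominator.

Choices worth recording:

* **No clumping inside the benchmark.** LD clumping (`ld_clump`,
  $r^2 < 0.2$, distance $> 100$ kb, smallest-P-first with lexicographic
  tie-break) is part of the real-data path. The benchmark's SNPs are
  generated *at* $r^2 = 0.2$, so clumping there would randomly discard
  instruments; all $p$ simulated SNPs are fed to the engines, which is
  what the LD-aware engines are for. `analyze_gene` therefore clumps only
  when the caller passes `clump_r2`.
* **GSMR in small designs.** With $p = 5$ and weak instruments the
  method's default filters can never leave 10 SNPs, so the benchmark
  calls it with `min_snps = 2` and no instrument-strength filter; the
  estimator is otherwise unchanged. This is what lets the power
  comparison include GSMR at $\alpha = 0.5$.
* **Genotypes are redrawn every replicate** (fully stochastic design),
  rather than fixing one genotype draw per setting.
* **Continuous-outcome overlap** applies to two 500-subject study
  samples drawn from one simulated population: at overlap 1 they are the
  same single cohort; at overlap 0 they are disjoint.
* **Beta-distributed SNP effects** (`snp_effect_mode =
  "beta_distributed"`) scale the $\alpha/p$ loading by i.i.d.
  $\mathrm{Beta}(1, 1)$ draws by default; the shape parameters are
  exposed in the configuration.

What the generator does *not* emulate: real LD blocks (equicorrelation
only), allele-frequency spectra (single MAF), population structure,
winner's-curse selection of instruments, or measurement platforms whose
QTL errors are correlated across omics layers. Passing the benchmark
therefore demonstrates correct behaviour of the estimators and
combination tests under the stated generative model, not robustness to
every failure mode of real data.

## Numerical safeguards

* $\Omega$, $V$ and LD submatrices are rejected when the reciprocal
  condition number drops below $10^{-10}$, naming the worst-conditioned
  SNP pair.
* SNPs monomorphic in any used subsample (or with non-converged logistic
  fits) are excluded from a replicate with a warning.
* Input P-values of exactly 0 are clamped to the smallest positive
  double with a warning; internally computed normal tails are clamped
  silently at the same bound.
* Exposures whose engine fails are dropped from the combination with a
  warning and $m$ reduced; a gene with no valid exposure yields an `NA`
  combined P-value.

## Problem sizes used in the shipped checks

The acceptance analyses run the null vertical-pleiotropy design
($p = 5$, $r^2 = 0.2$, $\alpha = 1$, continuous outcome) and the
full-overlap design ($p = 20$) at 10 000 replicates each, and the power
comparison at $\beta_X = 0.1$, $\alpha \in \{0.5, 2\}$ at 2000 replicates
per cell; property-style checks use $10^4$–$10^6$ draws as noted in the
tests. These sizes give Monte-Carlo standard errors of about 0.002 on a
rejection rate of 0.05, small enough for the three-standard-error bands
used throughout.
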