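#' @keywords internal
combined_result <- function(pval, statistic, method, weights, m) {
  pval <- min(max(pval, .Machine$double.xmin), 1)
  structure(list(pval = pval, statistic = statistic, method = method,
                 weights = weights, m = m),
            class = "combined_result")
}

#' @export
print.combined_result <- function(x, ...) {
  cat(sprintf("Combined P-value [%s], m = %d: T = %.6g, P = %.6g\n",
              x$method, x$m, x$statistic, x$pval))
  invisible(x)
}

check_pvals <- function(pvals, open_right = TRUE) {
  pvals <- as.numeric(pvals)
  if (!length(pvals)) stop("no P-values supplied")
  if (any(!is.finite(pvals))) stop("P-values must be finite")
  hi_bad <- if (open_right) any(pvals >= 1) else any(pvals > 1)
  if (any(pvals <= 0) || hi_bad)
    stop("P-values must lie strictly inside (0, 1)")
  pvals
}

check_weights <- function(weights, m) {
  if (is.null(weights)) weights <- rep(1 / m, m)
  weights <- as.numeric(weights)
  if (length(weights) != m) stop("need one weight per P-value")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  weights
}

#' Cauchy combination test (ACAT)
#'
#' Combines m possibly dependent P-values through
#' \eqn{T = \sum_k w_k \tan\{(0.5 - p_k)\pi\}}; under the null T is
#' approximately Cauchy regardless of the dependence, giving
#' \eqn{P = 0.5 - \arctan(T/\sum_k w_k)/\pi}. For very large
#' \eqn{T/\sum w_k} the numerically stable tail form
#' \eqn{P \approx (\sum_k w_k)/(\pi T)} is used.
#'
#' @param pvals P-values in (0, 1).
#' @param weights positive weights; default equal weights \eqn{1/m}.
#' @return a `combined_result`.
#' @export
combine_cauchy <- function(pvals, weights = NULL) {
  pvals <- check_pvals(pvals)
  m <- length(pvals)
  w <- check_weights(weights, m)
  # tan((0.5 - p) pi) ~ 1/(p pi) for tiny p; the direct tangent loses all
  # precision once 0.5 - p rounds to 0.5
  terms <- ifelse(pvals < 1e-16, 1 / (pvals * pi),
                  tan((0.5 - pvals) * pi))
  t_stat <- sum(w * terms)
  sw <- sum(w)
  ratio <- t_stat / sw
  pval <- if (ratio > 1e15) sw / (t_stat * pi)
          else 0.5 - atan(ratio) / pi
  combined_result(pval, t_stat, "cauchy", w, m)
}

# Upper tail of the standard (S1-parameterized) stable law with
# alpha = 1, beta = 1, unit scale, zero location: Gil-Pelaez inversion of
# phi(t) = exp(-t - i t (2/pi) log t), with the regularly-varying tail
# 2/(pi z) for large z where the oscillatory integral loses accuracy.
stable11_upper <- function(z) {
  if (z > 500) return(2 / (pi * z))
  f <- function(u) exp(-u) * sin(u * z + (2 / pi) * u * log(u)) / u
  int <- stats::integrate(f, 0, Inf, subdivisions = 2000L,
                          rel.tol = 1e-10, abs.tol = 1e-12)$value
  min(max(0.5 - int / pi, 0), 1)
}

#' Harmonic mean P-value (HMP)
#'
#' Combines dependent P-values through the weighted harmonic mean
#' \eqn{T = \sum_k w_k / \sum_k (w_k/p_k)} (weights normalized to sum 1).
#' Under the null, \eqn{1/T} follows asymptotically a one-sided stable
#' (Landau-type) law with tail index \eqn{\lambda = \beta = 1}, location
#' \eqn{\log m + 1 - \gamma + \log(\pi/2)} and scale \eqn{\pi/2}; the
#' combined P-value is the upper tail of that law at \eqn{1/T}.
#'
#' @inheritParams combine_cauchy
#' @return a `combined_result` with `statistic` = the harmonic mean T.
#' @export
combine_hmp <- function(pvals, weights = NULL) {
  pvals <- check_pvals(pvals)
  m <- length(pvals)
  w <- check_weights(weights, m)
  w <- w / sum(w)
  inv_t <- sum(w / pvals)
  t_hmp <- 1 / inv_t
  # Landau location in the Nolan S0 parameterization; for alpha = 1 this is
  # an additive shift of the standard S1 variable scaled by pi/2.
  location <- log(m) + 1 - 0.57721566490153286 + log(pi / 2)
  zstd <- (inv_t - location) / (pi / 2)
  pval <- stable11_upper(zstd)
  combined_result(pval, t_hmp, "hmp", w, m)
}

#' Minimum-P combination (no multiplicity adjustment)
#'
#' Takes the smallest of the m P-values as both statistic and combined
#' P-value, ignoring their number and correlation. Intentionally
#' anti-conservative; retained for benchmark comparison.
#'
#' @param pvals P-values in (0, 1].
#' @return a `combined_result`.
#' @export
combine_minp <- function(pvals) {
  pvals <- check_pvals(pvals, open_right = FALSE)
  combined_result(min(pvals), min(pvals), "minp",
                  rep(1 / length(pvals), length(pvals)), length(pvals))
}

#' Fisher combination with the chi-squared calibration
#'
#' \eqn{T = -2\sum_k \ln p_k} compared with \eqn{\chi^2_{2m}}; exact only
#' for independent P-values.
#'
#' @param pvals P-values in (0, 1].
#' @return a `combined_result`.
#' @export
combine_fisher_chisq <- function(pvals) {
  pvals <- check_pvals(pvals, open_right = FALSE)
  m <- length(pvals)
  t_stat <- -2 * sum(log(pvals))
  pval <- stats::pchisq(t_stat, df = 2 * m, lower.tail = FALSE)
  combined_result(pval, t_stat, "fisher_chisq", rep(1 / m, m), m)
}

#' Correlation of GLS z-statistics across exposures
#'
#' For the Fisher-gamma combiner the dependence between the per-exposure
#' GLS z-statistics is needed. Writing \eqn{\gamma_{Xk} =
#' (\hat\beta_{Xk1}/\hat\sigma_{Y1}, \ldots)} over exposure k's (clumped)
#' SNPs and approximating \eqn{\mathrm{cov}(z_Y) = R}, the first-order
#' covariance is the sandwich
#' \deqn{\mathrm{cov}(z_{k_1}, z_{k_2}) = a_{k_1}^\top R\, a_{k_2},\qquad
#'       a_k = \frac{R_k^{-1}\gamma_{Xk}}
#'                  {\sqrt{\gamma_{Xk}^\top R_k^{-1}\gamma_{Xk}}},}
#' where \eqn{R_k} is the LD submatrix over exposure k's SNPs and the outer
#' \eqn{R} is over the union of the two exposures' SNPs (vectors padded
#' with zeros). Estimates marginally outside \[-1, 1\] from numerical error
#' are clamped with a warning.
#'
#' @param qtls named list of exposure [summary_stats] (each restricted to
#'   that exposure's selected SNPs, all present in `ld`).
#' @param ld [ld_matrix] covering the union of all exposures' SNPs.
#' @param gwas optional outcome [summary_stats] supplying the
#'   \eqn{\hat\sigma_{Yj}} used to scale \eqn{\gamma_{Xk}}; when absent the
#'   raw \eqn{\hat\beta_{Xk}} are used (equivalent when the outcome
#'   standard errors are constant across SNPs).
#' @return an object of class `z_correlation`: list with `labels` and the
#'   m x m correlation matrix `rho`.
#' @export
gls_z_correlation <- function(qtls, ld, gwas = NULL) {
  m <- length(qtls)
  stopifnot(m >= 1L, inherits(ld, "ld_matrix"))
  labs <- vapply(seq_len(m), function(k) {
    if (!is.null(names(qtls)) && nzchar(names(qtls)[k])) names(qtls)[k]
    else qtls[[k]]$trait
  }, character(1))
  # per-exposure normalized weight vectors in the full LD space
  avec <- matrix(0, nrow = length(ld$snp), ncol = m,
                 dimnames = list(ld$snp, labs))
  for (k in seq_len(m)) {
    q <- qtls[[k]]
    idx <- match(q$snp, ld$snp)
    if (anyNA(idx))
      stop("exposure '", labs[k], "' has SNPs missing from the LD matrix")
    rk <- ld$r[idx, idx, drop = FALSE]
    check_invertible(rk, q$snp, sprintf("LD submatrix for '%s'", labs[k]))
    gamma_k <- if (is.null(gwas)) q$beta
               else q$beta / subset_snps(gwas, q$snp)$se
    ri_g <- solve(rk, gamma_k)
    quad <- sum(gamma_k * ri_g)
    if (quad <= 0) stop("non-positive GLS quadratic form for '", labs[k], "'")
    avec[idx, k] <- ri_g / sqrt(quad)
  }
  rho <- crossprod(avec, ld$r %*% avec)
  if (max(abs(rho)) > 1 + 1e-6)
    warning("z-correlation estimates outside [-1, 1]; clamped")
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  structure(list(labels = labs, rho = rho), class = "z_correlation")
}

# Brown/Kost-type covariance contribution of one correlated pair to the
# variance of the Fisher statistic; cubic polynomial in |rho| with
# c(0) = 0 and c(1) = 4 (two-sided tests make the dependence symmetric
# in the sign of rho).
fisher_gamma_kernel <- function(rho) {
  a <- abs(rho)
  3.263 * a + 0.710 * a^2 + 0.027 * a^3
}

#' Fisher combination with the gamma calibration for dependent tests
#'
#' \eqn{T = -2\sum_k \ln p_k} with null moments matched to a gamma
#' distribution: \eqn{E[T] = 2m} and
#' \eqn{\mathrm{Var}[T] = 4m + 2\sum_{i<j} c(\rho_{ij})}, where
#' \eqn{\rho_{ij}} is the correlation between the underlying GLS
#' z-statistics (see [gls_z_correlation()]) and \eqn{c(\cdot)} the
#' Brown/Kost cubic polynomial. The combined P-value is the upper gamma
#' tail (shape \eqn{E^2/\mathrm{Var}}, scale \eqn{\mathrm{Var}/E}) at T.
#' With all \eqn{\rho_{ij} = 0} this is exactly [combine_fisher_chisq()].
#'
#' @param pvals P-values in (0, 1].
#' @param zcorr a `z_correlation` from [gls_z_correlation()], or an m x m
#'   correlation matrix.
#' @return a `combined_result`.
#' @export
combine_fisher_gamma <- function(pvals, zcorr) {
  pvals <- check_pvals(pvals, open_right = FALSE)
  m <- length(pvals)
  rho <- if (inherits(zcorr, "z_correlation")) zcorr$rho else as.matrix(zcorr)
  if (!all(dim(rho) == c(m, m)))
    stop("correlation matrix dimension must match the number of P-values")
  if (max(abs(rho)) > 1 + 1e-6)
    stop("z-correlations must lie in [-1, 1]")
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  t_stat <- -2 * sum(log(pvals))
  e_t <- 2 * m
  pairs <- rho[upper.tri(rho)]
  var_t <- 4 * m + 2 * sum(fisher_gamma_kernel(pairs))
  shape <- e_t^2 / var_t
  scale <- var_t / e_t
  pval <- stats::pgamma(t_stat, shape = shape, scale = scale,
                        lower.tail = FALSE)
  combined_result(pval, t_stat, "fisher_gamma", rep(1 / m, m), m)
}
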