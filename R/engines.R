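#' @keywords internal
mr_result <- function(exposure, theta, var_theta, pval, method, n_snps,
                      statistic = NULL, status = "ok") {
  z <- if (is.na(theta) || is.na(var_theta)) NA_real_
       else theta / sqrt(var_theta)
  structure(list(exposure = exposure, theta = theta, var_theta = var_theta,
                 z = z, pval = pval, method = method, n_snps = n_snps,
                 statistic = statistic, status = status),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR result [%s] exposure '%s': ", x$method, x$exposure))
  if (x$status != "ok") {
    cat(x$status, "\n")
  } else {
    cat(sprintf("theta = %.4g (se %.4g), z = %.3f, P = %.3g, %d SNP(s)\n",
                x$theta, sqrt(x$var_theta), x$z, x$pval, x$n_snps))
  }
  invisible(x)
}

align_stats <- function(qtl, gwas, ld = NULL) {
  snps <- intersect(qtl$snp, gwas$snp)
  if (!length(snps)) stop("no shared SNPs between QTL and GWAS statistics")
  if (!is.null(ld)) snps <- snps[snps %in% ld$snp]
  if (!length(snps)) stop("no shared SNPs covered by the LD matrix")
  list(qtl = subset_snps(qtl, snps), gwas = subset_snps(gwas, snps),
       ld = if (is.null(ld)) NULL else ld_subset(ld, snps))
}

check_invertible <- function(m, snps, what = "Omega") {
  rc <- rcond(m)
  if (!is.finite(rc) || rc < 1e-10) {
    off <- abs(m / sqrt(diag(m) %o% diag(m)))
    diag(off) <- 0
    ij <- which(off == max(off), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "%s is numerically singular (rcond %.2e); worst-conditioned SNP pair: %s / %s",
      what, rc, snps[ij[1L]], snps[ij[2L]]))
  }
  invisible(rc)
}

#' Inverse-variance weighted MR estimate
#'
#' Fixed-effect IVW causal-effect estimate of the outcome on one exposure,
#' assuming uncorrelated instruments:
#' \deqn{\hat\theta = \frac{\sum_j \hat\beta_{Xj}\hat\beta_{Yj}\hat\sigma_{Yj}^{-2}}
#'                        {\sum_j \hat\beta_{Xj}^2\hat\sigma_{Yj}^{-2}},\quad
#'       \mathrm{var}(\hat\theta) = \Big(\sum_j \hat\beta_{Xj}^2\hat\sigma_{Yj}^{-2}\Big)^{-1}.}
#' Equivalent to [mr_gls()] with an identity LD matrix, and to the
#' no-intercept weighted-least-squares slope of \eqn{\hat\beta_Y} on
#' \eqn{\hat\beta_X} with weights \eqn{\hat\sigma_Y^{-2}}.
#'
#' @param qtl exposure [summary_stats] (the instruments' QTL effects).
#' @param gwas outcome [summary_stats] over the same SNPs.
#' @return an `mr_result`.
#' @export
mr_ivw <- function(qtl, gwas) {
  a <- align_stats(qtl, gwas)
  bx <- a$qtl$beta; by <- a$gwas$beta; w <- a$gwas$se^-2
  denom <- sum(bx^2 * w)
  if (denom == 0) stop("degenerate instruments: all exposure effects are zero")
  theta <- sum(bx * by * w) / denom
  v <- 1 / denom
  z <- theta / sqrt(v)
  mr_result(a$qtl$trait, theta, v, 2 * stats::pnorm(-abs(z)), "ivw",
            length(bx))
}

#' Generalized least squares MR estimate under LD
#'
#' GLS causal-effect estimate that accounts for residual linkage
#' disequilibrium between the instruments after clumping:
#' \deqn{\hat\theta = (\hat\beta_X^\top\Omega^{-1}\hat\beta_X)^{-1}
#'                    \hat\beta_X^\top\Omega^{-1}\hat\beta_Y,\qquad
#'       \Omega = \mathrm{diag}(\hat\sigma_Y)\,R\,\mathrm{diag}(\hat\sigma_Y),}
#' with \eqn{R} the unsquared LD correlation matrix. Reduces exactly to
#' [mr_ivw()] when \eqn{R = I}.
#'
#' @inheritParams mr_ivw
#' @param ld an [ld_matrix] covering the shared SNPs.
#' @return an `mr_result` (its `z` is the GLS z-statistic used by
#'   [gls_z_correlation()] / the Fisher-gamma combiner).
#' @export
mr_gls <- function(qtl, gwas, ld) {
  a <- align_stats(qtl, gwas, ld)
  bx <- a$qtl$beta; by <- a$gwas$beta; sy <- a$gwas$se
  omega <- a$ld$r * (sy %o% sy)
  check_invertible(omega, a$qtl$snp, "Omega")
  oi_bx <- solve(omega, bx)
  denom <- sum(bx * oi_bx)
  if (denom <= 0) stop("degenerate instruments: non-positive quadratic form")
  theta <- sum(oi_bx * by) / denom
  v <- 1 / denom
  z <- theta / sqrt(v)
  mr_result(a$qtl$trait, theta, v, 2 * stats::pnorm(-abs(z)), "gls",
            length(bx))
}

#' Single-SNP summary-data-based MR (SMR) test
#'
#' Approximate 1-df chi-squared statistic for the product of the QTL and
#' GWAS associations at one SNP:
#' \deqn{T = \frac{z_Y^2 z_X^2}{z_Y^2 + z_X^2}.}
#' At \eqn{z_X = z_Y = 0} the limit \eqn{T = 0}, \eqn{P = 1} is returned.
#'
#' @param z_x QTL z-value.
#' @param z_y GWAS z-value.
#' @param beta_x,beta_y optional effect sizes; when both are supplied the
#'   Wald ratio `beta_y/beta_x` is reported as the point estimate.
#' @param exposure exposure label carried into the result.
#' @return an `mr_result` with `statistic` = \eqn{T}.
#' @export
mr_smr <- function(z_x, z_y, beta_x = NULL, beta_y = NULL, exposure = "") {
  stopifnot(is.finite(z_x), is.finite(z_y))
  s <- z_x^2 + z_y^2
  t_smr <- if (s == 0) 0 else (z_y^2 * z_x^2) / s
  pval <- stats::pchisq(t_smr, df = 1, lower.tail = FALSE)
  theta <- if (!is.null(beta_x) && !is.null(beta_y) && beta_x != 0)
    beta_y / beta_x else NA_real_
  res <- mr_result(exposure, theta, NA_real_, pval, "smr", 1L,
                   statistic = t_smr)
  res$z <- sign(if (is.na(theta)) z_x * z_y else theta) * sqrt(t_smr)
  res
}

#' SMR P-values across exposures and SNPs
#'
#' `mode = "singleSNP"`: for each exposure, the SNP with the strongest QTL
#' (largest \eqn{|z_X|}) yields one SMR P-value. `mode = "allSNPs"`: every
#' SNP-by-exposure pair yields a P-value.
#'
#' @param qtls named list of exposure [summary_stats].
#' @param gwas outcome [summary_stats].
#' @param mode `"singleSNP"` or `"allSNPs"`.
#' @return data.frame with columns `exposure`, `snp`, `statistic`, `pval`.
#' @export
mr_smr_multi <- function(qtls, gwas, mode = c("singleSNP", "allSNPs")) {
  mode <- match.arg(mode)
  rows <- list()
  for (k in seq_along(qtls)) {
    q <- qtls[[k]]
    lab <- if (!is.null(names(qtls)) && nzchar(names(qtls)[k]))
      names(qtls)[k] else q$trait
    shared <- intersect(q$snp, gwas$snp)
    if (!length(shared)) {
      warning("exposure '", lab, "' shares no SNPs with the GWAS; skipped")
      next
    }
    q <- subset_snps(q, shared); g <- subset_snps(gwas, shared)
    idx <- if (mode == "singleSNP") which.max(abs(q$z)) else seq_along(shared)
    for (j in idx) {
      r <- mr_smr(q$z[j], g$z[j], q$beta[j], g$beta[j], exposure = lab)
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = lab, snp = shared[j], statistic = r$statistic,
        pval = r$pval, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no exposure shared SNPs with the GWAS")
  do.call(rbind, rows)
}

gsmr_cov_matrix <- function(bx, by, vx, vy, r) {
  p <- length(bx)
  v <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) {
      v[i, j] <- (by[i]^2 / bx[i]^2) *
        (vx[i] / bx[i]^2 + vy[i] / by[i]^2 - vx[i]^2 / bx[i]^4)
    } else {
      v[i, j] <- r[i, j] * sqrt(vy[i] * vy[j]) / (bx[i] * bx[j]) +
        (by[i] * by[j] / (bx[i] * bx[j])) *
          (r[i, j] * sqrt(vx[i] * vx[j]) / (bx[i] * bx[j]) -
             vx[i] * vx[j] / (bx[i]^2 * bx[j]^2))
    }
  }
  v
}

#' Generalized summary-data-based MR (GSMR)
#'
#' Extends SMR to multiple, possibly correlated instruments. Per-SNP Wald
#' ratios \eqn{\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}} are combined by
#' generalized least squares with a second-order covariance matrix \eqn{V}
#' built from the sampling variances of both sets of effect estimates and
#' the unsquared LD correlations:
#' \deqn{\hat\theta = (\mathbf{1}^\top V^{-1}\mathbf{1})^{-1}
#'                    \mathbf{1}^\top V^{-1}\hat\theta,\qquad
#'       T = \hat\theta^2/\mathrm{var}(\hat\theta) \sim \chi^2_1.}
#' SNP filters follow the method's defaults: drop one of any pair with
#' \eqn{r^2 \ge} `r2_filter` (visiting SNPs in descending \eqn{|z_X|}) and
#' drop SNPs with \eqn{z_X^2 \le} `chi2_filter`; at least `min_snps` must
#' survive or the result carries status `insufficient_ivs`.
#'
#' @inheritParams mr_gls
#' @param r2_filter squared-LD filter threshold (default 0.95).
#' @param chi2_filter instrument-strength filter on \eqn{z_X^2} (default 10).
#' @param min_snps minimum surviving instruments (default 10, the method's
#'   recommendation; lower it for designs with few SNPs).
#' @return an `mr_result`; `status` is `"insufficient_ivs"` (with `NA`
#'   estimate) when fewer than `min_snps` SNPs survive the filters.
#' @export
mr_gsmr <- function(qtl, gwas, ld, r2_filter = 0.95, chi2_filter = 10,
                    min_snps = 10) {
  a <- align_stats(qtl, gwas, ld)
  keep <- which(a$qtl$z^2 > chi2_filter & a$qtl$beta != 0)
  ord <- keep[order(-abs(a$qtl$z[keep]))]
  sel <- integer(0)
  r <- a$ld$r
  for (i in ord) {
    if (!length(sel) || all(r[i, sel]^2 < r2_filter)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  if (length(sel) < max(min_snps, 2L)) {
    return(mr_result(a$qtl$trait, NA_real_, NA_real_, NA_real_, "gsmr",
                     length(sel), status = "insufficient_ivs"))
  }
  bx <- a$qtl$beta[sel]; by <- a$gwas$beta[sel]
  vx <- a$qtl$se[sel]^2; vy <- a$gwas$se[sel]^2
  v <- gsmr_cov_matrix(bx, by, vx, vy, r[sel, sel, drop = FALSE])
  check_invertible(v, a$qtl$snp[sel], "GSMR covariance matrix V")
  one <- rep(1, length(sel))
  vi1 <- solve(v, one)
  denom <- sum(vi1)
  theta <- sum(vi1 * (by / bx)) / denom
  var_theta <- 1 / denom
  if (var_theta <= 0)
    stop("GSMR covariance matrix V is not positive definite")
  t_gsmr <- theta^2 / var_theta
  pval <- stats::pchisq(t_gsmr, df = 1, lower.tail = FALSE)
  mr_result(a$qtl$trait, theta, var_theta, pval, "gsmr", length(sel),
            statistic = t_gsmr)
}

#' Multivariable MR joint test across exposures
#'
#' Regresses the outcome effects on the exposure-effect matrix,
#' \eqn{\hat\beta_{Yj} = \sum_k \theta_k \hat\beta_{Xkj} + \epsilon} with
#' weights \eqn{\hat\sigma_{Yj}^{-2}} (or full GLS with
#' \eqn{\Omega = \mathrm{diag}(\hat\sigma_Y) R\, \mathrm{diag}(\hat\sigma_Y)}
#' when an LD matrix is supplied), and tests the joint null
#' \eqn{\theta_1 = \cdots = \theta_m = 0} with an m-df Wald statistic.
#' Requires more instruments than exposures (p >= m + 1) and a full-rank
#' design; otherwise the result has status `insufficient_ivs`.
#'
#' @param qtls named list of m exposure [summary_stats] sharing p SNPs.
#' @param gwas outcome [summary_stats].
#' @param ld optional [ld_matrix] for correlated instruments.
#' @return an object of class `mvmr_result`: list with `thetas`,
#'   `cov_theta`, `joint_stat`, `df`, `pval`, `status`, `snps`.
#' @export
mr_mvmr <- function(qtls, gwas, ld = NULL) {
  m <- length(qtls)
  stopifnot(m >= 1L)
  labs <- vapply(seq_len(m), function(k) {
    if (!is.null(names(qtls)) && nzchar(names(qtls)[k])) names(qtls)[k]
    else qtls[[k]]$trait
  }, character(1))
  snps <- Reduce(intersect, lapply(qtls, `[[`, "snp"))
  snps <- intersect(snps, gwas$snp)
  if (!is.null(ld)) snps <- intersect(snps, ld$snp)
  p <- length(snps)
  insufficient <- function() structure(
    list(thetas = rep(NA_real_, m), cov_theta = NULL, joint_stat = NA_real_,
         df = m, pval = NA_real_, status = "insufficient_ivs",
         exposures = labs, snps = snps),
    class = "mvmr_result")
  if (p < m + 1L) return(insufficient())
  x <- vapply(qtls, function(q) subset_snps(q, snps)$beta, numeric(p))
  x <- matrix(x, nrow = p, ncol = m)
  if (qr(x)$rank < m) return(insufficient())
  g <- subset_snps(gwas, snps)
  omega <- if (is.null(ld)) diag(g$se^2, p)
           else ld_subset(ld, snps)$r * (g$se %o% g$se)
  check_invertible(omega, snps, "Omega")
  oi_x <- solve(omega, x)
  xtox <- crossprod(x, oi_x)
  check_invertible(xtox, labs, "design information matrix")
  theta <- solve(xtox, crossprod(oi_x, g$beta))
  joint <- drop(t(theta) %*% xtox %*% theta)
  structure(list(thetas = drop(theta), cov_theta = solve(xtox),
                 joint_stat = joint, df = m,
                 pval = stats::pchisq(joint, df = m, lower.tail = FALSE),
                 status = "ok", exposures = labs, snps = snps),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable MR joint test (%d exposures, %d SNPs): ",
              x$df, length(x$snps)))
  if (x$status != "ok") cat(x$status, "\n")
  else cat(sprintf("Wald = %.3f on %d df, P = %.3g\n",
                   x$joint_stat, x$df, x$pval))
  invisible(x)
}
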