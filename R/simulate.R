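.calib_cache <- new.env(parent = emptyenv())

# P(Z1 < a, Z2 < a) for standard bivariate normal with correlation rho,
# by 1-D quadrature over the conditional CDF.
binorm_orthant <- function(a, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a)^2)
  f <- function(x) stats::dnorm(x) *
    stats::pnorm((a - rho * x) / sqrt(1 - rho^2))
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

# Latent equicorrelation giving Bernoulli(maf) haplotype correlation r.
latent_correlation <- function(r, maf) {
  key <- sprintf("%.10f_%.10f", r, maf)
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- stats::qnorm(maf)
  bern_corr <- function(rho) {
    (binorm_orthant(a, rho) - maf^2) / (maf * (1 - maf))
  }
  rho <- stats::uniroot(function(x) bern_corr(x) - r,
                        interval = c(1e-12, 1 - 1e-9),
                        tol = 1e-10)$root
  .calib_cache[[key]] <- rho
  rho
}

#' Simulate correlated SNP dosages with Binomial(2, maf) marginals
#'
#' Each subject's dosage at SNP j is the sum of two independent haplotypes;
#' each haplotype is a vector of Bernoulli(maf) indicators generated by
#' thresholding a one-factor equicorrelated Gaussian (a Gaussian copula),
#' with the latent correlation calibrated numerically so that the realized
#' pairwise dosage correlation equals \eqn{\sqrt{r^2}}. Marginals are
#' exactly Binomial(2, maf).
#'
#' @param n number of subjects.
#' @param p number of SNPs.
#' @param maf minor-allele frequency in (0, 0.5].
#' @param r2 target pairwise squared correlation between dosages, in
#'   \[0, 1).
#' @return an n x p integer matrix of dosages in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(n, p, maf = 0.3, r2 = 0) {
  stopifnot(n >= 1, p >= 1)
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)")
  if (r2 == 0 || p == 1L) {
    g <- matrix(stats::rbinom(n * p, 2L, maf), nrow = n, ncol = p)
  } else {
    rho <- latent_correlation(sqrt(r2), maf)
    a <- stats::qnorm(maf)
    hap <- function() {
      f <- stats::rnorm(n)
      lat <- sqrt(rho) * f +
        sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
      (lat < a) + 0L
    }
    g <- hap() + hap()
  }
  colnames(g) <- sprintf("snp%02d", seq_len(p))
  g
}

#' Simulation configuration for the pleiotropy benchmark
#'
#' Bundles and validates the generative parameters of the benchmark: the
#' pleiotropy model (exposures in series or in parallel), the number of
#' SNPs and their pairwise LD, the instrument strength `alpha`, the causal
#' effect `beta_x` of the terminal exposure path on the outcome, the
#' outcome type, and the sampling design (sample overlap between the QTL
#' and GWAS studies, shared vs independent QTL samples across omics,
#' controls-only QTL estimation for binary outcomes).
#'
#' @param pleiotropy `"vertical"` (exposures in series) or `"horizontal"`
#'   (in parallel).
#' @param p number of SNPs used as instruments (the benchmark uses 5 or 20).
#' @param r2 target pairwise LD between SNPs (0, 0.01 or 0.2 in the
#'   benchmark); any value in \[0, 1) is accepted.
#' @param alpha instrument strength: the per-SNP loading on the first
#'   exposure is `alpha/p` (0.5, 1 or 2 in the benchmark).
#' @param beta_x causal effect of the exposure path on the outcome (0 for
#'   type I error, 0.1 for power).
#' @param outcome `"continuous"` or `"binary"`.
#' @param overlap fraction of QTL-study subjects shared with the GWAS
#'   study (0, 0.5 or 1 in the benchmark).
#' @param shared_qtl_samples use the same subjects for all three omics'
#'   QTLs (`TRUE`) or independent samples per omic (`FALSE`).
#' @param controls_only_qtl for binary outcomes, estimate QTLs on control
#'   subjects only.
#' @param n_per_arm cases (and controls) per study arm; 250 gives the
#'   500-subject studies of the benchmark.
#' @param population_n size of the oversampled population from which the
#'   binary-outcome case/control quotas are drawn (default 5000; continuous
#'   designs size the population from the draws needed).
#' @param maf minor-allele frequency of the simulated SNPs.
#' @param snp_effect_mode `"constant"` per-SNP loadings `alpha/p`, or
#'   `"beta_distributed"` i.i.d. `alpha/p * Beta(beta_params)` loadings.
#' @param beta_params shape parameters for `"beta_distributed"` loadings.
#' @param seed optional integer seed consumed by [simulate_replicate()].
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(pleiotropy = c("vertical", "horizontal"),
                       p = 5, r2 = 0.2, alpha = 1, beta_x = 0,
                       outcome = c("continuous", "binary"),
                       overlap = 0, shared_qtl_samples = TRUE,
                       controls_only_qtl = TRUE, n_per_arm = 250,
                       population_n = NULL, maf = 0.3,
                       snp_effect_mode = c("constant", "beta_distributed"),
                       beta_params = c(1, 1), seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  outcome <- match.arg(outcome)
  snp_effect_mode <- match.arg(snp_effect_mode)
  p <- as.integer(p)
  stopifnot(p >= 1L, r2 >= 0, r2 < 1, alpha > 0,
            overlap >= 0, overlap <= 1, n_per_arm >= 2,
            maf > 0, maf <= 0.5, length(beta_params) == 2L,
            all(beta_params > 0))
  if (is.null(population_n))
    population_n <- if (outcome == "binary") 5000L else NA_integer_
  structure(list(pleiotropy = pleiotropy, p = p, r2 = r2, alpha = alpha,
                 beta_x = beta_x, outcome = outcome, overlap = overlap,
                 shared_qtl_samples = isTRUE(shared_qtl_samples),
                 controls_only_qtl = isTRUE(controls_only_qtl),
                 n_per_arm = as.integer(n_per_arm),
                 population_n = population_n, maf = maf,
                 snp_effect_mode = snp_effect_mode,
                 beta_params = as.numeric(beta_params),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Write / read a simulation configuration as key: value text
#'
#' @param config a [sim_config] object.
#' @param path file path.
#' @return `path` invisibly (`write_sim_config`); a `sim_config`
#'   (`read_sim_config`).
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- vapply(config, function(v)
    if (is.null(v)) "" else paste(format(v, digits = 17), collapse = ","),
    character(1))
  writeLines(sprintf("%s: %s", names(config), vals), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  named <- stats::setNames(as.list(vals), trimws(keys))
  conv <- function(key, f) {
    v <- named[[key]]
    if (is.null(v) || !nzchar(v) || identical(v, "NA")) NULL else f(v)
  }
  args <- list(
    pleiotropy = conv("pleiotropy", identity),
    p = conv("p", as.integer), r2 = conv("r2", as.numeric),
    alpha = conv("alpha", as.numeric), beta_x = conv("beta_x", as.numeric),
    outcome = conv("outcome", identity),
    overlap = conv("overlap", as.numeric),
    shared_qtl_samples = conv("shared_qtl_samples", as.logical),
    controls_only_qtl = conv("controls_only_qtl", as.logical),
    n_per_arm = conv("n_per_arm", as.integer),
    population_n = conv("population_n", as.integer),
    maf = conv("maf", as.numeric),
    snp_effect_mode = conv("snp_effect_mode", identity),
    beta_params = conv("beta_params", function(v)
      as.numeric(strsplit(v, ",")[[1]])),
    seed = conv("seed", as.integer))
  do.call(sim_config, args[!vapply(args, is.null, logical(1))])
}

snp_loadings <- function(config, n_snps) {
  base <- config$alpha / config$p
  if (config$snp_effect_mode == "constant") rep(base, n_snps)
  else base * stats::rbeta(n_snps, config$beta_params[1], config$beta_params[2])
}

draw_overlapping <- function(target, pool_overlap, pool_rest, n_overlap) {
  if (n_overlap > length(pool_overlap) ||
      (target - n_overlap) > length(pool_rest))
    stop("population exhausted before sampling quotas were met; ",
         "increase population_n")
  ov <- if (n_overlap > 0)
    sample(pool_overlap, n_overlap) else integer(0)
  rest <- if (target - n_overlap > 0)
    sample(pool_rest, target - n_overlap) else integer(0)
  c(ov, rest)
}

#' Simulate one replicate cohort under a pleiotropy model
#'
#' Generates individual-level dosages, the confounder U, the three omics
#' exposures, and the outcome, then assigns subjects to the GWAS sample and
#' the per-omic QTL samples with the configured overlap.
#'
#' Vertical pleiotropy (exposures in series):
#' \deqn{X_1 = \tfrac{\alpha}{p}\textstyle\sum_j Z_j + U + \epsilon_1,\;
#'       X_2 = 2X_1 - U + \epsilon_2,\;
#'       X_3 = -0.5X_2 + U + \epsilon_3,}
#' \deqn{Y_C = \beta_X X_3 - U + \epsilon_Y,\quad
#'       \mathrm{logit}(\tau) = -2 + \beta_X X_3 - U.}
#' Horizontal pleiotropy (in parallel): \eqn{X_1} loads on all p SNPs,
#' \eqn{X_2} on the first \eqn{\lfloor p/2\rfloor} with loading
#' \eqn{-\alpha/p} and confounder \eqn{-U}, \eqn{X_3} on the remaining SNPs
#' with \eqn{-U}; \eqn{Y_C = \beta_X\sum_k X_k + U + \epsilon_Y} and
#' \eqn{\mathrm{logit}(\tau) = -2 + \beta_X\sum_k X_k + U}. All of
#' \eqn{U, \epsilon} are independent standard normal.
#'
#' Binary outcomes oversample a population of `population_n` subjects and
#' draw `n_per_arm` cases plus `n_per_arm` controls for the GWAS and
#' `n_per_arm` (control, by default) subjects per omic for the QTLs;
#' continuous outcomes use studies of `2 * n_per_arm` subjects each.
#'
#' @param config a [sim_config].
#' @return a list of class `replicate_data`: `genotypes`, `exposures`
#'   (n x 3), `confounder`, `outcome`, `gwas_idx`, `qtl_idx` (list of three
#'   index vectors), `config`.
#' @export
simulate_replicate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_study <- 2L * config$n_per_arm
  n_omic_samples <- if (config$shared_qtl_samples) 1L else 3L
  if (config$outcome == "continuous") {
    n_ov <- round(config$overlap * n_study)
    n_total <- n_study + n_omic_samples * (n_study - n_ov)
  } else {
    n_total <- config$population_n
  }
  z <- simulate_genotypes(n_total, config$p, config$maf, config$r2)
  u <- stats::rnorm(n_total)
  p <- config$p
  h <- p %/% 2L
  if (config$pleiotropy == "vertical") {
    x1 <- drop(z %*% snp_loadings(config, p)) + u + stats::rnorm(n_total)
    x2 <- 2 * x1 - u + stats::rnorm(n_total)
    x3 <- -0.5 * x2 + u + stats::rnorm(n_total)
    lin <- config$beta_x * x3 - u
  } else {
    x1 <- drop(z %*% snp_loadings(config, p)) + u + stats::rnorm(n_total)
    x2 <- drop(z[, seq_len(h), drop = FALSE] %*%
                 (-snp_loadings(config, h))) - u + stats::rnorm(n_total)
    x3 <- if (h < p)
      drop(z[, (h + 1L):p, drop = FALSE] %*%
             snp_loadings(config, p - h)) - u + stats::rnorm(n_total)
    else -u + stats::rnorm(n_total)
    lin <- config$beta_x * (x1 + x2 + x3) + u
  }
  if (config$outcome == "continuous") {
    y <- lin + stats::rnorm(n_total)
    gwas_idx <- seq_len(n_study)
    n_keep <- n_study - round(config$overlap * n_study)
    qtl_idx <- vector("list", 3L)
    nxt <- n_study
    for (k in seq_len(n_omic_samples)) {
      n_ov <- n_study - n_keep
      idx <- c(if (n_ov > 0) seq_len(n_ov) else integer(0),
               if (n_keep > 0) nxt + seq_len(n_keep) else integer(0))
      nxt <- nxt + n_keep
      qtl_idx[[k]] <- idx
    }
    if (config$shared_qtl_samples)
      qtl_idx <- rep(qtl_idx[1L], 3L)
  } else {
    tau <- stats::plogis(-2 + lin)
    y <- stats::rbinom(n_total, 1L, tau)
    cases <- which(y == 1L)
    controls <- which(y == 0L)
    if (length(cases) < config$n_per_arm ||
        length(controls) < config$n_per_arm)
      stop("population exhausted before case/control quotas were met; ",
           "increase population_n")
    gwas_cases <- sample(cases, config$n_per_arm)
    gwas_controls <- sample(controls, config$n_per_arm)
    gwas_idx <- c(gwas_cases, gwas_controls)
    n_ov <- round(config$overlap * config$n_per_arm)
    pool_rest <- if (config$controls_only_qtl)
      setdiff(controls, gwas_idx) else setdiff(seq_len(n_total), gwas_idx)
    qtl_idx <- vector("list", 3L)
    for (k in seq_len(n_omic_samples)) {
      qtl_idx[[k]] <- draw_overlapping(config$n_per_arm, gwas_controls,
                                       pool_rest, n_ov)
      pool_rest <- setdiff(pool_rest, qtl_idx[[k]])
    }
    if (config$shared_qtl_samples)
      qtl_idx <- rep(qtl_idx[1L], 3L)
  }
  structure(list(genotypes = z,
                 exposures = cbind(X1 = x1, X2 = x2, X3 = x3),
                 confounder = u, outcome = y,
                 gwas_idx = gwas_idx, qtl_idx = qtl_idx, config = config),
            class = "replicate_data")
}

# Vectorized simple-regression scan: slope, se of y ~ Z_j for each column.
ols_scan <- function(y, z) {
  n <- length(y)
  zc <- sweep(z, 2L, colMeans(z))
  yc <- y - mean(y)
  szz <- colSums(zc^2)
  beta <- colSums(zc * yc) / szz
  rss <- sum(yc^2) - beta^2 * szz
  rss[rss < 0] <- 0
  se <- sqrt(rss / (n - 2) / szz)
  list(beta = beta, se = se)
}

logistic_scan <- function(y, z) {
  p <- ncol(z)
  beta <- se <- numeric(p)
  for (j in seq_len(p)) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, z[, j]), y, family = stats::binomial(),
                     control = list(epsilon = 1e-8, maxit = 50L)))
    if (!fit$converged) { beta[j] <- NA; se[j] <- NA; next }
    cov <- tryCatch(chol2inv(chol(crossprod(
      cbind(1, z[, j]) * sqrt(fit$weights)))), error = function(e) NULL)
    if (is.null(cov)) { beta[j] <- NA; se[j] <- NA; next }
    beta[j] <- fit$coefficients[2L]
    se[j] <- sqrt(cov[2L, 2L])
  }
  list(beta = beta, se = se)
}

#' Compute summary statistics and empirical LD from a simulated replicate
#'
#' Per SNP and exposure, the slope and standard error of the simple linear
#' regression of the exposure on the dosage over that omic's QTL sample;
#' per SNP, the linear (continuous outcome) or logistic (binary outcome)
#' regression of the outcome on the dosage over the GWAS sample; and the
#' empirical unsquared dosage correlation matrix over the GWAS sample.
#' SNPs monomorphic in any used subsample (or with a non-converged
#' logistic fit) are excluded with a warning.
#'
#' @param replicate a `replicate_data` from [simulate_replicate()].
#' @return list with `qtls` (named list of three [summary_stats]), `gwas`
#'   (a [summary_stats]), and `ld` (an [ld_matrix]).
#' @export
compute_summary <- function(replicate) {
  stopifnot(inherits(replicate, "replicate_data"))
  z <- replicate$genotypes
  config <- replicate$config
  samples <- c(replicate$qtl_idx, list(replicate$gwas_idx))
  ok <- rep(TRUE, ncol(z))
  for (idx in samples)
    ok <- ok & apply(z[idx, , drop = FALSE], 2L, stats::var) > 0
  qtls <- vector("list", 3L)
  names(qtls) <- colnames(replicate$exposures)
  gwas <- NULL
  repeat {
    if (!any(ok)) stop("all SNPs monomorphic in a subsample")
    zs <- z[, ok, drop = FALSE]
    for (k in 1:3) {
      idx <- replicate$qtl_idx[[k]]
      fit <- ols_scan(replicate$exposures[idx, k], zs[idx, , drop = FALSE])
      qtls[[k]] <- list(beta = fit$beta, se = fit$se)
    }
    idx <- replicate$gwas_idx
    gfit <- if (config$outcome == "binary")
      logistic_scan(replicate$outcome[idx], zs[idx, , drop = FALSE])
    else ols_scan(replicate$outcome[idx], zs[idx, , drop = FALSE])
    bad <- !is.finite(gfit$beta) | !is.finite(gfit$se) | gfit$se <= 0
    for (k in 1:3)
      bad <- bad | !is.finite(qtls[[k]]$se) | qtls[[k]]$se <= 0
    if (!any(bad)) { gwas <- gfit; break }
    ok[which(ok)[bad]] <- FALSE
  }
  if (!all(ok))
    warning(sum(!ok), " SNP(s) excluded (monomorphic or unstable fit)")
  snps <- colnames(z)[ok]
  out_qtls <- lapply(1:3, function(k)
    summary_stats(snps, qtls[[k]]$beta, qtls[[k]]$se,
                  trait = names(qtls)[k]))
  names(out_qtls) <- names(qtls)
  gwas_ss <- summary_stats(snps, gwas$beta, gwas$se, trait = "Y")
  r <- stats::cor(z[replicate$gwas_idx, ok, drop = FALSE])
  list(qtls = out_qtls, gwas = gwas_ss, ld = ld_matrix(snps, r))
}
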