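# Shared fixture builders: everything is generated in code at test time.

snp_ids <- function(p) sprintf("snp%02d", seq_len(p))

rand_stats <- function(p, trait = "X", beta_sd = 1, se_range = c(0.05, 0.3)) {
  summary_stats(snp_ids(p),
                beta = rnorm(p, sd = beta_sd),
                se = runif(p, se_range[1], se_range[2]),
                trait = trait)
}

# Random positive-definite correlation matrix with unit diagonal.
rand_ld <- function(p, strength = 3) {
  a <- matrix(rnorm(p * (p + strength)), p + strength, p)
  r <- stats::cov2cor(crossprod(a))
  ld_matrix(snp_ids(p), r)
}

# Draws of the standard S1-parameterized stable law with alpha = beta = 1
# (Chambers-Mallows-Stuck), used as a Monte-Carlo oracle for the HMP tail.
rstable11 <- function(n) {
  th <- runif(n, -pi / 2, pi / 2)
  w <- rexp(n)
  (2 / pi) * ((pi / 2 + th) * tan(th) -
                log((w * cos(th) * (pi / 2)) / (pi / 2 + th)))
}

# Correlated null z-scores (equicorrelation rho) and their two-sided P's.
null_pvals <- function(n, m, rho) {
  s <- matrix(rho, m, m)
  diag(s) <- 1
  z <- matrix(rnorm(n * m), ncol = m) %*% chol(s)
  list(p = 2 * pnorm(-abs(z)), sigma = s)
}

# Independent GSMR oracle: builds V entry by entry from the second-order
# ratio-variance and ratio-covariance formulas and solves the GLS system
# directly (no shared code with mr_gsmr beyond base solve()).
gsmr_oracle <- function(bx, by, sx, sy, r) {
  p <- length(bx)
  theta <- by / bx
  v <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    v[i, i] <- (by[i]^2 / bx[i]^2) *
      (sx[i]^2 / bx[i]^2 + sy[i]^2 / by[i]^2 - sx[i]^4 / bx[i]^4)
    for (j in seq_len(p)[-i]) {
      v[i, j] <- r[i, j] * sy[i] * sy[j] / (bx[i] * bx[j]) +
        (by[i] * by[j] / (bx[i] * bx[j])) *
          (r[i, j] * sx[i] * sx[j] / (bx[i] * bx[j]) -
             (sx[i]^2 * sx[j]^2) / (bx[i]^2 * bx[j]^2))
    }
  }
  vinv1 <- solve(v, rep(1, p))
  est <- sum(vinv1 * theta) / sum(vinv1)
  list(theta = est, var = 1 / sum(vinv1))
}

# Exhaustive greedy clumping oracle: literal restatement of the rule,
# independent of ld_clump's implementation.
clump_oracle <- function(snp, pval, r2, pos, r2_max, dist_max) {
  ord <- order(pval, snp)
  sel <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (s in sel) {
      if (r2[i, s] >= r2_max) conflict <- TRUE
      if (!is.null(pos) && abs(pos[i] - pos[s]) <= dist_max) conflict <- TRUE
    }
    if (!conflict) sel <- c(sel, i)
  }
  snp[sel]
}

quick_config <- function(...) {
  args <- utils::modifyList(
    list(pleiotropy = "vertical", p = 5, r2 = 0.2, alpha = 1,
         beta_x = 0, outcome = "continuous", overlap = 0),
    list(...))
  do.call(sim_config, args)
}
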