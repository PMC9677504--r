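test_that("IVW reduces to the Wald ratio for one SNP and pools replicates", {
  qtl <- summary_stats("rs1", beta = 0.5, se = 0.1, trait = "X1")
  gwas <- summary_stats("rs1", beta = 0.1, se = 0.05, trait = "Y")
  r <- mr_ivw(qtl, gwas)
  expect_equal(r$theta, 0.2)
  expect_equal(sqrt(r$var_theta), 0.1)
  expect_equal(r$z, 2)

  qtl2 <- summary_stats(c("rs1", "rs2"), beta = c(0.5, 0.5),
                        se = c(0.1, 0.1), trait = "X1")
  gwas2 <- summary_stats(c("rs1", "rs2"), beta = c(0.1, 0.1),
                         se = c(0.05, 0.05), trait = "Y")
  r2 <- mr_ivw(qtl2, gwas2)
  expect_equal(r2$theta, r$theta)
  expect_equal(r2$var_theta, r$var_theta / 2)

  zero <- summary_stats("rs1", beta = 0, se = 0.1)
  expect_error(mr_ivw(zero, gwas), "degenerate")
})

test_that("IVW equals the no-intercept WLS slope from an lm oracle", {
  set.seed(101)
  for (i in 1:10) {
    p <- sample(3:8, 1)
    qtl <- rand_stats(p, "X1")
    gwas <- rand_stats(p, "Y")
    fit <- lm(gwas$beta ~ 0 + qtl$beta, weights = gwas$se^-2)
    r <- mr_ivw(qtl, gwas)
    expect_equal(r$theta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("GLS reduces to IVW under identity LD and matches a direct
           matrix-inversion oracle", {
  set.seed(202)
  p <- 5
  qtl <- rand_stats(p, "X1")
  gwas <- rand_stats(p, "Y")
  ivw <- mr_ivw(qtl, gwas)
  gls <- mr_gls(qtl, gwas, ld_matrix(snp_ids(p), diag(p)))
  expect_equal(gls$theta, ivw$theta, tolerance = 1e-12)
  expect_equal(gls$var_theta, ivw$var_theta, tolerance = 1e-12)
  expect_equal(gls$pval, ivw$pval, tolerance = 1e-12)

  # explicit 2x2 oracle with r12 = 0.5
  q2 <- summary_stats(c("a", "b"), beta = c(0.4, 0.7), se = c(0.1, 0.1))
  g2 <- summary_stats(c("a", "b"), beta = c(0.08, 0.12), se = c(0.04, 0.06))
  r12 <- 0.5
  omega <- matrix(c(0.04^2, r12 * 0.04 * 0.06,
                    r12 * 0.04 * 0.06, 0.06^2), 2)
  oi <- solve(omega)
  denom <- drop(t(q2$beta) %*% oi %*% q2$beta)
  want_theta <- drop(t(q2$beta) %*% oi %*% g2$beta) / denom
  res <- mr_gls(q2, g2, ld_matrix(c("a", "b"), matrix(c(1, r12, r12, 1), 2)))
  expect_equal(res$theta, want_theta, tolerance = 1e-10)
  expect_equal(res$var_theta, 1 / denom, tolerance = 1e-10)

  # duplicate SNP (r = 1) is rank deficient
  dup <- ld_matrix(c("a", "b"), matrix(c(1, 1, 1, 1), 2))
  expect_error(mr_gls(q2, g2, dup), "singular")
})

test_that("SMR statistic, chi-squared calibration and degenerate limit", {
  expect_equal(mr_smr(2, 2)$statistic, 2)
  expect_equal(mr_smr(4, 3)$statistic, 144 / 25)
  expect_equal(mr_smr(4, 3)$pval,
               pchisq(5.76, df = 1, lower.tail = FALSE))
  z0 <- mr_smr(0, 0)
  expect_equal(z0$statistic, 0)
  expect_equal(z0$pval, 1)
})

test_that("multi-exposure SMR selects the strongest QTL or all pairs", {
  set.seed(303)
  q1 <- rand_stats(1, "X1")
  g1 <- rand_stats(1, "Y")
  single <- mr_smr_multi(list(X1 = q1), g1, mode = "singleSNP")
  all1 <- mr_smr_multi(list(X1 = q1), g1, mode = "allSNPs")
  expect_equal(single$pval, all1$pval)

  q2 <- summary_stats(c("s1", "s2"), beta = c(5, 3), se = c(1, 1),
                      trait = "X1")
  g2 <- summary_stats(c("s1", "s2"), beta = c(0.2, 0.4), se = c(0.1, 0.1))
  top <- mr_smr_multi(list(X1 = q2), g2, mode = "singleSNP")
  expect_identical(top$snp, "s1")
  expect_equal(top$pval, mr_smr(5, 2)$pval)

  qtls <- list(X1 = rand_stats(3, "X1"), X2 = rand_stats(3, "X2"))
  gw <- rand_stats(3, "Y")
  expect_equal(nrow(mr_smr_multi(qtls, gw, mode = "allSNPs")), 6L)
})

test_that("GSMR honors its SNP filters and the exchangeable-symmetry case", {
  # two independent identical SNPs: estimate is the common ratio and the
  # variance is half the single-SNP ratio variance
  q <- summary_stats(c("a", "b"), beta = c(0.5, 0.5), se = c(0.05, 0.05))
  g <- summary_stats(c("a", "b"), beta = c(0.2, 0.2), se = c(0.04, 0.04))
  res <- mr_gsmr(q, g, ld_matrix(c("a", "b"), diag(2)), min_snps = 2)
  expect_equal(res$theta, 0.2 / 0.5, tolerance = 1e-12)
  v1 <- (0.2^2 / 0.5^2) *
    (0.05^2 / 0.5^2 + 0.04^2 / 0.2^2 - 0.05^4 / 0.5^4)
  # half the single-ratio variance, up to the (tiny) second-order
  # cross-covariance term that survives even at r = 0
  expect_equal(res$var_theta, v1 / 2, tolerance = 0.01)
  expect_equal(res$var_theta,
               gsmr_oracle(c(0.5, 0.5), c(0.2, 0.2), c(0.05, 0.05),
                           c(0.04, 0.04), diag(2))$var,
               tolerance = 1e-12)

  # a SNP with z_X^2 = 9 fails the chi-squared > 10 instrument filter
  q3 <- summary_stats(c("a", "b", "c"), beta = c(0.5, 0.5, 0.3),
                      se = c(0.05, 0.05, 0.1))  # z^2 = 100, 100, 9
  g3 <- summary_stats(c("a", "b", "c"), beta = c(0.2, 0.21, 0.1),
                      se = c(0.04, 0.04, 0.05))
  res3 <- mr_gsmr(q3, g3, ld_matrix(c("a", "b", "c"), diag(3)),
                  min_snps = 2)
  expect_equal(res3$n_snps, 2L)

  # below min_snps: no estimate, insufficient_ivs status
  res4 <- mr_gsmr(q3, g3, ld_matrix(c("a", "b", "c"), diag(3)),
                  min_snps = 10)
  expect_identical(res4$status, "insufficient_ivs")
  expect_true(is.na(res4$theta))
})

test_that("GSMR matches the elementwise-V oracle on random instances", {
  set.seed(404)
  for (i in 1:15) {
    p <- 5
    ld <- rand_ld(p, strength = 20)  # mild LD so no filter binds
    bx <- runif(p, 1, 3) * sample(c(-1, 1), p, TRUE)
    sx <- runif(p, 0.05, 0.15)
    by <- rnorm(p, sd = 0.5)
    sy <- runif(p, 0.05, 0.15)
    q <- summary_stats(snp_ids(p), bx, sx)
    g <- summary_stats(snp_ids(p), by, sy)
    res <- mr_gsmr(q, g, ld, min_snps = p)
    want <- gsmr_oracle(bx, by, sx, sy, ld$r)
    expect_equal(res$theta, want$theta, tolerance = 1e-9)
    expect_equal(res$var_theta, want$var, tolerance = 1e-9)
  }
})

test_that("multivariable MR reduces to GLS at m = 1 and needs p > m IVs", {
  set.seed(505)
  p <- 5
  qtl <- rand_stats(p, "X1")
  gwas <- rand_stats(p, "Y")
  ld <- rand_ld(p)
  mv <- mr_mvmr(list(X1 = qtl), gwas, ld)
  gls <- mr_gls(qtl, gwas, ld)
  expect_equal(mv$thetas, gls$theta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mv$pval, gls$pval, tolerance = 1e-12)

  qtls3 <- list(X1 = rand_stats(3, "X1"), X2 = rand_stats(3, "X2"),
                X3 = rand_stats(3, "X3"))
  res <- mr_mvmr(qtls3, rand_stats(3, "Y"))
  expect_identical(res$status, "insufficient_ivs")
})

test_that("multivariable MR matches the weighted-least-squares closed form", {
  set.seed(606)
  p <- 6
  qtls <- list(X1 = rand_stats(p, "X1"), X2 = rand_stats(p, "X2"))
  gwas <- rand_stats(p, "Y")
  x <- cbind(qtls$X1$beta, qtls$X2$beta)
  w <- diag(gwas$se^-2)
  want <- solve(t(x) %*% w %*% x, t(x) %*% w %*% gwas$beta)
  res <- mr_mvmr(qtls, gwas)
  expect_equal(res$thetas, drop(want), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$joint_stat,
               drop(t(want) %*% t(x) %*% w %*% x %*% want),
               tolerance = 1e-10)
})

test_that("engines are sign-equivariant and SNP-order invariant", {
  set.seed(707)
  p <- 5
  qtl <- rand_stats(p, "X1")
  gwas <- rand_stats(p, "Y")
  ld <- rand_ld(p)
  flip <- summary_stats(qtl$snp, -qtl$beta, qtl$se, trait = "X1")
  for (f in list(mr_ivw, function(a, b) mr_gls(a, b, ld))) {
    a <- f(qtl, gwas)
    b <- f(flip, gwas)
    expect_equal(b$theta, -a$theta, tolerance = 1e-12)
    expect_equal(b$pval, a$pval, tolerance = 1e-12)
  }
  perm <- sample(p)
  qp <- subset_snps(qtl, qtl$snp[perm])
  gp <- subset_snps(gwas, gwas$snp[perm])
  expect_equal(mr_gls(qp, gp, ld)$pval, mr_gls(qtl, gwas, ld)$pval,
               tolerance = 1e-12)
  expect_equal(mr_ivw(qp, gp)$pval, mr_ivw(qtl, gwas)$pval,
               tolerance = 1e-12)
})
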