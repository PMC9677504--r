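known_engines <- c("ivw", "gls", "smr_singleSNP", "smr_allSNPs", "gsmr",
                   "mvmr", "mvmr_ivw")
known_combiners <- c("cauchy", "hmp", "minp", "fisher_chisq", "fisher_gamma")

apply_combiner <- function(combiner, pvals, weights = NULL, zcorr = NULL) {
  switch(combiner,
         cauchy = combine_cauchy(pvals, weights),
         hmp = combine_hmp(pvals, weights),
         minp = combine_minp(pvals),
         fisher_chisq = combine_fisher_chisq(pvals),
         fisher_gamma = combine_fisher_gamma(pvals, zcorr),
         stop("unknown combiner: ", combiner))
}

#' Gene-level multi-omics MR analysis
#'
#' Runs one MR engine per omics exposure and combines the per-exposure
#' P-values into a single gene-level P-value. Engine/combiner pairs follow
#' the benchmark's compatibility matrix: `fisher_gamma` needs the
#' covariance of GLS z-statistics and is therefore only available with the
#' `gls` engine; `mvmr` is a joint m-df test and ignores the combiner.
#' Exposures whose engine fails (e.g. insufficient instruments) are
#' dropped from the combination with a warning; a gene with no valid
#' exposure returns an `NA` P-value.
#'
#' @param qtls named list of exposure [summary_stats].
#' @param gwas outcome [summary_stats].
#' @param ld an [ld_matrix] (required by the `gls`, `gsmr` and LD-aware
#'   `mvmr` engines).
#' @param engine one of `"ivw"`, `"gls"`, `"smr_singleSNP"`,
#'   `"smr_allSNPs"`, `"gsmr"`, `"mvmr"` (GLS-weighted when `ld` given),
#'   `"mvmr_ivw"` (identity LD).
#' @param combiner one of `"cauchy"`, `"hmp"`, `"minp"`, `"fisher_chisq"`,
#'   `"fisher_gamma"`.
#' @param weights optional combiner weights (default equal).
#' @param clump_r2,clump_dist,positions when `clump_r2` is non-`NULL`,
#'   each exposure's SNPs are LD-clumped via [ld_clump()] before the
#'   engine runs (the simulation benchmark feeds all SNPs, so the default
#'   is no clumping).
#' @param gsmr_opts named list of options forwarded to [mr_gsmr()]
#'   (`r2_filter`, `chi2_filter`, `min_snps`).
#' @return list with `combined` (a `combined_result`, or the
#'   `mvmr_result` for the joint test), `per_exposure` (engine results),
#'   `dropped` (labels of exposures excluded), and `snps_used`.
#' @export
analyze_gene <- function(qtls, gwas, ld = NULL,
                         engine = c("gls", "ivw", "smr_singleSNP",
                                    "smr_allSNPs", "gsmr", "mvmr",
                                    "mvmr_ivw"),
                         combiner = c("cauchy", "hmp", "minp",
                                      "fisher_chisq", "fisher_gamma"),
                         weights = NULL, clump_r2 = NULL, clump_dist = 1e5,
                         positions = NULL, gsmr_opts = list()) {
  engine <- match.arg(engine)
  combiner <- match.arg(combiner)
  if (combiner == "fisher_gamma" && engine != "gls")
    stop("incompatible engine/combiner pair: fisher_gamma is only ",
         "implemented for the gls engine (the combination compatibility ",
         "matrix admits gls alone)")
  if (engine %in% c("gls", "gsmr") && is.null(ld))
    stop("engine '", engine, "' requires an LD matrix")
  labs <- if (!is.null(names(qtls))) names(qtls)
          else vapply(qtls, `[[`, character(1), "trait")
  names(qtls) <- labs
  if (!is.null(clump_r2)) {
    qtls <- lapply(qtls, function(q)
      subset_snps(q, ld_clump(q, ld, r2_max = clump_r2,
                              dist_max = clump_dist, positions = positions)))
  }
  if (startsWith(engine, "mvmr")) {
    res <- mr_mvmr(qtls, gwas, ld = if (engine == "mvmr_ivw") NULL else ld)
    return(list(combined = res, per_exposure = NULL,
                dropped = character(0), snps_used = res$snps))
  }
  if (startsWith(engine, "smr_")) {
    mode <- sub("^smr_", "", engine)
    tab <- mr_smr_multi(qtls, gwas, mode = mode)
    comb <- apply_combiner(combiner, tab$pval, weights)
    return(list(combined = comb, per_exposure = tab,
                dropped = setdiff(labs, unique(tab$exposure)),
                snps_used = unique(tab$snp)))
  }
  per <- vector("list", length(qtls))
  names(per) <- labs
  for (k in seq_along(qtls)) {
    per[[k]] <- tryCatch(
      switch(engine,
             ivw = mr_ivw(qtls[[k]], gwas),
             gls = mr_gls(qtls[[k]], gwas, ld),
             gsmr = do.call(mr_gsmr,
                            c(list(qtls[[k]], gwas, ld), gsmr_opts))),
      error = function(e) simpleError(conditionMessage(e)))
  }
  valid <- vapply(per, function(r)
    inherits(r, "mr_result") && r$status == "ok" && is.finite(r$pval),
    logical(1))
  if (any(!valid))
    warning("exposure(s) dropped from combination: ",
            paste(labs[!valid], collapse = ", "))
  if (!any(valid))
    return(list(combined = combined_result(NA, NA, combiner, numeric(0), 0L),
                per_exposure = per, dropped = labs, snps_used = character(0)))
  pvals <- vapply(per[valid], `[[`, numeric(1), "pval")
  zcorr <- NULL
  if (combiner == "fisher_gamma")
    zcorr <- gls_z_correlation(qtls[valid], ld, gwas = gwas)
  w <- if (is.null(weights)) NULL else weights[valid]
  comb <- apply_combiner(combiner, pvals, w, zcorr)
  list(combined = comb, per_exposure = per, dropped = labs[!valid],
       snps_used = unique(unlist(lapply(qtls[valid], `[[`, "snp"))))
}

parse_method <- function(label) {
  lab <- tolower(label)
  if (lab %in% c("mvmr", "mvmr_gls"))
    return(list(engine = "mvmr", combiner = "cauchy", label = label))
  if (lab == "mvmr_ivw")
    return(list(engine = "mvmr_ivw", combiner = "cauchy", label = label))
  for (cb in known_combiners) {
    suffix <- paste0("_", cb)
    if (endsWith(lab, suffix)) {
      eng <- substr(lab, 1L, nchar(lab) - nchar(suffix))
      eng <- unname(c(smr_singlesnp = "smr_singleSNP",
                      smr_allsnps = "smr_allSNPs",
                      singlesnp = "smr_singleSNP",
                      allsnps = "smr_allSNPs")[eng]) %||% eng
      if (eng %in% known_engines)
        return(list(engine = eng, combiner = cb, label = label))
    }
  }
  stop("cannot parse method label '", label,
       "'; expected <engine>_<combiner>, e.g. GLS_Cauchy")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

replicate_seed <- function(seed, setting_index, rep_index) {
  # distinct streams for up to 1e6 replicates per setting
  as.integer((seed * 1009 + setting_index * 1000003 + rep_index) %%
               2147483647)
}

#' Monte-Carlo benchmark of empirical type I error / power
#'
#' For each simulation setting and replicate: simulate a cohort, compute
#' summary statistics, run every requested engine+combiner method, and
#' record rejection of the gene-level null at `level`. Replicates where an
#' engine fails (singular covariance, insufficient instruments) are
#' counted separately and excluded from the rate denominator. Each
#' setting/replicate has its own RNG seed derived from `seed`, so any cell
#' is reproducible in isolation.
#'
#' @param settings a [sim_config] or list of them.
#' @param methods character vector of method labels such as
#'   `"GLS_Cauchy"`, `"GLS_Fisher_gamma"`, `"GSMR_Cauchy"`,
#'   `"SMR_singleSNP_HMP"`, `"MVMR"`.
#' @param n_reps Monte-Carlo replicates per setting (the full benchmark
#'   uses 10 000).
#' @param level nominal significance level (default 0.05).
#' @param seed integer master seed.
#' @param gsmr_opts options forwarded to [mr_gsmr()]; the default
#'   (`min_snps = 2`, `chi2_filter = 0`) lets designs with as few as five
#'   SNPs exercise GSMR, as the benchmark requires.
#' @return data.frame of class `benchmark_result` with one row per
#'   setting x method: columns `setting`, `method`, `n_reps`, `n_valid`,
#'   `n_failed`, `rejections`, `rate`, `mc_se`.
#' @export
run_benchmark <- function(settings, methods, n_reps = 1000, level = 0.05,
                          seed = 1,
                          gsmr_opts = list(min_snps = 2, chi2_filter = 0)) {
  if (inherits(settings, "sim_config")) settings <- list(settings)
  parsed <- lapply(methods, parse_method)
  rows <- list()
  for (s in seq_along(settings)) {
    config <- settings[[s]]
    nm <- length(methods)
    reject <- valid <- failed <- integer(nm)
    for (r in seq_len(n_reps)) {
      config$seed <- replicate_seed(seed, s, r)
      summ <- tryCatch({
        rep_data <- simulate_replicate(config)
        suppressWarnings(compute_summary(rep_data))
      }, error = function(e) NULL)
      if (is.null(summ)) { failed <- failed + 1L; next }
      for (mi in seq_len(nm)) {
        p <- tryCatch({
          res <- suppressWarnings(analyze_gene(
            summ$qtls, summ$gwas, summ$ld,
            engine = parsed[[mi]]$engine, combiner = parsed[[mi]]$combiner,
            gsmr_opts = gsmr_opts))
          res$combined$pval
        }, error = function(e) NA_real_)
        if (is.na(p)) {
          failed[mi] <- failed[mi] + 1L
        } else {
          valid[mi] <- valid[mi] + 1L
          if (p < level) reject[mi] <- reject[mi] + 1L
        }
      }
    }
    rate <- ifelse(valid > 0, reject / valid, NA_real_)
    rows[[s]] <- data.frame(
      setting = sprintf("%s_p%d_r2%g_a%g_bx%g_ov%g_%s",
                        config$pleiotropy, config$p, config$r2,
                        config$alpha, config$beta_x, config$overlap,
                        config$outcome),
      method = methods, n_reps = n_reps, n_valid = valid,
      n_failed = failed, rejections = reject, rate = rate,
      mc_se = sqrt(rate * (1 - rate) / pmax(valid, 1)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_result", class(out))
  out
}
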