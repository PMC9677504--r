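#' Per-SNP association summary statistics for one trait
#'
#' Container for GWAS or QTL summary statistics: one row per SNP with an
#' effect size (regression slope), its standard error, the Wald z-value and
#' a two-sided P-value. `z` and `pval` are filled in from `beta`/`se` when
#' not supplied; when supplied they are checked for internal consistency.
#'
#' @param snp character vector of SNP identifiers (unique).
#' @param beta numeric vector of per-SNP effect sizes.
#' @param se numeric vector of standard errors (strictly positive).
#' @param z optional numeric vector of z-values; must equal `beta/se`.
#' @param pval optional numeric vector of two-sided P-values in (0, 1].
#'   Exact zeros are clamped to the smallest positive double with a warning.
#' @param n optional sample size (scalar or per SNP).
#' @param trait label for the trait (exposure or outcome).
#'
#' @return An object of class `summary_stats`: a list with elements
#'   `snp`, `beta`, `se`, `z`, `pval`, `n`, `trait`.
#' @examples
#' summary_stats(c("rs1", "rs2"), beta = c(0.5, -0.2), se = c(0.1, 0.1),
#'               trait = "expression")
#' @export
summary_stats <- function(snp, beta, se, z = NULL, pval = NULL, n = NULL,
                          trait = "") {
  snp <- as.character(snp)
  beta <- as.numeric(beta)
  se <- as.numeric(se)
  p <- length(snp)
  if (p < 1L)
    stop("summary_stats requires at least one SNP")
  if (length(beta) != p || length(se) != p)
    stop("snp, beta and se must have equal length")
  if (anyDuplicated(snp))
    stop("duplicate SNP identifiers: ",
         paste(unique(snp[duplicated(snp)]), collapse = ", "))
  if (any(!is.finite(beta)) || any(!is.finite(se)))
    stop("beta and se must be finite")
  if (any(se <= 0))
    stop("standard errors must be strictly positive")

  z_calc <- beta / se
  if (is.null(z)) {
    z <- z_calc
  } else {
    z <- as.numeric(z)
    if (length(z) != p) stop("z must match the number of SNPs")
    tol <- 1e-10 * pmax(abs(z_calc), 1)
    if (any(abs(z - z_calc) > tol))
      stop("supplied z inconsistent with beta/se")
  }
  p_calc <- 2 * stats::pnorm(-abs(z))
  if (is.null(pval)) {
    # extreme z underflows the normal tail; keep P strictly positive
    pval <- pmax(p_calc, .Machine$double.xmin)
  } else {
    pval <- as.numeric(pval)
    if (length(pval) != p) stop("pval must match the number of SNPs")
    if (any(pval == 0)) {
      warning("P-values of exactly 0 clamped to smallest positive double")
      pval[pval == 0] <- .Machine$double.xmin
    }
    if (any(pval < 0 | pval > 1))
      stop("P-values must lie in (0, 1]")
    if (any(abs(pval - p_calc) > 1e-6))
      stop("supplied P-values inconsistent with two-sided normal tail of z")
  }
  if (!is.null(n)) {
    n <- as.numeric(n)
    if (length(n) == 1L) n <- rep(n, p)
    if (length(n) != p) stop("n must be scalar or per SNP")
  }
  structure(list(snp = snp, beta = beta, se = se, z = z, pval = pval,
                 n = n, trait = as.character(trait)[1L]),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Summary statistics for trait '%s' (%d SNPs)\n",
              x$trait, length(x$snp)))
  print(utils::head(as.data.frame(x), 10L))
  if (length(x$snp) > 10L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.summary_stats <- function(x, ...) {
  d <- data.frame(SNP = x$snp, BETA = x$beta, SE = x$se, Z = x$z,
                  P = x$pval, stringsAsFactors = FALSE)
  if (!is.null(x$n)) d$N <- x$n
  d
}

#' @export
length.summary_stats <- function(x) length(x$snp)

#' Subset summary statistics to a set of SNPs, in the given order
#'
#' @param x a [summary_stats] object.
#' @param snps character vector of SNP identifiers, all present in `x`.
#' @return a `summary_stats` object restricted to `snps`, in that order.
#' @export
subset_snps <- function(x, snps) {
  stopifnot(inherits(x, "summary_stats"))
  idx <- match(snps, x$snp)
  if (anyNA(idx))
    stop("SNPs not present in summary statistics: ",
         paste(snps[is.na(idx)], collapse = ", "))
  summary_stats(x$snp[idx], x$beta[idx], x$se[idx], x$z[idx], x$pval[idx],
                if (is.null(x$n)) NULL else x$n[idx], x$trait)
}

#' Read summary statistics from a tab-delimited file
#'
#' Expects a header with columns `SNP`, `BETA`, `SE` (mandatory) and
#' optionally `Z`, `P`, `N`; column names are matched case-insensitively.
#'
#' @param path file path.
#' @param trait trait label attached to the result.
#' @return a [summary_stats] object.
#' @export
read_summary_stats <- function(path, trait = "") {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  nm <- toupper(names(d))
  need <- c("SNP", "BETA", "SE")
  miss <- setdiff(need, nm)
  if (length(miss))
    stop("format error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  col <- function(k) if (k %in% nm) d[[match(k, nm)]] else NULL
  summary_stats(col("SNP"), col("BETA"), col("SE"), z = col("Z"),
                pval = col("P"), n = col("N"), trait = trait)
}

#' Write summary statistics to a tab-delimited file
#'
#' Full double precision is retained so that a read/write round trip is
#' lossless to numerical accuracy.
#'
#' @param x a [summary_stats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) sprintf("%.17g", v))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Unsquared linkage-disequilibrium correlation matrix
#'
#' @param snp character vector of SNP identifiers.
#' @param r square numeric matrix of unsquared correlations: symmetric,
#'   unit diagonal, entries in \[-1, 1\].
#' @return an object of class `ld_matrix` with elements `snp` and `r`.
#' @export
ld_matrix <- function(snp, r) {
  snp <- as.character(snp)
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("format error: LD matrix must be square")
  if (nrow(r) != length(snp)) stop("LD matrix dimension must match snp ids")
  if (anyDuplicated(snp)) stop("duplicate SNP identifiers in LD matrix")
  if (any(!is.finite(r))) stop("LD matrix entries must be finite")
  if (max(abs(r - t(r))) > 1e-8)
    stop("LD matrix asymmetric beyond tolerance 1e-8")
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-8)
    stop("LD matrix diagonal must be 1")
  diag(r) <- 1
  if (max(abs(r)) > 1 + 1e-8) stop("LD correlations must lie in [-1, 1]")
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- list(snp, snp)
  structure(list(snp = snp, r = r), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("LD correlation matrix over %d SNPs\n", length(x$snp)))
  print(x$r[seq_len(min(5, nrow(x$r))), seq_len(min(5, ncol(x$r))), drop = FALSE])
  invisible(x)
}

#' Extract an LD submatrix for a set of SNPs, in the given order
#'
#' @param x an [ld_matrix] object.
#' @param snps SNP identifiers, all present in `x`.
#' @return an `ld_matrix` over `snps`.
#' @export
ld_subset <- function(x, snps) {
  stopifnot(inherits(x, "ld_matrix"))
  idx <- match(snps, x$snp)
  if (anyNA(idx))
    stop("SNPs not present in LD matrix: ",
         paste(snps[is.na(idx)], collapse = ", "))
  ld_matrix(x$snp[idx], x$r[idx, idx, drop = FALSE])
}

#' Read an LD correlation matrix from a plain matrix file
#'
#' The file holds a square numeric matrix, whitespace- or comma-delimited,
#' with an optional single header row of SNP identifiers. When `snp_ids`
#' is given the matrix is aligned (reordered if necessary) to that order.
#'
#' @param path file path.
#' @param snp_ids optional ordered SNP identifiers to align to. Mandatory
#'   when the file has no header row.
#' @return an [ld_matrix] object.
#' @export
read_ld_matrix <- function(path, snp_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error: empty LD matrix file")
  split1 <- strsplit(trimws(lines[1]), "[,\t ]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(split1))))
  header <- NULL
  if (has_header) {
    header <- split1
    lines <- lines[-1]
  }
  rows <- lapply(strsplit(trimws(lines), "[,\t ]+"), function(v)
    suppressWarnings(as.numeric(v)))
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop("format error: ragged rows in LD matrix file")
  m <- do.call(rbind, rows)
  if (any(is.na(m))) stop("format error: non-numeric entries in LD matrix")
  if (nrow(m) != ncol(m)) stop("format error: LD matrix must be square")
  ids <- if (!is.null(header)) header else snp_ids
  if (is.null(ids))
    stop("snp_ids must be supplied when the LD file has no header")
  if (length(ids) != nrow(m))
    stop("format error: header/ids length does not match matrix dimension")
  out <- ld_matrix(ids, m)
  if (!is.null(snp_ids) && !identical(out$snp, as.character(snp_ids)))
    out <- ld_subset(out, snp_ids)
  out
}

#' Write an LD correlation matrix with a header row of SNP ids
#'
#' @param x an [ld_matrix] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(x, path) {
  stopifnot(inherits(x, "ld_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(x$snp, collapse = "\t"), con)
  apply(x$r, 1L, function(row)
    writeLines(paste(sprintf("%.17g", row), collapse = "\t"), con))
  invisible(path)
}

#' Greedy LD clumping by ascending QTL P-value
#'
#' Selects approximately independent index SNPs: candidates are visited in
#' ascending P-value order (ties broken by lexicographically smaller SNP id)
#' and accepted only if their squared correlation with every SNP already
#' selected is below `r2_max` AND their distance to every selected SNP
#' exceeds `dist_max`. The first (smallest-P) SNP is always selected.
#'
#' @param qtl a [summary_stats] object.
#' @param ld an [ld_matrix] covering the SNPs of `qtl`.
#' @param r2_max squared-correlation threshold; a candidate with
#'   \eqn{r^2 \ge} `r2_max` against any selected SNP is rejected. Default 0.2.
#' @param dist_max distance threshold in base pairs; a candidate at distance
#'   \eqn{\le} `dist_max` from any selected SNP is rejected. Default 1e5
#'   (100 kb). Ignored when `positions` is `NULL`.
#' @param positions optional named (or `qtl`-ordered) vector of 1-based
#'   coordinates; distance is the absolute difference.
#' @return character vector of selected SNP ids, in selection order.
#' @export
ld_clump <- function(qtl, ld, r2_max = 0.2, dist_max = 1e5, positions = NULL) {
  stopifnot(inherits(qtl, "summary_stats"), inherits(ld, "ld_matrix"))
  if (length(qtl$snp) < 1L) stop("empty input to ld_clump")
  r <- ld_subset(ld, qtl$snp)$r
  pos <- NULL
  if (!is.null(positions)) {
    if (!is.null(names(positions))) {
      pos <- positions[qtl$snp]
      if (anyNA(pos)) stop("positions missing for some SNPs")
    } else {
      if (length(positions) != length(qtl$snp))
        stop("positions must be named or match the SNP order")
      pos <- positions
    }
  }
  ord <- order(qtl$pval, qtl$snp)
  selected <- integer(0)
  for (i in ord) {
    ok <- TRUE
    if (length(selected)) {
      if (any(r[i, selected]^2 >= r2_max)) ok <- FALSE
      if (ok && !is.null(pos) && any(abs(pos[i] - pos[selected]) <= dist_max))
        ok <- FALSE
    }
    if (ok) selected <- c(selected, i)
  }
  qtl$snp[selected]
}
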