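#' Genotype matrix container
#'
#' Bundles an individuals-by-SNPs dosage matrix (entries 0/1/2, `NA` for
#' missing) with per-SNP metadata. A1 is always the effect allele: all
#' downstream effect sizes (association betas, risk-score weights) are
#' expressed per copy of A1.
#'
#' @param dosage numeric matrix, individuals in rows, SNPs in columns.
#'   Column names, when present, must match `snp_meta$snp`.
#' @param snp_meta data.frame with columns `snp`, `chr`, `pos`, `a1`, `a2`
#'   and optionally `maf`. One row per column of `dosage`.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosage` and `snp_meta`.
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'          dimnames = list(NULL, c("rs1", "rs2"))),
#'   data.frame(snp = c("rs1", "rs2"), chr = c(1, 1),
#'              pos = c(100, 200), a1 = c("A", "G"), a2 = c("G", "T")))
#' dim(g$dosage)
#' @export
genotype_matrix <- function(dosage, snp_meta) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  required <- c("snp", "chr", "pos", "a1", "a2")
  missing_cols <- setdiff(required, names(snp_meta))
  if (length(missing_cols))
    stop("snp_meta is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(snp_meta) != ncol(dosage))
    stop("snp_meta has ", nrow(snp_meta), " rows but dosage has ",
         ncol(dosage), " columns")
  if (anyDuplicated(snp_meta$snp))
    stop("duplicated SNP ids in snp_meta")
  if (any(!is.na(snp_meta$pos) & snp_meta$pos <= 0))
    stop("SNP positions must be positive integers")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("dosage entries must lie in [0, 2]")
  if (!"maf" %in% names(snp_meta)) snp_meta$maf <- NA_real_
  colnames(dosage) <- snp_meta$snp
  structure(list(dosage = dosage, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage rate: %.3g\n", miss))
  cat("  chromosomes:", paste(sort(unique(x$snp_meta$chr)), collapse = " "),
      "\n")
  invisible(x)
}

#' Observed minor allele frequency of each SNP
#'
#' MAF is recomputed from the dosages (folded to be at most 0.5), never
#' trusted from metadata. Missing entries are ignored.
#'
#' @param g a [genotype_matrix()].
#' @return named numeric vector of per-SNP MAFs.
#' @export
observed_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  names(maf) <- g$snp_meta$snp
  maf
}

#' MR estimate container
#'
#' Common output contract shared by every causal estimator in the package:
#' a method label, the causal effect in outcome units per exposure unit,
#' its standard error, a 95% confidence interval, a two-sided p-value, and
#' the number of individuals (one-sample) or SNPs (two-sample) used.
#'
#' @param method character label, e.g. `"IVW"` or `"2SLS"`.
#' @param beta point estimate.
#' @param se standard error.
#' @param p two-sided p-value. Defaults to the normal-based p.
#' @param n sample size, if individual-level.
#' @param nsnp number of instrument SNPs, if summary-level.
#' @param ci_lower,ci_upper confidence limits; default `beta +/- 1.96 se`
#'   using the exact normal quantile.
#' @param diagnostics named list of method-specific extras (first-stage F,
#'   heterogeneity Q, intercept tests, ...).
#' @return an object of class `mr_result`.
#' @export
mr_result <- function(method, beta, se, p = NULL, n = NULL, nsnp = NULL,
                      ci_lower = NULL, ci_upper = NULL,
                      diagnostics = list()) {
  stopifnot(is.finite(beta), is.finite(se), se >= 0)
  z975 <- stats::qnorm(0.975)
  if (is.null(ci_lower)) ci_lower <- beta - z975 * se
  if (is.null(ci_upper)) ci_upper <- beta + z975 * se
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(method = method, beta = beta, se = se,
                 ci_lower = ci_lower, ci_upper = ci_upper, p = p,
                 n = n, nsnp = nsnp, diagnostics = diagnostics),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  size <- if (!is.null(x$nsnp)) paste0(x$nsnp, " SNPs") else
    if (!is.null(x$n)) paste0("n = ", x$n) else ""
  cat(sprintf("%s estimate%s\n", x$method,
              if (nzchar(size)) paste0(" (", size, ")") else ""))
  cat(sprintf("  beta = %.*g (SE %.*g), 95%% CI (%.*g, %.*g), p = %.3g\n",
              digits, x$beta, digits, x$se, digits, x$ci_lower,
              digits, x$ci_upper, x$p))
  if (isTRUE(x$diagnostics$weak_instrument))
    cat("  WARNING: weak instrument (first-stage F < 10)\n")
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper, p = x$p,
             n = if (is.null(x$n)) NA_integer_ else x$n,
             nsnp = if (is.null(x$nsnp)) NA_integer_ else x$nsnp,
             stringsAsFactors = FALSE)
}
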