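#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the number of
#' heterozygotes follows a known distribution under random mating, and the
#' two-sided p-value sums the probabilities of all heterozygote counts
#' whose probability does not exceed that of the observed configuration.
#' This is the convention behind the genotyping-QC threshold p < 5.7e-7.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)   # modal configuration: p = 1
#' hwe_exact_test(50, 0, 50)    # maximal disequilibrium: p ~ 0
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("need at least one genotyped individual")
  # work with the rarer allele so the support is 0..n_rare
  n_a <- 2 * n_aa + n_Aa
  n_rare <- min(n_a, 2L * n - n_a)
  if (n_rare == 0) return(1)
  h_obs <- n_Aa
  h <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(h) up to a constant: 2^h / (n_hom_rare! h! n_hom_common!)
  hom_rare <- (n_rare - h) / 2
  hom_common <- n - hom_rare - h
  logp <- h * log(2) - lgamma(hom_rare + 1) - lgamma(h + 1) -
    lgamma(hom_common + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(h_obs, h)]
  if (is.na(p_obs)) stop("observed heterozygote count incompatible with allele counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Quality-control filter for a genotype matrix
#'
#' Applies the three standard marker filters: per-SNP call rate at least
#' `call_rate_min`, exact Hardy-Weinberg p-value at least `hwe_p_min`, and
#' observed minor allele frequency strictly greater than `maf_min`. MAF
#' and genotype counts are recomputed from the dosages (hard calls after
#' rounding); metadata frequencies are not trusted.
#'
#' @param g a [genotype_matrix()].
#' @param call_rate_min minimum fraction of non-missing genotypes.
#' @param hwe_p_min exclusion threshold for the exact HWE test.
#' @param maf_min SNPs must have MAF strictly above this.
#' @return list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `exclusions`, a data.frame logging each removed SNP with the first
#'   filter it failed (`call_rate`, `maf`, or `hwe`) and the offending
#'   value. An empty result is permitted (with a warning).
#' @export
qc_filter <- function(g, call_rate_min = 0.95, hwe_p_min = 5.7e-7,
                      maf_min = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  call_rate <- colMeans(!is.na(d))
  maf <- unname(observed_maf(g))
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- round(d[, j])
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  reason <- rep(NA_character_, ncol(d))
  value <- rep(NA_real_, ncol(d))
  bad_cr <- call_rate < call_rate_min
  bad_maf <- !bad_cr & (is.na(maf) | maf <= maf_min)
  bad_hwe <- !bad_cr & !bad_maf & (is.na(hwe_p) | hwe_p < hwe_p_min)
  reason[bad_cr] <- "call_rate"; value[bad_cr] <- call_rate[bad_cr]
  reason[bad_maf] <- "maf"; value[bad_maf] <- maf[bad_maf]
  reason[bad_hwe] <- "hwe"; value[bad_hwe] <- hwe_p[bad_hwe]
  drop <- !is.na(reason)
  exclusions <- data.frame(snp = g$snp_meta$snp[drop],
                           reason = reason[drop], value = value[drop],
                           stringsAsFactors = FALSE)
  keep <- which(!drop)
  if (!length(keep)) warning("no SNPs survived quality control")
  meta <- g$snp_meta[keep, , drop = FALSE]
  meta$maf <- maf[keep]
  rownames(meta) <- NULL
  out <- genotype_matrix(d[, keep, drop = FALSE], meta)
  list(genotypes = out, exclusions = exclusions)
}

#' Per-SNP additive association scan
#'
#' For each SNP, ordinary least squares of the phenotype on the dosage plus
#' covariates (additive allelic model); reports the dosage coefficient,
#' its standard error, and the two-sided t-test p-value. Missing dosages
#' are dropped per SNP (complete-case), so `n_used` can vary across SNPs.
#' SNPs that are constant after the missing-drop are returned flagged with
#' `NA` statistics rather than failing the scan.
#'
#' @param g a [genotype_matrix()].
#' @param phenotype numeric vector, one value per individual.
#' @param covariates optional data.frame or matrix of numeric covariates
#'   (e.g. age, sex, drinking status, educational attainment, ancestry
#'   principal components); must be full rank together with the intercept.
#' @return data.frame mirroring a GWAS results table: columns `chr`,
#'   `snp`, `a1`, `a2`, `maf`, `pos`, `beta`, `se`, `p`, `n_used`. Betas
#'   are phenotype units per A1 allele.
#' @export
assoc_scan <- function(g, phenotype, covariates = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  n <- nrow(d)
  if (length(phenotype) != n)
    stop("phenotype length does not match number of individuals")
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    storage.mode(C) <- "double"
    if (nrow(C) != n) stop("covariate rows do not match individuals")
    if (qr(cbind(1, C))$rank < ncol(C) + 1)
      stop("covariates are collinear (not full rank with intercept)")
  }
  ok_base <- !is.na(phenotype)
  if (!is.null(C)) ok_base <- ok_base & !apply(is.na(C), 1, any)
  res <- matrix(NA_real_, ncol(d), 4,
                dimnames = list(NULL, c("beta", "se", "p", "n_used")))
  for (j in seq_len(ncol(d))) {
    ok <- ok_base & !is.na(d[, j])
    x <- d[ok, j]
    res[j, "n_used"] <- sum(ok)
    if (length(unique(x)) < 2) next  # constant SNP: flagged, not fatal
    X <- if (is.null(C)) cbind(1, x) else cbind(1, x, C[ok, , drop = FALSE])
    fit <- stats::lm.fit(X, phenotype[ok])
    df <- length(x) - fit$rank
    if (df < 1) next
    rss <- sum(fit$residuals^2)
    R <- qr.R(fit$qr)
    xtx_inv <- chol2inv(R)
    se <- sqrt(rss / df * xtx_inv[2, 2])
    beta <- fit$coefficients[2]
    res[j, "beta"] <- beta
    res[j, "se"] <- se
    tval <- beta / se
    res[j, "p"] <- 2 * stats::pt(-abs(tval), df)
  }
  maf <- unname(observed_maf(g))
  data.frame(chr = g$snp_meta$chr, snp = g$snp_meta$snp,
             a1 = g$snp_meta$a1, a2 = g$snp_meta$a2, maf = maf,
             pos = g$snp_meta$pos, beta = res[, "beta"], se = res[, "se"],
             p = res[, "p"], n_used = as.integer(res[, "n_used"]),
             stringsAsFactors = FALSE)
}

#' Composite-genotype linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between two dosage vectors, computed on
#' pairwise-complete observations.
#'
#' @param g_a,g_b dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g_a, g_b) {
  if (length(g_a) != length(g_b)) stop("dosage vectors differ in length")
  ok <- !is.na(g_a) & !is.na(g_b)
  a <- g_a[ok]; b <- g_b[ok]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("cannot compute LD r2 for a constant dosage vector")
  stats::cor(a, b)^2
}

#' Greedy LD clumping to nearly independent index SNPs
#'
#' Repeatedly takes the smallest-p unclaimed SNP below `p_threshold` as an
#' index SNP and claims every unclaimed SNP on the same chromosome within
#' `window_kb` kilobases whose LD r-squared with the index reaches
#' `r2_threshold`. Ties in p at a selection step are broken by
#' (chromosome, position, id). The index SNPs are returned sorted by
#' chromosome then position.
#'
#' @param assoc association table as returned by [assoc_scan()] (columns
#'   `snp`, `chr`, `pos`, `p` are used).
#' @param g [genotype_matrix()] supplying the LD reference dosages; must
#'   contain every SNP of `assoc`.
#' @param p_threshold genome-wide significance threshold for index SNPs.
#' @param r2_threshold LD threshold at and above which a SNP is claimed.
#' @param window_kb window half-width in kilobases.
#' @return character vector of index SNP ids (possibly empty).
#' @export
clump <- function(assoc, g, p_threshold = 5e-8, r2_threshold = 0.01,
                  window_kb = 10000) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!all(assoc$snp %in% g$snp_meta$snp))
    stop("association table contains SNPs absent from the genotype matrix")
  cand <- assoc[!is.na(assoc$p) & assoc$p < p_threshold, , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  cand <- cand[order(cand$p, cand$chr, cand$pos, cand$snp), , drop = FALSE]
  claimed <- rep(FALSE, nrow(cand))
  index <- character(0)
  for (i in seq_len(nrow(cand))) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    index <- c(index, cand$snp[i])
    di <- g$dosage[, match(cand$snp[i], g$snp_meta$snp)]
    near <- which(!claimed & cand$chr == cand$chr[i] &
                    abs(cand$pos - cand$pos[i]) <= window_kb * 1000)
    for (k in near) {
      dk <- g$dosage[, match(cand$snp[k], g$snp_meta$snp)]
      r2 <- tryCatch(ld_r2(di, dk), error = function(e) NA_real_)
      if (!is.na(r2) && r2 >= r2_threshold) claimed[k] <- TRUE
    }
  }
  meta <- g$snp_meta[match(index, g$snp_meta$snp), ]
  index[order(meta$chr, meta$pos)]
}
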