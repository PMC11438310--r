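#' Joint instrument set for multivariable MR
#'
#' Takes the union of SNPs reaching `p_threshold` in any exposure,
#' deduplicates, clumps them to near-independence with [clump()] (ranking
#' SNPs by their smallest p-value across exposures), and harmonizes every
#' exposure and the outcome to a single allele orientation per SNP (the
#' first exposure's). SNPs missing from any table, or dropped during
#' harmonization (incompatible alleles, ambiguous palindromes), are
#' removed with a logged reason.
#'
#' @param exposure_stats named list (>= 2) of summary-statistic
#'   data.frames, one per exposure.
#' @param outcome_stats outcome summary-statistic data.frame.
#' @param p_threshold instrument-selection threshold.
#' @param clump_spec list with `r2_threshold` and `window_kb` for
#'   [clump()].
#' @param ld_reference [genotype_matrix()] supplying LD and positions for
#'   clumping; must contain the candidate SNPs.
#' @param eaf_tolerance,palindromic_policy passed to [harmonize()].
#' @return object of class `mv_instrument_set`: list with `snp`, `bx`
#'   (SNP x exposure matrix), `se_x`, `by`, `se_y`, and `log`
#'   (data.frame of dropped SNPs with reasons).
#' @export
mv_instruments <- function(exposure_stats, outcome_stats,
                           p_threshold = 5e-8,
                           clump_spec = list(r2_threshold = 0.01,
                                             window_kb = 10000),
                           ld_reference = NULL,
                           eaf_tolerance = 0.08,
                           palindromic_policy = "infer") {
  if (!is.list(exposure_stats) || length(exposure_stats) < 2)
    stop("need at least two exposures")
  if (is.null(names(exposure_stats)))
    names(exposure_stats) <- paste0("exposure", seq_along(exposure_stats))
  exposure_stats <- lapply(exposure_stats, validate_summary_stats)
  outcome_stats <- validate_summary_stats(outcome_stats, "outcome")
  sig <- unique(unlist(lapply(exposure_stats, function(s)
    s$snp[!is.na(s$p) & s$p < p_threshold])))
  if (!length(sig)) stop("no SNP reaches p_threshold in any exposure")
  log <- data.frame(snp = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  drop_snps <- function(snps, reason) {
    if (length(snps))
      log <<- rbind(log, data.frame(snp = snps, reason = reason,
                                    stringsAsFactors = FALSE))
  }
  present_everywhere <- Reduce(intersect,
                               c(lapply(exposure_stats, `[[`, "snp"),
                                 list(outcome_stats$snp)))
  drop_snps(setdiff(sig, present_everywhere), "missing_in_some_table")
  sig <- intersect(sig, present_everywhere)
  if (!length(sig)) stop("no candidate SNP present in every table")
  if (!is.null(ld_reference)) {
    min_p <- do.call(pmin, lapply(exposure_stats, function(s)
      s$p[match(sig, s$snp)]))
    meta <- ld_reference$snp_meta[match(sig, ld_reference$snp_meta$snp), ]
    if (anyNA(meta$snp))
      stop("ld_reference lacks candidate SNP(s): ",
           paste(sig[is.na(meta$snp)], collapse = ", "))
    assoc <- data.frame(snp = sig, chr = meta$chr, pos = meta$pos,
                        p = min_p, stringsAsFactors = FALSE)
    kept <- clump(assoc, ld_reference, p_threshold = 1,
                  r2_threshold = clump_spec$r2_threshold,
                  window_kb = clump_spec$window_kb)
    drop_snps(setdiff(sig, kept), "clumped")
    sig <- kept
  }
  ref <- exposure_stats[[1]][match(sig, exposure_stats[[1]]$snp), ]
  K <- length(exposure_stats)
  bx <- se_x <- matrix(NA_real_, length(sig), K,
                       dimnames = list(sig, names(exposure_stats)))
  bx[, 1] <- ref$beta; se_x[, 1] <- ref$se
  aligned_tables <- lapply(exposure_stats[-1], function(s)
    harmonize(ref, s, eaf_tolerance, palindromic_policy))
  out_h <- harmonize(ref, outcome_stats, eaf_tolerance,
                     palindromic_policy)
  ok <- rep(TRUE, length(sig))
  for (k in seq_along(aligned_tables)) {
    h <- aligned_tables[[k]]
    m <- match(sig, h$snp)
    good <- !is.na(m) & h$action[m] %in% c("kept", "flipped")
    bx[good, k + 1] <- h$by[m[good]]
    se_x[good, k + 1] <- h$se_y[m[good]]
    ok <- ok & good
  }
  mo <- match(sig, out_h$snp)
  good_o <- !is.na(mo) & out_h$action[mo] %in% c("kept", "flipped")
  ok <- ok & good_o
  drop_snps(sig[!ok], "harmonization_dropped")
  if (!any(ok)) stop("empty instrument set after harmonization")
  structure(list(snp = sig[ok], bx = bx[ok, , drop = FALSE],
                 se_x = se_x[ok, , drop = FALSE],
                 by = out_h$by[mo[ok]], se_y = out_h$se_y[mo[ok]],
                 log = log),
            class = "mv_instrument_set")
}

#' Multivariable IVW estimator
#'
#' Weighted least squares (no intercept, weights `1 / se_y^2`) of the
#' outcome effects on the SNP x exposure matrix of exposure effects. The
#' coefficient of exposure k is its direct causal effect conditional on
#' the other exposures. With a single exposure this reduces exactly to
#' the fixed-effect univariable [mr_ivw()]. An exposure whose instrument
#' effects are all exactly zero carries no information: it is excluded
#' from the regression (its entry in the result is `NULL`) so that the
#' remaining exposures are estimated as if it were absent; genuine
#' collinearity among non-zero columns is rejected. Residual
#' heterogeneity is reported as Q with J - K degrees of freedom.
#'
#' @param instruments an `mv_instrument_set` from [mv_instruments()], or
#'   any list with elements `bx` (J x K matrix), `by`, `se_y` (and
#'   optionally `snp`).
#' @return named list of [mr_result()] objects (method `"MV-IVW"`), one
#'   per exposure; each carries the shared `Q`, `Q_df`, `Q_p`
#'   diagnostics.
#' @export
mv_ivw <- function(instruments) {
  bx_all <- as.matrix(instruments$bx)
  by <- instruments$by
  se_y <- instruments$se_y
  if (is.null(colnames(bx_all)))
    colnames(bx_all) <- paste0("exposure", seq_len(ncol(bx_all)))
  zero_col <- apply(bx_all == 0, 2, all)
  bx <- bx_all[, !zero_col, drop = FALSE]
  J <- nrow(bx); K <- ncol(bx)
  if (K == 0) stop("every exposure has all-zero instrument effects")
  if (J <= K) stop("need more SNPs than exposures")
  if (any(se_y <= 0)) stop("all outcome SEs must be > 0")
  if (qr(bx)$rank < K) stop("rank-deficient exposure-effect matrix")
  w <- 1 / se_y^2
  XtWX <- crossprod(bx, bx * w)
  coef <- drop(solve(XtWX, crossprod(bx * w, by)))
  vc <- solve(XtWX)                      # fixed-effect covariance
  resid <- by - drop(bx %*% coef)
  Q <- sum(w * resid^2)
  Q_df <- J - K
  Q_p <- stats::pchisq(Q, Q_df, lower.tail = FALSE)
  nm <- colnames(bx)
  est <- lapply(seq_len(K), function(k)
    mr_result("MV-IVW", beta = unname(coef[k]), se = sqrt(vc[k, k]),
              nsnp = J,
              diagnostics = list(Q = Q, Q_df = Q_df, Q_p = Q_p,
                                 exposure = nm[k])))
  names(est) <- nm
  out <- stats::setNames(vector("list", ncol(bx_all)), colnames(bx_all))
  out[nm] <- est
  out
}
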