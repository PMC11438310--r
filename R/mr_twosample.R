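DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) DNA_COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two tables on SNP id and puts every retained SNP's
#' outcome effect on the exposure's effect allele:
#' \itemize{
#'   \item alleles identical: kept as is;
#'   \item alleles swapped (outcome's effect allele is the exposure's
#'     other allele): outcome beta negated and its EAF complemented;
#'   \item alleles matching only after strand complement: complemented
#'     then aligned as above;
#'   \item palindromic SNPs (A/T or C/G), whose strand cannot be resolved
#'     from alleles: under `policy = "infer"`, orientation is taken from
#'     the effect-allele frequencies provided both are outside
#'     `0.5 +/- eaf_tolerance`; otherwise (or under `policy = "drop"`)
#'     the SNP is dropped;
#'   \item incompatible allele sets: dropped.
#' }
#' Every input SNP in the intersection is accounted for by exactly one
#' action.
#'
#' @param exposure,outcome summary-statistic data.frames with columns
#'   `snp`, `a1`, `a2`, `eaf`, `beta`, `se` (and optionally `p`, `n`).
#' @param eaf_tolerance half-width of the ambiguous frequency zone around
#'   0.5 for palindromic SNPs.
#' @param palindromic_policy `"infer"` (frequency-based, the default) or
#'   `"drop"` (drop all palindromic SNPs).
#' @return data.frame of class `harmonized_pairs` with one row per
#'   intersected SNP: `snp`, `a1`, `a2`, `bx`, `se_x`, `by`, `se_y`,
#'   `eaf_x`, `eaf_y`, `action` (one of `kept`, `flipped`,
#'   `dropped_palindromic`, `dropped_incompatible`). Estimators use the
#'   rows with action `kept` or `flipped`.
#' @export
harmonize <- function(exposure, outcome, eaf_tolerance = 0.08,
                      palindromic_policy = c("infer", "drop")) {
  palindromic_policy <- match.arg(palindromic_policy)
  exposure <- validate_summary_stats(exposure, "exposure")
  outcome <- validate_summary_stats(outcome, "outcome")
  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared)) stop("no shared SNP ids between the two tables")
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]
  n <- length(shared)
  by <- ou$beta; eaf_y <- ou$eaf
  action <- character(n)
  for (i in seq_len(n)) {
    e1 <- ex$a1[i]; e2 <- ex$a2[i]
    o1 <- ou$a1[i]; o2 <- ou$a2[i]
    pal <- is_palindromic(e1, e2)
    if (pal) {
      same_set <- setequal(c(o1, o2), c(e1, e2))
      if (!same_set) { action[i] <- "dropped_incompatible"; next }
      if (palindromic_policy == "drop") {
        action[i] <- "dropped_palindromic"; next
      }
      fx <- ex$eaf[i]; fy <- ou$eaf[i]
      ambiguous <- is.na(fx) || is.na(fy) ||
        abs(fx - 0.5) <= eaf_tolerance || abs(fy - 0.5) <= eaf_tolerance
      if (ambiguous) { action[i] <- "dropped_palindromic"; next }
      # allele letters are uninformative for palindromic SNPs; the two
      # reported effect alleles are the same allele iff their
      # frequencies fall on the same side of 0.5
      if ((fx < 0.5) == (fy < 0.5)) {
        action[i] <- "kept"
      } else {
        by[i] <- -by[i]; eaf_y[i] <- 1 - eaf_y[i]
        action[i] <- "flipped"
      }
      next
    }
    o1c <- unname(DNA_COMPLEMENT[o1]); o2c <- unname(DNA_COMPLEMENT[o2])
    if (o1 == e1 && o2 == e2) {
      action[i] <- "kept"
    } else if (o1 == e2 && o2 == e1) {
      by[i] <- -by[i]; eaf_y[i] <- 1 - eaf_y[i]; action[i] <- "flipped"
    } else if (o1c == e1 && o2c == e2) {
      action[i] <- "kept"
    } else if (o1c == e2 && o2c == e1) {
      by[i] <- -by[i]; eaf_y[i] <- 1 - eaf_y[i]; action[i] <- "flipped"
    } else {
      action[i] <- "dropped_incompatible"
    }
  }
  out <- data.frame(snp = shared, a1 = ex$a1, a2 = ex$a2,
                    bx = ex$beta, se_x = ex$se, by = by, se_y = ou$se,
                    eaf_x = ex$eaf, eaf_y = eaf_y, action = action,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

# rows usable by the estimators
retained_pairs <- function(pairs, min_snps = 2, caller = "estimator") {
  if (inherits(pairs, "harmonized_pairs") && "action" %in% names(pairs))
    pairs <- pairs[pairs$action %in% c("kept", "flipped"), , drop = FALSE]
  need <- c("bx", "se_x", "by", "se_y")
  if (!all(need %in% names(pairs)))
    stop("pairs must contain columns ", paste(need, collapse = ", "))
  if (nrow(pairs) < min_snps)
    stop(caller, " needs at least ", min_snps, " retained SNPs")
  if (any(pairs$se_y <= 0) || any(pairs$se_x <= 0))
    stop("all standard errors must be > 0")
  pairs
}

#' Per-SNP Wald ratio
#'
#' The single-SNP causal estimate: outcome effect divided by exposure
#' effect, with the first-order delta-method standard error
#' `se_y / |bx|`.
#'
#' @param bx,se_x exposure effect and SE (bx must be nonzero).
#' @param by,se_y outcome effect and SE.
#' @return list with `ratio` and `se`.
#' @export
wald_ratio <- function(bx, se_x, by, se_y) {
  if (any(bx == 0)) stop("Wald ratio undefined for bx = 0")
  list(ratio = by / bx, se = se_y / abs(bx))
}

#' Inverse-variance-weighted (IVW) estimator
#'
#' Meta-analytic combination of the per-SNP Wald ratios, equivalent to a
#' weighted regression of the outcome effects on the exposure effects
#' through the origin with weights `1 / se_y^2`:
#' `beta = sum(bx by / se_y^2) / sum(bx^2 / se_y^2)`. The fixed-effect SE
#' is `(sum(bx^2 / se_y^2))^-1/2`; the multiplicative random-effects SE
#' scales it by `sqrt(max(1, Q / (J - 1)))`. Under `mode = "auto"` the
#' random-effects inflation is applied when Cochran's Q has p < 0.05,
#' i.e. when heterogeneity is present.
#'
#' @param pairs a `harmonized_pairs` table (or any data.frame with
#'   columns `bx`, `se_x`, `by`, `se_y`). With a single SNP the estimate
#'   collapses to that SNP's Wald ratio (heterogeneity undefined).
#' @param mode `"auto"` (default), `"fixed"`, or `"random"`.
#' @return [mr_result()] with method `"IVW"`; diagnostics hold `Q`,
#'   `Q_df`, `Q_p`, the mode actually used, and the fixed-effect SE.
#' @export
mr_ivw <- function(pairs, mode = c("auto", "fixed", "random")) {
  mode <- match.arg(mode)
  p <- retained_pairs(pairs, 1, "mr_ivw")
  w <- 1 / p$se_y^2
  denom <- sum(w * p$bx^2)
  beta <- sum(w * p$bx * p$by) / denom
  se_fixed <- sqrt(1 / denom)
  J <- nrow(p)
  Q <- sum(w * (p$by - beta * p$bx)^2)
  Q_p <- if (J > 1) stats::pchisq(Q, J - 1, lower.tail = FALSE)
         else NA_real_
  if (J == 1) mode <- "fixed"
  inflate <- sqrt(max(1, Q / (J - 1)))
  used <- switch(mode,
    fixed = "fixed",
    random = "random",
    auto = if (!is.na(Q_p) && Q_p < 0.05) "random" else "fixed")
  se <- if (used == "random") se_fixed * inflate else se_fixed
  mr_result("IVW", beta = beta, se = se, nsnp = J,
            diagnostics = list(Q = Q, Q_df = J - 1, Q_p = Q_p,
                               mode = used, se_fixed = se_fixed))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j - beta)^2` over the per-SNP Wald ratios, with
#' weights the inverse squared ratio SEs `(se_y_j / |bx_j|)^-2`;
#' chi-squared with J - 1 degrees of freedom under homogeneity.
#'
#' @param pairs as in [mr_ivw()].
#' @param beta the causal estimate the ratios are compared against
#'   (defaults to the fixed-effect IVW point estimate).
#' @return list with `Q`, `df`, `p`.
#' @export
cochrans_q <- function(pairs, beta = NULL) {
  p <- retained_pairs(pairs, 2, "cochrans_q")
  if (is.null(beta)) beta <- mr_ivw(p, mode = "fixed")$beta
  wr <- wald_ratio(p$bx, p$se_x, p$by, p$se_y)
  w <- 1 / wr$se^2
  Q <- sum(w * (wr$ratio - beta)^2)
  df <- nrow(p) - 1
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Weighted-median estimator
#'
#' Orders the per-SNP Wald ratios and takes the weighted median under
#' normalized inverse-variance weights: with cumulative midpoint
#' `S_j = sum_{k<=j} w'_k - w'_j / 2`, the estimate interpolates the
#' ordered ratios linearly at S = 0.5. Consistent when instruments
#' carrying at least half the total weight are valid. The SE comes from a
#' parametric bootstrap that redraws `bx` and `by` from their normal
#' sampling distributions.
#'
#' @param pairs as in [mr_ivw()]; at least 3 retained SNPs.
#' @param n_boot number of bootstrap draws for the SE.
#' @param seed integer seed for the bootstrap.
#' @return [mr_result()] with method `"Weighted median"`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = 1L) {
  p <- retained_pairs(pairs, 3, "mr_weighted_median")
  est <- weighted_median_point(p$bx, p$se_x, p$by, p$se_y)
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    weighted_median_point(stats::rnorm(nrow(p), p$bx, p$se_x), p$se_x,
                          stats::rnorm(nrow(p), p$by, p$se_y), p$se_y)
  }, numeric(1))
  se <- stats::sd(boot)
  mr_result("Weighted median", beta = est, se = se, nsnp = nrow(p),
            diagnostics = list(n_boot = n_boot))
}

weighted_median_point <- function(bx, se_x, by, se_y) {
  bx_nz <- ifelse(bx == 0, .Machine$double.eps, bx)
  ratio <- by / bx_nz
  w <- (abs(bx_nz) / se_y)^2
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  S <- cumsum(w) - w / 2
  if (S[1] >= 0.5) return(ratio[1])
  if (S[length(S)] <= 0.5) return(ratio[length(S)])
  stats::approx(S, ratio, xout = 0.5, ties = "ordered")$y
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept, weights `1 / se_y^2`, after orienting every pair so
#' that bx >= 0 (negating both members when bx < 0, to which the fit is
#' invariant). The slope is the causal estimate; the intercept estimates
#' the average directional pleiotropy, and its two-sided test is the
#' Egger pleiotropy test. Inference uses the t distribution with J - 2
#' degrees of freedom.
#'
#' @param pairs as in [mr_ivw()]; at least 3 retained SNPs with spread in
#'   |bx|.
#' @return list with `slope` (an [mr_result()], method `"MR-Egger"`) and
#'   `intercept` (list: `estimate`, `se`, `p`).
#' @export
mr_egger <- function(pairs) {
  p <- retained_pairs(pairs, 3, "mr_egger")
  flip <- p$bx < 0
  bx <- abs(p$bx)
  by <- ifelse(flip, -p$by, p$by)
  if (max(bx) - min(bx) < 1e-12)
    stop("no spread in |bx|: Egger regression has no leverage")
  w <- 1 / p$se_y^2
  X <- cbind(1, bx)
  WX <- X * w
  XtWX <- crossprod(X, WX)
  coef <- solve(XtWX, crossprod(WX, by))
  resid <- by - drop(X %*% coef)
  J <- nrow(p)
  df <- J - 2
  sigma2 <- sum(w * resid^2) / df   # multiplicative residual dispersion
  vc <- solve(XtWX) * sigma2
  se_sl <- sqrt(vc[2, 2]); se_in <- sqrt(vc[1, 1])
  t_sl <- coef[2] / se_sl; t_in <- coef[1] / se_in
  z975 <- stats::qt(0.975, df)
  slope <- mr_result("MR-Egger", beta = unname(coef[2]), se = se_sl,
                     p = 2 * stats::pt(-abs(t_sl), df), nsnp = J,
                     ci_lower = unname(coef[2]) - z975 * se_sl,
                     ci_upper = unname(coef[2]) + z975 * se_sl,
                     diagnostics = list(df = df, sigma2 = sigma2))
  list(slope = slope,
       intercept = list(estimate = unname(coef[1]), se = se_in,
                        p = 2 * stats::pt(-abs(t_in), df)))
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects horizontal pleiotropy as excess residual heterogeneity around
#' the IVW fit and identifies the SNPs responsible:
#' \itemize{
#'   \item global test: the observed residual sum of squares
#'     `RSS = sum_j w_j (by_j - beta_(-j) bx_j)^2` (leave-one-out IVW
#'     slopes, weights `1 / se_y^2`) is compared against its null
#'     distribution obtained by simulating `by'_j ~ Normal(beta_(-j)
#'     bx_j, se_y_j)` and recomputing the RSS `n_sim` times;
#'   \item outlier test: each SNP's observed weighted squared residual is
#'     referred to its own simulated distribution; the per-SNP empirical
#'     p-values are Bonferroni-adjusted over J and SNPs below `signif`
#'     are flagged;
#'   \item distortion test: the outlier-corrected IVW estimate (computed
#'     on the non-flagged SNPs only) is compared with the full estimate
#'     against a null distribution of distortions obtained by removing
#'     equally many randomly chosen SNPs.
#' }
#'
#' @param pairs as in [mr_ivw()]; at least 4 retained SNPs.
#' @param n_sim number of null simulations (>= 100).
#' @param signif significance level for outlier flagging (after
#'   Bonferroni) and implicitly for the global test.
#' @param seed integer seed.
#' @return list of class `presso_result`: `global_p`, `outlier_p`
#'   (Bonferroni-adjusted, named by SNP when ids are present),
#'   `outliers` (integer indices), `distortion_p`, `raw` (full-set IVW
#'   [mr_result()]) and `corrected` (outlier-corrected IVW, `NULL` when
#'   nothing was flagged or too few SNPs remain).
#' @export
mr_presso <- function(pairs, n_sim = 1000, signif = 0.05, seed = 1L) {
  if (n_sim < 100) stop("n_sim < 100 gives unstable empirical p-values")
  p <- retained_pairs(pairs, 4, "mr_presso")
  J <- nrow(p)
  w <- 1 / p$se_y^2
  sw_xy <- sum(w * p$bx * p$by)
  sw_xx <- sum(w * p$bx^2)
  beta_loo <- (sw_xy - w * p$bx * p$by) / (sw_xx - w * p$bx^2)
  obs_res2 <- w * (p$by - beta_loo * p$bx)^2
  rss_obs <- sum(obs_res2)
  if (!is.null(seed)) set.seed(seed)
  BY <- matrix(stats::rnorm(n_sim * J, mean = rep(beta_loo * p$bx,
                                                  each = n_sim),
                            sd = rep(p$se_y, each = n_sim)), n_sim, J)
  S1 <- BY %*% (w * p$bx)                     # sum_j w bx by' per sim
  num <- matrix(S1, n_sim, J) - BY * matrix(w * p$bx, n_sim, J,
                                            byrow = TRUE)
  den <- matrix(sw_xx - w * p$bx^2, n_sim, J, byrow = TRUE)
  B_loo <- num / den
  RES2 <- matrix(w, n_sim, J, byrow = TRUE) *
    (BY - B_loo * matrix(p$bx, n_sim, J, byrow = TRUE))^2
  rss_sim <- rowSums(RES2)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  # plain empirical proportion (can reach 0) so that Bonferroni-adjusted
  # flagging is not floored at J / n_sim for gross outliers
  outlier_p_raw <- vapply(seq_len(J), function(j)
    sum(RES2[, j] >= obs_res2[j]) / n_sim, numeric(1))
  outlier_p <- pmin(1, outlier_p_raw * J)
  if ("snp" %in% names(p)) names(outlier_p) <- p$snp
  outliers <- which(outlier_p < signif)
  raw <- mr_ivw(p, mode = "fixed")
  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outliers) && J - length(outliers) >= 2) {
    corrected <- mr_ivw(p[-outliers, , drop = FALSE], mode = "fixed")
    d_obs <- (raw$beta - corrected$beta) / abs(corrected$beta)
    keep_n <- length(outliers)
    pool <- setdiff(seq_len(J), outliers)
    s_xy <- sum(w * p$bx * p$by); s_xx <- sum(w * p$bx^2)
    d_sim <- vapply(seq_len(n_sim), function(b) {
      drop_b <- sample(pool, keep_n)
      bb <- (s_xy - sum(w[drop_b] * p$bx[drop_b] * p$by[drop_b])) /
        (s_xx - sum(w[drop_b] * p$bx[drop_b]^2))
      (raw$beta - bb) / abs(bb)
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }
  structure(list(global_p = global_p, outlier_p = outlier_p,
                 outliers = outliers, distortion_p = distortion_p,
                 raw = raw, corrected = corrected, n_sim = n_sim),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global p = %.3g, %d outlier(s)\n",
              x$global_p, length(x$outliers)))
  if (length(x$outliers)) {
    nm <- if (!is.null(names(x$outlier_p)))
      names(x$outlier_p)[x$outliers] else x$outliers
    cat("  outliers:", paste(nm, collapse = ", "),
        sprintf(" (distortion p = %.3g)\n", x$distortion_p))
    print(x$corrected)
  }
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values: `q_i = min over j with p_(j) >= p_(i) of
#' m p_(j) / j`, mapped back to the input order. Delegates to
#' [stats::p.adjust()] after validating the input range.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return q-values in (0, 1], same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
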