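#' Build a weighted genetic risk score (wGRS)
#'
#' wGRS_i = sum_j w_j g_ij over the instrument SNPs, after aligning each
#' weight's effect allele to the genotype matrix: when a weight's A1
#' matches the matrix A2 (and vice versa) the dosage is counted as 2 - g.
#' SNPs whose alleles neither match nor swap are rejected with a message.
#' Missing dosages are mean-imputed at twice the effect-allele frequency
#' observed in the data (2 * MAF when the effect allele is the minor
#' allele), which keeps the number of individuals constant across SNP
#' subsets during pruning.
#'
#' @param g a [genotype_matrix()].
#' @param weights data.frame with columns `snp`, `a1`, `weight` (per-A1
#'   effect sizes from the base-data GWAS).
#' @return object of class `instrument_set`: list with `weights` (the
#'   aligned weight table, on the matrix's A1), `wgrs` (per-individual
#'   score), and `check_log` (empty audit table, filled by
#'   [prune_instrument()]).
#' @export
build_wgrs <- function(g, weights) {
  stopifnot(inherits(g, "genotype_matrix"))
  weights <- as.data.frame(weights, stringsAsFactors = FALSE)
  if (!all(c("snp", "a1", "weight") %in% names(weights)))
    stop("weights needs columns snp, a1, weight")
  idx <- match(weights$snp, g$snp_meta$snp)
  if (anyNA(idx))
    stop("weight SNP(s) absent from genotype matrix: ",
         paste(weights$snp[is.na(idx)], collapse = ", "))
  if (any(!is.finite(weights$weight))) stop("weights must be finite")
  wgrs <- numeric(nrow(g$dosage))
  for (r in seq_len(nrow(weights))) {
    j <- idx[r]
    w <- weights$weight[r]
    freq_a1_matrix <- mean(g$dosage[, j], na.rm = TRUE) / 2
    if (identical(weights$a1[r], g$snp_meta$a1[j])) {
      dose <- g$dosage[, j]
      freq <- freq_a1_matrix
    } else if (identical(weights$a1[r], g$snp_meta$a2[j])) {
      dose <- 2 - g$dosage[, j]
      freq <- 1 - freq_a1_matrix
    } else {
      stop("irreconcilable alleles for SNP ", weights$snp[r],
           ": weight A1 = ", weights$a1[r], ", matrix has ",
           g$snp_meta$a1[j], "/", g$snp_meta$a2[j])
    }
    dose[is.na(dose)] <- 2 * freq
    wgrs <- wgrs + w * dose
  }
  structure(list(weights = weights, wgrs = wgrs,
                 check_log = empty_check_log()),
            class = "instrument_set")
}

empty_check_log <- function() {
  data.frame(step = integer(0), check = character(0),
             variable = character(0), test = character(0),
             p = numeric(0), action = character(0),
             snp = character(0), stringsAsFactors = FALSE)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("instrument_set:", nrow(x$weights), "SNPs,",
      length(x$wgrs), "individuals\n")
  if (!is.null(x$f)) cat(sprintf("  first-stage F = %.2f\n", x$f))
  if (nrow(x$check_log))
    cat("  audit log:", nrow(x$check_log), "entries (",
        sum(x$check_log$action == "remove_snp"), "removals )\n")
  invisible(x)
}

#' First-stage (partial) F statistic for instrument strength
#'
#' Partial F for the wGRS term in a regression of the exposure on wGRS
#' plus covariates: `((RSS_reduced - RSS_full) / 1) / (RSS_full /
#' (n - p_full))`, where the reduced model omits the wGRS. With no
#' covariates this reduces to `(n - 2) R^2 / (1 - R^2)`. F > 10 is the
#' conventional bar for a strong instrument.
#'
#' @param exposure numeric exposure vector.
#' @param wgrs per-individual instrument values.
#' @param covariates optional numeric covariate table (the marginal,
#'   unadjusted F is obtained by omitting it).
#' @return the F value (scalar).
#' @export
f_statistic <- function(exposure, wgrs, covariates = NULL) {
  n <- length(exposure)
  if (length(wgrs) != n) stop("exposure and wgrs lengths differ")
  C <- if (is.null(covariates)) matrix(nrow = n, ncol = 0)
       else as.matrix(as.data.frame(covariates))
  X_red <- cbind(1, C)
  X_full <- cbind(1, wgrs, C)
  if (qr(X_full)$rank < ncol(X_full))
    stop("collinear covariates in first-stage model")
  rss <- function(X) sum(stats::lm.fit(X, exposure)$residuals^2)
  rss_full <- rss(X_full)
  df <- n - ncol(X_full)
  if (df < 1) stop("too few observations for the first-stage model")
  (rss(X_red) - rss_full) / (rss_full / df)
}

#' Assumption checks for a wGRS instrument
#'
#' Tests the falsifiable implications of the independence assumption (the
#' instrument is unrelated to confounders of the exposure-outcome
#' association) and the exclusion restriction (the instrument affects the
#' outcome only through the exposure):
#' \itemize{
#'   \item independence: per confounder, a two-sample t-test of the wGRS
#'     between groups for binary confounders, or a Pearson correlation
#'     test for continuous confounders;
#'   \item exclusion: the two-sided Wald p-value of the wGRS coefficient
#'     in a least-squares regression of the outcome on wGRS + exposure +
#'     all confounders. A significant coefficient means the instrument
#'     reaches the outcome through paths other than the exposure.
#' }
#' A check passes when p >= alpha. A binary confounder with an empty
#' group is flagged untestable rather than failing.
#'
#' @param wgrs per-individual instrument values.
#' @param confounders data.frame of confounders; columns with exactly two
#'   distinct values are treated as binary.
#' @param eaa outcome vector.
#' @param exposure exposure vector.
#' @param alpha significance level for all checks.
#' @return data.frame of class `assumption_report`: one row per
#'   confounder plus one exclusion row, with columns `check`, `variable`,
#'   `test`, `p`, `pass`, `testable`.
#' @export
assumption_report <- function(wgrs, confounders, eaa, exposure,
                              alpha = 0.05) {
  confounders <- as.data.frame(confounders)
  n <- length(wgrs)
  stopifnot(nrow(confounders) == n, length(eaa) == n,
            length(exposure) == n)
  rows <- lapply(names(confounders), function(v) {
    x <- confounders[[v]]
    if (length(unique(x[!is.na(x)])) == 2) {
      grp <- split(wgrs, x)
      if (any(lengths(grp) < 2))
        return(data.frame(check = "independence", variable = v,
                          test = "two-sample t", p = NA_real_,
                          pass = NA, testable = FALSE))
      p <- stats::t.test(grp[[1]], grp[[2]])$p.value
      data.frame(check = "independence", variable = v,
                 test = "two-sample t", p = p, pass = p >= alpha,
                 testable = TRUE)
    } else {
      p <- stats::cor.test(wgrs, x)$p.value
      data.frame(check = "independence", variable = v,
                 test = "Pearson", p = p, pass = p >= alpha,
                 testable = TRUE)
    }
  })
  X <- cbind(1, wgrs, exposure, as.matrix(confounders))
  fit <- stats::lm.fit(X, eaa)
  df <- n - fit$rank
  sigma2 <- sum(fit$residuals^2) / df
  vc <- chol2inv(qr.R(fit$qr)) * sigma2
  tval <- fit$coefficients[2] / sqrt(vc[2, 2])
  p_ex <- 2 * stats::pt(-abs(tval), df)
  rows[[length(rows) + 1]] <-
    data.frame(check = "exclusion", variable = "outcome",
               test = "Wald-in-adjusted-regression", p = p_ex,
               pass = p_ex >= alpha, testable = TRUE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("assumption_report", "data.frame")
  out
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in a binary trait across the three genotype
#' groups, with scores (0, 1, 2). The statistic is the score test
#' `Z^2 = n [n T1 - n1 T2]^2 / (n1 (n - n1) [n T3 - T2^2])` with
#' `T1 = sum_k t_k n_{1k}`, `T2 = sum_k t_k n_{.k}`,
#' `T3 = sum_k t_k^2 n_{.k}`; Z is signed and referred to the standard
#' normal (two-sided).
#'
#' @param counts 2 x 3 matrix of counts: rows are the two trait groups,
#'   columns the genotype dosage groups 0, 1, 2.
#' @return list with elements `z` and `p`; for a table with all mass in
#'   one genotype column (zero trend variance) both are `NA` and
#'   `testable` is `FALSE`.
#' @export
cochran_armitage_trend <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 3)) || any(counts < 0))
    stop("counts must be a non-negative 2 x 3 table")
  if (any(rowSums(counts) == 0)) stop("both trait groups must be non-empty")
  t_k <- c(0, 1, 2)
  n <- sum(counts)
  n1 <- sum(counts[1, ])
  col <- colSums(counts)
  T1 <- sum(t_k * counts[1, ])
  T2 <- sum(t_k * col)
  T3 <- sum(t_k^2 * col)
  denom <- n1 * (n - n1) * (n * T3 - T2^2)
  if (denom <= 0)
    return(list(z = NA_real_, p = NA_real_, testable = FALSE))
  z <- (n * T1 - n1 * T2) / sqrt(denom / n)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), testable = TRUE)
}

#' Iterative SNP removal until the instrument passes its checks
#'
#' Runs [assumption_report()]; while any check fails, every SNP currently
#' in the instrument is tested against the violated variable -- a
#' Cochran-Armitage trend test for binary/categorical confounders, a
#' one-way ANOVA of the variable across genotype groups for continuous
#' confounders, and for an exclusion failure the per-SNP Wald test in the
#' same adjusted outcome regression with the single SNP in place of the
#' wGRS -- and the SNP with the smallest p-value is removed. The wGRS is
#' rebuilt and the loop repeats until all checks pass. Every decision is
#' appended to the instrument's audit log, which is sufficient to replay
#' the pruning deterministically.
#'
#' @param instrument an `instrument_set` from [build_wgrs()].
#' @param g the target-cohort [genotype_matrix()] (used to rebuild the
#'   wGRS and to test individual SNPs).
#' @param confounders,eaa,exposure as in [assumption_report()].
#' @param alpha significance level for all checks.
#' @param min_snps abort (with an error naming the unresolved check) if
#'   pruning would leave fewer SNPs than this.
#' @return the pruned `instrument_set`, with `f` (first-stage F) set and
#'   the full `check_log`.
#' @export
prune_instrument <- function(instrument, g, confounders, eaa, exposure,
                             alpha = 0.05, min_snps = 2) {
  stopifnot(inherits(instrument, "instrument_set"),
            inherits(g, "genotype_matrix"))
  if (nrow(instrument$weights) < min_snps)
    stop("instrument starts with fewer than min_snps SNPs")
  confounders <- as.data.frame(confounders)
  log <- instrument$check_log
  step <- max(c(0L, log$step)) + 1L
  weights <- instrument$weights
  cur <- instrument
  repeat {
    rep <- assumption_report(cur$wgrs, confounders, eaa, exposure, alpha)
    failed <- which(!is.na(rep$pass) & !rep$pass)
    if (!length(failed)) {
      for (r in seq_len(nrow(rep)))
        log <- rbind(log, data.frame(step = step, check = rep$check[r],
                                     variable = rep$variable[r],
                                     test = rep$test[r], p = rep$p[r],
                                     action = "pass", snp = NA_character_))
      break
    }
    worst <- failed[which.min(rep$p[failed])]
    var_name <- rep$variable[worst]
    snp_p <- per_snp_check_p(weights$snp, g, rep$check[worst], var_name,
                             confounders, eaa, exposure)
    victim <- weights$snp[which.min(snp_p)]
    if (nrow(weights) - 1 < min_snps)
      stop("pruning would drop below min_snps = ", min_snps,
           " with unresolved check: ", rep$check[worst], " (",
           var_name, ", p = ", signif(rep$p[worst], 3), ")")
    log <- rbind(log, data.frame(step = step, check = rep$check[worst],
                                 variable = var_name,
                                 test = rep$test[worst], p = rep$p[worst],
                                 action = "remove_snp", snp = victim))
    weights <- weights[weights$snp != victim, , drop = FALSE]
    cur <- build_wgrs(g, weights)
    step <- step + 1L
  }
  cur$check_log <- log
  cur$f <- f_statistic(exposure, cur$wgrs, confounders)
  cur
}

# smallest-p scan of each instrument SNP against the violated variable
per_snp_check_p <- function(snps, g, check, var_name, confounders, eaa,
                            exposure) {
  vapply(snps, function(s) {
    dose <- g$dosage[, match(s, g$snp_meta$snp)]
    maf <- mean(dose, na.rm = TRUE) / 2
    dose[is.na(dose)] <- 2 * min(maf, 1 - maf)
    geno <- round(dose)
    if (check == "exclusion") {
      X <- cbind(1, dose, exposure, as.matrix(confounders))
      fit <- stats::lm.fit(X, eaa)
      df <- length(eaa) - fit$rank
      vc <- chol2inv(qr.R(fit$qr)) * sum(fit$residuals^2) / df
      return(2 * stats::pt(-abs(fit$coefficients[2] / sqrt(vc[2, 2])), df))
    }
    x <- confounders[[var_name]]
    if (length(unique(x[!is.na(x)])) <= 3 &&
        all(x[!is.na(x)] == round(x[!is.na(x)])) &&
        length(unique(x[!is.na(x)])) == 2) {
      tab <- matrix(0, 2, 3)
      lev <- sort(unique(x))
      for (i in 1:2) for (k in 0:2)
        tab[i, k + 1] <- sum(x == lev[i] & geno == k, na.rm = TRUE)
      res <- cochran_armitage_trend(tab)
      if (isFALSE(res$testable)) return(1)
      return(res$p)
    }
    grp <- factor(geno)
    if (nlevels(grp) < 2) return(1)
    summary(stats::aov(x ~ grp))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
}

#' Replay an instrument audit log
#'
#' Re-applies the recorded SNP removals to the initial weight table and
#' rebuilds the wGRS, reproducing the final instrument exactly.
#'
#' @param g target-cohort [genotype_matrix()].
#' @param weights the initial weight table given to [build_wgrs()].
#' @param check_log audit log from a pruned instrument.
#' @return `instrument_set` with the replayed SNP set.
#' @export
replay_check_log <- function(g, weights, check_log) {
  removed <- check_log$snp[check_log$action == "remove_snp"]
  weights <- as.data.frame(weights, stringsAsFactors = FALSE)
  build_wgrs(g, weights[!weights$snp %in% removed, , drop = FALSE])
}
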