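# Independent oracles used across test files. These deliberately take
# different computational routes from the package implementation.

# HWE: enumerate the conditional distribution of the heterozygote count
# with the ratio recurrence (no log-gamma), two-sided by probability mass.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_r <- min(n_a, 2 * n - n_a)
  if (n_r == 0) return(1)
  hs <- seq(n_r %% 2, n_r, by = 2)
  pr <- numeric(length(hs))
  pr[1] <- 1
  if (length(hs) > 1) for (i in 2:length(hs)) {
    h <- hs[i]
    # P(h) / P(h-2) = 4 * hom_rare(h-2) * hom_common(h-2) / (h * (h-1))
    hom_r <- (n_r - (h - 2)) / 2
    hom_c <- n - hom_r - (h - 2)
    pr[i] <- pr[i - 1] * 4 * hom_r * hom_c / (h * (h - 1))
  }
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# per-SNP least squares via a plain lm() call
oracle_assoc <- function(dosage, phenotype, covariates = NULL) {
  t(vapply(seq_len(ncol(dosage)), function(j) {
    df <- data.frame(y = phenotype, g = dosage[, j])
    if (!is.null(covariates)) df <- cbind(df, covariates)
    fit <- summary(stats::lm(y ~ ., data = df))
    fit$coefficients["g", c("Estimate", "Std. Error", "Pr(>|t|)")]
  }, numeric(3)))
}

# brute-force greedy clumping, written directly from the stated rule
oracle_clump <- function(tab, dosage, p_threshold, r2_threshold,
                         window_kb) {
  tab <- tab[!is.na(tab$p) & tab$p < p_threshold, , drop = FALSE]
  chosen <- character(0)
  claimed <- character(0)
  while (nrow(tab[!tab$snp %in% claimed, ]) > 0) {
    rest <- tab[!tab$snp %in% claimed, ]
    rest <- rest[order(rest$p, rest$chr, rest$pos, rest$snp), ]
    idx <- rest[1, ]
    chosen <- c(chosen, idx$snp)
    claimed <- c(claimed, idx$snp)
    for (k in seq_len(nrow(rest))[-1]) {
      cand <- rest[k, ]
      if (cand$chr != idx$chr) next
      if (abs(cand$pos - idx$pos) > window_kb * 1000) next
      r2 <- stats::cor(dosage[, idx$snp], dosage[, cand$snp],
                       use = "pairwise.complete.obs")^2
      if (r2 >= r2_threshold) claimed <- c(claimed, cand$snp)
    }
  }
  chosen
}

# step-up BH directly from the definition:
# q_(i) = min over j >= i of m p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i)
    min(m * ps[i:m] / (i:m)), numeric(1))
  q <- numeric(m)
  q[o] <- pmin(1, qs)
  q
}

# summary-level pairs builder for estimator tests
make_pairs <- function(bx, by, se_x = 0.01, se_y = 0.05) {
  data.frame(snp = sprintf("s%02d", seq_along(bx)), bx = bx,
             se_x = rep_len(se_x, length(bx)), by = by,
             se_y = rep_len(se_y, length(bx)),
             action = "kept", stringsAsFactors = FALSE)
}
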