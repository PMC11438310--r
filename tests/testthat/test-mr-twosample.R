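ss_row <- function(snp, a1, a2, eaf, beta, se = 0.05) {
  data.frame(snp = snp, a1 = a1, a2 = a2, eaf = eaf, beta = beta,
             se = se, p = NA_real_, n = NA_real_, stringsAsFactors = FALSE)
}

test_that("harmonization handles matches, swaps, strand and palindromes", {
  ex <- rbind(ss_row("rs1", "A", "G", 0.3, 0.10),
              ss_row("rs2", "A", "T", 0.10, 0.20),
              ss_row("rs3", "C", "G", 0.48, 0.15),
              ss_row("rs4", "T", "C", 0.25, 0.12),
              ss_row("rs5", "A", "G", 0.40, 0.08))
  ou <- rbind(ss_row("rs1", "G", "A", 0.7, 0.05),    # swapped alleles
              ss_row("rs2", "A", "T", 0.12, 0.03),   # palindromic, clear EAF
              ss_row("rs3", "C", "G", 0.52, 0.02),   # palindromic, ambiguous
              ss_row("rs4", "A", "G", 0.75, 0.04),   # strand complement
              ss_row("rs5", "A", "C", 0.40, 0.01))   # incompatible
  h <- harmonize(ex, ou)
  expect_identical(h$action,
                   c("flipped", "kept", "dropped_palindromic", "kept",
                     "dropped_incompatible"))
  expect_equal(h$by[h$snp == "rs1"], -0.05)
  expect_equal(h$eaf_y[h$snp == "rs1"], 0.3)
  expect_equal(h$by[h$snp == "rs2"], 0.03)
  # conservation: every intersected SNP gets exactly one action
  expect_identical(nrow(h), 5L)
  # palindromic with frequencies on opposite sides of 0.5 gets flipped
  h2 <- harmonize(ss_row("rs2", "A", "T", 0.10, 0.20),
                  ss_row("rs2", "T", "A", 0.88, 0.03))
  expect_identical(h2$action, "flipped")
  expect_equal(h2$by, -0.03)
  # drop-all policy
  h3 <- harmonize(ex, ou, palindromic_policy = "drop")
  expect_identical(h3$action[h3$snp %in% c("rs2", "rs3")],
                   rep("dropped_palindromic", 2))
  expect_error(harmonize(ex, ss_row("zz", "A", "G", 0.5, 0.1)), "shared")
})

test_that("Wald ratio and its delta SE", {
  wr <- wald_ratio(0.2, 0.01, 0.4, 0.1)
  expect_equal(wr$ratio, 2)
  expect_equal(wr$se, 0.5)
  wr2 <- wald_ratio(-0.2, 0.01, -0.4, 0.1)
  expect_equal(wr2$ratio, 2)
  expect_error(wald_ratio(0, 0.01, 0.4, 0.1), "bx = 0")
})

test_that("IVW equals the weighted through-origin regression oracle", {
  set.seed(40)
  for (r in 1:5) {
    p <- make_pairs(bx = runif(50, -0.3, 0.3), by = rnorm(50, 0, 0.1),
                    se_y = runif(50, 0.02, 0.1))
    got <- mr_ivw(p, mode = "fixed")
    fit <- lm(by ~ 0 + bx, data = p, weights = 1 / p$se_y^2)
    expect_equal(got$beta, unname(coef(fit)[1]), tolerance = 1e-10)
    # fixed-effect SE is the WLS SE with dispersion forced to 1
    sm <- summary(fit)
    expect_equal(got$se, unname(sm$coefficients[1, 2] / sm$sigma),
                 tolerance = 1e-10)
  }
})

test_that("IVW special cases: exact fit, single SNP, random effects", {
  p <- make_pairs(bx = c(1, 2), by = c(1, 2), se_y = 0.05)
  res <- mr_ivw(p)
  expect_equal(res$beta, 1)
  expect_equal(res$diagnostics$Q, 0)
  expect_identical(res$diagnostics$mode, "fixed")
  # one SNP: IVW collapses to the Wald ratio
  p1 <- make_pairs(bx = 0.2, by = 0.5, se_y = 0.07)
  res1 <- mr_ivw(p1)
  expect_equal(res1$beta, 2.5)
  expect_equal(res1$se, 0.07 / 0.2)
  # heterogeneous ratios trigger the multiplicative random-effects SE
  p2 <- make_pairs(bx = rep(0.2, 6), by = c(0.02, 0.3, -0.2, 0.25, -0.15, 0.4),
                   se_y = 0.02)
  r2 <- mr_ivw(p2)
  expect_identical(r2$diagnostics$mode, "random")
  expect_equal(r2$se,
               r2$diagnostics$se_fixed *
                 sqrt(r2$diagnostics$Q / (nrow(p2) - 1)))
  expect_equal(mr_ivw(p2, mode = "fixed")$se, r2$diagnostics$se_fixed)
})

test_that("Cochran's Q: exact fit, hand computation, null calibration", {
  p <- make_pairs(bx = c(1, 2, 3), by = 2 * c(1, 2, 3), se_y = 0.1)
  q <- cochrans_q(p)
  expect_equal(q$Q, 0)
  expect_equal(q$p, 1)
  # two SNPs with ratios 1 and 2, both ratio-SE 1: at the weighted mean
  # 1.5, Q = (1 - 1.5)^2 + (2 - 1.5)^2 = 0.5
  p2 <- data.frame(bx = c(1, 1), se_x = c(0.1, 0.1), by = c(1, 2),
                   se_y = c(1, 1))
  expect_equal(cochrans_q(p2)$Q, 0.5)
  set.seed(41)
  rej <- mean(replicate(1000, {
    bx <- rnorm(30, 0.1, 0.03)
    p <- make_pairs(bx = bx, by = 0.5 * bx + rnorm(30, 0, 0.05),
                    se_y = 0.05)
    cochrans_q(p)$p < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("weighted median: middle value, interpolation, bootstrap SE", {
  p <- make_pairs(bx = c(1, 1, 1), by = c(1, 2, 3), se_y = 1)
  expect_equal(mr_weighted_median(p, n_boot = 100, seed = 1)$beta, 2)
  # two equally weighted ratios interpolate to their midpoint; a third
  # tiny-weight ratio barely moves it
  p2 <- make_pairs(bx = c(1, 1, 1), by = c(1, 3, 100),
                   se_y = c(1, 1, 1e4))
  expect_equal(mr_weighted_median(p2, n_boot = 100, seed = 1)$beta, 2,
               tolerance = 1e-3)
  r <- mr_weighted_median(make_pairs(bx = rnorm(30, 0.2, 0.05),
                                     by = rnorm(30, 0.1, 0.05)),
                          n_boot = 200, seed = 7)
  expect_gt(r$se, 0)
  expect_identical(r$nsnp, 30L)
  expect_error(mr_weighted_median(make_pairs(bx = c(1, 2), by = c(1, 2))),
               "at least 3")
})

test_that("Egger recovers an exact affine law and is orientation-invariant", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  p <- make_pairs(bx = bx, by = 0.5 + 1.5 * bx, se_y = 0.05)
  res <- mr_egger(p)
  expect_equal(res$slope$beta, 1.5, tolerance = 1e-10)
  expect_equal(res$intercept$estimate, 0.5, tolerance = 1e-10)
  # flipping the sign of any pair leaves the fit unchanged
  p2 <- p; p2$bx[2] <- -p2$bx[2]; p2$by[2] <- -p2$by[2]
  res2 <- mr_egger(p2)
  expect_equal(res2$slope$beta, res$slope$beta, tolerance = 1e-12)
  expect_equal(res2$intercept$estimate, res$intercept$estimate,
               tolerance = 1e-12)
  expect_error(mr_egger(make_pairs(bx = c(0.2, 0.2, -0.2), by = c(1, 2, 3))),
               "leverage")
})

test_that("Egger matches a weighted lm oracle on random instances", {
  set.seed(42)
  for (r in 1:5) {
    bx <- abs(runif(50, 0.05, 0.3))
    p <- make_pairs(bx = bx, by = 0.02 + 0.4 * bx + rnorm(50, 0, 0.05),
                    se_y = runif(50, 0.03, 0.08))
    got <- mr_egger(p)
    fit <- summary(lm(by ~ bx, data = p, weights = 1 / p$se_y^2))
    expect_equal(got$slope$beta, unname(fit$coefficients["bx", 1]),
                 tolerance = 1e-10)
    expect_equal(got$slope$se, unname(fit$coefficients["bx", 2]),
                 tolerance = 1e-10)
    expect_equal(got$intercept$p,
                 unname(fit$coefficients["(Intercept)", 4]),
                 tolerance = 1e-10)
  }
})

test_that("MR-PRESSO flags a gross outlier and corrects toward the truth", {
  set.seed(43)
  m <- 30
  bx <- runif(m, 0.05, 0.25)
  by <- 1 * bx + rnorm(m, 0, 0.03)
  by[5] <- 1 * bx[5] + 20 * 0.03
  p <- make_pairs(bx = bx, by = by, se_y = 0.03)
  res <- mr_presso(p, n_sim = 500, seed = 3)
  expect_true(5 %in% res$outliers)
  expect_lt(res$global_p, 0.05)
  expect_lt(abs(res$corrected$beta - 1), abs(res$raw$beta - 1))
  # determinism under a fixed seed
  res2 <- mr_presso(p, n_sim = 500, seed = 3)
  expect_identical(res$global_p, res2$global_p)
  expect_error(mr_presso(p, n_sim = 50), "n_sim")
  expect_error(mr_presso(p[1:3, ]), "at least 4")
})

test_that("estimators are invariant to SNP row order", {
  set.seed(44)
  p <- make_pairs(bx = runif(20, 0.05, 0.3), by = rnorm(20, 0.05, 0.05),
                  se_y = runif(20, 0.02, 0.08))
  perm <- sample(20)
  expect_equal(mr_ivw(p)$beta, mr_ivw(p[perm, ])$beta, tolerance = 1e-12)
  expect_equal(mr_egger(p)$slope$beta, mr_egger(p[perm, ])$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(p, n_boot = 50, seed = 1)$beta,
               mr_weighted_median(p[perm, ], n_boot = 50, seed = 1)$beta,
               tolerance = 1e-12)
})

test_that("exact-fit data collapse all estimators to theta", {
  bx <- c(0.1, 0.15, 0.22, 0.3, 0.45)
  p <- make_pairs(bx = bx, by = -0.8 * bx, se_y = 0.04)
  expect_equal(mr_ivw(p)$beta, -0.8, tolerance = 1e-12)
  expect_equal(mr_weighted_median(p, n_boot = 50, seed = 1)$beta, -0.8,
               tolerance = 1e-9)
  eg <- mr_egger(p)
  expect_equal(eg$slope$beta, -0.8, tolerance = 1e-10)
  expect_equal(eg$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(cochrans_q(p)$Q, 0, tolerance = 1e-20)
})

test_that("bh_fdr matches the step-up definition and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))
  set.seed(45)
  for (r in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})
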