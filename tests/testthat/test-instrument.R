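toy_geno <- function(dosages, a1 = NULL, a2 = NULL) {
  m <- ncol(dosages)
  genotype_matrix(dosages, data.frame(
    snp = paste0("s", seq_len(m)), chr = 1, pos = seq_len(m) * 1e6,
    a1 = if (is.null(a1)) rep("A", m) else a1,
    a2 = if (is.null(a2)) rep("G", m) else a2))
}

test_that("wGRS accumulates weights, flips alleles, imputes missing", {
  g <- toy_geno(matrix(c(2, 1, 1, 0), nrow = 2))
  w <- data.frame(snp = c("s1", "s2"), a1 = c("A", "A"),
                  weight = c(0.1, -0.2))
  expect_equal(build_wgrs(g, w)$wgrs, c(0.1 * 2 - 0.2 * 1,
                                        0.1 * 1 - 0.2 * 0))
  # allele swap: weight on the matrix's other allele counts 2 - g
  w_flip <- data.frame(snp = "s1", a1 = "G", weight = 0.1)
  expect_equal(build_wgrs(g, w_flip)$wgrs, 0.1 * (2 - c(2, 1)))
  # irreconcilable alleles rejected
  w_bad <- data.frame(snp = "s1", a1 = "T", weight = 0.1)
  expect_error(build_wgrs(g, w_bad), "irreconcilable")
  # missing dosage imputed at twice the effect-allele frequency
  d <- matrix(c(1, 1, 0, 0, NA, 1, 0, 0), ncol = 1)  # freq = 0.25/... :
  d <- matrix(c(1, 0, 0, 0, NA), ncol = 1)           # mean/2 = 0.125
  g2 <- toy_geno(d)
  w2 <- data.frame(snp = "s1", a1 = "A", weight = 0.4)
  expect_equal(build_wgrs(g2, w2)$wgrs[5], 0.4 * 2 * 0.125)
})

test_that("wGRS is invariant to SNP order and allele representation", {
  set.seed(20)
  d <- matrix(rbinom(300, 2, 0.3), ncol = 3)
  g <- toy_geno(d)
  w <- data.frame(snp = c("s1", "s2", "s3"), a1 = "A",
                  weight = c(0.3, -0.1, 0.2))
  ref <- build_wgrs(g, w)$wgrs
  expect_equal(build_wgrs(g, w[c(3, 1, 2), ])$wgrs, ref)
  # flip the stored representation of SNP 2: swap alleles, dosage 2 - g
  d2 <- d; d2[, 2] <- 2 - d[, 2]
  g2 <- genotype_matrix(d2, data.frame(
    snp = paste0("s", 1:3), chr = 1, pos = 1:3 * 1e6,
    a1 = c("A", "G", "A"), a2 = c("G", "A", "G")))
  expect_equal(build_wgrs(g2, w)$wgrs, ref)
})

test_that("partial F follows the R^2 formula and is affine-invariant", {
  set.seed(21)
  # construct an instrument/exposure pair with known R^2 = 0.5
  z <- rnorm(102)
  x <- z + rnorm(102)
  r2 <- cor(x, z)^2
  expect_equal(f_statistic(x, z), (102 - 2) * r2 / (1 - r2),
               tolerance = 1e-10)
  expect_equal(f_statistic(x, 3 * z - 7), f_statistic(x, z),
               tolerance = 1e-9)
  covars <- data.frame(c1 = rnorm(102))
  expect_equal(f_statistic(x, 3 * z - 7, covars),
               f_statistic(x, z, covars), tolerance = 1e-9)
  expect_error(f_statistic(x, z, data.frame(a = 1:102, b = 2 * (1:102) + 1)),
               "collinear")
})

test_that("the null F is calibrated against F(1, n-2)", {
  set.seed(22)
  n <- 200
  fs <- replicate(500, f_statistic(rnorm(n), rnorm(n)))
  rej <- mean(fs > qf(0.95, 1, n - 2))
  expect_gt(rej, 0.03); expect_lt(rej, 0.08)
})

test_that("assumption report has the right shape and passes under the null", {
  set.seed(23)
  n <- 600
  conf <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
                     drinking = rbinom(n, 1, 0.1), educ = sample(1:7, n, TRUE))
  rep <- assumption_report(rnorm(n), conf, rnorm(n), rnorm(n))
  expect_identical(nrow(rep), 5L)  # 4 confounders + exclusion
  expect_identical(rep$check, c(rep("independence", 4), "exclusion"))
  expect_identical(rep$test[rep$variable == "sex"], "two-sample t")
  expect_identical(rep$test[rep$variable == "age"], "Pearson")
  # degenerate binary confounder flagged untestable
  conf$solo <- c(1, rep(0, n - 1))
  rep2 <- assumption_report(rnorm(n), conf, rnorm(n), rnorm(n))
  expect_false(rep2$testable[rep2$variable == "solo"])
  # per-row pass rate about 95% under independence
  set.seed(24)
  passes <- replicate(200, {
    r <- assumption_report(rnorm(300), conf[1:300, 1:4], rnorm(300),
                           rnorm(300))
    r$pass
  })
  rate <- rowMeans(passes)
  expect_true(all(rate > 0.88) && all(rate <= 1))
})

test_that("exclusion check detects a planted direct path to the outcome", {
  set.seed(25)
  hits <- replicate(50, {
    n <- 2000
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -1 * x + 0.5 * z + rnorm(n)  # direct pleiotropic path, 0.5 sd
    conf <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
    r <- assumption_report(z, conf, y, x)
    !r$pass[r$check == "exclusion"]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Cochran-Armitage trend: nulls, scaling law, permutation oracle", {
  sym <- matrix(c(10, 20, 30, 10, 20, 30), nrow = 2, byrow = TRUE)
  res <- cochran_armitage_trend(sym)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  tab <- matrix(c(10, 20, 30, 30, 20, 10), nrow = 2, byrow = TRUE)
  r1 <- cochran_armitage_trend(tab)
  r2 <- cochran_armitage_trend(2 * tab)
  expect_equal(r2$z, sqrt(2) * r1$z, tolerance = 1e-12)
  # degenerate: all mass in one genotype column
  expect_false(cochran_armitage_trend(
    matrix(c(5, 0, 0, 7, 0, 0), 2, byrow = TRUE))$testable)
  # permutation oracle for the z-score
  set.seed(26)
  trait <- rep(c(1, 0), times = c(60, 60))
  geno <- c(rep(0:2, c(10, 20, 30)), rep(0:2, c(30, 20, 10)))
  obs <- sum(trait * geno)
  perm <- replicate(1e5, sum(trait * sample(geno)))
  z_perm <- (obs - mean(perm)) / sd(perm)
  expect_equal(abs(r1$z), abs(z_perm), tolerance = 0.02 * abs(z_perm))
})

test_that("pruning removes the pleiotropic SNP first and is replayable", {
  set.seed(27)
  n <- 2000; m <- 15
  g <- simulate_genotypes(n, runif(m, 0.2, 0.5))
  true_w <- runif(m, 0.2, 0.5)
  x <- drop(g$dosage %*% true_w) + rnorm(n)
  conf <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
                     drinking = rbinom(n, 1, 0.1),
                     educ = sample(1:7, n, TRUE))
  y <- -1 * x + 1.5 * g$dosage[, 7] + rnorm(n, 0, 2)  # SNP 7 pleiotropic
  w <- data.frame(snp = g$snp_meta$snp, a1 = g$snp_meta$a1,
                  weight = true_w)
  inst <- build_wgrs(g, w)
  pruned <- prune_instrument(inst, g, conf, y, x)
  removed <- pruned$check_log$snp[pruned$check_log$action == "remove_snp"]
  expect_identical(removed[1], "snp_007")
  expect_identical(nrow(pruned$weights), as.integer(m - length(removed)))
  # idempotence: the returned instrument passes all checks
  rep_after <- assumption_report(pruned$wgrs, conf, y, x)
  expect_true(all(rep_after$pass[rep_after$testable]))
  pruned2 <- prune_instrument(pruned, g, conf, y, x)
  expect_identical(pruned2$weights, pruned$weights)
  # replaying the audit log reproduces the final SNP set and wGRS
  replayed <- replay_check_log(g, w, pruned$check_log)
  expect_identical(replayed$weights$snp, pruned$weights$snp)
  expect_equal(replayed$wgrs, pruned$wgrs)
  expect_gt(pruned$f, 10)
})

test_that("pruning with no violations returns the instrument unchanged", {
  set.seed(28)
  n <- 1500; m <- 8
  g <- simulate_genotypes(n, runif(m, 0.2, 0.5))
  x <- drop(g$dosage %*% rep(0.4, m)) + rnorm(n)
  y <- x + rnorm(n)
  conf <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  inst <- build_wgrs(g, data.frame(snp = g$snp_meta$snp,
                                   a1 = g$snp_meta$a1, weight = 0.4))
  pruned <- prune_instrument(inst, g, conf, y, x)
  expect_identical(pruned$weights, inst$weights)
  expect_false(any(pruned$check_log$action == "remove_snp"))
})

test_that("pruning aborts at the min_snps floor when all SNPs violate", {
  set.seed(29)
  n <- 3000; m <- 3
  g <- simulate_genotypes(n, rep(0.3, m))
  x <- drop(g$dosage %*% rep(0.5, m)) + rnorm(n)
  # every SNP has a strong direct path to the outcome
  y <- x + drop(g$dosage %*% rep(2, m)) + rnorm(n)
  conf <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  inst <- build_wgrs(g, data.frame(snp = g$snp_meta$snp,
                                   a1 = g$snp_meta$a1, weight = 0.5))
  expect_error(prune_instrument(inst, g, conf, y, x, min_snps = 2),
               "min_snps")
})
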