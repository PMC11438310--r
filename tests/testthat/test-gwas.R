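test_that("HWE exact test matches hand cases and the enumeration oracle", {
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_error(hwe_exact_test(-1, 0, 5), "non-negative")
  # exhaustive comparison for all configurations with n <= 40
  for (n in c(1:10, 20, 40)) {
    for (n_aa in 0:n) for (n_het in 0:(n - n_aa)) {
      n_AA <- n - n_aa - n_het
      expect_equal(hwe_exact_test(n_AA, n_het, n_aa),
                   oracle_hwe(n_AA, n_het, n_aa), tolerance = 1e-10)
    }
  }
  # random configurations up to n = 200
  set.seed(11)
  for (r in 1:200) {
    cnt <- as.vector(rmultinom(1, sample(3:200, 1), runif(3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 do.call(oracle_hwe, as.list(cnt)), tolerance = 1e-10)
  }
})

test_that("qc_filter applies call-rate, strict MAF, and HWE rules", {
  set.seed(7)
  n <- 400
  d <- cbind(rbinom(n, 2, 0.3),           # clean
             rbinom(n, 2, 0.3),           # will get 6% missing
             rbinom(n, 2, 0.01),          # MAF at/below 0.01
             c(rep(0, 200), rep(2, 200))) # gross HWE violation
  d[sample(n, 24), 2] <- NA
  # set column 3 to an exact 1% MAF: 8 carriers among 400 individuals
  d[, 3] <- 0; d[sample(n, 8), 3] <- 1
  meta <- data.frame(snp = paste0("s", 1:4), chr = 1, pos = 1:4 * 1e6,
                     a1 = "A", a2 = "G")
  res <- qc_filter(genotype_matrix(d, meta))
  expect_identical(res$genotypes$snp_meta$snp, "s1")
  expect_setequal(res$exclusions$snp, c("s2", "s3", "s4"))
  expect_identical(res$exclusions$reason[res$exclusions$snp == "s2"],
                   "call_rate")
  expect_identical(res$exclusions$reason[res$exclusions$snp == "s3"],
                   "maf")  # MAF == 0.01 fails the strictly-greater filter
  expect_identical(res$exclusions$reason[res$exclusions$snp == "s4"],
                   "hwe")
})

test_that("HWE-conformant SNPs almost always survive the HWE filter", {
  set.seed(21)
  g <- simulate_genotypes(2000, runif(300, 0.05, 0.5))
  res <- qc_filter(g, maf_min = 0)
  expect_gte(ncol(res$genotypes$dosage), 297)  # >= 99% survive
})

test_that("assoc_scan equals the lm oracle on a random instance", {
  set.seed(5)
  n <- 50; m <- 20
  g <- simulate_genotypes(n, runif(m, 0.2, 0.5))
  y <- rnorm(n) + g$dosage[, 1] * 0.8
  covars <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  got <- assoc_scan(g, y, covars)
  want <- oracle_assoc(g$dosage, y, covars)
  expect_lt(max(abs(got$beta - want[, 1])), 1e-10)
  expect_lt(max(abs(got$se - want[, 2])), 1e-10)
  expect_lt(max(abs(got$p - want[, 3])), 1e-10)
})

test_that("assoc_scan handles exact fits, missingness, constant SNPs", {
  set.seed(6)
  g <- simulate_genotypes(80, c(0.4, 0.3, 0.2), missing_rate = 0.1)
  y <- 2 * ifelse(is.na(g$dosage[, 1]), 0, g$dosage[, 1])
  y[is.na(g$dosage[, 1])] <- NA
  res <- assoc_scan(g, y)
  expect_equal(res$beta[1], 2, tolerance = 1e-8)
  expect_lt(res$p[1], 1e-30)
  expect_true(all(res$n_used <= 80))
  # constant SNP flagged, not fatal
  d <- cbind(g$dosage[, 1], 1)
  gm <- genotype_matrix(d, data.frame(snp = c("a", "b"), chr = 1,
                                      pos = c(1e6, 2e6), a1 = "A", a2 = "G"))
  res2 <- assoc_scan(gm, rnorm(80))
  expect_true(is.na(res2$beta[2]))
  expect_error(assoc_scan(g, rnorm(80), data.frame(x = 1:80, y = 2 * (1:80))),
               "collinear")
})

test_that("null association p-values are uniform", {
  set.seed(9)
  g <- simulate_genotypes(500, runif(400, 0.1, 0.5))
  res <- assoc_scan(g, rnorm(500))
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("ld_r2: identity, complement, and independent-null behaviour", {
  set.seed(10)
  a <- rbinom(5000, 2, 0.3)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2 - a), 1)  # perfect negative correlation
  r2s <- replicate(300, ld_r2(rbinom(10000, 2, 0.3), rbinom(10000, 2, 0.3)))
  expect_gte(mean(r2s < 0.01), 0.99)
  expect_error(ld_r2(a, rep(1, 5000)), "constant")
  expect_error(ld_r2(a, a[-1]), "length")
})

test_that("clump follows the greedy rule on a hand-built instance", {
  # 3 SNPs within 10 Mb: 1-2 in strong LD, 3 independent
  set.seed(12)
  n <- 3000
  s1 <- rbinom(n, 2, 0.3)
  s2 <- ifelse(runif(n) < 0.95, s1, rbinom(n, 2, 0.3))
  s3 <- rbinom(n, 2, 0.3)
  g <- genotype_matrix(cbind(s1, s2, s3),
                       data.frame(snp = c("s1", "s2", "s3"), chr = 1,
                                  pos = c(1e6, 2e6, 3e6), a1 = "A",
                                  a2 = "G"))
  assoc <- data.frame(snp = c("s1", "s2", "s3"), chr = 1,
                      pos = c(1e6, 2e6, 3e6), p = c(1e-10, 1e-9, 1e-8))
  expect_identical(clump(assoc, g), c("s1", "s3"))
  # nothing significant -> empty
  assoc$p <- c(0.5, 0.2, 0.9)
  expect_identical(clump(assoc, g), character(0))
})

test_that("clump matches the brute-force greedy oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- 20; n <- 1500
    g <- simulate_genotypes(n, runif(m, 0.1, 0.5),
                            ld = list(block_size = 4, rho = 0.9))
    meta <- g$snp_meta
    meta$chr <- rep(1:2, each = 10)
    meta$pos <- rep(seq(1e6, by = 2e6, length.out = 10), 2)
    g <- genotype_matrix(g$dosage, meta)
    tab <- data.frame(snp = meta$snp, chr = meta$chr, pos = meta$pos,
                      p = 10^runif(m, -12, -4))
    got <- clump(tab, g, p_threshold = 1e-5, r2_threshold = 0.01,
                 window_kb = 5000)
    want <- oracle_clump(tab, g$dosage, 1e-5, 0.01, 5000)
    expect_setequal(got, want)
  }
})

test_that("independent SNPs each become their own clump index", {
  set.seed(14)
  g <- simulate_genotypes(4000, runif(8, 0.2, 0.5))
  tab <- data.frame(snp = g$snp_meta$snp, chr = g$snp_meta$chr,
                    pos = g$snp_meta$pos, p = rep(1e-9, 8))
  expect_setequal(clump(tab, g), g$snp_meta$snp)
})
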