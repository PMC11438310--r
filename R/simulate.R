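#' Simulate genotype dosages in Hardy-Weinberg proportions
#'
#' Each SNP column is an independent draw of minor-allele counts from the
#' Hardy-Weinberg proportions ((1-p)^2, 2p(1-p), p^2). Missing entries are
#' introduced completely at random and flagged `NA`, never zero-coded. An
#' optional block-correlation mode induces LD within consecutive blocks
#' (via a Gaussian copula on haplotypes) solely so that clumping has
#' something to prune; the default is independent SNPs.
#'
#' @param n_individuals number of individuals (> 0).
#' @param mafs vector of minor allele frequencies, each in (0, 0.5].
#' @param missing_rate probability in `[0, 1)` that any one dosage is
#'   missing.
#' @param seed optional integer seed for reproducibility.
#' @param ld optional list `list(block_size =, rho =)`: consecutive runs of
#'   `block_size` SNPs share haplotype-level latent correlation `rho`.
#' @param snp_meta optional metadata data.frame overriding the generated
#'   one (columns as in [genotype_matrix()]).
#' @return a [genotype_matrix()]. Generated metadata spreads SNPs across
#'   chromosomes with 1 Mb spacing and uses non-palindromic allele pairs.
#' @export
simulate_genotypes <- function(n_individuals, mafs, missing_rate = 0,
                               seed = NULL, ld = NULL, snp_meta = NULL) {
  if (!is.numeric(n_individuals) || n_individuals < 1)
    stop("n_individuals must be a positive count")
  bad <- which(!is.finite(mafs) | mafs <= 0 | mafs > 0.5)
  if (length(bad))
    stop("MAF outside (0, 0.5] for SNP ", bad[1], " (maf = ", mafs[bad[1]], ")")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_individuals)
  m <- length(mafs)
  if (is.null(ld)) {
    d <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), numeric(n))
    d <- matrix(d, nrow = n)
  } else {
    stopifnot(is.numeric(ld$block_size), ld$block_size >= 1,
              abs(ld$rho) < 1)
    d <- matrix(0, n, m)
    blocks <- split(seq_len(m), (seq_len(m) - 1) %/% ld$block_size)
    for (idx in blocks) {
      k <- length(idx)
      thr <- stats::qnorm(mafs[idx])
      for (hap in 1:2) {
        shared <- stats::rnorm(n)
        z <- sqrt(ld$rho) * matrix(shared, n, k) +
          sqrt(1 - ld$rho) * matrix(stats::rnorm(n * k), n, k)
        d[, idx] <- d[, idx] + (z < matrix(thr, n, k, byrow = TRUE))
      }
    }
  }
  if (missing_rate > 0)
    d[stats::runif(length(d)) < missing_rate] <- NA_real_
  if (is.null(snp_meta)) {
    n_chr <- min(22L, m)
    chr <- rep_len(seq_len(n_chr), m)
    pos <- integer(m)
    for (c in seq_len(n_chr)) {
      on_c <- which(chr == c)
      pos[on_c] <- 1e6 * seq_along(on_c)
    }
    pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                    ncol = 2, byrow = TRUE)
    pick <- rep_len(seq_len(nrow(pairs)), m)
    snp_meta <- data.frame(
      snp = sprintf("snp_%03d", seq_len(m)), chr = chr, pos = pos,
      a1 = pairs[pick, 1], a2 = pairs[pick, 2], maf = mafs,
      stringsAsFactors = FALSE)
  }
  genotype_matrix(d, snp_meta)
}

#' Configuration for a synthetic one-sample cohort
#'
#' The defaults emulate the study conditions of a biobank-scale
#' one-sample MR analysis: a target cohort of 2,383 individuals, 15
#' instrument SNPs with minor allele frequencies between 0.05 and 0.45,
#' confounding of the exposure-outcome relation by age, sex, drinking and
#' educational attainment, and a causal effect of -1 outcome unit per
#' point of the total CVH score.
#'
#' @param n_individuals cohort size.
#' @param n_snps number of SNPs.
#' @param maf_range range (low, high) within (0, 0.5] from which MAFs are
#'   drawn uniformly.
#' @param snp_effects_per_component named list mapping raw components
#'   (`tc`, `fg`, `sbp`, `dbp`, `bmi`) to per-SNP additive effects in
#'   component units per minor allele; each vector of length `n_snps`.
#'   `NULL` gives a default round-robin assignment in which every SNP
#'   perturbs one clinical component.
#' @param confounder_effects list with elements `components` (named list:
#'   component -> named vector of effects of `age`, `sex`, `drinking`,
#'   `educ`) and `eaa` (named vector: effects of the same confounders on
#'   every outcome). These shared effects are what make naive regression
#'   of outcome on exposure biased.
#' @param theta true causal effect of the total CVH score on each outcome
#'   (outcome units per point); scalar or named per-outcome vector.
#' @param pleiotropy per-SNP direct (horizontal) effects on every outcome,
#'   in outcome units per allele; length `n_snps`. These act on the
#'   outcome only, never through other components, so instrument validity
#'   is well defined in the truth record.
#' @param noise_sd named list of Gaussian noise standard deviations for
#'   `tc`, `fg`, `sbp`, `dbp`, `bmi` and `eaa`.
#' @param missing_rate genotype missingness (completely at random).
#' @param outcomes names of the outcome columns to generate.
#' @param n_pcs number of pure-noise "ancestry principal component"
#'   covariate columns to emit.
#' @param seed integer seed.
#' @return validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_individuals = 2383, n_snps = 15,
                              maf_range = c(0.05, 0.45),
                              snp_effects_per_component = NULL,
                              confounder_effects = NULL,
                              theta = -1, pleiotropy = NULL,
                              noise_sd = NULL, missing_rate = 0.01,
                              outcomes = c("HannumEAA", "IEAA", "PhenoEAA",
                                           "GrimEAA", "DNAmPAI1",
                                           "DunedinPACE"),
                              n_pcs = 10, seed = 1L) {
  if (n_snps < 1) stop("n_snps must be at least 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (is.null(snp_effects_per_component)) {
    comp <- c("tc", "fg", "sbp", "bmi")
    scale <- c(tc = 20, fg = 7.5, sbp = 7.5, bmi = 1.1)
    snp_effects_per_component <- lapply(
      stats::setNames(nm = c("tc", "fg", "sbp", "dbp", "bmi")),
      function(x) numeric(n_snps))
    for (j in seq_len(n_snps)) {
      k <- comp[1 + (j - 1) %% length(comp)]
      snp_effects_per_component[[k]][j] <- scale[[k]]
      if (k == "sbp") snp_effects_per_component$dbp[j] <- 5
    }
  }
  for (k in names(snp_effects_per_component)) {
    v <- snp_effects_per_component[[k]]
    if (length(v) != n_snps)
      stop("snp effect vector for '", k, "' has length ", length(v),
           ", expected n_snps = ", n_snps)
  }
  if (is.null(confounder_effects))
    confounder_effects <- list(
      components = list(
        tc  = c(age = 0.6, sex = 5, drinking = 4, educ = -2),
        fg  = c(age = 0.25, sex = 3, drinking = 2, educ = -1),
        sbp = c(age = 0.5, sex = 6, drinking = 4, educ = -1.5),
        dbp = c(age = 0.25, sex = 4, drinking = 3, educ = -1),
        bmi = c(age = 0.04, sex = 1, drinking = 0.5, educ = -0.3)),
      eaa = c(age = 0.03, sex = 1.2, drinking = 0.8, educ = -0.35))
  if (is.null(pleiotropy)) pleiotropy <- numeric(n_snps)
  if (length(pleiotropy) != n_snps)
    stop("pleiotropy vector has length ", length(pleiotropy),
         ", expected n_snps = ", n_snps)
  if (is.null(noise_sd))
    noise_sd <- list(tc = 28, fg = 9, sbp = 12, dbp = 8, bmi = 3, eaa = 4)
  if (any(unlist(noise_sd) <= 0)) stop("noise_sd entries must be > 0")
  theta <- if (length(theta) == 1)
    stats::setNames(rep(theta, length(outcomes)), outcomes)
  else {
    if (!all(outcomes %in% names(theta)))
      stop("theta must be scalar or named for every outcome")
    theta[outcomes]
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 snp_effects_per_component = snp_effects_per_component,
                 confounder_effects = confounder_effects, theta = theta,
                 pleiotropy = pleiotropy, noise_sd = noise_sd,
                 missing_rate = missing_rate, outcomes = outcomes,
                 n_pcs = as.integer(n_pcs), seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate an individual-level cohort with known causal structure
#'
#' Generates genotypes, confounders, raw CVH metrics, and outcome columns
#' from a linear structural model with a known causal effect:
#' each raw clinical component is a linear combination of its SNP effects,
#' confounder effects and Gaussian noise; component scores and the total
#' CVH score follow from [cvh_score()]; and each outcome equals
#' `theta * total + confounder effects + sum(pleiotropy_j * g_j) + noise`.
#' Smoking and physical activity are sampled categorically (they carry no
#' genetic effects by default, mirroring how few genome-wide significant
#' SNPs such behavioural scores yield at biobank scale).
#'
#' Confounder distributions: age Normal(50, 11) truncated to \[30, 70\];
#' sex Bernoulli(0.5); drinking Bernoulli(0.07); educational attainment
#' uniform on the integers 1..7.
#'
#' @param config a [cohort_sim_config()].
#' @return list with elements `genotypes` ([genotype_matrix()]),
#'   `covariates` (age/sex/drinking/educ + noise PCs), `metrics` (raw CVH
#'   metric table accepted by [cvh_score()]), `scores` (the derived
#'   [cvh_score()] table), `outcomes` (one column per outcome), and
#'   `truth` (every generating parameter, for closure tests).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  mafs <- stats::runif(config$n_snps, config$maf_range[1],
                       config$maf_range[2])
  g <- simulate_genotypes(n, mafs, missing_rate = config$missing_rate)
  # analysis dosages: mean-impute missing so the structural model is exact
  d <- g$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
  }
  age <- stats::qnorm(stats::runif(n, stats::pnorm(30, 50, 11),
                                   stats::pnorm(70, 50, 11)), 50, 11)
  covars <- data.frame(age = age,
                       sex = stats::rbinom(n, 1, 0.5),
                       drinking = stats::rbinom(n, 1, 0.07),
                       educ = sample(1:7, n, replace = TRUE))
  if (config$n_pcs > 0) {
    pcs <- matrix(stats::rnorm(n * config$n_pcs), n)
    colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))
    covars <- cbind(covars, pcs)
  }
  # predictors enter centred at their expectations so that `comp_mean`
  # is the realized population mean of each raw metric
  comp_mean <- c(tc = 195, fg = 97, sbp = 122, dbp = 76, bmi = 24)
  conf_mat <- as.matrix(covars[, c("age", "sex", "drinking", "educ")])
  conf_c <- sweep(conf_mat, 2, c(age = 50, sex = 0.5, drinking = 0.07,
                                 educ = 4))
  d_c <- sweep(d, 2, 2 * mafs)
  raw <- list()
  for (k in c("tc", "fg", "sbp", "dbp", "bmi")) {
    eff <- config$snp_effects_per_component[[k]]
    if (is.null(eff)) eff <- numeric(config$n_snps)
    ce <- config$confounder_effects$components[[k]]
    if (is.null(ce)) ce <- c(age = 0, sex = 0, drinking = 0, educ = 0)
    raw[[k]] <- comp_mean[[k]] + drop(d_c %*% eff) +
      drop(conf_c %*% ce[colnames(conf_mat)]) +
      stats::rnorm(n, 0, config$noise_sd[[k]])
    raw[[k]] <- pmax(raw[[k]], 1)  # clinical values are positive
  }
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.80, 0.08, 0.12))
  quit_months <- ifelse(smoking == "former",
                        stats::rexp(n, rate = 1 / 36), NA_real_)
  pa <- sample(c("never", "between", "regular"), n, replace = TRUE,
               prob = c(0.45, 0.20, 0.35))
  metrics <- data.frame(tc = raw$tc, fg = raw$fg, sbp = raw$sbp,
                        dbp = raw$dbp, bmi = raw$bmi, smoking = smoking,
                        quit_months = quit_months, pa = pa,
                        stringsAsFactors = FALSE)
  scores <- cvh_score(metrics)
  eaa_conf <- drop(conf_mat %*%
                     config$confounder_effects$eaa[colnames(conf_mat)])
  pleio <- drop(d %*% config$pleiotropy)
  outcomes <- as.data.frame(lapply(config$outcomes, function(o) {
    config$theta[[o]] * scores$total + eaa_conf + pleio +
      stats::rnorm(n, 0, config$noise_sd$eaa)
  }))
  names(outcomes) <- config$outcomes
  list(genotypes = g, covariates = covars, metrics = metrics,
       scores = scores, outcomes = outcomes,
       truth = list(config = config, mafs = mafs,
                    valid_instruments = config$pleiotropy == 0))
}

#' Configuration for synthetic two-sample summary statistics
#'
#' Defaults emulate the study conditions of the two-sample arm: 11
#' instrument SNPs (the CVH-score instruments surviving lookup in the
#' outcome GWAS), a large exposure GWAS (small `se_x`) and a causal effect
#' of -0.5 outcome units per exposure unit, with no horizontal pleiotropy
#' unless requested.
#'
#' @param n_snps number of instrument SNPs.
#' @param beta_x per-SNP true exposure effects; `NULL` draws magnitudes
#'   uniformly from 0.04--0.16 with random sign.
#' @param se_x,se_y per-SNP standard errors (scalar recycled or vectors).
#' @param theta true causal effect.
#' @param alpha per-SNP horizontal pleiotropic effects on the outcome;
#'   scalar 0, or a vector of length `n_snps`.
#' @param inside_violation if `TRUE`, pleiotropic effects are drawn
#'   correlated with `beta_x` (violating the InSIDE condition that
#'   MR-Egger needs); if `FALSE` any nonzero `alpha` is independent of
#'   `beta_x`.
#' @param outlier_indices indices of SNPs to be made gross outliers.
#' @param outlier_scale outlier pleiotropy in units of that SNP's `se_y`.
#' @param palindromic_frac fraction of SNPs assigned A/T or C/G alleles.
#' @param n_exposure,n_outcome GWAS sample sizes recorded in the tables.
#' @param seed integer seed.
#' @return validated list of class `two_sample_sim_config`.
#' @export
two_sample_sim_config <- function(n_snps = 11, beta_x = NULL, se_x = 0.01,
                                  se_y = 0.05, theta = -0.5, alpha = 0,
                                  inside_violation = FALSE,
                                  outlier_indices = integer(0),
                                  outlier_scale = 20,
                                  palindromic_frac = 0.2,
                                  n_exposure = 590000, n_outcome = 34710,
                                  seed = 1L) {
  if (n_snps < 1) stop("n_snps must be at least 1")
  se_x <- rep_len(se_x, n_snps); se_y <- rep_len(se_y, n_snps)
  if (any(se_x <= 0) || any(se_y <= 0)) stop("all SEs must be > 0")
  if (!is.null(beta_x) && length(beta_x) != n_snps)
    stop("beta_x must have length n_snps")
  if (length(alpha) == 1) alpha <- rep(alpha, n_snps)
  if (length(alpha) != n_snps) stop("alpha must have length n_snps")
  if (length(outlier_indices) &&
      (min(outlier_indices) < 1 || max(outlier_indices) > n_snps))
    stop("outlier_indices out of range")
  structure(list(n_snps = as.integer(n_snps), beta_x = beta_x,
                 se_x = se_x, se_y = se_y, theta = theta, alpha = alpha,
                 inside_violation = isTRUE(inside_violation),
                 outlier_indices = as.integer(outlier_indices),
                 outlier_scale = outlier_scale,
                 palindromic_frac = palindromic_frac,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 seed = as.integer(seed)),
            class = "two_sample_sim_config")
}

#' Simulate exposure and outcome GWAS summary statistics
#'
#' Per SNP j, the estimated exposure effect is Normal(beta_x_j, se_x_j)
#' and the estimated outcome effect is Normal(theta * beta_x_j + alpha_j,
#' se_y_j), where alpha_j is the horizontal-pleiotropy direct effect.
#' Alleles are assigned so a configurable fraction are palindromic (A/T or
#' C/G), and effect-allele frequencies are populated consistently across
#' the two studies (small sampling jitter) so that frequency-based
#' harmonization of palindromic SNPs is exercised.
#'
#' @param config a [two_sample_sim_config()].
#' @return list with `exposure` and `outcome` summary-statistic
#'   data.frames (columns `snp`, `a1`, `a2`, `eaf`, `beta`, `se`, `p`,
#'   `n`) and `truth` (the generating parameters, including the realized
#'   `beta_x` and `alpha`).
#' @export
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "two_sample_sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  beta_x <- config$beta_x
  if (is.null(beta_x))
    beta_x <- stats::runif(m, 0.04, 0.16) * sample(c(-1, 1), m, TRUE)
  alpha <- config$alpha
  if (config$inside_violation && any(alpha != 0))
    alpha <- alpha * sign(beta_x)
  if (length(config$outlier_indices))
    alpha[config$outlier_indices] <-
      config$outlier_scale * config$se_y[config$outlier_indices]
  snp <- sprintf("rs%05d", seq_len(m))
  n_pal <- round(config$palindromic_frac * m)
  pal_idx <- if (n_pal > 0) seq_len(n_pal) else integer(0)
  pairs_np <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                     ncol = 2, byrow = TRUE)
  pairs_p <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    if (j %in% pal_idx) {
      pr <- pairs_p[1 + j %% 2, ]
    } else pr <- pairs_np[1 + j %% 4, ]
    a1[j] <- pr[1]; a2[j] <- pr[2]
  }
  eaf <- stats::runif(m, 0.08, 0.92)
  eaf_out <- pmin(pmax(eaf + stats::rnorm(m, 0, 0.01), 0.001), 0.999)
  bx_hat <- stats::rnorm(m, beta_x, config$se_x)
  by_hat <- stats::rnorm(m, config$theta * beta_x + alpha, config$se_y)
  mk <- function(beta, se, eaf, n) {
    data.frame(snp = snp, a1 = a1, a2 = a2, eaf = eaf, beta = beta,
               se = se, p = 2 * stats::pnorm(-abs(beta / se)), n = n,
               stringsAsFactors = FALSE)
  }
  list(exposure = mk(bx_hat, config$se_x, eaf, config$n_exposure),
       outcome = mk(by_hat, config$se_y, eaf_out, config$n_outcome),
       truth = list(config = config, beta_x = beta_x, alpha = alpha,
                    theta = config$theta,
                    palindromic = seq_len(m) %in% pal_idx))
}
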