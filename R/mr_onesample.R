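#' One-sample Mendelian randomization by two-stage least squares
#'
#' Stage 1 regresses the exposure on the instrument (plus covariates) and
#' stage 2 regresses the outcome on the predicted exposure (plus the same
#' covariates); the coefficient of the predicted exposure is the causal
#' effect of the exposure on the outcome.
#'
#' The reported standard error is the IV-corrected one: the residual
#' variance is computed from the structural residuals
#' `outcome - beta * observed exposure - covariate part`, not from the
#' stage-2 fitted residuals (which use the predicted exposure and
#' understate the noise). The naive stage-2 OLS standard error is kept in
#' `diagnostics$naive_se` for comparison. Inference is normal-based.
#'
#' The first-stage partial F statistic is always computed and attached to
#' the diagnostics; when F < 10 the result carries
#' `diagnostics$weak_instrument = TRUE` and a warning is raised, but the
#' estimate is still returned.
#'
#' @param exposure,outcome numeric vectors, one value per individual.
#' @param instrument per-individual instrument values (e.g. a wGRS), or
#'   an `instrument_set` from [build_wgrs()].
#' @param covariates optional data.frame of covariates included in both
#'   stages.
#' @return an [mr_result()] with method `"2SLS"`; diagnostics hold
#'   `f_statistic`, `weak_instrument`, `naive_se` and the first-stage
#'   coefficient.
#' @examples
#' set.seed(1)
#' z <- rnorm(500); x <- z + rnorm(500); y <- 2 * x + rnorm(500)
#' tsls(x, y, z)$beta
#' @export
tsls <- function(exposure, outcome, instrument, covariates = NULL) {
  if (inherits(instrument, "instrument_set")) instrument <- instrument$wgrs
  n <- length(exposure)
  stopifnot(length(outcome) == n, length(instrument) == n)
  if (stats::sd(instrument) == 0) stop("instrument is constant")
  C <- if (is.null(covariates)) matrix(nrow = n, ncol = 0)
       else as.matrix(as.data.frame(covariates))
  f_stat <- f_statistic(exposure, instrument,
                        if (ncol(C)) C else NULL)
  X1 <- cbind(1, instrument, C)
  if (qr(X1)$rank < ncol(X1)) stop("perfect collinearity in first stage")
  s1 <- stats::lm.fit(X1, exposure)
  pred <- X1 %*% s1$coefficients
  X2 <- cbind(1, pred, C)
  if (qr(X2)$rank < ncol(X2)) stop("perfect collinearity in second stage")
  s2 <- stats::lm.fit(X2, outcome)
  beta <- unname(s2$coefficients[2])
  df <- n - ncol(X2)
  xtx_inv <- chol2inv(qr.R(s2$qr))
  # structural residuals: coefficient vector applied to OBSERVED exposure
  X_struct <- cbind(1, exposure, C)
  e <- outcome - drop(X_struct %*% s2$coefficients)
  sigma2_iv <- sum(e^2) / df
  se <- sqrt(sigma2_iv * xtx_inv[2, 2])
  sigma2_naive <- sum(s2$residuals^2) / df
  naive_se <- sqrt(sigma2_naive * xtx_inv[2, 2])
  weak <- f_stat < 10
  if (weak) warning(sprintf(
    "weak instrument: first-stage F = %.2f < 10; estimate may be biased",
    f_stat))
  mr_result("2SLS", beta = beta, se = se, n = n,
            diagnostics = list(f_statistic = f_stat,
                               weak_instrument = weak,
                               naive_se = naive_se,
                               first_stage_coef = unname(s1$coefficients[2])))
}
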