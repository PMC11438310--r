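#' The 12-point cardiovascular health (CVH) score
#'
#' Six CVH metrics -- total cholesterol (TC), fasting glucose (FG), blood
#' pressure (BP), body-mass index (BMI), smoking status (SMK), and physical
#' activity (PA) -- are each graded poor (0), intermediate (1) or ideal (2)
#' and summed to a 0--12 composite. The diet metric of the original
#' 14-point score is not part of this composite.
#'
#' Thresholds (lower bounds inclusive, upper bounds exclusive):
#' \describe{
#'   \item{BMI (kg/m^2)}{0: BMI >= 27; 1: 24 <= BMI < 27; 2: BMI < 24}
#'   \item{SMK}{0: current; 1: former, quit < 6 months; 2: never or former
#'     with quit >= 6 months}
#'   \item{PA}{0: never exercises; 1: between never and regular;
#'     2: regular (at least 30 min three times a week)}
#'   \item{TC (mg/dL)}{0: TC >= 240; 1: 200 <= TC < 240; 2: TC < 200}
#'   \item{FG (mg/dL)}{0: FG >= 126; 1: 100 <= FG < 126; 2: FG < 100}
#'   \item{BP (mmHg)}{0: SBP >= 140 or DBP >= 90; 2: SBP < 120 and
#'     DBP < 80; 1: otherwise}
#' }
#' The BP rule is implemented poor-first then ideal, everything else
#' intermediate; this is equivalent to the explicit intermediate clause
#' "(120 <= SBP < 140 and DBP < 90) or (80 <= DBP < 90 and SBP < 140)"
#' and leaves no gaps or overlaps at compound boundaries.
#'
#' @param records data.frame with one row per participant and columns
#'   `tc`, `fg`, `sbp`, `dbp`, `bmi` (positive numerics), `smoking`
#'   (`"current"`, `"former"`, `"never"`), `quit_months` (required and
#'   non-negative where `smoking == "former"`), and `pa` (`"never"`,
#'   `"between"`, `"regular"`).
#' @return data.frame of class `cvh_scores` with integer columns
#'   `tc_score`, `fg_score`, `bp_score`, `bmi_score`, `smk_score`,
#'   `pa_score` (each in 0..2) and `total` (0..12).
#' @examples
#' ideal <- data.frame(tc = 180, fg = 90, sbp = 110, dbp = 70, bmi = 22,
#'                     smoking = "never", quit_months = NA, pa = "regular")
#' cvh_score(ideal)$total  # 12
#' @seealso [score_component()] for a single metric.
#' @export
cvh_score <- function(records) {
  records <- validate_cvh_records(records)
  out <- data.frame(
    tc_score  = score_component("TC",  records),
    fg_score  = score_component("FG",  records),
    bp_score  = score_component("BP",  records),
    bmi_score = score_component("BMI", records),
    smk_score = score_component("SMK", records),
    pa_score  = score_component("PA",  records)
  )
  out$total <- as.integer(rowSums(out))
  class(out) <- c("cvh_scores", "data.frame")
  out
}

#' Score a single CVH metric
#'
#' @param metric one of `"TC"`, `"FG"`, `"BP"`, `"BMI"`, `"SMK"`, `"PA"`.
#' @param records as in [cvh_score()]; only the columns needed by `metric`
#'   are required.
#' @return integer vector in `{0, 1, 2}`, one value per row.
#' @export
score_component <- function(metric, records) {
  metric <- match.arg(toupper(metric), c("TC", "FG", "BP", "BMI", "SMK", "PA"))
  records <- validate_cvh_records(records, metric)
  switch(metric,
    TC = grade_threshold(records$tc, 200, 240),
    FG = grade_threshold(records$fg, 100, 126),
    BMI = grade_threshold(records$bmi, 24, 27),
    BP = {
      poor <- records$sbp >= 140 | records$dbp >= 90
      ideal <- records$sbp < 120 & records$dbp < 80
      as.integer(ifelse(poor, 0L, ifelse(ideal, 2L, 1L)))
    },
    SMK = {
      s <- records$smoking
      q <- records$quit_months
      as.integer(ifelse(s == "current", 0L,
                 ifelse(s == "never", 2L,
                 ifelse(q >= 6, 2L, 1L))))
    },
    PA = as.integer(c(never = 0L, between = 1L, regular = 2L)[records$pa])
  )
}

# ideal (2) below `lo`, intermediate (1) in [lo, hi), poor (0) at/above `hi`
grade_threshold <- function(x, lo, hi) {
  as.integer(ifelse(x >= hi, 0L, ifelse(x >= lo, 1L, 2L)))
}

validate_cvh_records <- function(records, metric = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need_num <- c(TC = "tc", FG = "fg", BMI = "bmi")
  cols <- if (is.null(metric)) c("tc", "fg", "sbp", "dbp", "bmi")
          else if (metric == "BP") c("sbp", "dbp")
          else if (metric %in% names(need_num)) need_num[[metric]]
          else character(0)
  for (cl in cols) {
    if (!cl %in% names(records)) stop("missing column: ", cl)
    v <- records[[cl]]
    if (!is.numeric(v) || any(is.na(v)) || any(v <= 0))
      stop("column '", cl, "' must be positive numeric with no missing values")
  }
  if (is.null(metric) || metric == "SMK") {
    if (!"smoking" %in% names(records)) stop("missing column: smoking")
    records$smoking <- as.character(records$smoking)
    bad <- !records$smoking %in% c("current", "former", "never")
    if (any(bad)) stop("invalid smoking status: ",
                       paste(unique(records$smoking[bad]), collapse = ", "))
    if (!"quit_months" %in% names(records)) records$quit_months <- NA_real_
    former <- records$smoking == "former"
    if (any(former & (is.na(records$quit_months))))
      stop("former smokers require quit_months")
    if (any(former & records$quit_months < 0, na.rm = TRUE))
      stop("quit_months must be non-negative")
  }
  if (is.null(metric) || metric == "PA") {
    if (!"pa" %in% names(records)) stop("missing column: pa")
    records$pa <- as.character(records$pa)
    bad <- !records$pa %in% c("never", "between", "regular")
    if (any(bad)) stop("invalid physical-activity level: ",
                       paste(unique(records$pa[bad]), collapse = ", "))
  }
  records
}

#' z-score standardization
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator). Used to express outcomes measured on arbitrary laboratory
#' scales -- e.g. a DNA-methylation surrogate protein in pg/mL -- in
#' standard-deviation units.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return numeric vector of the same length.
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(values) {
  if (!is.numeric(values) || length(values) < 2)
    stop("need a numeric vector of length >= 2")
  if (anyNA(values)) stop("missing values not allowed")
  s <- stats::sd(values)
  if (s == 0) stop("cannot z-score a constant vector")
  (values - mean(values)) / s
}
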