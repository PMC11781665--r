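# SCORE2: deterministic 10-year fatal + non-fatal cardiovascular risk.
#
# The model is a log-subdistribution-hazard linear predictor on centered risk
# factors, a 10-year baseline survival, and a region/sex-specific
# recalibration on the cloglog scale. Constants are shipped as a plain-text
# table (inst/extdata/score2_coefficients.txt) so they can be audited
# line-by-line against the published supplement.

#' SCORE2 model constants
#'
#' Returns the embedded SCORE2 constants: per-sex coefficient vectors,
#' 10-year baseline survivals, and region/sex recalibration scale pairs.
#' The table is read once from the package's plain-text data file and cached;
#' it is exposed read-only for auditing and testing.
#'
#' @return A list with elements `coefs` (named list of named numeric vectors,
#'   one per sex), `s0` (named numeric, baseline survival per sex), and
#'   `scales` (named list `scales[[region]][[sex]] = c(scale1, scale2)`).
#' @examples
#' score2_constants()$coefs$female["smoking"]
#' @export
score2_constants <- function() {
  cached <- .riskimpute_cache$score2
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "score2_coefficients.txt", package = "riskimpute")
  raw <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  coefs <- list()
  s0 <- c()
  scales <- list()
  for (sex in unique(raw$sex)) {
    cf <- raw[raw$kind == "coef" & raw$sex == sex, ]
    coefs[[sex]] <- stats::setNames(cf$value, cf$term)
    s0[[sex]] <- raw$value[raw$kind == "baseline" & raw$sex == sex]
  }
  for (region in unique(raw$region[raw$region != "-"])) {
    scales[[region]] <- list()
    for (sex in unique(raw$sex)) {
      s1 <- raw$value[raw$kind == "scale1" & raw$sex == sex & raw$region == region]
      s2 <- raw$value[raw$kind == "scale2" & raw$sex == sex & raw$region == region]
      scales[[region]][[sex]] <- c(scale1 = s1, scale2 = s2)
    }
  }
  out <- list(coefs = coefs, s0 = s0, scales = scales)
  assign("score2", out, envir = .riskimpute_cache)
  out
}

check_risk_input <- function(age, smoker, sbp, totalc, hdlc, diabetes) {
  args <- list(age = age, smoker = smoker, sbp = sbp, totalc = totalc,
               hdlc = hdlc, diabetes = diabetes)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (length(v) == 0 || anyNA(v) || any(!is.finite(v)))
      stop("incomplete risk input: '", nm, "' has missing or non-finite values",
           call. = FALSE)
  }
  if (any(!smoker %in% c(0, 1))) stop("'smoker' must be 0 or 1", call. = FALSE)
  if (any(!diabetes %in% c(0, 1))) stop("'diabetes' must be 0 or 1", call. = FALSE)
  for (nm in c("age", "sbp", "totalc", "hdlc")) {
    if (any(args[[nm]] <= 0))
      stop("'", nm, "' must be strictly positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' SCORE2 linear predictor
#'
#' Sum of coefficient x centered-covariate terms, including the age
#' interactions. Centering values: age 60 y (per 5 y), SBP 120 mmHg (per
#' 20 mmHg), total cholesterol 6 mmol/L (per 1 mmol/L), HDL cholesterol
#' 1.3 mmol/L (per 0.5 mmol/L).
#'
#' @param age age in years.
#' @param smoker current smoker, 0/1.
#' @param sbp systolic blood pressure, mmHg.
#' @param totalc total cholesterol, mmol/L.
#' @param hdlc HDL cholesterol, mmol/L.
#' @param diabetes diabetes mellitus, 0/1 (default 0).
#' @param sex `"female"` (default) or `"male"`.
#' @return Numeric vector of linear-predictor values (0 at the centering point).
#' @examples
#' score2_linear_predictor(60, 0, 120, 6, 1.3) # 0 by construction
#' @export
score2_linear_predictor <- function(age, smoker, sbp, totalc, hdlc,
                                    diabetes = 0, sex = "female") {
  check_risk_input(age, smoker, sbp, totalc, hdlc, diabetes)
  sex <- match.arg(sex, c("female", "male"))
  b <- score2_constants()$coefs[[sex]]
  cage <- (age - 60) / 5
  csbp <- (sbp - 120) / 20
  ctc <- totalc - 6
  chdl <- (hdlc - 1.3) / 0.5
  lp <- b[["age_per5"]] * cage + b[["smoking"]] * smoker +
    b[["sbp_per20"]] * csbp + b[["totalc_per1"]] * ctc +
    b[["hdlc_per05"]] * chdl + b[["diabetes"]] * diabetes +
    cage * (b[["smoking_x_age"]] * smoker + b[["sbp_x_age"]] * csbp +
              b[["totalc_x_age"]] * ctc + b[["hdlc_x_age"]] * chdl +
              b[["diabetes_x_age"]] * diabetes)
  unname(lp)
}

#' SCORE2 10-year cardiovascular disease risk
#'
#' Evaluates the calibrated SCORE2 risk: the uncalibrated risk is
#' `1 - S0^exp(lp)` with the 10-year baseline survival `S0`, then mapped
#' through the region/sex recalibration
#' `1 - exp(-exp(scale1 + scale2 * log(-log(1 - uncalibrated))))`.
#'
#' The intended age range is 40-69 years; ages outside it are evaluated with a
#' warning. Diabetics are outside SCORE2's target population; `diabetes = 1`
#' applies the published coefficients but warns.
#'
#' @inheritParams score2_linear_predictor
#' @param region risk region, one of `"low"` (default, Switzerland),
#'   `"moderate"`, `"high"`, `"very_high"`.
#' @return Numeric vector of risks in (0, 1).
#' @examples
#' score2_risk(65, 0, 110, 5.5, 1.0) # 0.043 (4.3%)
#' @export
score2_risk <- function(age, smoker, sbp, totalc, hdlc, diabetes = 0,
                        sex = "female", region = "low") {
  sex <- match.arg(sex, c("female", "male"))
  const <- score2_constants()
  if (!region %in% names(const$scales))
    stop("no calibration scales embedded for region '", region, "'", call. = FALSE)
  lp <- score2_linear_predictor(age, smoker, sbp, totalc, hdlc, diabetes, sex)
  if (any(age < 40 | age > 69))
    warning("age outside the intended 40-69 range; risk evaluated anyway")
  if (any(diabetes == 1))
    warning("SCORE2's target population excludes diabetics; ",
            "published diabetes coefficients applied")
  unc <- 1 - const$s0[[sex]]^exp(lp)
  sc <- const$scales[[region]][[sex]]
  cal <- 1 - exp(-exp(sc[["scale1"]] + sc[["scale2"]] * log(-log(1 - unc))))
  if (any(!is.finite(cal))) stop("non-finite intermediate in risk calibration")
  cal
}

#' SCORE2 risks for a cohort table
#'
#' Row-wise [score2_risk()] for a complete cohort table with the standard
#' columns `age, smoker, sbp, totalc, hdlc, diabetes, bmi`.
#'
#' @param cohort data frame with the standard cohort columns, no missing cells
#'   in the risk-factor columns.
#' @inheritParams score2_risk
#' @return Numeric vector of risks, one per row.
#' @export
cohort_risk <- function(cohort, sex = "female", region = "low") {
  score2_risk(cohort$age, cohort$smoker, cohort$sbp, cohort$totalc,
              cohort$hdlc, cohort$diabetes, sex = sex, region = region)
}

#' Classify a risk value into low / mid / high
#'
#' Strict thresholds: `low` iff risk < `low_cut`, `high` iff risk >
#' `high_cut`, `mid` otherwise (values exactly on a boundary fall in `mid`).
#'
#' @param risk numeric vector of risks in `[0, 1]`.
#' @param low_cut,high_cut category boundaries, defaults 1% and 5%.
#' @return Factor with levels `low`, `mid`, `high`.
#' @examples
#' risk_category(c(0.009, 0.05, 0.112))
#' @export
risk_category <- function(risk, low_cut = 0.01, high_cut = 0.05) {
  stopifnot(low_cut >= 0, low_cut < high_cut, high_cut <= 1)
  out <- ifelse(risk < low_cut, "low", ifelse(risk > high_cut, "high", "mid"))
  factor(out, levels = c("low", "mid", "high"))
}
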