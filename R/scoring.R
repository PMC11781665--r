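# Proper scoring rules for risk forecasts: the continuous ranked probability
# score (CRPS) and threshold Brier scores, plus cohort-level aggregation.

#' Continuous ranked probability score of an empirical forecast
#'
#' `CRPS(F, y) = integral (F(x) - 1{x >= y})^2 dx`, evaluated exactly for the
#' step-function empirical CDF by summing over the breakpoints (atom values
#' and the outcome). For a Dirac forecast this reduces to the absolute error
#' `|atom - y|`, so point and probabilistic methods are scored on the same
#' scale.
#'
#' @param f a [risk_forecast()].
#' @param y realized outcome (here the true risk), finite.
#' @return Nonnegative score; 0 iff the forecast is a Dirac at `y`.
#' @examples
#' crps(risk_forecast(0.3), 0.1) # 0.2, absolute error of a point forecast
#' @export
crps <- function(f, y) {
  stopifnot(inherits(f, "risk_forecast"), length(y) == 1, is.finite(y))
  a <- f$atoms # already sorted
  bp <- sort(unique(c(a, y)))
  if (length(bp) == 1) return(0)
  left <- bp[-length(bp)]
  width <- diff(bp)
  Fv <- findInterval(left, a) / length(a)
  ind <- as.numeric(left >= y)
  sum(width * (Fv - ind)^2)
}

# Independent energy (kernel) form: mean|X - y| - mean|X - X'| / 2 over the
# empirical atoms. Used as a cross-check of the integral form in tests.
crps_energy <- function(f, y) {
  a <- f$atoms
  mean(abs(a - y)) - mean(abs(outer(a, a, `-`))) / 2
}

#' Threshold Brier scores for risk forecasts
#'
#' Squared error between the forecast probability of a threshold event and
#' the event indicator of the true risk, with strict inequalities consistent
#' with [risk_category()]:
#' * `brier_low`: event "risk below `cut`" (default 1%); forecast probability
#'   `F(cut)`, outcome `1{true_risk < cut}`.
#' * `brier_high`: event "risk above `cut`" (default 5%); forecast
#'   probability `1 - F(cut)`, outcome `1{true_risk > cut}`.
#'
#' @param f a [risk_forecast()].
#' @param true_risk realized risk in `[0, 1]`.
#' @param cut event threshold in (0, 1).
#' @return Score in `[0, 1]`.
#' @export
brier_low <- function(f, true_risk, cut = 0.01) {
  stopifnot(cut > 0, cut < 1)
  (forecast_cdf(f, cut) - as.numeric(true_risk < cut))^2
}

#' @rdname brier_low
#' @export
brier_high <- function(f, true_risk, cut = 0.05) {
  stopifnot(cut > 0, cut < 1)
  (1 - forecast_cdf(f, cut) - as.numeric(true_risk > cut))^2
}

#' Aggregate per-patient scores into a method-by-scenario report
#'
#' @param scores data frame with columns `patient`, `method`, `scenario`,
#'   `crps`, `brier_low`, `brier_high`.
#' @return An object of class `score_report`: the per-patient table plus
#'   `means`, the arithmetic means per method x scenario.
#' @export
aggregate_scores <- function(scores) {
  needed <- c("patient", "method", "scenario", "crps", "brier_low", "brier_high")
  stopifnot(all(needed %in% names(scores)))
  means <- stats::aggregate(scores[c("crps", "brier_low", "brier_high")],
                            by = scores[c("method", "scenario")], FUN = mean)
  structure(list(per_patient = scores, means = means), class = "score_report")
}

#' Mean-score table in methods-as-rows, scenarios-as-columns layout
#'
#' @param report a `score_report`.
#' @param metric `"crps"`, `"brier_high"` or `"brier_low"`.
#' @return Data frame, one row per method, one column per scenario.
#' @export
score_table <- function(report, metric = c("crps", "brier_high", "brier_low")) {
  metric <- match.arg(metric)
  m <- report$means
  out <- stats::reshape(m[c("method", "scenario", metric)],
                        direction = "wide", idvar = "method",
                        timevar = "scenario")
  names(out) <- sub(paste0("^", metric, "\\."), "", names(out))
  rownames(out) <- NULL
  out[order(out$method), , drop = FALSE]
}

#' @export
print.score_report <- function(x, ...) {
  cat("score_report over", length(unique(x$per_patient$patient)), "patients\n")
  cat("mean CRPS (methods x scenarios):\n")
  tab <- score_table(x, "crps")
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
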