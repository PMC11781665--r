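# Leave-one-out benchmark of the five imputation methods, cut-off
# classification with confusion matrices and ROC sweeps, the BMI ablation,
# and the sample-size study.

#' Leave-one-out benchmark of imputation methods
#'
#' For every patient: mask the scenario's variables, refit every
#' training-side model (marginals, copula, MICE regressions) on the remaining
#' rows, produce the requested forecasts, and score them (CRPS and both
#' threshold Brier scores) against the patient's true calculated risk.
#' Randomness uses deterministic substreams of `seed` keyed by patient index
#' and method, so results are independent of evaluation order.
#'
#' @param cohort complete cohort table (true risks must be computable).
#' @param methods subset of `c("I1", ..., "I5")`.
#' @param scenarios list of [scenario()]s.
#' @param seed integer root seed.
#' @param n_mc Monte Carlo draws for I4 (and I3's conditional means); the
#'   study-scale value is 500, smaller values give a cheaper benchmark.
#' @param m,iterations,donors MICE settings for I2/I5 (study-scale `m` 500).
#' @param sex,region passed to the risk calculator.
#' @param keep_forecasts keep all forecasts in the result (needed for
#'   [classify()] / [roc_curve()]; default TRUE).
#' @return A `score_report` (see [aggregate_scores()]) with extra fields
#'   `truth` (true risks) and, if kept, `forecasts[[scenario]][[method]]`,
#'   a list of `risk_forecast`s in patient order.
#' @export
loo_benchmark <- function(cohort, methods = c("I1", "I2", "I3", "I4", "I5"),
                          scenarios = list(scenario(c("totalc", "hdlc", "sbp"))),
                          seed = 1, n_mc = 500, m = n_mc, iterations = 10,
                          donors = 5, sex = "female", region = "low",
                          keep_forecasts = TRUE) {
  stopifnot(all(methods %in% c("I1", "I2", "I3", "I4", "I5")))
  if (anyNA(cohort)) stop("cohort must be complete: true risks are undefined otherwise")
  n <- nrow(cohort)
  truth <- cohort_risk(cohort, sex = sex, region = region)
  rows <- list()
  forecasts <- list()
  for (sc in scenarios) {
    fc <- lapply(methods, function(m) vector("list", n))
    names(fc) <- methods
    for (i in seq_len(n)) {
      training <- cohort[-i, , drop = FALSE]
      patient <- cohort[i, , drop = FALSE]
      got <- list()
      if ("I1" %in% methods)
        got$I1 <- impute_I1(patient, training, sc, sex, region)
      if (any(c("I3", "I4") %in% methods)) {
        cf <- copula_forecasts(patient, training, sc, n = n_mc,
                               seed = derive_seed(seed, i, 34), sex = sex,
                               region = region)
        got$I3 <- cf$I3
        got$I4 <- cf$I4
      }
      if (any(c("I2", "I5") %in% methods)) {
        cfg <- mice_config(m = m, iterations = iterations, donors = donors,
                           predictors = scenario_known(sc),
                           seed = derive_seed(seed, i, 25))
        mf <- mice_forecasts(patient, training, sc, cfg, sex, region)
        got$I2 <- mf$I2
        got$I5 <- mf$I5
      }
      for (meth in methods) {
        f <- got[[meth]]
        fc[[meth]][[i]] <- f
        rows[[length(rows) + 1]] <- data.frame(
          patient = i, method = meth, scenario = sc$label,
          crps = crps(f, truth[i]),
          brier_low = brier_low(f, truth[i]),
          brier_high = brier_high(f, truth[i]))
      }
    }
    forecasts[[sc$label]] <- fc
  }
  report <- aggregate_scores(do.call(rbind, rows))
  report$truth <- truth
  if (keep_forecasts) report$forecasts <- forecasts
  report
}

#' Cut-off-probability classification of forecasts
#'
#' A patient is predicted positive when the forecast probability of the event
#' -- `1 - F(0.05)` for the high-risk direction, `F(0.01)` for the low-risk
#' direction -- is at least `alpha`. Truth uses the strict thresholds on the
#' true risk (above 5% / below 1%). For Dirac forecasts the event probability
#' is 0 or 1, so any `alpha` in (0, 1] reduces to point-estimate
#' thresholding.
#'
#' @param forecasts list of `risk_forecast`s.
#' @param truths true risks, same length.
#' @param alpha cut-off probability in `[0, 1]`.
#' @param direction `"high"` (risk above 5%) or `"low"` (risk below 1%).
#' @param cut event threshold (default 0.05 / 0.01 by direction).
#' @return An object of class `confusion_matrix` with counts `tn, fp, fn, tp`.
#' @export
classify <- function(forecasts, truths, alpha, direction = c("high", "low"),
                     cut = NULL) {
  direction <- match.arg(direction)
  stopifnot(alpha >= 0, alpha <= 1)
  if (length(forecasts) != length(truths))
    stop("forecasts and truths have different lengths")
  if (is.null(cut)) cut <- if (direction == "high") 0.05 else 0.01
  prob <- event_probs(forecasts, direction, cut)
  pred <- prob >= alpha
  truth_pos <- if (direction == "high") truths > cut else truths < cut
  structure(list(
    tn = sum(!pred & !truth_pos), fp = sum(pred & !truth_pos),
    fn = sum(!pred & truth_pos), tp = sum(pred & truth_pos),
    alpha = alpha, direction = direction),
    class = "confusion_matrix")
}

event_probs <- function(forecasts, direction, cut) {
  vapply(forecasts, function(f) {
    p <- forecast_cdf(f, cut)
    if (direction == "high") 1 - p else p
  }, 0)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  lbl <- if (x$direction == "high") "above 5%" else "below 1%"
  cat(sprintf("classification of risk %s at cut-off alpha = %g\n", lbl, x$alpha))
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(c("truth negative", "truth positive"),
                              c("predicted negative", "predicted positive")))
  print(m)
  invisible(x)
}

#' ROC curve over cut-off probabilities
#'
#' Sweeps `alpha` over the observed distinct event probabilities (plus the
#' degenerate end points), computing false- and true-positive rates; the
#' trapezoidal area under the curve is attached as `auc`.
#'
#' @inheritParams classify
#' @return An object of class `roc_points`: data frame `points` with columns
#'   `alpha, fpr, tpr` (from `(0, 0)` at high alpha to `(1, 1)` at alpha 0),
#'   plus `auc` and `direction`.
#' @export
roc_curve <- function(forecasts, truths, direction = c("high", "low"),
                      cut = NULL) {
  direction <- match.arg(direction)
  if (is.null(cut)) cut <- if (direction == "high") 0.05 else 0.01
  prob <- event_probs(forecasts, direction, cut)
  truth_pos <- if (direction == "high") truths > cut else truths < cut
  npos <- sum(truth_pos)
  nneg <- sum(!truth_pos)
  if (npos == 0 || nneg == 0)
    stop("ROC needs both positive and negative truths")
  alphas <- c(Inf, sort(unique(prob), decreasing = TRUE), 0)
  pts <- t(vapply(alphas, function(a) {
    pred <- prob >= a
    c(fpr = sum(pred & !truth_pos) / nneg, tpr = sum(pred & truth_pos) / npos)
  }, c(fpr = 0, tpr = 0)))
  pts <- data.frame(alpha = alphas, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, direction = direction),
            class = "roc_points")
}

#' @export
print.roc_points <- function(x, ...) {
  cat(sprintf("ROC (%s-risk direction): %d cut-offs, AUC %.3f\n",
              x$direction, nrow(x$points), x$auc))
  invisible(x)
}

#' BMI ablation: with-BMI versus age-only known sets
#'
#' Runs the leave-one-out benchmark for the all-clinical-missing scenario
#' twice: once with `(age, bmi)` known and once with age only, so the value
#' of the extra covariate can be read off the mean scores. I1 ignores extra
#' covariates, so its scores coincide across the two runs.
#'
#' @inheritParams loo_benchmark
#' @return List with `score_report`s `with_bmi` and `age_only`.
#' @export
ablation_no_bmi <- function(cohort, seed = 1, methods = c("I1", "I4"), ...) {
  missing_all <- c("totalc", "hdlc", "sbp")
  list(
    with_bmi = loo_benchmark(cohort, methods = methods,
                             scenarios = list(scenario(missing_all, use_bmi = TRUE)),
                             seed = seed, ...),
    age_only = loo_benchmark(cohort, methods = methods,
                             scenarios = list(scenario(missing_all, use_bmi = FALSE)),
                             seed = seed, ...))
}

#' Sample-size study by repeated subsampling
#'
#' For each subset size, draws `reps` random patient subsets, runs the
#' leave-one-out benchmark restricted to the subset, and collects the mean
#' scores -- the spread across repeats shows how score stability degrades
#' with smaller cohorts. The benchmark seed is shared across repeats, so at
#' the full cohort size (no subsampling randomness) all repeats coincide.
#'
#' @inheritParams loo_benchmark
#' @param sizes subset sizes (default `c(50, 100, 150, 200, 250, 300, n)`
#'   clipped to the cohort size).
#' @param reps repeats per size (default 20).
#' @param method single method to study (default `"I4"`).
#' @return Long-format data frame with columns `size, rep, crps, brier_low,
#'   brier_high`.
#' @export
sample_size_study <- function(cohort, sizes = NULL, reps = 20, method = "I4",
                              scenarios = list(scenario(c("totalc", "hdlc", "sbp"))),
                              seed = 1, ...) {
  n <- nrow(cohort)
  if (is.null(sizes)) sizes <- unique(pmin(c(50, 100, 150, 200, 250, 300, n), n))
  out <- list()
  for (s in sizes) {
    for (r in seq_len(reps)) {
      idx <- if (s == n) seq_len(n) else
        sort(withr::with_seed(derive_seed(seed, s, r), sample.int(n, s)))
      rep_report <- loo_benchmark(cohort[idx, , drop = FALSE], methods = method,
                                  scenarios = scenarios,
                                  seed = derive_seed(seed, s),
                                  keep_forecasts = FALSE, ...)
      mm <- rep_report$means
      out[[length(out) + 1]] <- data.frame(
        size = s, rep = r, crps = mm$crps[1],
        brier_low = mm$brier_low[1], brier_high = mm$brier_high[1])
    }
  }
  do.call(rbind, out)
}
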