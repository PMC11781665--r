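make_forecasts <- function(probs_above, n_atoms = 100) {
  # forecasts whose probability of exceeding 5% equals probs_above
  lapply(probs_above, function(p) {
    k <- round(p * n_atoms)
    risk_forecast(c(rep(0.02, n_atoms - k), rep(0.08, k)), "I4")
  })
}

test_that("classification thresholds forecast event probabilities", {
  f <- make_forecasts(c(0, 0.3, 0.9))
  truths <- c(0.02, 0.06, 0.09)
  cm0 <- classify(f, truths, alpha = 0, direction = "high")
  expect_equal(cm0$tp + cm0$fp, 3) # alpha 0 predicts everyone positive
  cm <- classify(f, truths, alpha = 0.5, direction = "high")
  expect_equal(c(cm$tn, cm$fp, cm$fn, cm$tp), c(1, 0, 1, 1))
  expect_error(classify(f, truths[1:2], 0.5), "length")
  # Dirac forecasts reduce to point-estimate thresholding for any alpha in (0,1]
  dir <- lapply(c(0.02, 0.06), dirac)
  cmd <- classify(dir, c(0.02, 0.06), alpha = 0.5, direction = "high")
  expect_equal(c(cmd$tn, cmd$tp), c(1, 1))
  # boundary arithmetic: 26/500 atoms above the cut, alpha = 0.05
  f26 <- risk_forecast(c(rep(0.02, 474), rep(0.08, 26)))
  cm26 <- classify(list(f26), 0.06, alpha = 0.05, direction = "high")
  expect_equal(cm26$tp, 1) # 0.052 >= 0.05
})

test_that("predicted positives are non-increasing in alpha", {
  set.seed(88)
  f <- make_forecasts(runif(60))
  truths <- runif(60, 0, 0.12)
  pos <- vapply(seq(0, 1, by = 0.05), function(a) {
    cm <- classify(f, truths, a, "high")
    cm$tp + cm$fp
  }, 0)
  expect_true(all(diff(pos) <= 0))
  sizes <- vapply(seq(0, 1, by = 0.05), function(a) {
    cm <- classify(f, truths, a, "high")
    cm$tp + cm$fp + cm$tn + cm$fn
  }, 0)
  expect_true(all(sizes == 60))
})

test_that("ROC curves are monotone paths with sensible AUC", {
  # perfectly separated
  f <- make_forecasts(c(0.1, 0.2, 0.8, 0.9))
  truths <- c(0.01, 0.02, 0.08, 0.09)
  roc <- roc_curve(f, truths, "high")
  expect_equal(roc$auc, 1)
  pts <- roc$points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # labels independent of forecasts: AUC near 1/2
  set.seed(9)
  n <- 600
  probs <- runif(n)
  f2 <- make_forecasts(probs)
  truths2 <- sample(c(0.02, 0.08), n, replace = TRUE)
  roc2 <- roc_curve(f2, truths2, "high")
  expect_lt(abs(roc2$auc - 0.5), 0.08)
  # single distinct probability: two informative points plus the end point
  f3 <- make_forecasts(c(0.5, 0.5))
  expect_equal(nrow(roc_curve(f3, c(0.02, 0.08), "high")$points), 3)
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  n <- 200
  probs <- runif(n)
  truth_risk <- ifelse(runif(n) < probs, 0.08, 0.02) # informative forecasts
  fl <- make_forecasts(probs)
  roc <- roc_curve(fl, truth_risk, "high")
  # same event probabilities (after atom discretization) through pROC
  ep <- vapply(fl, function(f) 1 - forecast_cdf(f, 0.05), 0)
  ref <- pROC::auc(pROC::roc(response = truth_risk > 0.05, predictor = ep,
                             quiet = TRUE, direction = "<"))
  expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("leave-one-out benchmark is deterministic and complete", {
  cohort <- small_cohort(n = 40, seed = 55)
  sc <- list(scenario("totalc"))
  r1 <- loo_benchmark(cohort, methods = c("I1", "I3", "I4"), scenarios = sc,
                      seed = 10, n_mc = 50)
  r2 <- loo_benchmark(cohort, methods = c("I1", "I3", "I4"), scenarios = sc,
                      seed = 10, n_mc = 50)
  expect_identical(r1$per_patient, r2$per_patient)
  expect_equal(nrow(r1$per_patient), 40 * 3)
  expect_true(all(r1$per_patient$crps >= 0))
  expect_length(r1$forecasts[["totalc"]][["I4"]], 40)
  expect_error(loo_benchmark(mask_scenario(cohort, scenario("totalc"))$masked),
               "complete")
  # a two-row cohort surfaces the copula's precondition
  expect_error(loo_benchmark(cohort[1:2, ], methods = "I3", scenarios = sc),
               "20 complete")
})

test_that("sample-size study has no subsampling noise at the full cohort", {
  cohort <- small_cohort(n = 45, seed = 77)
  out <- sample_size_study(cohort, sizes = c(25, 45), reps = 3, method = "I1",
                           seed = 5)
  expect_equal(nrow(out), 6)
  v_full <- var(out$crps[out$size == 45])
  v_sub <- var(out$crps[out$size == 25])
  expect_equal(v_full, 0)
  expect_gte(v_sub, v_full)
  one <- sample_size_study(cohort, sizes = 30, reps = 2, method = "I1", seed = 5)
  expect_equal(unique(one$size), 30)
})

test_that("mask_scenario blanks whole columns and keeps the truth", {
  cohort <- small_cohort(n = 25, seed = 1)
  mk <- mask_scenario(cohort, scenario("totalc"))
  expect_true(all(is.na(mk$masked$totalc)))
  expect_identical(mk$truth, cohort)
  expect_equal(sum(!is.na(mk$masked)), 25 * 6)
  mk3 <- mask_scenario(cohort, all_missing())
  expect_equal(sum(!is.na(mk3$masked)), 25 * 4)
})
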