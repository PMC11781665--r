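test_that("scenario validates its variable set", {
  expect_error(scenario(character(0)), "nonempty")
  expect_error(scenario("age"), "subset")
  sc <- scenario(c("totalc", "hdlc"))
  expect_equal(sc$label, "totalc+hdlc")
  expect_true(sc$use_bmi)
})

test_that("forecast atoms are validated and the CDF is right-continuous", {
  expect_error(risk_forecast(numeric(0)), "nonempty")
  expect_error(risk_forecast(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_equal(forecast_cdf(dirac(0.03), 0.03), 1) # right continuity
  f <- risk_forecast(c(0.01, 0.07))
  expect_equal(forecast_cdf(f, 0.05), 0.5)
  expect_equal(forecast_cdf(f, 0.005), 0)
  expect_equal(forecast_cdf(f, 0.5), 1)
})

test_that("I1 patches with training sample means", {
  p <- example2_patient()
  # two-row training whose sample means are the printed cohort means
  training <- patient_row(c(50, 54), c(0, 1), c(120, 128), c(5.0, 5.8),
                          c(1.6, 2.0), c(0, 0), c(25, 29))
  f <- impute_I1(p, training, all_missing())
  expect_equal(round(100 * f$atoms, 1), 4.0) # means (124, 5.4, 1.8)
  expect_equal(f$method, "I1")
  # a one-row training cohort patches with that row's values
  f1 <- impute_I1(p, training[1, ], all_missing())
  expect_equal(f1$atoms, score2_risk(65, 0, 120, 5.0, 1.6))
  expect_error(impute_I1(p, training[0, ], all_missing()), "empty")
})

test_that("I3 at the printed conditional means gives the printed risk", {
  # format check of the plug-in step: the conditional means (138, 5.8, 1.3)
  # plugged into the calculator for the 65-year-old non-smoker
  p <- example2_patient()
  r <- riskimpute:::patched_risk(p, list(sbp = 138, totalc = 5.8, hdlc = 1.3),
                                 all_missing(), "female", "low")
  expect_equal(round(100 * r, 1), 5.3)
})

test_that("I3 collapses to I1 under an independence copula", {
  spec <- cohort_spec(n = 2000, corr = diag(5), seed = 19)
  dimnames(spec$corr) <- list(riskimpute:::cont_vars(), riskimpute:::cont_vars())
  training <- generate_cohort(spec)
  p <- example2_patient()
  f1 <- impute_I1(p, training, all_missing())
  f3 <- impute_I3(p, training, all_missing(), n = 4000, seed = 7)
  expect_lt(abs(f3$atoms - f1$atoms), 0.005)
})

test_that("I4 propagates a distribution that brackets the I3 plug-in", {
  training <- small_cohort(n = 150, seed = 29)
  p <- example2_patient()
  f3 <- impute_I3(p, training, all_missing(), n = 300, seed = 11)
  f4 <- impute_I4(p, training, all_missing(), n = 300, seed = 11)
  expect_length(f4$atoms, 300)
  # the risk map is nonlinear, so mean(risk(draws)) != risk(mean(draws))
  expect_false(isTRUE(all.equal(mean(f4$atoms), f3$atoms)))
  expect_gte(f3$atoms, min(f4$atoms))
  expect_lte(f3$atoms, max(f4$atoms))
  expect_gte(mean(f4$atoms), min(f4$atoms))
  expect_lte(mean(f4$atoms), max(f4$atoms))
})

test_that("I2 is the mean of I5's atoms from the same MICE run", {
  training <- small_cohort(n = 80, seed = 37)
  p <- example2_patient()
  cfg <- mice_config(m = 40, iterations = 3, seed = 13)
  f2 <- impute_I2(p, training, all_missing(), cfg)
  f5 <- impute_I5(p, training, all_missing(), cfg)
  expect_equal(f2$atoms, mean(f5$atoms))
  expect_length(f5$atoms, 40)
  # m = 1: the two methods coincide
  cfg1 <- mice_config(m = 1, iterations = 3, seed = 13)
  expect_equal(impute_I2(p, training, all_missing(), cfg1)$atoms,
               impute_I5(p, training, all_missing(), cfg1)$atoms)
})

test_that("complete inputs collapse every forecast onto the true risk", {
  # the engine-level version of the no-missing collapse: a complete table
  # passes through MICE unchanged, so the patient row's risk is the truth
  cohort <- small_cohort(n = 50, seed = 41)
  truth <- cohort_risk(cohort)
  imp <- mice_impute(cohort, mice_config(m = 5, iterations = 2, seed = 3))
  risks <- vapply(imp$completions, function(c) cohort_risk(c)[17], 0)
  expect_equal(risks, rep(truth[17], 5))
})

test_that("forecast CSV export writes one row per atom", {
  path <- withr::local_tempfile(fileext = ".csv")
  fl <- list(p1 = dirac(0.03), p2 = risk_forecast(c(0.01, 0.02, 0.05), "I4"))
  out <- write_forecasts(fl, path, comment = "seed 7")
  expect_equal(nrow(out), 4)
  lines <- readLines(path)
  expect_match(lines[1], "^# seed 7")
  re <- read.csv(path, comment.char = "#")
  expect_equal(nrow(re), 4)
  expect_equal(re$atom[re$patient == "p2"], c(0.01, 0.02, 0.05))
})
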