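test_that("Gaussian conditioning matches the closed form", {
  cop <- std_normal_copula(corr2(0.5))
  law <- condition_copula(cop, c(x1 = 2))
  expect_equal(unname(law$mean), 1.0, tolerance = 1e-6)
  expect_equal(law$cov[1, 1], 0.75, tolerance = 1e-8)
  # zero correlation: conditional equals marginal
  law0 <- condition_copula(std_normal_copula(corr2(0)), c(x1 = 2))
  expect_equal(unname(law0$mean), 0, tolerance = 1e-6)
  expect_equal(law0$cov[1, 1], 1)
  # conditioning away everything is an error
  expect_error(condition_copula(cop, c(x1 = 1, x2 = 2)), "no unknown")
})

test_that("trivariate conditioning agrees with a rejection-sampling oracle", {
  v <- c("x1", "x2", "x3")
  C <- matrix(c(1, 0.5, 0.3,
                0.5, 1, -0.2,
                0.3, -0.2, 1), 3, 3, dimnames = list(v, v))
  cop <- std_normal_copula(C)
  law <- condition_copula(cop, c(x3 = 0.8))
  # oracle: simulate the joint normal, keep draws in a narrow window
  set.seed(61)
  Z <- matrix(rnorm(9e5), ncol = 3) %*% chol(C)
  keep <- abs(Z[, 3] - 0.8) < 0.05
  expect_gt(sum(keep), 5000)
  expect_lt(max(abs(unname(law$mean) - colMeans(Z[keep, 1:2]))), 0.05)
  expect_lt(max(abs(unname(diag(law$cov)) - apply(Z[keep, 1:2], 2, var))), 0.05)
})

test_that("fit_copula recovers a known correlation on gamma margins", {
  set.seed(77)
  n <- 2000
  Z <- matrix(rnorm(2 * n), ncol = 2) %*% chol(corr2(0.6))
  dat <- data.frame(totalc = qgamma(pnorm(Z[, 1]), 31.48, scale = 0.17),
                    sbp = qgamma(pnorm(Z[, 2]), 59.86, scale = 2.07))
  fit <- fit_copula(dat, variables = c("totalc", "sbp"))
  expect_lt(abs(fit$corr["totalc", "sbp"] - 0.6), 0.05)
})

test_that("independent columns fit near-zero correlation; one column fits [1]", {
  set.seed(8)
  n <- 3000
  dat <- data.frame(age = rnorm(n, 50, 6), bmi = rlnorm(n, 3.2, 0.2))
  fit <- fit_copula(dat, variables = c("age", "bmi"))
  expect_lt(abs(fit$corr["age", "bmi"]), 3 / sqrt(n))
  one <- fit_copula(dat, variables = "age")
  expect_equal(unname(one$corr), matrix(1, 1, 1))
  expect_error(fit_copula(dat[1:10, ], variables = c("age", "bmi")), "20 complete")
})

test_that("fitted correlation is invariant under increasing marginal transforms", {
  # exp() with the family switched normal -> lognormal leaves z-scores
  # identical, so the estimated dependence cannot change
  set.seed(15)
  n <- 500
  Z <- matrix(rnorm(2 * n), ncol = 2) %*% chol(corr2(0.4))
  dat <- data.frame(a = Z[, 1] * 2 + 1, b = Z[, 2] * 3 - 2)
  f1 <- fit_copula(dat, families = c(a = "normal", b = "normal"))
  dat2 <- data.frame(a = exp(dat$a), b = dat$b)
  f2 <- fit_copula(dat2, families = c(a = "lognormal", b = "normal"))
  expect_equal(f1$corr, f2$corr, tolerance = 1e-10)
})

test_that("conditional sampling is reproducible, in-support, and recovers marginals", {
  cohort <- small_cohort(n = 200, seed = 3)
  cop <- fit_copula(cohort)
  known <- list(age = 55, bmi = 30)
  d1 <- sample_conditional(cop, known, n = 200, seed = 99)
  d2 <- sample_conditional(cop, known, n = 200, seed = 99)
  expect_identical(d1, d2)
  expect_equal(nrow(sample_conditional(cop, known, n = 1, seed = 1)), 1)
  expect_true(all(d1 > 0)) # gamma/lognormal support
  # empty conditioning set: draws reproduce the unconditional marginals
  d0 <- sample_conditional(cop, known = NULL, n = 1e4, seed = 5)
  ks <- suppressWarnings(ks.test(d0$sbp, pgamma,
                                 shape = cop$marginals$sbp$params[["shape"]],
                                 scale = cop$marginals$sbp$params[["scale"]]))
  expect_gt(ks$p.value, 0.01)
})

test_that("conditional means behave at the independence and comonotone limits", {
  m2 <- list(x1 = marginal_model("gamma", c(30, 0.2)),
             x2 = marginal_model("lognormal", c(0.5, 0.3)))
  # independence: conditional mean ~= unconditional mean
  cop0 <- copula_model(m2, corr2(0))
  cm0 <- conditional_mean(cop0, c(x1 = 9), n = 2e4, seed = 4)
  expect_equal(cm0[["x2"]], marginal_mean(m2$x2), tolerance = 0.01)
  # comonotone limit: imputed x2 ~= F2^{-1}(F1(x1))
  cop1 <- copula_model(m2, corr2(0.999))
  cm1 <- conditional_mean(cop1, c(x1 = 9), n = 5e3, seed = 4)
  target <- marginal_quantile(m2$x2, marginal_cdf(m2$x1, 9))
  expect_equal(cm1[["x2"]], target, tolerance = 0.02)
  # Monte Carlo stabilization: two seeds at n = 1e5 agree within 0.5%
  a <- conditional_mean(cop0, c(x1 = 9), n = 1e5, seed = 1)[["x2"]]
  b <- conditional_mean(cop0, c(x1 = 9), n = 1e5, seed = 2)[["x2"]]
  expect_lt(abs(a - b) / a, 0.005)
})

test_that("copula serialization round-trips through plain text", {
  cohort <- small_cohort(n = 100, seed = 31)
  cop <- fit_copula(cohort)
  path <- withr::local_tempfile(fileext = ".txt")
  write_copula(cop, path)
  back <- read_copula(path)
  expect_equal(back$corr, cop$corr, tolerance = 1e-12)
  expect_equal(back$marginals$sbp$params, cop$marginals$sbp$params,
               tolerance = 1e-12)
  expect_equal(back$variables, cop$variables)
})
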