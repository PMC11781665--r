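# Univariate marginal models for the cohort covariates.
#
# Normal and lognormal MLEs are closed-form; the gamma MLE is numerical via
# MASS::fitdistr.
#
# Three families are supported: normal (age), log-normal (BMI, HDL
# cholesterol) and gamma (total cholesterol, systolic blood pressure). The
# gamma family is parameterized as (shape, scale) throughout -- NOT
# (shape, rate); the rate convention silently produces nonsense because the
# two are reciprocal.

#' Construct a marginal distribution model
#'
#' @param family `"normal"`, `"lognormal"` or `"gamma"`.
#' @param params numeric pair: normal `(mean, sd)`; lognormal
#'   `(meanlog, sdlog)` on the log scale; gamma `(shape, scale)`.
#' @return An object of class `marginal_model`.
#' @examples
#' marginal_model("gamma", c(shape = 59.86, scale = 2.07)) # systolic BP
#' @export
marginal_model <- function(family = c("normal", "lognormal", "gamma"), params) {
  family <- match.arg(family)
  params <- unname(as.numeric(params))
  stopifnot(length(params) == 2, all(is.finite(params)))
  if (params[2] <= 0)
    stop("second parameter (sd/sdlog/scale) must be strictly positive")
  if (family == "gamma" && params[1] <= 0)
    stop("gamma shape must be strictly positive")
  names(params) <- switch(family,
    normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    gamma = c("shape", "scale"))
  support <- if (family == "normal") c(-Inf, Inf) else c(0, Inf)
  structure(list(family = family, params = params, support = support),
            class = "marginal_model")
}

#' @export
print.marginal_model <- function(x, ...) {
  cat(sprintf("marginal_model: %s(%s)\n", x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", ")))
  invisible(x)
}

#' Fit a marginal distribution by maximum likelihood
#'
#' Normal and log-normal fits use the closed-form MLE (variance with the 1/n
#' denominator); the gamma fit is numerical via [MASS::fitdistr()] and
#' returned on the (shape, scale) parameterization.
#'
#' @param x numeric vector, at least 10 finite values; strictly positive for
#'   the lognormal and gamma families.
#' @param family distribution family, see [marginal_model()].
#' @return A `marginal_model`.
#' @examples
#' fit_marginal(rnorm(100, 50, 6), "normal")
#' @export
fit_marginal <- function(x, family = c("normal", "lognormal", "gamma")) {
  family <- match.arg(family)
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("need at least 10 finite values to fit a marginal")
  if (stats::var(x) == 0)
    stop("degenerate fit: input sequence is constant")
  if (family != "normal" && any(x <= 0))
    stop("domain error: ", family, " family requires strictly positive values")
  params <- switch(family,
    normal = {
      m <- mean(x)
      c(m, sqrt(mean((x - m)^2)))
    },
    lognormal = {
      lx <- log(x)
      m <- mean(lx)
      c(m, sqrt(mean((lx - m)^2)))
    },
    gamma = {
      fit <- suppressWarnings(MASS::fitdistr(x, "gamma"))
      c(unname(fit$estimate["shape"]), 1 / unname(fit$estimate["rate"]))
    })
  marginal_model(family, params)
}

#' @rdname marginal_cdf
#' @export
marginal_quantile <- function(m, p) {
  stopifnot(inherits(m, "marginal_model"), all(p > 0 & p < 1))
  pp <- m$params
  switch(m$family,
    normal = stats::qnorm(p, pp[1], pp[2]),
    lognormal = stats::qlnorm(p, pp[1], pp[2]),
    gamma = stats::qgamma(p, shape = pp[1], scale = pp[2]))
}

#' Marginal CDF and quantile function
#'
#' Values outside the support map to CDF 0/1 by convention.
#'
#' @param m a `marginal_model`.
#' @param x numeric vector of evaluation points.
#' @param p probabilities in (0, 1) for `marginal_quantile`.
#' @return Probabilities (CDF) or quantiles on the original scale.
#' @export
marginal_cdf <- function(m, x) {
  stopifnot(inherits(m, "marginal_model"))
  pp <- m$params
  switch(m$family,
    normal = stats::pnorm(x, pp[1], pp[2]),
    lognormal = stats::plnorm(x, pp[1], pp[2]),
    gamma = stats::pgamma(x, shape = pp[1], scale = pp[2]))
}

#' Analytic mean of a marginal model
#'
#' Normal: mean; lognormal: `exp(meanlog + sdlog^2/2)`; gamma: shape x scale.
#'
#' @param m a `marginal_model`.
#' @return The distribution mean.
#' @export
marginal_mean <- function(m) {
  stopifnot(inherits(m, "marginal_model"))
  pp <- m$params
  switch(m$family,
    normal = pp[[1]],
    lognormal = exp(pp[[1]] + pp[[2]]^2 / 2),
    gamma = pp[[1]] * pp[[2]])
}

#' Random draws from a marginal model
#' @param m a `marginal_model`.
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
marginal_random <- function(m, n) {
  stopifnot(inherits(m, "marginal_model"))
  pp <- m$params
  switch(m$family,
    normal = stats::rnorm(n, pp[1], pp[2]),
    lognormal = stats::rlnorm(n, pp[1], pp[2]),
    gamma = stats::rgamma(n, shape = pp[1], scale = pp[2]))
}

# Log-likelihood of data under a marginal model (used to check that MLE fits
# dominate moment-matched starts).
marginal_loglik <- function(m, x) {
  pp <- m$params
  sum(switch(m$family,
    normal = stats::dnorm(x, pp[1], pp[2], log = TRUE),
    lognormal = stats::dlnorm(x, pp[1], pp[2], log = TRUE),
    gamma = stats::dgamma(x, shape = pp[1], scale = pp[2], log = TRUE)))
}

#' Descriptive moment summary of a sample
#'
#' Mean, standard deviation (n-1 denominator), skewness `m3 / m2^(3/2)` and
#' excess kurtosis `m4 / m2^2 - 3` from plain central sample moments (no
#' small-sample bias correction), plus min/max and quartiles (type-7
#' interpolation, R's default).
#'
#' @param x numeric vector, at least 4 finite values.
#' @return One-row data frame with columns `mean, sd, skew, excess_kurtosis,
#'   min, q25, q75, max`.
#' @examples
#' moment_summary(c(1, 2, 3, 4))
#' @export
moment_summary <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("need at least 4 values for a moment summary")
  m <- mean(x)
  ctr <- x - m
  m2 <- mean(ctr^2)
  qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  data.frame(
    mean = m,
    sd = stats::sd(x),
    skew = mean(ctr^3) / m2^1.5,
    excess_kurtosis = mean(ctr^4) / m2^2 - 3,
    min = min(x),
    q25 = qs[1],
    q75 = qs[2],
    max = max(x))
}

#' Theoretical-vs-empirical quantile pairs for Q-Q plots
#'
#' @param m a fitted `marginal_model`.
#' @param x the observed sample.
#' @return Data frame with columns `p` (plotting positions `(i - 0.5)/n`),
#'   `theoretical` and `empirical`; plotting is left to the caller.
#' @export
qq_data <- function(m, x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  p <- (seq_len(n) - 0.5) / n
  data.frame(p = p, theoretical = marginal_quantile(m, p), empirical = x)
}
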