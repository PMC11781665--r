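# Synthetic cohort generator.
#
# Emulates a female menopause-clinic population of 359 patients aged 40-69:
# continuous covariates drawn from a Gaussian copula with configurable
# correlation over (age, bmi, totalc, hdlc, sbp) and the fitted marginal
# families (age Normal(50.82, 5.88); BMI logNormal(3.22, 0.19); total
# cholesterol Gamma(shape 31.48, scale 0.17); HDL cholesterol
# logNormal(0.54, 0.30); systolic BP Gamma(shape 59.86, scale 2.07));
# smoking prevalence 74/359, diabetes prevalence 0.

#' Default marginal models of the study covariates
#'
#' @return Named list of [marginal_model()] objects for
#'   `age, bmi, totalc, hdlc, sbp`.
#' @export
default_marginals <- function() {
  list(
    age = marginal_model("normal", c(50.82, 5.88)),
    bmi = marginal_model("lognormal", c(3.22, 0.19)),
    totalc = marginal_model("gamma", c(31.48, 0.17)),
    hdlc = marginal_model("lognormal", c(0.54, 0.30)),
    sbp = marginal_model("gamma", c(59.86, 2.07)))
}

#' Default generator correlation matrix
#'
#' A plausible dependence structure on the Gaussian scale over
#' `(age, bmi, totalc, hdlc, sbp)`. The sign pattern follows established
#' epidemiology (total cholesterol and blood pressure increase, HDL
#' cholesterol decreases, with BMI; cholesterol and blood pressure rise with
#' age); the magnitudes are generator conventions, not estimates from the
#' study population, whose correlation matrix is unpublished.
#'
#' @return A 5x5 positive-definite correlation matrix with dimnames.
#' @export
default_corr <- function() {
  v <- cont_vars()
  C <- diag(5)
  dimnames(C) <- list(v, v)
  set_pair <- function(a, b, r) {
    C[a, b] <<- r
    C[b, a] <<- r
  }
  set_pair("age", "bmi", 0.10)
  set_pair("age", "totalc", 0.30)
  set_pair("age", "hdlc", 0.05)
  set_pair("age", "sbp", 0.35)
  set_pair("bmi", "totalc", 0.25)
  set_pair("bmi", "hdlc", -0.30)
  set_pair("bmi", "sbp", 0.30)
  set_pair("totalc", "hdlc", 0.10)
  set_pair("totalc", "sbp", 0.15)
  set_pair("hdlc", "sbp", -0.10)
  C
}

#' Cohort generator specification
#'
#' @param n cohort size (default 359, the study size).
#' @param marginals named list of [marginal_model()]s over the continuous
#'   covariates (default [default_marginals()]).
#' @param corr correlation matrix over `(age, bmi, totalc, hdlc, sbp)`
#'   (default [default_corr()]).
#' @param smoker_prev smoking prevalence (default 74/359).
#' @param diabetes_prev diabetes prevalence (default 0, matching the study
#'   population and SCORE2's target population).
#' @param truncate_age keep ages inside `age_range` by resampling whole rows
#'   (default TRUE); resampling preserves the in-window marginal shape,
#'   unlike clipping, which would create boundary atoms.
#' @param age_range inclusive age window (default 40-69 years).
#' @param seed optional integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 359, marginals = default_marginals(),
                        corr = default_corr(), smoker_prev = 74 / 359,
                        diabetes_prev = 0, truncate_age = TRUE,
                        age_range = c(40, 69), seed = NULL) {
  stopifnot(n >= 1, smoker_prev >= 0, smoker_prev <= 1,
            diabetes_prev >= 0, diabetes_prev <= 1,
            setequal(names(marginals), cont_vars()))
  corr <- as.matrix(corr)
  stopifnot(nrow(corr) == 5, ncol(corr) == 5)
  if (is.null(dimnames(corr))) dimnames(corr) <- list(cont_vars(), cont_vars())
  ev <- eigen((corr + t(corr)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("corr is not positive semi-definite; consider a nearest-correlation ",
         "repair (eigenvalue clipping) before building the spec")
  structure(list(n = as.integer(n), marginals = marginals, corr = corr,
                 smoker_prev = smoker_prev, diabetes_prev = diabetes_prev,
                 truncate_age = isTRUE(truncate_age), age_range = age_range,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws the continuous block from the multivariate normal with the spec's
#' correlation, back-transforms per marginal, and draws smoking and diabetes
#' as independent Bernoulli columns. With `truncate_age` on, rows whose age
#' falls outside the window are fully redrawn.
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with columns `age, smoker, sbp, totalc, hdlc, diabetes,
#'   bmi`.
#' @examples
#' head(generate_cohort(cohort_spec(n = 50, seed = 1)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  v <- cont_vars()
  L <- t(chol(nearest_corr(spec$corr[v, v])))
  draw_cont <- function(k) {
    Z <- matrix(stats::rnorm(k * 5), nrow = 5)
    Zc <- t(L %*% Z)
    out <- lapply(seq_along(v), function(j)
      marginal_quantile(spec$marginals[[v[j]]],
                        pmin(pmax(stats::pnorm(Zc[, j]), 1e-12), 1 - 1e-12)))
    names(out) <- v
    as.data.frame(out)
  }
  with_seed_if(spec$seed, {
    cont <- draw_cont(spec$n)
    if (spec$truncate_age) {
      for (round in seq_len(1000)) {
        bad <- which(cont$age < spec$age_range[1] | cont$age > spec$age_range[2])
        if (length(bad) == 0) break
        cont[bad, ] <- draw_cont(length(bad))
      }
    }
    data.frame(
      age = cont$age,
      smoker = stats::rbinom(spec$n, 1, spec$smoker_prev),
      sbp = cont$sbp,
      totalc = cont$totalc,
      hdlc = cont$hdlc,
      diabetes = stats::rbinom(spec$n, 1, spec$diabetes_prev),
      bmi = cont$bmi)
  })
}

#' Mask a scenario's variables in every row
#'
#' Systematic missingness by design: the scenario's columns are set to `NA`
#' in all rows. The untouched original is returned alongside so true risks
#' remain computable.
#'
#' @param cohort complete cohort table.
#' @param sc a [scenario()].
#' @return List with elements `masked` and `truth`.
#' @export
mask_scenario <- function(cohort, sc) {
  stopifnot(inherits(sc, "scenario"))
  masked <- cohort
  masked[sc$missing] <- NA_real_
  list(masked = masked, truth = cohort)
}
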