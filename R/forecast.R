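# The five imputation-to-risk methods I1-I5. Each maps a patient with
# systematically missing inputs plus a complete training cohort to a risk
# forecast: an equally-weighted empirical distribution over risk values, a
# single atom (Dirac) for the point methods I1-I3.

#' Missingness scenario
#'
#' @param missing nonempty subset of the three clinical variables
#'   `c("totalc", "hdlc", "sbp")` treated as systematically missing.
#' @param use_bmi should BMI be used as an extra known covariate alongside
#'   age (default TRUE)?
#' @return An object of class `scenario`.
#' @examples
#' scenario(c("totalc", "hdlc", "sbp"))
#' @export
scenario <- function(missing, use_bmi = TRUE) {
  allowed <- c("totalc", "hdlc", "sbp")
  missing <- unique(missing)
  if (length(missing) == 0 || !all(missing %in% allowed))
    stop("'missing' must be a nonempty subset of ",
         paste(allowed, collapse = ", "))
  structure(list(missing = missing, use_bmi = isTRUE(use_bmi),
                 label = paste(missing, collapse = "+")),
            class = "scenario")
}

scenario_known <- function(sc) c("age", if (sc$use_bmi) "bmi")

#' Risk forecast
#'
#' An empirical distribution over risk values in `[0, 1]` with equally
#' weighted atoms; a single atom represents a point prediction interpreted as
#' a Dirac distribution.
#'
#' @param atoms numeric vector of risk values in `[0, 1]`.
#' @param method method tag, one of `"I1"`..`"I5"` (or another label).
#' @return An object of class `risk_forecast` with sorted atoms.
#' @export
risk_forecast <- function(atoms, method = "I1") {
  atoms <- as.numeric(atoms)
  if (length(atoms) == 0 || anyNA(atoms)) stop("forecast atoms must be nonempty and finite")
  if (any(atoms < 0 | atoms > 1)) stop("forecast atoms must lie in [0, 1]")
  structure(list(atoms = sort(atoms), method = method), class = "risk_forecast")
}

#' @export
print.risk_forecast <- function(x, ...) {
  a <- x$atoms
  if (length(a) == 1) {
    cat(sprintf("%s point forecast (Dirac): risk %.1f%%\n", x$method, 100 * a))
  } else {
    cat(sprintf("%s probabilistic forecast: %d atoms, mean %.1f%%, 90%% interval [%.1f%%, %.1f%%]\n",
                x$method, length(a), 100 * mean(a),
                100 * stats::quantile(a, 0.05), 100 * stats::quantile(a, 0.95)))
  }
  invisible(x)
}

#' @export
mean.risk_forecast <- function(x, ...) mean(x$atoms)

#' Empirical CDF of a risk forecast
#'
#' Right-continuous step function: the fraction of atoms `<= x`.
#'
#' @param f a `risk_forecast`.
#' @param x numeric vector of evaluation points.
#' @return Probabilities in `[0, 1]`.
#' @export
forecast_cdf <- function(f, x) {
  stopifnot(inherits(f, "risk_forecast"))
  findInterval(x, f$atoms) / length(f$atoms)
}

# Fill a patient's scenario-missing cells from a named source and return the
# evaluated risk.
patched_risk <- function(patient, values, sc, sex, region) {
  p <- as.list(patient)
  for (v in sc$missing) p[[v]] <- values[[v]]
  score2_risk(p$age, p$smoker, p$sbp, p$totalc, p$hdlc, p$diabetes,
              sex = sex, region = region)
}

#' Method I1: sample-mean patching
#'
#' Replaces the scenario's missing inputs by their training-cohort sample
#' means and evaluates the risk calculator once; the result is a Dirac
#' forecast.
#'
#' @param patient one-row data frame (or named list) with the standard cohort
#'   columns; the scenario's variables are treated as missing regardless of
#'   their cells.
#' @param training complete training cohort.
#' @param sc a [scenario()].
#' @param sex,region passed to [score2_risk()].
#' @return A single-atom `risk_forecast`.
#' @export
impute_I1 <- function(patient, training, sc, sex = "female", region = "low") {
  if (is.null(training) || nrow(training) == 0) stop("empty training cohort")
  means <- lapply(training[sc$missing], mean)
  risk_forecast(patched_risk(patient, means, sc, sex, region), "I1")
}

# Shared copula machinery for I3/I4: one marginal+copula fit, one Monte Carlo
# sample, used both for the conditional-mean plug-in and the propagated
# distribution.
copula_forecasts <- function(patient, training, sc, n = 500, seed = NULL,
                             sex = "female", region = "low") {
  known <- scenario_known(sc)
  vars <- c(known, sc$missing)
  model <- fit_copula(training, variables = vars)
  known_vals <- as.list(patient)[known]
  draws <- sample_conditional(model, known_vals, n = n, seed = seed)
  cmean <- as.list(colMeans(draws))
  i3 <- risk_forecast(patched_risk(patient, cmean, sc, sex, region), "I3")
  risks <- vapply(seq_len(nrow(draws)), function(i)
    patched_risk(patient, as.list(draws[i, , drop = FALSE]), sc, sex, region), 0)
  i4 <- risk_forecast(risks, "I4")
  list(I3 = i3, I4 = i4)
}

#' Methods I3 and I4: Gaussian-copula conditional imputation
#'
#' Both fit a Gaussian copula over the known covariates (age, optionally BMI)
#' and the scenario's missing ones, and condition on the patient's known
#' values. I3 plugs the Monte Carlo conditional means of the missing inputs
#' into the calculator (Dirac forecast); I4 propagates the full conditional
#' distribution, evaluating the calculator on each of `n` conditional draws.
#'
#' @inheritParams impute_I1
#' @param n Monte Carlo sample size (default 500).
#' @param seed optional integer seed for the conditional draw.
#' @return A `risk_forecast`: single atom for I3, `n` atoms for I4.
#' @export
impute_I3 <- function(patient, training, sc, n = 500, seed = NULL,
                      sex = "female", region = "low") {
  copula_forecasts(patient, training, sc, n, seed, sex, region)$I3
}

#' @rdname impute_I3
#' @export
impute_I4 <- function(patient, training, sc, n = 500, seed = NULL,
                      sex = "female", region = "low") {
  copula_forecasts(patient, training, sc, n, seed, sex, region)$I4
}

# Shared MICE machinery for I2/I5: append the patient (scenario cells
# missing) to the training cohort, run the FCS/PMM engine once, and evaluate
# the calculator on the patient's row of every completion.
mice_forecasts <- function(patient, training, sc, config = NULL,
                           sex = "female", region = "low") {
  if (is.null(config)) config <- mice_config(predictors = scenario_known(sc))
  patient <- as.data.frame(as.list(patient))[names(training)]
  patient[sc$missing] <- NA_real_
  tab <- rbind(training, patient)
  imp <- mice_impute(tab, config)
  i <- nrow(tab)
  risks <- vapply(imp$completions, function(comp)
    score2_risk(comp$age[i], comp$smoker[i], comp$sbp[i], comp$totalc[i],
                comp$hdlc[i], comp$diabetes[i], sex = sex, region = region), 0)
  list(I2 = risk_forecast(mean(risks), "I2"),
       I5 = risk_forecast(risks, "I5"))
}

#' Methods I2 and I5: MICE with predictive mean matching
#'
#' The patient (with the scenario's cells missing) is appended to the
#' training cohort and [mice_impute()] produces `m` completions; the risk
#' calculator is evaluated on the patient's row of each. I5 keeps the full
#' empirical distribution of the `m` risks; I2 is its arithmetic mean as a
#' Dirac forecast. Under the same configuration the two methods share one
#' MICE run, so `I2`'s atom equals the mean of `I5`'s atoms exactly.
#'
#' @inheritParams impute_I1
#' @param config a [mice_config()]; by default `m = 500` imputations with
#'   predictors matching the scenario's known covariates.
#' @return A `risk_forecast`: single atom for I2, `m` atoms for I5.
#' @export
impute_I2 <- function(patient, training, sc, config = NULL,
                      sex = "female", region = "low") {
  mice_forecasts(patient, training, sc, config, sex, region)$I2
}

#' @rdname impute_I2
#' @export
impute_I5 <- function(patient, training, sc, config = NULL,
                      sex = "female", region = "low") {
  mice_forecasts(patient, training, sc, config, sex, region)$I5
}

#' Write forecasts to CSV (one row per atom)
#'
#' @param forecasts named list of `risk_forecast` objects (names used as
#'   patient ids).
#' @param path output file.
#' @param comment optional header comment lines (written prefixed with `#`).
#' @return Invisibly, the long-format data frame written.
#' @export
write_forecasts <- function(forecasts, path, comment = NULL) {
  rows <- do.call(rbind, lapply(names(forecasts), function(id) {
    f <- forecasts[[id]]
    data.frame(patient = id, method = f$method, atom = f$atoms)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  for (line in comment) cat("# ", line, "\n", sep = "", file = con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(rows)
}
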