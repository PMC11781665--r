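# Shared fixtures: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

small_cohort <- function(n = 60, seed = 42, corr = default_corr()) {
  generate_cohort(cohort_spec(n = n, corr = corr, seed = seed))
}

patient_row <- function(age, smoker, sbp, totalc, hdlc, diabetes, bmi) {
  data.frame(age = age, smoker = smoker, sbp = sbp, totalc = totalc,
             hdlc = hdlc, diabetes = diabetes, bmi = bmi)
}

# The medium-risk artificial patient used in the worked examples: 65-year-old
# non-smoking woman, BMI 37, true clinical values (110, 5.5, 1.0).
example2_patient <- function() patient_row(65, 0, 110, 5.5, 1.0, 0, 37)

all_missing <- function(use_bmi = TRUE) {
  scenario(c("totalc", "hdlc", "sbp"), use_bmi = use_bmi)
}

dirac <- function(x) risk_forecast(x, "point")

# Standard-normal marginals make the Gaussian scale coincide with the
# original scale, so conditioning results can be checked in closed form.
std_normal_copula <- function(corr) {
  vars <- rownames(corr)
  marg <- lapply(vars, function(v) marginal_model("normal", c(0, 1)))
  names(marg) <- vars
  copula_model(marg, corr)
}

corr2 <- function(rho) {
  matrix(c(1, rho, rho, 1), 2, 2, dimnames = list(c("x1", "x2"), c("x1", "x2")))
}
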