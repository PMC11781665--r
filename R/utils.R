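# Shared internal helpers.

.riskimpute_cache <- new.env(parent = emptyenv())

#' Derive a reproducible sub-seed from a root seed and integer labels
#'
#' Mixes a root seed with any number of integer labels (patient index, method
#' id, chain number, ...) into a 31-bit seed, so that every stochastic step of
#' a benchmark has its own deterministic stream and results do not depend on
#' evaluation order.
#'
#' @param root integer root seed.
#' @param ... further integer labels.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(root, ...) {
  ids <- c(root, ...)
  h <- 0
  for (v in ids) {
    # multiplicative mixing kept in double precision; 2^31*69069 < 2^53
    h <- (h * 69069 + as.numeric(v) + 1) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under a fixed seed when one is supplied, otherwise as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Polynomial hash of a configuration (flags, values) for artifact headers.
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Repair a symmetric matrix to a valid correlation matrix: clip tiny negative
# eigenvalues, rescale to unit diagonal.
nearest_corr <- function(C, tol = 1e-10) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= -tol && all(abs(diag(C) - 1) < 1e-12)) return(C)
  vals <- pmax(e$values, tol)
  R <- e$vectors %*% (vals * t(e$vectors))
  R <- stats::cov2cor(R)
  dimnames(R) <- dimnames(C)
  (R + t(R)) / 2
}

# Matrix square root (lower-triangular-like factor) tolerant of PSD matrices
# with zero eigenvalues, used to draw from conditional Gaussians.
psd_factor <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), nrow = length(vals))
}

# The continuous covariates entering the joint (copula) model, in canonical
# order, and their marginal distribution families.
cont_vars <- function() c("age", "bmi", "totalc", "hdlc", "sbp")

default_families <- function() {
  c(age = "normal", bmi = "lognormal", totalc = "gamma",
    hdlc = "lognormal", sbp = "gamma")
}

cohort_cols <- function() c("age", "smoker", "sbp", "totalc", "hdlc", "diabetes", "bmi")
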