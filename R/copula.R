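# Gaussian-copula joint model of the continuous covariates.
#
# Each covariate is transformed to a standard-normal margin through its fitted
# marginal CDF, z = qnorm(F(x)); dependence is a correlation matrix on that
# Gaussian scale. Conditional distributions of unknown covariates given known
# ones follow from standard multivariate-normal conditioning and are
# back-transformed per variable via x = F^{-1}(pnorm(z)). Only continuous
# variables enter the model; binary covariates (smoker, diabetes) pass around
# it untouched.

#' Construct a Gaussian copula model from marginals and a correlation matrix
#'
#' @param marginals named list of [marginal_model()] objects.
#' @param corr correlation matrix on the Gaussian scale, dimnames matching
#'   `names(marginals)`; marginally non-PSD input is repaired.
#' @return An object of class `copula_model`.
#' @export
copula_model <- function(marginals, corr) {
  stopifnot(is.list(marginals), length(marginals) >= 1,
            all(vapply(marginals, inherits, TRUE, "marginal_model")))
  vars <- names(marginals)
  corr <- as.matrix(corr)
  stopifnot(nrow(corr) == length(vars), ncol(corr) == length(vars))
  if (is.null(dimnames(corr))) dimnames(corr) <- list(vars, vars)
  stopifnot(identical(rownames(corr), vars), identical(colnames(corr), vars))
  if (any(abs(diag(corr) - 1) > 1e-8)) stop("corr must have unit diagonal")
  ev <- eigen((corr + t(corr)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6)
    stop("corr is not positive semi-definite")
  corr <- nearest_corr(corr)
  structure(list(variables = vars, marginals = marginals, corr = corr),
            class = "copula_model")
}

#' @export
print.copula_model <- function(x, ...) {
  cat("Gaussian copula model on", length(x$variables), "variables:",
      paste(x$variables, collapse = ", "), "\n")
  cat("correlation matrix (Gaussian scale):\n")
  print(round(x$corr, 3))
  invisible(x)
}

# Transform observed values to the Gaussian scale through a fitted marginal,
# clamping CDF values away from {0,1} (eps = 1/(4n)) before qnorm.
z_transform <- function(m, x, eps) {
  u <- marginal_cdf(m, x)
  stats::qnorm(pmin(pmax(u, eps), 1 - eps))
}

#' Fit a Gaussian copula to cohort data
#'
#' Fits each variable's marginal by [fit_marginal()], transforms values to the
#' Gaussian scale, and estimates the correlation matrix as the Pearson
#' correlation of the transformed columns (repaired to a valid correlation
#' matrix if needed). CDF values are clamped to `[eps, 1 - eps]` with
#' `eps = 1/(4n)` before the normal quantile transform.
#'
#' @param table data frame of cohort rows.
#' @param families named character vector mapping variable name to family;
#'   defaults to the standard covariate map (age normal, BMI/HDLC lognormal,
#'   TotalC/SBP gamma).
#' @param variables which columns to model; defaults to `names(families)`
#'   intersected with the table's columns.
#' @return A `copula_model`.
#' @export
fit_copula <- function(table, families = default_families(),
                       variables = intersect(names(families), names(table))) {
  stopifnot(length(variables) >= 1, all(variables %in% names(table)),
            all(variables %in% names(families)))
  dat <- table[, variables, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 20)
    stop("fit_copula needs at least 20 complete rows on the modelled variables")
  marginals <- lapply(variables, function(v) fit_marginal(dat[[v]], families[[v]]))
  names(marginals) <- variables
  eps <- 1 / (4 * n)
  Z <- vapply(variables, function(v) z_transform(marginals[[v]], dat[[v]], eps),
              numeric(n))
  Z <- matrix(Z, nrow = n, dimnames = list(NULL, variables))
  corr <- if (length(variables) == 1) {
    matrix(1, 1, 1, dimnames = list(variables, variables))
  } else {
    nearest_corr(stats::cor(Z))
  }
  copula_model(marginals, corr)
}

#' Conditional law of the unknown variables given known ones
#'
#' Standard multivariate-normal conditioning of the zero-mean unit-variance
#' Gaussian vector underlying the copula: with the correlation partitioned
#' into unknown (1) and known (2) blocks, the conditional mean is
#' `S12 S22^-1 z_known` and the conditional covariance `S11 - S12 S22^-1 S21`.
#' A singular known-block is inverted with a small ridge (1e-8).
#'
#' @param model a `copula_model`.
#' @param known named numeric vector/list of known values (original scale);
#'   names must be a strict subset of the model's variables. May be empty, in
#'   which case the unconditional law is returned.
#' @return An object of class `conditional_law` with fields `unknown_names`,
#'   `mean` and `cov` (both on the Gaussian scale).
#' @export
condition_copula <- function(model, known) {
  stopifnot(inherits(model, "copula_model"))
  known <- unlist(known)
  kn <- names(known)
  stopifnot(all(kn %in% model$variables), all(is.finite(known)) || length(known) == 0)
  un <- setdiff(model$variables, kn)
  if (length(un) == 0) stop("no unknown variables left to condition")
  if (length(kn) == 0) {
    law <- list(unknown_names = un,
                mean = stats::setNames(rep(0, length(un)), un),
                cov = model$corr[un, un, drop = FALSE])
    return(structure(law, class = "conditional_law"))
  }
  zk <- vapply(kn, function(v)
    z_transform(model$marginals[[v]], known[[v]], eps = 1e-10), 0)
  S11 <- model$corr[un, un, drop = FALSE]
  S12 <- model$corr[un, kn, drop = FALSE]
  S22 <- model$corr[kn, kn, drop = FALSE]
  inv <- tryCatch(solve(S22), error = function(e) {
    solve(S22 + 1e-8 * diag(nrow(S22)))
  })
  mu <- drop(S12 %*% inv %*% zk)
  cv <- S11 - S12 %*% inv %*% t(S12)
  cv <- (cv + t(cv)) / 2
  structure(list(unknown_names = un,
                 mean = stats::setNames(mu, un),
                 cov = cv),
            class = "conditional_law")
}

#' Sample unknown covariates from their conditional distribution
#'
#' Draws from the Gaussian conditional law and back-transforms each variable
#' to the original scale via its marginal quantile function, so draws always
#' lie inside the marginal support.
#'
#' @inheritParams condition_copula
#' @param n number of Monte Carlo draws (default 500).
#' @param seed optional integer; a fixed seed makes the draw reproducible
#'   without touching the caller's RNG state.
#' @return Data frame of draws, one column per unknown variable.
#' @export
sample_conditional <- function(model, known, n = 500, seed = NULL) {
  stopifnot(n >= 1)
  law <- condition_copula(model, known)
  k <- length(law$unknown_names)
  L <- psd_factor(law$cov)
  Z <- with_seed_if(seed, matrix(stats::rnorm(n * k), nrow = n))
  Zc <- sweep(Z %*% t(L), 2, law$mean, `+`)
  out <- lapply(seq_len(k), function(j) {
    v <- law$unknown_names[j]
    u <- stats::pnorm(Zc[, j])
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    marginal_quantile(model$marginals[[v]], u)
  })
  names(out) <- law$unknown_names
  as.data.frame(out)
}

#' Conditional means of unknown covariates (original scale)
#'
#' Monte Carlo average of [sample_conditional()] draws on the original scale
#' (not the back-transform of the Gaussian-scale mean, which would differ for
#' skewed marginals).
#'
#' @inheritParams sample_conditional
#' @return Named numeric vector of per-variable conditional means.
#' @export
conditional_mean <- function(model, known, n = 500, seed = NULL) {
  colMeans(sample_conditional(model, known, n = n, seed = seed))
}

#' Serialize / restore a copula model as plain text
#'
#' The file holds one `marginal` line per variable (family and parameters)
#' followed by the correlation matrix rows, so benchmark models can be stored
#' and audited as text.
#'
#' @param model a `copula_model`.
#' @param path file path.
#' @return `write_copula` invisibly returns `path`; `read_copula` returns the
#'   restored `copula_model`.
#' @export
write_copula <- function(model, path) {
  stopifnot(inherits(model, "copula_model"))
  con <- file(path, "w")
  on.exit(close(con))
  for (v in model$variables) {
    m <- model$marginals[[v]]
    cat(sprintf("marginal %s %s %.15g %.15g\n", v, m$family,
                m$params[1], m$params[2]), file = con)
  }
  for (i in seq_along(model$variables)) {
    cat("corr", sprintf("%.15g", model$corr[i, ]), "\n", file = con)
  }
  invisible(path)
}

#' @rdname write_copula
#' @export
read_copula <- function(path) {
  lines <- readLines(path)
  mlines <- strsplit(grep("^marginal ", lines, value = TRUE), " ")
  marginals <- list()
  for (f in mlines) {
    marginals[[f[2]]] <- marginal_model(f[3], as.numeric(f[4:5]))
  }
  clines <- strsplit(trimws(grep("^corr ", lines, value = TRUE)), " +")
  corr <- do.call(rbind, lapply(clines, function(f) as.numeric(f[-1])))
  dimnames(corr) <- list(names(marginals), names(marginals))
  copula_model(marginals, corr)
}
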