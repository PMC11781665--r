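# Multiple imputation by chained equations (fully conditional specification)
# with predictive mean matching, implemented from first principles.
#
# The regression step is Bayesian linear regression: the residual variance is
# drawn from its scaled inverse-chi-square posterior, coefficients from their
# conditional normal posterior. Predicted means for the observed rows use the
# least-squares fit, predicted means for the missing rows use the drawn
# coefficients (type-1 matching); each missing row then receives the OBSERVED
# value of one of its `donors` nearest observed predictions.

#' MICE configuration
#'
#' @param m number of imputations / chains (default 500, so the probabilistic
#'   MICE forecast has the same resolution as the 500-sample copula forecast).
#' @param iterations FCS sweeps per chain (default 10; convergence is not
#'   tested formally, a per-iteration trace is returned instead).
#' @param donors PMM donor pool size (default 5).
#' @param predictors always-available covariates used in every regression
#'   (default age and BMI).
#' @param seed integer root seed; chains use deterministic substreams.
#' @return A list of class `mice_config`.
#' @export
mice_config <- function(m = 500, iterations = 10, donors = 5,
                        predictors = c("age", "bmi"), seed = NULL) {
  stopifnot(m >= 1, iterations >= 1, donors >= 1, length(predictors) >= 1)
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 donors = as.integer(donors), predictors = predictors,
                 seed = seed),
            class = "mice_config")
}

# Least-squares pieces reused across Bayesian draws for a fixed design.
pmm_prefit <- function(x_obs, y_obs, ridge_tol = 1e-10) {
  X <- cbind(intercept = 1, as.matrix(x_obs))
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2) stop("pmm needs at least donors+2 observed rows")
  qrX <- qr(X)
  ridged <- FALSE
  if (qrX$rank < p) {
    # rank-deficient predictors: ridge fallback
    ridged <- TRUE
    XtX <- crossprod(X) + 1e-6 * diag(p)
    XtXinv <- solve(XtX)
    betahat <- drop(XtXinv %*% crossprod(X, y_obs))
  } else {
    betahat <- qr.coef(qrX, y_obs)
    XtXinv <- chol2inv(qr.R(qrX))
  }
  res <- drop(y_obs - X %*% betahat)
  XtXinv <- (XtXinv + t(XtXinv)) / 2
  list(X = X, y = y_obs, p = p, n = n, betahat = betahat,
       XtXinv = XtXinv, cov_factor = psd_factor(XtXinv), ss = sum(res^2),
       df = max(n - p, 1), yhat_obs = drop(X %*% betahat), ridged = ridged)
}

# One PMM draw for a fixed prefit and a matrix of missing-row predictors.
pmm_draw_fit <- function(fit, x_mis, donors) {
  n_mis <- nrow(x_mis)
  if (n_mis == 0) return(numeric(0))
  Xm <- cbind(1, as.matrix(x_mis))
  sigma2 <- fit$ss / stats::rchisq(1, fit$df)
  beta <- fit$betahat +
    drop(fit$cov_factor %*% stats::rnorm(fit$p)) * sqrt(sigma2)
  yhat_mis <- drop(Xm %*% beta)
  shuffle <- sample.int(fit$n) # seeded tie-break among equal distances
  vapply(seq_len(n_mis), function(i) {
    d <- abs(fit$yhat_obs - yhat_mis[i])
    pool <- order(d, shuffle)[seq_len(min(donors, fit$n))]
    fit$y[pool[sample.int(length(pool), 1)]]
  }, 0)
}

#' One predictive-mean-matching imputation draw
#'
#' @param x_obs matrix/data frame of predictor rows with observed target.
#' @param y_obs observed target values.
#' @param x_mis predictor rows whose target is missing.
#' @param donors donor pool size (default 5).
#' @return Imputed target values, one per row of `x_mis`; each is one of the
#'   observed `y_obs` values.
#' @export
pmm_draw <- function(x_obs, y_obs, x_mis, donors = 5) {
  fit <- pmm_prefit(x_obs, y_obs)
  pmm_draw_fit(fit, as.matrix(x_mis), donors)
}

#' Multiple imputation by chained equations
#'
#' Missing cells are initialized with random draws from the observed values
#' of their column; each FCS sweep then cycles over the incomplete variables,
#' re-imputing each by [pmm_draw()] with design = the configured predictors
#' plus the current completions of the other incomplete variables. Chains are
#' independent, each on a deterministic substream of `config$seed`.
#'
#' @param table data frame; incomplete columns must be continuous, the
#'   configured predictors fully observed.
#' @param config a [mice_config()].
#' @return An object of class `imputed_set`: `completions` (list of `m`
#'   completed tables; observed cells identical across completions) and
#'   `trace` (data frame of per-chain, per-iteration imputed-value means).
#' @export
mice_impute <- function(table, config = mice_config()) {
  stopifnot(is.data.frame(table), inherits(config, "mice_config"))
  targets <- names(table)[vapply(table, anyNA, TRUE)]
  for (v in targets) {
    if (all(is.na(table[[v]])))
      stop("column '", v, "' is entirely missing; nothing to regress on")
    if (!is.numeric(table[[v]]) || all(table[[v]] %in% c(0, 1, NA)))
      stop("only continuous variables can be imputed (column '", v, "')")
  }
  for (v in config$predictors) {
    if (!v %in% names(table)) stop("predictor '", v, "' not in table")
    if (anyNA(table[[v]])) stop("predictor '", v, "' must be fully observed")
  }
  m <- config$m
  if (length(targets) == 0) {
    return(structure(list(completions = rep(list(table), m),
                          trace = data.frame()), class = "imputed_set"))
  }

  obs_rows <- lapply(targets, function(v) which(!is.na(table[[v]])))
  mis_rows <- lapply(targets, function(v) which(is.na(table[[v]])))
  names(obs_rows) <- names(mis_rows) <- targets
  pred_sets <- lapply(targets, function(v)
    union(config$predictors, setdiff(targets, v)))
  names(pred_sets) <- targets

  # When a target's observed rows are complete on its predictors in the
  # original table, the regression design never changes across chains or
  # iterations; prefit once.
  prefits <- list()
  for (v in targets) {
    sub <- table[obs_rows[[v]], pred_sets[[v]], drop = FALSE]
    if (!anyNA(sub))
      prefits[[v]] <- pmm_prefit(sub, table[[v]][obs_rows[[v]]])
  }

  completions <- vector("list", m)
  trace <- vector("list", m)
  for (k in seq_len(m)) {
    chain_seed <- derive_seed(if (is.null(config$seed)) 0 else config$seed,
                              104729, k)
    res <- withr::with_seed(chain_seed, {
      cur <- table
      for (v in targets) {
        obs <- table[[v]][obs_rows[[v]]]
        cur[[v]][mis_rows[[v]]] <-
          obs[sample.int(length(obs), length(mis_rows[[v]]), replace = TRUE)]
      }
      tr <- matrix(NA_real_, config$iterations, length(targets),
                   dimnames = list(NULL, targets))
      for (it in seq_len(config$iterations)) {
        for (v in targets) {
          fit <- prefits[[v]]
          if (is.null(fit)) {
            fit <- pmm_prefit(cur[obs_rows[[v]], pred_sets[[v]], drop = FALSE],
                              table[[v]][obs_rows[[v]]])
          }
          mis <- mis_rows[[v]]
          x_mis <- vapply(pred_sets[[v]], function(pc) cur[[pc]][mis],
                          numeric(length(mis)))
          if (length(mis) == 1) x_mis <- matrix(x_mis, nrow = 1)
          cur[[v]][mis] <- pmm_draw_fit(fit, x_mis, config$donors)
          tr[it, v] <- mean(cur[[v]][mis])
        }
      }
      list(cur = cur,
           tr = data.frame(chain = k,
                           iteration = rep(seq_len(config$iterations),
                                           times = length(targets)),
                           variable = rep(targets, each = config$iterations),
                           imputed_mean = as.vector(tr)))
    })
    completions[[k]] <- res$cur
    trace[[k]] <- res$tr
  }
  structure(list(completions = completions, trace = do.call(rbind, trace)),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("imputed_set:", length(x$completions), "completions,",
      if (nrow(x$trace)) max(x$trace$iteration) else 0, "FCS iterations\n")
  invisible(x)
}
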