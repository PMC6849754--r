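# Model-data comparison statistics: Model II regression, percent bias,
# bias-vs-covariate regressions with partial residuals and VIFs, AIC model
# comparison, Welch t-test.

#' Model II (standardized major axis) regression
#'
#' Reduced-major-axis line through predicted (x) versus observed (y)
#' values: `slope = sign(r) sd(y) / sd(x)`, `intercept = mean(y) - slope *
#' mean(x)`, `r2` the squared Pearson correlation. Both axes carry error,
#' so ordinary least squares would bias the slope toward zero; the SMA
#' estimator treats them symmetrically. 95% confidence intervals come from
#' a seeded nonparametric bootstrap (pairs resampling, percentile
#' intervals) — assumption-light, and converging to the analytic SMA
#' intervals at large n.
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @param nboot bootstrap resamples for the CIs (default 1999); 0 skips
#'   CIs.
#' @param seed RNG seed for the bootstrap (local; does not touch the
#'   global RNG stream).
#' @param conf confidence level.
#' @return list of class `"rma_fit"`: `slope`, `intercept`, `r2`, `n`,
#'   `slope_ci`, `intercept_ci`.
#' @examples
#' fit <- rma_fit(1:10, 2 * (1:10) + 5, nboot = 0)
#' c(fit$slope, fit$intercept)
#' @export
rma_fit <- function(x, y, nboot = 1999, seed = 1L, conf = 0.95) {
  if (length(x) != length(y)) vcx_domain_error("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) vcx_domain_error("need at least 3 complete pairs")
  if (stats::sd(x) == 0) vcx_domain_error("zero variance in x: degenerate fit")
  est <- function(x, y) {
    r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
    s <- sign(ifelse(r == 0, 1, r)) * stats::sd(y) / stats::sd(x)
    c(slope = s, intercept = mean(y) - s * mean(x), r2 = r^2)
  }
  e <- est(x, y)
  slope_ci <- intercept_ci <- c(NA_real_, NA_real_)
  if (nboot > 0) {
    boots <- withr_seed(seed, {
      vapply(seq_len(nboot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(x[idx]) == 0) return(c(NA_real_, NA_real_))
        est(x[idx], y[idx])[1:2]
      }, numeric(2))
    })
    a <- (1 - conf) / 2
    slope_ci <- stats::quantile(boots[1, ], c(a, 1 - a), na.rm = TRUE,
                                names = FALSE)
    intercept_ci <- stats::quantile(boots[2, ], c(a, 1 - a), na.rm = TRUE,
                                    names = FALSE)
  }
  structure(list(slope = unname(e["slope"]),
                 intercept = unname(e["intercept"]),
                 r2 = unname(e["r2"]), n = n,
                 slope_ci = slope_ci, intercept_ci = intercept_ci),
            class = "rma_fit")
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Percent model bias
#'
#' `B = (pred - obs) / obs * 100`. Observations must be positive;
#' non-positive observations yield NA with a warning.
#'
#' @param pred,obs numeric vectors.
#' @return percent bias, same length.
#' @examples
#' bias(45, 60)   # -25
#' @export
bias <- function(pred, obs) {
  if (length(pred) != length(obs)) vcx_domain_error("pred and obs lengths differ")
  bad <- !is.na(obs) & obs <= 0
  if (any(bad)) {
    warning(sprintf("%d record(s) with obs <= 0 rejected (NA)", sum(bad)))
    obs[bad] <- NA_real_
  }
  (pred - obs) / obs * 100
}

#' Regression of model bias on covariates
#'
#' Ordinary least squares of a response (typically percent bias per grid
#' cell) on a set of named covariates, with the companion diagnostics used
#' for model evaluation: per-term F statistics and p values (type II,
#' equal to the squared t tests in this main-effects-only setting),
#' variance inflation factors from auxiliary regressions, partial
#' residuals per covariate for plotting, and optionally seeded bootstrap
#' confidence intervals on the coefficients.
#'
#' @param data data.frame containing the response and covariates;
#'   incomplete rows are dropped.
#' @param response response column name (default `"bias"`).
#' @param covariates character vector of covariate column names.
#' @param weights optional column name of case weights (e.g. `n_obs`).
#' @param ci `"t"` for classical t-based intervals, `"boot"` for a pairs
#'   bootstrap.
#' @param nboot bootstrap resamples when `ci = "boot"`.
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return list of class `"bias_regression"`: `coefficients` (table with
#'   estimate, se, F, p, ci_low, ci_high), `vif`, `partial_residuals`
#'   (data.frame, one column per covariate), `r2`, `n`, `fit` (the `lm`
#'   object).
#' @export
bias_regression <- function(data, response = "bias", covariates,
                            weights = NULL, ci = c("t", "boot"),
                            nboot = 999, seed = 1L, conf = 0.95) {
  ci <- match.arg(ci)
  cols <- c(response, covariates, weights)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    vcx_parse_error(paste0("data lacks column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n < length(covariates) + 2L) {
    vcx_domain_error("too few complete cases for the requested model")
  }
  fml <- stats::reformulate(covariates, response = response)
  w <- if (is.null(weights)) NULL else d[[weights]]
  fit <- stats::lm(fml, data = d, weights = w)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    vcx_domain_error(paste0("rank-deficient design; aliased term(s): ",
                            paste(aliased, collapse = ", ")))
  }
  sm <- summary(fit)
  ct <- sm$coefficients[covariates, , drop = FALSE]
  Fstat <- ct[, "t value"]^2
  pval <- ct[, "Pr(>|t|)"]

  # VIF_j = 1 / (1 - R2 of covariate j regressed on the others)
  vif <- if (length(covariates) >= 2L) {
    vapply(covariates, function(cv) {
      aux <- stats::lm(stats::reformulate(setdiff(covariates, cv),
                                          response = cv), data = d)
      r2 <- summary(aux)$r.squared
      1 / (1 - min(r2, 1 - 1e-12))
    }, numeric(1))
  } else {
    stats::setNames(1, covariates)
  }

  # partial residual for term j: working residual + beta_j * x_j
  res <- stats::residuals(fit)
  pr <- as.data.frame(lapply(covariates, function(cv) {
    res + stats::coef(fit)[[cv]] * d[[cv]]
  }))
  names(pr) <- covariates

  a <- (1 - conf) / 2
  if (ci == "t") {
    cint <- stats::confint(fit, covariates, level = conf)
  } else {
    X <- d
    boots <- withr_seed(seed, {
      vapply(seq_len(nboot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        bf <- stats::lm(fml, data = X[idx, , drop = FALSE],
                        weights = if (is.null(w)) NULL else w[idx])
        stats::coef(bf)[covariates]
      }, numeric(length(covariates)))
    })
    boots <- matrix(boots, nrow = length(covariates))
    cint <- t(apply(boots, 1, stats::quantile, probs = c(a, 1 - a),
                    na.rm = TRUE))
    rownames(cint) <- covariates
  }

  coefs <- data.frame(
    term = covariates,
    estimate = unname(ct[, "Estimate"]),
    se = unname(ct[, "Std. Error"]),
    F = unname(Fstat),
    p = unname(pval),
    ci_low = unname(cint[, 1]),
    ci_high = unname(cint[, 2]),
    vif = unname(vif[covariates]),
    row.names = NULL
  )
  structure(list(coefficients = coefs, vif = vif,
                 partial_residuals = pr, r2 = sm$r.squared, n = n,
                 fit = fit),
            class = "bias_regression")
}

#' AIC comparison of nested covariate sets
#'
#' Fits one OLS model per named covariate set for a common response on the
#' identical complete-case set (rows complete for the union of all
#' covariates — comparisons on unequal data are refused), and reports AIC,
#' r2, number of parameters and delta-AIC. AIC uses the full Gaussian
#' likelihood, `n log(2 pi) + n log(RSS / n) + n + 2 (p + 1)`, matching
#' `stats::AIC`; only differences between models are meaningful.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param covariate_sets named list of character vectors, e.g.
#'   `list(climate = "vcmax_pred", soil = soil_vars, combined = c(...))`.
#' @return data.frame of class `"aic_comparison"`, one row per model,
#'   sorted by AIC: `model`, `k` (estimated parameters incl. the error
#'   variance), `aic`, `delta_aic`, `r2`, `n`.
#' @export
aic_model_comparison <- function(data, response, covariate_sets) {
  if (is.null(names(covariate_sets)) || any(names(covariate_sets) == "")) {
    vcx_config_error("covariate_sets must be a named list")
  }
  all_terms <- unique(unlist(covariate_sets))
  cols <- c(response, all_terms)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    vcx_parse_error(paste0("data lacks column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n < length(all_terms) + 2L) {
    vcx_domain_error("too few complete cases shared by all models")
  }
  rows <- lapply(names(covariate_sets), function(nm) {
    fml <- stats::reformulate(covariate_sets[[nm]], response = response)
    fit <- stats::lm(fml, data = d)
    rss <- sum(stats::residuals(fit)^2)
    p <- length(stats::coef(fit))
    aic <- n * log(2 * pi) + n * log(rss / n) + n + 2 * (p + 1)
    data.frame(model = nm, k = p + 1L, aic = aic,
               r2 = summary(fit)$r.squared, n = n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1L]
  rownames(out) <- NULL
  structure(out[c("model", "k", "aic", "delta_aic", "r2", "n")],
            class = c("aic_comparison", "data.frame"))
}

#' Welch two-sample t-test on subset biases
#'
#' Compares mean bias between two subsets (e.g. records standardized to
#' top-of-canopy light versus the rest) without assuming equal variances;
#' degrees of freedom are the fractional Welch-Satterthwaite value.
#'
#' @param bias_a,bias_b numeric vectors (n >= 2 each).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
subset_ttest <- function(bias_a, bias_b) {
  bias_a <- bias_a[is.finite(bias_a)]
  bias_b <- bias_b[is.finite(bias_b)]
  if (length(bias_a) < 2L || length(bias_b) < 2L) {
    vcx_domain_error("need at least 2 finite values per group")
  }
  if (stats::sd(bias_a) == 0 && stats::sd(bias_b) == 0) {
    vcx_domain_error("degenerate variance: both groups are constant")
  }
  tt <- stats::t.test(bias_a, bias_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(bias_a), mean_b = mean(bias_b))
}
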