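#' Ordinary least squares fit with coefficient t-tests
#'
#' Exact least-squares fit of the response on the selected features (plus an
#' intercept), with a two-sided t-test per coefficient on
#' `n - m - 1` degrees of freedom (`m` features).  Rejecting the null for a
#' coefficient means the model including that feature explains the response
#' significantly better than the nested model without it, i.e. the feature
#' matters jointly with the others even if its marginal association is weak.
#'
#' @param x Feature matrix restricted to the selected features (typically
#'   standardized); may have zero columns, giving the intercept-only model.
#' @param y Response vector aligned to `x`.
#' @param alpha Significance level for the reported significant set
#'   (default 0.01).
#' @return An `ols_fit` object with elements `intercept`, `coefficients`
#'   (named), `std_errors`, `t_stats`, `p_values` (all including the
#'   intercept under term `(Intercept)`), `significant` (feature names with
#'   p < alpha), `residuals`, `fitted`, `r_squared`, `sigma`, `df_residual`,
#'   and `t_defined` (FALSE when the fit interpolates the data and the
#'   t-tests are undefined).  Supports [predict()], [tidy()] and
#'   [glance()].
#' @examples
#' x <- matrix(c(-1, 0, 1), 3, 1, dimnames = list(NULL, "f"))
#' fit <- fit_ols(x, c(0, 1, 2))
#' fit$coefficients # f = 1
#' @export
fit_ols <- function(x, y, alpha = 0.01) {
  x <- as_feature_matrix(x)
  y <- align_response(x, y)
  n <- nrow(x)
  m <- ncol(x)
  if (m >= n - 1) {
    stop_validation("too many features (%d) for %d samples; need m < n - 1", m, n)
  }
  a <- cbind("(Intercept)" = 1, x)
  qx <- qr(a)
  if (qx$rank < ncol(a)) {
    aliased <- colnames(a)[qx$pivot[seq(qx$rank + 1L, ncol(a))]]
    stop_numerical("design is rank deficient; collinear column(s): %s",
                   paste(aliased, collapse = ", "))
  }
  cf <- qr.coef(qx, y)
  fitted <- drop(a %*% cf)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df <- n - m - 1L
  sigma2 <- rss / df
  xtxinv <- chol2inv(chol(crossprod(a)))
  se <- sqrt(pmax(diag(xtxinv), 0) * sigma2)
  t_defined <- rss > 1e-12 * max(tss, 1)
  if (t_defined) {
    tstat <- cf / se
    pval <- 2 * pt(-abs(tstat), df)
  } else {
    tstat <- pval <- stats::setNames(rep(NA_real_, length(cf)), names(cf))
    se[] <- NA_real_
  }
  feat_p <- pval[-1]
  structure(list(
    intercept = unname(cf[1]),
    coefficients = cf[-1],
    std_errors = stats::setNames(se, names(cf)),
    t_stats = stats::setNames(tstat, names(cf)),
    p_values = stats::setNames(pval, names(cf)),
    significant = names(feat_p)[!is.na(feat_p) & feat_p < alpha],
    alpha = alpha,
    residuals = res,
    fitted = fitted,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    sigma = sqrt(sigma2),
    df_residual = df,
    n = n,
    features = colnames(x),
    t_defined = t_defined
  ), class = "ols_fit")
}

#' Predict from an OLS fit
#'
#' @param object An `ols_fit`.
#' @param newdata Matrix or data frame containing every model feature as a
#'   column, transformed with the same (training) standardization as the
#'   design the model was fit on.
#' @param ... Unused.
#' @return Numeric vector of predictions `intercept + sum_k beta_k x_k`.
#' @export
predict.ols_fit <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    stop_validation("newdata is missing model feature(s): %s",
                    paste(miss, collapse = ", "))
  }
  if (length(object$features) == 0) {
    return(stats::setNames(rep(object$intercept, nrow(newdata)), rownames(newdata)))
  }
  drop(object$intercept +
         newdata[, object$features, drop = FALSE] %*% object$coefficients)
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %d feature(s), n = %d, R^2 = %.4f\n",
              length(x$features), x$n, x$r_squared))
  if (!x$t_defined) cat("  (zero residual variance: t-tests undefined)\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy an OLS fit
#'
#' @param x An `ols_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `significant` (at the fit's alpha; `NA` for the
#'   intercept).
#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) {
  terms <- names(x$p_values)
  tibble::tibble(
    term = terms,
    estimate = unname(c(x$intercept, x$coefficients)),
    std.error = unname(x$std_errors),
    statistic = unname(x$t_stats),
    p.value = unname(x$p_values),
    significant = ifelse(terms == "(Intercept)", NA,
                         terms %in% x$significant)
  )
}

#' Glance at an OLS fit
#'
#' @param x An `ols_fit`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `sigma`, `df.residual`, `nobs`,
#'   `n_features`, `t_defined`.
#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$sigma,
    df.residual = x$df_residual,
    nobs = x$n,
    n_features = length(x$features),
    t_defined = x$t_defined
  )
}
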