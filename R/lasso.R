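lasso_objective <- function(x, y, intercept, beta, lambda) {
  sum((y - intercept - drop(x %*% beta))^2) + lambda * sum(abs(beta))
}

# lambda path on the objective scale RSS + lambda * ||beta||_1.  All
# coefficients are zero exactly when lambda >= 2 * max |x_c' (y - ybar)|
# (KKT with the intercept profiled out).
lambda_path <- function(x, y, nlambda, lambda_min_ratio) {
  xc <- sweep(x, 2L, colMeans(x), "-")
  lmax <- 2 * max(abs(drop(crossprod(xc, y - mean(y)))))
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# Closed-form lasso for a single centered predictor: the soft-thresholded
# marginal coefficient.  Used where glmnet requires >= 2 columns.
soft_threshold_fit <- function(x1, y, lambda) {
  xb <- mean(x1)
  xc <- x1 - xb
  yb <- mean(y)
  sxy <- sum(xc * (y - yb))
  sxx <- sum(xc * xc)
  b <- sign(sxy) * max(0, abs(sxy) - lambda / 2) / sxx
  c(intercept = yb - b * xb, beta = b)
}

#' Lasso regression with an unpenalized intercept
#'
#' Minimizes \deqn{\sum_i (Y_i - \beta_0 - \sum_k \beta_k X_{ik})^2 +
#' \lambda \sum_k |\beta_k|} over the candidate features in `x`.  The
#' features with nonzero coefficients form the retained set used by the
#' iterative selection ([isirs_select()]).
#'
#' The penalty weight is either a fixed nonnegative number or chosen by
#' internal k-fold cross-validation (`lambda = "cv"`, the default) over a
#' log-spaced path of `nlambda` values from the smallest lambda that zeroes
#' every coefficient down to `lambda_min_ratio` times it, picking the
#' minimum-CV-error point.  Fitting is delegated to \pkg{glmnet} (with the
#' penalty rescaled to this objective); a single-feature candidate set uses
#' the closed-form soft-threshold solution and `lambda = 0` the exact
#' least-squares fit.
#'
#' @param x Candidate feature matrix (typically standardized columns).
#' @param y Response vector aligned to `x`.
#' @param lambda `"cv"` or a fixed nonnegative penalty on the objective
#'   scale above.
#' @param nfolds Folds for the internal lambda cross-validation.
#' @param nlambda,lambda_min_ratio Path resolution and depth.
#' @param seed Optional integer seed for the internal CV fold split; when
#'   `NULL` the current RNG stream is used.
#' @return A `lasso_fit` list: `intercept`, `beta` (full named coefficient
#'   vector, exact zeros for dropped features), `coefficients` (nonzero
#'   entries only), `retained` (named indices of nonzero coefficients),
#'   `lambda`, and `objective` (the criterion above at the solution).
#' @export
run_lasso <- function(x, y, lambda = "cv", nfolds = 5, nlambda = 100,
                      lambda_min_ratio = 1e-3, seed = NULL) {
  x <- as_feature_matrix(x)
  y <- align_response(x, y)
  n <- nrow(x)
  m <- ncol(x)
  if (m < 1) stop_validation("empty candidate set")
  if (n < 3) stop_validation("lasso needs at least 3 samples")
  fixed <- is.numeric(lambda)
  if (fixed && (length(lambda) != 1 || is.na(lambda) || lambda < 0)) {
    stop_validation("lambda must be a single nonnegative number or \"cv\"")
  }
  if (!fixed && !identical(lambda, "cv")) {
    stop_validation("lambda must be a number or \"cv\"")
  }

  run <- function() {
    path <- lambda_path(x, y, nlambda, lambda_min_ratio)
    lmax <- path[1]
    beta <- stats::setNames(numeric(m), colnames(x))
    if (fixed && lambda == 0) {
      fit <- lm.fit(cbind(1, x), y)
      if (fit$rank < m + 1) {
        stop_numerical("lambda = 0 requires a full-rank design")
      }
      cf <- fit$coefficients
      b0 <- cf[1]
      beta[] <- cf[-1]
      lam <- 0
    } else if (fixed && lambda >= lmax) {
      b0 <- mean(y)
      lam <- lambda
    } else if (m == 1) {
      lam <- if (fixed) lambda else cv_soft_threshold(x[, 1], y, path, nfolds)
      cf <- soft_threshold_fit(x[, 1], y, lam)
      b0 <- cf[["intercept"]]
      beta[1] <- cf[["beta"]]
    } else {
      glpath <- path / (2 * n)
      if (fixed) {
        fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                              lambda = glpath, standardize = FALSE,
                              thresh = 1e-12, maxit = 1e6)
        cf <- as.numeric(coef(fit, s = lambda / (2 * n), exact = TRUE,
                              x = x, y = y))
        lam <- lambda
      } else {
        foldid <- sample(rep_len(seq_len(nfolds), n))
        cvfit <- glmnet::cv.glmnet(x, y, family = "gaussian", alpha = 1,
                                   lambda = glpath, foldid = foldid,
                                   standardize = FALSE, thresh = 1e-12,
                                   maxit = 1e6)
        cf <- as.numeric(coef(cvfit, s = "lambda.min"))
        lam <- cvfit$lambda.min * 2 * n
      }
      b0 <- cf[1]
      beta[] <- cf[-1]
    }
    retained <- which(beta != 0)
    structure(list(
      intercept = unname(b0),
      beta = beta,
      coefficients = beta[retained],
      retained = retained,
      lambda = lam,
      objective = lasso_objective(x, y, b0, beta, lam)
    ), class = "lasso_fit")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# k-fold CV for the single-predictor soft-threshold path.
cv_soft_threshold <- function(x1, y, path, nfolds) {
  n <- length(y)
  foldid <- sample(rep_len(seq_len(nfolds), n))
  err <- matrix(NA_real_, nfolds, length(path))
  for (f in seq_len(nfolds)) {
    tr <- foldid != f
    for (j in seq_along(path)) {
      cf <- soft_threshold_fit(x1[tr], y[tr], path[j])
      pred <- cf[["intercept"]] + cf[["beta"]] * x1[!tr]
      err[f, j] <- mean((y[!tr] - pred)^2)
    }
  }
  path[which.min(colMeans(err))]
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("Lasso fit: %d retained feature(s), lambda = %.4g, objective = %.6g\n",
              length(x$retained), x$lambda, x$objective))
  invisible(x)
}
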