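#' Control parameters for iterative selection
#'
#' @param lambda `"cv"` (internal 5-fold lambda selection, the default) or a
#'   fixed nonnegative penalty, passed to [run_lasso()].
#' @param nfolds,nlambda,lambda_min_ratio Lambda-path settings for
#'   [run_lasso()].
#' @param max_iter Hard cap on the number of screen/lasso iterations
#'   (default 50); the size-based stopping rules normally trigger far
#'   earlier.
#' @param seed Optional integer seed consumed once at entry; when `NULL`
#'   the ambient RNG stream is used (this is how cross-validation drives
#'   per-fold determinism).
#' @return A named list of class-free control settings.
#' @export
isirs_control <- function(lambda = "cv", nfolds = 5, nlambda = 100,
                          lambda_min_ratio = 1e-3, max_iter = 50,
                          seed = NULL) {
  if (max_iter < 1) stop_validation("max_iter must be >= 1")
  list(lambda = lambda, nfolds = nfolds, nlambda = nlambda,
       lambda_min_ratio = lambda_min_ratio, max_iter = max_iter, seed = seed)
}

# Rank candidate indices by omega against a (possibly residual) response and
# return the top k, ties broken by ascending feature index.
screen_top <- function(x, cand, resp, k) {
  om <- omega_stat(x[, cand, drop = FALSE], resp)
  cand[order(-om, cand)][seq_len(k)]
}

#' Iterative sure independent ranking and screening (ISIRS)
#'
#' Selects up to `d` features by alternating rank-based marginal screening
#' with lasso refinement:
#' \enumerate{
#'   \item Screen: rank all features by the marginal utility statistic
#'     against the response and keep the top \eqn{K_1 = \lfloor 2d/3
#'     \rfloor} (set \eqn{A_1}); the deliberately small first screen keeps
#'     the procedure from stopping after one pass.
#'   \item Refine: lasso of the response on \eqn{A_1}; the nonzero
#'     coefficients form the retained set \eqn{M_1}.
#'   \item Iterate: fit the response on \eqn{M_s} by unpenalized least
#'     squares, take the residuals as a new response, screen the remaining
#'     features \eqn{\{1..p\} \setminus M_s} for the top
#'     \eqn{K_{s+1} = d - |M_s|} (set \eqn{A_{s+1}}), then lasso the
#'     ORIGINAL response on \eqn{A_{s+1} \cup M_s} to get \eqn{M_{s+1}}.
#'   \item Stop when \eqn{|M_s| = d}, when \eqn{|M_s| = |M_{s-1}|} (sizes,
#'     not membership), or at the iteration cap.
#' }
#' Screening on residuals is what lets features with weak marginal
#' association but strong joint effect enter the model, while re-running the
#' lasso against the original response lets marginally strong but jointly
#' unimportant features drop out.
#'
#' If a lasso step retains nothing, the event is recorded and the residual
#' falls back to the centered response; a second consecutive empty set stops
#' the iteration through the size rule.
#'
#' @param x Feature matrix (standardized internally when not already).
#' @param y Response vector aligned to `x`.
#' @param d Target number of selected features (>= 2, <= number of
#'   features).
#' @param control See [isirs_control()].
#' @return A `selection_trace` object: `final_set` (named feature indices,
#'   at most `d`), `stop_reason` (`"reached_d"`, `"size_unchanged"` or
#'   `"max_iter"`), `d`, `K1`, and `iterations`, a tibble with one row per
#'   iteration (`iteration`, `n_screened`, `n_retained`, `residual_norm`,
#'   `empty_lasso`, plus list-columns `screened` and `retained` of index
#'   sets).  Supports [tidy()].
#' @seealso [stf_select()], [sirs_select()] for the non-iterative
#'   baselines; [isirs()] for the full select-then-fit pipeline.
#' @export
isirs_select <- function(x, y, d, control = isirs_control()) {
  x <- as_feature_matrix(x)
  if (!is_standardized(x)) x <- standardize_features(x)
  y <- align_response(x, y)
  p <- ncol(x)
  if (length(d) != 1 || is.na(d) || d < 2) stop_validation("d must be >= 2")
  if (d > p) stop_validation("d (%d) exceeds the number of features (%d)", d, p)
  run <- function() isirs_select_impl(x, y, as.integer(d), control)
  if (is.null(control$seed)) run() else withr::with_seed(control$seed, run())
}

isirs_select_impl <- function(x, y, d, control) {
  p <- ncol(x)
  k1 <- max(1L, as.integer(floor(2 * d / 3)))
  m_prev <- integer(0)
  resid <- y
  iters <- list()
  stop_reason <- "max_iter"
  for (s in seq_len(control$max_iter)) {
    if (s == 1L) {
      a_s <- screen_top(x, seq_len(p), y, k1)
    } else {
      cand <- setdiff(seq_len(p), m_prev)
      a_s <- screen_top(x, cand, resid, d - length(m_prev))
    }
    pool <- sort(unique(c(a_s, m_prev)))
    lf <- run_lasso(x[, pool, drop = FALSE], y, lambda = control$lambda,
                    nfolds = control$nfolds, nlambda = control$nlambda,
                    lambda_min_ratio = control$lambda_min_ratio)
    m_s <- pool[lf$beta != 0]
    empty <- length(m_s) == 0L
    if (empty) {
      resid <- y - mean(y)
    } else {
      fit <- lm.fit(cbind(1, x[, m_s, drop = FALSE]), y)
      resid <- fit$residuals
    }
    iters[[s]] <- list(iteration = s, screened = a_s, retained = m_s,
                       residual_norm = sqrt(sum(resid^2)), empty_lasso = empty)
    if (length(m_s) == d) {
      stop_reason <- "reached_d"
      break
    }
    if (s >= 2L && length(m_s) == length(m_prev)) {
      stop_reason <- "size_unchanged"
      break
    }
    m_prev <- m_s
  }
  final <- iters[[length(iters)]]$retained
  structure(list(
    final_set = stats::setNames(final, colnames(x)[final]),
    stop_reason = stop_reason,
    d = d,
    K1 = k1,
    n_iter = length(iters),
    iterations = tibble::tibble(
      iteration = vapply(iters, `[[`, integer(1), "iteration"),
      n_screened = vapply(iters, function(i) length(i$screened), integer(1)),
      n_retained = vapply(iters, function(i) length(i$retained), integer(1)),
      residual_norm = vapply(iters, `[[`, numeric(1), "residual_norm"),
      empty_lasso = vapply(iters, `[[`, logical(1), "empty_lasso"),
      screened = lapply(iters, `[[`, "screened"),
      retained = lapply(iters, `[[`, "retained")
    )
  ), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("ISIRS selection: %d/%d features after %d iteration(s), stopped: %s\n",
              length(x$final_set), x$d, x$n_iter, x$stop_reason))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a selection trace
#'
#' @param x A `selection_trace`.
#' @param ... Unused.
#' @return Per-iteration tibble with the screened and retained set sizes and
#'   the residual norm.
#' @method tidy selection_trace
#' @export
tidy.selection_trace <- function(x, ...) {
  x$iterations[, c("iteration", "n_screened", "n_retained",
                   "residual_norm", "empty_lasso")]
}

#' Simple top features baseline (STF)
#'
#' Takes the `d` features with the largest marginal utility statistic; no
#' iteration, no lasso.  By construction it cannot recover a feature whose
#' marginal association with the response is null.
#'
#' @inheritParams isirs_select
#' @return Named integer vector of the top-`d` feature indices.
#' @export
stf_select <- function(x, y, d) {
  x <- as_feature_matrix(x)
  if (!is_standardized(x)) x <- standardize_features(x)
  y <- align_response(x, y)
  if (length(d) != 1 || is.na(d) || d < 1 || d > ncol(x)) {
    stop_validation("d must be in [1, %d]", ncol(x))
  }
  top_features(omega_scores(x, y), d)
}

#' Single-pass SIRS baseline
#'
#' One screening pass followed by one lasso refinement and no residual
#' iteration: the top-`d` features by the marginal utility statistic are
#' screened, the response is lasso-regressed on them, and the features with
#' nonzero coefficients (at most `d`) are returned in screening-rank order.
#'
#' @inheritParams isirs_select
#' @return Named integer vector of retained feature indices (subset of the
#'   top-`d` screen).
#' @export
sirs_select <- function(x, y, d, control = isirs_control()) {
  x <- as_feature_matrix(x)
  if (!is_standardized(x)) x <- standardize_features(x)
  y <- align_response(x, y)
  if (length(d) != 1 || is.na(d) || d < 1 || d > ncol(x)) {
    stop_validation("d must be in [1, %d]", ncol(x))
  }
  run <- function() {
    screened <- top_features(omega_scores(x, y), d)
    lf <- run_lasso(x[, screened, drop = FALSE], y, lambda = control$lambda,
                    nfolds = control$nfolds, nlambda = control$nlambda,
                    lambda_min_ratio = control$lambda_min_ratio)
    screened[lf$beta != 0]
  }
  if (is.null(control$seed)) run() else withr::with_seed(control$seed, run())
}

#' Fit the full ISIRS pipeline: standardize, select, and model
#'
#' Convenience wrapper running [standardize_features()], [isirs_select()]
#' and [fit_ols()] on the final set, keeping the standardization parameters
#' so that [predict()] can transform new samples consistently.
#'
#' @inheritParams isirs_select
#' @return An `isirs` object: `trace` (the [isirs_select()] result),
#'   `model` (the [fit_ols()] on the selected features), `scores` (the
#'   full-data screening scores of the selected features), `center`/`scale`
#'   standardization parameters, `d` and `control`.  Supports [predict()],
#'   [tidy()] and [glance()].
#' @examples
#' sim <- simulate_linear(n = 80, p = 30, active = 1:3, beta = 1,
#'                        sigma = 0.5, seed = 7)
#' fit <- isirs(sim$x, sim$y, d = 6, control = isirs_control(seed = 7))
#' tidy(fit)
#' @export
isirs <- function(x, y, d, control = isirs_control()) {
  x <- as_feature_matrix(x)
  y <- align_response(x, y)
  xs <- standardize_features(x)
  inner <- control
  inner$seed <- NULL
  run <- function() {
    trace <- isirs_select(xs, y, d, inner)
    sel <- trace$final_set
    model <- fit_ols(xs[, sel, drop = FALSE], y)
    sc <- omega_scores(xs, y)
    list(trace = trace, model = model,
         scores = sc[sc$index %in% sel, , drop = FALSE])
  }
  parts <- if (is.null(control$seed)) run() else withr::with_seed(control$seed, run())
  structure(c(parts, list(
    center = attr(xs, "center"),
    scale = attr(xs, "scale"),
    omics_type = attr(x, "omics_type", exact = TRUE),
    d = d,
    control = control
  )), class = "isirs")
}

#' @export
print.isirs <- function(x, ...) {
  cat(sprintf("ISIRS model: %d feature(s) (d = %d), stopped: %s, R^2 = %.4f\n",
              length(x$trace$final_set), x$d, x$trace$stop_reason,
              x$model$r_squared))
  print(tidy(x), ...)
  invisible(x)
}

#' Predict drug response from a fitted ISIRS pipeline
#'
#' New samples are standardized with the training center/scale before the
#' linear model is applied.
#'
#' @param object An `isirs` fit.
#' @param newdata Matrix or data frame of raw (unstandardized) features
#'   containing every selected feature.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.isirs <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  feats <- object$model$features
  miss <- setdiff(feats, colnames(newdata))
  if (length(miss)) {
    stop_validation("newdata is missing selected feature(s): %s",
                    paste(miss, collapse = ", "))
  }
  if (length(feats) == 0) {
    return(stats::setNames(rep(object$model$intercept, nrow(newdata)),
                           rownames(newdata)))
  }
  xs <- standardize_features(newdata[, feats, drop = FALSE],
                             center = object$center[feats],
                             scale = object$scale[feats])
  predict(object$model, xs)
}

#' Tidy an ISIRS fit
#'
#' @param x An `isirs` fit.
#' @param ... Unused.
#' @return Coefficient table of the final OLS model joined with each
#'   selected feature's screening score and rank (`omega`, `screen_rank`).
#' @method tidy isirs
#' @export
tidy.isirs <- function(x, ...) {
  co <- tidy(x$model)
  sc <- tibble::tibble(term = x$scores$feature, omega = x$scores$omega,
                       screen_rank = x$scores$rank)
  dplyr::left_join(co, sc, by = "term")
}

#' Glance at an ISIRS fit
#'
#' @param x An `isirs` fit.
#' @param ... Unused.
#' @return One-row tibble with the selected-set size, target `d`, stopping
#'   reason, iteration count and in-sample R-squared.
#' @method glance isirs
#' @export
glance.isirs <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$trace$final_set),
    d = x$d,
    stop_reason = x$trace$stop_reason,
    n_iter = x$trace$n_iter,
    r.squared = x$model$r_squared,
    n_significant = length(x$model$significant)
  )
}
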