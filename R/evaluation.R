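#' Pearson correlation between predictions and observations
#'
#' @param pred,true Numeric vectors of equal length (>= 3), neither
#'   constant.
#' @return The Pearson correlation coefficient in \[-1, 1\].
#' @export
pcc <- function(pred, true) {
  if (length(pred) != length(true)) stop_validation("pred and true differ in length")
  if (length(pred) < 3) stop_validation("correlation needs at least 3 values")
  if (stats::sd(pred) == 0 || stats::sd(true) == 0) {
    stop_validation("correlation undefined for a constant vector")
  }
  cor(pred, true)
}

#' Mean squared error
#'
#' @param pred,true Numeric vectors of equal length.
#' @return Mean of squared differences.
#' @export
mse <- function(pred, true) {
  if (length(pred) != length(true)) stop_validation("pred and true differ in length")
  if (length(pred) < 1) stop_validation("mse needs at least 1 value")
  mean((pred - true)^2)
}

# Near-equal random fold assignment: permute samples, chunk contiguously.
make_folds <- function(n, folds) {
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fa <- integer(n)
  fa[sample.int(n)] <- rep.int(seq_len(folds), sizes)
  fa
}

# Drop columns of X that are collinear with the preceding ones (QR pivots).
drop_collinear <- function(xsel) {
  qx <- qr(cbind(1, xsel))
  if (qx$rank == ncol(xsel) + 1L) return(seq_len(ncol(xsel)))
  piv <- qx$pivot[seq_len(qx$rank)]
  sort(piv[piv > 1L] - 1L)
}

# Train on (xtr, ytr), predict xte.  Standardization, screening, selection
# and model fitting all happen on the training samples only; the held-out
# samples are transformed with the training parameters.  Constant training
# columns are excluded from candidacy for that fold.
fit_and_predict <- function(xtr, ytr, xte, method, d, control) {
  ctr <- colMeans(xtr)
  xc <- sweep(xtr, 2L, ctr, "-")
  scl <- sqrt(colMeans(xc * xc))
  keep <- scl > (abs(ctr) + 1) * 1e-12
  xs <- standardize_features(xtr[, keep, drop = FALSE])
  d_eff <- min(d, ncol(xs))
  sel <- switch(method,
    isirs = isirs_select(xs, ytr, max(2L, d_eff), control)$final_set,
    stf = stf_select(xs, ytr, d_eff),
    sirs = sirs_select(xs, ytr, d_eff, control),
    pcc_screen = top_features(pcc_scores(xs, ytr), d_eff)
  )
  if (length(sel) == 0) {
    return(rep(mean(ytr), nrow(xte)))
  }
  if (length(sel) >= nrow(xs) - 1) sel <- sel[seq_len(nrow(xs) - 2L)]
  ok <- drop_collinear(xs[, sel, drop = FALSE])
  sel <- sel[ok]
  model <- fit_ols(xs[, sel, drop = FALSE], ytr)
  feats <- colnames(xs)[sel]
  xte_s <- standardize_features(xte[, feats, drop = FALSE],
                                center = attr(xs, "center")[feats],
                                scale = attr(xs, "scale")[feats])
  unname(predict(model, xte_s))
}

#' Cross-validated prediction assessment
#'
#' Repeated 10-fold (by default) cross-validation of the full
#' select-then-predict pipeline.  In every fold the nine training folds are
#' standardized, screened, selected and fit from scratch; the held-out fold
#' is transformed with the training standardization and predicted, so no
#' information from held-out responses reaches the model.  Out-of-fold
#' predictions are averaged across repeats and the Pearson correlation and
#' mean squared error of the averaged predictions against the observed
#' response are reported.
#'
#' Every (repeat, fold) model fit consumes its own seed derived
#' deterministically from `seed`, so reports are bit-identical across runs
#' and each sample's out-of-fold prediction depends only on the other
#' samples.
#'
#' @param x Feature matrix (raw scale; standardization happens per training
#'   fold).
#' @param y Response vector aligned to `x`.
#' @param method One of `"isirs"`, `"stf"`, `"sirs"`, `"pcc_screen"`.
#' @param d Target number of selected features.
#' @param folds Number of folds (default 10).
#' @param repeats Number of independent fold partitions to average over.
#' @param seed Integer seed governing all partitions and internal lambda
#'   cross-validations.
#' @param control See [isirs_control()]; its `seed` field is ignored here.
#' @return A `cv_report`: `method`, `d`, `folds`, `repeats`, `seed`,
#'   `pcc`, `mse`, `predictions` (tibble of per-sample observed and averaged
#'   out-of-fold predicted values) and `fold_assignments` (samples x repeats
#'   matrix).  Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' sim <- simulate_linear(n = 60, p = 20, active = 1:3, beta = 1,
#'                        sigma = 0.5, seed = 1)
#' rep <- cross_validate(sim$x, sim$y, method = "stf", d = 4, seed = 1)
#' glance(rep)
#' @export
cross_validate <- function(x, y, method = c("isirs", "stf", "sirs", "pcc_screen"),
                           d, folds = 10, repeats = 1, seed = 1,
                           control = isirs_control()) {
  method <- match.arg(method)
  x <- as_feature_matrix(x)
  y <- align_response(x, y)
  n <- nrow(x)
  if (n < 2 * folds) stop_validation("need at least %d samples for %d folds", 2 * folds, folds)
  if (d > ncol(x)) stop_validation("d (%d) exceeds the number of features (%d)", d, ncol(x))
  control$seed <- NULL
  preds <- matrix(NA_real_, n, repeats)
  assign <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    fa <- withr::with_seed(derive_seed(seed, r), make_folds(n, folds))
    assign[, r] <- fa
    for (f in seq_len(folds)) {
      te <- fa == f
      preds[te, r] <- withr::with_seed(
        derive_seed(seed, r, f),
        fit_and_predict(x[!te, , drop = FALSE], y[!te],
                        x[te, , drop = FALSE], method, d, control)
      )
    }
  }
  pred_avg <- rowMeans(preds)
  p_hat <- tryCatch(pcc(pred_avg, unname(y)), error = function(e) NA_real_)
  structure(list(
    method = method, d = d, folds = folds, repeats = repeats, seed = seed,
    pcc = p_hat,
    mse = mse(pred_avg, unname(y)),
    predictions = tibble::tibble(sample = rownames(x), observed = unname(y),
                                 predicted = pred_avg),
    fold_assignments = assign
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (%d repeat(s)) of %s at d = %d: PCC = %.4f, MSE = %.4f\n",
              x$folds, x$repeats, x$method, x$d, x$pcc, x$mse))
  invisible(x)
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Per-sample tibble of observed and averaged out-of-fold predicted
#'   responses.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$predictions

#' Glance at a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `d`, `folds`, `repeats`, `pcc`, `mse`,
#'   `seed`.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(method = x$method, d = x$d, folds = x$folds,
                 repeats = x$repeats, pcc = x$pcc, mse = x$mse, seed = x$seed)
}

#' Tune the number of selected features over a grid
#'
#' Runs [cross_validate()] for every grid value of `d` (the same seed is
#' used throughout, so all grid points see identical fold partitions) and
#' picks the `d` with the largest cross-validated Pearson correlation,
#' breaking ties toward the smallest `d`.  The default grid is the even
#' sequence 2, 4, ..., 50.
#'
#' @inheritParams cross_validate
#' @param d_grid Candidate values of `d`; all must be below the sample
#'   count.
#' @return A `d_selection`: `best_d`, `table` (tibble of `d`, `pcc`, `mse`),
#'   plus the settings used.  Supports [tidy()] and [autoplot()].
#' @export
select_d <- function(x, y, method = c("isirs", "stf", "sirs", "pcc_screen"),
                     d_grid = seq(2, 50, by = 2), folds = 10, repeats = 10,
                     seed = 1, control = isirs_control()) {
  method <- match.arg(method)
  x <- as_feature_matrix(x)
  y <- align_response(x, y)
  if (length(d_grid) == 0) stop_validation("empty d grid")
  if (max(d_grid) >= nrow(x)) {
    stop_validation("max of d grid (%d) must be below the sample count (%d)",
                    max(d_grid), nrow(x))
  }
  tab <- purrr::map_dfr(d_grid, function(d) {
    r <- cross_validate(x, y, method = method, d = d, folds = folds,
                        repeats = repeats, seed = seed, control = control)
    tibble::tibble(d = d, pcc = r$pcc, mse = r$mse)
  })
  best <- tab$d[order(-tab$pcc, tab$d)][1]
  structure(list(best_d = best, table = tab, method = method, folds = folds,
                 repeats = repeats, seed = seed), class = "d_selection")
}

#' @export
print.d_selection <- function(x, ...) {
  cat(sprintf("d tuning (%s, %d-fold CV x %d): best d = %d\n",
              x$method, x$folds, x$repeats, x$best_d))
  print(x$table, ...)
  invisible(x)
}

#' Tidy a d-tuning result
#'
#' @param x A `d_selection`.
#' @param ... Unused.
#' @return The per-grid-point tibble of `d`, `pcc`, `mse`.
#' @method tidy d_selection
#' @export
tidy.d_selection <- function(x, ...) x$table
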