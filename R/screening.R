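#' Standardize feature columns to zero mean and unit mean square
#'
#' Centers and scales every feature so that the per-column sample mean is 0
#' and the per-column mean square is 1, using the population (1/n)
#' convention: after the transform, `mean(x[, k]) == 0` and
#' `mean(x[, k]^2) == 1` for every column `k`.  This is the scaling the
#' marginal utility statistic [omega_scores()] assumes.
#'
#' When `center` and `scale` are supplied (named vectors from a previous
#' standardization, available as attributes of the returned matrix), they are
#' applied as-is; this is how held-out samples are transformed with training
#' parameters during cross-validation.
#'
#' @param x Feature matrix or data frame (samples x features).
#' @param center,scale Optional named numeric vectors of per-feature centers
#'   and scales to apply instead of computing them from `x`.
#' @return The standardized numeric matrix with attributes `standardized`
#'   (TRUE), `center` and `scale`.
#' @examples
#' x <- matrix(c(1, 3, 2, 8), 2, 2, dimnames = list(NULL, c("a", "b")))
#' xs <- standardize_features(x)
#' colMeans(xs)       # 0 0
#' colMeans(xs^2)     # 1 1
#' @export
standardize_features <- function(x, center = NULL, scale = NULL) {
  x <- as_feature_matrix(x)
  if (is.null(center)) {
    if (nrow(x) < 2) stop_validation("standardization needs at least 2 samples")
    center <- colMeans(x)
    xc <- sweep(x, 2L, center, "-")
    scale <- sqrt(colMeans(xc * xc))
    const <- scale <= (abs(center) + 1) * 1e-12
    if (any(const)) {
      stop_validation("constant feature column(s), zero scale is undefined: %s",
                      paste(colnames(x)[const], collapse = ", "))
    }
    out <- sweep(xc, 2L, scale, "/")
  } else {
    if (is.null(scale)) stop_validation("supply both center and scale, or neither")
    miss <- setdiff(colnames(x), names(center))
    if (length(miss)) {
      stop_validation("no standardization parameters for feature(s): %s",
                      paste(miss, collapse = ", "))
    }
    out <- sweep(sweep(x, 2L, center[colnames(x)], "-"), 2L,
                 scale[colnames(x)], "/")
    center <- center[colnames(x)]
    scale <- scale[colnames(x)]
  }
  attr(out, "omics_type") <- attr(x, "omics_type", exact = TRUE)
  attr(out, "standardized") <- TRUE
  attr(out, "center") <- stats::setNames(as.numeric(center), colnames(x))
  attr(out, "scale") <- stats::setNames(as.numeric(scale), colnames(x))
  out
}

# Core SIRS statistic.  For each feature k,
#   omega_k = (1/n) sum_j { (1/n) sum_i X_ik * I(Y_i < Y_j) }^2 ,
# computed in O(n log n + n p) by sorting Y once and taking prefix sums of
# the feature columns; ties in Y share the same strict-inequality prefix.
omega_stat <- function(x, y) {
  n <- nrow(x)
  o <- order(y)
  xs <- x[o, , drop = FALSE]
  ys <- y[o]
  cum <- apply(xs, 2L, cumsum)
  if (!is.matrix(cum)) cum <- matrix(cum, nrow = n)
  first <- !duplicated(ys)
  grp_start <- which(first)
  grp <- cumsum(first)
  prev_end <- grp_start[grp] - 1L # last sorted index strictly below each value
  s <- matrix(0, n, ncol(x))
  has <- prev_end > 0L
  if (any(has)) s[has, ] <- cum[prev_end[has], , drop = FALSE]
  colSums(s * s) / n^3
}

new_screening_scores <- function(features, omega, method) {
  ord <- order(-omega, seq_along(omega))
  rnk <- integer(length(omega))
  rnk[ord] <- seq_along(omega)
  out <- tibble::tibble(
    feature = features,
    index = seq_along(omega),
    omega = as.numeric(omega),
    rank = rnk
  )
  class(out) <- c("screening_scores", class(out))
  attr(out, "method") <- method
  out
}

#' Marginal utility screening scores (SIRS)
#'
#' Computes the rank-based marginal utility statistic for every feature:
#' \deqn{\hat\omega_k = \frac{1}{n}\sum_{j=1}^n\Big\{\frac{1}{n}
#'   \sum_{i=1}^n X_{ik}\, I(Y_i < Y_j)\Big\}^2,}
#' a sample functional of the conditional distribution of the response given
#' the feature.  Large values indicate that the distribution of `y` depends
#' on the feature.  The statistic depends on `y` only through its ranks, so
#' it is invariant to monotone transforms of the response and robust to
#' response outliers.  The indicator is strict, so tied responses contribute
#' zero; with standardized features the statistic lies in \[0, 1\].
#'
#' @param x Standardized feature matrix (see [standardize_features()]).
#' @param y Response: numeric vector aligned to the rows of `x` (named
#'   vectors are matched by sample id), or a two-column data frame of
#'   sample id and value.
#' @return A `screening_scores` tibble with columns `feature`, `index`,
#'   `omega` and `rank` (1 = largest omega; ties broken by ascending feature
#'   index), one row per feature in input order.
#' @examples
#' x <- standardize_features(matrix(c(1, 3), 2, 1))
#' omega_scores(x, c(1, 2))$omega # 0.125
#' @seealso [pcc_scores()] for the correlation-screening baseline,
#'   [top_features()] to extract the leading features.
#' @export
omega_scores <- function(x, y) {
  x <- as_feature_matrix(x)
  if (!is_standardized(x)) {
    stop_validation("features must be standardized first; see standardize_features()")
  }
  y <- align_response(x, y)
  if (nrow(x) < 2) stop_validation("screening needs at least 2 samples")
  new_screening_scores(colnames(x), omega_stat(x, y), "sirs")
}

#' Absolute Pearson correlation screening scores
#'
#' The correlation-screening baseline: each feature is scored by the
#' absolute Pearson correlation between the feature and the response.
#' The absolute value is taken because screening cares about the strength
#' of the marginal association, not its sign.
#'
#' @inheritParams omega_scores
#' @return A `screening_scores` tibble as in [omega_scores()], with `omega`
#'   holding absolute correlations.
#' @export
pcc_scores <- function(x, y) {
  x <- as_feature_matrix(x)
  if (!is_standardized(x)) {
    stop_validation("features must be standardized first; see standardize_features()")
  }
  y <- align_response(x, y)
  if (nrow(x) < 3) stop_validation("correlation screening needs at least 3 samples")
  if (stats::sd(y) == 0) stop_validation("response is constant; correlation undefined")
  r <- abs(drop(cor(x, y)))
  new_screening_scores(colnames(x), r, "pcc")
}

#' Top-ranked features from a screening
#'
#' @param scores A `screening_scores` tibble.
#' @param top_k Number of features to keep, between 1 and the number of
#'   features scored.
#' @return A named integer vector of feature indices (into the screened
#'   matrix), in descending score order; ties broken by ascending index.
#' @examples
#' sc <- isirs:::new_screening_scores(c("a", "b", "c"), c(0.3, 0.1, 0.2), "sirs")
#' top_features(sc, 2) # a = 1, c = 3
#' @export
top_features <- function(scores, top_k) {
  if (!inherits(scores, "screening_scores")) {
    stop_validation("scores must come from omega_scores() or pcc_scores()")
  }
  p <- nrow(scores)
  if (length(top_k) != 1 || is.na(top_k) || top_k < 1 || top_k > p) {
    stop_validation("top_k must be in [1, %d]", p)
  }
  ord <- order(scores$rank)
  idx <- scores$index[ord][seq_len(top_k)]
  stats::setNames(idx, scores$feature[ord][seq_len(top_k)])
}
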