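#' Mean redundancy score by absolute Pearson correlation
#'
#' Mean over all unordered pairs of selected features of the absolute
#' Pearson correlation between the pair.  Values near 0 indicate a
#' non-redundant selection; anticorrelated pairs count as redundant.
#'
#' @param x Feature matrix restricted to the selected features (>= 2
#'   columns, none constant).
#' @return Mean pairwise absolute correlation in \[0, 1\].
#' @export
mean_redundancy_pcc <- function(x) {
  x <- as_feature_matrix(x)
  if (ncol(x) < 2) stop_validation("redundancy needs at least 2 features")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_validation("constant feature column(s): %s",
                    paste(colnames(x)[sds == 0], collapse = ", "))
  }
  cm <- abs(cor(x))
  mean(cm[upper.tri(cm)])
}

# Equal-width binning of one column over its observed range.
bin_column <- function(v, bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  br <- seq(r[1], r[2], length.out = bins + 1)
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

# Plug-in mutual information (nats) of two binned columns from their joint
# histogram.
pair_mi <- function(a, b) {
  pj <- table(a, b) / length(a)
  pr <- rowSums(pj)
  pc <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pr, pc)[nz]))
}

#' Mean redundancy score by mutual information
#'
#' Each feature is discretized into `bins` equal-width bins over its range;
#' pairwise mutual information (in nats) is estimated by the plug-in joint
#' histogram and averaged over all unordered pairs.  The plug-in estimator
#' carries a small positive bias of roughly `(bins - 1)^2 / (2n)` nats for
#' independent features.
#'
#' @param x Feature matrix restricted to the selected features (>= 2
#'   columns).
#' @param bins Number of equal-width bins per feature (default 10).
#' @return Mean pairwise mutual information, nonnegative.
#' @export
mean_redundancy_mi <- function(x, bins = 10) {
  x <- as_feature_matrix(x)
  if (ncol(x) < 2) stop_validation("redundancy needs at least 2 features")
  if (bins < 2) stop_validation("bins must be >= 2")
  binned <- lapply(seq_len(ncol(x)), function(k) bin_column(x[, k], bins))
  pairs <- utils::combn(ncol(x), 2)
  mean(apply(pairs, 2L, function(pr) pair_mi(binned[[pr[1]]], binned[[pr[2]]])))
}

#' Redundancy report for a selected feature set
#'
#' @param x Feature matrix restricted to the selected features.
#' @param bins Bins for the mutual-information estimate.
#' @return One-row tibble: `mrs_pcc`, `mrs_mi`, `n_features`, `bins`.
#' @export
redundancy_report <- function(x, bins = 10) {
  x <- as_feature_matrix(x)
  tibble::tibble(
    mrs_pcc = mean_redundancy_pcc(x),
    mrs_mi = mean_redundancy_mi(x, bins = bins),
    n_features = ncol(x),
    bins = as.integer(bins)
  )
}

#' Sample skewness
#'
#' Third standardized moment with population (1/n) moments:
#' `m3 / m2^(3/2)`.  Drug-response distributions far from symmetric tend to
#' degrade least-squares prediction, which is why skewness is reported
#' alongside MSE comparisons.
#'
#' @param values Numeric vector, length >= 3, non-constant.
#' @return Sample skewness (sign-equivariant under affine maps).
#' @examples
#' skewness(c(-1, 0, 1)) # 0
#' @export
skewness <- function(values) {
  if (length(values) < 3) stop_validation("skewness needs at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop_validation("skewness undefined for a constant vector")
  mean((values - m)^3) / m2^1.5
}
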