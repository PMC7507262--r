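# Internal validation helpers. Validation failures and numerical failures
# carry distinct condition classes so the command-line wrapper can map them
# to exit codes (2 and 3 respectively).

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "isirs_validation_error")
}

stop_numerical <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "isirs_numerical_error")
}

#' Coerce input to a validated feature matrix
#'
#' Accepts a numeric matrix or a data frame (optionally with a leading
#' character column of sample identifiers) and returns a numeric
#' samples-by-features matrix with unique row and column names and no
#' missing or non-finite values.
#'
#' @param x A numeric matrix or data frame, samples as rows, features as
#'   columns.
#' @return A numeric matrix with `rownames` (sample ids) and `colnames`
#'   (feature ids).  Attributes `omics_type`, `standardized`, `center` and
#'   `scale` are preserved when present.
#' @export
as_feature_matrix <- function(x) {
  omics <- attr(x, "omics_type", exact = TRUE)
  std <- attr(x, "standardized", exact = TRUE)
  ctr <- attr(x, "center", exact = TRUE)
  scl <- attr(x, "scale", exact = TRUE)
  if (is.data.frame(x)) {
    rn <- rownames(x)
    if (ncol(x) >= 2 && (is.character(x[[1]]) || is.factor(x[[1]]))) {
      rn <- as.character(x[[1]])
      x <- x[, -1, drop = FALSE]
    }
    num <- vapply(x, is.numeric, logical(1))
    if (!all(num)) {
      stop_validation("non-numeric feature column(s): %s",
                      paste(names(x)[!num], collapse = ", "))
    }
    nm <- names(x)
    x <- as.matrix(x)
    colnames(x) <- nm
    if (!is.null(rn) && !all(rn == as.character(seq_len(nrow(x))))) {
      rownames(x) <- rn
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_validation("feature input must be a numeric matrix or data frame")
  }
  if (is.null(colnames(x)) && ncol(x) > 0) {
    colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  }
  if (is.null(rownames(x)) && nrow(x) > 0) {
    rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  }
  if (anyDuplicated(colnames(x))) {
    stop_validation("duplicated feature id(s): %s",
                    paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (anyDuplicated(rownames(x))) {
    stop_validation("duplicated sample id(s): %s",
                    paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop_validation("missing or non-finite value at sample '%s', feature '%s'",
                    rownames(x)[bad[1]], colnames(x)[bad[2]])
  }
  if (!is.null(omics)) attr(x, "omics_type") <- omics
  if (!is.null(std)) attr(x, "standardized") <- std
  if (!is.null(ctr)) attr(x, "center") <- ctr
  if (!is.null(scl)) attr(x, "scale") <- scl
  x
}

# Align a response (numeric vector, optionally named, or a two-column data
# frame of sample id + value) against the rows of a feature matrix.
align_response <- function(x, y) {
  if (is.data.frame(y)) {
    if (ncol(y) < 2) stop_validation("response data frame needs id and value columns")
    y <- stats::setNames(as.numeric(y[[2]]), as.character(y[[1]]))
  }
  if (!is.numeric(y)) stop_validation("response must be numeric")
  if (!is.null(names(y))) {
    if (!setequal(names(y), rownames(x)) || length(y) != nrow(x)) {
      stop_validation("response sample ids do not match the feature matrix (use align_samples() to intersect)")
    }
    y <- y[rownames(x)]
  } else if (length(y) != nrow(x)) {
    stop_validation("response length (%d) does not match sample count (%d)",
                    length(y), nrow(x))
  }
  if (anyNA(y) || any(!is.finite(y))) {
    stop_validation("response contains missing or non-finite values")
  }
  stats::setNames(as.numeric(y), rownames(x))
}

is_standardized <- function(x) isTRUE(attr(x, "standardized", exact = TRUE))

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.double(seed) + 1009 * a + 7919 * b) %% 2147483647)
}
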