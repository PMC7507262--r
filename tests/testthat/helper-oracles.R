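# Independent oracles used across tests.  These deliberately use naive
# formulations (double loops, direct moment sums, textbook normal
# equations) so they share no code path with the package implementations.

# Naive O(n^2 p) evaluation of the marginal utility statistic.
omega_oracle <- function(x, y) {
  n <- nrow(x)
  vapply(seq_len(ncol(x)), function(k) {
    tot <- 0
    for (j in seq_len(n)) {
      inner <- 0
      for (i in seq_len(n)) {
        inner <- inner + x[i, k] * as.numeric(y[i] < y[j])
      }
      tot <- tot + (inner / n)^2
    }
    tot / n
  }, numeric(1))
}

# Lasso objective evaluated directly.
objective_oracle <- function(x, y, b0, beta, lambda) {
  sum((y - b0 - drop(x %*% beta))^2) + lambda * sum(abs(beta))
}

# Mutual information of two discrete vectors via entropies,
# I(A;B) = H(A) + H(B) - H(A,B), in nats.
mi_entropy_oracle <- function(a, b) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  ent(a) + ent(b) - ent(paste(a, b))
}

# Random standardized feature matrix.
random_standardized <- function(n, p) {
  standardize_features(matrix(rnorm(n * p), n, p))
}

# Orthogonal standardized design: columns orthogonal to each other and to
# the intercept, each with mean 0 and mean square 1.
orthogonal_design <- function(n, m) {
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (m + 1)), n, m + 1))))[, 2:(m + 1)]
  x <- sqrt(n) * q
  colnames(x) <- paste0("f", seq_len(m))
  attr(x, "standardized") <- TRUE
  x
}
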