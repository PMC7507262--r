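name_xy <- function(x, y) {
  dimnames(x) <- list(paste0("sample_", seq_len(nrow(x))),
                      paste0("feature_", seq_len(ncol(x))))
  names(y) <- rownames(x)
  list(x = x, y = y)
}

#' Simulate a sparse linear drug-response scenario
#'
#' Generates `n` samples of `p` features, iid standard normal (or
#' equicorrelated at `rho` through a shared latent factor), and a response
#' `Y = sum_{k in active} beta_k X_k + eps`, `eps ~ N(0, sigma^2)`.
#' Generation is a pure function of the arguments including `seed`.
#'
#' @param n,p Sample and feature counts.
#' @param active Indices of the active features (default first 5).
#' @param beta Coefficient(s) for the active features, recycled to
#'   `length(active)`.
#' @param rho Pairwise feature correlation in \[0, 1).
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with `x` (feature matrix), `y` (named response) and `truth`
#'   (`active`, named `beta`, `rho`, `sigma`).
#' @export
simulate_linear <- function(n, p, active = 1:5, beta = 1, rho = 0,
                            sigma = 1, seed = 1) {
  if (length(active) && (min(active) < 1 || max(active) > p)) {
    stop_validation("active indices must lie in [1, %d]", p)
  }
  if (sigma < 0) stop_validation("sigma must be >= 0")
  if (rho < 0 || rho >= 1) stop_validation("rho must be in [0, 1)")
  b <- rep_len(beta, length(active))
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    if (rho > 0) x <- sqrt(1 - rho) * x + sqrt(rho) * rnorm(n)
    y <- drop(x[, active, drop = FALSE] %*% b) + sigma * rnorm(n)
  })
  out <- name_xy(x, y)
  out$truth <- list(active = as.integer(active),
                    beta = stats::setNames(b, colnames(out$x)[active]),
                    rho = rho, sigma = sigma)
  out
}

#' Simulate the hidden-predictor scenario
#'
#' Constructs a feature that is exactly uncorrelated with the response yet
#' jointly essential — the situation marginal screening cannot handle and
#' iterative screening exists to recover.  With latent iid N(0, 1) variables
#' `Z_1..Z_p`:
#' \deqn{X_j = Z_j \ (j \ne 4), \quad
#'   X_4 = \sqrt{\rho}\,(Z_1+Z_2+Z_3)/\sqrt{3} + \sqrt{1-\rho}\,Z_4,}
#' \deqn{Y = \beta (X_1+X_2+X_3) - \beta\sqrt{3\rho}\, X_4 + \epsilon.}
#' The coefficient on `X_4` makes `cov(X_4, Y) = 0` exactly, while
#' `cov(X_1, Y) = beta (1 - rho)`, so features 1-3 are marginally visible
#' and feature 4 is not.
#'
#' @param n,p Sample and feature counts (`p >= 4`).
#' @param beta Signal strength of the visible features.
#' @param rho Mixing weight in (0, 1).
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @return List with `x`, `y` and `truth` (`active = 1:4`, `hidden = 4`,
#'   the coefficient vector, `rho`, `sigma`).
#' @export
simulate_hidden_predictor <- function(n, p, beta = 2, rho = 0.5, sigma = 1,
                                      seed = 1) {
  if (p < 4) stop_validation("hidden-predictor scenario needs p >= 4")
  if (rho <= 0 || rho >= 1) stop_validation("rho must be in (0, 1)")
  if (sigma < 0) stop_validation("sigma must be >= 0")
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * p), n, p)
    x <- z
    x[, 4] <- sqrt(rho) * (z[, 1] + z[, 2] + z[, 3]) / sqrt(3) +
      sqrt(1 - rho) * z[, 4]
    y <- beta * (x[, 1] + x[, 2] + x[, 3]) - beta * sqrt(3 * rho) * x[, 4] +
      sigma * rnorm(n)
  })
  out <- name_xy(x, y)
  out$truth <- list(
    active = 1:4, hidden = 4L,
    beta = stats::setNames(c(beta, beta, beta, -beta * sqrt(3 * rho)),
                           colnames(out$x)[1:4]),
    rho = rho, sigma = sigma
  )
  out
}

#' Simulate a multi-omics-like feature matrix
#'
#' Emulates the structure of an integrated cancer cell line feature vector
#' at reduced scale: continuous Gaussian expression features, binary
#' mutation-status features with a given prevalence, and integer copy-number
#' features in \{-2, ..., 2\}.  Columns that come out constant (possible at
#' small `n` or extreme prevalence) are regenerated up to 10 times before
#' erroring, so the output always standardizes cleanly.
#'
#' @param n Samples.
#' @param p_expr,p_mut,p_cna Feature counts per omics type.
#' @param mutation_prevalence Bernoulli rate of the mutation features, in
#'   (0, 1).
#' @param seed Integer seed.
#' @return Feature matrix with an `omics_type` attribute (per-column labels
#'   `"expression"`, `"mutation"`, `"copy_number"`).
#' @export
simulate_multiomics <- function(n, p_expr, p_mut, p_cna,
                                mutation_prevalence = 0.1, seed = 1) {
  if (min(p_expr, p_mut, p_cna) < 1) stop_validation("feature counts must be positive")
  if (mutation_prevalence <= 0 || mutation_prevalence >= 1) {
    stop_validation("mutation_prevalence must be in (0, 1)")
  }
  gen_until_varying <- function(draw, what) {
    for (attempt in 1:10) {
      v <- draw()
      if (length(unique(v)) > 1) return(v)
    }
    stop_validation("could not generate a non-constant %s column in 10 attempts", what)
  }
  withr::with_seed(seed, {
    expr <- matrix(rnorm(n * p_expr), n, p_expr)
    mut <- vapply(seq_len(p_mut), function(k) {
      gen_until_varying(function() rbinom(n, 1, mutation_prevalence), "mutation")
    }, numeric(n))
    cna <- vapply(seq_len(p_cna), function(k) {
      gen_until_varying(function() {
        sample(-2:2, n, replace = TRUE, prob = c(0.05, 0.2, 0.5, 0.2, 0.05))
      }, "copy-number")
    }, numeric(n))
  })
  x <- cbind(expr, mut, cna)
  dimnames(x) <- list(
    paste0("sample_", seq_len(n)),
    c(paste0("expr_", seq_len(p_expr)), paste0("mut_", seq_len(p_mut)),
      paste0("cna_", seq_len(p_cna)))
  )
  attr(x, "omics_type") <- stats::setNames(
    rep(c("expression", "mutation", "copy_number"), c(p_expr, p_mut, p_cna)),
    colnames(x)
  )
  x
}
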