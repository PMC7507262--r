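test_that("standardization gives zero mean and unit mean square (1/n convention)", {
  x <- matrix(c(1, 3), 2, 1)
  xs <- standardize_features(x)
  expect_equal(as.numeric(xs), c(-1, 1))

  set.seed(11)
  x <- matrix(rnorm(100 * 7, mean = 3, sd = 5), 100, 7)
  xs <- standardize_features(x)
  expect_true(all(abs(colMeans(xs)) < 1e-10))
  expect_true(all(abs(colMeans(xs^2) - 1) < 1e-10))
  expect_true(is.matrix(x) && !isTRUE(attr(x, "standardized"))) # input untouched
})

test_that("constant columns are rejected by name", {
  x <- cbind(a = c(5, 5, 5), b = c(1, 2, 3))
  expect_error(standardize_features(x), "a", class = "isirs_validation_error")
})

test_that("stored center/scale reproduce the training transform on new data", {
  set.seed(2)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  xs <- standardize_features(x)
  again <- standardize_features(x, center = attr(xs, "center"),
                                scale = attr(xs, "scale"))
  expect_equal(unname(again[, ]), unname(xs[, ]))
})

test_that("omega matches hand-computed values and the brute-force oracle", {
  x1 <- standardize_features(matrix(c(1, 3), 2, 1))
  expect_equal(omega_scores(x1, c(1, 2))$omega, 0.125)
  expect_equal(omega_oracle(x1, c(1, 2)), 0.125)

  x2 <- matrix(c(-sqrt(1.5), 0, sqrt(1.5)), 3, 1)
  attr(x2, "standardized") <- TRUE
  expect_equal(omega_scores(x2, c(1, 2, 3))$omega, 1 / 9)
  expect_equal(omega_oracle(x2, c(1, 2, 3)), 1 / 9)
})

test_that("vectorized omega equals the double-loop oracle on random inputs with ties", {
  set.seed(101)
  worst <- 0
  for (r in 1:40) {
    n <- sample(3:50, 1)
    p <- sample(1:20, 1)
    xs <- random_standardized(n, p)
    y <- if (r %% 3 == 0) sample(1:4, n, replace = TRUE) else rnorm(n)
    worst <- max(worst, max(abs(omega_scores(xs, y)$omega - omega_oracle(xs, y))))
  }
  expect_lt(worst, 1e-12)
})

test_that("omega depends on the response only through its ranks", {
  set.seed(7)
  xs <- random_standardized(30, 6)
  y <- rnorm(30)
  base <- omega_scores(xs, y)$omega
  expect_equal(omega_scores(xs, exp(y))$omega, base, tolerance = 1e-13)
  expect_equal(omega_scores(xs, 3 * y + 10)$omega, base, tolerance = 1e-13)
  expect_equal(omega_scores(xs, y^3)$omega, base, tolerance = 1e-13)
  # scale invariance of the printed example
  x1 <- standardize_features(matrix(c(1, 3), 2, 1))
  expect_equal(omega_scores(x1, c(10, 20))$omega, 0.125)
})

test_that("omega is permutation-equivariant, bounded in [0,1], and zero under a constant response", {
  set.seed(21)
  for (r in 1:10) {
    xs <- random_standardized(25, 5)
    y <- rnorm(25)
    om <- omega_scores(xs, y)$omega
    expect_true(all(om >= 0 & om <= 1))
    perm <- sample(25)
    xp <- xs[perm, , drop = FALSE]
    attr(xp, "standardized") <- TRUE
    expect_equal(omega_scores(xp, y[perm])$omega, om, tolerance = 1e-13)
  }
  xs <- random_standardized(15, 3)
  expect_equal(omega_scores(xs, rep(2, 15))$omega, rep(0, 3))
})

test_that("omega requires standardized, aligned inputs", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(omega_scores(x, rnorm(10)), "standardized",
               class = "isirs_validation_error")
  xs <- random_standardized(10, 2)
  expect_error(omega_scores(xs, rnorm(9)), class = "isirs_validation_error")
  ybad <- stats::setNames(rnorm(10), paste0("other_", 1:10))
  expect_error(omega_scores(xs, ybad), class = "isirs_validation_error")
})

test_that("pcc screening scores self-correlation 1 and independent features near 0", {
  set.seed(5)
  n <- 10000
  y <- rnorm(n)
  x <- cbind(self = y, anti = -y, indep = rnorm(n))
  xs <- standardize_features(x)
  sc <- pcc_scores(xs, y)
  expect_equal(sc$omega[1], 1, tolerance = 1e-12)
  expect_equal(sc$omega[2], 1, tolerance = 1e-12) # absolute value by design
  expect_lt(sc$omega[3], 0.05)
  expect_error(pcc_scores(xs, rep(1, n)), class = "isirs_validation_error")
})

test_that("top_features ranks descending with index tie-break and validates top_k", {
  sc <- isirs:::new_screening_scores(c("a", "b", "c"), c(0.3, 0.1, 0.2), "sirs")
  expect_equal(unname(top_features(sc, 2)), c(1, 3))
  tie <- isirs:::new_screening_scores(c("a", "b"), c(0.2, 0.2), "sirs")
  expect_equal(unname(top_features(tie, 1)), 1)
  full <- top_features(sc, 3)
  expect_setequal(unname(full), 1:3)
  expect_true(all(diff(sc$omega[full]) <= 0))
  expect_error(top_features(sc, 0), class = "isirs_validation_error")
  expect_error(top_features(sc, 4), class = "isirs_validation_error")
})

test_that("active features outrank inactive ones with high probability", {
  hits <- logical(50)
  for (s in 1:50) {
    sim <- simulate_linear(n = 200, p = 1000, active = 1:5, beta = 1,
                           sigma = 1, seed = s)
    xs <- standardize_features(sim$x)
    hits[s] <- all(1:5 %in% top_features(omega_scores(xs, sim$y), 20))
  }
  expect_gte(mean(hits), 0.9)
})
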