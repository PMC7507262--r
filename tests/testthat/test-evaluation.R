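test_that("pcc and mse behave as the textbook formulas", {
  expect_equal(pcc(1:5, 1:5), 1)
  expect_equal(pcc(1:5, -(1:5)), -1)
  p <- c(1, 2, 3); t <- c(1, 2, 4)
  direct <- sum((p - mean(p)) * (t - mean(t))) /
    sqrt(sum((p - mean(p))^2) * sum((t - mean(t))^2))
  expect_equal(pcc(p, t), direct, tolerance = 1e-12)
  expect_error(pcc(c(1, 1, 1), 1:3), class = "isirs_validation_error")
  expect_error(pcc(1:4, 1:5), class = "isirs_validation_error")

  expect_equal(mse(1:4, 1:4), 0)
  expect_equal(mse(c(1, 2), c(2, 4)), 2.5)
  expect_equal(mse(c(1, 2) + 7, c(2, 4) + 7), 2.5) # translation invariant
  expect_error(mse(1:3, 1:4), class = "isirs_validation_error")
})

test_that("every sample is held out exactly once per repeat with near-equal folds", {
  sim <- simulate_linear(n = 103, p = 30, active = 1:3, seed = 51)
  rep <- cross_validate(sim$x, sim$y, method = "stf", d = 4, folds = 10,
                        repeats = 2, seed = 3)
  for (r in 1:2) {
    fa <- rep$fold_assignments[, r]
    expect_equal(sort(unique(fa)), 1:10)
    sizes <- table(fa)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_true(all(sizes %in% c(10, 11)))
  }
  expect_false(any(is.na(rep$predictions$predicted)))
})

test_that("cross-validation reports are bit-identical under a fixed seed", {
  sim <- simulate_linear(n = 60, p = 25, active = 1:3, seed = 52)
  r1 <- cross_validate(sim$x, sim$y, method = "isirs", d = 4, seed = 11)
  r2 <- cross_validate(sim$x, sim$y, method = "isirs", d = 4, seed = 11)
  expect_identical(r1, r2)
  r3 <- cross_validate(sim$x, sim$y, method = "isirs", d = 4, seed = 12)
  expect_false(identical(r1$predictions$predicted, r3$predictions$predicted))
})

test_that("held-out responses never leak into their own predictions", {
  sim <- simulate_linear(n = 60, p = 25, active = 1:3, seed = 53)
  base <- cross_validate(sim$x, sim$y, method = "stf", d = 4, seed = 21)
  for (i in c(1, 17, 60)) {
    y2 <- sim$y
    y2[i] <- y2[i] + 1000 # wildly perturb one held-out response
    mut <- cross_validate(sim$x, y2, method = "stf", d = 4, seed = 21)
    expect_identical(mut$predictions$predicted[i], base$predictions$predicted[i])
  }
})

test_that("high signal-to-noise data yields near-perfect cross-validated correlation", {
  sim <- simulate_linear(n = 300, p = 500, active = 1:5, beta = 1,
                         sigma = 0.2, seed = 54)
  rep <- cross_validate(sim$x, sim$y, method = "isirs", d = 10, seed = 1)
  expect_gte(rep$pcc, 0.9)
})

test_that("pure-noise data concentrates the cross-validated correlation near zero", {
  small <- logical(50)
  for (s in 1:50) {
    sim <- simulate_linear(n = 200, p = 60, active = integer(0),
                           beta = numeric(0), sigma = 1, seed = 100 + s)
    rep <- cross_validate(sim$x, sim$y, method = "stf", d = 5, seed = s)
    small[s] <- !is.na(rep$pcc) && abs(rep$pcc) < 0.2
  }
  expect_gte(mean(small), 0.9)
})

test_that("unknown methods and undersized samples are rejected", {
  sim <- simulate_linear(n = 30, p = 10, seed = 55)
  expect_error(cross_validate(sim$x, sim$y, method = "magic", d = 3),
               "arg")
  expect_error(cross_validate(sim$x[1:15, ], sim$y[1:15], method = "stf", d = 3),
               class = "isirs_validation_error")
})

test_that("d tuning scans the grid and picks the largest-PCC point", {
  sim <- simulate_linear(n = 80, p = 30, active = 1:3, beta = 1,
                         sigma = 0.5, seed = 56)
  single <- select_d(sim$x, sim$y, method = "stf", d_grid = 6, repeats = 1,
                     seed = 1)
  expect_equal(single$best_d, 6)
  ds <- select_d(sim$x, sim$y, method = "stf", d_grid = c(2, 4, 8),
                 repeats = 1, seed = 1)
  expect_equal(nrow(ds$table), 3)
  expect_true(all(ds$table$pcc >= -1 & ds$table$pcc <= 1, na.rm = TRUE))
  expect_equal(ds$best_d, ds$table$d[which.max(ds$table$pcc)])
  expect_error(select_d(sim$x, sim$y, d_grid = integer(0)),
               class = "isirs_validation_error")
  expect_error(select_d(sim$x, sim$y, d_grid = c(2, 90)),
               class = "isirs_validation_error")
})

test_that("the tuned d lands near the true sparsity", {
  ok <- logical(20)
  for (s in 1:20) {
    sim <- simulate_linear(n = 150, p = 60, active = 1:5, beta = 1,
                           sigma = 0.7, seed = 200 + s)
    ds <- select_d(sim$x, sim$y, method = "stf", d_grid = seq(2, 20, 2),
                   folds = 10, repeats = 1, seed = s)
    ok[s] <- ds$best_d >= 4 && ds$best_d <= 12
  }
  expect_gte(mean(ok), 0.8)
})

test_that("report accessors expose the tuning table and metrics", {
  sim <- simulate_linear(n = 60, p = 20, active = 1:2, sigma = 0.5, seed = 57)
  rep <- cross_validate(sim$x, sim$y, method = "stf", d = 3, seed = 5)
  expect_named(glance(rep), c("method", "d", "folds", "repeats", "pcc", "mse", "seed"))
  expect_equal(nrow(tidy(rep)), 60)
  expect_equal(rep$pcc, pcc(rep$predictions$predicted, rep$predictions$observed))
  expect_equal(rep$mse, mse(rep$predictions$predicted, rep$predictions$observed))
})
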