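test_that("trace geometry: K1, disjoint screens, nested retention, bounded size", {
  set.seed(41)
  sim <- simulate_linear(n = 100, p = 120, active = 1:5, beta = 1,
                         sigma = 1, seed = 41)
  d <- 9
  tr <- isirs_select(sim$x, sim$y, d = d, isirs_control(seed = 41))
  expect_equal(tr$K1, floor(2 * d / 3))
  expect_equal(tr$iterations$n_screened[1], tr$K1)
  expect_lte(length(tr$final_set), d)
  its <- tr$iterations
  for (s in seq_len(nrow(its))) {
    prev <- if (s == 1) integer(0) else its$retained[[s - 1]]
    if (s >= 2) {
      expect_length(intersect(its$screened[[s]], prev), 0)
      expect_equal(its$n_screened[s], d - length(prev))
    }
    expect_true(all(its$retained[[s]] %in% c(its$screened[[s]], prev)))
  }
  # every final feature appeared in some screened set
  expect_true(all(unname(tr$final_set) %in% unlist(its$screened)))
})

test_that("iteration terminates on noise, signal, and adversarial inputs", {
  set.seed(42)
  cases <- list()
  for (r in 1:10) {
    n <- sample(40:80, 1)
    p <- sample(30:120, 1)
    kind <- r %% 3
    x <- matrix(rnorm(n * p), n, p)
    y <- if (kind == 0) rnorm(n)                       # pure noise
    else if (kind == 1) drop(x %*% rnorm(p, sd = 1))   # all features active
    else rep(c(0, 1), length.out = n)                  # heavily tied response
    d <- sample(2:min(12, p), 1)
    tr <- isirs_select(x, y, d = d, isirs_control(seed = r))
    expect_lte(tr$n_iter, 50)
    expect_true(tr$stop_reason %in% c("reached_d", "size_unchanged", "max_iter"))
    expect_lte(length(tr$final_set), d)
  }
  # pure-noise case terminates via a size rule
  sim <- simulate_linear(n = 100, p = 200, active = integer(0), beta = numeric(0),
                         sigma = 1, seed = 5)
  tr <- isirs_select(sim$x, sim$y, d = 10, isirs_control(seed = 5))
  expect_true(tr$stop_reason %in% c("size_unchanged", "reached_d"))
})

test_that("iterative selection recovers all active features in a sparse linear model", {
  hits <- logical(50)
  for (s in 1:50) {
    sim <- simulate_linear(n = 200, p = 1000, active = 1:5, beta = 1,
                           sigma = 1, seed = s)
    tr <- isirs_select(sim$x, sim$y, d = 10, isirs_control(seed = s))
    hits[s] <- all(1:5 %in% tr$final_set)
  }
  expect_gte(mean(hits), 0.9)
})

test_that("the hidden predictor is recovered by iteration but not by top-ranking", {
  isirs_hit <- stf_hit <- logical(50)
  for (s in 1:50) {
    sim <- simulate_hidden_predictor(n = 200, p = 500, beta = 2, rho = 0.5,
                                     sigma = 1, seed = s)
    tr <- isirs_select(sim$x, sim$y, d = 10, isirs_control(seed = s))
    isirs_hit[s] <- 4 %in% tr$final_set
    stf_hit[s] <- 4 %in% stf_select(sim$x, sim$y, 10)
  }
  expect_gte(mean(isirs_hit), 0.8)
  expect_lte(mean(stf_hit), 0.2)
})

test_that("stf_select is exactly the top-d omega ranking", {
  sim <- simulate_linear(n = 80, p = 40, active = 1:3, beta = 2,
                         sigma = 0.5, seed = 6)
  xs <- standardize_features(sim$x)
  expect_identical(stf_select(sim$x, sim$y, 7),
                   top_features(omega_scores(xs, sim$y), 7))
  expect_error(stf_select(sim$x, sim$y, 41), class = "isirs_validation_error")
})

test_that("single-pass sirs returns a deterministic subset of the top-d screen", {
  sim <- simulate_linear(n = 120, p = 60, active = 1:4, beta = 2,
                         sigma = 0.5, seed = 7)
  d <- 8
  s1 <- sirs_select(sim$x, sim$y, d, isirs_control(seed = 7))
  s2 <- sirs_select(sim$x, sim$y, d, isirs_control(seed = 7))
  expect_identical(s1, s2)
  xs <- standardize_features(sim$x)
  screen <- top_features(omega_scores(xs, sim$y), d)
  expect_true(all(s1 %in% screen))
  expect_lte(length(s1), d)
})

test_that("single-pass sirs keeps strong orthogonal signals", {
  set.seed(8)
  n <- 150
  x <- orthogonal_design(n, 20)
  d <- 5
  y <- drop(x[, 1:d] %*% rep(3, d)) + rnorm(n, sd = 0.5)
  sel <- sirs_select(x, y, d, isirs_control(seed = 8))
  expect_setequal(unname(sel), 1:d)
})

test_that("reaching d features stops the iteration at that point", {
  # the first screen holds only floor(2d/3) < d candidates, so the earliest
  # the target size can be reached is the first iteration whose lasso pool
  # has size d; a dense strong signal makes the lasso keep the whole pool
  found <- FALSE
  for (s in 1:10) {
    sim <- simulate_linear(n = 200, p = 50, active = 1:10, beta = 2,
                           sigma = 0.3, seed = s)
    tr <- isirs_select(sim$x, sim$y, d = 6, isirs_control(seed = s))
    if (tr$stop_reason == "reached_d") {
      expect_length(tr$final_set, 6)
      expect_equal(tr$iterations$n_retained[tr$n_iter], 6)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("d is validated against the feature count", {
  sim <- simulate_linear(n = 50, p = 20, seed = 1)
  expect_error(isirs_select(sim$x, sim$y, d = 21), class = "isirs_validation_error")
  expect_error(isirs_select(sim$x, sim$y, d = 1), class = "isirs_validation_error")
})

test_that("the isirs() pipeline standardizes, selects, fits and predicts consistently", {
  sim <- simulate_linear(n = 100, p = 50, active = 1:3, beta = 1.5,
                         sigma = 0.5, seed = 9)
  fit <- isirs(sim$x, sim$y, d = 6, control = isirs_control(seed = 9))
  expect_s3_class(fit, "isirs")
  expect_true(all(1:3 %in% fit$trace$final_set))
  # in-sample predictions from raw features agree with the internal fit
  expect_equal(unname(predict(fit, sim$x)), unname(fit$model$fitted),
               tolerance = 1e-10)
  td <- tidy(fit)
  expect_true(all(c("omega", "screen_rank") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$n_selected, length(fit$trace$final_set))
})
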