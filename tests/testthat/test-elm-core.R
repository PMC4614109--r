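test_that("weighted sum and RSS agree with direct arithmetic", {
  expect_identical(weighted_sum(c(1, -2), c(3, 1)), 1)
  expect_identical(weighted_sum(c(5, -7, 2), c(0, 0, 0)), 0)
  set.seed(31)
  w <- rnorm(10)
  x <- matrix(rnorm(50), 5, 10)
  expect_equal(weighted_sum(w, x), as.vector(x %*% w))   # independent dot product
  expect_error(weighted_sum(c(1, 2), c(1, 2, 3)), class = "elm_dimension_error")
  expect_error(weighted_sum(c(1, NA), c(1, 2)), class = "elm_nonfinite_error")

  y <- rnorm(5)
  brute <- sum(sapply(1:5, function(j) (y[j] - sum(w * x[j, ]))^2))
  expect_equal(elm_rss(w, x, y), brute, tolerance = 1e-12)
  expect_equal(elm_rss(w, x, as.vector(x %*% w)), 0, tolerance = 1e-20)
  expect_equal(elm_rss(rep(0, 10), x, y), sum(y^2))
})

test_that("initial weights are the exact univariate least-squares slopes", {
  expect_equal(unname(fit_initial_weights(cbind(a = c(0, 1, 2)), c(0, 1, 2))), 1)
  expect_equal(unname(fit_initial_weights(cbind(a = c(1, 2, 3)), c(2, 4, 6))), 2)

  # oracle: 1-D numerical minimization of the per-descriptor RSS
  set.seed(41)
  n <- 40
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- sample(c(1, 2), n, replace = TRUE)
  w <- fit_initial_weights(x, y)
  for (j in 1:3) {
    # the slope minimizes the RSS of the centered univariate regression
    opt <- optimize(function(b) sum(((y - mean(y)) - b * (x[, j] - mean(x[, j])))^2),
                    interval = c(-10, 10), tol = 1e-10)
    expect_lt(abs(unname(w[j]) - opt$minimum), 1e-8)
  }
  expect_error(fit_initial_weights(cbind(a = rep(2, 5)), rep(1, 5)),
               class = "elm_zero_variance_error")
})

test_that("Andrews fitness has the exact wave shape and least-squares limit", {
  a <- 1.339
  expect_identical(andrews_fitness(numeric(5), a), 0)               # maximum at 0
  expect_equal(andrews_fitness(pi * a, a), -2 * a^2, tolerance = 1e-15)
  expect_equal(andrews_fitness(10 * a, a), -2 * a^2)                # constant beyond pi*a
  # small residuals: rho(r) ~ r^2 / 2
  r <- 0.01 * a
  expect_equal(-andrews_fitness(r, a) / (r^2 / 2), 1, tolerance = 1e-3)
  # a -> Inf recovers -RSS/2
  set.seed(51)
  res <- rnorm(100)
  expect_equal(andrews_fitness(res, 1e6), -sum(res^2) / 2, tolerance = 1e-6)
})

test_that("GA weight refinement never degrades the seeded initialization", {
  ds <- make_tiny_dataset(n = 60, p = 3, seed = 61)
  std <- standardize_descriptors(ds$x)
  y <- as.double(ds$labels)
  w0 <- fit_initial_weights(std$values, y)

  # generation cap 0 is the no-op limit
  opt0 <- optimize_weights_ga(std$values, y, w0, optimizer_config(max_generations = 0))
  expect_identical(opt0$weights, w0)
  expect_identical(opt0$generations, 0L)

  for (s in 1:5) {
    opt <- optimize_weights_ga(std$values, y, w0,
                               optimizer_config(max_generations = 80,
                                                stagnation_limit = 40, seed = s))
    expect_gte(opt$fitness, opt$initial_fitness)
    expect_true(all(diff(opt$best_fitness_trace) >= 0))
    expect_lte(elm_rss(opt$weights, std$values, y), elm_rss(w0, std$values, y) + 1e-9)
  }

  # determinism: identical seed, identical result
  o1 <- optimize_weights_ga(std$values, y, w0, optimizer_config(seed = 3, max_generations = 40))
  o2 <- optimize_weights_ga(std$values, y, w0, optimizer_config(seed = 3, max_generations = 40))
  expect_identical(o1, o2)
})

test_that("threshold modes follow their closed forms", {
  scores <- c(-1, -1, 1, 1)
  labels <- c(1, 1, 2, 2)
  expect_identical(compute_threshold(scores, labels, "midpoint"), 0)
  expect_identical(compute_threshold(scores, labels, "literal_difference"), -2)
  expect_identical(compute_threshold(rep(3.5, 4), labels, "midpoint"), 3.5)
  set.seed(71)
  s <- rnorm(30); l <- rep(c(1, 2), 15)
  expect_equal(compute_threshold(s, l, "midpoint"),
               (mean(s[l == 1]) + mean(s[l == 2])) / 2, tolerance = 1e-12)
  expect_equal(compute_threshold(s, l, "literal_difference"),
               mean(s[l == 1]) - mean(s[l == 2]), tolerance = 1e-12)
  expect_error(compute_threshold(s, rep(1, 30)), class = "elm_empty_class_error")
})

test_that("prediction applies the low-score-is-active rule with ties to inactive", {
  ds <- make_tiny_dataset(n = 40, seed = 81)
  model <- elm_train(ds, c("D1", "D2"), optimizer_config(max_generations = 10, seed = 1))
  scores <- predict(model, ds$x, type = "score")
  expect_identical(predict(model, ds$x), unname(ifelse(scores < model$threshold, 1L, 2L)))

  # force exact scores around the threshold through a hand-built model
  m <- model
  m$weights[] <- c(1, 0)
  m$standardization <- NULL
  m$threshold <- 2
  x <- cbind(D1 = c(1.9, 2.0, 2.1), D2 = 0)
  expect_identical(predict(m, x), c(1L, 2L, 2L))  # tie -> inactive
  expect_error(predict(m, cbind(Dx = 1)), class = "elm_missing_column_error")
})

test_that("training is deterministic and invariant to raw descriptor units", {
  ds <- make_tiny_dataset(n = 50, p = 3, seed = 91)
  cfg <- optimizer_config(max_generations = 40, seed = 13)
  m1 <- elm_train(ds, colnames(ds$x), cfg)
  m2 <- elm_train(ds, colnames(ds$x), cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$threshold, m2$threshold)
  f1 <- tempfile(); f2 <- tempfile()
  save_elm_model(m1, f1); save_elm_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))  # identical model files

  # rescale/shift raw units: standardization absorbs it, predictions match
  x2 <- sweep(sweep(ds$x, 2, c(10, 0.01, 3), "*"), 2, c(-5, 2, 100), "+")
  ds2 <- labeled_dataset(x2, ds$labels)
  m3 <- elm_train(ds2, colnames(ds$x), cfg)
  expect_identical(predict(m3, x2), predict(m1, ds$x))
  expect_equal(m3$weights, m1$weights, tolerance = 1e-9)
})

test_that("a separable training set is classified perfectly with the midpoint threshold", {
  syn <- generate_synthetic(synthetic_config(
    n_compounds = 100, n_descriptors = 12, n_informative = 4,
    effect_size = 6, seed = 17))
  ds <- syn$dataset
  model <- elm_train(ds, syn$informative, optimizer_config(max_generations = 0, seed = 1))
  expect_identical(predict(model, ds$x), ds$labels)
  expect_identical(classification_metrics(predict(model, ds$x), ds$labels)$acc, 100)
})
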