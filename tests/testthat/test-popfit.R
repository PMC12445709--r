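test_that("two-Gaussian sampling oracle is recovered", {
  set.seed(7)
  n <- 5000
  comp <- sample(1:2, n, replace = TRUE, prob = c(0.93, 0.07))
  v <- rnorm(n, c(0.38, 0.14)[comp], c(0.07, 0.05)[comp])
  fit <- fit_mixture(v, 2)
  expect_equal(fit$means[2], 0.38, tolerance = 0.01)
  expect_lt(abs(100 * fit$weights[2] - 93), 3)
})

test_that("K = 1 fit returns the sample mean", {
  set.seed(8)
  v <- rnorm(2000, 0.43, 0.06)
  fit <- fit_mixture(v, 1)
  expect_equal(fit$means, mean(v), tolerance = 2 * sd(v) / sqrt(2000))
})

test_that("LS and EM agree on a well-separated mixture", {
  set.seed(9)
  n <- 4000
  comp <- sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))
  v <- rnorm(n, c(0.15, 0.55)[comp], c(0.04, 0.05)[comp])
  ls <- fit_mixture(v, 2, method = "ls")
  em <- fit_mixture(v, 2, method = "em")
  expect_equal(ls$means, em$means, tolerance = 0.01)
  expect_equal(ls$weights, em$weights, tolerance = 0.03)
})

test_that("fit_mixture validates inputs", {
  expect_error(fit_mixture(rnorm(10), 2), "too few")
  expect_error(fit_mixture(rnorm(5000), 5), "between 1 and 4")
})

test_that("subset_error reports the spread across random subsets", {
  set.seed(10)
  v <- rnorm(300, 0.4, 0.05)
  se <- subset_error(v, mean, n_subsets = 3, seed = 2)
  expect_length(se$estimates, 3)
  expect_equal(se$mean, mean(v), tolerance = 0.01)
  expect_lt(se$sd, 0.02)
  # deterministic given the seed
  se2 <- subset_error(v, mean, n_subsets = 3, seed = 2)
  expect_identical(se$estimates, se2$estimates)
  expect_error(subset_error(v, mean, n_subsets = 1), "at least 2")
  expect_error(subset_error(rnorm(4), mean, n_subsets = 3), "too few")
})
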