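sim_2state <- function(n_traces = 20, len = 200, means = c(0.2, 0.6),
                       sd = 0.05, p_stay = 0.95, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_traces), function(i) {
    s <- integer(len)
    s[1] <- sample(1:2, 1)
    for (t in 2:len)
      s[t] <- if (runif(1) < p_stay) s[t - 1] else 3 - s[t - 1]
    rnorm(len, means[s], sd)
  })
}

test_that("viterbi_path equals exhaustive enumeration on short traces", {
  set.seed(4)
  means <- c(0.2, 0.7); sds <- c(0.08, 0.08)
  piv <- c(0.4, 0.6)
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  for (rep in 1:5) {
    x <- runif(8, 0, 1)
    vp <- viterbi_path(x, piv, A, means, sds)
    paths <- as.matrix(expand.grid(rep(list(1:2), 8)))
    lp <- apply(paths, 1, function(s) {
      log(piv[s[1]]) + sum(log(A[cbind(s[-8], s[-1])])) +
        sum(dnorm(x, means[s], sds[s], log = TRUE))
    })
    best <- paths[which.max(lp), ]
    expect_identical(as.integer(vp), as.integer(best))
  }
})

test_that("VB lower bound is monotone and the fit is seed-deterministic", {
  traj <- sim_2state(seed = 11)
  fit <- fit_hmm(traj, K = 2, seed = 3)
  expect_true(all(diff(fit$score_trace) >= -1e-6 * abs(fit$score_trace[-1])))
  fit2 <- fit_hmm(traj, K = 2, seed = 3)
  expect_identical(fit$means, fit2$means)
  expect_identical(fit$paths, fit2$paths)
})

test_that("VB recovers the parameters of a 2-state generator", {
  traj <- sim_2state(n_traces = 30, len = 300, seed = 12)
  fit <- fit_hmm(traj, K = 2, seed = 1)
  expect_equal(fit$means, c(0.2, 0.6), tolerance = 0.02)
  expect_equal(fit$sds, c(0.05, 0.05), tolerance = 0.02)
  expect_equal(diag(fit$trans), c(0.95, 0.95), tolerance = 0.03)
})

test_that("single-state noiseless data gives an exact trivial fit", {
  traj <- replicate(4, rep(0.4, 60), simplify = FALSE)
  fit <- fit_hmm(traj, K = 1, seed = 1)
  expect_equal(unname(fit$means), 0.4, tolerance = 1e-3)
  expect_equal(unname(fit$trans), matrix(1, 1, 1))
  em <- fit_hmm(traj, K = 1, seed = 1, method = "em")
  expect_equal(unname(em$means), 0.4, tolerance = 1e-9)
})

test_that("input validation errors are raised", {
  expect_error(fit_hmm(list(), 2), "at least one")
  expect_error(fit_hmm(list(rnorm(5)), 2), ">= 10 periods")
  expect_error(fit_hmm(list(rnorm(50)), 9), "between 1 and 6")
  expect_error(select_model(list(rnorm(50)), k_range = c(1, 9)), "\\[1, 6\\]")
})

test_that("overfitted states are flagged degenerate with a warning", {
  set.seed(5)
  traj <- replicate(6, rnorm(150, 0.4, 0.04), simplify = FALSE)
  expect_warning(fit <- fit_hmm(traj, K = 3, seed = 1), "degenerate")
  expect_true(any(fit$degenerate))
})

test_that("classify_dynamic applies the >= 3 transition rule", {
  fit <- structure(list(n_transitions = c(a = 0L, b = 2L, c = 3L, d = 7L)),
                   class = "hmm_fit")
  expect_identical(classify_dynamic(fit),
                   c(a = FALSE, b = FALSE, c = TRUE, d = TRUE))
})

test_that("transition density of an alternating path is off-diagonal", {
  fit <- structure(list(
    means = c(0.22, 0.59),
    paths = list(m1 = rep(c(1L, 2L), 10)),
    n_transitions = c(m1 = 19L)), class = "hmm_fit")
  td <- transition_density(fit)
  expect_identical(td$n_transitions, 19L)
  mids <- (td$edges[-1] + td$edges[-length(td$edges)]) / 2
  b1 <- findInterval(0.22, td$edges)
  b2 <- findInterval(0.59, td$edges)
  expect_identical(sum(td$counts), 19)
  expect_identical(td$counts[b1, b2] + td$counts[b2, b1], 19)
  expect_identical(sum(diag(td$counts)), 0)
  # no transitions -> empty density
  fit0 <- structure(list(means = 0.4, paths = list(m = rep(1L, 30)),
                         n_transitions = c(m = 0L)), class = "hmm_fit")
  td0 <- transition_density(fit0)
  expect_identical(td0$n_transitions, 0L)
  expect_identical(sum(td0$counts), 0)
})

test_that("EM fallback scores and selects like VB on clean data", {
  traj <- sim_2state(n_traces = 15, len = 150, seed = 21)
  sel <- select_model(traj, k_range = 1:3, seed = 1, method = "em")
  expect_identical(sel$K, 2L)
  expect_equal(sel$fit$means, c(0.2, 0.6), tolerance = 0.03)
})
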