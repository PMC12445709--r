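test_that("extract_dwells conserves time and flags censoring", {
  fit <- structure(list(paths = list(
    m1 = c(rep(1L, 10), rep(2L, 25), rep(1L, 15)),
    m2 = rep(2L, 40))), class = "hmm_fit")
  dw <- extract_dwells(fit, frame_period = 0.1)
  expect_equal(sum(dw$duration[dw$molecule == "m1"]), 5)  # 50 periods x 0.1
  expect_identical(dw$censored[dw$molecule == "m1"], c(TRUE, FALSE, TRUE))
  expect_true(all(dw$censored[dw$molecule == "m2"]))
  expect_error(extract_dwells(fit, frame_period = 0))
})

test_that("single-exponential MLE equals the uncensored sample mean", {
  set.seed(13)
  d <- data.frame(molecule = "m", state = 1L,
                  duration = rexp(400, 1 / 0.8),
                  censored = FALSE)
  f <- fit_dwells(d)
  expect_equal(unname(f$tau["tau"]), mean(d$duration), tolerance = 1e-12)
  expect_equal(f$tau_ls, unname(f$tau["tau"]), tolerance = 0.15)
})

test_that("peaked dwell model falls back to single when degenerate", {
  set.seed(14)
  d <- data.frame(molecule = "m", state = 1L, duration = rexp(300, 1 / 1),
                  censored = FALSE)
  expect_warning(f <- fit_dwells(d, form = "peaked"), "collapsed")
  expect_identical(f$form, "single")
})

test_that("fit_displacement recovers a known two-exponential mixture", {
  set.seed(15)
  n <- 4000
  comp <- sample(1:2, n, replace = TRUE, prob = c(0.9, 0.1))
  td <- rexp(n, 1 / c(14, 190)[comp])
  fit <- fit_displacement(td)
  expect_equal(fit$taus[1], 14, tolerance = 0.1 * 14)
  expect_equal(fit$taus[2], 190, tolerance = 0.15 * 190)
  expect_equal(fit$weights[1], 0.9, tolerance = 0.04)
  expect_error(fit_displacement(rep(2, 100), bin_width = 5), "single histogram bin")
  expect_error(fit_displacement(rexp(5)), "too few")
})

test_that("fast/slow boundary matches the frozen closed-form oracle", {
  # A = (0.9, 0.1), tau = (14, 190):
  # t_b = ln(9) / (1/14 - 1/190) = 33.21 s
  fit <- list(amplitudes = c(0.9, 0.1), taus = c(14, 190))
  tb <- fastslow_boundary(fit)
  expect_equal(tb, log(9) / (1 / 14 - 1 / 190), tolerance = 1e-12)
  expect_equal(tb, 33.2097, tolerance = 1e-4)
  expect_error(fastslow_boundary(list(amplitudes = c(0.1, 0.9),
                                      taus = c(14, 190))),
               "larger amplitude")
  expect_error(fastslow_boundary(list(amplitudes = c(0.9, 0),
                                      taus = c(14, 190))),
               "positive")
})

test_that("categorize_realtime applies the terminal-displacement rule", {
  fp <- 0.4
  mk_fit <- function(paths, means = c(0.15, 0.42)) {
    structure(list(means = means, paths = paths,
                   n_transitions = vapply(paths, function(p)
                     sum(diff(p) != 0), integer(1))),
              class = "hmm_fit")
  }
  paths <- list(
    disp = c(rep(2L, 150), rep(1L, 100)),         # displaced at 60 s
    dyn = rep(c(2L, 2L, 2L, 1L, 2L), 50),          # many transitions
    stat = rep(2L, 250),                           # static
    pre = c(rep(1L, 100), rep(2L, 150)))           # low band before t_inj only
  fit <- mk_fit(paths)
  rec <- categorize_realtime(fit, t_inj = 30, frame_period = fp,
                             boundary = 31)
  expect_identical(rec$class, c("I", "III", "IV", "IV"))
  expect_equal(rec$t_displace[1], 150 * fp - 30)
  rec2 <- categorize_realtime(fit, t_inj = 30, frame_period = fp,
                              boundary = 20)
  expect_identical(rec2$class[1], "II")
  expect_error(categorize_realtime(fit, t_inj = 500, frame_period = fp),
               "outside")
  expect_identical(displacement_times(rec), rec$t_displace[1])
})

test_that("pre-injection E* averages the window before injection", {
  series <- list(m1 = c(rep(0.46, 75), rep(0.15, 175)),
                 m2 = c(rep(0.48, 75), rep(0.15, 175)))
  rec <- data.frame(molecule = c("m1", "m2"), class = c("I", "II"),
                    t_displace = c(10, 50), stringsAsFactors = FALSE)
  out <- pre_injection_estar(series, rec, t_inj = 30, frame_period = 0.4)
  expect_equal(out$fast, 0.46)
  expect_equal(out$slow, 0.48)
  expect_warning(
    pre_injection_estar(list(m1 = rep(0.46, 100)),
                        rec[1, ], t_inj = 2, frame_period = 0.4),
    "shrunk")
})
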