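test_that("ground_truth validates its invariants", {
  states <- data.frame(label = "s1", mean = 0.4, sd = 0.06,
                       dwell_mean = NA_real_)
  arch <- list(one = list(kind = "static", state = 1L))
  gt <- ground_truth("toy", states, c(one = 1), arch)
  expect_s3_class(gt, "ground_truth")
  expect_error(ground_truth("bad", states, c(one = 0.5), arch),
               "sum to 1")
  states_bad <- states; states_bad$mean <- 1.4
  expect_error(ground_truth("bad", states_bad, c(one = 1), arch),
               "state means")
  expect_error(ground_truth("bad", states, c(one = 1), arch,
                            photobleach_means = c(donor = -1, acceptor = 5)),
               "photobleach")
})

test_that("dynamic_branching reproduces target occupancies and dwells", {
  occ <- c(0.17, 0.54, 0.29)
  dw <- c(0.6, 1.0, 0.8)
  B <- dynamic_branching(occ, dw)
  expect_equal(diag(B), rep(0, 3))
  expect_equal(rowSums(B), rep(1, 3))
  # stationary law of the jump chain weighted by dwells = occupancy
  v <- rep(1 / 3, 3)
  for (i in 1:500) v <- as.numeric(v %*% B)
  occ_hat <- v * dw / sum(v * dw)
  expect_equal(occ_hat, occ, tolerance = 1e-8)
  # infeasible combination errors
  expect_error(dynamic_branching(c(0.9, 0.05, 0.05), c(0.1, 1, 1)),
               "infeasible")
})

test_that("displacer detection probability matches Monte Carlo", {
  taus <- c(14, 190); w <- c(0.9, 0.1)
  pb <- c(donor = 400, acceptor = 667)
  p <- displacer_detection_prob(taus, w, pb, t_inj = 30, t_stab = 4)
  set.seed(99)
  n <- 200000
  comp <- sample(1:2, n, replace = TRUE, prob = w)
  t_d <- 30 + rexp(n, 1 / taus[comp])
  t_bl <- pmin(rexp(n, 1 / pb[1]), rexp(n, 1 / pb[2]))
  p_mc <- mean(t_bl > t_d + 4)
  expect_equal(p, p_mc, tolerance = 0.01)
})

test_that("fixture registry builds and rejects unknown names", {
  expect_true(length(fixture_names()) >= 8)
  for (nm in fixture_names()) {
    gt <- build_fixture(nm)
    expect_s3_class(gt, "ground_truth")
    expect_identical(gt$name, nm)
  }
  expect_error(build_fixture("GT-nonsense"), "available")
})

test_that("real-time fixtures encode observed class fractions", {
  gt <- build_fixture("GT-realtime-lacCONS-OH")
  expect_equal(gt$displacement_taus, c(14, 190))
  p_det <- displacer_detection_prob(gt$displacement_taus,
                                    gt$displacement_weights,
                                    gt$photobleach_means, gt$t_inj,
                                    t_stab = 10 * gt$frame_period)
  underlying <- sum(gt$ensemble[c("fast-displacer", "slow-displacer")])
  expect_equal(underlying * p_det, 0.25, tolerance = 1e-9)
})
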