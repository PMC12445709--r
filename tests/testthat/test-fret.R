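test_that("E* and S arithmetic matches hand computation", {
  tr <- alex_trace("m", time = c(0, 0.1), I_DD = c(300, 0),
                   I_DA = c(100, 0), I_AA = c(400, -5), frame_period = 0.1)
  fs <- compute_estar_s(tr)
  expect_equal(fs$E[1], 0.25)
  expect_equal(fs$S[1], 0.5)
  expect_false(fs$ok_E[2])
  expect_true(is.na(fs$E[2]))
  expect_false(fs$ok_S[2])
})

test_that("accurate FRET is the identity at Lk = Dir = 0, gamma = 1", {
  E <- c(0.1, 0.38, 0.9)
  out <- accurate_fret(E, rep(0.5, 3), correction_factors())
  expect_equal(out$E_pr, E, tolerance = 1e-12)
  expect_equal(out$E_a, E, tolerance = 1e-12)
})

test_that("accurate FRET matches the frozen hand-computed oracle", {
  # E* = 0.4, S = 0.5, Lk = 0.1, Dir = 0.1, gamma = 1.2:
  # E_PR = (1 - 0.1 - 0.1*1.5) / (1.5 + 1 - 0.1) = 0.75/2.4 = 0.3125
  # E_a  = 0.3125 / (1.2 - 0.2*0.3125) = 0.3125/1.1375
  out <- accurate_fret(0.4, 0.5, correction_factors(0.1, 0.1, 1.2))
  expect_equal(out$E_pr, 0.3125, tolerance = 1e-12)
  expect_equal(out$E_a, 0.3125 / 1.1375, tolerance = 1e-12)
  bad <- accurate_fret(c(0, 1.2), c(0.5, 0.5), correction_factors())
  expect_true(all(is.na(bad$E_pr)))
})

test_that("distance conversion hits the Forster anchor points", {
  expect_equal(distance_to_fret(60), 0.5)
  expect_equal(fret_to_distance(0.5), 60)
  # R = 75.6 A with R0 = 60 A -> E close to 0.20
  expect_equal(distance_to_fret(75.6), 0.2, tolerance = 1e-3)
  expect_equal(fret_to_distance(distance_to_fret(47)), 47, tolerance = 1e-9)
  expect_error(fret_to_distance(0), "inside")
  expect_error(fret_to_distance(1), "inside")
  expect_error(distance_to_fret(-3), "R must be > 0")
})

test_that("leakage and direct-excitation factors follow their definitions", {
  expect_equal(leakage_factor(rep(0.1, 50)), 0.1 / 0.9)
  expect_equal(direct_excitation_factor(rep(0.08, 50)), 0.08 / 0.92)
  expect_error(leakage_factor(numeric(0)), "donor-only")
  expect_error(correction_factors(gamma = 0))
})

test_that("gamma factor recovers a synthetic acceptor-bleach step", {
  n <- 100
  I_DA <- c(rep(200, 50), rep(0, 50))
  I_DD <- c(rep(400, 50), rep(560, 50))  # rise of 160 -> gamma = 200/160
  tr <- alex_trace("g", time = seq_len(n), I_DD = I_DD, I_DA = I_DA,
                   I_AA = c(rep(500, 50), rep(0, 50)), frame_period = 0.1)
  g <- gamma_factor(tr, bleach_period = 51)
  expect_equal(g, 200 / 160, tolerance = 1e-9)
  g2 <- gamma_factor(tr, bleach_period = 2)
  expect_true(is.na(g2))
  expect_match(attr(g2, "reason"), "bleach")
})

test_that("labelling efficiency reproduces the absorbance arithmetic", {
  # pick absorbances giving conc = 1e-6 M, 88% Cy3B, 75% Alexa647
  c_p <- 1e-6
  a570 <- 0.88 * c_p * 130000
  a665 <- 0.75 * c_p * 245000
  a280 <- c_p * 39760 + 0.88 * c_p * 10400 + 0.75 * c_p * 7350
  out <- labeling_efficiency(a280, a570, a665)
  expect_equal(out$concentration, c_p, tolerance = 1e-12)
  expect_equal(out$cy3b_pct, 88, tolerance = 1e-9)
  expect_equal(out$alexa647_pct, 75, tolerance = 1e-9)
  expect_error(labeling_efficiency(0.001, 5, 5), "not positive")
})
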