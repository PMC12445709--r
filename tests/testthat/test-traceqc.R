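test_that("bleach_steps finds a single clean downward step", {
  set.seed(1)
  x <- c(rnorm(80, 500, 15), rnorm(80, 5, 15))
  bs <- bleach_steps(x)
  expect_identical(bs$n_steps, 1L)
  expect_true(abs(bs$times[1] - 81) <= 2)
  expect_lt(abs(bs$background), 10)
})

test_that("bleach_steps counts two persistent steps and ignores flat traces", {
  set.seed(2)
  x2 <- c(rnorm(60, 800, 15), rnorm(60, 400, 15), rnorm(60, 3, 15))
  bs2 <- bleach_steps(x2)
  expect_identical(bs2$n_steps, 2L)
  flat <- rnorm(200, 500, 15)
  expect_identical(bleach_steps(flat)$n_steps, 0L)
})

test_that("blink_filter separates blinks from monotone bleaching", {
  set.seed(3)
  blink <- c(rnorm(40, 500, 10), rnorm(5, 2, 10), rnorm(40, 500, 10))
  expect_true(blink_filter(blink))
  bleach <- c(rnorm(40, 500, 10), rnorm(45, 2, 10))
  expect_false(blink_filter(bleach))
})

test_that("intensity_filter applies the acceptance bands", {
  mk <- function(dd, aa) alex_trace("m", seq_len(50), rep(dd, 50),
                                    rep(0, 50), rep(aa, 50),
                                    frame_period = 0.1)
  expect_false(intensity_filter(mk(500, 500)))
  expect_true(intensity_filter(mk(50, 500)))    # I_DD below 100
  expect_true(intensity_filter(mk(2000, 500)))  # I_DD above 1500
  expect_true(intensity_filter(mk(500, 1500)))  # I_AA above 1000
  expect_error(intensity_filter(alex_trace("e", numeric(0), numeric(0),
                                           numeric(0), numeric(0), 0.1)),
               "empty")
})

test_that("species_sort uses mean stoichiometry windows", {
  mk_fs <- function(s) {
    I_AA <- 600 * (1 - s) / s
    tr <- alex_trace("m", seq_len(40), rep(360, 40), rep(240, 40),
                     rep(I_AA, 40), frame_period = 0.1)
    compute_estar_s(tr)
  }
  expect_identical(species_sort(mk_fs(0.5)), "D+A")
  expect_identical(species_sort(mk_fs(0.95)), "D-only")
  expect_identical(species_sort(mk_fs(0.05)), "A-only")
  expect_identical(species_sort(mk_fs(0.85)), "ambiguous")
})

test_that("qc accepts clean simulated D+A traces and flags blinkers", {
  gt <- build_fixture("GT-RPitc2-lacCONS")
  sim <- simulate_ensemble(gt, 25, seed = 6)
  qc <- qc_ensemble(sim$traces)
  expect_identical(nrow(qc), 25L)
  expect_gt(mean(qc$accepted), 0.6)
  expect_true(all(qc$species[qc$accepted] == "D+A"))
  # inject an artificial blink into one accepted trace
  i <- which(qc$accepted)[1]
  tr <- sim$traces[[i]]
  mid <- floor(length(tr$I_AA) / 2)
  tr$I_AA[mid:(mid + 4)] <- 0
  v <- qc_trace(tr)
  expect_true(v$blinking)
  expect_false(v$accepted)
})

test_that("estar_series stays aligned to trace periods", {
  gt <- build_fixture("GT-RPitc2-lacCONS")
  sim <- simulate_ensemble(gt, 12, seed = 9)
  qc <- qc_ensemble(sim$traces)
  ser <- estar_series(sim$traces, qc)
  expect_gt(length(ser), 0)
  nm <- names(ser)[1]
  i <- which(vapply(sim$traces, function(t) t$id == nm, logical(1)))
  expect_identical(length(ser[[1]]),
                   as.integer(qc$n_pre[qc$molecule == nm]))
  fs <- compute_estar_s(sim$traces[[i]])
  ok <- which(fs$ok_E[seq_along(ser[[1]])])
  expect_equal(ser[[1]][ok], fs$E[ok])
})
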