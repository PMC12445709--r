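toy_gt <- function() {
  states <- rbind(
    data.frame(label = "lo", mean = 0.2, sd = 0.05, dwell_mean = 1),
    data.frame(label = "hi", mean = 0.6, sd = 0.05, dwell_mean = 1))
  ground_truth("toy2", states,
               c(stat = 0.5, dyn = 0.5),
               list(stat = list(kind = "static", state = 2L,
                                between_sd = 0),
                    dyn = list(kind = "dynamic", states = 1:2,
                               branching = dynamic_branching(c(0.5, 0.5),
                                                             c(1, 1)))),
               duration = 20)
}

test_that("simulation is deterministic given a seed", {
  gt <- toy_gt()
  a <- simulate_ensemble(gt, 5, seed = 3)
  b <- simulate_ensemble(gt, 5, seed = 3)
  expect_identical(a$archetypes, b$archetypes)
  expect_identical(a$traces[[4]]$I_DA, b$traces[[4]]$I_DA)
  d <- simulate_ensemble(gt, 5, seed = 4)
  expect_false(identical(a$traces[[4]]$I_DA, d$traces[[4]]$I_DA))
})

test_that("noiseless emission inverts to the exact state mean", {
  gt <- toy_gt()
  p <- simulate_state_path(gt, "stat", seed = 1)
  p$bleach_donor <- Inf; p$bleach_acceptor <- Inf
  tr <- emit_alex_trace(p, gt, noise = FALSE)
  fs <- compute_estar_s(tr)
  expect_equal(fs$E, rep(0.6, nrow(fs)), tolerance = 1e-12)
  expect_equal(fs$S, rep(0.5, nrow(fs)), tolerance = 1e-12)
})

test_that("donor and acceptor bleaching have the right signatures", {
  gt <- toy_gt()
  p <- simulate_state_path(gt, "stat", seed = 1)
  p$bleach_donor <- 10; p$bleach_acceptor <- Inf
  tr <- emit_alex_trace(p, gt, noise = FALSE)
  post <- tr$time > 10
  expect_true(all(tr$I_DD[post] == 0 & tr$I_DA[post] == 0))
  expect_true(all(tr$I_AA[post] == gt$total_rate))
  p$bleach_donor <- Inf; p$bleach_acceptor <- 10
  tr2 <- emit_alex_trace(p, gt, noise = FALSE)
  post2 <- tr2$time > 10
  expect_true(all(tr2$I_DA[post2] == 0 & tr2$I_AA[post2] == 0))
  # donor de-quenches to the full rate
  expect_true(all(tr2$I_DD[post2] == gt$total_rate))
})

test_that("unknown archetypes error with the valid set", {
  gt <- toy_gt()
  expect_error(simulate_state_path(gt, "nope"), "valid archetypes")
  expect_error(simulate_ensemble(gt, 3, archetype = "nope"), "unknown")
})

test_that("displacer paths switch permanently after injection", {
  gt <- build_fixture("GT-realtime-lacCONS-OH")
  p <- simulate_state_path(gt, "fast-displacer", seed = 8)
  expect_true(p$t_displace > gt$t_inj)
  if (p$t_displace < p$duration) {
    expect_identical(p$states[length(p$states)], gt$displaced_state)
    expect_identical(length(p$states), 2L)
  }
})

test_that("trace round trip through TSV preserves data", {
  gt <- toy_gt()
  sim <- simulate_ensemble(gt, 3, seed = 2)
  dir <- file.path(tempdir(), "roundtrip-traces")
  write_traces(sim$traces, dir, manifest = list(fixture = gt$name))
  back <- read_traces(dir)
  expect_length(back, 3)
  orig <- sim$traces[[2]]
  got <- back[[orig$id]]
  expect_equal(got$I_DD, orig$I_DD, tolerance = 1e-9)
  expect_equal(got$I_AA, orig$I_AA, tolerance = 1e-9)
  expect_equal(got$frame_period, orig$frame_period)
  unlink(dir, recursive = TRUE)
})

test_that("displacement delays follow the fixture mixture", {
  gt <- build_fixture("GT-realtime-lacCONS-OH")
  td <- draw_displacement_delays(gt, 20000, seed = 5)
  m_true <- sum(gt$displacement_weights * gt$displacement_taus)
  expect_equal(mean(td), m_true, tolerance = 0.05)
  eq <- build_fixture("GT-RPitc2-lacCONS")
  expect_error(draw_displacement_delays(eq, 10), "no displacement kinetics")
})
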