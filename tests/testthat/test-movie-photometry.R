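movie_toy <- function(n_periods = 30, seed = 2, noise = TRUE) {
  states <- data.frame(label = "s", mean = 0.4, sd = 0.05,
                       dwell_mean = NA_real_)
  gt <- ground_truth("mov", states, c(one = 1),
                     list(one = list(kind = "static", state = 1L,
                                     between_sd = 0)),
                     duration = n_periods * 0.1,
                     photobleach_means = c(donor = 1e6, acceptor = 1e6))
  sim <- simulate_ensemble(gt, 2, seed = seed, noise = noise)
  layout <- movie_layout(positions = rbind(c(10, 10), c(22, 20)))
  list(movie = render_movie(sim$traces, layout, seed = seed, noise = noise),
       traces = sim$traces)
}

test_that("layout validation rejects border and overlapping spots", {
  expect_error(movie_layout(positions = rbind(c(1, 10))), "borders")
  expect_error(movie_layout(positions = rbind(c(10, 10), c(12, 12))),
               "overlapping")
  expect_s3_class(movie_layout(positions = rbind(c(10, 10))), "movie_layout")
})

test_that("spot detection finds and pairs the rendered molecules", {
  mt <- movie_toy()
  spots <- detect_spots(mt$movie)
  expect_identical(nrow(spots$pairs), 2L)
  ref <- rbind(c(10, 10), c(22, 20))
  found <- spots$pairs[order(spots$pairs[, 1]), , drop = FALSE]
  expect_lt(max(abs(found - ref)), 0.5)
})

test_that("aperture photometry inverts the renderer", {
  mt <- movie_toy(noise = FALSE)
  got <- extract_traces(mt$movie, rbind(c(10, 10), c(22, 20)))
  expect_length(got, 2)
  for (i in 1:2) {
    # pixel-integrated PSF within r = 3 holds ~97% of the light; accurate
    # to a few percent after background subtraction
    expect_equal(mean(got[[i]]$I_DD), mean(mt$traces[[i]]$I_DD),
                 tolerance = 0.05)
    expect_equal(mean(got[[i]]$I_AA), mean(mt$traces[[i]]$I_AA),
                 tolerance = 0.05)
  }
  # downstream E* from the movie matches the state mean
  fs <- compute_estar_s(got[[1]])
  expect_equal(mean(fs$E), 0.4, tolerance = 0.02)
})

test_that("molecules off the image edge are dropped with a message", {
  mt <- movie_toy(noise = FALSE)
  expect_message(got <- extract_traces(mt$movie, rbind(c(10, 10), c(2, 2))),
                 "off image")
  expect_length(got, 1)
})

test_that("too-short movies are rejected", {
  mt <- movie_toy(n_periods = 3)
  expect_error(detect_spots(mt$movie), "at least 5 frames")
})

test_that("movie TIFF round trip preserves frames and metadata", {
  mt <- movie_toy(n_periods = 8)
  path <- file.path(tempdir(), "toy-movie.tif")
  write_movie(mt$movie, path)
  back <- read_movie(path)
  expect_equal(dim(back$frames), dim(mt$movie$frames))
  expect_equal(back$frames, mt$movie$frames, tolerance = 1e-3)
  expect_identical(back$excitation, mt$movie$excitation)
  expect_equal(back$frame_period, mt$movie$frame_period)
  unlink(c(path, paste0(path, ".json")))
})
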