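#' Default movie layout
#'
#' Geometry for a two-channel (donor left / acceptor right) emulated TIRF
#' frame. Positions are 0-based pixel coordinates (x = column, y = row)
#' within the donor half; the acceptor image of each molecule sits at the
#' same in-half coordinates (channels are pre-registered).
#'
#' @param width total frame width (px; both halves).
#' @param height frame height (px).
#' @param positions n x 2 matrix of spot coordinates (0-based, donor half).
#' @param psf_sd Gaussian PSF standard deviation (px).
#' @param bg_pixel mean background counts per pixel per frame.
#' @param read_noise_sd per-pixel Gaussian read noise sd (counts).
#' @param pixel_size nominal pixel size (nm); metadata only.
#' @return list of class `movie_layout`.
#' @export
movie_layout <- function(width = 64, height = 32, positions,
                         psf_sd = 1.1, bg_pixel = 2, read_noise_sd = 1,
                         pixel_size = 100) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  half <- width / 2
  if (nrow(positions) > 0) {
    if (any(positions[, 1] < 4 | positions[, 1] > half - 5 |
            positions[, 2] < 4 | positions[, 2] > height - 5))
      stop("spot positions must be >= 4 px from channel borders")
    if (nrow(positions) > 1) {
      d <- as.matrix(dist(positions))
      diag(d) <- Inf
      if (min(d) < 6) stop("overlapping spots: minimum separation is 6 px")
    }
  }
  structure(list(width = width, height = height, positions = positions,
                 psf_sd = psf_sd, bg_pixel = bg_pixel,
                 read_noise_sd = read_noise_sd, pixel_size = pixel_size),
            class = "movie_layout")
}

# pixelated Gaussian PSF: exact integral of the PSF over each pixel
psf_patch <- function(x0, y0, sd, nx, ny) {
  wx <- pnorm((seq_len(nx) + 0.5 - x0) / sd) -
    pnorm((seq_len(nx) - 0.5 - x0) / sd)
  wy <- pnorm((seq_len(ny) + 0.5 - y0) / sd) -
    pnorm((seq_len(ny) - 0.5 - y0) / sd)
  outer(wy, wx)  # rows = y, cols = x
}

#' Render ALEX traces into a two-channel movie stack
#'
#' Each molecule is rendered as a pixel-integrated 2-D Gaussian PSF in the
#' donor (left) and acceptor (right) half of every frame, with intensities
#' routed by the excitation of the frame: green frames carry `I_DD` (donor
#' half) and `I_DA` (acceptor half), red frames carry `I_AA` (acceptor half).
#' Per-pixel Poisson background and Gaussian read noise are added unless
#' `noise = FALSE`.
#'
#' @param traces list of `alex_trace` (equal length).
#' @param layout a [movie_layout()] with one position per trace.
#' @param seed integer RNG seed.
#' @param noise disable all noise for oracle checks.
#' @return a `movie_stack`: list with `frames` (height x width x n_frames
#'   array of counts), `excitation` (character per frame), `layout`,
#'   `frame_period`, `t_inj`.
#' @export
render_movie <- function(traces, layout, seed = 1L, noise = TRUE) {
  stopifnot(length(traces) == nrow(layout$positions))
  set.seed(seed)
  h <- layout$height; w <- layout$width; half <- w / 2
  n_periods <- if (length(traces)) length(traces[[1]]$I_DD) else 10
  n_frames <- 2 * n_periods
  frames <- array(0, dim = c(h, w, n_frames))
  excitation <- rep(c("green", "red"), n_periods)
  patches <- lapply(seq_len(nrow(layout$positions)), function(i) {
    # +1: convert 0-based coordinates to R's 1-based pixel grid
    psf_patch(layout$positions[i, 1] + 1, layout$positions[i, 2] + 1,
              layout$psf_sd, half, h)
  })
  for (p in seq_len(n_periods)) {
    g <- matrix(0, h, w); r <- matrix(0, h, w)
    for (i in seq_along(traces)) {
      tr <- traces[[i]]
      g[, 1:half] <- g[, 1:half] + max(tr$I_DD[p], 0) * patches[[i]]
      g[, (half + 1):w] <- g[, (half + 1):w] + max(tr$I_DA[p], 0) * patches[[i]]
      r[, (half + 1):w] <- r[, (half + 1):w] + max(tr$I_AA[p], 0) * patches[[i]]
    }
    if (noise) {
      g <- matrix(rpois(h * w, g + layout$bg_pixel) +
                    rnorm(h * w, 0, layout$read_noise_sd), h, w)
      r <- matrix(rpois(h * w, r + layout$bg_pixel) +
                    rnorm(h * w, 0, layout$read_noise_sd), h, w)
      g[g < 0] <- 0; r[r < 0] <- 0
    }
    frames[, , 2 * p - 1] <- g
    frames[, , 2 * p] <- r
  }
  structure(list(frames = frames, excitation = excitation, layout = layout,
                 frame_period = if (length(traces)) traces[[1]]$frame_period
                                else NA_real_,
                 t_inj = if (length(traces)) traces[[1]]$t_inj else NA_real_),
            class = "movie_stack")
}

gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(v, n) c(rep(v[1], n), v, rep(v[length(v)], n))
  conv1 <- function(v) {
    out <- stats::filter(pad(v, r), k, sides = 2)
    as.numeric(out[(r + 1):(length(v) + r)])
  }
  m2 <- apply(m, 2, conv1)
  t(apply(m2, 1, conv1))
}

#' Detect and pair single-molecule spots in a movie
#'
#' Averages frames per excitation type, band-pass filters each channel
#' image (difference of Gaussians), finds local maxima above
#' `threshold x` robust noise, refines each to a subpixel intensity-weighted
#' centroid, pairs donor and acceptor detections by nearest neighbour within
#' `pair_radius` (identity registration), and rejects detections closer than
#' `min_sep` as overlapping.
#'
#' @param movie a `movie_stack`.
#' @param threshold detection threshold in robust-sd units.
#' @param pair_radius maximum donor-acceptor pairing distance (px).
#' @param min_sep minimum separation between spots (px).
#' @return a `spot_map`: list with `donor`, `acceptor` (0-based centroid
#'   matrices), `pairs` (paired coordinates), `aperture_radius`,
#'   `annulus_radii`, and `n_rejected_overlap`.
#' @export
detect_spots <- function(movie, threshold = 4, pair_radius = 2, min_sep = 6) {
  exc <- movie$excitation
  if (sum(exc == "green") < 5 || sum(exc == "red") < 5)
    stop("need at least 5 frames of each excitation type")
  h <- movie$layout$height; w <- movie$layout$width; half <- w / 2
  avg_g <- apply(movie$frames[, , exc == "green", drop = FALSE], c(1, 2), mean)
  avg_all <- apply(movie$frames, c(1, 2), mean)
  find_channel <- function(img) {
    bp <- gauss_blur(img, 1) - gauss_blur(img, 4)
    noise <- mad(bp)
    if (noise == 0) noise <- max(sd(bp), 1e-9)
    cand <- which(bp > threshold * noise, arr.ind = TRUE)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      y <- cand[i, 1]; x <- cand[i, 2]
      if (y < 3 || y > nrow(img) - 2 || x < 3 || x > ncol(img) - 2) next
      nb <- bp[(y - 1):(y + 1), (x - 1):(x + 1)]
      keep[i] <- bp[y, x] >= max(nb)
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) return(matrix(numeric(0), 0, 2))
    cent <- t(apply(cand, 1, function(rc) {
      y <- rc[1]; x <- rc[2]
      win <- bp[(y - 2):(y + 2), (x - 2):(x + 2)]
      win[win < 0] <- 0
      ys <- (y - 2):(y + 2); xs <- (x - 2):(x + 2)
      c(sum(outer(rep(1, 5), xs) * win) / sum(win),
        sum(outer(ys, rep(1, 5)) * win) / sum(win))
    }))
    # back to 0-based (x, y)
    cbind(cent[, 1] - 1, cent[, 2] - 1)
  }
  don <- find_channel(avg_g[, 1:half, drop = FALSE])
  acc <- find_channel(avg_all[, (half + 1):w, drop = FALSE])
  drop_overlap <- function(p) {
    if (nrow(p) < 2) return(list(p = p, n = 0L))
    d <- as.matrix(dist(p)); diag(d) <- Inf
    bad <- apply(d, 1, min) < min_sep
    if (any(bad))
      message(sum(bad), " spot(s) rejected as overlapping (< ", min_sep,
              " px separation)")
    list(p = p[!bad, , drop = FALSE], n = sum(bad))
  }
  od <- drop_overlap(don); oa <- drop_overlap(acc)
  don <- od$p; acc <- oa$p
  pairs <- matrix(numeric(0), 0, 2)
  if (nrow(don) && nrow(acc)) {
    used <- logical(nrow(acc))
    for (i in seq_len(nrow(don))) {
      d2 <- sqrt((acc[, 1] - don[i, 1])^2 + (acc[, 2] - don[i, 2])^2)
      d2[used] <- Inf
      j <- which.min(d2)
      if (d2[j] <= pair_radius) {
        used[j] <- TRUE
        pairs <- rbind(pairs, (don[i, ] + acc[j, ]) / 2)
      }
    }
  }
  structure(list(donor = don, acceptor = acc, pairs = pairs,
                 aperture_radius = 3, annulus_radii = c(5, 7),
                 n_rejected_overlap = od$n + oa$n),
            class = "spot_map")
}

#' Extract ALEX traces from a movie by aperture photometry
#'
#' For each paired spot and ALEX period, sums pixels within the circular
#' aperture and subtracts the annulus median times the aperture area
#' (Twotone-style local background), routing the three signals by excitation
#' and channel: green frames give `I_DD` (donor half) and `I_DA` (acceptor
#' half), red frames give `I_AA`. Molecules whose aperture leaves the image
#' are dropped with a message.
#'
#' @param movie a `movie_stack`.
#' @param spots a `spot_map` from [detect_spots()], or a matrix of 0-based
#'   (x, y) positions in donor-half coordinates.
#' @param aperture_radius aperture radius (px).
#' @param annulus_radii inner/outer background annulus radii (px).
#' @return list of `alex_trace`.
#' @export
extract_traces <- function(movie, spots, aperture_radius = 3,
                           annulus_radii = c(5, 7)) {
  pos <- if (inherits(spots, "spot_map")) spots$pairs else
    matrix(as.numeric(spots), ncol = 2)
  h <- movie$layout$height; w <- movie$layout$width; half <- w / 2
  exc <- movie$excitation
  gi <- which(exc == "green"); ri <- which(exc == "red")
  n_periods <- min(length(gi), length(ri))
  out <- list()
  for (m in seq_len(nrow(pos))) {
    cx <- pos[m, 1] + 1; cy <- pos[m, 2] + 1  # 1-based centers
    xs <- floor(cx - annulus_radii[2]):ceiling(cx + annulus_radii[2])
    ys <- floor(cy - annulus_radii[2]):ceiling(cy + annulus_radii[2])
    if (min(xs) < 1 || max(xs) > half || min(ys) < 1 || max(ys) > h) {
      message("molecule ", m, " dropped: aperture/annulus off image")
      next
    }
    g <- expand.grid(y = ys, x = xs)
    r2 <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
    ap <- g[r2 <= aperture_radius, ]
    an <- g[r2 >= annulus_radii[1] & r2 <= annulus_radii[2], ]
    n_ap <- nrow(ap)
    phot <- function(frame_idx, col_off) {
      vapply(frame_idx, function(f) {
        fr <- movie$frames[, , f]
        s <- sum(fr[cbind(ap$y, ap$x + col_off)])
        b <- median(fr[cbind(an$y, an$x + col_off)])
        s - b * n_ap
      }, numeric(1))
    }
    I_DD <- phot(gi[seq_len(n_periods)], 0)
    I_DA <- phot(gi[seq_len(n_periods)], half)
    I_AA <- phot(ri[seq_len(n_periods)], half)
    out[[length(out) + 1]] <- alex_trace(
      id = sprintf("spot%03d", m),
      time = (seq_len(n_periods) - 1) *
        ifelse(is.na(movie$frame_period), 1, movie$frame_period),
      I_DD = I_DD, I_DA = I_DA, I_AA = I_AA,
      frame_period = movie$frame_period, t_inj = movie$t_inj,
      source = "movie")
  }
  out
}

#' Write / read a movie stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 16-bit multi-page TIFF; the excitation sequence,
#' layout and timing go into `<path>.json`.
#'
#' @param movie a `movie_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  mx <- max(movie$frames, 1)
  scale <- 65535 / mx
  pages <- lapply(seq_len(dim(movie$frames)[3]), function(i)
    pmin(pmax(movie$frames[, , i] * scale / 65535, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  side <- list(excitation = movie$excitation, scale = scale,
               frame_period = movie$frame_period, t_inj = movie$t_inj,
               layout = movie$layout[c("width", "height", "psf_sd",
                                       "bg_pixel", "pixel_size")],
               positions = movie$layout$positions)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] / side$scale
  layout <- movie_layout(width = side$layout$width,
                         height = side$layout$height,
                         positions = matrix(side$positions, ncol = 2),
                         psf_sd = side$layout$psf_sd,
                         bg_pixel = side$layout$bg_pixel,
                         pixel_size = side$layout$pixel_size)
  structure(list(frames = frames, excitation = side$excitation,
                 layout = layout, frame_period = side$frame_period,
                 t_inj = if (is.null(side$t_inj)) NA_real_ else side$t_inj),
            class = "movie_stack")
}
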