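#' Simulate the hidden state path of one molecule
#'
#' Draws a continuous-time state trajectory for a single molecule of the
#' given archetype: static molecules occupy one state for the whole trace
#' (with a small between-molecule offset of the state mean, `between_sd`,
#' default 0.03 E* units, mimicking molecule-to-molecule detection and
#' distance heterogeneity);
#' dynamic molecules switch between their substates with exponential dwells
#' (per-state means) and the fixture's embedded branching chain; displacer
#' molecules sit in their pre-displacement state until
#' `t_inj + Exp(tau)` and then switch permanently to the displaced state.
#' Donor and acceptor photobleach times are drawn exponentially.
#'
#' @param gt a `ground_truth` object.
#' @param archetype one of `names(gt$ensemble)`.
#' @param duration trace duration (s); defaults to `gt$duration`.
#' @param seed integer RNG seed.
#' @return a `state_path` object: list with `id`, `states` (row indices into
#'   `gt$states` per segment), `entry` (segment entry times, first at 0),
#'   `state_means` (molecule-specific realized state means), `bleach_donor`,
#'   `bleach_acceptor` (s, `Inf` if beyond the trace), `archetype`,
#'   `t_displace` (s or `NA`) and `duration`.
#' @export
simulate_state_path <- function(gt, archetype, duration = gt$duration,
                                seed = 1L) {
  if (duration <= 0) stop("duration must be > 0")
  if (!archetype %in% names(gt$ensemble))
    stop("unknown archetype '", archetype, "'; valid archetypes: ",
         paste(names(gt$ensemble), collapse = ", "))
  spec <- gt$archetypes[[archetype]]
  set.seed(seed)
  state_means <- gt$states$mean
  t_displace <- NA_real_
  if (spec$kind == "static") {
    states <- spec$state
    entry <- 0
    bs <- spec$between_sd %||% 0.03
    if (bs > 0)
      state_means[spec$state] <-
        min(0.99, max(0.01, rnorm(1, state_means[spec$state], bs)))
  } else if (spec$kind == "dynamic") {
    idx <- spec$states
    B <- spec$branching
    dw <- gt$states$dwell_mean[idx]
    # start from the jump-chain stationary law weighted by dwell (time-
    # stationary start)
    occ <- stationary_occupancy(B, dw)
    cur <- sample(seq_along(idx), 1, prob = occ)
    states <- idx[cur]
    entry <- 0
    t <- rexp(1, 1 / dw[cur])
    while (t < duration) {
      cur <- sample(seq_along(idx), 1, prob = B[cur, ])
      states <- c(states, idx[cur])
      entry <- c(entry, t)
      t <- t + rexp(1, 1 / dw[cur])
    }
  } else if (spec$kind == "displacer") {
    pre <- spec$pre_state
    if (!is.null(spec$pre_between_sd) && spec$pre_between_sd > 0)
      state_means[pre] <- rnorm(1, state_means[pre], spec$pre_between_sd)
    t_displace <- gt$t_inj + rexp(1, 1 / spec$tau)
    if (t_displace < duration) {
      states <- c(pre, gt$displaced_state)
      entry <- c(0, t_displace)
    } else {
      states <- pre
      entry <- 0
    }
  } else stop("unknown archetype kind '", spec$kind, "'")
  bl_d <- rexp(1, 1 / gt$photobleach_means[["donor"]])
  bl_a <- rexp(1, 1 / gt$photobleach_means[["acceptor"]])
  structure(list(
    id = paste0(archetype, "-", seed),
    states = as.integer(states), entry = as.numeric(entry),
    state_means = state_means,
    bleach_donor = if (bl_d < duration) bl_d else Inf,
    bleach_acceptor = if (bl_a < duration) bl_a else Inf,
    archetype = archetype, t_displace = t_displace,
    duration = duration
  ), class = "state_path")
}

# time-stationary occupancy of a semi-Markov switcher with embedded chain B
# and mean dwells dw (power iteration on the jump chain)
stationary_occupancy <- function(B, dw) {
  v <- rep(1 / nrow(B), nrow(B))
  for (i in 1:200) v <- as.numeric(v %*% B)
  occ <- v * dw
  occ / sum(occ)
}

state_at <- function(path, t) {
  path$states[findInterval(t, path$entry)]
}

#' Emit an ALEX intensity trace from a state path
#'
#' The generative inverse of the apparent-FRET equation: on each
#' green-excitation frame the expected intensities are
#' `I_DA = total_rate * E` and `I_DD = total_rate * (1 - E)` with `E` the
#' (jittered) current state mean; on each red frame `I_AA = total_rate` while
#' the acceptor is alive. Counts receive Poisson shot noise on signal plus
#' background and Gaussian read noise, then the known mean background is
#' subtracted (traces are background-corrected, so values can dip slightly
#' below zero). After donor bleach, `I_DD` and `I_DA` fall to background;
#' after acceptor bleach the FRET pathway is lost (`E` collapses to 0, the
#' donor de-quenches, and `I_AA` falls to background).
#'
#' @param path a `state_path`.
#' @param gt the `ground_truth` used to draw `path`.
#' @param seed integer RNG seed.
#' @param noise if `FALSE`, return exact expectations (no shot/read noise and
#'   no per-period emission jitter).
#' @return an `alex_trace` object.
#' @export
emit_alex_trace <- function(path, gt, seed = 1L, noise = TRUE) {
  n_periods <- floor(path$duration / gt$frame_period)
  if (n_periods < 2) stop("path must cover at least 2 ALEX periods")
  set.seed(seed)
  t0 <- (seq_len(n_periods) - 1) * gt$frame_period
  # state sampled at the midpoint of the green half-frame
  t_green <- t0 + gt$frame_period / 4
  t_red <- t0 + 3 * gt$frame_period / 4
  st <- state_at(path, t_green)
  E <- path$state_means[st]
  if (noise) {
    E <- E + rnorm(n_periods, 0, gt$states$sd[st])
    E <- pmin(0.999, pmax(0.001, E))
  }
  donor_alive <- t_green < path$bleach_donor
  acc_alive_g <- t_green < path$bleach_acceptor
  acc_alive_r <- t_red < path$bleach_acceptor
  rate <- gt$total_rate
  mu_dd <- ifelse(donor_alive, ifelse(acc_alive_g, rate * (1 - E), rate), 0)
  mu_da <- ifelse(donor_alive & acc_alive_g, rate * E, 0)
  mu_aa <- ifelse(acc_alive_r, rate, 0)
  bg_d <- gt$background[["donor"]]
  bg_a <- gt$background[["acceptor"]]
  if (noise) {
    rn <- gt$read_noise_sd
    I_DD <- rpois(n_periods, mu_dd + bg_d) + rnorm(n_periods, 0, rn) - bg_d
    I_DA <- rpois(n_periods, mu_da + bg_a) + rnorm(n_periods, 0, rn) - bg_a
    I_AA <- rpois(n_periods, mu_aa + bg_a) + rnorm(n_periods, 0, rn) - bg_a
  } else {
    I_DD <- mu_dd; I_DA <- mu_da; I_AA <- mu_aa
  }
  alex_trace(id = path$id, time = t0, I_DD = I_DD, I_DA = I_DA, I_AA = I_AA,
             frame_period = gt$frame_period, t_inj = gt$t_inj,
             source = "sim")
}

#' Construct an ALEX trace object
#'
#' Per-molecule, per-period background-corrected intensities. Channels must
#' have equal length; values may be slightly negative after background
#' subtraction.
#'
#' @param id molecule identifier.
#' @param time period start times (s).
#' @param I_DD,I_DA,I_AA per-period intensities (counts).
#' @param frame_period s per ALEX period.
#' @param t_inj injection time (s) or `NA`.
#' @param source `"sim"`, `"movie"` or `"table"`.
#' @return an `alex_trace` object.
#' @export
alex_trace <- function(id, time, I_DD, I_DA, I_AA, frame_period,
                       t_inj = NA_real_, source = "table") {
  n <- length(I_DD)
  stopifnot(length(I_DA) == n, length(I_AA) == n, length(time) == n,
            all(is.finite(I_DD)), all(is.finite(I_DA)), all(is.finite(I_AA)))
  structure(list(id = id, time = time, I_DD = I_DD, I_DA = I_DA, I_AA = I_AA,
                 frame_period = frame_period, t_inj = t_inj, source = source),
            class = "alex_trace")
}

#' @export
print.alex_trace <- function(x, ...) {
  cat("<alex_trace>", x$id, "-", length(x$I_DD), "periods @",
      x$frame_period, "s\n")
  invisible(x)
}

#' Simulate an ensemble of molecules from a ground-truth fixture
#'
#' Draws archetypes by the fixture's ensemble fractions, simulates a state
#' path and an ALEX trace per molecule (each with a deterministic child seed),
#' and returns both, so recovery can be scored against the known truth.
#'
#' @param gt a `ground_truth` object.
#' @param n_molecules number of molecules.
#' @param duration trace duration (s); defaults to `gt$duration`.
#' @param seed integer RNG seed (all child seeds derive from it).
#' @param noise passed to [emit_alex_trace()].
#' @param archetype optional single archetype name to override the ensemble
#'   draw (e.g. to simulate only dynamic molecules).
#' @return list with `paths` (list of `state_path`), `traces` (list of
#'   `alex_trace`) and `archetypes` (character vector).
#' @export
simulate_ensemble <- function(gt, n_molecules, duration = gt$duration,
                              seed = 1L, noise = TRUE, archetype = NULL) {
  set.seed(seed)
  if (is.null(archetype)) {
    arch <- sample(names(gt$ensemble), n_molecules, replace = TRUE,
                   prob = gt$ensemble)
  } else {
    if (!archetype %in% names(gt$ensemble))
      stop("unknown archetype '", archetype, "'")
    arch <- rep(archetype, n_molecules)
  }
  paths <- vector("list", n_molecules)
  traces <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    paths[[i]] <- simulate_state_path(gt, arch[i], duration,
                                      seed = (seed + 13L * i) %% 2000000000L)
    paths[[i]]$id <- sprintf("mol%04d", i)
    traces[[i]] <- emit_alex_trace(paths[[i]], gt,
                                   seed = (seed + 13L * i + 7L) %% 2000000000L,
                                   noise = noise)
  }
  list(paths = paths, traces = traces, archetypes = arch)
}

#' Draw displacement delays from a fixture's two-component mixture
#'
#' Samples `n` displacement times `t_d` (measured from injection) from the
#' fixture's exponential mixture `sum_i w_i Exp(tau_i)`.
#'
#' @param gt a real-time `ground_truth` with `displacement_taus`.
#' @param n number of draws.
#' @param seed integer RNG seed.
#' @return numeric vector of delays (s).
#' @export
draw_displacement_delays <- function(gt, n, seed = 1L) {
  if (is.null(gt$displacement_taus))
    stop("fixture has no displacement kinetics")
  set.seed(seed)
  comp <- sample(seq_along(gt$displacement_taus), n, replace = TRUE,
                 prob = gt$displacement_weights)
  rexp(n, 1 / gt$displacement_taus[comp])
}

#' Write / read ALEX traces as tabular text with a JSON manifest
#'
#' Traces are stored one row per period (`molecule`, `period`, `time`,
#' `I_DD`, `I_DA`, `I_AA`, tab-separated) next to a JSON manifest holding
#' `frame_period`, `t_inj`, the fixture name and the seed.
#'
#' @param traces list of `alex_trace`.
#' @param dir output directory (created if needed).
#' @param manifest named list of extra manifest fields.
#' @return `dir`, invisibly.
#' @export
write_traces <- function(traces, dir, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(traces, function(tr)
    data.frame(molecule = tr$id, period = seq_along(tr$I_DD), time = tr$time,
               I_DD = tr$I_DD, I_DA = tr$I_DA, I_AA = tr$I_AA)))
  write.table(tab, file.path(dir, "traces.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  man <- modifyList(list(frame_period = traces[[1]]$frame_period,
                         t_inj = traces[[1]]$t_inj,
                         n_molecules = length(traces)), manifest)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' @rdname write_traces
#' @export
read_traces <- function(dir) {
  tab <- read.table(file.path(dir, "traces.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  t_inj <- if (is.null(man$t_inj)) NA_real_ else man$t_inj
  lapply(split(tab, tab$molecule), function(d) {
    d <- d[order(d$period), ]
    alex_trace(d$molecule[1], d$time, d$I_DD, d$I_DA, d$I_AA,
               frame_period = man$frame_period, t_inj = t_inj,
               source = "table")
  })
}
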