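#' Ground-truth parameter set for the smFRET simulator
#'
#' A `ground_truth` object holds everything needed to simulate an ensemble of
#' ALEX smFRET molecules: an inventory of E* states (mean, emission sd, mean
#' dwell), an archetype composition (static molecules per state, dynamic
#' switchers, fast/slow displacers, inactive molecules), displacement-delay
#' time constants, photophysics (photobleaching, background, count rates) and
#' acquisition timing. The same object is used to generate data and to score
#' parameter recovery.
#'
#' @param name identifier for the parameter set.
#' @param states data.frame with columns `label`, `mean` (E*, in \[0,1\]),
#'   `sd` (per-period emission sd in E* units) and `dwell_mean` (s; `NA` for
#'   states only ever occupied statically).
#' @param ensemble named numeric vector of archetype fractions (sums to 1).
#' @param archetypes named list, one entry per ensemble name. Each entry is a
#'   list with `kind` one of `"static"` (field `state`: row index into
#'   `states`), `"dynamic"` (fields `states`, `branching`), or `"displacer"`
#'   (fields `pre_state`, `tau`, `pre_between_sd`).
#' @param displacement_taus length-2 numeric `(tau_short, tau_long)` in s, or
#'   `NULL` for equilibrium sets.
#' @param displacement_weights length-2 numeric summing to 1.
#' @param displaced_state row index of the displaced E* state.
#' @param photobleach_means named numeric `(donor, acceptor)` mean bleach
#'   times in s.
#' @param background named numeric `(donor, acceptor)` mean background
#'   counts/frame per channel.
#' @param total_rate detected counts per excitation frame for an unbleached
#'   molecule.
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param frame_period s per ALEX period.
#' @param alex_scheme `"interleaved-50ms"` or `"per-frame-400ms"`.
#' @param duration default trace duration (s).
#' @param t_inj NTP injection time (s) for real-time sets, `NA` otherwise.
#' @param reported named list of the published estimates this fixture encodes
#'   (used by recovery tests; not consumed by the simulator).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(name, states, ensemble, archetypes,
                         displacement_taus = NULL,
                         displacement_weights = NULL,
                         displaced_state = NULL,
                         photobleach_means = c(donor = 60, acceptor = 80),
                         background = c(donor = 50, acceptor = 50),
                         total_rate = 600, read_noise_sd = 10,
                         frame_period = 0.1,
                         alex_scheme = c("interleaved-50ms", "per-frame-400ms"),
                         duration = 50, t_inj = NA_real_,
                         reported = list()) {
  alex_scheme <- match.arg(alex_scheme)
  gt <- structure(list(
    name = name, states = states, ensemble = ensemble,
    archetypes = archetypes,
    displacement_taus = displacement_taus,
    displacement_weights = displacement_weights,
    displaced_state = displaced_state,
    photobleach_means = photobleach_means, background = background,
    total_rate = total_rate, read_noise_sd = read_noise_sd,
    frame_period = frame_period, alex_scheme = alex_scheme,
    duration = duration, t_inj = t_inj, reported = reported
  ), class = "ground_truth")
  validate_ground_truth(gt)
  gt
}

#' Validate a ground_truth object
#'
#' Checks the invariants: ensemble fractions nonnegative and summing to 1,
#' state means in \[0,1\], positive dwell/bleach means and displacement taus,
#' displacement weights summing to 1.
#'
#' @param gt a `ground_truth` object.
#' @return `gt`, invisibly; errors if an invariant is violated.
#' @export
validate_ground_truth <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  if (any(gt$ensemble < 0)) stop("ensemble fractions must be >= 0")
  if (abs(sum(gt$ensemble) - 1) > 1e-9) stop("ensemble fractions must sum to 1")
  if (!all(names(gt$ensemble) %in% names(gt$archetypes)))
    stop("every ensemble entry needs an archetype definition")
  if (any(gt$states$mean < 0 | gt$states$mean > 1))
    stop("state means must lie in [0, 1]")
  dw <- gt$states$dwell_mean
  if (any(!is.na(dw) & dw <= 0)) stop("dwell means must be > 0")
  if (any(gt$photobleach_means <= 0)) stop("photobleach means must be > 0")
  if (!is.null(gt$displacement_taus)) {
    if (any(gt$displacement_taus <= 0)) stop("displacement taus must be > 0")
    if (abs(sum(gt$displacement_weights) - 1) > 1e-9)
      stop("displacement weights must sum to 1")
  }
  invisible(gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", x$name, "\n")
  cat("  states:", paste(sprintf("%s(%.2f)", x$states$label, x$states$mean),
                         collapse = ", "), "\n")
  cat("  ensemble:", paste(sprintf("%s=%.3f", names(x$ensemble), x$ensemble),
                           collapse = ", "), "\n")
  cat("  scheme:", x$alex_scheme, " frame:", x$frame_period, "s",
      " duration:", x$duration, "s\n")
  if (!is.na(x$t_inj)) cat("  t_inj:", x$t_inj, "s  taus:",
                           paste(x$displacement_taus, collapse = "/"), "s\n")
  invisible(x)
}

#' Embedded jump chain matching target occupancies and dwell means
#'
#' For a continuous-time switcher with exponential dwells, the stationary
#' time-occupancy is occ_i proportional to p_i * dwell_i, where p is the
#' stationary law of the embedded jump chain. Given target occupancies and
#' per-state mean dwells this constructs a reversible zero-diagonal branching
#' matrix whose jump-chain stationary law is v_i proportional to
#' occ_i / dwell_i, using symmetric edge flows. Feasibility requires
#' max(v) <= 1/2 (a state cannot receive more jump flux than all others emit).
#'
#' @param occ target stationary occupancies (time fractions; sum to 1).
#' @param dwell per-state mean dwell times (s).
#' @return branching (embedded transition) matrix with zero diagonal.
#' @export
dynamic_branching <- function(occ, dwell) {
  stopifnot(length(occ) == length(dwell), all(occ > 0), all(dwell > 0))
  K <- length(occ)
  v <- occ / dwell
  v <- v / sum(v)
  if (K == 1) return(matrix(1, 1, 1))
  if (K == 2) {
    # forced alternation; occupancies are then dwell-determined
    return(matrix(c(0, 1, 1, 0), 2, 2))
  }
  if (max(v) > 0.5 + 1e-9)
    stop("infeasible occupancy/dwell combination: max jump flux ",
         sprintf("%.3f", max(v)), " exceeds 1/2")
  if (K == 3) {
    f <- matrix(0, 3, 3)
    f[1, 2] <- f[2, 1] <- (v[1] + v[2] - v[3]) / 2
    f[1, 3] <- f[3, 1] <- (v[1] + v[3] - v[2]) / 2
    f[2, 3] <- f[3, 2] <- (v[2] + v[3] - v[1]) / 2
    if (any(f < -1e-12)) stop("infeasible occupancy/dwell combination")
    f[f < 0] <- 0
    B <- f / rowSums(f)
    return(B)
  }
  # K > 3: proportional-attraction chain (approximate stationary law)
  B <- matrix(rep(v, each = K), K, K)
  diag(B) <- 0
  B / rowSums(B)
}

#' Probability that a displacement event is recorded before photobleaching
#'
#' A displacer's event is observed only if both fluorophores survive past the
#' displacement time plus the stabilization window. With exponential
#' bleaching (joint survival rate 1/tau_eff = 1/tau_D + 1/tau_A) and
#' displacement at t_inj + Exp(tau_i) drawn from a two-component mixture,
#' the detection probability has the closed form
#' sum_i w_i * exp(-(t_inj + t_stab)/tau_eff) / (1 + tau_i/tau_eff).
#'
#' @param taus displacement time constants (s).
#' @param weights mixture weights.
#' @param photobleach_means named `(donor, acceptor)` bleach means (s).
#' @param t_inj injection time (s).
#' @param t_stab stabilization window (s) required after displacement.
#' @return scalar probability.
#' @export
displacer_detection_prob <- function(taus, weights, photobleach_means,
                                     t_inj, t_stab = 4) {
  tau_eff <- 1 / sum(1 / photobleach_means)
  sum(weights * exp(-(t_inj + t_stab) / tau_eff) / (1 + taus / tau_eff))
}

state_row <- function(label, mean, sd, dwell = NA_real_) {
  data.frame(label = label, mean = mean, sd = sd, dwell_mean = dwell,
             stringsAsFactors = FALSE)
}

# Equilibrium fixture: static composition proportional to the published
# framewise decomposition, with the dynamic archetype layered on top.
equilibrium_fixture <- function(name, static_means, static_sds, static_occ,
                                dyn_frac = 0, dyn_means = NULL, dyn_sds = NULL,
                                dyn_occ = NULL, dyn_dwell = NULL,
                                reported = list()) {
  states <- do.call(rbind, lapply(seq_along(static_means), function(i)
    state_row(paste0("static-", i), static_means[i], static_sds[i])))
  archetypes <- list()
  ensemble <- numeric(0)
  for (i in seq_along(static_means)) {
    nm <- paste0("static-", i)
    archetypes[[nm]] <- list(kind = "static", state = i)
    ensemble[nm] <- (1 - dyn_frac) * static_occ[i]
  }
  if (dyn_frac > 0) {
    i0 <- nrow(states)
    states <- rbind(states, do.call(rbind, lapply(seq_along(dyn_means),
      function(i) state_row(paste0("dyn-", i), dyn_means[i], dyn_sds[i],
                            dyn_dwell[i]))))
    archetypes[["dynamic"]] <- list(
      kind = "dynamic", states = i0 + seq_along(dyn_means),
      branching = dynamic_branching(dyn_occ, dyn_dwell))
    ensemble["dynamic"] <- dyn_frac
  }
  ground_truth(name, states, ensemble, archetypes,
               displaced_state = which.min(static_means),
               reported = reported)
}

# Real-time fixture: published class fractions are post-censoring; the
# underlying displacer fraction is recovered by inverting the analytic
# detection probability so that the simulated observed Class I+II fraction
# matches the published one.
realtime_fixture <- function(name, taus, weights, classes_obs, pre_means,
                             pre_between_sd = 0.08, displaced_mean = 0.15,
                             t_inj = 30, reported = list()) {
  pb <- c(donor = 400, acceptor = 667)
  frame_period <- 0.4
  states <- rbind(
    state_row("displaced", displaced_mean, 0.045),
    state_row("dyn-1", 0.22, 0.055, 0.6),
    state_row("dyn-2", 0.37, 0.055, 1.0),
    state_row("dyn-3", 0.59, 0.055, 0.8),
    state_row("pre-fast", pre_means[1], 0.065),
    state_row("pre-slow", pre_means[2], 0.065),
    state_row("inactive", 0.40, 0.065))
  p_det <- displacer_detection_prob(taus, weights, pb, t_inj,
                                    t_stab = 10 * frame_period)
  f_disp <- classes_obs[1] / p_det
  f_dyn <- classes_obs[2]
  f_inact <- 1 - f_disp - f_dyn
  if (f_inact < 0) stop("infeasible real-time composition for ", name)
  ensemble <- c("fast-displacer" = f_disp * weights[1],
                "slow-displacer" = f_disp * weights[2],
                "dynamic" = f_dyn, "inactive" = f_inact)
  archetypes <- list(
    "fast-displacer" = list(kind = "displacer", pre_state = 5L,
                            tau = taus[1], pre_between_sd = pre_between_sd),
    "slow-displacer" = list(kind = "displacer", pre_state = 6L,
                            tau = taus[2], pre_between_sd = pre_between_sd),
    "dynamic" = list(kind = "dynamic", states = 2:4,
                     branching = dynamic_branching(c(0.17, 0.54, 0.29),
                                                   c(0.6, 1.0, 0.8))),
    "inactive" = list(kind = "static", state = 7L))
  ground_truth(name, states, ensemble, archetypes,
               displacement_taus = taus, displacement_weights = weights,
               displaced_state = 1L, photobleach_means = pb,
               frame_period = frame_period, alex_scheme = "per-frame-400ms",
               duration = 500, t_inj = t_inj, reported = reported)
}

fixture_builders <- function() list(
  "GT-RPitc2-lacCONS" = function() equilibrium_fixture(
    "GT-RPitc2-lacCONS",
    static_means = c(0.14, 0.38), static_sds = c(0.045, 0.065),
    static_occ = c(0.07, 0.93),
    dyn_frac = 0.18, dyn_means = c(0.22, 0.37, 0.59),
    dyn_sds = c(0.055, 0.055, 0.055),
    dyn_occ = c(0.17, 0.54, 0.29), dyn_dwell = c(0.6, 1.0, 0.8),
    reported = list(major_mean = 0.38, major_frac = 93, displaced_frac = 7,
                    dynamic_frac = 18, dyn_means = c(0.22, 0.37, 0.59),
                    dyn_occ = c(17, 54, 29))),
  "GT-holo" = function() equilibrium_fixture(
    "GT-holo",
    static_means = c(0.15, 0.37, 0.69), static_sds = c(0.045, 0.065, 0.06),
    static_occ = c(0.10, 0.72, 0.18),
    dyn_frac = 0.28, dyn_means = c(0.22, 0.45, 0.70),
    dyn_sds = c(0.055, 0.055, 0.055),
    dyn_occ = c(0.28, 0.54, 0.18), dyn_dwell = c(0.5, 0.8, 0.65),
    reported = list(dynamic_frac = 28, dyn_means = c(0.22, 0.45, 0.70))),
  "GT-RPitc11-lacCONS" = function() equilibrium_fixture(
    "GT-RPitc11-lacCONS",
    static_means = c(0.14, 0.38), static_sds = c(0.045, 0.065),
    static_occ = c(0.18, 0.82),
    dyn_frac = 0.21, dyn_means = c(0.23, 0.42, 0.64),
    dyn_sds = c(0.055, 0.055, 0.055),
    dyn_occ = c(0.06, 0.52, 0.42), dyn_dwell = c(1.4, 1.3, 1.1),
    reported = list(displaced_frac = 18, dynamic_frac = 21,
                    dyn_means = c(0.23, 0.42, 0.64))),
  "GT-RDe14" = function() equilibrium_fixture(
    "GT-RDe14",
    static_means = c(0.14, 0.38), static_sds = c(0.045, 0.065),
    static_occ = c(0.31, 0.69),
    dyn_frac = 0.13, dyn_means = c(0.23, 0.42, 0.64),
    dyn_sds = c(0.055, 0.055, 0.055),
    dyn_occ = c(0.06, 0.52, 0.42), dyn_dwell = c(1.4, 1.3, 1.1),
    reported = list(displaced_frac = 31, dynamic_frac = 13)),
  "GT-RPo-pR" = function() equilibrium_fixture(
    "GT-RPo-pR",
    static_means = c(0.14, 0.43), static_sds = c(0.045, 0.065),
    static_occ = c(0.14, 0.86),
    reported = list(major_mean = 0.43, major_frac = 86, displaced_frac = 14)),
  "GT-RPo-rrnBP1" = function() equilibrium_fixture(
    "GT-RPo-rrnBP1",
    static_means = c(0.14, 0.43), static_sds = c(0.045, 0.065),
    static_occ = c(0.06, 0.94),
    reported = list(incleft_frac = 94, displaced_frac = 6)),
  "GT-realtime-lacCONS-OH" = function() realtime_fixture(
    "GT-realtime-lacCONS-OH", taus = c(14, 190), weights = c(0.90, 0.10),
    classes_obs = c(0.25, 0.44, 0.31), pre_means = c(0.42, 0.47),
    reported = list(class_I_II = 25, class_III = 44, class_IV = 31,
                    tau_short = 14, tau_long = 190, frac_short = 90,
                    e0_fast = 0.42, e0_slow = 0.47, boundary_printed = 31)),
  "GT-realtime-lacCONS-ppp" = function() realtime_fixture(
    "GT-realtime-lacCONS-ppp", taus = c(1.4, 70), weights = c(0.97, 0.03),
    classes_obs = c(0.41, 0.27, 0.32), pre_means = c(0.42, 0.47),
    reported = list(class_I_II = 41, tau_short = 1.4, tau_long = 70,
                    frac_short = 97, boundary_printed = 4)),
  "GT-realtime-pR" = function() realtime_fixture(
    "GT-realtime-pR", taus = c(17, 185), weights = c(0.88, 0.12),
    classes_obs = c(0.42, 0.36, 0.22), pre_means = c(0.46, 0.48),
    reported = list(class_I_II = 42, tau_short = 17, tau_long = 185,
                    frac_short = 88, e0_fast = 0.46, e0_slow = 0.48)),
  "GT-realtime-rrnBP1" = function() realtime_fixture(
    "GT-realtime-rrnBP1", taus = c(3.8, 36), weights = c(0.84, 0.16),
    classes_obs = c(0.39, 0.23, 0.38), pre_means = c(0.49, 0.49),
    reported = list(class_I_II = 39, tau_short = 3.8, tau_long = 36,
                    frac_short = 84, e0_fast = 0.49, e0_slow = 0.49))
)

#' Named ground-truth fixtures
#'
#' Returns a versioned, named `ground_truth` parameter set from the built-in
#' registry. Fixture state means, occupancies, dwell ranges, displacement
#' time constants and class fractions encode the published estimates for the
#' corresponding complexes (lacCONS, pR and rrnBP1 promoters; equilibrium and
#' real-time NTP-injection experiments).
#'
#' @param name fixture name; see `fixture_names()`.
#' @return a `ground_truth` object.
#' @examples
#' gt <- build_fixture("GT-realtime-lacCONS-OH")
#' gt$displacement_taus  # 14 and 190 s
#' @export
build_fixture <- function(name) {
  reg <- fixture_builders()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]()
}

#' @rdname build_fixture
#' @export
fixture_names <- function() names(fixture_builders())
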