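#' Apparent FRET efficiency and stoichiometry from an ALEX trace
#'
#' Computes the per-period apparent FRET efficiency
#' `E* = I_DA / (I_DD + I_DA)` and stoichiometry
#' `S = (I_DD + I_DA) / (I_DD + I_DA + I_AA)`. Periods where the relevant
#' denominator is not positive are flagged undefined (`ok_E` / `ok_S` FALSE)
#' and carry `NA`; defined `E*` values are clipped to \[0, 1\].
#'
#' @param trace an `alex_trace`.
#' @return a `fret_series`: data.frame with columns `time`, `E`, `S`, `ok_E`,
#'   `ok_S`, with the trace's `id`, `frame_period` and `t_inj` as attributes.
#' @export
compute_estar_s <- function(trace) {
  den_e <- trace$I_DD + trace$I_DA
  den_s <- den_e + trace$I_AA
  ok_E <- den_e > 0
  ok_S <- den_s > 0
  E <- ifelse(ok_E, pmin(1, pmax(0, trace$I_DA / den_e)), NA_real_)
  S <- ifelse(ok_S, den_e / den_s, NA_real_)
  out <- data.frame(time = trace$time, E = E, S = S, ok_E = ok_E, ok_S = ok_S)
  attr(out, "id") <- trace$id
  attr(out, "frame_period") <- trace$frame_period
  attr(out, "t_inj") <- trace$t_inj
  class(out) <- c("fret_series", "data.frame")
  out
}

#' Leakage and direct-excitation correction factors
#'
#' `leakage_factor()` estimates donor leakage into the acceptor channel from
#' the mean apparent FRET of donor-only molecules,
#' `Lk = E*_D-only / (1 - E*_D-only)`. `direct_excitation_factor()` estimates
#' acceptor direct excitation from the mean stoichiometry of acceptor-only
#' molecules, `Dir = S_A-only / (1 - S_A-only)`.
#'
#' @param e_donly apparent FRET values of donor-only molecules.
#' @return the scalar correction factor.
#' @export
leakage_factor <- function(e_donly) {
  e_donly <- e_donly[is.finite(e_donly)]
  if (length(e_donly) == 0) stop("no donor-only E* values supplied")
  m <- mean(e_donly)
  m / (1 - m)
}

#' @rdname leakage_factor
#' @param s_aonly stoichiometry values of acceptor-only molecules.
#' @export
direct_excitation_factor <- function(s_aonly) {
  s_aonly <- s_aonly[is.finite(s_aonly)]
  if (length(s_aonly) == 0) stop("no acceptor-only S values supplied")
  m <- mean(s_aonly)
  m / (1 - m)
}

#' Correction factors container
#'
#' @param Lk leakage factor (>= 0).
#' @param Dir direct-excitation factor (>= 0).
#' @param gamma detection factor (> 0).
#' @return list of class `correction_factors`.
#' @export
correction_factors <- function(Lk = 0, Dir = 0, gamma = 1) {
  stopifnot(Lk >= 0, Dir >= 0, gamma > 0)
  structure(list(Lk = Lk, Dir = Dir, gamma = gamma),
            class = "correction_factors")
}

#' Accurate FRET from apparent FRET and stoichiometry
#'
#' Applies the leakage / direct-excitation correction to obtain the FRET
#' proximity ratio
#' `E_PR = (1 - Dir*(1-S)/S - Lk*(1-E*)/E*) / ((1-E*)/E* + 1 - Dir*(1-S)/S)`
#' and then the detection-factor correction
#' `E_a = E_PR / (gamma - (gamma - 1) * E_PR)`. With `Lk = Dir = 0` and
#' `gamma = 1` the transform is the identity on `E*`. Inputs outside (0, 1)
#' or yielding zero denominators are flagged `NA`.
#'
#' @param E apparent FRET values in (0, 1).
#' @param S stoichiometry values in (0, 1).
#' @param cf a [correction_factors()] object.
#' @return data.frame with columns `E_pr` and `E_a`.
#' @export
accurate_fret <- function(E, S, cf = correction_factors()) {
  stopifnot(length(E) == length(S))
  ok <- is.finite(E) & is.finite(S) & E > 0 & E < 1 & S > 0 & S < 1
  inv_e <- (1 - E) / E
  dterm <- cf$Dir * (1 - S) / S
  num <- 1 - dterm - cf$Lk * inv_e
  den <- inv_e + 1 - dterm
  e_pr <- ifelse(ok & abs(den) > .Machine$double.eps, num / den, NA_real_)
  den2 <- cf$gamma - (cf$gamma - 1) * e_pr
  e_a <- ifelse(is.finite(e_pr) & abs(den2) > .Machine$double.eps,
                e_pr / den2, NA_real_)
  data.frame(E_pr = e_pr, E_a = e_a)
}

#' Detection factor from an acceptor-photobleaching event
#'
#' The detection factor is `gamma = dI_DA / dI_DD`, the ratio of the drop in
#' acceptor emission to the rise in donor emission across a single acceptor
#' photobleach. Intensities are averaged over up to `flank` periods on either
#' side of the bleach; events within `min_flank` periods of either trace end
#' are rejected (insufficient flanking data).
#'
#' @param trace an `alex_trace`.
#' @param bleach_period acceptor bleach period index (e.g. from
#'   [qc_trace()]).
#' @param flank maximum flanking periods averaged on each side.
#' @param min_flank minimum flanking periods required.
#' @return scalar gamma, or `NA` with a `"reason"` attribute.
#' @export
gamma_factor <- function(trace, bleach_period, flank = 20, min_flank = 5) {
  n <- length(trace$I_DD)
  if (is.na(bleach_period) || bleach_period <= min_flank ||
      bleach_period > n - min_flank) {
    out <- NA_real_
    attr(out, "reason") <- "no usable acceptor bleach event"
    return(out)
  }
  pre <- max(1, bleach_period - flank):(bleach_period - 1)
  post <- bleach_period:min(n, bleach_period + flank - 1)
  d_da <- mean(trace$I_DA[pre]) - mean(trace$I_DA[post])
  d_dd <- mean(trace$I_DD[post]) - mean(trace$I_DD[pre])
  if (d_dd <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "donor intensity did not rise across bleach"
    return(out)
  }
  d_da / d_dd
}

#' Ensemble detection factor
#'
#' Median of per-molecule [gamma_factor()] values over traces with a usable
#' single acceptor-bleach event (robust at small n).
#'
#' @param traces list of `alex_trace`.
#' @param bleach_periods acceptor bleach period per trace (`NA` if none).
#' @param ... passed to [gamma_factor()].
#' @return list with `gamma` (ensemble median), `per_molecule`, `n_used`.
#' @export
ensemble_gamma <- function(traces, bleach_periods, ...) {
  g <- mapply(function(tr, bp) gamma_factor(tr, bp, ...),
              traces, bleach_periods)
  list(gamma = median(g, na.rm = TRUE), per_molecule = g,
       n_used = sum(is.finite(g)))
}

#' Convert between FRET efficiency and donor-acceptor distance
#'
#' `R = R0 * ((1 - E) / E)^(1/6)` and its inverse
#' `E = 1 / (1 + (R / R0)^6)`, with Förster radius `R0 = 60` Å by default.
#'
#' @param E FRET efficiency in (0, 1).
#' @param R distance in Å (> 0).
#' @param R0 Förster radius (Å).
#' @return distance in Å, or efficiency.
#' @export
fret_to_distance <- function(E, R0 = 60) {
  if (any(!is.finite(E) | E <= 0 | E >= 1))
    stop("E must lie strictly inside (0, 1)")
  R0 * ((1 - E) / E)^(1 / 6)
}

#' @rdname fret_to_distance
#' @export
distance_to_fret <- function(R, R0 = 60) {
  if (any(!is.finite(R) | R <= 0)) stop("R must be > 0")
  1 / (1 + (R / R0)^6)
}

#' Degree-of-labelling from absorbance measurements
#'
#' Computes the doubly labelled protein concentration and per-dye labelling
#' efficiencies from absorbances at 280 nm (protein), 570 nm (Cy3B) and
#' 665 nm (Alexa647), correcting the 280 nm signal for dye absorbance:
#' `conc = (A280 - eps_Cy3B,280 * A570/eps_Cy3B,570
#'          - eps_A647,280 * A665/eps_A647,665) / eps_P,280`,
#' `efficiency_dye = 100 * (A_dye/eps_dye) / conc` (%).
#'
#' @param A280,A570,A665 measured absorbances.
#' @param eps named molar extinction coefficients (1/M/cm); defaults are the
#'   values for sigma70, Cy3B and Alexa647.
#' @return list with `concentration` (M), `cy3b_pct`, `alexa647_pct`.
#' @export
labeling_efficiency <- function(A280, A570, A665,
                                eps = c(p280 = 39760, cy3b280 = 10400,
                                        a647_280 = 7350, cy3b570 = 130000,
                                        a647_665 = 245000)) {
  stopifnot(all(eps > 0), A280 >= 0, A570 >= 0, A665 >= 0)
  c_cy3b <- A570 / eps[["cy3b570"]]
  c_a647 <- A665 / eps[["a647_665"]]
  conc <- (A280 - eps[["cy3b280"]] * c_cy3b - eps[["a647_280"]] * c_a647) /
    eps[["p280"]]
  if (conc <= 0) stop("computed product concentration is not positive")
  list(concentration = conc,
       cy3b_pct = 100 * c_cy3b / conc,
       alexa647_pct = 100 * c_a647 / conc)
}
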