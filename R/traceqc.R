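#' Change-point detection of photobleach steps
#'
#' Binary segmentation on mean shifts, restricted to persistent downward
#' steps on a trace that ends near background. A candidate change-point is
#' accepted when its residual-sum-of-squares improvement exceeds
#' `penalty * sigma^2 * log(n)` with `sigma` the robust per-period noise
#' (MAD of first differences / sqrt(2)). A downward step counts as a bleach
#' step when (i) its drop exceeds `min_drop_sd * sigma`, (ii) no later
#' segment recovers above half the drop (persistence; blinking recovers and
#' is handled by [blink_filter()]), and (iii) the final segment level lies
#' below `near_bg_frac` of the maximum segment level (the channel really
#' bleached to background).
#'
#' @param x per-period intensity series (background-corrected counts).
#' @param penalty change-point acceptance penalty multiplier.
#' @param min_drop_sd minimum step size in noise-sd units.
#' @param near_bg_frac "near background" level as a fraction of the maximum
#'   segment level.
#' @param max_cp maximum number of change-points searched.
#' @return list with `n_steps`, `times` (period index of the first period
#'   after each step), `levels` (segment means), `background` (post-final-
#'   step median; 0 when no step).
#' @export
bleach_steps <- function(x, penalty = 10, min_drop_sd = 4,
                         near_bg_frac = 0.25, max_cp = 4) {
  n <- length(x)
  if (n < 20) return(list(n_steps = 0L, times = integer(0),
                          levels = mean(x), background = 0))
  sigma <- mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) sigma <- max(sd(x) / 10, 1e-9)
  pen <- penalty * sigma^2 * log(n)
  cps <- binseg_mean(x, pen, max_cp = max_cp, min_seg = 3)
  if (length(cps) == 0) return(list(n_steps = 0L, times = integer(0),
                                    levels = mean(x), background = 0))
  cps <- sort(cps)
  bounds <- c(0, cps, n)
  levels <- vapply(seq_len(length(bounds) - 1), function(i)
    mean(x[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
  final_near_bg <- levels[length(levels)] <
    near_bg_frac * max(levels)
  times <- integer(0)
  if (final_near_bg) {
    for (i in seq_along(cps)) {
      drop <- levels[i] - levels[i + 1]
      if (drop < min_drop_sd * sigma) next
      persistent <- all(levels[(i + 1):length(levels)] <=
                          levels[i] - 0.5 * drop)
      if (persistent) times <- c(times, cps[i] + 1L)
    }
  }
  bg <- if (length(times)) median(x[max(times):n]) else 0
  list(n_steps = length(times), times = times, levels = levels,
       background = bg)
}

# greedy binary segmentation for mean shifts; returns change-point indices
# (last index of the left segment)
binseg_mean <- function(x, pen, max_cp = 4, min_seg = 3) {
  best_split <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * min_seg) return(NULL)
    seg <- x[lo:hi]
    cs <- cumsum(seg)
    tot <- cs[n]
    ks <- min_seg:(n - min_seg)
    gain <- cs[ks]^2 / ks + (tot - cs[ks])^2 / (n - ks) - tot^2 / n
    i <- which.max(gain)
    list(k = lo + ks[i] - 1, gain = gain[i])
  }
  cps <- integer(0)
  queue <- list(c(1L, length(x)))
  while (length(queue) && length(cps) < max_cp) {
    cands <- lapply(queue, function(seg) best_split(seg[1], seg[2]))
    gains <- vapply(cands, function(cc) if (is.null(cc)) -Inf else cc$gain,
                    numeric(1))
    i <- which.max(gains)
    if (!is.finite(gains[i]) || gains[i] <= pen) break
    k <- cands[[i]]$k
    seg <- queue[[i]]
    cps <- c(cps, k)
    queue[[i]] <- NULL
    queue <- c(queue, list(c(seg[1], k)), list(c(k + 1L, seg[2])))
  }
  cps
}

#' Intensity-range exclusion filter
#'
#' Flags trajectories whose pre-bleach mean donor-excitation donor intensity
#' or acceptor-excitation acceptor intensity falls outside the acceptance
#' bands (defaults: I_DD in \[100, 1500\], I_AA in \[100, 1000\] counts). The
#' mean is taken over the pre-bleach region so bleached tails do not
#' trivially fail the lower bound.
#'
#' @param trace an `alex_trace`.
#' @param low_DD,high_DD I_DD acceptance band (counts).
#' @param low_AA,high_AA I_AA acceptance band (counts).
#' @param pre_end last pre-bleach period (defaults to the full trace).
#' @return TRUE when the trace should be excluded.
#' @export
intensity_filter <- function(trace, low_DD = 100, high_DD = 1500,
                             low_AA = 100, high_AA = 1000,
                             pre_end = length(trace$I_DD)) {
  if (length(trace$I_DD) == 0) stop("empty trace")
  idx <- seq_len(max(1, pre_end))
  m_dd <- mean(trace$I_DD[idx])
  m_aa <- mean(trace$I_AA[idx])
  (m_dd < low_DD || m_dd > high_DD || m_aa < low_AA || m_aa > high_AA)
}

#' Photoblinking filter
#'
#' Flags a trace when the acceptor-excitation intensity shows a dark
#' excursion (below 30% of the signal level) lasting at least
#' `min_dark` periods that subsequently recovers above 70% of the signal
#' level — the down-up signature of a blink. A monotone bleach does not
#' recover and is not flagged.
#'
#' @param x per-period `I_AA` series.
#' @param min_dark minimum dark-run length (periods).
#' @return TRUE when a blink is detected.
#' @export
blink_filter <- function(x, min_dark = 2) {
  n <- length(x)
  if (n < 20) return(FALSE)
  level <- quantile(x, 0.8, names = FALSE)
  if (level <= 0) return(FALSE)
  dark <- x < 0.3 * level
  r <- rle(dark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_dark) next
    if (ends[i] >= n) next
    after <- x[(ends[i] + 1):n]
    if (sum(after > 0.7 * level) >= 2) return(TRUE)
  }
  FALSE
}

#' Sort molecules into labelling species by stoichiometry
#'
#' Classifies a molecule from its mean pre-bleach stoichiometry: D+A for
#' `S` in \[0.25, 0.75\], donor-only for `S > 0.9`, acceptor-only for
#' `S < 0.1`, otherwise ambiguous. At least 10 valid `S` values are
#' required. Windows are configurable defaults, not published values.
#'
#' @param fs a `fret_series` from [compute_estar_s()].
#' @param pre_end last pre-bleach period (defaults to all).
#' @param da_window,donly_min,aonly_max species windows on mean S.
#' @return one of `"D+A"`, `"D-only"`, `"A-only"`, `"ambiguous"`.
#' @export
species_sort <- function(fs, pre_end = nrow(fs), da_window = c(0.25, 0.75),
                         donly_min = 0.9, aonly_max = 0.1) {
  s <- fs$S[seq_len(max(1, pre_end))]
  s <- s[is.finite(s)]
  if (length(s) < 10) return("ambiguous")
  m <- mean(s)
  if (m >= da_window[1] && m <= da_window[2]) return("D+A")
  if (m > donly_min) return("D-only")
  if (m < aonly_max) return("A-only")
  "ambiguous"
}

#' Quality-control verdict for one trajectory
#'
#' Codifies the trajectory-selection rules: intensity-range exclusion on
#' pre-bleach means, multi-step donor or acceptor photobleaching, acceptor
#' photoblinking, and S-based species sorting. A trace is accepted when no
#' exclusion flag is set and the species is D+A; a single bleach step per
#' fluorophore is allowed (the trace is truncated, not excluded).
#'
#' @param trace an `alex_trace`.
#' @param ... thresholds passed to [intensity_filter()].
#' @return a one-row data.frame (`qc_verdict`): molecule, species, flags,
#'   donor/acceptor bleach periods (`NA` if none), `n_pre` (pre-bleach
#'   periods) and `accepted`.
#' @export
qc_trace <- function(trace, ...) {
  n <- length(trace$I_DD)
  bs_a <- bleach_steps(trace$I_AA)
  # Donor bleaching is detected on the total green-excitation intensity:
  # FRET state changes only redistribute photons between I_DD and I_DA (and
  # acceptor bleach de-quenches the donor), so I_DD + I_DA steps down only
  # when the donor itself bleaches.
  bs_d <- bleach_steps(trace$I_DD + trace$I_DA)
  bleach_a <- if (bs_a$n_steps >= 1) bs_a$times[1] else NA_integer_
  bleach_d <- if (bs_d$n_steps >= 1) bs_d$times[1] else NA_integer_
  n_pre <- min(c(bleach_d - 1L, bleach_a - 1L, n), na.rm = TRUE)
  fs <- compute_estar_s(trace)
  species <- species_sort(fs, pre_end = n_pre)
  flag_int <- intensity_filter(trace, pre_end = n_pre, ...)
  flag_multi_d <- bs_d$n_steps >= 2
  flag_multi_a <- bs_a$n_steps >= 2
  flag_blink <- blink_filter(trace$I_AA[seq_len(
    if (is.na(bleach_a)) n else bleach_a - 1L)])
  accepted <- !flag_int && !flag_multi_d && !flag_multi_a && !flag_blink &&
    species == "D+A"
  data.frame(molecule = trace$id, species = species,
             intensity_out_of_range = flag_int,
             multistep_donor_bleach = flag_multi_d,
             multistep_acceptor_bleach = flag_multi_a,
             blinking = flag_blink,
             donor_bleach = bleach_d, acceptor_bleach = bleach_a,
             n_pre = n_pre, accepted = accepted,
             stringsAsFactors = FALSE)
}

#' @rdname qc_trace
#' @param traces list of `alex_trace`.
#' @export
qc_ensemble <- function(traces, ...) {
  out <- do.call(rbind, lapply(traces, qc_trace, ...))
  rownames(out) <- NULL
  out
}

#' Pre-bleach apparent-FRET series of accepted molecules
#'
#' Convenience extractor: per-molecule numeric vectors of E* values over the
#' pre-bleach analysis region, for molecules accepted by QC. Element `i` of
#' each series corresponds to trace period `i`, so downstream state paths
#' stay time-aligned; rare undefined periods are filled by carrying the last
#' defined value forward.
#'
#' @param traces list of `alex_trace`.
#' @param qc the [qc_ensemble()] verdict table.
#' @param min_len drop series shorter than this many periods.
#' @return named list of numeric E* vectors.
#' @export
estar_series <- function(traces, qc, min_len = 10) {
  keep <- which(qc$accepted)
  out <- list()
  for (i in keep) {
    fs <- compute_estar_s(traces[[i]])
    e <- fs$E[seq_len(qc$n_pre[i])]
    if (anyNA(e)) {
      bad <- which(!is.finite(e))
      for (j in bad) e[j] <- if (j > 1) e[j - 1] else e[is.finite(e)][1]
      if (anyNA(e)) next
    }
    if (length(e) >= min_len) out[[traces[[i]]$id]] <- e
  }
  out
}
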