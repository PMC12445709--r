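#' Dwell times from fitted state paths
#'
#' Runs of constant Viterbi state become dwells. The first and last run of
#' each trajectory are censored (their true start or end is unobserved) and
#' are flagged so estimators can exclude them.
#'
#' @param fit an `hmm_fit`.
#' @param frame_period seconds per period.
#' @return data.frame with `molecule`, `state`, `duration` (s), `censored`.
#' @export
extract_dwells <- function(fit, frame_period) {
  stopifnot(frame_period > 0)
  out <- lapply(seq_along(fit$paths), function(i) {
    p <- fit$paths[[i]]
    r <- rle(p)
    nr <- length(r$lengths)
    data.frame(molecule = names(fit$paths)[i] %||% as.character(i),
               state = r$values,
               duration = r$lengths * frame_period,
               censored = seq_len(nr) %in% c(1L, nr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Fit a dwell-time distribution
#'
#' For `form = "single"`, the exponential time constant is the mean of the
#' uncensored dwells (the maximum-likelihood estimator), cross-checked by a
#' least-squares fit of `A * exp(-t / tau)` to the dwell histogram. For
#' `form = "peaked"`, a two-step model `A * (exp(-t/tau1) - exp(-t/tau2))`
#' is fitted to the histogram; if the two time constants collapse to within
#' 5% of each other the fit falls back to the single-exponential form with
#' a warning.
#'
#' @param dwells data.frame from [extract_dwells()], optionally pre-filtered
#'   to one state.
#' @param form `"single"` or `"peaked"`.
#' @param bin_width histogram bin width (s); default Freedman-Diaconis.
#' @return a `dwell_fit`: list with `form`, `tau` (named vector), `n`,
#'   `tau_ls` (histogram cross-check) and `fitted`.
#' @export
fit_dwells <- function(dwells, form = c("single", "peaked"),
                       bin_width = NULL) {
  form <- match.arg(form)
  d <- dwells$duration[!dwells$censored]
  if (length(d) < 10) stop("too few uncensored dwells to fit")
  if (is.null(bin_width)) {
    bin_width <- 2 * IQR(d) / length(d)^(1 / 3)
    if (!is.finite(bin_width) || bin_width <= 0) bin_width <- diff(range(d)) / 10
  }
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  mids <- h$mids[h$counts > 0 | h$mids < max(d)]
  counts <- h$counts[seq_along(mids)]
  if (form == "single") {
    tau <- mean(d)
    ls <- tryCatch({
      f <- minpack.lm::nlsLM(counts ~ A * exp(-mids / tau1),
                             start = list(A = max(counts), tau1 = tau),
                             lower = c(0, 1e-6),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      as.numeric(coef(f)[["tau1"]])
    }, error = function(e) NA_real_)
    out <- list(form = form, tau = c(tau = tau), n = length(d),
                tau_ls = ls,
                fitted = data.frame(mid = h$mids, count = h$counts))
  } else {
    tau0 <- mean(d)
    fit <- tryCatch(
      minpack.lm::nlsLM(counts ~ A * (exp(-mids / tau1) - exp(-mids / tau2)),
                        start = list(A = 2 * max(counts), tau1 = tau0,
                                     tau2 = tau0 / 5),
                        lower = c(0, 1e-6, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    collapsed <- is.null(fit)
    if (!collapsed) {
      cf <- coef(fit)
      t1 <- max(cf[["tau1"]], cf[["tau2"]])
      t2 <- min(cf[["tau1"]], cf[["tau2"]])
      collapsed <- (t1 - t2) / t1 < 0.05
    }
    if (collapsed) {
      warning("peaked dwell model collapsed; falling back to single exponential")
      return(fit_dwells(dwells, form = "single", bin_width = bin_width))
    }
    out <- list(form = form, tau = c(tau_decay = t1, tau_rise = t2),
                n = length(d), tau_ls = t1,
                fitted = data.frame(mid = h$mids, count = h$counts))
  }
  class(out) <- "dwell_fit"
  out
}

#' Classify real-time trajectories by displacement outcome
#'
#' Applies the terminal-displacement rule to each fitted state path: the
#' maximal terminal run of periods assigned to displaced-band states (fitted
#' mean E* below `displaced_threshold`) marks a displacement event when it
#' lasts at least `min_stable` periods and begins after nucleotide injection
#' at `t_inj`. Such molecules are displacers — class `"I"` (fast) when the
#' displacement delay `t_d` is at most `boundary` seconds, `"II"` (slow)
#' otherwise. Non-displacers with at least `min_transitions` state
#' transitions are dynamic (`"III"`); the remainder are static (`"IV"`).
#'
#' @param fit an `hmm_fit` over the real-time E* series.
#' @param t_inj injection time (s), strictly inside the observation window.
#' @param frame_period seconds per period.
#' @param displaced_threshold E* ceiling of the displaced band.
#' @param min_stable minimum terminal run length (periods).
#' @param min_transitions dynamic-class transition threshold.
#' @param boundary fast/slow boundary on `t_d` (s).
#' @return data.frame with `molecule`, `class` (`"I"`, `"II"`, `"III"`,
#'   `"IV"`), `t_displace` (s since injection, `NA` for non-displacers),
#'   `n_transitions`.
#' @export
categorize_realtime <- function(fit, t_inj, frame_period,
                                displaced_threshold = 0.2, min_stable = 10,
                                min_transitions = 3, boundary = 31) {
  stopifnot(frame_period > 0, min_stable >= 1)
  max_len <- max(lengths(fit$paths))
  if (t_inj < 0 || t_inj >= max_len * frame_period)
    stop("t_inj lies outside the observation window")
  displaced <- which(fit$means < displaced_threshold)
  rows <- lapply(seq_along(fit$paths), function(i) {
    p <- fit$paths[[i]]
    n <- length(p)
    in_band <- p %in% displaced
    suffix <- 0L
    while (suffix < n && in_band[n - suffix]) suffix <- suffix + 1L
    t_d <- NA_real_
    cls <- NULL
    if (suffix >= min_stable) {
      entry <- (n - suffix) * frame_period  # time of first displaced period
      if (entry > t_inj) {
        t_d <- entry - t_inj
        cls <- if (t_d <= boundary) "I" else "II"
      }
    }
    if (is.null(cls))
      cls <- if (fit$n_transitions[i] >= min_transitions) "III" else "IV"
    data.frame(molecule = names(fit$paths)[i] %||% as.character(i),
               class = cls, t_displace = t_d,
               n_transitions = fit$n_transitions[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Displacement delays of classified displacers
#'
#' @param records output of [categorize_realtime()].
#' @return numeric vector of `t_displace` for class I and II molecules.
#' @export
displacement_times <- function(records) {
  records$t_displace[records$class %in% c("I", "II")]
}

#' Two-exponential fit of displacement delays
#'
#' Fits the delay distribution as a mixture of two exponentials. The primary
#' estimator is maximum likelihood by EM on the event times; the mixture
#' weights are therefore event fractions. A least-squares fit of
#' `A1 * exp(-t/tau1) + A2 * exp(-t/tau2)` to the delay histogram
#' cross-checks the time constants and supplies the histogram amplitudes
#' used by [fastslow_boundary()]. The histogram bin width defaults to the
#' Freedman-Diaconis rule clamped to `[frame_period, 5]` seconds
#' (histogram binning biases the amplitudes of an exponential, not its time
#' constant, so the clamp protects the amplitude estimate without touching
#' the MLE).
#'
#' @param td displacement delays (s).
#' @param bin_width histogram bin width (s); `NULL` for the default rule.
#' @param frame_period seconds per period (lower clamp of the default rule).
#' @return a `displacement_fit`: list with `taus` (ascending), `weights`
#'   (event fractions, same order), `amplitudes` (histogram density
#'   prefactors), `taus_ls`, `bin_width`, `n`, `loglik`.
#' @export
fit_displacement <- function(td, bin_width = NULL, frame_period = 0.4) {
  td <- td[is.finite(td) & td > 0]
  if (length(td) < 20) stop("too few displacement events to fit")
  if (is.null(bin_width)) {
    bin_width <- 2 * IQR(td) / length(td)^(1 / 3)
    bin_width <- min(max(bin_width, frame_period), 5)
  }
  breaks <- seq(0, max(td) + bin_width, by = bin_width)
  if (length(unique(findInterval(td, breaks))) < 2)
    stop("all displacement delays fall in a single histogram bin")
  # maximum likelihood: EM on the exponential mixture (deterministic init
  # from a quantile split)
  split_q <- quantile(td, 0.7, names = FALSE)
  tau <- c(mean(td[td <= split_q]), max(mean(td[td > split_q]), split_q))
  w <- c(0.7, 0.3)
  ll <- -Inf
  for (it in 1:500) {
    dens <- cbind(w[1] / tau[1] * exp(-td / tau[1]),
                  w[2] / tau[2] * exp(-td / tau[2]))
    tot <- rowSums(dens)
    ll_new <- sum(log(tot))
    r <- dens / tot
    w <- colMeans(r)
    tau <- colSums(r * td) / colSums(r)
    if (is.finite(ll) && abs(ll_new - ll) < 1e-10 * (1 + abs(ll_new))) break
    ll <- ll_new
  }
  o <- order(tau)
  tau <- tau[o]; w <- w[o]
  # histogram least-squares cross-check and amplitudes
  h <- hist(td, breaks = breaks, plot = FALSE)
  amp0 <- w * length(td) * bin_width / tau
  ls <- tryCatch({
    f <- minpack.lm::nlsLM(
      counts ~ A1 * exp(-mids / t1) + A2 * exp(-mids / t2),
      data = list(counts = h$counts, mids = h$mids),
      start = list(A1 = amp0[1], A2 = amp0[2], t1 = tau[1], t2 = tau[2]),
      lower = c(0, 0, 1e-6, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    coef(f)
  }, error = function(e) c(A1 = amp0[1], A2 = amp0[2],
                           t1 = tau[1], t2 = tau[2]))
  taus_ls <- sort(c(ls[["t1"]], ls[["t2"]]))
  amps <- if (ls[["t1"]] <= ls[["t2"]]) c(ls[["A1"]], ls[["A2"]]) else
    c(ls[["A2"]], ls[["A1"]])
  structure(list(taus = tau, weights = w, amplitudes = amps,
                 taus_ls = taus_ls, bin_width = bin_width,
                 n = length(td), loglik = ll),
            class = "displacement_fit")
}

#' @export
print.displacement_fit <- function(x, ...) {
  cat("<displacement_fit> n =", x$n, "\n")
  cat(sprintf("  tau = %.2f s (%.0f%%), %.2f s (%.0f%%)\n",
              x$taus[1], 100 * x$weights[1], x$taus[2], 100 * x$weights[2]))
  invisible(x)
}

#' Fast/slow boundary of a two-exponential delay distribution
#'
#' The time at which the two exponential components contribute equally:
#' `t_b = log(A1 / A2) / (1/tau1 - 1/tau2)` with `A1`, `A2` the histogram
#' amplitudes of the short- and long-lived component. The closed form is
#' cross-checked with a root finder on the amplitude difference.
#'
#' @param fit a `displacement_fit`, or a list with `amplitudes` and `taus`
#'   (short component first).
#' @return boundary time (s).
#' @export
fastslow_boundary <- function(fit) {
  A <- fit$amplitudes
  tau <- fit$taus
  if (length(A) != 2 || length(tau) != 2)
    stop("need exactly two components")
  if (A[2] <= 0) stop("long-component amplitude must be positive")
  if (A[1] <= A[2]) stop("short component must have the larger amplitude")
  tb <- log(A[1] / A[2]) / (1 / tau[1] - 1 / tau[2])
  g <- function(t) A[1] * exp(-t / tau[1]) - A[2] * exp(-t / tau[2])
  tb_root <- tryCatch(
    uniroot(g, lower = tb / 10, upper = tb * 10, tol = 1e-10)$root,
    error = function(e) tb)
  if (abs(tb_root - tb) > 1e-6 * (1 + tb))
    warning("closed-form and numerical boundary disagree")
  tb
}

#' Pre-injection E* of fast and slow displacers
#'
#' Mean apparent FRET over the last `window` periods before injection, for
#' class I (fast) and class II (slow) molecules separately. Molecules with
#' fewer pre-injection periods use the shorter window with a warning.
#'
#' @param series named list of per-molecule E* vectors (time-aligned to the
#'   trace, see [estar_series()]).
#' @param records output of [categorize_realtime()].
#' @param t_inj injection time (s).
#' @param frame_period seconds per period.
#' @param window averaging window (periods).
#' @return list with `fast`, `slow` (mean E*), `per_molecule` data.frame.
#' @export
pre_injection_estar <- function(series, records, t_inj, frame_period,
                                window = 10) {
  n_pre <- floor(t_inj / frame_period)
  if (n_pre < 1) stop("no pre-injection periods")
  rows <- lapply(which(records$class %in% c("I", "II")), function(i) {
    e <- series[[records$molecule[i]]]
    if (is.null(e)) return(NULL)
    avail <- min(n_pre, length(e))
    win <- min(window, avail)
    if (win < window)
      warning("molecule ", records$molecule[i],
              ": pre-injection window shrunk to ", win, " periods")
    data.frame(molecule = records$molecule[i], class = records$class[i],
               e_pre = mean(e[(avail - win + 1):avail]),
               stringsAsFactors = FALSE)
  })
  pm <- do.call(rbind, rows)
  list(fast = mean(pm$e_pre[pm$class == "I"]),
       slow = mean(pm$e_pre[pm$class == "II"]),
       per_molecule = pm)
}

#' End-to-end analysis of a real-time displacement experiment
#'
#' Runs the full real-time chain on raw traces: quality control, E* series
#' extraction, a two-pass shared HMM (pass 1 fits all molecules and
#' classifies them; pass 2 refits the displacer subset so the displaced-band
#' means and hence the displacement delays are not biased by non-displacer
#' molecules), terminal-displacement classification, the two-exponential
#' delay fit, and the fast/slow boundary (classes are re-assigned with the
#' fitted boundary). Accepted molecules whose usable region is too short for
#' state fitting stay in the denominator as static class IV (their
#' displacement status is unobservable).
#'
#' @param traces list of `alex_trace`.
#' @param t_inj injection time (s).
#' @param K number of HMM states.
#' @param seed seed for the HMM initialization.
#' @param qc optional precomputed [qc_ensemble()] table.
#' @param two_pass refit the displacer subset (pass 2)?
#' @return list with `records`, `class_fractions` (per class, of all
#'   accepted molecules), `displacement_fit`, `boundary` (s), `fit`
#'   (the pass-1 `hmm_fit`), `fit_displacers` (pass-2 fit or `NULL`),
#'   `qc`, `series`.
#' @export
analyze_realtime <- function(traces, t_inj, K = 4, seed = 1L, qc = NULL,
                             two_pass = TRUE) {
  if (is.null(qc)) qc <- qc_ensemble(traces)
  series <- estar_series(traces, qc)
  if (length(series) < 5) stop("too few accepted molecules")
  frame_period <- traces[[1]]$frame_period
  fit <- suppressWarnings(fit_hmm(series, K = K, seed = seed))
  records <- categorize_realtime(fit, t_inj = t_inj,
                                 frame_period = frame_period)
  fit2 <- NULL
  if (two_pass) {
    disp_ids <- records$molecule[records$class %in% c("I", "II")]
    if (length(disp_ids) >= 5) {
      fit2 <- suppressWarnings(fit_hmm(series[disp_ids], K = K, seed = seed))
      rec2 <- categorize_realtime(fit2, t_inj = t_inj,
                                  frame_period = frame_period)
      # refined records replace the pass-1 ones for these molecules
      keep <- !(records$molecule %in% disp_ids)
      records <- rbind(records[keep, ], rec2)
    }
  }
  td <- displacement_times(records)
  disp_fit <- NULL
  boundary <- NA_real_
  if (length(td) >= 20) {
    disp_fit <- fit_displacement(td, frame_period = frame_period)
    boundary <- tryCatch(fastslow_boundary(disp_fit),
                         error = function(e) NA_real_)
    if (is.finite(boundary)) {
      is_disp <- records$class %in% c("I", "II")
      records$class[is_disp] <-
        ifelse(records$t_displace[is_disp] <= boundary, "I", "II")
    }
  }
  # accepted molecules without a usable series are unclassifiable: class IV
  acc <- qc$molecule[qc$accepted]
  missing <- setdiff(acc, records$molecule)
  if (length(missing))
    records <- rbind(records,
                     data.frame(molecule = missing, class = "IV",
                                t_displace = NA_real_, n_transitions = 0L,
                                stringsAsFactors = FALSE))
  rownames(records) <- NULL
  fr <- vapply(c("I", "II", "III", "IV"),
               function(cl) mean(records$class == cl), numeric(1))
  list(records = records, class_fractions = fr, displacement_fit = disp_fit,
       boundary = boundary, fit = fit, fit_displacers = fit2, qc = qc,
       series = series)
}
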