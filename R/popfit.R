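#' Gaussian-mixture fit to a framewise E* histogram
#'
#' Fits a sum of K Gaussians to the histogram of pooled per-period E*
#' values. The default estimator is least squares on histogram counts
#' (Levenberg-Marquardt), matching how population fractions are usually
#' extracted from framewise FRET histograms; `method = "em"` fits the same
#' mixture by maximum likelihood (unequal-variance EM) as a cross-check.
#' Population fractions are area fractions `A_i * sigma_i / sum(A_j *
#' sigma_j)` for the LS fit and the mixture weights for EM. Components are
#' returned sorted by mean.
#'
#' @param values pooled E* values.
#' @param K number of components (1-4).
#' @param init optional list with numeric vectors `means`, `sds`, `weights`
#'   used as starting values; defaults to quantile-spread means.
#' @param bin_width histogram bin width on E*.
#' @param method `"ls"` (histogram least squares, default) or `"em"`.
#' @return a `mixture_fit`: list with `means`, `sds`, `weights` (fractions
#'   summing to 1), `K`, `method`, `n`, and for LS fits `amplitudes`,
#'   `fitted` (data.frame of bin mids, counts, fit) and `rss`.
#' @export
fit_mixture <- function(values, K, init = NULL, bin_width = 0.025,
                        method = c("ls", "em")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 20 * K)
    stop("too few observations for a ", K, "-component mixture")
  if (K < 1 || K > 4) stop("K must be between 1 and 4")
  if (is.null(init)) init <- init_mixture(values, K, bin_width)
  if (method == "em") {
    fit <- mixture_em(values, K, init)
  } else {
    fit <- mixture_ls(values, K, init, bin_width)
  }
  o <- order(fit$means)
  fit$means <- fit$means[o]
  fit$sds <- fit$sds[o]
  fit$weights <- fit$weights[o]
  if (!is.null(fit$amplitudes)) fit$amplitudes <- fit$amplitudes[o]
  fit$K <- K
  fit$method <- method
  fit$n <- length(values)
  class(fit) <- "mixture_fit"
  fit
}

# default starting values. For K = 2 the decomposition separates a low-E*
# (displaced) band from the major band, so the minor component starts at the
# mass centre of the low-E* flank and the major at the global mode — the
# usual practice of initializing at the physically expected peaks. For other
# K: the K tallest well-separated modes of a smoothed histogram, padded with
# quantiles.
init_mixture <- function(values, K, bin_width) {
  h <- hist(values, breaks = seq(min(values) - bin_width,
                                 max(values) + bin_width, by = bin_width),
            plot = FALSE)
  mode_e <- h$mids[which.max(h$counts)]
  if (K == 2) {
    low <- values[values < mode_e - 0.15]
    if (length(low) >= 0.01 * length(values)) {
      return(list(means = c(mean(low), mode_e), sds = c(0.05, 0.07),
                  weights = c(length(low) / length(values),
                              1 - length(low) / length(values))))
    }
  }
  cs <- as.numeric(filter(h$counts, rep(1 / 3, 3)))
  cs[is.na(cs)] <- h$counts[is.na(cs)]
  n <- length(cs)
  is_peak <- cs >= c(-Inf, cs[-n]) & cs >= c(cs[-1], -Inf) & cs > 0
  peaks <- h$mids[is_peak][order(cs[is_peak], decreasing = TRUE)]
  sel <- numeric(0)
  for (p in peaks) {
    if (length(sel) == K) break
    if (all(abs(p - sel) > 0.08)) sel <- c(sel, p)
  }
  if (length(sel) < K) {
    fill <- quantile(values, (seq_len(K) - 0.5) / K, names = FALSE)
    fill <- fill[order(vapply(fill, function(f)
      if (length(sel)) min(abs(f - sel)) else Inf, numeric(1)),
      decreasing = TRUE)]
    sel <- c(sel, fill[seq_len(K - length(sel))])
  }
  list(means = sort(sel), sds = rep(0.05, K), weights = rep(1 / K, K))
}

mixture_ls <- function(values, K, init, bin_width) {
  breaks <- seq(-0.1, 1.1, by = bin_width)
  h <- hist(pmin(pmax(values, -0.1 + 1e-9), 1.1 - 1e-9),
            breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  model <- function(par) {
    A <- par[seq_len(K)]
    mu <- par[K + seq_len(K)]
    sg <- par[2 * K + seq_len(K)]
    rowSums(vapply(seq_len(K), function(k)
      A[k] * exp(-0.5 * ((mids - mu[k]) / sg[k])^2),
      numeric(length(mids))))
  }
  peak_amp <- function(w, s)
    w * length(values) * bin_width / (s * sqrt(2 * pi))
  start <- c(peak_amp(init$weights, init$sds), init$means, init$sds)
  run <- function(par0) {
    minpack.lm::nls.lm(par = par0,
                       fn = function(p) counts - model(p),
                       lower = c(rep(0, K), rep(-0.1, K), rep(1e-3, K)),
                       upper = c(rep(Inf, K), rep(1.1, K), rep(0.5, K)),
                       control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  res <- run(start)
  par <- res$par
  sg <- par[2 * K + seq_len(K)]
  if (any(sg <= 2e-3)) {
    # singular component: reinitialize once with widened spread, then error
    start2 <- c(peak_amp(rep(1 / K, K), rep(0.08, K)),
                seq(min(values), max(values), length.out = K + 2)[2:(K + 1)],
                rep(0.08, K))
    res <- run(start2)
    par <- res$par
    sg <- par[2 * K + seq_len(K)]
    if (any(sg <= 2e-3))
      stop("mixture fit collapsed onto a singular component")
  }
  A <- par[seq_len(K)]
  mu <- par[K + seq_len(K)]
  area <- A * sg
  list(means = mu, sds = sg, weights = area / sum(area), amplitudes = A,
       fitted = data.frame(mid = mids, count = counts, fit = model(par)),
       rss = sum(res$fvec^2))
}

mixture_em <- function(values, K, init) {
  if (K == 1)
    return(list(means = mean(values), sds = sd(values), weights = 1))
  fit <- Mclust(values, G = K, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("EM mixture fit failed")
  list(means = as.numeric(fit$parameters$mean),
       sds = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
       weights = as.numeric(fit$parameters$pro))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit>", x$method, "K =", x$K, " n =", x$n, "\n")
  for (k in seq_len(x$K))
    cat(sprintf("  E* = %.3f (sd %.3f), %.1f%%\n",
                x$means[k], x$sds[k], 100 * x$weights[k]))
  invisible(x)
}

#' Subset-based uncertainty of a summary statistic
#'
#' Splits the molecules (or values) into `n_subsets` equal-size random
#' subsets, evaluates `stat_fn` on each, and reports the spread across
#' subsets — the empirical error bar used for histogram-derived quantities.
#'
#' @param values list or vector of observations (split along its length).
#' @param stat_fn function mapping a subset (same type as `values`) to a
#'   scalar.
#' @param n_subsets number of subsets (>= 2).
#' @param seed seed for the random split.
#' @return list with `estimates` (per subset), `mean`, `sd`, `sem`.
#' @export
subset_error <- function(values, stat_fn, n_subsets = 3, seed = 1L) {
  if (n_subsets < 2) stop("need at least 2 subsets")
  n <- length(values)
  if (n < 2 * n_subsets)
    stop("too few observations to form ", n_subsets, " subsets")
  set.seed(seed)
  grp <- sample(rep_len(seq_len(n_subsets), n))
  est <- vapply(seq_len(n_subsets), function(g)
    stat_fn(values[grp == g]), numeric(1))
  list(estimates = est, mean = mean(est), sd = sd(est),
       sem = sd(est) / sqrt(n_subsets))
}
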