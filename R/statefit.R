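#' Ensemble hidden Markov model for E* trajectories
#'
#' Fits a K-state HMM with Gaussian emissions (state-specific variance)
#' shared across all trajectories, in the style of ebFRET. The default
#' estimator is variational Bayes with conjugate priors (Dirichlet on the
#' initial distribution and transition rows, Normal-Gamma on emission
#' mean/precision); the model score is the evidence lower bound. A
#' maximum-likelihood EM fallback is available, scored by the BIC-penalized
#' log-likelihood. Initialization is a k-means partition of the pooled E*
#' values seeded from quantiles, so repeated fits with the same seed are
#' identical.
#'
#' @param trajectories list of numeric E* vectors (one per molecule, each
#'   with at least 10 periods).
#' @param K number of states (1-6).
#' @param method `"vb"` (default) or `"em"`.
#' @param seed integer seed (initialization is deterministic given it).
#' @param max_iter maximum iterations.
#' @param tol relative convergence tolerance on the score.
#' @param priors optional named list overriding `beta0`, `a0`, `b0`,
#'   `dir_alpha` (VB hyperparameters).
#' @return an `hmm_fit`: list with `K`, `means` (sorted ascending), `sds`,
#'   `trans` (row-stochastic per-period transition matrix), `init`,
#'   `occupancy`, `paths` (per-molecule Viterbi paths, 1-based state
#'   indices), `n_transitions`, `lower_bound`, `score_trace`, `converged`,
#'   `degenerate` (per-state flag: weight < 1% or mean separation < 0.02),
#'   `method`, `n_obs`.
#' @export
fit_hmm <- function(trajectories, K, method = c("vb", "em"), seed = 1L,
                    max_iter = 200, tol = 1e-8, priors = NULL) {
  method <- match.arg(method)
  if (length(trajectories) < 1) stop("need at least one trajectory")
  lens <- lengths(trajectories)
  if (any(lens < 10)) stop("each trajectory must have >= 10 periods")
  if (K < 1 || K > 6) stop("K must be between 1 and 6")
  x_all <- unlist(trajectories, use.names = FALSE)
  centers <- init_centers(x_all, K, seed)
  if (method == "vb") {
    fit <- vb_hmm(trajectories, x_all, K, centers, max_iter, tol, priors)
  } else {
    fit <- em_hmm(trajectories, x_all, K, centers, max_iter, tol)
  }
  # sort states by mean and decode
  o <- order(fit$means)
  fit$means <- fit$means[o]
  fit$sds <- fit$sds[o]
  fit$trans <- fit$trans[o, o, drop = FALSE]
  fit$init <- fit$init[o]
  fit$occupancy <- fit$occupancy[o]
  fit$paths <- decode_paths(trajectories, fit$init, fit$trans, fit$means,
                            fit$sds)
  names(fit$paths) <- names(trajectories)
  fit$n_transitions <- vapply(fit$paths,
                              function(p) sum(diff(p) != 0), integer(1))
  sep <- if (K > 1) c(Inf, diff(fit$means)) else Inf
  fit$degenerate <- fit$occupancy < 0.01 | sep < 0.02
  if (any(fit$degenerate))
    warning("fit has ", sum(fit$degenerate),
            " degenerate state(s) (weight < 1% or mean separation < 0.02)")
  fit$K <- K
  fit$n_obs <- length(x_all)
  class(fit) <- "hmm_fit"
  fit
}

init_centers <- function(x, K, seed) {
  set.seed(seed)
  qs <- quantile(x, (seq_len(K) - 0.5) / K, names = FALSE)
  if (anyDuplicated(qs)) qs <- qs + seq(0, 1e-6, length.out = K)
  if (length(unique(x)) > K) {
    km <- tryCatch(kmeans(x, centers = matrix(qs, ncol = 1), iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km)) qs <- sort(as.numeric(km$centers))
  }
  qs
}

vb_hmm <- function(trajectories, x_all, K, centers, max_iter, tol, priors) {
  pr <- modifyList(list(beta0 = 0.25, a0 = 2.5, b0 = 0.015, dir_alpha = 1),
                   if (is.null(priors)) list() else priors)
  m0 <- centers
  beta0 <- pr$beta0; a0 <- pr$a0; b0 <- pr$b0
  upi <- rep(pr$dir_alpha, K)
  uA <- matrix(pr$dir_alpha, K, K)
  # initialize hyperparameters from a hard assignment to the init centers
  assign <- vapply(x_all, function(v) which.min(abs(v - centers)), integer(1))
  Nk <- vapply(seq_len(K), function(k) sum(assign == k) + 1e-3, numeric(1))
  xbar <- vapply(seq_len(K), function(k) {
    xs <- x_all[assign == k]
    if (length(xs)) mean(xs) else centers[k]
  }, numeric(1))
  Sk <- vapply(seq_len(K), function(k) {
    xs <- x_all[assign == k]
    if (length(xs) > 1) sum((xs - mean(xs))^2) else 0
  }, numeric(1))
  beta <- beta0 + Nk
  m <- (beta0 * m0 + Nk * xbar) / beta
  a <- a0 + Nk / 2
  b <- b0 + 0.5 * (Sk + beta0 * Nk * (xbar - m0)^2 / beta)
  wpi <- upi + Nk / sum(Nk)
  W <- uA + diag(K) * 1  # mildly sticky start
  score_trace <- numeric(0)
  F_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ln_pi <- digamma(wpi) - digamma(sum(wpi))
    ln_A <- digamma(W) - digamma(rowSums(W))
    pi_t <- exp(ln_pi)
    A_t <- matrix(exp(ln_A), K, K)
    e_lnlam <- digamma(a) - log(b)
    g1 <- numeric(K); xi <- matrix(0, K, K)
    Nk <- numeric(K); sx <- numeric(K); sx2 <- numeric(K)
    logZ <- 0
    for (tr in trajectories) {
      lnB <- 0.5 * outer(rep(1, length(tr)), e_lnlam) -
        0.5 * log(2 * pi) -
        0.5 * (outer(rep(1, length(tr)), 1 / beta) +
                 outer(tr, m, "-")^2 *
                 matrix(a / b, length(tr), K, byrow = TRUE))
      mx <- apply(lnB, 1, max)
      B <- exp(lnB - mx)
      r <- fb_scaled(B, mx, pi_t, A_t)
      logZ <- logZ + r$logZ
      g1 <- g1 + r$gamma[1, ]
      xi <- xi + r$xi
      Nk <- Nk + colSums(r$gamma)
      sx <- sx + as.numeric(crossprod(r$gamma, tr))
      sx2 <- sx2 + as.numeric(crossprod(r$gamma, tr^2))
    }
    xbar <- ifelse(Nk > 0, sx / pmax(Nk, 1e-12), m0)
    Sk <- pmax(sx2 - Nk * xbar^2, 0)
    wpi <- upi + g1
    W <- uA + xi
    beta <- beta0 + Nk
    m <- (beta0 * m0 + Nk * xbar) / beta
    a <- a0 + Nk / 2
    b <- b0 + 0.5 * (Sk + beta0 * Nk * (xbar - m0)^2 / beta)
    kl <- kl_dirichlet(wpi, upi) +
      sum(vapply(seq_len(K), function(j)
        kl_dirichlet(W[j, ], uA[j, ]), numeric(1))) +
      sum(kl_normal_gamma(m, beta, a, b, m0, beta0, a0, b0))
    F_cur <- logZ - kl
    score_trace <- c(score_trace, F_cur)
    if (is.finite(F_prev) && abs(F_cur - F_prev) < tol * (1 + abs(F_cur))) {
      converged <- TRUE
      break
    }
    F_prev <- F_cur
  }
  list(means = m, sds = sqrt(b / a), trans = W / rowSums(W),
       init = wpi / sum(wpi), occupancy = Nk / sum(Nk),
       lower_bound = score_trace[length(score_trace)],
       score_trace = score_trace, converged = converged, method = "vb")
}

em_hmm <- function(trajectories, x_all, K, centers, max_iter, tol) {
  mu <- centers
  sig2 <- rep(max(var(x_all) / max(K, 2), 1e-6), K)
  piv <- rep(1 / K, K)
  A <- matrix(0.05 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.95 else 1
  score_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g1 <- numeric(K); xi <- matrix(0, K, K)
    Nk <- numeric(K); sx <- numeric(K); sx2 <- numeric(K)
    ll <- 0
    for (tr in trajectories) {
      lnB <- vapply(seq_len(K), function(k)
        dnorm(tr, mu[k], sqrt(sig2[k]), log = TRUE), numeric(length(tr)))
      lnB <- matrix(lnB, ncol = K)
      mx <- apply(lnB, 1, max)
      r <- fb_scaled(exp(lnB - mx), mx, piv, A)
      ll <- ll + r$logZ
      g1 <- g1 + r$gamma[1, ]
      xi <- xi + r$xi
      Nk <- Nk + colSums(r$gamma)
      sx <- sx + as.numeric(crossprod(r$gamma, tr))
      sx2 <- sx2 + as.numeric(crossprod(r$gamma, tr^2))
    }
    score_trace <- c(score_trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    piv <- g1 / sum(g1)
    if (K > 1) {
      rs <- rowSums(xi)
      A <- sweep(xi, 1, pmax(rs, 1e-300), "/")
      A[rs == 0, ] <- 1 / K
      A <- A / rowSums(A)
    }
    mu <- sx / pmax(Nk, 1e-12)
    sig2 <- pmax(sx2 / pmax(Nk, 1e-12) - mu^2, 1e-8)
  }
  npar <- (K - 1) + K * (K - 1) + 2 * K
  list(means = mu, sds = sqrt(sig2), trans = A, init = piv,
       occupancy = Nk / sum(Nk),
       lower_bound = score_trace[length(score_trace)] -
         0.5 * npar * log(length(x_all)),
       score_trace = score_trace, converged = converged, method = "em")
}

kl_dirichlet <- function(w, u) {
  lgamma(sum(w)) - sum(lgamma(w)) - lgamma(sum(u)) + sum(lgamma(u)) +
    sum((w - u) * (digamma(w) - digamma(sum(w))))
}

kl_normal_gamma <- function(m, beta, a, b, m0, beta0, a0, b0) {
  kl_gam <- (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
  e_kl_norm <- 0.5 * (log(beta / beta0) + beta0 / beta - 1 +
                        beta0 * (m - m0)^2 * a / b)
  kl_gam + e_kl_norm
}

decode_paths <- function(trajectories, init, trans, means, sds) {
  K <- length(means)
  logpi <- log(pmax(init, 1e-300))
  logA <- matrix(log(pmax(trans, 1e-300)), K, K)
  lapply(trajectories, function(tr) {
    lnB <- vapply(seq_len(K), function(k)
      dnorm(tr, means[k], pmax(sds[k], 1e-6), log = TRUE),
      numeric(length(tr)))
    viterbi_core(matrix(lnB, ncol = K), logpi, logA)
  })
}

#' Viterbi decoding of one E* trajectory
#'
#' Most-likely state path under a Gaussian-emission HMM with the given
#' parameters (maximum a posteriori joint path).
#'
#' @param x numeric E* series.
#' @param init initial state distribution.
#' @param trans row-stochastic transition matrix.
#' @param means,sds per-state Gaussian emission parameters.
#' @return integer vector of 1-based state indices.
#' @export
viterbi_path <- function(x, init, trans, means, sds) {
  decode_paths(list(x), init, matrix(trans, length(means)), means, sds)[[1]]
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("<hmm_fit>", x$method, "K =", x$K, "\n")
  cat("  means:", sprintf("%.3f", x$means), "\n")
  cat("  occupancy:", sprintf("%.3f", x$occupancy), "\n")
  cat("  score:", format(x$lower_bound), " converged:", x$converged, "\n")
  invisible(x)
}

#' Model selection by lower bound
#'
#' Fits each candidate state count and returns the one maximizing the model
#' score (evidence lower bound for VB, BIC-penalized log-likelihood for EM).
#' Ties break to the smaller K. If the winning fit contains degenerate
#' states, the selection steps down to the corresponding effective state
#' count.
#'
#' @param trajectories list of E* series.
#' @param k_range candidate K values (within 1-6).
#' @param ... passed to [fit_hmm()].
#' @return list with `K` (selected), `fit` (the selected `hmm_fit`),
#'   `bounds` (named score per K), `fits` (all fits).
#' @export
select_model <- function(trajectories, k_range = 1:5, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1 | k_range > 6)) stop("K range must lie within [1, 6]")
  fits <- lapply(k_range, function(k)
    suppressWarnings(fit_hmm(trajectories, k, ...)))
  bounds <- vapply(fits, function(f) f$lower_bound, numeric(1))
  names(bounds) <- k_range
  best <- which.max(bounds)  # first max: ties go to smaller K
  k_star <- k_range[best]
  fit <- fits[[best]]
  eff <- k_star - sum(fit$degenerate)
  if (eff < k_star && eff %in% k_range) {
    k_star <- eff
    fit <- fits[[match(eff, k_range)]]
  }
  list(K = k_star, fit = fit, bounds = bounds, fits = fits)
}

#' Classify molecules as dynamic by Viterbi transition count
#'
#' A molecule is dynamic when its Viterbi path contains at least
#' `min_transitions` transitions between different states (default 3; a
#' molecule with exactly 2 transitions is not dynamic).
#'
#' @param fit an `hmm_fit`.
#' @param min_transitions threshold.
#' @return named logical vector, one element per molecule.
#' @export
classify_dynamic <- function(fit, min_transitions = 3) {
  fit$n_transitions >= min_transitions
}

#' Transition density plot data
#'
#' 2-D histogram of (E* before, E* after) over all Viterbi transitions,
#' using the fitted state means as coordinates. Total mass equals the
#' number of transitions.
#'
#' @param fit an `hmm_fit`.
#' @param bin_edges histogram bin edges on the E* axis.
#' @return a `transition_density`: list with `counts` (matrix, rows = E*
#'   before), `edges`, `n_transitions`, `pairs` (data.frame of from/to state
#'   indices and means).
#' @export
transition_density <- function(fit, bin_edges = seq(0, 1, by = 0.05)) {
  pairs <- do.call(rbind, lapply(fit$paths, function(p) {
    ch <- which(diff(p) != 0)
    if (!length(ch)) return(NULL)
    data.frame(from = p[ch], to = p[ch + 1])
  }))
  nb <- length(bin_edges) - 1
  counts <- matrix(0, nb, nb)
  if (!is.null(pairs) && nrow(pairs)) {
    ef <- fit$means[pairs$from]
    et <- fit$means[pairs$to]
    bf <- pmin(pmax(findInterval(ef, bin_edges, all.inside = TRUE), 1), nb)
    bt <- pmin(pmax(findInterval(et, bin_edges, all.inside = TRUE), 1), nb)
    for (i in seq_along(bf)) counts[bf[i], bt[i]] <- counts[bf[i], bt[i]] + 1
    pairs$e_from <- ef
    pairs$e_to <- et
  } else {
    pairs <- data.frame(from = integer(0), to = integer(0),
                        e_from = numeric(0), e_to = numeric(0))
  }
  structure(list(counts = counts, edges = bin_edges,
                 n_transitions = nrow(pairs), pairs = pairs),
            class = "transition_density")
}
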