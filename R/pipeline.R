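#' Run the full analysis pipeline from a config
#'
#' Drives the chain simulate -> quality control -> framewise histogram
#' mixture -> ensemble HMM -> kinetics from a single configuration, writing
#' tabular/JSON results and PNG figures into an output directory. The run
#' manifest records the configuration, its MD5 hash and per-stage record
#' counts but no timestamps, so re-running the same config reproduces the
#' outputs byte for byte.
#'
#' Config fields (YAML file or named list): `fixture` (ground-truth name),
#' `n_molecules`, `seed`, `out_dir`, optional `duration`, `mixture_K`
#' (default 2), `hmm_K` (default 3 equilibrium / 4 real-time), `stages`
#' (subset of `simulate`, `qc`, `histogram`, `hmm`, `kinetics`; default
#' all). Real-time fixtures (those with an injection time) run the
#' displacement analysis in the kinetics stage; equilibrium fixtures run
#' the dynamic-molecule dwell analysis.
#'
#' @param config path to a YAML file, or a named list.
#' @return invisibly, a list with the per-stage results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("fixture", "n_molecules", "seed", "out_dir")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config is missing fields: ",
                         paste(miss, collapse = ", "))
  stages <- config$stages %||% c("simulate", "qc", "histogram", "hmm",
                                 "kinetics")
  gt <- build_fixture(config$fixture)
  realtime <- is.finite(gt$t_inj)
  mixture_K <- config$mixture_K %||% 2L
  hmm_K <- config$hmm_K %||% (if (realtime) 4L else 3L)
  duration <- config$duration %||% gt$duration
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  results <- list(out_dir = out_dir)
  counts <- list()

  message("[simulate] fixture ", gt$name, ": ", config$n_molecules,
          " molecules, ", duration, " s")
  sim <- simulate_ensemble(gt, config$n_molecules, duration = duration,
                           seed = config$seed)
  traces <- sim$traces
  counts$simulated <- length(traces)
  if ("simulate" %in% stages)
    write_traces(traces, file.path(out_dir, "traces"),
                 manifest = list(fixture = gt$name, seed = config$seed))
  results$sim <- sim

  qc <- NULL
  series <- NULL
  if (any(c("qc", "histogram", "hmm", "kinetics") %in% stages)) {
    qc <- qc_ensemble(traces)
    counts$accepted <- sum(qc$accepted)
    message("[qc] accepted ", counts$accepted, " / ", nrow(qc), " molecules")
    write.table(qc, file.path(out_dir, "qc.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    series <- estar_series(traces, qc)
    results$qc <- qc
    results$series <- series
  }

  if ("histogram" %in% stages) {
    pooled <- unlist(series, use.names = FALSE)
    mix <- fit_mixture(pooled, K = mixture_K)
    counts$histogram_frames <- mix$n
    message("[histogram] ", mix$n, " frames, K = ", mixture_K)
    jsonlite::write_json(
      list(means = mix$means, sds = mix$sds, weights = mix$weights,
           K = mix$K, n = mix$n),
      file.path(out_dir, "histogram_fit.json"),
      auto_unbox = TRUE, digits = NA)
    plot_histogram_fit(mix, file.path(out_dir, "histogram.png"))
    results$mixture <- mix
  }

  hmm <- NULL
  if (any(c("hmm", "kinetics") %in% stages) && length(series) >= 2) {
    hmm <- suppressWarnings(fit_hmm(series, K = hmm_K, seed = config$seed))
    counts$hmm_molecules <- length(series)
    message("[hmm] K = ", hmm_K, " on ", length(series), " molecules; ",
            "means ", paste(sprintf("%.2f", hmm$means), collapse = " "))
    jsonlite::write_json(
      list(K = hmm$K, means = hmm$means, sds = hmm$sds,
           occupancy = hmm$occupancy, trans = as.data.frame(hmm$trans),
           lower_bound = hmm$lower_bound, converged = hmm$converged),
      file.path(out_dir, "hmm_fit.json"), auto_unbox = TRUE, digits = NA)
    if ("hmm" %in% stages) {
      td <- transition_density(hmm)
      plot_transition_density(td, file.path(out_dir,
                                            "transition_density.png"))
      results$transition_density <- td
    }
    results$hmm <- hmm
  }

  if ("kinetics" %in% stages) {
    if (realtime) {
      rt <- analyze_realtime(traces, t_inj = gt$t_inj, K = hmm_K,
                             seed = config$seed, qc = qc)
      counts$displacers <- sum(rt$records$class %in% c("I", "II"))
      message("[kinetics] classes ",
              paste(sprintf("%s=%.0f%%", names(rt$class_fractions),
                            100 * rt$class_fractions), collapse = " "))
      kin <- list(class_fractions = as.list(rt$class_fractions),
                  boundary = rt$boundary)
      if (!is.null(rt$displacement_fit))
        kin <- c(kin, list(taus = rt$displacement_fit$taus,
                           weights = rt$displacement_fit$weights))
      jsonlite::write_json(kin, file.path(out_dir, "kinetics.json"),
                           auto_unbox = TRUE, digits = NA)
      results$realtime <- rt
    } else if (!is.null(hmm)) {
      dyn <- classify_dynamic(hmm)
      dwells <- extract_dwells(hmm, traces[[1]]$frame_period)
      dwells <- dwells[dwells$molecule %in% names(dyn)[dyn], ]
      counts$dynamic <- sum(dyn)
      message("[kinetics] ", sum(dyn), " dynamic molecules, ",
              sum(!dwells$censored), " uncensored dwells")
      kin <- list(dynamic_fraction = mean(dyn))
      if (sum(!dwells$censored) >= 10) {
        df <- fit_dwells(dwells)
        kin$dwell_tau <- unname(df$tau["tau"])
      }
      jsonlite::write_json(kin, file.path(out_dir, "kinetics.json"),
                           auto_unbox = TRUE, digits = NA)
      results$kinetics <- kin
    }
  }

  jsonlite::write_json(
    list(config = config, config_md5 = cfg_hash, counts = counts),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  results$counts <- counts
  invisible(results)
}

plot_histogram_fit <- function(mix, file) {
  grDevices::png(file, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  with(mix$fitted, {
    plot(mid, count, type = "h", lwd = 3, col = "grey70",
         xlab = "apparent FRET E*", ylab = "frames",
         main = "framewise E* histogram")
    lines(mid, fit, col = "firebrick", lwd = 2)
  })
}

plot_transition_density <- function(td, file) {
  grDevices::png(file, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  mids <- (td$edges[-1] + td$edges[-length(td$edges)]) / 2
  graphics::image(mids, mids, td$counts,
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  xlab = "E* before transition", ylab = "E* after transition",
                  main = sprintf("transition density (n = %d)",
                                 td$n_transitions))
  graphics::abline(0, 1, lty = 2)
}
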