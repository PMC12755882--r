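#' Pipeline configuration
#'
#' Bundles the settings of every stage of the end-to-end analysis:
#' synthetic-data generation (or a path to an epochs file), trial
#' rejection, the sequential-event model, the psychophysical law
#' comparison, and the event-level statistics. A single `seed` drives
#' all stochastic stages.
#'
#' @param sim A `sim_config` (ignored when `epochs_path` is given).
#' @param epochs_path Optional path to a dataset saved by
#'   [write_epochs()].
#' @param rt_min_ms,rt_max_ms,volt_max_uV Trial-rejection rules.
#' @param rt_offset_ms Analysis-window extension, ms.
#' @param width_ms Event template width, ms.
#' @param gamma_shape Gamma stage-duration shape.
#' @param var_target PCA variance fraction to retain.
#' @param n_events Fixed number of events, or `NULL` to estimate it by
#'   [cumulative_fit()].
#' @param max_events Cap for the cumulative fit.
#' @param n_bins Contrast bins for the law comparison.
#' @param laws Laws entered in the comparison.
#' @param n_perm Permutations for the cluster test.
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), epochs_path = NULL,
                            rt_min_ms = 100, rt_max_ms = 3000,
                            volt_max_uV = 100, rt_offset_ms = 10,
                            width_ms = 25, gamma_shape = 2,
                            var_target = 0.999, n_events = NULL,
                            max_events = 10, n_bins = 10,
                            laws = c("linear", "pieron", "fechner"),
                            n_perm = 1024, seed = 1L) {
  structure(list(
    sim = sim, epochs_path = epochs_path,
    rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms,
    volt_max_uV = volt_max_uV, rt_offset_ms = rt_offset_ms,
    width_ms = width_ms, gamma_shape = gamma_shape,
    var_target = var_target, n_events = n_events,
    max_events = max_events, n_bins = n_bins, laws = laws,
    n_perm = n_perm, seed = as.integer(seed)
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Sequences simulate (or load) -> reject trials -> extend windows ->
#' principal components -> template cross-correlation -> event-model fit
#' -> single-trial event times -> inter-event interval law comparison ->
#' event-level statistics, and returns a reproducible report.
#'
#' @param config A `pipeline_config`.
#' @param verbose Print stage progress.
#' @return Object of class `run_report`: list with `rejection`,
#'   `n_events`, `model`, `mean_peak_ms`, `interval_cv` (per-interval
#'   `cv_result`), `asymmetry`, `buildup` (summary + accuracy
#'   correlations), `truth` (when simulated), `config`, `config_hash`,
#'   and `versions`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$seed)
  truth <- NULL
  if (is.null(config$epochs_path)) {
    say("simulating %d x %d trials",
        config$sim$n_participants, config$sim$n_trials)
    gen <- generate_dataset(config$sim)
    epochs <- gen$epochs
    truth <- gen$truth
  } else {
    epochs <- read_epochs(config$epochs_path)
  }
  epochs <- reject_trials(epochs, config$rt_min_ms, config$rt_max_ms,
                          config$volt_max_uV)
  rejection <- attr(epochs, "rejection")
  say("rejected %d/%d trials", rejection$n_rejected, rejection$n_total)
  epochs <- offset_rts(epochs, config$rt_offset_ms)
  pcs <- principal_components(epochs, config$var_target)
  tpl <- halfsine_template(config$width_ms, epochs$sfreq)
  md <- pattern_crosscorrelation(pcs, tpl)
  say("fitting the event model")
  fit <- if (is.null(config$n_events)) {
    cumulative_fit(md, gamma_shape = config$gamma_shape,
                   max_events = config$max_events, verbose = verbose)
  } else {
    em_fit(md, config$n_events, gamma_shape = config$gamma_shape)
  }
  n_ev <- fit$model$n_events
  say("selected %d events", n_ev)
  times <- max_probability_times(fit$posterior)
  times_ms <- times / epochs$sfreq * 1000
  beh <- epochs$behavior
  delta <- if (!is.null(config$sim)) config$sim$delta else 0.05
  # interval table: stimulus -> Ev1, Ev i -> Ev i+1, Ev N -> response, RT
  ints <- cbind(times_ms[, 1],
                if (n_ev > 1) times_ms[, -1] - times_ms[, -n_ev],
                epochs$rt - times_ms[, n_ev])
  colnames(ints) <- c("S-Ev1",
                      if (n_ev > 1) paste0("Ev", 1:(n_ev - 1), "-Ev", 2:n_ev),
                      paste0("Ev", n_ev, "-R"))
  interval_tab <- data.frame(beh, rt_ms = epochs$rt, check.names = FALSE)
  interval_tab[colnames(ints)] <- ints
  if (n_ev == 5) {
    cmb <- combine_intervals(times_ms, epochs$rt)
    interval_tab$encoding <- cmb$encoding_ms
    interval_tab$decision <- cmb$decision_ms
  }
  say("comparing laws per interval")
  iv_names <- c("rt_ms", colnames(ints),
                intersect(c("encoding", "decision"), names(interval_tab)))
  interval_cv <- lapply(stats::setNames(iv_names, iv_names), function(v) {
    tr <- data.frame(participant = beh$participant,
                     contrast = beh$contrast, correct = beh$correct)
    tr[[v]] <- interval_tab[[v]]
    bins <- bin_by_contrast(tr, config$n_bins, value = v)
    tryCatch(loo_cv(bins, config$laws, delta), error = function(e) e)
  })
  topo <- event_topographies(epochs, times)
  asym <- if (dim(epochs$data)[2] == 32 &&
              length(unique(beh$participant)) >= 2) {
    asymmetry_tests(topo)
  }
  say("build-up statistics on the final event")
  last_topo <- colMeans(topo[, , n_ev, drop = FALSE], dims = 1)
  ms <- match_time_series(epochs, as.numeric(last_topo), times[, n_ev])
  bu <- buildup_regression(ms, times[, n_ev])
  bu_tab <- data.frame(beh, bu[, c("intercept", "slope", "dropped")])
  bins10 <- cut(beh$contrast, seq(0.035, 0.955, length.out = 11),
                include.lowest = TRUE, labels = FALSE)
  agg <- stats::aggregate(
    cbind(intercept = bu_tab$intercept, slope = bu_tab$slope,
          accuracy = as.numeric(bu_tab$correct)),
    by = list(bin = bins10), FUN = mean, na.rm = TRUE)
  buildup <- list(
    fits = bu_tab, per_bin = agg,
    intercept_accuracy = accuracy_correlation(agg$intercept, agg$accuracy),
    slope_accuracy = accuracy_correlation(agg$slope, agg$accuracy)
  )
  # contrast effect on the final event's expression: cluster-level
  # paired test of high (> 50%) vs low (< 50%) contrast on
  # participant-averaged match series over a common stimulus-locked
  # window
  clusters <- NULL
  parts <- unique(beh$participant)
  if (length(parts) >= 2) {
    Tmin <- min(lengths(ms$series))
    avg_trace <- function(p, hi) {
      idx <- which(beh$participant == p & (beh$contrast > 0.5) == hi)
      if (length(idx) == 0) return(rep(NA_real_, Tmin))
      colMeans(do.call(rbind, lapply(ms$series[idx], `[`, seq_len(Tmin))))
    }
    hiM <- do.call(rbind, lapply(parts, avg_trace, hi = TRUE))
    loM <- do.call(rbind, lapply(parts, avg_trace, hi = FALSE))
    if (!anyNA(hiM) && !anyNA(loM)) {
      clusters <- cluster_permutation_test(hiM, loM, n_perm = config$n_perm,
                                           seed = config$seed)
    }
  }
  report <- structure(list(
    rejection = rejection, n_events = n_ev, model = fit$model,
    posterior_loglik = fit$model$loglik,
    mean_peak_ms = colMeans(times_ms),
    interval_table = interval_tab,
    interval_cv = interval_cv,
    topographies = topo, asymmetry = asym, buildup = buildup,
    clusters = clusters,
    truth = truth, config = config, config_hash = config_hash(config),
    versions = list(r = R.version.string,
                    package = as.character(utils::packageVersion("chronodecomp")))
  ), class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d events selected, %d/%d trials rejected, config %s\n",
              x$n_events, x$rejection$n_rejected, x$rejection$n_total,
              substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Export the law-comparison table
#'
#' Writes the leave-one-contrast-out comparison as a CSV with one row
#' per law and one column per interval (RT, stimulus->Ev1, inter-event
#' intervals, Ev->response, encoding, decision). Cells hold
#' `RMSE (R2)` in milliseconds, with `*` marking the winning (minimum
#' RMSE) law per interval. Intervals whose comparison failed are
#' omitted with a warning.
#'
#' @param report A `run_report`.
#' @param path Optional CSV output path.
#' @return The table as a data frame (invisibly written to `path`).
#' @export
export_table1_analogue <- function(report, path = NULL) {
  cvs <- report$interval_cv
  ok <- vapply(cvs, inherits, logical(1), "cv_result")
  if (any(!ok)) {
    warning("omitting intervals with failed law comparison: ",
            paste(names(cvs)[!ok], collapse = ", "))
    cvs <- cvs[ok]
  }
  laws <- cvs[[1]]$law
  tab <- data.frame(law = laws)
  for (nm in names(cvs)) {
    cv <- cvs[[nm]]
    tab[[nm]] <- sprintf("%.2f (%.2f)%s", cv$rmse, cv$r2,
                         ifelse(cv$winner, "*", ""))
  }
  attr(tab, "units") <- "RMSE in ms; R2 dimensionless; * = winner"
  attr(tab, "config_hash") <- report$config_hash
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(tab)
}
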