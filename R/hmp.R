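#' Event model for the sequential multivariate pattern decomposition
#'
#' Holds the parameters of an N-event model: per-event magnitudes on the
#' principal components (the spatial pattern in component space), the
#' gamma stage-duration scales (in samples) for the N + 1 stages, the
#' fixed gamma shape, and the template geometry.
#'
#' @param n_events Number of events N (>= 1).
#' @param magnitudes N x K matrix of component magnitudes.
#' @param gamma_scales Length N + 1 vector of gamma scales, samples.
#' @param gamma_shape Gamma shape (default 2).
#' @param width_ms,sfreq Template width (ms) and sampling rate (Hz).
#' @param location Per-stage minimum duration offset in samples (length
#'   N + 1, default 0): stage durations are `location + gamma`, so
#'   consecutive event peaks must lie more than `location` samples
#'   apart. Fitting routines default interior stages to the template
#'   width minus one sample, which forbids two events from explaining
#'   the same half-sine deflection.
#' @param loglik Optional log-likelihood of the fitted model.
#' @return Object of class `event_model`.
#' @export
event_model <- function(n_events, magnitudes, gamma_scales,
                        gamma_shape = 2, width_ms = 25, sfreq = 200,
                        location = 0, loglik = NA_real_) {
  magnitudes <- rbind(magnitudes)
  location <- rep_len(location, n_events + 1)
  stopifnot(n_events >= 1, nrow(magnitudes) == n_events,
            length(gamma_scales) == n_events + 1,
            all(gamma_scales > 0), gamma_shape > 0, all(location >= 0))
  structure(list(
    n_events = as.integer(n_events), magnitudes = magnitudes,
    gamma_shape = gamma_shape, gamma_scales = as.numeric(gamma_scales),
    location = as.integer(location),
    width_ms = width_ms, sfreq = sfreq, loglik = loglik
  ), class = "event_model")
}

#' @export
print.event_model <- function(x, ...) {
  cat(sprintf(
    "<event_model> %d events, %d components, gamma(shape %g) scales [%s] samples, loglik %.2f\n",
    x$n_events, ncol(x$magnitudes), x$gamma_shape,
    paste(sprintf("%.1f", x$gamma_scales), collapse = ", "), x$loglik
  ))
  invisible(x)
}

# discretized gamma duration pmf over integer durations 1..Tmax:
# mass(d) = CDF(d - location + 0.5) - CDF(d - location - 0.5),
# renormalized; zero mass at or below `location`
stage_duration_pmf <- function(shape, scale, Tmax, location = 0) {
  d <- seq_len(Tmax) - location
  pr <- ifelse(d > 0,
               stats::pgamma(d + 0.5, shape, scale = scale) -
                 stats::pgamma(d - 0.5, shape, scale = scale),
               0)
  s <- sum(pr)
  if (s <= 0) stop("degenerate stage duration pmf (scale = ", scale, ")")
  pr / s
}

# stage-duration pmfs as a Tmax x (N+1) matrix (one column per stage)
model_pmf_matrix <- function(model, Tmax) {
  loc <- if (is.null(model$location)) rep(0L, length(model$gamma_scales)) else
    model$location
  P <- vapply(seq_along(model$gamma_scales), function(i) {
    stage_duration_pmf(model$gamma_shape, model$gamma_scales[i], Tmax, loc[i])
  }, numeric(Tmax))
  dmax <- apply(P, 2, function(p) {
    d <- which(cumsum(p) >= 1 - 1e-12)[1]
    if (is.na(d)) Tmax else d
  })
  list(P = P, dmax = as.integer(pmax(dmax, 2L)))
}

trial_log_evidence <- function(x, valid, model) {
  logf <- x %*% t(model$magnitudes)
  logf <- sweep(logf, 2, rowSums(model$magnitudes^2) / 2, "-")
  logf[!valid, ] <- -Inf
  logf
}

#' Exact posterior over event placements for one trial
#'
#' Runs the forward-backward recursion for a single trial under a given
#' event model. The stage-duration prior is the discretized gamma; the
#' event evidence is a unit-variance Gaussian model on the
#' template-cross-correlated component scores,
#' `log f_i(t) = sum_k (m_ik x_k(t) - m_ik^2 / 2)`.
#'
#' @param x Samples x components matrix of match scores for the trial.
#' @param valid Logical vector marking admissible peak samples.
#' @param model An `event_model`.
#' @return List with `gamma` (samples x events posterior, each column
#'   sums to 1), `loglik`, and `expected_times` (posterior mean peak
#'   sample per event).
#' @export
forward_backward <- function(x, valid, model) {
  x <- as.matrix(x)
  T_i <- nrow(x)
  pm <- model_pmf_matrix(model, T_i)
  logf <- trial_log_evidence(x, valid, model)
  res <- fb_trial(logf, pm$P, pm$dmax)
  res$expected_times <- as.numeric(seq_len(T_i) %*% res$gamma)
  res
}

estep <- function(matchdata, model, pm = NULL) {
  n <- length(matchdata$x)
  Tmax <- max(vapply(matchdata$x, nrow, integer(1)))
  if (is.null(pm)) pm <- model_pmf_matrix(model, Tmax)
  gam <- vector("list", n)
  et <- matrix(NA_real_, n, model$n_events)
  ll <- 0
  for (i in seq_len(n)) {
    logf <- trial_log_evidence(matchdata$x[[i]], matchdata$valid[[i]], model)
    res <- fb_trial(logf, pm$P, pm$dmax)
    gam[[i]] <- res$gamma
    et[i, ] <- seq_len(nrow(logf)) %*% res$gamma
    ll <- ll + res$loglik
  }
  list(gamma = gam, expected_times = et, loglik = ll)
}

mstep <- function(matchdata, e, shape, location, min_scale = 0.25) {
  n <- length(matchdata$x)
  K <- ncol(matchdata$x[[1]])
  N <- ncol(e$expected_times)
  m <- matrix(0, N, K)
  for (i in seq_len(n)) {
    m <- m + t(e$gamma[[i]]) %*% matchdata$x[[i]]
  }
  m <- m / n
  Tlen <- vapply(matchdata$x, nrow, integer(1))
  bounds <- cbind(0, e$expected_times, Tlen)
  mean_dur <- colMeans(bounds[, -1, drop = FALSE] -
                       bounds[, -ncol(bounds), drop = FALSE])
  list(magnitudes = m,
       scales = pmax((mean_dur - location) / shape, min_scale))
}

#' Fit an N-event model by expectation maximization
#'
#' Alternates the exact forward-backward pass (E step) with closed-form
#' updates of the component magnitudes and gamma scales (M step; the
#' scale update uses posterior-expected event times). Iteration stops
#' when the relative log-likelihood gain falls below `tol` or after
#' `max_iter` iterations.
#'
#' @param matchdata A `match_data` from [pattern_crosscorrelation()].
#' @param n_events Number of events to fit.
#' @param init Optional `event_model` (or list with `magnitudes` and
#'   `gamma_scales`) used as starting point; by default magnitudes start
#'   at zero and scales split the mean trial length evenly.
#' @param gamma_shape Gamma shape parameter (default 2).
#' @param location Per-stage minimum duration offsets in samples
#'   (recycled to length N + 1). The default forces consecutive event
#'   peaks at least one template width apart (interior stages) while
#'   leaving the boundary stages unconstrained beyond the edge mask.
#' @param tol Relative log-likelihood stopping tolerance (default 1e-4).
#' @param max_iter Maximum EM iterations (default 200).
#' @return List with `model` (an `event_model`; stages whose expected
#'   duration is below the template width are flagged in attribute
#'   `degenerate_stages`), `posterior` (class `event_posterior`: per-trial
#'   `gamma`, `expected_times`, `loglik`), and `trace` (log-likelihood per
#'   iteration).
#' @export
em_fit <- function(matchdata, n_events, init = NULL, gamma_shape = 2,
                   location = NULL, tol = 1e-4, max_iter = 200) {
  stopifnot(n_events >= 1)
  K <- ncol(matchdata$x[[1]])
  Tlen <- vapply(matchdata$x, nrow, integer(1))
  width_smp <- length(matchdata$template$weights)
  if (is.null(location)) {
    location <- c(0L, rep(width_smp - 1L, max(n_events - 1L, 0L)), 0L)
  }
  location <- as.integer(rep_len(location, n_events + 1))
  if (any(Tlen - 2 * floor(width_smp / 2) - sum(location) < n_events)) {
    stop("some trials are too short for ", n_events, " events")
  }
  if (is.null(init)) {
    model <- event_model(
      n_events, matrix(0, n_events, K),
      rep(mean(Tlen) / (gamma_shape * (n_events + 1)), n_events + 1),
      gamma_shape, matchdata$template$width_ms, matchdata$sfreq,
      location = location
    )
  } else {
    model <- event_model(n_events, init$magnitudes, init$gamma_scales,
                         gamma_shape, matchdata$template$width_ms,
                         matchdata$sfreq, location = location)
  }
  trace <- numeric(0)
  ll_prev <- -Inf
  e <- NULL
  for (iter in seq_len(max_iter)) {
    e <- estep(matchdata, model)
    trace <- c(trace, e$loglik)
    if (is.finite(ll_prev) &&
        (e$loglik - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- e$loglik
    m <- mstep(matchdata, e, gamma_shape, location)
    model$magnitudes <- m$magnitudes
    model$gamma_scales <- m$scales
  }
  model$loglik <- e$loglik
  # a healthy stage's expected duration beyond the hard minimum
  # separation must itself reach the template width; a stage pinned at
  # the minimum signals an event duplicated onto its neighbour
  attr(model, "degenerate_stages") <-
    which(model$gamma_shape * model$gamma_scales < width_smp)
  posterior <- structure(list(
    gamma = e$gamma, expected_times = e$expected_times,
    loglik = e$loglik, n_samples = Tlen, sfreq = matchdata$sfreq
  ), class = "event_posterior")
  list(model = model, posterior = posterior, trace = trace)
}

#' Estimate the number of events by cumulative fitting
#'
#' Grows the model one event at a time: the (n+1)-event model is
#' initialized from the n-event solution with a zero-magnitude event
#' inserted into each stage in turn (scale split in half), each candidate
#' is refined by a short EM run, the best is refined to convergence, and
#' the larger model is accepted while the log-likelihood improves by more
#' than `tol` and no stage is degenerate (every stage's expected duration
#' beyond the hard minimum separation must reach the template width; see
#' [em_fit()]). A 1-event model is always returned at minimum; if its
#' magnitudes are all near zero the result carries the
#' `no_reliable_events` flag.
#'
#' @param matchdata A `match_data`.
#' @param gamma_shape Gamma shape (default 2).
#' @param max_events Upper bound on the number of events.
#' @param tol Log-likelihood acceptance tolerance. The default, `NULL`,
#'   requires an average gain of `tol_per_trial` per trial: noise
#'   self-alignment yields well under 0.3 per trial whereas a genuine
#'   event at calibrated SNR yields several units, so the bar rejects
#'   chance structure at any dataset size.
#' @param tol_per_trial Per-trial gain used to build the default `tol`.
#' @param scan_iter EM iterations used to score each insertion candidate.
#' @param verbose Print progress.
#' @return As [em_fit()], for the selected model; attribute
#'   `candidate_loglik` records the accepted log-likelihood path.
#' @export
cumulative_fit <- function(matchdata, gamma_shape = 2, max_events = 10,
                           tol = NULL, tol_per_trial = 1,
                           scan_iter = 15, verbose = FALSE) {
  width_smp <- length(matchdata$template$weights)
  n_tr <- length(matchdata$x)
  if (is.null(tol)) tol <- tol_per_trial * n_tr
  cur <- em_fit(matchdata, 1, gamma_shape = gamma_shape)
  path <- cur$model$loglik
  while (cur$model$n_events < max_events) {
    n <- cur$model$n_events
    cand_best <- NULL
    for (g in 0:n) {
      mags <- cur$model$magnitudes
      new_m <- rbind(mags[seq_len(g), , drop = FALSE],
                     0,
                     if (g < n) mags[(g + 1):n, , drop = FALSE])
      sc <- cur$model$gamma_scales
      new_s <- append(sc[-(g + 1)], rep(sc[g + 1] / 2, 2), after = g)
      cand <- em_fit(matchdata, n + 1,
                     init = list(magnitudes = new_m, gamma_scales = new_s),
                     gamma_shape = gamma_shape, max_iter = scan_iter)
      if (is.null(cand_best) || cand$model$loglik > cand_best$model$loglik) {
        cand_best <- cand
      }
    }
    refined <- em_fit(matchdata, n + 1,
                      init = cand_best$model, gamma_shape = gamma_shape)
    ok <- refined$model$loglik > cur$model$loglik + tol &&
      length(attr(refined$model, "degenerate_stages")) == 0
    if (verbose) {
      message(sprintf("n = %d -> %d: loglik %.2f -> %.2f, %s",
                      n, n + 1, cur$model$loglik, refined$model$loglik,
                      if (ok) "accepted" else "rejected"))
    }
    if (!ok) break
    cur <- refined
    path <- c(path, cur$model$loglik)
  }
  # a dataset without trial-recurrent events: even the single fitted
  # event barely improves on flat (zero-magnitude) evidence
  flat <- cur$model
  flat$magnitudes[] <- 0
  flat_ll <- estep(matchdata, flat)$loglik
  attr(cur$model, "no_reliable_events") <-
    (cur$model$loglik - flat_ll) / n_tr < tol_per_trial
  attr(cur$model, "candidate_loglik") <- path
  cur
}

#' Most likely single-trial event times
#'
#' The per-trial per-event maximum-probability peak sample (ties broken
#' to the earliest sample). The sequence is reported as-is, without
#' enforcing monotonicity.
#'
#' @param posterior An `event_posterior`.
#' @return Trials x events integer matrix of peak samples.
#' @export
max_probability_times <- function(posterior) {
  N <- ncol(posterior$gamma[[1]])
  matrix(vapply(posterior$gamma,
                function(g) as.integer(apply(g, 2, which.max)),
                integer(N)),
         ncol = N, byrow = TRUE)
}

#' Event topographies from single-trial event times
#'
#' Samples the channel values of every trial at its estimated event
#' times (`mode = "peak"`: the value at the peak sample; `mode =
#' "mean"`: averaged over the template width centered on the peak), then
#' averages per participant and event.
#'
#' @param dataset An `epoched_dataset`.
#' @param times Trials x events matrix of peak samples.
#' @param mode `"peak"` or `"mean"`.
#' @param width_ms Averaging window for `mode = "mean"`, ms.
#' @return Array participants x channels x events, with participant ids
#'   as first dimnames.
#' @export
event_topographies <- function(dataset, times, mode = c("peak", "mean"),
                               width_ms = 25) {
  mode <- match.arg(mode)
  n <- n_trials(dataset)
  stopifnot(nrow(times) == n)
  if (any(times < 1 | times > dataset$n_samples)) {
    stop("event time outside the trial window")
  }
  n_ch <- dim(dataset$data)[2]
  n_ev <- ncol(times)
  hw <- floor(round(width_ms * dataset$sfreq / 1000) / 2)
  parts <- unique(dataset$behavior$participant)
  out <- array(NA_real_, c(length(parts), n_ch, n_ev),
               dimnames = list(parts, dataset$channel_names, NULL))
  for (pi in seq_along(parts)) {
    idx <- which(dataset$behavior$participant == parts[pi])
    for (e in seq_len(n_ev)) {
      vals <- vapply(idx, function(i) {
        if (mode == "peak") {
          dataset$data[i, , times[i, e]]
        } else {
          lo <- max(1, times[i, e] - hw)
          hi <- min(dataset$n_samples[i], times[i, e] + hw)
          rowMeans(array(dataset$data[i, , lo:hi], c(n_ch, hi - lo + 1)))
        }
      }, numeric(n_ch))
      out[pi, , e] <- rowMeans(vals)
    }
  }
  out
}

#' Back-project component magnitudes to channel space
#'
#' Reconstructs each event's channel-space topography implied by the
#' fitted component magnitudes, undoing the per-participant z-scoring by
#' the pooled standard deviation (averaged over participants).
#'
#' @param model An `event_model`.
#' @param matchdata The `match_data` the model was fitted on (supplies
#'   loadings and z-scale).
#' @return Channels x events matrix.
#' @export
backproject_topographies <- function(model, matchdata) {
  sd_bar <- mean(vapply(matchdata$zscale, `[[`, numeric(1), "sd"))
  matchdata$loadings %*% t(model$magnitudes) * sd_bar
}
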