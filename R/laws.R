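#' Mean duration under Pieron's law
#'
#' Pieron's law states that detection latency decreases as a power function
#' of stimulus intensity. The fitted form used throughout the package
#' includes an intercept, `alpha + beta * C^-nu`; the classical
#' intercept-free form `beta * C^-nu` is obtained with `alpha = 0`.
#'
#' @param C Stimulus contrast, a fraction in (0, 1]. Vectorized.
#' @param params List or named vector with elements `alpha` (ms), `beta`
#'   (ms), and `nu` (dimensionless exponent, >= 0).
#' @return Predicted mean duration in milliseconds.
#' @examples
#' pieron_mean(0.25, list(alpha = 100, beta = 50, nu = 0.5)) # 200 ms
#' @export
pieron_mean <- function(C, params) {
  stopifnot(all(C > 0))
  params <- as.list(params)
  if (params$nu < 0) stop("Pieron exponent `nu` must be >= 0")
  params$alpha + params$beta * C^(-params$nu)
}

#' Mean duration under an atheoretical linear model
#'
#' @param C Stimulus contrast. Vectorized.
#' @param params List with `alpha` (intercept, ms) and `beta`
#'   (slope, ms per contrast unit).
#' @return Predicted mean duration in milliseconds.
#' @export
linear_mean <- function(C, params) {
  params <- as.list(params)
  params$alpha + params$beta * C
}

#' Perceived contrast difference under Fechner's law
#'
#' For two patches at contrasts `C + delta/2` and `C - delta/2`, the
#' perceived difference is the sensitivity-scaled log-ratio of the two
#' physical intensities: `p = beta * log((C + delta/2) / (C - delta/2))`.
#'
#' @param C Mean contrast of the two patches, must exceed `delta/2`.
#' @param delta Total physical contrast difference between the patches.
#' @param beta Sensitivity (dimensionless), default 1.
#' @return Perceived difference `p` (drift rate when multiplied into the
#'   diffusion model).
#' @export
fechner_p <- function(C, delta, beta = 1) {
  if (any(C <= delta / 2)) {
    stop("fechner_p undefined: contrast must exceed delta/2")
  }
  beta * log((C + delta / 2) / (C - delta / 2))
}

#' Mean RT under the proportional-rate Fechner diffusion model
#'
#' Mean decision time of a drift diffusion process whose drift is
#' proportional to the Fechner perceived difference `p`:
#' `RT = A / (beta * p) * tanh(A * p) + T0`, with
#' `p = beta * log((C + delta/2) / (C - delta/2))`. As `p -> 0` the
#' expression tends to the analytic limit `A^2 / beta + T0`. Because `p`
#' decreases with the overall contrast `C` (fixed `delta`), predicted RT
#' increases with `C`.
#'
#' @param C Mean contrast, vectorized.
#' @param delta Total contrast difference between the two patches.
#' @param params List with `beta` (sensitivity, > 0), `A` (decision
#'   criterion, evidence units, > 0), `t0` (residual/nondecision time, ms).
#' @param unit Time unit of the diffusion term: `"s"` (default) converts
#'   the `A/(beta p) tanh(A p)` term from seconds to milliseconds before
#'   adding `t0` (which is always in ms); `"ms"` uses it as-is.
#' @return Predicted mean RT (or stage duration) in milliseconds.
#' @export
fechner_rt <- function(C, delta, params, unit = c("s", "ms")) {
  unit <- match.arg(unit)
  params <- as.list(params)
  p <- fechner_p(C, delta, params$beta)
  dt <- ifelse(abs(p) < 1e-12,
    params$A^2 / params$beta,
    params$A / (params$beta * p) * tanh(params$A * p)
  )
  if (unit == "s") dt <- dt * 1000
  dt + params$t0
}

#' Predicted proportion correct under the Fechner diffusion model
#'
#' `Pc = 1 / (1 + exp(-2 * A * p))` with `p = beta * log((C + delta/2) /
#' (C - delta/2))`. At `p = 0` accuracy is at chance (0.5); accuracy
#' decreases with the overall contrast because `p` does.
#'
#' @inheritParams fechner_rt
#' @return Predicted proportion of correct responses in (0.5, 1) for p > 0.
#' @export
fechner_pc <- function(C, delta, params) {
  params <- as.list(params)
  p <- fechner_p(C, delta, params$beta)
  1 / (1 + exp(-2 * params$A * p))
}

#' Bin trials by contrast and summarize durations and accuracy
#'
#' Partitions the contrast range into `n_bins` equal-width bins and
#' computes, per participant and bin, the mean of the chosen duration
#' column and the proportion of correct responses. Empty bins are dropped
#' with a warning.
#'
#' @param trials Data frame with columns `participant`, `contrast`,
#'   `correct` (logical), and the duration column named by `value`.
#' @param n_bins Number of equal-width bins (>= 2), default 10.
#' @param value Name of the duration column (ms), default `"rt"`.
#' @param range Contrast range to partition; defaults to the observed range.
#' @return Object of class `contrast_bins`: a data frame with columns
#'   `participant`, `bin`, `contrast` (mean contrast of the trials in
#'   the bin), `mean_ms`, `accuracy`, `n`, plus a `breaks` attribute.
#' @export
bin_by_contrast <- function(trials, n_bins = 10, value = "rt", range = NULL) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  stopifnot(value %in% names(trials))
  if (is.null(range)) range <- base::range(trials$contrast)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- cut(trials$contrast, breaks, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(trials)),
                                     list(trials$participant, bin),
                                     drop = TRUE), function(idx) {
    data.frame(
      participant = trials$participant[idx[1]],
      bin = bin[idx[1]],
      contrast = mean(trials$contrast[idx]),
      mean_ms = mean(trials[[value]][idx]),
      accuracy = mean(trials$correct[idx]),
      n = length(idx)
    )
  }))
  out <- out[order(out$participant, out$bin), ]
  rownames(out) <- NULL
  n_empty <- n_bins * length(unique(trials$participant)) - nrow(out)
  if (n_empty > 0) {
    warning(sprintf("%d empty participant x contrast bins dropped", n_empty))
  }
  attr(out, "breaks") <- breaks
  attr(out, "delta") <- attr(trials, "delta")
  class(out) <- c("contrast_bins", class(out))
  out
}

law_predict <- function(law, C, params, delta) {
  switch(law,
    linear = linear_mean(C, params),
    pieron = pieron_mean(C, params),
    fechner = fechner_rt(C, delta, params),
    stop("unknown law: ", law)
  )
}

law_par_info <- function(law, y, C) {
  # start values, box bounds, and jitter scale per law
  yr <- max(diff(range(y)), 1)
  switch(law,
    linear = list(
      start = c(alpha = min(y), beta = 0),
      lower = c(-Inf, -Inf), upper = c(Inf, Inf)
    ),
    pieron = list(
      start = c(alpha = min(y) * 0.5, beta = yr * 0.3, nu = 0.5),
      lower = c(0, 0, 0), upper = c(Inf, Inf, 5)
    ),
    fechner = list(
      # diffusion term in seconds; t0 in ms
      start = c(beta = 5, A = 1, t0 = max(min(y) * 0.5, 0)),
      lower = c(1e-3, 1e-3, 0), upper = c(50, 10, max(min(y), 1))
    )
  )
}

fit_law_one <- function(C, y, law, delta, n_starts = 5, seed = 1L) {
  info <- law_par_info(law, y, C)
  resid_fn <- function(par) {
    names(par) <- names(info$start)
    law_predict(law, C, as.list(par), delta) - y
  }
  rng <- local({ set.seed(seed); lapply(seq_len(n_starts), function(i) runif(length(info$start), 0.25, 2)) })
  best <- NULL
  for (i in seq_len(n_starts)) {
    start <- info$start * rng[[i]]
    start <- pmin(pmax(start, info$lower + 1e-8), info$upper)
    fit <- try(minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = info$lower, upper = info$upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) {
      par <- fit$par
      names(par) <- names(info$start)
      best <- list(par = as.list(par), sse = sse)
    }
  }
  if (is.null(best)) stop("law fit failed to converge for law '", law, "'")
  best
}

#' Fit a psychophysical law to per-participant binned durations
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box
#' constraints, 5 jittered multi-starts) of the chosen law to the
#' per-participant per-bin mean durations. The Pieron exponent is
#' constrained nonnegative so predictions decrease with contrast; the
#' Fechner diffusion parameters are bounded (`beta` in (0, 50], `A` in
#' (0, 10], `t0` between 0 and the minimum duration).
#'
#' @param bins A `contrast_bins` object from [bin_by_contrast()].
#' @param law One of `"linear"`, `"pieron"`, `"fechner"`.
#' @param delta Physical contrast difference (needed for `"fechner"`).
#' @param n_starts Number of jittered starts, default 5.
#' @return Object of class `law_fit`: list with `law`, per-participant
#'   `params`, `fitted`, `residuals`, and `rmse`.
#' @export
fit_law <- function(bins, law = c("linear", "pieron", "fechner"),
                    delta = 0.05, n_starts = 5) {
  law <- match.arg(law)
  parts <- split(bins, bins$participant)
  fits <- lapply(parts, function(b) {
    if (nrow(b) < length(law_par_info(law, b$mean_ms, b$contrast)$start)) {
      stop("need at least as many bins as parameters")
    }
    fit_law_one(b$contrast, b$mean_ms, law, delta, n_starts)
  })
  fitted <- unlist(lapply(names(parts), function(p) {
    law_predict(law, parts[[p]]$contrast, fits[[p]]$par, delta)
  }))
  observed <- unlist(lapply(parts, `[[`, "mean_ms"))
  structure(list(
    law = law,
    delta = delta,
    params = lapply(fits, `[[`, "par"),
    fitted = fitted,
    residuals = observed - fitted,
    rmse = sqrt(mean((observed - fitted)^2))
  ), class = "law_fit")
}

#' @export
print.law_fit <- function(x, ...) {
  cat(sprintf("<law_fit> law = %s, %d participant(s), in-sample RMSE = %.2f ms\n",
              x$law, length(x$params), x$rmse))
  invisible(x)
}

#' Leave-one-contrast-out cross-validation of competing laws
#'
#' For every contrast bin in turn, each law is refitted per participant on
#' the remaining bins and used to predict the held-out bin mean; the
#' square root of the mean squared prediction error (RMSE, ms) is pooled
#' across held-out bins and participants. Also reports the R-squared of
#' predicted versus observed bin means, and flags the winning law
#' (minimum RMSE).
#'
#' @param bins A `contrast_bins` object.
#' @param laws Character vector of laws to compare.
#' @param delta Physical contrast difference for the Fechner law.
#' @return Object of class `cv_result`: data frame with one row per law
#'   (`law`, `rmse`, `r2`, `winner`), with per-law prediction tables in
#'   attribute `predictions`.
#' @export
loo_cv <- function(bins, laws = c("linear", "pieron", "fechner"),
                   delta = 0.05) {
  parts <- split(bins, bins$participant)
  preds <- list()
  rows <- lapply(laws, function(law) {
    pred_tab <- do.call(rbind, lapply(parts, function(b) {
      ubins <- unique(b$bin)
      npar <- length(law_par_info(law, b$mean_ms, b$contrast)$start)
      if (length(ubins) < npar + 1) stop("need at least #params + 1 bins")
      pred <- vapply(ubins, function(hold) {
        train <- b[b$bin != hold, ]
        fit <- fit_law_one(train$contrast, train$mean_ms, law, delta)
        law_predict(law, b$contrast[b$bin == hold], fit$par, delta)
      }, numeric(1))
      data.frame(participant = b$participant[1], bin = ubins,
                 observed = b$mean_ms[match(ubins, b$bin)], predicted = pred)
    }))
    preds[[law]] <<- pred_tab
    err <- pred_tab$predicted - pred_tab$observed
    ss_tot <- sum((pred_tab$observed - mean(pred_tab$observed))^2)
    data.frame(law = law, rmse = sqrt(mean(err^2)),
               r2 = 1 - sum(err^2) / ss_tot)
  })
  out <- do.call(rbind, rows)
  out$winner <- out$rmse == min(out$rmse)
  attr(out, "predictions") <- preds
  class(out) <- c("cv_result", class(out))
  out
}

#' Predict accuracy from an RT-only Fechner diffusion fit
#'
#' Applies the accuracy equation of the proportional-rate diffusion model
#' with the parameters estimated from durations alone, and reports the
#' R-squared against the observed per-bin proportion correct. If the
#' observed accuracies are (near-)constant the R-squared is undefined and
#' flagged `NA` with `degenerate = TRUE`.
#'
#' @param fit A `law_fit` with `law == "fechner"`.
#' @param bins The `contrast_bins` the fit should be evaluated on.
#' @return List with `predictions` (per participant x bin data frame of
#'   predicted and observed accuracy), `r2`, and `degenerate`.
#' @export
predict_accuracy <- function(fit, bins) {
  stopifnot(inherits(fit, "law_fit"), fit$law == "fechner")
  parts <- split(bins, bins$participant)
  tab <- do.call(rbind, lapply(names(parts), function(p) {
    b <- parts[[p]]
    data.frame(participant = p, bin = b$bin, contrast = b$contrast,
               observed = b$accuracy,
               predicted = fechner_pc(b$contrast, fit$delta, fit$params[[p]]))
  }))
  ss_tot <- sum((tab$observed - mean(tab$observed))^2)
  degenerate <- ss_tot < 1e-12
  r2 <- if (degenerate) NA_real_ else 1 - sum((tab$predicted - tab$observed)^2) / ss_tot
  list(predictions = tab, r2 = r2, degenerate = degenerate)
}

#' Combine inter-event intervals into encoding and decision times
#'
#' With five events, the encoding time is the sum of the Event 1 to 2 and
#' Event 2 to 3 intervals (t3 - t1) and the decision time the sum of the
#' Event 3 to 4 and 4 to 5 intervals (t5 - t3).
#'
#' @param event_times Matrix (trials x 5) of event peak times, ms.
#' @param rt Optional RT vector (ms), used only to sanity-check bounds.
#' @return Data frame with `encoding_ms`, `decision_ms`, and a logical
#'   `flagged` column marking trials with non-monotone event times.
#' @export
combine_intervals <- function(event_times, rt = NULL) {
  stopifnot(ncol(event_times) == 5)
  flagged <- apply(event_times, 1, function(t) any(diff(t) <= 0))
  out <- data.frame(
    encoding_ms = event_times[, 3] - event_times[, 1],
    decision_ms = event_times[, 5] - event_times[, 3],
    flagged = flagged
  )
  if (!is.null(rt) && any(event_times[, 5] > rt)) {
    out$flagged <- out$flagged | event_times[, 5] > rt
  }
  out
}
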