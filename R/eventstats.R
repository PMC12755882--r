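#' Hemispheric asymmetry tests of event topographies
#'
#' For every lateral electrode pair and event, subtracts the
#' right-hemisphere channel value from its left counterpart per
#' participant and tests the differences against zero with a one-sample
#' paired t-test. Significance uses Bonferroni correction over all
#' pairs x events tests at base level `alpha`. Zero-variance differences
#' get p = 1 and are flagged.
#'
#' @param topographies Participants x channels x events array from
#'   [event_topographies()] (channel dimnames required).
#' @param pairing Data frame with `left`/`right` channel name columns;
#'   default the standard 14-pair montage of [montage_pairs()].
#' @param alpha Base alpha level (default 0.05).
#' @return Object of class `asymmetry_result`: data frame with one row
#'   per pair x event (`pair`, `event`, `mean_diff`, `t`, `p`,
#'   `significant`, `zero_variance`); attributes `n_tests` and
#'   `threshold` (the Bonferroni-corrected alpha).
#' @export
asymmetry_tests <- function(topographies, pairing = montage_pairs(),
                            alpha = 0.05) {
  stopifnot(length(dim(topographies)) == 3)
  n_part <- dim(topographies)[1]
  if (n_part < 2) stop("need at least 2 participants")
  ch_names <- dimnames(topographies)[[2]]
  if (is.null(ch_names)) stop("topographies must carry channel names")
  n_ev <- dim(topographies)[3]
  n_tests <- nrow(pairing) * n_ev
  threshold <- alpha / n_tests
  rows <- list()
  for (k in seq_len(nrow(pairing))) {
    li <- match(pairing$left[k], ch_names)
    ri <- match(pairing$right[k], ch_names)
    if (is.na(li) || is.na(ri)) stop("pairing channel not in montage")
    for (e in seq_len(n_ev)) {
      d <- topographies[, li, e] - topographies[, ri, e]
      zero_var <- stats::sd(d) < 1e-12
      if (zero_var) {
        tval <- 0; pval <- 1
      } else {
        tt <- stats::t.test(d)
        tval <- unname(tt$statistic); pval <- tt$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste0(pairing$left[k], "-", pairing$right[k]),
        event = e, mean_diff = mean(d), t = tval, p = pval,
        significant = pval < threshold, zero_variance = zero_var
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- n_tests
  attr(out, "threshold") <- threshold
  class(out) <- c("asymmetry_result", class(out))
  out
}

#' Bonferroni-corrected alpha for the asymmetry analysis
#'
#' @param n_pairs Number of lateral electrode pairs (default 14).
#' @param n_events Number of events (default 5).
#' @param alpha Base alpha level (default 0.05).
#' @return `alpha / (n_pairs * n_events)`.
#' @export
bonferroni_threshold <- function(n_pairs = 14, n_events = 5, alpha = 0.05) {
  alpha / (n_pairs * n_events)
}

#' Single-trial topography match time series
#'
#' Uses an event's average topography as a spatial filter: for every
#' trial and sample from stimulus onset to `end_pad_ms` after the
#' trial's event peak, computes the dot product between the channel
#' vector and the topography weights.
#'
#' @param dataset An `epoched_dataset`.
#' @param topography Length-`n_channels` weight vector.
#' @param peak_times Per-trial peak samples (length = trials), or `NULL`
#'   to use the full trial window.
#' @param end_pad_ms Window extension beyond the peak, ms (default 100).
#' @return Object of class `match_series`: list of per-trial numeric
#'   vectors, with `peak_times`, `sfreq`, `truncated` (logical per
#'   trial: window clipped at the recorded epoch end), and `behavior`.
#' @export
match_time_series <- function(dataset, topography, peak_times = NULL,
                              end_pad_ms = 100) {
  n_ch <- dim(dataset$data)[2]
  stopifnot(length(topography) == n_ch)
  n <- n_trials(dataset)
  pad <- round(end_pad_ms / 1000 * dataset$sfreq)
  avail <- apply(!is.na(dataset$data[, 1, , drop = FALSE]), 1, sum)
  series <- vector("list", n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    end <- if (is.null(peak_times)) dataset$n_samples[i] else
      peak_times[i] + pad
    if (end > avail[i]) {
      end <- avail[i]
      truncated[i] <- TRUE
    }
    series[[i]] <- as.numeric(topography %*% dataset$data[i, , seq_len(end)])
  }
  structure(list(
    series = series, peak_times = peak_times, sfreq = dataset$sfreq,
    truncated = truncated, behavior = dataset$behavior
  ), class = "match_series")
}

#' Event-locked averaging of match time series
#'
#' Re-centers every trial's series so that its event peak falls at lag 0
#' and averages within groups, using per-sample trial counts (trials
#' contribute only to lags they cover). Event-locked averaging undoes
#' the latency smearing of stimulus-locked averages.
#'
#' @param mseries A `match_series` with `peak_times` set, or a list of
#'   numeric vectors (then `peak_times` must be supplied).
#' @param peak_times Per-trial peak samples (defaults to those stored).
#' @param groups Factor/vector assigning each trial to a group
#'   (default: one group).
#' @return List per group: `lag` (samples, 0 = peak), `average`, `n`
#'   (trials contributing per lag).
#' @export
event_locked_average <- function(mseries, peak_times = NULL, groups = NULL) {
  series <- if (inherits(mseries, "match_series")) mseries$series else mseries
  if (is.null(peak_times)) peak_times <- mseries$peak_times
  stopifnot(!is.null(peak_times), length(peak_times) == length(series))
  if (is.null(groups)) groups <- rep("all", length(series))
  lags <- lapply(seq_along(series), function(i) {
    seq_along(series[[i]]) - peak_times[i]
  })
  lo <- min(unlist(lapply(lags, min)))
  hi <- max(unlist(lapply(lags, max)))
  lag_axis <- lo:hi
  lapply(split(seq_along(series), groups), function(idx) {
    sums <- numeric(length(lag_axis))
    cnt <- numeric(length(lag_axis))
    for (i in idx) {
      pos <- lags[[i]] - lo + 1
      sums[pos] <- sums[pos] + series[[i]]
      cnt[pos] <- cnt[pos] + 1
    }
    avg <- ifelse(cnt > 0, sums / cnt, NA_real_)
    list(lag = lag_axis, average = avg, n = cnt)
  })
}

#' Cluster-level paired permutation test
#'
#' Nonparametric control of multiple comparisons over time for paired
#' participant-averaged traces. Per-sample paired t statistics are
#' thresholded at the two-sided p = 0.05 t quantile (n - 1 df);
#' contiguous suprathreshold runs of equal sign form clusters whose mass
#' is the sum of t values. The null distribution of the maximum absolute
#' cluster mass is built from random within-participant sign flips of
#' the condition difference (the identity assignment is included among
#' the permutations, so p >= 1/n_perm).
#'
#' @param tracesA,tracesB Participants x time matrices (paired rows).
#' @param n_perm Number of permutations (default 1024; < 100 warns).
#' @param seed Integer seed for the permutation draws (required).
#' @param cluster_alpha Two-sided cluster-forming alpha (default 0.05).
#' @return Object of class `cluster_test`: data frame of clusters
#'   (`start`, `end`, `mass`, `p`), with attributes `t_series`,
#'   `t_threshold`, and `null_max_mass`.
#' @export
cluster_permutation_test <- function(tracesA, tracesB, n_perm = 1024,
                                     seed, cluster_alpha = 0.05) {
  stopifnot(all(dim(tracesA) == dim(tracesB)))
  if (n_perm < 100) warning("n_perm < 100: p-values are coarse")
  n <- nrow(tracesA)
  d <- tracesA - tracesB
  t_thresh <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  tser <- function(dd) {
    mu <- colMeans(dd)
    se <- apply(dd, 2, stats::sd) / sqrt(n)
    ifelse(se > 0, mu / se, 0)
  }
  find_clusters <- function(tv) {
    above <- abs(tv) > t_thresh
    sgn <- sign(tv)
    # contiguous runs of suprathreshold samples with constant sign
    out <- list()
    i <- 1
    while (i <= length(tv)) {
      if (above[i]) {
        j <- i
        while (j < length(tv) && above[j + 1] && sgn[j + 1] == sgn[i]) j <- j + 1
        out[[length(out) + 1]] <- c(start = i, end = j,
                                    mass = sum(tv[i:j]))
        i <- j + 1
      } else i <- i + 1
    }
    out
  }
  t_obs <- tser(d)
  obs <- find_clusters(t_obs)
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(b) {
    flips <- if (b == 1) rep(1, n) else sample(c(-1, 1), n, replace = TRUE)
    cl <- find_clusters(tser(d * flips))
    if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  }, numeric(1))
  res <- if (length(obs) == 0) {
    data.frame(start = integer(0), end = integer(0),
               mass = numeric(0), p = numeric(0))
  } else {
    do.call(rbind, lapply(obs, function(cl) {
      data.frame(start = cl[["start"]], end = cl[["end"]],
                 mass = cl[["mass"]],
                 p = mean(null_max >= abs(cl[["mass"]])))
    }))
  }
  attr(res, "t_series") <- t_obs
  attr(res, "t_threshold") <- t_thresh
  attr(res, "null_max_mass") <- null_max
  class(res) <- c("cluster_test", class(res))
  res
}

#' Single-trial build-up regression before an event peak
#'
#' Ordinary least squares of the match series on time over the window
#' ending at the event peak (default the preceding 250 ms, peak
#' included), with time zeroed at the peak: the intercept is the fitted
#' match value at the peak (evidence at commitment) and the slope the
#' build-up rate per second. Trials with fewer than 3 in-window samples
#' are dropped.
#'
#' @param mseries A `match_series` with `peak_times`, or list of vectors.
#' @param peak_times Per-trial peak samples (defaults to those stored).
#' @param window_ms Regression window before the peak, ms (default 250).
#' @param sfreq Sampling rate (defaults to the stored one).
#' @return Data frame with one row per trial: `trial`, `intercept`
#'   (match units at peak), `slope` (match units per second),
#'   `n_samples`, `truncated` (window clipped at trial start),
#'   `dropped`.
#' @export
buildup_regression <- function(mseries, peak_times = NULL,
                               window_ms = 250, sfreq = NULL) {
  series <- if (inherits(mseries, "match_series")) mseries$series else mseries
  if (is.null(peak_times)) peak_times <- mseries$peak_times
  if (is.null(sfreq)) sfreq <- mseries$sfreq
  stopifnot(!is.null(peak_times), !is.null(sfreq))
  w <- round(window_ms / 1000 * sfreq)
  out <- lapply(seq_along(series), function(i) {
    pk <- peak_times[i]
    lo <- pk - w
    truncated <- lo < 1
    lo <- max(lo, 1)
    if (pk > length(series[[i]])) pk <- length(series[[i]])
    idx <- lo:pk
    if (length(idx) < 3) {
      return(data.frame(trial = i, intercept = NA_real_, slope = NA_real_,
                        n_samples = length(idx), truncated = truncated,
                        dropped = TRUE))
    }
    tsec <- (idx - peak_times[i]) / sfreq
    fit <- stats::lm.fit(cbind(1, tsec), series[[i]][idx])
    data.frame(trial = i, intercept = fit$coefficients[1],
               slope = fit$coefficients[2], n_samples = length(idx),
               truncated = truncated, dropped = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of build-up statistics with accuracy
#'
#' Rank correlation between contrast-bin-averaged build-up statistics
#' (intercepts or slopes) and the per-bin proportion of correct
#' responses. Ties are handled by average ranks.
#'
#' @param stat Per-bin averaged statistic (length >= 4).
#' @param accuracy Per-bin proportion correct, same length.
#' @return List with `rho` and `p`.
#' @export
accuracy_correlation <- function(stat, accuracy) {
  stopifnot(length(stat) == length(accuracy))
  if (length(stat) < 4) stop("need at least 4 contrast bins")
  ct <- suppressWarnings(
    stats::cor.test(stat, accuracy, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}
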