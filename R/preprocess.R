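#' Reject artifact and outlier trials
#'
#' Applies the three rejection rules used throughout the analyses: RT
#' faster than `rt_min_ms`, RT slower than `rt_max_ms`, or any channel
#' exceeding `volt_max_uV` (in absolute value) between stimulus and
#' response.
#'
#' @param x An `epoched_dataset`.
#' @param rt_min_ms,rt_max_ms RT bounds, ms (defaults 100 and 3000).
#' @param volt_max_uV Voltage threshold, microvolts (default 100).
#' @return The filtered `epoched_dataset`, with attribute `rejection`
#'   (a list with counts per criterion and the surviving fraction).
#' @export
reject_trials <- function(x, rt_min_ms = 100, rt_max_ms = 3000,
                          volt_max_uV = 100) {
  n <- n_trials(x)
  fast <- x$rt < rt_min_ms
  slow <- x$rt > rt_max_ms
  volt <- vapply(seq_len(n), function(i) {
    v <- x$data[i, , seq_len(x$n_samples[i]), drop = FALSE]
    any(abs(v) > volt_max_uV, na.rm = TRUE)
  }, logical(1))
  keep <- !(fast | slow | volt)
  if (!any(keep)) stop("all trials rejected")
  out <- subset_trials(x, keep)
  attr(out, "rejection") <- list(
    n_total = n, n_rejected = sum(!keep),
    rt_fast = sum(fast), rt_slow = sum(slow), voltage = sum(volt),
    fraction_rejected = mean(!keep)
  )
  out
}

#' Extend the analysis window beyond the response
#'
#' Adds a fixed offset to every trial's RT-defined analysis window so
#' that events peaking near the response are not clipped by the
#' cross-correlation edge mask.
#'
#' @param x An `epoched_dataset`.
#' @param offset_ms Window extension, ms (default 10; must be >= 0).
#' @return The dataset with `n_samples` extended (never beyond the
#'   recorded epoch length); `rt` itself is unchanged.
#' @export
offset_rts <- function(x, offset_ms = 10) {
  if (offset_ms < 0) stop("offset_ms must be >= 0")
  if (offset_ms == 0) return(x)
  max_s <- dim(x$data)[3]
  new_n <- pmin(round((x$rt + offset_ms) / 1000 * x$sfreq), max_s)
  # only extend into samples that were actually recorded
  avail <- apply(!is.na(x$data[, 1, , drop = FALSE]), 1, sum)
  x$n_samples <- as.integer(pmin(pmax(new_n, x$n_samples), avail))
  attr(x, "rt_offset_ms") <- offset_ms
  x
}

#' Project epochs onto principal components and z-score
#'
#' Eigendecomposition of the participant-averaged channel variance-
#' covariance matrix (each participant's covariance pooled over all
#' trials and in-window samples). The smallest number of components
#' whose cumulative eigenvalues reach `var_target` of the total variance
#' is retained; null eigenvalues are dropped. Component scores are then
#' z-scored per participant using the mean and standard deviation pooled
#' over all of that participant's trials, samples, and components.
#'
#' @param x An `epoched_dataset`.
#' @param var_target Fraction of variance to retain (default 0.999).
#' @return Object of class `pc_dataset`: list with `scores` (per-trial
#'   list of samples x components matrices), `loadings` (channels x
#'   components), `var_explained`, `zscale` (per-participant mean/sd),
#'   `n_samples`, `sfreq`, `behavior`, `rt`.
#' @export
principal_components <- function(x, var_target = 0.999) {
  stopifnot(dim(x$data)[2] >= 2, var_target > 0, var_target <= 1)
  parts <- unique(x$behavior$participant)
  covs <- lapply(parts, function(p) {
    idx <- which(x$behavior$participant == p)
    mats <- lapply(idx, function(i) {
      t(x$data[i, , seq_len(x$n_samples[i])])
    })
    stats::cov(do.call(rbind, mats))
  })
  avg_cov <- Reduce(`+`, covs) / length(covs)
  eig <- eigen(avg_cov, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12
  values <- eig$values[pos]
  cumvar <- cumsum(values) / sum(values)
  k <- which(cumvar >= var_target)[1]
  if (is.na(k)) k <- length(values)
  loadings <- eig$vectors[, seq_len(k), drop = FALSE]
  scores <- lapply(seq_len(n_trials(x)), function(i) {
    t(x$data[i, , seq_len(x$n_samples[i])]) %*% loadings
  })
  zscale <- list()
  for (p in parts) {
    idx <- which(x$behavior$participant == p)
    all_vals <- unlist(scores[idx])
    mu <- mean(all_vals)
    sd_ <- stats::sd(all_vals)
    for (i in idx) scores[[i]] <- (scores[[i]] - mu) / sd_
    zscale[[p]] <- c(mean = mu, sd = sd_)
  }
  structure(list(
    scores = scores, loadings = loadings,
    var_explained = cumvar[seq_len(k)],
    zscale = zscale,
    n_samples = x$n_samples, sfreq = x$sfreq,
    behavior = x$behavior, rt = x$rt,
    channel_names = x$channel_names
  ), class = "pc_dataset")
}

#' @export
print.pc_dataset <- function(x, ...) {
  cat(sprintf(
    "<pc_dataset> %d trials, %d components (%.3f%% variance), z-scored per participant\n",
    length(x$scores), ncol(x$loadings),
    100 * x$var_explained[length(x$var_explained)]
  ))
  invisible(x)
}

#' Cross-correlate component scores with the event template
#'
#' Matched filtering: for every trial, component, and sample t, computes
#' the peak-centered dot product of the template with the surrounding
#' score samples, `x[t] = sum_j w[j] * score[t + j - hw]`. The first and
#' last `hw = floor(L/2)` samples, where zero padding would leak into the
#' window, are masked invalid; event peaks are never placed there.
#'
#' @param pcdata A `pc_dataset`.
#' @param template An `event_template` (its `sfreq` must match).
#' @return Object of class `match_data`: list with `x` (per-trial
#'   samples x components matrices of match scores), `valid` (per-trial
#'   logical vectors), the template, and metadata carried over.
#' @export
pattern_crosscorrelation <- function(pcdata, template) {
  stopifnot(inherits(template, "event_template"),
            template$sfreq == pcdata$sfreq)
  w <- template$weights
  L <- length(w)
  hw <- floor(L / 2)
  xs <- vector("list", length(pcdata$scores))
  valid <- vector("list", length(pcdata$scores))
  for (i in seq_along(pcdata$scores)) {
    s <- pcdata$scores[[i]]
    T_i <- nrow(s)
    if (T_i < L) stop("trial ", i, " shorter than the template")
    pad <- rbind(matrix(0, hw, ncol(s)), s, matrix(0, L - hw - 1, ncol(s)))
    out <- matrix(0, T_i, ncol(s))
    for (j in seq_len(L)) {
      out <- out + w[j] * pad[j:(j + T_i - 1), , drop = FALSE]
    }
    v <- rep(TRUE, T_i)
    v[seq_len(hw)] <- FALSE
    v[(T_i - hw + 1):T_i] <- FALSE
    xs[[i]] <- out
    valid[[i]] <- v
  }
  structure(list(
    x = xs, valid = valid, template = template,
    n_samples = pcdata$n_samples, sfreq = pcdata$sfreq,
    behavior = pcdata$behavior, rt = pcdata$rt,
    loadings = pcdata$loadings, zscale = pcdata$zscale,
    channel_names = pcdata$channel_names
  ), class = "match_data")
}
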