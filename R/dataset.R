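#' Epoched multichannel dataset
#'
#' Container for stimulus-locked epochs truncated at the response:
#' a trials x channels x samples array (samples beyond each trial's RT
#' are `NA`), the sampling rate, per-trial RT, and a behavior table.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param sfreq Sampling frequency, Hz.
#' @param rt Per-trial response time, ms.
#' @param behavior Data frame with at least `participant`, `contrast`,
#'   `sat`, `correct`.
#' @param channel_names Character vector, one name per channel.
#' @return Object of class `epoched_dataset`.
#' @export
epoched_dataset <- function(data, sfreq, rt, behavior, channel_names) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(rt),
            dim(data)[1] == nrow(behavior),
            dim(data)[2] == length(channel_names))
  n_samples <- pmin(pmax(round(rt / 1000 * sfreq), 1L), dim(data)[3])
  structure(list(
    data = data, sfreq = sfreq, rt = rt,
    n_samples = as.integer(n_samples),
    behavior = behavior, channel_names = channel_names
  ), class = "epoched_dataset")
}

#' @export
print.epoched_dataset <- function(x, ...) {
  cat(sprintf(
    "<epoched_dataset> %d trials x %d channels @ %g Hz, RT %d-%d ms, %d participant(s)\n",
    dim(x$data)[1], dim(x$data)[2], x$sfreq,
    round(min(x$rt)), round(max(x$rt)),
    length(unique(x$behavior$participant))
  ))
  invisible(x)
}

#' Number of trials in an epoched dataset
#' @param x An `epoched_dataset`.
#' @export
n_trials <- function(x) dim(x$data)[1]

subset_trials <- function(x, keep) {
  x$data <- x$data[keep, , , drop = FALSE]
  x$rt <- x$rt[keep]
  x$n_samples <- x$n_samples[keep]
  x$behavior <- x$behavior[keep, , drop = FALSE]
  rownames(x$behavior) <- NULL
  x
}

#' Save / load an epoched dataset
#'
#' The epoch array is stored as an RDS file; the behavior table is also
#' written alongside as a plain CSV (same basename, `.csv` extension)
#' for inspection with external tools.
#'
#' @param x An `epoched_dataset`.
#' @param path File path (`.rds`).
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns
#'   the `epoched_dataset`.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoched_dataset"))
  saveRDS(x, path)
  utils::write.csv(x$behavior, sub("\\.rds$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @param path File path written by [write_epochs()].
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "epoched_dataset"))
  x
}

#' Serialize an event model to JSON
#'
#' @param model An `event_model` from [em_fit()] or [cumulative_fit()].
#' @param path Output JSON path.
#' @export
write_event_model <- function(model, path) {
  stopifnot(inherits(model, "event_model"))
  out <- model[c("n_events", "magnitudes", "gamma_shape", "gamma_scales",
                 "width_ms", "sfreq", "loglik")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_event_model
#' @export
read_event_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    n_events = as.integer(raw$n_events),
    magnitudes = matrix(unlist(raw$magnitudes), nrow = raw$n_events,
                        byrow = FALSE),
    gamma_shape = raw$gamma_shape,
    gamma_scales = as.numeric(raw$gamma_scales),
    width_ms = raw$width_ms, sfreq = raw$sfreq,
    loglik = raw$loglik
  ), class = "event_model")
}
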