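#' Discretized half-sine event template
#'
#' The trial-recurrent multivariate events are modeled as short half-sine
#' deflections. The template discretizes a half-sine of `width_ms`
#' milliseconds at `sfreq` Hz: the k-th of n samples is proportional to
#' `sin(pi * (k + 0.5) / n)` (k = 0..n-1) and the weights are normalized
#' to unit sum of squares.
#'
#' @param width_ms Template width in milliseconds (default 25).
#' @param sfreq Sampling frequency in Hz.
#' @return Object of class `event_template`: list with `width_ms`,
#'   `sfreq`, and `weights` (length `round(width_ms * sfreq / 1000)`).
#' @examples
#' tpl <- halfsine_template(25, 200) # 5 samples
#' sum(tpl$weights^2)                # 1
#' @export
halfsine_template <- function(width_ms = 25, sfreq = 200) {
  n <- round(width_ms * sfreq / 1000)
  if (n < 2) {
    stop("sampling rate too coarse: template must span at least 2 samples")
  }
  w <- sin(pi * (seq_len(n) - 0.5) / n)
  structure(
    list(width_ms = width_ms, sfreq = sfreq, weights = w / sqrt(sum(w^2))),
    class = "event_template"
  )
}

#' Ramp event template
#'
#' A linear rise from zero ending at its last sample, as expected for a
#' signal built up by evidence accumulation; used as an alternative event
#' shape in the synthetic generator. Unit sum of squares.
#'
#' @inheritParams halfsine_template
#' @return Object of class `event_template` with attribute `shape = "ramp"`.
#' @export
ramp_template <- function(width_ms = 25, sfreq = 200) {
  n <- round(width_ms * sfreq / 1000)
  if (n < 2) {
    stop("sampling rate too coarse: template must span at least 2 samples")
  }
  w <- seq_len(n) / n
  out <- structure(
    list(width_ms = width_ms, sfreq = sfreq, weights = w / sqrt(sum(w^2))),
    class = "event_template"
  )
  attr(out, "shape") <- "ramp"
  out
}
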