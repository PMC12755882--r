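#' Stage-law constructors
#'
#' A stage law describes how the mean duration of one processing stage
#' (stimulus to first event, event to event, last event to response)
#' depends on the trial's stimulus contrast. Three generative laws are
#' available: a contrast-independent constant, Pieron's power law
#' (early, perceptual stages: duration decreases with contrast), and the
#' Fechner proportional-rate diffusion (late, decision stages: duration
#' increases with contrast because the log-ratio evidence shrinks).
#'
#' @param mean_ms Constant stage mean, ms.
#' @param alpha,beta,nu Pieron intercept (ms), slope (ms) and exponent.
#' @param A,t0 Diffusion decision criterion (evidence units) and residual
#'   time (ms); `beta` is the Fechner sensitivity.
#' @return A `stage_law` list usable in [simulate_behavior()].
#' @name stage_laws
NULL

#' @rdname stage_laws
#' @export
stage_constant <- function(mean_ms) {
  stopifnot(mean_ms > 0)
  structure(list(law = "constant", mean_ms = mean_ms), class = "stage_law")
}

#' @rdname stage_laws
#' @export
stage_pieron <- function(alpha, beta, nu) {
  stopifnot(alpha >= 0, beta >= 0, nu >= 0)
  structure(list(law = "pieron", alpha = alpha, beta = beta, nu = nu),
            class = "stage_law")
}

#' @rdname stage_laws
#' @export
stage_fechner <- function(beta, A, t0 = 0) {
  stopifnot(beta > 0, A > 0, t0 >= 0)
  structure(list(law = "fechner", beta = beta, A = A, t0 = t0),
            class = "stage_law")
}

#' Mean duration of a stage at a given contrast
#'
#' @param law A `stage_law`.
#' @param contrast Contrast value(s) in (0, 1].
#' @param delta Physical contrast difference (Fechner law only).
#' @return Mean duration(s), ms. Errors if the mean is not finite and
#'   positive (e.g., contrast at or below `delta/2` under Fechner).
#' @export
stage_mean <- function(law, contrast, delta = 0.05) {
  m <- switch(law$law,
    constant = rep(law$mean_ms, length(contrast)),
    pieron = pieron_mean(contrast, law),
    fechner = fechner_rt(contrast, delta, law),
    stop("unknown stage law: ", law$law)
  )
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("stage mean not finite and positive at the requested contrast")
  }
  m
}

#' Default generative stage structure (5 events, 6 stages)
#'
#' Mirrors the sequence identified in visual decision making: a constant
#' early visual stage, two Pieron (perceptual encoding) stages, two
#' Fechner-diffusion (decision) stages, and a constant motor tail. The
#' first Fechner stage carries the `decision` attribute: its diffusion
#' parameters generate response correctness.
#'
#' @return List of six `stage_law` objects.
#' @export
default_stage_laws <- function() {
  laws <- list(
    stage_constant(70),                 # stimulus -> Ev1 (early visual)
    stage_pieron(35, 25, 0.5),          # Ev1 -> Ev2 (encoding)
    stage_pieron(45, 30, 0.5),          # Ev2 -> Ev3 (encoding)
    stage_fechner(8, 1.5, t0 = 60),     # Ev3 -> Ev4 (decision)
    stage_fechner(15, 0.8, t0 = 35),    # Ev4 -> Ev5 (decision tail)
    stage_constant(55)                  # Ev5 -> response (motor)
  )
  attr(laws, "decision_stage") <- 4L
  laws
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults describe
#' the reference condition used throughout the package: 32 channels at
#' 200 Hz, five 25 ms half-sine events with gamma(shape 2) stage
#' durations, contrast uniform on [0.035, 0.955] with a fixed total side
#' difference of 0.05, and AR(1) Gaussian channel noise.
#'
#' @param n_participants,n_trials Number of participants / trials each.
#' @param n_channels Number of channels (default 32, standard montage).
#' @param sfreq Sampling rate, Hz (default 200; the 25 ms template must
#'   span at least 2 samples).
#' @param stage_laws List of `stage_law` objects, one per stage
#'   (N events imply N + 1 stages).
#' @param gamma_shape Shape of the gamma stage-duration distribution
#'   (default 2; scale is mean / shape).
#' @param delta Total physical contrast difference between sides.
#' @param event_shape `"halfsine"` or `"ramp"` (ramp ends at the peak).
#' @param width_ms Event template width, ms.
#' @param topographies Channels x events matrix of unit-norm spatial
#'   patterns; `NULL` draws smooth deterministic defaults (the 4th event
#'   gets an added lateralized component).
#' @param amplitudes Per-event amplitudes, uV.
#' @param noise_sd Marginal standard deviation of the AR(1) channel
#'   noise, uV.
#' @param noise_ar1 AR(1) coefficient in [0, 1).
#' @param sat_A_factor Multiplier applied to the diffusion criterion `A`
#'   under speed instructions (speed lowers the decision boundary,
#'   shortening decision stages and lowering accuracy).
#' @param sat_mean_factor Multiplier applied to all non-diffusion stage
#'   means except the first under speed instructions.
#' @param seed Integer seed; the full dataset is a deterministic
#'   function of the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 5, n_trials = 100,
                       n_channels = 32, sfreq = 200,
                       stage_laws = default_stage_laws(),
                       gamma_shape = 2, delta = 0.05,
                       event_shape = c("halfsine", "ramp"),
                       width_ms = 25,
                       topographies = NULL,
                       amplitudes = NULL,
                       noise_sd = 2.5, noise_ar1 = 0.9,
                       sat_A_factor = 0.8, sat_mean_factor = 0.9,
                       seed = 1L) {
  event_shape <- match.arg(event_shape)
  n_events <- length(stage_laws) - 1L
  stopifnot(n_events >= 1, gamma_shape > 0, delta > 0,
            noise_ar1 >= 0, noise_ar1 < 1, noise_sd >= 0)
  if (round(width_ms * sfreq / 1000) < 2) {
    stop("sfreq too low for the template width")
  }
  if (is.null(topographies)) {
    topographies <- default_topographies(n_channels, n_events)
  }
  stopifnot(nrow(topographies) == n_channels,
            ncol(topographies) == n_events)
  nrm <- sqrt(colSums(topographies^2))
  if (any(abs(nrm - 1) > 1e-8)) {
    topographies <- sweep(topographies, 2, nrm, "/")
  }
  if (is.null(amplitudes)) amplitudes <- rep(20, n_events)
  stopifnot(length(amplitudes) == n_events, all(amplitudes > 0))
  structure(list(
    n_participants = n_participants, n_trials = n_trials,
    n_channels = n_channels, sfreq = sfreq,
    stage_laws = stage_laws, n_events = n_events,
    gamma_shape = gamma_shape, delta = delta,
    event_shape = event_shape, width_ms = width_ms,
    topographies = topographies, amplitudes = amplitudes,
    noise_sd = noise_sd, noise_ar1 = noise_ar1,
    sat_A_factor = sat_A_factor, sat_mean_factor = sat_mean_factor,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Standard 32-channel montage and lateral pairing
#'
#' Channel names of the standard 32-electrode 10-20 montage used by the
#' generator, with 14 left/right lateral pairs and 4 midline channels.
#'
#' @return `montage_32()`: character vector of 32 channel names.
#' @export
montage_32 <- function() {
  c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3", "CP1", "CP5",
    "P7", "P3", "Pz", "PO3", "O1", "Oz", "O2", "PO4", "P4", "P8",
    "CP6", "CP2", "C4", "T8", "FC6", "FC2", "F4", "F8", "AF4", "Fp2",
    "Fz", "Cz")
}

#' @rdname montage_32
#' @return `montage_pairs()`: data frame with columns `left` and `right`,
#'   one row per lateral electrode pair (14 rows for the default montage).
#' @export
montage_pairs <- function() {
  data.frame(
    left  = c("Fp1", "AF3", "F7", "F3", "FC5", "FC1", "T7", "C3",
              "CP5", "CP1", "P7", "P3", "PO3", "O1"),
    right = c("Fp2", "AF4", "F8", "F4", "FC6", "FC2", "T8", "C4",
              "CP6", "CP2", "P8", "P4", "PO4", "O2"),
    stringsAsFactors = FALSE
  )
}

#' Default event topographies
#'
#' Deterministic smooth unit-norm spatial patterns, one per event,
#' mutually distinct (low pairwise correlation). The 4th event (when
#' present) receives an added lateralized component over the central
#' channel pair, emulating a motor readiness potential, so that the
#' asymmetry statistics have signal to detect.
#'
#' @param n_channels Number of channels.
#' @param n_events Number of events.
#' @param lateralized_event Index of the event given the lateralized
#'   component (`NA` for none); default 4 when `n_events >= 4`.
#' @return Channels x events matrix with unit-norm columns.
#' @export
default_topographies <- function(n_channels, n_events,
                                 lateralized_event = if (n_events >= 4) 4L else NA) {
  ch <- seq_len(n_channels)
  topo <- vapply(seq_len(n_events), function(e) {
    # smooth sinusoidal profiles with event-specific spatial frequency/phase
    v <- sin(2 * pi * (e * 0.7 + 0.3) * ch / n_channels + e) +
      0.5 * cos(2 * pi * (e * 0.3 + 1.1) * ch / n_channels - 2 * e)
    v / sqrt(sum(v^2))
  }, numeric(n_channels))
  if (!is.na(lateralized_event) && n_channels == 32) {
    pairs <- montage_pairs()
    names32 <- montage_32()
    lat <- numeric(n_channels)
    central <- match(c("C3", "C4"), names32)
    lat[central] <- c(1, -1)
    v <- topo[, lateralized_event] + 0.8 * lat / sqrt(sum(lat^2))
    topo[, lateralized_event] <- v / sqrt(sum(v^2))
  }
  topo
}

#' Sample stimulus specifications
#'
#' Contrast means are uniform on [0.035, 0.955]; the correct side is
#' equiprobable left/right and carries `+delta/2` contrast while the
#' incorrect side carries `-delta/2`.
#'
#' @param n Number of stimuli.
#' @param delta Total contrast difference, in (0, 0.07).
#' @return Data frame with `contrast` and `correct_side`.
#' @export
sample_stimulus <- function(n, delta = 0.05) {
  if (delta <= 0 || delta >= 0.07) stop("delta must lie in (0, 0.07)")
  data.frame(
    contrast = runif(n, 0.035, 0.955),
    correct_side = sample(c("left", "right"), n, replace = TRUE)
  )
}

apply_sat <- function(stage_laws, config) {
  # speed instructions: lower decision boundary, mildly compress the
  # remaining stages; the first (stimulus -> Ev1) stage is unaffected
  lapply(seq_along(stage_laws), function(i) {
    law <- stage_laws[[i]]
    if (i == 1) return(law)
    if (law$law == "fechner") {
      law$A <- law$A * config$sat_A_factor
      law$t0 <- law$t0 * config$sat_mean_factor
    } else if (law$law == "constant") {
      law$mean_ms <- law$mean_ms * config$sat_mean_factor
    } else if (law$law == "pieron") {
      law$alpha <- law$alpha * config$sat_mean_factor
      law$beta <- law$beta * config$sat_mean_factor
    }
    law
  })
}

#' Simulate behavioral trials from stage laws
#'
#' Each stage duration is drawn from a gamma distribution with the given
#' shape and scale = (stage mean at the trial's contrast) / shape, so the
#' stage mean follows its generative law exactly. RT is the sum of all
#' stage durations. Correctness is Bernoulli with probability given by
#' the accuracy equation of the proportional-rate diffusion model,
#' evaluated with the decision stage's parameters (trials without a
#' diffusion stage get probability 0.75).
#'
#' @param stimuli Data frame from [sample_stimulus()] (columns `contrast`,
#'   `correct_side`), one row per trial.
#' @param stage_laws List of `stage_law` objects (N + 1 for N events).
#' @param gamma_shape Gamma shape parameter, default 2.
#' @param delta Total contrast difference.
#' @param sat Character vector (recycled): `"speed"` or `"accuracy"`.
#' @param config Optional `sim_config` supplying the SAT multipliers.
#' @return Data frame of class `behavioral_trials` with one row per trial:
#'   `contrast`, `correct_side`, `sat`, per-stage durations
#'   `stage_1 ... stage_{N+1}` (ms), `rt` (ms), `correct`, and an
#'   attribute `p_correct` with the generating correctness probability.
#' @export
simulate_behavior <- function(stimuli, stage_laws, gamma_shape = 2,
                              delta = 0.05, sat = "accuracy",
                              config = NULL) {
  n <- nrow(stimuli)
  sat <- rep_len(sat, n)
  n_stage <- length(stage_laws)
  decision_stage <- attr(stage_laws, "decision_stage")
  if (is.null(decision_stage)) {
    decision_stage <- which(vapply(stage_laws, function(l) l$law == "fechner",
                                   logical(1)))[1]
  }
  dur <- matrix(NA_real_, n, n_stage)
  p_correct <- rep(0.75, n)
  for (cond in unique(sat)) {
    idx <- which(sat == cond)
    laws <- stage_laws
    if (cond == "speed") {
      if (is.null(config)) config <- sim_config()
      laws <- apply_sat(stage_laws, config)
    }
    for (s in seq_len(n_stage)) {
      m <- stage_mean(laws[[s]], stimuli$contrast[idx], delta)
      dur[idx, s] <- rgamma(length(idx), shape = gamma_shape,
                            scale = m / gamma_shape)
    }
    if (!is.na(decision_stage)) {
      p_correct[idx] <- fechner_pc(stimuli$contrast[idx], delta,
                                   laws[[decision_stage]])
    }
  }
  colnames(dur) <- paste0("stage_", seq_len(n_stage))
  out <- data.frame(stimuli, sat = sat, dur,
                    rt = rowSums(dur),
                    correct = runif(n) < p_correct,
                    p_correct = p_correct)
  attr(out, "delta") <- delta
  class(out) <- c("behavioral_trials", class(out))
  out
}

ar1_noise <- function(n_channels, n_samples, sd, phi) {
  if (sd == 0) return(matrix(0, n_channels, n_samples))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- matrix(rnorm(n_channels * n_samples, sd = innov_sd),
              n_channels, n_samples)
  if (phi > 0) {
    e[, 1] <- rnorm(n_channels, sd = sd) # stationary start
    for (t in 2:n_samples) e[, t] <- phi * e[, t - 1] + e[, t]
  }
  e
}

#' Render multichannel epochs from behavioral trials
#'
#' Builds the channel x time signal of each trial as the sum of
#' amplitude-scaled topography-weighted event templates centered (half-
#' sine) or ending (ramp) at the trial's true event peaks, plus AR(1)
#' Gaussian channel noise. Trials whose stage durations do not leave
#' room for the template (any stage shorter than the template width) are
#' rejected by the caller; here they raise an error.
#'
#' @param trials `behavioral_trials` data frame.
#' @param config A `sim_config`.
#' @return List with `epochs` (an `epoched_dataset`) and `truth` (a
#'   `ground_truth` list: per-trial true peak samples, stage durations,
#'   topographies, amplitudes, stage laws, correctness probabilities).
#' @export
render_epochs <- function(trials, config) {
  n_events <- config$n_events
  sfreq <- config$sfreq
  tpl <- if (config$event_shape == "halfsine") {
    halfsine_template(config$width_ms, sfreq)
  } else {
    ramp_template(config$width_ms, sfreq)
  }
  L <- length(tpl$weights)
  hw <- floor(L / 2)
  dur_cols <- grep("^stage_", names(trials))
  dur <- as.matrix(trials[, dur_cols])
  n <- nrow(trials)
  n_samples <- pmax(round(trials$rt / 1000 * sfreq), 1L)
  peak_ms <- t(apply(dur[, seq_len(n_events), drop = FALSE], 1, cumsum))
  if (n_events == 1) peak_ms <- matrix(peak_ms, ncol = 1)
  peak_smp <- round(peak_ms / 1000 * sfreq)
  # template support must fit inside the trial
  bad <- peak_smp[, 1] <= hw | peak_smp[, n_events] > n_samples - hw |
    apply(peak_smp, 1, function(p) any(diff(p) < 1))
  if (any(bad)) {
    stop(sum(bad), " trial(s) cannot host the event template; regenerate")
  }
  max_s <- max(n_samples)
  data <- array(NA_real_, dim = c(n, config$n_channels, max_s))
  offs <- if (config$event_shape == "halfsine") {
    seq_len(L) - hw - 1L       # centered on the peak
  } else {
    seq_len(L) - L             # ramp ends at the peak
  }
  for (i in seq_len(n)) {
    sig <- ar1_noise(config$n_channels, n_samples[i],
                     config$noise_sd, config$noise_ar1)
    for (e in seq_len(n_events)) {
      ts <- peak_smp[i, e] + offs
      keep <- ts >= 1 & ts <= n_samples[i]
      sig[, ts[keep]] <- sig[, ts[keep]] +
        config$amplitudes[e] * config$topographies[, e] %o% tpl$weights[keep]
    }
    data[i, , seq_len(n_samples[i])] <- sig
  }
  behavior <- trials[, c("contrast", "correct_side", "sat", "rt", "correct")]
  if (!is.null(trials$participant)) behavior$participant <- trials$participant
  epochs <- epoched_dataset(
    data = data, sfreq = sfreq, rt = trials$rt,
    behavior = behavior,
    channel_names = if (config$n_channels == 32) montage_32() else
      paste0("ch", seq_len(config$n_channels))
  )
  truth <- structure(list(
    peak_samples = peak_smp, peak_ms = peak_ms,
    stage_durations_ms = dur,
    topographies = config$topographies,
    amplitudes = config$amplitudes,
    stage_laws = config$stage_laws,
    gamma_shape = config$gamma_shape,
    p_correct = trials$p_correct,
    template_shape = config$event_shape
  ), class = "ground_truth")
  list(epochs = epochs, truth = truth)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Draws stimuli, behavior, and epochs for all participants. Trials in
#' which any stage is too short to host the event template are
#' regenerated (bounded retries) so that all events are separable, the
#' implicit assumption of the sequential-event model.
#'
#' @param config A `sim_config`.
#' @param max_retries Per-trial regeneration budget.
#' @return List with `epochs` (`epoched_dataset`) and `truth`
#'   (`ground_truth`).
#' @export
generate_dataset <- function(config = sim_config(), max_retries = 200) {
  set.seed(config$seed)
  width <- config$width_ms
  sfreq <- config$sfreq
  L <- round(width * sfreq / 1000)
  hw <- floor(L / 2)
  all_trials <- NULL
  for (p in seq_len(config$n_participants)) {
    got <- 0
    acc <- NULL
    tries <- 0
    while (got < config$n_trials) {
      tries <- tries + 1
      if (tries > max_retries) {
        stop("trial regeneration budget exhausted; stage means too close ",
             "to the template width")
      }
      need <- config$n_trials - got
      stim <- sample_stimulus(need, config$delta)
      sat <- sample(c("speed", "accuracy"), need, replace = TRUE)
      beh <- simulate_behavior(stim, config$stage_laws, config$gamma_shape,
                               config$delta, sat, config)
      dur <- as.matrix(beh[, grep("^stage_", names(beh))])
      # every stage must exceed the template width, and the first/last
      # peaks must keep half a template clear of the window edges
      ok <- apply(dur, 1, min) >= width &
        round(dur[, 1] / 1000 * sfreq) > hw &
        round(beh$rt / 1000 * sfreq) - round((beh$rt - dur[, ncol(dur)]) /
                                             1000 * sfreq) > hw
      keep <- beh[ok, , drop = FALSE]
      acc <- if (is.null(acc)) keep else rbind(acc, keep)
      got <- nrow(acc)
    }
    acc <- acc[seq_len(config$n_trials), , drop = FALSE]
    acc$participant <- sprintf("P%02d", p)
    all_trials <- if (is.null(all_trials)) acc else rbind(all_trials, acc)
  }
  attr(all_trials, "delta") <- config$delta
  render_epochs(all_trials, config)
}
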