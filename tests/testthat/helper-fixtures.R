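# small fixtures built in code, shared across test files

# epoched dataset with hand-set data, no noise unless asked
make_toy_epochs <- function(n_trials = 4, n_channels = 3, rt = NULL,
                            sfreq = 200, fill = 0) {
  if (is.null(rt)) rt <- rep(500, n_trials)
  max_s <- max(round(rt / 1000 * sfreq))
  data <- array(fill, dim = c(n_trials, n_channels, max_s))
  for (i in seq_len(n_trials)) {
    ns <- round(rt[i] / 1000 * sfreq)
    if (ns < max_s) data[i, , (ns + 1):max_s] <- NA
  }
  epoched_dataset(
    data = data, sfreq = sfreq, rt = rt,
    behavior = data.frame(
      participant = rep("P01", n_trials),
      contrast = seq(0.1, 0.9, length.out = n_trials),
      sat = "accuracy", correct = TRUE
    ),
    channel_names = paste0("ch", seq_len(n_channels))
  )
}

# a tiny noiseless simulation, handy for identifiability checks
noiseless_config <- function(n_events = 2, n_trials = 20, seed = 42,
                             n_channels = 8) {
  laws <- switch(as.character(n_events),
    "1" = list(stage_constant(150), stage_constant(150)),
    "2" = list(stage_constant(120), stage_constant(160), stage_constant(120)),
    "5" = default_stage_laws(),
    stop("unsupported n_events for fixture")
  )
  sim_config(
    n_participants = 1, n_trials = n_trials, n_channels = n_channels,
    stage_laws = laws, noise_sd = 0, seed = seed,
    topographies = diag(n_channels)[, seq_len(n_events), drop = FALSE],
    amplitudes = rep(10, n_events)
  )
}

# brute-force enumeration of the sequential-event posterior: direct sum
# over all ordered placements t_1 < ... < t_N; the oracle for the
# forward-backward recursion
enumerate_posterior <- function(x, valid, model) {
  T_i <- nrow(x)
  N <- model$n_events
  loc <- if (is.null(model$location)) rep(0, N + 1) else model$location
  P <- sapply(seq_len(N + 1), function(i) {
    chronodecomp:::stage_duration_pmf(model$gamma_shape,
                                      model$gamma_scales[i], T_i, loc[i])
  })
  logf <- x %*% t(model$magnitudes) -
    matrix(rowSums(model$magnitudes^2) / 2, T_i, N, byrow = TRUE)
  logf[!valid, ] <- -Inf
  f <- exp(logf)
  combos <- utils::combn(T_i, N)
  gamma <- matrix(0, T_i, N)
  total <- 0
  for (j in seq_len(ncol(combos))) {
    tt <- combos[, j]
    d <- c(tt[1], diff(tt), T_i - tt[N])
    if (any(d < 1)) next
    w <- prod(P[cbind(d, seq_len(N + 1))]) * prod(f[cbind(tt, seq_len(N))])
    gamma[cbind(tt, seq_len(N))] <- gamma[cbind(tt, seq_len(N))] + w
    total <- total + w
  }
  list(gamma = gamma / total, loglik = log(total))
}
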