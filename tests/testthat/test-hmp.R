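test_that("with flat evidence the 1-event posterior is the prior product", {
  T_i <- 30
  model <- event_model(1, matrix(0, 1, 2), c(5, 7), gamma_shape = 2,
                       sfreq = 200)
  x <- matrix(rnorm(T_i * 2), T_i, 2) # irrelevant: magnitudes are zero
  res <- forward_backward(x, rep(TRUE, T_i), model)
  P0 <- chronodecomp:::stage_duration_pmf(2, 5, T_i)
  P1 <- chronodecomp:::stage_duration_pmf(2, 7, T_i)
  expected <- P0 * c(P1[(T_i - 1):1], 0) # terminal duration T - t
  expected <- expected / sum(expected)
  expect_equal(as.numeric(res$gamma), expected, tolerance = 1e-12)
})

test_that("forward-backward equals brute-force enumeration", {
  set.seed(8)
  cases <- list(
    list(T = 20, N = 2, K = 2, scales = c(3, 4, 3), loc = c(0, 0, 0)),
    list(T = 25, N = 3, K = 3, scales = c(2, 3, 2, 3), loc = c(0, 2, 2, 0)),
    list(T = 18, N = 1, K = 2, scales = c(4, 5), loc = c(0, 0)),
    list(T = 22, N = 2, K = 2, scales = c(4, 3, 4), loc = c(1, 3, 0))
  )
  for (cs in cases) {
    model <- event_model(cs$N, matrix(rnorm(cs$N * cs$K, sd = 0.8),
                                      cs$N, cs$K),
                         cs$scales, gamma_shape = 2, location = cs$loc)
    x <- matrix(rnorm(cs$T * cs$K), cs$T, cs$K)
    valid <- rep(TRUE, cs$T)
    valid[c(1, cs$T)] <- FALSE
    fb <- forward_backward(x, valid, model)
    en <- enumerate_posterior(x, valid, model)
    expect_equal(fb$gamma, en$gamma, tolerance = 1e-10)
    expect_equal(fb$loglik, en$loglik, tolerance = 1e-10)
    # posterior columns are proper distributions
    expect_equal(colSums(fb$gamma), rep(1, cs$N), tolerance = 1e-12)
    # expected event times are strictly ordered
    expect_true(all(diff(fb$expected_times) > 0))
  }
})

test_that("EM increases the log-likelihood and recovers a small model", {
  cfg <- noiseless_config(n_events = 2, n_trials = 25, n_channels = 8)
  cfg$noise_sd <- 0.5
  gen <- generate_dataset(cfg)
  md <- pattern_crosscorrelation(principal_components(gen$epochs),
                                 halfsine_template(25, 200))
  fit <- em_fit(md, 2)
  expect_true(all(diff(fit$trace) > -1e-6 * abs(fit$trace[-1])))
  times <- max_probability_times(fit$posterior)
  # at this SNR the peaks are recovered almost exactly
  for (e in 1:2) {
    expect_gt(cor(times[, e], gen$truth$peak_samples[, e]), 0.95)
    expect_lt(median(abs(times[, e] - gen$truth$peak_samples[, e])), 2)
  }
  expect_length(attr(fit$model, "degenerate_stages"), 0)
})

test_that("cumulative fit finds the true event count on clean data", {
  cfg <- noiseless_config(n_events = 2, n_trials = 25, n_channels = 8)
  cfg$noise_sd <- 0.5
  gen <- generate_dataset(cfg)
  md <- pattern_crosscorrelation(principal_components(gen$epochs),
                                 halfsine_template(25, 200))
  fit <- cumulative_fit(md, max_events = 5)
  expect_equal(fit$model$n_events, 2)
  expect_false(attr(fit$model, "no_reliable_events"))
})

test_that("cumulative fit stays at one weak event on pure noise", {
  set.seed(12)
  n <- 30
  scores <- lapply(seq_len(n), function(i) matrix(rnorm(80 * 3), 80, 3))
  pcs <- list(scores = scores, n_samples = rep(80L, n), sfreq = 200,
              behavior = data.frame(participant = rep("P01", n)),
              rt = rep(400, n), loadings = diag(3),
              zscale = list(P01 = c(mean = 0, sd = 1)),
              channel_names = c("a", "b", "c"))
  class(pcs) <- "pc_dataset"
  md <- pattern_crosscorrelation(pcs, halfsine_template(25, 200))
  fit <- cumulative_fit(md, max_events = 4)
  expect_equal(fit$model$n_events, 1)
  expect_true(attr(fit$model, "no_reliable_events"))
})

test_that("maximum-probability times break ties to the earliest sample", {
  g1 <- matrix(0, 10, 1); g1[4, 1] <- 1          # delta posterior
  g2 <- matrix(1 / 10, 10, 1)                    # uniform: first sample
  post <- structure(list(gamma = list(g1, g2)), class = "event_posterior")
  tm <- max_probability_times(post)
  expect_equal(tm[, 1], c(4L, 1L))
  # matches a brute-force argmax on a random posterior
  set.seed(13)
  g3 <- matrix(runif(30), 10, 3)
  g3 <- sweep(g3, 2, colSums(g3), "/")
  post3 <- structure(list(gamma = list(g3)), class = "event_posterior")
  expect_equal(as.integer(max_probability_times(post3)),
               as.integer(apply(g3, 2, which.max)))
})

test_that("event topographies recover amplitude-scaled patterns", {
  cfg <- noiseless_config(n_events = 2, n_trials = 10, n_channels = 6)
  gen <- generate_dataset(cfg)
  topo <- event_topographies(gen$epochs, gen$truth$peak_samples)
  # noiseless: channel value at the peak is amplitude * topography
  for (e in 1:2) {
    expect_equal(as.numeric(topo[1, , e]),
                 cfg$amplitudes[e] * cfg$topographies[, e] *
                   max(halfsine_template(25, 200)$weights),
                 tolerance = 1e-10)
  }
  # constant data give a constant map
  ep <- make_toy_epochs(3, n_channels = 4, fill = 2)
  tm <- matrix(10, 3, 1)
  topo2 <- event_topographies(ep, tm)
  expect_true(all(topo2 == 2))
  expect_error(event_topographies(ep, matrix(1e4, 3, 1)), "outside")
  # averaging sign-alternating noise shrinks toward zero
  set.seed(14)
  epn <- make_toy_epochs(200, n_channels = 2, rt = rep(500, 200))
  epn$data[] <- rnorm(length(epn$data))
  tpn <- event_topographies(epn, matrix(50, 200, 1))
  expect_lt(max(abs(tpn)), 4 / sqrt(200))
})
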