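test_that("Bonferroni correction matches the montage test count", {
  expect_equal(bonferroni_threshold(14, 5, 0.05), 0.05 / 70)
  expect_equal(signif(bonferroni_threshold(), 2), 0.00071)
  expect_equal(nrow(montage_pairs()), 14)
  # every channel in at most one pair; midline excluded
  pr <- montage_pairs()
  expect_equal(anyDuplicated(c(pr$left, pr$right)), 0)
  expect_false(any(c("Fz", "Cz", "Pz", "Oz") %in% c(pr$left, pr$right)))
})

test_that("asymmetry tests detect lateralized events and only those", {
  set.seed(21)
  n_part <- 20
  topo <- array(rnorm(n_part * 32 * 5, sd = 0.1),
                dim = c(n_part, 32, 5),
                dimnames = list(paste0("P", 1:n_part), montage_32(), NULL))
  # symmetric copy: left = right everywhere
  sym <- topo
  pr <- montage_pairs()
  li <- match(pr$left, montage_32()); ri <- match(pr$right, montage_32())
  sym[, ri, ] <- sym[, li, ]
  res_sym <- asymmetry_tests(sym)
  expect_equal(attr(res_sym, "n_tests"), 70)
  expect_true(all(res_sym$t == 0))
  expect_true(all(res_sym$zero_variance))
  expect_false(any(res_sym$significant))
  # a left-lateralized central component on event 4 only
  lat <- sym
  c3 <- match("C3", montage_32())
  lat[, c3, 4] <- lat[, c3, 4] + 1 + rnorm(n_part, sd = 0.05)
  res <- asymmetry_tests(lat)
  hit <- res[res$significant, ]
  expect_true(all(hit$event == 4))
  expect_true("C3-C4" %in% hit$pair)
  # t and p agree with a reference paired test
  d <- lat[, c3, 4] - lat[, match("C4", montage_32()), 4]
  tt <- t.test(d)
  row <- res[res$pair == "C3-C4" & res$event == 4, ]
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(row$p, tt$p.value, tolerance = 1e-12)
})

test_that("the topography match series is the channel dot product", {
  topo <- c(0.5, -0.5, 0.7)
  ep <- make_toy_epochs(2, n_channels = 3, rt = c(400, 400))
  for (i in 1:2) for (ch in 1:3) ep$data[i, ch, ] <- topo[ch]
  ms <- match_time_series(ep, topo, peak_times = c(40, 50), end_pad_ms = 100)
  expect_equal(unique(ms$series[[1]]), sum(topo^2))
  expect_length(ms$series[[1]], 60) # peak 40 + 100 ms * 200 Hz
  # orthogonal data give a zero series
  ep$data[1, , ] <- c(1, 1, 0)
  ms2 <- match_time_series(ep, c(0.5, -0.5, 0.7), peak_times = c(40, 50))
  expect_true(all(abs(ms2$series[[1]]) < 1e-12))
  # brute-force loop equality on random data
  set.seed(22)
  ep$data[] <- rnorm(length(ep$data))
  ms3 <- match_time_series(ep, topo, peak_times = c(40, 50))
  brute <- sapply(seq_len(60), function(t) sum(topo * ep$data[1, , t]))
  expect_equal(ms3$series[[1]], brute, tolerance = 1e-12)
  # a window reaching past the recorded epoch is truncated and flagged
  ms4 <- match_time_series(ep, topo, peak_times = c(79, 50))
  expect_true(ms4$truncated[1])
  expect_length(ms4$series[[1]], 80)
})

test_that("event-locked averaging undoes latency jitter", {
  tpl <- halfsine_template(25, 200)$weights
  set.seed(23)
  peaks <- sample(20:60, 40, replace = TRUE)
  series <- lapply(peaks, function(p) {
    s <- numeric(80)
    s[p + (-2:2)] <- tpl
    s
  })
  # identical trials: average equals any one trial
  same <- event_locked_average(series[c(1, 1, 1)],
                               peak_times = rep(peaks[1], 3))
  expect_equal(max(same$all$average, na.rm = TRUE), max(tpl))
  # realigned average recovers the template; stimulus-locked average is
  # lower and wider (latency smearing)
  locked <- event_locked_average(series, peak_times = peaks)$all
  at0 <- locked$average[locked$lag == 0]
  expect_equal(at0, max(tpl), tolerance = 1e-12)
  stim_locked <- colMeans(do.call(rbind, series))
  expect_gt(at0, max(stim_locked))
  # single-trial group returns that trial
  g <- event_locked_average(series[1:2], peak_times = peaks[1:2],
                            groups = c("a", "b"))
  expect_equal(max(g$a$average, na.rm = TRUE), max(tpl))
})

test_that("cluster permutation test is exchangeable and detects shifts", {
  set.seed(24)
  A <- matrix(rnorm(20 * 60), 20, 60)
  # identical conditions: no clusters at all
  res0 <- cluster_permutation_test(A, A, n_perm = 128, seed = 1)
  expect_equal(nrow(res0), 0)
  # a 1-SD mean shift over samples 21:40 is detected
  B <- A
  B[, 21:40] <- B[, 21:40] + 1
  res1 <- cluster_permutation_test(B, A, n_perm = 256, seed = 2)
  expect_gt(nrow(res1), 0)
  top <- res1[which.max(abs(res1$mass)), ]
  expect_lt(top$p, 0.05)
  covered <- seq(top$start, top$end)
  expect_gte(length(intersect(covered, 21:40)), 10)
  # p can never undercut 1/n_perm (identity flip included in the null)
  expect_gte(min(res1$p), 1 / 256)
  expect_warning(cluster_permutation_test(B, A, n_perm = 50, seed = 3),
                 "n_perm")
})

test_that("build-up regression reads slope and value at the peak", {
  sfreq <- 200
  # a ramp rising 2 units/s, value 5 at its final sample (the peak)
  n <- 90
  tsec <- (seq_len(n) - n) / sfreq
  ramp <- 5 + 2 * tsec
  bu <- buildup_regression(list(ramp), peak_times = n, window_ms = 250,
                           sfreq = sfreq)
  expect_equal(bu$intercept, 5, tolerance = 1e-10)
  expect_equal(bu$slope, 2, tolerance = 1e-10)
  expect_equal(bu$n_samples, 51) # 250 ms * 200 Hz + the peak sample
  # flat series: zero slope
  bu2 <- buildup_regression(list(rep(3, 90)), peak_times = 80,
                            window_ms = 250, sfreq = sfreq)
  expect_equal(bu2$slope, 0, tolerance = 1e-12)
  expect_equal(bu2$intercept, 3, tolerance = 1e-12)
  # equivariance: adding a constant shifts intercepts, not slopes
  bu3 <- buildup_regression(list(ramp + 10), peak_times = n,
                            window_ms = 250, sfreq = sfreq)
  expect_equal(bu3$intercept, bu$intercept + 10, tolerance = 1e-10)
  expect_equal(bu3$slope, bu$slope, tolerance = 1e-10)
  # too-short windows are dropped, truncation flagged
  bu4 <- buildup_regression(list(c(1, 2)), peak_times = 2,
                            window_ms = 250, sfreq = sfreq)
  expect_true(bu4$dropped)
  expect_true(bu4$truncated)
})

test_that("Spearman correlation with accuracy handles monotone and ties", {
  expect_equal(accuracy_correlation(1:10, seq(0.5, 0.95, length.out = 10))$rho, 1)
  expect_equal(accuracy_correlation(10:1, seq(0.5, 0.95, length.out = 10))$rho, -1)
  expect_error(accuracy_correlation(1:3, c(0.5, 0.6, 0.7)), "4")
  # ties are averaged, not an error
  out <- accuracy_correlation(c(1, 2, 2, 3, 4), c(0.5, 0.6, 0.6, 0.7, 0.8))
  expect_gt(out$rho, 0.9)
})
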