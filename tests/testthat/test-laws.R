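test_that("Pieron and linear closed forms evaluate correctly", {
  # 1^-nu = 1 so C = 1 gives alpha + beta
  expect_equal(pieron_mean(1, list(alpha = 300, beta = 50, nu = 0.7)), 350)
  # nu = 0 flattens the law
  expect_equal(pieron_mean(c(0.1, 0.5, 0.9), list(alpha = 10, beta = 5, nu = 0)),
               rep(15, 3))
  # alpha + beta / sqrt(C)
  expect_equal(pieron_mean(0.25, list(alpha = 100, beta = 50, nu = 0.5)), 200)
  expect_equal(pieron_mean(0.035, list(alpha = 300, beta = 50, nu = 0.5)),
               300 + 50 / sqrt(0.035), tolerance = 1e-12)
  expect_error(pieron_mean(0, list(alpha = 1, beta = 1, nu = 1)))
  expect_error(pieron_mean(0.5, list(alpha = 1, beta = 1, nu = -1)), "nu")

  expect_equal(linear_mean(0, list(alpha = 120, beta = 40)), 120)
  expect_equal(linear_mean(0.5, list(alpha = 120, beta = 0)), 120)
  # matches a least-squares line fitted on noiseless linear data
  C <- seq(0.1, 0.9, by = 0.1)
  y <- 200 + 80 * C
  ls <- stats::lm(y ~ C)
  expect_equal(linear_mean(C, list(alpha = coef(ls)[1], beta = coef(ls)[2])),
               y, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("Fechner perceived difference follows the log-intensity ratio", {
  expect_equal(fechner_p(0.5, 0.05, beta = 1), log(0.525 / 0.475),
               tolerance = 1e-12)
  expect_equal(fechner_p(0.5, 0.05, beta = 3), 3 * log(0.525 / 0.475))
  # strictly decreasing in contrast: a fixed physical difference is
  # perceived as smaller on brighter backgrounds
  C <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(fechner_p(C, 0.05)) < 0))
  expect_error(fechner_p(0.025, 0.05), "delta")
  expect_error(fechner_p(0.02, 0.05), "delta")
})

test_that("diffusion mean RT and accuracy obey the analytic limits", {
  pars <- list(beta = 4, A = 1.2, t0 = 150)
  # p -> 0 (contrast so high the difference is imperceptible):
  # RT -> A^2 / beta + t0, accuracy -> 1/2
  lim <- pars$A^2 / pars$beta * 1000 + pars$t0
  expect_equal(fechner_rt(1e6, 1e-9, pars), lim, tolerance = 1e-4)
  expect_equal(fechner_pc(1e6, 1e-9, pars), 0.5, tolerance = 1e-6)
  # A p -> Inf: accuracy -> 1 and RT -> A/(beta p) + t0
  easy <- fechner_pc(0.0255, 0.05, list(beta = 50, A = 10, t0 = 0))
  expect_equal(easy, 1, tolerance = 1e-8)
  # closed-form spot checks
  p <- fechner_p(0.5, 0.05, pars$beta)
  expect_equal(fechner_rt(0.5, 0.05, pars),
               pars$A / (pars$beta * p) * tanh(pars$A * p) * 1000 + pars$t0,
               tolerance = 1e-12)
  expect_equal(fechner_pc(0.5, 0.05, pars), 1 / (1 + exp(-2 * pars$A * p)),
               tolerance = 1e-12)
  # A p = 1 gives the canonical accuracy value
  A <- 2; dl <- 0.05
  C1 <- (dl / 2) * (exp(1 / A) + 1) / (exp(1 / A) - 1) # solves A*log(...) = 1
  expect_equal(fechner_pc(C1, dl, list(beta = 1, A = A, t0 = 0)),
               1 / (1 + exp(-2)), tolerance = 1e-10)
  # RT increases with contrast (p shrinks), accuracy decreases
  C <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(fechner_rt(C, 0.05, pars)) > 0))
  expect_true(all(diff(fechner_pc(C, 0.05, pars)) < 0))
})

test_that("contrast binning partitions the range and summarizes trials", {
  set.seed(1)
  tr <- data.frame(
    participant = rep(c("a", "b"), each = 500),
    contrast = runif(1000, 0.035, 0.955),
    correct = rep(c(TRUE, FALSE), 500),
    rt = 300
  )
  bins <- bin_by_contrast(tr, 10)
  expect_s3_class(bins, "contrast_bins")
  expect_equal(nrow(bins), 20) # all bins populated at this n
  expect_true(all(bins$mean_ms == 300))
  expect_equal(range(attr(bins, "breaks")), range(tr$contrast))
  expect_error(bin_by_contrast(tr, 1), "n_bins")
  # empty bins are dropped with a warning
  tr2 <- tr[tr$contrast < 0.5, ]
  expect_warning(b2 <- bin_by_contrast(tr2, 10, range = c(0.035, 0.955)),
                 "empty")
  expect_true(all(b2$contrast < 0.5))
})

test_that("bounded least squares recovers noiseless generating laws", {
  C <- seq(0.05, 0.95, length.out = 10)
  true_p <- list(alpha = 120, beta = 60, nu = 0.6)
  tr <- data.frame(participant = "a", contrast = C, correct = TRUE,
                   rt = pieron_mean(C, true_p))
  bins <- bin_by_contrast(tr, 10)
  fit <- fit_law(bins, "pieron")
  expect_lt(sqrt(mean(fit$residuals^2)), 1e-6)
  expect_equal(fit$params$a$alpha, true_p$alpha, tolerance = 1e-3)
  expect_equal(fit$params$a$nu, true_p$nu, tolerance = 1e-3)

  tr$rt <- linear_mean(C, list(alpha = 250, beta = -90))
  fitl <- fit_law(bin_by_contrast(tr, 10), "linear")
  expect_lt(fitl$rmse, 1e-8)

  # diffusion fit on its own noiseless predictions
  dp <- list(beta = 6, A = 1.4, t0 = 80)
  tr$rt <- fechner_rt(C, 0.05, dp)
  fitf <- fit_law(bin_by_contrast(tr, 10), "fechner", delta = 0.05)
  expect_lt(fitf$rmse, 0.5)
})

test_that("LOO-CV RMSE matches the hand-computed toy value and ranks laws", {
  # 3 bins, linear refits on 2 points are exact lines; held-out errors
  # computed by hand: holding (0.4, 5) -> line through (0.1,1),(0.2,2)
  # predicts 4 (err 1); holding (0.2, 2) -> err 1/3; holding (0.1, 1)
  # -> err 0.5
  tr <- data.frame(participant = "a", contrast = c(0.1, 0.2, 0.4),
                   correct = TRUE, rt = c(1, 2, 5))
  bins <- bin_by_contrast(tr, 3, range = c(0.05, 0.45))
  expect_equal(bins$bin, 1:3)
  cv <- loo_cv(bins, laws = "linear")
  expect_equal(cv$rmse, sqrt(mean(c(1, 1 / 3, 0.5)^2)), tolerance = 1e-8)

  # the generating law wins on noiseless data
  C <- seq(0.05, 0.95, length.out = 10)
  tr <- data.frame(participant = "a", contrast = C, correct = TRUE,
                   rt = pieron_mean(C, list(alpha = 120, beta = 60, nu = 0.6)))
  cv <- loo_cv(bin_by_contrast(tr, 10), c("linear", "pieron"))
  expect_lt(cv$rmse[cv$law == "pieron"], 1e-4)
  expect_true(cv$winner[cv$law == "pieron"])
  expect_equal(sum(cv$winner), 1)
})

test_that("accuracy is predicted from RT-only diffusion parameters", {
  C <- seq(0.05, 0.95, length.out = 10)
  dp <- list(beta = 6, A = 1.4, t0 = 80)
  tr <- data.frame(participant = "a", contrast = C, correct = TRUE,
                   rt = fechner_rt(C, 0.05, dp))
  bins <- bin_by_contrast(tr, 10)
  fit <- fit_law(bins, "fechner", delta = 0.05)
  # overwrite observed accuracy with the exact model value: prediction
  # from the RT-only fit should then be near-perfect
  bins$accuracy <- fechner_pc(bins$contrast, 0.05, dp)
  pa <- predict_accuracy(fit, bins)
  expect_gt(pa$r2, 0.99)
  expect_true(all(pa$predictions$predicted > 0.5 &
                  pa$predictions$predicted < 1))
  # constant observed accuracy has no variance to explain
  bins$accuracy <- 1
  pa2 <- predict_accuracy(fit, bins)
  expect_true(pa2$degenerate)
  expect_true(is.na(pa2$r2))
})

test_that("encoding and decision intervals are sums of stated stages", {
  tm <- matrix(c(40, 110, 200, 400, 480), 1)
  ci <- combine_intervals(tm)
  expect_equal(ci$encoding_ms, 160)
  expect_equal(ci$decision_ms, 280)
  expect_false(ci$flagged)
  # telescoping: t1 + encoding + decision + (rt - t5) = rt
  rt <- 520
  expect_equal(tm[1] + ci$encoding_ms + ci$decision_ms + (rt - tm[5]), rt)
  # non-monotone times are flagged
  tm2 <- matrix(c(40, 30, 200, 400, 480), 1)
  expect_true(combine_intervals(tm2)$flagged)
})
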