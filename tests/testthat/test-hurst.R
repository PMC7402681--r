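test_that("FIP simulator reproduces closed-form second-order structure", {
  # d = 0: white noise, lag-1 autocorrelation within sampling error
  x0 <- simulate_fip(0, 2048, seed = 1)
  r1 <- sum(x0[-1] * x0[-length(x0)]) / sum(x0^2)
  expect_lt(abs(r1), 3 / sqrt(2048))
  # d = 0.4: non-centered lag-1 autocorrelation matches d/(1-d) = 2/3
  # (the process mean is known to be zero, so no centering bias)
  r1s <- sapply(1:10, function(s) {
    x <- simulate_fip(0.4, 8192, seed = s)
    sum(x[-1] * x[-length(x)]) / sum(x^2)
  })
  expect_lt(abs(mean(r1s) - 0.4 / 0.6), 0.05)
  # variance matches Gamma(1-2d)/Gamma(1-d)^2
  v <- mean(sapply(1:10, function(s) mean(simulate_fip(0.4, 8192, seed = s)^2)))
  expect_lt(abs(v - gamma(0.2) / gamma(0.6)^2) / v, 0.1)
  # d = 1: differencing recovers white noise, estimated d near 0
  x1 <- simulate_fip(1, 4096, seed = 3)
  expect_lt(abs(estimate_hurst_fip(diff(x1))$H - 0.5), 0.1)
  expect_error(simulate_fip(1.5, 100), "d must lie")
  expect_error(simulate_fip(-0.5, 100), "d must lie")
  expect_error(simulate_fip(0.2, 8), "at least 16")
})

test_that("white noise is estimated at H = 0.5 and a random walk at 1.5", {
  set.seed(42)
  h <- replicate(40, estimate_hurst_fip(rnorm(512))$H)
  expect_lt(abs(mean(h) - 0.5), 0.05)
  set.seed(43)
  hr <- replicate(10, estimate_hurst_fip(cumsum(rnorm(4096)))$H)
  expect_gt(mean(hr), 1.35)
  expect_lt(mean(hr), 1.65)
})

test_that("memory parameter is recovered across the stationarity boundary", {
  for (d in c(0, 0.2, 0.4, 0.9)) {
    hs <- sapply(1:20, function(s) {
      estimate_hurst_fip(simulate_fip(d, 4096, seed = 1000 * d + s))$H
    })
    expect_lt(abs(mean(hs) - (d + 0.5)), 0.07)
  }
})

test_that("ML estimate agrees with the log-variance regression oracle", {
  devs <- sapply(1:10, function(s) {
    x <- simulate_fip(0.3, 4096, seed = 300 + s)
    estimate_hurst_fip(x)$H - oracle_hurst_logvar(x)
  })
  expect_lt(mean(abs(devs)), 0.05)
})

test_that("estimate is invariant to affine transforms of the series", {
  x <- simulate_fip(0.25, 1024, seed = 77)
  h0 <- estimate_hurst_fip(x)$H
  expect_equal(estimate_hurst_fip(5.3 * x + 11)$H, h0, tolerance = 1e-6)
  expect_equal(estimate_hurst_fip(-2 * x)$H, h0, tolerance = 1e-6)
})

test_that("estimator rejects degenerate input and flags bound hits", {
  expect_error(estimate_hurst_fip(rep(1, 512)), "constant")
  expect_error(estimate_hurst_fip(c(rnorm(511), NA)), "non-finite")
  expect_error(estimate_hurst_fip(rnorm(8)), "too short")
  est <- estimate_hurst_fip(simulate_fip(0.2, 512, seed = 1))
  expect_equal(est$H, est$d + 0.5)
  expect_true(is.finite(est$log_lik))
})

test_that("sliding windows count and degenerate to the global estimate", {
  x <- simulate_fip(0.2, 515, seed = 9)
  w1 <- sliding_window_hurst(x[1:512], window = 512)
  expect_equal(nrow(w1$estimates), 1)
  expect_equal(w1$estimates$H[1], estimate_hurst_fip(x[1:512])$H)
  w4 <- sliding_window_hurst(x, window = 512, step = 1)
  expect_equal(nrow(w4$estimates), 4)
  expect_error(sliding_window_hurst(x[1:100], window = 512), "window")
})

test_that("windowed H is flat for a stationary series", {
  x <- simulate_fip(0.2, 2048, seed = 21)
  wh <- sliding_window_hurst(x, window = 512, step = 64)
  expect_lt(sd(wh$estimates$H), 0.15)
  expect_lt(abs(mean(wh$estimates$H) - estimate_hurst_fip(x)$H), 0.1)
})
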