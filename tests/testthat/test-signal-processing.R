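test_that("deep-passband signals pass the zero-lag filter unchanged", {
  t <- seq(0, 5, by = 1 / 240)
  x <- sin(2 * pi * 1 * t)
  spec <- filter_spec(4, 12, 240)
  y <- butterworth_zero_lag(x, spec)
  expect_gt(max(abs(y)) / max(abs(x)), 0.999)
  expect_lt(max(abs(y)) / max(abs(x)), 1.001)
  cc <- ccf(y, x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # DC gain 1
  expect_lt(max(abs(butterworth_zero_lag(rep(2.5, 1200), spec) - 2.5)), 1e-4)
})

test_that("attenuation at the cutoff matches the analytic two-pass response", {
  for (ord in c(4, 2)) {
    rate <- if (ord == 4) 240 else 128
    spec <- filter_spec(ord, 12, rate)
    t <- seq(0, 6, by = 1 / rate)
    x <- sin(2 * pi * 12 * t)
    y <- butterworth_zero_lag(x, spec)
    mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
    gain_measured <- max(abs(y[mid]))
    gain_analytic <- gaitcom:::filter_gain_two_pass(spec, 12)
    expect_equal(gain_measured, gain_analytic, tolerance = 1e-3)
    # two passes of the half-power point give gain 1/2
    expect_equal(gain_analytic, 0.5, tolerance = 1e-6)
  }
})

test_that("zero-lag holds for band-limited random signals", {
  set.seed(1)
  t <- seq(0, 4, by = 1 / 240)
  x <- rowSums(sapply(c(1, 2.3, 4.1, 6), function(f) {
    runif(1, 0.5, 1) * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  }))
  y <- butterworth_zero_lag(x, filter_spec(4, 12, 240))
  cc <- ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter and differentiator are linear operators", {
  set.seed(2)
  x <- rnorm(500); y <- rnorm(500)
  a <- 1.7; b <- -0.4
  spec <- filter_spec(4, 12, 240)
  lhs <- butterworth_zero_lag(a * x + b * y, spec)
  rhs <- a * butterworth_zero_lag(x, spec) + b * butterworth_zero_lag(y, spec)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  for (ord in 1:2) {
    lhs <- finite_difference(a * x + b * y, 240, ord)
    rhs <- a * finite_difference(x, 240, ord) + b * finite_difference(y, 240, ord)
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  }
})

test_that("filter specs are validated", {
  expect_error(filter_spec(4, 70, 128), "Nyquist")
  expect_error(filter_spec(3, 12, 240), "even")
  expect_error(butterworth_zero_lag(c(1, 2), filter_spec(4, 12, 240)), "short")
})

test_that("central differences are exact on polynomials", {
  t <- seq(0, 2, by = 1 / 100)
  d2 <- finite_difference(t^2, 100, 2)
  expect_lt(max(abs(d2[2:(length(t) - 1)] - 2)), 1e-9)
  # linear ramp: first derivative exact everywhere including endpoints
  d1 <- finite_difference(5 + 3 * t, 100, 1)
  expect_lt(max(abs(d1 - 3)), 1e-9)
  # quadratic endpoints via the one-sided second-order stencils
  expect_lt(max(abs(d2 - 2)), 1e-6)
})

test_that("second derivative of a sinusoid meets the truncation bound", {
  rate <- 240
  t <- seq(0, 3, by = 1 / rate)
  x <- sin(2 * pi * t)
  d2 <- finite_difference(x, rate, 2)
  truth <- -(2 * pi)^2 * sin(2 * pi * t)
  inner <- 2:(length(t) - 1)
  # central-difference truncation: |err| <= w^4 dt^2 / 12 for sin(w t)
  bound <- (2 * pi)^4 / rate^2 / 12 * 1.01
  expect_lt(max(abs(d2[inner] - truth[inner])), bound)
})

test_that("differentiating twice agrees with the direct second difference", {
  t <- seq(0, 2, by = 1 / 240)
  x <- sin(2 * pi * 1.3 * t) + 0.3 * cos(2 * pi * 3 * t)
  once_twice <- finite_difference(finite_difference(x, 240, 1), 240, 1)
  direct <- finite_difference(x, 240, 2)
  inner <- 5:(length(t) - 4)
  # both are O(dt^2) schemes; they agree to the same order
  expect_lt(max(abs(once_twice[inner] - direct[inner])), (2 * pi * 3)^4 / 240^2)
  expect_error(finite_difference(c(1, 2), 240, 1), "3 samples")
})

test_that("gravity correction zeroes a stationary vertical reading only", {
  expect_equal(unname(gravity_correct(rbind(c(0, 0, 9.81)))[1, ]), c(0, 0, 0))
  expect_equal(unname(gravity_correct(rbind(c(0.3, -0.1, 9.81)))[1, ]),
               c(0.3, -0.1, 0))
  # noise-free synthetic IMU: corrected vertical mean over whole strides ~ 0
  tr <- generate_trial(clean_trial_config(stride_duration = 1.0, n_strides = 10), 1)
  corr <- gravity_correct(tr$imu$acc)
  expect_lt(abs(mean(corr[seq_len(10 * 128), 3])), 1e-6)
})
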