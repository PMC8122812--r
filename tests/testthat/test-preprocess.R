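test_that("bandpass filter passes mid-band, rejects drift, and preserves zero", {
  fs <- 125
  expect_equal(bandpass_filter(numeric(3750)), numeric(3750))

  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  inner <- 1000:6500  # steady-state region away from edges
  # magnitude-response oracle for the zero-phase cascade
  expect_equal(filter_response(2), 1, tolerance = 0.05)
  expect_lt(filter_response(0.1), 0.01)

  mid <- bandpass_filter(sin(2 * pi * 2 * t))
  expect_equal(max(abs(mid[inner])), 1, tolerance = 0.05)

  slow <- bandpass_filter(sin(2 * pi * 0.1 * t))
  expect_lt(max(abs(slow[inner])), 0.1)  # >= 20 dB attenuation

  expect_error(bandpass_filter(rnorm(10)), "too short")
})

test_that("filtering is idempotent in the passband sense", {
  fs <- 125
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  once <- bandpass_filter(x)
  twice <- bandpass_filter(once)
  inner <- 1000:6500
  expect_lt(abs(max(abs(twice[inner])) - max(abs(once[inner]))) /
              max(abs(once[inner])), 0.1)
})

test_that("zscore matches hand-computed population statistics and inverts exactly", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z$params$mu, 2)
  expect_equal(z$params$sigma, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(z$x, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)

  x <- rnorm(200)
  z2 <- zscore(x)
  expect_equal(mean(z2$x), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z2$x - mean(z2$x))^2)), 1, tolerance = 1e-12)
  expect_equal(invert_zscore(z2$x, z2$params), x, tolerance = 1e-12)

  expect_error(zscore(c(5, 5, 5)), "constant")
})

test_that("global normalization parameters are the means of the per-signal parameters", {
  expect_equal(fit_global_norm(list(list(mu = 1, sigma = 2),
                                    list(mu = 3, sigma = 4))),
               list(mu_bar = 2, sigma_bar = 3))
  one <- list(mu = 0.4, sigma = 1.7)
  expect_equal(fit_global_norm(list(one)),
               list(mu_bar = 0.4, sigma_bar = 1.7))
  set.seed(1)
  ps <- replicate(100, list(mu = rnorm(1, 5), sigma = runif(1, 1, 2)),
                  simplify = FALSE)
  g <- fit_global_norm(ps)
  expect_equal(g$mu_bar, mean(vapply(ps, `[[`, 0, "mu")), tolerance = 1e-12)
  expect_equal(g$sigma_bar, mean(vapply(ps, `[[`, 0, "sigma")),
               tolerance = 1e-12)
  expect_error(fit_global_norm(list()), "empty")
})

test_that("alignment finds the exact lag against a brute-force oracle", {
  s <- generate_segment(clean_config())
  al0 <- align_signals(s$ppg, s$abp, max_lag = 100)
  expect_identical(al0$delta_t, 0L)

  # identical signals: self-correlation peaks at zero
  expect_identical(align_signals(s$abp, s$abp, max_lag = 50)$delta_t, 0L)

  for (L in c(10L, 35L)) {
    g <- generate_segment(clean_config(lag_samples = L))
    al <- align_signals(g$ppg, g$abp, max_lag = 100)
    # brute-force oracle over every lag
    n <- length(g$ppg)
    brute <- vapply(0:99, function(k)
      sum(g$abp[1:(n - k)] * g$ppg[(1 + k):n]), 0.0)
    expect_identical(al$delta_t, which.max(brute) - 1L)
    expect_identical(al$delta_t, L)
    expect_equal(al$score, max(brute))
    # PPG advanced, ABP never shifted, lengths kept equal
    expect_length(al$shifted_ppg, n - L)
    expect_identical(al$abp, g$abp[seq_len(n - L)])
    expect_identical(al$shifted_ppg, g$ppg[(1 + L):n])
  }
})

test_that("degenerate all-zero input is flagged rather than aligned", {
  expect_warning(al <- align_signals(numeric(300), numeric(300),
                                     max_lag = 10), "undefined")
  expect_true(is.na(al$delta_t))
})

test_that("central difference is exact on ramps, zero on constants, and meets the Taylor bound on sinusoids", {
  h <- 0.008
  ramp <- central_difference(3.5 * (0:49) * h, h)
  expect_equal(ramp[2:49], rep(3.5, 48), tolerance = 1e-9)
  expect_equal(central_difference(rep(2, 30), h), numeric(30))

  t <- (0:999) * h
  d <- central_difference(sin(2 * pi * t), h)
  bound <- (2 * pi)^3 * h^2 / 6
  err <- abs(d - 2 * pi * cos(2 * pi * t))[2:999]
  expect_lte(max(err), bound)

  expect_error(central_difference(c(1, 2), h), "3 samples")
})

test_that("the derivative operator is linear", {
  set.seed(4)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(central_difference(2 * x - 3 * y, 0.008),
               2 * central_difference(x, 0.008) -
                 3 * central_difference(y, 0.008),
               tolerance = 1e-12)
})

test_that("feature stacks carry (ppg, velocity, acceleration) channels", {
  h <- 1 / 125
  t <- (0:499) * h
  x <- sin(2 * pi * t)
  st <- make_feature_stack(x, h)
  expect_identical(dim(st), c(500L, 3L))
  expect_identical(st[, 1], x)
  expect_identical(st[, 2], central_difference(x, h))
  # second derivative of sin is -(2 pi)^2 sin; the composed stencil has
  # truncation error ~ f''''(x) (2h)^2 / 12
  inner <- 3:498
  expect_lt(max(abs(st[inner, 3] + (2 * pi)^2 * sin(2 * pi * t[inner]))),
            2 * (2 * pi)^4 * (2 * h)^2 / 12)
  expect_equal(attr(st, "step_h"), h)
})
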