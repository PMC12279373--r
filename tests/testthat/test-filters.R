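test_that("0th-order Slepian taper is concentrated, positive and unit-sum", {
  tp <- dpss_taper(15, 0.1)
  expect_equal(sum(tp), 1)
  expect_true(all(tp > 0))
  expect_equal(which.max(tp), 8)               # symmetric, peaked in the middle
  expect_equal(tp, rev(tp), tolerance = 1e-12)
  # concentration: most energy below the design bandwidth
  spec <- abs(fft(c(tp, numeric(241))))^2
  f <- (0:255) / 256
  inband <- sum(spec[f <= 0.1 | f >= 0.9]) / sum(spec)
  expect_gt(inband, 0.99)
})

test_that("identity system yields a unit-area pulse at lag zero", {
  set.seed(1)
  x <- time_series(rnorm(20000), 100)
  f <- estimate_filter(x, x, bandwidth = 15)
  expect_equal(f$lags[which.max(f$values)], 0)
  expect_equal(sum(f$values), 1, tolerance = 1e-3)
})

test_that("estimation is linear in the input scale", {
  set.seed(2)
  x <- rnorm(12000)
  y <- rnorm(12000)
  f1 <- estimate_filter(time_series(x, 100), time_series(y, 100))
  f2 <- estimate_filter(time_series(3 * x, 100), time_series(y, 100))
  expect_equal(f2$values, f1$values / 3, tolerance = 1e-12)
})

test_that("white-noise input reduces the estimate to the cross-correlation", {
  # with a white (flat-spectrum) input, dividing the cross-spectrum by the
  # input power spectrum is equivalent to scaling the plain cross-correlation
  # by a constant; assert the full ratio estimator agrees with an independent
  # scalar-denominator (pure cross-correlation) implementation
  set.seed(3)
  n <- 480000
  rate <- 100
  x <- rnorm(n)
  kern <- steering_kernel("monophasic", rate, peak = 0.5, support = 0.8)
  y <- steerlab:::conv_causal(x, kern) + rnorm(n, sd = 0.005)
  f <- estimate_filter(time_series(x, rate), time_series(y, rate),
                       window = 2, bandwidth = 15, demean = FALSE)
  # independent oracle: averaged windowed cross-correlation via FFT with a
  # scalar power normalization
  w <- 200L
  hop <- 50L
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1)) / (w - 1))
  starts <- seq(1L, n - w + 1L, by = hop)
  sxy <- complex(w); pwr <- 0
  for (s0 in starts) {
    xs <- x[s0:(s0 + w - 1L)]; ys <- y[s0:(s0 + w - 1L)]
    xf <- fft(xs * taper); yf <- fft(ys * taper)
    sxy <- sxy + Conj(xf) * yf
    pwr <- pwr + mean(Re(Conj(xf) * xf))
  }
  h2 <- Re(fft(sxy / pwr, inverse = TRUE)) / w
  h2 <- steerlab:::fftshift_vec(h2)
  lagn <- abs(round(f$lags * rate))
  rho <- vapply(lagn, function(l) sum(taper[1:(w - l)] * taper[(1 + l):w]),
                numeric(1)) / sum(taper^2)
  h2 <- h2 / pmax(rho, 0.05)
  tp <- dpss_taper(7, 15 / rate)
  h2s <- steerlab:::conv_same_reflect(h2, tp)
  sup <- f$lags >= -0.8 & f$lags <= 0.8
  rms <- sqrt(mean((f$values[sup] - h2s[sup])^2)) / sd(h2s[sup])
  expect_lt(rms, 0.02)
})

test_that("known kernels are recovered from noisy simulated sessions", {
  cfg <- sim_config(duration = 300, immobility_bout_rate = 0,
                    simulate_voltage = FALSE, seed = 4)
  s <- simulate_steering_session(cfg)
  rin <- s$true_rate$left
  f_b <- estimate_filter(rin, kin_channel(s$kinematics, "v_r"), bandwidth = 15)
  f_m <- estimate_filter(rin, kin_channel(s$kinematics, "v_s"), bandwidth = 15)
  kb <- cfg$ground_truth_filters[["left.v_r"]]
  km <- cfg$ground_truth_filters[["left.v_s"]]
  sup <- which(f_b$lags >= 0)
  expect_gte(cor(f_b$values[sup[seq_along(kb)]], kb), 0.95)
  expect_gte(cor(f_m$values[sup[seq_along(km)]], km), 0.95)
  # biphasic sign structure: positive early lobe, negative late lobe
  rec <- f_b$values[sup[seq_along(kb)]]
  expect_gt(max(rec[1:30]), 0)
  expect_lt(min(rec[40:120]), 0)
  # independent output: filter amplitude at the noise floor of lag-reversed
  # surrogates
  set.seed(5)
  indep <- time_series(rnorm(length(rin$values), 0, 50), 100)
  f0 <- estimate_filter(rin, indep, bandwidth = 15)
  surrogate <- estimate_filter(
    time_series(rev(rin$values), 100), indep, bandwidth = 15)
  expect_lt(max(abs(f0$values)), 5 * max(abs(surrogate$values)))
})

test_that("hop = 1 exact mode agrees with the default hop", {
  set.seed(6)
  x <- time_series(rnorm(60000), 100)
  y <- time_series(steerlab:::conv_causal(
    x$values, steering_kernel("monophasic", 100, support = 0.8)), 100)
  f_default <- estimate_filter(x, y, window = 2)
  f_exact <- estimate_filter(x, y, window = 2, hop = 1)
  rms <- sqrt(mean((f_default$values - f_exact$values)^2)) /
    sd(f_exact$values)
  expect_lt(rms, 0.01)
})

test_that("prediction is self-consistent, null-calibrated, and noise-monotone", {
  cfg <- sim_config(duration = 200, cells = "left", immobility_bout_rate = 0,
                    simulate_voltage = FALSE, seed = 7)
  s <- simulate_steering_session(cfg)
  rin <- s$true_rate$left
  kb <- cfg$ground_truth_filters[["left.v_r"]]
  w <- 400
  lags <- (seq_len(w) - 1 - w / 2) / 100
  vals <- numeric(w)
  i0 <- which.min(abs(lags))
  vals[i0:(i0 + length(kb) - 1)] <- kb
  ftrue <- linear_filter(lags, vals, rate = 100)

  # noise-free observations from the same filter: R^2 >= 0.999
  obs <- time_series(steerlab:::apply_filter(rin, ftrue), 100)
  rep1 <- suppressWarnings(predict_behavior(ftrue, rin, obs))
  expect_gte(rep1$report$r2, 0.999)
  expect_true(rep1$report$filter_length_used >= 0.1 &&
              rep1$report$filter_length_used <= 4)

  # pure-noise observations: R^2 near zero at n >= 1e4
  set.seed(8)
  noise_obs <- time_series(rnorm(length(rin$values), 0, 50), 100)
  rep0 <- predict_behavior(ftrue, rin, noise_obs)
  expect_lte(rep0$report$r2, 0.05)

  # R^2 decreases monotonically along a fixed noise sweep
  set.seed(9)
  eps <- rnorm(length(obs$values))
  r2s <- vapply(c(0, 50, 150, 400), function(sd_n) {
    noisy <- time_series(obs$values + sd_n * eps, 100)
    suppressWarnings(predict_behavior(ftrue, rin, noisy)$report$r2)
  }, numeric(1))
  expect_true(all(diff(r2s) < 0))
})

test_that("dual predictions sum with equal weight", {
  a <- time_series(c(1, 2, 3, 4), 100)
  zero <- time_series(rep(0, 4), 100)
  expect_equal(dual_prediction(a, zero)$values, a$values)
  b <- time_series(-c(1, 2, 3, 4), 100)
  expect_equal(dual_prediction(a, b)$values, rep(0, 4))
  masked <- dual_prediction(a, zero, active_mask = c(TRUE, FALSE, TRUE, TRUE))
  expect_true(is.na(masked$values[2]))

  # two-cell simulator, noise-free: dual prediction at least as good as the
  # best single cell
  cfg <- sim_config(duration = 150, immobility_bout_rate = 0,
                    noise_sd = c(v_r = 0, v_s = 0, v_f = 0),
                    simulate_voltage = FALSE, seed = 10)
  s <- simulate_steering_session(cfg)
  vr <- kin_channel(s$kinematics, "v_r")
  preds <- lapply(c("right", "left"), function(cell) {
    f <- estimate_filter(s$true_rate[[cell]], vr, bandwidth = 15)
    suppressWarnings(predict_behavior(f, s$true_rate[[cell]], vr))
  })
  dual <- dual_prediction(preds[[1]]$predicted, preds[[2]]$predicted)
  n <- length(vr$values)
  ei <- seq(floor(0.2 * n) + 1, n)
  r2_dual <- summary(lm(vr$values[ei] ~ dual$values[ei]))$r.squared
  expect_gte(r2_dual + 1e-9, max(vapply(preds, function(p) p$report$r2, numeric(1))))
})

test_that("autocorrelation is biased-normalized with acf(0) = 1", {
  set.seed(11)
  wn <- time_series(rnorm(10000), 100)
  a <- autocorrelation(wn, max_lag = 1)
  expect_equal(a$acf[1], 1)
  expect_true(all(abs(a$acf[-1]) < 4 / sqrt(10000)))
  sn <- time_series(sin(2 * pi * (0:4999) / 100), 100)  # period 1 s
  as <- autocorrelation(sn, max_lag = 1.4)
  peak_lag <- as$lag[-1][which.max(as$acf[-1][as$lag[-1] > 0.5])]
  expect_equal(as$lag[which(as$acf == max(as$acf[as$lag > 0.5 & as$lag < 1.4]))],
               1, tolerance = 0.02)
})
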