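test_that("offset correction subtracts the median of inactive periods", {
  # whole trace inactive: constant maps to zero
  cst <- time_series(rep(3, 100), 100)
  expect_equal(correct_offset(cst)$values, rep(0, 100))

  # flat rest segments at +2 map to zero
  x <- c(rep(2, 50), 2 + 5 * sin(seq(0, 4 * pi, length.out = 200)), rep(2, 50))
  out <- correct_offset(time_series(x, 100))
  expect_equal(out$values[1:50], rep(0, 50))
  expect_equal(attr(out, "offset"), 2)

  # random trace: equals input minus the brute-force median over
  # {i : |x(i) - x(i-1)| < 0.025}
  set.seed(1)
  v <- cumsum(rnorm(500, 0, 0.02)) + 1.3
  idx <- which(abs(diff(v)) < 0.025) + 1L
  expected <- v - median(v[idx])
  expect_equal(correct_offset(time_series(v, 100))$values, expected)

  # no inactive samples: unchanged with a warning
  y <- seq(0, 10, by = 0.5)
  expect_warning(out2 <- correct_offset(time_series(y, 100)), "offset not corrected")
  expect_equal(out2$values, y)
  expect_true(attr(out2, "no_inactive"))

  expect_error(correct_offset(time_series(c(NaN, NaN), 100)), "NaN")
})

test_that("Gaussian smoothing uses a unit-sum truncated kernel", {
  cst <- time_series(rep(5, 200), 100)
  expect_equal(smooth_gaussian(cst)$values, rep(5, 200))

  imp <- time_series(c(rep(0, 100), 1, rep(0, 100)), 100)
  sm <- smooth_gaussian(imp)
  expect_equal(sum(sm$values), 1, tolerance = 1e-12)

  # white-noise variance shrinks by the kernel's sum of squares
  set.seed(2)
  wn <- time_series(rnorm(20000), 1000)
  k <- steerlab:::gaussian_kernel(0.05, 1000)
  sm2 <- smooth_gaussian(wn)
  expect_equal(var(sm2$values) / var(wn$values), sum(k^2), tolerance = 0.1)

  expect_error(smooth_gaussian(time_series(1:10, 10), width_s = 0.05),
               "exceed 2 samples")
})

test_that("random-walk MAP smoother matches a numerical optimizer", {
  set.seed(3)
  for (i in 1:3) {
    y <- cumsum(rnorm(400, 0.02, 0.5)) + rnorm(400, 0, 0.4)
    z <- smooth_random_walk_map(time_series(y, 100))
    pr <- attr(z, "params")
    obj <- function(zv) {
      sum((y - zv)^2) / pr$alpha + sum((diff(zv) - pr$mu)^2) / (1 - pr$alpha)
    }
    opt <- optim(y, obj, method = "L-BFGS-B",
                 control = list(maxit = 5000, factr = 1e2))
    expect_lt(sqrt(mean((z$values - opt$par)^2)), 1e-6)
  }
})

test_that("random-walk smoother limits and equivariance", {
  set.seed(4)
  y <- cumsum(rnorm(300)) + rnorm(300)
  yts <- time_series(y, 100)
  # alpha -> 0: no observation noise, output equals input
  z0 <- smooth_random_walk_map(yts, random_walk_params(alpha = 1e-6))
  expect_lt(max(abs(z0$values - y)) / max(abs(y)), 1e-5)
  # constant input returns the constant with mu ~ 0
  zc <- smooth_random_walk_map(time_series(rep(2.5, 100), 100))
  expect_equal(zc$values, rep(2.5, 100))
  expect_equal(attr(zc, "params")$mu, 0)
  # shift equivariance
  z <- smooth_random_walk_map(yts)
  zs <- smooth_random_walk_map(time_series(y + 7, 100))
  expect_equal(zs$values, z$values + 7, tolerance = 1e-10)
  expect_error(random_walk_params(alpha = 1.2), "strictly inside")
})

test_that("total speed sums componentwise absolute values", {
  k <- kinematics_trace(c(0, 10, -75), c(0, -20, 0), c(0, 5, 0), rate = 100)
  expect_equal(total_speed(k)$values, c(0, 35, 75))
  # property: per-sample equality with the direct sum
  set.seed(5)
  k2 <- kinematics_trace(rnorm(200, 0, 100), rnorm(200, 0, 40),
                         rnorm(200, 0, 60), rate = 100)
  expect_identical(total_speed(k2)$values,
                   abs(k2$v_r) + abs(k2$v_s) + abs(k2$v_f))
})

test_that("inactivity classification finds the rest mode", {
  # all-zero trace: everything inactive, degenerate flagged
  k0 <- kinematics_trace(rep(0, 50), rep(0, 50), rep(0, 50))
  i0 <- classify_inactivity(k0)
  expect_true(all(i0))
  expect_true(attr(i0, "degenerate"))

  # distinct rest/walk modes with rest majority: rest labeled inactive
  set.seed(6)
  n <- 6000
  walk <- 2501:5000
  mk <- function(mu, sd_w) {
    v <- rnorm(n, 0, 0.6)
    v[walk] <- rnorm(length(walk), mu, sd_w)
    v
  }
  k <- kinematics_trace(mk(100, 25), mk(40, 15), mk(60, 20), rate = 100)
  inact <- classify_inactivity(k)
  expect_gt(mean(inact[-walk]), 0.95)
  expect_gt(mean(!inact[walk]), 0.99)

  # single non-zero sample stays active
  z <- rep(0, 100); z[50] <- 5
  i2 <- classify_inactivity(kinematics_trace(z, rep(0, 100), rep(0, 100)))
  expect_false(i2[50])
  expect_true(all(i2[-50]))
})

test_that("polyphase resampling preserves amplitude with no net lag", {
  cst <- time_series(rep(3, 5000), 1000)
  rc <- resample_neural_to_kinematics(cst, 100)
  expect_equal(rc$values, rep(3, length(rc$values)), tolerance = 1e-2)
  expect_equal(length(rc$values), ceiling(5000 * 100 / 1000))

  tt <- (0:49999) / 10000
  sn <- time_series(sin(2 * pi * 5 * tt), 10000)
  rs <- resample_neural_to_kinematics(sn, 100)
  expect_equal(length(rs$values), ceiling(50000 * 100 / 10000))
  # amplitude within 1% and phase aligned with the analytic sine
  ref <- sin(2 * pi * 5 * ts_time(rs))
  expect_equal(max(abs(rs$values)), 1, tolerance = 0.01)
  expect_lt(max(abs(rs$values - ref)[50:450]), 0.02)
  expect_error(resample_neural_to_kinematics(rc, 1000), "below the source")
})

test_that("preprocessing pipeline preserves length and time base", {
  set.seed(7)
  x <- time_series(cumsum(rnorm(1000)), 100, t0 = 5)
  out <- smooth_random_walk_map(smooth_gaussian(correct_offset(x)))
  expect_equal(length(out$values), 1000)
  expect_equal(out$rate, 100)
  expect_equal(out$t0, 5)
})
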