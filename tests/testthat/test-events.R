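test_that("transition detector applies the consistency rules", {
  expect_equal(nrow(detect_transitions(time_series(rep(0, 1000), 100))), 0)

  # clean step held >= 750 ms on each side: exactly one start at the crossing
  spd <- c(rep(0, 200), rep(150, 300))
  ev <- detect_transitions(time_series(spd, 100))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "start")
  expect_equal(ev$index, 201)

  expect_error(detect_transitions(time_series(rep(0, 50), 100)), "shorter")
})

test_that("transition detector matches the brute-force oracle on bout trains", {
  for (seed in 1:8) {
    set.seed(seed)
    # random alternation of rest and walk bouts with jitter
    segs <- pmax(30, round(rexp(20, 1 / 120)))
    lvl <- rep(c(0, 150), 10)[seq_along(segs)]
    x <- unlist(mapply(function(l, n) l + runif(n, 0, 35), lvl, segs))
    got <- detect_transitions(time_series(x, 100))
    want <- oracle_transitions(x, 100)
    expect_equal(got$index, want$index)
    expect_equal(got$kind, want$kind)
  }
})

test_that("transition detection is translation-equivariant", {
  set.seed(9)
  x <- c(rep(0, 150), rep(160, 200), rep(0, 150)) + runif(500, 0, 30)
  base <- detect_transitions(time_series(x, 100))
  shifted <- detect_transitions(time_series(c(rep(0, 300), x), 100))
  expect_equal(shifted$index, base$index + 300)
  expect_equal(shifted$kind, base$kind)
})

test_that("event-triggered averaging is two-level with sem across experiments", {
  tpl <- sin(seq(0, 2 * pi, length.out = 101))
  sig <- time_series(c(rep(0, 200), tpl, rep(0, 200)), 100)
  # identical copies: mean equals the signal snippet, sem = 0
  out <- align_and_average(list(sig, sig, sig),
                           list(2.5, 2.5, 2.5), span = 0.5)
  expect_equal(out$mean, sig$values[201:301], tolerance = 1e-12)
  expect_equal(max(out$sem), 0)

  # events at known offsets of a template reproduce the template
  set.seed(1)
  n <- 6000
  events <- c(10, 20, 30, 40)
  v <- numeric(n)
  for (te in events) v[(te * 100 + 1):(te * 100 + 101)] <- tpl
  noisy <- time_series(v + rnorm(n, 0, 0.05), 100)
  out2 <- align_and_average(list(noisy), list(events), span = 0.5)
  expect_lt(max(abs(out2$mean[51:101] - tpl[1:51])), 4 * 0.05 / sqrt(4))
  # single experiment: sem flagged undefined, not an error
  expect_false(out2$sem_defined)
  expect_true(all(is.na(out2$sem)))
})

test_that("binned behavior maps agree with brute-force re-binning", {
  # constant behavior fills every unmasked bin with the constant
  set.seed(2)
  ra <- time_series(rnorm(20000, 50, 15), 100, units = "spikes/s")
  rb <- time_series(rnorm(20000, 50, 15), 100, units = "spikes/s")
  cst <- time_series(rep(7, 20000), 100)
  m1 <- binned_behavior_map(ra, rb, cst, min_count = 5)
  expect_true(all(abs(m1$map[!is.na(m1$map)] - 7) < 1e-12))

  # behavior = (shifted) rate difference: map values match the bin-center
  # difference within half a diagonal bin width
  beh <- time_series(steerlab:::shift_forward(ra, 0.15)$values -
                     steerlab:::shift_forward(rb, 0.15)$values, 100)
  m2 <- binned_behavior_map(ra, rb, beh, min_count = 10)
  ac <- (m2$a_breaks[-length(m2$a_breaks)] + m2$a_breaks[-1]) / 2
  bc <- (m2$b_breaks[-length(m2$b_breaks)] + m2$b_breaks[-1]) / 2
  pred <- outer(ac, bc, "-")
  dev <- abs(m2$map - pred)
  expect_lt(max(dev, na.rm = TRUE), 10)  # bin width

  # exact agreement with an independent re-binning of the window triples
  for (seed in 1:50) {
    set.seed(seed)
    nw <- 400
    a <- rnorm(nw, 40, 12); b <- rnorm(nw, 40, 12); beh <- rnorm(nw, 0, 30)
    a_breaks <- seq(floor(min(a) / 10) * 10, ceiling(max(a) / 10) * 10 + 10, 10)
    b_breaks <- seq(floor(min(b) / 10) * 10, ceiling(max(b) / 10) * 10 + 10, 10)
    want <- oracle_bin_map(a, b, beh, a_breaks, b_breaks, min_count = 3)
    ai <- findInterval(a, a_breaks, rightmost.closed = TRUE)
    bi <- findInterval(b, b_breaks, rightmost.closed = TRUE)
    # reconstruct through the package path by faking 1-sample windows
    ra2 <- time_series(a, 20); rb2 <- time_series(b, 20)
    beh2 <- time_series(beh, 20)
    got <- binned_behavior_map(ra2, rb2, beh2, shift = 0, window = 0.05,
                               bin_width = 10, min_count = 3)
    expect_equal(got$count, want$count)
    expect_equal(got$map, want$map, tolerance = 1e-12)
  }
})

test_that("bin means weighted by counts reconstruct the global mean", {
  set.seed(3)
  ra <- time_series(rnorm(5000, 50, 15), 100)
  rb <- time_series(rnorm(5000, 50, 15), 100)
  beh <- time_series(rnorm(5000, 10, 40), 100)
  m <- binned_behavior_map(ra, rb, beh, min_count = 0)
  ok <- m$count > 0
  expect_equal(sum(m$map[ok] * m$count[ok]) / sum(m$count),
               mean(m$windows$behavior), tolerance = 1e-12)
})

test_that("right-left difference tuning recovers slope and nulls", {
  set.seed(4)
  n <- 30000
  l <- time_series(rnorm(n, 50, 12), 100)
  r <- time_series(rnorm(n, 50, 12), 100)
  # v_r = 2 * (shifted) difference exactly
  vr <- time_series(2 * (steerlab:::shift_forward(l, 0.15)$values -
                         steerlab:::shift_forward(r, 0.15)$values), 100)
  fit <- suppressWarnings(rl_difference_tuning(l, r, vr))
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)

  # independent rotational velocity: slope CI covers zero
  vr0 <- time_series(rnorm(n, 0, 100), 100)
  fit0 <- rl_difference_tuning(l, r, vr0)
  expect_true(fit0$slope_ci[1] < 0 && fit0$slope_ci[2] > 0)

  # see-saw simulator: binned curve monotone non-decreasing
  cfg <- sim_config(duration = 300, immobility_bout_rate = 0,
                    simulate_voltage = FALSE, seed = 5)
  s <- simulate_steering_session(cfg)
  vr_s <- kin_channel(s$kinematics, "v_r")
  tun <- rl_difference_tuning(s$true_rate$left, s$true_rate$right, vr_s)
  curve <- tun$curve[tun$curve$count >= 100, ]
  expect_gt(tun$slope, 0)
  expect_gt(cor(curve$delta, curve$mean_v_r, method = "spearman"), 0.9)
  expect_true(all(diff(curve$mean_v_r) > -10))  # monotone up to bin noise
})
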