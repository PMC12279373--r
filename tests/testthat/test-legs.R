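test_that("body velocities decompose translation and rotation", {
  # pure translation along the body axis at 5 mm/s
  nf <- 400; rate <- 400
  tt <- (0:(nf - 1)) / rate
  df <- data.frame(head_x = 5 * tt + 1.25, head_y = 0,
                   ab_x = 5 * tt - 1.25, ab_y = 0)
  for (leg in c("L1", "L2", "L3", "R1", "R2", "R3")) {
    df[[paste0(leg, "_x")]] <- 5 * tt
    df[[paste0(leg, "_y")]] <- 0.8
  }
  bv <- body_velocities(pose_track(df, rate))
  expect_equal(mean(bv$forward), 5, tolerance = 1e-9)
  expect_equal(mean(bv$sideways), 0, tolerance = 1e-9)
  expect_equal(mean(bv$rotational), 0, tolerance = 1e-9)
  expect_true(all(bv$keep))

  # pure rotation about the centroid at 30 deg/s: window discarded
  a <- 30 * pi / 180 * tt
  dfr <- data.frame(head_x = 1.25 * cos(a), head_y = 1.25 * sin(a),
                    ab_x = -1.25 * cos(a), ab_y = -1.25 * sin(a))
  for (leg in c("L1", "L2", "L3", "R1", "R2", "R3")) {
    dfr[[paste0(leg, "_x")]] <- 0.8; dfr[[paste0(leg, "_y")]] <- 0.8
  }
  bvr <- body_velocities(pose_track(dfr, rate))
  expect_equal(mean(bvr$rotational), 30, tolerance = 0.01)
  expect_false(any(bvr$keep))

  # scripted curvature on the gait generator: rotational speed within 5%
  g <- simulate_gait(turn = list(rotation_dps = 40, inner_side = "R"))
  bvg <- body_velocities(g)
  expect_equal(mean(bvg$rotational), 40, tolerance = 0.05)
})

test_that("swing/stance labeling thresholds the smoothed limb speed", {
  g <- simulate_gait()
  lab <- label_swing_stance(g)
  # stationary epochs exist and durations match the scripted stance time
  truth <- attr(g, "truth")
  ep <- lab$epochs[lab$epochs$complete & lab$epochs$leg == "L2" &
                   lab$epochs$phase == "stance", ]
  dur <- (ep$end - ep$start) / g$rate
  expect_equal(mean(dur), truth$stance_duration_s[["L2"]], tolerance = 0.03)

  # square-wave speed: epochs match the wave edges within one frame
  nf <- 1000; rate <- 100
  x <- numeric(nf)
  moving <- rep(rep(c(FALSE, TRUE), each = 100), 5)
  x <- cumsum(ifelse(moving, 30 / rate, 0))
  df <- data.frame(head_x = rep(1.25, nf), head_y = 0, ab_x = -1.25, ab_y = 0)
  for (leg in c("L1", "L2", "L3", "R1", "R2", "R3")) {
    df[[paste0(leg, "_x")]] <- x; df[[paste0(leg, "_y")]] <- 0
  }
  lab2 <- label_swing_stance(pose_track(df, rate))
  on <- which(!lab2$stance[-nf, "L1"] & lab2$stance[-1, "L1"]) + 1L
  expected_on <- seq(201, 1000, by = 200)
  expect_true(all(abs(on - expected_on) <= 2))

  # stationary leg: all stance
  df0 <- df
  for (leg in c("L1", "L2", "L3", "R1", "R2", "R3")) {
    df0[[paste0(leg, "_x")]] <- 0.8
  }
  lab0 <- label_swing_stance(pose_track(df0, rate))
  expect_true(all(lab0$stance))
})

test_that("rotation events replicate the brute-force scan", {
  expect_equal(nrow(detect_rotation_events(time_series(rep(0, 1000), 100))), 0)

  single <- time_series(c(rep(0, 200), rep(30, 100), rep(0, 300)), 100)
  ev <- detect_rotation_events(single)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$crossing_time, 2)
  expect_equal(ev$start, 1.9)
  expect_equal(ev$end, 2.4)

  for (seed in 1:10) {
    set.seed(seed)
    x <- pmax(0, 25 * sin(2 * pi * (0:2999) / 500) + rnorm(3000, 0, 6))
    got <- detect_rotation_events(time_series(x, 100))
    # independent scan
    above <- x > 20
    r <- rle(above); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    want <- starts[r$values & r$lengths >= 10]
    want_t <- (want - 1) / 100
    want_t <- want_t[want_t - 0.1 >= 0 & want_t + 0.4 <= (3000 - 1) / 100]
    expect_equal(got$crossing_time, want_t)
  }
})

test_that("turning metrics sit at their null values for symmetric gait", {
  g <- simulate_gait()
  tm <- turn_metrics(g, inner_side = "R")
  expect_lt(abs(tm$metrics[["stance_direction"]]), 1)
  expect_lt(abs(tm$metrics[["swing_direction"]]), 1)
  expect_equal(tm$metrics[["swing_distance_ratio"]], 1, tolerance = 0.02)
  expect_equal(tm$metrics[["stance_duration_ratio"]], 1, tolerance = 0.02)
  nominal_swing <- (1 - attr(g, "truth")$duty) / attr(g, "truth")$stride_hz
  expect_equal(tm$metrics[["swing_duration"]], nominal_swing, tolerance = 0.05)
  expect_length(tm$omitted, 0)
})

test_that("iB stance prolongation is recovered by the duration ratio", {
  g <- simulate_gait(turn = list(ib_stance_factor = 1.5))
  tm <- turn_metrics(g, inner_side = "R")
  expect_equal(tm$metrics[["stance_duration_ratio"]], 1.5, tolerance = 0.05)
})

test_that("windows missing a relevant epoch are omitted with a reason", {
  g <- simulate_gait(n_strides = 24)
  # a slice too short to hold any complete oM swing epoch
  short <- pose_track(g$df[1:30, ], rate = g$rate)
  tm <- turn_metrics(short, inner_side = "R")
  expect_true(is.na(tm$metrics[["swing_distance_ratio"]]))
  expect_true("swing_distance_ratio" %in% names(tm$omitted))
})

test_that("mirror reflection swaps sides and negates direction metrics", {
  g <- simulate_gait(turn = list(rotation_dps = 40, inner_side = "R"))
  tm <- turn_metrics(g)
  expect_equal(tm$inner_side, "R")
  df <- g$df
  for (cname in grep("_y$", names(df), value = TRUE)) df[[cname]] <- -df[[cname]]
  names(df) <- chartr("LR", "RL", names(df))
  tmm <- turn_metrics(pose_track(df, g$rate))
  expect_equal(tmm$inner_side, "L")
  expect_equal(tmm$metrics[["stance_direction"]],
               -tm$metrics[["stance_direction"]], tolerance = 1e-9)
  expect_equal(tmm$metrics[["swing_direction"]],
               -tm$metrics[["swing_direction"]], tolerance = 1e-9)
  expect_equal(tmm$metrics[["swing_distance_ratio"]],
               tm$metrics[["swing_distance_ratio"]], tolerance = 1e-9)
  expect_equal(tmm$metrics[["stance_duration_ratio"]],
               tm$metrics[["stance_duration_ratio"]], tolerance = 1e-9)
})

test_that("windowed gait statistics recover the scripted stride", {
  g <- simulate_gait()   # 4 Hz stride, 2 mm steps
  gs <- window_gait_stats(g)
  kept <- gs[gs$keep, ]
  expect_gt(nrow(kept), 10)
  expect_equal(mean(kept$step_frequency), 4, tolerance = 0.02)
  expect_equal(mean(kept$step_length), 2, tolerance = 0.04)
  expect_equal(mean(kept$forward), 8, tolerance = 0.02)

  # static pose: no complete stride anywhere, every window flagged out
  df0 <- g$df[1:401, ]
  for (cname in setdiff(names(df0), "t")) df0[[cname]] <- df0[[cname]][1]
  gs0 <- window_gait_stats(pose_track(df0, g$rate))
  expect_false(any(gs0$keep))
  expect_true(all(gs0$n_strides == 0))
})
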