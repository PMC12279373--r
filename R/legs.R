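#' Pose track from keypoint tables
#'
#' Per-frame 2D positions (mm, camera frame) of the head, abdomen tip and the
#' six tarsi. Legs are named by side and segment: `L1`/`R1` front, `L2`/`R2`
#' middle, `L3`/`R3` back; inner/outer assignment happens per analysis window
#' from the sign of the net rotation.
#'
#' @param df Data.frame with columns `head_x, head_y, ab_x, ab_y` and
#'   `<leg>_x, <leg>_y` for legs L1, L2, L3, R1, R2, R3.
#' @param rate Frame rate in Hz.
#' @return A `pose_track`.
#' @export
pose_track <- function(df, rate) {
  legs <- c("L1", "L2", "L3", "R1", "R2", "R3")
  need <- c("head_x", "head_y", "ab_x", "ab_y",
            paste0(rep(legs, each = 2), c("_x", "_y")))
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing pose columns: ", paste(missing, collapse = ", "))
  structure(list(df = df, rate = rate, legs = legs), class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames @ %g Hz, 8 keypoints\n", nrow(x$df), x$rate))
  invisible(x)
}

LEG_SEGMENTS <- c("1" = "F", "2" = "M", "3" = "B")

# body axis angle per frame (radians; 0 = +x, counterclockwise positive)
body_angle <- function(p) {
  with(p$df, atan2(head_y - ab_y, head_x - ab_x))
}

unwrap_rad <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}

#' Body velocities from the head-abdomen vector
#'
#' The body axis is the head minus abdomen-tip vector. Per frame, forward
#' velocity is the centroid velocity component along the axis, sideways speed
#' the unsigned orthogonal component, and rotational speed the unsigned rate
#' of change of the axis angle; all are averaged over non-overlapping windows.
#' Windows whose mean forward velocity is below `min_forward` are flagged
#' discarded.
#'
#' @param p A `pose_track` (positions in mm).
#' @param window Window length in seconds (default 0.5).
#' @param min_forward Minimum forward velocity in mm/s (default 2.0).
#' @return A data.frame per window: `t0`, `forward` (mm/s), `sideways` (mm/s,
#'   >= 0), `rotational` (deg/s, >= 0), `keep`.
#' @export
body_velocities <- function(p, window = 0.5, min_forward = 2.0) {
  stopifnot(inherits(p, "pose_track"))
  df <- p$df
  rate <- p$rate
  cx <- (df$head_x + df$ab_x) / 2
  cy <- (df$head_y + df$ab_y) / 2
  ang <- unwrap_rad(body_angle(p))
  n <- nrow(df)
  vx <- c(diff(cx), NA) * rate
  vy <- c(diff(cy), NA) * rate
  fwd <- vx * cos(ang) + vy * sin(ang)
  side <- abs(-vx * sin(ang) + vy * cos(ang))
  rot <- abs(c(diff(ang), NA)) * rate * 180 / pi
  w <- as.integer(round(window * rate))
  n_win <- (n - 1L) %/% w
  if (n_win < 1) stop("track shorter than one window")
  out <- data.frame(t0 = numeric(n_win), forward = numeric(n_win),
                    sideways = numeric(n_win), rotational = numeric(n_win))
  for (k in seq_len(n_win)) {
    idx <- ((k - 1L) * w + 1L):(k * w)
    out$t0[k] <- (idx[1] - 1L) / rate
    out$forward[k] <- mean(fwd[idx], na.rm = TRUE)
    out$sideways[k] <- mean(side[idx], na.rm = TRUE)
    out$rotational[k] <- mean(rot[idx], na.rm = TRUE)
  }
  out$keep <- out$forward >= min_forward
  out
}

#' Label swing and stance per leg
#'
#' A leg is in stance when its smoothed instantaneous camera-frame speed
#' (3-frame moving average) is below `threshold` (default 8 mm/s), otherwise
#' in swing. Contiguous runs become epochs; epochs touching the track edges
#' are flagged incomplete.
#'
#' @param p A `pose_track`.
#' @param threshold Stance speed threshold in mm/s (default 8).
#' @return A list with `stance` (frames x legs logical matrix) and `epochs`
#'   (data.frame: leg, phase, start, end (frame indices), complete).
#' @export
label_swing_stance <- function(p, threshold = 8) {
  stopifnot(inherits(p, "pose_track"))
  df <- p$df
  rate <- p$rate
  n <- nrow(df)
  stance <- matrix(NA, n, length(p$legs), dimnames = list(NULL, p$legs))
  epochs <- list()
  for (leg in p$legs) {
    x <- df[[paste0(leg, "_x")]]
    y <- df[[paste0(leg, "_y")]]
    spd <- c(sqrt(diff(x)^2 + diff(y)^2) * rate, NA)
    spd[n] <- spd[n - 1L]
    sm <- as.numeric(stats::filter(spd, rep(1 / 3, 3), sides = 2))
    sm[is.na(sm)] <- spd[is.na(sm)]
    st <- sm < threshold
    stance[, leg] <- st
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    epochs[[leg]] <- data.frame(
      leg = leg,
      phase = ifelse(r$values, "stance", "swing"),
      start = starts, end = ends,
      complete = starts > 1L & ends < n
    )
  }
  list(stance = stance, epochs = do.call(rbind, c(epochs, make.row.names = FALSE)))
}

#' Detect body-rotation events
#'
#' Searches forward in time for moments where rotational speed exceeds
#' `threshold` and stays above it for at least `min_hold`; extracts a window
#' of `window` seconds starting `pre` seconds before the crossing. The scan
#' resumes after the supra-threshold run.
#'
#' @param rot A `time_series` of rotational speed (deg/s).
#' @param threshold Threshold in deg/s (default 20).
#' @param min_hold Minimum supra-threshold duration in seconds (default 0.1).
#' @param window Extracted window length in seconds (default 0.5).
#' @param pre Lead before the crossing in seconds (default 0.1).
#' @return A data.frame: `crossing_time`, `start`, `end` (seconds).
#' @export
detect_rotation_events <- function(rot, threshold = 20, min_hold = 0.1,
                                   window = 0.5, pre = 0.1) {
  assert_ts(rot, "rot")
  x <- rot$values
  n <- length(x)
  rate <- rot$rate
  hold <- as.integer(round(min_hold * rate))
  above <- x > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= hold)
  rows <- list()
  for (i in sel) {
    cross <- starts[i]
    s <- (cross - 1L) / rate - pre
    if (s < 0 || s + window > (n - 1L) / rate) next
    rows[[length(rows) + 1L]] <- data.frame(
      crossing_time = rot$t0 + (cross - 1L) / rate,
      start = rot$t0 + s, end = rot$t0 + s + window
    )
  }
  if (!length(rows)) {
    return(data.frame(crossing_time = numeric(0), start = numeric(0),
                      end = numeric(0)))
  }
  do.call(rbind, rows)
}

# wrap degrees into (-180, 180]
wrap_deg <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# Displacement direction of a leg over an epoch, in body-centric coordinates.
# reference: "backward" for stance (0 deg = straight backward along the body
# axis), "forward" for swing. Positive angles = motion toward the fly's right,
# so stance directions are positive during left turns (and mirror-reflection
# of the arena negates them).
epoch_direction <- function(p, leg, start, end, reference = c("backward", "forward")) {
  reference <- match.arg(reference)
  df <- p$df
  ang <- body_angle(p)
  cx <- (df$head_x + df$ab_x) / 2
  cy <- (df$head_y + df$ab_y) / 2
  # tarsus position in the body frame (origin = centroid, +x = forward,
  # +y = fly's left) at one frame
  body_xy <- function(i) {
    rx <- df[[paste0(leg, "_x")]][i] - cx[i]
    ry <- df[[paste0(leg, "_y")]][i] - cy[i]
    a <- ang[i]
    c(rx * cos(-a) - ry * sin(-a), rx * sin(-a) + ry * cos(-a))
  }
  d <- body_xy(end) - body_xy(start)
  alpha <- atan2(d[2], d[1]) * 180 / pi
  if (reference == "backward") wrap_deg(alpha - 180) else wrap_deg(-alpha)
}

epoch_distance <- function(p, leg, start, end) {
  df <- p$df
  dx <- df[[paste0(leg, "_x")]][end] - df[[paste0(leg, "_x")]][start]
  dy <- df[[paste0(leg, "_y")]][end] - df[[paste0(leg, "_y")]][start]
  sqrt(dx^2 + dy^2)
}

# Map side labels to inner/outer given the inner side ("L" or "R").
leg_roles <- function(inner_side) {
  outer_side <- if (inner_side == "L") "R" else "L"
  roles <- c(iF = paste0(inner_side, "1"), iM = paste0(inner_side, "2"),
             iB = paste0(inner_side, "3"), oF = paste0(outer_side, "1"),
             oM = paste0(outer_side, "2"), oB = paste0(outer_side, "3"))
  roles
}

#' Five turning metrics for one rotation-event window
#'
#' Computes, on a window of pose data with labeled swing/stance epochs, the
#' five multi-leg turning metrics: stance direction (mean over stance epochs
#' of the oF, iF, iM legs; 0 deg = straight backward), swing direction (mean
#' over swing epochs of the same legs; 0 deg = straight forward; set
#' `literal_swing = TRUE` to reproduce the literal stance-epoch reading),
#' swing distance ratio (mean swing distance of oF and oM over that of iM and
#' iB), stance duration ratio (iB stance duration over the mean of iF, oF,
#' oM, oB), and swing duration (mean swing duration of iM and iB, seconds).
#' Only epochs complete within the window count; if any involved leg lacks a
#' complete relevant epoch, that metric is `NA` with the missing legs named.
#'
#' @param p A `pose_track` restricted to the analysis window.
#' @param inner_side `"L"` or `"R"`: the side the fly turns toward. If `NULL`,
#'   inferred from the sign of the window's net body rotation.
#' @param threshold Stance speed threshold in mm/s (default 8).
#' @param literal_swing Use stance epochs for the swing-direction metric.
#' @return A list: `metrics` (named numeric: stance_direction,
#'   swing_direction, swing_distance_ratio, stance_duration_ratio,
#'   swing_duration), `inner_side`, `omitted` (named character reasons).
#' @export
turn_metrics <- function(p, inner_side = NULL, threshold = 8,
                         literal_swing = FALSE) {
  stopifnot(inherits(p, "pose_track"))
  if (is.null(inner_side)) {
    ang <- unwrap_rad(body_angle(p))
    net <- ang[length(ang)] - ang[1]
    # positive (counterclockwise) body rotation = left turn
    inner_side <- if (net >= 0) "L" else "R"
  }
  roles <- leg_roles(inner_side)
  lab <- label_swing_stance(p, threshold = threshold)
  ep <- lab$epochs[lab$epochs$complete, , drop = FALSE]
  rate <- p$rate
  get_epochs <- function(role, phase) {
    ep[ep$leg == roles[[role]] & ep$phase == phase, , drop = FALSE]
  }
  mean_over_epochs <- function(rolelist, phase, fn) {
    vals <- c(); missing <- c()
    for (role in rolelist) {
      e <- get_epochs(role, phase)
      if (nrow(e) == 0) { missing <- c(missing, role); next }
      vals <- c(vals, vapply(seq_len(nrow(e)),
                             function(i) fn(roles[[role]], e$start[i], e$end[i]),
                             numeric(1)))
    }
    list(value = if (length(missing)) NA_real_ else mean(vals), missing = missing)
  }
  omitted <- character(0)
  dir_fn <- function(leg, s, e) epoch_direction(p, leg, s, e, "backward")
  swing_dir_fn <- function(leg, s, e) epoch_direction(p, leg, s, e, "forward")
  dist_fn <- function(leg, s, e) epoch_distance(p, leg, s, e)
  dur_fn <- function(leg, s, e) (e - s) / rate

  m1 <- mean_over_epochs(c("oF", "iF", "iM"), "stance", dir_fn)
  if (length(m1$missing)) omitted["stance_direction"] <-
    paste("no complete stance epoch:", paste(m1$missing, collapse = ","))

  swing_phase <- if (literal_swing) "stance" else "swing"
  swing_fn <- if (literal_swing) dir_fn else swing_dir_fn
  m2 <- mean_over_epochs(c("oF", "iF", "iM"), swing_phase, swing_fn)
  if (length(m2$missing)) omitted["swing_direction"] <-
    paste("no complete epoch:", paste(m2$missing, collapse = ","))

  num <- mean_over_epochs(c("oF", "oM"), "swing", dist_fn)
  den <- mean_over_epochs(c("iM", "iB"), "swing", dist_fn)
  m3 <- if (is.na(num$value) || is.na(den$value)) NA_real_ else num$value / den$value
  if (is.na(m3)) omitted["swing_distance_ratio"] <-
    paste("no complete swing epoch:", paste(c(num$missing, den$missing), collapse = ","))

  num4 <- mean_over_epochs("iB", "stance", dur_fn)
  den4 <- mean_over_epochs(c("iF", "oF", "oM", "oB"), "stance", dur_fn)
  m4 <- if (is.na(num4$value) || is.na(den4$value)) NA_real_ else num4$value / den4$value
  if (is.na(m4)) omitted["stance_duration_ratio"] <-
    paste("no complete stance epoch:", paste(c(num4$missing, den4$missing), collapse = ","))

  m5 <- mean_over_epochs(c("iM", "iB"), "swing", dur_fn)
  if (length(m5$missing)) omitted["swing_duration"] <-
    paste("no complete swing epoch:", paste(m5$missing, collapse = ","))

  list(
    metrics = c(stance_direction = m1$value, swing_direction = m2$value,
                swing_distance_ratio = m3, stance_duration_ratio = m4,
                swing_duration = m5$value),
    inner_side = inner_side,
    omitted = omitted
  )
}

#' Windowed gait statistics
#'
#' Per non-overlapping window: step frequency (inverse of the stride period,
#' stance onset to next stance onset, averaged over all complete strides of
#' all six legs), step length (net tarsus displacement over those strides),
#' and forward velocity of the body axis. Windows with mean forward velocity
#' below `min_forward` or with no complete stride are flagged.
#'
#' @param p A `pose_track`.
#' @param window Window length in seconds (default 0.5).
#' @param threshold Stance speed threshold in mm/s (default 8).
#' @param min_forward Minimum forward velocity in mm/s (default 2.0).
#' @return A data.frame per window: `t0`, `step_frequency` (Hz), `step_length`
#'   (mm), `forward` (mm/s), `n_strides`, `keep`.
#' @export
window_gait_stats <- function(p, window = 0.5, threshold = 8, min_forward = 2.0) {
  stopifnot(inherits(p, "pose_track"))
  rate <- p$rate
  n <- nrow(p$df)
  lab <- label_swing_stance(p, threshold = threshold)
  # stance onsets per leg (frame indices)
  onsets <- lapply(p$legs, function(leg) {
    st <- lab$stance[, leg]
    which(!st[-n] & st[-1]) + 1L
  })
  names(onsets) <- p$legs
  bv <- body_velocities(p, window = window, min_forward = min_forward)
  w <- as.integer(round(window * rate))
  out <- bv
  out$step_frequency <- NA_real_
  out$step_length <- NA_real_
  out$n_strides <- 0L
  for (k in seq_len(nrow(out))) {
    lo <- (k - 1L) * w + 1L
    hi <- k * w
    freqs <- c(); lens <- c()
    for (leg in p$legs) {
      on <- onsets[[leg]]
      on_in <- on[on >= lo & on <= hi]
      if (length(on_in) < 2) next
      for (j in seq_len(length(on_in) - 1L)) {
        s <- on_in[j]; e <- on_in[j + 1L]
        freqs <- c(freqs, rate / (e - s))
        lens <- c(lens, epoch_distance(p, leg, s, e))
      }
    }
    if (length(freqs)) {
      out$step_frequency[k] <- mean(freqs)
      out$step_length[k] <- mean(lens)
      out$n_strides[k] <- length(freqs)
    }
  }
  out$keep <- out$keep & out$n_strides > 0L
  out[, c("t0", "step_frequency", "step_length", "forward", "n_strides", "keep")]
}
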