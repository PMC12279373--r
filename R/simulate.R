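# Synthetic-data generators: seeded, ground-truth-carrying emulations of every
# input modality the pipeline consumes (treadmill kinematics coupled to two
# descending-neuron firing rates, raw intracellular voltage, eight-sector bump
# movies, six-leg gait keypoints, synapse tables).

#' Ground-truth steering kernel shapes
#'
#' Canonical linear-filter shapes linking a cell's centered firing rate
#' (spikes/s) to a kinematic channel (deg/s): `monophasic` is a single-lobed
#' alpha function (low-gain, sustained steering), `biphasic` a fast positive
#' lobe followed by a slower negative lobe (high-gain, transient steering).
#' Values are per-sample convolution weights on the kinematics time base.
#'
#' @param shape `"monophasic"` or `"biphasic"`.
#' @param rate Sampling rate in Hz (default 100).
#' @param peak Peak absolute gain, (deg/s)/(spikes/s) per sample.
#' @param support Kernel support in seconds (must be <= 4).
#' @return Numeric vector of kernel weights (lag 0 first).
#' @export
steering_kernel <- function(shape = c("monophasic", "biphasic"), rate = 100,
                            peak = 0.25, support = 1.5) {
  shape <- match.arg(shape)
  if (support > 4) stop("kernel support must be <= 4 s")
  t <- seq(0, support, by = 1 / rate)
  alpha_fn <- function(tau) (t / tau) * exp(1 - t / tau)
  k <- switch(shape,
    monophasic = alpha_fn(0.15),
    # fast positive lobe, slower shallow undershoot; net area positive so a
    # sustained rate increase still drives a net ipsiversive turn
    biphasic = alpha_fn(0.08) - 0.2 * alpha_fn(0.30)
  )
  k * peak / max(abs(k))
}

#' Configuration of a synthetic steering session
#'
#' Defines the generative model: one latent steering drive feeds a right/left
#' pair of descending-neuron firing rates whose anticorrelation is set by
#' `seesaw_coupling`; each kinematic axis is the sum over cells of a known
#' linear kernel convolved with the centered rate, plus Gaussian noise; spikes
#' are an inhomogeneous Poisson process given the rate; raw voltage is a
#' spline-interpolated subthreshold potential plus a stereotyped 2 ms biphasic
#' spike waveform and noise. Immobility bouts gate the drive multiplicatively
#' (kinematics ~ 0) and hyperpolarize the cells (rates suppressed below
#' baseline).
#'
#' @param duration Session length in seconds.
#' @param kinematics_rate Kinematics rate in Hz (default 100).
#' @param voltage_rate Voltage rate in Hz (default 10000).
#' @param cells Character vector of cell names (default `c("right", "left")`).
#' @param ground_truth_filters Named list `"<cell>.<axis>"` -> kernel (lag-0
#'   first, on the kinematics time base, support <= 4 s). Default: biphasic
#'   rotational kernels of opposite sign for the two cells, smaller monophasic
#'   sideways kernels, and same-sign monophasic forward kernels.
#' @param baseline_rate Baseline firing rate, spikes/s (default 40).
#' @param drive_gain Firing-rate excursion per unit latent drive, spikes/s
#'   (default 12).
#' @param drive_tau Latent-drive correlation time in seconds (default 0.5).
#' @param seesaw_coupling Right-left anticorrelation in [0, 1] (default 0.6).
#' @param noise_sd Named per-axis kinematic noise SD in deg/s.
#' @param immobility_bout_rate Immobility bouts per minute (default 2).
#' @param immobility_bout_duration Mean bout length in seconds (default 1.5).
#' @param immobility_suppression Fraction of baseline rate retained during
#'   bouts (default 0.2).
#' @param refractory Spike refractory period in seconds (default 2e-3);
#'   enforced by thinning.
#' @param v_rest Resting potential in mV (default -55).
#' @param vm_gain Subthreshold mV per (spikes/s) of rate excursion (0.15).
#' @param vm_hyperpol Immobility hyperpolarization in mV (default 8).
#' @param spike_amp_mV Spike waveform amplitude in mV (default 40).
#' @param voltage_noise_sd Voltage noise SD in mV (default 2; the waveform
#'   amplitude over this SD is the detection SNR knob).
#' @param simulate_voltage Generate raw voltage traces (default TRUE; skip for
#'   speed when only rates/kinematics are needed).
#' @param seed Integer seed; equal seeds give bit-identical sessions.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration = 600, kinematics_rate = 100,
                       voltage_rate = 10000, cells = c("right", "left"),
                       ground_truth_filters = NULL, baseline_rate = 40,
                       drive_gain = 12, drive_tau = 0.5, seesaw_coupling = 0.6,
                       noise_sd = c(v_r = 20, v_s = 8, v_f = 10),
                       immobility_bout_rate = 2, immobility_bout_duration = 1.5,
                       immobility_suppression = 0.2, refractory = 2e-3,
                       v_rest = -55, vm_gain = 0.15, vm_hyperpol = 8,
                       spike_amp_mV = 40, voltage_noise_sd = 2,
                       simulate_voltage = TRUE, seed = 1) {
  vals <- c(duration, kinematics_rate, voltage_rate, baseline_rate, drive_gain,
            drive_tau, seesaw_coupling, noise_sd, immobility_bout_rate,
            immobility_bout_duration)
  if (any(!is.finite(vals))) stop("non-finite config values")
  stopifnot(duration > 0, kinematics_rate > 0, voltage_rate > 0,
            baseline_rate > 0)
  if (seesaw_coupling < 0 || seesaw_coupling > 1) {
    stop("seesaw_coupling must lie in [0, 1]")
  }
  if (is.null(ground_truth_filters)) {
    r <- kinematics_rate
    ground_truth_filters <- list()
    # rotational/sideways sign convention: positive v_r = leftward
    # (counterclockwise) rotation, so the left cell carries positive kernels
    signs <- stats::setNames(rep(1, length(cells)), cells)
    if ("right" %in% cells) signs["right"] <- -1
    for (cell in cells) {
      ground_truth_filters[[paste0(cell, ".v_r")]] <-
        signs[[cell]] * steering_kernel("biphasic", r, peak = 0.25)
      ground_truth_filters[[paste0(cell, ".v_s")]] <-
        signs[[cell]] * steering_kernel("monophasic", r, peak = 0.08)
      ground_truth_filters[[paste0(cell, ".v_f")]] <-
        steering_kernel("monophasic", r, peak = 0.12, support = 2)
    }
  }
  for (k in names(ground_truth_filters)) {
    kern <- ground_truth_filters[[k]]
    if (length(kern) / kinematics_rate > 4) stop("kernel support > 4 s: ", k)
    if (length(kern) / kinematics_rate > duration) {
      stop("kernel support exceeds the session duration: ", k)
    }
  }
  structure(list(
    duration = duration, kinematics_rate = kinematics_rate,
    voltage_rate = voltage_rate, cells = cells,
    ground_truth_filters = ground_truth_filters, baseline_rate = baseline_rate,
    drive_gain = drive_gain, drive_tau = drive_tau,
    seesaw_coupling = seesaw_coupling, noise_sd = noise_sd,
    immobility_bout_rate = immobility_bout_rate,
    immobility_bout_duration = immobility_bout_duration,
    immobility_suppression = immobility_suppression, refractory = refractory,
    v_rest = v_rest, vm_gain = vm_gain, vm_hyperpol = vm_hyperpol,
    spike_amp_mV = spike_amp_mV, voltage_noise_sd = voltage_noise_sd,
    simulate_voltage = simulate_voltage, seed = seed
  ), class = "sim_config")
}

# Ornstein-Uhlenbeck noise, stationary unit variance.
ou_process <- function(n, dt, tau) {
  a <- exp(-dt / tau)
  innov <- stats::rnorm(n, sd = sqrt(1 - a^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  x <- as.numeric(stats::filter(innov, a, method = "recursive", init = x[1]))
  x
}

# causal convolution, zero-padded history; output length == input length
conv_causal <- function(x, kern) {
  nk <- length(kern)
  xp <- c(numeric(nk - 1L), x)
  y <- stats::filter(xp, kern, method = "convolution", sides = 1)
  as.numeric(y)[nk:(nk - 1L + length(x))]
}

# stereotyped biphasic spike waveform, ~2 ms, unit peak amplitude
spike_waveform <- function(rate) {
  t <- seq(0, 2e-3, by = 1 / rate)
  w <- exp(-((t - 4e-4) / 2e-4)^2) - 0.45 * exp(-((t - 1.1e-3) / 3e-4)^2)
  w / max(w)
}

#' Simulate a steering session
#'
#' Draws a full synthetic recording under a [sim_config()]: latent steering
#' drive, right/left firing rates with see-saw anticorrelation, inhomogeneous
#' Poisson spikes (refractory-thinned), kinematics generated by the
#' ground-truth kernels plus noise, immobility bouts, and (optionally) raw
#' voltage traces with spike waveforms.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_session` list: `kinematics` (`kinematics_trace`),
#'   `true_rate` (named list of `time_series`), `true_spike_times` (named list
#'   of numeric vectors), `voltage` (named list of `time_series` or NULL),
#'   `immobility_bouts` (data.frame onset/offset), `active` (logical vector on
#'   the kinematics time base), `truth` (the config).
#' @export
simulate_steering_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rate <- config$kinematics_rate
  n <- as.integer(round(config$duration * rate))
  dt <- 1 / rate

  # latent drives: shared steering component + per-cell private components
  c2 <- config$seesaw_coupling
  s <- ou_process(n, dt, config$drive_tau)
  drives <- list()
  for (cell in config$cells) {
    u <- ou_process(n, dt, config$drive_tau)
    sgn <- if (cell == "left") -1 else 1
    drives[[cell]] <- sgn * sqrt(c2) * s + sqrt(1 - c2) * u
  }

  # immobility bouts: Poisson onsets, exponential durations
  gate <- rep(1, n)
  bouts <- data.frame(onset = numeric(0), offset = numeric(0))
  if (config$immobility_bout_rate > 0) {
    n_bouts <- stats::rpois(1, config$immobility_bout_rate * config$duration / 60)
    if (n_bouts > 0) {
      onsets <- sort(stats::runif(n_bouts, 0, config$duration))
      durs <- stats::rexp(n_bouts, 1 / config$immobility_bout_duration)
      offs <- pmin(onsets + durs, config$duration)
      for (b in seq_len(n_bouts)) {
        i0 <- max(1L, as.integer(onsets[b] * rate) + 1L)
        i1 <- min(n, as.integer(offs[b] * rate) + 1L)
        gate[i0:i1] <- 0
      }
      bouts <- data.frame(onset = onsets, offset = offs)
    }
  }

  base <- config$baseline_rate
  rates <- list(); spikes <- list()
  for (cell in config$cells) {
    active_rate <- pmax(0, base + config$drive_gain * drives[[cell]])
    true_rate <- gate * active_rate + (1 - gate) * config$immobility_suppression * base
    rates[[cell]] <- time_series(true_rate, rate = rate, units = "spikes/s")
    counts <- stats::rpois(n, true_rate * dt)
    times <- rep((seq_len(n) - 1L) * dt, counts) + stats::runif(sum(counts), 0, dt)
    times <- sort(times)
    if (config$refractory > 0 && length(times) > 1) {
      keep <- logical(length(times))
      keep[1] <- TRUE
      last <- times[1]
      for (i in 2:length(times)) {
        if (times[i] - last >= config$refractory) { keep[i] <- TRUE; last <- times[i] }
      }
      times <- times[keep]
    }
    spikes[[cell]] <- times
  }

  # kinematics: sum over cells of kernel (*) centered active rate, then the
  # whole motor output is gated by immobility (a planted fly does not move,
  # so kernel tails from pre-bout drive are silenced too) and Gaussian noise
  # is added, shrunk to sensor-level jitter during bouts
  axes <- list(v_r = numeric(n), v_s = numeric(n), v_f = numeric(n))
  for (cell in config$cells) {
    centered <- gate * (pmax(0, base + config$drive_gain * drives[[cell]]) - base)
    for (ax in names(axes)) {
      key <- paste0(cell, ".", ax)
      kern <- config$ground_truth_filters[[key]]
      if (!is.null(kern)) axes[[ax]] <- axes[[ax]] + conv_causal(centered, kern)
    }
  }
  noise_gate <- gate + 0.02 * (1 - gate)
  for (ax in names(axes)) {
    sd_ax <- config$noise_sd[[ax]]
    axes[[ax]] <- gate * axes[[ax]]
    if (sd_ax > 0) axes[[ax]] <- axes[[ax]] + noise_gate * stats::rnorm(n, sd = sd_ax)
  }
  kin <- kinematics_trace(axes$v_r, axes$v_s, axes$v_f, rate = rate)

  voltage <- NULL
  if (config$simulate_voltage) {
    vr <- config$voltage_rate
    nv <- as.integer(round(config$duration * vr))
    tv <- (seq_len(nv) - 1L) / vr
    tk <- (seq_len(n) - 1L) * dt
    wf <- spike_waveform(vr) * config$spike_amp_mV
    voltage <- list()
    for (cell in config$cells) {
      sub <- config$v_rest + config$vm_gain * (rates[[cell]]$values - base) -
        config$vm_hyperpol * (1 - gate)
      v <- stats::spline(tk, sub, xout = tv)$y
      idx <- as.integer(round(spikes[[cell]] * vr)) + 1L
      for (j in idx) {
        hi <- min(nv, j + length(wf) - 1L)
        span <- j:hi
        v[span] <- v[span] + wf[seq_along(span)]
      }
      v <- v + stats::rnorm(nv, sd = config$voltage_noise_sd)
      voltage[[cell]] <- time_series(v, rate = vr, units = "mV")
    }
  }

  structure(list(
    kinematics = kin, true_rate = rates, true_spike_times = spikes,
    voltage = voltage, immobility_bouts = bouts, active = gate == 1,
    truth = config
  ), class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session> %.0f s, cells: %s, %s voltage, %d immobility bout(s)\n",
    x$truth$duration, paste(x$truth$cells, collapse = "/"),
    if (is.null(x$voltage)) "no" else "with", nrow(x$immobility_bouts)
  ))
  invisible(x)
}

#' Simulate an eight-sector bump movie
#'
#' A von-Mises-shaped activity bump over 8 sectors follows `heading / 45 deg`;
#' scripted jumps displace the bump by a sector offset and, after a dwell, the
#' bump is steered back at a constant return speed (the shortest way). Fades
#' set the bump amplitude to zero for a scripted period. Output is raw
#' fluorescence (baseline plus bump), suitable for [sector_dff()].
#'
#' @param heading A `time_series` of heading in degrees (its rate is the frame
#'   rate).
#' @param jumps List of `list(time, offset, return = TRUE)`: offset in sectors
#'   (positive = counterclockwise).
#' @param width Bump half-width in sectors (default 1.2).
#' @param amplitude Bump amplitude over baseline (default 1).
#' @param baseline Positive fluorescence baseline (default 0.25).
#' @param noise_sd Additive noise SD (default 0).
#' @param return_delay Dwell before the return starts, seconds (default 1).
#' @param return_speed Return speed in sectors/s (default 2).
#' @param fades List of `list(time, duration)` amplitude dropouts.
#' @param f0 Fluorescence scale (default 100).
#' @param seed Optional integer seed.
#' @return A list: `fluorescence` (8 x T matrix), `rate`, `truth` (list with
#'   per-frame `center` (sectors), `offset`, `amp`); attribute `clipped` on
#'   the matrix flags negative values clipped to zero.
#' @export
simulate_bump_movie <- function(heading, jumps = list(), width = 1.2,
                                amplitude = 1, baseline = 0.25, noise_sd = 0,
                                return_delay = 1, return_speed = 2,
                                fades = list(), f0 = 100, seed = NULL) {
  assert_ts(heading, "heading")
  if (!all(is.finite(heading$values))) stop("heading must be finite")
  if (width <= 0) stop("width must be positive")
  if (!is.null(seed)) set.seed(seed)
  rate <- heading$rate
  n <- length(heading$values)
  tt <- ts_time(heading)
  base_center <- heading$values / 45

  # scripted offset trace: step at each jump, constant for return_delay, then
  # ramp back to zero at return_speed
  offset <- numeric(n)
  o <- 0
  last_jump <- -Inf
  returning <- TRUE
  jump_times <- vapply(jumps, function(j) j$time, numeric(1))
  for (i in seq_len(n)) {
    hit <- which(jump_times <= tt[i] & jump_times > tt[i] - 1 / rate)
    for (h in hit) {
      o <- o + jumps[[h]]$offset
      last_jump <- tt[i]
      returning <- !isFALSE(jumps[[h]]$return)
    }
    if (returning && o != 0 && tt[i] - last_jump > return_delay) {
      o <- o - sign(o) * min(return_speed / rate, abs(o))
    }
    offset[i] <- o
  }

  amp <- rep(amplitude, n)
  for (f in fades) {
    amp[tt >= f$time & tt < f$time + f$duration] <- 0
  }

  center <- (base_center + offset) %% 8
  kappa <- 1 / (width * pi / 4)^2
  sect <- 0:7
  mat <- matrix(0, 8, n)
  for (i in seq_len(n)) {
    mat[, i] <- baseline + amp[i] * exp(kappa * (cos(2 * pi * (sect - center[i]) / 8) - 1))
  }
  if (noise_sd > 0) mat <- mat + matrix(stats::rnorm(8 * n, sd = noise_sd), 8, n)
  clipped <- any(mat < 0)
  mat[mat < 0] <- 0
  fl <- f0 * mat
  attr(fl, "clipped") <- clipped
  list(fluorescence = fl, rate = rate,
       truth = list(center = center, offset = offset, amp = amp))
}

#' Simulate six-leg tripod gait keypoints
#'
#' Alternating-tripod gait with configurable turning asymmetries: the inner
#' back (iB) leg's stance can be prolonged, inner/outer swing (step) distances
#' scaled, and a constant body rotation imposed. Legs are planted in the world
#' during stance and swing linearly to the next touchdown, so swing/stance
#' labels, durations and distances have exact ground truth.
#'
#' @param n_strides Number of stride cycles (default 24).
#' @param stride_hz Stride frequency in Hz (default 4).
#' @param step_len Base step length in mm (default 2).
#' @param frame_rate Frame rate in Hz (default 400).
#' @param duty Stance fraction of the cycle (default 0.55).
#' @param turn List of asymmetries: `ib_stance_factor` (default 1),
#'   `outer_swing_scale`, `inner_swing_scale` (default 1),
#'   `rotation_dps` (deg/s, default 0), `inner_side` ("R" or "L").
#' @param body_len Head-to-abdomen distance in mm (default 2.5).
#' @param noise_mm Keypoint jitter SD in mm (default 0).
#' @param seed Optional integer seed (used when `noise_mm > 0`).
#' @return A `pose_track`; attribute `truth` carries the turn configuration
#'   and per-leg stance durations in seconds.
#' @export
simulate_gait <- function(n_strides = 24, stride_hz = 4, step_len = 2,
                          frame_rate = 400, duty = 0.55, turn = list(),
                          body_len = 2.5, noise_mm = 0, seed = NULL) {
  turn <- utils::modifyList(list(ib_stance_factor = 1, outer_swing_scale = 1,
                                 inner_swing_scale = 1, rotation_dps = 0,
                                 inner_side = "R"), turn)
  if (!is.null(seed)) set.seed(seed)
  T_cyc <- 1 / stride_hz
  dur <- n_strides * T_cyc
  nf <- as.integer(round(dur * frame_rate))
  tt <- (seq_len(nf) - 1L) / frame_rate
  v <- step_len * stride_hz
  # body rotation: inner side R = clockwise = negative angle rate
  omega <- turn$rotation_dps * pi / 180 * (if (turn$inner_side == "R") -1 else 1)
  phi <- function(t) omega * t
  pos <- function(t) {
    if (omega == 0) cbind(v * t, 0)
    else cbind(v / omega * sin(omega * t), v / omega * (1 - cos(omega * t)))
  }
  to_world <- function(t, xy_body) {
    p <- pos(t); a <- phi(t)
    cbind(p[, 1] + xy_body[1] * cos(a) - xy_body[2] * sin(a),
          p[, 2] + xy_body[1] * sin(a) + xy_body[2] * cos(a))
  }
  legs <- c("L1", "L2", "L3", "R1", "R2", "R3")
  home <- list(L1 = c(0.8, 0.8), L2 = c(0, 1.0), L3 = c(-0.8, 0.8),
               R1 = c(0.8, -0.8), R2 = c(0, -1.0), R3 = c(-0.8, -0.8))
  phase <- c(L1 = 0.5, L2 = 0, L3 = 0.5, R1 = 0, R2 = 0.5, R3 = 0)
  ib_leg <- paste0(turn$inner_side, "3")
  inner <- paste0(turn$inner_side, 1:3)
  df <- data.frame(t = tt)
  bw <- pos(tt); ba <- phi(tt)
  df$head_x <- bw[, 1] + body_len / 2 * cos(ba)
  df$head_y <- bw[, 2] + body_len / 2 * sin(ba)
  df$ab_x <- bw[, 1] - body_len / 2 * cos(ba)
  df$ab_y <- bw[, 2] - body_len / 2 * sin(ba)
  stance_dur <- stats::setNames(numeric(length(legs)), legs)
  for (leg in legs) {
    duty_leg <- duty * (if (leg == ib_leg) turn$ib_stance_factor else 1)
    if (duty_leg >= 0.98) stop("ib_stance_factor leaves no swing time")
    step_leg <- step_len * (if (leg %in% inner) turn$inner_swing_scale
                            else turn$outer_swing_scale)
    stance_dur[leg] <- duty_leg * T_cyc
    h <- home[[leg]]
    target <- c(h[1] + step_leg / 2, h[2])
    # plant positions at each stance onset
    k_all <- -1:(n_strides + 1)
    t_on <- (k_all + phase[leg]) * T_cyc
    plants <- t(vapply(t_on, function(t0) as.numeric(to_world(t0, target)),
                       numeric(2)))
    k_idx <- floor(tt / T_cyc - phase[leg])
    u <- tt - (k_idx + phase[leg]) * T_cyc
    ki <- match(k_idx, k_all)
    in_stance <- u < duty_leg * T_cyc
    w <- pmin(1, pmax(0, (u - duty_leg * T_cyc) / (T_cyc - duty_leg * T_cyc)))
    px <- plants[ki, 1] * (1 - w) + plants[ki + 1L, 1] * w
    py <- plants[ki, 2] * (1 - w) + plants[ki + 1L, 2] * w
    px[in_stance] <- plants[ki[in_stance], 1]
    py[in_stance] <- plants[ki[in_stance], 2]
    if (noise_mm > 0) {
      px <- px + stats::rnorm(nf, sd = noise_mm)
      py <- py + stats::rnorm(nf, sd = noise_mm)
    }
    df[[paste0(leg, "_x")]] <- px
    df[[paste0(leg, "_y")]] <- py
  }
  out <- pose_track(df, rate = frame_rate)
  attr(out, "truth") <- c(turn, list(stance_duration_s = stance_dur,
                                     stride_hz = stride_hz,
                                     step_len = step_len, duty = duty))
  out
}

#' Simulate a cell-type-labeled synapse table
#'
#' Generates unitary connections per specification row: every presynaptic cell
#' of the pre type contacts every postsynaptic cell of the post type on the
#' same side, with a synapse count drawn from the stated distribution.
#'
#' @param spec Data.frame with columns `pre_type`, `post_type`, `n_pre`,
#'   `n_post` (cells per side), `mean_synapses`, and optionally `dist`
#'   (`"fixed"` or `"poisson"`, default `"fixed"`).
#' @param seed Optional integer seed.
#' @return A `synapse_table`.
#' @export
simulate_connectivity <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(pre_id = character(0), pre_type = character(0),
                      pre_side = character(0), post_id = character(0),
                      post_type = character(0), post_side = character(0),
                      count = numeric(0))
  if (is.null(spec) || nrow(spec) == 0) return(synapse_table(empty))
  if (is.null(spec$dist)) spec$dist <- "fixed"
  rows <- list()
  for (r in seq_len(nrow(spec))) {
    for (side in c("L", "R")) {
      pre_ids <- sprintf("%s_%s_%d", spec$pre_type[r], side, seq_len(spec$n_pre[r]))
      post_ids <- sprintf("%s_%s_%d", spec$post_type[r], side, seq_len(spec$n_post[r]))
      grid <- expand.grid(pre_id = pre_ids, post_id = post_ids,
                          stringsAsFactors = FALSE)
      cnt <- if (spec$dist[r] == "poisson") {
        stats::rpois(nrow(grid), spec$mean_synapses[r])
      } else {
        rep(spec$mean_synapses[r], nrow(grid))
      }
      keep <- cnt >= 1
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pre_id = grid$pre_id[keep], pre_type = spec$pre_type[r],
        pre_side = side, post_id = grid$post_id[keep],
        post_type = spec$post_type[r], post_side = side, count = cnt[keep]
      )
    }
  }
  if (!length(rows)) return(synapse_table(empty))
  synapse_table(do.call(rbind, rows))
}
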