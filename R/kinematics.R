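#' Treadmill kinematics trace
#'
#' Aligned rotational, sideways and forward velocity channels from a spherical
#' treadmill, all in deg/s on a shared uniform time base. Sideways/forward
#' channels can be viewed in mm/s through the ball radius (3.175 mm).
#'
#' @param v_r,v_s,v_f Numeric vectors: rotational, sideways and forward
#'   velocity in deg/s; equal lengths.
#' @param rate Sampling rate in Hz (default 100).
#' @param t0 Start time in seconds.
#' @return A `kinematics_trace`.
#' @export
kinematics_trace <- function(v_r, v_s, v_f, rate = 100, t0 = 0) {
  n <- length(v_r)
  stopifnot(length(v_s) == n, length(v_f) == n, rate > 0)
  if (!all(is.finite(v_r), is.finite(v_s), is.finite(v_f))) {
    stop("kinematics channels must be finite")
  }
  structure(
    list(v_r = as.numeric(v_r), v_s = as.numeric(v_s), v_f = as.numeric(v_f),
         rate = rate, t0 = t0),
    class = "kinematics_trace"
  )
}

#' @export
print.kinematics_trace <- function(x, ...) {
  cat(sprintf("<kinematics_trace> %d samples @ %g Hz (v_r, v_s, v_f in deg/s)\n",
              length(x$v_r), x$rate))
  invisible(x)
}

#' Ball radius (mm) used to convert translational channels to mm/s
#' @export
BALL_RADIUS_MM <- 3.175

#' Extract one kinematic channel as a time series
#' @param k A `kinematics_trace`.
#' @param channel One of `"v_r"`, `"v_s"`, `"v_f"`.
#' @param mm_per_s Convert a translational channel to mm/s via the ball radius.
#' @return A `time_series`.
#' @export
kin_channel <- function(k, channel = c("v_r", "v_s", "v_f"), mm_per_s = FALSE) {
  channel <- match.arg(channel)
  v <- k[[channel]]
  units <- "deg/s"
  if (mm_per_s) {
    if (channel == "v_r") stop("rotational velocity has no mm/s view")
    v <- v * pi / 180 * BALL_RADIUS_MM
    units <- "mm/s"
  }
  time_series(v, rate = k$rate, t0 = k$t0, units = units)
}

#' Correct the zero-point offset of a kinematic channel
#'
#' Treadmill channels carry a small sensor offset. The offset is estimated as
#' the median of samples lying in "periods of inactivity", defined as samples
#' whose instantaneous difference from the previous sample is below a
#' threshold (default 0.025 deg/s), and subtracted globally.
#'
#' @param x A `time_series`.
#' @param diff_threshold Inactivity threshold on |x_i - x_{i-1}| (deg/s).
#' @return A `time_series`; attribute `offset` holds the subtracted value and
#'   attribute `no_inactive` is `TRUE` when no inactive samples were found (in
#'   which case the input is returned unchanged, with a warning).
#' @export
correct_offset <- function(x, diff_threshold = 0.025) {
  assert_ts(x)
  v <- x$values
  if (length(v) < 2) stop("need at least 2 samples")
  if (all(is.na(v))) stop("all-NaN input")
  inactive <- which(abs(diff(v)) < diff_threshold) + 1L
  if (length(inactive) == 0L) {
    warning("no inactive samples below diff threshold; offset not corrected")
    out <- ts_with(x, v)
    attr(out, "offset") <- 0
    attr(out, "no_inactive") <- TRUE
    return(out)
  }
  offset <- stats::median(v[inactive])
  out <- ts_with(x, v - offset)
  attr(out, "offset") <- offset
  attr(out, "no_inactive") <- FALSE
  out
}

#' Light Gaussian smoothing
#'
#' Convolution with a Gaussian kernel truncated at +/- 3.5 sigma and
#' renormalized to unit sum; edges are reflect-padded so the output has the
#' same length and time base as the input.
#'
#' @param x A `time_series`.
#' @param width_s Kernel sigma in seconds (default 0.05, i.e. 50 ms).
#' @return Smoothed `time_series`.
#' @export
smooth_gaussian <- function(x, width_s = 0.05) {
  assert_ts(x)
  if (width_s * x$rate <= 2) stop("kernel width must exceed 2 samples")
  k <- gaussian_kernel(width_s, x$rate)
  ts_with(x, conv_same_reflect(x$values, k))
}

#' Parameters of the random-walk MAP smoother
#'
#' Local-level Gaussian state-space model: the latent path follows a random
#' walk with drift `mu` and innovation variance `(1 - alpha) * sigma2`; the
#' observations add noise of variance `alpha * sigma2`. `alpha` therefore
#' fixes the fraction of signal variance attributed to observation noise.
#'
#' @param alpha Noise fraction, strictly inside (0, 1); default 0.2.
#' @param mu Drift per step; `NULL` to estimate as the mean first difference.
#' @param sigma2 Variance scale; `NULL` to estimate from the increments.
#' @return A `random_walk_params` list.
#' @export
random_walk_params <- function(alpha = 0.2, mu = NULL, sigma2 = NULL) {
  stopifnot(length(alpha) == 1, is.finite(alpha))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly inside (0, 1)")
  structure(list(alpha = alpha, mu = mu, sigma2 = sigma2),
            class = "random_walk_params")
}

# Thomas algorithm for a symmetric tridiagonal system with constant
# off-diagonal `off` and main diagonal `d`.
solve_tridiag_sym <- function(d, off, rhs) {
  n <- length(d)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- off / d[1]
  dp[1] <- rhs[1] / d[1]
  for (i in 2:n) {
    m <- d[i] - off * cp[i - 1]
    cp[i] <- off / m
    dp[i] <- (rhs[i] - off * dp[i - 1]) / m
  }
  z <- numeric(n)
  z[n] <- dp[n]
  for (i in (n - 1):1) z[i] <- dp[i] - cp[i] * z[i + 1]
  z
}

#' MAP smoothing under a Gaussian random-walk model
#'
#' Smooths a signal by taking the maximum a posteriori latent path of the
#' local-level model `z_i ~ N(z_{i-1} + mu, (1 - alpha) sigma2)`,
#' `y_i ~ N(z_i, alpha sigma2)`. Because the model is linear-Gaussian the MAP
#' path equals the posterior mean and solves a symmetric tridiagonal linear
#' system exactly; no iterative optimizer is needed. `sigma2` cancels from the
#' MAP solution (only `alpha` and `mu` matter); it is still estimated and
#' reported for reference.
#'
#' @param y A `time_series`.
#' @param params A [random_walk_params()] object.
#' @return Smoothed `time_series`; attribute `params` carries the `alpha`,
#'   fitted `mu` and `sigma2` actually used.
#' @export
smooth_random_walk_map <- function(y, params = random_walk_params()) {
  assert_ts(y)
  v <- y$values
  n <- length(v)
  if (n < 3) stop("need at least 3 samples")
  alpha <- params$alpha
  mu <- if (is.null(params$mu)) mean(diff(v)) else params$mu
  if (stats::var(v) == 0) {
    out <- ts_with(y, v)
    attr(out, "params") <- list(alpha = alpha, mu = mu, sigma2 = 0)
    return(out)
  }
  # minimize sum (y - z)^2 + lam * sum (z_i - z_{i-1} - mu)^2,  lam = a/(1-a)
  lam <- alpha / (1 - alpha)
  d <- c(1 + lam, rep(1 + 2 * lam, n - 2), 1 + lam)
  rhs <- v
  rhs[1] <- rhs[1] - lam * mu
  rhs[n] <- rhs[n] + lam * mu
  z <- solve_tridiag_sym(d, -lam, rhs)
  sigma2 <- stats::var(diff(v)) / (1 + alpha)
  out <- ts_with(y, z)
  attr(out, "params") <- list(alpha = alpha, mu = mu, sigma2 = sigma2)
  out
}

#' Total speed of a kinematics trace
#'
#' Scalar movement index: `|v_r| + |v_s| + |v_f|` per sample, all channels in
#' deg/s (translational channels deliberately not converted to mm/s so the sum
#' is unit-homogeneous).
#'
#' @param k A `kinematics_trace`.
#' @return A `time_series` in deg/s.
#' @export
total_speed <- function(k) {
  stopifnot(inherits(k, "kinematics_trace"))
  time_series(abs(k$v_r) + abs(k$v_s) + abs(k$v_f),
              rate = k$rate, t0 = k$t0, units = "deg/s")
}

# Freedman-Diaconis bin width; 0 for degenerate channels.
fd_bin_width <- function(v) {
  2 * stats::IQR(v) / length(v)^(1 / 3)
}

# Modal value of a channel, localized on a grid 5x finer than the FD width so
# the FD-width bin can be centered on it; ties toward zero.
modal_center <- function(v, h) {
  h <- h / 5
  breaks <- seq(min(v) - h / 2, max(v) + h, by = h)
  counts <- graphics::hist(v, breaks = breaks, plot = FALSE)
  centers <- counts$mids
  top <- which(counts$counts == max(counts$counts))
  centers[top][which.min(abs(centers[top]))]
}

#' Classify inactivity from the three kinematic channels
#'
#' Histogram-based movement classifier: each channel is binned with the
#' outlier-robust Freedman-Diaconis width, centered on the channel's modal
#' value; a sample is inactive iff all three channels lie inside their modal
#' bin (close to zero net ball motion).
#'
#' @param k A `kinematics_trace`.
#' @return Logical vector, `TRUE` = inactive. Attribute `degenerate` flags
#'   constant channels (whole trace classified inactive).
#' @export
classify_inactivity <- function(k) {
  stopifnot(inherits(k, "kinematics_trace"))
  channels <- list(k$v_r, k$v_s, k$v_f)
  degenerate <- FALSE
  inside <- lapply(channels, function(v) {
    if (max(v) == min(v)) {
      degenerate <<- TRUE
      return(rep(TRUE, length(v)))
    }
    h <- fd_bin_width(v)
    if (h == 0) {
      # zero IQR: the channel sits at one value almost everywhere; fall back
      # to exact membership in the modal value
      m <- stats::median(v)
      return(v == m)
    }
    m <- modal_center(v, h)
    abs(v - m) <= h / 2
  })
  out <- inside[[1]] & inside[[2]] & inside[[3]]
  attr(out, "degenerate") <- degenerate
  out
}

#' Resample a neural signal onto the kinematics time base
#'
#' Rational (polyphase) resampling: upsample by an integer factor, apply a
#' linear-phase FIR anti-alias filter with compensated group delay, then
#' downsample, so the output has no net lag relative to the input.
#'
#' @param x A `time_series` (e.g. firing rate or voltage at 10 kHz).
#' @param target_rate Output rate in Hz.
#' @param up Intermediate upsampling factor (default 4).
#' @param fir_order FIR order (default `10 * down_factor`).
#' @return A `time_series` at `target_rate` with
#'   `ceiling(n * target_rate / source_rate)` samples.
#' @export
resample_neural_to_kinematics <- function(x, target_rate, up = 4,
                                          fir_order = NULL) {
  assert_ts(x)
  src <- x$rate
  if (target_rate >= src) stop("target rate must be below the source rate")
  n <- length(x$values)
  n_out <- ceiling(n * target_rate / src)
  # exact rational step on the upsampled grid
  down <- up * src / target_rate
  if (abs(down - round(down)) > 1e-9) {
    stop("up * source_rate / target_rate must be an integer")
  }
  down <- as.integer(round(down))
  if (is.null(fir_order)) fir_order <- 10L * down
  if (fir_order %% 2L == 1L) fir_order <- fir_order + 1L
  cutoff <- 1 / down  # normalized to upsampled Nyquist
  h <- as.numeric(signal::fir1(fir_order, cutoff, type = "low"))
  # reflect-pad the input so the filter startup transient falls outside the
  # signal, zero-stuff, filter, compensate the FIR group delay (order/2)
  pad_n <- min(n - 1L, as.integer(ceiling(fir_order / up)) + 1L)
  v <- x$values
  xe <- c(v[(pad_n + 1):2], v, v[(n - 1):(n - pad_n)])
  ne <- length(xe)
  xu <- numeric(ne * up)
  xu[seq(1, by = up, length.out = ne)] <- xe * up
  delay <- fir_order / 2L
  yf <- as.numeric(signal::filter(h, 1, c(xu, numeric(delay))))
  offset <- delay + pad_n * up
  idx <- offset + seq(1, by = down, length.out = n_out)
  idx[idx > length(yf)] <- length(yf)
  time_series(yf[idx], rate = target_rate, t0 = x$t0, units = x$units)
}
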