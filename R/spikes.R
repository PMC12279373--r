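#' Spike train
#'
#' Sorted spike times plus the detection parameters that produced them.
#'
#' @param times Numeric vector of spike times in seconds, strictly increasing.
#' @param span Recording span `c(t0, t1)` in seconds.
#' @param detection_params Optional list (prominence, windows) for provenance.
#' @return A `spike_train`.
#' @export
spike_train <- function(times, span, detection_params = list()) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < span[1] || times[length(times)] > span[2])) {
    stop("spike times outside the recording span")
  }
  structure(list(times = times, span = span, detection_params = detection_params),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.1f s (mean %.2f spikes/s)\n",
              length(x$times), diff(x$span),
              length(x$times) / max(diff(x$span), .Machine$double.eps)))
  invisible(x)
}

# Upper bound on windowed prominence from block minima: prominence can never
# exceed peak height minus the larger of the two windowed side minima, and a
# covering-block minimum is a valid lower bound for each side minimum. Used to
# discard the bulk of sub-threshold local maxima cheaply before exact scans.
prominence_upper_bound <- function(x, peaks, half, block = 512L) {
  n <- length(x)
  nb <- (n - 1L) %/% block + 1L
  bmin <- vapply(seq_len(nb), function(b) {
    min(x[((b - 1L) * block + 1L):min(n, b * block)])
  }, numeric(1))
  vapply(peaks, function(i) {
    bi <- (i - 1L) %/% block + 1L
    bl <- (max(1L, i - half) - 1L) %/% block + 1L
    br <- (min(n, i + half) - 1L) %/% block + 1L
    x[i] - max(min(bmin[bl:bi]), min(bmin[bi:br]))
  }, numeric(1))
}

# Exact one-sided prominence base: scan outward from the peak (in growing
# chunks) until a strictly higher sample or the window edge; return the
# minimum of the stretch between the peak and that barrier.
side_min <- function(x, i, half, dir) {
  n <- length(x)
  xi <- x[i]
  edge <- if (dir < 0) max(1L, i - half) else min(n, i + half)
  run_min <- Inf
  pos <- i + dir
  chunk <- 256L
  while ((dir < 0 && pos >= edge) || (dir > 0 && pos <= edge)) {
    stop_at <- if (dir < 0) max(edge, pos - chunk + 1L) else min(edge, pos + chunk - 1L)
    seg <- x[pos:stop_at]  # ordered moving away from the peak
    barrier <- which(seg > xi)
    if (length(barrier)) {
      j <- barrier[1]
      if (j > 1) run_min <- min(run_min, seg[1:(j - 1L)])
      return(run_min)
    }
    run_min <- min(run_min, seg)
    pos <- stop_at + dir
    chunk <- chunk * 4L
  }
  run_min
}

# scipy-style peak prominence restricted to a +/- wlen/2 window
peak_prominences <- function(x, peaks, wlen) {
  half <- max(1L, as.integer(wlen %/% 2))
  vapply(peaks, function(i) {
    x[i] - max(side_min(x, i, half, -1L), side_min(x, i, half, 1L))
  }, numeric(1))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect spikes in an intracellular voltage trace
#'
#' The trace is zero-phase high-pass filtered (first-order Butterworth,
#' forward-backward, 3 dB corner `band_corner`; an optional `upper_corner`
#' turns it into a band-pass), normalized by a rolling median absolute
#' deviation (times 1.4826 for asymptotically normal consistency), and peaks
#' are kept when their relative prominence - evaluated within a
#' `prominence_window` neighborhood - exceeds `prominence`. Peaks closer than
#' the refractory limit are merged, keeping the larger.
#'
#' @param v A `time_series` in mV, rate >= 1 kHz.
#' @param prominence Prominence threshold in normalized (MAD) units. Must be
#'   chosen per recording in practice; the default (8) is calibrated on the
#'   synthetic session generator at a waveform-to-noise ratio of 8, where it
#'   gives precision and recall above 0.99.
#' @param band_corner High-pass corner in Hz (default 100).
#' @param upper_corner Optional low-pass corner making the filter band-pass.
#' @param mad_window Rolling MAD window in seconds (default 0.5).
#' @param prominence_window Prominence neighborhood in seconds (default 10).
#' @param refractory Merge window in seconds (default 1e-3).
#' @return A `spike_train`.
#' @export
detect_spikes <- function(v, prominence = 8, band_corner = 100, upper_corner = NULL,
                          mad_window = 0.5, prominence_window = 10,
                          refractory = 1e-3) {
  assert_ts(v)
  if (v$rate < 1000) stop("voltage rate must be >= 1 kHz")
  if (prominence <= 0) stop("prominence must be positive")
  x <- v$values
  nyq <- v$rate / 2
  if (is.null(upper_corner)) {
    bf <- signal::butter(1, band_corner / nyq, type = "high")
  } else {
    bf <- signal::butter(1, c(band_corner, upper_corner) / nyq, type = "pass")
  }
  xf <- as.numeric(signal::filtfilt(bf, x))
  # rolling MAD: median over the window of |x - global median|, consistent
  # with a Gaussian sigma after multiplying by 1.4826
  k <- as.integer(mad_window * v$rate)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(xf) %% 2L == 0L) length(xf) - 1L else length(xf))
  dev <- abs(xf - stats::median(xf))
  rmad <- as.numeric(stats::runmed(dev, k, endrule = "median"))
  if (any(rmad == 0)) {
    bad <- which(rmad == 0)[1]
    stop(sprintf("rolling MAD is zero near t = %.3f s (flat trace)",
                 (bad - 1) / v$rate + v$t0))
  }
  z <- xf / (MAD_CONSISTENCY * rmad)
  peaks <- local_maxima(z)
  if (length(peaks)) {
    half <- max(1L, as.integer((prominence_window * v$rate) %/% 2))
    ub <- prominence_upper_bound(z, peaks, half)
    peaks <- peaks[ub >= prominence]
  }
  if (length(peaks)) {
    prom <- peak_prominences(z, peaks, wlen = prominence_window * v$rate)
    peaks <- peaks[prom >= prominence]
  }
  # refractory merge: greedy by height, reject peaks within min_gap of an
  # already-accepted higher peak
  if (length(peaks) > 1) {
    min_gap <- refractory * v$rate
    ord <- peaks[order(z[peaks], decreasing = TRUE)]
    accepted <- integer(0)
    for (p in ord) {
      if (!length(accepted) || min(abs(accepted - p)) >= min_gap) {
        accepted <- c(accepted, p)
      }
    }
    peaks <- sort(accepted)
  }
  span <- c(v$t0, v$t0 + (length(x) - 1) / v$rate)
  spike_train(v$t0 + (peaks - 1) / v$rate, span,
              detection_params = list(prominence = prominence,
                                      mad_window = mad_window,
                                      prominence_window = prominence_window))
}

#' MAD-to-sigma consistency constant for Gaussian data
#'
#' Multiplying a median absolute deviation by this constant (the inverse of
#' the 0.75 normal quantile) makes it a consistent estimator of a Gaussian
#' standard deviation.
#' @export
MAD_CONSISTENCY <- 1.4826

# Bin spike times on a regular grid covering the span; returns counts.
bin_spikes <- function(s, binwidth) {
  edges <- seq(s$span[1], s$span[2] + binwidth, by = binwidth)
  counts <- graphics::hist(s$times, breaks = edges, plot = FALSE)$counts
  list(counts = counts, t0 = s$span[1] + binwidth / 2, rate = 1 / binwidth)
}

#' Fine-timescale firing rate (1.25 ms bins, 2.5 ms Gaussian)
#'
#' Spike counts in 1.25 ms bins, divided by the bin width and smoothed with a
#' 2.5 ms-sigma Gaussian kernel (truncated at +/- 3.5 sigma, unit sum).
#'
#' @param s A `spike_train`.
#' @param binwidth Bin width in seconds (default 1.25e-3).
#' @param sigma Gaussian sigma in seconds (default 2.5e-3).
#' @return A `time_series` in spikes/s with attribute `method`.
#' @export
rate_fine <- function(s, binwidth = 1.25e-3, sigma = 2.5e-3) {
  stopifnot(inherits(s, "spike_train"))
  b <- bin_spikes(s, binwidth)
  r <- b$counts / binwidth
  k <- gaussian_kernel(sigma, b$rate)
  out <- time_series(conv_same_reflect(r, k), rate = b$rate, t0 = b$t0,
                     units = "spikes/s")
  attr(out, "method") <- "fine-1.25ms-gauss2.5ms"
  out
}

#' Coarse firing rate (10 ms bins, 30 ms exponential filter)
#'
#' Spike counts in 10 ms non-overlapping bins smoothed with a causal
#' exponential moving average. The decay is set so the stated window holds
#' about 86% (1 - exp(-2)) of the kernel mass.
#'
#' @param s A `spike_train`.
#' @param binwidth Bin width in seconds (default 0.01).
#' @param window Exponential window in seconds (default 0.03).
#' @return A `time_series` in spikes/s with attribute `method`.
#' @export
rate_coarse <- function(s, binwidth = 0.01, window = 0.03) {
  stopifnot(inherits(s, "spike_train"))
  b <- bin_spikes(s, binwidth)
  r <- b$counts / binwidth
  a <- exp(-2 * binwidth / window)
  # unit-gain causal EMA: y_t = (1 - a) x_t + a y_{t-1}
  y <- as.numeric(stats::filter((1 - a) * r, a, method = "recursive"))
  out <- time_series(y, rate = b$rate, t0 = b$t0, units = "spikes/s")
  attr(out, "method") <- "coarse-10ms-exp30ms"
  out
}

# Tiled piecewise-linear trend: independent OLS line per `seg_s` segment.
piecewise_linear_trend <- function(v, rate, seg_s) {
  n <- length(v)
  seg <- max(2L, as.integer(seg_s * rate))
  starts <- seq(1L, n, by = seg)
  trend <- numeric(n)
  for (s0 in starts) {
    s1 <- min(n, s0 + seg - 1L)
    idx <- s0:s1
    if (length(idx) < 2) { trend[idx] <- v[idx]; next }
    tt <- idx - s0
    fit <- stats::lm.fit(cbind(1, tt), v[idx])
    trend[idx] <- fit$fitted.values
  }
  trend
}

#' Subthreshold membrane voltage
#'
#' Removes spikes and drift from a raw voltage trace: 35 ms median filter,
#' 5 ms Gaussian smoothing, then detrending by the average of tiled piecewise
#' linear fits over 30 s and 120 s segments, with the initial offset (median
#' of the first `offset_window` seconds) added back.
#'
#' @param v A `time_series` in mV.
#' @param median_kernel Median filter length in seconds (default 0.035).
#' @param gauss_sigma Gaussian sigma in seconds (default 5e-3).
#' @param offset_window Seconds used for the initial offset (default 30).
#' @param detrend_segments Segment lengths in seconds (default `c(30, 120)`).
#' @return A `time_series` in mV.
#' @export
subthreshold_voltage <- function(v, median_kernel = 0.035, gauss_sigma = 5e-3,
                                 offset_window = 30,
                                 detrend_segments = c(30, 120)) {
  assert_ts(v)
  x <- v$values
  n <- length(x)
  n_off <- min(n, max(1L, as.integer(offset_window * v$rate)))
  offset <- stats::median(x[1:n_off])
  k <- as.integer(median_kernel * v$rate)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 0L) n - 1L else n)
  y <- as.numeric(stats::runmed(x, k, endrule = "median"))
  y <- conv_same_reflect(y, gaussian_kernel(gauss_sigma, v$rate))
  trends <- vapply(detrend_segments,
                   function(s) piecewise_linear_trend(y, v$rate, s),
                   numeric(n))
  y <- y - rowMeans(trends) + offset
  ts_with(v, y, units = "mV")
}

#' Recording quality control
#'
#' Flags recordings shorter than the minimum duration and marks extended
#' epochs where the (median-filtered) membrane voltage is more depolarized
#' than `vmax` for exclusion.
#'
#' @param v A `time_series` in mV.
#' @param min_duration Minimum acceptable duration in seconds (default 900).
#' @param vmax Depolarization limit in mV (default -33).
#' @param min_epoch Minimum excluded-epoch length in seconds (default 1).
#' @param median_kernel Median filter length in seconds (default 0.035).
#' @return A list: `pass` (logical), `reasons` (character),
#'   `excluded_epochs` (data.frame with onset/offset seconds).
#' @export
qc_recording <- function(v, min_duration = 900, vmax = -33, min_epoch = 1,
                         median_kernel = 0.035) {
  assert_ts(v)
  reasons <- character(0)
  dur <- ts_duration(v)
  if (dur < min_duration) {
    reasons <- c(reasons, sprintf("duration %.1f s < %.0f s minimum", dur, min_duration))
  }
  k <- as.integer(median_kernel * v$rate)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(v$values) %% 2L == 0L) length(v$values) - 1L else length(v$values))
  y <- as.numeric(stats::runmed(v$values, k, endrule = "median"))
  r <- rle(y > vmax)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & (r$lengths >= min_epoch * v$rate)
  epochs <- data.frame(
    onset = v$t0 + (starts[sel] - 1) / v$rate,
    offset = v$t0 + (ends[sel] - 1) / v$rate
  )
  if (nrow(epochs) > 0) {
    reasons <- c(reasons, sprintf("%d depolarized epoch(s) above %g mV", nrow(epochs), vmax))
  }
  list(pass = length(reasons) == 0, reasons = reasons, excluded_epochs = epochs)
}
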