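#' Two-sided linear filter between two signals
#'
#' Lag-indexed gain from an input channel to an output channel. Values are
#' per-sample kernel weights on the shared time base: convolving the input
#' with `values` (respecting `lags`) yields the predicted output. Positive lag
#' means the output follows the input.
#'
#' @param lags Lags in seconds, symmetric about 0, uniformly spaced.
#' @param values Filter weights.
#' @param direction `"neuron->behavior"` or `"behavior->neuron"`.
#' @param bandwidth Low-pass (Slepian) bandwidth in Hz used on the filter.
#' @param rate Sampling rate in Hz.
#' @return A `linear_filter`.
#' @export
linear_filter <- function(lags, values,
                          direction = c("neuron->behavior", "behavior->neuron"),
                          bandwidth = NA_real_, rate = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(lags) == length(values), all(is.finite(values)))
  if (abs(lags[1] + lags[length(lags)]) > 1.01 * mean(diff(lags))) {
    stop("lags must be (near-)symmetric about 0")
  }
  if (is.null(rate)) rate <- 1 / mean(diff(lags))
  structure(list(lags = as.numeric(lags), values = as.numeric(values),
                 direction = direction, bandwidth = bandwidth, rate = rate),
            class = "linear_filter")
}

#' @export
print.linear_filter <- function(x, ...) {
  pk <- which.max(abs(x$values))
  cat(sprintf("<linear_filter> %s, %d lags in [%.2f, %.2f] s, peak %.3g at %.3f s\n",
              x$direction, length(x$lags), min(x$lags), max(x$lags),
              x$values[pk], x$lags[pk]))
  invisible(x)
}

#' 0th-order Slepian (DPSS) taper
#'
#' Discrete prolate spheroidal sequence of order 0: the unit-norm sequence of
#' length `n` maximally concentrated in the frequency band `[-w, w]` (w in
#' cycles/sample). Computed from the standard symmetric tridiagonal
#' formulation; returned renormalized to unit sum so it can serve as a
#' low-pass smoothing kernel.
#'
#' @param n Taper length in samples.
#' @param w Half-bandwidth in cycles per sample (0 < w < 0.5).
#' @return Numeric vector of length `n`, positive, summing to 1.
#' @export
dpss_taper <- function(n, w) {
  stopifnot(n >= 2, w > 0, w < 0.5)
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t[-1] * (n - t[-1])) / 2
  m <- diag(diag_main)
  for (i in seq_len(n - 1)) {
    m[i, i + 1] <- diag_off[i]
    m[i + 1, i] <- diag_off[i]
  }
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v / sum(v)
}

# fftshift for a length-n spectrum-derived kernel: reorder so lags run
# -n/2 ... n/2 - 1
fftshift_vec <- function(x) {
  n <- length(x)
  h <- ceiling(n / 2)
  c(x[(h + 1):n], x[1:h])
}

#' Estimate a linear (Wiener) filter in the frequency domain
#'
#' Averages the cross-spectrum and input power spectrum over overlapping
#' windows and forms `F(w) = <input* x output> / <input* x input>` (with a
#' small ridge on the denominator), then inverse-FFTs to a two-sided
#' time-domain filter and low-pass filters it with a unit-sum 0th-order
#' Slepian taper of half-bandwidth `bandwidth` Hz (length `rate / bandwidth`
#' samples). Windows are Hann-tapered and (by default) de-meaned, and the
#' taper's known multiplicative lag bias is divided out of the result.
#'
#' @param input,output `time_series` at the same rate covering the same span.
#' @param window Window length in seconds (default 4).
#' @param hop Hop between window starts in samples; default 25% of the window.
#'   `hop = 1` reproduces maximally overlapped averaging exactly.
#' @param bandwidth Slepian half-bandwidth in Hz (15 for neuron->behavior,
#'   6 for behavior->neuron).
#' @param direction Direction tag stored on the filter.
#' @param ridge Relative ridge on the denominator (default 1e-6 of the peak
#'   input power).
#' @param demean Subtract each window's mean before transforming (default
#'   TRUE, the standard Welch detrend; disable for already-centered signals).
#' @return A `linear_filter`; attribute `ridge_active` reports whether the
#'   ridge materially affected any frequency bin.
#' @export
estimate_filter <- function(input, output, window = 4, hop = NULL,
                            bandwidth = 15,
                            direction = c("neuron->behavior", "behavior->neuron"),
                            ridge = 1e-6, demean = TRUE) {
  assert_ts(input, "input"); assert_ts(output, "output")
  direction <- match.arg(direction)
  if (abs(input$rate - output$rate) > 1e-9) stop("input and output rates differ")
  x <- input$values
  y <- output$values
  n <- min(length(x), length(y))
  x <- x[1:n]; y <- y[1:n]
  w <- as.integer(round(window * input$rate))
  if (w > n) stop("window longer than the signals")
  if (is.null(hop)) hop <- max(1L, w %/% 4L)
  starts <- seq(1L, n - w + 1L, by = hop)
  sxx <- numeric(w)
  sxy <- complex(w)
  # Hann taper per segment limits leakage of low-frequency power into the
  # quiet part of the input spectrum; it cancels in the cross/power ratio
  taper_seg <- 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
  for (s0 in starts) {
    xs <- x[s0:(s0 + w - 1L)]
    ys <- y[s0:(s0 + w - 1L)]
    if (demean) {
      xs <- xs - mean(xs)
      ys <- ys - mean(ys)
    }
    xf <- stats::fft(xs * taper_seg)
    yf <- stats::fft(ys * taper_seg)
    sxx <- sxx + Re(Conj(xf) * xf)
    sxy <- sxy + Conj(xf) * yf
  }
  sxx <- sxx / length(starts)
  sxy <- sxy / length(starts)
  eps <- ridge * max(sxx)
  if (max(sxx) <= 0) stop("input has no power")
  fw <- sxy / (sxx + eps)
  h <- Re(stats::fft(fw, inverse = TRUE)) / w
  h <- fftshift_vec(h)
  lags <- (seq_len(w) - 1 - floor(w / 2)) / input$rate
  # windowed spectra shrink the filter at lag l by the taper autocorrelation
  # rho(l); undo this known multiplicative bias (floored so the far tail,
  # where rho ~ 0, is not blown up)
  lag_samp <- abs(round(lags * input$rate))
  rho <- vapply(lag_samp, function(l) {
    if (l >= w) return(0)
    sum(taper_seg[1:(w - l)] * taper_seg[(1 + l):w])
  }, numeric(1)) / sum(taper_seg^2)
  h <- h / pmax(rho, 0.05)
  taper_n <- max(3L, as.integer(round(input$rate / bandwidth)))
  if (taper_n %% 2L == 0L) taper_n <- taper_n + 1L
  taper <- dpss_taper(taper_n, bandwidth / input$rate)
  half <- (taper_n - 1L) %/% 2L
  hs <- stats::filter(c(numeric(half), h, numeric(half)), taper,
                      method = "convolution", sides = 2)
  hs <- as.numeric(hs)[(half + 1):(half + w)]
  out <- linear_filter(lags, hs, direction = direction, bandwidth = bandwidth,
                       rate = input$rate)
  attr(out, "ridge_active") <- any(sxx < 100 * eps)
  out
}

# Convolve an input series with a two-sided filter; returns values aligned on
# the input time base (edges where the filter sticks out use zero padding).
apply_filter <- function(input, filt) {
  x <- input$values
  v <- filt$values
  lag0 <- which.min(abs(filt$lags))
  # full convolution c[m] = sum_j v[j] x[m - j + 1];
  # y[t] = sum_j v[j] x[t - (j - lag0)] = c[t + lag0 - 1]
  cfull <- stats::convolve(x, rev(v), conj = TRUE, type = "open")
  cfull[lag0 + seq_along(x) - 1L]
}

#' Predict behavior from a firing-rate input and a linear filter
#'
#' Truncates the two-sided filter to candidate lengths on a fixed grid inside
#' `length_bounds`, convolves the input with each truncation, and scores each
#' prediction by the R-squared of an ordinary least-squares regression
#' (with intercept) of observed on predicted over the evaluation segment (by
#' default the final 80% of the session; the first 20% is reserved for filter
#' estimation). Returns the best truncation.
#'
#' @param filt A `linear_filter`.
#' @param input A `time_series` (firing rate).
#' @param observed A `time_series` (behavior) on the same time base.
#' @param length_bounds Candidate total filter lengths in seconds
#'   (default `c(0.1, 4)`).
#' @param n_lengths Number of candidate lengths on the grid (default 12).
#' @param eval_fraction Final fraction of the session used for evaluation
#'   (default 0.8).
#' @param active_mask Optional logical vector: evaluate only where `TRUE`
#'   (used to exclude inactivity).
#' @return A list: `predicted` (`time_series`), `report` (list with `r2`,
#'   `filter_length_used`, `train_fraction`, `eval_fraction`).
#' @export
predict_behavior <- function(filt, input, observed,
                             length_bounds = c(0.1, 4), n_lengths = 12,
                             eval_fraction = 0.8, active_mask = NULL) {
  stopifnot(inherits(filt, "linear_filter"))
  assert_ts(input, "input"); assert_ts(observed, "observed")
  n <- min(length(input$values), length(observed$values))
  eval_idx <- seq.int(n - floor(eval_fraction * n) + 1L, n)
  if (!is.null(active_mask)) {
    eval_idx <- eval_idx[active_mask[eval_idx]]
  }
  max_support <- max(abs(filt$lags)) * 2
  lens <- exp(seq(log(length_bounds[1]), log(min(length_bounds[2], max_support)),
                  length.out = n_lengths))
  best <- list(r2 = -Inf)
  for (len in lens) {
    keep <- abs(filt$lags) <= len / 2
    ft <- filt
    ft$values <- filt$values * keep
    pred <- apply_filter(input, ft)
    obs <- observed$values[eval_idx]
    prd <- pred[eval_idx]
    if (stats::var(prd) == 0) next
    fit <- stats::lm(obs ~ prd)
    r2 <- summary(fit)$r.squared
    if (r2 > best$r2) {
      best <- list(r2 = r2, filter_length_used = len, predicted = pred)
    }
  }
  if (!is.finite(best$r2)) stop("no candidate filter produced a varying prediction")
  list(
    predicted = ts_with(input, best$predicted, units = observed$units),
    report = list(r2 = best$r2, filter_length_used = best$filter_length_used,
                  train_fraction = 1 - eval_fraction,
                  eval_fraction = eval_fraction)
  )
}

#' Combine left and right single-cell predictions
#'
#' Elementwise sum with equal weighting; an optional activity mask zeroes out
#' (marks `NA`) inactive periods.
#'
#' @param pred_left,pred_right `time_series` predictions on one time base.
#' @param active_mask Optional logical vector (`TRUE` = active).
#' @return A `time_series`.
#' @export
dual_prediction <- function(pred_left, pred_right, active_mask = NULL) {
  assert_ts(pred_left, "pred_left"); assert_ts(pred_right, "pred_right")
  stopifnot(length(pred_left$values) == length(pred_right$values))
  v <- pred_left$values + pred_right$values
  if (!is.null(active_mask)) v[!active_mask] <- NA_real_
  ts_with(pred_left, v)
}

#' Biased normalized autocorrelation
#'
#' @param x A `time_series`.
#' @param max_lag Maximum lag in seconds.
#' @return A data.frame with `lag` (s) and `acf`; `acf[lag == 0] == 1`.
#' @export
autocorrelation <- function(x, max_lag) {
  assert_ts(x)
  lm <- as.integer(max_lag * x$rate)
  a <- stats::acf(x$values, lag.max = lm, plot = FALSE, demean = TRUE)
  data.frame(lag = (0:lm) / x$rate, acf = as.numeric(a$acf))
}
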