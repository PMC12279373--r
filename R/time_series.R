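#' Uniformly sampled time series
#'
#' The universal signal carrier in steerlab: a numeric vector sampled at a
#' fixed rate, with a start time and a unit label. All preprocessing,
#' filtering and event operations consume and return `time_series` objects.
#'
#' @param values Numeric vector of samples.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param units Unit label, e.g. `"deg/s"` or `"mV"`.
#' @return An object of class `time_series`.
#' @export
#' @examples
#' x <- time_series(sin(seq(0, 2 * pi, length.out = 100)), rate = 100)
#' ts_duration(x)
time_series <- function(values, rate, t0 = 0, units = "") {
  stopifnot(is.numeric(values), length(rate) == 1, is.finite(rate), rate > 0)
  structure(
    list(values = as.numeric(values), rate = rate, t0 = t0, units = units),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf(
    "<time_series> %d samples @ %g Hz (%.3f s)%s\n",
    length(x$values), x$rate, ts_duration(x),
    if (nzchar(x$units)) paste0(" [", x$units, "]") else ""
  ))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

#' Sample times of a time series
#' @param x A `time_series`.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(x) x$t0 + (seq_along(x$values) - 1) / x$rate

#' Duration spanned by a time series
#' @param x A `time_series`.
#' @return Duration in seconds (n / rate).
#' @export
ts_duration <- function(x) length(x$values) / x$rate

# Replace values, keep time base/metadata.
ts_with <- function(x, values, units = x$units) {
  time_series(values, rate = x$rate, t0 = x$t0, units = units)
}

is_time_series <- function(x) inherits(x, "time_series")

assert_ts <- function(x, what = "x") {
  if (!is_time_series(x)) stop(sprintf("`%s` must be a time_series", what))
  invisible(x)
}

# Truncated, renormalized Gaussian kernel (unit sum), bounded at +/- 3.5 sigma.
gaussian_kernel <- function(sigma_s, rate) {
  half <- max(1L, ceiling(3.5 * sigma_s * rate))
  k <- stats::dnorm((-half:half) / rate, sd = sigma_s)
  k / sum(k)
}

# Centered convolution with reflect-padded edges; output length == input.
conv_same_reflect <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1L) %/% 2L
  if (half == 0L) return(x * kernel)
  if (half >= n) {
    pad_l <- rev(x)[rep(seq_len(n), length.out = half)]
    pad_r <- rev(x)[rep(seq_len(n), length.out = half)]
    padded <- c(rev(pad_l), x, pad_r)
  } else {
    padded <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  }
  out <- stats::filter(padded, kernel, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}
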