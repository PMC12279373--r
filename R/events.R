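#' Detect movement/immobility transitions from total speed
#'
#' Threshold crossings of total speed (default 75 deg/s) in each direction,
#' kept only when the fly behaves consistently around the crossing: a start
#' requires >= 90% of the 750 ms pre-window at or below half the threshold and
#' >= 90% of the post-window above the threshold; a stop requires >= 90% of
#' the pre-window above the threshold and >= 90% of the post-window at or
#' below half the threshold. Crossings whose windows stick out of the trace
#' are discarded.
#'
#' @param speed A `time_series` of total speed (deg/s), rate >= 50 Hz.
#' @param threshold Crossing threshold in deg/s (default 75).
#' @param window Consistency window in seconds (default 0.75).
#' @param consistency Required fraction inside the window (default 0.9).
#' @return A data.frame with columns `kind` ("start"/"stop"), `time` (s) and
#'   `index` (sample of the first post-crossing value).
#' @export
detect_transitions <- function(speed, threshold = 75, window = 0.75,
                               consistency = 0.9) {
  assert_ts(speed, "speed")
  if (speed$rate < 50) stop("rate must be >= 50 Hz")
  x <- speed$values
  n <- length(x)
  w <- as.integer(round(window * speed$rate))
  if (n < 2 * w) stop("trace shorter than twice the consistency window")
  up <- which(x[-n] <= threshold & x[-1] > threshold) + 1L
  down <- which(x[-n] > threshold & x[-1] <= threshold) + 1L
  frac <- function(idx, cond) mean(cond[idx])
  keep_start <- vapply(up, function(i) {
    if (i - w < 1 || i + w - 1 > n) return(FALSE)
    pre <- x[(i - w):(i - 1)]
    post <- x[i:(i + w - 1)]
    mean(pre <= threshold / 2) >= consistency && mean(post > threshold) >= consistency
  }, logical(1))
  keep_stop <- vapply(down, function(i) {
    if (i - w < 1 || i + w - 1 > n) return(FALSE)
    pre <- x[(i - w):(i - 1)]
    post <- x[i:(i + w - 1)]
    mean(pre > threshold) >= consistency && mean(post <= threshold / 2) >= consistency
  }, logical(1))
  ev <- rbind(
    if (any(keep_start)) data.frame(kind = "start", index = up[keep_start]),
    if (any(keep_stop)) data.frame(kind = "stop", index = down[keep_stop])
  )
  if (is.null(ev) || nrow(ev) == 0) {
    return(data.frame(kind = character(0), time = numeric(0), index = integer(0)))
  }
  ev <- ev[order(ev$index), , drop = FALSE]
  ev$time <- speed$t0 + (ev$index - 1) / speed$rate
  rownames(ev) <- NULL
  ev[, c("kind", "time", "index")]
}

#' Event-triggered average with two-level averaging
#'
#' Snippets of each experiment's signal are aligned on that experiment's event
#' times, averaged within the experiment, and the per-experiment means are
#' then averaged across experiments; the s.e.m. is computed across
#' experiments. With a single experiment the s.e.m. is undefined and flagged.
#'
#' @param signals List of `time_series`, one per experiment (equal rates).
#' @param event_times List of numeric vectors of event times (seconds), one
#'   per experiment.
#' @param span Half-window in seconds extracted around each event.
#' @return A list: `lag` (s), `mean`, `sem` (NA with `sem_defined = FALSE`
#'   when only one experiment contributes), `n_experiments`, `n_events`.
#' @export
align_and_average <- function(signals, event_times, span) {
  stopifnot(length(signals) == length(event_times), length(signals) >= 1)
  rate <- signals[[1]]$rate
  w <- as.integer(round(span * rate))
  lag <- (-w:w) / rate
  exp_means <- list()
  n_events <- 0L
  for (e in seq_along(signals)) {
    s <- signals[[e]]
    stopifnot(abs(s$rate - rate) < 1e-9)
    snips <- list()
    for (tev in event_times[[e]]) {
      i <- as.integer(round((tev - s$t0) * rate)) + 1L
      if (i - w < 1 || i + w > length(s$values)) next
      snips[[length(snips) + 1L]] <- s$values[(i - w):(i + w)]
    }
    if (length(snips)) {
      exp_means[[length(exp_means) + 1L]] <- colMeans(do.call(rbind, snips))
      n_events <- n_events + length(snips)
    }
  }
  if (!length(exp_means)) stop("no complete event windows")
  m <- do.call(rbind, exp_means)
  out_mean <- colMeans(m)
  if (nrow(m) > 1) {
    sem <- apply(m, 2, stats::sd) / sqrt(nrow(m))
    sem_defined <- TRUE
  } else {
    sem <- rep(NA_real_, ncol(m))
    sem_defined <- FALSE
  }
  list(lag = lag, mean = out_mean, sem = sem, sem_defined = sem_defined,
       n_experiments = nrow(m), n_events = n_events)
}

# Shift a series forward in time by `shift` seconds (value at t becomes the
# value recorded shift earlier); leading samples repeat the first value.
shift_forward <- function(ts, shift) {
  k <- as.integer(round(shift * ts$rate))
  v <- ts$values
  if (k > 0) v <- c(rep(v[1], k), v[seq_len(length(v) - k)])
  ts_with(ts, v)
}

# Means over non-overlapping windows of `w` samples.
window_means <- function(v, w) {
  n_win <- length(v) %/% w
  if (n_win == 0) stop("signal shorter than one window")
  colMeans(matrix(v[1:(n_win * w)], nrow = w))
}

#' Behavior binned on a two-neuron firing-rate grid
#'
#' Neural channels are shifted forward by `shift` (default 150 ms) to account
#' for the neural-to-behavior delay, all three signals are reduced to means
#' over non-overlapping `window`-second windows, and the behavior means are
#' binned on the 2D grid of the two neural means. Bins with fewer than
#' `min_count` windows are masked.
#'
#' @param rate_a,rate_b `time_series` firing rates (same rate as `behavior`).
#' @param behavior A `time_series`.
#' @param shift Neural lead time in seconds (default 0.15).
#' @param window Window length in seconds (default 0.05).
#' @param bin_width Bin width in spikes/s (default 10).
#' @param min_count Minimum windows per bin (default 20).
#' @return A list: `map` (matrix of mean behavior, masked bins `NA`),
#'   `count`, `a_breaks`, `b_breaks`, plus the per-window triples in `windows`.
#' @export
binned_behavior_map <- function(rate_a, rate_b, behavior, shift = 0.15,
                                window = 0.05, bin_width = 10, min_count = 20) {
  assert_ts(rate_a, "rate_a"); assert_ts(rate_b, "rate_b")
  assert_ts(behavior, "behavior")
  stopifnot(abs(rate_a$rate - behavior$rate) < 1e-9,
            abs(rate_b$rate - behavior$rate) < 1e-9)
  w <- as.integer(round(window * behavior$rate))
  a <- window_means(shift_forward(rate_a, shift)$values, w)
  b <- window_means(shift_forward(rate_b, shift)$values, w)
  n <- min(length(a), length(b))
  beh <- window_means(behavior$values, w)[1:n]
  a <- a[1:n]; b <- b[1:n]
  a_breaks <- seq(floor(min(a) / bin_width) * bin_width,
                  ceiling(max(a) / bin_width) * bin_width + bin_width, by = bin_width)
  b_breaks <- seq(floor(min(b) / bin_width) * bin_width,
                  ceiling(max(b) / bin_width) * bin_width + bin_width, by = bin_width)
  ai <- findInterval(a, a_breaks, rightmost.closed = TRUE)
  bi <- findInterval(b, b_breaks, rightmost.closed = TRUE)
  na <- length(a_breaks) - 1L
  nb <- length(b_breaks) - 1L
  map <- matrix(NA_real_, na, nb)
  count <- matrix(0L, na, nb)
  sums <- matrix(0, na, nb)
  for (i in seq_len(n)) {
    sums[ai[i], bi[i]] <- sums[ai[i], bi[i]] + beh[i]
    count[ai[i], bi[i]] <- count[ai[i], bi[i]] + 1L
  }
  nz <- count > 0
  map[nz] <- sums[nz] / count[nz]
  map[count < min_count] <- NA_real_
  list(map = map, count = count, a_breaks = a_breaks, b_breaks = b_breaks,
       windows = data.frame(a = a, b = b, behavior = beh),
       min_count = min_count)
}

#' Rotational-velocity tuning to the right-left firing-rate difference
#'
#' Bins the bilateral rate difference (left minus right, after shifting the
#' neural channels forward) and reports mean rotational velocity per bin,
#' together with an OLS fit of the unbinned pairs.
#'
#' @param rate_left,rate_right `time_series` firing rates.
#' @param v_r A `time_series` of rotational velocity.
#' @param shift Neural lead in seconds (default 0.15).
#' @param window Averaging window in seconds (default 0.05).
#' @param bin_width Bin width in spikes/s (default 10).
#' @return A list: `curve` (data.frame delta, mean_v_r, count), `slope`,
#'   `intercept`, `slope_ci` (95% Wald interval).
#' @export
rl_difference_tuning <- function(rate_left, rate_right, v_r, shift = 0.15,
                                 window = 0.05, bin_width = 10) {
  w <- as.integer(round(window * v_r$rate))
  l <- window_means(shift_forward(rate_left, shift)$values, w)
  r <- window_means(shift_forward(rate_right, shift)$values, w)
  n <- min(length(l), length(r))
  vr <- window_means(v_r$values, w)[1:n]
  delta <- l[1:n] - r[1:n]
  fit <- stats::lm(vr ~ delta)
  ci <- stats::confint(fit)["delta", ]
  breaks <- seq(floor(min(delta) / bin_width) * bin_width,
                ceiling(max(delta) / bin_width) * bin_width + bin_width,
                by = bin_width)
  bi <- findInterval(delta, breaks, rightmost.closed = TRUE)
  curve <- data.frame(
    delta = (breaks[-length(breaks)] + breaks[-1]) / 2,
    mean_v_r = as.numeric(tapply(vr, factor(bi, levels = seq_len(length(breaks) - 1L)), mean)),
    count = as.integer(table(factor(bi, levels = seq_len(length(breaks) - 1L))))
  )
  list(curve = curve[curve$count > 0, ],
       slope = unname(stats::coef(fit)["delta"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       slope_ci = unname(ci))
}
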