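# Circular helpers on the 8-sector circle (period 8, sector = 45 degrees).
# Sectors are indexed 0-7 counterclockwise viewed from the rear; a clockwise
# fly rotation produces a counter-clockwise bump rotation. Positive circular
# differences are counterclockwise.
N_SECTORS <- 8L

sector_to_rad <- function(p) p * 2 * pi / N_SECTORS
rad_to_sector <- function(a) a * N_SECTORS / (2 * pi)

# shortest signed arc from a to b, in sectors, result in (-4, 4]
circ_diff_sectors <- function(b, a) {
  d <- (b - a) %% N_SECTORS
  d - N_SECTORS * (d > N_SECTORS / 2)
}

circ_mean_sectors <- function(p) {
  a <- sector_to_rad(p)
  (rad_to_sector(atan2(mean(sin(a)), mean(cos(a))))) %% N_SECTORS
}

# circular SD in sectors via the resultant length
circ_sd_sectors <- function(p) {
  a <- sector_to_rad(p)
  r <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  rad_to_sector(sqrt(-2 * log(max(r, .Machine$double.xmin))))
}

#' Eight-sector fluorescence trace
#'
#' Sector-resolved fluorescence from the ellipsoid body, an 8 x T matrix at a
#' fixed frame rate. Row k covers the 45-degree wedge centered on sector k - 1.
#'
#' @param mat Numeric 8 x T matrix.
#' @param rate Frame rate in Hz (default 11.4).
#' @param t0 Time of the first frame in seconds.
#' @return A `sector_trace`.
#' @export
sector_trace <- function(mat, rate = 11.4, t0 = 0) {
  mat <- as.matrix(mat)
  if (nrow(mat) != N_SECTORS) stop("sector trace must have exactly 8 rows")
  if (!all(is.finite(mat))) stop("sector trace must be finite")
  structure(list(dff = mat, rate = rate, t0 = t0), class = "sector_trace")
}

#' @export
print.sector_trace <- function(x, ...) {
  cat(sprintf("<sector_trace> 8 x %d frames @ %g Hz\n", ncol(x$dff), x$rate))
  invisible(x)
}

#' Sector-wise Delta-F/F
#'
#' Per sector, the baseline F is the time-average of the lower half of the raw
#' fluorescence values (samples at or below the sector median); dff is
#' (raw - F) / F.
#'
#' @param raw Numeric 8 x T matrix of raw fluorescence.
#' @param rate Frame rate in Hz.
#' @param t0 Start time in seconds.
#' @return A `sector_trace` of dff values.
#' @export
sector_dff <- function(raw, rate = 11.4, t0 = 0) {
  raw <- as.matrix(raw)
  if (nrow(raw) != N_SECTORS) stop("raw fluorescence must have exactly 8 rows")
  dff <- raw
  for (k in seq_len(N_SECTORS)) {
    v <- raw[k, ]
    f0 <- mean(v[v <= stats::median(v)])
    if (!is.finite(f0) || f0 <= 0) {
      stop(sprintf("non-positive baseline F in sector %d", k - 1L))
    }
    dff[k, ] <- (v - f0) / f0
  }
  sector_trace(dff, rate = rate, t0 = t0)
}

#' Population vector average of the sector trace
#'
#' Per frame, the vector sum of the 8 unit vectors at the sector centers
#' weighted by dff (negative weights clipped to zero); the bump position is
#' the argument in sector units and the magnitude the modulus. Frames with
#' zero resultant get `NA` position.
#'
#' @param s A `sector_trace`.
#' @return A data.frame: `t` (s), `position` (sectors, in [0, 8)),
#'   `magnitude`. Attribute `clipped_fraction` reports the share of negative
#'   weights clipped.
#' @export
pva <- function(s) {
  stopifnot(inherits(s, "sector_trace"))
  w <- pmax(s$dff, 0)
  clipped <- mean(s$dff < 0)
  angles <- sector_to_rad(0:(N_SECTORS - 1))
  re <- colSums(w * cos(angles))
  im <- colSums(w * sin(angles))
  mag <- sqrt(re^2 + im^2)
  pos <- (rad_to_sector(atan2(im, re))) %% N_SECTORS
  pos[mag < 1e-12 * max(mag, 1)] <- NA_real_
  out <- data.frame(
    t = s$t0 + (seq_len(ncol(s$dff)) - 1) / s$rate,
    position = pos, magnitude = mag
  )
  attr(out, "clipped_fraction") <- clipped
  out
}

# unwrap a circular sector trace to a continuous one
unwrap_sectors <- function(p) {
  d <- circ_diff_sectors(p[-1], p[-length(p)])
  c(p[1], p[1] + cumsum(d))
}

# longest run length of TRUE in a logical vector (in samples)
longest_run <- function(mask) {
  if (!any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

#' Classify bump-jump trials
#'
#' Applies, in order, the inclusion criteria for stimulation trials:
#' (1) exclude when the PVA magnitude drops below the experiment-wide 7th
#' percentile for more than `fade_max_s` during the trial ("faded");
#' (2) exclude when the circular SD of bump position in the 1 s pre-puff
#' window exceeds 1.5 sectors ("pre-moving"); (3) take the initial position as
#' the circular mean of that window; (4) exclude when the post-puff excursion
#' from the initial position never reaches 0.5 sectors ("no-jump");
#' (5) exclude when the bump never dwells within 0.5 sectors of the initial
#' position for at least 0.5 s after the jump ("no-return"). Surviving trials
#' get a signed jump size (at maximum excursion), a return direction
#' (counterclockwise = positive movement back), and an alignment time at the
#' frame of maximal return speed (computed on a 3-frame Gaussian-smoothed
#' position derivative; earlier frame on ties) within the return period, which
#' runs from maximum excursion to re-entry into the 0.5-sector band.
#'
#' @param s A `sector_trace` of dff.
#' @param puff_times Numeric vector of stimulus times (seconds).
#' @param trial_post Trial length after the puff in seconds (default 10).
#' @param pre_window Pre-puff window in seconds (default 1).
#' @param fade_percentile Magnitude percentile defining fading (default 0.07).
#' @param fade_max_s Maximum tolerated faded run in seconds (default 1).
#' @param pre_sd_max Maximum pre-puff circular SD in sectors (default 1.5).
#' @param min_jump Minimum jump in sectors (default 0.5).
#' @param dwell_band Return band in sectors (default 0.5).
#' @param dwell_min_s Minimum dwell in seconds (default 0.5).
#' @return A data.frame, one row per trial: `puff_time`, `include`, `reason`,
#'   `initial_position`, `jump_size` (signed sectors, + = counterclockwise),
#'   `return_path` ("clockwise"/"counterclockwise"/"none"), `alignment_time`.
#' @export
classify_trials <- function(s, puff_times, trial_post = 10, pre_window = 1,
                            fade_percentile = 0.07, fade_max_s = 1,
                            pre_sd_max = 1.5, min_jump = 0.5,
                            dwell_band = 0.5, dwell_min_s = 0.5) {
  stopifnot(inherits(s, "sector_trace"))
  p <- pva(s)
  thr <- stats::quantile(p$magnitude, fade_percentile, names = FALSE)
  rate <- s$rate
  res <- lapply(puff_times, function(tp) {
    row <- list(puff_time = tp, include = FALSE, reason = NA_character_,
                initial_position = NA_real_, jump_size = NA_real_,
                return_path = "none", alignment_time = NA_real_)
    i_puff <- which.min(abs(p$t - tp))
    i0 <- max(1L, i_puff - as.integer(round(pre_window * rate)))
    i1 <- min(nrow(p), i_puff + as.integer(round(trial_post * rate)))
    trial <- i0:i1
    # (1) faded bump
    if (longest_run(p$magnitude[trial] < thr) > fade_max_s * rate) {
      row$reason <- "faded"; return(row)
    }
    pre <- i0:(i_puff - 1L)
    pos_pre <- p$position[pre]
    if (anyNA(pos_pre) || circ_sd_sectors(pos_pre) > pre_sd_max) {
      row$reason <- "pre-moving"; return(row)
    }
    init <- circ_mean_sectors(pos_pre)
    row$initial_position <- init
    post <- i_puff:i1
    pos_post <- p$position[post]
    if (anyNA(pos_post)) { row$reason <- "faded"; return(row) }
    disp <- circ_diff_sectors(pos_post, init)
    if (max(abs(disp)) < min_jump) { row$reason <- "no-jump"; return(row) }
    i_max <- which.max(abs(disp))  # maximum excursion, earliest on ties
    row$jump_size <- disp[i_max]
    # (5) dwell within the band for >= dwell_min_s after the jump
    after <- seq.int(i_max, length(post))
    inband <- abs(disp[after]) <= dwell_band
    if (longest_run(inband) < dwell_min_s * rate) {
      row$reason <- "no-return"; return(row)
    }
    # return period: max excursion -> first re-entry into the band that
    # begins the qualifying dwell
    r <- rle(inband)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= dwell_min_s * rate)[1]
    reentry <- starts[ok]
    ret_idx <- after[seq_len(reentry)]
    # return direction: sign of net movement back toward the initial position
    row$return_path <- if (row$jump_size > 0) "clockwise" else "counterclockwise"
    # return speed on the smoothed unwrapped position
    pos_ret <- unwrap_sectors(p$position[post][ret_idx])
    if (length(pos_ret) >= 3) {
      k <- stats::dnorm(-1:1); k <- k / sum(k)  # 3-frame Gaussian
      pos_s <- conv_same_reflect(pos_ret, k)
      spd <- abs(diff(pos_s)) * rate
      i_spd <- which.max(spd)  # which.max takes the earlier frame on ties
      row$alignment_time <- p$t[post][ret_idx[i_spd]]
    } else {
      row$alignment_time <- p$t[post][ret_idx[length(ret_idx)]]
    }
    row$include <- TRUE
    row$reason <- "included"
    row
  })
  do.call(rbind, lapply(res, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Align trials on the time of maximal bump-return speed and average
#'
#' Groups included trials by return direction, extracts a window of each
#' trial's companion signal around the trial's alignment time, averages within
#' fly and then across flies.
#'
#' @param trials Data.frame as returned by [classify_trials()], plus a `fly`
#'   column; only `include == TRUE` rows are used.
#' @param signals List of `time_series`, one per trial (same order/rate).
#' @param span Half-window in seconds (default 2).
#' @return A named list per return direction with `lag`, `mean`, `n_flies`,
#'   `n_trials`.
#' @export
align_trials_by_return <- function(trials, signals, span = 2) {
  stopifnot(nrow(trials) == length(signals))
  if (is.null(trials$fly)) trials$fly <- 1L
  keep <- which(trials$include)
  out <- list()
  for (dir in unique(trials$return_path[keep])) {
    idx <- keep[trials$return_path[keep] == dir]
    rate <- signals[[idx[1]]]$rate
    w <- as.integer(round(span * rate))
    by_fly <- split(idx, trials$fly[idx])
    fly_means <- list()
    n_trials <- 0L
    for (ids in by_fly) {
      snips <- list()
      for (i in ids) {
        s <- signals[[i]]
        c0 <- as.integer(round((trials$alignment_time[i] - s$t0) * s$rate)) + 1L
        if (c0 - w < 1 || c0 + w > length(s$values)) next
        snips[[length(snips) + 1L]] <- s$values[(c0 - w):(c0 + w)]
      }
      if (length(snips)) {
        fly_means[[length(fly_means) + 1L]] <- colMeans(do.call(rbind, snips))
        n_trials <- n_trials + length(snips)
      }
    }
    if (!length(fly_means)) next
    m <- do.call(rbind, fly_means)
    out[[dir]] <- list(lag = (-w:w) / rate, mean = colMeans(m),
                       n_flies = nrow(m), n_trials = n_trials)
  }
  out
}
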