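# Shared fixtures and independent brute-force oracles used across tests.

# fraction of detected spikes within +/- tol of a true spike, and vice versa
match_spikes <- function(detected, truth, tol = 1e-3) {
  precision <- if (length(detected)) {
    mean(vapply(detected, function(t) any(abs(truth - t) <= tol), logical(1)))
  } else NA_real_
  recall <- if (length(truth)) {
    mean(vapply(truth, function(t) any(abs(detected - t) <= tol), logical(1)))
  } else NA_real_
  list(precision = precision, recall = recall)
}

# brute-force transition scan following the consistency rules literally
oracle_transitions <- function(x, rate, threshold = 75, window = 0.75,
                               consistency = 0.9) {
  w <- as.integer(round(window * rate))
  n <- length(x)
  out <- data.frame(kind = character(0), index = integer(0))
  for (i in 2:n) {
    if (i - w < 1 || i + w - 1 > n) next
    pre <- x[(i - w):(i - 1)]
    post <- x[i:(i + w - 1)]
    if (x[i - 1] <= threshold && x[i] > threshold &&
        mean(pre <= threshold / 2) >= consistency &&
        mean(post > threshold) >= consistency) {
      out <- rbind(out, data.frame(kind = "start", index = i))
    }
    if (x[i - 1] > threshold && x[i] <= threshold &&
        mean(pre > threshold) >= consistency &&
        mean(post <= threshold / 2) >= consistency) {
      out <- rbind(out, data.frame(kind = "stop", index = i))
    }
  }
  out
}

# brute-force 2D re-binning of window triples
oracle_bin_map <- function(a, b, beh, a_breaks, b_breaks, min_count) {
  na <- length(a_breaks) - 1L
  nb <- length(b_breaks) - 1L
  map <- matrix(NA_real_, na, nb)
  count <- matrix(0L, na, nb)
  for (i in seq_along(a)) {
    ai <- findInterval(a[i], a_breaks, rightmost.closed = TRUE)
    bi <- findInterval(b[i], b_breaks, rightmost.closed = TRUE)
    count[ai, bi] <- count[ai, bi] + 1L
  }
  for (i in seq_along(a)) {
    ai <- findInterval(a[i], a_breaks, rightmost.closed = TRUE)
    bi <- findInterval(b[i], b_breaks, rightmost.closed = TRUE)
    if (count[ai, bi] >= min_count) {
      map[ai, bi] <- sum(map[ai, bi], beh[i] / count[ai, bi], na.rm = TRUE)
    }
  }
  list(map = map, count = count)
}

# brute-force connectome grouping/filtering following the rule text literally
oracle_group_filter <- function(df, unitary_min, group_min, frac_min) {
  u <- df[df$count >= unitary_min, , drop = FALSE]
  if (nrow(u) == 0) return(NULL)
  key <- paste(u$pre_type, u$post_type, sep = "->")
  tot <- tapply(u$count, key, sum)
  pre_tot <- tapply(u$count, u$pre_type, sum)
  post_tot <- tapply(u$count, u$post_type, sum)
  keep <- character(0)
  for (k in names(tot)) {
    parts <- strsplit(k, "->", fixed = TRUE)[[1]]
    ok <- tot[[k]] >= group_min &&
      tot[[k]] / pre_tot[[parts[1]]] >= frac_min &&
      tot[[k]] / post_tot[[parts[2]]] >= frac_min
    if (ok) keep <- c(keep, k)
  }
  sort(keep)
}

# random synapse table for oracle comparisons
random_synapse_table <- function(n_rows, n_types = 4) {
  types <- paste0("T", seq_len(n_types))
  synapse_table(data.frame(
    pre_id = paste0("c", sample.int(50, n_rows, TRUE)),
    pre_type = sample(types, n_rows, TRUE),
    pre_side = sample(c("L", "R"), n_rows, TRUE),
    post_id = paste0("d", sample.int(50, n_rows, TRUE)),
    post_type = sample(types, n_rows, TRUE),
    post_side = sample(c("L", "R"), n_rows, TRUE),
    count = sample.int(30, n_rows, TRUE)
  ))
}

# staircase heading that parks the bump on a different sector each trial, so
# per-sector dff baselines are well defined
staircase_heading <- function(n_trials, trial_s = 15, rate = 12) {
  nfr <- as.integer(n_trials * trial_s * rate)
  tt <- (seq_len(nfr) - 1) / rate
  time_series(90 * floor(tt / trial_s), rate)
}
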