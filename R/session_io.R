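# Session bundle I/O and the end-to-end demonstration pipeline. Dense arrays
# are stored as plain-text CSV at full (17 significant digit) precision, which
# round-trips doubles losslessly; metadata travels in a JSON sidecar.

fmt_full <- function(x) formatC(x, digits = 17, format = "g")

write_numeric_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) fmt_full(col) else col
  }))
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a session bundle to a directory
#'
#' Serializes a synthetic or recorded session (kinematics, per-cell voltage
#' and firing rate, spike times, metadata) as plain-text CSV plus a JSON
#' manifest. Numeric round-trip through [read_session()] is lossless.
#'
#' @param session A `synthetic_session` (or a list with the same fields).
#' @param path Directory to create/fill.
#' @param metadata Named list merged into the manifest; `fly_id` and
#'   `genotype` are required.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, metadata = list(fly_id = "fly1",
                                                         genotype = "wt")) {
  required <- c("fly_id", "genotype")
  missing <- setdiff(required, names(metadata))
  if (length(missing)) stop("missing required metadata: ",
                            paste(missing, collapse = ", "))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  k <- session$kinematics
  write_numeric_csv(data.frame(v_r = k$v_r, v_s = k$v_s, v_f = k$v_f),
                    file.path(path, "kinematics.csv"))
  manifest <- list(
    format_version = 1L,
    kinematics = list(rate = k$rate, t0 = k$t0, n = length(k$v_r)),
    cells = names(session$true_rate),
    metadata = metadata
  )
  for (cell in names(session$true_rate)) {
    r <- session$true_rate[[cell]]
    write_numeric_csv(data.frame(rate = r$values),
                      file.path(path, sprintf("rate_%s.csv", cell)))
    manifest$rates[[cell]] <- list(rate = r$rate, t0 = r$t0, n = length(r$values))
    write_numeric_csv(data.frame(time = session$true_spike_times[[cell]]),
                      file.path(path, sprintf("spikes_%s.csv", cell)))
    if (!is.null(session$voltage[[cell]])) {
      v <- session$voltage[[cell]]
      write_numeric_csv(data.frame(mV = v$values),
                        file.path(path, sprintf("voltage_%s.csv", cell)))
      manifest$voltage[[cell]] <- list(rate = v$rate, t0 = v$t0, n = length(v$values))
    }
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_checked_csv <- function(path, expected_n = NULL) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("corrupt session file ", path, ": ",
                                          conditionMessage(e)))
  if (!is.null(expected_n) && nrow(df) != expected_n) {
    stop(sprintf("corrupt session file %s: expected %d rows, found %d",
                 path, expected_n, nrow(df)))
  }
  df
}

#' Read a session bundle written by [write_session()]
#'
#' @param path Session directory.
#' @return A list mirroring the written session: `kinematics`, `true_rate`,
#'   `true_spike_times`, `voltage` (may be NULL), `metadata`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a session directory (no manifest.json): ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  required <- c("fly_id", "genotype")
  missing <- setdiff(required, names(manifest$metadata))
  if (length(missing)) stop("manifest missing required metadata: ",
                            paste(missing, collapse = ", "))
  km <- manifest$kinematics
  kdf <- read_checked_csv(file.path(path, "kinematics.csv"), km$n)
  kin <- kinematics_trace(kdf$v_r, kdf$v_s, kdf$v_f, rate = km$rate, t0 = km$t0)
  rates <- list(); spikes <- list(); voltage <- NULL
  for (cell in manifest$cells) {
    rm_ <- manifest$rates[[cell]]
    rdf <- read_checked_csv(file.path(path, sprintf("rate_%s.csv", cell)), rm_$n)
    rates[[cell]] <- time_series(rdf$rate, rate = rm_$rate, t0 = rm_$t0,
                                 units = "spikes/s")
    sdf <- read_checked_csv(file.path(path, sprintf("spikes_%s.csv", cell)))
    spikes[[cell]] <- sdf$time
    vm <- manifest$voltage[[cell]]
    if (!is.null(vm)) {
      vdf <- read_checked_csv(file.path(path, sprintf("voltage_%s.csv", cell)), vm$n)
      voltage[[cell]] <- time_series(vdf$mV, rate = vm$rate, t0 = vm$t0,
                                     units = "mV")
    }
  }
  list(kinematics = kin, true_rate = rates, true_spike_times = spikes,
       voltage = voltage, metadata = manifest$metadata)
}

#' Run the end-to-end demonstration pipeline
#'
#' Simulate -> preprocess -> (optionally detect spikes) -> estimate filters ->
#' predict behavior -> detect transitions, logging parameters at every stage.
#' Re-running the same config reproduces all outputs exactly.
#'
#' @param config A [sim_config()]; keep `simulate_voltage = FALSE` for a fast
#'   rate-based run, `TRUE` to exercise spike detection.
#' @param prominence Spike-detection prominence (normalized units; used only
#'   when voltage is simulated).
#' @param alpha Random-walk smoothing noise fraction (default 0.2).
#' @return A list: `session`, `kinematics_smoothed`, `rates` (per cell, on the
#'   kinematics time base), `filters`, `predictions` (per cell and axis
#'   reports), `transitions`, `log` (data.frame of stage parameters).
#' @export
run_pipeline <- function(config = sim_config(duration = 120,
                                             simulate_voltage = FALSE),
                         prominence = 6, alpha = 0.2) {
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage,
                                           params = paste(..., sep = "; "))
  }
  note("simulate", sprintf("seed=%d duration=%.0f", config$seed, config$duration))
  session <- simulate_steering_session(config)

  k <- session$kinematics
  smooth_chan <- function(v) {
    x <- time_series(v, rate = k$rate, units = "deg/s")
    x <- correct_offset(x)
    x <- smooth_gaussian(x)
    smooth_random_walk_map(x, random_walk_params(alpha = alpha))
  }
  note("preprocess", sprintf("alpha=%.2f offset_threshold=0.025", alpha))
  kin_s <- kinematics_trace(smooth_chan(k$v_r)$values, smooth_chan(k$v_s)$values,
                            smooth_chan(k$v_f)$values, rate = k$rate)

  rates <- list()
  for (cell in config$cells) {
    if (!is.null(session$voltage)) {
      note("spikes", sprintf("cell=%s prominence=%.1f", cell, prominence))
      st <- detect_spikes(session$voltage[[cell]], prominence = prominence)
    } else {
      st <- spike_train(session$true_spike_times[[cell]],
                        span = c(0, config$duration))
    }
    rf <- rate_fine(st)
    rates[[cell]] <- resample_neural_to_kinematics(rf, k$rate)
  }

  n <- length(kin_s$v_r)
  n_train <- floor(0.2 * n)
  filters <- list(); predictions <- list()
  vr <- kin_channel(kin_s, "v_r")
  for (cell in config$cells) {
    r <- rates[[cell]]
    r$values <- r$values[seq_len(min(n, length(r$values)))]
    train_in <- time_series(r$values[1:n_train], rate = k$rate, units = r$units)
    train_out <- time_series(vr$values[1:n_train], rate = k$rate, units = "deg/s")
    note("filters", sprintf("cell=%s direction=n2b bandwidth=15", cell))
    filters[[cell]] <- estimate_filter(train_in, train_out, bandwidth = 15)
    predictions[[cell]] <- predict_behavior(filters[[cell]], r, vr)$report
  }

  note("events", "threshold=75 window=0.75")
  transitions <- detect_transitions(total_speed(kin_s))

  list(session = session, kinematics_smoothed = kin_s, rates = rates,
       filters = filters, predictions = predictions,
       transitions = transitions, log = do.call(rbind, log))
}
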