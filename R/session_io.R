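# Session data model, delimited-table readers/writers, and clock synchronization.

EVENT_CODES <- c("trial_available", "initiation_poke", "cue_on",
                 "side_poke_left", "side_poke_right", "reward_delivery",
                 "iti_start")

#' Construct a session recording
#'
#' Holds per-cell deconvolved calcium event-amplitude traces sampled on the
#' imaging clock. The traces are the output contract of an upstream
#' deconvolution step: non-negative per-frame amplitudes, one row per cell.
#'
#' @param traces numeric matrix, cells x frames, non-negative.
#' @param frame_rate sampling rate in Hz (20 for the miniscope).
#' @param cell_ids character vector of cell identifiers (default from
#'   rownames or `cell_1..n`).
#' @param start_time time of the first frame on the imaging clock, seconds.
#' @return a `session_recording` object.
#' @export
session_recording <- function(traces, frame_rate = 20, cell_ids = NULL,
                              start_time = 0) {
  traces <- as.matrix(traces)
  if (any(!is.finite(traces))) abort("traces must be finite")
  if (any(traces < 0)) abort("traces must be non-negative (deconvolved amplitudes)")
  if (frame_rate <= 0) abort("frame_rate must be positive")
  if (is.null(cell_ids)) {
    cell_ids <- rownames(traces)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(traces)))
  }
  if (length(cell_ids) != nrow(traces)) abort("cell_ids length must match rows of traces")
  rownames(traces) <- cell_ids
  frame_times <- start_time + (seq_len(ncol(traces)) - 1) / frame_rate
  structure(list(cell_ids = as.character(cell_ids),
                 frame_rate = frame_rate,
                 traces = traces,
                 frame_times = frame_times),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording: %d cells x %d frames @ %g Hz (%.1f s)>\n",
              nrow(x$traces), ncol(x$traces), x$frame_rate,
              ncol(x$traces) / x$frame_rate))
  invisible(x)
}

#' Construct a behavioral event log
#'
#' @param events data.frame with columns `time_s` (behavioral clock,
#'   non-decreasing), `event_code` (one of the operant event codes), and
#'   `port` (`"left"`, `"right"`, `"center"`, or `""`).
#' @param sync_edges numeric vector of sync-pulse edge times on the
#'   behavioral clock.
#' @return a `behavior_log` object.
#' @export
behavior_log <- function(events, sync_edges = numeric()) {
  req <- c("time_s", "event_code", "port")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    abort(sprintf("events table missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  events <- as.data.frame(events)[req]
  events$time_s <- as.numeric(events$time_s)
  events$event_code <- as.character(events$event_code)
  events$port <- as.character(events$port)
  if (is.unsorted(events$time_s)) abort("event times must be non-decreasing")
  bad <- setdiff(unique(events$event_code), EVENT_CODES)
  if (length(bad)) abort(sprintf("unknown event_code(s): %s", paste(bad, collapse = ", ")))
  # every reward must follow at least one side poke
  rewards <- which(events$event_code == "reward_delivery")
  if (length(rewards)) {
    first_poke <- match(TRUE, events$event_code %in% c("side_poke_left", "side_poke_right"))
    if (is.na(first_poke) || rewards[1] < first_poke) {
      abort("reward_delivery precedes any side poke: invalid event stream")
    }
  }
  structure(list(events = events, sync_edges = as.numeric(sync_edges)),
            class = "behavior_log")
}

#' @export
print.behavior_log <- function(x, ...) {
  cat(sprintf("<behavior_log: %d events, %d sync edges>\n",
              nrow(x$events), length(x$sync_edges)))
  invisible(x)
}

#' Fit the behavioral-to-imaging clock map
#'
#' The behavioral controller and the imaging acquisition share a train of
#' 5 s on/off sync pulses; both record the edge times on their own clocks.
#' Edges are matched by rank order (after trimming unpaired leading/trailing
#' edges when the trains differ in length) and an affine map
#' `imaging = offset + drift * behavior` is fit by least squares. A pure
#' offset is the `drift = 1` special case; over a 40 min session real
#' acquisition clocks drift, so the gain is estimated too.
#'
#' @param behavior_edges edge times on the behavioral clock.
#' @param imaging_edges edge times on the imaging clock.
#' @param tolerance maximum acceptable residual RMS in seconds (default
#'   0.025 s, half a frame at 20 Hz).
#' @return a `clock_map` with `offset`, `drift`, `residual_rms`, `n_edges`.
#' @export
fit_clock_map <- function(behavior_edges, imaging_edges, tolerance = 0.025) {
  b <- as.numeric(behavior_edges)
  im <- as.numeric(imaging_edges)
  nb <- length(b); ni <- length(im)
  n <- min(nb, ni)
  if (n < 3) abort("need at least 3 shared sync edges to fit the clock map")
  # slide the shorter train along the longer and keep the alignment with the
  # smallest residual RMS (trims unpaired leading/trailing edges)
  lag_max <- abs(nb - ni)
  best <- NULL
  for (lag in 0:lag_max) {
    if (nb >= ni) {
      bb <- b[(1 + lag):(lag + n)]; ii <- im
    } else {
      bb <- b; ii <- im[(1 + lag):(lag + n)]
    }
    fit <- lm(ii ~ bb)
    rms <- sqrt(mean(resid(fit)^2))
    if (is.null(best) || rms < best$rms) {
      best <- list(offset = unname(coef(fit)[1]), drift = unname(coef(fit)[2]),
                   rms = rms)
    }
  }
  if (best$drift <= 0.9 || best$drift >= 1.1) {
    abort(sprintf("fitted clock drift %.4f outside (0.9, 1.1): edge trains misaligned",
                  best$drift))
  }
  if (best$rms > tolerance) {
    abort(sprintf("clock fit residual RMS %.4f s exceeds tolerance %.4f s: desynchronized",
                  best$rms, tolerance))
  }
  structure(list(offset = best$offset, drift = best$drift,
                 residual_rms = best$rms, n_edges = n),
            class = "clock_map")
}

#' Identity clock map (offset 0, drift 1)
#' @export
identity_clock_map <- function() {
  structure(list(offset = 0, drift = 1, residual_rms = 0, n_edges = NA_integer_),
            class = "clock_map")
}

#' @export
print.clock_map <- function(x, ...) {
  cat(sprintf("<clock_map: imaging = %.6g + %.8g * behavior, residual RMS %.4g s>\n",
              x$offset, x$drift, x$residual_rms))
  invisible(x)
}

#' Map behavioral-clock times onto imaging clock
#' @param times_behavior times on the behavioral clock, seconds.
#' @param clock a [fit_clock_map()] result.
#' @return times on the imaging clock.
#' @export
to_imaging_time <- function(times_behavior, clock) {
  clock$offset + clock$drift * times_behavior
}

#' Map behavioral times to imaging frame indices
#'
#' Applies the clock map and assigns each time to the frame whose half-open
#' interval \[frame start, next frame start) contains it:
#' `floor((t - t0) * frame_rate)`, 0-based. Times mapping outside the
#' recording are returned as `NA` and counted in the `n_out_of_range`
#' attribute (a message reports the count).
#'
#' @param times_behavior times on the behavioral clock, seconds.
#' @param clock a `clock_map`.
#' @param recording a [session_recording()].
#' @return integer vector of 0-based frame indices (NA where out of range),
#'   with attribute `n_out_of_range`.
#' @export
map_to_frames <- function(times_behavior, clock, recording) {
  t_img <- to_imaging_time(times_behavior, clock)
  t0 <- recording$frame_times[1]
  idx <- floor((t_img - t0) * recording$frame_rate + 1e-9)
  out <- idx < 0 | idx >= ncol(recording$traces)
  idx[out] <- NA_integer_
  n_out <- sum(out)
  if (n_out > 0) {
    message(sprintf("map_to_frames: %d event(s) outside the recording excluded", n_out))
  }
  structure(as.integer(idx), n_out_of_range = n_out)
}

# ---- delimited-table session bundle -----------------------------------------

#' Write a session bundle to disk
#'
#' Writes the traces as a delimited matrix (row = cell, column = frame),
#' the behavioral events and sync tables, any ground-truth tables, and a
#' YAML manifest referencing them all.
#'
#' @param recording a [session_recording()].
#' @param log a [behavior_log()].
#' @param dir output directory (created if needed).
#' @param imaging_sync_edges optional sync edge times on the imaging clock,
#'   paired by order with `log$sync_edges`.
#' @param trials optional ground-truth trial table (data.frame).
#' @param profiles optional list of [tuning_profile()] ground truths.
#' @param sep field delimiter (`","` default).
#' @return the manifest path, invisibly.
#' @export
write_session <- function(recording, log, dir, imaging_sync_edges = NULL,
                          trials = NULL, profiles = NULL, sep = ",") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- data.table::data.table(cell_id = recording$cell_ids)
  tr <- cbind(tr, data.table::as.data.table(unname(recording$traces)))
  data.table::setnames(tr, c("cell_id", paste0("f", seq_len(ncol(recording$traces)) - 1)))
  traces_path <- file.path(dir, "traces.csv")
  data.table::fwrite(tr, traces_path, sep = sep)

  events_path <- file.path(dir, "events.csv")
  data.table::fwrite(log$events, events_path, sep = sep)

  sync_path <- file.path(dir, "sync.csv")
  sync <- data.frame(edge_time_behavior_s = log$sync_edges)
  if (!is.null(imaging_sync_edges)) {
    n <- min(length(log$sync_edges), length(imaging_sync_edges))
    sync <- data.frame(edge_time_behavior_s = log$sync_edges[seq_len(n)],
                       edge_time_imaging_s = imaging_sync_edges[seq_len(n)])
  }
  data.table::fwrite(sync, sync_path, sep = sep)

  manifest <- list(
    format = "miniepoch-session/1",
    frame_rate = recording$frame_rate,
    start_time = recording$frame_times[1],
    traces = basename(traces_path),
    events = basename(events_path),
    sync = basename(sync_path)
  )
  if (!is.null(trials)) {
    trials_path <- file.path(dir, "trials_truth.csv")
    data.table::fwrite(as.data.frame(trials), trials_path, sep = sep)
    manifest$trials_truth <- basename(trials_path)
  }
  if (!is.null(profiles)) {
    prof_path <- file.path(dir, "tuning_truth.csv")
    data.table::fwrite(profiles_to_table(profiles), prof_path, sep = sep)
    manifest$tuning_truth <- basename(prof_path)
  }
  manifest_path <- file.path(dir, "session.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

profiles_to_table <- function(profiles) {
  data.table::rbindlist(lapply(profiles, function(p) {
    mult <- setNames(rep(1, length(EPOCH_ORDER)), EPOCH_ORDER)
    mult[names(p$epoch_multipliers)] <- p$epoch_multipliers
    c(list(cell_id = p$cell_id, baseline_rate = p$baseline_rate,
           amplitude_scale = p$amplitude_scale),
      as.list(setNames(mult, paste0("mult_", names(mult)))))
  }))
}

#' Read a session bundle
#'
#' Reads a bundle written by [write_session()] (or any bundle conforming to
#' the same manifest schema: delimited traces with a `cell_id` column and
#' one column per frame, an events table with `time_s`/`event_code`/`port`,
#' and a sync table). The delimiter is auto-detected. Validation errors name
#' the offending field.
#'
#' @param dir_or_manifest a bundle directory or the path of its YAML
#'   manifest.
#' @return list with `recording`, `log`, `imaging_sync_edges` (or NULL), and
#'   any ground-truth tables present.
#' @export
read_session <- function(dir_or_manifest) {
  manifest_path <- if (dir.exists(dir_or_manifest)) {
    file.path(dir_or_manifest, "session.yaml")
  } else dir_or_manifest
  if (!file.exists(manifest_path)) abort(sprintf("no manifest at %s", manifest_path))
  manifest <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  for (field in c("traces", "events", "sync", "frame_rate")) {
    if (is.null(manifest[[field]])) abort(sprintf("manifest missing field '%s'", field))
  }

  tr <- data.table::fread(file.path(dir, manifest$traces))
  if (!"cell_id" %in% names(tr)) abort("traces table missing column 'cell_id'")
  cell_ids <- as.character(tr$cell_id)
  mat <- as.matrix(tr[, -1, drop = FALSE])
  if (any(mat < 0)) abort("traces contain negative amplitudes")
  recording <- session_recording(mat, frame_rate = manifest$frame_rate,
                                 cell_ids = cell_ids,
                                 start_time = manifest$start_time %||% 0)

  ev <- data.table::fread(file.path(dir, manifest$events))
  sync <- data.table::fread(file.path(dir, manifest$sync))
  if (!"edge_time_behavior_s" %in% names(sync)) {
    abort("sync table missing column 'edge_time_behavior_s'")
  }
  log <- behavior_log(as.data.frame(ev), sync_edges = sync$edge_time_behavior_s)

  out <- list(recording = recording, log = log,
              imaging_sync_edges = sync$edge_time_imaging_s)
  if (!is.null(manifest$trials_truth)) {
    out$trials_truth <- as.data.frame(
      data.table::fread(file.path(dir, manifest$trials_truth)))
  }
  if (!is.null(manifest$tuning_truth)) {
    out$tuning_truth <- as.data.frame(
      data.table::fread(file.path(dir, manifest$tuning_truth)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
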