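# Trial categorization, epoch windows, and per-trial epoch/baseline rates.

#' Parse a behavioral event log into a trial table
#'
#' Each initiation poke starts exactly one trial. Outcomes follow the
#' operant rules: *correct* = a response at the cued port within the
#' response window (rewarded), *incorrect* = a response at the non-cued
#' port, *omitted* = no response within the window. In the delay task, side
#' pokes during the delay increment `premature_count` only and never change
#' the outcome. The ITI preceding each trial (from `iti_start` to
#' `trial_available`) is recorded; trials whose preceding ITI is missing or
#' shorter than the baseline window are retained but flagged
#' `baseline_complete = FALSE`.
#'
#' @param log a [behavior_log()].
#' @param task a [task_spec()].
#' @return a `trial_table` data.frame (times on the behavioral clock).
#' @export
build_trials <- function(log, task) {
  ev <- log$events
  inits <- which(ev$event_code == "initiation_poke")
  rows <- vector("list", length(inits))
  for (k in seq_along(inits)) {
    i <- inits[k]
    init_t <- ev$time_s[i]
    # preceding availability and ITI start
    before <- ev[seq_len(i - 1), , drop = FALSE]
    avail_idx <- max(which(before$event_code == "trial_available"), -Inf)
    avail_t <- if (is.finite(avail_idx)) before$time_s[avail_idx] else NA_real_
    iti_idx <- if (is.finite(avail_idx)) {
      w <- which(before$event_code == "iti_start" & before$time_s <= avail_t)
      if (length(w)) max(w) else NA_integer_
    } else NA_integer_
    iti_start_t <- if (!is.na(iti_idx)) before$time_s[iti_idx] else NA_real_

    # events belonging to this trial: up to the next initiation (or end)
    hi <- if (k < length(inits)) inits[k + 1] - 1 else nrow(ev)
    span <- ev[i:hi, , drop = FALSE]
    cue_idx <- which(span$event_code == "cue_on")
    if (!length(cue_idx)) next  # malformed trial: no cue record
    cue_t <- span$time_s[cue_idx[1]]
    cued_port <- span$port[cue_idx[1]]
    win_end <- cue_t + task$cue_duration

    pokes <- span[span$event_code %in% c("side_poke_left", "side_poke_right"), ,
                  drop = FALSE]
    premature <- 0L
    if (task$task_kind == "delay") {
      premature <- sum(pokes$time_s >= init_t & pokes$time_s < cue_t)
    }
    in_win <- pokes[pokes$time_s >= cue_t & pokes$time_s < win_end, , drop = FALSE]
    if (nrow(in_win)) {
      resp_t <- in_win$time_s[1]
      resp_port <- in_win$port[1]
      outcome <- if (resp_port == cued_port) "correct" else "incorrect"
    } else {
      resp_t <- NA_real_; resp_port <- NA_character_; outcome <- "omitted"
    }
    rew <- span[span$event_code == "reward_delivery", , drop = FALSE]
    reward_t <- if (nrow(rew)) rew$time_s[1] else NA_real_
    if ((outcome == "correct") != !is.na(reward_t)) {
      abort(sprintf(
        "event stream inconsistent at trial %d: outcome '%s' but reward %s",
        k, outcome, if (is.na(reward_t)) "absent" else "present"))
    }
    iti_len <- avail_t - iti_start_t
    rows[[k]] <- data.frame(
      trial = k, availability_time = avail_t, initiation_time = init_t,
      cue_on_time = cue_t, response_time = resp_t, response_port = resp_port,
      cued_port = cued_port, reward_time = reward_t, outcome = outcome,
      premature_count = premature, iti_start = iti_start_t,
      baseline_complete = !is.na(iti_len) && iti_len >= task$baseline_window,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) abort("no trials found in the event log")
  out$trial <- seq_len(nrow(out))
  class(out) <- c("trial_table", "data.frame")
  attr(out, "task_kind") <- task$task_kind
  out
}

#' Epoch windows of one correct trial
#'
#' Returns the absolute half-open windows (behavioral clock) of every epoch
#' analysed for a correct trial. Cue-guided task: T = 2 s before initiation,
#' C = initiation through the cue response, R = 0--3 s after reward,
#' P = 3--6 s after reward. Delay task adds D = the 3 s delay and anchors C
#' at cue onset. The baseline window is the last 6 s of the preceding ITI
#' (ending at trial availability).
#'
#' @param trial one row of a [build_trials()] table.
#' @param task a [task_spec()].
#' @param include_cue_in_delay see [task_epochs()].
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
epoch_windows <- function(trial, task, include_cue_in_delay = TRUE) {
  if (trial$outcome != "correct") {
    abort("epoch windows are defined for correct trials only")
  }
  if (is.na(trial$reward_time)) {
    abort("correct trial without a reward time: inconsistent trial record")
  }
  init <- trial$initiation_time
  rew <- trial$reward_time
  w <- list(c("T", init - 2, init))
  if (task$task_kind == "delay") {
    w <- c(w, list(c("D", init, init + task$delay_duration)))
    if (include_cue_in_delay) {
      w <- c(w, list(c("C", trial$cue_on_time, trial$response_time)))
    }
  } else {
    w <- c(w, list(c("C", init, trial$response_time)))
  }
  w <- c(w, list(
    c("R", rew, rew + task$reward_epoch),
    c("P", rew + task$post_reward_epoch[1], rew + task$post_reward_epoch[2]),
    c("baseline", trial$availability_time - task$baseline_window,
      trial$availability_time)))
  out <- data.frame(label = vapply(w, `[[`, "", 1),
                    start = as.numeric(vapply(w, `[[`, "", 2)),
                    end = as.numeric(vapply(w, `[[`, "", 3)),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) {
    abort("degenerate epoch window (end <= start)")
  }
  out
}

#' Calcium event rate within a frame window
#'
#' The event rate is the number of supra-threshold frames per second of the
#' deconvolved amplitude trace: `#\{frames with amplitude > threshold\} /
#' (n_frames / frame_rate)`.
#'
#' @param trace numeric vector of one cell's per-frame amplitudes.
#' @param frames integer vector of (1-based) frame indices in the window.
#' @param frame_rate frames per second.
#' @param threshold amplitude threshold (default 0: any nonzero event
#'   counts).
#' @return events per second.
#' @export
event_rate <- function(trace, frames, frame_rate = 20, threshold = 0) {
  if (!length(frames)) abort("empty window")
  if (any(frames < 1 | frames > length(trace))) abort("window outside trace")
  sum(trace[frames] > threshold) / (length(frames) / frame_rate)
}

# Convert a half-open time window on the behavioral clock into 1-based
# imaging frame indices; NULL when the window falls (partly) outside.
window_frames <- function(start, end, clock, recording) {
  t0 <- recording$frame_times[1]
  fr <- recording$frame_rate
  s_img <- to_imaging_time(start, clock)
  e_img <- to_imaging_time(end, clock)
  f1 <- as.integer(ceiling((s_img - t0) * fr - 1e-9))  # first frame time >= start
  f2 <- as.integer(ceiling((e_img - t0) * fr - 1e-9))  # first frame time >= end
  if (f1 < 0 || f2 > ncol(recording$traces) || f2 <= f1) return(NULL)
  (f1 + 1):f2  # 0-based [f1, f2) -> 1-based indices
}

#' Build the cells x trials x epochs event-rate table
#'
#' For every correct trial with a complete baseline, computes each cell's
#' event rate in every task epoch and in the paired baseline window (the
#' last 6 s of that trial's preceding ITI). Trials that are incorrect,
#' omitted, baseline-incomplete, or whose windows fall outside the recording
#' are excluded; the exclusion counts are stored in attributes.
#'
#' @param recording a [session_recording()].
#' @param trials a [build_trials()] table.
#' @param task a [task_spec()].
#' @param clock a `clock_map` aligning behavioral times to the imaging
#'   clock (default: identity).
#' @param threshold amplitude threshold for [event_rate()].
#' @param baseline_pairing `"per_trial"` pairs each trial's epoch rates with
#'   that trial's own preceding-ITI rate; `"session_mean"` pairs every trial
#'   with the cell's across-ITI average baseline.
#' @param include_cue_in_delay see [task_epochs()].
#' @return a `rate_table` data.frame with columns `cell_id`, `trial`,
#'   `epoch`, `rate`, `baseline_rate`; attributes `epochs`,
#'   `n_trials_used`, `n_excluded` (named counts).
#' @export
build_rate_table <- function(recording, trials, task, clock = identity_clock_map(),
                             threshold = 0,
                             baseline_pairing = c("per_trial", "session_mean"),
                             include_cue_in_delay = TRUE) {
  baseline_pairing <- match.arg(baseline_pairing)
  epochs <- task_epochs(task, include_cue_in_delay)
  correct <- trials[trials$outcome == "correct", , drop = FALSE]
  n_excluded <- c(not_correct = nrow(trials) - nrow(correct),
                  incomplete_baseline = sum(!correct$baseline_complete),
                  outside_recording = 0L)
  correct <- correct[correct$baseline_complete, , drop = FALSE]

  fr <- recording$frame_rate
  tr <- recording$traces
  supra <- tr > threshold
  blocks <- list()
  for (k in seq_len(nrow(correct))) {
    trial <- correct[k, ]
    wins <- epoch_windows(trial, task, include_cue_in_delay)
    frames <- lapply(seq_len(nrow(wins)), function(j) {
      window_frames(wins$start[j], wins$end[j], clock, recording)
    })
    if (any(vapply(frames, is.null, TRUE))) {
      n_excluded[["outside_recording"]] <- n_excluded[["outside_recording"]] + 1L
      next
    }
    names(frames) <- wins$label
    rates <- vapply(epochs, function(ep) {
      f <- frames[[ep]]
      rowSums(supra[, f, drop = FALSE]) / (length(f) / fr)
    }, numeric(nrow(tr)))
    fb <- frames[["baseline"]]
    base <- rowSums(supra[, fb, drop = FALSE]) / (length(fb) / fr)
    blocks[[length(blocks) + 1]] <- data.frame(
      cell_id = rep(recording$cell_ids, times = length(epochs)),
      trial = trial$trial,
      epoch = rep(epochs, each = nrow(tr)),
      rate = as.vector(rates),
      baseline_rate = rep(base, times = length(epochs)),
      stringsAsFactors = FALSE)
  }
  if (!length(blocks)) abort("no usable trials (correct with complete baseline)")
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  if (baseline_pairing == "session_mean") {
    # one baseline value per (cell, trial); average the per-trial values
    per_ct <- out[out$epoch == epochs[1], c("cell_id", "baseline_rate")]
    means <- tapply(per_ct$baseline_rate, per_ct$cell_id, mean)
    out$baseline_rate <- as.numeric(means[out$cell_id])
  }
  class(out) <- c("rate_table", "data.frame")
  attr(out, "epochs") <- epochs
  attr(out, "task_kind") <- task$task_kind
  attr(out, "n_trials_used") <- length(unique(out$trial))
  attr(out, "n_excluded") <- n_excluded
  attr(out, "baseline_pairing") <- baseline_pairing
  out
}
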