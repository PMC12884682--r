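# Synthetic operant imaging sessions with ground-truth tuning.
#
# The generator emulates the structure the downstream analysis assumes:
# self-initiated trials with a variable ITI, a ~59/5/37% correct/incorrect/
# omitted outcome mixture, Poisson per-frame calcium event counts with
# gamma-distributed amplitudes and per-epoch multiplicative tuning, and a
# 5 s on/off sync-pulse train recorded on both clocks with configurable
# offset/drift/jitter.

#' Generate one synthetic session
#'
#' Draws a trial schedule on the behavioral clock, an event log, sync-pulse
#' edge times on both clocks, and cells-by-frames event-amplitude traces on
#' the imaging clock. Per-frame event counts are Poisson with rate
#' `baseline_rate * multiplier(current epoch) / frame_rate`; event
#' amplitudes are gamma distributed with mean `amplitude_scale`. Epoch
#' multipliers act on the ground-truth epoch windows of each trial (T on
#' every trial; C on responded trials; D on delay-task trials; R and P on
#' rewarded trials only).
#'
#' @param task a [task_spec()].
#' @param profiles list of [tuning_profile()], one per cell.
#' @param cohort a [cohort_spec()] supplying behavioral parameters
#'   (outcome mixture, latencies, premature rate).
#' @param seed integer seed; regeneration with the same arguments is
#'   bit-identical.
#' @param clock true behavioral-to-imaging clock: list with `offset`
#'   (seconds), `drift` (gain), `jitter_sd` (per-edge jitter, seconds).
#' @param frame_rate imaging frame rate, Hz.
#' @return list with `recording` ([session_recording()]), `log`
#'   ([behavior_log()]), `imaging_sync_edges`, ground-truth `trials`
#'   data.frame, `profiles`, and the true `clock`.
#' @export
generate_session <- function(task, profiles, cohort, seed,
                             clock = list(offset = 0, drift = 1, jitter_sd = 0),
                             frame_rate = 20) {
  if (!length(profiles)) abort("at least one tuning profile (cell) is required")
  if (is.null(task$session_length) && task$n_trials < 1) {
    abort("at least one trial is required")
  }
  clock <- modifyList(list(offset = 0, drift = 1, jitter_sd = 0), clock)
  with_seed(seed, {
    trials <- schedule_trials(task, cohort)
    if (nrow(trials) == 0) {
      abort("session too short for one full trial plus ITI")
    }
    log <- trials_to_log(trials, task)
    session_end <- max(trials$trial_end) + task$iti_mean / 2

    beh_edges <- seq(0, session_end, by = 5)
    img_edges <- clock$offset + clock$drift * beh_edges +
      (if (clock$jitter_sd > 0) rnorm(length(beh_edges), 0, clock$jitter_sd) else 0)
    log$sync_edges <- beh_edges

    n_frames <- ceiling((clock$offset + clock$drift * session_end) * frame_rate)
    traces <- synth_traces(profiles, trials, task, clock, n_frames, frame_rate)
    recording <- session_recording(traces, frame_rate = frame_rate,
                                   cell_ids = vapply(profiles, `[[`, "", "cell_id"))
    list(recording = recording, log = log, imaging_sync_edges = img_edges,
         trials = trials, profiles = profiles, clock = clock)
  })
}

# Draw the trial schedule on the behavioral clock.
schedule_trials <- function(task, cohort) {
  iti_lo <- task$iti_mean * task$iti_range[1]
  iti_hi <- task$iti_mean * task$iti_range[2]
  outcomes <- names(cohort$trial_outcome_mixture)
  lat_mean <- cohort$response_latency[["mean"]]
  lat_sd <- cohort$response_latency[["sd"]]
  lat_shape <- (lat_mean / lat_sd)^2
  lat_rate <- lat_mean / lat_sd^2
  rows <- list()
  t_cursor <- 0
  i <- 0L
  repeat {
    i <- i + 1L
    if (is.null(task$session_length)) {
      if (i > task$n_trials) break
    }
    iti <- runif(1, iti_lo, iti_hi)
    avail <- t_cursor + iti
    init <- avail + rexp(1, 1 / cohort$initiation_latency)
    cue_on <- if (task$task_kind == "delay") init + task$delay_duration else init
    if (!is.null(task$session_length) &&
        cue_on + task$cue_duration + task$post_reward_epoch[2] > task$session_length) {
      break
    }
    outcome <- sample(outcomes, 1, prob = cohort$trial_outcome_mixture)
    cued_port <- sample(c("left", "right"), 1)
    premature <- 0L
    if (task$task_kind == "delay" && cohort$premature_rate > 0) {
      premature <- rpois(1, cohort$premature_rate * task$delay_duration)
    }
    # response latency: truncated gamma via inverse CDF so it always lands
    # inside the response window
    if (outcome == "omitted") {
      response <- NA_real_; response_port <- NA_character_; reward <- NA_real_
    } else {
      fmax <- stats::pgamma(task$cue_duration, shape = lat_shape, rate = lat_rate)
      latency <- stats::qgamma(runif(1, 0, fmax), shape = lat_shape, rate = lat_rate)
      response <- cue_on + latency
      response_port <- if (outcome == "correct") cued_port else {
        setdiff(c("left", "right"), cued_port)
      }
      reward <- if (outcome == "correct") response else NA_real_
    }
    trial_end <- if (outcome == "correct") {
      reward + task$post_reward_epoch[2]
    } else if (outcome == "incorrect") {
      response
    } else {
      cue_on + task$cue_duration
    }
    rows[[i]] <- data.frame(
      trial = i, availability_time = avail, initiation_time = init,
      cue_on_time = cue_on, response_time = response,
      response_port = response_port, cued_port = cued_port,
      reward_time = reward, outcome = outcome,
      premature_count = premature, iti_start = t_cursor, trial_end = trial_end,
      stringsAsFactors = FALSE)
    t_cursor <- trial_end
  }
  do.call(rbind, rows) %||% data.frame()
}

# Expand the schedule into the event stream a behavioral controller logs.
trials_to_log <- function(trials, task) {
  ev <- list()
  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    ev[[length(ev) + 1]] <- data.frame(time_s = tr$iti_start, event_code = "iti_start",
                                       port = "")
    ev[[length(ev) + 1]] <- data.frame(time_s = tr$availability_time,
                                       event_code = "trial_available", port = "center")
    ev[[length(ev) + 1]] <- data.frame(time_s = tr$initiation_time,
                                       event_code = "initiation_poke", port = "center")
    if (task$task_kind == "delay" && tr$premature_count > 0) {
      # premature pokes: uniform order statistics over the delay
      pts <- sort(runif(tr$premature_count, tr$initiation_time, tr$cue_on_time))
      ports <- sample(c("side_poke_left", "side_poke_right"), tr$premature_count,
                      replace = TRUE)
      ev[[length(ev) + 1]] <- data.frame(time_s = pts, event_code = ports, port =
                                           ifelse(ports == "side_poke_left", "left", "right"))
    }
    ev[[length(ev) + 1]] <- data.frame(time_s = tr$cue_on_time, event_code = "cue_on",
                                       port = tr$cued_port)
    if (!is.na(tr$response_time)) {
      code <- if (tr$response_port == "left") "side_poke_left" else "side_poke_right"
      ev[[length(ev) + 1]] <- data.frame(time_s = tr$response_time, event_code = code,
                                         port = tr$response_port)
    }
    if (!is.na(tr$reward_time)) {
      ev[[length(ev) + 1]] <- data.frame(time_s = tr$reward_time,
                                         event_code = "reward_delivery",
                                         port = tr$response_port)
    }
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$time_s), ]
  rownames(events) <- NULL
  behavior_log(events)
}

# Ground-truth epoch windows used for tuning (behavior clock).
truth_epoch_windows <- function(tr, task) {
  w <- list()
  w$T <- c(tr$initiation_time - 2, tr$initiation_time)
  if (task$task_kind == "delay") {
    w$D <- c(tr$initiation_time, tr$cue_on_time)
  }
  if (!is.na(tr$response_time)) {
    w$C <- c(tr$cue_on_time, tr$response_time)
  }
  if (!is.na(tr$reward_time)) {
    w$R <- c(tr$reward_time, tr$reward_time + task$reward_epoch)
    w$P <- c(tr$reward_time + task$post_reward_epoch[1],
             tr$reward_time + task$post_reward_epoch[2])
  }
  w
}

# Draw the cells-by-frames amplitude matrix. Cells sharing a tuning pattern
# share one per-frame multiplier vector.
synth_traces <- function(profiles, trials, task, clock, n_frames, frame_rate) {
  pattern_key <- vapply(profiles, function(p) {
    if (!length(p$epoch_multipliers)) "" else {
      paste(names(p$epoch_multipliers), p$epoch_multipliers,
            sep = ":", collapse = ";")
    }
  }, "")
  traces <- matrix(0, nrow = length(profiles), ncol = n_frames)
  for (key in unique(pattern_key)) {
    idx <- which(pattern_key == key)
    mult <- rep(1, n_frames)
    if (nzchar(key)) {
      mults <- profiles[[idx[1]]]$epoch_multipliers
      for (k in seq_len(nrow(trials))) {
        w <- truth_epoch_windows(trials[k, ], task)
        for (ep in names(mults)) {
          if (!is.null(w[[ep]])) {
            # tune frames whose start falls inside the half-open window,
            # matching the analysis-side frame selection convention
            t_img <- clock$offset + clock$drift * w[[ep]]
            f1 <- max(0L, as.integer(ceiling(t_img[1] * frame_rate - 1e-9)))
            f2 <- min(n_frames, as.integer(ceiling(t_img[2] * frame_rate - 1e-9)))
            if (f2 > f1) mult[(f1 + 1):f2] <- mults[[ep]]
          }
        }
      }
    }
    for (i in idx) {
      p <- profiles[[i]]
      lambda <- p$baseline_rate * mult / frame_rate
      counts <- rpois(n_frames, lambda)
      row <- numeric(n_frames)
      nz <- counts > 0
      if (any(nz)) {
        # sum of k Gamma(2, rate) amplitudes is Gamma(2k, rate); mean per
        # event = amplitude_scale
        row[nz] <- rgamma(sum(nz), shape = 2 * counts[nz],
                          rate = 2 / p$amplitude_scale)
      }
      traces[i, ] <- row
    }
  }
  traces
}

#' Generate a multi-group synthetic cohort
#'
#' One session per mouse; per-session seeds are derived deterministically
#' from each group's `rng_seed` and the mouse index. Each cell's
#' mixed-selectivity category is drawn from the group's `category_mixture`
#' and converted to a [tuning_profile()] using the group's excited /
#' inhibited multipliers.
#'
#' @param specs list of [cohort_spec()], one per group (labels must be
#'   unique).
#' @param task a [task_spec()].
#' @param clock true clock parameters passed to [generate_session()].
#' @return list of session bundles; each bundle adds `group_label`, `mouse`,
#'   `seed`, and `true_categories` (per-cell seeded category strings).
#' @export
generate_cohort <- function(specs, task,
                            clock = list(offset = 0, drift = 1, jitter_sd = 0)) {
  if (!length(specs)) abort("at least one cohort_spec is required")
  labels <- vapply(specs, `[[`, "", "group_label")
  if (anyDuplicated(labels)) abort("duplicate group labels")
  bundles <- list()
  for (spec in specs) {
    for (mouse in seq_len(spec$n_mice)) {
      seed <- derive_seed(spec$rng_seed, mouse, spec$group_label)
      cats <- with_seed(derive_seed(seed, 0L, "categories"), {
        sample(names(spec$category_mixture), spec$cells_per_mouse,
               replace = TRUE, prob = spec$category_mixture)
      })
      profiles <- lapply(seq_len(spec$cells_per_mouse), function(i) {
        category_profile(sprintf("%s_m%d_c%03d", spec$group_label, mouse, i),
                         cats[i], spec)
      })
      bundle <- generate_session(task, profiles, spec, seed = seed, clock = clock)
      bundle$group_label <- spec$group_label
      bundle$mouse <- mouse
      bundle$seed <- seed
      bundle$true_categories <- ifelse(cats %in% c("null", ""), "", cats)
      bundles[[length(bundles) + 1]] <- bundle
    }
  }
  bundles
}

# Category string -> tuning profile under a cohort's effect sizes.
category_profile <- function(cell_id, category, spec) {
  if (category %in% c("null", "")) {
    return(tuning_profile(cell_id, baseline_rate = spec$baseline_rate,
                          amplitude_scale = spec$amplitude_scale))
  }
  dirs <- parse_category(category)
  mults <- ifelse(dirs == "+", spec$excited_multiplier, spec$inhibited_multiplier)
  tuning_profile(cell_id, baseline_rate = spec$baseline_rate,
                 epoch_multipliers = setNames(as.numeric(mults), names(dirs)),
                 amplitude_scale = spec$amplitude_scale)
}

#' Generate a synthetic grayscale frame stack with a moving blob
#'
#' Builds an 8-bit grayscale stack in which a square blob of fixed intensity
#' moves horizontally by a known number of pixels between consecutive
#' frames, over a background of optional sub-threshold uniform noise. Used
#' as a fixture with an exactly computable pixel-change motion index.
#'
#' @param n_frames number of frames.
#' @param blob_displacement_schedule integer vector of length `n_frames - 1`
#'   giving the horizontal displacement (pixels) applied between consecutive
#'   frames.
#' @param noise_amplitude uniform noise amplitude in gray units; must stay
#'   below the 10-unit motion threshold.
#' @param seed RNG seed for the noise.
#' @param dim frame dimensions `c(height, width)`.
#' @param blob_size blob side length in pixels.
#' @param blob_value blob intensity in gray units.
#' @param start top-left corner `c(row, col)` of the blob in frame 1.
#' @return integer array `height x width x n_frames` with values in 0..255.
#' @export
generate_motion_frames <- function(n_frames, blob_displacement_schedule = NULL,
                                   noise_amplitude = 0, seed = 1,
                                   dim = c(40, 60), blob_size = 5,
                                   blob_value = 100, start = c(10, 10)) {
  if (n_frames < 2) abort("need at least 2 frames")
  if (is.null(blob_displacement_schedule)) {
    blob_displacement_schedule <- rep(0L, n_frames - 1)
  }
  if (length(blob_displacement_schedule) != n_frames - 1) {
    abort("blob_displacement_schedule must have length n_frames - 1")
  }
  if (noise_amplitude >= 10) abort("noise_amplitude must stay below the 10-unit threshold")
  h <- dim[1]; w <- dim[2]
  cols <- start[2] + c(0, cumsum(blob_displacement_schedule))
  if (any(cols < 1) || any(cols + blob_size - 1 > w)) {
    abort("displacement schedule moves the blob out of frame")
  }
  with_seed(seed, {
    stack <- array(0L, dim = c(h, w, n_frames))
    for (f in seq_len(n_frames)) {
      frame <- matrix(0, h, w)
      if (noise_amplitude > 0) {
        # integer noise in 0..noise_amplitude: consecutive-frame differences
        # stay strictly below the 10-unit motion threshold
        frame <- frame + matrix(floor(runif(h * w, 0, noise_amplitude + 1)), h, w)
      }
      rows_b <- start[1]:(start[1] + blob_size - 1)
      cols_b <- cols[f]:(cols[f] + blob_size - 1)
      frame[rows_b, cols_b] <- blob_value
      frame[frame > 255] <- 255
      stack[, , f] <- as.integer(frame)
    }
    stack
  })
}
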