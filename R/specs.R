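# Task, tuning and cohort specifications for the synthetic-session generator.

EPOCH_ORDER <- c("T", "C", "D", "R", "P")

#' Specify an operant task
#'
#' Describes the trial structure of a self-initiated two-choice operant
#' session: either the cue-guided task (cue light at initiation, short
#' response window) or the delay ("waiting") task in which a fixed delay is
#' interposed between initiation and cue onset.
#'
#' @param task_kind `"cue_guided"` or `"delay"`.
#' @param cue_duration response-window length in seconds after cue onset
#'   (default 1.5 s, the time-pressured cue of the cue-guided task).
#' @param delay_duration delay between initiation and cue onset in seconds
#'   (delay task only; default 3 s).
#' @param iti_mean mean intertrial interval in seconds. The printed task uses
#'   45 s; shorter values make compact test sessions.
#' @param iti_range ITI range as multipliers of `iti_mean`; the ITI is drawn
#'   uniformly on `iti_mean * iti_range`.
#' @param session_length session length in seconds, or `NULL` to derive it
#'   from `n_trials`.
#' @param n_trials number of trials to schedule when `session_length` is
#'   `NULL`.
#' @param reward_epoch length of the reward epoch R in seconds (3 s).
#' @param post_reward_epoch offsets of the post-reward epoch P relative to
#'   reward delivery, in seconds (3--6 s).
#' @param baseline_window length of the pre-availability baseline window
#'   taken from the tail of each ITI, in seconds (6 s).
#' @return a `task_spec` object (list).
#' @export
task_spec <- function(task_kind = c("cue_guided", "delay"),
                      cue_duration = 1.5,
                      delay_duration = 3.0,
                      iti_mean = 45,
                      iti_range = c(0.5, 1.5),
                      session_length = NULL,
                      n_trials = 40L,
                      reward_epoch = 3.0,
                      post_reward_epoch = c(3.0, 6.0),
                      baseline_window = 6.0) {
  task_kind <- match.arg(task_kind)
  if (cue_duration <= 0 || delay_duration <= 0 || iti_mean <= 0 ||
      reward_epoch <= 0 || baseline_window <= 0) {
    abort("all task durations must be positive")
  }
  if (length(iti_range) != 2L || iti_range[1] > iti_range[2] || iti_range[1] <= 0) {
    abort("iti_range must be an increasing pair of positive multipliers")
  }
  if (length(post_reward_epoch) != 2L || diff(post_reward_epoch) <= 0) {
    abort("post_reward_epoch must be an increasing (start, end) pair")
  }
  if (!is.null(session_length) && session_length <= 0) {
    abort("session_length must be positive")
  }
  structure(list(
    task_kind = task_kind,
    cue_duration = cue_duration,
    delay_duration = delay_duration,
    iti_mean = iti_mean,
    iti_range = iti_range,
    session_length = session_length,
    n_trials = as.integer(n_trials),
    reward_epoch = reward_epoch,
    post_reward_epoch = post_reward_epoch,
    baseline_window = baseline_window
  ), class = "task_spec")
}

#' Epoch labels tested for a task
#'
#' Cue-guided task: T (2 s pre-initiation), C (initiation to cue response),
#' R (0--3 s post-reward), P (3--6 s post-reward). Delay task adds the 3 s
#' delay epoch D; the cue epoch C (cue onset to response) is retained as the
#' fifth epoch.
#'
#' @param task a [task_spec()].
#' @param include_cue_in_delay keep C in the delay-task epoch set (default
#'   `TRUE`, giving the five-epoch set; `FALSE` gives \{T, D, R, P\}).
#' @return character vector of epoch labels in canonical order.
#' @export
task_epochs <- function(task, include_cue_in_delay = TRUE) {
  if (task$task_kind == "cue_guided") {
    c("T", "C", "R", "P")
  } else if (include_cue_in_delay) {
    c("T", "D", "C", "R", "P")
  } else {
    c("T", "D", "R", "P")
  }
}

#' Ground-truth tuning profile for one synthetic cell
#'
#' @param cell_id identifier.
#' @param baseline_rate baseline calcium event rate in events/second.
#' @param epoch_multipliers named numeric vector mapping epoch labels to
#'   multiplicative rate modulation (1 = untuned, 0 = silenced).
#' @param amplitude_scale mean of the per-event amplitude distribution.
#' @return a `tuning_profile` object.
#' @export
tuning_profile <- function(cell_id, baseline_rate = 1.0,
                           epoch_multipliers = numeric(), amplitude_scale = 1.0) {
  if (baseline_rate < 0) abort("baseline_rate must be >= 0")
  if (amplitude_scale <= 0) abort("amplitude_scale must be > 0")
  if (length(epoch_multipliers)) {
    if (is.null(names(epoch_multipliers)) || any(!nzchar(names(epoch_multipliers)))) {
      abort("epoch_multipliers must be named by epoch label")
    }
    if (any(epoch_multipliers < 0)) abort("epoch multipliers must be >= 0")
  }
  structure(list(cell_id = as.character(cell_id),
                 baseline_rate = baseline_rate,
                 epoch_multipliers = epoch_multipliers,
                 amplitude_scale = amplitude_scale),
            class = "tuning_profile")
}

#' Parse a mixed-selectivity category string
#'
#' A category string lists, in canonical epoch order T, C, D, R, P, each
#' epoch in which a cell is significantly modulated, suffixed with `+`
#' (excited) or `-` (inhibited); the empty string denotes a nonresponsive
#' cell. `"C+R+P+"` and `"R-P-"` are typical examples.
#'
#' @param category a category string.
#' @return named character vector of directions (`"+"`/`"-"`) keyed by epoch.
#' @export
parse_category <- function(category) {
  if (is.na(category) || !nzchar(category)) {
    return(setNames(character(0), character(0)))
  }
  chars <- strsplit(category, "")[[1]]
  if (length(chars) %% 2 != 0) abort(sprintf("malformed category '%s'", category))
  epochs <- chars[seq(1, length(chars), by = 2)]
  dirs <- chars[seq(2, length(chars), by = 2)]
  if (!all(epochs %in% EPOCH_ORDER)) {
    abort(sprintf("unknown epoch in category '%s'", category))
  }
  if (!all(dirs %in% c("+", "-"))) {
    abort(sprintf("bad direction in category '%s'", category))
  }
  if (anyDuplicated(epochs)) abort(sprintf("repeated epoch in category '%s'", category))
  setNames(dirs, epochs)
}

#' Compose a category string from per-epoch directions
#'
#' @param directions named character vector (`"+"`, `"-"`, or `"0"`) keyed by
#'   epoch label; `"0"` entries are dropped.
#' @return a category string in canonical epoch order (empty if none).
#' @export
compose_category <- function(directions) {
  keep <- directions[directions %in% c("+", "-")]
  if (!length(keep)) return("")
  ord <- EPOCH_ORDER[EPOCH_ORDER %in% names(keep)]
  paste0(ord, keep[ord], collapse = "")
}

#' Specify a synthetic cohort (one group of mice)
#'
#' @param group_label group name (e.g., a genotype label).
#' @param n_mice number of mice (one session each).
#' @param cells_per_mouse cells recorded per session.
#' @param category_mixture named numeric vector of category-string
#'   proportions; the name `"null"` (or `""`) denotes untuned cells. Must
#'   sum to 1.
#' @param trial_outcome_mixture proportions of (correct, incorrect, omitted)
#'   trials; defaults to the empirical 59/5/37\% split.
#' @param response_latency mean and sd (seconds) of the cue-response latency
#'   (gamma distributed); default mean 0.93 s, sd 0.3 s.
#' @param initiation_latency mean of the exponential latency from trial
#'   availability to the initiation poke, seconds.
#' @param premature_rate rate (pokes/second) of the homogeneous Poisson
#'   premature-poke process during the delay (delay task only).
#' @param baseline_rate baseline event rate (events/s) given to every cell.
#' @param excited_multiplier epoch multiplier applied for `+` categories.
#' @param inhibited_multiplier epoch multiplier applied for `-` categories.
#' @param amplitude_scale mean per-event amplitude.
#' @param rng_seed integer seed for the group's random stream.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(group_label, n_mice = 1L, cells_per_mouse = 50L,
                        category_mixture = c(null = 1),
                        trial_outcome_mixture = c(correct = 0.59, incorrect = 0.05,
                                                  omitted = 0.36),
                        response_latency = c(mean = 0.93, sd = 0.3),
                        initiation_latency = 2.0,
                        premature_rate = 0.2,
                        baseline_rate = 1.0,
                        excited_multiplier = 5.0,
                        inhibited_multiplier = 0.1,
                        amplitude_scale = 1.0,
                        rng_seed = 1L) {
  if (!nzchar(group_label)) abort("group_label must be non-empty")
  if (n_mice < 1 || cells_per_mouse < 1) abort("n_mice and cells_per_mouse must be >= 1")
  if (abs(sum(category_mixture) - 1) > 1e-9) {
    abort("category_mixture proportions must sum to 1")
  }
  if (is.null(names(category_mixture))) abort("category_mixture must be named")
  if (length(trial_outcome_mixture) != 3L ||
      abs(sum(trial_outcome_mixture) - 1) > 1e-9) {
    abort("trial_outcome_mixture must be 3 proportions summing to 1")
  }
  names(trial_outcome_mixture) <- c("correct", "incorrect", "omitted")
  # validate every non-null category string up front
  for (cat in names(category_mixture)) {
    if (!cat %in% c("null", "")) parse_category(cat)
  }
  structure(list(
    group_label = group_label,
    n_mice = as.integer(n_mice),
    cells_per_mouse = as.integer(cells_per_mouse),
    category_mixture = category_mixture,
    trial_outcome_mixture = trial_outcome_mixture,
    response_latency = response_latency,
    initiation_latency = initiation_latency,
    premature_rate = premature_rate,
    baseline_rate = baseline_rate,
    excited_multiplier = excited_multiplier,
    inhibited_multiplier = inhibited_multiplier,
    amplitude_scale = amplitude_scale,
    rng_seed = as.integer(rng_seed)
  ), class = "cohort_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec: %s task, cue %.3gs, delay %.3gs, ITI mean %.3gs>\n",
              x$task_kind, x$cue_duration, x$delay_duration, x$iti_mean))
  invisible(x)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec '%s': %d mice x %d cells, seed %d>\n",
              x$group_label, x$n_mice, x$cells_per_mouse, x$rng_seed))
  invisible(x)
}
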