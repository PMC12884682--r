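# Compact session builders for tests. The short ITI (12 s, range 0.6-1.4)
# keeps sessions small while leaving every baseline window (6 s) complete.

fast_task <- function(kind = "cue_guided", n_trials = 15, iti_mean = 12,
                      iti_range = c(0.6, 1.4), ...) {
  task_spec(kind, iti_mean = iti_mean, iti_range = iti_range,
            n_trials = n_trials, ...)
}

# cohort in which every trial is correct (maximizes usable trials per frame)
all_correct_cohort <- function(label = "g", cells = 1, seed = 1, ...) {
  cohort_spec(label, cells_per_mouse = cells,
              trial_outcome_mixture = c(correct = 1, incorrect = 0, omitted = 0),
              rng_seed = seed, ...)
}

null_profiles <- function(n, baseline = 1) {
  lapply(seq_len(n), function(i) {
    tuning_profile(sprintf("cell_%03d", i), baseline_rate = baseline)
  })
}

# hand-built behavior log from a list of (time, code, port) rows
make_log <- function(...) {
  rows <- list(...)
  ev <- data.frame(
    time_s = vapply(rows, function(r) as.numeric(r[[1]]), 0),
    event_code = vapply(rows, function(r) r[[2]], ""),
    port = vapply(rows, function(r) if (length(r) > 2) r[[3]] else "", ""),
    stringsAsFactors = FALSE)
  behavior_log(ev)
}

# synthetic rate table built directly from Poisson counts: one cell,
# baseline Poisson(rate*6)/6 and per-epoch Poisson(rate*mult*len)/len
simulate_rate_table <- function(cell_ids, n_trials, epochs, epoch_len,
                                baseline_rate = 1, multipliers = NULL) {
  rows <- list()
  for (ci in seq_along(cell_ids)) {
    base <- rpois(n_trials, baseline_rate * 6) / 6
    for (j in seq_along(epochs)) {
      mult <- 1
      if (!is.null(multipliers) && epochs[j] %in% names(multipliers[[ci]])) {
        mult <- multipliers[[ci]][[epochs[j]]]
      }
      len <- epoch_len[j]
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = cell_ids[ci], trial = seq_len(n_trials), epoch = epochs[j],
        rate = rpois(n_trials, baseline_rate * mult * len) / len,
        baseline_rate = base, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rate_table", "data.frame")
  attr(out, "epochs") <- epochs
  out
}
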