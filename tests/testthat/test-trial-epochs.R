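# Trial parsing, epoch window geometry, event rates, rate tables.

test_that("trial outcomes follow the operant rules", {
  task <- task_spec("cue_guided", cue_duration = 1.5)
  # correct: cued-left, left poke 1.0 s after cue
  log <- make_log(
    list(0, "iti_start"), list(10, "trial_available", "center"),
    list(12, "initiation_poke", "center"), list(12, "cue_on", "left"),
    list(13.0, "side_poke_left", "left"), list(13.0, "reward_delivery", "left"),
    list(19, "iti_start"), list(29, "trial_available", "center"),
    # omitted: no side poke within 1.5 s
    list(30, "initiation_poke", "center"), list(30, "cue_on", "right"),
    list(31.6, "iti_start"), list(41.6, "trial_available", "center"),
    # incorrect: right cued, left poke inside the window
    list(43, "initiation_poke", "center"), list(43, "cue_on", "right"),
    list(43.8, "side_poke_left", "left"), list(43.8, "iti_start"))
  tt <- build_trials(log, task)
  expect_equal(tt$outcome, c("correct", "omitted", "incorrect"))
  expect_equal(tt$reward_time[1], 13.0)
  expect_true(is.na(tt$reward_time[2]) && is.na(tt$reward_time[3]))
  expect_equal(tt$premature_count, c(0, 0, 0))
  # trial accounting: correct + incorrect + omitted = total initiated
  expect_equal(sum(table(tt$outcome)), nrow(tt))
})

test_that("delay-task pokes during the delay only increment premature_count", {
  task <- task_spec("delay", cue_duration = 1.5, delay_duration = 3)
  log <- make_log(
    list(0, "iti_start"), list(10, "trial_available", "center"),
    list(12, "initiation_poke", "center"),
    list(12.5, "side_poke_left", "left"), list(14.0, "side_poke_right", "right"),
    list(15, "cue_on", "left"),
    list(15.8, "side_poke_left", "left"), list(15.8, "reward_delivery", "left"),
    list(22, "iti_start"))
  tt <- build_trials(log, task)
  expect_equal(tt$outcome, "correct")
  expect_equal(tt$premature_count, 2L)
})

test_that("epoch windows match their definitions on hand-constructed trials", {
  task <- task_spec("cue_guided")
  trial <- data.frame(availability_time = 95, initiation_time = 100.0,
                      cue_on_time = 100.0, response_time = 100.9,
                      reward_time = 100.9, outcome = "correct")
  w <- epoch_windows(trial, task)
  expect_equal(w$start[w$label == "T"], 98.0)
  expect_equal(w$end[w$label == "T"], 100.0)
  expect_equal(unlist(w[w$label == "C", c("start", "end")], use.names = FALSE),
               c(100.0, 100.9))
  expect_equal(unlist(w[w$label == "R", c("start", "end")], use.names = FALSE),
               c(100.9, 103.9))
  expect_equal(unlist(w[w$label == "P", c("start", "end")], use.names = FALSE),
               c(103.9, 106.9))
  expect_equal(unlist(w[w$label == "baseline", c("start", "end")],
                      use.names = FALSE), c(89.0, 95.0))

  dtask <- task_spec("delay")
  dtrial <- data.frame(availability_time = 195, initiation_time = 200.0,
                       cue_on_time = 203.0, response_time = 203.7,
                       reward_time = 203.7, outcome = "correct")
  dw <- epoch_windows(dtrial, dtask)
  expect_equal(unlist(dw[dw$label == "D", c("start", "end")], use.names = FALSE),
               c(200.0, 203.0))
  expect_setequal(dw$label, c("T", "D", "C", "R", "P", "baseline"))

  expect_error(epoch_windows(transform(trial, outcome = "omitted"), task),
               "correct trials only")
  expect_error(epoch_windows(transform(trial, reward_time = NA), task),
               "inconsistent")
})

test_that("epoch windows never overlap where the task forbids it", {
  task <- fast_task(n_trials = 10)
  s <- generate_session(task, null_profiles(1), all_correct_cohort(), seed = 3)
  for (k in which(s$trials$outcome == "correct")) {
    w <- epoch_windows(s$trials[k, ], task)
    r <- w[w$label == "R", ]; p <- w[w$label == "P", ]
    expect_lte(r$end, p$start + 1e-9)          # R and P disjoint
    expect_lte(w$end[w$label == "T"], s$trials$initiation_time[k] + 1e-9)
    expect_lte(w$end[w$label == "baseline"],
               s$trials$availability_time[k] + 1e-9)
  }
})

test_that("event_rate counts supra-threshold frames per second", {
  trace <- rep(0, 100)
  trace[c(3, 10, 20, 30, 40, 55)] <- c(0.5, 1, 2, 0.2, 3, 1)
  expect_equal(event_rate(trace, 1:60, frame_rate = 20), 6 / 3)
  expect_equal(event_rate(rep(0, 50), 1:50), 0)
  expect_error(event_rate(trace, integer()), "empty window")
  # threshold excludes the 0.2-amplitude event
  expect_equal(event_rate(trace, 1:60, frame_rate = 20, threshold = 0.4), 5 / 3)

  set.seed(4)
  sparse <- ifelse(runif(400) < 0.05, runif(400, 0, 2), 0)
  frames <- 37:250
  expect_equal(event_rate(sparse, frames),
               event_rate_oracle(sparse, frames))
})

test_that("rate tables have one row per cell x usable trial x epoch", {
  task <- fast_task(n_trials = 8)
  s <- generate_session(task, null_profiles(2), all_correct_cohort(cells = 2),
                        seed = 13)
  trials <- build_trials(s$log, task)
  rt <- build_rate_table(s$recording, trials, task)
  n_used <- attr(rt, "n_trials_used")
  expect_equal(nrow(rt), 2 * n_used * 4)
  expect_setequal(attr(rt, "epochs"), c("T", "C", "R", "P"))
  expect_true(all(rt$rate >= 0) && all(rt$baseline_rate >= 0))
  # each (cell, trial) pair carries exactly one baseline value
  per <- tapply(rt$baseline_rate, interaction(rt$cell_id, rt$trial), function(x) {
    length(unique(x))
  })
  expect_true(all(per == 1))
})

test_that("untuned sessions show epoch rates at the baseline level", {
  task <- fast_task(n_trials = 40)
  s <- generate_session(task, null_profiles(3, baseline = 2),
                        all_correct_cohort(cells = 3), seed = 17)
  trials <- build_trials(s$log, task)
  rt <- build_rate_table(s$recording, trials, task)
  for (ep in attr(rt, "epochs")) {
    d <- rt[rt$epoch == ep, ]
    diffs <- d$rate - d$baseline_rate
    se <- sd(diffs) / sqrt(length(diffs))
    expect_lt(abs(mean(diffs)), 3 * se + 1e-9)
  }
})

test_that("trials without a usable baseline are excluded and counted", {
  task <- task_spec("cue_guided", cue_duration = 1.5)
  # first trial has no preceding iti_start; second is complete
  log <- make_log(
    list(2, "trial_available", "center"),
    list(3, "initiation_poke", "center"), list(3, "cue_on", "left"),
    list(3.5, "side_poke_left", "left"), list(3.5, "reward_delivery", "left"),
    list(10, "iti_start"), list(22, "trial_available", "center"),
    list(23, "initiation_poke", "center"), list(23, "cue_on", "left"),
    list(23.5, "side_poke_left", "left"), list(23.5, "reward_delivery", "left"),
    list(30, "iti_start"))
  tt <- build_trials(log, task)
  expect_equal(tt$baseline_complete, c(FALSE, TRUE))
  rec <- session_recording(matrix(1, 1, 40 * 20), frame_rate = 20)
  rt <- build_rate_table(rec, tt, task)
  expect_equal(unique(rt$trial), 2)
  expect_equal(attr(rt, "n_excluded")[["incomplete_baseline"]], 1L)
})

test_that("session-mean baseline pairing averages across ITIs", {
  task <- fast_task(n_trials = 8)
  s <- generate_session(task, null_profiles(2), all_correct_cohort(cells = 2),
                        seed = 19)
  trials <- build_trials(s$log, task)
  per_trial <- build_rate_table(s$recording, trials, task)
  sess <- build_rate_table(s$recording, trials, task,
                           baseline_pairing = "session_mean")
  for (cid in unique(sess$cell_id)) {
    expect_equal(unique(sess$baseline_rate[sess$cell_id == cid]),
                 mean(per_trial$baseline_rate[per_trial$cell_id == cid &
                                                per_trial$epoch == "T"]))
  }
})
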