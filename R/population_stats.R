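# Group-level summaries: normalized peri-event traces, proportion tables
# with chi-square tests, category frequency tables, mixed-design ANOVA, and
# behavior-activity correlations.

#' Per-cell baseline statistics
#'
#' Mean and SD across trials of each cell's per-trial baseline event rate,
#' used to z-normalize peri-event traces.
#'
#' @param rate_table a [build_rate_table()] result.
#' @return data.frame `cell_id`, `baseline_mean`, `baseline_sd`.
#' @export
baseline_stats <- function(rate_table) {
  ep1 <- attr(rate_table, "epochs")[1]
  one <- rate_table[rate_table$epoch == ep1, c("cell_id", "baseline_rate")]
  mu <- tapply(one$baseline_rate, one$cell_id, mean)
  sdv <- tapply(one$baseline_rate, one$cell_id, sd)
  data.frame(cell_id = names(mu), baseline_mean = as.numeric(mu),
             baseline_sd = as.numeric(sdv), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Normalized peri-event population trace
#'
#' For each cell, averages the per-frame event rate across correct trials
#' in a window around an alignment event, z-scores the averaged trace
#' against the cell's baseline mean and SD, and summarizes cells within
#' each group as mean +/- SEM per time bin. Cells with zero baseline SD
#' cannot be z-scored and are excluded with a message.
#'
#' @param recording a [session_recording()].
#' @param trials a [build_trials()] table.
#' @param baseline data.frame from [baseline_stats()] (or compatible, with
#'   `cell_id`, `baseline_mean`, `baseline_sd`).
#' @param alignment_event `"response"`, `"initiation"`, or `"reward"`.
#' @param window time window around the alignment event, seconds.
#' @param clock behavioral-to-imaging `clock_map`.
#' @param groups optional per-cell group labels (named by cell_id or in
#'   recording order); default one group `"all"`.
#' @param threshold amplitude threshold for event detection.
#' @return data.frame `group`, `time`, `mean`, `sem`, `n_cells`; the
#'   per-cell z matrix is in attribute `z` (cells x bins), excluded cell
#'   ids in attribute `excluded`.
#' @export
normalized_population_trace <- function(recording, trials, baseline,
                                        alignment_event = c("response",
                                                            "initiation",
                                                            "reward"),
                                        window = c(-5, 5),
                                        clock = identity_clock_map(),
                                        groups = NULL, threshold = 0) {
  alignment_event <- match.arg(alignment_event)
  anchor_col <- switch(alignment_event, response = "response_time",
                       initiation = "initiation_time", reward = "reward_time")
  correct <- trials[trials$outcome == "correct", , drop = FALSE]
  if (!nrow(correct)) abort("no correct trials to align")
  fr <- recording$frame_rate
  offs <- seq(ceiling(window[1] * fr), ceiling(window[2] * fr) - 1)
  anchors <- to_imaging_time(correct[[anchor_col]], clock)
  t0 <- recording$frame_times[1]
  a_frames <- floor((anchors - t0) * fr + 1e-9)
  usable <- a_frames + offs[1] >= 0 & a_frames + offs[length(offs)] < ncol(recording$traces)
  if (!any(usable)) abort("alignment window falls outside the recording for every trial")
  a_frames <- a_frames[usable]

  supra <- (recording$traces > threshold) * fr  # per-frame rate, events/s
  acc <- matrix(0, nrow(supra), length(offs))
  for (af in a_frames) {
    acc <- acc + supra[, af + offs + 1, drop = FALSE]
  }
  mean_rate <- acc / length(a_frames)

  b <- baseline[match(recording$cell_ids, baseline$cell_id), ]
  ok <- is.finite(b$baseline_sd) & b$baseline_sd > 0
  if (any(!ok)) {
    message(sprintf("normalized_population_trace: %d cell(s) with zero baseline SD excluded",
                    sum(!ok)))
  }
  if (!any(ok)) abort("no cells with positive baseline SD remain")
  z <- (mean_rate[ok, , drop = FALSE] - b$baseline_mean[ok]) / b$baseline_sd[ok]
  rownames(z) <- recording$cell_ids[ok]
  times <- offs / fr

  if (is.null(groups)) {
    groups <- rep("all", length(recording$cell_ids))
  }
  if (!is.null(names(groups))) groups <- groups[recording$cell_ids]
  groups <- as.character(groups)[ok]
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    zg <- z[groups == g, , drop = FALSE]
    sem <- if (nrow(zg) > 1) apply(zg, 2, sd) / sqrt(nrow(zg)) else {
      rep(0, ncol(zg))  # a single cell has no across-cell spread
    }
    data.frame(group = g, time = times, mean = colMeans(zg),
               sem = sem, n_cells = nrow(zg), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "z") <- z
  attr(out, "groups") <- groups
  attr(out, "excluded") <- recording$cell_ids[!ok]
  out
}

#' Per-epoch proportion table across groups
#'
#' Counts excited, inhibited and nonresponsive cells per epoch in each
#' group and tests the group difference with a chi-square test per epoch.
#'
#' @param classes a [classify_population()] table.
#' @param groups per-cell group labels (recording order or named by
#'   cell_id).
#' @return data.frame with per epoch x group counts and proportions, plus
#'   attribute `tests` (per-epoch chi-square statistic, df, p over the
#'   3-level cell-type distribution).
#' @export
proportion_table <- function(classes, groups) {
  if (!is.null(names(groups))) groups <- groups[classes$cell_id]
  groups <- as.character(groups)
  epochs <- attr(classes, "epochs")
  glab <- unique(groups)
  rows <- list(); tests <- list()
  for (ep in epochs) {
    d <- classes[[paste0("dir_", ep)]]
    counts <- vapply(glab, function(g) {
      c(excited = sum(d == "+" & groups == g),
        inhibited = sum(d == "-" & groups == g),
        nonresponsive = sum(d == "0" & groups == g))
    }, numeric(3))
    for (g in glab) {
      n <- sum(counts[, g])
      rows[[length(rows) + 1]] <- data.frame(
        epoch = ep, group = g,
        excited = counts["excited", g], inhibited = counts["inhibited", g],
        nonresponsive = counts["nonresponsive", g], n_cells = n,
        prop_excited = counts["excited", g] / n,
        prop_inhibited = counts["inhibited", g] / n,
        stringsAsFactors = FALSE)
    }
    if (length(glab) >= 2) {
      keep <- rowSums(counts) > 0  # drop empty cell-type rows
      tab <- t(counts[keep, , drop = FALSE])
      tests[[ep]] <- tryCatch(chi_square_2xk(tab),
                              error = function(e) list(statistic = NA_real_,
                                                       df = NA_real_, p = NA_real_))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(tests)) {
    attr(out, "tests") <- data.frame(
      epoch = names(tests),
      statistic = vapply(tests, `[[`, 0, "statistic"),
      df = vapply(tests, `[[`, 0, "df"),
      p = vapply(tests, `[[`, 0, "p"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction (a Yates-corrected
#' variant is available via `correct = TRUE`).
#'
#' @param counts matrix of non-negative counts (groups x categories).
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return list `statistic`, `df`, `p`.
#' @export
chi_square_2xk <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero row or column margin in contingency table")
  }
  res <- suppressWarnings(chisq.test(counts, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Mixed-selectivity category frequency table
#'
#' Tabulates category strings among responsive cells, sorted by descending
#' frequency, and reports the minimal set of categories whose cumulative
#' share reaches a coverage target.
#'
#' @param classes a [classify_population()] table or a character vector of
#'   category strings (empty string = nonresponsive).
#' @param coverage_target cumulative share of responsive cells to cover
#'   (default 0.80).
#' @return data.frame `category`, `count`, `share`, `cum_share` with
#'   attributes `minimal_set` and `n_responsive`; empty (with a warning)
#'   when no cell is responsive.
#' @export
category_frequencies <- function(classes, coverage_target = 0.80) {
  cats <- if (is.character(classes)) classes else classes$category
  cats <- cats[nzchar(cats)]
  if (!length(cats)) {
    warning("no responsive cells")
    out <- data.frame(category = character(), count = integer(),
                      share = numeric(), cum_share = numeric())
    attr(out, "minimal_set") <- character()
    attr(out, "n_responsive") <- 0L
    return(out)
  }
  tab <- sort(table(cats), decreasing = TRUE)
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    share = as.numeric(tab) / length(cats),
                    stringsAsFactors = FALSE)
  out$cum_share <- cumsum(out$share)
  k <- match(TRUE, out$cum_share >= coverage_target - 1e-12)
  attr(out, "minimal_set") <- out$category[seq_len(k)]
  attr(out, "n_responsive") <- length(cats)
  out
}

#' Mixed-design ANOVA: group x time on z-normalized traces
#'
#' Classical sums-of-squares decomposition with cells as the
#' repeated-measures unit: group is the between-cells factor, time bin the
#' within-cell factor. Fit with `aov` using an `Error(cell)` stratum; the
#' group effect is tested against between-cell variation, time and the
#' group x time interaction against the within-cell residual.
#'
#' @param z matrix cells x time bins of z-scored rates.
#' @param groups per-cell group labels.
#' @return data.frame `effect`, `df1`, `df2`, `F`, `p`.
#' @export
mixed_anova_genotype_time <- function(z, groups) {
  z <- as.matrix(z)
  groups <- as.character(groups)
  if (length(groups) != nrow(z)) abort("one group label per cell (row) required")
  if (length(unique(groups)) < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("need at least 2 cells per group")
  n_cells <- nrow(z); n_bins <- ncol(z)
  long <- data.frame(
    value = as.vector(z),
    cell = factor(rep(seq_len(n_cells), times = n_bins)),
    time = factor(rep(seq_len(n_bins), each = n_cells)),
    group = factor(rep(groups, times = n_bins)))
  fit <- aov(value ~ group * time + Error(cell), data = long)
  s <- summary(fit)
  between <- s[["Error: cell"]][[1]]
  within <- s[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    resid_i <- match("Residuals", trimws(rownames(tab)))
    data.frame(effect = term, df1 = tab$Df[i], df2 = tab$Df[resid_i],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i],
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick(between, "group"), pick(within, "time"),
               pick(within, "group:time"))
  rownames(out) <- NULL
  out
}

#' Pearson correlation with two-tailed p
#'
#' @param x,y numeric vectors of per-animal metrics (length >= 3, finite,
#'   non-constant).
#' @return list `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  res <- cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), p = res$p.value, n = length(x))
}
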