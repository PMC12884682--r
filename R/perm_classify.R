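# Paired sign-flip permutation testing, Bonferroni control, and
# mixed-selectivity category composition.

#' Two-tailed paired permutation test
#'
#' Tests whether a cell's event rate in a trial epoch differs from its
#' paired baseline rate. The statistic is the mean paired difference
#' (epoch minus baseline, events/s); the null distribution is generated by
#' independent random sign flips of each paired difference, which is the
#' exact null when epoch and baseline labels are exchangeable within a
#' trial. When all `2^n` sign assignments number no more than `n_perm`, the
#' exact enumeration is used automatically, eliminating Monte-Carlo noise on
#' small trial counts; otherwise `n_perm` random sign patterns are drawn and
#' the add-one-corrected p-value `(1 + #extreme) / (1 + n_perm)` is
#' returned. Ties count toward the tail.
#'
#' @param epoch_rates per-trial epoch event rates (events/s).
#' @param baseline_rates paired per-trial baseline rates (same length).
#' @param n_perm number of permutation rounds (default 10,000).
#' @param seed optional seed for the Monte-Carlo sign draws; when `NULL`
#'   the current RNG stream is used.
#' @param method `"auto"` (default), `"exact"`, or `"montecarlo"`.
#' @return a `perm_result` list: `statistic` (mean difference), `p`,
#'   `direction` (`"+"`, `"-"`, `"0"`: the sign of the statistic), `n`
#'   trials, `n_perm`, `method`.
#' @export
paired_permutation_test <- function(epoch_rates, baseline_rates, n_perm = 10000,
                                    seed = NULL,
                                    method = c("auto", "exact", "montecarlo")) {
  method <- match.arg(method)
  if (length(epoch_rates) != length(baseline_rates)) {
    abort("epoch and baseline rate vectors must have equal length")
  }
  n <- length(epoch_rates)
  if (n < 2) abort("need at least 2 paired trials")
  if (n_perm < 1) abort("n_perm must be >= 1")
  d <- as.numeric(epoch_rates) - as.numeric(baseline_rates)
  if (any(!is.finite(d))) abort("non-finite paired differences")

  if (method == "auto") {
    method <- if (n <= 25 && 2^n <= n_perm) "exact" else "montecarlo"
  }
  if (method == "exact" && n > 25) abort("exact enumeration limited to n <= 25")
  p <- if (method == "exact") {
    perm_p_exact(d)
  } else if (!is.null(seed)) {
    with_seed(seed, perm_p_mc(d, as.integer(n_perm)))
  } else {
    perm_p_mc(d, as.integer(n_perm))
  }
  stat <- mean(d)
  structure(list(statistic = stat, p = p,
                 direction = if (stat > 0) "+" else if (stat < 0) "-" else "0",
                 n = n,
                 n_perm = if (method == "exact") 2^n else as.integer(n_perm),
                 method = method),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result: stat %+.4g events/s, p = %.4g (%s, n = %d)>\n",
              x$statistic, x$p, x$method, x$n))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' Controls the familywise error across epochs and between the excitation
#' and inhibition directions: `alpha / (2 * n_epochs)`. For the four-epoch
#' cue-guided task this is 0.05/8.
#'
#' @param alpha familywise error rate (in (0, 1)).
#' @param n_epochs number of epochs tested.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_epochs = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)")
  }
  if (n_epochs < 1) abort("n_epochs must be >= 1")
  alpha / (2 * n_epochs)
}

#' Classify one cell across epochs
#'
#' Runs the paired permutation test for every epoch, thresholds the
#' p-values at the Bonferroni-adjusted level, and composes the cell's
#' mixed-selectivity category from the significant epochs and their
#' directions (e.g., `"C+R+P+"`, `"R-P-"`; empty string = nonresponsive).
#'
#' @param cell_rates rows of a [build_rate_table()] for one cell.
#' @param alpha familywise error rate.
#' @param n_perm permutation rounds.
#' @param seed seed for this cell's test stream.
#' @param epochs epoch labels to test (default: those in `cell_rates`).
#' @return one-row data.frame: `cell_id`, `category`, `responsive`, and per
#'   epoch `p_<epoch>`, `stat_<epoch>`, `dir_<epoch>` (direction `"0"` when
#'   not significant).
#' @export
classify_cell <- function(cell_rates, alpha = 0.05, n_perm = 10000, seed = NULL,
                          epochs = NULL) {
  if (is.null(epochs)) {
    epochs <- attr(cell_rates, "epochs") %||% intersect(EPOCH_ORDER,
                                                        unique(cell_rates$epoch))
  }
  cell_id <- unique(cell_rates$cell_id)
  if (length(cell_id) != 1) abort("classify_cell expects rows for exactly one cell")
  thr <- bonferroni_threshold(alpha, length(epochs))
  run <- function() {
    res <- lapply(seq_along(epochs), function(j) {
      rows <- cell_rates[cell_rates$epoch == epochs[j], , drop = FALSE]
      paired_permutation_test(rows$rate, rows$baseline_rate, n_perm = n_perm)
    })
    names(res) <- epochs
    res
  }
  res <- if (!is.null(seed)) with_seed(seed, run()) else run()
  p <- vapply(res, `[[`, 0, "p")
  stat <- vapply(res, `[[`, 0, "statistic")
  dir <- ifelse(p < thr, vapply(res, `[[`, "", "direction"), "0")
  names(dir) <- epochs
  out <- data.frame(cell_id = cell_id,
                    category = compose_category(dir),
                    stringsAsFactors = FALSE)
  out$responsive <- nzchar(out$category)
  for (ep in epochs) {
    out[[paste0("p_", ep)]] <- p[[ep]]
    out[[paste0("stat_", ep)]] <- stat[[ep]]
    out[[paste0("dir_", ep)]] <- dir[[ep]]
  }
  out
}

#' Classify every cell in a rate table
#'
#' Applies [classify_cell()] to each cell with per-cell seeds derived
#' deterministically from `master_seed`, so the classification table is
#' reproducible regardless of cell order or parallel scheduling.
#'
#' @param rate_table a [build_rate_table()] result.
#' @param alpha familywise error rate.
#' @param n_perm permutation rounds per test.
#' @param master_seed integer master seed.
#' @return a `cell_class_table` data.frame (one row per cell) with an
#'   `epoch_summary` attribute counting excited / inhibited / nonresponsive
#'   cells per epoch.
#' @export
classify_population <- function(rate_table, alpha = 0.05, n_perm = 10000,
                                master_seed = 1L) {
  epochs <- attr(rate_table, "epochs") %||% intersect(EPOCH_ORDER,
                                                      unique(rate_table$epoch))
  ids <- unique(rate_table$cell_id)
  split_rows <- split(seq_len(nrow(rate_table)), rate_table$cell_id)
  rows <- lapply(seq_along(ids), function(i) {
    cr <- rate_table[split_rows[[ids[i]]], , drop = FALSE]
    classify_cell(cr, alpha = alpha, n_perm = n_perm,
                  seed = derive_seed(master_seed, i, "classify"),
                  epochs = epochs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(epochs, function(ep) {
    d <- out[[paste0("dir_", ep)]]
    data.frame(epoch = ep, excited = sum(d == "+"), inhibited = sum(d == "-"),
               nonresponsive = sum(d == "0"), stringsAsFactors = FALSE)
  }))
  class(out) <- c("cell_class_table", "data.frame")
  attr(out, "epochs") <- epochs
  attr(out, "epoch_summary") <- summ
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- bonferroni_threshold(alpha, length(epochs))
  out
}

#' @export
summary.cell_class_table <- function(object, ...) {
  cat(sprintf("Classified %d cells (%d responsive) at threshold %.4g\n",
              nrow(object), sum(object$responsive), attr(object, "threshold")))
  print(attr(object, "epoch_summary"))
  invisible(attr(object, "epoch_summary"))
}
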