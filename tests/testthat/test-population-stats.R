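# Population summaries: chi-square, z traces, category tables, ANOVA,
# correlations.

test_that("chi-square matches the 2x2 closed form and handles margins", {
  hom <- chi_square_2xk(matrix(c(10, 10, 10, 10), 2))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p, 1)

  m <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  res <- chi_square_2xk(m)
  expect_equal(res$statistic, 20.0)
  expect_equal(res$df, 1)
  expect_equal(res$statistic, chisq_2x2_oracle(m))

  set.seed(31)
  for (rep in 1:20) {
    m <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(chi_square_2xk(m)$statistic, chisq_2x2_oracle(m))
  }
  expect_error(chi_square_2xk(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
  expect_error(chi_square_2xk(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("chi-square p-values are calibrated under homogeneity", {
  set.seed(32)
  ps <- replicate(400, {
    tab <- matrix(rbinom(2, 200, 0.4), ncol = 1)
    tab <- cbind(tab, 200 - tab)
    chi_square_2xk(tab)$p
  })
  # uniform p on (0,1): check the empirical CDF at a few quantiles
  for (q in c(0.1, 0.25, 0.5)) {
    expect_lt(abs(mean(ps <= q) - q), 3 * sqrt(q * (1 - q) / 400) + 0.02)
  }
})

test_that("z-normalization is exact for constructed baselines", {
  # 1 cell, constant event on every frame: peri-event rate = 20 events/s
  task <- task_spec("cue_guided", iti_mean = 12, iti_range = c(1, 1),
                    n_trials = 4)
  s <- generate_session(task, null_profiles(1), all_correct_cohort(), seed = 41)
  rec <- session_recording(matrix(1, 1, ncol(s$recording$traces)),
                           cell_ids = "c1")
  trials <- build_trials(s$log, task)
  base <- data.frame(cell_id = "c1", baseline_mean = 4, baseline_sd = 8)
  tr <- normalized_population_trace(rec, trials, base, "response",
                                    window = c(-1, 1))
  expect_equal(unique(tr$mean), (20 - 4) / 8)   # z = 2 by construction
  expect_equal(unique(tr$sem), 0)               # single cell

  # identity normalization: baseline mean 0, sd 1 returns the raw rate
  ident <- data.frame(cell_id = "c1", baseline_mean = 0, baseline_sd = 1)
  tr0 <- normalized_population_trace(rec, trials, ident, "response",
                                     window = c(-1, 1))
  expect_equal(unique(tr0$mean), 20)

  # zero baseline SD cells are excluded with a message
  base$baseline_sd <- 0
  expect_message(
    expect_error(normalized_population_trace(rec, trials, base, "response",
                                             window = c(-1, 1))),
    "zero baseline SD")
})

test_that("a group of identical cells has SEM zero and z near zero", {
  task <- fast_task(n_trials = 12)
  s <- generate_session(task, null_profiles(1, baseline = 3),
                        all_correct_cohort(), seed = 42)
  rec3 <- session_recording(s$recording$traces[c(1, 1, 1), , drop = FALSE],
                            cell_ids = c("a", "b", "c"))
  trials <- build_trials(s$log, task)
  rt <- build_rate_table(rec3, trials, task)
  tr <- normalized_population_trace(rec3, trials, baseline_stats(rt),
                                    "response", window = c(-2, 2))
  expect_equal(unique(tr$sem), 0)
  # untuned cell: z fluctuates around 0 with no systematic offset
  expect_lt(abs(mean(tr$mean)), 2)
})

test_that("category frequency tables rank and cover responsive cells", {
  single <- category_frequencies(rep("R+", 10))
  expect_equal(nrow(single), 1)
  expect_equal(single$cum_share, 1)
  expect_equal(attr(single, "minimal_set"), "R+")

  cats <- c(rep("T+C+", 50), rep("R+", 30), rep("R-P-", 20), rep("", 17))
  tab <- category_frequencies(cats, coverage_target = 0.8)
  expect_equal(tab$category, c("T+C+", "R+", "R-P-"))
  expect_equal(attr(tab, "n_responsive"), 100L)
  expect_equal(attr(tab, "minimal_set"), c("T+C+", "R+"))

  expect_warning(empty <- category_frequencies(c("", "")), "no responsive")
  expect_equal(nrow(empty), 0)
})

test_that("mixed-design ANOVA detects group offsets and not clones", {
  set.seed(33)
  z <- matrix(rnorm(40 * 8), 40, 8)
  # duplicate group A as group B: group effect exactly zero
  res <- mixed_anova_genotype_time(rbind(z, z), rep(c("A", "B"), each = 40))
  expect_equal(res$F[res$effect == "group"], 0, tolerance = 1e-10)

  # +1 z offset in all bins at n = 50/group: group effect detected
  za <- matrix(rnorm(50 * 8), 50, 8)
  zb <- matrix(rnorm(50 * 8) + 1, 50, 8)
  res2 <- mixed_anova_genotype_time(rbind(za, zb), rep(c("A", "B"), each = 50))
  expect_lt(res2$p[res2$effect == "group"], 0.01)
  expect_setequal(res2$effect, c("group", "time", "group:time"))

  expect_error(mixed_anova_genotype_time(z, rep("A", 40)), "at least 2 groups")
  expect_error(mixed_anova_genotype_time(z[1:3, ], c("A", "A", "B")),
               "2 cells per group")
})

test_that("group ANOVA type-I error is near nominal under the null", {
  set.seed(34)
  ps <- replicate(120, {
    z <- matrix(rnorm(20 * 5), 20, 5)
    res <- mixed_anova_genotype_time(z, rep(c("A", "B"), each = 10))
    res$p[res$effect == "group"]
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 120) + 0.01)
})

test_that("pearson_r reproduces the covariance formula and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  set.seed(35)
  a <- rnorm(12); b <- rnorm(12)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b)$r, direct)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("proportion tables account for every cell and test group contrasts", {
  set.seed(36)
  rt <- simulate_rate_table(sprintf("c%03d", 1:40), n_trials = 30,
                            epochs = c("T", "C", "R", "P"),
                            epoch_len = c(2, 1, 3, 3),
                            multipliers = c(lapply(1:20, function(i) c(R = 5)),
                                            lapply(1:20, function(i) NULL)))
  cl <- classify_population(rt, master_seed = 9)
  groups <- setNames(rep(c("A", "B"), each = 20), sprintf("c%03d", 1:40))
  pt <- proportion_table(cl, groups)
  expect_true(all(pt$excited + pt$inhibited + pt$nonresponsive == pt$n_cells))
  expect_true(all(abs(pt$prop_excited + pt$prop_inhibited +
                        pt$nonresponsive / pt$n_cells - 1) < 1e-12))
  tests <- attr(pt, "tests")
  expect_setequal(tests$epoch, c("T", "C", "R", "P"))
  # the R contrast (tuned group A vs untuned B) is overwhelming
  expect_lt(tests$p[tests$epoch == "R"], 1e-4)
})
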