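# Paired sign-flip permutation test, Bonferroni control, category
# composition.

test_that("exact enumeration matches the brute-force oracle", {
  # canonical worked case: differences (+1, +1, +1) over 2^3 = 8 patterns
  res <- paired_permutation_test(c(2, 2, 2), c(1, 1, 1), method = "exact")
  expect_equal(res$p, 0.25)
  expect_equal(res$p, perm_p_oracle(c(1, 1, 1)))
  expect_equal(res$statistic, 1)
  expect_equal(res$direction, "+")
  expect_equal(res$method, "exact")

  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    d <- round(rnorm(n), 2)
    res <- paired_permutation_test(d + 1, rep(1, n), method = "exact")
    expect_equal(res$p, perm_p_oracle(d))
  }
})

test_that("degenerate all-zero differences give p = 1 without error", {
  res <- paired_permutation_test(rep(2, 6), rep(2, 6))
  expect_equal(res$p, 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$direction, "0")
})

test_that("Monte-Carlo p agrees with exhaustive enumeration", {
  set.seed(22)
  for (rep in 1:20) {
    d <- rnorm(10)
    pe <- paired_permutation_test(d, rep(0, 10), method = "exact")$p
    pm <- paired_permutation_test(d, rep(0, 10), n_perm = 10000,
                                  method = "montecarlo", seed = 100 + rep)$p
    expect_lt(abs(pm - pe), 3 * sqrt(pe * (1 - pe) / 10000) + 2e-4)
  }
})

test_that("auto method switches to enumeration on small trial counts", {
  d <- rnorm(8)
  expect_equal(paired_permutation_test(d, rep(0, 8))$method, "exact")
  expect_equal(paired_permutation_test(rnorm(20), rep(0, 20))$method,
               "montecarlo")
})

test_that("p-values are invariant under positive rescaling of differences", {
  set.seed(23)
  d <- rnorm(9)
  p1 <- paired_permutation_test(d, rep(0, 9), method = "exact")$p
  p2 <- paired_permutation_test(d * 1e3, rep(0, 9), method = "exact")$p
  p3 <- paired_permutation_test(d * 1e-4, rep(0, 9), method = "exact")$p
  expect_identical(p1, p2)
  expect_identical(p1, p3)
  d20 <- rnorm(20)
  m1 <- paired_permutation_test(d20, rep(0, 20), seed = 7, method = "montecarlo")$p
  m2 <- paired_permutation_test(d20 * 50, rep(0, 20), seed = 7,
                                method = "montecarlo")$p
  expect_identical(m1, m2)
})

test_that("input validation rejects unusable vectors", {
  expect_error(paired_permutation_test(1, 1), "at least 2")
  expect_error(paired_permutation_test(1:3, 1:2), "equal length")
  expect_error(paired_permutation_test(c(1, NA, 2), c(0, 0, 0)), "non-finite")
})

test_that("Bonferroni thresholds divide alpha across epochs and directions", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.00625)  # the 0.05/8 rule
  expect_equal(bonferroni_threshold(0.05, 5), 0.005)
  expect_equal(bonferroni_threshold(0.05, 1), 0.025)
  expect_error(bonferroni_threshold(1.5, 4), "alpha")
  expect_error(bonferroni_threshold(0, 4), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_epochs")
})

test_that("strongly tuned cells are classified into their seeded category", {
  set.seed(24)
  epochs <- c("T", "C", "R", "P")
  lens <- c(2, 1, 3, 3)
  rt <- simulate_rate_table(c("exc", "inh", "null"), n_trials = 40,
                            epochs = epochs, epoch_len = lens,
                            multipliers = list(c(R = 5), c(R = 0.1, P = 0.1),
                                               NULL))
  cl <- classify_population(rt, master_seed = 31)
  expect_equal(cl$category[cl$cell_id == "exc"], "R+")
  expect_equal(cl$category[cl$cell_id == "inh"], "R-P-")
  expect_equal(cl$category[cl$cell_id == "null"], "")
})

test_that("categories name exactly the epochs below the adjusted threshold", {
  set.seed(25)
  rt <- simulate_rate_table(sprintf("c%02d", 1:12), n_trials = 25,
                            epochs = c("T", "C", "R", "P"),
                            epoch_len = c(2, 1, 3, 3),
                            multipliers = lapply(1:12, function(i) {
                              if (i %% 3 == 0) c(R = 4) else if (i %% 3 == 1) {
                                c(T = 0.2, P = 3)
                              } else NULL
                            }))
  cl <- classify_population(rt, master_seed = 32)
  thr <- attr(cl, "threshold")
  for (i in seq_len(nrow(cl))) {
    dirs <- parse_category(cl$category[i])
    for (ep in c("T", "C", "R", "P")) {
      sig <- cl[[paste0("p_", ep)]][i] < thr
      expect_equal(ep %in% names(dirs), sig)
      if (sig) {
        expect_equal(unname(dirs[ep]),
                     if (cl[[paste0("stat_", ep)]][i] > 0) "+" else "-")
      }
    }
  }
})

test_that("population classification is reproducible from the master seed", {
  set.seed(26)
  rt <- simulate_rate_table(c("a", "b"), n_trials = 30,
                            epochs = c("T", "C", "R", "P"),
                            epoch_len = c(2, 1, 3, 3))
  c1 <- classify_population(rt, master_seed = 5)
  c2 <- classify_population(rt, master_seed = 5)
  expect_identical(c1, c2)
  summ <- attr(c1, "epoch_summary")
  expect_true(all(summ$excited + summ$inhibited + summ$nonresponsive == 2))
})

test_that("untuned cells stay nonresponsive under familywise control", {
  set.seed(27)
  rt <- simulate_rate_table(sprintf("n%03d", 1:50), n_trials = 30,
                            epochs = c("T", "C", "R", "P"),
                            epoch_len = c(2, 1, 3, 3))
  cl <- classify_population(rt, master_seed = 6)
  # FWER <= 0.05: expect at most a couple of false positives in 50 cells
  expect_lte(sum(cl$responsive), 3)
})
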