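test_that("two-group test matches the textbook formula and edge cases", {
  tab <- data.frame(group = rep(c("ND", "HFD"), each = 3),
                    m = c(1.1, 2.3, 3.1, 4.0, 5.2, 6.5))
  res <- two_group_test(tab, "m")
  oracle <- welch_t_oracle(tab$m[tab$group == "HFD"],
                           tab$m[tab$group == "ND"])
  expect_equal(abs(res$statistic), abs(oracle), tolerance = 1e-10)
  expect_equal(unname(res$means[["ND"]]), mean(c(1.1, 2.3, 3.1)))
  expect_equal(unname(res$sems[["ND"]]),
               sd(c(1.1, 2.3, 3.1)) / sqrt(3))

  same <- data.frame(group = rep(c("A", "B"), each = 3), m = rep(1:3, 2))
  res0 <- two_group_test(same, "m")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  flat <- data.frame(group = rep(c("A", "B"), each = 3), m = rep(5, 6))
  expect_error(two_group_test(flat, "m"), "zero variance")
})

test_that("pooled-variance option matches classic Student's t", {
  tab <- data.frame(group = rep(c("A", "B"), each = 4),
                    m = c(1, 2, 3, 4, 2, 4, 6, 9))
  res <- two_group_test(tab, "m", pooled = TRUE)
  ref <- t.test(m ~ group, data = tab, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})

test_that("group means of a simulated cohort recover the design values", {
  acq <- default_acq(n_timepoints = 30)
  co <- simulate_cohort(cohort_spec(n_per_group = 5, seed = 11), acq)
  res <- two_group_test(co$truth, "kp_true")
  expect_lt(abs(res$means[["ND"]] - 0.021), 0.009)
  expect_lt(abs(res$means[["HFD"]] - 0.056), 0.015)
  expect_lt(res$p_value, 0.05)
})

test_that("two-group direction agrees with a permutation test on fixtures", {
  set.seed(3)
  tab <- data.frame(group = rep(c("A", "B"), each = 6),
                    m = c(rnorm(6, 0), rnorm(6, 2)))
  res <- two_group_test(tab, "m")
  obs <- mean(tab$m[tab$group == "B"]) - mean(tab$m[tab$group == "A"])
  perm <- replicate(999, {
    g <- sample(tab$group)
    mean(tab$m[g == "B"]) - mean(tab$m[g == "A"])
  })
  # t.test orders factor levels A then B, so t has the opposite sign of obs
  expect_equal(sign(res$statistic), -sign(obs))
  expect_lt(mean(abs(perm) >= abs(obs)), 0.05)
  expect_lt(res$p_value, 0.05)
})

test_that("Pearson correlation handles exact, null and modelled structure", {
  x <- seq(1, 10)
  tab <- data.frame(x = x, y = -x)
  res <- pearson_correlation(tab, "x", "y")
  expect_equal(res$r, -1)

  big <- withr::with_seed(21, data.frame(x = rnorm(500), y = rnorm(500)))
  res2 <- pearson_correlation(big, "x", "y")
  expect_lt(abs(res2$r), 0.12)

  expect_error(pearson_correlation(data.frame(x = rep(1, 5), y = 1:5),
                                   "x", "y"), "constant")
})

test_that("behavior scores correlate negatively with the lactate ratio", {
  acq <- default_acq(n_timepoints = 30)
  co <- simulate_cohort(cohort_spec(n_per_group = 8, seed = 17), acq)
  res <- pearson_correlation(co$truth, "ratio_true", "target_time")
  expect_lt(res$r, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("behavior indices implement the printed formulas", {
  bi <- behavior_indices(30, 10)
  expect_equal(bi$discrimination_index, 0.5)
  expect_equal(bi$preference_pct, 75)

  eqv <- behavior_indices(12, 12)
  expect_equal(eqv$discrimination_index, 0)
  expect_equal(eqv$preference_pct, 50)

  bound <- behavior_indices(8, 0)
  expect_equal(bound$discrimination_index, 1)
  expect_equal(bound$preference_pct, 100)

  expect_error(behavior_indices(0, 0), "both zero")
  expect_error(behavior_indices(-1, 2), "nonnegative")
})

test_that("DI is antisymmetric and preference complements under swap", {
  tn <- c(5, 12, 33, 0.4, 7)
  tf <- c(9, 12, 3, 11, 0.1)
  a <- behavior_indices(tn, tf)
  b <- behavior_indices(tf, tn)
  expect_equal(a$discrimination_index, -b$discrimination_index)
  expect_equal(a$preference_pct, 100 - b$preference_pct)
  expect_true(all(abs(a$discrimination_index) <= 1))
})
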