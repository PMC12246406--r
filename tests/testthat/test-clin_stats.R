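test_that("Welch t-test matches the hand formula and degenerate rules", {
  r <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  # equal variances, equal n: t = -3/sqrt(2/3), Satterthwaite df = 4
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4, tolerance = 1e-9)
  # identical groups: t = 0, p = 1
  z <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  # swapping groups flips the sign only
  rf <- welch_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rf$statistic, -r$statistic)
  expect_equal(rf$p_value, r$p_value)
  expect_error(welch_t_test(c(1), c(2, 3)), "two finite")
})

test_that("Welch p-values are uniform under the null", {
  set.seed(101)
  p <- replicate(4000, welch_t_test(rnorm(12), rnorm(15, sd = 2))$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("chi-square test is uncorrected Pearson and matches the cell loop", {
  ind <- rbind(c(50, 50), c(50, 50))
  r <- chi_square_test(ind)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(7)
  for (k in 1:5) {
    tab <- matrix(rpois(12, 30) + 1, 3, 4)
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chisq_loop <- sum((tab - exp_tab)^2 / exp_tab)
    r <- chi_square_test(tab)
    expect_equal(r$statistic, chisq_loop, tolerance = 1e-10)
    expect_equal(r$df, 6)
  }
  expect_error(chi_square_test(rbind(c(1, 0), c(2, 0))), "all-zero")
  expect_error(chi_square_test(rbind(c(1.5, 2), c(2, 3))), "integer")
})

test_that("published HER2 counts reproduce the uncorrected p-value", {
  # an uncorrected 2x2 chi-square gives ~0.514; Yates would give ~0.58
  r <- chi_square_test(reference_cohort_counts()$her2)
  expect_equal(round(r$p_value, 3), 0.514)
})

test_that("Cohen's d pooled-SD arithmetic and antisymmetry", {
  expect_equal(cohens_d(c(2, 3, 4), c(1, 2, 3)), 1)
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(5, 6, 7), c(5, 6, 7)), 0)
  x <- rnorm(20); y <- rnorm(25, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  # whole-sample convention differs from pooled when means differ
  expect_false(isTRUE(all.equal(cohens_d(c(0, 1), c(10, 11)),
                                cohens_d(c(0, 1), c(10, 11), sd = "whole"))))
})

test_that("df-scaled Cramer's V equals the classical V on 2x2 tables", {
  tab <- rbind(c(30, 10), c(20, 40))
  cv <- cramers_v(tab)
  chisq <- chi_square_test(tab)$statistic
  expect_equal(cv$V, sqrt(chisq / sum(tab)), tolerance = 1e-12)
  expect_equal(cv$df, 1)
  # independence: V = 0
  expect_equal(cramers_v(rbind(c(10, 20), c(30, 60)))$V, 0, tolerance = 1e-12)
})

test_that("df scaling (not min-dim scaling) reproduces the published values", {
  counts <- reference_cohort_counts()
  # 2x3 histotype: df-scaled V ~0.054; the min-dim variant would give ~0.076
  cv <- cramers_v(counts$histotype)
  expect_equal(round(cv$V, 3), 0.054)
  chisq <- chi_square_test(counts$histotype)$statistic
  v_mindim <- sqrt(chisq / (sum(counts$histotype) * 1))
  expect_equal(round(v_mindim, 3), 0.076)
  expect_equal(round(cramers_v(counts$detection_mode)$V, 3), 0.166)
})

test_that("nontriviality thresholds depend on effect type and df", {
  expect_true(nontrivial_effect(0.55, "d"))
  expect_false(nontrivial_effect(-0.49, "d"))
  expect_true(nontrivial_effect(0.31, "V", df = 1))
  expect_false(nontrivial_effect(0.29, "V", df = 1))
  expect_true(nontrivial_effect(0.22, "V", df = 2))
  expect_true(nontrivial_effect(0.18, "V", df = 3))
  expect_false(nontrivial_effect(0.16, "V", df = 3))
})

test_that("univariable table excludes missing entries per variable", {
  cohort <- generate_cohort(cohort_config(n_patients = 500, seed = 11))
  tab <- univariable_table(cohort)
  expect_true(all(c("age", "outcome_tsize", "her2", "outcome_lvi") %in%
                  tab$variable))
  for (v in c("bmi", "her2", "outcome_lvi")) {
    n_miss <- sum(is.na(cohort[[v]]) | cohort[[v]] == "missing",
                  na.rm = TRUE)
    row <- tab[tab$variable == v, ]
    expect_equal(row$n_missing, n_miss)
    expect_equal(row$n_used, nrow(cohort) - n_miss)
  }
  # planted associations carry the expected signs
  expect_gt(tab$effect[tab$variable == "outcome_tsize"], 0)
  expect_gt(tab$effect[tab$variable == "outcome_lvi"], 0)
  expect_lt(tab$effect[tab$variable == "age"], 0)
})

test_that("null cohorts show no spurious categorical associations", {
  cohort <- generate_cohort(cohort_config(n_patients = 1200,
                                          null_associations = TRUE,
                                          seed = 23))
  tab <- univariable_table(cohort)
  cat_rows <- tab[tab$type == "categorical", ]
  expect_true(all(cat_rows$effect < 0.09))
  # roughly the nominal type-I rate: few of the 15 null tests significant
  null_rows <- tab[tab$variable != "outcome_n_lnm", ]
  expect_lte(sum(null_rows$p_value < 0.05), 3)
})
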