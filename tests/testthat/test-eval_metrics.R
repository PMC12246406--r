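# brute-force ROC AUC over all positive-negative pairs (ties count 1/2)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("roc_auc matches brute-force pair counting", {
  expect_equal(roc_auc(c(0.4, 0.3, 0.2, 0.1), c(0, 1, 0, 1)), 0.25)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(3)
  for (k in 1:20) {
    n <- sample(5:60, 1)
    labels <- c(1, 0, rbinom(n, 1, 0.4))
    scores <- round(runif(n + 2), 2)   # rounded to force ties
    expect_equal(roc_auc(scores, labels), auc_bruteforce(scores, labels))
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("pr_auc average-precision identities", {
  expect_equal(pr_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # all-equal scores: single tie group, AP = prevalence
  expect_equal(pr_auc(rep(0.2, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  # single positive ranked last of n: AP = 1/n
  n <- 8
  expect_equal(pr_auc(seq_len(n), c(1, rep(0, n - 1))), 1 / n)
  expect_error(pr_auc(c(1, 2), c(0, 0)), "no positives")
})

test_that("pearson_r hand case and degeneracies", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(-1, -2, -3)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.98198, tolerance = 1e-5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("threshold at sensitivity floor maximizes specificity", {
  # single positive: threshold is its score
  expect_equal(threshold_at_sensitivity(c(0.3, 0.8), c(0, 1)), 0.8)
  # the stated enumeration case
  t <- threshold_at_sensitivity(c(0.9, 0.4, 0.5), c(1, 1, 0), 0.90)
  expect_equal(t, 0.4)
  cm <- confusion_metrics(c(0.9, 0.4, 0.5), c(1, 1, 0), t)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 0)
  # 10 positives at floor 0.9: at least 9 admitted
  set.seed(5)
  scores <- runif(40)
  labels <- c(rep(1, 10), rep(0, 30))
  t <- threshold_at_sensitivity(scores, labels, 0.90)
  expect_gte(sum(scores[labels == 1] >= t), 9)
})

test_that("confusion metrics, SLNB reduction and net benefit arithmetic", {
  # constructed 2x2: tp=9 fn=1 tn=50 fp=40
  scores <- c(rep(0.8, 9), 0.2, rep(0.1, 50), rep(0.9, 40))
  labels <- c(rep(1, 10), rep(0, 50), rep(0, 40))
  cm <- confusion_metrics(scores, labels, 0.5)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(9, 1, 50, 40))
  expect_equal(cm$sensitivity, 0.90)
  expect_equal(100 * cm$specificity, 55.6, tolerance = 0.05)
  expect_equal(100 * cm$ppv, 18.4, tolerance = 0.05)
  expect_equal(slnb_reduction_rate(cm), 51)
  # all predicted positive: NPV undefined, reduction 0
  cm_all <- confusion_metrics(scores, labels, 0)
  expect_true(is.na(cm_all$npv))
  expect_false(cm_all$defined[["npv"]])
  expect_equal(slnb_reduction_rate(cm_all), 0)
  expect_equal(slnb_reduction_rate(confusion_metrics(scores, labels, 2)), 100)
  # net benefit hand case: tp=20 fp=30 n=100 at pt=0.2
  nb <- net_benefit(list(tp = 20, fp = 30, n = 100), 0.2)
  expect_equal(nb, 0.125)
  expect_equal(net_benefit(list(tp = 0, fp = 0, n = 50), 0.3), 0)
})

test_that("decision curve references: treat-all closed form, break-even", {
  set.seed(8)
  labels <- rbinom(200, 1, 0.3)
  scores <- runif(200)
  prev <- mean(labels)
  dc <- decision_curve(scores, labels, pt_grid = c(0.1, prev, 0.5))
  expect_true(all(dc$treat_none == 0))
  expect_equal(dc$treat_all, prev - (1 - prev) * dc$pt / (1 - dc$pt))
  # treat-all at pt = prevalence is exactly 0
  expect_equal(dc$treat_all[dc$pt == prev], 0, tolerance = 1e-12)
  # model curve of a perfect model is nonnegative everywhere
  dc2 <- decision_curve(labels, labels, pt_grid = seq(0.1, 0.9, 0.2))
  expect_true(all(dc2$model >= 0))
})

test_that("calibration curve bins and degenerate cases", {
  # scores equal to labels: both occupied bins sit on the diagonal
  cc <- calibration_curve(c(0, 0, 1, 1), c(0, 0, 1, 1), n_bins = 10)
  expect_equal(cc$mean_pred, cc$obs_rate)
  # constant score at the event rate: a single point (0.3, 0.3)
  set.seed(2)
  y <- rep(c(1, 0, 0, 0, 1, 0, 0, 1, 0, 0), 3)
  cc2 <- calibration_curve(rep(0.3, 30), y, n_bins = 10)
  expect_equal(nrow(cc2), 1)
  expect_equal(cc2$mean_pred, 0.3)
  expect_equal(cc2$obs_rate, 0.3)
  cc3 <- calibration_curve(runif(57), rbinom(57, 1, 0.4))
  expect_equal(sum(cc3$n), 57)
})

test_that("reversed-percentile CI matches direct quantile arithmetic", {
  set.seed(9)
  reps <- rnorm(500, 0.7, 0.05)
  est <- 0.72
  ci <- reversed_percentile_ci(est, reps)
  q <- quantile(reps, c(0.975, 0.025), names = FALSE)
  expect_equal(unname(ci), c(2 * est - q[1], 2 * est - q[2]))
  expect_lte(ci[1], ci[2])
})

test_that("bootstrap report: paired resamples, constant metric, SD scale", {
  set.seed(4)
  n <- 120
  labels <- rbinom(n, 1, 0.3)
  s1 <- runif(n) + 0.5 * labels
  s2 <- runif(n) + 0.3 * labels
  rep <- bootstrap_report(list(a = s1, b = s2), labels, B = 100, seed = 7)
  expect_equal(dim(rep$indices), c(n, 100))
  # resampled indices shared across models makes differences paired
  expect_equal(rep$B, 100)
  # every resample kept both classes
  expect_true(all(apply(rep$indices, 2,
                        function(i) length(unique(labels[i]))) == 2))
  # constant metric: SD 0 and CI collapsed at the constant
  const <- list(m = function(scores, labels) 0.42)
  repc <- bootstrap_report(list(a = s1), labels, metrics = const,
                           B = 50, seed = 1)
  expect_equal(repc$boot_sd[1, 1], 0)
  expect_equal(unname(repc$ci[1, 1, ]), c(0.42, 0.42))
  # bootstrap SD of the AUC approximates the replicate-to-replicate SD
  boot_sd <- rep$boot_sd["roc_auc", "a"]
  mc_sd <- sd(replicate(60, {
    lab <- rbinom(n, 1, 0.3)
    roc_auc(runif(n) + 0.5 * lab, lab)
  }))
  expect_lt(abs(boot_sd - mc_sd), 0.5 * mc_sd)
})

test_that("paired permutation test identities and exhaustive enumeration", {
  set.seed(6)
  labels <- rbinom(40, 1, 0.5)
  s <- runif(40)
  expect_equal(permutation_test(s, s, labels, B = 99), 1)
  p <- permutation_test(s, runif(40), labels, B = 99, seed = 2)
  expect_gte(p, 1 / 100)
  expect_lte(p, 1)
  # 3-patient exhaustive enumeration oracle vs large-B estimate
  lab3 <- c(1, 0, 1)
  a3 <- c(0.9, 0.2, 0.8); b3 <- c(0.4, 0.6, 0.3)
  metric <- function(scores, labels) mean(scores[labels == 1]) -
    mean(scores[labels == 0])
  d_obs <- metric(a3, lab3) - metric(b3, lab3)
  hits <- 0
  for (m in 0:7) {
    swap <- as.logical(bitwAnd(m, c(1, 2, 4)))
    pa <- ifelse(swap, b3, a3); pb <- ifelse(swap, a3, b3)
    if (abs(metric(pa, lab3) - metric(pb, lab3)) >= abs(d_obs) - 1e-12)
      hits <- hits + 1
  }
  p_exact_limit <- hits / 8
  p_hat <- permutation_test(a3, b3, lab3, metric = metric, B = 4000, seed = 3)
  expect_lt(abs(p_hat - p_exact_limit), 0.05)
})
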