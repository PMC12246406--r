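test_that("image-feature ensembling is the elementwise model mean", {
  b1 <- data.frame(lnm_prob = 0.2, n_lnm_pred = 1, lvi_prob = 0.4,
                   tsize_pred = 10, multifoc_prob = 0.1)
  b2 <- data.frame(lnm_prob = 0.6, n_lnm_pred = 3, lvi_prob = 0.2,
                   tsize_pred = 20, multifoc_prob = 0.5)
  expect_equal(ensemble_image_feature(list(b1)), unlist(b1))
  expect_equal(ensemble_image_feature(list(b1, b2))[["lnm_prob"]], 0.4)
  # direct-loop oracle over 25 synthetic bundles
  set.seed(15)
  bundles <- lapply(1:25, function(i) as.data.frame(as.list(
    stats::setNames(runif(5), names(b1)))))
  ens <- ensemble_image_feature(bundles)
  loop <- rep(0, 5)
  for (b in bundles) loop <- loop + unlist(b)
  expect_equal(unname(ens), unname(loop / 25))
})

test_that("patient aggregation is the elementwise view maximum", {
  v1 <- data.frame(lnm_prob = 0.2, n_lnm_pred = 3, lvi_prob = 0.1,
                   tsize_pred = 12, multifoc_prob = 0.6)
  v2 <- data.frame(lnm_prob = 0.7, n_lnm_pred = 1, lvi_prob = 0.3,
                   tsize_pred = 9, multifoc_prob = 0.2)
  expect_equal(aggregate_patient(list(v1)), unlist(v1))
  agg <- aggregate_patient(list(v1, v2))
  expect_equal(agg[["lnm_prob"]], 0.7)
  expect_equal(agg[["tsize_pred"]], 12)
  expect_error(aggregate_patient(list()), "empty")
})

test_that("aggregation order is mean over models then max over views", {
  # constructed 2-view x 2-model table where the order matters
  man <- data.frame(image_id = c("i1", "i2"), patient_id = c("p", "p"))
  m1 <- data.frame(image_id = c("i1", "i2"), f = c(0.9, 0.0))
  m2 <- data.frame(image_id = c("i1", "i2"), f = c(0.0, 0.8))
  got <- patient_mammo_features(list(m1, m2), man)
  # mean-then-max: max(0.45, 0.40) = 0.45; max-then-mean would be 0.85
  expect_equal(got[[2]], 0.45)
  expect_false(isTRUE(all.equal(got[[2]], 0.85)))
})

test_that("clinical encoding contract: 29 columns, flags, one-hots", {
  cohort <- generate_cohort(cohort_config(n_patients = 200, seed = 21))
  stats_tr <- fit_clinical_stats(cohort[1:150, ])
  enc <- encode_clinical(cohort, stats_tr)
  expect_equal(ncol(enc), 29)
  expect_equal(nrow(enc), 200)
  # fully observed record: all missing flags zero
  full_row <- which(!is.na(cohort$age) & !is.na(cohort$bmi) &
    cohort$menopausal != "missing" & cohort$grade != "missing" &
    cohort$er != "missing" & cohort$pgr != "missing" &
    cohort$her2 != "missing" & cohort$ki67 != "missing" &
    cohort$subtype != "missing")[1]
  expect_equal(unname(enc[full_row, 19:29]), rep(0, 11))
  # LVI is an outcome, not a predictor: its missingness leaves the
  # encoding untouched
  rec <- cohort[full_row, ]; rec$outcome_lvi <- NA
  expect_equal(encode_clinical(rec, stats_tr), enc[full_row, , drop = FALSE])
  # grade II one-hot
  g2 <- which(cohort$grade == "II")[1]
  expect_equal(unname(enc[g2, c("grade_I", "grade_II", "grade_III")]),
               c(0, 1, 0))
  # one-hot groups sum to one iff observed
  oh_sum <- rowSums(enc[, c("grade_I", "grade_II", "grade_III")])
  expect_true(all(oh_sum == 1 - enc[, "miss_grade"]))
  # z-scoring parameters come from the training records only
  stats_tr2 <- fit_clinical_stats(cohort[1:150, ])
  expect_identical(stats_tr[], stats_tr2[])
  rec_bad <- cohort[1, ]; rec_bad$grade <- "IV"
  expect_error(encode_clinical(rec_bad, stats_tr), "unknown category")
})

test_that("fusion classifier: seeded fit, S3 methods, separable sanity", {
  set.seed(23)
  n <- 120
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(x[, 1] + 0.8 * x[, 2] + rnorm(n, 0, 0.4) > 0)
  cfg <- fusion_config(hidden = 16, epochs = 15, seed = 7)
  f1 <- fusion_fit(x, y, cfg)
  f2 <- fusion_fit(x, y, cfg)
  expect_identical(predict(f1, x), predict(f2, x))
  expect_true(all(predict(f1, x) >= 0 & predict(f1, x) <= 1))
  expect_gte(roc_auc(predict(f1, x), y), 0.85)
  expect_equal(rownames(coef(f1)), paste0("f", 1:6))
  expect_output(print(f1), "fusion classifier")
  expect_error(fusion_fit(x, rep(1, n)), "single-class")
  # default configuration carries the printed hyperparameters
  d <- fusion_config()
  expect_equal(d$hidden, 128)
  expect_equal(d$batch_size, 32)
  expect_equal(d$dropout, 0.2)
  expect_equal(d$lr, 0.01)
  expect_equal(d$weight_decay, 1e-4)
})

test_that("double-CV fusion produces leakage-audited out-of-fold scores", {
  set.seed(25)
  n <- 80
  ids <- sprintf("P%03d", 1:n)
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, paste0("f", 1:4)))
  y <- stats::setNames(as.integer(x[, 1] + rnorm(n, 0, 0.5) > 0), ids)
  plan <- make_plan(ids, y, k_outer = 3, k_inner = 2, seed = 1)
  fit <- fusion_double_cv(x, y, plan,
                          fusion_config(hidden = 8, epochs = 8, seed = 2))
  expect_length(fit$oof, n)
  expect_true(audit_provenance(fit$cv)$ok)
  expect_gte(fit$auc, 0.7)
  expect_output(print(fit), "Double cross-validated")
})
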