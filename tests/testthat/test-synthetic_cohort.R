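test_that("cohort generation is deterministic and respects the config", {
  cfg <- cohort_config(n_patients = 300, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 300)
  # config validation
  expect_error(cohort_config(prevalence_lnm = 1.2), "probabilities")
  expect_error(cohort_config(size_mean_pos = 10, size_mean_neg = 12),
               "size_mean_pos")
  expect_error(cohort_config(peritumoral_signal_strength = -1), ">= 0")
})

test_that("empirical prevalence falls in the exact binomial 99% band", {
  n <- 1200
  cfg <- cohort_config(n_patients = n, prevalence_lnm = 0.30, seed = 7)
  cohort <- generate_cohort(cfg)
  k <- sum(cohort$outcome_lnm)
  band <- qbinom(c(0.005, 0.995), n, 0.30)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("tumor size carries the configured conditional shift", {
  cfg <- cohort_config(n_patients = 1200, size_mean_pos = 18.9,
                       size_mean_neg = 14.2, size_sd = 8, seed = 19)
  cohort <- generate_cohort(cfg)
  d <- cohens_d(cohort$outcome_tsize[cohort$outcome_lnm == 1],
                cohort$outcome_tsize[cohort$outcome_lnm == 0])
  expect_gt(d, 0.4)
  expect_lt(d, 0.8)
  expect_true(all(cohort$outcome_tsize > 0 & cohort$outcome_tsize <= 50))
})

test_that("node-count coupling invariant holds in every record", {
  cohort <- generate_cohort(cohort_config(n_patients = 800, seed = 3))
  expect_true(all((cohort$outcome_lnm == 0) == (cohort$outcome_n_lnm == 0)))
  expect_true(all(cohort$outcome_n_lnm[cohort$outcome_lnm == 1] >= 1))
  # overdispersion target: SD of positive-node counts well above Poisson
  pos <- cohort$outcome_n_lnm[cohort$outcome_lnm == 1]
  expect_gt(sd(pos), sqrt(mean(pos)))
})

test_that("rendering is deterministic in (patient, view, seed) and jittered", {
  cfg <- cohort_config(n_patients = 4, image_height = 96, image_width = 64,
                       px_per_mm = 1, seed = 5)
  cohort <- generate_cohort(cfg)
  r1 <- render_mammogram(cohort[1, ], 0, cfg)
  r2 <- render_mammogram(cohort[1, ], 0, cfg)
  expect_identical(r1$image, r2$image)
  r_other_view <- render_mammogram(cohort[1, ], 1, cfg)
  expect_false(identical(r1$image, r_other_view$image))
  expect_true(all(r1$image >= 0 & r1$image <= 1))
  # annotation inside bounds (0-based x = column)
  expect_gte(r1$annotation$center_x, 0)
  expect_lt(r1$annotation$center_x, 64)
  expect_lt(r1$annotation$center_y, 96)
  expect_error(render_mammogram(cohort[1, ], 5, cfg), "out of range")
})

test_that("lesion size maps to pixels and oversize lesions error", {
  cfg <- cohort_config(n_patients = 2, image_height = 128, image_width = 96,
                       px_per_mm = 2, peritumoral_signal_strength = 0,
                       seed = 9)
  cohort <- generate_cohort(cfg)
  rec <- cohort[1, ]
  rec$outcome_tsize <- 15; rec$outcome_multifoc <- 0
  r <- render_mammogram(rec, 0, cfg)
  ann <- r$annotation
  # lesion major axis 15 mm * 2 px/mm = 30 px: center clearly brighter than
  # a ring far outside the lesion
  cx <- ann$center_x + 1; cy <- ann$center_y + 1
  core <- r$image[cy, cx]
  ring <- mean(r$image[cy, pmin(pmax(cx + c(-40, 40), 1), 96)])
  expect_gt(core - ring, 0.2)
  rec_big <- rec
  rec_big$outcome_tsize <- 49  # 98 px > 96-px width
  expect_error(render_mammogram(rec_big, 0, cfg), "exceeds image")
})

test_that("multifocal records render at least two lesion components", {
  cfg <- cohort_config(n_patients = 1, image_height = 192, image_width = 128,
                       px_per_mm = 2, peritumoral_signal_strength = 0,
                       seed = 13)
  cohort <- generate_cohort(cfg)
  rec <- cohort[1, ]
  rec$outcome_multifoc <- 1; rec$outcome_tsize <- 12
  rec$lesion_u <- 0.3; rec$lesion_theta <- 0
  r <- render_mammogram(rec, 0, cfg)
  lab <- EBImage::bwlabel(EBImage::Image(t(r$image > 0.55)))
  expect_gte(max(lab), 2)
})

test_that("peritumoral signal is off at strength zero and monotone in AUC", {
  mk <- function(strength, rec_override = NULL) {
    cfg <- cohort_config(n_patients = 150, image_height = 96,
                         image_width = 64, px_per_mm = 1,
                         peritumoral_signal_strength = strength, seed = 31)
    cohort <- generate_cohort(cfg)
    if (!is.null(rec_override)) cohort <- rec_override(cohort)
    list(cfg = cfg, cohort = cohort)
  }
  # switched-off signal: records differing only in LNM/LVI render identically
  z <- mk(0)
  rec_a <- z$cohort[1, ]
  rec_a$outcome_lnm <- 1; rec_a$latent_lvi <- 1; rec_a$outcome_n_lnm <- 3
  rec_b <- rec_a
  rec_b$outcome_lnm <- 0; rec_b$latent_lvi <- 0; rec_b$outcome_n_lnm <- 0
  ia <- render_mammogram(rec_a, 0, z$cfg)$image
  ib <- render_mammogram(rec_b, 0, z$cfg)$image
  expect_equal(mean(abs(ia - ib)), 0)
  # AUC of a pixel-sum statistic does not decrease with signal strength
  auc_at <- function(strength) {
    d <- mk(strength)
    stat <- vapply(seq_len(nrow(d$cohort)), function(i)
      mean(render_mammogram(d$cohort[i, ], 0, d$cfg)$image),
      numeric(1))
    roc_auc(stat, d$cohort$outcome_lnm)
  }
  a0 <- auc_at(0); a1 <- auc_at(1); a2 <- auc_at(2)
  expect_gt(a1, a0)
  expect_gte(a2, a1 - 0.02)
})

test_that("cohort validation flags hold for default and null configs", {
  cfg <- cohort_config(n_patients = 1200, seed = 17)
  cohort <- generate_cohort(cfg)
  v <- validate_cohort(cohort, cfg)
  expect_true(all(v$checks$ok))
  # all-equal conditional rates: categorical effect sizes near zero
  cfg0 <- cohort_config(n_patients = 1200, null_associations = TRUE,
                        seed = 29)
  tab0 <- univariable_table(generate_cohort(cfg0))
  expect_true(all(tab0$effect[tab0$variable %in%
    c("menopausal", "detection_mode", "her2", "ki67")] < 0.05 * sqrt(2)))
  expect_error(validate_cohort(cohort[0, ], cfg), "empty")
})

test_that("cohort disk roundtrip preserves tables and 16-bit images", {
  dir <- file.path(tempdir(), "cohort-io")
  cfg <- cohort_config(n_patients = 3, image_height = 64, image_width = 48,
                       px_per_mm = 1, views_per_patient = 2, seed = 2)
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, cfg, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$cohort), 3)
  expect_equal(nrow(back$manifest), 6)
  rc <- render_cohort_images(cohort, cfg)
  id <- back$manifest$image_id[1]
  # 16-bit quantization error bound
  expect_lt(max(abs(back$images[[id]] - rc$images[[id]])), 1 / 65535 + 1e-9)
  unlink(dir, recursive = TRUE)
})
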