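#' Desk-scale comparison experiments
#'
#' End-to-end experiment helpers that reproduce the workflow's comparison
#' protocols on the seeded phantom cohort at desk scale: initialization
#' comparisons (self-supervised vs random), neck comparisons (Transformer
#' vs ResBlock), scope comparisons (full-breast vs tumor ROI when the
#' planted peritumoral signal lies outside the ROI), fusion-variant
#' comparisons (clinical vs clinical + mammogram features) and null/
#' recovery controls. Problem sizes default to small phantom cohorts and
#' tiny networks so each experiment runs in seconds to a few minutes on
#' one CPU.
#'
#' @name experiments
NULL

# stratified holdout split of indices by a binary label
split_stratified <- function(labels, val_fraction, seed) {
  local_rng(seed)
  val <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
    idx <- sample(idx)
    idx[seq_len(max(1, round(length(idx) * val_fraction)))]
  }))
  list(train = setdiff(seq_along(labels), val), val = sort(unname(val)))
}

#' Finetune-evaluation protocol for backbone initializations
#'
#' Trains neck + heads (backbone finetuned) from a given initialization
#' under a fixed protocol -- stratified train/validation split, identical
#' split and seed across initializations -- and reports validation ROC AUC
#' for the classification tasks and Pearson r for the regressions.
#'
#' @param init `"random"`, `"ssl"` or `"external"`.
#' @param images Named list of normalized image matrices.
#' @param labels Aligned outcome `data.frame` (see [train_neck()]).
#' @param weights Backbone weights for `"ssl"`/`"external"` inits.
#' @param config A [neck_config()].
#' @param val_fraction Validation fraction (stratified on LNM).
#' @param seed Split seed (keep fixed when comparing initializations).
#' @return List with `metrics` (`data.frame`: task, metric, value),
#'   `mean_cls_auc` (mean validation AUC over classification tasks) and
#'   the fitted `model`.
#' @export
finetune_evaluate <- function(init = c("random", "ssl", "external"),
                              images, labels, weights = NULL,
                              config = neck_config(), val_fraction = 0.3,
                              seed = 1) {
  init <- match.arg(init)
  if (init != "random" && is.null(weights))
    stop("weights required for init = '", init, "'")
  if (all(vapply(c("outcome_lnm", "outcome_lvi", "outcome_multifoc"),
                 function(cc) all(is.na(labels[[cc]])), logical(1))) &&
      all(is.na(labels$outcome_tsize)))
    stop("labels missing for all tasks")
  sp <- split_stratified(labels$outcome_lnm, val_fraction,
                         string_seed("ft-split", seed))
  model <- train_neck(if (init == "random") NULL else weights,
                      images, labels, sp, config)
  pv <- predict(model, images[sp$val])
  lv <- labels[sp$val, ]
  rows <- list()
  add <- function(task, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(task = task, metric = metric,
                                            value = value)
  auc_of <- function(scores, y) {
    ok <- !is.na(y)
    if (length(unique(y[ok])) < 2) return(NA_real_)
    roc_auc(scores[ok], y[ok])
  }
  add("lnm", "roc_auc", auc_of(pv$lnm_prob, lv$outcome_lnm))
  add("lvi", "roc_auc", auc_of(pv$lvi_prob, lv$outcome_lvi))
  add("multifoc", "roc_auc", auc_of(pv$multifoc_prob, lv$outcome_multifoc))
  r_of <- function(pred, y) {
    ok <- !is.na(y)
    if (sum(ok) < 3 || stats::var(y[ok]) == 0 || stats::var(pred[ok]) == 0)
      return(NA_real_)
    pearson_r(pred[ok], y[ok])
  }
  add("n_lnm", "pearson_r", r_of(pv$n_lnm_pred, lv$outcome_n_lnm))
  add("tsize", "pearson_r", r_of(pv$tsize_pred, lv$outcome_tsize))
  metrics <- do.call(rbind, rows)
  cls <- metrics$value[metrics$metric == "roc_auc"]
  list(metrics = metrics, mean_cls_auc = mean(cls, na.rm = TRUE),
       model = model, split = sp)
}

#' Generate and preprocess a desk-scale phantom imaging cohort
#'
#' Generates a phantom cohort, renders one view per patient, segments and
#' normalizes each image, and extracts the tumor-ROI crop.
#'
#' @param n Patients.
#' @param seed Cohort seed.
#' @param image_height,image_width,px_per_mm,peritumoral_signal_strength
#'   Generator settings (see [cohort_config()]).
#' @param halo_inner_mm,halo_width_mm Halo annulus; raise `halo_inner_mm`
#'   above `roi_size / (2 * px_per_mm)` to plant the LNM/LVI signal
#'   entirely outside the ROI crop.
#' @param roi_size ROI side in pixels.
#' @return List with `cohort`, `full` (normalized full images, one per
#'   patient), `roi` (ROI crops), `labels`, `config`.
#' @export
desk_phantom_data <- function(n = 90, seed = 1, image_height = 96,
                              image_width = 64, px_per_mm = 1,
                              peritumoral_signal_strength = 2,
                              halo_inner_mm = 2, halo_width_mm = 25,
                              roi_size = 32) {
  cfg <- cohort_config(n_patients = n, views_per_patient = 1,
                       image_height = image_height,
                       image_width = image_width, px_per_mm = px_per_mm,
                       peritumoral_signal_strength =
                         peritumoral_signal_strength,
                       halo_inner_mm = halo_inner_mm,
                       halo_width_mm = halo_width_mm, seed = seed)
  cohort <- generate_cohort(cfg)
  full <- list(); roi <- list()
  pcfg <- preprocess_config(roi_size = roi_size)
  for (i in seq_len(n)) {
    r <- render_mammogram(cohort[i, ], 0, cfg)
    nrm <- normalize_intensity(r$image, r$mask, pcfg)
    pid <- cohort$patient_id[i]
    full[[pid]] <- nrm
    roi[[pid]] <- extract_roi(nrm, r$annotation, roi_size)
  }
  labels <- cohort[, c("outcome_lnm", "outcome_n_lnm", "outcome_lvi",
                       "outcome_tsize", "outcome_multifoc")]
  list(cohort = cohort, full = full, roi = roi, labels = labels,
       config = cfg)
}

# tiny backbone/neck settings shared by the desk experiments
desk_backbone <- function() backbone_config(c(8, 16, 32))

desk_neck <- function(neck_type, scope, seed, epochs = 8, patience = 3) {
  neck_config(neck_type = neck_type, scope = scope,
              backbone = desk_backbone(), tf_depth = 1, tf_heads = 2,
              tf_dim = 32, epochs = epochs, batch_size = 8, lr = 2e-3,
              patience = patience, seed = seed)
}

#' Initialization comparison: self-supervised vs random
#'
#' Per seed: generate a phantom cohort, pretrain the backbone with the
#' chosen SSL objective on tiled patches, then finetune-evaluate the SSL
#' and random initializations under the identical protocol and record the
#' mean classification AUC of each.
#'
#' @param n_seeds Replicate seeds.
#' @param n Patients per replicate.
#' @param method SSL objective.
#' @param ssl_epochs,finetune_epochs Epoch budgets.
#' @param seed Base seed.
#' @return `data.frame` with one row per seed: `auc_ssl`, `auc_random`.
#' @export
experiment_ssl_effect <- function(n_seeds = 5, n = 90,
                                  method = "barlow_twins", ssl_epochs = 8,
                                  finetune_epochs = 8, seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    dat <- desk_phantom_data(n = n, seed = string_seed("ssl-exp", s, seed))
    pcfg <- preprocess_config(patch_size = 32, min_tissue_fraction = 0.25)
    patches <- list()
    for (img in dat$full) {
      mask <- img > 0
      patches <- c(patches, tile_patches(img, mask, pcfg)$patches)
    }
    scfg <- ssl_config(method = method, backbone = desk_backbone(),
                       epochs = ssl_epochs, batch_size = 16,
                       seed = string_seed("ssl", s, seed))
    pre <- pretrain_backbone(patches, scfg)
    ncfg <- desk_neck("resblock", "full", seed = string_seed("ft", s, seed),
                      epochs = finetune_epochs)
    ft_ssl <- finetune_evaluate("ssl", dat$full, dat$labels,
                                weights = pre$weights, config = ncfg,
                                seed = s)
    ft_rnd <- finetune_evaluate("random", dat$full, dat$labels,
                                config = ncfg, seed = s)
    data.frame(seed = s, auc_ssl = ft_ssl$mean_cls_auc,
               auc_random = ft_rnd$mean_cls_auc)
  })
  do.call(rbind, rows)
}

#' Neck comparison: Transformer vs ResBlock for tumor-size regression
#'
#' Per seed, trains both necks on full-breast phantom images under the
#' same protocol (shared random initialization seed, split, epoch budget
#' and early stopping) and records the validation Pearson r of the
#' tumor-size head.
#'
#' @inheritParams experiment_ssl_effect
#' @param epochs,patience Training budget per model.
#' @param val_fraction Validation fraction.
#' @return `data.frame` per seed: `r_transformer`, `r_resblock`.
#' @export
experiment_neck_effect <- function(n_seeds = 5, n = 100, epochs = 12,
                                   patience = 4, val_fraction = 0.4,
                                   seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    dat <- desk_phantom_data(n = n, seed = string_seed("neck-exp", s, seed))
    r_of <- function(neck_type) {
      ncfg <- desk_neck(neck_type, "full",
                        seed = string_seed("neck", neck_type, s, seed),
                        epochs = epochs, patience = patience)
      ft <- finetune_evaluate("random", dat$full, dat$labels, config = ncfg,
                              val_fraction = val_fraction, seed = s)
      ft$metrics$value[ft$metrics$task == "tsize"]
    }
    data.frame(seed = s, r_transformer = r_of("transformer"),
               r_resblock = r_of("resblock"))
  })
  do.call(rbind, rows)
}

#' Scope comparison: full-breast vs tumor ROI for LNM prediction
#'
#' The peritumoral halo is planted outside the ROI footprint
#' (`halo_inner_mm` beyond the ROI half-width), so ROI models see lesion
#' geometry but not the nodal-status signal; full-image models see both.
#' Per seed both scopes are trained identically and validation LNM AUC is
#' recorded.
#'
#' @inheritParams experiment_neck_effect
#' @return `data.frame` per seed: `auc_full`, `auc_roi`.
#' @export
experiment_scope_effect <- function(n_seeds = 5, n = 90, epochs = 8,
                                    seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    dat <- desk_phantom_data(n = n, seed = string_seed("scope-exp", s, seed),
                             halo_inner_mm = 20, halo_width_mm = 14,
                             roi_size = 32)
    auc_of <- function(scope) {
      imgs <- if (scope == "full") dat$full else dat$roi
      ncfg <- desk_neck("resblock", scope,
                        seed = string_seed("scope", scope, s, seed),
                        epochs = epochs)
      ft <- finetune_evaluate("random", imgs, dat$labels, config = ncfg,
                              seed = s)
      ft$metrics$value[ft$metrics$task == "lnm"]
    }
    data.frame(seed = s, auc_full = auc_of("full"), auc_roi = auc_of("roi"))
  })
  do.call(rbind, rows)
}

#' Fusion-variant comparison on a phantom cohort
#'
#' Builds leakage-free patient-level mammogram features by training
#' full-image neck models in a small nested plan (each development
#' patient's features come from models that never saw them), then
#' compares double-cross-validated fusion AUCs of the clinical-only model
#' and the clinical + full-breast-mammogram model.
#'
#' @param n Patients.
#' @param seed Seed.
#' @param neck_epochs,k_img Image-stage epochs and fold count (the image
#'   stage uses a `k_img x k_img` nested plan at desk scale).
#' @param k_outer,k_inner Fusion-stage double-CV plan.
#' @return List with per-variant AUCs (`auc_clinical`,
#'   `auc_clinical_mammo`), the fusion fits and the feature table.
#' @export
experiment_fusion_variants <- function(n = 120, seed = 1, neck_epochs = 6,
                                       k_img = 2, k_outer = 5, k_inner = 5) {
  dat <- desk_phantom_data(n = n, seed = string_seed("fusion-exp", seed))
  ids <- dat$cohort$patient_id
  y <- stats::setNames(dat$cohort$outcome_lnm, ids)
  # image stage: k_img x k_img nested plan for out-of-fold mammo features
  img_plan <- make_plan(ids, y, k_outer = k_img, k_inner = k_img,
                        seed = string_seed("img-plan", seed))
  trainer <- function(train_ids, es_ids, slot_id) {
    ncfg <- desk_neck("resblock", "full",
                      seed = string_seed("fus-neck", slot_id, seed),
                      epochs = neck_epochs)
    model <- train_neck(NULL, dat$full[c(train_ids, es_ids)],
                        dat$labels[match(c(train_ids, es_ids), ids), ],
                        list(train = seq_along(train_ids),
                             val = length(train_ids) + seq_along(es_ids)),
                        ncfg)
    function(pids) predict(model, dat$full[pids])
  }
  img_cv <- run_double_cv(img_plan, trainer)
  mammo <- img_cv$oof
  names(mammo) <- c("patient_id", paste0("mammo_", c("lnm_prob", "n_lnm",
                    "lvi_prob", "tsize", "multifoc_prob")))
  # clinical encoding: statistics from the full development table (each
  # fusion slot re-fits its own z-scoring inside fusion_double_cv folds at
  # full scale; at desk scale a single development-set fit keeps the
  # comparison between variants paired)
  cs <- fit_clinical_stats(dat$cohort)
  clin <- encode_clinical(dat$cohort, cs)
  rownames(clin) <- ids
  mm <- as.matrix(mammo[match(ids, mammo$patient_id), -1])
  rownames(mm) <- ids
  plan <- make_plan(ids, y, k_outer = k_outer, k_inner = k_inner,
                    seed = string_seed("fus-plan", seed))
  fcfg <- fusion_config(seed = string_seed("fus", seed))
  fit_clin <- fusion_double_cv(clin, y, plan, fcfg)
  fit_both <- fusion_double_cv(cbind(clin, mm), y, plan, fcfg)
  list(auc_clinical = fit_clin$auc, auc_clinical_mammo = fit_both$auc,
       fit_clinical = fit_clin, fit_clinical_mammo = fit_both,
       features = cbind(data.frame(patient_id = ids), clin, mm),
       labels = y)
}

#' Null control: fusion training on shuffled labels
#'
#' Permutes the LNM labels, trains the double-cross-validated fusion
#' classifier on clinical features and returns the out-of-fold AUC with
#' its bootstrap SD: a sound pipeline stays within sampling error of 0.5.
#'
#' @param n Patients.
#' @param seed Seed.
#' @param B Bootstrap samples for the SD.
#' @return List with `auc`, `boot_sd`, `n`.
#' @export
experiment_null_fusion <- function(n = 400, seed = 1, B = 200) {
  cfg <- cohort_config(n_patients = n, seed = string_seed("null-exp", seed))
  cohort <- generate_cohort(cfg)
  ids <- cohort$patient_id
  local_rng(string_seed("null-shuffle", seed))
  y <- stats::setNames(sample(cohort$outcome_lnm), ids)
  cs <- fit_clinical_stats(cohort)
  clin <- encode_clinical(cohort, cs)
  rownames(clin) <- ids
  plan <- make_plan(ids, y, seed = string_seed("null-plan", seed))
  fit <- fusion_double_cv(clin, y, plan,
                          fusion_config(seed = string_seed("null-fus", seed)))
  rep <- bootstrap_report(list(m = fit$oof), y[names(fit$oof)], B = B,
                          seed = string_seed("null-boot", seed))
  list(auc = fit$auc, boot_sd = rep$boot_sd["roc_auc", 1], n = n)
}

#' Parameter recovery of the synthetic generator
#'
#' Regenerates a cohort at the configured study conditions and measures
#' the empirical LNM prevalence and the conditional tumor-size means.
#'
#' @param n Patients.
#' @param seed Seed.
#' @return List with `prevalence`, `tsize_mean_pos`, `tsize_mean_neg`,
#'   `tsize_shift`, `cohens_d`.
#' @export
experiment_parameter_recovery <- function(n = 1200, seed = 1) {
  cfg <- cohort_config(n_patients = n, seed = string_seed("recov", seed))
  cohort <- generate_cohort(cfg)
  pos <- cohort$outcome_tsize[cohort$outcome_lnm == 1]
  neg <- cohort$outcome_tsize[cohort$outcome_lnm == 0]
  list(prevalence = mean(cohort$outcome_lnm),
       tsize_mean_pos = mean(pos), tsize_mean_neg = mean(neg),
       tsize_shift = mean(pos) - mean(neg),
       cohens_d = cohens_d(pos, neg))
}
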