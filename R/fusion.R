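#' Patient-level fusion of mammogram features and clinical predictors
#'
#' Aggregates image-level task predictions to patient-level "mammogram
#' features" (average over cross-validation models, then maximum over
#' views -- in that order), encodes the 11 preoperative clinical variables
#' into a 29-dimensional vector (z-scored continuous variables, binary and
#' one-hot categoricals, per-variable missing indicators; all statistics
#' fitted on training folds only), and trains the final LNM classifier: a
#' single-hidden-layer MLP with 128 neurons, dropout 0.2, AdamW, learning
#' rate 0.01, weight decay 0.0001 and batch size 32.
#'
#' @name patient_fusion
NULL

#' Ensemble image-level bundles across models
#'
#' Elementwise arithmetic mean of one image's prediction bundle over
#' cross-validation models.
#'
#' @param per_model_bundles `data.frame`/matrix with one row per model, or
#'   list of single-row bundles.
#' @return Named numeric vector (the averaged bundle).
#' @export
ensemble_image_feature <- function(per_model_bundles) {
  if (is.list(per_model_bundles) && !is.data.frame(per_model_bundles)) {
    if (length(per_model_bundles) == 0) stop("empty bundle list")
    per_model_bundles <- do.call(rbind, lapply(per_model_bundles, as.data.frame))
  }
  m <- as.matrix(per_model_bundles)
  if (nrow(m) == 0) stop("empty bundle list")
  colMeans(m)
}

#' Aggregate per-view bundles to the patient level
#'
#' Elementwise maximum across a patient's views, applied per feature --
#' the aggregation runs after the cross-model average (mean over models,
#' then max over views).
#'
#' @param per_view_bundles `data.frame`/matrix with one row per view, or a
#'   list of single-row bundles.
#' @return Named numeric vector (the patient-level bundle).
#' @export
aggregate_patient <- function(per_view_bundles) {
  if (is.list(per_view_bundles) && !is.data.frame(per_view_bundles)) {
    if (length(per_view_bundles) == 0) stop("empty view list")
    per_view_bundles <- do.call(rbind, lapply(per_view_bundles, as.data.frame))
  }
  m <- as.matrix(per_view_bundles)
  if (nrow(m) == 0) stop("empty view list")
  apply(m, 2, max)
}

#' Patient-level mammogram features from per-model image predictions
#'
#' Applies the fixed aggregation order: for every image, average the
#' bundle over the supplied models; then, per patient, take the
#' elementwise maximum across views.
#'
#' @param pred_tables List (one per model) of `data.frame`s with
#'   `image_id` plus the five bundle columns.
#' @param manifest `data.frame` with `image_id` and `patient_id`.
#' @return `data.frame` keyed by `patient_id` with columns
#'   `mammo_lnm_prob`, `mammo_n_lnm`, `mammo_lvi_prob`, `mammo_tsize`,
#'   `mammo_multifoc_prob`.
#' @export
patient_mammo_features <- function(pred_tables, manifest) {
  stopifnot(length(pred_tables) >= 1)
  feat_cols <- setdiff(names(pred_tables[[1]]), "image_id")
  ids <- pred_tables[[1]]$image_id
  stacked <- lapply(pred_tables, function(tb) {
    stopifnot(identical(tb$image_id, ids))
    as.matrix(tb[, feat_cols])
  })
  img_mean <- Reduce(`+`, stacked) / length(stacked)
  pid <- manifest$patient_id[match(ids, manifest$image_id)]
  out <- do.call(rbind, lapply(split(seq_along(ids), pid), function(rows)
    apply(img_mean[rows, , drop = FALSE], 2, max)))
  df <- data.frame(patient_id = rownames(out), out, stringsAsFactors = FALSE,
                   row.names = NULL)
  std <- c(lnm_prob = "lnm_prob", n_lnm_pred = "n_lnm", lvi_prob = "lvi_prob",
           tsize_pred = "tsize", multifoc_prob = "multifoc_prob")
  mapped <- ifelse(feat_cols %in% names(std), std[feat_cols], feat_cols)
  names(df) <- c("patient_id", paste0("mammo_", mapped))
  df
}

.grade_levels <- c("I", "II", "III")
.histo_levels <- c("NST", "ILC", "other")
.subtype_levels <- c("LumA", "LumB", "HER2+", "TNBC")
.clin_vars <- c("age", "bmi", "menopausal", "detection_mode", "grade",
                "histotype", "er", "pgr", "her2", "ki67", "subtype")

#' Fit clinical encoding statistics on training patients
#'
#' Computes the z-scoring means/SDs and imputation medians for age and BMI
#' (and pathological tumor size, used by the postoperative benchmark
#' variant) from training-fold patients only.
#'
#' @param train_records Training-fold rows of the cohort `data.frame`.
#' @return List of class `clinical_stats`.
#' @export
fit_clinical_stats <- function(train_records) {
  s <- function(x) list(mean = mean(x, na.rm = TRUE),
                        sd = max(stats::sd(x, na.rm = TRUE), 1e-8),
                        median = stats::median(x, na.rm = TRUE))
  structure(list(age = s(train_records$age), bmi = s(train_records$bmi),
                 tsize = s(train_records$outcome_tsize)),
            class = "clinical_stats")
}

#' Encode preoperative clinical variables
#'
#' Encodes each patient's 11 preoperative predictors into 29 numbers:
#' z-scored age and BMI (2), binary menopausal status, detection mode, ER,
#' PgR, HER2, Ki67 (6), one-hot grade (3), histotype (3) and St Gallen
#' subtype (4), plus 11 per-variable missing indicators. Missing
#' continuous values are imputed at the training median (flagged); missing
#' categoricals get an all-zero one-hot (flagged). Statistics come from
#' [fit_clinical_stats()] on training folds only. Postoperative outcomes
#' (including LVI) are not part of the encoding.
#'
#' @param records Cohort rows to encode.
#' @param stats A `clinical_stats` object.
#' @return Numeric matrix `n x 29` with column names.
#' @export
encode_clinical <- function(records, stats) {
  stopifnot(inherits(stats, "clinical_stats"))
  n <- nrow(records)
  z <- function(x, st) {
    miss <- is.na(x)
    x[miss] <- st$median
    list(v = (x - st$mean) / st$sd, miss = as.numeric(miss))
  }
  bin <- function(x, pos_level) {
    miss <- is.na(x) | x == "missing"
    list(v = as.numeric(!miss & x == pos_level), miss = as.numeric(miss))
  }
  onehot <- function(x, levels) {
    miss <- is.na(x) | x == "missing"
    bad <- !miss & !x %in% levels
    if (any(bad)) stop("unknown category level: ",
                       paste(unique(x[bad]), collapse = ", "))
    m <- sapply(levels, function(l) as.numeric(!miss & x == l))
    if (n == 1) m <- matrix(m, 1, dimnames = list(NULL, levels))
    list(v = m, miss = as.numeric(miss))
  }
  age <- z(records$age, stats$age); bmi <- z(records$bmi, stats$bmi)
  men <- bin(records$menopausal, "pre")
  det <- bin(records$detection_mode, "symptomatic")
  er <- bin(records$er, "pos"); pgr <- bin(records$pgr, "pos")
  her2 <- bin(records$her2, "pos"); ki67 <- bin(records$ki67, "pos")
  gr <- onehot(records$grade, .grade_levels)
  hi <- onehot(records$histotype, .histo_levels)
  su <- onehot(records$subtype, .subtype_levels)
  out <- cbind(age = age$v, bmi = bmi$v, menopausal_pre = men$v,
               detection_sympt = det$v, er_pos = er$v, pgr_pos = pgr$v,
               her2_pos = her2$v, ki67_pos = ki67$v,
               gr$v, hi$v, su$v)
  colnames(out)[9:11] <- paste0("grade_", .grade_levels)
  colnames(out)[12:14] <- paste0("histo_", .histo_levels)
  colnames(out)[15:18] <- paste0("subtype_", c("LumA", "LumB", "HER2pos",
                                               "TNBC"))
  missing_flags <- cbind(age$miss, bmi$miss, men$miss, det$miss, gr$miss,
                         hi$miss, er$miss, pgr$miss, her2$miss, ki67$miss,
                         su$miss)
  colnames(missing_flags) <- paste0("miss_", .clin_vars)
  out <- cbind(out, missing_flags)
  stopifnot(ncol(out) == 29)
  out
}

#' Fusion classifier configuration
#'
#' Defaults are the printed fusion hyperparameters: one hidden layer of
#' 128 neurons, batch size 32, dropout 0.2, AdamW, learning rate 0.01,
#' weight decay 0.0001.
#'
#' @param hidden Hidden units.
#' @param batch_size,dropout,lr,weight_decay,epochs Training settings.
#' @param patience Early-stopping patience (used when validation data are
#'   supplied to [fusion_fit()]).
#' @param seed Integer seed.
#' @return List of class `fusion_config`.
#' @export
fusion_config <- function(hidden = 128, batch_size = 32, dropout = 0.2,
                          lr = 0.01, weight_decay = 1e-4, epochs = 30,
                          patience = 5, seed = 1) {
  structure(list(hidden = hidden, batch_size = batch_size,
                 dropout = dropout, lr = lr, weight_decay = weight_decay,
                 epochs = epochs, patience = patience, seed = seed),
            class = "fusion_config")
}

fusion_forward_node <- function(tape, lv, x, dropout, training) {
  h <- op_relu(op_add_bias(op_matmul(x, lv$w1, tape), lv$b1, tape), tape)
  h <- op_dropout(h, dropout, tape, training = training)
  op_sigmoid(op_add_bias(op_matmul(h, lv$w2, tape), lv$b2, tape), tape)
}

#' Fit the patient-level LNM fusion classifier
#'
#' Trains the single-hidden-layer MLP on a patient-by-feature matrix with
#' binary cross-entropy and the printed hyperparameters. When validation
#' data are supplied, training stops early on the validation loss.
#'
#' @param x Numeric feature matrix (patients x features), e.g. a clinical
#'   encoding optionally concatenated with mammogram features.
#' @param y 0/1 LNM labels.
#' @param config A [fusion_config()].
#' @param x_val,y_val Optional validation data for early stopping.
#' @return Object of class `lnm_fusion` with `params`, `config`, `log`,
#'   `feature_names`; supports [predict()], [coef()], `print` and
#'   `summary`.
#' @export
fusion_fit <- function(x, y, config = fusion_config(), x_val = NULL,
                       y_val = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("single-class labels")
  local_rng(config$seed)
  d <- ncol(x)
  params <- list(w1 = init_mat(d, config$hidden, scale = sqrt(2 / d)),
                 b1 = matrix(0, 1, config$hidden),
                 w2 = init_mat(config$hidden, 1,
                               scale = sqrt(1 / config$hidden)),
                 b2 = matrix(0, 1, 1))
  opt <- adamw_new(params, lr = config$lr,
                   weight_decay = config$weight_decay)
  n <- nrow(x)
  eval_loss <- function(params, xe, ye) {
    tape <- tp_new()
    lv <- lapply(params, function(p) tp_leaf(tape, p))
    p <- fusion_forward_node(tape, lv, tp_leaf(tape, xe), 0, FALSE)
    pv <- clamp(p$v, 1e-7, 1 - 1e-7)
    -mean(ye * log(pv) + (1 - ye) * log(1 - pv))
  }
  best <- list(loss = Inf, params = params, epoch = 0L)
  since <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tl <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      b <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- x[b, , drop = FALSE]; yb <- matrix(y[b], ncol = 1)
      step <- nn_grad_step(params, function(tape, lv) {
        p <- fusion_forward_node(tape, lv, tp_leaf(tape, xb),
                                 config$dropout, TRUE)
        op_bce_masked(p, yb, matrix(1, length(b), 1), tape)
      })
      params <- adamw_step(opt, params, step$grads)
      tl <- c(tl, step$loss)
    }
    vl <- if (!is.null(x_val)) eval_loss(params, as.matrix(x_val),
                                         as.numeric(y_val)) else NA_real_
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(tl),
                                 val_loss = vl))
    if (!is.null(x_val)) {
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = params, epoch = ep); since <- 0L
      } else {
        since <- since + 1L
        if (since >= config$patience) break
      }
    }
  }
  if (is.null(x_val)) best <- list(loss = utils::tail(log$train_loss, 1),
                                   params = params, epoch = config$epochs)
  structure(list(params = best$params, config = config, log = log,
                 best_epoch = best$epoch,
                 feature_names = colnames(x) %||% paste0("x", seq_len(d))),
            class = "lnm_fusion")
}

#' @describeIn fusion_fit Predicted LNM probabilities for new patients.
#' @param object,newdata,... S3 method arguments.
#' @export
predict.lnm_fusion <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  tape <- tp_new()
  lv <- lapply(object$params, function(p) tp_leaf(tape, p))
  as.vector(fusion_forward_node(tape, lv, tp_leaf(tape, x), 0, FALSE)$v)
}

#' @describeIn fusion_fit First-layer weight matrix (features x hidden).
#' @export
coef.lnm_fusion <- function(object, ...) {
  w <- object$params$w1
  rownames(w) <- object$feature_names
  w
}

#' @export
print.lnm_fusion <- function(x, ...) {
  cat("LNM fusion classifier (MLP ", length(x$feature_names), " -> ",
      x$config$hidden, " -> 1, dropout ", x$config$dropout, ")\n",
      "trained ", nrow(x$log), " epochs (best ", x$best_epoch, ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.lnm_fusion <- function(object, ...) {
  print(object)
  cat("final train loss:",
      format(utils::tail(object$log$train_loss, 1), digits = 4), "\n")
  invisible(object)
}

#' Double cross-validated fusion model
#'
#' Trains one fusion classifier per (outer, inner) slot -- on the outer
#' training set minus the inner fold, early-stopped on the inner fold --
#' and assembles leakage-audited out-of-fold predictions for the
#' development set plus a 25-model average for held-out patients.
#'
#' @param features Patient-by-feature matrix with rownames = patient ids.
#' @param labels Named 0/1 vector (names = patient ids).
#' @param plan A [make_plan()] over the development patient ids.
#' @param config A [fusion_config()].
#' @param test_ids Optional held-out patient ids present in `features`.
#' @return Object of class `lnm_fusion_cv`: `oof` (out-of-fold LNM
#'   probabilities), `test`, `cv` (the [run_double_cv()] result), `auc`
#'   (out-of-fold ROC AUC).
#' @export
fusion_double_cv <- function(features, labels, plan,
                             config = fusion_config(), test_ids = NULL) {
  features <- as.matrix(features)
  stopifnot(!is.null(rownames(features)))
  trainer <- function(train_ids, es_ids, slot_id) {
    cfg <- config
    cfg$seed <- string_seed(slot_id, base = config$seed)
    fit <- fusion_fit(features[train_ids, , drop = FALSE], labels[train_ids],
                      cfg, features[es_ids, , drop = FALSE], labels[es_ids])
    function(ids) data.frame(
      lnm_prob = predict(fit, features[ids, , drop = FALSE]))
  }
  cv <- run_double_cv(plan, trainer, test_ids = test_ids)
  oof <- stats::setNames(cv$oof$lnm_prob, cv$oof$patient_id)
  structure(list(oof = oof, test = cv$test, cv = cv, plan = plan,
                 config = config,
                 auc = roc_auc(oof, labels[names(oof)])),
            class = "lnm_fusion_cv")
}

#' @export
print.lnm_fusion_cv <- function(x, ...) {
  cat("Double cross-validated LNM fusion model (",
      x$plan$k_outer, "x", x$plan$k_inner, " slots)\n",
      "out-of-fold ROC AUC: ", format(x$auc, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn fusion_double_cv Out-of-fold summary with bootstrap AUC.
#' @param object,... S3 method arguments.
#' @param B Bootstrap samples.
#' @export
summary.lnm_fusion_cv <- function(object, B = 200, ...) {
  labels <- object$plan$lnm_labels[match(names(object$oof),
                                         object$plan$patient_ids)]
  rep <- bootstrap_report(list(fusion = object$oof), labels, B = B,
                          seed = object$plan$seed)
  out <- list(auc = object$auc,
              auc_boot_mean = rep$boot_mean["roc_auc", 1],
              auc_boot_sd = rep$boot_sd["roc_auc", 1],
              auc_ci = rep$ci["roc_auc", 1, ])
  cat("out-of-fold ROC AUC:", format(out$auc, digits = 3),
      "+/-", format(out$auc_boot_sd, digits = 2),
      " CI [", format(out$auc_ci[1], digits = 3), ",",
      format(out$auc_ci[2], digits = 3), "]\n")
  invisible(out)
}

#' @describeIn fusion_double_cv ROC and decision curves of the
#'   out-of-fold predictions.
#' @export
plot.lnm_fusion_cv <- function(x, ...) {
  labels <- x$plan$lnm_labels[match(names(x$oof), x$plan$patient_ids)]
  scores <- x$oof
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(c(0, fpr, 1), c(0, sens, 1), type = "l", xlab = "1 - spec",
                 ylab = "sensitivity", main = "out-of-fold ROC")
  graphics::abline(0, 1, lty = 3)
  dc <- decision_curve(scores, labels)
  graphics::plot(dc$pt, dc$model, type = "l", xlab = "threshold prob",
                 ylab = "net benefit", main = "decision curve",
                 ylim = range(c(dc$model, dc$treat_all, 0)))
  graphics::lines(dc$pt, dc$treat_all, lty = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
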