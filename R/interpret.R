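#' Model interpretation: Shapley attributions and Grad-CAM
#'
#' Permutation-sampling Shapley values explain the fusion classifier's
#' patient-level LNM predictions (feature importance = mean absolute
#' attribution across patients, averaged over cross-validation models);
#' Grad-CAM activation maps localize the image evidence of the neck
#' models. Grad-CAM targets are restricted to LNM, LVI and tumor size.
#'
#' @name interpret
NULL

#' Permutation-sampling Shapley attributions
#'
#' Estimates Shapley values by averaging marginal contributions along
#' random feature permutations: each permutation draws a background row,
#' walks from the background to the instance adding one feature at a
#' time, and credits each feature with its prediction delta. The
#' telescoping sum makes the attributions satisfy efficiency -- per
#' instance they sum to `f(x)` minus the mean prediction over the sampled
#' background rows -- up to Monte-Carlo error in the per-feature split.
#'
#' @param predict_fun Function mapping a numeric matrix (rows = instances)
#'   to a numeric vector of predictions.
#' @param instances Matrix of instances to explain.
#' @param background Matrix of background (training-fold) instances.
#' @param n_samples Number of permutations per instance (default 2048
#'   gives efficiency residuals well below 1e-3 for small feature sets).
#' @param seed Integer seed.
#' @return `n_instances x n_features` matrix of attributions with an
#'   attribute `baseline` (mean background prediction per instance).
#' @export
shapley_attributions <- function(predict_fun, instances, background,
                                 n_samples = 2048, seed = 1) {
  instances <- as.matrix(instances); background <- as.matrix(background)
  if (nrow(background) == 0) stop("empty background")
  d <- ncol(instances)
  local_rng(seed)
  out <- matrix(0, nrow(instances), d,
                dimnames = list(NULL, colnames(instances)))
  baselines <- numeric(nrow(instances))
  for (i in seq_len(nrow(instances))) {
    x <- instances[i, ]
    bg_idx <- sample.int(nrow(background), n_samples, replace = TRUE)
    phi <- numeric(d)
    base_acc <- 0
    # build all coalition rows of all permutations, evaluate in one call
    rows <- matrix(0, n_samples * (d + 1), d)
    perms <- matrix(0L, n_samples, d)
    for (m in seq_len(n_samples)) {
      pi_m <- sample.int(d)
      perms[m, ] <- pi_m
      z <- background[bg_idx[m], ]
      cur <- z
      off <- (m - 1) * (d + 1)
      rows[off + 1, ] <- cur
      for (j in seq_len(d)) {
        cur[pi_m[j]] <- x[pi_m[j]]
        rows[off + 1 + j, ] <- cur
      }
    }
    preds <- predict_fun(rows)
    for (m in seq_len(n_samples)) {
      off <- (m - 1) * (d + 1)
      delta <- diff(preds[(off + 1):(off + d + 1)])
      phi[perms[m, ]] <- phi[perms[m, ]] + delta
      base_acc <- base_acc + preds[off + 1]
    }
    out[i, ] <- phi / n_samples
    baselines[i] <- base_acc / n_samples
  }
  attr(out, "baseline") <- baselines
  out
}

#' Mean-absolute-attribution importance report
#'
#' Per model, the mean absolute attribution per feature across instances;
#' then the mean across models, ranked in decreasing importance. With
#' `merge_lnm = TRUE` the two mammographic LNM features (binary
#' probability and continuous node count) are reported as one combined
#' feature whose importance is the sum of the two components.
#'
#' @param attributions_by_model List of attribution matrices (instances x
#'   features, identical column sets).
#' @param merge_lnm Merge `mammo_lnm_prob` and `mammo_n_lnm` into
#'   `mammo_lnm_combined`.
#' @return `data.frame` with `feature`, `importance`, `rank`.
#' @export
mean_abs_importance <- function(attributions_by_model, merge_lnm = FALSE) {
  stopifnot(length(attributions_by_model) >= 1)
  per_model <- lapply(attributions_by_model, function(a)
    colMeans(abs(as.matrix(a))))
  imp <- Reduce(`+`, per_model) / length(per_model)
  if (merge_lnm && all(c("mammo_lnm_prob", "mammo_n_lnm") %in% names(imp))) {
    comb <- imp[["mammo_lnm_prob"]] + imp[["mammo_n_lnm"]]
    imp <- imp[!names(imp) %in% c("mammo_lnm_prob", "mammo_n_lnm")]
    imp <- c(imp, mammo_lnm_combined = comb)
  }
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}

#' Grad-CAM activation map for a neck model
#'
#' Channel weights are the spatially averaged gradients of the target
#' head's pre-sigmoid score with respect to the selected layer's
#' activations; the heatmap is the ReLU of the weighted activation sum,
#' bilinearly upsampled to the input size and max-normalized. For
#' ResBlock necks the selected layer is the last convolutional output
#' before global average pooling (the final residual block); for
#' Transformer necks it is the last convolutional layer before the
#' attention blocks (the backbone output). Targets are limited to LNM,
#' LVI and tumor size.
#'
#' @param model A `neck_model` from [train_neck()].
#' @param image Input image matrix.
#' @param target One of `"lnm"`, `"lvi"`, `"tsize"`.
#' @return Heatmap matrix (same shape as `image`, values in `[0, 1]`).
#' @export
grad_cam <- function(model, image, target = c("lnm", "lvi", "tsize")) {
  target <- match.arg(target)
  cfg <- model$config; bcfg <- model$backbone_config
  tape <- tp_new()
  lv <- lapply(model$params, function(p) tp_leaf(tape, p))
  x <- tp_leaf(tape, images_to_array(list(image)))
  f <- backbone_forward(tape, lv, x, bcfg)
  if (cfg$neck_type == "resblock") {
    h <- f
    for (b in seq_len(cfg$n_blocks)) {
      y <- op_relu(op_conv1x1(h, lv[[sprintf("nb%d_w1", b)]],
                              lv[[sprintf("nb%d_b1", b)]], tape), tape)
      y <- op_relu(op_dwconv3x3(y, lv[[sprintf("nb%d_dw", b)]], tape), tape)
      y <- op_conv1x1(y, lv[[sprintf("nb%d_w2", b)]],
                      lv[[sprintf("nb%d_b2", b)]], tape)
      h <- op_add(h, y, tape)
    }
    layer <- h
    rep_n <- op_gap(h, tape)
  } else {
    layer <- f
    rep_n <- neck_tf_forward(tape, lv, f, cfg)
  }
  raw <- op_add_bias(op_matmul(rep_n, lv[[paste0("head_", target, "_w")]],
                               tape),
                     lv[[paste0("head_", target, "_b")]], tape)
  tp_backward(tape, raw)
  act <- layer$v[1, , , , drop = TRUE]
  grad <- layer$g[1, , , , drop = TRUE]
  dims <- dim(act)
  wts <- apply(grad, 3, mean)
  cam <- matrix(0, dims[1], dims[2])
  for (cc in seq_len(dims[3])) cam <- cam + wts[cc] * act[, , cc]
  cam <- pmax(cam, 0)
  cam <- resize_bilinear(cam, nrow(image), ncol(image))
  if (max(cam) > 0) cam <- cam / max(cam)
  cam
}
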