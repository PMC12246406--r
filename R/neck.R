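#' Multi-task neck architectures over backbone feature maps
#'
#' Two neck modules aggregate the backbone's spatial feature map into a
#' global representation: a stack of residual blocks (1x1 bottleneck,
#' depthwise 3x3, 1x1 expansion, identity skip, then global average
#' pooling) or a small vision Transformer using shifted patch tokenization
#' (SPT) and locality self-attention (LSA: learnable temperature, masked
#' self-token). Five linear heads predict the postoperative outcomes: LNM
#' (probability), number of metastatic nodes (log1p-transformed
#' regression), LVI (probability), tumor size (regression, scaled by
#' 1/50 mm), and multifocality (probability). Training minimizes a
#' missing-label-masked multi-task loss; ROI and full-image models share
#' this code path and differ only in their input crops and the default
#' block count.
#'
#' @name multitask_neck
NULL

.task_names <- c("lnm", "n_lnm", "lvi", "tsize", "multifoc")
.task_types <- c(lnm = "cls", n_lnm = "reg", lvi = "cls",
                 tsize = "reg", multifoc = "cls")

#' Regression target transforms and inverses
#'
#' The node-count head regresses `log1p(count)`; the tumor-size head
#' regresses `size / 50` (fraction of the 50 mm inclusion bound). The
#' inverses are exact: `expm1` and multiplication by 50.
#'
#' @param x Counts (nlnm) or sizes in mm (tsize); transformed values for
#'   the inverses.
#' @return Transformed or back-transformed numeric vector.
#' @export
nlnm_transform <- function(x) log1p(x)

#' @rdname nlnm_transform
#' @export
nlnm_inverse <- function(x) expm1(x)

#' @rdname nlnm_transform
#' @export
tsize_transform <- function(x) x / 50

#' @rdname nlnm_transform
#' @export
tsize_inverse <- function(x) x * 50

#' Neck configuration
#'
#' @param neck_type `"resblock"` or `"transformer"`.
#' @param scope `"roi"` or `"full"`; sets the default `n_blocks` (1 for
#'   ROI, 2 for full-breast input) and is otherwise informational -- both
#'   scopes run the identical code path.
#' @param backbone A [backbone_config()] used when training from random
#'   initialization (ignored when pretrained weights are supplied).
#' @param n_blocks Residual block count (default tied to scope).
#' @param mid_channels Bottleneck width of the residual blocks (default
#'   `feature_dim / 8`, mirroring a 1024 -> 128 narrowing at full scale).
#' @param tf_depth,tf_heads,tf_dim Transformer depth, head count and token
#'   dimension.
#' @param task_weights Five non-negative loss weights (LNM, node count,
#'   LVI, tumor size, multifocality); equal by default.
#' @param epochs,batch_size,lr,weight_decay,patience Optimization and
#'   early-stopping settings (patience in epochs past the inner-validation
#'   minimum).
#' @param freeze_backbone Keep backbone weights fixed during supervised
#'   training (default: finetuned).
#' @param seed Integer seed.
#' @return List of class `neck_config`.
#' @export
neck_config <- function(neck_type = c("resblock", "transformer"),
                        scope = c("roi", "full"),
                        backbone = backbone_config(c(8, 16, 32)),
                        n_blocks = NULL, mid_channels = NULL,
                        tf_depth = 2, tf_heads = 2, tf_dim = 32,
                        task_weights = rep(1, 5),
                        epochs = 8, batch_size = 8, lr = 1e-3,
                        weight_decay = 1e-4, patience = 3,
                        freeze_backbone = FALSE, seed = 1) {
  neck_type <- match.arg(neck_type)
  scope <- match.arg(scope)
  if (is.null(n_blocks)) n_blocks <- if (scope == "roi") 1L else 2L
  if (!n_blocks %in% 1:2) stop("n_blocks must be 1 or 2")
  if (length(task_weights) != 5 || any(task_weights < 0) ||
      all(task_weights == 0)) stop("task_weights: 5 non-negative, not all 0")
  if (tf_dim %% tf_heads != 0) stop("tf_dim must be divisible by tf_heads")
  structure(list(neck_type = neck_type, scope = scope, backbone = backbone,
                 n_blocks = as.integer(n_blocks),
                 mid_channels = mid_channels, tf_depth = tf_depth,
                 tf_heads = tf_heads, tf_dim = tf_dim,
                 task_weights = task_weights, epochs = epochs,
                 batch_size = batch_size, lr = lr,
                 weight_decay = weight_decay, patience = patience,
                 freeze_backbone = freeze_backbone, seed = seed),
            class = "neck_config")
}

# spatial size of the backbone output for an input of (h, w)
backbone_out_hw <- function(bcfg, h, w) {
  for (i in seq_along(bcfg$channels)) {
    h <- conv_out_len(h, 2L); w <- conv_out_len(w, 2L)
  }
  c(h, w)
}

# ---- parameter initialization --------------------------------------------

neck_init <- function(config, feature_dim, map_h, map_w, seed = config$seed) {
  local_rng(seed)
  p <- list()
  if (config$neck_type == "resblock") {
    mid <- config$mid_channels %||% max(4L, feature_dim %/% 8L)
    for (b in seq_len(config$n_blocks)) {
      p[[sprintf("nb%d_w1", b)]] <- init_mat(feature_dim, mid)
      p[[sprintf("nb%d_b1", b)]] <- matrix(0, 1, mid)
      p[[sprintf("nb%d_dw", b)]] <- array(stats::rnorm(9 * mid, 0, 1 / 3),
                                          c(3, 3, mid))
      p[[sprintf("nb%d_w2", b)]] <- init_mat(mid, feature_dim)
      p[[sprintf("nb%d_b2", b)]] <- matrix(0, 1, feature_dim)
    }
  } else {
    D <- config$tf_dim
    p$spt_g <- matrix(1, 1, 5 * feature_dim)
    p$spt_b <- matrix(0, 1, 5 * feature_dim)
    p$spt_w <- init_mat(5 * feature_dim, D, scale = sqrt(1 / (5 * feature_dim)))
    p$spt_pb <- matrix(0, 1, D)
    p$cls <- matrix(stats::rnorm(D, 0, 0.02), 1, D)
    p$posemb <- matrix(stats::rnorm((map_h * map_w + 1) * D, 0, 0.02),
                       map_h * map_w + 1, D)
    dh <- D / config$tf_heads
    for (l in seq_len(config$tf_depth)) {
      pre <- sprintf("tf%d", l)
      p[[paste0(pre, "_ln1g")]] <- matrix(1, 1, D)
      p[[paste0(pre, "_ln1b")]] <- matrix(0, 1, D)
      p[[paste0(pre, "_wq")]] <- init_mat(D, D, scale = sqrt(1 / D))
      p[[paste0(pre, "_wk")]] <- init_mat(D, D, scale = sqrt(1 / D))
      p[[paste0(pre, "_wv")]] <- init_mat(D, D, scale = sqrt(1 / D))
      p[[paste0(pre, "_tau")]] <- matrix(sqrt(dh), 1, 1)
      p[[paste0(pre, "_wo")]] <- init_mat(D, D, scale = sqrt(1 / D))
      p[[paste0(pre, "_bo")]] <- matrix(0, 1, D)
      p[[paste0(pre, "_ln2g")]] <- matrix(1, 1, D)
      p[[paste0(pre, "_ln2b")]] <- matrix(0, 1, D)
      p[[paste0(pre, "_mw1")]] <- init_mat(D, 2 * D, scale = sqrt(1 / D))
      p[[paste0(pre, "_mb1")]] <- matrix(0, 1, 2 * D)
      p[[paste0(pre, "_mw2")]] <- init_mat(2 * D, D, scale = sqrt(1 / (2 * D)))
      p[[paste0(pre, "_mb2")]] <- matrix(0, 1, D)
    }
    p$rd_w <- init_mat(D, feature_dim, scale = sqrt(1 / D))
    p$rd_b <- matrix(0, 1, feature_dim)
  }
  for (tk in .task_names) {
    p[[paste0("head_", tk, "_w")]] <- init_mat(feature_dim, 1,
                                               scale = sqrt(1 / feature_dim))
    p[[paste0("head_", tk, "_b")]] <- matrix(0, 1, 1)
  }
  p
}

# ---- forward passes -------------------------------------------------------

# extract the token matrix (H*W x C) of image i from an (N,H,W,C) map node
op_tokens_from_map <- function(x, i, tape) {
  d <- dim(x$v)
  v <- x$v[i, , , , drop = TRUE]
  dim(v) <- c(d[2] * d[3], d[4])
  nd(tape, v, list(x), function(g) {
    out <- array(0, d)
    gi <- g; dim(gi) <- c(1, d[2], d[3], d[4])
    out[i, , , ] <- gi
    list(out)
  })
}

neck_res_forward <- function(tape, lv, f, config) {
  h <- f
  for (b in seq_len(config$n_blocks)) {
    y <- op_relu(op_conv1x1(h, lv[[sprintf("nb%d_w1", b)]],
                            lv[[sprintf("nb%d_b1", b)]], tape), tape)
    y <- op_relu(op_dwconv3x3(y, lv[[sprintf("nb%d_dw", b)]], tape), tape)
    y <- op_conv1x1(y, lv[[sprintf("nb%d_w2", b)]],
                    lv[[sprintf("nb%d_b2", b)]], tape)
    h <- op_add(h, y, tape)
  }
  op_gap(h, tape)
}

# SPT: concatenate the map with its four diagonal unit shifts; tokens per
# image are layer-normalized, projected and prepended with a class token.
spt_tokens_batch <- function(tape, lv, f, config) {
  shifts <- list(f,
                 op_shift2d(f, 1, 1, tape), op_shift2d(f, 1, -1, tape),
                 op_shift2d(f, -1, 1, tape), op_shift2d(f, -1, -1, tape))
  d <- dim(f$v)
  lapply(seq_len(d[1]), function(i) {
    toks <- op_concat_cols(lapply(shifts, op_tokens_from_map, i = i,
                                  tape = tape), tape)
    toks <- op_layernorm(toks, lv$spt_g, lv$spt_b, tape)
    toks <- op_add_bias(op_matmul(toks, lv$spt_w, tape), lv$spt_pb, tape)
    toks <- op_concat_rows(list(nd(tape, lv$cls$v, list(lv$cls),
                                   function(g) list(g)), toks), tape)
    op_add(toks, lv$posemb, tape)
  })
}

lsa_block <- function(tape, lv, pre, x, heads) {
  D <- ncol(x$v); dh <- D / heads
  xn <- op_layernorm(x, lv[[paste0(pre, "_ln1g")]],
                     lv[[paste0(pre, "_ln1b")]], tape)
  q <- op_matmul(xn, lv[[paste0(pre, "_wq")]], tape)
  k <- op_matmul(xn, lv[[paste0(pre, "_wk")]], tape)
  v <- op_matmul(xn, lv[[paste0(pre, "_wv")]], tape)
  outs <- lapply(seq_len(heads), function(hh) {
    cols <- ((hh - 1) * dh + 1):(hh * dh)
    qh <- op_slice_cols(q, cols, tape)
    kh <- op_slice_cols(k, cols, tape)
    vh <- op_slice_cols(v, cols, tape)
    s <- op_div_temp(op_matmul(qh, op_transpose(kh, tape), tape),
                     lv[[paste0(pre, "_tau")]], tape)
    op_matmul(op_masked_softmax(s, tape, mask_diag = TRUE), vh, tape)
  })
  att <- op_add_bias(op_matmul(op_concat_cols(outs, tape),
                               lv[[paste0(pre, "_wo")]], tape),
                     lv[[paste0(pre, "_bo")]], tape)
  x <- op_add(x, att, tape)
  xn2 <- op_layernorm(x, lv[[paste0(pre, "_ln2g")]],
                      lv[[paste0(pre, "_ln2b")]], tape)
  h <- op_relu(op_add_bias(op_matmul(xn2, lv[[paste0(pre, "_mw1")]], tape),
                           lv[[paste0(pre, "_mb1")]], tape), tape)
  h <- op_add_bias(op_matmul(h, lv[[paste0(pre, "_mw2")]], tape),
                   lv[[paste0(pre, "_mb2")]], tape)
  op_add(x, h, tape)
}

neck_tf_forward <- function(tape, lv, f, config) {
  tok_list <- spt_tokens_batch(tape, lv, f, config)
  reps <- lapply(tok_list, function(toks) {
    x <- toks
    for (l in seq_len(config$tf_depth))
      x <- lsa_block(tape, lv, sprintf("tf%d", l), x, config$tf_heads)
    cls <- op_gather_rows(x, 1L, tape)
    op_add_bias(op_matmul(cls, lv$rd_w, tape), lv$rd_b, tape)
  })
  op_concat_rows(reps, tape)
}

neck_forward <- function(tape, lv, f, config) {
  if (config$neck_type == "resblock") neck_res_forward(tape, lv, f, config)
  else neck_tf_forward(tape, lv, f, config)
}

heads_forward <- function(tape, lv, rep) {
  out <- list()
  for (tk in .task_names) {
    raw <- op_add_bias(op_matmul(rep, lv[[paste0("head_", tk, "_w")]], tape),
                       lv[[paste0("head_", tk, "_b")]], tape)
    out[[tk]] <- if (.task_types[[tk]] == "cls") op_sigmoid(raw, tape) else raw
  }
  out
}

# ---- public functional wrappers ------------------------------------------

#' ResBlock neck forward pass
#'
#' Applies `n_blocks` residual bottleneck blocks (1x1 down to
#' `mid_channels`, depthwise 3x3, 1x1 back up, identity skip) and global
#' average pooling. With all block weights zero the output equals the
#' global average pool of the input (pure skip path).
#'
#' @param feature_map `H x W x C` numeric array (one image's backbone map).
#' @param config A [neck_config()] with `neck_type = "resblock"`.
#' @param params Optional parameter list from [neck_init()]; freshly
#'   initialized when omitted.
#' @return Numeric vector of length `C`.
#' @export
resblock_neck_forward <- function(feature_map, config = neck_config(),
                                  params = NULL) {
  d <- dim(feature_map)
  if (length(d) != 3) stop("feature_map must be H x W x C")
  if (is.null(params)) params <- neck_init(config, d[3], d[1], d[2])
  tape <- tp_new()
  lv <- lapply(params, function(p) tp_leaf(tape, p))
  x <- tp_leaf(tape, array(feature_map, c(1, d)))
  as.vector(neck_res_forward(tape, lv, x, config)$v)
}

#' Shifted patch tokenization
#'
#' Concatenates a feature map with its four diagonal one-cell shifts
#' (zero-padded) channel-wise, flattens spatial positions to `H*W` tokens
#' of dimension `5C`, layer-normalizes, projects linearly to `embed_dim`,
#' prepends a learnable class token and adds positional embeddings.
#'
#' @param feature_map `H x W x C` numeric array.
#' @param embed_dim Token dimension after projection.
#' @param params Optional parameter list (fields `spt_g`, `spt_b`,
#'   `spt_w`, `spt_pb`, `cls`, `posemb`); freshly initialized when omitted.
#' @return `(H*W + 1) x embed_dim` token matrix (class token first).
#' @export
spt_tokenize <- function(feature_map, embed_dim = 32, params = NULL) {
  d <- dim(feature_map)
  if (length(d) != 3 || d[1] * d[2] == 0) stop("feature_map must be H x W x C")
  cfg <- neck_config(neck_type = "transformer", tf_dim = embed_dim,
                     tf_heads = 1)
  if (is.null(params)) params <- neck_init(cfg, d[3], d[1], d[2])
  tape <- tp_new()
  lv <- lapply(params, function(p) tp_leaf(tape, p))
  x <- tp_leaf(tape, array(feature_map, c(1, d)))
  spt_tokens_batch(tape, lv, x, cfg)[[1]]$v
}

#' Locality self-attention (functional form)
#'
#' Scaled dot-product self-attention with a learnable temperature in place
#' of the fixed `sqrt(d)` divisor and the diagonal (self-token) masked to
#' `-Inf` before the softmax; rows of the attention matrix sum to one over
#' the non-self tokens. This functional form uses identity query/key/value
#' projections; the trained neck learns the projections.
#'
#' @param tokens `T x D` token matrix, `T >= 2`.
#' @param temperature Positive scalar temperature.
#' @return List with `tokens` (attention-weighted values, `T x D`) and
#'   `attention` (`T x T` row-stochastic matrix with zero diagonal).
#' @export
lsa_attention <- function(tokens, temperature = sqrt(ncol(tokens))) {
  tokens <- as.matrix(tokens)
  if (nrow(tokens) < 2) stop("diagonal masking needs at least two tokens")
  if (temperature <= 0) stop("temperature must be positive")
  tape <- tp_new()
  x <- tp_leaf(tape, tokens)
  s <- op_scale(op_matmul(x, op_transpose(x, tape), tape),
                1 / temperature, tape)
  a <- op_masked_softmax(s, tape, mask_diag = TRUE)
  list(tokens = a$v %*% tokens, attention = a$v)
}

#' Transformer neck forward pass
#'
#' [spt_tokenize()] followed by `tf_depth` pre-norm transformer blocks
#' (LSA attention + MLP, residual connections) and a linear projection of
#' the class token to a `feature_dim` representation.
#'
#' @inheritParams resblock_neck_forward
#' @export
transformer_neck_forward <- function(feature_map,
                                     config = neck_config("transformer"),
                                     params = NULL) {
  d <- dim(feature_map)
  if (length(d) != 3) stop("feature_map must be H x W x C")
  if (is.null(params)) params <- neck_init(config, d[3], d[1], d[2])
  tape <- tp_new()
  lv <- lapply(params, function(p) tp_leaf(tape, p))
  x <- tp_leaf(tape, array(feature_map, c(1, d)))
  as.vector(neck_tf_forward(tape, lv, x, config)$v)
}

#' Five-task prediction heads
#'
#' Linear heads over a global representation: sigmoid probabilities for
#' LNM, LVI and multifocality; regressions in transformed space for the
#' node count (log1p) and tumor size (1/50 mm), returned after the inverse
#' transforms. A zero representation with zero-initialized heads yields
#' probabilities 0.5 and regressions at the inverse of 0.
#'
#' @param representation Numeric vector (length `feature_dim`) or
#'   `N x feature_dim` matrix.
#' @param params Parameter list holding `head_<task>_w/b` entries (freshly
#'   initialized to zero weights when omitted).
#' @return A `data.frame` (one row per representation row) with columns
#'   `lnm_prob`, `n_lnm_pred`, `lvi_prob`, `tsize_pred`, `multifoc_prob`.
#' @export
multitask_heads <- function(representation, params = NULL) {
  m <- if (is.null(dim(representation))) matrix(representation, 1)
       else as.matrix(representation)
  if (is.null(params)) {
    params <- list()
    for (tk in .task_names) {
      params[[paste0("head_", tk, "_w")]] <- matrix(0, ncol(m), 1)
      params[[paste0("head_", tk, "_b")]] <- matrix(0, 1, 1)
    }
  }
  tape <- tp_new()
  lv <- lapply(params, function(p) tp_leaf(tape, p))
  rep_node <- tp_leaf(tape, m)
  preds <- heads_forward(tape, lv, rep_node)
  data.frame(
    lnm_prob = as.vector(preds$lnm$v),
    n_lnm_pred = nlnm_inverse(as.vector(preds$n_lnm$v)),
    lvi_prob = as.vector(preds$lvi$v),
    tsize_pred = tsize_inverse(as.vector(preds$tsize$v)),
    multifoc_prob = as.vector(preds$multifoc$v))
}

#' Masked multi-task loss
#'
#' Weighted sum of per-task means -- binary cross-entropy for the three
#' classification tasks, squared error for the two regressions (in
#' transformed target space) -- where missing entries contribute zero loss
#' and each task is normalized by its count of observed labels. Tasks with
#' no observed labels are skipped; an all-missing batch is an error.
#'
#' @param preds `n x 5` matrix/data.frame in task order (LNM prob, node
#'   count in log1p space, LVI prob, tumor size in 1/50 mm space,
#'   multifocality prob).
#' @param labels Same shape, targets in the same (transformed) spaces.
#' @param missing_mask Same shape; 1 = observed, 0 = missing.
#' @param task_weights Five non-negative weights.
#' @return Scalar loss.
#' @export
multitask_loss <- function(preds, labels, missing_mask,
                           task_weights = rep(1, 5)) {
  preds <- as.matrix(preds); labels <- as.matrix(labels)
  missing_mask <- as.matrix(missing_mask)
  stopifnot(ncol(preds) == 5, all(dim(preds) == dim(labels)),
            all(dim(preds) == dim(missing_mask)))
  if (sum(missing_mask) == 0) stop("all labels missing in every task")
  total <- 0
  for (t in seq_len(5)) {
    mk <- missing_mask[, t]
    m <- sum(mk)
    if (m == 0) next
    if (.task_types[[t]] == "cls") {
      p <- clamp(preds[, t], 1e-7, 1 - 1e-7)
      lt <- -sum(mk * (labels[, t] * log(p) +
                       (1 - labels[, t]) * log(1 - p))) / m
    } else {
      lt <- sum(mk * (preds[, t] - labels[, t])^2) / m
    }
    total <- total + task_weights[t] * lt
  }
  total
}

# ---- training -------------------------------------------------------------

# build transformed label/mask matrices (n x 5) from a cohort label frame
task_label_matrices <- function(labels) {
  n <- nrow(labels)
  y <- matrix(0, n, 5, dimnames = list(NULL, .task_names))
  mk <- matrix(1, n, 5, dimnames = list(NULL, .task_names))
  grab <- function(col) if (col %in% names(labels)) labels[[col]] else
    rep(NA_real_, n)
  set <- function(tk, vals, transform = identity) {
    obs <- !is.na(vals)
    y[, tk] <<- ifelse(obs, transform(ifelse(is.na(vals), 0, vals)), 0)
    mk[, tk] <<- as.numeric(obs)
  }
  set("lnm", grab("outcome_lnm"))
  set("n_lnm", grab("outcome_n_lnm"), nlnm_transform)
  set("lvi", grab("outcome_lvi"))
  set("tsize", grab("outcome_tsize"), tsize_transform)
  set("multifoc", grab("outcome_multifoc"))
  list(y = y, mask = mk)
}

model_loss_node <- function(tape, lv, xarr, y, mk, bcfg, config) {
  x <- tp_leaf(tape, xarr)
  f <- backbone_forward(tape, lv, x, bcfg)
  rep_n <- neck_forward(tape, lv, f, config)
  preds <- heads_forward(tape, lv, rep_n)
  total <- NULL
  for (t in seq_len(5)) {
    if (sum(mk[, t]) == 0 || config$task_weights[t] == 0) next
    tk <- .task_names[t]
    yt <- matrix(y[, t], ncol = 1); mt <- matrix(mk[, t], ncol = 1)
    lt <- if (.task_types[[tk]] == "cls")
      op_bce_masked(preds[[tk]], yt, mt, tape)
    else op_mse_masked(preds[[tk]], yt, mt, tape)
    lt <- op_scale(lt, config$task_weights[t], tape)
    total <- if (is.null(total)) lt else op_add(total, lt, tape)
  }
  if (is.null(total)) stop("all labels missing in every task")
  total
}

#' Train a neck model on labeled images for one cross-validation slot
#'
#' Finetunes the backbone (unless frozen) jointly with the neck and the
#' five task heads under the masked multi-task loss, with early stopping
#' on the inner-validation loss, and emits per-image prediction bundles
#' for every supplied image.
#'
#' @param backbone_weights Pretrained backbone parameter list (from
#'   [pretrain_backbone()]'s `weights`) or `NULL` for random
#'   initialization per `config$backbone`.
#' @param images Named list of equal-size image matrices (model input is a
#'   single image; predictions are image-level).
#' @param labels `data.frame` aligned with `images` rows holding the
#'   outcome columns (`outcome_lnm`, `outcome_n_lnm`, `outcome_lvi`,
#'   `outcome_tsize`, `outcome_multifoc`; NAs = missing).
#' @param fold_assignment List with integer indices `train` and `val`
#'   (inner-validation used for early stopping).
#' @param config A [neck_config()].
#' @return List of class `neck_model` with `params`, `config`,
#'   `backbone_config`, `log` (per-epoch train/validation loss),
#'   `best_epoch`, and `predictions` (a `data.frame` with one row per
#'   image: id, the five bundle columns).
#' @export
train_neck <- function(backbone_weights, images, labels, fold_assignment,
                       config = neck_config()) {
  stopifnot(length(images) == nrow(labels))
  tr <- fold_assignment$train; va <- fold_assignment$val
  if (length(tr) < 2 || length(va) < 1) stop("degenerate fold assignment")
  cls_cols <- c("outcome_lnm", "outcome_lvi", "outcome_multifoc")
  one_class <- vapply(cls_cols, function(cc)
    length(unique(stats::na.omit(labels[[cc]][tr]))) < 2, logical(1))
  if (all(one_class))
    stop("training fold has a single class for all classification tasks")
  local_rng(string_seed("train-neck", config$seed))
  bcfg <- if (!is.null(backbone_weights)) attr(backbone_weights, "config")
          else config$backbone
  fd <- bcfg$feature_dim
  hw <- backbone_out_hw(bcfg, nrow(images[[1]]), ncol(images[[1]]))
  bb <- if (!is.null(backbone_weights)) backbone_weights
        else backbone_init(bcfg, seed = string_seed("bb", config$seed))
  params <- c(bb, neck_init(config, fd, hw[1], hw[2]))
  attr(params, "config") <- NULL
  lm <- task_label_matrices(labels)
  frozen <- if (config$freeze_backbone)
    grep("^s[0-9]+_", names(params), value = TRUE) else character(0)
  opt <- adamw_new(params, lr = config$lr, weight_decay = config$weight_decay)
  eval_loss <- function(idx) {
    tot <- 0; wt <- 0
    for (start in seq(1, length(idx), by = config$batch_size)) {
      b <- idx[start:min(start + config$batch_size - 1, length(idx))]
      tape <- tp_new()
      lv <- lapply(params, function(p) tp_leaf(tape, p))
      ln <- model_loss_node(tape, lv, images_to_array(images[b]),
                            lm$y[b, , drop = FALSE],
                            lm$mask[b, , drop = FALSE], bcfg, config)
      tot <- tot + as.numeric(ln$v) * length(b); wt <- wt + length(b)
    }
    tot / wt
  }
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  since_best <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    tl <- c()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      b <- ord[start:min(start + config$batch_size - 1, length(ord))]
      if (length(b) < 2) next
      step <- nn_grad_step(params, function(tape, lv)
        model_loss_node(tape, lv, images_to_array(images[b]),
                        lm$y[b, , drop = FALSE],
                        lm$mask[b, , drop = FALSE], bcfg, config))
      if (length(frozen)) step$grads[frozen] <- list(NULL)
      params <- adamw_step(opt, params, step$grads)
      tl <- c(tl, step$loss)
    }
    vl <- eval_loss(va)
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(tl),
                                 val_loss = vl))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = params, epoch = ep)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  model <- structure(list(params = best$params, config = config,
                          backbone_config = bcfg, log = log,
                          best_epoch = best$epoch), class = "neck_model")
  model$predictions <- cbind(data.frame(image_id = names(images) %||%
                                          seq_along(images)),
                             predict(model, images))
  model
}

#' Predict task bundles for images
#'
#' @param object A `neck_model`.
#' @param images Named list of image matrices.
#' @param batch_size Forward batch size.
#' @param ... Unused.
#' @return `data.frame` of per-image bundles (`lnm_prob`, `n_lnm_pred`,
#'   `lvi_prob`, `tsize_pred`, `multifoc_prob`).
#' @export
predict.neck_model <- function(object, images, batch_size = 16, ...) {
  params <- object$params
  cfg <- object$config; bcfg <- object$backbone_config
  out <- NULL
  idx <- seq_along(images)
  for (start in seq(1, length(idx), by = batch_size)) {
    b <- idx[start:min(start + batch_size - 1, length(idx))]
    tape <- tp_new()
    lv <- lapply(params, function(p) tp_leaf(tape, p))
    x <- tp_leaf(tape, images_to_array(images[b]))
    f <- backbone_forward(tape, lv, x, bcfg)
    rep_n <- neck_forward(tape, lv, f, cfg)
    preds <- heads_forward(tape, lv, rep_n)
    df <- data.frame(
      lnm_prob = as.vector(preds$lnm$v),
      n_lnm_pred = nlnm_inverse(as.vector(preds$n_lnm$v)),
      lvi_prob = as.vector(preds$lvi$v),
      tsize_pred = tsize_inverse(as.vector(preds$tsize$v)),
      multifoc_prob = as.vector(preds$multifoc$v))
    out <- rbind(out, df)
  }
  out
}
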