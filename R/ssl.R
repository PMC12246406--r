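#' Self-supervised pretraining of the backbone
#'
#' Pretrains the convolutional backbone on unlabeled mammogram patches by
#' maximizing consistency between two stochastic augmentations of the same
#' patch. Three objectives are implemented: Barlow Twins (identity
#' cross-correlation of batch-standardized embeddings), BYOL (normalized
#' mean squared error against an exponential-moving-average teacher) and
#' SwAV (swapped prediction of Sinkhorn-normalized prototype assignments).
#'
#' @name ssl_pretrain
NULL

#' Augmentation parameters
#'
#' @param crop_scale Range of the side-length fraction for the random
#'   resized crop (a crop at scale s covers s^2 of the patch area before
#'   being resized back).
#' @param hflip,vflip Allow horizontal/vertical flips (probability 1/2).
#' @param jitter Intensity jitter magnitude (multiplicative gain in
#'   `1 +- jitter`, additive offset in `+- jitter/2`); 0 disables.
#' @param blur Allow 3x3 Gaussian blur (probability 1/2).
#' @return A list of class `augment_params`. `augment_identity()` is the
#'   degenerate configuration under which both views equal the input.
#' @export
augment_params <- function(crop_scale = c(0.6, 1), hflip = TRUE,
                           vflip = TRUE, jitter = 0.1, blur = TRUE) {
  stopifnot(length(crop_scale) == 2, crop_scale[1] <= crop_scale[2],
            crop_scale[1] > 0, crop_scale[2] <= 1, jitter >= 0)
  structure(list(crop_scale = crop_scale, hflip = hflip, vflip = vflip,
                 jitter = jitter, blur = blur), class = "augment_params")
}

#' @rdname augment_params
#' @export
augment_identity <- function() {
  augment_params(crop_scale = c(1, 1), hflip = FALSE, vflip = FALSE,
                 jitter = 0, blur = FALSE)
}

# bilinear resize of a matrix to (out_h, out_w)
resize_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  ry <- if (out_h == 1) rep(1, 1) else seq(1, h, length.out = out_h)
  rx <- if (out_w == 1) rep(1, 1) else seq(1, w, length.out = out_w)
  y0 <- pmin(floor(ry), h - 1); x0 <- pmin(floor(rx), w - 1)
  fy <- ry - y0; fx <- rx - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x0 + 1, drop = FALSE]
  c_ <- m[y0 + 1, x0, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
  top <- a * (1 - fx)[col(a)] + b * fx[col(b)]
  bot <- c_ * (1 - fx)[col(c_)] + d * fx[col(d)]
  top * (1 - fy)[row(top)] + bot * fy[row(bot)]
}

blur3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  k <- c(1, 2, 1) / 4
  ri <- function(d) clamp(seq_len(h) + d, 1, h)
  ci <- function(d) clamp(seq_len(w) + d, 1, w)
  out <- matrix(0, h, w)
  for (d in -1:1) out <- out + k[d + 2] * m[ri(d), ]
  out2 <- matrix(0, h, w)
  for (d in -1:1) out2 <- out2 + k[d + 2] * out[, ci(d)]
  out2
}

# crop window dimensions at side-length scale s (area fraction s^2)
crop_dims <- function(h, w, s) c(max(2L, round(s * h)), max(2L, round(s * w)))

augment_once <- function(m, p) {
  h <- nrow(m); w <- ncol(m)
  s <- stats::runif(1, p$crop_scale[1], p$crop_scale[2])
  cd <- crop_dims(h, w, s)
  ch <- cd[1]; cw <- cd[2]
  r0 <- sample.int(h - ch + 1L, 1L); c0 <- sample.int(w - cw + 1L, 1L)
  out <- m[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
  out <- resize_bilinear(out, h, w)
  if (p$hflip && stats::runif(1) < 0.5) out <- out[, w:1]
  if (p$vflip && stats::runif(1) < 0.5) out <- out[h:1, ]
  if (p$jitter > 0) {
    gain <- 1 + stats::runif(1, -p$jitter, p$jitter)
    off <- stats::runif(1, -p$jitter / 2, p$jitter / 2)
    out <- clamp(out * gain + off, 0, 1)
  }
  if (p$blur && stats::runif(1) < 0.5) out <- blur3(out)
  out
}

#' Generate a stochastic augmentation pair
#'
#' Two independent augmentations (random resized crop, flips, intensity
#' jitter, Gaussian blur) of the same normalized patch, deterministic given
#' `seed`.
#'
#' @param patch Numeric matrix in `[0, 1]`.
#' @param seed Integer seed.
#' @param params An [augment_params()] object.
#' @return List with `view_a` and `view_b`.
#' @export
augment_pair <- function(patch, seed = 1, params = augment_params()) {
  local_rng(seed)
  list(view_a = augment_once(patch, params),
       view_b = augment_once(patch, params))
}

#' Barlow Twins loss
#'
#' Batch-standardizes both embedding matrices per dimension (population SD
#' with a small epsilon guard against zero-variance dimensions), forms the
#' cross-correlation `C = Z_a' Z_b / N`, and returns
#' `sum_i (1 - C_ii)^2 + lambda * sum_{i != j} C_ij^2`.
#'
#' @param z_a,z_b N x D embedding matrices (N >= 2).
#' @param lambda_offdiag Off-diagonal weight (default 0.005).
#' @return Scalar loss.
#' @export
barlow_twins_loss <- function(z_a, z_b, lambda_offdiag = 0.005) {
  z_a <- as.matrix(z_a); z_b <- as.matrix(z_b)
  if (nrow(z_a) < 2 || !identical(dim(z_a), dim(z_b)))
    stop("need two equal-shape batches with N >= 2")
  std <- function(z) {
    zc <- sweep(z, 2, colMeans(z), "-")
    sweep(zc, 2, sqrt(colMeans(zc^2) + 1e-8), "/")
  }
  C <- crossprod(std(z_a), std(z_b)) / nrow(z_a)
  I <- diag(ncol(C))
  sum((diag(C) - 1)^2) + lambda_offdiag * sum((C * (1 - I))^2)
}

#' BYOL loss
#'
#' Normalized mean squared error between predictor output and stop-gradient
#' teacher target, `||p/|p| - z/|z|||^2 = 2 - 2 cos(p, z)` averaged over the
#' batch. Bounded in `[0, 4]` and invariant to positive rescaling.
#'
#' @param p,z Matrices (rows = batch) or vectors; no zero rows allowed.
#' @return Scalar loss.
#' @export
byol_loss <- function(p, z) {
  if (is.null(dim(p))) p <- matrix(p, 1)
  if (is.null(dim(z))) z <- matrix(z, 1)
  pn <- sqrt(rowSums(p^2)); zn <- sqrt(rowSums(z^2))
  if (any(pn == 0) || any(zn == 0)) stop("zero vector in BYOL loss")
  mean(2 - 2 * rowSums((p / pn) * (z / zn)))
}

#' Sinkhorn-Knopp prototype assignment
#'
#' Normalizes `exp(scores / eps)` to a transport plan with row sums `1/B`
#' and column sums `1/K` by alternating column/row scaling. `iters` is the
#' minimum number of full sweeps; sweeps continue (up to `max_iters`) until
#' both marginals are within `tol`. Rows are normalized last, so row sums
#' are exact by construction.
#'
#' @param scores B x K score matrix (finite).
#' @param eps Assignment temperature (larger = more uniform codes).
#' @param iters Minimum number of sweeps.
#' @param tol Marginal tolerance.
#' @param max_iters Safety cap on sweeps.
#' @return B x K matrix of assignment codes summing to 1/B per row.
#' @export
swav_sinkhorn <- function(scores, eps = 0.05, iters = 3, tol = 1e-8,
                          max_iters = 200) {
  if (any(!is.finite(scores))) stop("non-finite scores")
  B <- nrow(scores); K <- ncol(scores)
  q <- exp((scores - max(scores)) / eps)
  q <- q / sum(q)
  for (it in seq_len(max_iters)) {
    q <- sweep(q, 2, colSums(q) * K, "/")
    q <- sweep(q, 1, rowSums(q) * B, "/")
    if (it >= iters &&
        max(abs(colSums(q) - 1 / K)) < tol &&
        max(abs(rowSums(q) - 1 / B)) < tol) break
  }
  q
}

#' Self-supervised pretraining configuration
#'
#' Defaults follow the method papers: Barlow Twins lambda 0.005, BYOL EMA
#' momentum 0.996, SwAV epsilon 0.05 with 3 Sinkhorn sweeps.
#'
#' @param method One of `"barlow_twins"`, `"byol"`, `"swav"`.
#' @param backbone A [backbone_config()].
#' @param embed_dim Projector output dimension.
#' @param lambda_offdiag Barlow Twins off-diagonal weight.
#' @param ema_momentum BYOL teacher momentum in `[0, 1]`; 1 freezes the
#'   teacher (degenerate, flagged with a warning).
#' @param n_prototypes,sinkhorn_eps,sinkhorn_iters SwAV settings.
#' @param epochs,batch_size,lr,weight_decay Optimization settings
#'   (batch_size >= 2: the objectives use batch statistics).
#' @param augment An [augment_params()].
#' @param seed Integer seed controlling initialization, batching and
#'   augmentation.
#' @return List of class `ssl_config`.
#' @export
ssl_config <- function(method = c("barlow_twins", "byol", "swav"),
                       backbone = backbone_config(c(8, 16, 32)),
                       embed_dim = 32, lambda_offdiag = 0.005,
                       ema_momentum = 0.996, n_prototypes = 16,
                       sinkhorn_eps = 0.05, sinkhorn_iters = 3,
                       epochs = 5, batch_size = 16, lr = 1e-3,
                       weight_decay = 1e-4, augment = augment_params(),
                       seed = 1) {
  method <- match.arg(method)
  if (batch_size < 2) stop("batch_size must be >= 2 (batch statistics)")
  if (lambda_offdiag <= 0) stop("lambda_offdiag must be > 0")
  if (ema_momentum < 0 || ema_momentum > 1)
    stop("ema_momentum must lie in [0, 1]")
  structure(list(method = method, backbone = backbone,
                 embed_dim = embed_dim, lambda_offdiag = lambda_offdiag,
                 ema_momentum = ema_momentum, n_prototypes = n_prototypes,
                 sinkhorn_eps = sinkhorn_eps, sinkhorn_iters = sinkhorn_iters,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 weight_decay = weight_decay, augment = augment, seed = seed),
            class = "ssl_config")
}

# projector forward: GAP(backbone(x)) -> linear-relu-linear
ssl_embed <- function(tape, lv, xarr, bcfg) {
  x <- tp_leaf(tape, xarr)
  f <- backbone_forward(tape, lv, x, bcfg)
  h <- op_gap(f, tape)
  h <- op_relu(op_add_bias(op_matmul(h, lv$proj_w1, tape), lv$proj_b1, tape),
               tape)
  op_add_bias(op_matmul(h, lv$proj_w2, tape), lv$proj_b2, tape)
}

ssl_init_params <- function(config) {
  p <- backbone_init(config$backbone, seed = string_seed("ssl-init",
                                                         config$seed))
  fd <- config$backbone$feature_dim; ed <- config$embed_dim
  p$proj_w1 <- init_mat(fd, ed)
  p$proj_b1 <- matrix(0, 1, ed)
  p$proj_w2 <- init_mat(ed, ed)
  p$proj_b2 <- matrix(0, 1, ed)
  if (config$method == "byol") {
    p$pred_w1 <- init_mat(ed, ed)
    p$pred_b1 <- matrix(0, 1, ed)
    p$pred_w2 <- init_mat(ed, ed)
    p$pred_b2 <- matrix(0, 1, ed)
  }
  if (config$method == "swav") {
    p$prototypes <- init_mat(ed, config$n_prototypes, scale = 1 / sqrt(ed))
  }
  p
}

#' Pretrain the backbone on unlabeled patches
#'
#' Runs the configured self-supervised objective over augmented patch
#' pairs with AdamW, logging the mean loss per epoch. Deterministic under
#' the configuration seed (single-threaded BLAS assumed for bitwise
#' reproducibility).
#'
#' @param patches List of equal-size numeric matrices in `[0, 1]`.
#' @param config An [ssl_config()].
#' @return List of class `ssl_pretrain` with `weights` (backbone parameter
#'   list ready for [train_neck()]), `projector` (full parameter set),
#'   `log` (`data.frame` of epoch and mean loss) and `config`.
#' @export
pretrain_backbone <- function(patches, config = ssl_config()) {
  if (length(patches) < config$batch_size)
    stop("need at least batch_size patches")
  local_rng(config$seed)
  params <- ssl_init_params(config)
  bcfg <- config$backbone
  teacher <- NULL
  if (config$method == "byol") {
    teacher <- params[grep("^(s[0-9]+_|proj_)", names(params))]
    if (config$ema_momentum == 1)
      warning("ema_momentum = 1: BYOL teacher is frozen at initialization")
  }
  opt <- adamw_new(params, lr = config$lr, weight_decay = config$weight_decay)
  n <- length(patches)
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n - config$batch_size + 1, by = config$batch_size)) {
      idx <- ord[start:(start + config$batch_size - 1)]
      va <- lapply(patches[idx], augment_once, p = config$augment)
      vb <- lapply(patches[idx], augment_once, p = config$augment)
      xa <- images_to_array(va); xb <- images_to_array(vb)
      B <- length(idx)
      fwd <- switch(config$method,
        barlow_twins = function(tape, lv) {
          za <- op_standardize_cols(ssl_embed(tape, lv, xa, bcfg), tape)
          zb <- op_standardize_cols(ssl_embed(tape, lv, xb, bcfg), tape)
          cc <- op_scale(op_matmul(op_transpose(za, tape), zb, tape),
                         1 / B, tape)
          op_bt_from_cc(cc, config$lambda_offdiag, tape)
        },
        byol = function(tape, lv) {
          predict_head <- function(z) {
            h <- op_relu(op_add_bias(op_matmul(z, lv$pred_w1, tape),
                                     lv$pred_b1, tape), tape)
            op_add_bias(op_matmul(h, lv$pred_w2, tape), lv$pred_b2, tape)
          }
          pa <- predict_head(ssl_embed(tape, lv, xa, bcfg))
          pb <- predict_head(ssl_embed(tape, lv, xb, bcfg))
          # teacher targets: plain forward through the EMA weights
          tt <- tp_new()
          tl <- lapply(teacher, function(p) tp_leaf(tt, p))
          za_t <- ssl_embed(tt, tl, xa, bcfg)$v
          zb_t <- ssl_embed(tt, tl, xb, bcfg)$v
          la <- op_byol_row(pa, zb_t, tape)
          lb <- op_byol_row(pb, za_t, tape)
          op_scale(op_add(la, lb, tape), 0.5, tape)
        },
        swav = function(tape, lv) {
          za <- op_l2norm_rows(ssl_embed(tape, lv, xa, bcfg), tape)
          zb <- op_l2norm_rows(ssl_embed(tape, lv, xb, bcfg), tape)
          sa <- op_matmul(za, lv$prototypes, tape)
          sb <- op_matmul(zb, lv$prototypes, tape)
          qa <- swav_sinkhorn(sa$v, config$sinkhorn_eps,
                              config$sinkhorn_iters) * B
          qb <- swav_sinkhorn(sb$v, config$sinkhorn_eps,
                              config$sinkhorn_iters) * B
          la <- op_ce_soft(op_scale(sa, 10, tape), qb, tape)
          lb <- op_ce_soft(op_scale(sb, 10, tape), qa, tape)
          op_scale(op_add(la, lb, tape), 0.5, tape)
        })
      step <- nn_grad_step(params, fwd)
      params <- adamw_step(opt, params, step$grads)
      if (config$method == "byol" && config$ema_momentum < 1) {
        m <- config$ema_momentum
        for (k in names(teacher))
          teacher[[k]] <- m * teacher[[k]] + (1 - m) * params[[k]]
      }
      losses <- c(losses, step$loss)
    }
    log <- rbind(log, data.frame(epoch = ep, loss = mean(losses)))
  }
  bb_keys <- grep("^s[0-9]+_", names(params), value = TRUE)
  weights <- params[bb_keys]
  attr(weights, "config") <- bcfg
  structure(list(weights = weights, projector = params, log = log,
                 config = config), class = "ssl_pretrain")
}
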