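#' Reverse-mode automatic differentiation core
#'
#' A small tape-based autodiff engine over numeric matrices/arrays that
#' powers the convolutional backbone, the neck architectures and the fusion
#' MLP. Each forward pass records operation nodes on a tape; `tp_backward()`
#' walks the tape in reverse, accumulating gradients into leaf (parameter)
#' nodes. Heavy operations (convolutions, attention, normalizations, masked
#' losses) are fused single nodes with hand-derived backward rules built on
#' BLAS matrix products.
#'
#' @name nn_core
#' @keywords internal
NULL

tp_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

# create a node; back(g) must return a list of parent gradients (NULL to skip)
nd <- function(tape, v, parents = list(), back = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v; e$g <- NULL; e$parents <- parents; e$back <- back
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- e
  e
}

# leaf node for a parameter or input (gradient collected if requested)
tp_leaf <- function(tape, v) nd(tape, v)

tp_backward <- function(tape, loss) {
  loss$g <- array(1, dim = dim(loss$v) %||% length(loss$v))
  for (i in seq.int(tape$n, 1L)) {
    e <- tape$nodes[[i]]
    if (is.null(e$g) || is.null(e$back)) next
    gs <- e$back(e$g)
    ps <- e$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      p$g <- if (is.null(p$g)) gj else p$g + gj
    }
  }
  invisible(NULL)
}

## ---- elementwise and linear-algebra ops ----------------------------------

op_add <- function(a, b, tape) {
  nd(tape, a$v + b$v, list(a, b), function(g) list(g, g))
}

op_sub <- function(a, b, tape) {
  nd(tape, a$v - b$v, list(a, b), function(g) list(g, -g))
}

op_mul <- function(a, b, tape) {
  av <- a$v; bv <- b$v
  nd(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

op_scale <- function(a, k, tape) {   # k plain scalar
  nd(tape, a$v * k, list(a), function(g) list(g * k))
}

op_matmul <- function(a, b, tape) {
  av <- a$v; bv <- b$v
  nd(tape, av %*% bv, list(a, b),
     function(g) list(g %*% t(bv), t(av) %*% g))
}

# add a length-ncol row vector (bias) to every row of a matrix
op_add_bias <- function(a, b, tape) {
  bv <- as.vector(b$v)
  nd(tape, sweep(a$v, 2, bv, "+"), list(a, b),
     function(g) list(g, matrix(colSums(g), 1)))
}

op_relu <- function(a, tape) {
  keep <- a$v > 0
  nd(tape, a$v * keep, list(a), function(g) list(g * keep))
}

op_sigmoid <- function(a, tape) {
  s <- 1 / (1 + exp(-a$v))
  nd(tape, s, list(a), function(g) list(g * s * (1 - s)))
}

op_mean <- function(a, tape) {
  n <- length(a$v)
  nd(tape, matrix(mean(a$v), 1, 1), list(a),
     function(g) list(array(as.numeric(g) / n, dim = dim(a$v) %||% n)))
}

op_reshape <- function(a, new_dim, tape) {
  old <- dim(a$v) %||% length(a$v)
  v <- a$v; dim(v) <- new_dim
  nd(tape, v, list(a), function(g) { dim(g) <- old; list(g) })
}

op_gather_rows <- function(a, idx, tape) {
  av <- a$v
  nd(tape, av[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    # accumulate duplicate indices
    agg <- rowsum(g, group = idx)
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

op_slice_cols <- function(a, idx, tape) {
  av <- a$v
  nd(tape, av[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    out[, idx] <- g
    list(out)
  })
}

op_concat_cols <- function(nodes, tape) {
  widths <- vapply(nodes, function(x) ncol(x$v), integer(1))
  ends <- cumsum(widths); starts <- ends - widths + 1
  nd(tape, do.call(cbind, lapply(nodes, function(x) x$v)), nodes,
     function(g) lapply(seq_along(nodes), function(j)
       g[, starts[j]:ends[j], drop = FALSE]))
}

op_dropout <- function(a, rate, tape, training = TRUE) {
  if (!training || rate <= 0) return(a)
  keep <- (stats::runif(length(a$v)) >= rate) / (1 - rate)
  dim(keep) <- dim(a$v)
  nd(tape, a$v * keep, list(a), function(g) list(g * keep))
}

# row-wise layer normalization with learnable gain/shift (eps-guarded)
op_layernorm <- function(a, gamma, beta, tape, eps = 1e-5) {
  x <- a$v
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xh <- xc * inv
  gv <- as.vector(gamma$v); bv <- as.vector(beta$v)
  y <- sweep(xh, 2, gv, "*")
  y <- sweep(y, 2, bv, "+")
  D <- ncol(x)
  nd(tape, y, list(a, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xh), 1)
    dbeta <- matrix(colSums(g), 1)
    gxh <- sweep(g, 2, gv, "*")
    # dx = inv * (gxh - mean(gxh) - xh * mean(gxh * xh)) per row
    m1 <- rowMeans(gxh)
    m2 <- rowMeans(gxh * xh)
    dx <- inv * (gxh - m1 - xh * m2)
    list(dx, dgamma, dbeta)
  })
}

# per-column batch standardization (z-scoring over the batch dimension)
op_standardize_cols <- function(a, tape, eps = 1e-8) {
  x <- a$v
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  sd <- sqrt(colMeans(xc^2) + eps)
  xh <- sweep(xc, 2, sd, "/")
  nd(tape, xh, list(a), function(g) {
    m1 <- colMeans(g)
    m2 <- colMeans(g * xh)
    dx <- sweep(sweep(g, 2, m1, "-") - sweep(xh, 2, m2, "*"), 2, sd, "/")
    list(dx)
  })
}

# softmax over rows with optional diagonal (self-token) masking
op_masked_softmax <- function(a, tape, mask_diag = FALSE) {
  s <- a$v
  if (mask_diag) {
    if (nrow(s) < 2) stop("diagonal masking needs at least two tokens")
    diag(s) <- -Inf
  }
  s <- s - apply(s, 1, max)
  e <- exp(s)
  p <- e / rowSums(e)
  nd(tape, p, list(a), function(g) {
    dp <- p * (g - rowSums(g * p))
    if (mask_diag) diag(dp) <- 0
    list(dp)
  })
}

# divide a matrix by a learnable positive scalar temperature
op_div_temp <- function(a, tau, tape) {
  tv <- as.numeric(tau$v)
  nd(tape, a$v / tv, list(a, tau), function(g)
    list(g / tv, matrix(-sum(g * a$v) / tv^2, 1, 1)))
}

## ---- convolution ops (NHWC arrays) ---------------------------------------

conv_out_len <- function(l, stride) floor((l - 1) / stride) + 1  # pad=1, k=3

pad_hw <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2, d[3] + 2, d[4]))
  xp[, 2:(d[2] + 1), 2:(d[3] + 1), ] <- x
  xp
}

# standard 3x3 convolution, zero padding 1, given stride; W: (3,3,Ci,Co)
op_conv3x3 <- function(x, w, b, stride, tape) {
  xv <- x$v; wv <- w$v; bv <- as.vector(b$v)
  d <- dim(xv); N <- d[1]; H <- d[2]; W <- d[3]; Ci <- d[4]; Co <- dim(wv)[4]
  Ho <- conv_out_len(H, stride); Wo <- conv_out_len(W, stride)
  xp <- pad_hw(xv)
  ri <- function(k) k + (0:(Ho - 1)) * stride  # 1-based rows in padded array
  ci <- function(k) k + (0:(Wo - 1)) * stride
  y <- matrix(0, N * Ho * Wo, Co)
  xs_list <- vector("list", 9)
  for (kx in 1:3) for (ky in 1:3) {
    idx <- (kx - 1) * 3 + ky
    xs <- xp[, ri(ky), ci(kx), , drop = FALSE]
    m <- xs; dim(m) <- c(N * Ho * Wo, Ci)
    xs_list[[idx]] <- m
    y <- y + m %*% matrix(wv[ky, kx, , ], Ci, Co)
  }
  y <- sweep(y, 2, bv, "+")
  dim(y) <- c(N, Ho, Wo, Co)
  nd(tape, y, list(x, w, b), function(g) {
    gm <- g; dim(gm) <- c(N * Ho * Wo, Co)
    dw <- array(0, dim(wv))
    dxp <- array(0, dim(xp))
    for (kx in 1:3) for (ky in 1:3) {
      idx <- (kx - 1) * 3 + ky
      m <- xs_list[[idx]]
      dw[ky, kx, , ] <- t(m) %*% gm
      dxs <- gm %*% t(matrix(wv[ky, kx, , ], Ci, Co))
      dim(dxs) <- c(N, Ho, Wo, Ci)
      dxp[, ri(ky), ci(kx), ] <- dxp[, ri(ky), ci(kx), , drop = FALSE] + dxs
    }
    dx <- dxp[, 2:(H + 1), 2:(W + 1), , drop = FALSE]
    db <- matrix(colSums(gm), 1)
    list(dx, dw, db)
  })
}

# depthwise 3x3 convolution, stride 1, zero padding 1; W: (3,3,C)
op_dwconv3x3 <- function(x, w, tape) {
  xv <- x$v; wv <- w$v
  d <- dim(xv); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  xp <- pad_hw(xv)
  y <- array(0, d)
  for (kx in 1:3) for (ky in 1:3) {
    xs <- xp[, ky + 0:(H - 1), kx + 0:(W - 1), , drop = FALSE]
    y <- y + xs * rep(wv[ky, kx, ], each = N * H * W)
  }
  nd(tape, y, list(x, w), function(g) {
    dw <- array(0, dim(wv))
    dxp <- array(0, dim(xp))
    for (kx in 1:3) for (ky in 1:3) {
      xs <- xp[, ky + 0:(H - 1), kx + 0:(W - 1), , drop = FALSE]
      prod <- g * xs
      dim(prod) <- c(N * H * W, C)
      dw[ky, kx, ] <- colSums(prod)
      gs <- g * rep(wv[ky, kx, ], each = N * H * W)
      dxp[, ky + 0:(H - 1), kx + 0:(W - 1), ] <-
        dxp[, ky + 0:(H - 1), kx + 0:(W - 1), , drop = FALSE] + gs
    }
    list(dxp[, 2:(H + 1), 2:(W + 1), , drop = FALSE], dw)
  })
}

# pointwise (1x1) convolution as a per-position linear map
op_conv1x1 <- function(x, w, b, tape) {
  d <- dim(x$v); N <- d[1]; H <- d[2]; W <- d[3]; Ci <- d[4]
  Co <- ncol(w$v)
  xm <- op_reshape(x, c(N * H * W, Ci), tape)
  y <- op_add_bias(op_matmul(xm, w, tape), b, tape)
  op_reshape(y, c(N, H, W, Co), tape)
}

# global average pooling (N,H,W,C) -> (N,C)
op_gap <- function(x, tape) {
  d <- dim(x$v); N <- d[1]; HW <- d[2] * d[3]; C <- d[4]
  m <- x$v; dim(m) <- c(N * HW, C)
  grp <- rep_len(seq_len(N), N * HW)
  out <- rowsum(m, grp) / HW
  nd(tape, out, list(x), function(g) {
    dm <- g[grp, , drop = FALSE] / HW
    dim(dm) <- d
    list(dm)
  })
}

## ---- fused losses --------------------------------------------------------

# masked binary cross-entropy: preds (n,1) probabilities, y/mask constants
op_bce_masked <- function(p, y, mask, tape, eps = 1e-7) {
  m <- sum(mask)
  if (m == 0) stop("no observed labels in batch")
  pv <- clamp(p$v, eps, 1 - eps)
  l <- -sum(mask * (y * log(pv) + (1 - y) * log(1 - pv))) / m
  nd(tape, matrix(l, 1, 1), list(p), function(g) {
    gd <- as.numeric(g) * mask * (pv - y) / (pv * (1 - pv)) / m
    dim(gd) <- dim(p$v)
    list(gd)
  })
}

# masked mean squared error on raw (already transformed) targets
op_mse_masked <- function(p, y, mask, tape) {
  m <- sum(mask)
  if (m == 0) stop("no observed labels in batch")
  diff <- (p$v - y) * mask
  l <- sum(diff^2) / m
  nd(tape, matrix(l, 1, 1), list(p), function(g) {
    gd <- as.numeric(g) * 2 * diff / m
    dim(gd) <- dim(p$v)
    list(gd)
  })
}

# Barlow Twins redundancy-reduction loss from a cross-correlation matrix
op_bt_from_cc <- function(cc, lambda, tape) {
  C <- cc$v
  D <- nrow(C)
  I <- diag(D)
  l <- sum((diag(C) - 1)^2) + lambda * sum((C * (1 - I))^2)
  nd(tape, matrix(l, 1, 1), list(cc), function(g) {
    gd <- as.numeric(g) * (2 * (C - I) * I + 2 * lambda * C * (1 - I))
    list(gd)
  })
}

# BYOL regression loss: 2 - 2*cos(p, z) per row, averaged; z is constant
op_byol_row <- function(p, z, tape, eps = 1e-12) {
  pv <- p$v
  pn <- sqrt(rowSums(pv^2)) + eps
  zn <- sqrt(rowSums(z^2)) + eps
  if (any(pn < 1e-8) || any(zn < 1e-8)) stop("zero vector in BYOL loss")
  ph <- pv / pn
  zh <- z / zn
  cosv <- rowSums(ph * zh)
  l <- mean(2 - 2 * cosv)
  n <- nrow(pv)
  nd(tape, matrix(l, 1, 1), list(p), function(g) {
    # d/dp of -2*cos: -2*(zh - cos*ph)/|p|
    gd <- as.numeric(g) * (-2) * (zh - cosv * ph) / pn / n
    list(gd)
  })
}

## ---- parameters and optimizer --------------------------------------------

init_mat <- function(nin, nout, scale = sqrt(2 / nin)) {
  matrix(stats::rnorm(nin * nout, 0, scale), nin, nout)
}

init_conv <- function(k, ci, co) {
  array(stats::rnorm(k * k * ci * co, 0, sqrt(2 / (k * k * ci))),
        c(k, k, ci, co))
}

#' AdamW optimizer state
#'
#' Decoupled weight decay Adam. `adamw_step()` updates a parameter list in
#' place (the returned list) given a gradient list of the same shape.
#'
#' @param params Named list of numeric arrays.
#' @param lr Learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param beta1,beta2,eps Adam moment constants.
#' @return An environment holding the optimizer state.
#' @keywords internal
adamw_new <- function(params, lr = 1e-3, weight_decay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  st$v <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  st$t <- 0L
  st$lr <- lr; st$wd <- weight_decay
  st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st
}

adamw_step <- function(st, params, grads, no_decay = character(0)) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    st$m[[k]] <- st$b1 * st$m[[k]] + (1 - st$b1) * g
    st$v[[k]] <- st$b2 * st$v[[k]] + (1 - st$b2) * g^2
    upd <- (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + st$eps)
    wd <- if (k %in% no_decay) 0 else st$wd
    params[[k]] <- params[[k]] - st$lr * (upd + wd * params[[k]])
  }
  params
}

# run a forward/backward pass: fwd(tape, leaves) must return the loss node.
# Returns list(loss, grads) where grads align with params.
nn_grad_step <- function(params, fwd) {
  tape <- tp_new()
  leaves <- lapply(params, function(p) tp_leaf(tape, p))
  loss <- fwd(tape, leaves)
  tp_backward(tape, loss)
  grads <- lapply(leaves, function(l) l$g)
  list(loss = as.numeric(loss$v), grads = grads)
}

op_transpose <- function(a, tape) {
  nd(tape, t(a$v), list(a), function(g) list(t(g)))
}

# L2-normalize each row (eps-guarded)
op_l2norm_rows <- function(a, tape, eps = 1e-12) {
  x <- a$v
  nrm <- sqrt(rowSums(x^2)) + eps
  xh <- x / nrm
  nd(tape, xh, list(a), function(g) {
    dot <- rowSums(g * xh)
    list((g - xh * dot) / nrm)
  })
}

# soft-target cross-entropy over rows: -mean_b sum_k q[b,k] * log softmax(logits)[b,k]
op_ce_soft <- function(logits, q, tape) {
  s <- logits$v - apply(logits$v, 1, max)
  e <- exp(s)
  p <- e / rowSums(e)
  B <- nrow(p)
  l <- -sum(q * log(pmax(p, 1e-12))) / B
  nd(tape, matrix(l, 1, 1), list(logits), function(g) {
    list(as.numeric(g) * (p * rowSums(q) - q) / B)
  })
}

op_concat_rows <- function(nodes, tape) {
  heights <- vapply(nodes, function(x) nrow(x$v), integer(1))
  ends <- cumsum(heights); starts <- ends - heights + 1
  nd(tape, do.call(rbind, lapply(nodes, function(x) x$v)), nodes,
     function(g) lapply(seq_along(nodes), function(j)
       g[starts[j]:ends[j], , drop = FALSE]))
}

# zero-padded spatial shift of an (N,H,W,C) map: y[,i,j,] = x[,i-dy,j-dx,]
op_shift2d <- function(x, dy, dx, tape) {
  d <- dim(x$v)
  shift <- function(a, sy, sx) {
    out <- array(0, dim(a))
    ys <- seq_len(d[2]); xs <- seq_len(d[3])
    yt <- ys + sy; xt <- xs + sx
    ok_y <- yt >= 1 & yt <= d[2]; ok_x <- xt >= 1 & xt <= d[3]
    out[, yt[ok_y], xt[ok_x], ] <- a[, ys[ok_y], xs[ok_x], , drop = FALSE]
    out
  }
  nd(tape, shift(x$v, dy, dx), list(x),
     function(g) list(shift(g, -dy, -dx)))
}
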