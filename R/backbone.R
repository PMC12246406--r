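#' Residual convolutional backbone
#'
#' A compact residual encoder mapping a grayscale image to a spatial
#' feature map: each stage halves the resolution with a stride-2 3x3
#' convolution and applies one residual 3x3 convolution. The number of
#' stages and channels is configurable; the last stage's channel count is
#' the backbone's `feature_dim` (128 at desk scale, 1024 at full scale).
#'
#' @name backbone
NULL

#' Backbone configuration
#'
#' @param channels Integer vector of per-stage output channels; the length
#'   sets the downsampling factor (2^stages) and the last entry the
#'   feature dimension.
#' @param in_channels Input image channels (1 for mammograms).
#' @return A list of class `backbone_config`.
#' @export
backbone_config <- function(channels = c(16, 32, 64, 128), in_channels = 1) {
  stopifnot(length(channels) >= 1, all(channels >= 1))
  structure(list(channels = as.integer(channels),
                 in_channels = as.integer(in_channels),
                 feature_dim = as.integer(channels[length(channels)])),
            class = "backbone_config")
}

#' Initialize backbone weights
#'
#' He-normal initialization; deterministic under `seed`. The returned
#' parameter list is the serializable `BackboneWeights` object (plain
#' numeric arrays; save with [save_weights()]).
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed.
#' @return Named list of parameter arrays with attribute `config`.
#' @export
backbone_init <- function(config = backbone_config(), seed = 1) {
  local_rng(seed)
  p <- list()
  ci <- config$in_channels
  for (i in seq_along(config$channels)) {
    co <- config$channels[i]
    p[[sprintf("s%d_w", i)]] <- init_conv(3, ci, co)
    p[[sprintf("s%d_b", i)]] <- matrix(0, 1, co)
    p[[sprintf("s%d_rw", i)]] <- init_conv(3, co, co)
    p[[sprintf("s%d_rb", i)]] <- matrix(0, 1, co)
    ci <- co
  }
  attr(p, "config") <- config
  p
}

# forward through the backbone; x is a leaf/op node holding (N,H,W,C)
backbone_forward <- function(tape, leaves, x, config) {
  h <- x
  for (i in seq_along(config$channels)) {
    y <- op_relu(op_conv3x3(h, leaves[[sprintf("s%d_w", i)]],
                            leaves[[sprintf("s%d_b", i)]], 2L, tape), tape)
    r <- op_conv3x3(y, leaves[[sprintf("s%d_rw", i)]],
                    leaves[[sprintf("s%d_rb", i)]], 1L, tape)
    h <- op_relu(op_add(y, r, tape), tape)
  }
  h
}

# stack a list of equal-size matrices into an (N,H,W,1) array
images_to_array <- function(imgs) {
  if (length(imgs) == 0) stop("no images")
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  x <- array(0, c(length(imgs), h, w, 1))
  for (i in seq_along(imgs)) x[i, , , 1] <- imgs[[i]]
  x
}

#' Save / load a parameter list
#'
#' Checkpoints are single-file serialized parameter lists (`saveRDS`);
#' loading restores the arrays bit-exactly.
#'
#' @param params Named list of numeric arrays.
#' @param path File path.
#' @return `path` (save) or the parameter list (load).
#' @export
save_weights <- function(params, path) {
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) readRDS(path)
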