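# Network building blocks operating on single-image activations stored as
# [H, W, C] arrays. Convolutions are evaluated as sums of shifted-slice
# matrix products, which keeps the arithmetic in BLAS.

# He-normal initialized convolution parameters, kernel k x k. The weight is
# stored GEMM-ready: rows ordered (channel fastest, then kernel dy, dx) to
# match the im2col patch layout.
init_conv <- function(k, c_in, c_out) {
  sd <- sqrt(2 / (k * k * c_in))
  arr <- array(rnorm(k * k * c_in * c_out, sd = sd),
               dim = c(k, k, c_in, c_out))
  list(W = matrix(aperm(arr, c(3, 1, 2, 4)), k * k * c_in, c_out),
       b = rep(0, c_out), k = k, c_in = c_in, stride = 1L)
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

init_dense_he <- function(d_in, d_out) {
  list(W = matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = rep(0, d_out))
}

# Same-padding convolution, arbitrary odd kernel and stride.
conv2d <- function(x, p, stride = p$stride) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; c_in <- d[3]
  k <- p$k
  pad <- (k - 1) %/% 2
  c_out <- ncol(p$W)
  xp <- array(0, dim = c(h + 2 * pad, w + 2 * pad, c_in))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  rows <- seq(1, h, by = stride)
  cols <- seq(1, w, by = stride)
  ho <- length(rows); wo <- length(cols)
  # im2col: one patch row per output position, one DGEMM for the whole
  # layer; columns blocked by kernel offset (all channels contiguous)
  patches <- matrix(0, ho * wo, k * k * c_in)
  dd <- 0
  for (dx in seq_len(k)) {
    for (dy in seq_len(k)) {
      slice <- xp[rows + dy - 1, cols + dx - 1, , drop = FALSE]
      dim(slice) <- c(ho * wo, c_in)
      patches[, dd * c_in + seq_len(c_in)] <- slice
      dd <- dd + 1
    }
  }
  acc <- sweep(patches %*% p$W, 2, p$b, "+")
  array(acc, dim = c(ho, wo, c_out))
}

# Inference-mode batch normalization using the stored running statistics.
bn_apply <- function(x, p, eps = 1e-3) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  m <- sweep(sweep(m, 2, p$run_mean, "-"), 2, 1 / sqrt(p$run_var + eps), "*")
  m <- sweep(sweep(m, 2, p$gamma, "*"), 2, p$beta, "+")
  array(m, dim = d)
}

channel_means <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

channel_maxs <- function(x) {
  d <- dim(x)
  apply(matrix(x, d[1] * d[2], d[3]), 2, max)
}

scale_channels <- function(x, g) {
  d <- dim(x)
  array(sweep(matrix(x, d[1] * d[2], d[3]), 2, g, "*"), dim = d)
}

init_se <- function(c, ratio) {
  assert_that_(c %% ratio == 0, "SE ratio must divide the channel count")
  list(fc1 = init_dense_he(c, c %/% ratio), fc2 = init_dense_he(c %/% ratio, c))
}

#' Squeeze-excite channel gating (functional form)
#'
#' Global average pool, bottleneck dense + ReLU, dense back to the channel
#' count, sigmoid gate, channel-wise multiplication.
#'
#' @param x H x W x C activation array.
#' @param params SE parameter list (`fc1`, `fc2`); channel count must be
#'   divisible by the configured ratio at initialization time.
#' @return Gated activation, same shape; gate values in attribute `gate`.
#' @export
se_apply <- function(x, params) {
  s <- channel_means(x)
  z <- relu(as.vector(s %*% params$fc1$W) + params$fc1$b)
  g <- sigmoid(as.vector(z %*% params$fc2$W) + params$fc2$b)
  out <- scale_channels(x, g)
  attr(out, "gate") <- g
  out
}

init_cbam <- function(c, ratio = 16) {
  hidden <- max(1L, c %/% ratio)
  list(mlp1 = init_dense_he(c, hidden), mlp2 = init_dense_he(hidden, c),
       spatial = init_conv(7, 2, 1))
}

#' Convolutional block attention (functional form)
#'
#' Channel attention (shared bottleneck MLP over average- and max-pooled
#' channel descriptors, sigmoid) followed by spatial attention (7 x 7
#' convolution over the channel-wise mean/max maps, sigmoid), both applied
#' multiplicatively.
#'
#' @param x H x W x C activation array.
#' @param params CBAM parameter list.
#' @return Attended activation, same shape; the two attention maps ride
#'   along as attributes `channel_attention`, `spatial_attention`.
#' @export
cbam_apply <- function(x, params) {
  mlp <- function(v) {
    as.vector(relu(as.vector(v %*% params$mlp1$W) + params$mlp1$b) %*%
                params$mlp2$W) + params$mlp2$b
  }
  mc <- sigmoid(mlp(channel_means(x)) + mlp(channel_maxs(x)))
  x1 <- scale_channels(x, mc)
  d <- dim(x1)
  m <- matrix(x1, d[1] * d[2], d[3])
  maps <- array(c(rowMeans(m), apply(m, 1, max)), dim = c(d[1], d[2], 2))
  ms <- sigmoid(conv2d(maps, params$spatial, stride = 1L)[, , 1])
  out <- x1 * as.vector(ms)  # recycles over channels
  attr(out, "channel_attention") <- mc
  attr(out, "spatial_attention") <- ms
  out
}

init_rse <- function(c_in, filters, ratio, stride = 1L, merge = "add") {
  p <- list(conv1 = init_conv(3, c_in, filters),
            bn1 = init_bn(filters),
            conv2 = init_conv(3, filters, filters),
            bn2 = init_bn(filters),
            se = init_se(filters, ratio),
            stride = as.integer(stride), merge = merge)
  if (merge == "add" && (c_in != filters || stride != 1L)) {
    p$proj <- init_conv(1, c_in, filters)
    p$bn_proj <- init_bn(filters)
  }
  p
}

# 2x2 average pooling with stride 2 (used to align the skip branch of
# concat-merge blocks when the residual branch downsamples).
avg_pool2 <- function(x) {
  d <- dim(x)
  rows <- seq(1, d[1], by = 2)
  cols <- seq(1, d[2], by = 2)
  r2 <- pmin(rows + 1, d[1])
  c2 <- pmin(cols + 1, d[2])
  (x[rows, cols, , drop = FALSE] + x[r2, cols, , drop = FALSE] +
     x[rows, c2, , drop = FALSE] + x[r2, c2, , drop = FALSE]) / 4
}

#' Residual squeeze-excite block (functional form)
#'
#' Residual branch `g(x) = SE(BN(Conv3x3(Dropout(GeLU(BN(Conv3x3(x)))))))`
#' (dropout is inactive at inference). With `merge = "add"` the block input
#' joins by addition (through a 1 x 1 projection + BN when channels or
#' stride differ) and with `merge = "concat"` by channel concatenation
#' (average-pooled when the branch downsamples); GeLU activates the merge.
#'
#' @param x H x W x C activation array.
#' @param params RSE parameter list from the network builder.
#' @return Output activation array.
#' @export
rse_apply <- function(x, params) {
  g <- conv2d(x, params$conv1, stride = params$stride)
  g <- gelu(bn_apply(g, params$bn1))
  g <- conv2d(g, params$conv2, stride = 1L)
  g <- bn_apply(g, params$bn2)
  g <- se_apply(g, params$se)
  attributes(g)$gate <- NULL
  if (params$merge == "add") {
    skip <- x
    if (!is.null(params$proj)) {
      skip <- bn_apply(conv2d(x, params$proj, stride = params$stride),
                       params$bn_proj)
    }
    gelu(skip + g)
  } else {
    skip <- x
    if (params$stride > 1L) skip <- avg_pool2(x)
    d1 <- dim(skip); d2 <- dim(g)
    out <- array(0, dim = c(d2[1], d2[2], d1[3] + d2[3]))
    out[, , seq_len(d1[3])] <- skip
    out[, , d1[3] + seq_len(d2[3])] <- g
    gelu(out)
  }
}

# Trainable parameter count of a (nested) parameter list; running statistics
# and structural scalars are excluded.
count_leaf_params <- function(p) {
  skip_names <- c("run_mean", "run_var", "k", "c_in", "stride", "merge")
  walk <- function(obj, name = "") {
    if (name %in% skip_names) return(0)
    if (is.list(obj)) {
      nms <- names(obj) %||% rep("", length(obj))
      sum(vapply(seq_along(obj), function(i) walk(obj[[i]], nms[i]),
                 numeric(1)))
    } else if (is.numeric(obj)) {
      length(obj)
    } else {
      0
    }
  }
  walk(p)
}
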