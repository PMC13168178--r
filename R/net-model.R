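# The dual-stream residual squeeze-excite network (DSRSENet).
#
# Shallow stream: 3x3/64 stem, RSE blocks 64-64-128 at stride 1, CBAM.
# Deep stream: 3x3/64 stem at stride 2, RSE blocks 128-256-512-1024 each
# downsampling by 2 on their first convolution, CBAM. Both streams are
# globally average-pooled, concatenated, and projected by a 2048-wide GeLU
# dense layer -- the deep feature vector. A dropout + sigmoid dense head on
# top gives the binary training objective.

#' Network configuration
#'
#' @param input_size Input image side in pixels (images are
#'   `input_size x input_size x 3`; the published setting is 299).
#' @param se_ratio Squeeze-excite bottleneck ratio (divides every RSE filter
#'   count; default 16).
#' @param block_dropout Dropout rate inside RSE blocks during training
#'   (default 0.2).
#' @param head_dropout Dropout before the classification dense (default 0.3).
#' @param head_width Width of the post-concatenation dense feature layer
#'   (default 2048).
#' @param merge Residual merge of RSE blocks: `"add"` (1 x 1 projection on
#'   mismatch; default) or `"concat"`.
#' @param seed Seed for the deterministic weight initialization.
#' @return A `net_config` object carrying the stream schedules.
#' @export
net_config <- function(input_size = 299, se_ratio = 16, block_dropout = 0.2,
                       head_dropout = 0.3, head_width = 2048,
                       merge = c("add", "concat"), seed = 42) {
  merge <- match.arg(merge)
  assert_that_(input_size >= 32, "`input_size` must be at least 32 px")
  shallow_filters <- c(64, 64, 128)
  deep_filters <- c(128, 256, 512, 1024)
  assert_that_(all(c(shallow_filters, deep_filters) %% se_ratio == 0),
               "`se_ratio` must divide every RSE filter count")
  structure(list(input_size = as.integer(input_size),
                 stem_filters = 64L,
                 shallow_filters = shallow_filters,
                 deep_filters = deep_filters,
                 se_ratio = se_ratio, block_dropout = block_dropout,
                 head_dropout = head_dropout,
                 head_width = as.integer(head_width),
                 merge = merge, seed = as.integer(seed)),
            class = "net_config")
}

#' Build the dual-stream network
#'
#' All weights are initialized deterministically from the configuration
#' seed (He-scaled Gaussians).
#'
#' @param config A [net_config()].
#' @return A `dsrsenet` model object.
#' @export
build_network <- function(config = net_config()) {
  assert_that_(inherits(config, "net_config"), "`config` must be a net_config")
  with_seed_(config$seed, {
    mk_stream <- function(filters, stem_stride, block_stride) {
      stream <- list(stem = init_conv(3, 3, config$stem_filters),
                     stem_bn = init_bn(config$stem_filters))
      stream$stem$stride <- as.integer(stem_stride)
      c_in <- config$stem_filters
      blocks <- list()
      for (i in seq_along(filters)) {
        blocks[[i]] <- init_rse(c_in, filters[i], config$se_ratio,
                                stride = block_stride, merge = config$merge)
        c_in <- if (config$merge == "add") filters[i] else c_in + filters[i]
      }
      stream$blocks <- blocks
      stream$cbam <- init_cbam(c_in, 16)
      stream$out_channels <- c_in
      stream
    }
    shallow <- mk_stream(config$shallow_filters, 1L, 1L)
    deep <- mk_stream(config$deep_filters, 2L, 2L)
    trunk_width <- shallow$out_channels + deep$out_channels
    params <- list(shallow = shallow, deep = deep,
                   feature_dense = init_dense_he(trunk_width,
                                                 config$head_width),
                   out_dense = init_dense_he(config$head_width, 1))
    structure(list(params = params, config = config,
                   trunk_width = trunk_width),
              class = "dsrsenet")
  })
}

#' Trainable parameter count of the network
#'
#' @param model A `dsrsenet` model.
#' @return Integer count of trainable parameters (batch-normalization
#'   running statistics excluded).
#' @export
count_params <- function(model) {
  assert_that_(inherits(model, "dsrsenet"), "`model` must be a dsrsenet")
  count_leaf_params(model$params)
}

#' @export
print.dsrsenet <- function(x, ...) {
  cat(sprintf(
    "<dsrsenet> input %dx%dx3, merge=%s, head %d | %.2fM trainable parameters\n",
    x$config$input_size, x$config$input_size, x$config$merge,
    x$config$head_width, count_params(x) / 1e6))
  invisible(x)
}

stream_forward <- function(x, stream) {
  a <- gelu(bn_apply(conv2d(x, stream$stem), stream$stem_bn))
  for (blk in stream$blocks) a <- rse_apply(a, blk)
  a <- cbam_apply(a, stream$cbam)
  channel_means(a)  # global average pooling
}

# Trunk forward: image -> concatenated GAP vector (pre-dense).
trunk_forward <- function(model, img) {
  d <- dim(img)
  s <- model$config$input_size
  assert_that_(length(d) == 3 && d[1] == s && d[2] == s && d[3] == 3,
               sprintf("input must be %d x %d x 3 (no silent resize)", s, s))
  c(stream_forward(img, model$params$shallow),
    stream_forward(img, model$params$deep))
}

head_features <- function(model, trunk_vec) {
  gelu(as.vector(trunk_vec %*% model$params$feature_dense$W) +
         model$params$feature_dense$b)
}

head_prob <- function(model, feat) {
  sigmoid(as.vector(feat %*% model$params$out_dense$W) +
            model$params$out_dense$b)
}

#' Full forward pass for one image
#'
#' @param model A `dsrsenet`.
#' @param img `input_size x input_size x 3` array in `[0, 1]`.
#' @return List with `trunk` (pooled stream concatenation), `features`
#'   (head-width deep feature vector) and `prob` (malignant probability from
#'   the training head).
#' @export
network_forward <- function(model, img) {
  tv <- trunk_forward(model, img)
  ft <- head_features(model, tv)
  list(trunk = tv, features = ft, prob = head_prob(model, ft))
}

#' Deep feature extraction
#'
#' Deterministic inference-mode forward pass; one row of the post-
#' concatenation dense layer activation per image, in input order.
#'
#' @param model A `dsrsenet`.
#' @param images List of `input_size x input_size x 3` arrays (or a single
#'   array). Inputs of any other size are rejected.
#' @return An `n x head_width` matrix (rows named by list names, if any).
#' @export
extract_features <- function(model, images) {
  if (!is.list(images)) images <- list(images)
  out <- matrix(NA_real_, length(images), model$config$head_width)
  for (i in seq_along(images)) {
    out[i, ] <- head_features(model, trunk_forward(model, images[[i]]))
  }
  rownames(out) <- names(images)
  colnames(out) <- sprintf("f%04d", seq_len(ncol(out)) - 1)
  out
}

#' Network training configuration
#'
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Epoch cap (default 100).
#' @param patience Early-stopping patience on validation accuracy
#'   (default 15).
#' @param seed Integer seed.
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 0.001, batch_size = 32, max_epochs = 100,
                         patience = 15, seed = 1) {
  assert_that_(lr > 0 && batch_size >= 1 && max_epochs >= 1 && patience >= 1,
               "training settings must be positive")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the network's dense head
#'
#' Desk-scale training strategy: the convolutional trunk keeps its seeded
#' initialization (a fixed random convolutional feature map) and the
#' post-concatenation dense layer plus the sigmoid output -- the layers that
#' define the extracted deep features -- are optimized with Adam on binary
#' cross-entropy, with dropout before the output dense and early stopping on
#' validation accuracy. Trunk activations are computed once per image and
#' cached, so training cost is independent of the trunk depth.
#'
#' @param model A `dsrsenet`.
#' @param images,labels Training images (list of arrays) and labels.
#' @param config A [train_config()].
#' @param val_images,val_labels Optional validation set for early stopping.
#' @return The model with trained head weights and a `history` tibble
#'   attached (per-epoch train/val loss and accuracy).
#' @export
train_network <- function(model, images, labels, config = train_config(),
                          val_images = NULL, val_labels = NULL) {
  assert_that_(length(images) > 0, "empty training split")
  y <- encode_labels(labels)
  TR <- t(vapply(images, function(im) trunk_forward(model, im),
                 numeric(model$trunk_width)))
  VA <- NULL; yv <- NULL
  if (!is.null(val_images)) {
    assert_that_(length(val_images) > 0, "empty validation split")
    VA <- t(vapply(val_images, function(im) trunk_forward(model, im),
                   numeric(model$trunk_width)))
    yv <- encode_labels(val_labels)
  }
  W1 <- model$params$feature_dense$W; b1 <- model$params$feature_dense$b
  W2 <- model$params$out_dense$W; b2 <- model$params$out_dense$b
  drop_p <- model$config$head_dropout
  fwd <- function(X, W1, b1, W2, b2) {
    Z <- sweep(X %*% W1, 2, b1, "+")
    H <- gelu(Z)
    p <- sigmoid(as.vector(H %*% W2) + b2)
    list(Z = Z, H = H, p = p)
  }
  n <- nrow(TR)
  with_seed_(config$seed, {
    adam <- lapply(list(W1, b1, W2, b2), function(x) list(m = x * 0, v = x * 0))
    t_step <- 0
    history <- list()
    best <- list(acc = -Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2, epoch = 0)
    stall <- 0
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(n)
      for (b in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
        X <- TR[b, , drop = FALSE]
        Z <- sweep(X %*% W1, 2, b1, "+")
        H <- gelu(Z)
        keep <- matrix(runif(length(H)) >= drop_p, nrow(H), ncol(H))
        Hd <- H * keep / (1 - drop_p)
        p <- sigmoid(as.vector(Hd %*% W2) + b2)
        dlog <- matrix((p - y[b]) / length(b), length(b), 1)
        gW2 <- crossprod(Hd, dlog)
        gb2 <- sum(dlog)
        dH <- (dlog %*% t(W2)) * keep / (1 - drop_p)
        dZ <- dH * (pnorm(Z) + Z * stats::dnorm(Z))  # GeLU derivative
        gW1 <- crossprod(X, dZ)
        gb1 <- colSums(dZ)
        t_step <- t_step + 1
        upd <- function(p, g, st) {
          st$m <- 0.9 * st$m + 0.1 * g
          st$v <- 0.999 * st$v + 0.001 * g^2
          mh <- st$m / (1 - 0.9^t_step)
          vh <- st$v / (1 - 0.999^t_step)
          list(p = p - config$lr * mh / (sqrt(vh) + 1e-8), st = st)
        }
        r <- upd(W1, gW1, adam[[1]]); W1 <- r$p; adam[[1]] <- r$st
        r <- upd(b1, gb1, adam[[2]]); b1 <- r$p; adam[[2]] <- r$st
        r <- upd(W2, gW2, adam[[3]]); W2 <- r$p; adam[[3]] <- r$st
        r <- upd(b2, gb2, adam[[4]]); b2 <- r$p; adam[[4]] <- r$st
      }
      tr_fw <- fwd(TR, W1, b1, W2, b2)
      train_loss <- bce_loss(tr_fw$p, y)
      train_acc <- mean((tr_fw$p > 0.5) == (y == 1))
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(VA)) {
        v_fw <- fwd(VA, W1, b1, W2, b2)
        val_loss <- bce_loss(v_fw$p, yv)
        val_acc <- mean((v_fw$p > 0.5) == (yv == 1))
        if (val_acc > best$acc) {
          best <- list(acc = val_acc, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                       epoch = epoch)
          stall <- 0
        } else {
          stall <- stall + 1
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_loss, train_acc = train_acc,
        val_loss = val_loss, val_acc = val_acc)
      if (!is.null(VA) && stall >= config$patience) break
    }
    if (!is.null(VA) && is.finite(best$acc)) {
      W1 <- best$W1; b1 <- best$b1; W2 <- best$W2; b2 <- best$b2
    }
    model$params$feature_dense <- list(W = W1, b = b1)
    model$params$out_dense <- list(W = W2, b = b2)
    model$history <- dplyr::bind_rows(history)
    model$best_epoch <- if (!is.null(VA)) best$epoch else NA_integer_
    model
  })
}

#' Per-epoch network training history
#' @param x A trained `dsrsenet`.
#' @param ... Unused.
#' @return Tibble of per-epoch losses/accuracies.
#' @method tidy dsrsenet
#' @export
tidy.dsrsenet <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                                train_acc = numeric(), val_loss = numeric(),
                                val_acc = numeric())
}

#' One-row network summary
#' @param x A `dsrsenet`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance dsrsenet
#' @export
glance.dsrsenet <- function(x, ...) {
  tibble::tibble(parameters = count_params(x),
                 head_width = x$config$head_width,
                 merge = x$config$merge,
                 epochs_trained = if (is.null(x$history)) 0L
                 else nrow(x$history))
}
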