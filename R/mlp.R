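# Multilayer perceptron binary classifier.
#
# Three ReLU hidden layers (128/64/32 by default), each followed by batch
# normalization and dropout, sigmoid output, binary cross-entropy loss,
# Adam optimizer, optional early stopping on validation accuracy. Written
# directly on matrix algebra so training stays fully deterministic under a
# seed.

#' MLP configuration
#'
#' @param hidden Hidden layer widths (default `c(128, 64, 32)`).
#' @param dropout Dropout rate per hidden layer, `[0, 1)` (default 0.3).
#' @param lr Adam learning rate (default 0.01, the fused-classifier setting;
#'   the network stage uses 0.001).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience on validation accuracy (used when
#'   a validation set is supplied).
#' @param standardize Z-score inputs using training-set statistics.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An `mlp_config` object.
#' @export
mlp_config <- function(hidden = c(128, 64, 32), dropout = 0.3, lr = 0.01,
                       batch_size = 32, max_epochs = 60, patience = 15,
                       standardize = TRUE, seed = 1) {
  assert_that_(all(hidden >= 1), "hidden widths must be positive")
  assert_that_(dropout >= 0 && dropout < 1, "dropout must lie in [0, 1)")
  assert_that_(lr > 0 && batch_size >= 1 && max_epochs >= 1 && patience >= 1,
               "optimizer settings must be positive")
  structure(list(hidden = hidden, dropout = dropout, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 standardize = standardize, seed = as.integer(seed)),
            class = "mlp_config")
}

# He-uniform initialization.
init_dense <- function(d_in, d_out) {
  lim <- sqrt(6 / d_in)
  list(W = matrix(runif(d_in * d_out, -lim, lim), d_in, d_out),
       b = rep(0, d_out))
}

init_mlp_params <- function(d, hidden) {
  dims <- c(d, hidden)
  layers <- lapply(seq_along(hidden), function(i) {
    c(init_dense(dims[i], dims[i + 1]),
      list(gamma = rep(1, dims[i + 1]), beta = rep(0, dims[i + 1]),
           run_mean = rep(0, dims[i + 1]), run_var = rep(1, dims[i + 1])))
  })
  list(layers = layers, out = init_dense(dims[length(dims)], 1))
}

# Forward pass. training = TRUE uses batch statistics and dropout and
# returns the caches needed for backprop.
mlp_forward <- function(params, X, dropout, training = FALSE, eps = 1e-5,
                        momentum = 0.9) {
  caches <- list()
  A <- X
  for (i in seq_along(params$layers)) {
    ly <- params$layers[[i]]
    Z <- sweep(A %*% ly$W, 2, ly$b, "+")
    if (training && nrow(Z) > 1) {
      mu <- colMeans(Z)
      v <- colMeans(sweep(Z, 2, mu, "-")^2)
      params$layers[[i]]$run_mean <- momentum * ly$run_mean + (1 - momentum) * mu
      params$layers[[i]]$run_var <- momentum * ly$run_var + (1 - momentum) * v
    } else {
      mu <- ly$run_mean
      v <- ly$run_var
    }
    inv_sd <- 1 / sqrt(v + eps)
    Zhat <- sweep(sweep(Z, 2, mu, "-"), 2, inv_sd, "*")
    Zbn <- sweep(sweep(Zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    H <- relu(Zbn)
    if (training && dropout > 0) {
      keep <- matrix(runif(length(H)) >= dropout, nrow(H), ncol(H))
      H <- H * keep / (1 - dropout)
    } else {
      keep <- NULL
    }
    caches[[i]] <- list(A = A, Z = Z, Zhat = Zhat, Zbn = Zbn, mu = mu,
                        inv_sd = inv_sd, keep = keep, batch_stats = training && nrow(Z) > 1)
    A <- H
  }
  logits <- sweep(A %*% params$out$W, 2, params$out$b, "+")
  p <- sigmoid(logits)
  list(p = as.vector(p), A_last = A, caches = caches, params = params)
}

# Backprop of mean BCE loss; returns gradients shaped like params.
mlp_backward <- function(params, fw, y, dropout) {
  n <- length(y)
  grads <- list(layers = vector("list", length(params$layers)), out = NULL)
  dlogits <- matrix((fw$p - y) / n, n, 1)
  grads$out <- list(W = crossprod(fw$A_last, dlogits),
                    b = colSums(dlogits))
  dA <- dlogits %*% t(params$out$W)
  for (i in rev(seq_along(params$layers))) {
    cache <- fw$caches[[i]]
    ly <- params$layers[[i]]
    if (!is.null(cache$keep)) dA <- dA * cache$keep / (1 - dropout)
    dZbn <- dA * (cache$Zbn > 0)
    dgamma <- colSums(dZbn * cache$Zhat)
    dbeta <- colSums(dZbn)
    dZhat <- sweep(dZbn, 2, ly$gamma, "*")
    if (cache$batch_stats) {
      m <- nrow(dZhat)
      sum_d <- colSums(dZhat)
      sum_dz <- colSums(dZhat * cache$Zhat)
      dZ <- sweep(dZhat, 2, sum_d / m, "-") -
        sweep(cache$Zhat, 2, sum_dz / m, "*")
      dZ <- sweep(dZ, 2, cache$inv_sd, "*")
    } else {
      dZ <- sweep(dZhat, 2, cache$inv_sd, "*")
    }
    grads$layers[[i]] <- list(W = crossprod(cache$A, dZ), b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    dA <- dZ %*% t(ly$W)
  }
  grads
}

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      nms <- names(p) %||% rep("", length(p))
      for (i in seq_along(p)) {
        if (nms[i] %in% c("run_mean", "run_var")) next  # not optimized
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      upd(p, g, m, v)
    }
  }
  walk(params, grads, state$m, state$v)
}

#' Train the MLP classifier
#'
#' @param x Feature matrix or tibble (n x d).
#' @param y Labels: factor/character with levels benign/malignant, or 0/1
#'   (1 = malignant). Both classes must appear at least twice.
#' @param config An [mlp_config()].
#' @param x_val,y_val Optional validation set; when given, training stops
#'   early after `patience` epochs without a validation-accuracy improvement
#'   and the best weights are restored.
#' @return An `mlp_model` with weights, training history and the
#'   preprocessing statistics.
#' @export
train_mlp <- function(x, y, config = mlp_config(), x_val = NULL,
                      y_val = NULL) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- encode_labels(y)
  assert_that_(length(unique(y)) == 2 && min(table(y)) >= 2,
               "need at least 2 samples of each class in the training split")
  center <- NULL; scale <- NULL
  if (config$standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
    X <- zscore_cols(X, center, scale)
  }
  XV <- NULL; yv <- NULL
  if (!is.null(x_val)) {
    XV <- as.matrix(x_val)
    if (config$standardize) XV <- zscore_cols(XV, center, scale)
    yv <- encode_labels(y_val)
  }
  n <- nrow(X)
  with_seed_(config$seed, {
    params <- init_mlp_params(ncol(X), config$hidden)
    state <- list(m = adam_init(params), v = adam_init(params))
    history <- list()
    best <- list(acc = -Inf, params = params, epoch = 0)
    stall <- 0
    t_step <- 0
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      for (b in batches) {
        fw <- mlp_forward(params, X[b, , drop = FALSE], config$dropout,
                          training = TRUE)
        params <- fw$params  # running-stat updates
        grads <- mlp_backward(params, fw, y[b], config$dropout)
        t_step <- t_step + 1
        r <- adam_update(params, grads, state, config$lr, t_step)
        params <- r$p; state <- list(m = r$m, v = r$v)
      }
      tr <- mlp_forward(params, X, 0, training = FALSE)
      train_loss <- bce_loss(tr$p, y)
      train_acc <- mean((tr$p > 0.5) == (y == 1))
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(XV)) {
        vl <- mlp_forward(params, XV, 0, training = FALSE)
        val_loss <- bce_loss(vl$p, yv)
        val_acc <- mean((vl$p > 0.5) == (yv == 1))
        if (val_acc > best$acc) {
          best <- list(acc = val_acc, params = params, epoch = epoch)
          stall <- 0
        } else {
          stall <- stall + 1
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_loss, train_acc = train_acc,
        val_loss = val_loss, val_acc = val_acc)
      if (!is.null(XV) && stall >= config$patience) break
    }
    if (!is.null(XV) && is.finite(best$acc)) params <- best$params
    structure(list(params = params, config = config,
                   center = center, scale = scale,
                   d_in = ncol(X), feature_names = colnames(X),
                   history = dplyr::bind_rows(history),
                   best_epoch = if (!is.null(XV)) best$epoch else NA_integer_),
              class = "mlp_model")
  })
}

bce_loss <- function(p, y) {
  p <- clamp(p, 1e-10, 1 - 1e-10)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

encode_labels <- function(y) {
  if (is.numeric(y)) {
    assert_that_(all(y %in% c(0, 1)), "numeric labels must be 0/1")
    return(as.integer(y))
  }
  y <- as.character(y)
  assert_that_(all(y %in% c("benign", "malignant")),
               "labels must be benign/malignant (or 0/1)")
  as.integer(y == "malignant")
}

#' Predict with a trained MLP
#'
#' @param object An `mlp_model`.
#' @param newdata Feature matrix/tibble with the training feature width.
#' @param threshold Probability cut for the malignant call (default 0.5;
#'   label is malignant when probability strictly exceeds it).
#' @param ... Unused.
#' @return A tibble with `prob` (malignant probability) and `label`.
#' @export
predict.mlp_model <- function(object, newdata, threshold = 0.5, ...) {
  X <- as.matrix(newdata)
  assert_that_(ncol(X) == object$d_in,
               "feature width does not match the training data")
  if (object$config$standardize) X <- zscore_cols(X, object$center, object$scale)
  p <- mlp_forward(object$params, X, 0, training = FALSE)$p
  tibble::tibble(prob = p,
                 label = factor(ifelse(p > threshold, "malignant", "benign"),
                                levels = c("benign", "malignant")))
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> hidden %s, %d epochs trained%s\n",
              paste(x$config$hidden, collapse = "-"),
              nrow(x$history),
              if (!is.na(x$best_epoch)) sprintf(" (best at %d)", x$best_epoch)
              else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of an MLP
#' @param x An `mlp_model`.
#' @param ... Unused.
#' @return Tibble with epoch, losses and accuracies.
#' @method tidy mlp_model
#' @export
tidy.mlp_model <- function(x, ...) x$history

#' One-row training summary of an MLP
#' @param x An `mlp_model`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance mlp_model
#' @export
glance.mlp_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), train_loss = last$train_loss,
                 train_acc = last$train_acc, val_acc = last$val_acc,
                 best_epoch = x$best_epoch)
}

#' Training-curve plot for an MLP
#' @param object An `mlp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mlp_model
#' @export
autoplot.mlp_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            dplyr::any_of(c("train_loss", "val_loss",
                                            "train_acc", "val_acc")),
                            names_to = "series", values_to = "value")
  df <- df[is.finite(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = NULL, colour = NULL)
}
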