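# OFS: relevance-score optimized feature selection on the fused
# handcrafted + deep feature table.
#
# Each feature's relevance is sigmoid(alpha * MI + beta * variance -
# gamma * redundancy), the three statistics min-max normalized across
# features; alpha/beta/gamma are tuned by an accuracy-driven update rule and
# k (the number of retained top-relevance features) by random search, with
# validation accuracy as the objective.

#' Fuse handcrafted and deep feature tables
#'
#' Column-wise concatenation with provenance tags; every column is z-scored
#' using training-split statistics (all rows when no split is given).
#'
#' @param handcrafted Tibble/matrix of selected handcrafted features.
#' @param deep Matrix/tibble of deep features (same row count; if both
#'   inputs carry an `id` column the ids must agree row-wise).
#' @param train_mask Optional logical/integer row subset whose statistics
#'   standardize all rows.
#' @return A tibble with `hc_*` then `deep_*` columns; provenance in
#'   attribute `provenance`.
#' @export
fuse_features <- function(handcrafted, deep, train_mask = NULL) {
  hid <- if (is.data.frame(handcrafted) && "id" %in% names(handcrafted))
    handcrafted$id else NULL
  did <- if (is.data.frame(deep) && "id" %in% names(deep)) deep$id else NULL
  if (!is.null(hid) && !is.null(did)) {
    assert_that_(identical(as.character(hid), as.character(did)),
                 "sample ids of the two feature blocks do not match")
  }
  drop_id <- function(x) {
    if (is.data.frame(x) && "id" %in% names(x)) x <- x[setdiff(names(x), "id")]
    as.matrix(x)
  }
  H <- drop_id(handcrafted)
  D <- drop_id(deep)
  assert_that_(nrow(H) == nrow(D), "row counts differ between feature blocks")
  colnames(H) <- paste0("hc_", sub("^hc_", "", colnames(H) %||%
                                    paste0("h", seq_len(ncol(H)))))
  colnames(D) <- paste0("deep_", sub("^deep_", "", colnames(D) %||%
                                       sprintf("f%04d", seq_len(ncol(D)))))
  X <- cbind(H, D)
  rows <- if (is.null(train_mask)) seq_len(nrow(X)) else train_mask
  center <- colMeans(X[rows, , drop = FALSE])
  scale <- apply(X[rows, , drop = FALSE], 2, sd)
  X <- zscore_cols(X, center, scale)
  out <- tibble::as_tibble(X)
  if (!is.null(hid)) out <- dplyr::bind_cols(tibble::tibble(id = hid), out)
  attr(out, "provenance") <- c(rep("handcrafted", ncol(H)),
                               rep("deep", ncol(D)))
  out
}

# MI / variance / max-|correlation| redundancy statistics, min-max
# normalized across features. Computed once per search on the training rows.
relevance_stats <- function(X, y, n_bins = 10) {
  X <- as.matrix(X)
  assert_that_(ncol(X) >= 2, "relevance scores need at least 2 features")
  mi <- mi_with_labels(X, y, n_bins)
  v <- apply(X, 2, var)
  cm <- suppressWarnings(abs(cor(X)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  rd <- apply(cm, 2, max)
  list(mi = minmax_norm(mi), v = minmax_norm(v), rd = minmax_norm(rd),
       raw = list(mi = mi, v = v, rd = rd))
}

#' Relevance scores of a feature table
#'
#' `R_i = sigmoid(alpha * MI_i + beta * v_i - gamma * Rd_i)` with MI against
#' the label, variance, and redundancy `Rd_i = max_{j != i} |cor(f_i, f_j)|`,
#' each min-max normalized across features before weighting.
#'
#' @param features Feature tibble/matrix (>= 2 columns).
#' @param labels Class labels.
#' @param alpha,beta,gamma Weights in `[0, 1]`.
#' @param n_bins MI estimator bins.
#' @return Named numeric vector of relevance scores in `(0, 1)`.
#' @export
relevance_scores <- function(features, labels, alpha, beta, gamma,
                             n_bins = 10) {
  assert_that_(all(c(alpha, beta, gamma) >= 0 & c(alpha, beta, gamma) <= 1),
               "alpha, beta, gamma must lie in [0, 1]")
  st <- relevance_stats(features, encode_labels(labels), n_bins)
  r <- sigmoid(alpha * st$mi + beta * st$v - gamma * st$rd)
  setNames(r, colnames(as.matrix(features)))
}

#' Accuracy-driven parameter update
#'
#' `delta_next = clip(delta_t + eta * (acc_t - acc_prev) * (delta_t -
#' delta_prev), 0, 1)`; the step grows with the accuracy change along the
#' direction of the last parameter move.
#'
#' @param delta_t,delta_prev Current and previous parameter values.
#' @param acc_t,acc_prev Current and previous objective accuracies.
#' @param eta Step scale (default 0.01).
#' @return Updated parameter value(s), clipped to `[0, 1]`.
#' @export
update_param <- function(delta_t, delta_prev, acc_t, acc_prev, eta = 0.01) {
  assert_that_(all(is.finite(c(delta_t, delta_prev, acc_t, acc_prev, eta))),
               "update_param inputs must be finite")
  clamp(delta_t + eta * (acc_t - acc_prev) * (delta_t - delta_prev), 0, 1)
}

#' Optimized feature selection search
#'
#' Random-search / update-rule tuning of (alpha, beta, gamma, k) on the
#' fused feature table: per iteration the current relevance weighting ranks
#' the features, the top-k are used to train the MLP on the training split,
#' and validation accuracy is the objective. On an improving iteration
#' alpha/beta/gamma move by the accuracy-driven drift of [update_param()]
#' (the first iteration uses a small random perturbation as the previous
#' step); on a failed iteration the weights are re-proposed by bounded
#' random search around the incumbent best -- the drift step alone is of
#' order `eta * dAcc * ddelta` and cannot leave an adverse initialization --
#' and k is re-drawn uniformly from `[2, d]`. The search stops
#' after `n_iter` iterations or `patience` iterations without improvement,
#' then reports test metrics of the best configuration.
#'
#' @param fused Fused feature tibble (from [fuse_features()]; an `id`
#'   column, if present, is ignored).
#' @param labels Class labels for all rows.
#' @param splits Either a character/factor vector (train/val/test per row)
#'   or a list with `train`, `val`, `test` index vectors.
#' @param n_iter Iteration budget (default 50).
#' @param patience Early-stopping patience on the best validation accuracy
#'   (default 15).
#' @param seed Integer seed for initialization and the random search.
#' @param config [mlp_config()] for the per-iteration classifiers.
#' @param n_bins MI estimator bins.
#' @return An `ofs_result`: `best` (alpha, beta, gamma, k, columns,
#'   val_accuracy), `history` tibble, `test_metrics`, `model` (the final
#'   MLP trained at the best configuration).
#' @export
ofs_search <- function(fused, labels, splits, n_iter = 50, patience = 15,
                       seed = 1, config = mlp_config(max_epochs = 25),
                       n_bins = 10) {
  X <- as.matrix(if (is.data.frame(fused) && "id" %in% names(fused))
    fused[setdiff(names(fused), "id")] else fused)
  y <- encode_labels(labels)
  idx <- resolve_splits(splits, nrow(X))
  d <- ncol(X)
  assert_that_(d >= 2, "need at least 2 fused features")
  st <- relevance_stats(X[idx$train, , drop = FALSE], y[idx$train], n_bins)
  eval_cfg <- function(delta, k) {
    r <- sigmoid(delta[1] * st$mi + delta[2] * st$v - delta[3] * st$rd)
    cols <- order(-r)[seq_len(k)]
    fit <- train_mlp(X[idx$train, cols, drop = FALSE], y[idx$train], config)
    pred <- predict(fit, X[idx$val, cols, drop = FALSE])
    acc <- mean((pred$prob > 0.5) == (y[idx$val] == 1))
    list(acc = acc, cols = cols, fit = fit)
  }
  with_seed_(seed, {
    delta <- runif(3)
    k <- if (d == 2) 2L else sample(2:d, 1)
    delta_prev <- clamp(delta + runif(3, -0.05, 0.05), 0, 1)
    acc_prev <- 0
    best <- list(acc = -Inf)
    stall <- 0
    history <- list()
    for (it in seq_len(n_iter)) {
      if (k > d) {
        warn("proposed k exceeds feature count; clamping to d")
        k <- d
      }
      ev <- eval_cfg(delta, k)
      improved <- ev$acc > best$acc
      if (improved) {
        best <- list(acc = ev$acc, alpha = delta[1], beta = delta[2],
                     gamma = delta[3], k = k, cols = ev$cols, fit = ev$fit,
                     iter = it)
        stall <- 0
      } else {
        stall <- stall + 1
      }
      history[[it]] <- tibble::tibble(
        iter = it, alpha = delta[1], beta = delta[2], gamma = delta[3],
        k = k, val_accuracy = ev$acc, best_accuracy = best$acc)
      if (stall >= patience) break
      drift <- update_param(delta, delta_prev, ev$acc, acc_prev)
      delta_prev <- delta
      acc_prev <- ev$acc
      if (improved) {
        delta <- drift
      } else {
        # the accuracy-driven drift step is O(eta * dAcc * ddelta) and
        # cannot escape an adverse initialization on its own, so failed
        # iterations also re-draw the weights by bounded random search
        # around the incumbent optimum (greedy acceptance, like k)
        anchor <- if (is.finite(best$acc)) {
          c(best$alpha, best$beta, best$gamma)
        } else {
          drift
        }
        delta <- clamp(anchor + runif(3, -0.15, 0.15), 0, 1)
        k <- if (d == 2) 2L else sample(2:d, 1)
      }
    }
  })
  cols <- best$cols
  pred_test <- predict(best$fit, X[idx$test, cols, drop = FALSE])
  test_metrics <- suppressWarnings(
    classification_metrics(y[idx$test], pred_test$label, pred_test$prob))
  feat_names <- colnames(X) %||% paste0("f", seq_len(d))
  structure(list(
    best = list(alpha = best$alpha, beta = best$beta, gamma = best$gamma,
                k = best$k, columns = feat_names[cols],
                val_accuracy = best$acc, iter = best$iter),
    history = dplyr::bind_rows(history),
    test_metrics = test_metrics,
    model = best$fit,
    column_index = cols,
    stats = st),
    class = "ofs_result")
}

resolve_splits <- function(splits, n) {
  if (is.list(splits) && all(c("train", "val", "test") %in% names(splits))) {
    return(splits[c("train", "val", "test")])
  }
  s <- as.character(splits)
  assert_that_(length(s) == n, "`splits` length must match the row count")
  assert_that_(all(c("train", "val", "test") %in% s),
               "`splits` must contain train, val and test rows")
  list(train = which(s == "train"), val = which(s == "val"),
       test = which(s == "test"))
}

#' @export
print.ofs_result <- function(x, ...) {
  cat(sprintf(
    "<ofs_result> best val accuracy %.3f at iter %d: alpha %.3f beta %.3f gamma %.3f, k = %d\n",
    x$best$val_accuracy, x$best$iter, x$best$alpha, x$best$beta,
    x$best$gamma, x$best$k))
  cat(sprintf("  test accuracy %.3f\n", x$test_metrics$accuracy))
  invisible(x)
}

#' Iteration history of an OFS search
#' @param x An `ofs_result`.
#' @param ... Unused.
#' @return Tibble with per-iteration parameters and accuracies.
#' @method tidy ofs_result
#' @export
tidy.ofs_result <- function(x, ...) x$history

#' One-row summary of an OFS search
#' @param x An `ofs_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance ofs_result
#' @export
glance.ofs_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(alpha = x$best$alpha, beta = x$best$beta,
                   gamma = x$best$gamma, k = x$best$k,
                   val_accuracy = x$best$val_accuracy,
                   iterations = nrow(x$history)),
    dplyr::rename_with(x$test_metrics, ~ paste0("test_", .x)))
}

#' Validation-accuracy trajectory of an OFS search
#' @param object An `ofs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ofs_result
#' @export
autoplot.ofs_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("val_accuracy", "best_accuracy"),
                            names_to = "series", values_to = "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iter, y = .data$accuracy,
                                   colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "iteration", colour = NULL)
}
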