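# SAMI: self-attention + mutual-information weighted feature ranking for
# the handcrafted block.
#
# Features act as attention tokens, each embedded by its standardized sample
# vector. Attention logits Q K' / sqrt(d_k) are biased additively by the
# symmetric pairwise feature-feature MI matrix before the row softmax; the
# output embedding norm of each feature, multiplied by the feature's MI with
# the class label, is its score (ranking and weighting combined). The
# projection matrices are fixed seeded random orthonormal maps -- they are
# not trained.

row_softmax <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

# Seeded random orthonormal projection (n x d_k), via QR of a Gaussian.
random_projection <- function(n, d_k, seed) {
  with_seed_(seed, {
    G <- matrix(rnorm(n * d_k), n, d_k)
    qr.Q(qr(G))[, seq_len(d_k), drop = FALSE]
  })
}

#' SAMI feature scores
#'
#' @param features Feature tibble/matrix (n samples x d features, d >= 2).
#' @param labels Class labels (benign/malignant or 0/1).
#' @param d_k Attention projection width; defaults to `min(64, n)` and must
#'   not exceed the sample count.
#' @param n_bins Bins for the MI estimator.
#' @param seed Seed for the fixed Q/K/V projections.
#' @return A `sami_scores` tibble with columns `feature`, `score`,
#'   `attention_norm`, `mi_label` and `rank` (1 = best); the attention
#'   weight matrix is attached as attribute `attention`.
#' @export
sami_scores <- function(features, labels, d_k = NULL, n_bins = 10, seed = 1) {
  X <- as.matrix(features)
  assert_that_(ncol(X) >= 2, "SAMI needs at least 2 features")
  n <- nrow(X)
  d <- ncol(X)
  d_k <- d_k %||% min(64L, n)
  assert_that_(d_k <= n, "`d_k` must not exceed the sample count")
  y <- encode_labels(labels)
  Xz <- zscore_cols(X)
  tokens <- t(Xz)  # d x n: one embedded token per feature
  WQ <- random_projection(n, d_k, sub_seed(seed, 1))
  WK <- random_projection(n, d_k, sub_seed(seed, 2))
  WV <- random_projection(n, d_k, sub_seed(seed, 3))
  Q <- tokens %*% WQ
  K <- tokens %*% WK
  V <- tokens %*% WV
  MI <- mi_matrix(Xz, n_bins)
  A <- row_softmax(Q %*% t(K) / sqrt(d_k) + MI)
  O <- A %*% V
  att_norm <- sqrt(rowSums(O^2))
  mi_y <- mi_with_labels(Xz, y, n_bins)
  score <- att_norm * mi_y
  out <- tibble::tibble(
    feature = colnames(X) %||% paste0("f", seq_len(d)),
    score = unname(score),
    attention_norm = unname(att_norm),
    mi_label = unname(mi_y)
  )
  out$rank <- rank(-out$score, ties.method = "first")
  attr(out, "attention") <- A
  class(out) <- c("sami_scores", class(out))
  out
}

#' Select-k-best over SAMI scores by cross-validated accuracy
#'
#' For each candidate `k`, the top-k features by SAMI score are evaluated
#' with a stratified 5-fold cross-validated MLP; the `k` maximizing mean
#' accuracy wins, ties going to the smaller `k`.
#'
#' @param features Feature tibble/matrix.
#' @param labels Class labels.
#' @param scores A [sami_scores()] result (or tibble with `feature`,
#'   `score`).
#' @param k_grid Candidate k values within `[2, d]` (default `2:d`).
#' @param cv Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param config [mlp_config()] for the fold models (a reduced-epoch
#'   configuration keeps the sweep fast).
#' @return A `sami_selection`: `chosen_k`, `selected` feature names,
#'   `per_k` tibble of mean CV accuracies, and the score table.
#' @export
select_k_best <- function(features, labels, scores, k_grid = NULL, cv = 5,
                          seed = 1,
                          config = mlp_config(max_epochs = 25, lr = 0.01)) {
  X <- as.matrix(features)
  d <- ncol(X)
  k_grid <- sort(unique(as.integer(k_grid %||% seq(2L, d))))
  assert_that_(length(k_grid) >= 1, "`k_grid` must be non-empty")
  assert_that_(all(k_grid >= 2 & k_grid <= d), "`k_grid` must lie in [2, d]")
  ord <- scores$feature[order(scores$rank)]
  per_k <- lapply(k_grid, function(k) {
    cols <- ord[seq_len(k)]
    cvr <- cross_validate(X[, cols, drop = FALSE], labels, config,
                          folds = cv, seed = seed)
    tibble::tibble(k = k, mean_accuracy = cvr$mean_accuracy,
                   sd_accuracy = cvr$sd_accuracy)
  })
  per_k <- dplyr::bind_rows(per_k)
  chosen <- per_k$k[which.max(per_k$mean_accuracy)]  # ties: first = smallest
  structure(list(chosen_k = chosen,
                 selected = ord[seq_len(chosen)],
                 per_k = per_k, scores = scores),
            class = "sami_selection")
}

#' @export
print.sami_selection <- function(x, ...) {
  cat(sprintf("<sami_selection> k = %d of %d features: %s\n",
              x$chosen_k, nrow(x$scores),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Accuracy-versus-k table of a SAMI selection
#' @param x A `sami_selection`.
#' @param ... Unused.
#' @return Tibble with k and mean/sd CV accuracy.
#' @method tidy sami_selection
#' @export
tidy.sami_selection <- function(x, ...) x$per_k

#' One-row summary of a SAMI selection
#' @param x A `sami_selection`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance sami_selection
#' @export
glance.sami_selection <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k,
                 best_accuracy = max(x$per_k$mean_accuracy),
                 n_features = nrow(x$scores))
}

#' Mean CV accuracy against number of selected features
#' @param object A `sami_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sami_selection
#' @export
autoplot.sami_selection <- function(object, ...) {
  ggplot2::ggplot(object$per_k,
                  ggplot2::aes(x = .data$k, y = .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::labs(x = "features kept (k)", y = "mean CV accuracy") +
    ggplot2::theme_minimal()
}
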