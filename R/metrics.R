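# Evaluation: confusion counts, binary and class-weighted metrics, ROC AUC,
# stratified cross-validation.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Confusion counts (positive = malignant)
#'
#' @param truth,estimate Label vectors (benign/malignant or 0/1), equal
#'   length.
#' @return Named list `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, estimate) {
  assert_that_(length(truth) == length(estimate) && length(truth) > 0,
               "`truth` and `estimate` must be non-empty and equal length")
  yt <- encode_labels(truth)
  yp <- encode_labels(estimate)
  list(tp = sum(yt == 1 & yp == 1), tn = sum(yt == 0 & yp == 0),
       fp = sum(yt == 0 & yp == 1), fn = sum(yt == 1 & yp == 0))
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warn(sprintf("%s undefined (zero denominator); returning 0", what))
    return(0)
  }
  num / den
}

# Mann-Whitney rank statistic; ties handled by midranks.
roc_auc <- function(truth, prob) {
  y <- encode_labels(truth)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics report
#'
#' Accuracy, precision, recall and F1 with malignant as the positive class,
#' their class-frequency-weighted variants, and (when probabilities are
#' supplied) the ROC AUC. Zero-denominator metrics are reported as 0 with a
#' warning. For a binary problem the weighted recall equals the accuracy.
#'
#' @param truth,estimate Label vectors.
#' @param prob Optional malignant-class probabilities for the AUC.
#' @return A one-row `metrics_report` tibble; the confusion counts ride
#'   along as attribute `counts`.
#' @export
classification_metrics <- function(truth, estimate, prob = NULL) {
  cc <- confusion_counts(truth, estimate)
  n <- cc$tp + cc$tn + cc$fp + cc$fn
  per_class <- function(tp, fp, fn) {
    prec <- safe_div(tp, tp + fp, "precision")
    rec <- safe_div(tp, tp + fn, "recall")
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }
  pos <- suppressWarnings(per_class(cc$tp, cc$fp, cc$fn))
  neg <- suppressWarnings(per_class(cc$tn, cc$fn, cc$fp))
  prec <- safe_div(cc$tp, cc$tp + cc$fp, "precision")
  rec <- safe_div(cc$tp, cc$tp + cc$fn, "recall")
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  w_pos <- (cc$tp + cc$fn) / n
  w_neg <- 1 - w_pos
  weighted <- w_pos * pos + w_neg * neg
  out <- tibble::tibble(
    accuracy = (cc$tp + cc$tn) / n,
    precision = prec, recall = rec, f1 = f1,
    precision_weighted = weighted[1],
    recall_weighted = weighted[2],
    f1_weighted = weighted[3],
    auc = if (is.null(prob)) NA_real_ else roc_auc(truth, prob)
  )
  attr(out, "counts") <- cc
  class(out) <- c("metrics_report", class(out))
  out
}

#' Stratified k-fold cross-validation of the MLP
#'
#' @param x Feature matrix/tibble.
#' @param y Labels (benign/malignant or 0/1).
#' @param config An [mlp_config()].
#' @param folds Number of folds (default 5); every class must have at least
#'   `folds` members.
#' @param seed Integer seed controlling the fold assignment.
#' @return A `cv_result`: `folds` tibble (per-fold metrics), `mean_accuracy`,
#'   `sd_accuracy`, `assignments`.
#' @export
cross_validate <- function(x, y, config = mlp_config(), folds = 5, seed = 1) {
  X <- as.matrix(x)
  yy <- encode_labels(y)
  assert_that_(min(table(yy)) >= folds,
               "every class needs at least `folds` samples")
  assign <- integer(length(yy))
  with_seed_(seed, {
    for (cls in unique(yy)) {
      rows <- which(yy == cls)
      rows <- rows[sample.int(length(rows))]
      assign[rows] <- rep(seq_len(folds), length.out = length(rows))
    }
  })
  fold_rows <- lapply(seq_len(folds), function(f) {
    tr <- which(assign != f)
    te <- which(assign == f)
    cfg <- config
    cfg$seed <- sub_seed(config$seed, f)
    fit <- train_mlp(X[tr, , drop = FALSE], yy[tr], cfg)
    pred <- predict(fit, X[te, , drop = FALSE])
    m <- suppressWarnings(
      classification_metrics(yy[te], pred$label, pred$prob))
    dplyr::bind_cols(tibble::tibble(fold = f), m)
  })
  folds_tb <- dplyr::bind_rows(fold_rows)
  structure(list(folds = folds_tb,
                 mean_accuracy = mean(folds_tb$accuracy),
                 sd_accuracy = sd(folds_tb$accuracy),
                 assignments = assign),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: mean accuracy %.3f (sd %.3f)\n",
              nrow(x$folds), x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Per-fold cross-validation metrics
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble of per-fold metrics.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' One-row cross-validation summary
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble with mean/sd accuracy.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(folds = nrow(x$folds), mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy)
}
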