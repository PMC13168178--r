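# End-to-end orchestration: preprocess -> handcrafted features -> SAMI ->
# deep features -> fusion -> OFS -> MLP -> test metrics.

#' Pipeline configuration
#'
#' Bundles the per-stage settings of the full hybrid pipeline. The defaults
#' follow the published study settings (handcrafted features at 256 px,
#' network input 299 px, SAMI select-k-best by 5-fold CV, OFS with 50
#' iterations and patience 15, MLP 128/64/32 at learning rate 0.01); the
#' sizes can be scaled down for desk-scale runs.
#'
#' @param seed Master seed; per-stage seeds derive from it.
#' @param image_size Resize target for handcrafted extraction (default 256).
#' @param net_input_size Network input side (default 299).
#' @param hair_removal Apply [dull_razor()] before feature extraction.
#' @param augment Balance the training split by augmented copies.
#' @param train_net Train the network head before deep-feature extraction
#'   (otherwise the seeded initialization is used as a fixed random feature
#'   extractor).
#' @param head_width Deep feature width (default 2048).
#' @param sami_k_grid Candidate k values for SAMI select-k-best (default
#'   `2:11`).
#' @param ofs_iter,ofs_patience OFS search budget (defaults 50 / 15).
#' @param selection_mlp [mlp_config()] used inside SAMI CV and the OFS loop
#'   (reduced epochs by default).
#' @param net_train [train_config()] for the network head.
#' @param corrected_red Use the sign-corrected red color rule.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1, image_size = 256, net_input_size = 299,
                            hair_removal = TRUE, augment = TRUE,
                            train_net = TRUE, head_width = 2048,
                            sami_k_grid = 2:11, ofs_iter = 50,
                            ofs_patience = 15,
                            selection_mlp = mlp_config(max_epochs = 25,
                                                       lr = 0.01),
                            net_train = train_config(),
                            corrected_red = FALSE) {
  structure(list(seed = as.integer(seed), image_size = as.integer(image_size),
                 net_input_size = as.integer(net_input_size),
                 hair_removal = hair_removal, augment = augment,
                 train_net = train_net, head_width = as.integer(head_width),
                 sami_k_grid = sami_k_grid, ofs_iter = as.integer(ofs_iter),
                 ofs_patience = as.integer(ofs_patience),
                 selection_mlp = selection_mlp, net_train = net_train,
                 corrected_red = corrected_red),
            class = "pipeline_config")
}

# Median-impute NA feature cells using training-row statistics.
impute_train_median <- function(X, train_rows) {
  for (j in seq_len(ncol(X))) {
    bad <- is.na(X[, j])
    if (any(bad)) {
      med <- median(X[train_rows, j], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      X[bad, j] <- med
    }
  }
  X
}

#' Run the full hybrid classification pipeline
#'
#' Preprocesses an in-memory dataset (hair removal, resize), splits it
#' 70/10/20 stratified, balances the training split by augmentation,
#' extracts the 11 handcrafted features and SAMI-selects among them, builds
#' (optionally trains) the dual-stream network and extracts deep features,
#' fuses both blocks, runs the OFS search, and reports test metrics.
#'
#' @param ds Dataset tibble with list-columns `image` and `mask`, plus
#'   `label` (benign/malignant) and optionally `id` (e.g. from
#'   [simulate_lesion_dataset()] or [load_dataset()]).
#' @param config A [pipeline_config()].
#' @return A `derma_report` list with every stage's selections, parameters
#'   and metrics.
#' @export
run_pipeline <- function(ds, config = pipeline_config()) {
  assert_that_(inherits(config, "pipeline_config"),
               "`config` must be a pipeline_config")
  assert_that_(all(c("image", "mask", "label") %in% names(ds)),
               "`ds` needs image, mask and label columns")
  if (!"id" %in% names(ds)) ds$id <- sprintf("img%04d", seq_len(nrow(ds)))
  stage <- function(what, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage [%s] failed: %s", what,
                    conditionMessage(e)))
    })
  }

  ds <- stage("preprocess", {
    ds$image <- lapply(ds$image, function(im) {
      im <- if (config$hair_removal) dull_razor(im) else im
      resize_image(im, config$image_size, config$image_size)
    })
    ds$mask <- lapply(ds$mask, function(m) {
      resize_image(m, config$image_size, config$image_size, mask = TRUE)
    })
    ds
  })

  ds <- stage("split", split_dataset(ds, seed = sub_seed(config$seed, 1)))

  train_ds <- ds[ds$split == "train", ]
  if (config$augment) {
    train_ds <- stage("augment", augment_balance(
      train_ds, augment_policy(seed = sub_seed(config$seed, 2))))
  }
  full <- dplyr::bind_rows(train_ds, ds[ds$split != "train", ])

  hand <- stage("handcrafted", handcrafted_table(
    full, corrected_red = config$corrected_red))
  hc_names <- handcrafted_feature_names()
  Xh <- as.matrix(hand[hc_names])
  train_rows <- which(full$split == "train")
  Xh <- impute_train_median(Xh, train_rows)

  sami <- stage("sami", {
    sc <- sami_scores(Xh[train_rows, , drop = FALSE],
                      full$label[train_rows],
                      seed = sub_seed(config$seed, 3))
    select_k_best(Xh[train_rows, , drop = FALSE], full$label[train_rows],
                  sc, k_grid = config$sami_k_grid,
                  seed = sub_seed(config$seed, 4),
                  config = config$selection_mlp)
  })

  net <- stage("network", {
    model <- build_network(net_config(
      input_size = config$net_input_size, head_width = config$head_width,
      seed = sub_seed(config$seed, 5)))
    net_imgs <- lapply(full$image, function(im) {
      resize_image(im, config$net_input_size, config$net_input_size)
    })
    if (config$train_net) {
      val_rows <- which(full$split == "val")
      cfg <- config$net_train
      cfg$seed <- sub_seed(config$seed, 6)
      model <- train_network(model, net_imgs[train_rows],
                             full$label[train_rows], cfg,
                             net_imgs[val_rows], full$label[val_rows])
    }
    list(model = model, features = extract_features(model, net_imgs))
  })

  fused <- stage("fusion", fuse_features(
    Xh[, sami$selected, drop = FALSE], net$features,
    train_mask = train_rows))

  ofs <- stage("ofs", ofs_search(
    fused, full$label, full$split, n_iter = config$ofs_iter,
    patience = config$ofs_patience, seed = sub_seed(config$seed, 7),
    config = config$selection_mlp))

  structure(list(
    config = config,
    split_counts = table(ds$split),
    n_augmented = sum(full$augmented %||% FALSE, na.rm = TRUE),
    sami = sami,
    network = list(parameters = count_params(net$model),
                   head_width = config$head_width,
                   trained = config$train_net,
                   history = net$model$history),
    ofs = ofs,
    selected_features = ofs$best$columns,
    test_metrics = ofs$test_metrics,
    handcrafted = dplyr::bind_cols(full[c("id", "label", "split")],
                                   tibble::as_tibble(Xh))),
    class = "derma_report")
}

#' @export
print.derma_report <- function(x, ...) {
  cat("<derma_report>\n")
  cat(sprintf("  splits: %s\n",
              paste(sprintf("%s=%d", names(x$split_counts), x$split_counts),
                    collapse = " ")))
  cat(sprintf("  SAMI: kept %d/11 handcrafted features (%s)\n",
              x$sami$chosen_k, paste(x$sami$selected, collapse = ", ")))
  cat(sprintf("  network: %.2fM parameters, %d-wide deep features%s\n",
              x$network$parameters / 1e6, x$network$head_width,
              if (x$network$trained) " (head trained)" else " (untrained)"))
  cat(sprintf("  OFS: alpha %.3f beta %.3f gamma %.3f, k = %d\n",
              x$ofs$best$alpha, x$ofs$best$beta, x$ofs$best$gamma,
              x$ofs$best$k))
  cat(sprintf("  test accuracy %.3f (weighted F1 %.3f)\n",
              x$test_metrics$accuracy, x$test_metrics$f1_weighted))
  invisible(x)
}

#' One-row pipeline summary
#' @param x A `derma_report`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance derma_report
#' @export
glance.derma_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sami_k = x$sami$chosen_k, ofs_k = x$ofs$best$k,
                   parameters = x$network$parameters),
    x$test_metrics)
}

#' Write a pipeline report to JSON
#'
#' @param report A `derma_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    splits = as.list(setNames(as.integer(report$split_counts),
                              names(report$split_counts))),
    n_augmented = report$n_augmented,
    sami = list(chosen_k = report$sami$chosen_k,
                selected = report$sami$selected,
                per_k = report$sami$per_k),
    network = list(parameters = report$network$parameters,
                   head_width = report$network$head_width,
                   trained = report$network$trained),
    ofs = list(alpha = report$ofs$best$alpha, beta = report$ofs$best$beta,
               gamma = report$ofs$best$gamma, k = report$ofs$best$k,
               val_accuracy = report$ofs$best$val_accuracy,
               selected_columns = report$selected_features,
               history = report$ofs$history),
    test_metrics = as.list(report$test_metrics))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
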