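# Mutual information, SAMI ranking, fusion, relevance scores and OFS.

test_that("the MI estimator matches closed forms and basic identities", {
  x <- rep(c(0, 1), 500)
  expect_equal(mutual_information(x, x), log(2), tolerance = 1e-12)
  withr::with_seed(5, {
    a <- rbinom(10000, 1, 0.5)
    b <- rbinom(10000, 1, 0.5)
  })
  expect_lte(mutual_information(a, b), 0.01)
  # direct four-term oracle on random 2x2 joint tables
  withr::with_seed(6, {
    for (i in 1:200) {
      p <- runif(4); p <- p / sum(p)
      joint <- matrix(p, 2, 2)
      expect_equal(dermafuse:::mi_from_joint(joint),
                   mi4_oracle(p[1], p[3], p[2], p[4]), tolerance = 1e-9)
    }
  })
  expect_equal(dermafuse:::mi_from_joint(matrix(c(.4, .1, .1, .4), 2)),
               0.1927, tolerance = 1e-3)
  # symmetry and a constant-variable warning
  withr::with_seed(7, {
    u <- rnorm(200); v <- u + rnorm(200)
  })
  expect_equal(mutual_information(u, v), mutual_information(v, u))
  expect_warning(z <- mutual_information(rep(1, 50), rnorm(50)), "constant")
  expect_equal(z, 0)
})

test_that("SAMI attention is normalized, equivariant and label-aware", {
  tab <- generate_feature_table(table_spec(
    n_samples = 500, n_informative = 3, n_redundant = 0, n_noise = 4,
    effect_size = 1.5, seed = 13))
  sc <- sami_scores(tab$features, tab$labels, seed = 2)
  A <- attr(sc, "attention")
  expect_equal(unname(rowSums(A)), rep(1, ncol(tab$features)), tolerance = 1e-9)
  # every pure-noise feature scores at most every informative feature
  noise_max <- max(sc$score[grepl("^noise", sc$feature)])
  inf_min <- min(sc$score[grepl("^inf", sc$feature)])
  expect_lte(noise_max, inf_min)
  # permuting the feature columns permutes scores identically
  perm <- c(4, 1, 7, 3, 2, 6, 5)
  sc_p <- sami_scores(tab$features[, perm], tab$labels, seed = 2)
  expect_equal(sc_p$score, sc$score[perm], tolerance = 1e-9)
  expect_error(sami_scores(tab$features, tab$labels, d_k = 1000), "sample count")
})

test_that("select-k-best recovers planted features and handles edge grids", {
  tab <- generate_feature_table(table_spec(
    n_samples = 300, n_informative = 3, n_redundant = 0, n_noise = 4,
    effect_size = 1.5, seed = 19))
  sc <- sami_scores(tab$features, tab$labels, seed = 3)
  sel <- select_k_best(tab$features, tab$labels, sc, k_grid = 2:5,
                       seed = 4, config = tiny_mlp())
  expect_true(all(c("inf01", "inf02", "inf03") %in% sel$selected))
  expect_equal(nrow(sel$per_k), 4)
  expect_true(all(sel$per_k$mean_accuracy >= 0 &
                    sel$per_k$mean_accuracy <= 1))
  # degenerate grid k = d selects everything
  sel_all <- select_k_best(tab$features, tab$labels, sc, k_grid = 7,
                           seed = 4, config = tiny_mlp())
  expect_setequal(sel_all$selected, names(tab$features))
  expect_error(select_k_best(tab$features, tab$labels, sc, k_grid = 1),
               "\\[2, d\\]")
})

test_that("fusion concatenates blocks with provenance and standardization", {
  withr::with_seed(8, {
    hand <- matrix(rnorm(10 * 6), 10, 6,
                   dimnames = list(NULL, paste0("h", 1:6)))
    deep <- matrix(rnorm(10 * 2048), 10, 2048)
  })
  fused <- fuse_features(hand, deep)
  expect_equal(ncol(fused), 2054)
  expect_equal(as.vector(table(attr(fused, "provenance"))[c("handcrafted", "deep")]),
               c(6L, 2048L))
  fused8 <- fuse_features(cbind(hand, h7 = rnorm(10), h8 = rnorm(10)), deep)
  expect_equal(ncol(fused8), 2056)
  # row order preserved: rank order of a column survives standardization
  expect_equal(order(fused$hc_h1), order(hand[, 1]))
  expect_error(
    fuse_features(dplyr::bind_cols(tibble::tibble(id = letters[1:10]),
                                   tibble::as_tibble(hand)),
                  dplyr::bind_cols(
                    tibble::tibble(id = letters[11:20]),
                    tibble::as_tibble(deep[, 1:5],
                                      .name_repair = ~ paste0("d", 1:5)))),
    "ids")
})

test_that("relevance scores respond to MI, variance and redundancy", {
  withr::with_seed(9, {
    base <- rnorm(300)
    y <- rbinom(300, 1, 0.5)
    X <- tibble::tibble(a = base, b = base + rnorm(300, sd = 0.01),
                        c = rnorm(300), d = rnorm(300) + y)
  })
  r0 <- relevance_scores(X, y, 0, 0, 0)
  expect_equal(unname(r0), rep(0.5, 4))
  r <- relevance_scores(X, y, 0.5, 0.2, 0.8)
  expect_true(all(r > 0 & r < 1))
  # duplicated pair is punished under gamma > 0
  expect_lt(r[["a"]], r[["c"]])
  expect_lt(r[["b"]], r[["c"]])
  # monotonicity by finite differences on the weights
  st <- dermafuse:::relevance_stats(as.matrix(X), y)
  i <- which.max(st$mi)
  up <- sigmoid(0.6 * st$mi + 0.2 * st$v - 0.2 * st$rd)
  dn <- sigmoid(0.4 * st$mi + 0.2 * st$v - 0.2 * st$rd)
  expect_gte(up[i], dn[i])
  expect_error(relevance_scores(X, y, 2, 0, 0), "\\[0, 1\\]")
})

test_that("the OFS update rule follows its closed form", {
  expect_equal(update_param(0.4, 0.2, 0.7, 0.7), 0.4)  # no accuracy change
  expect_equal(update_param(0.5, 0.3, 0.8, 0.7), 0.5002)
  expect_equal(update_param(1, 0, 1, 0, eta = 5), 1)  # clipped above
  expect_equal(update_param(0, 1, 1, 0, eta = 5), 0)  # clipped below
})

test_that("OFS is deterministic, keeps the best, and recovers planted columns", {
  tab <- generate_feature_table(table_spec(
    n_samples = 400, n_informative = 5, n_redundant = 5, n_noise = 30,
    effect_size = 1.2, seed = 23))
  splits <- split_dataset(dplyr::mutate(tab$features, label = tab$labels),
                          seed = 2)$split
  run <- function() ofs_search(tab$features, tab$labels, splits, n_iter = 12,
                               patience = 8, seed = 31, config = tiny_mlp())
  a <- run()
  b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$best[c("alpha", "beta", "gamma", "k")],
                   b$best[c("alpha", "beta", "gamma", "k")])
  expect_true(all(diff(a$history$best_accuracy) >= 0))
  # the selected set is dominated by signal-carrying columns (planted
  # informative features or their correlated copies)
  expect_gte(sum(grepl("^inf|^red", a$best$columns)), 4)
  expect_gte(a$test_metrics$accuracy, 0.8)
  expect_true(all(a$history$alpha >= 0 & a$history$alpha <= 1))
})

test_that("OFS on pure noise stays at chance-level validation accuracy", {
  tab <- generate_feature_table(table_spec(
    n_samples = 600, n_informative = 0, n_redundant = 0, n_noise = 12,
    seed = 41))
  splits <- split_dataset(dplyr::mutate(tab$features, label = tab$labels),
                          seed = 3)$split
  res <- ofs_search(tab$features, tab$labels, splits, n_iter = 6,
                    patience = 6, seed = 5, config = tiny_mlp())
  expect_gte(res$best$val_accuracy, 0.4)
  expect_lte(res$best$val_accuracy, 0.6)
})
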