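# Planted-ground-truth tabular generator used to exercise the feature
# selection stages: informative columns separate the classes by a known
# standardized effect, redundant columns are noisy copies of informative
# ones at a target correlation, noise columns are independent of the label.

#' Specification for a planted feature table
#'
#' @param n_samples Number of rows (balanced classes). At least 10.
#' @param n_informative,n_redundant,n_noise Column counts by role.
#' @param effect_size Standardized mean difference between classes for each
#'   informative column.
#' @param redundancy_corr Target Pearson correlation between each redundant
#'   column and its informative parent.
#' @param seed Integer seed.
#' @return A `table_spec` object.
#' @export
table_spec <- function(n_samples = 200, n_informative = 3, n_redundant = 2,
                       n_noise = 5, effect_size = 1.5, redundancy_corr = 0.9,
                       seed = 1) {
  assert_that_(is_scalar_number(n_samples) && n_samples >= 10,
               "`n_samples` must be at least 10")
  assert_that_(n_informative >= 0 && n_redundant >= 0 && n_noise >= 0,
               "column counts must be non-negative")
  assert_that_(n_informative + n_redundant + n_noise >= 1,
               "at least one feature column required")
  assert_that_(n_redundant == 0 || n_informative >= 1,
               "redundant columns need at least one informative parent")
  assert_that_(redundancy_corr > 0 && redundancy_corr < 1,
               "`redundancy_corr` must lie in (0, 1)")
  structure(
    list(n_samples = as.integer(n_samples),
         n_informative = as.integer(n_informative),
         n_redundant = as.integer(n_redundant),
         n_noise = as.integer(n_noise),
         effect_size = effect_size, redundancy_corr = redundancy_corr,
         seed = as.integer(seed)),
    class = "table_spec")
}

#' Generate a planted feature table
#'
#' @param spec A [table_spec()].
#' @return A list with `features` (tibble, columns named `inf*`, `red*`,
#'   `noise*`), `labels` (factor benign/malignant, balanced) and
#'   `informative` (named logical mask over columns).
#' @export
generate_feature_table <- function(spec) {
  assert_that_(inherits(spec, "table_spec"), "`spec` must be a table_spec")
  n <- spec$n_samples
  with_seed_(spec$seed, {
    labels <- sample(rep(c("benign", "malignant"), length.out = n))
    y <- as.integer(labels == "malignant")
    cols <- list()
    parents <- matrix(NA_real_, n, max(1L, spec$n_informative))
    for (i in seq_len(spec$n_informative)) {
      x <- rnorm(n) + (y - 0.5) * spec$effect_size
      parents[, i] <- x
      cols[[sprintf("inf%02d", i)]] <- x
    }
    for (i in seq_len(spec$n_redundant)) {
      parent_idx <- ((i - 1) %% spec$n_informative) + 1
      p <- parents[, parent_idx]
      rho <- spec$redundancy_corr
      noise_sd <- sd(p) * sqrt(1 / rho^2 - 1)
      cols[[sprintf("red%02d", i)]] <- p + rnorm(n, sd = noise_sd)
    }
    for (i in seq_len(spec$n_noise)) {
      cols[[sprintf("noise%02d", i)]] <- rnorm(n)
    }
    features <- tibble::as_tibble(cols)
    informative <- grepl("^inf", names(features))
    names(informative) <- names(features)
    list(features = features,
         labels = factor(labels, levels = c("benign", "malignant")),
         informative = informative,
         spec = spec)
  })
}
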