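# Plug-in mutual information with equal-frequency discretization.

# Discretize a variable for histogram MI: continuous vectors are cut at
# equal-frequency (quantile) breakpoints; variables with few distinct values
# are used as-is.
discretize_ef <- function(x, n_bins = 10) {
  ux <- unique(x)
  if (!is.numeric(x) || length(ux) <= n_bins) return(as.integer(factor(x)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) return(as.integer(factor(x)))
  br[1] <- -Inf; br[length(br)] <- Inf
  as.integer(cut(x, breaks = br))
}

#' Mutual information between two variables
#'
#' Plug-in estimate `sum p(x, y) log(p(x, y) / (p(x) p(y)))` in nats from the
#' joint histogram after equal-frequency binning of continuous inputs.
#' Symmetric and non-negative; a constant variable carries no information
#' and returns 0 with a warning.
#'
#' @param x,y Vectors of equal length (>= 10). Factors/characters are used
#'   as discrete variables directly.
#' @param n_bins Number of equal-frequency bins for continuous variables
#'   (default 10, minimum 2).
#' @return Mutual information in nats.
#' @export
mutual_information <- function(x, y, n_bins = 10) {
  assert_that_(length(x) == length(y), "`x` and `y` must have equal length")
  assert_that_(length(x) >= 10, "need at least 10 observations")
  assert_that_(n_bins >= 2, "`n_bins` must be at least 2")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warn("constant variable: mutual information is 0")
    return(0)
  }
  xi <- discretize_ef(x, n_bins)
  yi <- discretize_ef(y, n_bins)
  joint <- table(xi, yi) / length(xi)
  mi_from_joint(joint)
}

# MI in nats of a joint probability table.
mi_from_joint <- function(joint) {
  joint <- as.matrix(joint)
  px <- rowSums(joint)
  py <- colSums(joint)
  outerp <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outerp[nz]))
}

# MI of every column of X with the label vector.
mi_with_labels <- function(X, y, n_bins = 10) {
  X <- as.matrix(X)
  apply(X, 2, function(col) {
    if (length(unique(col)) < 2) return(0)
    mutual_information(col, y, n_bins)
  })
}

# Symmetric pairwise feature-feature MI matrix.
mi_matrix <- function(X, n_bins = 10) {
  X <- as.matrix(X)
  d <- ncol(X)
  disc <- lapply(seq_len(d), function(j) discretize_ef(X[, j], n_bins))
  M <- matrix(0, d, d, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(d)) {
    for (j in i:d) {
      joint <- table(disc[[i]], disc[[j]]) / length(disc[[i]])
      M[i, j] <- M[j, i] <- mi_from_joint(joint)
    }
  }
  M
}
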