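# Auxiliary shape descriptors feeding the border-irregularity clustering:
# box-counting fractal dimension, Zernike moment magnitudes, circularity,
# solidity, convexity and eccentricity.

# Chain-code perimeter with Vossepoel-Smeulders step weights (0.948 for
# axial, 1.343 for diagonal moves), which debiases the staircase
# overestimate of rasterized smooth boundaries; non-unit steps fall back to
# their Euclidean length.
chain_perimeter <- function(pts) {
  n <- nrow(pts)
  d <- abs(pts - pts[c(2:n, 1), , drop = FALSE])
  axial <- d[, 1] + d[, 2] == 1
  diagonal <- d[, 1] == 1 & d[, 2] == 1
  other <- !(axial | diagonal)
  sum(0.948 * axial + 1.343 * diagonal) +
    sum(sqrt(d[other, 1]^2 + d[other, 2]^2))
}

# 4-neighbour binary erosion (used to isolate the 1-px contour band).
erode4 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], 0)
  dn <- rbind(0, mask[-n, , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], 0)
  rt <- cbind(0, mask[, -m, drop = FALSE])
  (mask & up & dn & lf & rt) * 1L
}

#' Box-counting fractal dimension of a mask outline
#'
#' Counts occupied boxes of the contour image over dyadic box sizes
#' `2, 4, 8, ..., min(H, W) / 4` and returns the least-squares slope of
#' `log N` against `log(1 / s)`.
#'
#' @param mask H x W 0/1 matrix.
#' @return Fractal dimension estimate (about 1 for smooth outlines).
#' @export
fractal_dimension <- function(mask) {
  assert_that_(sum(mask) > 0, "empty mask")
  edge <- mask - erode4(mask)
  idx <- which(edge == 1, arr.ind = TRUE)
  smax <- min(dim(mask)) / 4
  sizes <- 2^(1:floor(log2(smax)))
  assert_that_(length(sizes) >= 2, "mask too small for box counting")
  counts <- vapply(sizes, function(s) {
    boxes <- paste(ceiling(idx[, 1] / s), ceiling(idx[, 2] / s))
    length(unique(boxes))
  }, numeric(1))
  unname(coef(lm(log(counts) ~ log(1 / sizes)))[2])
}

# Radial Zernike polynomial R_nm(rho) for m >= 0, (n - m) even.
zernike_radial <- function(n, m, rho) {
  k <- 0:((n - m) / 2)
  coefs <- (-1)^k * factorial(n - k) /
    (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k))
  out <- numeric(length(rho))
  for (i in seq_along(k)) out <- out + coefs[i] * rho^(n - 2 * k[i])
  out
}

#' Zernike moment magnitudes of a binary mask
#'
#' Magnitudes `|Z_nm|` up to radial order `order` (m >= 0, n - m even),
#' computed on the unit disk circumscribing the mask about its centroid.
#' Magnitudes are rotation-invariant shape descriptors.
#'
#' @param mask H x W 0/1 matrix.
#' @param order Maximum radial order (default 8).
#' @return Named numeric vector `zernike_<n><m>`.
#' @export
zernike_moments <- function(mask, order = 8) {
  idx <- which(mask == 1, arr.ind = TRUE)
  assert_that_(nrow(idx) > 0, "empty mask")
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  dy <- idx[, 1] - cy; dx <- idx[, 2] - cx
  radius <- max(sqrt(dx^2 + dy^2)) + 0.5
  rho <- sqrt(dx^2 + dy^2) / radius
  theta <- atan2(dy, dx)
  scale <- 1 / radius^2  # pixel area on the unit disk
  out <- c()
  for (n in 0:order) {
    for (m in seq(n %% 2, n, by = 2)) {
      rad <- zernike_radial(n, m, rho)
      re <- sum(rad * cos(m * theta)) * scale
      im <- -sum(rad * sin(m * theta)) * scale
      z <- (n + 1) / pi * complex(real = re, imaginary = im)
      out[sprintf("zernike_%d%d", n, m)] <- Mod(z)
    }
  }
  out
}

#' Auxiliary shape features of a lesion mask
#'
#' @param mask H x W 0/1 matrix.
#' @param zernike_order Maximum Zernike radial order.
#' @return One-row tibble: `fractal_dim`, `circularity` (4 pi A / P^2),
#'   `solidity` (A / A_hull), `convexity` (P_hull / P), `eccentricity`
#'   (from the ellipse fit) and the Zernike magnitude columns.
#' @export
aux_shape_features <- function(mask, zernike_order = 8) {
  assert_that_(sum(mask) > 0, "empty mask")
  if (any(mask[1, ] == 1) || any(mask[nrow(mask), ] == 1) ||
      any(mask[, 1] == 1) || any(mask[, ncol(mask)] == 1)) {
    warn("mask touches the image border; contour features may be clipped")
  }
  contour <- extract_contour(mask)
  pts <- as.matrix(as.data.frame(contour)[, c("x", "y")])
  per <- chain_perimeter(pts)
  area <- sum(mask)
  hull_idx <- chull(pts)
  hull <- pts[hull_idx, , drop = FALSE]
  hull_area <- polygon_area(hull)
  nh <- nrow(hull)
  hull_per <- sum(sqrt(rowSums((hull - hull[c(2:nh, 1), ])^2)))
  fit <- fit_ellipse(contour)
  ecc <- sqrt(1 - (fit$semi_axes[2] / fit$semi_axes[1])^2)
  zk <- zernike_moments(mask, zernike_order)
  tibble::tibble(
    fractal_dim = fractal_dimension(mask),
    circularity = min(4 * pi * area / per^2, 1.05),
    solidity = min(area / max(hull_area, 1), 1),
    convexity = min(hull_per / per, 1),
    eccentricity = unname(ecc),
    !!!as.list(zk)
  )
}

#' Cluster lesions into regular / irregular border classes
#'
#' Standardizes the feature columns, runs 2-means with a deterministic
#' initialization (the rows with the smallest and largest standardized
#' |delta_area| seed the two centres, Lloyd iterations), and labels the
#' cluster with the larger mean |delta_area| as "irregular".
#'
#' @param features Tibble of per-lesion border features; must contain a
#'   `delta_area` column plus any numeric shape descriptors. At least 4 rows.
#' @return A `border_classes` list: `labels` (factor regular/irregular, one
#'   per row), `kmeans` (the fitted object), `dropped` (zero-variance columns
#'   removed).
#' @export
classify_borders <- function(features) {
  assert_that_(nrow(features) >= 4, "need at least 4 lesions to cluster")
  assert_that_("delta_area" %in% names(features),
               "`features` must contain a delta_area column")
  num <- features[vapply(features, is.numeric, logical(1))]
  sds <- vapply(num, sd, numeric(1))
  dropped <- names(num)[!is.finite(sds) | sds < 1e-12]
  if (length(dropped) > 0) {
    warn(paste("dropping zero-variance feature columns:",
               paste(dropped, collapse = ", ")))
    num <- num[setdiff(names(num), dropped)]
  }
  assert_that_(ncol(num) >= 1,
               "degenerate input: all feature columns are constant")
  z <- zscore_cols(as.matrix(num))
  da <- abs(features$delta_area)
  # deterministic, permutation-invariant initialization: centres of the
  # |delta_area| median split (the primary irregularity axis)
  lo <- da <= median(da)
  if (all(lo) || !any(lo)) lo <- seq_along(da) <= length(da) / 2
  centers <- rbind(colMeans(z[lo, , drop = FALSE]),
                   colMeans(z[!lo, , drop = FALSE]))
  assert_that_(!isTRUE(all.equal(centers[1, ], centers[2, ])),
               "degenerate input: identical feature rows")
  km <- suppressWarnings(kmeans(z, centers = centers, iter.max = 100,
                                algorithm = "Lloyd"))
  mean_da <- tapply(da, km$cluster, mean)
  irregular_cluster <- as.integer(names(mean_da)[which.max(mean_da)])
  labels <- factor(ifelse(km$cluster == irregular_cluster,
                          "irregular", "regular"),
                   levels = c("regular", "irregular"))
  structure(list(labels = labels, kmeans = km, dropped = dropped),
            class = "border_classes")
}
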