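# Preprocessing: resizing, dull-razor hair removal, stratified splitting and
# class-balancing augmentation.

#' Resize an image or mask
#'
#' Images are resampled bilinearly; masks (`mask = TRUE`) use nearest
#' neighbour and are re-binarized so the output stays strictly 0/1.
#'
#' @param img H x W x 3 array or H x W matrix.
#' @param height,width Target size in pixels (positive).
#' @param mask Treat `img` as a binary mask.
#' @return The resized array/matrix.
#' @export
resize_image <- function(img, height, width, mask = FALSE) {
  assert_that_(length(img) > 0, "`img` must be non-empty")
  assert_that_(height >= 1 && width >= 1, "target size must be positive")
  d <- dim(img)
  if (d[1] == height && d[2] == width) return(img)
  out <- from_ebimage(EBImage::resize(as_ebimage(img), w = width, h = height,
                                      filter = if (mask) "none" else "bilinear"))
  if (mask) out <- (out > 0.5) * 1L
  out
}

# Grayscale morphology with a cross structuring element, via the identity
# dilate(A, H union V) = max(dilate(A, H), dilate(A, V)) for the horizontal
# and vertical arms (and min for erosion). Edge handling replicates borders.
gray_morph_cross <- function(x, size, op = c("dilate", "erode")) {
  op <- match.arg(op)
  half <- (size - 1) %/% 2
  n <- nrow(x); m <- ncol(x)
  comb <- if (op == "dilate") pmax else pmin
  run <- x
  for (k in seq_len(half)) {
    up <- x[clamp(seq_len(n) - k, 1, n), , drop = FALSE]
    dn <- x[clamp(seq_len(n) + k, 1, n), , drop = FALSE]
    run <- comb(run, up, dn)
  }
  runh <- x
  for (k in seq_len(half)) {
    lf <- x[, clamp(seq_len(m) - k, 1, m), drop = FALSE]
    rt <- x[, clamp(seq_len(m) + k, 1, m), drop = FALSE]
    runh <- comb(runh, lf, rt)
  }
  comb(run, runh)
}

#' Dull-razor hair removal
#'
#' Classical pipeline: grayscale, morphological blackhat with a cross
#' structuring element, fixed threshold, diffusion inpainting of the flagged
#' pixels. An image without hair-like dark curvilinear structures passes
#' through essentially unchanged.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param kernel_size Side of the cross structuring element (default 17).
#' @param threshold Blackhat threshold on the 0-255 intensity scale
#'   (default 10).
#' @param inpaint_radius Dilation radius applied to the hair mask before
#'   inpainting so anti-aliased stroke fringes are covered (default 3).
#' @return The inpainted image, same shape, with the detected hair mask as
#'   attribute `hair_mask`.
#' @export
dull_razor <- function(img, kernel_size = 17, threshold = 10,
                       inpaint_radius = 3) {
  assert_that_(length(dim(img)) == 3 && dim(img)[3] == 3,
               "`img` must be a 3-channel array")
  gray <- rgb_to_gray(img)
  closed <- gray_morph_cross(gray_morph_cross(gray, kernel_size, "dilate"),
                             kernel_size, "erode")
  blackhat <- closed - gray
  hair <- blackhat > threshold / 255
  out <- img
  if (any(hair)) {
    brush_size <- 2 * floor(inpaint_radius / 2) + 1
    fill <- from_ebimage(EBImage::dilate(
      as_ebimage(hair * 1), EBImage::makeBrush(brush_size, "disc"))) > 0.5
    for (ch in 1:3) out[, , ch] <- diffuse_inpaint(out[, , ch], fill)
  }
  attr(out, "hair_mask") <- hair * 1L
  out
}

# Jacobi diffusion fill of `mask` pixels from their 4-neighbourhood.
diffuse_inpaint <- function(plane, mask, max_iter = 400, tol = 1e-5) {
  n <- nrow(plane); m <- ncol(plane)
  known_mean <- mean(plane[!mask])
  plane[mask] <- known_mean
  idx_up <- clamp(seq_len(n) - 1, 1, n)
  idx_dn <- clamp(seq_len(n) + 1, 1, n)
  idx_lf <- clamp(seq_len(m) - 1, 1, m)
  idx_rt <- clamp(seq_len(m) + 1, 1, m)
  for (it in seq_len(max_iter)) {
    nb <- (plane[idx_up, ] + plane[idx_dn, ] +
             plane[, idx_lf] + plane[, idx_rt]) / 4
    delta <- max(abs(nb[mask] - plane[mask]))
    plane[mask] <- nb[mask]
    if (delta < tol) break
  }
  plane
}

# Largest-remainder apportionment of n into fractions, ties resolved in the
# order of `fracs` (train first).
apportion <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(-(raw - base), seq_along(fracs))
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  base
}

#' Stratified train/validation/test split
#'
#' Assigns each record to train/val/test at the requested fractions,
#' stratified by label: per-class quotas come from largest-remainder
#' apportionment and are then repaired so the global counts equal the
#' largest-remainder apportionment of the full dataset.
#'
#' @param manifest Tibble with a `label` column (two classes present) and at
#'   least 10 rows.
#' @param seed Integer seed (determines the within-class shuffling).
#' @param fractions Named numeric `c(train =, val =, test =)`, summing to 1.
#' @return The manifest with a `split` factor column.
#' @export
split_dataset <- function(manifest, seed = 1,
                          fractions = c(train = 0.7, val = 0.1, test = 0.2)) {
  assert_that_(nrow(manifest) >= 10, "need at least 10 records to split")
  assert_that_(abs(sum(fractions) - 1) < 1e-8, "fractions must sum to 1")
  labs <- as.character(manifest$label)
  assert_that_(length(unique(labs)) >= 2,
               "single-class manifest cannot be split with stratification")
  if ("image" %in% names(manifest) && !is.list(manifest$image)) {
    assert_that_(!anyDuplicated(manifest$image),
                 "duplicate image paths in manifest")
  }
  classes <- sort(unique(labs))
  global <- apportion(nrow(manifest), fractions)
  quotas <- t(vapply(classes,
                     function(cl) apportion(sum(labs == cl), fractions),
                     numeric(3)))
  colnames(quotas) <- names(fractions)
  # repair global totals: move one record at a time from an over-full split
  # to an under-full one, taking it from the class with the largest count
  for (guard in seq_len(nrow(manifest))) {
    excess <- colSums(quotas) - global
    if (all(excess == 0)) break
    s_from <- which.max(excess)
    s_to <- which.min(excess)
    cl <- which.max(quotas[, s_from])
    quotas[cl, s_from] <- quotas[cl, s_from] - 1
    quotas[cl, s_to] <- quotas[cl, s_to] + 1
  }
  split <- character(nrow(manifest))
  with_seed_(seed, {
    for (ci in seq_along(classes)) {
      rows <- which(labs == classes[ci])
      rows <- rows[sample.int(length(rows))]
      q <- quotas[ci, ]
      split[rows] <- rep(names(fractions), times = q)
    }
  })
  manifest$split <- factor(split, levels = names(fractions))
  manifest
}

#' Augmentation policy
#'
#' Probabilities follow the study defaults: rotation applied with
#' probability 0.7, zoom and horizontal flip with probability 0.3 each.
#' Magnitudes (rotation range, zoom interval) are configuration choices.
#'
#' @param p_rotation,p_zoom,p_flip Application probabilities in `[0, 1]`.
#' @param rotation_range Max absolute rotation, degrees.
#' @param zoom_range Length-2 scale interval.
#' @param seed Integer seed.
#' @return An `augment_policy` object.
#' @export
augment_policy <- function(p_rotation = 0.7, p_zoom = 0.3, p_flip = 0.3,
                           rotation_range = 45, zoom_range = c(0.8, 1.2),
                           seed = 1) {
  probs <- c(p_rotation, p_zoom, p_flip)
  assert_that_(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  assert_that_(length(zoom_range) == 2 && zoom_range[1] <= zoom_range[2],
               "`zoom_range` must be an increasing length-2 interval")
  structure(list(p_rotation = p_rotation, p_zoom = p_zoom, p_flip = p_flip,
                 rotation_range = rotation_range, zoom_range = zoom_range,
                 seed = as.integer(seed)),
            class = "augment_policy")
}

# Apply one sampled geometric transform to an image (bilinear) or mask
# (nearest + re-binarize). Zoom resizes about the centre and crops/pads back
# to the original frame.
apply_augment <- function(img, ops, mask = FALSE) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  filt <- if (mask) "none" else "bilinear"
  x <- img
  if (ops$flipped) {
    x <- if (length(d) == 3) x[, w:1, , drop = FALSE] else x[, w:1, drop = FALSE]
  }
  if (ops$rotated) {
    e <- EBImage::rotate(as_ebimage(x), ops$rotation_deg, filter = filt,
                         output.dim = c(w, h), bg.col = "black")
    x <- from_ebimage(e)
  }
  if (ops$zoomed) {
    nh <- max(2L, round(h * ops$zoom_factor))
    nw <- max(2L, round(w * ops$zoom_factor))
    z <- from_ebimage(EBImage::resize(as_ebimage(x), w = nw, h = nh,
                                      filter = filt))
    if (nh >= h) {
      r0 <- floor((nh - h) / 2); c0 <- floor((nw - w) / 2)
      x <- if (length(d) == 3) z[r0 + seq_len(h), c0 + seq_len(w), , drop = FALSE]
           else z[r0 + seq_len(h), c0 + seq_len(w), drop = FALSE]
    } else {
      pad <- if (length(d) == 3) array(0, dim = d) else matrix(0, h, w)
      r0 <- floor((h - nh) / 2); c0 <- floor((w - nw) / 2)
      if (length(d) == 3) pad[r0 + seq_len(nh), c0 + seq_len(nw), ] <- z
      else pad[r0 + seq_len(nh), c0 + seq_len(nw)] <- z
      x <- pad
    }
  }
  if (mask) x <- (x > 0.5) * 1L
  x
}

#' Balance a training set by augmented minority-class copies
#'
#' Up-samples the minority class with geometrically transformed copies
#' (rotation/zoom/horizontal flip, each applied with its policy probability,
#' image and mask receiving the identical transform) until class counts are
#' equal. Only the training split may be augmented.
#'
#' @param ds In-memory dataset tibble with list-columns `image` and `mask`,
#'   a `label` column, and (if present) a `split` column equal to "train".
#' @param policy An [augment_policy()].
#' @return The dataset with augmented rows appended; new rows carry
#'   `augmented = TRUE` plus the applied transform parameters.
#' @export
augment_balance <- function(ds, policy) {
  assert_that_(inherits(policy, "augment_policy"), "`policy` must be an augment_policy")
  if ("split" %in% names(ds)) {
    assert_that_(all(as.character(ds$split) == "train"),
                 "augmentation is restricted to the training split")
  }
  counts <- table(as.character(ds$label))
  assert_that_(length(counts) == 2, "need exactly two classes to balance")
  minority <- names(counts)[which.min(counts)]
  n_new <- max(counts) - min(counts)
  if (!"augmented" %in% names(ds)) ds$augmented <- FALSE
  if (n_new == 0) return(ds)
  src_rows <- which(as.character(ds$label) == minority)
  new_rows <- with_seed_(policy$seed, {
    picks <- rep(src_rows, length.out = n_new)
    lapply(seq_len(n_new), function(i) {
      ops <- list(
        rotated = runif(1) < policy$p_rotation,
        rotation_deg = runif(1, -policy$rotation_range, policy$rotation_range),
        zoomed = runif(1) < policy$p_zoom,
        zoom_factor = runif(1, policy$zoom_range[1], policy$zoom_range[2]),
        flipped = runif(1) < policy$p_flip
      )
      row <- ds[picks[i], ]
      row$image <- list(apply_augment(row$image[[1]], ops, mask = FALSE))
      row$mask <- list(apply_augment(row$mask[[1]], ops, mask = TRUE))
      row$augmented <- TRUE
      row$rotated <- ops$rotated
      row$rotation_deg <- ifelse(ops$rotated, ops$rotation_deg, 0)
      row$zoomed <- ops$zoomed
      row$zoom_factor <- ifelse(ops$zoomed, ops$zoom_factor, 1)
      row$flipped <- ops$flipped
      if ("id" %in% names(row)) row$id <- paste0(row$id, "_aug", i)
      row
    })
  })
  dplyr::bind_rows(ds, dplyr::bind_rows(new_rows))
}
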