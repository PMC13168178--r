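# File-format plumbing: images, masks and manifest CSVs.
#
# Images are handled internally as base R arrays indexed [row, col, channel]
# with values in [0, 1]; masks as [row, col] 0/1 matrices. EBImage stores
# pixels [x, y, channel], so the two helpers below transpose at the boundary.

as_ebimage <- function(img) {
  if (length(dim(img)) == 3) {
    EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  } else {
    EBImage::Image(t(img), colormode = "Grayscale")
  }
}

from_ebimage <- function(x) {
  d <- dim(x)
  a <- EBImage::imageData(x)
  if (length(d) == 3) aperm(a, c(2, 1, 3)) else t(a)
}

#' Read an RGB lesion image
#'
#' @param path PNG/JPEG/TIFF file path.
#' @return An H x W x 3 array in `[0, 1]`; grayscale inputs are replicated
#'   across channels.
#' @export
read_lesion_image <- function(path) {
  assert_that_(file.exists(path), paste0("no such image file: ", path))
  img <- from_ebimage(EBImage::readImage(path))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  clamp(img, 0, 1)
}

#' Read a binary lesion mask
#'
#' @param path PNG mask path, foreground > 127 on the 0-255 scale.
#' @return An H x W matrix of 0/1 integers.
#' @export
read_lesion_mask <- function(path) {
  assert_that_(file.exists(path), paste0("no such mask file: ", path))
  m <- from_ebimage(EBImage::readImage(path))
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 0.5) * 1L
}

#' Write an image or mask as PNG
#'
#' @param img H x W x 3 array or H x W matrix in `[0, 1]`.
#' @param path Output path (extension selects the format).
#' @export
write_lesion_image <- function(img, path) {
  EBImage::writeImage(as_ebimage(clamp(img, 0, 1)), path)
  invisible(path)
}

#' Read a dataset manifest CSV
#'
#' Expected columns: `image`, `mask`, `label` (benign/malignant) and
#' optionally `split`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  assert_that_(file.exists(path), paste0("no such manifest: ", path))
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  assert_that_(all(c("image", "label") %in% names(df)),
               "manifest must have `image` and `label` columns")
  df
}

#' Write a dataset manifest CSV
#'
#' @param manifest A tibble with at least `image` and `label` columns.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  keep <- !vapply(manifest, is.list, logical(1))
  utils::write.csv(manifest[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Load the images of a manifest into an in-memory dataset
#'
#' @param manifest Tibble from [read_manifest()].
#' @param generate_masks If `TRUE`, rows without a usable mask path get a
#'   [fallback_mask()] computed from the image.
#' @return The manifest with list-columns `image` and `mask` added.
#' @export
load_dataset <- function(manifest, generate_masks = TRUE) {
  imgs <- lapply(manifest$image, read_lesion_image)
  masks <- vector("list", nrow(manifest))
  has_mask <- if ("mask" %in% names(manifest)) {
    !is.na(manifest$mask) & nzchar(manifest$mask) & file.exists(manifest$mask)
  } else rep(FALSE, nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    masks[[i]] <- if (has_mask[i]) {
      read_lesion_mask(manifest$mask[i])
    } else if (generate_masks) {
      fallback_mask(imgs[[i]])
    } else {
      abort(sprintf("row %d has no mask and generate_masks = FALSE", i))
    }
  }
  manifest$image <- imgs
  manifest$mask <- masks
  manifest
}

#' Threshold-based fallback lesion mask
#'
#' Otsu threshold on the gray image (lesion assumed darker than surrounding
#' skin), largest connected component, holes filled. This is a convenience
#' stand-in for rows lacking an expert mask, not a segmentation model.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @return H x W 0/1 matrix with attribute `fallback = TRUE`.
#' @export
fallback_mask <- function(img) {
  gray <- rgb_to_gray(img)
  thr <- EBImage::otsu(as_ebimage(gray))
  m <- (gray < thr) * 1L
  m <- largest_component(m)
  m <- from_ebimage(EBImage::fillHull(as_ebimage(m))) * 1L
  attr(m, "fallback") <- TRUE
  m
}

# Largest connected foreground component of a 0/1 matrix.
largest_component <- function(mask) {
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(mask)))
  if (max(lab) < 1) return(mask * 0L)
  counts <- tabulate(lab[lab > 0])
  (lab == which.max(counts)) * 1L
}
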