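# Handcrafted ABCD + texture + Fitzpatrick features.
#
# The 11-feature handcrafted vector per lesion: asymmetry score, serrated
# contour area difference (border), number of reference colors present,
# diameter, Fitzpatrick ordinal, and six GLCM texture statistics.

#' Chord-midpoint asymmetry of a lesion mask
#'
#' For each of `n_orientations` directions sampled uniformly over
#' `[0, 180)` degrees, the lesion pixels are rotated about the ellipse-fit
#' centroid so chords lie along pixel rows; each chord's midpoint is
#' collected, a straight symmetry axis is fitted through the midpoints, and
#' the orientation's deviation is the mean squared residual of the midpoints
#' about that axis (px^2). The score is the mean over orientations, and the
#' lesion is flagged asymmetric above `threshold`.
#'
#' Rotation acts on the pixel coordinate set, not on a resampled raster, so
#' the score of a mask and of its mirror image agree to rasterization
#' accuracy.
#'
#' @param mask H x W 0/1 matrix.
#' @param n_orientations Orientations over `[0, 180)` (default 9, step 20
#'   degrees).
#' @param threshold Asymmetry decision threshold on the score (default 5).
#' @return An `asymmetry_result` list: `mu_de` (mean deviation, px^2),
#'   `per_orientation` tibble, `is_asymmetric`.
#' @export
asymmetry <- function(mask, n_orientations = 9, threshold = 5) {
  assert_that_(sum(mask) > 0, "empty mask")
  contour <- extract_contour(mask)
  fit <- fit_ellipse(contour)
  cx <- fit$center[1]; cy <- fit$center[2]
  idx <- which(mask == 1, arr.ind = TRUE)
  px <- idx[, 2] - 1 - cx  # 0-based x relative to centroid
  py <- idx[, 1] - 1 - cy
  angles <- seq(0, 180, length.out = n_orientations + 1)[1:n_orientations]
  devs <- vapply(angles, function(a) {
    th <- a * pi / 180
    xr <- cos(th) * px + sin(th) * py
    yr <- -sin(th) * px + cos(th) * py
    chord <- round(yr)
    mids <- tapply(xr, chord, function(v) (min(v) + max(v)) / 2)
    ypos <- as.numeric(names(mids))
    if (length(mids) < 3) {
      warn(sprintf("orientation %.0f deg skipped: fewer than 3 chords", a))
      return(NA_real_)
    }
    res <- stats::lm.fit(cbind(1, ypos), as.numeric(mids))$residuals
    mean(res^2)
  }, numeric(1))
  mu <- mean(devs, na.rm = TRUE)
  structure(list(
    mu_de = mu,
    per_orientation = tibble::tibble(angle = angles, deviation = devs),
    is_asymmetric = mu > threshold,
    threshold = threshold),
    class = "asymmetry_result")
}

# The six reference-color inequality systems on [0, 1] channels, as printed
# in the defining rule set. The red rule is printed with R < 0.8 (which
# makes every black pixel also red); `corrected_red` flips it to R > 0.8's
# complement-free reading R > 0.45 is NOT used -- the corrected variant uses
# R > 0.8 exactly.
color_rules <- function(corrected_red = FALSE) {
  list(
    "black"       = function(R, G, B) R < 0.2 & G < 0.2 & B < 0.2,
    "red"         = if (corrected_red) {
      function(R, G, B) R > 0.8 & G < 0.2 & B < 0.2
    } else {
      function(R, G, B) R < 0.8 & G < 0.2 & B < 0.2
    },
    "white"       = function(R, G, B) R > 0.8 & G > 0.8 & B > 0.8,
    "blue-gray"   = function(R, G, B) R < 0.2 & G > 0.32 & G < 0.72 &
      B > 0.34 & B < 0.74,
    "light-brown" = function(R, G, B) R > 0.6 & R < 1 & G > 0.32 & G < 0.72 &
      B > 0.05 & B < 0.45,
    "dark-brown"  = function(R, G, B) R > 0.2 & R < 0.6 & G > 0.06 & G < 0.46 &
      B > 0 & B < 0.33
  )
}

#' Six-color rule counts inside the lesion
#'
#' Counts lesion pixels satisfying each of the six reference-color threshold
#' systems (black, red, white, blue-gray, light-brown, dark-brown) on
#' `[0, 1]` channels. Memberships may overlap, as the rules define them. A
#' color is "present" when its pixel fraction reaches `presence_frac` of the
#' lesion area.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param mask H x W 0/1 matrix with at least one lesion pixel.
#' @param presence_frac Presence threshold as a fraction of lesion area
#'   (default 0.05).
#' @param corrected_red The printed red rule reads `R < 0.8`, which also
#'   captures every black pixel; `TRUE` flips it to `R > 0.8`.
#' @return A `color_counts` list: `counts` tibble (color, count, fraction,
#'   present) and `n_colors_present`.
#' @export
color_features <- function(img, mask, presence_frac = 0.05,
                           corrected_red = FALSE) {
  lesion <- mask == 1
  assert_that_(any(lesion), "empty lesion")
  R <- img[, , 1][lesion]; G <- img[, , 2][lesion]; B <- img[, , 3][lesion]
  rules <- color_rules(corrected_red)
  counts <- vapply(rules, function(f) sum(f(R, G, B)), numeric(1))
  frac <- counts / length(R)
  tb <- tibble::tibble(color = names(rules), count = unname(counts),
                       fraction = unname(frac),
                       present = unname(frac >= presence_frac))
  structure(list(counts = tb, n_colors_present = sum(tb$present),
                 lesion_pixels = length(R)),
            class = "color_counts")
}

#' Lesion diameter from antipodal contour points
#'
#' For every contour point, candidate partners are the points whose polar
#' angle about the centroid differs by 180 degrees within `tol_deg`; the
#' diameter is the maximum Euclidean distance over all such antipodal pairs.
#' If no pair falls within tolerance the tolerance widens to 5 degrees with
#' a warning.
#'
#' @param contour A [extract_contour()] result (>= 8 points).
#' @param centroid Numeric length-2 (x, y); defaults to the contour's
#'   ellipse-fit centre.
#' @param tol_deg Angular tolerance around 180 degrees (default 2).
#' @return A `diameter_result` list: `diameter` (px), `endpoints` (2 x 2
#'   matrix), `tol_used`.
#' @export
lesion_diameter <- function(contour, centroid = NULL, tol_deg = 2) {
  pts <- as.matrix(as.data.frame(contour)[, c("x", "y")])
  assert_that_(nrow(pts) >= 8, "diameter needs at least 8 contour points")
  centroid <- centroid %||% fit_ellipse(contour)$center
  ang <- (atan2(pts[, 2] - centroid[2], pts[, 1] - centroid[1]) * 180 / pi) %% 360
  find_best <- function(tol) {
    diff_ang <- abs((outer(ang, ang, "-") + 180) %% 360 - 180)
    anti <- abs(diff_ang - 180) <= tol
    if (!any(anti)) return(NULL)
    d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
    d2[!anti] <- -Inf
    best <- arrayInd(which.max(d2), dim(d2))
    list(diameter = sqrt(d2[best]), endpoints = pts[as.vector(best), ])
  }
  res <- find_best(tol_deg)
  tol_used <- tol_deg
  if (is.null(res)) {
    warn(sprintf("no antipodal pair within %.1f deg; widening to 5 deg", tol_deg))
    res <- find_best(5)
    tol_used <- 5
    assert_that_(!is.null(res), "no antipodal contour pairs found")
  }
  structure(list(diameter = res$diameter, endpoints = res$endpoints,
                 tol_used = tol_used),
            class = "diameter_result")
}

#' GLCM texture statistics of the lesion
#'
#' Quantizes lesion pixels to `levels` gray levels over the full `[0, 1]`
#' range, accumulates a symmetric normalized co-occurrence matrix per offset
#' angle (both pixels inside the mask), computes contrast, dissimilarity,
#' homogeneity, ASM (`sum P^2`), energy (`sqrt(ASM)`) and correlation from
#' the matrix marginals, and averages each statistic over the angles. A
#' constant region has zero marginal deviation; its correlation is defined
#' as 1.
#'
#' @param gray H x W matrix in `[0, 1]` (8-bit data rescaled).
#' @param mask H x W 0/1 matrix with more than one lesion pixel.
#' @param levels Quantization levels (default 64).
#' @param distance Offset length in pixels (default 1).
#' @param angles Offset angles in degrees (default `c(0, 45, 90, 135)`).
#' @return A `glcm_features` list: `features` one-row tibble (contrast,
#'   dissimilarity, homogeneity, energy, asm, correlation), `per_angle`
#'   tibble, `levels`.
#' @export
glcm_features <- function(gray, mask, levels = 64, distance = 1,
                          angles = c(0, 45, 90, 135)) {
  assert_that_(sum(mask) > 1, "lesion must have more than one pixel")
  q <- pmin(floor(clamp(gray, 0, 1) * levels), levels - 1)
  offsets <- lapply(angles, function(a) {
    # angle 0 = rightward offset; 90 = upward (row decreasing)
    round(distance * c(-sin(a * pi / 180), cos(a * pi / 180)))
  })
  per_angle <- lapply(seq_along(angles), function(i) {
    off <- offsets[[i]]
    P <- cooccurrence_matrix(q, mask, off[1], off[2], levels)
    glcm_stats(P)
  })
  feats <- dplyr::summarise(dplyr::bind_rows(per_angle),
                            dplyr::across(dplyr::everything(), mean))
  structure(list(features = feats,
                 per_angle = dplyr::bind_cols(
                   tibble::tibble(angle = angles),
                   dplyr::bind_rows(per_angle)),
                 levels = levels),
            class = "glcm_features")
}

# Symmetric normalized co-occurrence matrix for an integer offset (dr, dc).
cooccurrence_matrix <- function(q, mask, dr, dc, levels) {
  n <- nrow(q); m <- ncol(q)
  r1 <- max(1, 1 - dr):min(n, n - dr)
  c1 <- max(1, 1 - dc):min(m, m - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- (mask[r1, c1, drop = FALSE] == 1) & (mask[r1 + dr, c1 + dc, drop = FALSE] == 1)
  P <- matrix(0, levels, levels)
  if (any(ok)) {
    tab <- table(factor(a[ok], levels = 0:(levels - 1)),
                 factor(b[ok], levels = 0:(levels - 1)))
    P <- unclass(tab) + t(unclass(tab))
    P <- P / sum(P)
  }
  P
}

glcm_stats <- function(P) {
  levels <- nrow(P)
  lv <- 0:(levels - 1)
  X <- matrix(lv, levels, levels)
  Y <- t(X)
  asm <- sum(P^2)
  mu_x <- sum(X * P)
  mu_y <- sum(Y * P)
  s_x <- sqrt(sum(P * (X - mu_x)^2))
  s_y <- sqrt(sum(P * (Y - mu_y)^2))
  corr <- if (s_x < 1e-12 || s_y < 1e-12) 1 else
    sum((X - mu_x) * (Y - mu_y) * P) / (s_x * s_y)
  tibble::tibble(
    contrast = sum((X - Y)^2 * P),
    dissimilarity = sum(abs(X - Y) * P),
    homogeneity = sum(P / (1 + abs(X - Y))),
    energy = sqrt(asm),
    asm = asm,
    correlation = corr
  )
}

#' Locate a clean skin patch away from the lesion
#'
#' Splits the frame into quadrants, picks the quadrant with the least lesion
#' overlap, splits that quadrant into four again and returns the sub-block
#' with the least overlap.
#'
#' @param mask H x W 0/1 lesion mask (must not cover the whole frame).
#' @return A list: `bounds` (row1, row2, col1, col2), `overlap` (lesion
#'   fraction inside the chosen block).
#' @export
extract_skin_patch <- function(mask) {
  split4 <- function(r1, r2, c1, c2) {
    rm_ <- r1 + (r2 - r1 + 1) %/% 2
    cm_ <- c1 + (c2 - c1 + 1) %/% 2
    list(c(r1, rm_ - 1, c1, cm_ - 1), c(r1, rm_ - 1, cm_, c2),
         c(rm_, r2, c1, cm_ - 1), c(rm_, r2, cm_, c2))
  }
  overlap <- function(b) mean(mask[b[1]:b[2], b[3]:b[4]])
  quads <- split4(1, nrow(mask), 1, ncol(mask))
  q_best <- quads[[which.min(vapply(quads, overlap, numeric(1)))]]
  subs <- split4(q_best[1], q_best[2], q_best[3], q_best[4])
  ovls <- vapply(subs, overlap, numeric(1))
  assert_that_(min(ovls) <= 0.5,
               "no clean skin region: every candidate block is mostly lesion")
  b <- subs[[which.min(ovls)]]
  list(bounds = c(row1 = b[1], row2 = b[2], col1 = b[3], col2 = b[4]),
       overlap = min(ovls))
}

#' Individual typology angle (ITA)
#'
#' `ITA = arctan((L - 50) / b) * 180 / pi` in CIELab. When `|b|` vanishes the
#' limit convention `90 * sign(L - 50)` applies.
#'
#' @param mean_L,mean_b CIELab luminance and yellow-blue chroma.
#' @return ITA in degrees.
#' @export
ita_angle <- function(mean_L, mean_b) {
  ifelse(abs(mean_b) < 1e-6,
         90 * sign(mean_L - 50),
         atan((mean_L - 50) / mean_b) * 180 / pi)
}

#' Fitzpatrick skin type from ITA
#'
#' Interval lookup: F-I for `ita >= 50`, F-II `[25, 50)`, F-III `[0, 25)`,
#' F-IV `[-25, 0)`, F-V `[-50, -25)`, F-VI below -50.
#'
#' @param ita ITA in degrees (finite).
#' @return Integer ordinal 1-6 with the roman label as names.
#' @export
fitzpatrick_class <- function(ita) {
  assert_that_(all(is.finite(ita)), "`ita` must be finite")
  cls <- ifelse(ita >= 50, 1L,
         ifelse(ita >= 25, 2L,
         ifelse(ita >= 0, 3L,
         ifelse(ita >= -25, 4L,
         ifelse(ita >= -50, 5L, 6L)))))
  names(cls) <- paste0("F-", c("I", "II", "III", "IV", "V", "VI"))[cls]
  cls
}

#' Fitzpatrick skin typing of a lesion image
#'
#' Extracts the cleanest skin block ([extract_skin_patch()]), converts its
#' mean color to CIELab, and maps the ITA of the mean to the Fitzpatrick
#' ordinal.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param mask H x W 0/1 lesion mask.
#' @return A `fitzpatrick_result` list: `ita`, `skin_type` (1-6), `mean_L`,
#'   `mean_b`, `bounds`.
#' @export
fitzpatrick <- function(img, mask) {
  patch <- extract_skin_patch(mask)
  b <- patch$bounds
  sub <- img[b[1]:b[2], b[3]:b[4], , drop = FALSE]
  mean_rgb <- c(mean(sub[, , 1]), mean(sub[, , 2]), mean(sub[, , 3]))
  lab <- rgb_to_lab(mean_rgb)
  ita <- ita_angle(lab[1, "L"], lab[1, "b"])
  structure(list(ita = unname(ita),
                 skin_type = unname(fitzpatrick_class(ita)),
                 mean_L = unname(lab[1, "L"]), mean_b = unname(lab[1, "b"]),
                 bounds = b, patch_overlap = patch$overlap),
            class = "fitzpatrick_result")
}

#' The 11-feature handcrafted vector of one lesion
#'
#' Runs all handcrafted extractors -- asymmetry, serrated-contour border
#' irregularity, six-color rule, diameter, Fitzpatrick typing and GLCM
#' texture -- and assembles the 11 named feature columns
#' (`asymmetry`, `border_delta_area`, `n_colors`, `diameter_px`,
#' `fitzpatrick`, `contrast`, `dissimilarity`, `homogeneity`, `energy`,
#' `asm`, `correlation`). Auxiliary quantities (boolean asymmetry flag, ITA,
#' border class inputs) ride along as `aux_*` columns. An extractor failure
#' leaves its columns `NA` and records the reason in `aux_failed`.
#'
#' @param img H x W x 3 array in `[0, 1]` (preprocessed).
#' @param mask H x W 0/1 lesion mask.
#' @param presence_frac Color presence threshold.
#' @param corrected_red See [color_features()].
#' @return A one-row tibble.
#' @export
handcrafted_vector <- function(img, mask, presence_frac = 0.05,
                               corrected_red = FALSE) {
  out <- tibble::tibble(
    asymmetry = NA_real_, border_delta_area = NA_real_, n_colors = NA_real_,
    diameter_px = NA_real_, fitzpatrick = NA_real_, contrast = NA_real_,
    dissimilarity = NA_real_, homogeneity = NA_real_, energy = NA_real_,
    asm = NA_real_, correlation = NA_real_,
    aux_is_asymmetric = NA, aux_ita = NA_real_, aux_failed = ""
  )
  record_failure <- function(stage, e) {
    out$aux_failed <<- paste0(out$aux_failed,
                              sprintf("[%s: %s]", stage, conditionMessage(e)))
  }
  tryCatch({
    a <- asymmetry(mask)
    out$asymmetry <- a$mu_de
    out$aux_is_asymmetric <- a$is_asymmetric
  }, error = function(e) record_failure("asymmetry", e))
  tryCatch({
    out$border_delta_area <- border_irregularity(mask)$delta_area
  }, error = function(e) record_failure("border", e))
  tryCatch({
    out$n_colors <- color_features(img, mask, presence_frac,
                                   corrected_red)$n_colors_present
  }, error = function(e) record_failure("color", e))
  tryCatch({
    out$diameter_px <- lesion_diameter(extract_contour(mask))$diameter
  }, error = function(e) record_failure("diameter", e))
  tryCatch({
    fz <- fitzpatrick(img, mask)
    out$fitzpatrick <- fz$skin_type
    out$aux_ita <- fz$ita
  }, error = function(e) record_failure("fitzpatrick", e))
  tryCatch({
    g <- glcm_features(rgb_to_gray(img), mask)$features
    out$contrast <- g$contrast
    out$dissimilarity <- g$dissimilarity
    out$homogeneity <- g$homogeneity
    out$energy <- g$energy
    out$asm <- g$asm
    out$correlation <- g$correlation
  }, error = function(e) record_failure("glcm", e))
  out
}

#' Names of the 11 handcrafted feature columns
#' @export
handcrafted_feature_names <- function() {
  c("asymmetry", "border_delta_area", "n_colors", "diameter_px",
    "fitzpatrick", "contrast", "dissimilarity", "homogeneity", "energy",
    "asm", "correlation")
}

#' Handcrafted feature table for a dataset
#'
#' @param ds In-memory dataset tibble with list-columns `image`, `mask` and
#'   (optionally) `id`, `label`, `split`.
#' @param ... Passed to [handcrafted_vector()].
#' @return A tibble: one row per lesion, `id`/`label`/`split` carried over,
#'   then the 11 feature columns and auxiliaries.
#' @export
handcrafted_table <- function(ds, ...) {
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    handcrafted_vector(ds$image[[i]], ds$mask[[i]], ...)
  })
  feats <- dplyr::bind_rows(rows)
  keep <- intersect(c("id", "label", "split"), names(ds))
  dplyr::bind_cols(ds[keep], feats)
}
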