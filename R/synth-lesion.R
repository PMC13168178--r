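# Synthetic lesion image generator.
#
# Renders a lesion as a star-shaped region around the image centre whose
# boundary radius is base_radius * (1 + amplitude * sin(frequency * theta)),
# optionally warped by a smooth one-sided radial scaling (asymmetry), painted
# with concentric rings of the six dermoscopic reference colors on a skin
# background of known ITA, with optional dark curvilinear hair strokes.
# Every ground-truth property is stored alongside the render so downstream
# extractors can be validated against it.

# Representative values and clamping boxes for the six reference colors; the
# boxes keep the per-pixel noise inside each color's defining inequalities.
REFERENCE_COLORS <- list(
  "black"       = list(rgb = c(0.10, 0.10, 0.10),
                       lo = c(0.02, 0.02, 0.02), hi = c(0.18, 0.18, 0.18)),
  "red"         = list(rgb = c(0.60, 0.10, 0.10),
                       lo = c(0.45, 0.02, 0.02), hi = c(0.75, 0.18, 0.18)),
  "white"       = list(rgb = c(0.90, 0.90, 0.90),
                       lo = c(0.82, 0.82, 0.82), hi = c(0.98, 0.98, 0.98)),
  "blue-gray"   = list(rgb = c(0.10, 0.52, 0.54),
                       lo = c(0.02, 0.34, 0.36), hi = c(0.18, 0.70, 0.72)),
  "light-brown" = list(rgb = c(0.80, 0.52, 0.25),
                       lo = c(0.62, 0.34, 0.07), hi = c(0.98, 0.70, 0.43)),
  "dark-brown"  = list(rgb = c(0.40, 0.26, 0.16),
                       lo = c(0.22, 0.08, 0.02), hi = c(0.58, 0.44, 0.31))
)

#' Specification for a synthetic lesion render
#'
#' @param image_size Side of the square output image, pixels.
#' @param base_radius Unperturbed lesion radius, pixels. Must exceed 2 and be
#'   smaller than `image_size / 2` (after amplitude/asymmetry inflation).
#' @param border_amplitude Sinusoidal border perturbation as a fraction of the
#'   radius; 0 renders a smooth circular (elliptical) boundary.
#' @param border_frequency Integer number of border lobes.
#' @param asymmetry_ratio One-sided radial inflation applied smoothly to the
#'   upper half of the lesion; 0 keeps the shape mirror-symmetric.
#' @param colors Character vector, subset of
#'   `c("black", "red", "white", "blue-gray", "light-brown", "dark-brown")`.
#' @param background_ita Individual typology angle of the background skin,
#'   degrees in `[-85, 85]`.
#' @param hair_count Number of dark curvilinear hair strokes overlaid.
#' @param seed Integer seed; a fixed seed reproduces the render bit for bit.
#' @return A `lesion_spec` object (validated list).
#' @export
lesion_spec <- function(image_size = 256, base_radius = 60,
                        border_amplitude = 0, border_frequency = 8,
                        asymmetry_ratio = 0, colors = "dark-brown",
                        background_ita = 30, hair_count = 0, seed = 1) {
  assert_that_(is_scalar_number(image_size) && image_size >= 32,
               "`image_size` must be a single number >= 32")
  assert_that_(is_scalar_number(base_radius) && base_radius > 2,
               "degenerate spec: `base_radius` must exceed 2 px")
  assert_that_(is_scalar_number(border_amplitude) && border_amplitude >= 0,
               "`border_amplitude` must be >= 0")
  assert_that_(is_scalar_number(asymmetry_ratio) && asymmetry_ratio >= 0,
               "`asymmetry_ratio` must be >= 0")
  max_r <- base_radius * (1 + border_amplitude) * (1 + asymmetry_ratio)
  assert_that_(max_r < image_size / 2,
               "lesion does not fit: inflated radius must stay below image_size / 2")
  assert_that_(all(colors %in% names(REFERENCE_COLORS)) && length(colors) >= 1,
               "`colors` must be a non-empty subset of the six reference colors")
  assert_that_(is_scalar_number(background_ita) && abs(background_ita) <= 85,
               "`background_ita` must lie in [-85, 85] degrees")
  assert_that_(is_scalar_number(hair_count) && hair_count >= 0,
               "`hair_count` must be >= 0")
  structure(
    list(image_size = as.integer(image_size), base_radius = base_radius,
         border_amplitude = border_amplitude,
         border_frequency = as.integer(border_frequency),
         asymmetry_ratio = asymmetry_ratio, colors = unique(colors),
         background_ita = background_ita, hair_count = as.integer(hair_count),
         seed = as.integer(seed)),
    class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat("<lesion_spec>", x$image_size, "px,", "radius", x$base_radius,
      "px, amplitude", x$border_amplitude, "x", x$border_frequency, "lobes,",
      "asymmetry", x$asymmetry_ratio, "\n  colors:",
      paste(x$colors, collapse = ", "),
      "| background ITA", x$background_ita, "deg |", x$hair_count,
      "hairs | seed", x$seed, "\n")
  invisible(x)
}

# Boundary radius at polar angle theta (radians), before no clipping.
lesion_boundary_radius <- function(spec, theta) {
  r <- spec$base_radius *
    (1 + spec$border_amplitude * sin(spec$border_frequency * theta))
  # one-sided smooth inflation of the upper half plane
  r * (1 + spec$asymmetry_ratio * pmax(0, sin(theta)))
}

#' Render a synthetic lesion image, mask and ground-truth record
#'
#' @param spec A [lesion_spec()].
#' @return A list with `image` (H x W x 3 array in `[0, 1]`), `mask`
#'   (H x W matrix of 0/1) and `truth` (one-row tibble of all ground-truth
#'   properties, including the hair coverage mask used for the overlay).
#' @export
generate_lesion <- function(spec) {
  assert_that_(inherits(spec, "lesion_spec"), "`spec` must be a lesion_spec")
  n <- spec$image_size
  with_seed_(spec$seed, {
    cx <- (n + 1) / 2
    cy <- (n + 1) / 2
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
    dx <- xs - cx
    dy <- ys - cy
    theta <- atan2(dy, dx)
    r <- sqrt(dx^2 + dy^2)
    rb <- lesion_boundary_radius(spec, theta)
    mask <- (r <= rb) * 1L

    # background skin, then concentric equal-area color rings
    img <- skin_patch_from_ita(spec$background_ita, n,
                               seed = sub_seed(spec$seed, 1))
    k <- length(spec$colors)
    frac <- clamp(r / rb, 0, 1)
    ring <- pmin(k, floor(frac^2 * k) + 1)  # sqrt spacing -> equal areas
    inside <- mask == 1
    for (i in seq_len(k)) {
      colinfo <- REFERENCE_COLORS[[spec$colors[i]]]
      sel <- inside & (ring == i)
      npx <- sum(sel)
      if (npx == 0) next
      for (ch in 1:3) {
        vals <- colinfo$rgb[ch] + rnorm(npx, sd = 0.015)
        plane <- img[, , ch]
        plane[sel] <- clamp(vals, colinfo$lo[ch], colinfo$hi[ch])
        img[, , ch] <- plane
      }
    }

    hair_cov <- matrix(0, n, n)
    if (spec$hair_count > 0) {
      hair_cov <- render_hairs(n, spec$hair_count)
      hair_rgb <- c(0.08, 0.06, 0.05)
      for (ch in 1:3) {
        img[, , ch] <- (1 - hair_cov) * img[, , ch] + hair_cov * hair_rgb[ch]
      }
    }

    truth <- tibble::tibble(
      image_size = n, base_radius = spec$base_radius,
      border_amplitude = spec$border_amplitude,
      border_frequency = spec$border_frequency,
      asymmetry_ratio = spec$asymmetry_ratio,
      n_colors = k, colors = paste(spec$colors, collapse = ";"),
      background_ita = spec$background_ita, hair_count = spec$hair_count,
      true_diameter = 2 * spec$base_radius, seed = spec$seed
    )
    list(image = img, mask = mask, truth = truth,
         hair_coverage = hair_cov)
  })
}

# Accumulate anti-aliased coverage of `count` cubic Bezier strokes 1-3 px
# wide; coverage in [0, 1] per pixel.
render_hairs <- function(n, count) {
  cov <- matrix(0, n, n)
  for (h in seq_len(count)) {
    p0 <- runif(2, 0.05 * n, 0.95 * n)
    p3 <- runif(2, 0.05 * n, 0.95 * n)
    p1 <- p0 + runif(2, -0.4 * n, 0.4 * n)
    p2 <- p3 + runif(2, -0.4 * n, 0.4 * n)
    width <- runif(1, 1, 3)
    # chord-length based sampling density, ~2 samples per pixel
    approx_len <- sum(sqrt(rowSums(rbind(p1 - p0, p2 - p1, p3 - p2)^2)))
    t <- seq(0, 1, length.out = max(16, ceiling(2 * approx_len)))
    bx <- (1 - t)^3 * p0[1] + 3 * (1 - t)^2 * t * p1[1] +
      3 * (1 - t) * t^2 * p2[1] + t^3 * p3[1]
    by <- (1 - t)^3 * p0[2] + 3 * (1 - t)^2 * t * p1[2] +
      3 * (1 - t) * t^2 * p2[2] + t^3 * p3[2]
    half <- width / 2
    win <- ceiling(half + 1)
    offs <- -win:win
    for (s in seq_along(t)) {
      px <- bx[s]; py <- by[s]
      ix <- round(px) + offs
      iy <- round(py) + offs
      okx <- ix >= 1 & ix <= n
      oky <- iy >= 1 & iy <= n
      if (!any(okx) || !any(oky)) next
      ix <- ix[okx]; iy <- iy[oky]
      d <- sqrt(outer((iy - py)^2, (ix - px)^2, "+"))
      a <- clamp(half + 0.5 - d, 0, 1)
      cov[iy, ix] <- pmax(cov[iy, ix], a)
    }
  }
  cov
}

#' Generate a uniform skin patch with a prescribed individual typology angle
#'
#' The patch is drawn in CIELab (where ITA is defined) around the point
#' `L = 50 + rho * sin(ita)`, `b = rho * cos(ita)` with `rho = 25` and a mild
#' red chromatic component `a = 12`, plus per-pixel Lab noise, then converted
#' to sRGB (D65). The mean ITA recovered from the patch stays within about
#' 3 degrees of the request.
#'
#' @param ita Target ITA in degrees, `[-85, 85]`.
#' @param size Patch side in pixels.
#' @param seed Integer seed.
#' @return An `size x size x 3` sRGB array in `[0, 1]`.
#' @export
skin_patch_from_ita <- function(ita, size, seed = 1) {
  assert_that_(is_scalar_number(ita) && ita >= -85 && ita <= 85,
               "`ita` must lie in [-85, 85] degrees")
  with_seed_(seed, {
    rho <- 25
    ita_rad <- ita * pi / 180
    L0 <- 50 + rho * sin(ita_rad)
    b0 <- rho * cos(ita_rad)
    npx <- size * size
    lab <- cbind(L = L0 + rnorm(npx, sd = 1.2),
                 a = 12 + rnorm(npx, sd = 0.6),
                 b = b0 + rnorm(npx, sd = 0.6))
    rgb <- lab_to_rgb(lab)
    array(c(matrix(rgb[, 1], size, size),
            matrix(rgb[, 2], size, size),
            matrix(rgb[, 3], size, size)), dim = c(size, size, 3))
  })
}

#' Simulate a labelled synthetic lesion dataset
#'
#' Convenience wrapper used by tests, examples and the CLI: benign lesions are
#' smooth single-color disks, malignant lesions have serrated borders, asymmetry
#' and several colors, mirroring how the ABCD criteria separate the classes.
#'
#' @param n Number of images (half benign, half malignant).
#' @param image_size Image side, pixels.
#' @param seed Integer seed.
#' @param malignant_amplitude Border amplitude for the malignant class.
#' @param hair_count Hairs overlaid on every image.
#' @return A tibble with list-columns `image`, `mask`, plus `id`, `label` and
#'   the ground-truth columns.
#' @export
simulate_lesion_dataset <- function(n = 60, image_size = 128, seed = 1,
                                    malignant_amplitude = 0.3,
                                    hair_count = 0) {
  assert_that_(n >= 2, "`n` must be at least 2")
  labels <- rep(c("benign", "malignant"), length.out = n)
  base_r <- image_size * 0.22
  rows <- lapply(seq_len(n), function(i) {
    malignant <- labels[i] == "malignant"
    sp <- lesion_spec(
      image_size = image_size,
      base_radius = base_r * runif_det(sub_seed(seed, i), 0.8, 1.1),
      border_amplitude = if (malignant) malignant_amplitude else 0,
      border_frequency = 8,
      asymmetry_ratio = if (malignant) 0.2 else 0,
      colors = if (malignant) c("dark-brown", "black", "blue-gray")
               else "light-brown",
      background_ita = if (i %% 2 == 0) 40 else 15,
      hair_count = hair_count,
      seed = sub_seed(seed, 1000 + i)
    )
    lesion <- generate_lesion(sp)
    tibble::tibble(id = sprintf("syn%04d", i), label = labels[i],
                   image = list(lesion$image), mask = list(lesion$mask),
                   lesion$truth)
  })
  dplyr::bind_rows(rows)
}

# Single deterministic uniform draw keyed by a seed (used for per-image
# jitter without touching the caller's RNG).
runif_det <- function(seed, lo, hi) {
  with_seed_(seed, runif(1, lo, hi))
}
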