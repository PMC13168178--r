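# Asymmetry, color rule, diameter, GLCM, skin patch and Fitzpatrick typing.

test_that("chord-midpoint asymmetry scores symmetric and lopsided shapes", {
  disk <- make_disk(160, 50)
  a <- asymmetry(disk)
  expect_lt(a$mu_de, 0.5)
  expect_false(a$is_asymmetric)
  # mirror invariance
  am <- asymmetry(disk[, 160:1])
  expect_lt(abs(am$mu_de - a$mu_de) / max(a$mu_de, 1e-9), 0.01)
  # crescent: disk minus an offset disk is clearly asymmetric
  xs <- matrix(rep(1:160, each = 160), 160)
  ys <- matrix(rep(1:160, times = 160), 160)
  crescent <- (((xs - 80.5)^2 + (ys - 80.5)^2 <= 50^2) &
                 !((xs - 100)^2 + (ys - 80.5)^2 <= 42^2)) * 1L
  ac <- asymmetry(crescent)
  expect_true(ac$is_asymmetric)
  acm <- asymmetry(crescent[, 160:1])
  expect_lt(abs(acm$mu_de - ac$mu_de) / ac$mu_de, 0.01)
})

test_that("color counts follow the printed inequality systems", {
  m <- matrix(1L, 25, 20)
  paint <- function(rgb) {
    arr <- array(0, c(25, 20, 3))
    for (ch in 1:3) arr[, , ch] <- rgb[ch]
    arr
  }
  dark <- color_features(paint(c(0.1, 0.1, 0.1)), m)
  counts <- setNames(dark$counts$count, dark$counts$color)
  expect_equal(unname(counts["black"]), 500)
  # the printed red rule (R < 0.8) also captures black pixels
  expect_equal(unname(counts["red"]), 500)
  corrected <- color_features(paint(c(0.1, 0.1, 0.1)), m, corrected_red = TRUE)
  expect_equal(corrected$counts$count[corrected$counts$color == "red"], 0)
  white <- color_features(paint(c(0.9, 0.9, 0.9)), m)
  wc <- setNames(white$counts$count, white$counts$color)
  expect_equal(unname(wc["white"]), 500)
  expect_equal(sum(wc[setdiff(names(wc), "white")]), 0)
  expect_equal(white$n_colors_present, 1)
  # brute-force check of all six systems on random pixels
  set.seed(4)
  px <- matrix(runif(300), 100, 3)
  img <- array(0, c(10, 10, 3)); for (ch in 1:3) img[, , ch] <- px[, ch]
  cf <- color_features(img, matrix(1L, 10, 10))
  oracle <- c(
    black = sum(px[, 1] < .2 & px[, 2] < .2 & px[, 3] < .2),
    red = sum(px[, 1] < .8 & px[, 2] < .2 & px[, 3] < .2),
    white = sum(px[, 1] > .8 & px[, 2] > .8 & px[, 3] > .8),
    "blue-gray" = sum(px[, 1] < .2 & px[, 2] > .32 & px[, 2] < .72 &
                        px[, 3] > .34 & px[, 3] < .74),
    "light-brown" = sum(px[, 1] > .6 & px[, 1] < 1 & px[, 2] > .32 &
                          px[, 2] < .72 & px[, 3] > .05 & px[, 3] < .45),
    "dark-brown" = sum(px[, 1] > .2 & px[, 1] < .6 & px[, 2] > .06 &
                         px[, 2] < .46 & px[, 3] > 0 & px[, 3] < .33))
  expect_equal(setNames(cf$counts$count, cf$counts$color), oracle)
  expect_error(color_features(img, matrix(0L, 10, 10)), "empty lesion")
})

test_that("antipodal diameter recovers 2r and the ellipse major axis", {
  ct <- extract_contour(make_disk(128, 50))
  d <- lesion_diameter(ct)
  expect_gte(d$diameter, 98)
  expect_lte(d$diameter, 102)
  ell <- make_ellipse_mask(160, 60, 20)
  de <- lesion_diameter(extract_contour(ell))
  expect_lt(abs(de$diameter - 120) / 120, 0.02)
  # rotation invariance: transpose rotates the raster by 90 degrees
  dr <- lesion_diameter(extract_contour(t(ell)))
  expect_lt(abs(dr$diameter - de$diameter) / de$diameter, 0.02)
  expect_error(lesion_diameter(ct[1:5, ]), "at least 8")
})

test_that("GLCM features match a hand-built co-occurrence oracle", {
  flat <- glcm_features(matrix(0.5, 16, 16), matrix(1L, 16, 16))$features
  expect_equal(flat$contrast, 0)
  expect_equal(flat$dissimilarity, 0)
  expect_equal(flat$homogeneity, 1)
  expect_equal(flat$asm, 1)
  expect_equal(flat$energy, 1)
  expect_equal(flat$correlation, 1)  # sigma = 0 convention
  # vertical two-tone stripes at angle 0, 2 levels
  img <- matrix(rep(c(0, 0.9), times = 2, each = 4), 4, 4)
  got <- glcm_features(img, matrix(1L, 4, 4), levels = 2,
                       angles = 0)$features
  oracle <- glcm_oracle(img, matrix(1L, 4, 4), 2, 0)
  for (nm in names(oracle)) {
    expect_equal(got[[nm]], oracle[[nm]], tolerance = 1e-9)
  }
  # 200 random two-level 4x4 instances, all four angles
  set.seed(11)
  for (rep_i in 1:200) {
    img <- matrix(sample(c(0.2, 0.8), 16, replace = TRUE), 4, 4)
    mask <- matrix(rbinom(16, 1, 0.85), 4, 4)
    if (sum(mask) < 2) mask[1:2] <- 1L
    ang <- sample(c(0, 45, 90, 135), 1)
    got <- glcm_features(img, mask, levels = 2, angles = ang)$features
    oracle <- glcm_oracle(img, mask, 2, ang)
    for (nm in names(oracle)) {
      expect_equal(got[[nm]], oracle[[nm]], tolerance = 1e-9)
    }
  }
})

test_that("skin patch search picks the minimum-overlap sub-block", {
  centered <- make_disk(64, 15)
  sp <- extract_skin_patch(centered)
  expect_equal(sp$overlap, 0)
  # lesion filling the top-left quadrant pushes the patch elsewhere
  tl <- matrix(0L, 64, 64); tl[1:32, 1:32] <- 1L
  sp_tl <- extract_skin_patch(tl)
  expect_true(sp_tl$bounds["row1"] > 32 || sp_tl$bounds["col1"] > 32)
  # chosen block overlap is minimal over all 16 sub-blocks
  all_blocks <- function(mask) {
    out <- c()
    qs <- list(c(1, 32, 1, 32), c(1, 32, 33, 64),
               c(33, 64, 1, 32), c(33, 64, 33, 64))
    for (q in qs) {
      rm_ <- q[1] + 16; cm_ <- q[3] + 16
      for (b in list(c(q[1], rm_ - 1, q[3], cm_ - 1),
                     c(q[1], rm_ - 1, cm_, q[4]),
                     c(rm_, q[2], q[3], cm_ - 1),
                     c(rm_, q[2], cm_, q[4]))) {
        out <- c(out, mean(mask[b[1]:b[2], b[3]:b[4]]))
      }
    }
    out
  }
  for (mask in list(centered, tl)) {
    sp_i <- extract_skin_patch(mask)
    expect_lte(sp_i$overlap, min(all_blocks(mask)) + 1e-12)
  }
  expect_error(extract_skin_patch(matrix(1L, 64, 64)), "no clean skin")
})

test_that("ITA angle and Fitzpatrick intervals follow their definitions", {
  expect_equal(ita_angle(50, 10), 0)
  expect_equal(ita_angle(80, 15), atan(2) * 180 / pi, tolerance = 1e-9)
  expect_equal(ita_angle(80, 15), 63.43, tolerance = 1e-2)
  expect_equal(ita_angle(30, 1e-9), -90)
  expect_equal(ita_angle(70, 1e-9), 90)
  itas <- c(55, 30, 10, -10, -40, -50, -60, 50, 25, 0, -25)
  expect_equal(unname(fitzpatrick_class(itas)),
               c(1L, 2L, 3L, 4L, 5L, 5L, 6L, 1L, 2L, 3L, 4L))
  expect_error(fitzpatrick_class(NaN), "finite")
})

test_that("fitzpatrick() types the synthetic background skin", {
  for (case in list(list(ita = 55, cls = 1L), list(ita = -60, cls = 6L),
                    list(ita = 30, cls = 2L))) {
    sp <- lesion_spec(image_size = 96, base_radius = 20,
                      background_ita = case$ita, seed = 17)
    les <- generate_lesion(sp)
    fz <- fitzpatrick(les$image, les$mask)
    expect_equal(fz$skin_type, case$cls)
    expect_lt(abs(fz$ita - case$ita), 6)
  }
})

test_that("the handcrafted vector has the 11-feature schema and ground truth", {
  sp <- lesion_spec(image_size = 160, base_radius = 40, colors = "dark-brown",
                    background_ita = 30, seed = 23)
  les <- generate_lesion(sp)
  v <- handcrafted_vector(les$image, les$mask)
  expect_true(all(handcrafted_feature_names() %in% names(v)))
  expect_equal(sum(grepl("^aux_", names(v))), 3)
  expect_equal(ncol(v), 14)  # 11 features + 3 auxiliaries
  expect_false(v$aux_is_asymmetric)
  expect_equal(v$n_colors, 1)
  expect_lt(abs(v$diameter_px - 80) / 80, 0.05)
  expect_equal(v$aux_failed, "")
  # determinism
  expect_identical(handcrafted_vector(les$image, les$mask), v)
})
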