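# Serrated-contour border irregularity: contours, ellipse fits,
# intersections, serration geometry, areas, shape descriptors, clustering.

test_that("contour extraction finds the largest component's boundary ring", {
  m <- matrix(0L, 9, 9); m[4:6, 4:6] <- 1L
  ct <- extract_contour(m)
  expect_equal(nrow(ct), 8)
  expect_gt(dermafuse:::shoelace_signed(ct$x, ct$y), 0)  # CCW orientation
  # two components: only the larger one is traced
  m2 <- matrix(0L, 40, 40)
  m2[5:14, 5:14] <- 1L        # 100 px
  m2[30:32, 30:33] <- 1L      # 12 px
  ct2 <- extract_contour(m2)
  expect_true(all(ct2$x < 20) && all(ct2$y < 20))
  # disk perimeter close to 2 pi r
  ct3 <- extract_contour(make_disk(128, 50))
  pts <- as.matrix(ct3)
  per <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
  expect_lt(abs(per - 2 * pi * 50) / (2 * pi * 50), 0.05)
  expect_error(extract_contour(matrix(0L, 5, 5)), "empty mask")
})

test_that("direct least-squares ellipse fit recovers analytic ellipses", {
  fit <- fit_ellipse(ellipse_points(40, 20, cx = 100, cy = 80))
  expect_lt(abs(fit$semi_axes[1] - 40) / 40, 0.02)
  expect_lt(abs(fit$semi_axes[2] - 20) / 20, 0.02)
  expect_equal(unname(fit$center), c(100, 80), tolerance = 0.1)
  circ <- fit_ellipse(ellipse_points(30, 30))
  expect_lt(abs(circ$semi_axes[1] - 30) / 30, 0.02)
  expect_lt(abs(circ$semi_axes[2] - 30) / 30, 0.02)
  rot <- fit_ellipse(ellipse_points(50, 25, angle_deg = 30))
  expect_lt(min(abs(rot$rotation - 30), abs(rot$rotation - 210) %% 180), 3)
  expect_error(fit_ellipse(ellipse_points(40, 20)[1:4, ]), "at least 5")
  line_pts <- tibble::tibble(x = 1:20, y = 2 * (1:20) + 1)
  expect_error(fit_ellipse(line_pts), "degenerate|collinear")
})

test_that("intersection analysis counts crossings and averages angles", {
  # contour identical to the fitted ellipse: everything intersects
  ct <- extract_contour(make_disk(160, 60))
  fit <- fit_ellipse(ct)
  inter <- intersections(ct, fit)
  expect_gte(inter$frac_on_ellipse, 0.9)
  # 4-lobe star: two crossings per lobe = 8 intersection runs
  star <- make_star(256, 70, amp = 0.25, lobes = 4)
  ct_s <- extract_contour(star)
  fit_s <- fit_ellipse(ct_s)
  inter_s <- intersections(ct_s, fit_s, tol = 1)
  expect_equal(nrow(inter_s$points), 8)
  expect_equal(inter_s$mean_gap, 45)
  # single synthetic intersection at 45 degrees -> circular mean is 45
  fit_c <- structure(list(center = c(x = 0, y = 0),
                          semi_axes = c(major = 10, minor = 10),
                          rotation = 0), class = "ellipse_fit")
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  pts <- tibble::tibble(x = 20 * cos(th), y = 20 * sin(th))
  pts[which.min(abs(th - pi / 4)), ] <- list(10 * cos(pi / 4),
                                             10 * sin(pi / 4))
  one <- intersections(pts, fit_c, tol = 0.5)
  expect_equal(nrow(one$points), 1)
  expect_equal(one$mu_theta, 45, tolerance = 1e-6)
})

test_that("serrated contours of a disk reproduce inscribed polygons", {
  r <- 80
  ct <- extract_contour(make_disk(200, r))
  fit <- fit_ellipse(ct)
  sq <- serrated_contour(ct, fit$center, 90)
  expect_equal(nrow(sq), 4)
  expect_lt(abs(polygon_area(sq) - 2 * r^2) / (2 * r^2), 0.02)
  hx <- serrated_contour(ct, fit$center, 60)
  expect_lt(abs(polygon_area(hx) - 1.5 * sqrt(3) * r^2) /
              (1.5 * sqrt(3) * r^2), 0.02)
  expect_error(serrated_contour(ct, fit$center, 150), "\\(0, 120\\]")
  # star: every serration vertex lies on the mask contour
  star <- make_star(192, 55, amp = 0.3, lobes = 6)
  ct_s <- extract_contour(star)
  fit_s <- fit_ellipse(ct_s)
  serr <- serrated_contour(ct_s, fit_s$center, 30)
  for (i in seq_len(nrow(serr))) {
    d <- sqrt((ct_s$x - serr$x[i])^2 + (ct_s$y - serr$y[i])^2)
    expect_lt(min(d), 1.01)
  }
})

test_that("polygon areas match the cross-product oracle", {
  expect_equal(polygon_area(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))), 4)
  expect_equal(polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  for (s in 1:100) {
    pts <- random_polygon(10, seed = s)
    expect_equal(polygon_area(pts), polygon_area_oracle(pts),
                 tolerance = 1e-9)
  }
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("area difference is signed, zero on identity, shift-invariant", {
  sq <- tibble::tibble(x = c(0, 4, 4, 0), y = c(0, 0, 4, 4))
  expect_equal(area_difference(sq, sq), 0)
  r <- 60
  ct <- extract_contour(make_disk(160, r))
  fit <- fit_ellipse(ct)
  sq90 <- serrated_contour(ct, fit$center, 90)
  expect_equal(area_difference(ct, sq90), pi * r^2 - 2 * r^2,
               tolerance = 0.04 * pi * r^2)
  shifted_ct <- dplyr::mutate(ct, x = x + 17, y = y - 5)
  shifted_sq <- dplyr::mutate(sq90, x = x + 17, y = y - 5)
  expect_equal(area_difference(shifted_ct, shifted_sq),
               area_difference(ct, sq90), tolerance = 1e-9)
})

test_that("border irregularity pipeline is translation/rotation stable", {
  star <- make_star(200, 45, amp = 0.25, lobes = 8, cx = 70, cy = 70)
  da1 <- border_irregularity(star)$delta_area
  star_shift <- make_star(200, 45, amp = 0.25, lobes = 8, cx = 120, cy = 110)
  da2 <- border_irregularity(star_shift)$delta_area
  expect_lt(abs(da1 - da2) / abs(da1), 0.02)
  rot90 <- t(star)[200:1, ]  # 90-degree rotation of the raster
  da3 <- border_irregularity(rot90)$delta_area
  expect_lt(abs(da1 - da3) / abs(da1), 0.02)
})

test_that("mean |dA| grows with the border amplitude of rendered lesions", {
  mean_da <- vapply(c(0, 0.15, 0.3), function(amp) {
    mean(vapply(1:6, function(s) {
      sp <- lesion_spec(image_size = 160, base_radius = 42,
                        border_amplitude = amp, seed = 100 + s)
      abs(border_irregularity(generate_lesion(sp)$mask)$delta_area)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_da) > 0))
})

test_that("shape descriptors separate smooth disks from serrated stars", {
  disk <- make_disk(160, 50)
  star <- make_star(160, 45, amp = 0.3, lobes = 8)
  fd <- aux_shape_features(disk)
  fs <- aux_shape_features(star)
  expect_gte(fd$circularity, 0.95)
  expect_gte(fd$solidity, 0.98)
  expect_gt(fs$fractal_dim, fd$fractal_dim)
  expect_gt(1 - fs$solidity, 1 - fd$solidity)
  expect_named(fd, c("fractal_dim", "circularity", "solidity", "convexity",
                     "eccentricity", grep("^zernike", names(fd),
                                          value = TRUE)))
  # a 1-px straight segment has box-counting dimension about 1
  line <- matrix(0L, 128, 128); line[64, 8:120] <- 1L
  expect_gt(fractal_dimension(line), 0.9)
  expect_lt(fractal_dimension(line), 1.1)
})

test_that("k-means border classification separates disks from stars", {
  feats <- dplyr::bind_rows(lapply(1:40, function(i) {
    mask <- if (i <= 20) {
      make_disk(128, 30 + i %% 5)
    } else {
      make_star(128, 28 + i %% 5, amp = 0.3, lobes = 4 + i %% 3)
    }
    bi <- border_irregularity(mask)
    dplyr::bind_cols(tibble::tibble(delta_area = bi$delta_area),
                     aux_shape_features(mask))
  }))
  truth <- rep(c("regular", "irregular"), each = 20)
  cls <- suppressWarnings(classify_borders(feats))
  expect_equal(ari_oracle(cls$labels, truth), 1)
  # permutation invariance
  perm <- sample(seq_len(nrow(feats)))
  cls_p <- suppressWarnings(classify_borders(feats[perm, ]))
  expect_identical(as.character(cls_p$labels),
                   as.character(cls$labels)[perm])
  # identical rows are degenerate
  same <- feats[rep(1, 6), ]
  expect_error(suppressWarnings(classify_borders(same)), "degenerate")
})
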