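# Resizing, dull-razor hair removal, stratified splitting, augmentation.

test_that("resize_image honors shape, identity and mask re-binarization", {
  img <- array(runif(600 * 450 * 3), c(450, 600, 3))
  out <- resize_image(img, 256, 256)
  expect_equal(dim(out), c(256, 256, 3))
  same <- resize_image(out, 256, 256)
  expect_identical(same, out)
  mask <- make_disk(100, 30)
  rm_ <- resize_image(mask, 47, 47, mask = TRUE)
  expect_true(all(rm_ %in% c(0L, 1L)))
  expect_error(resize_image(img, 0, 10), "positive")
})

test_that("dull razor leaves hair-free images essentially untouched", {
  flat <- array(0.6, c(64, 64, 3))
  expect_equal(dull_razor(flat), flat, ignore_attr = TRUE)
  sp <- lesion_spec(image_size = 128, base_radius = 30, hair_count = 0,
                    seed = 14)
  clean <- generate_lesion(sp)$image
  out <- dull_razor(clean)
  expect_lt(mean(abs(out - clean)), 2 / 255)
})

test_that("dull razor moves hair pixels toward the hair-free background", {
  sp_hair <- lesion_spec(image_size = 128, base_radius = 30, hair_count = 8,
                         seed = 14)
  sp_none <- lesion_spec(image_size = 128, base_radius = 30, hair_count = 0,
                         seed = 14)
  hairy <- generate_lesion(sp_hair)
  plain <- generate_lesion(sp_none)   # same seed: identical except hairs
  out <- dull_razor(hairy$image)
  hair_px <- which(hairy$hair_coverage > 0.6)
  err <- function(img) {
    d <- 0
    for (ch in 1:3) d <- d + abs(img[, , ch][hair_px] -
                                   plain$image[, , ch][hair_px])
    d
  }
  improved <- mean(err(out) < err(hairy$image))
  expect_gte(improved, 0.7)
})

test_that("stratified split hits 70/10/20 and is deterministic", {
  manifest <- tibble::tibble(
    image = sprintf("img%04d.png", 1:1000),
    label = rep(c("benign", "malignant"), each = 500))
  sp <- split_dataset(manifest, seed = 3)
  expect_equal(as.vector(table(sp$split)), c(700, 100, 200))
  # stratified: per-class train counts equal for balanced input
  expect_equal(as.vector(table(sp$label, sp$split)["benign", ]),
               c(350, 50, 100))
  expect_identical(split_dataset(manifest, seed = 3)$split, sp$split)
  expect_false(identical(split_dataset(manifest, seed = 4)$split, sp$split))
})

test_that("a 10-record balanced manifest splits 7/1/2 with train coverage", {
  manifest <- tibble::tibble(image = sprintf("i%d.png", 1:10),
                             label = rep(c("benign", "malignant"), 5))
  sp <- split_dataset(manifest, seed = 1)
  expect_equal(as.vector(table(sp$split)), c(7, 1, 2))
  train_labels <- sp$label[sp$split == "train"]
  expect_setequal(unique(train_labels), c("benign", "malignant"))
  expect_error(split_dataset(dplyr::mutate(manifest, label = "benign")),
               "single-class")
})

test_that("augmentation balances classes and applies identical transforms", {
  set.seed(42)
  mk_row <- function(i, label) {
    mask <- make_disk(24, 6 + (i %% 3))
    img <- array(runif(24 * 24 * 3), c(24, 24, 3))
    tibble::tibble(id = sprintf("r%02d", i), label = label,
                   image = list(img), mask = list(mask), split = "train")
  }
  ds <- dplyr::bind_rows(c(lapply(1:30, mk_row, label = "benign"),
                           lapply(31:40, mk_row, label = "malignant")))
  out <- augment_balance(ds, augment_policy(seed = 5))
  expect_equal(as.vector(table(out$label)), c(30, 30))
  expect_equal(sum(out$augmented), 20)
  # all-zero policy duplicates pixels exactly
  out0 <- augment_balance(ds, augment_policy(p_rotation = 0, p_zoom = 0,
                                             p_flip = 0, seed = 5))
  aug_rows <- which(out0$augmented)
  src <- which(ds$label == "malignant")
  for (i in seq_along(aug_rows)) {
    expect_identical(out0$image[[aug_rows[i]]],
                     ds$image[[src[(i - 1) %% length(src) + 1]]])
  }
  # augmenting a non-train split is rejected
  expect_error(augment_balance(dplyr::mutate(ds, split = "test"),
                               augment_policy()), "training split")
})

test_that("rotation probability is honored and mask follows the image", {
  mask <- make_disk(24, 8)
  img <- array(rep(mask, 3), c(24, 24, 3))
  # 1005 benign vs 5 malignant -> exactly 1000 augmented copies
  big <- dplyr::bind_rows(
    lapply(1:1010, function(i) tibble::tibble(
      id = as.character(i),
      label = if (i <= 1005) "benign" else "malignant",
      image = list(img), mask = list(mask))))
  out <- augment_balance(big, augment_policy(p_rotation = 0.7, seed = 9))
  frac_rot <- mean(out$rotated[out$augmented])
  expect_gte(frac_rot, 0.65)
  expect_lte(frac_rot, 0.75)
  # image and mask get the same geometric transform: binarized image channel
  # agrees with the transformed mask almost everywhere
  aug <- which(out$augmented)[1:25]
  ious <- vapply(aug, function(i) {
    a <- out$image[[i]][, , 1] > 0.5
    b <- out$mask[[i]] == 1
    sum(a & b) / max(1, sum(a | b))
  }, numeric(1))
  expect_gt(min(ious), 0.85)
  expect_gt(mean(ious), 0.9)
})

test_that("fallback mask segments a dark lesion on light skin", {
  sp <- lesion_spec(image_size = 96, base_radius = 25,
                    colors = "dark-brown", background_ita = 50, seed = 2)
  les <- generate_lesion(sp)
  fm <- fallback_mask(les$image)
  iou <- sum(fm & les$mask) / sum(fm | les$mask)
  expect_gt(iou, 0.8)
})
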