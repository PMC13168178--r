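# Dual-stream residual squeeze-excite network: blocks, shapes, parameter
# accounting, feature extraction and head training.

tiny_cfg <- function(...) {
  args <- list(input_size = 64, ...)
  if (!"head_width" %in% names(args)) args$head_width <- 128
  do.call(net_config, args)
}

test_that("squeeze-excite gates multiply channels through a sigmoid", {
  withr::with_seed(1, {
    x <- array(runif(8 * 8 * 32), c(8, 8, 32))
    p <- dermafuse:::init_se(32, 16)
    out <- se_apply(x, p)
    expect_equal(dim(out), dim(x))
    gate <- attr(out, "gate")
    expect_true(all(gate > 0 & gate < 1))
    # forced-zero excitation weights leave a 0.5 gate everywhere
    p0 <- list(fc1 = list(W = p$fc1$W * 0, b = p$fc1$b * 0),
               fc2 = list(W = p$fc2$W * 0, b = p$fc2$b * 0))
    half <- se_apply(x, p0)
    expect_equal(as.vector(half), as.vector(0.5 * x), tolerance = 1e-12)
    expect_error(dermafuse:::init_se(30, 16), "divide")
    # gates stay in (0, 1) across random activations
    for (i in 1:20) {
      xi <- array(rnorm(8 * 8 * 32), c(8, 8, 32))
      g <- attr(se_apply(xi, p), "gate")
      expect_true(all(g > 0 & g < 1))
    }
  })
})

test_that("RSE blocks honor merge-mode channel arithmetic and null input", {
  withr::with_seed(2, {
    x <- array(runif(16 * 16 * 64), c(16, 16, 64))
    add_same <- dermafuse:::init_rse(64, 64, 16, merge = "add")
    expect_equal(dim(rse_apply(x, add_same)), c(16, 16, 64))
    add_proj <- dermafuse:::init_rse(64, 128, 16, stride = 2L, merge = "add")
    expect_equal(dim(rse_apply(x, add_proj)), c(8, 8, 128))
    cc <- dermafuse:::init_rse(64, 128, 16, merge = "concat")
    expect_equal(dim(rse_apply(x, cc)), c(16, 16, 192))
    # zero input propagates to zero output (GeLU(0) = 0, biases start at 0)
    zero <- array(0, c(16, 16, 64))
    expect_true(all(rse_apply(zero, add_proj) == 0))
    expect_true(all(rse_apply(zero, cc) == 0))
  })
})

test_that("CBAM preserves shape with attention maps in (0, 1)", {
  withr::with_seed(3, {
    x <- array(runif(12 * 12 * 32), c(12, 12, 32))
    p <- dermafuse:::init_cbam(32, 16)
    out <- cbam_apply(x, p)
    expect_equal(dim(out), dim(x))
    expect_true(all(attr(out, "channel_attention") > 0 &
                      attr(out, "channel_attention") < 1))
    expect_true(all(attr(out, "spatial_attention") > 0 &
                      attr(out, "spatial_attention") < 1))
    # constant input -> spatially uniform spatial-attention map away from
    # the zero-padded border of the 7x7 spatial convolution
    const <- array(0.3, c(12, 12, 32))
    sp <- attr(cbam_apply(const, p), "spatial_attention")
    expect_lt(diff(range(sp[4:9, 4:9])), 1e-12)
  })
})

test_that("network construction is seeded, counted and merge-sensitive", {
  m1 <- build_network(tiny_cfg(seed = 5))
  m2 <- build_network(tiny_cfg(seed = 5))
  expect_identical(m1$params, m2$params)
  m3 <- build_network(tiny_cfg(seed = 6))
  expect_false(identical(m1$params, m3$params))
  # parameter count: input-size invariant, head-width monotone, merge-dependent
  expect_equal(count_params(build_network(tiny_cfg())),
               count_params(build_network(net_config(input_size = 299,
                                                     head_width = 128))))
  expect_lt(count_params(build_network(tiny_cfg(head_width = 64))),
            count_params(build_network(tiny_cfg(head_width = 256))))
  expect_false(count_params(build_network(tiny_cfg(merge = "concat"))) ==
                 count_params(build_network(tiny_cfg(merge = "add"))))
})

test_that("feature extraction is deterministic, finite and shape-checked", {
  model <- build_network(tiny_cfg(seed = 9))
  withr::with_seed(4, {
    imgs <- lapply(1:3, function(i) array(runif(64 * 64 * 3), c(64, 64, 3)))
  })
  f <- extract_features(model, c(imgs, imgs[1]))
  expect_equal(dim(f), c(4, 128))
  expect_true(all(is.finite(f)))
  expect_equal(f[1, ], f[4, ])  # duplicate input -> duplicate features
  expect_error(extract_features(model,
                                list(array(0, c(32, 32, 3)))), "64 x 64")
  fw <- network_forward(model, imgs[[1]])
  expect_length(fw$trunk, model$trunk_width)
  expect_gt(fw$prob, 0); expect_lt(fw$prob, 1)
})

test_that("head training reduces the loss on color-separable lesions", {
  ds <- simulate_lesion_dataset(n = 24, image_size = 64, seed = 3)
  model <- build_network(tiny_cfg(seed = 11))
  fit <- train_network(model, ds$image[1:16], ds$label[1:16],
                       train_config(max_epochs = 60, patience = 3, seed = 2),
                       ds$image[17:24], ds$label[17:24])
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
  # early stopping halts well before the epoch cap
  expect_lt(nrow(fit$history), 60)
  expect_true(all(c("val_loss", "val_acc") %in% names(fit$history)))
})
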