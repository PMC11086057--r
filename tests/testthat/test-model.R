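test_that("configuration is validated", {
  expect_error(countnet_config(width_multiplier = 0), "width_multiplier")
  expect_error(countnet_config(width_multiplier = 2), "width_multiplier")
  expect_error(countnet_config(cbam_spatial_kernel = 4), "odd")
  expect_error(countnet_config(decoder_channels = c(512, 512)), "6 widths")
  # too few channels for the attention bottleneck
  expect_error(countnet_config(width_multiplier = 1 / 64,
                               cbam_reduction = 16), "cbam_reduction")
})

test_that("the frontend has 13 convolution layers and scales with width", {
  m <- build_countnet(tiny_config(seed = 1))
  expect_length(m$params$frontend, 13L)
  n_full <- local({
    # count parameters of the full-width model without building it:
    # build at 1/8 and at 1/4 to check the quadratic channel scaling, then
    # compare 1/8 against full width directly
    m8 <- build_countnet(countnet_config(width_multiplier = 1 / 8, seed = 1))
    m1 <- build_countnet(countnet_config(width_multiplier = 1, seed = 1))
    expect_lt(n_parameters(m8) / n_parameters(m1), 0.02)
    n_parameters(m1)
  })
  expect_gt(n_full, 1e7)    # full model is in the tens of millions
})

test_that("construction is deterministic given the seed", {
  a <- build_countnet(tiny_config(seed = 42))
  b <- build_countnet(tiny_config(seed = 42))
  expect_identical(a$params, b$params)
  c <- build_countnet(tiny_config(seed = 43))
  expect_false(identical(a$params, c$params))
})

test_that("frontend output sits at one eighth of the input", {
  m <- build_countnet(tiny_config(seed = 2))
  img <- array(runif(768 * 576 * 3), dim = c(576, 768, 3))
  ff <- frontend_forward(m, img)
  expect_equal(dim(ff$F2$tensor)[1:2], c(576 / 8, 768 / 8))
  expect_equal(dim(ff$F1$tensor)[1:2], c(576 / 4, 768 / 4))
  expect_equal(ff$F1$scale, 4L)
  expect_equal(ff$F2$scale, 8L)
  img2 <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  ff2 <- frontend_forward(m, img2)
  expect_equal(dim(ff2$F2$tensor)[1:2], c(8, 8))
  expect_error(frontend_forward(m, array(0, dim = c(60, 64, 3))),
               "divisible by 8")
  # zero input through a finite network stays finite
  ffz <- frontend_forward(m, array(0, dim = c(64, 64, 3)))
  expect_true(all(is.finite(ffz$F2$tensor)))
})

test_that("fusion keeps F2's grid, consumes F1, and can be bypassed", {
  m <- build_countnet(tiny_config(seed = 3))
  img <- array(runif(96 * 96 * 3), dim = c(96, 96, 3))
  ff <- frontend_forward(m, img)
  fused <- multiscale_fuse(m, ff$F1, ff$F2)
  expect_equal(dim(fused$tensor), dim(ff$F2$tensor))
  # perturbing F1 with F2 held fixed changes the fusion output
  F1b <- ff$F1
  F1b$tensor <- F1b$tensor + 0.5
  fused_b <- multiscale_fuse(m, F1b, ff$F2)
  expect_gt(max(abs(fused_b$tensor - fused$tensor)), 0)
  # ablated fusion is the identity on F2
  moff <- build_countnet(tiny_config(seed = 3, fusion_enabled = FALSE))
  expect_identical(multiscale_fuse(moff, ff$F1, ff$F2)$tensor, ff$F2$tensor)
})

test_that("attention preserves shape, gates in (0,1), and can be bypassed", {
  m <- build_countnet(tiny_config(seed = 4))
  x <- array(runif(8 * 8 * 16), dim = c(8, 8, 16))
  y <- cbam_forward(m, feature_map(x, 8L))
  expect_equal(dim(y$tensor), dim(x))
  # a spatially constant input yields a spatially constant attention
  # output away from the borders (the zero-padded spatial-attention
  # convolution perturbs a 3-px rim for the 7x7 kernel)
  xc <- array(rep(runif(16), each = 256), dim = c(16, 16, 16))
  yc <- cbam_forward(m, feature_map(xc, 8L))$tensor
  for (c in 1:16)
    expect_lt(diff(range(yc[4:13, 4:13, c])), 1e-12)
  # bypass
  moff <- build_countnet(tiny_config(seed = 4, cbam_enabled = FALSE))
  expect_identical(cbam_forward(moff, feature_map(x, 8L))$tensor, x)
})

test_that("decoder maps fused features to a one-channel grid", {
  m <- build_countnet(tiny_config(seed = 5, output_activation = "relu"))
  x <- array(rnorm(12 * 9 * 16), dim = c(12, 9, 16))
  raw <- decoder_forward(m, feature_map(x, 8L))
  expect_equal(dim(raw), c(12L, 9L, 1L))
  expect_gte(min(raw), 0)            # relu head clamps
  mlin <- build_countnet(tiny_config(seed = 5))
  raw2 <- decoder_forward(mlin, feature_map(x, 8L))
  expect_equal(dim(raw2), c(12L, 9L, 1L))
})

test_that("decoder receptive field matches five dilation-2 layers", {
  m <- build_countnet(tiny_config(seed = 6))
  x <- array(rnorm(32 * 32 * 16), dim = c(32, 32, 16))
  base <- decoder_forward(m, feature_map(x, 8L))
  x2 <- x
  x2[16, 16, 3] <- x2[16, 16, 3] + 1
  pert <- decoder_forward(m, feature_map(x2, 8L))
  changed <- which(abs(pert - base) > 1e-12, arr.ind = TRUE)
  # each 3x3 dilation-2 layer adds radius 2; five layers give radius 10
  expect_true(all(abs(changed[, 1] - 16) <= 10))
  expect_true(all(abs(changed[, 2] - 16) <= 10))
  expect_gt(nrow(changed), 0)
})

test_that("the full model returns input-sized maps deterministically", {
  m <- build_countnet(tiny_config(seed = 7))
  for (hw in list(c(64, 64), c(64, 144), c(128, 64))) {
    img <- array(runif(hw[1] * hw[2] * 3), dim = c(hw[1], hw[2], 3))
    dm <- model_forward(m, img)
    expect_equal(dim(dm$grid), hw)
  }
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  expect_identical(model_forward(m, img)$grid, model_forward(m, img)$grid)
  # relu-head model gives a finite non-negative integral
  mr <- build_countnet(tiny_config(seed = 7, output_activation = "relu"))
  v <- integrate_density(model_forward(mr, img))
  expect_true(is.finite(v))
  expect_gte(v, 0)
})

test_that("the published init recipe gives std-0.01 backend, zero biases", {
  m <- build_countnet(countnet_config(width_multiplier = 1 / 4, seed = 8))
  m <- init_weights(m)
  for (i in 1:5) {
    W <- m$params$decoder[[i]]$W
    if (length(W) >= 10000)
      expect_lt(abs(stats::sd(W) - 0.01) / 0.01, 0.1)
    expect_identical(m$params$decoder[[i]]$b,
                     numeric(length(m$params$decoder[[i]]$b)))
  }
  expect_identical(m$params$fusion$f3$b,
                   numeric(length(m$params$fusion$f3$b)))
  # asking for pretrained weights fails with guidance
  mp <- build_countnet(tiny_config(seed = 8, use_pretrained_frontend = TRUE))
  expect_error(init_weights(mp), "use_pretrained_frontend = FALSE")
})

test_that("checkpoints round trip weights bit-exactly", {
  m <- build_countnet(tiny_config(seed = 9))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f, epoch = 17L)
  back <- load_checkpoint(f)
  expect_identical(back$model$params, m$params)
  expect_equal(back$epoch, 17L)
})

test_that("model config files mirror field names and reject unknown keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("width_multiplier: 0.125", "cbam_enabled: no",
               "seed: 99"), f)
  cfg <- read_model_config(f)
  expect_equal(cfg$width_multiplier, 0.125)
  expect_false(cfg$cbam_enabled)
  expect_equal(cfg$seed, 99L)
  writeLines("widht_multiplier: 0.5", f)
  expect_error(read_model_config(f), "unknown")
})
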