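test_that("centre crop computes floor offsets and shifts points", {
  img <- array(runif(720 * 1280 * 3), dim = c(720, 1280, 3))
  ps <- point_set(cbind(c(640, 100, 639.5), c(360, 100, 359.5)), 1280, 720)
  cr <- center_crop(img, ps, 768, 576)
  expect_equal(dim(cr$image), c(576, 768, 3))
  expect_equal(unname(cr$offset), c(256, 72))
  # the original centre maps to the crop centre; far corner point dropped
  expect_equal(n_points(cr$points), 2L)
  expect_equal(unname(cr$points$points[1, ]), c(640 - 256, 360 - 72))
  expect_equal(unname(cr$points$points[2, ]), c(639.5 - 256, 359.5 - 72))
  # already at target size: unchanged
  img2 <- array(runif(576 * 768 * 3), dim = c(576, 768, 3))
  ps2 <- point_set(cbind(10, 20), 768, 576)
  cr2 <- center_crop(img2, ps2, 768, 576)
  expect_identical(cr2$image, img2)
  expect_equal(cr2$points$points, ps2$points)
  expect_error(center_crop(array(0, dim = c(100, 100, 3)), NULL, 768, 576),
               "smaller")
})

test_that("augmentation transforms image, map, and points together", {
  set.seed(31)
  sc <- render_scene(scene_spec(width = 64, height = 48, n_fry = 12,
                                seed = 5))
  dm <- gaussian_density(sc$points)
  id_cfg <- train_config(flip_prob = 0, rotate180_prob = 0,
                         crop_width = 64, crop_height = 48)
  a0 <- augment(sc$image, dm, sc$points, id_cfg)
  expect_identical(a0$image, sc$image)
  expect_identical(a0$density$grid, dm$grid)
  # forced mirror: point (x, y) -> (W-1-x, y); applying twice is identity
  m_cfg <- train_config(flip_prob = 1, rotate180_prob = 0,
                        crop_width = 64, crop_height = 48)
  a1 <- augment(sc$image, dm, sc$points, m_cfg)
  expect_equal(a1$points$points[, 1], 63 - sc$points$points[, 1])
  expect_equal(a1$points$points[, 2], sc$points$points[, 2])
  a2 <- augment(a1$image, a1$density, a1$points, m_cfg)
  expect_identical(a2$image, sc$image)
  expect_equal(a2$points$points, sc$points$points)
  # count invariance under any draw
  r_cfg <- train_config(flip_prob = 0.5, rotate180_prob = 0.5,
                        crop_width = 64, crop_height = 48)
  for (i in 1:6) {
    ai <- augment(sc$image, dm, sc$points, r_cfg)
    expect_equal(n_points(ai$points), 12L)
    expect_lt(abs(integrate_density(ai$density) - integrate_density(dm)),
              1e-9)
  }
})

make_tiny_samples <- function(n, seed, n_fry = c(2L, 6L)) {
  lapply(seq_len(n), function(i) {
    sc <- render_scene(scene_spec(width = 48, height = 48,
                                  n_fry = sample(seq(n_fry[1], n_fry[2]), 1),
                                  fry_length = c(5, 9), fry_width = c(1.5, 2),
                                  seed = seed * 1000L + i))
    list(image = sc$image, points = sc$points, count = n_points(sc$points))
  })
}

test_that("zero-epoch fits return untouched weights and empty history", {
  set.seed(61)
  train <- make_tiny_samples(4, 1)
  m <- build_countnet(tiny_config(seed = 10))
  fit <- fit_countnet(m, train, train,
                      train_config(epochs = 0, batch_size = 2,
                                   crop_width = 48, crop_height = 48))
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$history), 0L)
})

test_that("a short seeded fit reduces the training loss and reproduces", {
  set.seed(62)
  train <- make_tiny_samples(8, 2)
  val <- make_tiny_samples(3, 3)
  cfg <- train_config(epochs = 5, batch_size = 4, learning_rate = 1e-5,
                      crop_width = 48, crop_height = 48, seed = 42)
  m <- build_countnet(countnet_config(width_multiplier = 1 / 16, seed = 11))
  fit <- fit_countnet(m, train, val, cfg)
  expect_equal(nrow(fit$history), 5L)
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  expect_equal(fit$best_epoch, which.min(fit$history$val_mae))
  # identical config and seed reproduce the history exactly
  fit2 <- fit_countnet(build_countnet(countnet_config(width_multiplier = 1 / 16,
                                                      seed = 11)),
                       train, val, cfg)
  expect_equal(fit$history, fit2$history, tolerance = 1e-6)
  expect_error(fit_countnet(m, list(), val, cfg), "empty")
  expect_error(fit_countnet(m, train, val,
                            train_config(epochs = 1, batch_size = 20,
                                         crop_width = 48, crop_height = 48)),
               "batch size")
})

test_that("predicted counts integrate the returned map", {
  m <- build_countnet(tiny_config(seed = 12))
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  pr <- predict_count(m, img)
  expect_identical(pr$count, integrate_density(pr$map))
  # zeroed output projection predicts exactly zero everywhere
  m0 <- m
  m0$params$decoder[[6]]$W[] <- 0
  m0$params$decoder[[6]]$b[] <- 0
  pr0 <- predict_count(m0, img)
  expect_identical(pr0$count, 0)
  # non-multiple-of-8 input is padded and cropped back
  img2 <- array(runif(50 * 70 * 3), dim = c(50, 70, 3))
  pr2 <- predict_count(m, img2)
  expect_equal(dim(pr2$map$grid), c(50, 70))
})

test_that("evaluation reports MAE and RMSE over a dataset", {
  set.seed(63)
  samples <- make_tiny_samples(6, 4)
  m <- build_countnet(tiny_config(seed = 13))
  # oracle predictor reproduces the truth: zero errors
  oracle <- local({
    counts <- vapply(samples, `[[`, numeric(1), "count")
    i <- 0
    function(model, image) { i <<- i + 1; counts[i] }
  })
  rep0 <- evaluate_countnet(m, samples, predict_fun = oracle)
  expect_identical(rep0$mae, 0)
  expect_identical(rep0$rmse, 0)
  rep1 <- evaluate_countnet(m, samples)
  expect_gte(rep1$rmse, rep1$mae)
  expect_equal(rep1$n_images, 6L)
  # per-level MAEs recombine to the overall MAE as a count-weighted mean
  w <- rep1$per_level$n_images
  expect_lt(abs(sum(w * rep1$per_level$mae) / sum(w) - rep1$mae), 1e-9)
  expect_error(evaluate_countnet(m, list()), "empty")
  f <- tempfile(fileext = ".csv")
  write_eval_report(rep1, csv_path = f)
  expect_equal(nrow(utils::read.csv(f)), 6L)
})

test_that("density levels bin counts at the documented edges", {
  expect_equal(as.character(assign_density_level(c(0, 249, 250, 499, 500,
                                                   749, 750, 1000, 1500))),
               c("Low", "Low", "Medium", "Medium", "High", "High",
                 "Higher", "Higher", "Higher"))
  expect_error(assign_density_level(-1), "non-negative")
})

test_that("train config files validate keys and nested loss settings", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("epochs: 12", "learning_rate: 1.0e-6",
               "loss:", "  alpha: 0.01"), f)
  cfg <- read_train_config(f)
  expect_equal(cfg$epochs, 12L)
  expect_equal(cfg$loss$alpha, 0.01)
  writeLines("lerning_rate: 1", f)
  expect_error(read_train_config(f), "unknown")
  expect_error(train_config(flip_prob = 1.5), "probabilities")
  expect_error(train_config(crop_width = 100), "divisible")
})
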