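test_that("scene rendering is seeded, exact, and in range", {
  spec <- scene_spec(width = 96, height = 64, n_fry = 15, seed = 7)
  a <- render_scene(spec)
  b <- render_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$points$points, b$points$points)
  expect_equal(n_points(a$points), 15L)
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_equal(dim(a$image), c(64, 96, 3))
  c <- render_scene(scene_spec(width = 96, height = 64, n_fry = 15,
                               seed = 8))
  expect_false(identical(a$image, c$image))
  # empty scene: background only
  e <- render_scene(scene_spec(width = 96, height = 64, n_fry = 0,
                               seed = 7))
  expect_equal(n_points(e$points), 0L)
  expect_error(scene_spec(n_fry = 1001), "n_fry")
  expect_error(scene_spec(n_fry = -1), "n_fry")
})

test_that("fry strokes darken the image near their annotations", {
  spec <- scene_spec(width = 96, height = 96, n_fry = 6, noise_std = 0,
                     vignette_strength = 0, seed = 21)
  sc <- render_scene(spec)
  bg <- spec$background_level
  for (i in 1:6) {
    x <- round(sc$points$points[i, 1]) + 1
    y <- round(sc$points$points[i, 2]) + 1
    patch <- sc$image[max(1, y - 4):min(96, y + 4),
                      max(1, x - 4):min(96, x + 4), 2]
    expect_lt(min(patch), bg - 0.2)   # a dark body lies within 4 px
  }
})

test_that("density maps of generated annotations integrate to the count", {
  sc <- render_scene(scene_spec(width = 128, height = 96, n_fry = 40,
                                seed = 3))
  dm <- gaussian_density(sc$points)
  expect_lt(abs(integrate_density(dm) - 40), 1e-6)
})

test_that("easy benchmark scenes are deterministic and well separated", {
  bench <- easy_benchmark(n_images = 12, counts = c(5, 40), seed = 42)
  bench2 <- easy_benchmark(n_images = 12, counts = c(5, 40), seed = 42)
  expect_length(bench, 12L)
  expect_identical(bench[[4]]$image, bench2[[4]]$image)
  counts <- vapply(bench, `[[`, numeric(1), "count")
  expect_true(all(counts >= 5 & counts <= 40))
  expect_gt(diff(range(counts)), 10)   # the histogram spans the range
  for (s in bench[1:3]) {
    p <- s$points$points
    if (nrow(p) > 1) {
      d <- as.matrix(stats::dist(p))
      diag(d) <- Inf
      expect_gte(min(d), 6)
    }
  }
  expect_error(easy_benchmark(counts = c(0, 80)), "\\[0, 60\\]")
})

test_that("dataset generation reproduces the configured split plan", {
  sp <- data.frame(level = c("Low", "Medium"), lo = c(0L, 250L),
                   hi = c(249L, 499L), train = c(2L, 1L),
                   validation = c(1L, 0L), test = c(1L, 1L))
  scene <- scene_spec(width = 96, height = 64)
  out <- file.path(tempdir(), "ds_small")
  manifest <- make_dataset(dataset_spec(sp, scene, seed = 5), out)
  expect_equal(nrow(manifest), 6L)
  expect_equal(sum(manifest$split == "train"), 3L)
  expect_equal(sum(manifest$split == "validation"), 1L)
  expect_equal(sum(manifest$split == "test"), 2L)
  # every image's count lies in its level's range
  r <- density_level_ranges()
  for (i in seq_len(nrow(manifest))) {
    row <- r[r$level == manifest$level[i], ]
    expect_gte(manifest$count[i], row$lo)
    expect_lte(manifest$count[i], row$hi)
  }
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "generator_params.json")))
  # the directory round trips through the loader
  samples <- load_count_dataset(out, split = "train")
  expect_length(samples, 3L)
  expect_equal(samples[[1]]$count,
               manifest$count[manifest$split == "train"][1])
  expect_equal(dim(samples[[1]]$image), c(64, 96, 3))
  expect_lt(abs(integrate_density(samples[[1]]$density) -
                samples[[1]]$count), 1e-6)
  # density cache
  densify_dataset(out)
  expect_true(file.exists(file.path(out, "densities",
                                    paste0(samples[[1]]$name, ".npy"))))
  unlink(out, recursive = TRUE)
})

test_that("an all-zero dataset spec produces an empty manifest", {
  sp <- density_level_ranges()
  sp$train <- sp$validation <- sp$test <- 0L
  out <- file.path(tempdir(), "ds_empty")
  manifest <- make_dataset(dataset_spec(sp, scene_spec(), seed = 1), out)
  expect_equal(nrow(manifest), 0L)
  expect_false(dir.exists(file.path(out, "images")))
})
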