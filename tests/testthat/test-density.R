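test_that("impulse matrix places unit spikes with half-up rounding", {
  expect_equal(sum(impulse_matrix(point_set(NULL, 8, 8))), 0L)
  ps <- point_set(cbind(c(2.2, 2.2), c(3.7, 3.7)), 8, 8)
  im <- impulse_matrix(ps)
  expect_equal(im[5, 3], 2L)          # y=3.7 -> row 4 (0-based) -> index 5
  expect_equal(sum(im), 2L)
  # ties round toward +infinity
  im2 <- impulse_matrix(point_set(cbind(2.5, 1.5), 8, 8))
  expect_equal(im2[3, 4], 1L)
  set.seed(5)
  ps3 <- random_point_set(500, 64, 48)
  expect_equal(sum(impulse_matrix(ps3)), 500L)
})

test_that("gaussian density conserves the count, including borders", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(0:200, 1)
    ps <- random_point_set(n, 96, 80)
    expect_lt(abs(integrate_density(gaussian_density(ps)) - n), 1e-6)
  }
  # points hugging every border
  ps <- point_set(cbind(c(0, 95.9, 0.3, 95), c(0.2, 0, 79.9, 79.5)), 96, 80)
  expect_lt(abs(integrate_density(gaussian_density(ps)) - 4), 1e-6)
})

test_that("gaussian density matches the per-point per-pixel oracle", {
  set.seed(21)
  for (i in 1:5) {
    ps <- random_point_set(sample(1:50, 1), 64, 64)
    dm <- gaussian_density(ps)
    expect_lt(max(abs(dm$grid - oracle_density(ps))), 1e-9)
  }
  # non-default bandwidth and truncation
  ps <- random_point_set(10, 48, 40)
  dm <- gaussian_density(ps, sigma = 1.5, truncate = 3)
  expect_lt(max(abs(dm$grid - oracle_density(ps, 1.5, 3))), 1e-9)
})

test_that("without renormalisation border kernels lose clipped mass", {
  centre <- point_set(cbind(32, 32), 64, 64)
  corner <- point_set(cbind(0, 0), 64, 64)
  # an interior kernel keeps its analytic mass up to the 4-sigma
  # truncation tail (~1e-4)
  expect_lt(abs(integrate_density(gaussian_density(centre,
                                                   renormalize = FALSE)) - 1),
            1e-3)
  # a corner kernel keeps roughly one quadrant of its mass (slightly more
  # on the discrete grid, which includes the centre row and column)
  expect_lt(integrate_density(gaussian_density(corner, renormalize = FALSE)),
            0.35)
})

test_that("density generation is translation equivariant in the interior", {
  set.seed(3)
  base <- cbind(runif(12, 20, 30), runif(12, 20, 30))
  d1 <- gaussian_density(point_set(base, 96, 96))$grid
  d2 <- gaussian_density(point_set(base + 5, 96, 96))$grid
  # shift rows/cols by 5: interior windows are identical
  expect_equal(d2[6:96, 6:96], d1[1:91, 1:91], tolerance = 1e-12)
})

test_that("density superposes over point-set unions", {
  set.seed(9)
  a <- cbind(runif(15, 0, 63), runif(15, 0, 63))
  b <- cbind(runif(10, 0, 63), runif(10, 0, 63))
  da <- gaussian_density(point_set(a, 64, 64))$grid
  db <- gaussian_density(point_set(b, 64, 64))$grid
  dab <- gaussian_density(point_set(rbind(a, b), 64, 64))$grid
  expect_lt(max(abs(dab - (da + db))), 1e-9)
})

test_that("integration is linear and defaults are as documented", {
  expect_identical(integrate_density(density_map(matrix(0, 5, 5))), 0)
  ps <- random_point_set(250, 256, 256)
  dm <- gaussian_density(ps)
  expect_equal(dm$sigma, 3)           # default kernel bandwidth
  expect_lt(abs(integrate_density(dm) - 250), 1e-6)
  scaled <- density_map(dm$grid * 2)
  expect_equal(integrate_density(scaled), 2 * integrate_density(dm))
  expect_error(gaussian_density(ps, sigma = 0), "positive")
  expect_error(gaussian_density(ps, sigma = -2), "positive")
})

test_that("density archives round trip grid and metadata", {
  ps <- random_point_set(20, 40, 30)
  dm <- gaussian_density(ps)
  f <- tempfile(fileext = ".npy")
  save_density(dm, f, source = "scene_0001.png")
  back <- load_density(f)
  expect_equal(back$grid, dm$grid, tolerance = 1e-12)
  expect_equal(back$sigma, 3)
  png_path <- tempfile(fileext = ".png")
  density_png(dm, png_path)
  expect_true(file.exists(png_path))
})
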