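# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's own code paths: densities are
# evaluated per point on the full grid, SSIM windows are extracted and
# reduced explicitly.

# Direct per-point, per-pixel Gaussian density evaluation with the same
# per-axis truncation window and in-bounds renormalisation convention.
oracle_density <- function(ps, sigma = 3, truncate = 4, renormalize = TRUE) {
  H <- ps$height; W <- ps$width
  grid <- matrix(0, H, W)
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  r <- truncate * sigma
  for (i in seq_len(n_points(ps))) {
    x <- ps$points[i, 1L]; y <- ps$points[i, 2L]
    k <- exp(-outer((ys - y)^2, (xs - x)^2, "+") / (2 * sigma^2)) /
      (2 * pi * sigma^2)
    mask <- outer(abs(ys - y) <= r, abs(xs - x) <= r, "&")
    k[!mask] <- 0
    if (renormalize) k <- k / sum(k)
    grid <- grid + k
  }
  grid
}

# Windowed SSIM by explicit window extraction (valid region, Gaussian
# weights), averaged over window positions.
oracle_ssim <- function(p, g, cfg) {
  n <- cfg$ssim_window
  half <- (n - 1) / 2
  k1 <- exp(-((-half):half)^2 / (2 * cfg$ssim_window_sigma^2))
  k2 <- outer(k1, k1) / sum(k1)^2
  H <- nrow(p); W <- ncol(p)
  vals <- numeric(0)
  for (i in 1:(H - n + 1)) {
    for (j in 1:(W - n + 1)) {
      wp <- p[i:(i + n - 1), j:(j + n - 1)]
      wg <- g[i:(i + n - 1), j:(j + n - 1)]
      mp <- sum(k2 * wp); mg <- sum(k2 * wg)
      vp <- sum(k2 * wp^2) - mp^2
      vg <- sum(k2 * wg^2) - mg^2
      cv <- sum(k2 * wp * wg) - mp * mg
      vals <- c(vals, ((2 * mp * mg + cfg$c1) * (2 * cv + cfg$c2)) /
                      ((mp^2 + mg^2 + cfg$c1) * (vp + vg + cfg$c2)))
    }
  }
  mean(vals)
}

# random in-bounds point set (border-adjacent points included)
random_point_set <- function(n, width, height) {
  point_set(cbind(stats::runif(n, 0, width - 1e-9),
                  stats::runif(n, 0, height - 1e-9)), width, height)
}

# a tiny model configuration cheap enough for unit tests
tiny_config <- function(...) {
  countnet_config(width_multiplier = 1 / 32, cbam_reduction = 4, ...)
}

# run the package CLI script in a child R process
run_cli <- function(args) {
  script <- system.file("cli", "frycount.R", package = "frycount")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(script, args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(),
                                  collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
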