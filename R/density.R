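#' Ground-truth density maps from point annotations
#'
#' The regression target for counting is a per-pixel density field whose
#' spatial integral equals the object count.  Each annotated point
#' contributes an isotropic 2-D Gaussian of scale `sigma` centred at its
#' continuous (x, y) coordinate and evaluated at pixel centres; summing the
#' per-point kernels gives the map.
#'
#' @name density-maps
NULL

#' Construct a density map object
#' @param grid numeric matrix (height x width) of non-negative densities.
#' @param sigma Gaussian bandwidth used to generate the map (pixels), or
#'   `NA` for maps not produced by kernel smoothing (e.g. model output).
#' @return an object of class `density_map`.
#' @export
density_map <- function(grid, sigma = NA_real_) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("`grid` must be a numeric matrix")
  structure(list(grid = grid, sigma = as.numeric(sigma)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d, integral %.6f, sigma %s\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid),
              ifelse(is.na(x$sigma), "NA", format(x$sigma))))
  invisible(x)
}

.as_grid <- function(dm) {
  if (inherits(dm, "density_map")) dm$grid
  else if (is.matrix(dm)) dm
  else stop("expected a density_map or a matrix")
}

#' Impulse (delta) matrix of a point set
#'
#' Places a unit spike at the nearest pixel of every annotation (ties round
#' toward +infinity), the discrete delta field that kernel smoothing turns
#' into a density map.  The grid sum equals the number of points; coincident
#' points accumulate.
#'
#' @param ps a [point_set].
#' @return an integer matrix of dimension height x width.
#' @export
impulse_matrix <- function(ps) {
  stopifnot(inherits(ps, "point_set"))
  grid <- matrix(0L, nrow = ps$height, ncol = ps$width)
  if (n_points(ps) == 0L) return(grid)
  # 0-based coords -> 1-based indices; round half up, then clip the edge
  # case x = width - 0.5 which would round just past the last pixel
  cx <- pmin(floor(ps$points[, 1L] + 0.5), ps$width - 1L) + 1L
  cy <- pmin(floor(ps$points[, 2L] + 0.5), ps$height - 1L) + 1L
  for (i in seq_along(cx))
    grid[cy[i], cx[i]] <- grid[cy[i], cx[i]] + 1L
  grid
}

#' Gaussian-kernel density map
#'
#' Each point contributes a truncated isotropic Gaussian of scale `sigma`.
#' With `renormalize = TRUE` (default) every kernel is rescaled so that its
#' on-grid, in-bounds mass is exactly 1, making the map integral equal to
#' the point count regardless of truncation or border proximity.  With
#' `renormalize = FALSE` the analytic normalisation 1/(2*pi*sigma^2) is kept
#' (the strict untruncated-convolution convention); border-adjacent points
#' then lose clipped mass.
#'
#' @param ps a [point_set].
#' @param sigma Gaussian bandwidth in pixels (default 3).
#' @param truncate kernel support radius in units of `sigma` (default 4);
#'   `Inf` evaluates every kernel on the full grid.
#' @param renormalize rescale each kernel to unit in-bounds mass.
#' @return a [density_map] with `integrate_density(map) == n_points(ps)`
#'   (up to float rounding) when `renormalize = TRUE`.
#' @export
gaussian_density <- function(ps, sigma = 3, truncate = 4, renormalize = TRUE) {
  stopifnot(inherits(ps, "point_set"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a positive number")
  if (!is.numeric(truncate) || length(truncate) != 1L || truncate <= 0)
    stop("`truncate` must be positive")
  H <- ps$height; W <- ps$width
  grid <- matrix(0, nrow = H, ncol = W)
  norm <- 1 / (2 * pi * sigma^2)
  r <- truncate * sigma
  for (i in seq_len(n_points(ps))) {
    x <- ps$points[i, 1L]; y <- ps$points[i, 2L]
    if (is.finite(r)) {
      ix <- max(0, ceiling(x - r)):min(W - 1, floor(x + r))
      iy <- max(0, ceiling(y - r)):min(H - 1, floor(y + r))
    } else {
      ix <- 0:(W - 1); iy <- 0:(H - 1)
    }
    kx <- exp(-(ix - x)^2 / (2 * sigma^2))
    ky <- exp(-(iy - y)^2 / (2 * sigma^2))
    patch <- norm * outer(ky, kx)
    if (renormalize) patch <- patch / sum(patch)
    grid[iy + 1L, ix + 1L] <- grid[iy + 1L, ix + 1L] + patch
  }
  density_map(grid, sigma = sigma)
}

#' Integrate a density map
#'
#' The count-by-integration convention: the predicted (possibly fractional)
#' object count is the sum of all cells of the density map.
#'
#' @param dm a [density_map] or plain matrix.
#' @return a non-negative real (for non-negative maps).
#' @export
integrate_density <- function(dm) {
  sum(.as_grid(dm))
}

#' Save a density map archive
#'
#' Writes the grid as a `.npy` float array plus a JSON sidecar
#' (`<path>.json`) carrying `sigma` and the source image name.
#'
#' @param dm a [density_map].
#' @param path output `.npy` path.
#' @param source optional source image filename recorded in the sidecar.
#' @export
save_density <- function(dm, path, source = NA_character_) {
  stopifnot(inherits(dm, "density_map"))
  write_npy(dm$grid, path)
  jsonlite::write_json(list(sigma = dm$sigma, source = source),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a density map archive written by [save_density()]
#' @param path the `.npy` path.
#' @return a [density_map].
#' @export
load_density <- function(path) {
  grid <- read_npy(path)
  sigma <- NA_real_
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    if (!is.null(meta$sigma)) sigma <- as.numeric(meta$sigma)
  }
  density_map(grid, sigma = sigma)
}

#' Write a colour-mapped visualization of a density map
#'
#' For display only: the map is normalised per image to `[0, 1]` and pushed
#' through a perceptually uniform palette, echoing the usual colour-bar
#' rendering of predicted density fields.
#'
#' @param dm a [density_map] or matrix.
#' @param path output PNG path.
#' @param palette a palette name understood by [grDevices::hcl.colors()].
#' @export
density_png <- function(dm, path, palette = "viridis") {
  grid <- .as_grid(dm)
  rng <- range(grid)
  norm <- if (diff(rng) > 0) (grid - rng[1L]) / diff(rng) else grid * 0
  cols <- grDevices::hcl.colors(256L, palette)
  idx <- pmin(255L, pmax(0L, as.integer(round(norm * 255)))) + 1L
  rgb <- grDevices::col2rgb(cols[idx]) / 255
  img <- array(0, dim = c(nrow(grid), ncol(grid), 3L))
  img[, , 1L] <- matrix(rgb[1L, ], nrow(grid))
  img[, , 2L] <- matrix(rgb[2L, ], nrow(grid))
  img[, , 3L] <- matrix(rgb[3L, ], nrow(grid))
  png::writePNG(img, path)
  invisible(path)
}
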