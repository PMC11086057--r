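#' Synthetic shrimp-fry scenes
#'
#' The generator emulates the acquisition setting the counting pipeline is
#' designed for: a light tank bottom photographed top-down under diffuse
#' LED light, with up to a thousand small, elongated, slightly curved dark
#' fry per frame.  Each fry is an anti-aliased quadratic-Bezier stroke with
#' a Gaussian cross-profile, alpha-composited on a vignetted light
#' background with additive Gaussian pixel noise.  The annotation point is
#' the stroke centroid, and the point count is exact by construction, so
#' every stage of the pipeline can be exercised with known ground truth.
#'
#' @name synthetic-scenes
NULL

#' Specification of one synthetic scene
#'
#' @param width,height image size in pixels.
#' @param n_fry number of fry to draw (0 to 1000).
#' @param fry_length body length range in pixels.
#' @param fry_width body width range in pixels.
#' @param curvature bend range in radians (quadratic-Bezier control-point
#'   deflection).
#' @param fry_intensity body gray-level range in `[0, 1]` (dark bodies).
#' @param background_level tank-bottom gray level in `[0, 1]`.
#' @param vignette_strength radial light falloff in `[0, 1]`.
#' @param noise_std additive Gaussian pixel noise standard deviation.
#' @param allow_overlap permit overlapping bodies; if `FALSE`, centres are
#'   rejection-sampled to keep pairwise distances `>= min_distance`.
#' @param min_distance minimum centre spacing when `allow_overlap = FALSE`.
#' @param seed RNG seed; the rendered image and points are bitwise
#'   reproducible.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width = 768L, height = 576L, n_fry = 250L,
                       fry_length = c(8, 22), fry_width = c(1.5, 3.5),
                       curvature = c(-0.5, 0.5),
                       fry_intensity = c(0.05, 0.35),
                       background_level = 0.75, vignette_strength = 0.25,
                       noise_std = 0.02, allow_overlap = TRUE,
                       min_distance = 6, seed = 1L) {
  n_fry <- as.integer(n_fry)
  if (is.na(n_fry) || n_fry < 0L || n_fry > 1000L)
    stop("`n_fry` must be in [0, 1000]")
  if (any(fry_length <= 0) || any(fry_width <= 0))
    stop("geometric ranges must be positive")
  if (any(fry_intensity < 0) || any(fry_intensity > 1) ||
      background_level < 0 || background_level > 1)
    stop("intensities must be in [0, 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_fry = n_fry, fry_length = fry_length,
                 fry_width = fry_width, curvature = curvature,
                 fry_intensity = fry_intensity,
                 background_level = background_level,
                 vignette_strength = vignette_strength,
                 noise_std = noise_std,
                 allow_overlap = isTRUE(allow_overlap),
                 min_distance = min_distance, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render one synthetic scene
#'
#' @param spec a [scene_spec()].
#' @return a list with `image` (H x W x 3 array in `[0, 1]`) and `points`
#'   (a [point_set] with exactly `spec$n_fry` centroid annotations).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  W <- spec$width; H <- spec$height
  .with_seed(spec$seed, {
    # vignetted background
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    r2 <- outer(((0:(H - 1)) - cy)^2 / cy^2, ((0:(W - 1)) - cx)^2 / cx^2, "+") / 2
    gray <- spec$background_level * (1 - spec$vignette_strength * r2)
    # fry centres
    margin <- spec$fry_length[2L] / 2 + 4
    if (2 * margin >= min(W, H))
      stop("image too small for the configured fry length")
    centres <- matrix(numeric(0), ncol = 2L)
    if (spec$n_fry > 0L) {
      if (spec$allow_overlap) {
        centres <- cbind(stats::runif(spec$n_fry, margin, W - 1 - margin),
                         stats::runif(spec$n_fry, margin, H - 1 - margin))
      } else {
        centres <- matrix(NA_real_, spec$n_fry, 2L)
        placed <- 0L
        tries <- 0L
        while (placed < spec$n_fry) {
          if (tries > 1000L * spec$n_fry)
            stop("could not place fry without overlap; lower n_fry or min_distance")
          cand <- c(stats::runif(1, margin, W - 1 - margin),
                    stats::runif(1, margin, H - 1 - margin))
          tries <- tries + 1L
          if (placed > 0L) {
            d2 <- (centres[seq_len(placed), 1L] - cand[1L])^2 +
                  (centres[seq_len(placed), 2L] - cand[2L])^2
            if (min(d2) < spec$min_distance^2) next
          }
          placed <- placed + 1L
          centres[placed, ] <- cand
        }
      }
    }
    pts <- matrix(numeric(0), ncol = 2L)
    if (spec$n_fry > 0L) {
      pts <- matrix(0, spec$n_fry, 2L)
      tseq <- seq(0, 1, length.out = 33L)
      for (i in seq_len(spec$n_fry)) {
        L <- stats::runif(1, spec$fry_length[1L], spec$fry_length[2L])
        bw <- stats::runif(1, spec$fry_width[1L], spec$fry_width[2L])
        th <- stats::runif(1, 0, 2 * pi)
        kap <- stats::runif(1, spec$curvature[1L], spec$curvature[2L])
        ii <- stats::runif(1, spec$fry_intensity[1L], spec$fry_intensity[2L])
        u <- c(cos(th), sin(th))          # body axis
        nv <- c(-sin(th), cos(th))        # normal
        c0 <- centres[i, ]
        p0 <- c0 - u * L / 2
        p2 <- c0 + u * L / 2
        p1 <- c0 + nv * (kap * L / 4)
        sx <- (1 - tseq)^2 * p0[1L] + 2 * tseq * (1 - tseq) * p1[1L] +
              tseq^2 * p2[1L]
        sy <- (1 - tseq)^2 * p0[2L] + 2 * tseq * (1 - tseq) * p1[2L] +
              tseq^2 * p2[2L]
        pts[i, ] <- c(mean(sx), mean(sy))
        # stamp the stroke: Gaussian cross-profile around the sampled curve
        pad <- bw + 1.5
        ix <- max(0, floor(min(sx) - pad)):min(W - 1, ceiling(max(sx) + pad))
        iy <- max(0, floor(min(sy) - pad)):min(H - 1, ceiling(max(sy) + pad))
        px <- rep(ix, each = length(iy))
        py <- rep(iy, times = length(ix))
        d2 <- rep(Inf, length(px))
        for (j in seq_along(sx))
          d2 <- pmin(d2, (px - sx[j])^2 + (py - sy[j])^2)
        a <- exp(-d2 / (2 * (bw / 2)^2))
        sub <- gray[iy + 1L, ix + 1L]
        gray[iy + 1L, ix + 1L] <- sub * (1 - a) + ii * a
      }
    }
    gray <- gray + matrix(stats::rnorm(H * W, sd = spec$noise_std), H, W)
    gray <- pmin(pmax(gray, 0), 1)
    # faint cool tint so the three channels are not identical
    img <- array(0, dim = c(H, W, 3L))
    img[, , 1L] <- pmin(pmax(gray * 0.97, 0), 1)
    img[, , 2L] <- gray
    img[, , 3L] <- pmin(pmax(gray * 1.02, 0), 1)
    list(image = img, points = point_set(pts, W, H))
  })
}

#' Specification of a full synthetic dataset
#'
#' Defaults mirror the dataset bookkeeping the pipeline was built around:
#' four density levels (Low `[0, 249]`, Medium `[250, 499]`, High
#' `[500, 749]`, Higher `[750, 1000]`) with per-level image counts of
#' 121/139/105/25 (train), 21/15/14/13 (validation), and 55/11/19/18
#' (test) — 390, 63, and 103 images per split.
#'
#' @param splits data frame with columns `level`, `lo`, `hi`, `train`,
#'   `validation`, `test`.
#' @param scene a [scene_spec()] template (its `n_fry` and `seed` are
#'   overridden per image).
#' @param seed master seed for per-image counts and scene seeds.
#' @return an object of class `dataset_spec`.
#' @export
dataset_spec <- function(splits = NULL, scene = scene_spec(), seed = 1L) {
  if (is.null(splits)) {
    r <- density_level_ranges()
    splits <- data.frame(level = r$level, lo = r$lo, hi = r$hi,
                         train = c(121L, 139L, 105L, 25L),
                         validation = c(21L, 15L, 14L, 13L),
                         test = c(55L, 11L, 19L, 18L),
                         stringsAsFactors = FALSE)
  }
  need <- c("level", "lo", "hi", "train", "validation", "test")
  if (!all(need %in% names(splits)))
    stop("`splits` must have columns ", paste(need, collapse = ", "))
  if (any(splits$train < 0L | splits$validation < 0L | splits$test < 0L))
    stop("per-level image counts must be >= 0")
  structure(list(splits = splits, scene = scene, seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Generate and write a synthetic dataset
#'
#' For every split and density level, draws each image's fry count
#' uniformly within the level's range, renders the scene, and writes
#' `images/<stem>.png`, `points/<stem>.csv`, a `manifest.csv`
#' (filename, split, count, level), and a `generator_params.json`
#' provenance record.
#'
#' @param ds a [dataset_spec()].
#' @param out_dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
make_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "dataset_spec"))
  sp <- ds$splits
  total <- sum(sp$train + sp$validation + sp$test)
  manifest <- data.frame(filename = character(0), split = character(0),
                         count = integer(0), level = character(0),
                         stringsAsFactors = FALSE)
  if (total == 0L) return(invisible(manifest))
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "points"), recursive = TRUE,
             showWarnings = FALSE)
  plan <- do.call(rbind, lapply(c("train", "validation", "test"),
    function(split) do.call(rbind, lapply(seq_len(nrow(sp)), function(r) {
      n <- sp[[split]][r]
      if (n == 0L) return(NULL)
      data.frame(split = split, level = sp$level[r], lo = sp$lo[r],
                 hi = sp$hi[r], stringsAsFactors = FALSE)[rep(1L, n), ]
    }))))
  rownames(plan) <- NULL
  draws <- .with_seed(ds$seed, list(
    counts = sp$lo[match(plan$level, sp$level)] +
      floor(stats::runif(nrow(plan)) *
              (sp$hi[match(plan$level, sp$level)] -
                 sp$lo[match(plan$level, sp$level)] + 1L)),
    seeds = sample.int(.Machine$integer.max - 1L, nrow(plan))))
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    spec <- ds$scene
    spec$n_fry <- as.integer(draws$counts[i])
    spec$seed <- draws$seeds[i]
    sc <- render_scene(spec)
    stem <- sprintf("%s_%s_%04d", plan$split[i], tolower(plan$level[i]), i)
    png::writePNG(sc$image, file.path(out_dir, "images",
                                      paste0(stem, ".png")))
    write_points(sc$points, file.path(out_dir, "points",
                                      paste0(stem, ".csv")))
    rows[[i]] <- data.frame(filename = paste0(stem, ".png"),
                            split = plan$split[i],
                            count = spec$n_fry, level = plan$level[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  gp <- ds$scene
  gp$seed <- ds$seed
  jsonlite::write_json(unclass(gp), file.path(out_dir,
                                              "generator_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' In-memory benchmark of easy low-density scenes
#'
#' Small (192 x 144), high-contrast, low-noise scenes with widely spaced
#' fry, intended for CPU-scale training experiments.  Counts are drawn
#' uniformly within `counts` (bounded by `[0, 60]`).
#'
#' @param n_images number of scenes.
#' @param counts integer count range `c(lo, hi)` within `[0, 60]`.
#' @param seed master seed; generation is deterministic.
#' @return a list of samples, each a list with `image`, `points`, `count`,
#'   and `name`.
#' @export
easy_benchmark <- function(n_images = 60L, counts = c(5L, 40L), seed = 42L) {
  if (counts[1L] < 0L || counts[2L] > 60L || counts[1L] > counts[2L])
    stop("`counts` must lie within [0, 60]")
  draws <- .with_seed(seed, list(
    counts = counts[1L] + floor(stats::runif(n_images) *
                                  (counts[2L] - counts[1L] + 1L)),
    seeds = sample.int(.Machine$integer.max - 1L, n_images)))
  lapply(seq_len(n_images), function(i) {
    spec <- scene_spec(width = 192L, height = 144L,
                       n_fry = as.integer(draws$counts[i]),
                       fry_length = c(7, 14), fry_width = c(1.5, 2.5),
                       fry_intensity = c(0.05, 0.2),
                       vignette_strength = 0.1, noise_std = 0.01,
                       allow_overlap = FALSE, min_distance = 8,
                       seed = draws$seeds[i])
    sc <- render_scene(spec)
    list(image = sc$image, points = sc$points, count = spec$n_fry,
         name = sprintf("easy_%03d", i))
  })
}
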