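#' Load a dataset directory
#'
#' Reads the `manifest.csv` layout written by [make_dataset()]:
#' `images/` (PNG), `points/` (matching stems, csv/json/npy), and an
#' optional `densities/` cache of `.npy` maps written by
#' [densify_dataset()].  Without a cache, ground-truth density maps are
#' generated on the fly with [gaussian_density()].
#'
#' @param dir dataset directory.
#' @param split optional split filter (`"train"`, `"validation"`,
#'   `"test"`).
#' @param sigma Gaussian bandwidth for on-the-fly density maps.
#' @param with_density attach density maps (set `FALSE` to save memory
#'   when only counts are needed).
#' @return a list of samples (`image`, `points`, `density`, `count`,
#'   `name`, `split`).
#' @export
load_count_dataset <- function(dir, split = NULL, sigma = 3,
                               with_density = TRUE) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop(sprintf("no manifest.csv under %s", dir))
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  if (!is.null(split)) manifest <- manifest[manifest$split == split, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    fn <- manifest$filename[i]
    stem <- tools::file_path_sans_ext(fn)
    img <- png::readPNG(file.path(dir, "images", fn))
    if (length(dim(img)) == 2L)
      img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
    ppath <- NULL
    for (ext in c(".csv", ".json", ".npy")) {
      cand <- file.path(dir, "points", paste0(stem, ext))
      if (file.exists(cand)) { ppath <- cand; break }
    }
    if (is.null(ppath)) stop(sprintf("no annotation file for %s", stem))
    ps <- read_points(ppath, width = dim(img)[2L], height = dim(img)[1L])
    dens <- NULL
    if (with_density) {
      dpath <- file.path(dir, "densities", paste0(stem, ".npy"))
      dens <- if (file.exists(dpath)) load_density(dpath)
              else gaussian_density(ps, sigma = sigma)
    }
    list(image = img, points = ps, density = dens,
         count = n_points(ps), name = stem, split = manifest$split[i])
  })
}

#' Precompute and cache ground-truth density maps
#'
#' Runs [gaussian_density()] over every annotated image of a dataset
#' directory and writes the maps to `densities/<stem>.npy` archives.
#'
#' @param dir dataset directory with `manifest.csv`.
#' @param sigma Gaussian bandwidth in pixels (default 3).
#' @return the number of maps written, invisibly.
#' @export
densify_dataset <- function(dir, sigma = 3) {
  samples <- load_count_dataset(dir, with_density = FALSE)
  dir.create(file.path(dir, "densities"), showWarnings = FALSE)
  for (s in samples) {
    dm <- gaussian_density(s$points, sigma = sigma)
    save_density(dm, file.path(dir, "densities", paste0(s$name, ".npy")),
                 source = s$name)
  }
  invisible(length(samples))
}
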