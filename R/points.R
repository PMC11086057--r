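#' Point annotations for one image
#'
#' A `point_set` holds one (x, y) click per animal, in 0-based pixel
#' coordinates (`x` = column, `y` = row, sub-pixel positions allowed),
#' together with the image dimensions.  Duplicate points are legal: two fry
#' annotated at the same pixel count twice.
#'
#' @param points numeric matrix or data frame with two columns (x, y); may
#'   have zero rows.
#' @param width,height image dimensions in pixels.
#' @param clamp if `TRUE`, out-of-bounds coordinates are clamped into
#'   `[0, width)` x `[0, height)` with a warning instead of raising an error.
#' @return an object of class `point_set`.
#' @export
point_set <- function(points, width, height, clamp = FALSE) {
  if (is.null(points) || (is.data.frame(points) && nrow(points) == 0L) ||
      (is.matrix(points) && nrow(points) == 0L) || length(points) == 0L) {
    pts <- matrix(numeric(0), ncol = 2L)
  } else {
    if (is.data.frame(points)) points <- as.matrix(points)
    if (!is.matrix(points) || ncol(points) != 2L)
      stop("`points` must be an N x 2 matrix of (x, y) coordinates")
    pts <- matrix(as.numeric(points), ncol = 2L)
  }
  width <- as.integer(width); height <- as.integer(height)
  if (length(width) != 1L || length(height) != 1L ||
      is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("`width` and `height` must be positive integers")
  if (nrow(pts) > 0L) {
    bad <- pts[, 1L] < 0 | pts[, 1L] >= width |
           pts[, 2L] < 0 | pts[, 2L] >= height | !is.finite(pts[, 1L]) |
           !is.finite(pts[, 2L])
    if (any(bad)) {
      if (!clamp)
        stop(sprintf("%d point(s) outside [0, %d) x [0, %d); use clamp = TRUE to clip",
                     sum(bad), width, height))
      warning(sprintf("clamped %d out-of-bounds point(s)", sum(bad)))
      eps <- 1e-9
      pts[, 1L] <- pmin(pmax(pts[, 1L], 0), width - eps)
      pts[, 2L] <- pmin(pmax(pts[, 2L], 0), height - eps)
    }
  }
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, width = width, height = height),
            class = "point_set")
}

#' Number of annotated points
#' @param ps a [point_set].
#' @return integer count.
#' @export
n_points <- function(ps) {
  stopifnot(inherits(ps, "point_set"))
  nrow(ps$points)
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d point(s) on a %d x %d image\n",
              n_points(x), x$width, x$height))
  invisible(x)
}

.ps_format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         npy = "npy", csv = "csv", json = "json",
         stop(sprintf("cannot infer annotation format from extension '.%s'", ext)))
}

.ps_dims <- function(width, height, image, path) {
  if (!is.null(width) && !is.null(height)) return(c(width, height))
  if (!is.null(image)) {
    img <- png::readPNG(image)
    return(c(dim(img)[2L], dim(img)[1L]))
  }
  # companion image with the same stem
  stem <- tools::file_path_sans_ext(path)
  for (ext in c(".png", ".PNG")) {
    cand <- paste0(stem, ext)
    if (file.exists(cand)) {
      img <- png::readPNG(cand)
      return(c(dim(img)[2L], dim(img)[1L]))
    }
  }
  stop("image dimensions unavailable: pass `width`/`height`, an `image` path, ",
       "or keep a companion .png next to the annotation file")
}

#' Read point annotations
#'
#' Supported formats: `npy` (an N x 2 float array, the convention of common
#' point-labelling tools), `csv` (header `x,y`), and `json` (either a bare
#' list of `[x, y]` pairs or an object with `width`, `height` and `points`
#' fields).  Image dimensions come from the JSON sidecar fields, from
#' explicit `width`/`height` arguments, or from a companion PNG with the
#' same stem.
#'
#' @param path annotation file.
#' @param format one of `"auto"`, `"npy"`, `"csv"`, `"json"`.
#' @param width,height image dimensions (required for npy/csv unless a
#'   companion image exists).
#' @param image optional path to the annotated PNG, used for dimensions.
#' @param clamp passed to [point_set()].
#' @return a [point_set].
#' @export
read_points <- function(path, format = c("auto", "npy", "csv", "json"),
                        width = NULL, height = NULL, image = NULL,
                        clamp = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  if (format == "auto") format <- .ps_format_from_path(path)
  if (format == "npy") {
    arr <- read_npy(path)
    if (length(dim(arr)) != 2L || ncol(arr) != 2L)
      stop(sprintf("expected an N x 2 array, got shape (%s)",
                   paste(dim(arr), collapse = ", ")))
    dims <- .ps_dims(width, height, image, path)
    return(point_set(arr, dims[1L], dims[2L], clamp = clamp))
  }
  if (format == "csv") {
    df <- utils::read.csv(path)
    if (!all(c("x", "y") %in% names(df)))
      stop("CSV annotations need columns 'x' and 'y'")
    dims <- .ps_dims(width, height, image, path)
    return(point_set(as.matrix(df[, c("x", "y")]), dims[1L], dims[2L],
                     clamp = clamp))
  }
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.list(obj) && !is.null(obj$points)) {
    pts <- obj$points
    if (length(pts) == 0L) pts <- matrix(numeric(0), ncol = 2L)
    dims <- c(
      if (!is.null(width)) width else obj$width,
      if (!is.null(height)) height else obj$height
    )
    if (length(dims) != 2L) dims <- .ps_dims(width, height, image, path)
    return(point_set(pts, dims[1L], dims[2L], clamp = clamp))
  }
  pts <- if (length(obj) == 0L) matrix(numeric(0), ncol = 2L) else obj
  dims <- .ps_dims(width, height, image, path)
  point_set(pts, dims[1L], dims[2L], clamp = clamp)
}

#' Write point annotations
#'
#' Inverse of [read_points()].  JSON output carries `width`/`height` sidecar
#' fields; npy and CSV store coordinates only.
#'
#' @param ps a [point_set].
#' @param path output file.
#' @param format one of `"auto"`, `"npy"`, `"csv"`, `"json"`.
#' @export
write_points <- function(ps, path, format = c("auto", "npy", "csv", "json")) {
  stopifnot(inherits(ps, "point_set"))
  format <- match.arg(format)
  if (format == "auto") format <- .ps_format_from_path(path)
  if (format == "npy") {
    write_npy(ps$points, path)
  } else if (format == "csv") {
    utils::write.csv(as.data.frame(ps$points), path, row.names = FALSE)
  } else {
    obj <- list(width = ps$width, height = ps$height,
                points = unname(ps$points))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  invisible(path)
}

# --- minimal .npy (NumPy array format v1.0) reader/writer ------------------
# Only what point annotations need: little-endian f8/f4/i8/i4 numeric arrays
# of rank 1 or 2, C or Fortran order.

#' Read a .npy numeric array
#' @param path file path.
#' @return a numeric vector or matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY"))))
    stop("not a .npy file (bad magic)")
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1L]) >= 2L)
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  else
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header, regexpr("'descr':\\s*'[^']+'", header))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", descr)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- if (length(shape) == 0L) 1L else prod(shape)
  type <- substr(descr, 2L, 2L)
  size <- as.integer(substr(descr, 3L, 3L))
  vals <- switch(type,
    f = readBin(con, "double", n, size = size, endian = "little"),
    i = readBin(con, "integer", n, size = size, endian = "little"),
    u = readBin(con, "integer", n, size = size, signed = FALSE,
                endian = "little"),
    stop(sprintf("unsupported .npy dtype '%s'", descr)))
  vals <- as.numeric(vals)
  if (length(shape) <= 1L) return(vals)
  if (length(shape) != 2L) stop("only rank-1 or rank-2 .npy arrays supported")
  if (fortran) matrix(vals, nrow = shape[1L], ncol = shape[2L])
  else t(matrix(vals, nrow = shape[2L], ncol = shape[1L]))
}

#' Write a numeric vector or matrix as .npy (float64, C order)
#' @param x numeric vector or matrix.
#' @param path output file.
#' @export
write_npy <- function(x, path) {
  shape <- if (is.matrix(x)) sprintf("(%d, %d)", nrow(x), ncol(x))
           else sprintf("(%d,)", length(x))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                    shape)
  # pad so that magic(6) + version(2) + hlen(2) + header is a multiple of 64
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  data <- if (is.matrix(x)) as.numeric(t(x)) else as.numeric(x)
  writeBin(data, con, size = 8L, endian = "little")
  invisible(path)
}
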