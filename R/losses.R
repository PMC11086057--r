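#' Loss configuration
#'
#' The training objective is a Euclidean (sum-of-squared-differences) loss
#' on the density maps plus an `alpha`-weighted structural-similarity term:
#' `L = LE + alpha * LSSIM`.  `alpha` defaults to 0.001, balancing the
#' magnitudes of the two terms.  SSIM uses the standard protocol: an 11x11
#' Gaussian window of scale 1.5 px, stabilising constants `c1 = (0.01 L)^2`
#' and `c2 = (0.03 L)^2` with dynamic range `L = 1`, applied to the density
#' maps as-is.
#'
#' @param alpha weight of the SSIM loss term (>= 0).
#' @param ssim_window odd window size in pixels (>= 3).
#' @param ssim_window_sigma Gaussian window scale in pixels.
#' @param c1,c2 SSIM stabilising constants (> 0).
#' @param euclidean_norm `"sum_half_batch"` for `(1/2B) * sum of squared
#'   differences` (the convention matching very small learning rates), or
#'   `"mean"` for a per-pixel mean.
#' @param windowed if `FALSE`, SSIM uses single global image statistics
#'   instead of the windowed local protocol.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.001, ssim_window = 11L,
                        ssim_window_sigma = 1.5, c1 = 1e-4, c2 = 9e-4,
                        euclidean_norm = c("sum_half_batch", "mean"),
                        windowed = TRUE) {
  euclidean_norm <- match.arg(euclidean_norm)
  ssim_window <- as.integer(ssim_window)
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (ssim_window < 3L || ssim_window %% 2L == 0L)
    stop("`ssim_window` must be an odd integer >= 3")
  if (c1 <= 0 || c2 <= 0) stop("`c1` and `c2` must be > 0")
  if (ssim_window_sigma <= 0) stop("`ssim_window_sigma` must be > 0")
  structure(list(alpha = alpha, ssim_window = ssim_window,
                 ssim_window_sigma = ssim_window_sigma, c1 = c1, c2 = c2,
                 euclidean_norm = euclidean_norm, windowed = windowed),
            class = "loss_config")
}

.as_batch <- function(x) {
  if (inherits(x, "density_map")) return(list(x$grid))
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) return(lapply(x, .as_grid))
  stop("expected a matrix, density_map, or list of them")
}

.check_batch <- function(pred, gt) {
  if (length(pred) != length(gt))
    stop("prediction and ground-truth batches differ in length")
  for (i in seq_along(pred))
    if (!identical(dim(pred[[i]]), dim(gt[[i]])))
      stop("prediction and ground-truth map shapes differ")
}

#' Euclidean density-map loss
#'
#' `(1/(2B)) * sum_b ||pred_b - gt_b||^2` over a batch of B maps (default
#' convention), or the per-pixel mean squared difference when
#' `norm = "mean"`.
#'
#' @param pred,gt matrices, [density_map]s, or lists of them (a batch).
#' @param norm see [loss_config()].
#' @return a non-negative scalar.
#' @export
euclidean_loss <- function(pred, gt, norm = c("sum_half_batch", "mean")) {
  norm <- match.arg(norm)
  pred <- .as_batch(pred); gt <- .as_batch(gt)
  .check_batch(pred, gt)
  ss <- vapply(seq_along(pred),
               function(i) sum((pred[[i]] - gt[[i]])^2), numeric(1L))
  if (norm == "sum_half_batch") sum(ss) / (2 * length(pred))
  else sum(ss) / sum(vapply(pred, length, numeric(1L)))
}

.ssim_kernel <- function(cfg) {
  half <- (cfg$ssim_window - 1L) / 2L
  k <- exp(-((-half):half)^2 / (2 * cfg$ssim_window_sigma^2))
  k / sum(k)
}

.ssim_stats <- function(p, g, cfg) {
  k <- .ssim_kernel(cfg)
  if (cfg$ssim_window > min(dim(p)))
    stop("SSIM window larger than image")
  mu_p <- cpp_sepconv_valid(p, k)
  mu_g <- cpp_sepconv_valid(g, k)
  m_pp <- cpp_sepconv_valid(p * p, k)
  m_gg <- cpp_sepconv_valid(g * g, k)
  m_pg <- cpp_sepconv_valid(p * g, k)
  list(k = k, mu_p = mu_p, mu_g = mu_g,
       var_p = m_pp - mu_p^2, var_g = m_gg - mu_g^2,
       cov = m_pg - mu_p * mu_g)
}

.ssim_map <- function(st, cfg) {
  A1 <- 2 * st$mu_p * st$mu_g + cfg$c1
  A2 <- 2 * st$cov + cfg$c2
  B1 <- st$mu_p^2 + st$mu_g^2 + cfg$c1
  B2 <- st$var_p + st$var_g + cfg$c2
  list(A1 = A1, A2 = A2, B1 = B1, B2 = B2, S = (A1 * A2) / (B1 * B2))
}

#' Structural similarity index between two density maps
#'
#' Local means, variances, and covariance are computed with a Gaussian
#' window over the valid region (pixels where the full window fits) and the
#' similarity is averaged over those pixels.  Returns a value in
#' `[-1, 1]`, 1 meaning structurally identical maps.  With
#' `cfg$windowed = FALSE` the statistics are global image moments and a
#' single similarity value is computed.
#'
#' @param pred,gt single-channel matrices (or [density_map]s) of equal size.
#' @param cfg a [loss_config()].
#' @return a scalar in `[-1, 1]`.
#' @export
ssim_index <- function(pred, gt, cfg = loss_config()) {
  p <- .as_grid(pred); g <- .as_grid(gt)
  if (!identical(dim(p), dim(g))) stop("map shapes differ")
  if (!cfg$windowed) {
    mu_p <- mean(p); mu_g <- mean(g)
    var_p <- mean((p - mu_p)^2); var_g <- mean((g - mu_g)^2)
    cov <- mean((p - mu_p) * (g - mu_g))
    return(((2 * mu_p * mu_g + cfg$c1) * (2 * cov + cfg$c2)) /
           ((mu_p^2 + mu_g^2 + cfg$c1) * (var_p + var_g + cfg$c2)))
  }
  st <- .ssim_stats(p, g, cfg)
  mean(.ssim_map(st, cfg)$S)
}

# Gradient of ssim_index(p, g) with respect to p (same shape as p).
.ssim_index_grad <- function(p, g, cfg) {
  st <- .ssim_stats(p, g, cfg)
  sm <- .ssim_map(st, cfg)
  n_valid <- length(sm$S)
  dS <- matrix(1 / n_valid, nrow(sm$S), ncol(sm$S))
  dA1 <- dS * sm$A2 / (sm$B1 * sm$B2)
  dA2 <- dS * sm$A1 / (sm$B1 * sm$B2)
  dB1 <- -dS * sm$S / sm$B1
  dB2 <- -dS * sm$S / sm$B2
  # through the pointwise formulas to the windowed moments
  g_mu_p <- dA1 * 2 * st$mu_g + dB1 * 2 * st$mu_p +
            dA2 * 2 * (-st$mu_g) + dB2 * (-2 * st$mu_p)
  g_mpp <- dB2                  # d var_p / d m_pp = 1
  g_mpg <- dA2 * 2              # d cov / d m_pg = 1
  H <- nrow(p); W <- ncol(p)
  cpp_sepconv_valid_t(g_mu_p, st$k, H, W) +
    2 * p * cpp_sepconv_valid_t(g_mpp, st$k, H, W) +
    g * cpp_sepconv_valid_t(g_mpg, st$k, H, W)
}

#' SSIM loss
#'
#' `1 - mean over the batch of ssim_index(pred_b, gt_b)`, in `[0, 2]`.
#'
#' @inheritParams euclidean_loss
#' @param cfg a [loss_config()].
#' @return a scalar in `[0, 2]`.
#' @export
ssim_loss <- function(pred, gt, cfg = loss_config()) {
  pred <- .as_batch(pred); gt <- .as_batch(gt)
  .check_batch(pred, gt)
  idx <- vapply(seq_along(pred),
                function(i) ssim_index(pred[[i]], gt[[i]], cfg), numeric(1L))
  1 - mean(idx)
}

#' Combined training loss
#'
#' `L = LE + alpha * LSSIM`: Euclidean loss plus the `alpha`-weighted SSIM
#' loss (default `alpha = 0.001`).
#'
#' @inheritParams ssim_loss
#' @return a non-negative scalar; 0 iff the batches are pixelwise equal
#'   (for `alpha > 0`).
#' @export
combined_loss <- function(pred, gt, cfg = loss_config()) {
  euclidean_loss(pred, gt, norm = cfg$euclidean_norm) +
    cfg$alpha * ssim_loss(pred, gt, cfg)
}

# Gradient of combined_loss with respect to each predicted map.
.combined_loss_grad <- function(pred, gt, cfg) {
  pred <- .as_batch(pred); gt <- .as_batch(gt)
  .check_batch(pred, gt)
  B <- length(pred)
  lapply(seq_len(B), function(i) {
    dE <- if (cfg$euclidean_norm == "sum_half_batch")
      (pred[[i]] - gt[[i]]) / B
    else
      2 * (pred[[i]] - gt[[i]]) /
        (B * length(pred[[i]]))
    dS <- if (cfg$alpha > 0)
      -cfg$alpha / B * .ssim_index_grad(pred[[i]], gt[[i]], cfg)
    else 0
    dE + dS
  })
}

#' Mean absolute counting error
#'
#' `MAE = (1/N) * sum |y_i - yhat_i|` over per-image (true, predicted)
#' count pairs.
#'
#' @param truth,predicted numeric vectors of equal, positive length.
#' @return a non-negative scalar.
#' @export
count_mae <- function(truth, predicted) {
  .check_pairs(truth, predicted)
  mean(abs(truth - predicted))
}

#' Root-mean-square counting error
#'
#' `RMSE = sqrt((1/N) * sum (y_i - yhat_i)^2)`; always `>= count_mae()` on
#' the same pairs.
#'
#' @inheritParams count_mae
#' @return a non-negative scalar.
#' @export
count_rmse <- function(truth, predicted) {
  .check_pairs(truth, predicted)
  sqrt(mean((truth - predicted)^2))
}

.check_pairs <- function(truth, predicted) {
  if (length(truth) == 0L) stop("empty count vector")
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length")
  invisible(NULL)
}
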