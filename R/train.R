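#' Training configuration
#'
#' The published optimisation recipe: SGD with momentum 0.95, weight decay
#' 5e-4, learning rate 1e-7, batch size 10, 300 epochs, 768 x 576 centre
#' crops, and two independent 50%-probability augmentations (horizontal
#' mirror and 180-degree rotation).  The default learning rate is matched
#' to the sum-convention Euclidean loss on full-size data; scaled-down
#' smoke runs typically raise it (e.g. 1e-6).
#'
#' @param epochs number of training epochs.
#' @param batch_size images per SGD step.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay coefficient.
#' @param optimizer only `"sgd"`.
#' @param flip_prob probability of a horizontal mirror per sample.
#' @param rotate180_prob probability of a 180-degree rotation per sample.
#' @param crop_width,crop_height centre-crop target (divisible by 8).
#' @param seed RNG seed covering shuffling and augmentation.
#' @param loss a [loss_config()].
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, batch_size = 10L,
                         learning_rate = 1e-7, momentum = 0.95,
                         weight_decay = 5e-4, optimizer = c("sgd"),
                         flip_prob = 0.5, rotate180_prob = 0.5,
                         crop_width = 768L, crop_height = 576L,
                         seed = 42L, loss = loss_config()) {
  optimizer <- match.arg(optimizer)
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 0L) stop("`epochs` must be >= 0")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  if (flip_prob < 0 || flip_prob > 1 || rotate180_prob < 0 ||
      rotate180_prob > 1)
    stop("augmentation probabilities must be in [0, 1]")
  if (crop_width %% 8L != 0L || crop_height %% 8L != 0L)
    stop("crop dimensions must be divisible by 8")
  stopifnot(inherits(loss, "loss_config"))
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, optimizer = optimizer,
                 flip_prob = flip_prob, rotate180_prob = rotate180_prob,
                 crop_width = as.integer(crop_width),
                 crop_height = as.integer(crop_height),
                 seed = as.integer(seed), loss = loss),
            class = "train_config")
}

#' Read a training configuration from a YAML file
#'
#' Keys mirror [train_config()] (a nested `loss` block maps onto
#' [loss_config()]); unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `train_config`.
#' @export
read_train_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(train_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop(sprintf("unknown train config key(s): %s", paste(bad, collapse = ", ")))
  if (!is.null(vals$loss)) {
    lknown <- names(formals(loss_config))
    lbad <- setdiff(names(vals$loss), lknown)
    if (length(lbad) > 0L)
      stop(sprintf("unknown loss config key(s): %s", paste(lbad, collapse = ", ")))
    vals$loss <- do.call(loss_config, vals$loss)
  }
  do.call(train_config, vals)
}

#' Centre-crop an image and its annotations
#'
#' The crop window is centred with floor offsets on odd remainders; points
#' outside the window are dropped and survivors are shifted into window
#' coordinates.
#'
#' @param image H x W x 3 array (or H x W matrix).
#' @param ps optional [point_set] for the same image.
#' @param width,height crop target; the image must be at least this large.
#' @return a list with `image`, `points` (or `NULL`), and the window
#'   `offset` `c(x, y)`.
#' @export
center_crop <- function(image, ps = NULL, width = 768L, height = 576L) {
  d <- dim(image)
  H <- d[1L]; W <- d[2L]
  if (H < height || W < width)
    stop(sprintf("image (%d x %d) smaller than crop target (%d x %d)",
                 W, H, width, height))
  ox <- (W - width) %/% 2L
  oy <- (H - height) %/% 2L
  img <- if (length(d) == 3L)
    image[oy + seq_len(height), ox + seq_len(width), , drop = FALSE]
  else image[oy + seq_len(height), ox + seq_len(width), drop = FALSE]
  out_ps <- NULL
  if (!is.null(ps)) {
    stopifnot(inherits(ps, "point_set"))
    x <- ps$points[, 1L] - ox
    y <- ps$points[, 2L] - oy
    keep <- x >= 0 & x < width & y >= 0 & y < height
    out_ps <- point_set(cbind(x[keep], y[keep]), width, height)
  }
  list(image = img, points = out_ps, offset = c(x = ox, y = oy))
}

.flip_h <- function(a) {
  if (length(dim(a)) == 3L) a[, rev(seq_len(dim(a)[2L])), , drop = FALSE]
  else a[, rev(seq_len(ncol(a))), drop = FALSE]
}

.rot180 <- function(a) {
  if (length(dim(a)) == 3L)
    a[rev(seq_len(dim(a)[1L])), rev(seq_len(dim(a)[2L])), , drop = FALSE]
  else a[rev(seq_len(nrow(a))), rev(seq_len(ncol(a))), drop = FALSE]
}

#' Random flip augmentation
#'
#' With probability `cfg$flip_prob` applies a horizontal mirror and,
#' independently, with probability `cfg$rotate180_prob` a 180-degree
#' rotation.  Image, density map, and points are transformed identically,
#' so the annotated count is invariant.  Randomness is drawn from the
#' caller's RNG stream.
#'
#' @param image H x W x 3 array.
#' @param dm [density_map] or matrix aligned with `image` (or `NULL`).
#' @param ps [point_set] (or `NULL`).
#' @param cfg a [train_config()].
#' @return a list with transformed `image`, `density`, `points`.
#' @export
augment <- function(image, dm = NULL, ps = NULL, cfg = train_config()) {
  W <- dim(image)[2L]; H <- dim(image)[1L]
  grid <- if (is.null(dm)) NULL else .as_grid(dm)
  pts <- if (is.null(ps)) NULL else ps$points
  if (stats::runif(1) < cfg$flip_prob) {
    image <- .flip_h(image)
    if (!is.null(grid)) grid <- .flip_h(grid)
    if (!is.null(pts) && nrow(pts) > 0L) pts[, 1L] <- W - 1 - pts[, 1L]
  }
  if (stats::runif(1) < cfg$rotate180_prob) {
    image <- .rot180(image)
    if (!is.null(grid)) grid <- .rot180(grid)
    if (!is.null(pts) && nrow(pts) > 0L) {
      pts[, 1L] <- W - 1 - pts[, 1L]
      pts[, 2L] <- H - 1 - pts[, 2L]
    }
  }
  list(image = image,
       density = if (is.null(grid)) NULL else
         density_map(grid, if (inherits(dm, "density_map")) dm$sigma
                     else NA_real_),
       points = if (is.null(pts)) NULL else point_set(pts, W, H))
}

.sample_count <- function(s) {
  if (!is.null(s$count)) return(s$count)
  if (!is.null(s$points)) return(n_points(s$points))
  if (!is.null(s$density)) return(integrate_density(s$density))
  stop("dataset sample has no count, points, or density")
}

.sample_density <- function(s, sigma = 3) {
  if (!is.null(s$density)) return(.as_grid(s$density))
  if (!is.null(s$points)) return(gaussian_density(s$points, sigma)$grid)
  stop("dataset sample has no density map or points")
}

#' Train the counting network
#'
#' Minimises the combined Euclidean + SSIM loss with SGD (momentum,
#' weight decay) at the configured recipe.  Per epoch the training set is
#' reshuffled, each sample is augmented, batches are formed, and validation
#' MAE/RMSE are computed from integrated counts.  The returned model
#' carries the weights of the epoch with the lowest validation MAE; the
#' history records every epoch.  Fully deterministic given `cfg$seed`.
#'
#' @param model a `countnet` (its weights are the starting point).
#' @param train_set,val_set lists of samples; each sample is a list with an
#'   `image` (H x W x 3 array) and a `density` matrix and/or `points`
#'   ([point_set]) and/or a `count`.
#' @param cfg a [train_config()].
#' @param sigma Gaussian bandwidth used when density maps must be derived
#'   from points (default 3).
#' @param verbose print a line per epoch.
#' @return a list of class `countnet_fit` with `model` (best validation
#'   MAE weights), `history` (data frame: epoch, train_loss, val_mae,
#'   val_rmse), `best_epoch`, and `final_model`.
#' @export
fit_countnet <- function(model, train_set, val_set, cfg = train_config(),
                         sigma = 3, verbose = FALSE) {
  stopifnot(inherits(model, "countnet"), inherits(cfg, "train_config"))
  if (length(train_set) == 0L) stop("empty training set")
  if (length(val_set) == 0L) stop("empty validation set")
  if (cfg$batch_size > length(train_set))
    stop("batch size exceeds the training set size")
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_mae = numeric(0), val_rmse = numeric(0))
  if (cfg$epochs == 0L)
    return(structure(list(model = model, history = history,
                          best_epoch = NA_integer_, final_model = model),
                     class = "countnet_fit"))
  densities <- lapply(train_set, .sample_density, sigma = sigma)
  val_truth <- vapply(val_set, .sample_count, numeric(1L))
  velocity <- .zero_grads(model)
  best <- list(mae = Inf, params = model$params, epoch = NA_integer_)
  .with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(train_set))
      n_batches <- length(ord) %/% cfg$batch_size
      ep_loss <- 0
      for (bi in seq_len(n_batches)) {
        idx <- ord[(bi - 1L) * cfg$batch_size + seq_len(cfg$batch_size)]
        images <- vector("list", length(idx))
        gts <- vector("list", length(idx))
        for (k in seq_along(idx)) {
          s <- train_set[[idx[k]]]
          au <- augment(s$image, densities[[idx[k]]], NULL, cfg)
          images[[k]] <- au$image
          gts[[k]] <- au$density$grid
        }
        bl <- .batch_loss_grads(model, images, gts, cfg$loss)
        ep_loss <- ep_loss + bl$loss
        # SGD with momentum and decoupled-from-nothing L2 weight decay:
        # v <- mu * v + (g + wd * p);  p <- p - lr * v
        velocity <- .zip_param_leaves(
          velocity,
          .zip_param_leaves(bl$grads, model$params,
                            function(g, p) g + cfg$weight_decay * p),
          function(v, g) cfg$momentum * v + g)
        model$params <- .zip_param_leaves(
          model$params, velocity,
          function(p, v) p - cfg$learning_rate * v)
      }
      val_pred <- vapply(val_set, function(s)
        integrate_density(model_forward(model, s$image)), numeric(1L))
      vm <- count_mae(val_truth, val_pred)
      vr <- count_rmse(val_truth, val_pred)
      history[ep, ] <- list(ep, ep_loss / max(1L, n_batches), vm, vr)
      if (vm < best$mae)
        best <- list(mae = vm, params = model$params, epoch = ep)
      if (verbose)
        message(sprintf("epoch %3d  loss %.6f  val MAE %.3f  val RMSE %.3f",
                        ep, ep_loss / max(1L, n_batches), vm, vr))
    }
  })
  best_model <- model
  best_model$params <- best$params
  structure(list(model = best_model, history = history,
                 best_epoch = best$epoch, final_model = model),
            class = "countnet_fit")
}

#' @export
print.countnet_fit <- function(x, ...) {
  cat(sprintf("<countnet_fit> %d epoch(s), best epoch %s (val MAE %.3f)\n",
              nrow(x$history),
              ifelse(is.na(x$best_epoch), "NA", x$best_epoch),
              ifelse(is.na(x$best_epoch), NA,
                     x$history$val_mae[x$best_epoch])))
  invisible(x)
}

#' Write a per-epoch history CSV
#' @param fit a `countnet_fit` (or a history data frame).
#' @param path output CSV.
#' @export
write_history <- function(fit, path) {
  h <- if (inherits(fit, "countnet_fit")) fit$history else fit
  utils::write.csv(h, path, row.names = FALSE)
  invisible(path)
}

.reflect_pad_to8 <- function(image) {
  d <- dim(image)
  H <- d[1L]; W <- d[2L]
  ph <- (8L - H %% 8L) %% 8L
  pw <- (8L - W %% 8L) %% 8L
  if (ph == 0L && pw == 0L) return(list(image = image, H = H, W = W))
  ri <- c(seq_len(H), rev(seq_len(H))[seq_len(ph)])
  ci <- c(seq_len(W), rev(seq_len(W))[seq_len(pw)])
  list(image = image[ri, ci, , drop = FALSE], H = H, W = W)
}

#' Predict a count for one image
#'
#' Runs the model and integrates the predicted density map.  Images whose
#' dimensions are not divisible by 8 are reflect-padded up to the next
#' multiple and the output map is cropped back.
#'
#' @param model a `countnet` or `countnet_fit`.
#' @param image H x W x 3 array in `[0, 1]`.
#' @return a list with `count` (a real, possibly fractional) and `map`
#'   (a [density_map] at the original resolution).
#' @export
predict_count <- function(model, image) {
  if (inherits(model, "countnet_fit")) model <- model$model
  pp <- .reflect_pad_to8(image)
  dm <- model_forward(model, pp$image)
  grid <- dm$grid[seq_len(pp$H), seq_len(pp$W), drop = FALSE]
  map <- density_map(grid)
  list(count = integrate_density(map), map = map)
}

#' Evaluate the model on an annotated dataset
#'
#' True counts come from the annotations; predicted counts from
#' [predict_count()].  Returns MAE/RMSE with a per-density-level breakdown.
#'
#' @param model a `countnet` or `countnet_fit`.
#' @param dataset list of samples as in [fit_countnet()].
#' @param predict_fun predictor taking `(model, image)` and returning a
#'   count; defaults to [predict_count()].  Mainly for oracle baselines in
#'   tests.
#' @return an [eval_report].
#' @export
evaluate_countnet <- function(model, dataset,
                              predict_fun = NULL) {
  if (length(dataset) == 0L) stop("empty dataset")
  truth <- vapply(dataset, .sample_count, numeric(1L))
  pred <- if (is.null(predict_fun))
    vapply(dataset, function(s) predict_count(model, s$image)$count,
           numeric(1L))
  else
    vapply(dataset, function(s) predict_fun(model, s$image), numeric(1L))
  names_ <- vapply(seq_along(dataset), function(i) {
    nm <- dataset[[i]]$name
    if (is.null(nm)) sprintf("image_%03d", i) else nm
  }, character(1L))
  eval_report(truth, pred, image = names_)
}
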