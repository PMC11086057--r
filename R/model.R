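#' Density-regression counting network
#'
#' The counting model is a fully convolutional density-map regressor with
#' four stages: (1) a VGG-style frontend of 13 3x3 convolution layers whose
#' output sits at 1/8 of the input resolution; (2) a multi-scale fusion
#' block combining a 1/4-scale frontend tap, the 1/8-scale frontend output,
#' and an internally derived 1/16-scale map; (3) a convolutional block
#' attention module (CBAM: channel attention then spatial attention); and
#' (4) a decoder of five 3x3 dilated (rate-2) convolutions plus a 1x1
#' projection to a single channel, bilinearly upsampled in-graph to the full
#' input resolution.  Integrating the output map gives the predicted count.
#'
#' @name countnet
NULL

.vgg_channels <- c(64L, 64L, 128L, 128L, 256L, 256L, 256L,
                   512L, 512L, 512L, 512L, 512L, 512L)
.pool_after <- c(2L, 4L, 7L)   # keep three 2x poolings -> 1/8 resolution

.ch <- function(c, m) pmax(1L, as.integer(round(c * m)))

# run `expr` under a private RNG stream without disturbing the caller's
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Model configuration
#'
#' @param width_multiplier positive rational `<= 1` scaling every channel
#'   count; `1` is the full-size architecture, `1/8` a CPU-trainable
#'   miniature.
#' @param use_pretrained_frontend if `TRUE`, [init_weights()] insists on
#'   pretrained classification weights for the frontend (not bundled; see
#'   its error message).  Default `FALSE`.
#' @param frontend_conv_layers number of frontend convolution layers (13).
#' @param fusion_enabled,cbam_enabled ablation switches for the multi-scale
#'   fusion block and the attention module.
#' @param cbam_reduction channel-attention bottleneck reduction ratio.
#' @param cbam_spatial_kernel odd spatial-attention kernel size.
#' @param decoder_channels six pre-multiplier widths: the first is the
#'   decoder input width (must match the fused feature width), the
#'   remaining five are the output widths of the dilated layers.
#' @param decoder_dilation dilation rate of the decoder convolutions.
#' @param output_activation `"none"` (linear head, the default) or
#'   `"relu"` (clamps the raw map to non-negative values).  A linear head
#'   is the convention of the dilated-backend counting lineage: with
#'   near-empty density targets a rectified head starts almost entirely
#'   inactive and the one-sided gradient extinguishes it, so from-scratch
#'   training requires the linear form.
#' @param seed integer seed making construction deterministic.
#' @return an object of class `countnet_config`.
#' @export
countnet_config <- function(width_multiplier = 1,
                            use_pretrained_frontend = FALSE,
                            frontend_conv_layers = 13L,
                            fusion_enabled = TRUE,
                            cbam_enabled = TRUE,
                            cbam_reduction = 16L,
                            cbam_spatial_kernel = 7L,
                            decoder_channels = c(512L, 512L, 512L, 256L,
                                                 128L, 64L),
                            decoder_dilation = 2L,
                            output_activation = c("none", "relu"),
                            seed = 1L) {
  output_activation <- match.arg(output_activation)
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("`width_multiplier` must be in (0, 1]")
  if (frontend_conv_layers != 13L)
    stop("the frontend is defined with 13 convolution layers")
  if (cbam_spatial_kernel %% 2L == 0L)
    stop("`cbam_spatial_kernel` must be odd")
  if (length(decoder_channels) != 6L)
    stop("`decoder_channels` must list 6 widths (input + 5 dilated layers)")
  if (decoder_channels[1L] != 512L)
    stop("decoder input width must be 512 (pre-multiplier) to match the fused features")
  cfg <- structure(list(
    width_multiplier = width_multiplier,
    use_pretrained_frontend = isTRUE(use_pretrained_frontend),
    frontend_conv_layers = 13L,
    fusion_enabled = isTRUE(fusion_enabled),
    cbam_enabled = isTRUE(cbam_enabled),
    cbam_reduction = as.integer(cbam_reduction),
    cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
    decoder_channels = as.integer(decoder_channels),
    decoder_dilation = as.integer(decoder_dilation),
    output_activation = output_activation,
    seed = as.integer(seed)), class = "countnet_config")
  if (cfg$cbam_enabled) {
    C <- .ch(512L, cfg$width_multiplier)
    if (C < cfg$cbam_reduction)
      stop(sprintf("channel count %d after the width multiplier is smaller than cbam_reduction %d",
                   C, cfg$cbam_reduction))
  }
  cfg
}

#' A feature map with its scale
#' @param tensor H' x W' x C numeric array.
#' @param scale resolution denominator relative to the input (4, 8 or 16).
#' @return an object of class `feature_map`.
#' @export
feature_map <- function(tensor, scale) {
  structure(list(tensor = tensor, scale = as.integer(scale)),
            class = "feature_map")
}

.fm_tensor <- function(f) {
  if (inherits(f, "feature_map")) f$tensor
  else if (is.array(f) && length(dim(f)) == 3L) f
  else stop("expected a feature_map or a 3-D array")
}

.he_mat <- function(cout, fanin) {
  matrix(stats::rnorm(cout * fanin, sd = sqrt(2 / fanin)), nrow = cout)
}

.conv_layer <- function(cin, cout, k = 3L, pad = 1L, dil = 1L, sd = NULL) {
  fanin <- cin * k * k
  W <- if (is.null(sd)) .he_mat(cout, fanin)
       else matrix(stats::rnorm(cout * fanin, sd = sd), nrow = cout)
  list(W = W, b = numeric(cout), k = as.integer(k), pad = as.integer(pad),
       dil = as.integer(dil), cin = as.integer(cin), cout = as.integer(cout))
}

# Near-identity initialisation: channel c passes through on the centre
# kernel tap (for c <= min(cin, cout)) plus small Gaussian noise.  A
# backend initialised this way preserves the frontend's feature content at
# the start of from-scratch training instead of scrambling it through
# random narrowing projections, which keeps the count signal linearly
# readable by the output head (the same motivation as identity-oriented
# schemes like Net2Net or Fixup).  `offset` shifts which input channel
# block is passed through (used by the fusion projection to forward the
# 1/8-scale frontend block of the concatenation).
.identity_conv <- function(cin, cout, k = 3L, pad = 1L, dil = 1L,
                           noise_sd = 0.01, offset = 0L) {
  W <- matrix(stats::rnorm(cout * cin * k * k, sd = noise_sd), nrow = cout)
  centre <- ((k * k) - 1L) %/% 2L   # centre tap index within a channel block
  avail <- cin - offset
  if (avail >= 2L * cout) {
    # narrowing layer: each output channel averages a block of inputs on
    # the centre tap, so aggregate feature content survives the squeeze
    g <- avail %/% cout
    for (c in seq_len(cout)) {
      for (j in seq_len(g)) {
        ci <- offset + (c - 1L) * g + j
        W[c, (ci - 1L) * k * k + centre + 1L] <-
          W[c, (ci - 1L) * k * k + centre + 1L] + 1 / g
      }
    }
  } else {
    for (c in seq_len(min(avail, cout))) {
      W[c, (offset + c - 1L) * k * k + centre + 1L] <-
        W[c, (offset + c - 1L) * k * k + centre + 1L] + 1
    }
  }
  list(W = W, b = numeric(cout), k = as.integer(k), pad = as.integer(pad),
       dil = as.integer(dil), cin = as.integer(cin), cout = as.integer(cout))
}

#' Build the counting network
#'
#' Construction is deterministic given `cfg$seed`.  The default
#' initialisation is variance-preserving (He) Gaussian weights with zero
#' biases, suitable for from-scratch training; [init_weights()] applies the
#' published small-Gaussian backend recipe instead.
#'
#' @param cfg a [countnet_config()].
#' @return an object of class `countnet`.
#' @export
build_countnet <- function(cfg = countnet_config()) {
  stopifnot(inherits(cfg, "countnet_config"))
  m <- cfg$width_multiplier
  ch <- .ch(.vgg_channels, m)
  .with_seed(cfg$seed, {
    frontend <- vector("list", 13L)
    cin <- 3L
    for (l in seq_len(13L)) {
      frontend[[l]] <- .conv_layer(cin, ch[l])
      cin <- ch[l]
    }
    C <- ch[13L]                       # 512 * m, fused feature width
    C1 <- ch[4L]                       # 128 * m, scale-4 tap width
    fusion <- list(
      f3 = .conv_layer(C, C),
      # the 1x1 projection starts as a near-identity on the 1/8-scale
      # frontend block of [F1-down, F2, F3-up]
      proj = .identity_conv(C1 + C + C, C, k = 1L, pad = 0L, offset = C1)
    )
    Cr <- max(1L, C %/% cfg$cbam_reduction)
    ks <- cfg$cbam_spatial_kernel
    cbam <- list(
      W1 = .he_mat(Cr, C),
      W2 = .he_mat(C, Cr),
      Wsp = .he_mat(1L, 2L * ks * ks),
      bsp = numeric(1L)
    )
    dc <- .ch(cfg$decoder_channels, m)
    decoder <- vector("list", 6L)
    cin <- C
    for (i in 1:5) {
      # noise_sd 0.03: narrowing layers also carry random projections of
      # the full channel space, which measurably preserves more of the
      # count signal through the squeeze than the pass-through taps alone
      decoder[[i]] <- .identity_conv(cin, dc[i + 1L],
                                     pad = cfg$decoder_dilation,
                                     dil = cfg$decoder_dilation,
                                     noise_sd = 0.03)
      cin <- dc[i + 1L]
    }
    # the output projection starts near zero (small-Gaussian weights) so
    # that the initial map is approximately flat; with the default linear
    # head the gradient still reaches every pixel
    decoder[[6L]] <- .conv_layer(cin, 1L, k = 1L, pad = 0L, sd = 0.01)
    structure(list(cfg = cfg,
                   params = list(frontend = frontend, fusion = fusion,
                                 cbam = cbam, decoder = decoder)),
              class = "countnet")
  })
}

#' @export
print.countnet <- function(x, ...) {
  cat(sprintf("<countnet> width multiplier %s, fusion %s, CBAM %s, %s parameters\n",
              format(x$cfg$width_multiplier),
              ifelse(x$cfg$fusion_enabled, "on", "off"),
              ifelse(x$cfg$cbam_enabled, "on", "off"),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a `countnet`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(unlist(.map_param_leaves(model$params, function(x) length(x))))
}

# apply f to every numeric parameter leaf (weights W*, biases b*)
.map_param_leaves <- function(node, f) {
  if (is.list(node) && !is.null(names(node)) &&
      all(c("W", "b") %in% names(node))) {
    node$W <- f(node$W); node$b <- f(node$b)
    return(node)
  }
  if (is.list(node)) {
    nm <- names(node)
    for (i in seq_along(node)) {
      if (is.numeric(node[[i]]) && !is.null(nm) &&
          grepl("^(W|b)", nm[i])) {
        node[[i]] <- f(node[[i]])
      } else if (is.list(node[[i]])) {
        node[[i]] <- .map_param_leaves(node[[i]], f)
      }
    }
    return(node)
  }
  node
}

# elementwise combine two parameter trees with the same shape
.zip_param_leaves <- function(a, b, f) {
  if (is.list(a) && all(c("W", "b") %in% names(a))) {
    a$W <- f(a$W, b$W); a$b <- f(a$b, b$b)
    return(a)
  }
  if (is.list(a)) {
    nm <- names(a)
    for (i in seq_along(a)) {
      if (is.numeric(a[[i]]) && !is.null(nm) && grepl("^(W|b)", nm[i]))
        a[[i]] <- f(a[[i]], b[[i]])
      else if (is.list(a[[i]]))
        a[[i]] <- .zip_param_leaves(a[[i]], b[[i]], f)
    }
    return(a)
  }
  a
}

#' Re-initialise weights with the published recipe
#'
#' Backend (fusion, attention, decoder) convolution weights are drawn from
#' `Normal(0, backend_std^2)` with biases exactly 0.  For the frontend,
#' `frontend = "he"` (default) keeps variance-preserving Gaussian weights —
#' the workable choice when training from scratch, since a 13-layer stack of
#' std-0.01 weights attenuates the signal to numerical zero — while
#' `frontend = "gaussian"` applies the same small-Gaussian scheme to the
#' frontend too.  If the model was configured with
#' `use_pretrained_frontend = TRUE` this raises an error: pretrained
#' classification weights are not bundled with the package; rebuild with
#' `use_pretrained_frontend = FALSE` to train from scratch.
#'
#' @param model a `countnet`.
#' @param backend_std standard deviation of backend weights (default 0.01).
#' @param frontend `"he"` or `"gaussian"`.
#' @param seed RNG seed; defaults to `model$cfg$seed`.
#' @return the re-initialised model.
#' @export
init_weights <- function(model, backend_std = 0.01,
                         frontend = c("he", "gaussian"), seed = NULL) {
  stopifnot(inherits(model, "countnet"))
  frontend <- match.arg(frontend)
  if (model$cfg$use_pretrained_frontend)
    stop("pretrained frontend weights are not bundled with this package; ",
         "rebuild the model with use_pretrained_frontend = FALSE to ",
         "initialise the frontend from scratch")
  if (is.null(seed)) seed <- model$cfg$seed
  .with_seed(seed, {
    model$params$frontend <- lapply(model$params$frontend, function(l) {
      fanin <- ncol(l$W)
      sd <- if (frontend == "he") sqrt(2 / fanin) else backend_std
      l$W <- matrix(stats::rnorm(length(l$W), sd = sd), nrow = nrow(l$W))
      l$b <- numeric(length(l$b))
      l
    })
    gauss <- function(x) {
      if (is.matrix(x)) matrix(stats::rnorm(length(x), sd = backend_std),
                               nrow = nrow(x))
      else numeric(length(x))
    }
    for (part in c("fusion", "cbam", "decoder"))
      model$params[[part]] <- .map_param_leaves(model$params[[part]], gauss)
    model
  })
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.check_div8 <- function(H, W) {
  if (H %% 8L != 0L || W %% 8L != 0L)
    stop(sprintf("input height and width must be divisible by 8 (got %d x %d)",
                 W, H))
}

# ---------------------------------------------------------------------------
# Forward pass.  `keep = TRUE` caches every intermediate needed by .bwd().
# ---------------------------------------------------------------------------

# per-channel standardisation applied before the first convolution: the
# usual preprocessing of VGG-style frontends.  Centred inputs keep the
# local contrast (dark bodies on a light tank bottom) from being drowned
# by the large DC background component.
.input_mean <- c(0.485, 0.456, 0.406)
.input_sd <- c(0.229, 0.224, 0.225)

.normalize_image <- function(image) {
  sweep(sweep(image, 3L, .input_mean, "-"), 3L, .input_sd, "/")
}

.fwd_frontend <- function(model, image, keep = FALSE) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("image must be an H x W x 3 array")
  .check_div8(d[1L], d[2L])
  cache <- if (keep) list(conv_in = vector("list", 13L),
                          out = vector("list", 13L),
                          pool = list()) else NULL
  x <- .normalize_image(image)
  F1 <- NULL
  for (l in seq_len(13L)) {
    ly <- model$params$frontend[[l]]
    if (keep) cache$conv_in[[l]] <- x
    x <- cpp_conv2d(x, ly$W, ly$b, ly$k, ly$k, ly$pad, ly$dil)
    x <- pmax(x, 0)
    if (keep) cache$out[[l]] <- x
    if (l %in% .pool_after) {
      mp <- cpp_maxpool2(x)
      if (keep) cache$pool[[as.character(l)]] <-
          list(idx = mp$idx, H = dim(x)[1L], W = dim(x)[2L])
      x <- mp$out
    }
    if (l == 4L) F1 <- x
  }
  list(F1 = F1, F2 = x, cache = cache)
}

#' Frontend feature extraction
#'
#' Runs the 13-layer frontend and returns the 1/4-scale tap `F1` (after the
#' second pooling stage) and the 1/8-scale output `F2`.
#'
#' @param model a `countnet`.
#' @param image H x W x 3 array with values in `[0, 1]`; H and W must be
#'   divisible by 8.
#' @return a list with `feature_map`s `F1` (scale 4) and `F2` (scale 8).
#' @export
frontend_forward <- function(model, image) {
  r <- .fwd_frontend(model, image)
  list(F1 = feature_map(r$F1, 4L), F2 = feature_map(r$F2, 8L))
}

.fwd_fusion <- function(model, F1, F2, keep = FALSE) {
  if (!model$cfg$fusion_enabled)
    return(list(out = F2, cache = NULL))
  p <- model$params$fusion
  cache <- if (keep) list() else NULL
  f3_pre_in <- F2
  f3 <- cpp_conv2d(F2, p$f3$W, p$f3$b, 3L, 3L, 1L, 1L)
  f3 <- pmax(f3, 0)
  mp <- cpp_maxpool2(f3)
  F3 <- mp$out
  h <- dim(F2)[1L]; w <- dim(F2)[2L]
  F1d <- cpp_resize_bilinear(F1, h, w)
  F3u <- cpp_resize_bilinear(F3, h, w)
  cat <- array(c(F1d, F2, F3u),
               dim = c(h, w, dim(F1d)[3L] + dim(F2)[3L] + dim(F3u)[3L]))
  pre <- cpp_conv2d(cat, p$proj$W, p$proj$b, 1L, 1L, 0L, 0L)
  out <- pmax(pre, 0)
  if (keep)
    cache <- list(f3_relu = f3, f3_pool_idx = mp$idx,
                  f3_pool_dims = dim(f3)[1:2], F3 = F3, F1 = F1,
                  cat = cat, out = out,
                  c1 = dim(F1d)[3L], c2 = dim(F2)[3L], c3 = dim(F3u)[3L])
  list(out = out, cache = cache)
}

#' Multi-scale feature fusion
#'
#' Derives a 1/16-scale map from `F2` (3x3 convolution + 2x2 max pooling),
#' bilinearly resamples the 1/4-scale tap down and the 1/16-scale map up to
#' `F2`'s grid, concatenates `[F1-down, F2, F3-up]` along channels and
#' projects back to the fused width with a 1x1 convolution.  With
#' `fusion_enabled = FALSE` the input `F2` is returned unchanged.
#'
#' @param model a `countnet`.
#' @param F1,F2 feature maps from the same [frontend_forward()] pass.
#' @return a `feature_map` at scale 8.
#' @export
multiscale_fuse <- function(model, F1, F2) {
  r <- .fwd_fusion(model, .fm_tensor(F1), .fm_tensor(F2))
  feature_map(r$out, 8L)
}

.fwd_cbam <- function(model, x, keep = FALSE) {
  if (!model$cfg$cbam_enabled)
    return(list(out = x, cache = NULL))
  p <- model$params$cbam
  d <- dim(x); HW <- d[1L] * d[2L]; C <- d[3L]
  xm <- matrix(x, nrow = HW, ncol = C)
  avg <- colMeans(xm)
  mx_idx <- max.col(t(xm), ties.method = "first")   # argmax pixel per channel
  mx <- xm[cbind(mx_idx, seq_len(C))]
  h1a <- pmax(p$W1 %*% avg, 0)
  h1m <- pmax(p$W1 %*% mx, 0)
  z <- p$W2 %*% h1a + p$W2 %*% h1m
  s <- .sigmoid(as.numeric(z))
  y1 <- x * rep(s, each = HW)
  y1m <- matrix(y1, nrow = HW, ncol = C)
  avgmap <- matrix(rowMeans(y1m), d[1L], d[2L])
  ch_idx <- max.col(y1m, ties.method = "first")     # argmax channel per pixel
  maxmap <- matrix(y1m[cbind(seq_len(HW), ch_idx)], d[1L], d[2L])
  sp_in <- array(c(avgmap, maxmap), dim = c(d[1L], d[2L], 2L))
  ks <- model$cfg$cbam_spatial_kernel
  spre <- cpp_conv2d(sp_in, p$Wsp, p$bsp, ks, ks, (ks - 1L) %/% 2L, 1L)
  m <- .sigmoid(spre[, , 1L])
  out <- y1 * rep(as.numeric(m), times = C)
  cache <- if (keep)
    list(x = x, avg = avg, mx = mx, mx_idx = mx_idx, h1a = h1a, h1m = h1m,
         s = s, y1 = y1, ch_idx = ch_idx, sp_in = sp_in, m = m) else NULL
  list(out = out, cache = cache)
}

#' Convolutional block attention (CBAM)
#'
#' Channel attention (a shared bottleneck MLP over the global average- and
#' max-pooled channel vectors, sigmoid-gated) followed by spatial attention
#' (a convolution over the stacked channelwise mean/max maps,
#' sigmoid-gated).  Shape is preserved; with `cbam_enabled = FALSE` this is
#' the identity.
#'
#' @param model a `countnet`.
#' @param f a `feature_map` (or 3-D array).
#' @return a `feature_map` of the same shape and scale.
#' @export
cbam_forward <- function(model, f) {
  x <- .fm_tensor(f)
  r <- .fwd_cbam(model, x)
  feature_map(r$out, if (inherits(f, "feature_map")) f$scale else 8L)
}

.fwd_decoder <- function(model, x, keep = FALSE) {
  cache <- if (keep) list(conv_in = vector("list", 6L)) else NULL
  for (i in 1:5) {
    ly <- model$params$decoder[[i]]
    if (keep) cache$conv_in[[i]] <- x
    x <- cpp_conv2d(x, ly$W, ly$b, ly$k, ly$k, ly$pad, ly$dil)
    x <- pmax(x, 0)
    if (keep) cache[[paste0("out", i)]] <- x
  }
  ly <- model$params$decoder[[6L]]
  if (keep) cache$conv_in[[6L]] <- x
  x <- cpp_conv2d(x, ly$W, ly$b, ly$k, ly$k, ly$pad, ly$dil)
  if (model$cfg$output_activation == "relu") x <- pmax(x, 0)
  if (keep) cache$raw <- x
  list(out = x, cache = cache)
}

#' Decoder: dilated convolutions to a raw density map
#'
#' Five 3x3 rate-2 dilated convolutions (ReLU) then a 1x1 projection to one
#' channel, at 1/8 resolution.  With `output_activation = "relu"` the raw
#' map is non-negative.
#'
#' @param model a `countnet`.
#' @param f fused `feature_map` at scale 8.
#' @return an H/8 x W/8 x 1 array.
#' @export
decoder_forward <- function(model, f) {
  .fwd_decoder(model, .fm_tensor(f))$out
}

.fwd <- function(model, image, keep = FALSE) {
  fr <- .fwd_frontend(model, image, keep)
  fu <- .fwd_fusion(model, fr$F1, fr$F2, keep)
  cb <- .fwd_cbam(model, fu$out, keep)
  de <- .fwd_decoder(model, cb$out, keep)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  out <- cpp_resize_bilinear(de$out, H, W)[, , 1L]
  cache <- if (keep) list(frontend = fr$cache, fusion = fu$cache,
                          cbam = cb$cache, decoder = de$cache,
                          F1 = fr$F1, F2 = fr$F2, fused = fu$out,
                          attended = cb$out, H = H, W = W,
                          raw_dims = dim(de$out)[1:2]) else NULL
  list(out = out, cache = cache)
}

#' Full model forward pass
#'
#' Produces a density map at the full input resolution: the 1/8-scale
#' decoder output is bilinearly upsampled inside the differentiable graph
#' (the upsampling is trained through).
#'
#' @param model a `countnet`.
#' @param image H x W x 3 array in `[0, 1]`, H and W divisible by 8.
#' @return a [density_map] of dimension H x W.
#' @export
model_forward <- function(model, image) {
  density_map(.fwd(model, image)$out)
}

# ---------------------------------------------------------------------------
# Backward pass: gradient of a scalar loss with respect to every parameter,
# given d(loss)/d(output map).  Returns a tree mirroring model$params.
# ---------------------------------------------------------------------------

.zero_grads <- function(model) {
  .map_param_leaves(model$params, function(x) x * 0)
}

.bwd <- function(model, cache, dmap) {
  grads <- .zero_grads(model)
  rd <- cache$raw_dims
  dres <- cpp_resize_bilinear_bwd(array(dmap, dim = c(dim(dmap), 1L)),
                                  rd[1L], rd[2L])
  # --- decoder ---
  dx <- dres
  if (model$cfg$output_activation == "relu")
    dx <- dx * (cache$decoder$raw > 0)
  for (i in 6:1) {
    ly <- model$params$decoder[[i]]
    if (i < 6L) dx <- dx * (cache$decoder[[paste0("out", i)]] > 0)
    bw <- cpp_conv2d_bwd(cache$decoder$conv_in[[i]], ly$W, dx,
                         ly$k, ly$k, ly$pad, ly$dil)
    grads$decoder[[i]]$W <- bw$dW
    grads$decoder[[i]]$b <- as.numeric(bw$db)
    dx <- bw$dx
  }
  # --- CBAM ---
  if (model$cfg$cbam_enabled) {
    cc <- cache$cbam
    p <- model$params$cbam
    d <- dim(cc$x); HW <- d[1L] * d[2L]; C <- d[3L]
    dm_sp <- matrix(0, d[1L], d[2L])       # grad wrt spatial gate m
    y1m <- matrix(cc$y1, HW, C)
    dym <- matrix(dx, HW, C)
    dm_sp[] <- rowSums(dym * y1m)
    dy1 <- dx * rep(as.numeric(cc$m), times = C)
    # spatial attention block
    dspre <- dm_sp * cc$m * (1 - cc$m)
    ks <- model$cfg$cbam_spatial_kernel
    bsp <- cpp_conv2d_bwd(cc$sp_in, p$Wsp,
                          array(dspre, dim = c(d[1L], d[2L], 1L)),
                          ks, ks, (ks - 1L) %/% 2L, 1L)
    grads$cbam$Wsp <- bsp$dW
    grads$cbam$bsp <- as.numeric(bsp$db)
    davgmap <- bsp$dx[, , 1L]
    dmaxmap <- bsp$dx[, , 2L]
    dy1m <- matrix(dy1, HW, C)
    dy1m <- dy1m + as.numeric(davgmap) / C       # mean over channels
    sc <- cbind(seq_len(HW), cc$ch_idx)          # max over channels
    dy1m[sc] <- dy1m[sc] + as.numeric(dmaxmap)
    # channel attention block: y1 = x * s (per channel)
    xm <- matrix(cc$x, HW, C)
    ds <- colSums(dy1m * xm)
    dxm <- dy1m * rep(cc$s, each = HW)
    dz <- ds * cc$s * (1 - cc$s)
    dh1a <- as.numeric(t(p$W2) %*% dz) * (cc$h1a > 0)
    dh1m <- as.numeric(t(p$W2) %*% dz) * (cc$h1m > 0)
    grads$cbam$W2 <- outer(dz, as.numeric(cc$h1a)) +
                     outer(dz, as.numeric(cc$h1m))
    grads$cbam$W1 <- outer(as.numeric(dh1a), cc$avg) +
                     outer(as.numeric(dh1m), cc$mx)
    davg <- as.numeric(t(p$W1) %*% dh1a)
    dmx <- as.numeric(t(p$W1) %*% dh1m)
    dxm <- dxm + matrix(davg / HW, HW, C, byrow = TRUE)
    mc <- cbind(cc$mx_idx, seq_len(C))           # argmax pixel per channel
    dxm[mc] <- dxm[mc] + dmx
    dx <- array(dxm, dim = d)
  }
  # --- fusion ---
  if (model$cfg$fusion_enabled) {
    fc <- cache$fusion
    p <- model$params$fusion
    dx <- dx * (fc$out > 0)
    bw <- cpp_conv2d_bwd(fc$cat, p$proj$W, dx, 1L, 1L, 0L, 0L)
    grads$fusion$proj$W <- bw$dW
    grads$fusion$proj$b <- as.numeric(bw$db)
    dcat <- bw$dx
    c1 <- fc$c1; c2 <- fc$c2; c3 <- fc$c3
    dF1d <- dcat[, , seq_len(c1), drop = FALSE]
    dF2 <- dcat[, , c1 + seq_len(c2), drop = FALSE]
    dF3u <- dcat[, , c1 + c2 + seq_len(c3), drop = FALSE]
    dF1 <- cpp_resize_bilinear_bwd(dF1d, dim(fc$F1)[1L], dim(fc$F1)[2L])
    dF3 <- cpp_resize_bilinear_bwd(dF3u, dim(fc$F3)[1L], dim(fc$F3)[2L])
    df3 <- cpp_maxpool2_bwd(dF3, fc$f3_pool_idx,
                            fc$f3_pool_dims[1L], fc$f3_pool_dims[2L])
    df3 <- df3 * (fc$f3_relu > 0)
    bw3 <- cpp_conv2d_bwd(cache$F2, p$f3$W, df3, 3L, 3L, 1L, 1L)
    grads$fusion$f3$W <- bw3$dW
    grads$fusion$f3$b <- as.numeric(bw3$db)
    dF2 <- dF2 + bw3$dx
  } else {
    dF1 <- NULL
    dF2 <- dx
  }
  # --- frontend (reverse traversal with pooling and the scale-4 tap) ---
  frc <- cache$frontend
  dx <- dF2
  for (l in 13:1) {
    if (l == 4L && !is.null(dF1)) dx <- dx + dF1
    if (l %in% .pool_after) {
      pc <- frc$pool[[as.character(l)]]
      dx <- cpp_maxpool2_bwd(dx, pc$idx, pc$H, pc$W)
    }
    dx <- dx * (frc$out[[l]] > 0)
    ly <- model$params$frontend[[l]]
    bw <- cpp_conv2d_bwd(frc$conv_in[[l]], ly$W, dx, ly$k, ly$k,
                         ly$pad, ly$dil)
    grads$frontend[[l]]$W <- bw$dW
    grads$frontend[[l]]$b <- as.numeric(bw$db)
    dx <- bw$dx
  }
  grads
}

# loss + gradients for one batch of (image, gt density map) pairs
.batch_loss_grads <- function(model, images, gts, lcfg) {
  B <- length(images)
  preds <- vector("list", B)
  caches <- vector("list", B)
  for (i in seq_len(B)) {
    r <- .fwd(model, images[[i]], keep = TRUE)
    preds[[i]] <- r$out
    caches[[i]] <- r$cache
  }
  loss <- combined_loss(preds, gts, lcfg)
  dmaps <- .combined_loss_grad(preds, gts, lcfg)
  grads <- NULL
  for (i in seq_len(B)) {
    g <- .bwd(model, caches[[i]], dmaps[[i]])
    grads <- if (is.null(grads)) g
             else .zip_param_leaves(grads, g, `+`)
  }
  list(loss = loss, grads = grads, preds = preds)
}

# ---------------------------------------------------------------------------
# Checkpoints and config files
# ---------------------------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file serialisation of weights, configuration, epoch, and an
#' optional training history; the weight round trip is bit-exact.
#'
#' @param model a `countnet`.
#' @param path output file.
#' @param epoch epoch number to record.
#' @param history optional history data frame from [fit_countnet()].
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_,
                            history = NULL) {
  saveRDS(list(model = model, epoch = epoch, history = history,
               package_version = as.character(utils::packageVersion("frycount"))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a list with `model`, `epoch`, `history`.
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}

#' Read a model configuration from a YAML file
#'
#' Field names mirror [countnet_config()] exactly; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return a `countnet_config`.
#' @export
read_model_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(countnet_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop(sprintf("unknown model config key(s): %s", paste(bad, collapse = ", ")))
  do.call(countnet_config, vals)
}
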