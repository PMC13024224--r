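# 3D residual convolutional backbone with SHPM terminal pooling.
#
# The network is a fixed topology (stem conv -> BN -> ReLU, then stages of
# basic residual blocks, then SHPM and a single linear classification
# layer), so forward and backward passes are written explicitly rather than
# through a generic autodiff graph. Convolutions run through the compiled
# im2col/gemm kernels in src/; batch norm, ReLU, SHPM and the classifier
# are vectorised R.

conv_fwd <- function(x, w, b, stride, pad, want_col = FALSE) {
  conv3d_fwd_cpp(x, w, b, as.integer(stride), as.integer(pad), want_col)
}

conv_bwd <- function(x, w, dy, stride, pad, col = NULL) {
  conv3d_bwd_cpp(x, w, dy, as.integer(stride), as.integer(pad), col)
}

# --- batch norm -------------------------------------------------------------

bn_fwd <- function(x, gamma, beta, rmean, rvar, train, momentum = 0.1,
                   eps = 1e-5) {
  out <- bn_fwd_cpp(x, gamma, beta, rmean, rvar, train, momentum, eps)
  list(y = out$y,
       cache = list(x = x, mu = out$mu, invstd = out$invstd, gamma = gamma),
       rmean = out$rmean, rvar = out$rvar)
}

bn_bwd <- function(cache, dy) {
  bn_bwd_cpp(cache$x, dy, cache$gamma, cache$mu, cache$invstd)
}

relu_fwd <- function(x) relu_cpp(x)

# --- configuration ----------------------------------------------------------

#' Backbone configuration
#'
#' Describes the 3D residual network. The `"resnet18"` preset is the
#' full-scale topology (4 stages of 2 basic blocks, channels
#' 64/128/256/512); the `"tiny"` preset is a reduced variant (2 stages,
#' channels 8/16, spatial downsampling only from stage 2) sized for
#' desk-scale 32 x 32 clips while keeping a non-trivial final spatial map
#' for the SHPM pyramid.
#'
#' @param preset `"tiny"` or `"resnet18"`.
#' @param num_classes number of output classes.
#' @param in_channels input channels (1 for grayscale clips).
#' @param input_shape expected clip shape `c(T, H, W)`; used to derive the
#'   final feature-map shape and validate the SHPM pyramid at build time.
#' @param shpm_levels optional list of SHPM block sizes; default is the
#'   dyadic 1x1 / 2x2 / 4x4 bin-grid pyramid on the final map (grids that do
#'   not divide the map evenly are dropped).
#' @param shpm_combine,shpm_temporal passed to [shpm_config()].
#' @param stage_channels,blocks_per_stage,stage_strides optional overrides
#'   of the preset topology.
#' @return an object of class `backbone_config`.
#' @export
backbone_config <- function(preset = c("tiny", "resnet18"), num_classes = 3L,
                            in_channels = 1L, input_shape = c(8L, 32L, 32L),
                            shpm_levels = NULL,
                            shpm_combine = "concat", shpm_temporal = "mean",
                            stage_channels = NULL, blocks_per_stage = NULL,
                            stage_strides = NULL) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    stem <- list(out = 6L, kernel = c(3L, 3L, 3L), stride = c(1L, 2L, 2L),
                 pad = c(1L, 1L, 1L))
    stage_channels <- stage_channels %||% c(6L, 12L)
    blocks_per_stage <- blocks_per_stage %||% c(1L, 1L)
    stage_strides <- stage_strides %||% list(c(1L, 1L, 1L), c(1L, 2L, 2L))
  } else {
    stem <- list(out = 64L, kernel = c(3L, 7L, 7L), stride = c(1L, 2L, 2L),
                 pad = c(1L, 3L, 3L))
    stage_channels <- stage_channels %||% c(64L, 128L, 256L, 512L)
    blocks_per_stage <- blocks_per_stage %||% c(2L, 2L, 2L, 2L)
    stage_strides <- stage_strides %||%
      list(c(1L, 1L, 1L), c(1L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 2L))
  }
  ns <- length(stage_channels)
  if (length(blocks_per_stage) != ns || length(stage_strides) != ns)
    stop("stage_channels, blocks_per_stage and stage_strides must align")
  if (ns < 2)
    stop("the backbone needs at least 2 stages so SHPM sees a nontrivial map")

  cfg <- structure(list(preset = preset, num_classes = as.integer(num_classes),
                        in_channels = as.integer(in_channels),
                        input_shape = as.integer(input_shape),
                        stem = stem, stage_channels = as.integer(stage_channels),
                        blocks_per_stage = as.integer(blocks_per_stage),
                        stage_strides = stage_strides,
                        shpm = NULL), class = "backbone_config")

  fs <- backbone_feature_shape(cfg)
  if (any(fs < 1) || any(fs[3:4] < 4))
    stop("input_shape too small for this topology: the final spatial map ",
         "must be at least 4x4 so the SHPM pyramid is nontrivial")
  levels <- shpm_levels %||% shpm_default_levels(fs[3], fs[4])
  cfg$shpm <- shpm_config(levels, combine = shpm_combine,
                          temporal = shpm_temporal)
  # build-time divisibility guarantee: every configured level must divide
  for (lv in cfg$shpm$levels) partition_bins(fs[3], fs[4], lv[1], lv[2])
  cfg$feature_shape <- fs
  nb <- vapply(cfg$shpm$levels,
               function(lv) prod(partition_bins(fs[3], fs[4], lv[1], lv[2])),
               numeric(1))
  cfg$vec_dim <- as.integer(fs[1] * sum(nb) *
                              (if (cfg$shpm$combine == "concat") 2 else 1))
  cfg
}

conv_out_size <- function(s, k, stride, pad) (s + 2 * pad - k) %/% stride + 1

# final feature-map shape (C', T', H', W') for the configured input
backbone_feature_shape <- function(cfg) {
  shp <- cfg$input_shape
  st <- cfg$stem
  shp <- mapply(conv_out_size, shp, st$kernel, st$stride, st$pad)
  for (i in seq_along(cfg$stage_channels)) {
    s <- cfg$stage_strides[[i]]
    shp <- mapply(conv_out_size, shp, c(3, 3, 3), s, c(1, 1, 1))
  }
  c(cfg$stage_channels[length(cfg$stage_channels)], shp)
}

# --- construction -----------------------------------------------------------

he_conv <- function(cout, cin, kernel) {
  fan_out <- cout * prod(kernel)
  array(rnorm(cout * cin * prod(kernel), sd = sqrt(2 / fan_out)),
        c(cout, cin, kernel))
}

block_specs <- function(cfg) {
  specs <- list()
  inc <- cfg$stem$out
  for (i in seq_along(cfg$stage_channels)) {
    outc <- cfg$stage_channels[i]
    for (j in seq_len(cfg$blocks_per_stage[i])) {
      stride <- if (j == 1) cfg$stage_strides[[i]] else c(1L, 1L, 1L)
      specs[[paste0("s", i, "b", j)]] <-
        list(inc = inc, outc = outc, stride = stride,
             proj = (inc != outc) || any(stride != 1))
      inc <- outc
    }
  }
  specs
}

#' Build a backbone model
#'
#' Instantiates parameters (He fan-out initialisation for convolutions,
#' unit-gamma/zero-beta batch norms, zero classifier bias) and running
#' batch-norm statistics. Two constructions from the same config and seed
#' are identical.
#'
#' @param config a [backbone_config()].
#' @param seed RNG seed for the initial weights.
#' @return an object of class `backbone3d` holding `config`, `params` and
#'   `buffers`.
#' @export
backbone_build <- function(config, seed = NULL) {
  stopifnot(inherits(config, "backbone_config"))
  with_seed(seed, {
    params <- list()
    buffers <- list()
    add_bn <- function(name, C) {
      params[[paste0(name, ".gamma")]] <<- rep(1, C)
      params[[paste0(name, ".beta")]] <<- rep(0, C)
      buffers[[paste0(name, ".mean")]] <<- rep(0, C)
      buffers[[paste0(name, ".var")]] <<- rep(1, C)
    }
    st <- config$stem
    params[["stem.conv.w"]] <- he_conv(st$out, config$in_channels, st$kernel)
    params[["stem.conv.b"]] <- rep(0, st$out)
    add_bn("stem.bn", st$out)
    for (nm in names(block_specs(config))) {
      sp <- block_specs(config)[[nm]]
      params[[paste0(nm, ".conv1.w")]] <- he_conv(sp$outc, sp$inc, c(3, 3, 3))
      params[[paste0(nm, ".conv1.b")]] <- rep(0, sp$outc)
      add_bn(paste0(nm, ".bn1"), sp$outc)
      params[[paste0(nm, ".conv2.w")]] <- he_conv(sp$outc, sp$outc, c(3, 3, 3))
      params[[paste0(nm, ".conv2.b")]] <- rep(0, sp$outc)
      add_bn(paste0(nm, ".bn2"), sp$outc)
      if (sp$proj) {
        params[[paste0(nm, ".proj.w")]] <- he_conv(sp$outc, sp$inc, c(1, 1, 1))
        params[[paste0(nm, ".proj.b")]] <- rep(0, sp$outc)
        add_bn(paste0(nm, ".projbn"), sp$outc)
      }
    }
    D <- config$vec_dim
    params[["fc.w"]] <- matrix(rnorm(D * config$num_classes, sd = sqrt(2 / D)),
                               D, config$num_classes)
    params[["fc.b"]] <- rep(0, config$num_classes)
    structure(list(config = config, params = params, buffers = buffers),
              class = "backbone3d")
  })
}

#' @export
print.backbone3d <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  fs <- x$config$feature_shape
  cat(sprintf(
    "<backbone3d '%s': %d stages, %s parameters, feature map %dx%dx%dx%d, %d classes>\n",
    x$config$preset, length(x$config$stage_channels), format(np, big.mark = ","),
    fs[1], fs[2], fs[3], fs[4], x$config$num_classes))
  invisible(x)
}

# --- forward / backward -----------------------------------------------------

# One conv -> BN (-> optional ReLU) unit; returns output plus caches.
unit_fwd <- function(x, params, buffers, prefix, stride, pad, train,
                     update_buffers, relu = TRUE, keep_col = FALSE) {
  cw <- params[[paste0(prefix, ".w")]]
  cf <- conv_fwd(x, cw, params[[paste0(prefix, ".b")]], stride, pad,
                 want_col = keep_col)
  if (keep_col) { y <- cf$y; col <- cf$col } else { y <- cf; col <- NULL }
  bn_name <- sub("conv1$", "bn1", sub("conv2$", "bn2",
              sub("conv$", "bn", sub("proj$", "projbn", prefix))))
  bn <- bn_fwd(y, params[[paste0(bn_name, ".gamma")]],
               params[[paste0(bn_name, ".beta")]],
               buffers[[paste0(bn_name, ".mean")]],
               buffers[[paste0(bn_name, ".var")]], train)
  out <- if (relu) relu_fwd(bn$y) else bn$y
  list(out = out,
       cache = list(x = x, col = col, bn = bn$cache, prefix = prefix,
                    bn_name = bn_name, stride = stride, pad = pad,
                    relu = relu, relu_out = if (relu) out else NULL),
       rmean = bn$rmean, rvar = bn$rvar,
       bn_name_full = bn_name, update = update_buffers)
}

unit_bwd <- function(cache, params, dy, grads) {
  if (cache$relu) dy <- dy * (cache$relu_out > 0)
  bnb <- bn_bwd(cache$bn, dy)
  grads[[paste0(cache$bn_name, ".gamma")]] <-
    (grads[[paste0(cache$bn_name, ".gamma")]] %||% 0) + bnb$dgamma
  grads[[paste0(cache$bn_name, ".beta")]] <-
    (grads[[paste0(cache$bn_name, ".beta")]] %||% 0) + bnb$dbeta
  cb <- conv_bwd(cache$x, params[[paste0(cache$prefix, ".w")]], bnb$dx,
                 cache$stride, cache$pad, col = cache$col)
  grads[[paste0(cache$prefix, ".w")]] <-
    (grads[[paste0(cache$prefix, ".w")]] %||% 0) + cb$dw
  grads[[paste0(cache$prefix, ".b")]] <-
    (grads[[paste0(cache$prefix, ".b")]] %||% 0) + cb$db
  list(dx = cb$dx, grads = grads)
}

#' Forward pass through the backbone
#'
#' Runs a clip batch through the network. In training mode batch-norm uses
#' batch statistics (and, when `update_buffers = TRUE`, updates the running
#' statistics); in evaluation mode it uses the stored running statistics, so
#' batch rows are independent.
#'
#' @param model a [backbone_build()] object.
#' @param x a (B, C, T, H, W) clip tensor matching the configured shape.
#' @param train use batch statistics in batch norm?
#' @param want_cache keep the activation cache for [backbone_backward()]?
#' @param update_buffers update running batch-norm statistics (training)?
#' @return list with `logits` (B x num_classes), `feature` (the last
#'   convolutional activations consumed by SHPM), `vector` (pooled feature
#'   matrix), and optionally `cache` and updated `buffers`.
#' @export
backbone_forward <- function(model, x, train = FALSE, want_cache = FALSE,
                             update_buffers = train) {
  cfg <- model$config
  params <- model$params
  buffers <- model$buffers
  d <- dim(x)
  if (d[2] != cfg$in_channels || any(d[3:5] != cfg$input_shape))
    stop("clip shape (", paste(d, collapse = ","),
         ") does not match the configured input shape")
  caches <- list()

  u <- unit_fwd(x, params, buffers, "stem.conv", cfg$stem$stride,
                cfg$stem$pad, train, update_buffers, keep_col = want_cache)
  if (update_buffers) {
    buffers[["stem.bn.mean"]] <- u$rmean
    buffers[["stem.bn.var"]] <- u$rvar
  }
  h <- u$out
  caches$stem <- u$cache

  specs <- block_specs(cfg)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    u1 <- unit_fwd(h, params, buffers, paste0(nm, ".conv1"), sp$stride,
                   c(1, 1, 1), train, update_buffers, keep_col = want_cache)
    u2 <- unit_fwd(u1$out, params, buffers, paste0(nm, ".conv2"), c(1, 1, 1),
                   c(1, 1, 1), train, update_buffers, relu = FALSE,
                   keep_col = want_cache)
    if (sp$proj) {
      up <- unit_fwd(h, params, buffers, paste0(nm, ".proj"), sp$stride,
                     c(0, 0, 0), train, update_buffers, relu = FALSE,
                     keep_col = want_cache)
      sc <- up$out
    } else {
      up <- NULL
      sc <- h
    }
    if (update_buffers) {
      for (uu in Filter(Negate(is.null), list(u1, u2, up))) {
        buffers[[paste0(uu$bn_name_full, ".mean")]] <- uu$rmean
        buffers[[paste0(uu$bn_name_full, ".var")]] <- uu$rvar
      }
    }
    pre <- u2$out + sc
    h <- relu_fwd(pre)
    caches[[nm]] <- list(u1 = u1$cache, u2 = u2$cache,
                         up = if (sp$proj) up$cache else NULL,
                         out = h, proj = sp$proj)
  }

  feature <- h
  sh <- shpm_fwd(feature, cfg$shpm)
  logits <- sh$vector %*% params$fc.w +
    matrix(params$fc.b, nrow(sh$vector), cfg$num_classes, byrow = TRUE)

  out <- list(logits = logits, feature = feature, vector = sh$vector,
              buffers = buffers)
  if (want_cache) out$cache <- list(layers = caches, shpm = sh$cache,
                                    vector = sh$vector)
  out
}

#' Last-stage convolutional feature map
#'
#' Returns the exact activations consumed by SHPM (and used as the Grad-CAM
#' target layer).
#'
#' @inheritParams backbone_forward
#' @return a (B, C', T', H', W') activation array.
#' @export
backbone_feature_map <- function(model, x, train = FALSE) {
  backbone_forward(model, x, train = train)$feature
}

#' Recompute logits from a feature map
#'
#' Applies the SHPM head and linear classifier to a stored feature map;
#' `backbone_forward()` composed through this function reproduces its own
#' logits exactly.
#'
#' @param model a [backbone_build()] object.
#' @param feature a (B, C', T', H', W') activation array.
#' @return logits matrix (B x num_classes).
#' @export
backbone_head <- function(model, feature) {
  sh <- shpm_fwd(feature, model$config$shpm)
  sh$vector %*% model$params$fc.w +
    matrix(model$params$fc.b, nrow(sh$vector), model$config$num_classes,
           byrow = TRUE)
}

# gradient of the head only: classifier grads + d loss / d feature map
head_bwd <- function(model, cache, dlogits) {
  grads <- list()
  grads[["fc.w"]] <- t(cache$vector) %*% dlogits
  grads[["fc.b"]] <- colSums(dlogits)
  dvec <- dlogits %*% t(model$params$fc.w)
  list(dfeature = shpm_bwd(cache$shpm, dvec), grads = grads)
}

#' Backward pass: parameter gradients from logit gradients
#'
#' @param model a [backbone_build()] object.
#' @param cache the cache returned by `backbone_forward(..., want_cache
#'   = TRUE, train = TRUE)`.
#' @param dlogits gradient of the loss w.r.t. the logits (B x num_classes).
#' @return named list of gradients matching `model$params`, plus the
#'   gradient w.r.t. the feature map in attribute `"dfeature"`.
#' @export
backbone_backward <- function(model, cache, dlogits) {
  hb <- head_bwd(model, cache, dlogits)
  grads <- hb$grads
  dh <- hb$dfeature
  specs <- block_specs(model$config)
  for (nm in rev(names(specs))) {
    cc <- cache$layers[[nm]]
    dpre <- dh * (cc$out > 0)
    b2 <- unit_bwd(cc$u2, model$params, dpre, grads)
    grads <- b2$grads
    b1 <- unit_bwd(cc$u1, model$params, b2$dx, grads)
    grads <- b1$grads
    if (cc$proj) {
      bp <- unit_bwd(cc$up, model$params, dpre, grads)
      grads <- bp$grads
      dh <- b1$dx + bp$dx
    } else {
      dh <- b1$dx + dpre
    }
  }
  bs <- unit_bwd(cache$layers$stem, model$params, dh, grads)
  grads <- bs$grads
  # zero gradients for any parameter never touched (none expected)
  for (nm in names(model$params))
    if (is.null(grads[[nm]])) grads[[nm]] <- model$params[[nm]] * 0
  structure(grads[names(model$params)], dfeature = hb$dfeature)
}
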