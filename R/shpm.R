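# Spatial Hierarchical Pooling Module (SHPM).
#
# The terminal pooling of the backbone: the final feature map is divided
# into a pyramid of spatial bin grids; every block contributes its maximum
# (mu) and its average (eta). Pooling is applied per frame, the statistics
# are then reduced over the temporal axis and all levels are concatenated
# into one feature vector that feeds the linear classifier.
#
# Vector layout (documented, stable): levels in config order; within a
# level, in `concat` mode the max block comes first, then the average
# block; each block is the (C, H_bins, W_bins) array flattened in
# column-major order.

#' SHPM configuration
#'
#' @param levels list of `c(H_size, W_size)` block-size pairs, one per
#'   pyramid level. Every size must divide the feature-map extent it is
#'   applied to (checked at build/forward time; no silent padding).
#' @param combine how to merge the max and average statistics: `"concat"`
#'   keeps both, `"sum"` adds them, `"avg"` keeps only the average (used for
#'   the global-average-pool ablation).
#' @param temporal reduction over the temporal axis after spatial pooling:
#'   `"mean"` (default) or `"max"`.
#' @return an object of class `shpm_config`.
#' @export
shpm_config <- function(levels, combine = c("concat", "sum", "avg"),
                        temporal = c("mean", "max")) {
  combine <- match.arg(combine)
  temporal <- match.arg(temporal)
  if (!is.list(levels) || length(levels) < 1)
    stop("levels must be a non-empty list of (H_size, W_size) pairs")
  levels <- lapply(levels, function(l) {
    if (length(l) != 2 || any(l < 1)) stop("each level needs two sizes >= 1")
    as.integer(l)
  })
  structure(list(levels = levels, combine = combine, temporal = temporal),
            class = "shpm_config")
}

# Default dyadic pyramid for an H x W feature map: 1x1, 2x2 and 4x4 bin
# grids, keeping only grids whose block sizes divide the map evenly.
shpm_default_levels <- function(H, W) {
  lv <- list()
  for (k in c(1L, 2L, 4L)) {
    if (H %% k == 0 && W %% k == 0 && H >= k && W >= k)
      lv[[length(lv) + 1]] <- c(H %/% k, W %/% k)
  }
  lv
}

#' Number of spatial bins for a block size
#'
#' @param H,W feature-map height and width.
#' @param H_size,W_size block (bin) sizes.
#' @return integer vector `c(H_bins, W_bins) = c(H / H_size, W / W_size)`.
#'   Non-divisible dimensions are an error naming the offending level.
#' @export
partition_bins <- function(H, W, H_size, W_size) {
  if (H %% H_size != 0 || W %% W_size != 0)
    stop(sprintf(
      "SHPM level (%d, %d) does not divide the %dx%d feature map evenly",
      H_size, W_size, H, W))
  c(H_bins = as.integer(H %/% H_size), W_bins = as.integer(W %/% W_size))
}

# internal: pooled stats + argmax cache for one level
block_pool_cache <- function(x, H_size, W_size) {
  d <- dim(x)
  B <- d[1]; C <- d[2]; Tn <- d[3]; H <- d[4]; W <- d[5]
  bins <- partition_bins(H, W, H_size, W_size)
  Hb <- unname(bins[1]); Wb <- unname(bins[2])
  dim(x) <- c(B, C, Tn, H_size, Hb, W_size, Wb)
  y <- aperm(x, c(4, 6, 1, 2, 3, 5, 7))      # (hs, ws, B, C, T, Hb, Wb)
  m <- matrix(y, nrow = H_size * W_size)
  eta <- .colMeans(m, nrow(m), ncol(m))
  mu <- m[1, ]
  idx <- rep(1L, ncol(m))
  if (nrow(m) > 1) {
    for (r in 2:nrow(m)) {
      upd <- m[r, ] > mu                     # strict: first max wins
      mu[upd] <- m[r, upd]
      idx[upd] <- r
    }
  }
  shp <- c(B, C, Tn, Hb, Wb)
  list(mu = array(mu, shp), eta = array(eta, shp), idx = idx,
       H_size = H_size, W_size = W_size,
       in_dim = c(B, C, Tn, H_size, Hb, W_size, Wb))
}

#' Per-block max and average pooling
#'
#' Partitions the spatial extent of a 5-axis feature tensor into
#' `H_size x W_size` blocks and returns, for every (batch, channel, frame,
#' bin) index, the block maximum `mu` and block average `eta`.
#'
#' @param x a (B, C, T, H, W) numeric array.
#' @param H_size,W_size block sizes; must divide H and W.
#' @return list with arrays `mu` and `eta` of shape
#'   (B, C, T, H_bins, W_bins).
#' @export
block_pool <- function(x, H_size, W_size) {
  bp <- block_pool_cache(x, H_size, W_size)
  list(mu = bp$mu, eta = bp$eta)
}

temporal_reduce <- function(arr, mode) {
  d <- dim(arr)                              # (B, C, T, Hb, Wb)
  y <- aperm(arr, c(3, 1, 2, 4, 5))
  m <- matrix(y, nrow = d[3])
  if (mode == "mean") {
    red <- .colMeans(m, nrow(m), ncol(m))
    idx <- NULL
  } else {
    red <- m[1, ]
    idx <- rep(1L, ncol(m))
    if (nrow(m) > 1) for (r in 2:nrow(m)) {
      upd <- m[r, ] > red
      red[upd] <- m[r, upd]
      idx[upd] <- r
    }
  }
  list(val = array(red, d[c(1, 2, 4, 5)]), idx = idx, Tn = d[3])
}

# internal fast path: feature vector + cache for backprop
shpm_fwd <- function(x, config) {
  d <- dim(x)
  B <- d[1]
  caches <- vector("list", length(config$levels))
  pieces <- list()
  for (li in seq_along(config$levels)) {
    lv <- config$levels[[li]]
    bp <- block_pool_cache(x, lv[1], lv[2])
    rmu <- temporal_reduce(bp$mu, config$temporal)
    reta <- temporal_reduce(bp$eta, config$temporal)
    caches[[li]] <- list(bp = bp, rmu = rmu, reta = reta)
    if (config$combine == "concat") {
      pieces[[length(pieces) + 1]] <- matrix(rmu$val, nrow = B)
      pieces[[length(pieces) + 1]] <- matrix(reta$val, nrow = B)
    } else if (config$combine == "sum") {
      pieces[[length(pieces) + 1]] <- matrix(rmu$val + reta$val, nrow = B)
    } else {
      pieces[[length(pieces) + 1]] <- matrix(reta$val, nrow = B)
    }
  }
  list(vector = do.call(cbind, pieces),
       cache = list(levels = caches, config = config, in_dim = d))
}

# gradient of the temporal reduction
temporal_reduce_bwd <- function(dred, red, d5) {
  # dred: (B, C, Hb, Wb); returns (B, C, T, Hb, Wb)
  Tn <- d5[3]
  if (is.null(red$idx)) {
    tmp <- array(as.vector(dred) / Tn, c(d5[1], d5[2], d5[4], d5[5], Tn))
    aperm(tmp, c(1, 2, 5, 3, 4))
  } else {
    m <- matrix(0, Tn, length(red$idx))
    m[cbind(red$idx, seq_along(red$idx))] <- as.vector(dred)
    y <- array(m, c(Tn, d5[1], d5[2], d5[4], d5[5]))
    aperm(y, c(2, 3, 1, 4, 5))
  }
}

# gradient through one pooling level; dmu/deta are (B, C, T, Hb, Wb)
block_pool_bwd <- function(bp, dmu, deta) {
  hs <- bp$H_size; ws <- bp$W_size
  d7 <- bp$in_dim                            # (B, C, T, hs, Hb, ws, Wb)
  ncols <- length(bp$idx)
  dm <- matrix(rep(as.vector(deta) / (hs * ws), each = hs * ws),
               nrow = hs * ws, ncol = ncols)
  dm[cbind(bp$idx, seq_len(ncols))] <-
    dm[cbind(bp$idx, seq_len(ncols))] + as.vector(dmu)
  y <- array(dm, c(hs, ws, d7[1], d7[2], d7[3], d7[5], d7[7]))
  x7 <- aperm(y, c(3, 4, 5, 1, 6, 2, 7))
  dim(x7) <- c(d7[1], d7[2], d7[3], d7[4] * d7[5], d7[6] * d7[7])
  x7
}

shpm_bwd <- function(cache, dvec) {
  cfg <- cache$config
  d <- cache$in_dim
  B <- d[1]
  dx <- array(0, d)
  off <- 0L
  for (li in seq_along(cfg$levels)) {
    cc <- cache$levels[[li]]
    nblk <- length(cc$rmu$val) / B
    d5 <- dim(cc$bp$mu)
    if (cfg$combine == "concat") {
      dmu4 <- array(dvec[, off + seq_len(nblk), drop = FALSE], dim(cc$rmu$val))
      off <- off + nblk
      deta4 <- array(dvec[, off + seq_len(nblk), drop = FALSE], dim(cc$reta$val))
      off <- off + nblk
    } else if (cfg$combine == "sum") {
      dmu4 <- array(dvec[, off + seq_len(nblk), drop = FALSE], dim(cc$rmu$val))
      deta4 <- dmu4
      off <- off + nblk
    } else {
      deta4 <- array(dvec[, off + seq_len(nblk), drop = FALSE], dim(cc$reta$val))
      dmu4 <- array(0, dim(cc$rmu$val))
      off <- off + nblk
    }
    dmu <- temporal_reduce_bwd(dmu4, cc$rmu, d5)
    deta <- temporal_reduce_bwd(deta4, cc$reta, d5)
    dx <- dx + block_pool_bwd(cc$bp, dmu, deta)
  }
  dx
}

#' Spatial hierarchical pooling forward pass
#'
#' Applies [block_pool()] at every pyramid level, merges the max and average
#' statistics per `config$combine`, reduces over the temporal axis
#' (`config$temporal`) and concatenates the levels into one feature vector
#' per batch row. The vector layout follows the level order in `config`.
#'
#' @param x a (B, C, T, H, W) feature tensor.
#' @param config an [shpm_config()].
#' @return an object of class `pooled_feature`: list with `mu` and `eta`
#'   (per-level arrays of shape (B, C, T, H_bins, W_bins)) and `vector`
#'   (B x D feature matrix).
#' @export
shpm_forward <- function(x, config) {
  stopifnot(inherits(config, "shpm_config"))
  fw <- shpm_fwd(x, config)
  structure(list(
    mu = lapply(fw$cache$levels, function(cc) cc$bp$mu),
    eta = lapply(fw$cache$levels, function(cc) cc$bp$eta),
    vector = fw$vector,
    config = config), class = "pooled_feature")
}

#' @export
print.pooled_feature <- function(x, ...) {
  cat(sprintf("<pooled_feature: %d levels, %s merge, vector %d x %d>\n",
              length(x$mu), x$config$combine,
              nrow(x$vector), ncol(x$vector)))
  invisible(x)
}
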