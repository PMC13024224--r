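# Preprocessing, subject-level splitting and video augmentation.
#
# Coordinate convention: 0-based, half-open crop windows. A center crop of
# size c from an H x W frame starts at offsets (floor((H-c)/2),
# floor((W-c)/2)) and covers rows [r0, r0+c), cols [c0, c0+c).

#' Center-crop frames
#'
#' Crops a square `crop_size` region from the spatial center of the input.
#' Works on a single frame matrix, a (T, H, W) frame stack or a 5-axis clip
#' tensor; the spatial axes are always the last two. Frames smaller than the
#' crop are an error -- there is no implicit padding.
#'
#' @param x frame matrix, (T, H, W) array or (B, C, T, H, W) clip tensor.
#' @param crop_size side length of the square crop, in pixels.
#' @return object of the same kind with spatial size `crop_size`.
#' @export
clip_center_crop <- function(x, crop_size) {
  d <- dim(x)
  nd <- length(d)
  H <- d[nd - 1]; W <- d[nd]
  if (H < crop_size || W < crop_size)
    stop("frame (", H, "x", W, ") smaller than crop_size ", crop_size)
  r0 <- floor((H - crop_size) / 2)   # 0-based offset
  c0 <- floor((W - crop_size) / 2)
  ri <- (r0 + 1):(r0 + crop_size)
  ci <- (c0 + 1):(c0 + crop_size)
  if (nd == 2) x[ri, ci, drop = FALSE]
  else if (nd == 3) x[, ri, ci, drop = FALSE]
  else if (nd == 5) x[, , , ri, ci, drop = FALSE]
  else stop("unsupported input rank ", nd)
}

#' Group frames into fixed-length clips
#'
#' Slices a frame sequence into consecutive windows of `clip_len` frames at
#' the given stride; a tail shorter than `clip_len` is dropped. Fewer than
#' `clip_len` frames yield an empty list (not an error).
#'
#' @param x a (T, H, W) frame stack, a (B=1, C, T, H, W) clip tensor, or a
#'   [gait_sample()].
#' @param clip_len frames per clip (default 16).
#' @param stride step between clip starts; defaults to `clip_len`
#'   (non-overlapping).
#' @return list of (1, C, clip_len, H, W) clip tensors.
#' @export
frames_to_clips <- function(x, clip_len = 16L, stride = clip_len) {
  stopifnot(clip_len >= 1, stride >= 1)
  if (inherits(x, "gait_sample")) x <- x$clip
  if (length(dim(x)) == 3)
    x <- array(x, c(1, 1, dim(x)))
  d <- dim(x)
  Tn <- d[3]
  if (Tn < clip_len) return(list())
  starts <- seq(1L, Tn - clip_len + 1L, by = stride)
  lapply(starts, function(s) x[, , s:(s + clip_len - 1L), , , drop = FALSE])
}

#' Subject-level train/validation/test split
#'
#' Assigns every subject to exactly one of train/validation/test, so no
#' individual contributes data to more than one partition. Validation and
#' test counts are `round(n * fraction)` (half away from zero); the training
#' set absorbs the remainder. Deterministic given `seed`.
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param fractions length-3 proportions for (train, validation, test);
#'   must sum to 1. Default 0.64/0.16/0.20.
#' @param seed RNG seed for the shuffle.
#' @param strata optional factor (parallel to `subject_ids`, e.g. class
#'   labels); when given, the split is applied within each stratum so that
#'   small cohorts keep all classes represented in every partition.
#' @return data frame with columns `subject_id` and `split`
#'   (factor train/validation/test).
#' @export
subject_split <- function(subject_ids, fractions = c(0.64, 0.16, 0.20),
                          seed = NULL, strata = NULL) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject_ids")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (!is.null(strata)) {
    if (length(strata) != length(subject_ids))
      stop("strata must parallel subject_ids")
    groups <- split(subject_ids, strata)
    parts <- lapply(seq_along(groups), function(g)
      subject_split(groups[[g]], fractions, seed = derive_seed(seed, g)))
    out <- do.call(rbind, parts)
    return(out[order(match(out$subject_id, subject_ids)), , drop = FALSE])
  }
  n <- length(subject_ids)
  n_val <- round_half_away(n * fractions[2])
  n_test <- round_half_away(n * fractions[3])
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 0) stop("fractions incompatible with n")
  perm <- with_seed(seed, sample(subject_ids))
  split <- factor(rep(c("train", "validation", "test"),
                      c(n_train, n_val, n_test)),
                  levels = c("train", "validation", "test"))
  data.frame(subject_id = perm, split = split, stringsAsFactors = FALSE)[
    order(match(perm, subject_ids)), , drop = FALSE]
}

#' Horizontally flip a clip
#'
#' Mirrors the width axis; applying it twice returns the original clip.
#'
#' @param clip a (B, C, T, H, W) clip tensor.
#' @return the flipped clip.
#' @export
clip_hflip <- function(clip) {
  W <- dim(clip)[5]
  clip[, , , , rev(seq_len(W)), drop = FALSE]
}

# integer translation with zero padding
clip_translate <- function(clip, dy, dx) {
  d <- dim(clip)
  H <- d[4]; W <- d[5]
  out <- array(0, d)
  rs <- max(1, 1 + dy):min(H, H + dy)   # destination rows
  cs <- max(1, 1 + dx):min(W, W + dx)
  if (!length(rs) || !length(cs)) return(out)
  out[, , , rs, cs] <- clip[, , , rs - dy, cs - dx, drop = FALSE]
  out
}

# resample the frame index by `factor` with nearest-frame interpolation,
# clamping at the ends (output length unchanged)
clip_speed <- function(clip, factor) {
  Tn <- dim(clip)[3]
  idx <- pmin(pmax(round((seq_len(Tn) - 1) * factor) + 1, 1), Tn)
  clip[, , idx, , , drop = FALSE]
}

clip_temporal_shift <- function(clip, k) {
  Tn <- dim(clip)[3]
  idx <- ((seq_len(Tn) - 1 + k) %% Tn) + 1
  clip[, , idx, , , drop = FALSE]
}

#' Weak augmentation (teacher branch)
#'
#' Light random translation plus a horizontal flip with probability
#' `flip_prob`. Output shape equals input shape; values stay in \[0, 1\].
#' Deterministic given `seed`. With `max_shift = 0` and `flip_prob = 0` this
#' is the identity.
#'
#' @param clip a (B, C, T, H, W) clip tensor.
#' @param seed optional RNG seed.
#' @param max_shift maximum absolute translation in pixels; default scales
#'   the 8-pixel full-scale (224 px) value to the clip width.
#' @param flip_prob probability of a horizontal flip.
#' @return augmented clip tensor.
#' @export
augment_weak <- function(clip, seed = NULL, max_shift = NULL, flip_prob = 0.5) {
  W <- dim(clip)[5]
  if (is.null(max_shift)) max_shift <- max(1L, round(8 * W / 224))
  with_seed(seed, {
    if (max_shift > 0)
      clip <- clip_translate(clip, sample(-max_shift:max_shift, 1),
                             sample(-max_shift:max_shift, 1))
    if (flip_prob > 0 && runif(1) < flip_prob) clip <- clip_hflip(clip)
    clip
  })
}

#' Strong augmentation (student branch)
#'
#' Composition of random crop (translation), color jitter
#' (brightness/contrast), Gaussian noise, random erasing, temporal jitter and
#' speed perturbation. Output shape equals input shape; values are clipped to
#' \[0, 1\]; deterministic given `seed`. Degenerate magnitudes reduce each
#' component to the identity.
#'
#' @param clip a (B, C, T, H, W) clip tensor.
#' @param seed optional RNG seed.
#' @param max_shift maximum translation in pixels (default: 16-pixel
#'   full-scale value rescaled to the clip width).
#' @param brightness,contrast maximum additive / multiplicative jitter.
#' @param noise_sd Gaussian noise standard deviation.
#' @param erase_prob probability of erasing one random rectangle.
#' @param erase_frac maximum erased fraction per spatial dimension.
#' @param temporal_jitter maximum circular start-frame offset (frames).
#' @param speed_range range of frame-index resampling factors.
#' @param flip_prob probability of a horizontal flip.
#' @return augmented clip tensor.
#' @export
augment_strong <- function(clip, seed = NULL, max_shift = NULL,
                           brightness = 0.1, contrast = 0.1,
                           noise_sd = 0.02, erase_prob = 0.5,
                           erase_frac = 0.3, temporal_jitter = 2L,
                           speed_range = c(0.8, 1.25), flip_prob = 0.5) {
  d <- dim(clip)
  H <- d[4]; W <- d[5]
  if (is.null(max_shift)) max_shift <- max(1L, round(16 * W / 224))
  with_seed(seed, {
    if (!isTRUE(all.equal(speed_range, c(1, 1))))
      clip <- clip_speed(clip, runif(1, speed_range[1], speed_range[2]))
    if (temporal_jitter > 0)
      clip <- clip_temporal_shift(clip, sample(-temporal_jitter:temporal_jitter, 1))
    if (max_shift > 0)
      clip <- clip_translate(clip, sample(-max_shift:max_shift, 1),
                             sample(-max_shift:max_shift, 1))
    if (flip_prob > 0 && runif(1) < flip_prob) clip <- clip_hflip(clip)
    if (brightness > 0 || contrast > 0) {
      a <- 1 + runif(1, -contrast, contrast)
      b <- runif(1, -brightness, brightness)
      clip <- clip * a + b
    }
    if (noise_sd > 0)
      clip <- clip + rnorm(length(clip), sd = noise_sd)
    if (erase_prob > 0 && runif(1) < erase_prob) {
      eh <- sample(seq_len(max(1L, floor(erase_frac * H))), 1)
      ew <- sample(seq_len(max(1L, floor(erase_frac * W))), 1)
      r0 <- sample(seq_len(H - eh + 1L), 1)
      c0 <- sample(seq_len(W - ew + 1L), 1)
      clip[, , , r0:(r0 + eh - 1L), c0:(c0 + ew - 1L)] <- 0
    }
    clamp01(clip)
  })
}
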