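# Synthetic frontal-view walker videos with controllable knee alignment.
#
# The walker is an articulated stick figure seen from the front: head disc,
# torso, hip bar and two two-segment legs. The class-defining degree of
# freedom is `knee_offset`, a signed horizontal displacement of each knee
# from its hip-ankle line, in fraction-of-leg-length units:
#   knee_offset <= -delta  -> knees displaced outward  -> genu varum
#   knee_offset >= +delta  -> knees displaced inward   -> genu valgum
#   otherwise              -> normal alignment
# This mirrors the anatomical criteria for the three classes: varum means
# the ankles approximate while the inter-knee (intercondylar) gap stays
# open; valgum means the knees approximate while the inter-ankle
# (intermalleolar) gap stays open.

# Figure proportions as fractions of walker height; shared by the renderer
# and the geometric classifier.
.gait_geom <- list(
  head_r    = 0.08,
  neck_y    = 0.18,
  pelvis_y  = 0.50,
  hip_half  = 0.10,
  ankle_y   = 0.96,   # stance ankle height
  leg_len   = 0.46,   # vertical hip -> ankle distance
  lift_amp  = 0.05,
  sway_amp  = 0.02,
  foot_len  = 0.06
)

# Per-subject nuisance ranges used by generate_gait_dataset()
.gait_nuisance <- list(
  stride_period = c(8L, 24L),
  height_frac   = c(0.5, 0.9),    # walker height as fraction of frame height
  noise_sd      = c(0, 0.05),
  knee_offset   = list(normal = c(-0.02, 0.02),
                       varum  = c(-0.25, -0.10),
                       valgum = c(0.10, 0.25))
)

#' Walker parameters for the synthetic gait renderer
#'
#' @param knee_offset signed horizontal knee displacement relative to the
#'   hip-ankle line, in fraction-of-leg-length units. Negative values push the
#'   knees outward (genu varum), positive values inward (genu valgum), values
#'   near zero give normal alignment.
#' @param stride_period frames per full gait cycle (>= 4).
#' @param walker_height figure height in pixels.
#' @param noise_sd standard deviation of per-pixel additive Gaussian noise.
#' @param phase0 initial gait phase in \[0, 1).
#' @param frame_h,frame_w frame dimensions in pixels; the walker is centered.
#' @return an object of class `walker_params`.
#' @seealso [pose_at_phase()], [render_clip()]
#' @export
walker_params <- function(knee_offset = 0, stride_period = 12L,
                          walker_height = 24, noise_sd = 0, phase0 = 0,
                          frame_h = 32L, frame_w = 32L) {
  if (stride_period < 4) stop("stride_period must be >= 4 frames")
  if (phase0 < 0 || phase0 >= 1) stop("phase0 must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  p <- structure(list(knee_offset = knee_offset,
                      stride_period = as.numeric(stride_period),
                      walker_height = walker_height,
                      noise_sd = noise_sd, phase0 = phase0,
                      frame_h = as.integer(frame_h),
                      frame_w = as.integer(frame_w)),
                 class = "walker_params")
  check_walker_fits(p)
  p
}

limb_thickness <- function(h) max(1.4, 0.045 * h)

check_walker_fits <- function(p) {
  h <- p$walker_height
  g <- .gait_geom
  th <- limb_thickness(h)
  half_w <- g$hip_half * h + max(0, -p$knee_offset) * g$leg_len * h +
    g$foot_len * h + g$sway_amp * h + th / 2 + 1
  y0 <- (p$frame_h - h) / 2
  if (p$frame_w / 2 - half_w < 0 || p$frame_w / 2 + half_w > p$frame_w ||
      y0 < 0 || y0 + g$ankle_y * h + th / 2 + 1 > p$frame_h)
    stop("walker configuration error: figure of height ", h,
         " with knee_offset ", p$knee_offset, " exceeds the ",
         p$frame_h, "x", p$frame_w, " frame bounds")
  invisible(p)
}

#' Map a knee offset to its 3-class label
#'
#' The class label is a deterministic function of `knee_offset` with a
#' class-boundary margin `delta`: offsets at or below `-delta` are genu varum
#' (code 21), at or above `+delta` genu valgum (code 22), otherwise normal
#' (code 11).
#'
#' @param knee_offset numeric vector of knee offsets.
#' @param delta class-boundary margin in leg-length units (default 0.05).
#' @return integer vector of 3-class codes (11 normal / 21 varum / 22 valgum).
#' @export
classify_knee_offset <- function(knee_offset, delta = 0.05) {
  ifelse(knee_offset <= -delta, 21L, ifelse(knee_offset >= delta, 22L, 11L))
}

#' Joint positions of the walker at a gait phase
#'
#' Returns frame-pixel coordinates of the walker's joints at gait phase
#' `phase0 + phase`. The legs swing periodically with period `stride_period`;
#' the two legs are half a cycle out of phase. For varum parameters the
#' horizontal inter-knee distance exceeds the inter-ankle distance, for
#' valgum it is smaller, at every phase.
#'
#' @param params a [walker_params()] object.
#' @param phase gait phase offset in cycles (any real; wrapped mod 1).
#' @return numeric matrix with rows head, neck, pelvis, hip_l, hip_r, knee_l,
#'   knee_r, ankle_l, ankle_r, foot_l, foot_r and columns x, y.
#' @export
pose_at_phase <- function(params, phase = 0) {
  stopifnot(inherits(params, "walker_params"))
  g <- .gait_geom
  h <- params$walker_height
  phi <- (params$phase0 + phase) %% 1
  cx <- params$frame_w / 2
  y0 <- (params$frame_h - h) / 2
  sway <- g$sway_amp * h * sin(2 * pi * phi)

  lift_l <- g$lift_amp * h * max(0, sin(2 * pi * phi))
  lift_r <- g$lift_amp * h * max(0, sin(2 * pi * (phi + 0.5)))

  hipy <- y0 + g$pelvis_y * h
  anky <- y0 + g$ankle_y * h
  hw <- g$hip_half * h
  L <- g$leg_len * h
  ko <- params$knee_offset

  leg <- function(side, lift) {  # side: -1 left, +1 right
    hip <- c(cx + sway + side * hw, hipy)
    ank <- c(cx + sway + side * hw, anky - lift)
    knee <- c((hip[1] + ank[1]) / 2 - side * ko * L,
              (hip[2] + ank[2]) / 2 - 0.3 * lift)
    foot <- c(ank[1] + side * g$foot_len * h, ank[2])
    rbind(hip = hip, knee = knee, ankle = ank, foot = foot)
  }
  lft <- leg(-1, lift_l)
  rgt <- leg(+1, lift_r)

  out <- rbind(
    head   = c(cx + sway, y0 + g$head_r * h),
    neck   = c(cx + sway, y0 + g$neck_y * h),
    pelvis = c(cx + sway, hipy),
    hip_l  = lft["hip", ],  hip_r  = rgt["hip", ],
    knee_l = lft["knee", ], knee_r = rgt["knee", ],
    ankle_l = lft["ankle", ], ankle_r = rgt["ankle", ],
    foot_l = lft["foot", ], foot_r = rgt["foot", ])
  colnames(out) <- c("x", "y")
  out
}

# --- rasterizer -------------------------------------------------------------

# Draw an anti-aliased thick segment into img (H x W matrix, row = y).
# Pixel (r, c) has center (c - 0.5, r - 0.5).
draw_segment <- function(img, p1, p2, thick) {
  H <- nrow(img); W <- ncol(img)
  m <- thick / 2 + 1.5
  r0 <- max(1L, floor(min(p1[2], p2[2]) - m)); r1 <- min(H, ceiling(max(p1[2], p2[2]) + m))
  c0 <- max(1L, floor(min(p1[1], p2[1]) - m)); c1 <- min(W, ceiling(max(p1[1], p2[1]) + m))
  if (r0 > r1 || c0 > c1) return(img)
  ys <- (r0:r1) - 0.5; xs <- (c0:c1) - 0.5
  px <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  py <- matrix(ys, nrow = length(ys), ncol = length(xs))
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  tt <- if (len2 < 1e-12) 0 else pmin(pmax(((px - p1[1]) * vx + (py - p1[2]) * vy) / len2, 0), 1)
  d <- sqrt((px - (p1[1] + tt * vx))^2 + (py - (p1[2] + tt * vy))^2)
  val <- clamp01(thick / 2 + 0.5 - d)
  img[r0:r1, c0:c1] <- pmax(img[r0:r1, c0:c1], val)
  img
}

draw_disc <- function(img, center, radius) {
  H <- nrow(img); W <- ncol(img)
  m <- radius + 1.5
  r0 <- max(1L, floor(center[2] - m)); r1 <- min(H, ceiling(center[2] + m))
  c0 <- max(1L, floor(center[1] - m)); c1 <- min(W, ceiling(center[1] + m))
  if (r0 > r1 || c0 > c1) return(img)
  ys <- (r0:r1) - 0.5; xs <- (c0:c1) - 0.5
  px <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  py <- matrix(ys, nrow = length(ys), ncol = length(xs))
  d <- sqrt((px - center[1])^2 + (py - center[2])^2)
  val <- clamp01(radius + 0.5 - d)
  img[r0:r1, c0:c1] <- pmax(img[r0:r1, c0:c1], val)
  img
}

render_frame <- function(params, phase) {
  pose <- pose_at_phase(params, phase)
  h <- params$walker_height
  th <- limb_thickness(h)
  img <- matrix(0, params$frame_h, params$frame_w)
  img <- draw_disc(img, pose["head", ], .gait_geom$head_r * h)
  img <- draw_segment(img, pose["neck", ], pose["pelvis", ], max(1.8, 0.07 * h))
  img <- draw_segment(img, pose["hip_l", ], pose["hip_r", ], th)
  for (side in c("l", "r")) {
    img <- draw_segment(img, pose[paste0("hip_", side), ],
                        pose[paste0("knee_", side), ], th)
    img <- draw_segment(img, pose[paste0("knee_", side), ],
                        pose[paste0("ankle_", side), ], th)
    img <- draw_segment(img, pose[paste0("ankle_", side), ],
                        pose[paste0("foot_", side), ], th)
  }
  img
}

#' Construct a gait sample
#'
#' A gait sample bundles one clip tensor (batch size 1) with a subject id and
#' optional labels. The binary label is derived from the 3-class label:
#' 1 (normal) iff the 3-class code is 11, else 2 (abnormal, merging varum and
#' valgum).
#'
#' @param clip a (1, C, T, H, W) clip tensor with values in \[0, 1\].
#' @param subject_id opaque subject identifier.
#' @param label3 optional 3-class code (11/21/22) or `NULL` for unlabeled.
#' @param params optional [walker_params()] the clip was rendered from.
#' @param pseudo logical; `TRUE` marks `label3` as a model-assigned
#'   pseudo-label rather than ground truth.
#' @return an object of class `gait_sample`.
#' @export
gait_sample <- function(clip, subject_id, label3 = NULL, params = NULL,
                        pseudo = FALSE) {
  as_clip_tensor(clip)
  if (dim(clip)[1] != 1L) stop("a gait sample holds a single clip (B = 1)")
  if (!is.null(label3)) {
    if (!label3 %in% c(11L, 21L, 22L)) stop("label3 must be 11, 21 or 22")
    label2 <- if (label3 == 11L) 1L else 2L
  } else label2 <- NULL
  structure(list(clip = clip, subject_id = as.character(subject_id),
                 label3 = if (is.null(label3)) NULL else as.integer(label3),
                 label2 = label2, params = params, pseudo = isTRUE(pseudo)),
            class = "gait_sample")
}

#' @export
print.gait_sample <- function(x, ...) {
  d <- dim(x$clip)
  cat(sprintf("<gait_sample %s: %dx%dx%dx%d clip, label3 = %s%s>\n",
              x$subject_id, d[2], d[3], d[4], d[5],
              if (is.null(x$label3)) "unlabeled" else x$label3,
              if (x$pseudo) " (pseudo)" else ""))
  invisible(x)
}

#' Render a walker video clip
#'
#' Renders `T` grayscale frames of the articulated walker, adds optional
#' per-pixel Gaussian noise (clipped to \[0, 1\]) and packs them into a
#' (1, 1, T, H, W) clip tensor. Rendering is deterministic given
#' (`params`, `seed`).
#'
#' @param params a [walker_params()] object.
#' @param T number of frames (>= 1).
#' @param seed RNG seed for the additive noise; unused when `noise_sd = 0`.
#' @param subject_id subject identifier for the returned sample.
#' @param labeled attach the geometry-determined 3-class label?
#' @return a [gait_sample()].
#' @export
render_clip <- function(params, T = 16L, seed = NULL, subject_id = "S1",
                        labeled = TRUE) {
  stopifnot(inherits(params, "walker_params"), T >= 1)
  H <- params$frame_h; W <- params$frame_w
  clip <- array(0, c(1, 1, T, H, W))
  for (t in seq_len(T))
    clip[1, 1, t, , ] <- render_frame(params, (t - 1) / params$stride_period)
  if (params$noise_sd > 0) {
    clip <- with_seed(seed, clip + rnorm(length(clip), sd = params$noise_sd))
    clip <- clamp01(clip)
  }
  gait_sample(clip, subject_id,
              label3 = if (labeled) classify_knee_offset(params$knee_offset) else NULL,
              params = params)
}

#' Generate a synthetic gait video dataset
#'
#' Produces one clip per subject with per-subject nuisance variation (stride
#' period, figure scale, noise level, initial phase) drawn from fixed ranges,
#' and class-determining knee offsets drawn per class. Class counts follow
#' `class_mix` by largest-remainder rounding. Labels (and the generating
#' walker parameters) are removed from the unlabeled fraction, not merely
#' hidden.
#'
#' @param n_subjects number of subjects (one video each).
#' @param class_mix proportions over (normal, varum, valgum); must sum to 1.
#' @param labeled_fraction fraction of subjects that keep their label.
#' @param frames frames per subject video.
#' @param frame_h,frame_w frame dimensions in pixels.
#' @param seed RNG seed controlling every random draw.
#' @param noise_sd_range range of per-subject noise standard deviations;
#'   set to `c(0, 0)` for noise-free data.
#' @param stride_period_range range (frames per gait cycle) the per-subject
#'   walking speed is drawn from.
#' @param height_frac_range range of figure heights as a fraction of
#'   `frame_h`.
#' @return a list of [gait_sample()] objects (class `gait_dataset`).
#' @export
generate_gait_dataset <- function(n_subjects,
                                  class_mix = c(1, 1, 1) / 3,
                                  labeled_fraction = 1,
                                  frames = 16L, frame_h = 32L, frame_w = 32L,
                                  seed = NULL,
                                  noise_sd_range = .gait_nuisance$noise_sd,
                                  stride_period_range = .gait_nuisance$stride_period,
                                  height_frac_range = .gait_nuisance$height_frac) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (labeled_fraction < 0 || labeled_fraction > 1)
    stop("labeled_fraction must lie in [0, 1]")
  n_classes <- sum(class_mix > 0)
  if (n_subjects < n_classes)
    stop("n_subjects must be at least the number of classes with nonzero proportion")

  # largest-remainder apportionment: deterministic, ties to earlier class
  raw <- n_subjects * class_mix
  counts <- floor(raw)
  rem <- n_subjects - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    ord <- order(-frac, seq_along(frac))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }

  cls <- rep(c("normal", "varum", "valgum"), counts)
  nz <- .gait_nuisance
  with_seed(seed, {
    cls <- sample(cls)  # interleave classes across subject ids
    samples <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      rng <- nz$knee_offset[[cls[i]]]
      p <- walker_params(
        knee_offset  = runif(1, rng[1], rng[2]),
        stride_period = sample(seq(stride_period_range[1],
                                   stride_period_range[2]), 1),
        walker_height = runif(1, height_frac_range[1],
                              height_frac_range[2]) * frame_h,
        noise_sd = runif(1, noise_sd_range[1], noise_sd_range[2]),
        phase0   = runif(1),
        frame_h = frame_h, frame_w = frame_w)
      samples[[i]] <- render_clip(p, T = frames,
                                  seed = sample.int(2^30, 1),
                                  subject_id = sprintf("S%03d", i))
    }
    n_unlab <- round(n_subjects * (1 - labeled_fraction))
    if (n_unlab > 0) {
      unlab <- sample(n_subjects, n_unlab)
      for (i in unlab) {
        s <- samples[[i]]
        samples[[i]] <- gait_sample(s$clip, s$subject_id, label3 = NULL)
      }
    }
    structure(samples, class = c("gait_dataset", "list"))
  })
}

#' @export
print.gait_dataset <- function(x, ...) {
  lab <- vapply(x, function(s) !is.null(s$label3), logical(1))
  tab <- table(factor(vapply(x[lab], function(s) s$label3, integer(1)),
                      levels = c(11, 21, 22)))
  cat(sprintf("<gait_dataset: %d subjects, %d labeled (11:%d 21:%d 22:%d)>\n",
              length(x), sum(lab), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Manifest table for a gait dataset
#'
#' @param samples a list of [gait_sample()] objects.
#' @param split optional data frame from [subject_split()] to merge in.
#' @return data frame with subject_id, label3, label2, n_frames (and split).
#' @export
gait_manifest <- function(samples, split = NULL) {
  df <- data.frame(
    subject_id = vapply(samples, function(s) s$subject_id, character(1)),
    label3 = vapply(samples, function(s) s$label3 %||% NA_integer_, integer(1)),
    label2 = vapply(samples, function(s) s$label2 %||% NA_integer_, integer(1)),
    n_frames = vapply(samples, function(s) dim(s$clip)[3], integer(1)),
    stringsAsFactors = FALSE)
  if (!is.null(split)) df <- merge(df, split, by = "subject_id", sort = FALSE)
  df
}

#' Write a gait dataset to disk
#'
#' One directory per subject containing the frames as PNG files, plus a
#' `manifest.csv` (subject_id, path, label3, label2, n_frames, split) at the
#' dataset root.
#'
#' @param samples list of [gait_sample()] objects.
#' @param dir output directory (created if missing).
#' @param split optional split assignment data frame.
#' @return the manifest data frame, invisibly.
#' @export
write_gait_dataset <- function(samples, dir, split = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- gait_manifest(samples, split)
  man$path <- file.path(man$subject_id)
  for (s in samples) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    for (t in seq_len(dim(s$clip)[3]))
      png::writePNG(s$clip[1, 1, t, , ], file.path(sd, sprintf("frame_%03d.png", t)))
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a gait dataset written by [write_gait_dataset()]
#'
#' @param dir dataset root directory containing `manifest.csv`.
#' @return a list of [gait_sample()] objects (class `gait_dataset`).
#' @export
read_gait_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  samples <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sd <- file.path(dir, man$path[i])
    files <- sort(list.files(sd, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
    frames <- lapply(files, png::readPNG)
    H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
    clip <- array(0, c(1, 1, length(frames), H, W))
    for (t in seq_along(frames)) clip[1, 1, t, , ] <- frames[[t]]
    lb <- man$label3[i]
    samples[[i]] <- gait_sample(clip, man$subject_id[i],
                                label3 = if (is.na(lb)) NULL else lb)
  }
  structure(samples, class = c("gait_dataset", "list"))
}

# --- geometric reference classifier ----------------------------------------

row_width <- function(v, xs, floor_val = 0.25) {
  v[v < floor_val] <- 0
  if (sum(v) <= 0) return(NA_real_)
  mid <- sum(v * xs) / sum(v)
  lf <- xs < mid
  if (sum(v[lf]) <= 0 || sum(v[!lf]) <= 0) return(NA_real_)
  sum(v[!lf] * xs[!lf]) / sum(v[!lf]) - sum(v[lf] * xs[lf]) / sum(v[lf])
}

#' Classify a rendered clip from its leg geometry
#'
#' Model-free reference classifier that recovers the class from the rendered
#' pixels: it locates the figure, measures the horizontal width between the
#' two leg strokes at knee height and at shank height on the most
#' stance-like frame, converts the difference back to a knee-offset estimate
#' and applies the same class-boundary margin as [classify_knee_offset()].
#' On noise-free renders this recovers the generating label exactly, which
#' guarantees the learning problem is well posed.
#'
#' @param x a [gait_sample()] or a (1, 1, T, H, W) clip tensor.
#' @param delta class-boundary margin (as in [classify_knee_offset()]).
#' @return a 3-class code (11/21/22), or `NA` if no figure is found.
#' @export
gait_geometry_classify <- function(x, delta = 0.05) {
  clip <- if (inherits(x, "gait_sample")) x$clip else x
  as_clip_tensor(clip, check_range = FALSE)
  g <- .gait_geom
  Tn <- dim(clip)[3]
  W <- dim(clip)[5]
  xs <- seq_len(W) - 0.5

  # rank frames by how low the feet reach (closest to double stance) and
  # average the offset estimate over the most stance-like frames
  bottoms <- vapply(seq_len(Tn), function(t) {
    fr <- clip[1, 1, t, , ]
    rows <- which(apply(fr > 0.3, 1, any))
    if (!length(rows)) NA_real_ else max(rows) + mean(fr[max(rows), ] > 0.3)
  }, numeric(1))
  if (all(is.na(bottoms))) return(NA_integer_)
  pick <- order(bottoms, decreasing = TRUE)[seq_len(min(3L, Tn))]
  est <- vapply(pick, function(t)
    knee_offset_from_frame(clip[1, 1, t, , ], xs), numeric(1))
  if (all(is.na(est))) return(NA_integer_)
  classify_knee_offset(mean(est, na.rm = TRUE), delta)
}

# single-frame knee-offset estimate from the width profile
knee_offset_from_frame <- function(fr, xs) {
  g <- .gait_geom
  rows <- which(apply(fr > 0.3, 1, any))
  if (!length(rows)) return(NA_real_)
  top <- min(rows); bot <- max(rows)
  span <- bot - top + 1

  # anatomical landmarks from the pixels themselves: the hip bar is the
  # widest-mass row in the middle band of the figure, the ankles sit just
  # above the lowest ink row, and the knee is their midpoint.
  band <- max(1, round(top + 0.35 * span)):min(nrow(fr), round(top + 0.65 * span))
  mass <- vapply(band, function(r) { v <- fr[r, ]; sum(v[v >= 0.25]) },
                 numeric(1))
  hip_row <- band[which.max(mass)]
  ankle_row <- bot - 1.5
  knee_row <- (hip_row + ankle_row) / 2
  L_px <- ankle_row - hip_row                 # leg length in pixels
  if (L_px < 3) return(NA_real_)

  # linear interpolation of the width profile at a fractional row
  width_at <- function(r) {
    r0 <- floor(r); r1 <- r0 + 1
    if (r0 < 1 || r1 > nrow(fr)) return(NA_real_)
    w0 <- row_width(fr[r0, ], xs); w1 <- row_width(fr[r1, ], xs)
    if (!is.finite(w0) || !is.finite(w1)) return(NA_real_)
    w0 + (r - r0) * (w1 - w0)
  }
  # knee width versus mid-thigh / upper-shank reference rows (each carries
  # half the knee displacement): the difference is |knee_offset| * L_px.
  w_knee <- width_at(knee_row)
  w_ref <- mean(c(width_at((hip_row + knee_row) / 2),
                  width_at((knee_row + ankle_row) / 2)), na.rm = TRUE)
  if (!is.finite(w_knee) || !is.finite(w_ref)) return(NA_real_)

  -(w_knee - w_ref) / L_px
}
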