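# Evaluation: confusion-matrix metrics, macro averages, PR curves and
# Grad-CAM saliency for the 3D backbone.

#' Binary screening decision from an abnormality probability
#'
#' `"Abnormal"` iff `p_abnormal` strictly exceeds the threshold; the tie at
#' the threshold is decided toward `"Normal"` (conservative screening
#' default). The pseudo-label confidence threshold used during training
#' plays no role here.
#'
#' @param p_abnormal probability (vector) of the abnormal class.
#' @param threshold decision threshold (default 0.5).
#' @return character vector of `"Normal"` / `"Abnormal"`.
#' @export
binary_decision <- function(p_abnormal, threshold = 0.5) {
  if (any(p_abnormal < 0 | p_abnormal > 1)) stop("probabilities must lie in [0, 1]")
  ifelse(p_abnormal > threshold, "Abnormal", "Normal")
}

#' Binary confusion counts
#'
#' @param truth,pred vectors of labels.
#' @param positive the positive-class value (default `"Abnormal"`).
#' @return list with fields `TP`, `FP`, `FN`, `TN` (class
#'   `confusion_counts`).
#' @export
confusion_counts <- function(truth, pred, positive = "Abnormal") {
  tp <- truth == positive
  pp <- pred == positive
  structure(list(TP = sum(tp & pp), FP = sum(!tp & pp),
                 FN = sum(tp & !pp), TN = sum(!tp & !pp)),
            class = "confusion_counts")
}

ratio_or_na <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); returning NA")
    return(NA_real_)
  }
  num / den
}

#' Clinical metrics from binary confusion counts
#'
#' Precision = TP/(TP+FP), recall (sensitivity) = TP/(TP+FN), specificity =
#' TN/(TN+FP), PPV = precision, NPV = TN/(TN+FN), accuracy and F1.
#' Zero-denominator cases return `NA` with a warning, never a silent 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return named list of metric values.
#' @export
binary_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    precision <- ratio_or_na(TP, TP + FP, "precision")
    recall <- ratio_or_na(TP, TP + FN, "recall")
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
      NA_real_ else 2 * precision * recall / (precision + recall)
    list(accuracy = (TP + TN) / (TP + FP + FN + TN),
         precision = precision, recall = recall,
         sensitivity = recall,
         specificity = ratio_or_na(TN, TN + FP, "specificity"),
         ppv = precision,
         npv = ratio_or_na(TN, TN + FN, "NPV"),
         f1 = f1)
  })
}

#' Multiclass confusion matrix
#'
#' @param truth,pred vectors of class codes.
#' @param classes class codes fixing the row/column order.
#' @return C x C integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, classes = sort(unique(truth))) {
  tab <- table(factor(truth, levels = classes),
               factor(pred, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(truth = classes, pred = classes))
  m
}

#' Macro-averaged multiclass metrics
#'
#' Per-class one-vs-rest precision and recall are averaged unweighted;
#' macro F1 is the harmonic mean of macro precision and macro recall (not
#' the mean of per-class F1 scores, which generally differs). Per-class
#' values with a zero denominator are `NA` (flagged with a warning) and are
#' excluded from the average.
#'
#' @param mat C x C confusion matrix (rows = truth, columns = prediction).
#' @return list with `macro_p`, `macro_r`, `macro_f1`, `accuracy` and the
#'   per-class values.
#' @export
macro_metrics <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat) || nrow(mat) < 2)
    stop("need a square confusion matrix with C >= 2")
  C <- nrow(mat)
  p_i <- r_i <- rep(NA_real_, C)
  for (i in seq_len(C)) {
    p_i[i] <- ratio_or_na(mat[i, i], sum(mat[, i]), paste0("precision[", i, "]"))
    r_i[i] <- ratio_or_na(mat[i, i], sum(mat[i, ]), paste0("recall[", i, "]"))
  }
  macro_p <- mean(p_i, na.rm = TRUE)
  macro_r <- mean(r_i, na.rm = TRUE)
  macro_f1 <- if (macro_p + macro_r == 0) NA_real_ else
    2 * macro_p * macro_r / (macro_p + macro_r)
  list(macro_p = macro_p, macro_r = macro_r, macro_f1 = macro_f1,
       accuracy = sum(diag(mat)) / sum(mat),
       per_class_precision = p_i, per_class_recall = r_i)
}

#' Precision-recall curve and PR-AUC
#'
#' Computes precision and recall at every distinct score threshold (ties
#' grouped), sweeping from the highest score down, and the area under the
#' curve by the step rule `sum (R_k - R_{k-1}) * P_k` (average precision).
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores for the positive class.
#' @param truth logical (or 0/1) vector; `TRUE` = positive.
#' @return list with a `curve` data frame (threshold, precision, recall)
#'   and `auc`.
#' @export
pr_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  if (!any(truth) || all(truth))
    stop("need at least one positive and one negative sample")
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(truth)
  prec <- rec <- numeric(length(ths))
  for (k in seq_along(ths)) {
    sel <- scores >= ths[k]
    prec[k] <- sum(truth & sel) / sum(sel)
    rec[k] <- sum(truth & sel) / n_pos
  }
  auc <- sum(diff(c(0, rec)) * prec)
  list(curve = data.frame(threshold = ths, precision = prec, recall = rec),
       auc = auc)
}

# --- Grad-CAM ---------------------------------------------------------------

# bilinear resize of a matrix to H x W (pixel-center alignment)
resize_bilinear <- function(m, H, W) {
  h0 <- nrow(m); w0 <- ncol(m)
  if (h0 == H && w0 == W) return(m)
  sy <- h0 / H; sx <- w0 / W
  yy <- pmin(pmax((seq_len(H) - 0.5) * sy - 0.5, 0), h0 - 1)
  xx <- pmin(pmax((seq_len(W) - 0.5) * sx - 0.5, 0), w0 - 1)
  y0 <- pmin(floor(yy), h0 - 1); y1 <- pmin(y0 + 1, h0 - 1)
  x0 <- pmin(floor(xx), w0 - 1); x1 <- pmin(x0 + 1, w0 - 1)
  fy <- yy - y0; fx <- xx - x0
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - fy, 1 - fx)
  b <- m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - fy, fx)
  d <- m[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, 1 - fx)
  e <- m[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
  a + b + d + e
}

#' Grad-CAM saliency map for a clip
#'
#' Computes the gradient of the chosen class logit with respect to the last
#' convolutional feature map (the activations consumed by SHPM), averages
#' it over the batch/temporal/spatial extent to obtain one weight per
#' channel, forms the rectified weighted activation sum, upsamples it to the
#' input frame size (bilinear in space, nearest in time) and min-max
#' normalises within the clip. An all-zero map is returned flat with a
#' warning (degenerate, not fatal).
#'
#' @param object a fitted [gaitmt()] model.
#' @param x a [gait_sample()] or (1, C, T, H, W) clip tensor.
#' @param class_index class position (1..C) to explain; default the
#'   predicted class.
#' @param which use the `"student"` (default) or `"teacher"` network.
#' @return an object of class `saliency_map`: list with `values`
#'   (a (T, H, W) array in \[0, 1\]), `class_index` and the class `code`.
#' @export
grad_cam <- function(object, x, class_index = NULL,
                     which = c("student", "teacher")) {
  stopifnot(inherits(object, "gaitmt"))
  clip <- if (inherits(x, "gait_sample")) x$clip else x
  as_clip_tensor(clip, check_range = FALSE)
  P <- prepare_clips(list(gait_sample(clamp01(clip), "cam")), object$config)
  net <- as_backbone(object, match.arg(which))
  d_in <- dim(P$clips[[1]])
  Tn <- d_in[3]; H <- d_in[4]; W <- d_in[5]

  cams <- vector("list", length(P$clips))
  for (ci in seq_along(P$clips)) {
    fwd <- backbone_forward(net, P$clips[[ci]], train = FALSE,
                            want_cache = TRUE)
    if (is.null(class_index))
      class_index <- which.max(fwd$logits[1, ])
    dlog <- matrix(0, 1, ncol(fwd$logits))
    dlog[1, class_index] <- 1
    hb <- head_bwd(net, fwd$cache, dlog)
    dfeat <- hb$dfeature                      # (1, C', T', H', W')
    feat <- fwd$feature
    Cp <- dim(feat)[2]; Tp <- dim(feat)[3]
    wgt <- vapply(seq_len(Cp), function(c) mean(dfeat[1, c, , , ]),
                  numeric(1))
    cam <- array(0, c(Tp, dim(feat)[4], dim(feat)[5]))
    for (c in seq_len(Cp)) cam <- cam + wgt[c] * feat[1, c, , , ]
    cam[cam < 0] <- 0
    # upsample: nearest in time, bilinear in space
    tmap <- pmin(pmax(ceiling(seq_len(Tn) * Tp / Tn), 1), Tp)
    out <- array(0, c(Tn, H, W))
    for (t in seq_len(Tn))
      out[t, , ] <- resize_bilinear(cam[tmap[t], , ], H, W)
    cams[[ci]] <- out
  }
  # stitch per-clip maps back into one (T_total, H, W) array
  vals <- array(0, c(Tn * length(cams), H, W))
  for (ci in seq_along(cams))
    vals[(ci - 1L) * Tn + seq_len(Tn), , ] <- cams[[ci]]
  rng <- range(vals)
  if (rng[2] - rng[1] < 1e-12) {
    if (rng[2] == 0)
      warning("all-zero saliency map (degenerate gradients); returning flat map")
    vals <- vals * 0
  } else {
    vals <- (vals - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(values = vals, class_index = class_index,
                 code = object$classes[class_index]), class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<saliency_map: %d frames %dx%d, class %s, range [%.2f, %.2f]>\n",
              d[1], d[2], d[3], x$code, min(x$values), max(x$values)))
  invisible(x)
}

#' Overlay a saliency map on a frame
#'
#' Renders one frame with the saliency map alpha-blended in a fixed
#' colormap; the same colormap and transparency are used for every class.
#'
#' @param sample a [gait_sample()].
#' @param map a [grad_cam()] saliency map for that clip.
#' @param frame frame index.
#' @param alpha overlay transparency.
#' @return an (H, W, 3) RGB array in \[0, 1\].
#' @export
saliency_overlay <- function(sample, map, frame = 1L, alpha = 0.5) {
  fr <- sample$clip[1, 1, frame, , ]
  sal <- map$values[frame, , ]
  out <- array(0, c(nrow(fr), ncol(fr), 3))
  out[, , 1] <- clamp01(fr * (1 - alpha) + alpha * sal)       # heat in red
  out[, , 2] <- fr * (1 - alpha)
  out[, , 3] <- clamp01(fr * (1 - alpha) + alpha * (1 - sal) * 0.3)
  out
}

# --- end-to-end evaluation --------------------------------------------------

#' Evaluate a fitted model on a labeled test set
#'
#' Scores video-level predictions (mean clip softmax) on held-out labeled
#' samples. Subjects that appeared anywhere in training (labeled, unlabeled
#' or validation pool) are a hard error -- the subject-leakage guard. For the
#' binary task the abnormal probability is the summed probability of the two
#' abnormal classes and decisions use [binary_decision()].
#'
#' @param object a fitted [gaitmt()] model.
#' @param samples labeled test samples.
#' @param task `"3class"` or `"binary"`.
#' @param threshold binary decision threshold.
#' @return an object of class `gaitmt_eval`: metrics, confusion matrix,
#'   video-level probabilities and truth.
#' @export
gaitmt_evaluate <- function(object, samples, task = c("3class", "binary"),
                            threshold = 0.5) {
  task <- match.arg(task)
  ids <- vapply(samples, function(s) s$subject_id, character(1))
  leak <- intersect(ids, object$train_subjects)
  if (length(leak))
    stop("subject leakage: test subjects also used in training: ",
         paste(leak, collapse = ", "))
  probs <- predict(object, samples, type = "prob", level = "video")
  truth3 <- vapply(samples, function(s) {
    if (is.null(s$label3)) stop("test sample ", s$subject_id, " is unlabeled")
    s$label3
  }, integer(1))
  names(truth3) <- ids
  truth3 <- truth3[rownames(probs)]

  if (task == "3class") {
    pred <- object$classes[max.col(probs, ties.method = "first")]
    cm <- confusion_matrix(truth3, pred, classes = object$classes)
    mm <- macro_metrics(cm)
    res <- list(task = task, confusion = cm, metrics = mm, probs = probs,
                truth = truth3)
  } else {
    p_abn <- rowSums(probs[, as.character(c(21L, 22L)), drop = FALSE])
    truth_bin <- ifelse(truth3 == 11L, "Normal", "Abnormal")
    pred <- binary_decision(p_abn, threshold)
    cc <- confusion_counts(truth_bin, pred)
    bm <- binary_metrics(cc)
    pr <- pr_curve(p_abn, truth_bin == "Abnormal")
    bm$pr_auc <- pr$auc
    cm <- matrix(c(cc$TN, cc$FN, cc$FP, cc$TP), 2, 2,
                 dimnames = list(truth = c("Normal", "Abnormal"),
                                 pred = c("Normal", "Abnormal")))
    res <- list(task = task, confusion = cm, metrics = bm, counts = cc,
                pr = pr, probs = cbind(probs, p_abnormal = p_abn),
                truth = truth3)
  }
  structure(res, class = "gaitmt_eval")
}

#' @export
print.gaitmt_eval <- function(x, ...) {
  cat(sprintf("Evaluation (%s task), %d videos\n", x$task, sum(x$confusion)))
  print(x$confusion)
  m <- x$metrics
  if (x$task == "3class") {
    cat(sprintf("accuracy %.3f | macro P %.3f | macro R %.3f | macro F1 %.3f\n",
                m$accuracy, m$macro_p, m$macro_r, m$macro_f1))
  } else {
    cat(sprintf(
      "accuracy %.3f | precision %.3f | recall %.3f | specificity %.3f | PR-AUC %.3f\n",
      m$accuracy, m$precision, m$recall, m$specificity, m$pr_auc))
  }
  invisible(x)
}
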