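# The gaitmt() fitting function and S3 methods for the fitted model.

# --- clip preparation -------------------------------------------------------

# Turn a list of gait_samples into a clip-level table: list of (1,C,T,H,W)
# arrays plus parallel label / video-id vectors. Frames larger than the
# configured crop are center-cropped first (the test-time path applies
# center crop only).
prepare_clips <- function(samples, config, require_labels = FALSE) {
  nc <- config$model$num_classes
  classes <- if (nc == 3) c(11L, 21L, 22L) else c(1L, 2L)
  clips <- list(); labels <- integer(0); videos <- character(0)
  for (s in samples) {
    clip <- s$clip
    d <- dim(clip)
    if (d[4] > config$data$crop || d[5] > config$data$crop)
      clip <- clip_center_crop(clip, config$data$crop)
    lb <- if (nc == 3) s$label3 else s$label2
    if (require_labels && is.null(lb))
      stop("sample ", s$subject_id, " carries no label")
    li <- if (is.null(lb)) NA_integer_ else match(lb, classes)
    if (require_labels && is.na(li))
      stop("sample ", s$subject_id, " has label outside the class set")
    cl <- frames_to_clips(clip, config$data$clip_len, config$data$stride)
    for (one in cl) {
      clips[[length(clips) + 1]] <- one
      labels <- c(labels, li)
      videos <- c(videos, s$subject_id)
    }
  }
  list(clips = clips, label = labels, video = videos, classes = classes)
}

stack_clips <- function(cliplist) {
  n <- length(cliplist)
  d <- dim(cliplist[[1]])
  out <- array(0, c(n, d[2], d[3], d[4], d[5]))
  for (i in seq_len(n)) out[i, , , , ] <- cliplist[[i]][1, , , , ]
  out
}

one_hot <- function(idx, n_classes) {
  Y <- matrix(0, length(idx), n_classes)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

# eval-mode clip probabilities in batches
forward_probs <- function(model, cliplist, batch = 16L) {
  n <- length(cliplist)
  probs <- NULL
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch - 1L)
    x <- stack_clips(cliplist[i:j])
    p <- softmax_prob(backbone_forward(model, x, train = FALSE)$logits)
    probs <- rbind(probs, p)
    i <- j + 1L
  }
  probs
}

# mean of clip softmax vectors per video
aggregate_video <- function(probs, videos) {
  vids <- unique(videos)
  out <- t(vapply(vids, function(v)
    colMeans(probs[videos == v, , drop = FALSE]), numeric(ncol(probs))))
  rownames(out) <- vids
  out
}

as_backbone <- function(object, which = c("student", "teacher")) {
  which <- match.arg(which)
  if (which == "student")
    structure(list(config = object$backbone, params = object$params,
                   buffers = object$buffers), class = "backbone3d")
  else
    structure(list(config = object$backbone, params = object$teacher,
                   buffers = object$teacher_buffers), class = "backbone3d")
}

# --- fitting ----------------------------------------------------------------

#' Fit a semi-supervised gait classification model
#'
#' Trains the 3D residual backbone with SHPM terminal pooling on labeled
#' walking clips, optionally exploiting an unlabeled pool through Mean
#' Teacher training: the student sees strongly augmented clips, an
#' exponential-moving-average teacher sees weakly augmented ones, and their
#' predictive distributions are pulled together by a consistency loss whose
#' weight ramps up linearly over the early epochs. Teacher predictions whose
#' confidence strictly exceeds `tau` additionally contribute a hard
#' pseudo-label cross-entropy term. The student is optimised by Adam; the
#' teacher is updated only by EMA after every step. Early stopping and
#' learning-rate halving are driven by the validation loss.
#'
#' With an empty unlabeled pool the procedure reduces exactly to supervised
#' training.
#'
#' @param labeled list of labeled [gait_sample()] objects (one per video).
#' @param unlabeled optional list of unlabeled samples.
#' @param validation optional labeled validation samples; when omitted, a
#'   subject-level fraction (`config$train$val_fraction`) of `labeled` is
#'   carved out.
#' @param config a [gaitmt_config()].
#' @param seed integer seed controlling initialisation, data order and
#'   augmentation.
#' @return an object of class `gaitmt`.
#' @seealso [predict.gaitmt()], [gaitmt_evaluate()], [grad_cam()]
#' @export
gaitmt <- function(labeled, unlabeled = NULL, validation = NULL,
                   config = gaitmt_config(), seed = 1L) {
  if (inherits(labeled, "gait_sample")) labeled <- list(labeled)
  if (length(labeled) == 0) stop("the labeled set must be non-empty")
  tr <- config$train
  nc <- config$model$num_classes

  if (is.null(validation) && tr$val_fraction > 0 && length(labeled) >= 5) {
    ids <- vapply(labeled, function(s) s$subject_id, character(1))
    sp <- subject_split(ids, c(1 - tr$val_fraction, tr$val_fraction, 0),
                        seed = derive_seed(seed, 11))
    validation <- labeled[sp$split == "validation"]
    labeled <- labeled[sp$split == "train"]
  }

  L <- prepare_clips(labeled, config, require_labels = TRUE)
  U <- if (length(unlabeled)) prepare_clips(unlabeled, config) else NULL
  V <- if (length(validation)) prepare_clips(validation, config,
                                             require_labels = TRUE) else NULL

  bcfg <- backbone_config(preset = config$model$preset, num_classes = nc,
                          in_channels = config$model$in_channels,
                          input_shape = config$model$input_shape,
                          shpm_levels = config$model$shpm_levels,
                          shpm_combine = config$model$shpm_combine,
                          shpm_temporal = config$model$shpm_temporal)
  model <- backbone_build(bcfg, seed = derive_seed(seed, 1))
  teacher_params <- model$params          # theta' <- theta
  teacher_buffers <- model$buffers
  opt <- adam_init(model$params)
  lr <- tr$lr

  nL <- length(L$clips)
  nU <- if (is.null(U)) 0L else length(U$clips)
  hist <- list()
  best <- list(acc = -Inf, loss = Inf, epoch = NA_integer_,
               params = model$params, buffers = model$buffers,
               teacher = teacher_params, teacher_buffers = teacher_buffers)
  stagnant_stop <- 0L
  stagnant_lr <- 0L
  best_plateau <- Inf

  aug_s <- function(clip) do.call(augment_strong,
                                  c(list(clip), config$augment$strong))
  aug_w <- function(clip) do.call(augment_weak,
                                  c(list(clip), config$augment$weak))

  with_seed(derive_seed(seed, 2), {
    # cycling shuffled iterators over the labeled and unlabeled clip pools
    make_iter <- function(n) {
      ord <- NULL  # drawn lazily so an unused iterator consumes no RNG
      ptr <- 1L
      function(k) {
        out <- integer(0)
        while (length(out) < k && n > 0) {
          if (is.null(ord)) ord <<- sample(n)
          take <- min(k - length(out), n - ptr + 1L)
          out <- c(out, ord[ptr:(ptr + take - 1L)])
          ptr <<- ptr + take
          if (ptr > n) { ord <<- sample(n); ptr <<- 1L }
        }
        out
      }
    }
    next_lab <- make_iter(nL)
    next_unlab <- make_iter(nU)
    steps <- tr$steps_per_epoch %||% ceiling(nL / tr$batch)

    for (epoch in 0:(tr$epochs - 1L)) {
      lambda <- ramp_lambda(epoch, tr$ramp, tr$lambda_ceiling)
      ep_sup <- c(); ep_cons <- c(); ep_acc <- 0L; ep_gate <- 0L

      for (step in seq_len(steps)) {
        bidx <- next_lab(min(tr$batch, nL))
        xb <- stack_clips(lapply(L$clips[bidx], aug_s))
        Y <- one_hot(L$label[bidx], nc)
        fwd <- backbone_forward(model, xb, train = TRUE, want_cache = TRUE)
        model$buffers <- fwd$buffers
        p <- softmax_prob(fwd$logits)
        ep_sup <- c(ep_sup, cross_entropy_loss(p, Y))
        dlog <- (p - Y) / nrow(p)
        grads <- backbone_backward(model, fwd$cache, dlog)

        if (nU > 0 && lambda > 0) {
          ui <- next_unlab(tr$unlabeled_batch %||% tr$batch)
          xs <- stack_clips(lapply(U$clips[ui], aug_s))
          xt <- stack_clips(lapply(U$clips[ui], aug_w))
          sfwd <- backbone_forward(model, xs, train = TRUE, want_cache = TRUE)
          model$buffers <- sfwd$buffers
          tmodel <- structure(list(config = bcfg, params = teacher_params,
                                   buffers = teacher_buffers),
                              class = "backbone3d")
          tfwd <- backbone_forward(tmodel, xt, train = TRUE,
                                   update_buffers = FALSE)
          ps <- softmax_prob(sfwd$logits)
          pt <- softmax_prob(tfwd$logits)
          nu <- nrow(ps)
          ep_cons <- c(ep_cons, rowSums((ps - pt)^2))
          dmat <- 2 * (ps - pt)
          dlog_u <- ps * (dmat - rowSums(dmat * ps)) * (lambda / nu)
          if (isTRUE(tr$pseudo_ce)) {
            gate <- confidence_gate(pt, tr$tau)
            acc <- which(gate$accepted)
            ep_gate <- ep_gate + nu
            if (length(acc)) {
              ep_acc <- ep_acc + length(acc)
              Yp <- one_hot(gate$hard_label[acc], nc)
              # batch expectation: rejected samples contribute zero, so few
              # confident clips carry proportionally little weight
              dlog_u[acc, ] <- dlog_u[acc, ] +
                (ps[acc, , drop = FALSE] - Yp) * (lambda / nu)
            }
          }
          grads_u <- backbone_backward(model, sfwd$cache, dlog_u)
          grads <- param_map2(grads, grads_u, `+`)
        }

        stepped <- adam_step(opt, model$params, grads, lr, tr$beta1, tr$beta2)
        model$params <- stepped$params
        opt <- stepped$opt
        teacher_params <- ema_update(teacher_params, model$params, tr$alpha)
        teacher_buffers <- ema_update(teacher_buffers, model$buffers, tr$alpha)
      }

      if (!is.null(V)) {
        vp <- forward_probs(model, V$clips, tr$batch)
        vag <- aggregate_video(vp, V$video)
        vtruth <- L_video_labels(V)
        val_loss <- mean(-log(pmax(vag[cbind(seq_len(nrow(vag)),
                                             vtruth[rownames(vag)])], 1e-12)))
        val_acc <- mean(max.col(vag, ties.method = "first") ==
                          vtruth[rownames(vag)])
      } else {
        val_loss <- NA_real_; val_acc <- NA_real_
      }
      # model selection / early stopping follow the validation metric:
      # accuracy first, loss as the tiebreak; without a validation set the
      # training loss is the only monitor
      if (!is.null(V)) {
        metric_up <- val_acc > best$acc + 1e-12
        improved <- metric_up ||
          (val_acc >= best$acc - 1e-12 && val_loss < best$loss - 1e-8)
        mon_acc <- val_acc; mon_loss <- val_loss
      } else {
        mon_acc <- 0; mon_loss <- mean(ep_sup)
        improved <- metric_up <- mon_loss < best$loss - 1e-8
      }

      hist[[length(hist) + 1]] <- data.frame(
        epoch = epoch, lambda = lambda, lr = lr,
        train_sup = mean(ep_sup),
        train_cons = if (length(ep_cons)) mean(ep_cons) else NA_real_,
        n_pseudo = ep_acc, n_gate = ep_gate,
        val_loss = val_loss, val_acc = val_acc)

      if (improved) {
        best <- list(acc = mon_acc, loss = mon_loss, epoch = epoch,
                     params = model$params, buffers = model$buffers,
                     teacher = teacher_params,
                     teacher_buffers = teacher_buffers)
      }
      # patience runs on the validation metric itself, not the tiebreak
      if (metric_up) stagnant_stop <- 0L else
        stagnant_stop <- stagnant_stop + 1L
      # reduce-on-plateau watches the validation loss
      plateau_loss <- if (!is.null(V)) val_loss else mean(ep_sup)
      if (plateau_loss < best_plateau - 1e-8) {
        best_plateau <- plateau_loss
        stagnant_lr <- 0L
      } else {
        stagnant_lr <- stagnant_lr + 1L
        if (stagnant_lr >= tr$plateau) {
          lr <- lr * tr$plateau_factor
          stagnant_lr <- 0L
        }
      }
      if (stagnant_stop >= tr$early_stop) break
    }
  })

  subjects <- unique(c(vapply(labeled, function(s) s$subject_id, character(1)),
                       if (length(unlabeled))
                         vapply(unlabeled, function(s) s$subject_id, character(1)),
                       if (length(validation))
                         vapply(validation, function(s) s$subject_id, character(1))))
  structure(list(params = best$params, buffers = best$buffers,
                 teacher = best$teacher, teacher_buffers = best$teacher_buffers,
                 backbone = bcfg, config = config, classes = L$classes,
                 history = do.call(rbind, hist), best_epoch = best$epoch,
                 seed = seed, train_subjects = subjects,
                 n_labeled = length(labeled), n_unlabeled = length(unlabeled),
                 call = match.call()), class = "gaitmt")
}

# video-level integer labels (named by video id) from a prepared clip table
L_video_labels <- function(P) {
  tapply(P$label, P$video, function(v) v[1])
}

# --- methods ----------------------------------------------------------------

#' Predict from a fitted gait model
#'
#' Applies the test-time path (center crop only, no augmentation): every
#' video is sliced into fixed-length clips, clip softmax probabilities are
#' computed in evaluation mode and averaged into one video-level
#' distribution.
#'
#' @param object a fitted [gaitmt()] model.
#' @param newdata a [gait_sample()], list of samples, or a clip tensor.
#' @param type `"prob"` for class probabilities, `"class"` for predicted
#'   class codes.
#' @param level `"video"` (default; clip probabilities averaged per subject)
#'   or `"clip"`.
#' @param which predict with the `"student"` (default) or `"teacher"`
#'   network.
#' @param ... unused.
#' @return probability matrix (rows named by subject for video level) or a
#'   vector of class codes.
#' @export
predict.gaitmt <- function(object, newdata, type = c("prob", "class"),
                           level = c("video", "clip"),
                           which = c("student", "teacher"), ...) {
  type <- match.arg(type)
  level <- match.arg(level)
  if (is.array(newdata) && length(dim(newdata)) == 5)
    newdata <- list(gait_sample(newdata, "clip1"))
  if (inherits(newdata, "gait_sample")) newdata <- list(newdata)
  P <- prepare_clips(newdata, object$config)
  net <- as_backbone(object, match.arg(which))
  probs <- forward_probs(net, P$clips, object$config$train$batch)
  colnames(probs) <- as.character(object$classes)
  if (level == "video") probs <- aggregate_video(probs, P$video)
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.gaitmt <- function(x, ...) {
  cat("Semi-supervised gait classification model\n")
  cat(sprintf("  backbone: %s, %d classes; SHPM %d levels (%s)\n",
              x$backbone$preset, x$backbone$num_classes,
              length(x$backbone$shpm$levels), x$backbone$shpm$combine))
  cat(sprintf("  trained on %d labeled + %d unlabeled videos, seed %d\n",
              x$n_labeled, x$n_unlabeled, x$seed))
  h <- x$history
  i <- match(x$best_epoch, h$epoch)
  cat(sprintf("  %d epochs run; best epoch %s (val loss %s, val acc %s)\n",
              nrow(h), x$best_epoch,
              ifelse(is.na(h$val_loss[i]), "NA", sprintf("%.4f", h$val_loss[i])),
              ifelse(is.na(h$val_acc[i]), "NA", sprintf("%.3f", h$val_acc[i]))))
  invisible(x)
}

#' @export
summary.gaitmt <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.gaitmt <- function(object, which = c("student", "teacher"), ...) {
  if (match.arg(which) == "student") object$params else object$teacher
}

#' Plot training history
#'
#' Shows supervised and consistency loss trajectories and (when available)
#' validation accuracy against the epoch index.
#'
#' @param x a fitted [gaitmt()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gaitmt <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(h$epoch, h$train_sup, type = "l", xlab = "epoch", ylab = "loss",
       main = "training loss", ...)
  if (any(is.finite(h$train_cons)))
    lines(h$epoch, h$train_cons * h$lambda, lty = 2)
  if (any(is.finite(h$val_loss))) lines(h$epoch, h$val_loss, col = 2)
  legend("topright", bty = "n", lty = c(1, 2, 1), col = c(1, 1, 2),
         legend = c("supervised", "lambda * consistency", "validation"))
  if (any(is.finite(h$val_acc))) {
    plot(h$epoch, h$val_acc, type = "b", xlab = "epoch", ylab = "accuracy",
         main = "validation accuracy", ylim = c(0, 1))
    abline(v = x$best_epoch, lty = 3)
  } else plot.new()
  invisible(x)
}
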