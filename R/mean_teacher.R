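# Mean Teacher training engine: losses, EMA teacher tracking, consistency
# ramp-up, confidence-gated pseudo-labeling and the training loop.
#
# Objective (per optimisation step):
#   total = mean CE(student, labels) + lambda(epoch) * mean ||p_s - p_t||^2
#           + lambda(epoch) * mean CE(student, gated hard pseudo-labels)
# The teacher is never updated by gradients; after every step its parameters
# (and batch-norm running statistics) follow the student by an exponential
# moving average theta' <- alpha * theta' + (1 - alpha) * theta.

#' Numerically stable softmax
#'
#' Computes `p_i = exp(l_i) / sum_j exp(l_j)` shift-invariantly (the maximum
#' logit is subtracted first), so large logits do not overflow.
#'
#' @param logits numeric vector, or matrix with one row per sample.
#' @return probability vector / matrix of the same shape; rows sum to 1.
#' @export
softmax_prob <- function(logits) {
  if (is.matrix(logits)) {
    z <- exp(logits - apply(logits, 1, max))
    z / rowSums(z)
  } else {
    z <- exp(logits - max(logits))
    z / sum(z)
  }
}

check_one_hot <- function(Y) {
  if (!all(Y %in% c(0, 1)))
    stop("labels must be one-hot (0/1 entries)")
  s <- if (is.matrix(Y)) rowSums(Y) else sum(Y)
  if (any(s != 1)) stop("labels must be one-hot (each row sums to 1)")
  invisible(Y)
}

#' Cross-entropy between predicted probabilities and one-hot labels
#'
#' `-log p_true`, with probabilities clamped below at 1e-12.
#'
#' @param p probability vector, or matrix with one row per sample.
#' @param Y one-hot label vector / matrix matching `p`.
#' @return per-sample loss (scalar for vector input).
#' @export
cross_entropy_loss <- function(p, Y) {
  check_one_hot(Y)
  if (is.matrix(p)) {
    if (!is.matrix(Y) || !all(dim(Y) == dim(p))) stop("label shape mismatch")
    -log(pmax(rowSums(p * Y), 1e-12))
  } else {
    if (length(Y) != length(p)) stop("label shape mismatch")
    -log(pmax(sum(p * Y), 1e-12))
  }
}

#' Consistency loss between student and teacher distributions
#'
#' Squared 2-norm distance between the two probability vectors, averaged
#' over the batch for matrix input. Computed on softmax outputs, not logits.
#'
#' @param p_student,p_teacher probability vectors, or matrices with one row
#'   per sample.
#' @return scalar loss value.
#' @export
consistency_loss <- function(p_student, p_teacher) {
  if (length(p_student) != length(p_teacher))
    stop("student and teacher distributions differ in length")
  d2 <- (p_student - p_teacher)^2
  if (is.matrix(p_student)) mean(rowSums(d2)) else sum(d2)
}

#' Combine supervised and consistency losses
#'
#' `total = mean(supervised) + lambda * mean(consistency)`; an empty
#' consistency batch contributes 0 for any lambda.
#'
#' @param supervised per-sample supervised (cross-entropy) losses.
#' @param consistency per-sample consistency losses (may be empty).
#' @param lambda consistency weight (>= 0).
#' @return an object of class `loss_breakdown` with fields `supervised`,
#'   `consistency`, `lambda_used` and `total`.
#' @export
combined_loss <- function(supervised, consistency = numeric(0), lambda = 0) {
  if (lambda < 0) stop("lambda must be non-negative")
  sup <- if (length(supervised)) mean(supervised) else 0
  cons <- if (length(consistency)) mean(consistency) else 0
  structure(list(supervised = sup, consistency = cons, lambda_used = lambda,
                 total = sup + lambda * cons), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.4f = supervised %.4f + %.2f * consistency %.4f\n",
              x$total, x$supervised, x$lambda_used, x$consistency))
  invisible(x)
}

#' Consistency-weight ramp-up schedule
#'
#' Linear ramp from 0 at epoch 0 to `ceiling` at `ramp_epochs`, constant
#' afterwards: `lambda = ceiling * min(1, epoch / ramp_epochs)`.
#'
#' @param epoch epoch index (0-based); vectorised.
#' @param ramp_epochs ramp length in epochs (default 30).
#' @param ceiling final weight (default 1.0).
#' @return lambda value(s).
#' @export
ramp_lambda <- function(epoch, ramp_epochs = 30, ceiling = 1.0) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  ceiling * pmin(1, epoch / ramp_epochs)
}

#' Exponential-moving-average teacher update
#'
#' Every teacher parameter becomes `alpha * old + (1 - alpha) * student`.
#' Works on numeric arrays or identically-structured named lists of arrays
#' (parameter collections). The teacher receives no gradient; this update is
#' its only learning rule.
#'
#' @param theta_prime teacher parameters.
#' @param theta student parameters with identical structure.
#' @param alpha EMA rate in (0, 1); values close to 1 (e.g. 0.99) smooth the
#'   student trajectory strongly.
#' @return updated teacher parameters.
#' @export
ema_update <- function(theta_prime, theta, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (is.list(theta_prime)) {
    if (!is.list(theta) || !identical(names(theta_prime), names(theta)))
      stop("parameter structure mismatch between teacher and student")
    return(param_map2(theta_prime, theta,
                      function(a, b) alpha * a + (1 - alpha) * b))
  }
  if (length(theta_prime) != length(theta))
    stop("parameter structure mismatch between teacher and student")
  alpha * theta_prime + (1 - alpha) * theta
}

#' Confidence gate for pseudo-labels
#'
#' A teacher prediction is an efficient pseudo-label when its maximum
#' probability strictly exceeds `tau`. The soft distribution is kept for
#' consistency training; the hard label (argmax) is kept for promotion.
#'
#' @param p_teacher probability matrix (one row per sample) or vector.
#' @param tau confidence threshold (default 0.8).
#' @return data frame with columns `sample`, `confidence`, `hard_label`
#'   (class index) and `accepted`; the soft labels are in attribute `soft`.
#' @export
confidence_gate <- function(p_teacher, tau = 0.8) {
  if (!is.matrix(p_teacher)) p_teacher <- matrix(p_teacher, nrow = 1)
  conf <- apply(p_teacher, 1, max)
  hard <- max.col(p_teacher, ties.method = "first")
  out <- data.frame(sample = seq_len(nrow(p_teacher)), confidence = conf,
                    hard_label = hard, accepted = conf > tau)
  attr(out, "soft") <- p_teacher
  out
}

#' Promote confident pseudo-labels into the supervising pool
#'
#' Repeatedly predicts the unlabeled pool with the teacher, moves every
#' sample whose confidence strictly exceeds `tau` into the labeled pool with
#' its hard pseudo-label (flagged `pseudo = TRUE`; ground-truth labels are
#' never overwritten), and stops when the pool is empty or a full pass
#' promotes nothing (termination guard).
#'
#' @param object a fitted [gaitmt()] model (its teacher makes predictions),
#'   or `NULL` when `predict_fn` is supplied.
#' @param labeled current supervising pool (list of [gait_sample()]).
#' @param unlabeled unlabeled pool.
#' @param tau confidence threshold.
#' @param predict_fn optional `function(samples) -> probability matrix`
#'   overriding the teacher (used for controlled experiments).
#' @param classes class codes corresponding to probability columns.
#' @param max_rounds safety bound on promotion passes.
#' @return list with the updated `labeled` and `unlabeled` pools and the
#'   number of samples promoted per `rounds`.
#' @export
promote_pseudo_labels <- function(object, labeled, unlabeled, tau = 0.8,
                                  predict_fn = NULL,
                                  classes = c(11L, 21L, 22L),
                                  max_rounds = 100L) {
  if (is.null(predict_fn)) {
    stopifnot(inherits(object, "gaitmt"))
    classes <- object$classes
    predict_fn <- function(samples)
      predict(object, samples, type = "prob", which = "teacher")
  }
  rounds <- integer(0)
  while (length(unlabeled) > 0 && length(rounds) < max_rounds) {
    probs <- predict_fn(unlabeled)
    gate <- confidence_gate(probs, tau)
    acc <- which(gate$accepted)
    if (!length(acc)) break
    for (i in acc) {
      s <- unlabeled[[i]]
      if (!is.null(s$label3))
        stop("refusing to overwrite a ground-truth label for subject ",
             s$subject_id)
      labeled[[length(labeled) + 1]] <-
        gait_sample(s$clip, s$subject_id,
                    label3 = classes[gate$hard_label[i]], pseudo = TRUE)
    }
    unlabeled <- unlabeled[-acc]
    rounds <- c(rounds, length(acc))
  }
  list(labeled = labeled, unlabeled = unlabeled, rounds = rounds,
       n_promoted = sum(rounds))
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
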