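test_that("softmax is shift-invariant and overflow-safe", {
  expect_equal(softmax_prob(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax_prob(c(5, 5 + log(2))), c(1 / 3, 2 / 3))
  p <- softmax_prob(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p, c(1, 0), tolerance = 1e-12)
  m <- softmax_prob(matrix(c(0, 0, 0, log(3)), 2, 2))
  expect_equal(rowSums(m), c(1, 1))
  expect_equal(m[2, ], c(1 / 4, 3 / 4))
})

test_that("cross-entropy matches its closed forms", {
  expect_equal(cross_entropy_loss(c(1, 0, 0), c(1, 0, 0)), 0)
  for (C in 2:5)
    expect_equal(cross_entropy_loss(rep(1 / C, C),
                                    c(1, rep(0, C - 1))), log(C),
                 tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(0.7, 0.2, 0.1), c(0, 1, 0)), -log(0.2),
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(c(0.5, 0.5), c(1, 1)), "one-hot")
  expect_error(cross_entropy_loss(c(0.5, 0.5), c(0.3, 0.7)), "one-hot")
  # clamp keeps impossible labels finite
  expect_true(is.finite(cross_entropy_loss(c(1, 0), c(0, 1))))
})

test_that("consistency loss is the squared 2-norm on probabilities", {
  expect_equal(consistency_loss(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(consistency_loss(c(1, 0), c(0, 1)), 2)
  expect_equal(consistency_loss(c(0.6, 0.4), c(0.5, 0.5)), 0.02,
               tolerance = 1e-12)
  m1 <- rbind(c(1, 0), c(0.6, 0.4))
  m2 <- rbind(c(0, 1), c(0.5, 0.5))
  expect_equal(consistency_loss(m1, m2), mean(c(2, 0.02)), tolerance = 1e-12)
  expect_error(consistency_loss(c(1, 0), c(1, 0, 0)), "length")
})

test_that("the combined objective weights consistency by lambda", {
  lb <- combined_loss(0.5, 0.2, lambda = 1)
  expect_equal(lb$total, 0.7)
  expect_equal(combined_loss(c(0.4, 0.6), 5, lambda = 0)$total, 0.5)
  expect_equal(combined_loss(0.9, numeric(0), lambda = 3)$total, 0.9)
  expect_error(combined_loss(0.5, 0.2, lambda = -1), "non-negative")
})

test_that("the consistency weight ramps linearly then saturates", {
  expect_equal(ramp_lambda(0), 0)
  expect_equal(ramp_lambda(30), 1.0)
  expect_equal(ramp_lambda(15), 0.5)
  lam <- ramp_lambda(0:100)
  expect_true(all(diff(lam) >= 0))
  expect_true(all(lam >= 0 & lam <= 1))
  expect_equal(ramp_lambda(10, ramp_epochs = 20, ceiling = 0.5), 0.25)
})

test_that("the EMA update follows its closed form", {
  expect_equal(ema_update(0, 1, 0.99), 0.01)
  expect_equal(ema_update(0.37, 0.37, 0.99), 0.37)
  # constant student: theta'_t = alpha^t theta'_0 + (1 - alpha^t) theta
  tp <- 1; theta <- -2; alpha <- 0.99
  for (t in 1:50) {
    tp <- ema_update(tp, theta, alpha)
    expect_equal(tp, alpha^t * 1 + (1 - alpha^t) * theta, tolerance = 1e-10)
  }
  # parameter lists update elementwise; structure mismatches are errors
  a <- list(w = matrix(0, 2, 2), b = c(0, 0))
  b <- list(w = matrix(1, 2, 2), b = c(2, 2))
  u <- ema_update(a, b, 0.9)
  expect_equal(u$w, matrix(0.1, 2, 2))
  expect_error(ema_update(a, list(w = matrix(1, 2, 2)), 0.9), "mismatch")
})

test_that("the confidence gate accepts only strictly confident predictions", {
  g <- confidence_gate(rbind(c(0.85, 0.10, 0.05),
                             c(0.80, 0.10, 0.10),
                             c(1, 1, 1) / 3), tau = 0.8)
  expect_identical(g$accepted, c(TRUE, FALSE, FALSE))
  expect_identical(g$hard_label[1], 1L)
  expect_true(all(abs(rowSums(attr(g, "soft")) - 1) < 1e-6))
})

test_that("pseudo-label promotion moves exactly the gated samples", {
  mk <- function(i) gait_sample(array(runif(32, 0, 1), c(1, 1, 2, 4, 4)),
                                sprintf("u%02d", i))
  pool <- lapply(1:10, mk)
  # 4 vectors strictly above 0.8, the rest at or below
  probs <- rbind(c(0.9, 0.05, 0.05), c(0.05, 0.85, 0.10), c(0.1, 0.09, 0.81),
                 c(0.95, 0.04, 0.01), c(0.8, 0.1, 0.1), c(0.5, 0.25, 0.25),
                 c(1, 1, 1) / 3, c(0.7, 0.2, 0.1), c(0.2, 0.6, 0.2),
                 c(0.79, 0.11, 0.10))
  calls <- 0
  pfn <- function(samples) {
    calls <<- calls + 1
    idx <- as.integer(sub("u", "", vapply(samples, function(s) s$subject_id,
                                          character(1))))
    probs[idx, , drop = FALSE]
  }
  out <- promote_pseudo_labels(NULL, labeled = list(), unlabeled = pool,
                               tau = 0.8, predict_fn = pfn)
  expect_equal(out$n_promoted, 4)
  expect_length(out$labeled, 4)
  expect_length(out$unlabeled, 6)
  # second pass found nothing above the gate, then the loop terminated
  expect_identical(out$rounds, 4L)
  expect_equal(calls, 2)
  # promoted samples carry hard pseudo-labels, flagged as pseudo
  expect_identical(vapply(out$labeled, function(s) s$label3, integer(1)),
                   c(11L, 21L, 22L, 11L))
  expect_true(all(vapply(out$labeled, function(s) s$pseudo, logical(1))))

  # an all-confident pool empties in one pass
  conf <- matrix(0.02, 10, 3); conf[, 2] <- 0.96
  out2 <- promote_pseudo_labels(NULL, list(), pool, tau = 0.8,
                                predict_fn = function(s)
                                  conf[seq_along(s), , drop = FALSE])
  expect_length(out2$unlabeled, 0)
  expect_equal(out2$n_promoted, 10)

  # ground-truth labels are never overwritten
  labeled_pool <- list(gait_sample(array(0.1, c(1, 1, 2, 4, 4)), "g1", 11L))
  expect_error(promote_pseudo_labels(NULL, list(), labeled_pool, tau = 0.1,
                                     predict_fn = function(s)
                                       matrix(c(0.9, 0.05, 0.05), 1)),
               "ground-truth")
})

test_that("training reduces to supervised learning without unlabeled data", {
  ds <- small_dataset(8, seed = 500)
  cfg <- small_config(train = list(epochs = 2L, val_fraction = 0))
  f1 <- gaitmt(ds, unlabeled = NULL, config = cfg, seed = 5)
  f2 <- gaitmt(ds, unlabeled = list(), config = cfg, seed = 5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history$train_sup, f2$history$train_sup)

  # a zero consistency ceiling with unlabeled data present gives the same
  # trajectory as having no unlabeled data at all
  unlab <- lapply(small_dataset(4, seed = 501),
                  function(s) gait_sample(s$clip, paste0("u", s$subject_id)))
  cfg0 <- small_config(train = list(epochs = 2L, val_fraction = 0,
                                    lambda_ceiling = 0))
  f3 <- gaitmt(ds, unlabeled = unlab, config = cfg0, seed = 5)
  f4 <- gaitmt(ds, unlabeled = NULL, config = cfg0, seed = 5)
  expect_identical(f3$params, f4$params)

  expect_error(gaitmt(list()), "non-empty")
})

test_that("alpha = 0 makes the teacher track the student exactly", {
  ds <- small_dataset(6, seed = 502)
  cfg <- small_config(train = list(epochs = 1L, alpha = 0, val_fraction = 0))
  fit <- gaitmt(ds, config = cfg, seed = 2)
  expect_equal(fit$params, fit$teacher, tolerance = 1e-12)
})

test_that("teacher and student agree exactly when augmentation is disabled", {
  # with identity augmentation and theta' = theta the two networks see the
  # same input with the same parameters, so the consistency loss is zero
  ds <- small_dataset(4, seed = 503)
  clip <- ds[[1]]$clip
  cfg <- backbone_config("tiny", input_shape = c(8, 16, 16))
  mdl <- backbone_build(cfg, seed = 9)
  x <- array(clip[1, , , , ], c(1, dim(clip)[2:5]))
  ps <- softmax_prob(backbone_forward(mdl, x, train = TRUE)$logits)
  pt <- softmax_prob(backbone_forward(mdl, x, train = TRUE)$logits)
  expect_equal(consistency_loss(ps, pt), 0)
})
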