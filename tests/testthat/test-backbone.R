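test_that("backbone configuration validates shapes and the SHPM pyramid", {
  cfg <- backbone_config("tiny", input_shape = c(8, 32, 32))
  expect_identical(cfg$feature_shape, c(12, 8, 8, 8))
  expect_length(cfg$shpm$levels, 3)
  # the full preset keeps the reference topology
  full <- backbone_config("resnet18", input_shape = c(16, 224, 224))
  expect_identical(full$stage_channels, c(64L, 128L, 256L, 512L))
  expect_identical(full$blocks_per_stage, c(2L, 2L, 2L, 2L))
  # non-dividing pyramid levels are a build-time error
  expect_error(backbone_config("tiny", input_shape = c(8, 32, 32),
                               shpm_levels = list(c(3, 3))),
               "does not divide")
  expect_error(backbone_config("tiny", input_shape = c(2, 2, 2)), "too small")
})

test_that("construction is deterministic given the seed", {
  cfg <- backbone_config("tiny", input_shape = c(4, 16, 16))
  m1 <- backbone_build(cfg, seed = 3)
  m2 <- backbone_build(cfg, seed = 3)
  expect_identical(m1$params, m2$params)
  m3 <- backbone_build(cfg, seed = 4)
  expect_false(identical(m1$params, m3$params))
})

test_that("forward pass honors the shape contract and batch independence", {
  cfg <- backbone_config("tiny", num_classes = 3, input_shape = c(8, 32, 32))
  mdl <- backbone_build(cfg, seed = 1)
  clip <- render_clip(walker_params(walker_height = 24), T = 8)$clip
  x <- array(0, c(2, 1, 8, 32, 32))
  x[1, , , , ] <- clip[1, , , , ]
  x[2, , , , ] <- clip[1, , , , ]
  out <- backbone_forward(mdl, x)
  expect_identical(dim(out$logits), c(2L, 3L))
  expect_true(all(is.finite(out$logits)))
  expect_equal(out$logits[1, ], out$logits[2, ], tolerance = 1e-12)

  # prediction for one sample does not depend on its batch companions
  y <- array(runif(2 * 1 * 8 * 32 * 32), c(2, 1, 8, 32, 32))
  y[1, , , , ] <- clip[1, , , , ]
  mixed <- backbone_forward(mdl, y)
  expect_equal(mixed$logits[1, ], out$logits[1, ], tolerance = 1e-10)
})

test_that("a zero classifier yields uniform class probabilities", {
  cfg <- backbone_config("tiny", num_classes = 3, input_shape = c(4, 16, 16))
  mdl <- backbone_build(cfg, seed = 2)
  mdl$params$fc.w[] <- 0
  mdl$params$fc.b[] <- 0
  x <- array(runif(1 * 1 * 4 * 16 * 16), c(1, 1, 4, 16, 16))
  out <- backbone_forward(mdl, x)
  expect_equal(as.numeric(out$logits), c(0, 0, 0))
  expect_equal(as.numeric(softmax_prob(out$logits)), rep(1 / 3, 3))
})

test_that("the stored feature map reproduces the logits through the head", {
  cfg <- backbone_config("tiny", input_shape = c(4, 16, 16))
  mdl <- backbone_build(cfg, seed = 6)
  x <- array(runif(2 * 1 * 4 * 16 * 16), c(2, 1, 4, 16, 16))
  out <- backbone_forward(mdl, x)
  fm <- backbone_feature_map(mdl, x)
  expect_equal(fm, out$feature)
  expect_equal(backbone_head(mdl, fm), out$logits, tolerance = 1e-12)
  # final spatial dims divisible by every configured level (build guarantee)
  for (lv in cfg$shpm$levels)
    expect_silent(partition_bins(dim(fm)[4], dim(fm)[5], lv[1], lv[2]))
})

test_that("analytic gradients match finite differences through every layer", {
  set.seed(11)
  cfg <- backbone_config("tiny", input_shape = c(4, 16, 16))
  mdl <- backbone_build(cfg, seed = 5)
  x <- array(runif(2 * 1 * 4 * 16 * 16), c(2, 1, 4, 16, 16))
  Y <- matrix(0, 2, 3); Y[1, 1] <- 1; Y[2, 3] <- 1
  fwd <- backbone_forward(mdl, x, train = TRUE, want_cache = TRUE)
  p <- softmax_prob(fwd$logits)
  grads <- backbone_backward(mdl, fwd$cache, (p - Y) / 2)
  loss_fn <- function(m)
    mean(cross_entropy_loss(softmax_prob(
      backbone_forward(m, x, train = TRUE)$logits), Y))
  eps <- 1e-5
  for (nm in names(mdl$params)) {
    v <- mdl$params[[nm]]
    for (k in sample(length(v), min(2, length(v)))) {
      m2 <- mdl
      m2$params[[nm]][k] <- v[k] + eps; lp <- loss_fn(m2)
      m2$params[[nm]][k] <- v[k] - eps; lm <- loss_fn(m2)
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(fd - grads[[nm]][k]) / max(1e-4, abs(fd)), 1e-3,
                label = paste("gradient of", nm))
    }
  }
  # the feature-map gradient used by saliency is finite and nonzero
  dfeat <- attr(grads, "dfeature")
  expect_true(all(is.finite(dfeat)))
  expect_gt(max(abs(dfeat)), 0)
})

test_that("the tiny variant overfits a small separable clip set quickly", {
  # 12 well-separated noise-free clips; 100% training accuracy within a
  # small optimisation budget establishes the learnability floor
  set.seed(20)
  offs <- c(runif(4, -0.25, -0.15), runif(4, -0.01, 0.01), runif(4, 0.15, 0.25))
  clips <- lapply(offs, function(ko)
    render_clip(walker_params(knee_offset = ko, walker_height = 12,
                              frame_h = 16, frame_w = 16,
                              stride_period = 8, phase0 = runif(1)), T = 8))
  x <- array(0, c(12, 1, 8, 16, 16))
  for (i in 1:12) x[i, , , , ] <- clips[[i]]$clip[1, , , , ]
  yi <- match(vapply(clips, function(s) s$label3, integer(1)), c(11, 21, 22))
  Y <- matrix(0, 12, 3); Y[cbind(1:12, yi)] <- 1

  cfg <- backbone_config("tiny", input_shape = c(8, 16, 16))
  mdl <- backbone_build(cfg, seed = 20)
  opt <- gaitmt:::adam_init(mdl$params)
  acc <- 0
  for (step in 1:200) {
    fwd <- backbone_forward(mdl, x, train = TRUE, want_cache = TRUE)
    mdl$buffers <- fwd$buffers
    p <- softmax_prob(fwd$logits)
    grads <- backbone_backward(mdl, fwd$cache, (p - Y) / 12)
    st <- gaitmt:::adam_step(opt, mdl$params, grads, 1e-3)
    mdl$params <- st$params; opt <- st$opt
    acc <- mean(max.col(p) == yi)
    if (acc == 1) break
  }
  expect_equal(acc, 1)
})
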