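test_that("binary decisions use a strict threshold with ties to Normal", {
  expect_identical(binary_decision(c(0.51, 0.5, 0, 1)),
                   c("Abnormal", "Normal", "Normal", "Abnormal"))
  expect_error(binary_decision(1.2), "\\[0, 1\\]")
})

test_that("binary metrics follow the confusion-count formulas", {
  m <- binary_metrics(structure(list(TP = 8, FP = 2, FN = 2, TN = 8),
                                class = "confusion_counts"))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$npv, 0.8)
  expect_equal(m$accuracy, 0.8)

  perfect <- confusion_counts(rep(c("Abnormal", "Normal"), c(3, 4)),
                              rep(c("Abnormal", "Normal"), c(3, 4)))
  mp <- binary_metrics(perfect)
  expect_equal(mp$precision, 1)
  expect_equal(mp$recall, 1)

  # zero denominators surface as NA with warnings, never silent zeros
  none <- confusion_counts(rep("Normal", 5), rep("Normal", 5))
  w <- capture_warnings(mz <- binary_metrics(none))
  expect_true(any(grepl("precision undefined", w)))
  expect_true(any(grepl("recall undefined", w)))
  expect_true(is.na(mz$precision))
  expect_true(is.na(mz$recall))
})

test_that("macro metrics match hand computation and use the harmonic form", {
  d <- diag(c(5, 7, 9))
  dimnames(d) <- NULL
  mm <- macro_metrics(d)
  expect_equal(mm$macro_p, 1)
  expect_equal(mm$macro_r, 1)
  expect_equal(mm$macro_f1, 1)
  expect_equal(mm$accuracy, 1)

  m <- rbind(c(10, 0, 0), c(0, 10, 0), c(10, 0, 0))
  expect_warning(mm2 <- macro_metrics(m), "undefined")
  expect_equal(mm2$macro_r, 2 / 3)

  # macro F1 is the harmonic mean of the macro averages, not the mean of
  # per-class F1 scores; on this matrix the two differ
  m3 <- rbind(c(80, 20), c(40, 60))
  mm3 <- macro_metrics(m3)
  p <- c(80 / 120, 60 / 80); r <- c(0.8, 0.6)
  f1_per_class <- mean(2 * p * r / (p + r))
  harmonic <- 2 * mean(p) * mean(r) / (mean(p) + mean(r))
  expect_equal(mm3$macro_f1, harmonic, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(mm3$macro_f1, f1_per_class)))

  set.seed(33)
  for (i in 1:20) {
    C <- sample(2:5, 1)
    mat <- matrix(sample(1:30, C * C, replace = TRUE), C, C)
    got <- macro_metrics(mat)
    ref <- naive_macro(mat)
    expect_equal(got$macro_p, ref$macro_p)
    expect_equal(got$macro_r, ref$macro_r)
    expect_equal(got$macro_f1, ref$macro_f1)
    expect_equal(got$accuracy, ref$accuracy)
  }
  expect_error(macro_metrics(matrix(1, 1, 1)), "C >= 2")
})

test_that("the PR curve and its area follow the step rule", {
  expect_equal(pr_curve(c(0.9, 0.8, 0.7, 0.2, 0.1),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(pr_curve(rep(0.5, 10), rep(c(TRUE, FALSE), c(3, 7)))$auc, 0.3)

  # one inversion: check against exhaustive enumeration
  sc <- c(0.95, 0.9, 0.45, 0.4, 0.3, 0.1)
  tr <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(pr_curve(sc, tr)$auc, naive_pr_auc(sc, tr))

  set.seed(14)
  for (i in 1:10) {
    sc <- runif(12)
    tr <- runif(12) > 0.5
    if (!any(tr) || all(tr)) next
    expect_equal(pr_curve(sc, tr)$auc, naive_pr_auc(sc, tr))
    # invariance under strictly monotone transforms
    expect_equal(pr_curve(qlogis(sc / 2 + 0.25), tr)$auc,
                 pr_curve(sc, tr)$auc)
  }
  expect_error(pr_curve(c(0.1, 0.9), c(TRUE, TRUE)), "one positive and one")
})

test_that("merged 3-class probabilities and direct binary scores agree", {
  set.seed(15)
  p3 <- matrix(runif(30), 10, 3)
  p3 <- p3 / rowSums(p3)
  p_abn <- p3[, 2] + p3[, 3]
  expect_identical(binary_decision(p_abn),
                   binary_decision(1 - p3[, 1]))
})

test_that("evaluation guards against subject leakage", {
  fx <- trained_fixture()
  overlap <- fx$fit$train_subjects[1]
  bogus <- list(gait_sample(fx$test[[1]]$clip, overlap, 11L))
  expect_error(gaitmt_evaluate(fx$fit, bogus), "leakage")
})

test_that("evaluation reports coherent 3-class and binary metrics", {
  fx <- trained_fixture()
  ev3 <- suppressWarnings(gaitmt_evaluate(fx$fit, fx$test, task = "3class"))
  expect_s3_class(ev3, "gaitmt_eval")
  expect_equal(sum(ev3$confusion), length(fx$test))
  expect_true(ev3$metrics$accuracy >= 0 && ev3$metrics$accuracy <= 1)

  ev2 <- suppressWarnings(gaitmt_evaluate(fx$fit, fx$test, task = "binary"))
  expect_equal(sum(ev2$confusion), length(fx$test))
  expect_true(ev2$metrics$pr_auc >= 0 && ev2$metrics$pr_auc <= 1)
  # binary accuracy from the merged probabilities matches the confusion
  expect_equal(ev2$metrics$accuracy,
               (ev2$counts$TP + ev2$counts$TN) / length(fx$test))
})

test_that("saliency maps are normalized, deterministic and leg-focused", {
  fx <- trained_fixture()
  s <- fx$test[[1]]
  cam1 <- grad_cam(fx$fit, s)
  cam2 <- grad_cam(fx$fit, s)
  expect_identical(cam1$values, cam2$values)
  expect_identical(dim(cam1$values), dim(s$clip)[3:5])
  expect_gte(min(cam1$values), 0)
  expect_lte(max(cam1$values), 1)
  expect_equal(max(cam1$values), 1)

  ov <- saliency_overlay(s, cam1, frame = 1)
  expect_identical(dim(ov), c(dim(s$clip)[4], dim(s$clip)[5], 3L))
  expect_true(all(ov >= 0 & ov <= 1))
})
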