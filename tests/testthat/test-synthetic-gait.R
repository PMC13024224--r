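test_that("walker parameters are validated", {
  expect_error(walker_params(stride_period = 3), "stride_period")
  expect_error(walker_params(walker_height = 40, frame_h = 32), "frame bounds")
  expect_error(walker_params(knee_offset = -2, walker_height = 28), "frame bounds")
  expect_s3_class(walker_params(), "walker_params")
})

test_that("class labels are a thresholded function of knee offset", {
  expect_identical(classify_knee_offset(c(-0.3, -0.05, -0.049, 0, 0.049, 0.05, 0.3)),
                   c(21L, 21L, 11L, 11L, 11L, 22L, 22L))
})

test_that("zero knee offset keeps knees on the hip-ankle lines", {
  p <- walker_params(knee_offset = 0, walker_height = 24)
  for (phi in seq(0, 0.9, by = 0.1)) {
    pose <- pose_at_phase(p, phi)
    expect_equal(pose["knee_l", "x"], pose["hip_l", "x"], tolerance = 1e-12)
    expect_equal(pose["knee_r", "x"], pose["hip_r", "x"], tolerance = 1e-12)
    # inter-knee distance equals the hip/ankle interpolation
    expect_equal(pose["knee_r", "x"] - pose["knee_l", "x"],
                 pose["ankle_r", "x"] - pose["ankle_l", "x"])
  }
})

test_that("varum widens and valgum narrows the knee gap at every phase", {
  for (phi in seq(0, 0.9, by = 0.18)) {
    pv <- pose_at_phase(walker_params(knee_offset = -0.2, walker_height = 24), phi)
    expect_gt((pv["knee_r", "x"] - pv["knee_l", "x"]) -
                (pv["ankle_r", "x"] - pv["ankle_l", "x"]), 0)
    pg <- pose_at_phase(walker_params(knee_offset = 0.2, walker_height = 24), phi)
    expect_lt((pg["knee_r", "x"] - pg["knee_l", "x"]) -
                (pg["ankle_r", "x"] - pg["ankle_l", "x"]), 0)
  }
})

test_that("pose is equivariant under phase shifts", {
  base <- walker_params(knee_offset = -0.1, stride_period = 10, phase0 = 0.2,
                        walker_height = 22)
  for (phi in seq(0, 1.7, by = 0.23)) {
    shifted <- walker_params(knee_offset = -0.1, stride_period = 10,
                             phase0 = (0.2 + phi) %% 1, walker_height = 22)
    expect_equal(pose_at_phase(base, phi), pose_at_phase(shifted, 0),
                 tolerance = 1e-12)
  }
})

test_that("rendering is deterministic and respects the shape contract", {
  p <- walker_params(noise_sd = 0.03, walker_height = 40, frame_h = 64,
                     frame_w = 64)
  s1 <- render_clip(p, T = 16, seed = 9)
  s2 <- render_clip(p, T = 16, seed = 9)
  expect_identical(s1$clip, s2$clip)
  expect_identical(dim(s1$clip), c(1L, 1L, 16L, 64L, 64L))
  expect_true(all(s1$clip >= 0 & s1$clip <= 1))
  s3 <- render_clip(p, T = 16, seed = 10)
  expect_false(identical(s1$clip, s3$clip))
  # noise-free renders need no RNG at all
  p0 <- walker_params(noise_sd = 0, walker_height = 24)
  expect_identical(render_clip(p0, T = 4)$clip, render_clip(p0, T = 4)$clip)
})

test_that("knee offset changes pixels only below the pelvis", {
  mk <- function(ko) walker_params(knee_offset = ko, walker_height = 24,
                                   stride_period = 8)
  a <- render_clip(mk(0), T = 8)$clip
  b <- render_clip(mk(0.3), T = 8)$clip
  d <- abs(a - b)
  h <- 24; y0 <- (32 - h) / 2
  pelvis_row <- floor(y0 + 0.5 * h) - 1
  expect_equal(max(d[, , , 1:pelvis_row, ]), 0)
  expect_gt(max(d[, , , (pelvis_row + 1):32, ]), 0.5)
})

test_that("generated datasets honor class mix, labeling and determinism", {
  ds <- generate_gait_dataset(9, labeled_fraction = 1, seed = 3)
  labs <- vapply(ds, function(s) s$label3, integer(1))
  expect_identical(as.integer(table(factor(labs, levels = c(11, 21, 22)))),
                   c(3L, 3L, 3L))
  ids <- vapply(ds, function(s) s$subject_id, character(1))
  expect_false(anyDuplicated(ids) > 0)

  ds0 <- generate_gait_dataset(8, labeled_fraction = 0, seed = 3)
  expect_true(all(vapply(ds0, function(s) is.null(s$label3), logical(1))))
  expect_true(all(vapply(ds0, function(s) is.null(s$label2), logical(1))))
  # labels are removed, not hidden: no generating parameters retained
  expect_true(all(vapply(ds0, function(s) is.null(s$params), logical(1))))

  ds2 <- generate_gait_dataset(60, class_mix = c(0.5, 0.25, 0.25), seed = 11)
  labs2 <- vapply(ds2, function(s) s$label3, integer(1))
  expect_identical(as.integer(table(factor(labs2, levels = c(11, 21, 22)))),
                   c(30L, 15L, 15L))

  expect_error(generate_gait_dataset(2), "at least")
  # identical seed, identical bytes
  expect_identical(generate_gait_dataset(5, seed = 8)[[3]]$clip,
                   generate_gait_dataset(5, seed = 8)[[3]]$clip)
})

test_that("binary labels merge varum and valgum into abnormal", {
  expect_identical(gait_sample(array(0, c(1, 1, 2, 4, 4)), "a", 11L)$label2, 1L)
  expect_identical(gait_sample(array(0, c(1, 1, 2, 4, 4)), "a", 21L)$label2, 2L)
  expect_identical(gait_sample(array(0, c(1, 1, 2, 4, 4)), "a", 22L)$label2, 2L)
  expect_error(gait_sample(array(0, c(1, 1, 2, 4, 4)), "a", 12L), "label3")
})

test_that("the rendered geometry recovers the assigned label on noise-free data", {
  ds <- generate_gait_dataset(36, seed = 21, noise_sd_range = c(0, 0))
  geom <- vapply(ds, gait_geometry_classify, integer(1))
  truth <- vapply(ds, function(s) s$label3, integer(1))
  expect_identical(geom, truth)
})

test_that("datasets round-trip through the PNG/manifest writer", {
  dir <- withr::local_tempdir()
  ds <- generate_gait_dataset(4, frames = 6, seed = 5)
  sp <- subject_split(vapply(ds, function(s) s$subject_id, character(1)),
                      seed = 1)
  man <- write_gait_dataset(ds, dir, split = sp)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_gait_dataset(dir)
  expect_length(back, 4)
  for (i in seq_along(ds)) {
    expect_identical(back[[i]]$label3, ds[[i]]$label3)
    # 8-bit PNG quantisation
    expect_lt(max(abs(back[[i]]$clip - ds[[i]]$clip)), 1 / 255)
  }
})
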