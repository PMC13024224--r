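test_that("center crop takes the exact central window", {
  fr <- matrix(runif(224 * 224), 224, 224)
  expect_identical(clip_center_crop(fr, 224), fr)

  # full-resolution frame: 1440 rows x 2560 cols, 0-based offsets (608, 1168)
  big <- outer(seq_len(1440), seq_len(2560),
               function(r, c) (r - 1) * 3000 + (c - 1))
  cr <- clip_center_crop(big, 224)
  expect_identical(dim(cr), c(224L, 224L))
  expect_equal(cr[1, 1], 608 * 3000 + 1168)
  expect_equal(cr[224, 224], (608 + 223) * 3000 + 1168 + 223)

  # floor tie-break: odd surplus goes below/right
  odd <- matrix(seq_len(225^2), 225, 225)
  expect_equal(clip_center_crop(odd, 224)[1, 1], odd[1, 1])

  expect_error(clip_center_crop(matrix(0, 100, 100), 224), "smaller")
})

test_that("frame sequences are grouped into clips with tails dropped", {
  mk <- function(T) array(seq_len(T * 4 * 4) / (T * 16), c(T, 4, 4))
  expect_length(frames_to_clips(mk(32), 16, 16), 2)
  expect_length(frames_to_clips(mk(47), 16, 16), 2)
  expect_length(frames_to_clips(mk(15), 16, 16), 0)
  one <- frames_to_clips(mk(16), 16, 1)
  expect_length(one, 1)
  expect_equal(one[[1]][1, 1, , , ], mk(16))
  expect_identical(dim(one[[1]]), c(1L, 1L, 16L, 4L, 4L))
})

test_that("subject splits have the right sizes and never overlap", {
  ids <- sprintf("P%03d", 1:100)
  sp <- subject_split(ids, seed = 4)
  expect_identical(as.integer(table(sp$split)), c(64L, 16L, 20L))
  expect_setequal(sp$subject_id, ids)

  sp10 <- subject_split(sprintf("q%d", 1:10), seed = 4)
  expect_identical(as.integer(table(sp10$split)), c(6L, 2L, 2L))

  expect_error(subject_split(c("a", "a", "b")), "duplicate")
  expect_error(subject_split(ids, fractions = c(0.5, 0.2, 0.2)), "sum to 1")

  expect_identical(subject_split(ids, seed = 7), subject_split(ids, seed = 7))

  # stratified split keeps each stratum at the same proportions
  strata <- rep(c("x", "y"), 50)
  strat <- subject_split(ids, seed = 5, strata = strata)
  tab <- table(strata[match(strat$subject_id, ids)], strat$split)
  expect_identical(as.integer(tab["x", ]), c(32L, 8L, 10L))
  expect_identical(as.integer(tab["y", ]), c(32L, 8L, 10L))
})

test_that("augmentations degenerate to the identity and stay in range", {
  clip <- render_clip(walker_params(walker_height = 20), T = 8)$clip
  expect_identical(augment_weak(clip, max_shift = 0, flip_prob = 0), clip)
  expect_identical(
    augment_strong(clip, max_shift = 0, brightness = 0, contrast = 0,
                   noise_sd = 0, erase_prob = 0, temporal_jitter = 0,
                   speed_range = c(1, 1), flip_prob = 0),
    clip)
  out <- augment_strong(clip, seed = 3)
  expect_identical(dim(out), dim(clip))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(augment_strong(clip, seed = 3), out)
})

test_that("horizontal flip is an involution", {
  clip <- render_clip(walker_params(knee_offset = -0.2, walker_height = 20),
                      T = 4)$clip
  expect_identical(clip_hflip(clip_hflip(clip)), clip)
  expect_false(identical(clip_hflip(clip), clip))
})

test_that("augmentation noise has the configured scale", {
  clip <- array(0.5, c(1, 1, 4, 48, 48))
  out <- augment_strong(clip, seed = 1, max_shift = 0, brightness = 0,
                        contrast = 0, noise_sd = 0.1, erase_prob = 0,
                        temporal_jitter = 0, speed_range = c(1, 1),
                        flip_prob = 0)
  expect_lt(abs(sd(out - clip) - 0.1) / 0.1, 0.2)
})
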