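# Shared fixtures. Heavy objects (a trained model) are built once per test
# run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# small frames / small walker configuration for fast training in unit tests
small_config <- function(...) {
  gaitmt_config("desk",
                data = list(clip_len = 8L, crop = 16L, stride = 8L),
                model = list(input_shape = c(8L, 16L, 16L)),
                ...)
}

# noise-free, well-separated small-frame cohort
small_dataset <- function(n, seed, frames = 8L) {
  generate_gait_dataset(n, frames = frames, frame_h = 16L, frame_w = 16L,
                        seed = seed, noise_sd_range = c(0, 0),
                        height_frac_range = c(0.45, 0.7))
}

# a tiny model trained briefly on small frames; enough to have meaningful
# features without dominating the test-suite runtime
trained_fixture <- function() {
  if (!is.null(.fixtures$model)) return(.fixtures$model)
  ds <- small_dataset(24, seed = 400)
  ids <- vapply(ds, function(s) s$subject_id, character(1))
  labels <- vapply(ds, function(s) s$label3, integer(1))
  sp <- subject_split(ids, seed = 400, strata = labels)
  fit <- gaitmt(ds[sp$split == "train"],
                validation = ds[sp$split == "validation"],
                config = small_config(train = list(epochs = 10L)),
                seed = 400)
  .fixtures$model <- list(fit = fit, test = ds[sp$split == "test"])
  .fixtures$model
}
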