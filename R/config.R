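# Experiment configuration with two named profiles.
#
# "full" mirrors the reference training protocol exactly: 16-frame clips,
# 224x224 center crop, ResNet-18 topology, Adam (lr 1e-4, beta 0.9/0.999),
# batch 16, 100 epochs, early stopping after 10 stagnant validation epochs,
# learning rate halved after 5, EMA rate 0.99, pseudo-label confidence
# threshold 0.8, consistency weight ramped 0 -> 1.0 over 30 epochs.
#
# "desk" is the reduced profile this package trains routinely on one CPU:
# 8-frame 32x32 clips, the tiny backbone, a higher learning rate (1e-3,
# appropriate for the much smaller network), shorter schedules. It changes
# scale only, never the semantics.

gaitmt_defaults <- function(profile) {
  full <- list(
    data = list(clip_len = 16L, crop = 224L, stride = 16L,
                fractions = c(0.64, 0.16, 0.20)),
    model = list(preset = "resnet18", num_classes = 3L, in_channels = 1L,
                 input_shape = c(16L, 224L, 224L), shpm_levels = NULL,
                 shpm_combine = "concat", shpm_temporal = "mean"),
    train = list(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, batch = 16L,
                 epochs = 100L, early_stop = 10L, plateau = 5L,
                 plateau_factor = 0.5, alpha = 0.99, tau = 0.8,
                 ramp = 30L, lambda_ceiling = 1.0, val_fraction = 0.2,
                 pseudo_ce = TRUE, steps_per_epoch = NULL,
                 unlabeled_batch = NULL),
    augment = list(
      weak = list(max_shift = NULL, flip_prob = 0.5),
      strong = list(max_shift = NULL, brightness = 0.1, contrast = 0.1,
                    noise_sd = 0.02, erase_prob = 0.5, erase_frac = 0.3,
                    temporal_jitter = 2L, speed_range = c(0.8, 1.25),
                    flip_prob = 0.5)),
    eval = list(task = "3class", threshold = 0.5))
  if (profile == "full") return(full)
  desk <- full
  desk$data$clip_len <- 8L
  desk$data$crop <- 32L
  desk$data$stride <- 8L
  desk$model$preset <- "tiny"
  desk$model$input_shape <- c(8L, 32L, 32L)
  desk$train$lr <- 1e-3
  desk$train$epochs <- 30L
  desk$train$ramp <- 10L
  desk$train$alpha <- 0.9   # EMA horizon scaled to the ~150-step schedule
  desk$train$unlabeled_batch <- 8L  # supervision dominates every step
  desk$augment$strong$erase_frac <- 0.25
  desk$augment$strong$temporal_jitter <- 1L
  desk
}

merge_config <- function(defaults, overrides, path = "") {
  for (nm in names(overrides)) {
    if (!nm %in% names(defaults))
      stop("unknown config key", if (nzchar(path)) paste0(" in ", path),
           ": ", nm)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Experiment configuration
#'
#' Returns the nested configuration list (data / model / train / augment /
#' eval sections) for one of two named profiles, with optional overrides.
#' Unknown keys in an override are an error listing the offending name.
#'
#' @param profile `"desk"` (reduced scale, the default for examples and
#'   tests) or `"full"` (the reference protocol values).
#' @param ... named override lists per section, e.g.
#'   `train = list(epochs = 5)`.
#' @return an object of class `gaitmt_config`.
#' @export
gaitmt_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- gaitmt_defaults(profile)
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("config overrides must be named")
    cfg <- merge_config(cfg, overrides)
  }
  cfg$profile <- profile
  class(cfg) <- "gaitmt_config"
  cfg
}

#' @export
print.gaitmt_config <- function(x, ...) {
  cat(sprintf("<gaitmt_config '%s': %s backbone, clip %dx%dx%d, batch %d, %d epochs, lr %g>\n",
              x$profile, x$model$preset, x$data$clip_len, x$data$crop,
              x$data$crop, x$train$batch, x$train$epochs, x$train$lr))
  invisible(x)
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [gaitmt_config()] object.
#' @return `read_gaitmt_config()` returns a validated `gaitmt_config`;
#'   `write_gaitmt_config()` returns `path` invisibly.
#' @export
read_gaitmt_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profile <- raw$profile %||% "desk"
  raw$profile <- NULL
  do.call(gaitmt_config, c(list(profile = profile), raw))
}

#' @rdname read_gaitmt_config
#' @export
write_gaitmt_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}
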