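# Reproducible desk-scale benchmark experiments on synthetic gait data.

# Cohort generation is deterministic in (n, frames, seed), so cohorts are
# memoised per session; experiment arms that share a seed share the data.
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_dataset <- function(n_subjects, frames, seed) {
  key <- paste(n_subjects, frames, seed %||% "none", sep = "_")
  if (is.null(.benchmark_cache[[key]]))
    .benchmark_cache[[key]] <- generate_gait_dataset(n_subjects,
                                                     frames = frames,
                                                     seed = seed)
  .benchmark_cache[[key]]
}

#' Run one synthetic-gait benchmark experiment
#'
#' Generates a synthetic cohort, splits it at subject level (stratified by
#' class so every partition contains all three alignments), optionally
#' strips labels from part of the training subjects, fits the requested
#' model variant and scores it on the held-out test subjects.
#'
#' Variants: `"mean_teacher"` (full engine: labeled + unlabeled pool),
#' `"supervised"` (labeled subset only, no unlabeled data) and `"gap"`
#' (Mean Teacher engine with the SHPM pyramid replaced by a single global
#' average pool).
#'
#' @param seed integer seed controlling the cohort, splits and training.
#' @param n_subjects cohort size (one video each).
#' @param labeled_fraction fraction of training subjects whose labels are
#'   kept; the rest become the unlabeled pool.
#' @param arm model variant, see Details.
#' @param config a [gaitmt_config()]; the desk profile by default.
#' @param dataset optional pre-generated cohort (from
#'   [generate_gait_dataset()] with this `seed`), so several arms can share
#'   one cohort.
#' @return list with the fitted model (`fit`), the 3-class test evaluation
#'   (`eval`), the test `accuracy` and the split sizes.
#' @export
gait_benchmark <- function(seed, n_subjects = 60, labeled_fraction = 1,
                           arm = c("mean_teacher", "supervised", "gap"),
                           config = gaitmt_config("desk"), dataset = NULL) {
  arm <- match.arg(arm)
  ds <- dataset %||% benchmark_dataset(n_subjects, 2L * config$data$clip_len,
                                       seed)
  n_subjects <- length(ds)
  # benchmark arms run the full fixed-length schedule so every variant gets
  # the identical optimisation budget
  config$train$early_stop <- config$train$epochs
  ids <- vapply(ds, function(s) s$subject_id, character(1))
  labels <- vapply(ds, function(s) s$label3, integer(1))
  sp <- subject_split(ids, fractions = config$data$fractions,
                      seed = derive_seed(seed, 23), strata = labels)
  tr <- ds[sp$split == "train"]
  va <- ds[sp$split == "validation"]
  te <- ds[sp$split == "test"]

  if (labeled_fraction < 1) {
    tids <- vapply(tr, function(s) s$subject_id, character(1))
    tlab <- vapply(tr, function(s) s$label3, integer(1))
    pick <- subject_split(tids, c(labeled_fraction, 1 - labeled_fraction, 0),
                          seed = derive_seed(seed, 29), strata = tlab)
    lab <- tr[pick$split == "train"]
    unlab <- lapply(tr[pick$split == "validation"],
                    function(s) gait_sample(s$clip, s$subject_id))
  } else {
    lab <- tr
    unlab <- NULL
  }

  if (arm == "gap") {
    bc <- backbone_config(preset = config$model$preset,
                          num_classes = config$model$num_classes,
                          in_channels = config$model$in_channels,
                          input_shape = config$model$input_shape)
    fs <- bc$feature_shape
    config$model$shpm_levels <- list(fs[3:4])
    config$model$shpm_combine <- "avg"
  }
  if (arm == "supervised") unlab <- NULL

  # equalise the optimisation budget across arms: every variant takes the
  # number of steps a fully labeled epoch over the training split would
  if (is.null(config$train$steps_per_epoch)) {
    clips_per_video <- pmax(1L, vapply(tr, function(s)
      dim(s$clip)[3] %/% config$data$clip_len, integer(1)))
    config$train$steps_per_epoch <-
      as.integer(ceiling(sum(clips_per_video) / config$train$batch))
  }

  fit <- gaitmt(lab, unlabeled = unlab, validation = va, config = config,
                seed = seed)
  ev <- suppressWarnings(gaitmt_evaluate(fit, te, task = "3class"))
  list(fit = fit, eval = ev, accuracy = ev$metrics$accuracy,
       n_labeled = length(lab), n_unlabeled = length(unlab),
       n_test = length(te))
}
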