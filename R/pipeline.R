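#' Split subjects into train / validation / test
#'
#' Subject-level, optionally stratified assignment with the
#' largest-remainder rounding rule (each stratum first receives
#' `floor(n * fraction)` subjects per split; leftovers go to the splits
#' with the largest fractional remainders, ties in split order).
#' Deterministic given `seed`.
#'
#' @param subject_ids Character vector of unique ids.
#' @param fractions Named or ordered fractions `(train, validation,
#'   test)`; must sum to 1.
#' @param seed Integer seed.
#' @param strata Optional cohort tag per subject; each stratum is split
#'   separately so every cohort appears in every split when counts
#'   permit.
#' @return Named character vector mapping subject id to split.
#' @export
split_subjects <- function(subject_ids, fractions = c(0.7, 0.1, 0.2),
                           seed, strata = NULL) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9,
            !anyDuplicated(subject_ids))
  if (length(subject_ids) < 3L)
    stop("need at least 3 subjects to populate 3 splits")
  splits <- c("train", "validation", "test")
  strata <- strata %||% rep("all", length(subject_ids))
  out <- character(0)
  with_seed(seed, {
    for (st in unique(strata)) {
      ids <- sample(subject_ids[strata == st])
      n <- length(ids)
      base <- floor(n * fractions)
      rem <- n * fractions - base
      extra <- n - sum(base)
      if (extra > 0) {
        give <- order(rem, decreasing = TRUE)[seq_len(extra)]
        base[give] <- base[give] + 1L
      }
      assign_vec <- rep(splits, times = base)
      out <- c(out, stats::setNames(assign_vec, ids))
    }
  })
  out[match(subject_ids, names(out))]
}

#' Experiment configuration
#'
#' One structured configuration for the full simulate - preprocess -
#' encode - train - delineate - evaluate pipeline.  All randomness
#' derives from `seed` via fixed named substreams.
#'
#' @param n_subjects,duration,fs Cohort size, seconds per recording, Hz.
#' @param population Ranges for [sample_subject()].
#' @param preprocess,unet,train,postprocess,match Stage configurations.
#' @param fractions Subject split fractions.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 25, duration = 150, fs = 320,
                       population = default_population(cd_fraction = 0),
                       preprocess = preprocess_config(),
                       unet = unet_config(),
                       train = train_config(max_epochs = 20L,
                                            batch_size = 1L),
                       postprocess = postprocess_config(),
                       match = match_config(),
                       fractions = c(0.68, 0.12, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  if (round(duration * fs) %% 16L != 0L ||
      round(preprocess$window_len * fs) %% 16L != 0L)
    stop("window_len * fs must be divisible by 16")
  structure(list(n_subjects = n_subjects, duration = duration, fs = fs,
                 population = population, preprocess = preprocess,
                 unet = unet, train = train, postprocess = postprocess,
                 match = match, fractions = fractions,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline end to end
#'
#' Simulates a cohort, splits it by subject, band-limits and windows the
#' recordings, encodes ground-truth maps, trains the U-Net on the
#' training split with epoch selection on the validation split, then
#' delineates the held-out test recordings and scores them per subject.
#'
#' @param config A [run_config].
#' @param verbose Print stage progress.
#' @return An `scg_experiment` list: `split`, `train_result`,
#'   `per_subject` metric rows, `summary` (per-label aggregates over test
#'   subjects), `sm_accuracy`, `sm_centers`, `config`.
#' @export
run_experiment <- function(config = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulating ", config$n_subjects, " subjects")
  cohort <- simulate_cohort(config$n_subjects, config$duration,
                            config$fs, seed = config$seed + 1000L,
                            population = config$population)
  split <- split_subjects(names(cohort), config$fractions,
                          seed = config$seed + 2000L)
  segs <- list(train = list(), validation = list())
  for (id in names(cohort)) {
    if (split[[id]] == "test") next
    rec <- bandlimit(cohort[[id]]$recording, config$preprocess)
    ws <- window_recording(rec, cohort[[id]]$truth, config$preprocess)
    segs[[split[[id]]]] <- c(segs[[split[[id]]]], ws)
  }
  say("training on ", length(segs$train), " segments, validating on ",
      length(segs$validation))
  model <- unet_build(config$unet, seed = config$seed + 3000L)
  tr_cfg <- config$train
  tr_cfg$seed <- config$seed + 4000L
  fit <- unet_train(model, segs$train, segs$validation, tr_cfg,
                    verbose = verbose)
  test_ids <- names(split)[split == "test"]
  per_subject <- list(); sm_acc <- list(); sm_cent <- list()
  for (id in test_ids) {
    say("delineating ", id)
    synth <- cohort[[id]]
    det <- delineate_recording(fit$model, synth$recording,
                               config$preprocess, config$postprocess)
    rep_df <- match_fiducials(synth$truth, det, config$fs, config$match,
                              labels = fiducial_labels())
    per_subject[[id]] <- data.frame(
      subject = id, label = rep_df$label, TP = rep_df$TP, FP = rep_df$FP,
      FN = rep_df$FN, ppv = ppv(rep_df$TP, rep_df$FP),
      sensitivity = sensitivity(rep_df$TP, rep_df$FN))
    truth_maps <- encode_segmaps(synth$truth,
                                 length(synth$recording$samples),
                                 config$fs)
    rec_f <- bandlimit(synth$recording, config$preprocess)
    pred_maps <- predict_full(fit$model, rec_f, config$preprocess)
    fc <- filter_complex_maps(pred_maps, config$postprocess)
    fm <- filter_interval_maps(pred_maps, fc, config$postprocess)
    sm_acc[[id]] <- sample_accuracy(truth_maps, fm)
    sm_cent[[id]] <- cbind(subject = id,
                           sm_center_eval(truth_maps, fm, config$match))
  }
  per_subject <- do.call(rbind, per_subject)
  rownames(per_subject) <- NULL
  structure(list(
    split = split, train_result = fit, per_subject = per_subject,
    summary = aggregate_metrics(per_subject),
    sm_accuracy = do.call(rbind, sm_acc),
    sm_centers = do.call(rbind, sm_cent),
    config = config), class = "scg_experiment")
}

#' @export
print.scg_experiment <- function(x, ...) {
  cat("<scg_experiment>", x$config$n_subjects, "subjects, best epoch",
      x$train_result$best_epoch, "\n")
  enc <- setdiff(fiducial_labels(), c("Es", "Bd"))
  s <- x$summary[x$summary$label %in% enc, ]
  cat("  encoded-label median PPV:",
      sprintf("%.3f", median(s$median[s$metric == "ppv"], na.rm = TRUE)),
      " median sensitivity:",
      sprintf("%.3f", median(s$median[s$metric == "sensitivity"],
                             na.rm = TRUE)), "\n")
  invisible(x)
}
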