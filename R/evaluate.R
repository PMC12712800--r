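#' Matching configuration
#'
#' @param tolerance Matching tolerance in ms (inclusive); a prediction
#'   within `tolerance` of a truth counts as a true positive.
#' @param center_tolerance Tolerance for segmentation-map-center matching.
#' @return A `match_config` list.
#' @export
match_config <- function(tolerance = 10, center_tolerance = 10) {
  stopifnot(tolerance > 0, center_tolerance > 0)
  structure(list(tolerance = tolerance,
                 center_tolerance = center_tolerance),
            class = "match_config")
}

# Greedy one-to-one matching of two sample vectors: ascending absolute
# error, ties broken by earlier truth then earlier prediction.  Returns
# TP/FP/FN and the matched pairs with signed errors.
match_points <- function(truth, pred, tol_samples, fs) {
  if (!length(truth) || !length(pred)) {
    return(list(TP = 0L, FP = length(pred), FN = length(truth),
                pairs = data.frame(truth = integer(0), pred = integer(0),
                                   error_ms = numeric(0))))
  }
  grid <- expand.grid(ti = seq_along(truth), pi = seq_along(pred))
  grid$err <- abs(truth[grid$ti] - pred[grid$pi])
  grid <- grid[grid$err <= tol_samples, , drop = FALSE]
  grid <- grid[order(grid$err, grid$ti, grid$pi), , drop = FALSE]
  used_t <- logical(length(truth)); used_p <- logical(length(pred))
  pairs <- list()
  for (r in seq_len(nrow(grid))) {
    ti <- grid$ti[r]; pi <- grid$pi[r]
    if (used_t[ti] || used_p[pi]) next
    used_t[ti] <- TRUE; used_p[pi] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      truth = truth[ti], pred = pred[pi],
      error_ms = (pred[pi] - truth[ti]) / fs * 1000)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(truth = integer(0), pred = integer(0),
               error_ms = numeric(0))
  list(TP = sum(used_t), FP = sum(!used_p), FN = sum(!used_t),
       pairs = pairs)
}

#' Match predicted fiducials against ground truth
#'
#' Greedy nearest-first one-to-one matching per label within the
#' (inclusive) tolerance; unmatched predictions are false positives,
#' unmatched truths false negatives.
#'
#' @param truth An [scg_annotations] table.
#' @param pred An `scg_delineation` (or any data.frame with `label` and
#'   `sample`).
#' @param fs Sampling frequency, Hz (must be shared by both tables).
#' @param config A [match_config].
#' @param labels Labels to score (default: the 11 fiducials present in
#'   either table).
#' @return A `match_report` data.frame: `label`, `TP`, `FP`, `FN`, with
#'   attribute `pairs` (matched pairs and signed errors in ms).
#' @export
match_fiducials <- function(truth, pred, fs, config = match_config(),
                            labels = NULL) {
  tol <- ms_to_samples(config$tolerance, fs)
  labels <- labels %||% intersect(fiducial_labels(),
                                  union(truth$label, pred$label))
  rows <- lapply(labels, function(lab) {
    m <- match_points(truth$sample[truth$label == lab],
                      pred$sample[pred$label == lab], tol, fs)
    structure(data.frame(label = lab, TP = m$TP, FP = m$FP, FN = m$FN),
              pairs = m$pairs)
  })
  rep_df <- do.call(rbind, rows)
  attr(rep_df, "pairs") <- stats::setNames(lapply(rows, attr, "pairs"),
                                           labels)
  class(rep_df) <- c("match_report", "data.frame")
  rep_df
}

#' Positive predictive value and sensitivity
#'
#' `PPV = TP / (TP + FP)` and `S = TP / (TP + FN)`; an undefined 0/0 is
#' reported as `NA` (absent), never coerced to 0 or 1.
#'
#' @param TP,FP,FN Non-negative counts (vectorized).
#' @return Numeric value(s) in `[0, 1]` or `NA`.
#' @export
ppv <- function(TP, FP) {
  stopifnot(all(TP >= 0), all(FP >= 0))
  ifelse(TP + FP == 0, NA_real_, TP / (TP + FP))
}

#' @rdname ppv
#' @export
sensitivity <- function(TP, FN) {
  stopifnot(all(TP >= 0), all(FN >= 0))
  ifelse(TP + FN == 0, NA_real_, TP / (TP + FN))
}

#' Aggregate per-subject metrics across subjects
#'
#' Metrics are computed per subject first and summarized across subjects
#' (never pooled over beats): median, IQR (type-7 linear-interpolation
#' quantiles), mean and SD per label and metric.  `NA` (undefined 0/0)
#' entries are excluded.
#'
#' @param per_subject data.frame with columns `subject`, `label`, and one
#'   or more metric columns (e.g. `ppv`, `sensitivity`).
#' @param metrics Names of the metric columns to summarize.
#' @return data.frame with one row per (label, metric).
#' @export
aggregate_metrics <- function(per_subject,
                              metrics = c("ppv", "sensitivity")) {
  stopifnot(nrow(per_subject) > 0, all(metrics %in% names(per_subject)))
  out <- list()
  for (lab in unique(per_subject$label)) {
    sub <- per_subject[per_subject$label == lab, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]; v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        label = lab, metric = m, n_subjects = length(v),
        median = if (length(v)) median(v) else NA_real_,
        iqr = if (length(v)) unname(diff(quantile(v, c(.25, .75))))
          else NA_real_,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else if (length(v)) 0 else NA_real_)
    }
  }
  do.call(rbind, out)
}

# Centers of runs of ones: floor midpoint of the inclusive run.
run_centers <- function(x) {
  r <- runs_of_ones(x)
  if (!nrow(r)) return(integer(0))
  (r$start + r$end) %/% 2L
}

#' Evaluate segmentation maps by run centers
#'
#' The centers (floor midpoints) of the predicted runs of ones are
#' matched one-to-one against the centers of the true runs with the same
#' tolerance procedure as the fiducials; PPV and sensitivity are reported
#' per map.
#'
#' @param true_maps,pred_maps Binary `scg_segmaps` of equal length.
#' @param config A [match_config] (`center_tolerance` applies).
#' @return data.frame: `sm`, `TP`, `FP`, `FN`, `ppv`, `sensitivity`.
#' @export
sm_center_eval <- function(true_maps, pred_maps,
                           config = match_config()) {
  stopifnot(true_maps$n_samples == pred_maps$n_samples)
  tol <- ms_to_samples(config$center_tolerance, true_maps$fs)
  out <- lapply(seq_len(19L), function(k) {
    m <- match_points(run_centers(true_maps$maps[k, ]),
                      run_centers(pred_maps$maps[k, ]), tol,
                      true_maps$fs)
    data.frame(sm = sm_index()$sm[k], TP = m$TP, FP = m$FP, FN = m$FN,
               ppv = ppv(m$TP, m$FP),
               sensitivity = sensitivity(m$TP, m$FN))
  })
  do.call(rbind, out)
}

#' Sample-by-sample segmentation accuracy
#'
#' Fraction of samples per map where the predicted binary value equals
#' the annotated value.
#'
#' @param true_maps,pred_maps Binary `scg_segmaps` of equal length.
#' @return Named numeric vector over SM01..SM19.
#' @export
sample_accuracy <- function(true_maps, pred_maps) {
  if (true_maps$n_samples != pred_maps$n_samples)
    stop("segmentation maps differ in length: ", true_maps$n_samples,
         " vs ", pred_maps$n_samples)
  rowMeans((true_maps$maps != 0) == (pred_maps$maps != 0))
}
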