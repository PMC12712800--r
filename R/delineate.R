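#' Postprocessing configuration
#'
#' Rule thresholds for converting the 19 probability maps into clean
#' binary maps and fiducial timings.  All durations are stored in
#' milliseconds and converted to samples at call time.
#'
#' @param gap_merge_sm05,gap_merge_sm17 Adjacent runs separated by less
#'   than this are merged (systolic complex map SM05: 30 ms; diastolic
#'   SM17: 15 ms).
#' @param min_dur_sm05,min_dur_sm17 Runs shorter than this are removed
#'   (50 ms / 20 ms).
#' @param binarize_threshold Interval-map probability threshold; values
#'   `>=` the threshold map to 1.
#' @param edge_search_halfwidth Half-width (ms) of the peak/valley search
#'   window around each run edge.
#' @param shoulder_search Length (ms) of the pre-valley window searched
#'   for the Es/Bd shoulder.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(gap_merge_sm05 = 30, gap_merge_sm17 = 15,
                               min_dur_sm05 = 50, min_dur_sm17 = 20,
                               binarize_threshold = 0.5,
                               edge_search_halfwidth = 50,
                               shoulder_search = 60) {
  stopifnot(gap_merge_sm05 > 0, gap_merge_sm17 > 0, min_dur_sm05 > 0,
            min_dur_sm17 > 0, binarize_threshold > 0,
            binarize_threshold < 1, edge_search_halfwidth > 0,
            shoulder_search > 0)
  structure(as.list(environment()), class = "postprocess_config")
}

# Merge runs separated by gaps shorter than gap_ms, then drop runs
# shorter than min_ms; returns the rebuilt binary vector.
merge_and_prune <- function(x, gap_ms, min_ms, fs) {
  r <- runs_of_ones(x)
  out <- numeric(length(x))
  if (!nrow(r)) return(out)
  # merge: gap in samples, strictly less than the threshold duration
  merged <- r[1, , drop = FALSE]
  if (nrow(r) > 1) for (i in 2:nrow(r)) {
    gap <- r$start[i] - merged$end[nrow(merged)] - 1L
    if (gap / fs * 1000 < gap_ms) {
      merged$end[nrow(merged)] <- r$end[i]
    } else merged <- rbind(merged, r[i, ])
  }
  dur <- (merged$end - merged$start + 1L) / fs * 1000
  merged <- merged[dur >= min_ms, , drop = FALSE]
  for (i in seq_len(nrow(merged))) out[merged$start[i]:merged$end[i]] <- 1
  out
}

#' Filter the complex maps (SM05, SM17, SM19)
#'
#' Step 1 of postprocessing: (a) per-sample max-binarization across SM05,
#' SM17 and SM19 (ties resolved by the fixed priority SM05 > SM17 >
#' SM19); (b) runs separated by less than 30 ms (SM05) / 15 ms (SM17) are
#' merged; (c) runs shorter than 50 ms (SM05) / 20 ms (SM17) are removed;
#' (d) SM19 is recomputed as the complement of the filtered SM05 and
#' SM17.
#'
#' @param segmaps Probability `scg_segmaps`.
#' @param config A [postprocess_config].
#' @return `scg_segmaps` whose SM05/SM17/SM19 rows are binary (other rows
#'   passed through unchanged).
#' @export
filter_complex_maps <- function(segmaps, config = postprocess_config()) {
  stopifnot(inherits(segmaps, "scg_segmaps"))
  fs <- segmaps$fs
  p <- segmaps$maps[c(5L, 17L, 19L), , drop = FALSE]
  # argmax with tie priority SM05 > SM17 > SM19: the earlier row wins ties
  win <- max.col(t(p), ties.method = "first")
  sm05 <- merge_and_prune(as.numeric(win == 1L),
                          config$gap_merge_sm05, config$min_dur_sm05, fs)
  sm17 <- merge_and_prune(as.numeric(win == 2L),
                          config$gap_merge_sm17, config$min_dur_sm17, fs)
  # a sample claimed by both after merging keeps its argmax assignment
  both <- sm05 > 0 & sm17 > 0
  if (any(both)) {
    sm05[both & win != 1L] <- 0
    sm17[both & win != 2L] <- 0
  }
  maps <- segmaps$maps
  maps[5L, ] <- sm05
  maps[17L, ] <- sm17
  maps[19L, ] <- as.numeric(sm05 == 0 & sm17 == 0)
  new_segmaps(maps, fs)
}

#' Filter the 16 interval maps against the complex runs
#'
#' Step 2 of postprocessing: every interval map is zeroed wherever the
#' filtered SM19 is 1, binarized at the 0.5 threshold (`>= 0.5` maps to
#' 1), and restricted to at most one run per containing complex run, the
#' longest winning (first on ties).  Systolic interval maps are restricted
#' to SM05 runs and diastolic ones to SM17 runs; runs not wholly inside a
#' complex run of the matching type are removed.
#'
#' @param segmaps The original probability `scg_segmaps`.
#' @param filtered Output of [filter_complex_maps()].
#' @param config A [postprocess_config].
#' @return Fully binary `scg_segmaps`.
#' @export
filter_interval_maps <- function(segmaps, filtered,
                                 config = postprocess_config()) {
  idx <- sm_index()
  maps <- filtered$maps
  sm19 <- filtered$maps[19L, ]
  complex_runs <- list(systolic = runs_of_ones(filtered$maps[5L, ]),
                       diastolic = runs_of_ones(filtered$maps[17L, ]))
  for (k in setdiff(1:18, c(5L, 17L))) {
    x <- as.numeric(segmaps$maps[k, ] >= config$binarize_threshold)
    x[sm19 == 1] <- 0
    out <- numeric(length(x))
    runs <- runs_of_ones(x)
    cx <- complex_runs[[idx$complex[k]]]
    for (q in seq_len(nrow(cx))) {
      inside <- runs$start >= cx$start[q] & runs$end <= cx$end[q]
      if (!any(inside)) next
      cand <- runs[inside, , drop = FALSE]
      best <- which.max(cand$end - cand$start)  # first wins ties
      out[cand$start[best]:cand$end[best]] <- 1
    }
    maps[k, ] <- out
  }
  new_segmaps(maps, segmaps$fs)
}

# Snap a run edge to the nearest local extremum of the required polarity
# within +/- halfwidth samples; NA when none exists.
snap_to_extremum <- function(scg, edge, polarity, hw) {
  lo <- max(1L, edge - hw); hi <- min(length(scg), edge + hw)
  if (hi - lo < 2L) return(NA_integer_)
  ex <- find_extrema(scg[lo:hi],
                     type = if (polarity == "valley") "min" else "max")
  if (!length(ex)) return(NA_integer_)
  ex <- ex + lo - 1L
  ex[which.min(abs(ex - edge))]
}

#' Extract one fiducial's timing in every cardiac cycle
#'
#' For each complex run (SM05 runs for systolic labels, SM17 runs for
#' diastolic ones) the edges of the label's candidate maps (see
#' [candidate_maps()]) are snapped to the nearest local extremum of the
#' label's polarity within `edge_search_halfwidth`; the modal candidate
#' sample wins (ties between equal-count modes are broken by the lower
#' median of the tied samples).  Cycles with no candidate yield no
#' detection.
#'
#' @param label One of the nine encoded labels.
#' @param filtered_maps Binary `scg_segmaps` from [filter_interval_maps()].
#' @param scg Numeric signal the maps align to (used for peak/valley
#'   snapping).
#' @param config A [postprocess_config].
#' @return data.frame with columns `cycle`, `sample`, `n_votes`.
#' @export
extract_fiducial <- function(label, filtered_maps, scg,
                             config = postprocess_config()) {
  if (!label %in% c(valley_labels(), peak_labels()))
    stop("unknown or non-encoded fiducial label: ", label)
  fs <- filtered_maps$fs
  hw <- round(ms_to_samples(config$edge_search_halfwidth, fs))
  polarity <- if (label %in% valley_labels()) "valley" else "peak"
  cyc_map <- if (label %in% c("Cd", "Dd", "Ed")) 17L else 5L
  cycles <- runs_of_ones(filtered_maps$maps[cyc_map, ])
  cmaps <- candidate_maps(label)
  sm_row <- match(cmaps$sm, sm_index()$sm)
  out <- list()
  for (q in seq_len(nrow(cycles))) {
    cand <- integer(0)
    for (i in seq_len(nrow(cmaps))) {
      runs <- runs_of_ones(filtered_maps$maps[sm_row[i], ])
      runs <- runs[runs$start >= cycles$start[q] &
                     runs$end <= cycles$end[q], , drop = FALSE]
      if (!nrow(runs)) next
      edge <- if (cmaps$side[i] == "start") runs$start[1] else runs$end[1]
      hit <- snap_to_extremum(scg, edge, polarity, hw)
      if (!is.na(hit)) cand <- c(cand, hit)
    }
    if (!length(cand)) next
    tab <- table(cand)
    modes <- as.integer(names(tab)[tab == max(tab)])
    pick <- sort(modes)[ceiling(length(modes) / 2)]  # lower median
    out[[length(out) + 1L]] <- data.frame(cycle = q, sample = pick,
                                          n_votes = max(tab))
  }
  if (!length(out))
    return(data.frame(cycle = integer(0), sample = integer(0),
                      n_votes = integer(0)))
  do.call(rbind, out)
}

#' Locate the Es/Bd shoulder before a valley fiducial
#'
#' Es precedes Fs and Bd precedes Cd; each sits where the descending
#' slope briefly flattens before giving way to the final drop (a
#' curvature feature, not an extremum).  The shoulder is taken as the
#' point of strongest downward curvature of the lightly smoothed signal
#' -- the minimum of its second difference -- within the
#' `shoulder_search` window strictly before the valley: the elbow where
#' the flattened slope re-accelerates into the valley.  (The *maximum*
#' of the second difference is unsuitable: the concave-up approach to
#' the valley bottom always dominates it.)  A strictly linear descent
#' has no curvature change; the earliest window sample is then returned
#' with `low_confidence = TRUE`.
#'
#' @param valley_label `"Fs"` (gives Es) or `"Cd"` (gives Bd).
#' @param valley_sample Detected valley sample.
#' @param scg Numeric signal.
#' @param fs Sampling frequency, Hz.
#' @param config A [postprocess_config].
#' @return List `(sample, low_confidence)`; `sample` is `NA` when the
#'   window does not fit inside the record.
#' @export
detect_shoulder <- function(valley_label, valley_sample, scg, fs,
                            config = postprocess_config()) {
  stopifnot(valley_label %in% c("Fs", "Cd"))
  w <- round(ms_to_samples(config$shoulder_search, fs))
  lo <- valley_sample - w + 1L; hi <- valley_sample - 1L
  if (lo < 2L || hi - lo < 3L) {
    warning("shoulder window outside record before sample ",
            valley_sample)
    return(list(sample = NA_integer_, low_confidence = TRUE))
  }
  # light smoothing (~5 ms moving average) before differencing
  sw <- max(3L, round(ms_to_samples(5, fs)))
  if (sw %% 2L == 0L) sw <- sw + 1L
  pad <- (sw - 1L) %/% 2L
  a <- max(1L, lo - pad - 1L); bnd <- min(length(scg), hi + pad + 1L)
  seg <- stats::filter(scg[a:bnd], rep(1 / sw, sw), sides = 2)
  seg_idx <- a:bnd
  d2 <- c(NA, diff(seg, differences = 2), NA)
  use <- seg_idx >= lo & seg_idx <= hi & !is.na(d2)
  if (!any(use)) return(list(sample = NA_integer_, low_confidence = TRUE))
  vals <- d2[use]; at <- seg_idx[use]
  flat <- diff(range(vals)) <= 1e-12 * max(1, diff(range(scg[lo:hi])))
  if (flat) return(list(sample = at[1], low_confidence = TRUE))
  list(sample = at[which.min(vals)], low_confidence = FALSE)
}

#' Delineate a whole recording
#'
#' Runs the full pipeline on either predicted or ground-truth maps:
#' complex-map filtering, interval-map filtering, candidate-voting
#' extraction of the nine encoded fiducials, and shoulder detection for
#' Es and Bd.  Diastolic cycles are paired with the nearest preceding
#' systolic cycle within 2 s so every detection carries one beat index.
#'
#' @param model_or_maps A trained `unet_model`, a prediction function, or
#'   a probability/binary `scg_segmaps` covering the recording.
#' @param recording An [scg_recording]; its samples are used for
#'   peak/valley snapping.
#' @param pre_config A [preprocess_config] (windowing for model
#'   prediction; also used when `bandlimit_first`).
#' @param post_config A [postprocess_config].
#' @param bandlimit_first Band-limit the recording before prediction and
#'   snapping (set `FALSE` when the caller already filtered, e.g. for
#'   ground-truth round trips on clean signals).
#' @return An `scg_delineation` data.frame: `beat`, `label`, `sample`,
#'   `time_s`, `n_votes` plus attribute `complexes`.
#' @export
delineate_recording <- function(model_or_maps, recording,
                                pre_config = preprocess_config(),
                                post_config = postprocess_config(),
                                bandlimit_first = TRUE) {
  rec <- if (bandlimit_first) bandlimit(recording, pre_config) else
    recording
  maps <- if (inherits(model_or_maps, "scg_segmaps")) model_or_maps else
    predict_full(model_or_maps, rec, pre_config)
  stopifnot(maps$n_samples == length(rec$samples))
  fc <- filter_complex_maps(maps, post_config)
  fm <- filter_interval_maps(maps, fc, post_config)
  sys_runs <- runs_of_ones(fm$maps[5L, ])
  dia_runs <- runs_of_ones(fm$maps[17L, ])
  fs <- rec$fs
  # attach each diastolic run to the nearest preceding systolic run <= 2 s
  dia_beat <- rep(NA_integer_, nrow(dia_runs))
  for (q in seq_len(nrow(dia_runs))) {
    prev <- which(sys_runs$end < dia_runs$start[q])
    if (!length(prev)) next
    p <- max(prev)
    if ((dia_runs$start[q] - sys_runs$end[p]) / fs <= 2) dia_beat[q] <- p
  }
  rows <- list()
  add <- function(beat, label, sample, votes) {
    rows[[length(rows) + 1L]] <<- data.frame(
      beat = beat, label = label, sample = sample,
      time_s = (sample - 1L) / fs, n_votes = votes)
  }
  for (lab in c("Cs", "Ds", "Fs", "Gs", "Ks", "Ls")) {
    det <- extract_fiducial(lab, fm, rec$samples, post_config)
    for (i in seq_len(nrow(det)))
      add(det$cycle[i], lab, det$sample[i], det$n_votes[i])
  }
  for (lab in c("Cd", "Dd", "Ed")) {
    det <- extract_fiducial(lab, fm, rec$samples, post_config)
    for (i in seq_len(nrow(det))) {
      b <- dia_beat[det$cycle[i]]
      if (!is.na(b)) add(b, lab, det$sample[i], det$n_votes[i])
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(beat = integer(0), label = character(0),
               sample = integer(0), time_s = numeric(0),
               n_votes = integer(0))
  # shoulders from the detected valleys
  for (src in list(c("Fs", "Es"), c("Cd", "Bd"))) {
    vrows <- res[res$label == src[1], , drop = FALSE]
    for (i in seq_len(nrow(vrows))) {
      sh <- detect_shoulder(src[1], vrows$sample[i], rec$samples, fs,
                            post_config)
      if (!is.na(sh$sample))
        res <- rbind(res, data.frame(
          beat = vrows$beat[i], label = src[2], sample = sh$sample,
          time_s = (sh$sample - 1L) / fs, n_votes = 1L))
    }
  }
  res <- res[order(res$beat, res$sample), ]
  rownames(res) <- NULL
  attr(res, "complexes") <- list(systolic = sys_runs, diastolic = dia_runs)
  class(res) <- c("scg_delineation", "data.frame")
  res
}
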