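#' SCG recording container
#'
#' @param samples Numeric acceleration samples (arbitrary units).
#' @param fs Sampling frequency, Hz.
#' @param subject_id Identifier.
#' @param split One of `"train"`, `"validation"`, `"test"`, `"none"`.
#' @return An `scg_recording` list.
#' @export
scg_recording <- function(samples, fs, subject_id = "anon",
                          split = "none") {
  stopifnot(fs > 0, length(samples) > 0)
  if (any(!is.finite(samples)))
    stop("recording contains non-finite samples")
  split <- match.arg(split, c("train", "validation", "test", "none"))
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject_id = subject_id, split = split),
            class = "scg_recording")
}

#' @export
print.scg_recording <- function(x, ...) {
  cat("<scg_recording>", x$subject_id, ":", length(x$samples),
      "samples @", x$fs, "Hz (", round(length(x$samples) / x$fs, 1),
      "s )\n")
  invisible(x)
}

#' Preprocessing configuration
#'
#' Defaults: zero-phase order-3 Butterworth low-pass at 60 Hz followed by
#' order-3 high-pass at 1 Hz; 10-s windows with 2-s overlap.
#'
#' @param lp_cutoff,hp_cutoff Cutoffs in Hz.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective magnitude response is squared).
#' @param window_len,overlap Window length and overlap in seconds.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(lp_cutoff = 60, hp_cutoff = 1,
                              filter_order = 3, window_len = 10,
                              overlap = 2) {
  stopifnot(0 < hp_cutoff, hp_cutoff < lp_cutoff, filter_order >= 1,
            overlap >= 0, overlap < window_len)
  structure(list(lp_cutoff = lp_cutoff, hp_cutoff = hp_cutoff,
                 filter_order = filter_order, window_len = window_len,
                 overlap = overlap),
            class = "preprocess_config")
}

# Steady-state initial filter state (direct form II transposed), so a step
# input produces no startup transient.
lfilter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  m <- max(length(a), length(b))
  a <- c(a, rep(0, m - length(a)))
  b <- c(b, rep(0, m - length(b)))
  if (m == 1L) return(numeric(0))
  comp <- matrix(0, m - 1L, m - 1L)
  comp[1L, ] <- -a[2:m]
  if (m > 2L) comp[cbind(2:(m - 1L), 1:(m - 2L))] <- 1
  solve(diag(m - 1L) - t(comp), b[2:m] - a[2:m] * b[1])
}

# Zero-phase filtering: odd-reflection padding of 3x the filter order,
# steady-state initial conditions, forward pass, time-reversed pass.
filtfilt_oddpad <- function(b, a, x, order) {
  pad <- 3L * order
  n <- length(x)
  if (n <= pad + 1L)
    stop("signal too short for zero-phase filtering: need more than ",
         pad + 1L, " samples, got ", n)
  ext <- c(2 * x[1] - x[(pad + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- cpp_lfilter(b, a, ext, zi * ext[1])
  y <- rev(cpp_lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

#' Band-limit a recording with zero-phase Butterworth filters
#'
#' Applies a forward-backward low-pass (default 60 Hz, order 3) followed by
#' a forward-backward high-pass (default 1 Hz, order 3).  Zero-phase
#' application leaves event timings unshifted; the effective magnitude
#' response of each stage is the squared Butterworth magnitude.
#'
#' @param recording An [scg_recording].
#' @param config A [preprocess_config].
#' @return The filtered recording (same length, same metadata).
#' @export
bandlimit <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "scg_recording"))
  fs <- recording$fs
  if (config$lp_cutoff >= fs / 2)
    stop("lp_cutoff must be below the Nyquist frequency ", fs / 2, " Hz")
  lp <- signal::butter(config$filter_order, config$lp_cutoff / (fs / 2),
                       type = "low")
  hp <- signal::butter(config$filter_order, config$hp_cutoff / (fs / 2),
                       type = "high")
  x <- filtfilt_oddpad(lp$b, lp$a, recording$samples, config$filter_order)
  x <- filtfilt_oddpad(hp$b, hp$a, x, config$filter_order)
  out <- recording
  out$samples <- x
  out
}

# Min-max normalization to [0, 1]; a constant segment maps to all zeros
# (flagged with a warning: dead channel).
minmax_norm <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) {
    warning("degenerate constant window; normalized to all zeros")
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Window a recording into fixed-length normalized segments
#'
#' Consecutive windows advance by `window_len - overlap` seconds; the 2-s
#' default overlap guarantees that every beat appears in full length in at
#' least one window.  When the stride grid does not reach the end of the
#' recording, a final full-length window anchored at the recording end is
#' added so that every sample is covered.  Each segment is min-max
#' normalized independently.  When ground-truth annotations are supplied,
#' each segment carries binary segmentation maps with the complete-beat
#' rule applied (see [drop_incomplete_beats()]).
#'
#' @param recording An [scg_recording].
#' @param truth Optional [scg_annotations] for the whole recording.
#' @param config A [preprocess_config].
#' @return List of `scg_segment` objects (fields `samples`, `fs`,
#'   `origin = c(subject_id, start_sample)`, optional `sm_truth`,
#'   `truth` with window-local samples).
#' @export
window_recording <- function(recording, truth = NULL,
                             config = preprocess_config()) {
  fs <- recording$fs
  wlen <- round(config$window_len * fs)
  stride <- round((config$window_len - config$overlap) * fs)
  n <- length(recording$samples)
  if (n < wlen) {
    warning("recording shorter than one window; returning no segments")
    return(list())
  }
  starts <- seq(1L, n - wlen + 1L, by = stride)
  if (starts[length(starts)] + wlen - 1L < n)
    starts <- c(starts, n - wlen + 1L)
  lapply(starts, function(s0) {
    idx <- s0:(s0 + wlen - 1L)
    seg <- list(samples = minmax_norm(recording$samples[idx]), fs = fs,
                origin = list(subject_id = recording$subject_id,
                              start = s0))
    if (!is.null(truth)) {
      keep <- complete_beats(truth, s0, s0 + wlen - 1L)
      local <- truth[truth$beat %in% keep, , drop = FALSE]
      local$sample <- local$sample - s0 + 1L
      local <- scg_annotations(local$beat, local$label, local$sample)
      seg$truth <- local
      seg$sm_truth <- encode_segmaps(local, wlen, fs)
    }
    class(seg) <- "scg_segment"
    seg
  })
}

# Beats whose full annotated extent [first, last fiducial sample] lies
# inside [w0, w1].
complete_beats <- function(truth, w0, w1) {
  if (nrow(truth) == 0L) return(integer(0))
  lo <- tapply(truth$sample, truth$beat, min)
  hi <- tapply(truth$sample, truth$beat, max)
  as.integer(names(lo))[lo >= w0 & hi <= w1]
}

#' Remove incompletely windowed beats from segmentation maps
#'
#' For every beat whose first-to-last annotated sample is not fully inside
#' the window, all 18 interval maps are zeroed over that beat's extent
#' (clipped to the window) and SM19 is recomputed as the complement of the
#' union of the interval maps.
#'
#' @param segmaps `scg_segmaps` aligned to the window.
#' @param beats [scg_annotations] in the same (window-local) coordinates;
#'   samples may fall outside `[window[1], window[2]]`.
#' @param window Inclusive sample interval `c(start, end)` of the window in
#'   the same coordinates as `beats`.
#' @return Filtered `scg_segmaps`.
#' @export
drop_incomplete_beats <- function(segmaps, beats, window) {
  stopifnot(inherits(segmaps, "scg_segmaps"), length(window) == 2L)
  maps <- segmaps$maps
  if (nrow(beats)) {
    keep <- complete_beats(beats, window[1], window[2])
    for (b in setdiff(unique(beats$beat), keep)) {
      rows <- beats[beats$beat == b, ]
      s0 <- max(window[1], min(rows$sample)) - window[1] + 1L
      s1 <- min(window[2], max(rows$sample)) - window[1] + 1L
      if (s0 <= s1) maps[1:18, s0:s1] <- 0
    }
  }
  maps[19L, ] <- as.numeric(colSums(maps[1:18, , drop = FALSE]) == 0)
  new_segmaps(maps, segmaps$fs)
}
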