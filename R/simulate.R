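#' Default fiducial latency template
#'
#' Mean latencies (s) of the 11 fiducial points from beat onset, in
#' canonical order.  The values sketch a plausible SCG beat: a systolic
#' complex over roughly the first 230 ms (Cs through Ls) and a diastolic
#' complex between about 370 and 480 ms (Bd through Ed), so the full beat
#' spans about 0.55 s and fits inside one cycle even at 94 bpm.
#'
#' @return Named numeric vector over [fiducial_labels()].
#' @export
default_fiducial_offsets <- function() {
  c(Cs = 0.010, Ds = 0.045, Es = 0.085, Fs = 0.110, Gs = 0.150,
    Ks = 0.190, Ls = 0.230, Bd = 0.370, Cd = 0.395, Dd = 0.435,
    Ed = 0.480)
}

#' @rdname default_fiducial_offsets
#' @details `default_amplitude_profile()` gives the signed relative
#'   amplitude of each fiducial: negative for valley points (Cs, Fs, Ks,
#'   Cd, Ed), positive for peak points (Ds, Gs, Ls, Dd) and for the two
#'   shoulder levels (Es, Bd).
#' @export
default_amplitude_profile <- function() {
  c(Cs = -0.30, Ds = 1.00, Es = 0.45, Fs = -0.80, Gs = 0.65,
    Ks = -0.55, Ls = 0.45, Bd = 0.18, Cd = -0.35, Dd = 0.30,
    Ed = -0.20)
}

#' Subject-level simulation parameters
#'
#' @param mean_hr Mean heart rate, beats/min.
#' @param hr_jitter_sd SD of beat-to-beat period jitter, seconds.
#' @param fiducial_offsets Named mean latencies (s) from beat onset; must
#'   respect the canonical ordering and fit inside one beat period.
#' @param offset_jitter_sd SD of per-beat latency jitter, seconds.
#' @param amplitude_profile Named signed relative amplitudes.
#' @param resp_rate Respiratory rate, breaths/min; modulates the diastolic
#'   complex amplitude.
#' @param resp_mod_depth Modulation depth, fraction in `[0, 1)`.
#' @param noise_sd Additive Gaussian noise SD relative to the peak
#'   amplitude of the clean waveform.
#' @param cd_like If `TRUE`, emulate an irregular morphology: per-beat
#'   random attenuation of one complex and (via [sample_subject()]) wider
#'   latency jitter.  Not a claim of physiological fidelity.
#' @return A validated `scg_subject_params` list.
#' @export
scg_subject_params <- function(mean_hr = 60, hr_jitter_sd = 0.01,
                               fiducial_offsets = default_fiducial_offsets(),
                               offset_jitter_sd = 0.002,
                               amplitude_profile = default_amplitude_profile(),
                               resp_rate = 15, resp_mod_depth = 0.2,
                               noise_sd = 0.02, cd_like = FALSE) {
  labs <- fiducial_labels()
  stopifnot(all(labs %in% names(fiducial_offsets)),
            all(labs %in% names(amplitude_profile)),
            mean_hr > 0, hr_jitter_sd >= 0, offset_jitter_sd >= 0,
            resp_rate > 0, resp_mod_depth >= 0, resp_mod_depth < 1,
            noise_sd >= 0)
  off <- fiducial_offsets[labs]
  if (is.unsorted(off, strictly = TRUE))
    stop("fiducial offsets must be strictly increasing in the order ",
         paste(labs, collapse = " < "))
  span <- off["Ed"] + 0.05 - (off["Cs"] - 0.02)
  if (span >= 60 / mean_hr)
    stop("beat span (", round(span, 3), " s) must be shorter than one ",
         "period (", round(60 / mean_hr, 3), " s) at ", mean_hr, " bpm")
  structure(list(mean_hr = mean_hr, hr_jitter_sd = hr_jitter_sd,
                 fiducial_offsets = off, offset_jitter_sd = offset_jitter_sd,
                 amplitude_profile = amplitude_profile[labs],
                 resp_rate = resp_rate, resp_mod_depth = resp_mod_depth,
                 noise_sd = noise_sd, cd_like = isTRUE(cd_like)),
            class = "scg_subject_params")
}

#' Default population ranges for subject sampling
#'
#' Heart-rate range 36--94 bpm matches the span of median heart rates in
#' the cohorts the package targets; the remaining ranges describe modest
#' inter-subject variation in timing jitter, respiration and noise.
#'
#' @param cd_fraction Probability that a sampled subject has the irregular
#'   "CD-like" morphology.
#' @return A named list of `c(min, max)` ranges plus `cd_fraction`.
#' @export
default_population <- function(cd_fraction = 0.2) {
  list(mean_hr = c(36, 94), hr_jitter_sd = c(0.005, 0.02),
       offset_jitter_sd = c(0.001, 0.003), resp_rate = c(10, 20),
       resp_mod_depth = c(0.1, 0.3), noise_sd = c(0.005, 0.02),
       amp_scale = c(0.8, 1.2), cd_fraction = cd_fraction)
}

#' Draw one subject's parameters from population ranges
#'
#' Uniform draws inside each range, plus mild subject-level morphology
#' variation (log-normal amplitude jitter and small latency shifts).
#' Deterministic given `seed`.
#'
#' @param population A list of ranges as from [default_population()].
#' @param seed Integer seed.
#' @return An `scg_subject_params` object.
#' @export
sample_subject <- function(population = default_population(), seed) {
  for (nm in setdiff(names(population), "cd_fraction")) {
    r <- population[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop("invalid range for ", nm, ": min must not exceed max")
  }
  with_seed(seed, {
    draw <- function(nm) {
      r <- population[[nm]]; runif(1, r[1], r[2])
    }
    cd <- runif(1) < (population$cd_fraction %||% 0)
    off <- default_fiducial_offsets()
    shift <- rnorm(length(off), 0, 0.003)
    # keep Es/Bd shoulder plateaus attached to their template position
    shift[names(off) %in% c("Es", "Bd")] <- 0
    off <- enforce_order(off + shift, min_gap = 0.010)
    amp <- default_amplitude_profile() *
      exp(rnorm(11, 0, 0.08)) * draw("amp_scale")
    ojs <- draw("offset_jitter_sd")
    scg_subject_params(
      mean_hr = draw("mean_hr"), hr_jitter_sd = draw("hr_jitter_sd"),
      fiducial_offsets = off,
      offset_jitter_sd = if (cd) 3 * ojs else ojs,
      amplitude_profile = amp, resp_rate = draw("resp_rate"),
      resp_mod_depth = draw("resp_mod_depth"), noise_sd = draw("noise_sd"),
      cd_like = cd)
  })
}

# Force strictly increasing latencies with a minimum spacing (seconds).
enforce_order <- function(t, min_gap) {
  for (i in seq_along(t)[-1]) t[i] <- max(t[i], t[i - 1] + min_gap)
  t
}

# Piecewise half-cosine interpolation through knots (sample, value).
# Each segment is monotone with zero slope at both ends, so every knot
# whose neighbours lie on the same side is an exact local extremum of the
# sampled waveform.
eval_knots <- function(samples, values, out, weight = 1) {
  for (k in seq_len(length(samples) - 1L)) {
    s0 <- samples[k]; s1 <- samples[k + 1L]
    if (s1 <= s0) next
    idx <- s0:s1
    phase <- (idx - s0) / (s1 - s0)
    out[idx] <- values[k] + (values[k + 1L] - values[k]) *
      (1 - cos(pi * phase)) / 2
  }
  out
}

#' Synthesize an annotated SCG recording
#'
#' Builds a quasi-periodic acceleration waveform as a train of beats, each
#' a piecewise half-cosine complex whose knots are the fiducial points:
#' valley fiducials (Cs, Fs, Ks, Cd, Ed) fall on exact local minima of the
#' noise-free waveform and peak fiducials (Ds, Gs, Ls, Dd) on exact local
#' maxima.  Es and Bd are realized as short plateau shoulders on the
#' descent into Fs and Cd.  The diastolic complex amplitude is multiplied
#' by `1 + resp_mod_depth * sin(2*pi*resp_rate/60 * t)` and Gaussian noise
#' with SD `noise_sd * max(abs(clean))` is added.  Only beats that fit
#' entirely inside the record are annotated (and rendered).
#'
#' @param params An [scg_subject_params] object.
#' @param duration Record duration in seconds; must fit at least one beat.
#' @param fs Sampling frequency in Hz (>= 250).
#' @param seed Integer seed; identical `(params, duration, fs, seed)` give
#'   bit-identical output.
#' @param subject_id Identifier stored in the recording.
#' @return A `scg_synth` list: `recording` (noisy [scg_recording]),
#'   `clean` (noise-free samples), `truth` ([scg_annotations]) and
#'   `params`.
#' @export
synthesize <- function(params, duration, fs = 5000, seed,
                       subject_id = "synthetic") {
  stopifnot(inherits(params, "scg_subject_params"))
  if (fs < 250) stop("fs must be at least 250 Hz")
  off <- params$fiducial_offsets
  span <- off["Ed"] + 0.05 - (off["Cs"] - 0.02)
  if (duration < span + 0.05)
    stop("duration (", duration, " s) shorter than one full beat (",
         round(span + 0.05, 2), " s)")
  n <- round(duration * fs)
  labs <- fiducial_labels()
  wp <- 0.008  # shoulder plateau width (s)

  with_seed(seed, {
    # beat onset grid
    onsets <- numeric(0)
    t0 <- 0.025
    while (t0 + span <= duration) {
      onsets <- c(onsets, t0)
      period <- 60 / params$mean_hr + rnorm(1, 0, params$hr_jitter_sd)
      period <- max(period, span + 0.04)
      t0 <- t0 + period
    }
    clean <- numeric(n)
    ann <- list()
    resp_w <- 2 * pi * params$resp_rate / 60
    for (b in seq_along(onsets)) {
      t_lab <- onsets[b] + off + rnorm(11, 0, params$offset_jitter_sd)
      names(t_lab) <- labs
      t_lab <- enforce_order(t_lab, min_gap = 0.008)
      amp <- params$amplitude_profile * exp(rnorm(11, 0, 0.05))
      if (params$cd_like && runif(1) < 0.5) {
        which_cx <- if (runif(1) < 0.5) 1:7 else 8:11
        amp[which_cx] <- amp[which_cx] * 0.3
      }
      # respiratory modulation of the diastolic complex
      m <- 1 + params$resp_mod_depth * sin(resp_w * t_lab[["Cd"]])
      amp[c("Bd", "Cd", "Dd", "Ed")] <- amp[c("Bd", "Cd", "Dd", "Ed")] * m
      kt <- c(t_lab[["Cs"]] - 0.020,                       # baseline
              t_lab[["Cs"]], t_lab[["Ds"]],
              t_lab[["Es"]] - wp, t_lab[["Es"]],           # Es plateau
              t_lab[["Fs"]], t_lab[["Gs"]], t_lab[["Ks"]], t_lab[["Ls"]],
              t_lab[["Ls"]] + 0.050,                       # systolic tail
              t_lab[["Bd"]] - wp - 0.015,                  # pre-Bd crest
              t_lab[["Bd"]] - wp, t_lab[["Bd"]],           # Bd plateau
              t_lab[["Cd"]], t_lab[["Dd"]], t_lab[["Ed"]],
              t_lab[["Ed"]] + 0.050)                       # back to baseline
      kv <- c(0,
              amp[["Cs"]], amp[["Ds"]], amp[["Es"]], amp[["Es"]],
              amp[["Fs"]], amp[["Gs"]], amp[["Ks"]], amp[["Ls"]],
              0.05 * m,
              abs(amp[["Bd"]]) + 0.12 * m,
              amp[["Bd"]], amp[["Bd"]],
              amp[["Cd"]], amp[["Dd"]], amp[["Ed"]],
              0)
      ks <- round(kt * fs) + 1L
      # keep auxiliary knots off the fiducial samples
      for (i in seq_along(ks)[-1])
        if (ks[i] <= ks[i - 1]) ks[i] <- ks[i - 1] + 1L
      if (ks[1] < 1L || ks[length(ks)] > n) next
      clean <- eval_knots(ks, kv, clean)
      fid_samples <- ks[c(2, 3, 5, 6, 7, 8, 9, 13, 14, 15, 16)]
      ann[[length(ann) + 1L]] <-
        data.frame(beat = b, label = labs, sample = fid_samples)
    }
    noise <- if (params$noise_sd > 0 && length(ann))
      rnorm(n, 0, params$noise_sd * max(abs(clean))) else numeric(n)
    ann <- if (length(ann)) do.call(rbind, ann) else
      data.frame(beat = integer(0), label = character(0),
                 sample = integer(0))
    truth <- scg_annotations(ann$beat, ann$label, ann$sample)
    structure(list(
      recording = scg_recording(clean + noise, fs, subject_id),
      clean = clean, truth = truth, params = params),
      class = "scg_synth")
  })
}

#' Simulate an annotated cohort
#'
#' Convenience wrapper: draws `n_subjects` parameter sets from
#' `population` and synthesizes one recording per subject with
#' deterministic per-subject seeds derived from `seed`.
#'
#' @inheritParams sample_subject
#' @param n_subjects Number of subjects.
#' @param duration Seconds per recording.
#' @param fs Sampling frequency, Hz.
#' @return A list of `scg_synth` objects named by subject id.
#' @export
simulate_cohort <- function(n_subjects, duration, fs = 5000, seed,
                            population = default_population()) {
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    id <- sprintf("S%03d", i)
    p <- sample_subject(population, seed = seed + 131L * i)
    out[[i]] <- synthesize(p, duration, fs, seed = seed + 131L * i + 1L,
                           subject_id = id)
    names(out)[i] <- id
  }
  out
}

#' @export
print.scg_synth <- function(x, ...) {
  cat("<scg_synth>", x$recording$subject_id, ":",
      length(x$recording$samples), "samples @", x$recording$fs, "Hz,",
      length(unique(x$truth$beat)), "annotated beats\n")
  invisible(x)
}
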