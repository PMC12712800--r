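---
title: "Delineating SCG fiducial points with interval segmentation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating SCG fiducial points with interval segmentation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgdelin)
```

## The problem

A seismocardiogram (SCG) records chest-wall acceleration at the xiphoid
process.  Within every heartbeat the waveform traces two oscillatory
groups: a systolic complex, whose landmarks are labelled Cs, Ds, Es, Fs,
Gs, Ks and Ls, and a diastolic complex with Bd, Cd, Dd and Ed.  These
eleven fiducial points mark mechanical events (valve openings and
closures, peak systolic outflow, filling), and their beat-to-beat timing
is the raw material for cardiac time-interval analysis.  `scgdelin`
delineates all eleven points from a single-axis SCG signal with no
concurrent ECG.

The delineation strategy converts the pointwise labelling problem into
dense semantic segmentation.  Nine of the eleven points (Es and Bd
excluded, see below) span intervals: every pair of encoded points inside
one complex defines a binary **segmentation map** (SM) that is 1 on the
inclusive interval between them and 0 elsewhere.  Six systolic points
give $\binom{6}{2} = 15$ maps, three diastolic points $\binom{3}{2} = 3$,
and a final no-event map SM19 is 1 exactly where all 18 interval maps
are 0.  A 1-D U-Net predicts all 19 maps per sample; rule-based
postprocessing cleans them; the run edges of the cleaned maps, snapped
to peaks and valleys of the signal, vote on each fiducial's sample.

Es and Bd are not extrema but *shoulders* on the descending slopes into
Fs and Cd, so they cannot bound interval maps with well-defined edges;
they are recovered afterwards from the detected Fs and Cd valleys.

## Preprocessing

Signals are band-limited by a zero-phase (forward–backward) cascade: a
third-order low-pass Butterworth at 60 Hz followed by a third-order
high-pass at 1 Hz.  Forward–backward application squares each filter's
magnitude response and cancels its phase, so fiducial timings are not
shifted; the package verifies this by the unshifted argmax of a filtered
impulse and a zero-lag cross-correlation of broadband noise.  Each pass
uses odd-reflection padding of three times the filter order together
with steady-state initial conditions, the standard construction that
suppresses (but cannot eliminate) startup transients.  Stopband checks
against the analytic squared Butterworth magnitude are therefore made on
the interior of a long record: boundary transients are a finite-length
artifact, not part of the frequency response.

Filtered recordings are cut into 10-s windows with a 2-s overlap — long
enough that every beat (even at 36 bpm) lies wholly inside at least one
window.  When the stride grid does not reach the end of the recording, a
final full-length window anchored at the last sample is added, so the
fixed network input length is preserved *and* every sample is covered.
Each window is min–max normalized to $[0, 1]$ independently; a constant
(dead) window maps to all zeros with a warning.  Ground-truth maps
follow the complete-beat rule: a beat whose annotated extent (first to
last fiducial sample) crosses a window edge is erased from that window's
maps, and SM19 is recomputed, so the network never sees truncated beats.
Sample indices are 1-based with inclusive run endpoints throughout, the
R convention; a fiducial sample therefore belongs to every interval it
bounds, which makes the edge-to-fiducial identity exact.

## The network

The U-Net is one-dimensional with four encoder levels of 4, 8, 16 and
32 filters, a 64-filter bottleneck, and four decoder levels of 32, 16,
8 and 4 filters, ending in a 19-channel output projection.  Each level
is one block of two subblocks (convolution, batch normalization,
LeakyReLU with slope 0.01).  Dilation doubles down the encoder
(1, 2, 4, 8), is 16 in the bottleneck, and halves back up the decoder.
Factor-2 max pooling separates encoder levels (hence input lengths must
be divisible by $2^4 = 16$); stride-2 transposed convolutions upsample,
and skip connections concatenate each encoder output onto its mirror
decoder level.  Training uses Adam at learning rate 0.001 and
element-wise binary cross-entropy.  A per-channel sigmoid output is
forced by the encoding itself: the 18 interval maps overlap (a sample
between Cs and Ds is 1 in five maps), which rules out a softmax.

Choices the architecture description leaves open are fixed as follows
and are configurable: kernel size 3 with dilation-aware "same" padding;
transposed-convolution kernel 2 (exact doubling, no overlap);
fan-in-scaled normal weight initialization; batch size 4 with seeded
per-epoch shuffling (the packaged end-to-end experiment uses batch 1:
with the epoch count capped, the optimizer-step count is what drives
convergence, and smaller batches buy more steps at the same compute).  The epoch with the lowest validation loss is
restored at the end of training; an optional ceiling on the
(validation − training) gap restricts that argmin to epochs where the
two curves have not yet diverged, and the gap at the selected epoch is
always reported.  All randomness (initialization, shuffling,
simulation) flows through per-call seeded generators; two runs with the
same configuration are bit-identical.

Windows overlap at prediction time too; `predict_full()` merges them by
the arithmetic mean of the predicted probabilities over every window
covering a sample — unbiased and independent of window order.

## Postprocessing and extraction

Step 1 operates on the two complex maps and the no-event map.  The
per-sample argmax across SM05 (Cs–Ls), SM17 (Cd–Ed) and SM19 is
binarized, with knife-edge ties resolved by the fixed priority
SM05 > SM17 > SM19 (prefer detecting a complex over no-event).  Runs of
ones separated by less than 30 ms (SM05) or 15 ms (SM17) are merged;
runs shorter than 50 ms (SM05) or 20 ms (SM17) are removed; SM19 is
recomputed as the complement.  The merge-then-prune pair is idempotent,
and afterwards SM05, SM17 and SM19 tile the record exactly.

Step 2 masks every interval map wherever the filtered SM19 is 1,
binarizes at 0.5 (a probability of exactly 0.5 maps to 1), and keeps at
most one run — the longest — inside each containing complex run.
Systolic interval maps are restricted to SM05 runs and diastolic ones
to SM17 runs; masking by SM19 alone cannot prevent, say, a stray
systolic run from surviving inside a diastolic complex, and a run that
survived there would have no meaningful edge.

Each fiducial is then extracted per cardiac cycle, one cycle per
filtered SM05 run (systolic labels) or SM17 run (diastolic labels).
Every candidate map of the label contributes the appropriate run edge,
snapped to the nearest local extremum of the correct polarity — valleys
for Cs, Fs, Ks, Cd, Ed; peaks for Ds, Gs, Ls, Dd — within ±50 ms.
Snapping collapses near-agreements onto exact samples, so the vote is a
simple mode over five candidates (systolic) or two (diastolic); tied
modes resolve to the lower median of the tied samples, which is
deterministic.  A cycle in which no candidate finds an extremum yields
no detection — the package never invents a point.  Local extrema use
strict neighbour comparison with plateaus resolved to their midpoint,
and a monotone shelf is not an extremum.  Diastolic cycles attach to
the nearest preceding systolic cycle within 2 s to form beats.

**Shoulder points.**  The descending slope into Fs (for Es) and into Cd
(for Bd) briefly flattens before the final drop.  The shoulder is
located as the *minimum* of the second difference of the lightly
smoothed signal (≈5-ms moving average) in a 60-ms window strictly
before the valley: the point of strongest downward curvature, where the
flattened slope gives way to the drop.  The maximum of the second
difference is unsuitable, although it is the first idea one tries: the
concave-up approach to the valley bottom always carries the largest
positive curvature in that window, so an argmax lands at the valley
instead of the shoulder.  The packaged tests hold the argmin form to
within 5 ms of the constructed plateau end.  A strictly linear descent has
no curvature feature at all; the earliest window sample is returned
flagged low-confidence.

## Evaluation

A prediction within 10 ms (inclusive) of a true point of the same label
is a true positive; matching is greedy by ascending absolute error with
one-to-one consumption, ties broken deterministically.  Against an
exhaustive maximum-matching oracle the greedy matcher is exact whenever
same-label points are separated by more than twice the tolerance —
always the case for beats hundreds of milliseconds apart.  PPV
($TP/(TP+FP)$) and sensitivity ($TP/(TP+FN)$) are computed per subject
and per label; an undefined 0/0 is reported absent and excluded from
aggregation, never coerced to 0 or 1, which would bias subject
summaries.  Aggregates (median, IQR, mean, SD) are taken across
subjects, never across pooled beats; the IQR uses R's default type-7
linear-interpolation quantiles.  Segmentation maps themselves are
scored two ways: one-to-one matching of run centers (floor midpoint of
the inclusive run) at the same tolerance, and the per-map fraction of
samples agreeing with the truth.

## The synthetic cohort

The study data behind this delineation approach are private, so the
package carries a seeded simulator that every downstream stage —
including training — is tested against.  A beat is a train of
piecewise half-cosine segments through knots placed at the fiducial
samples: each segment is monotone with zero slope at both ends, so
every valley/peak fiducial is an *exact* local extremum of the sampled
noise-free waveform, by construction rather than approximately.  Es and
Bd are realized as 8-ms plateaus on the descents into Fs and Cd.  Beats
repeat at the subject's mean heart rate with Gaussian period jitter;
per-beat latency and amplitude jitter perturb the morphology; the
diastolic complex is amplitude-modulated by
$1 + d\,\sin(2\pi f_\mathrm{resp} t)$; Gaussian noise is added with SD
proportional to the clean waveform's peak.  Subjects are drawn from
population ranges — heart rate 36–94 bpm, matching the span of median
heart rates in the cohorts this method targets; respiration 10–20
breaths/min with depth 0.1–0.3; relative noise 0.005–0.02 — plus mild
subject-level morphology variation.  "CD-like" subjects (irregular
morphology, as seen in cardiac disease) are emulated by tripling the
latency jitter and randomly attenuating one complex per beat; this is a
stress fixture, not a physiological claim.

What the simulator does *not* emulate matters for interpreting green
tests: real SCG morphology varies far more than cosine atoms allow;
motion and sensor artifacts, arrhythmic beats, and inter-beat waveform
correlation are absent; noise is white and stationary.  Passing the
round-trip and end-to-end checks therefore demonstrates that the
*algorithmic chain* is implemented coherently — maps encode and decode
exactly, filtering rules behave as stated, voting recovers constructed
truth — not that the trained fixture model would transfer to clinical
recordings.

## Numerical choices and problem sizes

Thresholds are stored in milliseconds and converted through the
sampling frequency at call time.  The simulator accepts any
`fs ≥ 250 Hz` and defaults to 5,000 Hz; the packaged experiments run at
320–400 Hz, where a 10-s window (3,200–4,000 samples) is divisible by
16 and a training run of twenty subjects fits in minutes on one CPU.
The end-to-end experiment trains on 17 subjects (150-s recordings,
~320 windows) for 20 epochs with batch 1, selects the epoch with the
lowest validation loss on 3 further subjects, and evaluates on 5
held-out subjects; the round-trip exactness property runs 20 noise-free
subjects through encode → filter → extract.  With identical seeds every
one of these numbers reproduces exactly.

## Known limitations

* The network is trained and evaluated on synthetic data only; headline
  clinical performance cannot be established here.
* Shoulder (Es/Bd) placement is a declared convention; annotated
  agreement on real data would need its own validation.
* Recordings shorter than one window are not processed (no padding).
* The compiled network implementation is minimal by design: no GPU
  path, no architecture search, no augmentation.
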