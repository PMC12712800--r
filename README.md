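# scgdelin

Beat-to-beat delineation of eleven fiducial points in seismocardiogram
(SCG) signals.

The SCG is the chest-wall acceleration signal produced by the beating
heart, recorded with an accelerometer at the xiphoid process.  Each beat
carries a systolic oscillation complex with landmarks **Cs, Ds, Es, Fs,
Gs, Ks, Ls** and a diastolic complex with **Bd, Cd, Dd, Ed**; their
timings mark mechanical events (valve openings/closures, peak systolic
outflow, filling) and feed cardiac time-interval analysis.  `scgdelin`
locates all eleven points per beat from a single-axis SCG, with no
concurrent ECG, for researchers working on mechanical cardiac timing.

## Method

Pointwise labelling is recast as dense semantic segmentation.  Every
pair of encoded fiducials within one complex defines a binary
*segmentation map* that is 1 on the inclusive interval between them:
$\binom{6}{2} = 15$ systolic maps (Es is not encoded), $\binom{3}{2} =
3$ diastolic maps (Bd is not encoded), plus a no-event map SM19 with
$\mathrm{SM19}[t] = 1 \iff$ all 18 interval maps are 0 at $t$.  A 1-D
dilated U-Net (encoder filters 4-8-16-32, bottleneck 64, decoder
32-16-8-4, 19 sigmoid output channels; dilation 1,2,4,8,16,8,4,2,1)
maps a min–max-normalized 10-s segment of the band-limited signal
(zero-phase Butterworth, 60 Hz low-pass and 1 Hz high-pass, order 3) to
the 19 probability maps.  Postprocessing max-binarizes {SM05, SM17,
SM19}, merges runs split by gaps < 30 ms (SM05) / 15 ms (SM17), removes
runs < 50 ms / 20 ms, masks and thresholds (≥ 0.5) the interval maps,
and keeps the longest run per complex run.  Each fiducial is then voted
on per cardiac cycle: every candidate map contributes its run edge
snapped to the nearest correct-polarity extremum (valleys for Cs, Fs,
Ks, Cd, Ed; peaks for Ds, Gs, Ls, Dd), and the modal sample wins.  Es
and Bd are recovered as the curvature shoulder preceding the Fs and Cd
valleys.  Matching a prediction to truth within 10 ms (inclusive,
one-to-one) defines TP/FP/FN, and

$$\mathrm{PPV} = \frac{TP}{TP+FP}, \qquad S = \frac{TP}{TP+FN},$$

computed per subject and per label, then summarized across subjects
(median, IQR, mean, SD).

Because the recordings behind this method are not publicly available,
the package includes a seeded synthetic-SCG simulator whose beats place
every valley/peak fiducial on an exact extremum by construction; it
drives all tests, including network training.  See the methods vignette
(`vignettes/scg-delineation-methods.Rmd`) for the model, conventions
and limitations.

## Worked example

Simulate an annotated subject, encode its ground-truth maps, run the
postprocessing + extraction chain, and score it:

```r
library(scgdelin)

params <- scg_subject_params(mean_hr = 72, noise_sd = 0.01)
synth  <- synthesize(params, duration = 20, fs = 1000, seed = 42)
synth
#> <scg_synth> synthetic : 20000 samples @ 1000 Hz, 24 annotated beats

maps <- encode_segmaps(synth$truth, length(synth$clean), fs = 1000)
det  <- delineate_recording(maps, synth$recording)   # band-limits first
head(as.data.frame(det), 3)
#>   beat label sample time_s n_votes
#> 1    1    Cs     39  0.038       5
#> 2    1    Ds     70  0.069       5
#> 3    1    Es    114  0.113       1

report <- match_fiducials(synth$truth, det, fs = 1000)
report$ppv <- ppv(report$TP, report$FP)
report$sensitivity <- sensitivity(report$TP, report$FN)
report
#>    label TP FP FN ppv sensitivity
#> 1     Cs 24  0  0   1           1
#> ...
#> 11    Ed 24  0  0   1           1
```

Every one of the 24 beats' 11 fiducials is recovered within the 10-ms
tolerance (`n_votes` counts the agreeing candidate maps: 5 for systolic
labels, 2 for diastolic, 1 for the shoulder points).  Training the
U-Net instead of using ground-truth maps is one call:

```r
ex <- run_experiment(run_config(seed = 1))   # simulate, train, evaluate
ex$summary                                   # per-label PPV/S across subjects
```

A thin command-line wrapper over the same functions lives at
`inst/cli/scgdelin.R` (subcommands `simulate`, `preprocess`, `encode`,
`train`, `delineate`, `evaluate`, `run-all`).

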