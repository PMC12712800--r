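Package: scgdelin
Title: Beat-to-Beat Fiducial-Point Delineation in Seismocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates eleven fiducial points (Cs, Ds, Es, Fs, Gs, Ks, Ls,
    Bd, Cd, Dd, Ed) in seismocardiogram (SCG) acceleration signals on a
    beat-to-beat basis.  The signal is band-limited with zero-phase
    Butterworth filters, windowed into fixed-length normalized segments, and
    passed through a one-dimensional dilated U-Net that predicts nineteen
    interval segmentation maps; rule-based postprocessing (max-binarization,
    gap merging, minimum-duration filtering, longest-run restriction) and
    candidate-voting peak/valley extraction convert the maps into per-beat
    fiducial timings.  Includes a seeded synthetic-SCG simulator with exact
    ground-truth annotations, evaluation metrics (positive predictive value
    and sensitivity under a 10-ms matching tolerance, segmentation-map
    center and sample-accuracy scores), and a reproducible
    simulate-train-evaluate pipeline.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
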