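test_that("gap merging and duration pruning follow the 30/15 and 50/20 ms rules", {
  fs <- 1000; n <- 600
  # SM05: 19 ms gap (< 30 ms) merges; a 40 ms run is then pruned (< 50 ms)
  p <- prob_maps(n, fs, rows = list(
    "5" = runs_vec(n, list(c(1, 101), c(121, 301), c(401, 440))),
    "19" = 1 - runs_vec(n, list(c(1, 101), c(121, 301), c(401, 440)))))
  out <- filter_complex_maps(p)
  expect_equal(scgdelin:::runs_of_ones(out$maps[5, ]),
               data.frame(start = 1L, end = 301L))
  # SM17: a 40 ms run survives (threshold 20 ms), a 35 ms gap stays open
  p2 <- prob_maps(n, fs, rows = list(
    "17" = runs_vec(n, list(c(100, 139), c(175, 300))),
    "19" = 1 - runs_vec(n, list(c(100, 139), c(175, 300)))))
  out2 <- filter_complex_maps(p2)
  expect_equal(scgdelin:::runs_of_ones(out2$maps[17, ]),
               data.frame(start = c(100L, 175L), end = c(139L, 300L)))
  # brute-force oracle for the merge rule on random binary vectors
  set.seed(12)
  for (rep in 1:10) {
    x <- as.numeric(runif(400) < 0.4)
    got <- scgdelin:::merge_and_prune(x, gap_ms = 30, min_ms = 50, fs)
    r <- oracle_runs(x)
    if (nrow(r) > 1) for (i in 2:nrow(r)) {
      # oracle: fill gaps < 30 samples
      if (r$start[i] - r$end[i - 1] - 1 < 30)
        x[(r$end[i - 1] + 1):(r$start[i] - 1)] <- 1
    }
    r2 <- oracle_runs(x)
    keep <- r2[r2$end - r2$start + 1 >= 50, , drop = FALSE]
    expected <- runs_vec(400, split(as.matrix(keep), seq_len(nrow(keep))))
    expect_identical(got, expected)
  }
})

test_that("gap-merge plus min-duration filtering is idempotent", {
  fs <- 1000
  set.seed(3)
  for (rep in 1:8) {
    x <- as.numeric(runif(500) < 0.5)
    once <- scgdelin:::merge_and_prune(x, 30, 50, fs)
    twice <- scgdelin:::merge_and_prune(once, 30, 50, fs)
    expect_identical(once, twice)
  }
})

test_that("max-binarization is deterministic with SM05 > SM17 > SM19 priority", {
  fs <- 1000; n <- 300
  m <- matrix(0, 19, n)
  m[5, ] <- 0.4; m[17, ] <- 0.4; m[19, ] <- 0.2   # SM05 wins the tie
  maps <- scgdelin:::new_segmaps(m, fs)
  out <- filter_complex_maps(maps)
  expect_true(all(out$maps[5, ] == 1))
  expect_true(all(out$maps[17, ] == 0))
  m2 <- m; m2[5, ] <- 0.1                          # SM17 wins over SM19
  out2 <- filter_complex_maps(scgdelin:::new_segmaps(m2, fs))
  expect_true(all(out2$maps[17, ] == 1))
  # partition invariant: SM05, SM17, SM19 tile the record
  s <- out$maps[5, ] + out$maps[17, ] + out$maps[19, ]
  expect_true(all(s == 1))
  expect_true(all(out$maps[5, ] * out$maps[17, ] == 0))
})

test_that("interval maps are masked, thresholded at >= 0.5 and one-run-restricted", {
  fs <- 1000; n <- 1000
  sm05 <- runs_vec(n, list(c(100, 500)))
  base <- prob_maps(n, fs, rows = list("5" = sm05, "19" = 1 - sm05))
  fc <- filter_complex_maps(base)
  # two runs inside one systolic run: only the longer survives
  probs <- prob_maps(n, fs, rows = list(
    "5" = sm05, "19" = 1 - sm05,
    "1" = runs_vec(n, list(c(120, 149), c(200, 279), c(600, 700)))))
  out <- filter_interval_maps(probs, fc)
  expect_equal(scgdelin:::runs_of_ones(out$maps[1, ]),
               data.frame(start = 200L, end = 279L))   # longest wins
  # a probability of exactly 0.5 maps to 1
  half <- prob_maps(n, fs, rows = list("5" = sm05, "19" = 1 - sm05))
  half$maps[1, 150:200] <- 0.5
  half$maps[1, 300:340] <- 0.499
  out2 <- filter_interval_maps(half, fc)
  expect_equal(scgdelin:::runs_of_ones(out2$maps[1, ]),
               data.frame(start = 150L, end = 200L))
  # every surviving run lies inside a complex run of the matching type
  expect_true(all(which(out$maps[1, ] == 1) %in% 100:500))
})

test_that("candidate voting returns the modal snapped sample", {
  # synthetic vote sets exercised through the documented tie rules
  s <- clean_synth(duration = 6, fs = 1000, seed = 21, resp = 0)
  maps <- encode_segmaps(s$truth, length(s$clean), 1000)
  fc <- filter_complex_maps(maps)
  fm <- filter_interval_maps(maps, fc)
  det <- extract_fiducial("Fs", fm, s$clean)
  truth_fs <- s$truth$sample[s$truth$label == "Fs"]
  expect_equal(det$sample, truth_fs)
  expect_true(all(det$n_votes == 5L))
  # diastolic label: two candidate maps
  det_cd <- extract_fiducial("Cd", fm, s$clean)
  expect_equal(det_cd$sample,
               s$truth$sample[s$truth$label == "Cd"])
  expect_true(all(det_cd$n_votes == 2L))
  expect_error(extract_fiducial("Xx", fm, s$clean), "unknown")
})

test_that("modal vote picks the most frequent candidate", {
  # direct check of the documented example {200,200,200,198,205} -> 200:
  # five candidate maps whose snapped edges disagree
  fs <- 1000; n <- 400
  x <- rep(0, n)
  for (v in c(198, 200, 205)) x[v] <- -1          # three distinct valleys
  x[c(197, 199, 201, 204, 206)] <- 0.2            # strict neighbours
  sm05 <- runs_vec(n, list(c(150, 320)))
  rows <- list("5" = sm05, "19" = 1 - sm05)
  # Cs starts SM01..SM05; the five run edges snap to the candidate set
  # {200, 200, 200, 198, 198}, so the mode 200 must win with 3 votes
  rows[["1"]] <- runs_vec(n, list(c(200, 260)))
  rows[["2"]] <- runs_vec(n, list(c(200, 270)))
  rows[["3"]] <- runs_vec(n, list(c(201, 280)))
  rows[["4"]] <- runs_vec(n, list(c(198, 290)))
  maps <- prob_maps(n, fs, rows)
  det <- extract_fiducial("Cs", maps, x)
  expect_equal(det$sample, 200L)
  expect_equal(det$n_votes, 3L)
})

test_that("edges without a correct-polarity extremum yield no detection", {
  fs <- 1000; n <- 400
  x <- seq(0, 1, length.out = n)       # strictly increasing: no valleys
  sm05 <- runs_vec(n, list(c(100, 300)))
  rows <- list("5" = sm05, "19" = 1 - sm05)
  for (k in 1:4) rows[[as.character(k)]] <- runs_vec(n, list(c(150, 250)))
  maps <- prob_maps(n, fs, rows)
  maps$maps[5, ] <- sm05
  det <- extract_fiducial("Cs", maps, x)
  expect_equal(nrow(det), 0L)
})

test_that("shoulder detection lands on the constructed plateau end", {
  s <- clean_synth(duration = 10, fs = 1000, seed = 13, resp = 0)
  truth <- s$truth
  for (pair in list(c("Fs", "Es"), c("Cd", "Bd"))) {
    valleys <- truth$sample[truth$label == pair[1]]
    anns <- truth$sample[truth$label == pair[2]]
    for (i in seq_along(valleys)) {
      sh <- detect_shoulder(pair[1], valleys[i], s$clean, 1000)
      expect_false(sh$low_confidence)
      expect_lte(abs(sh$sample - anns[i]) / 1000 * 1000, 5)  # within 5 ms
    }
  }
})

test_that("shoulder degenerate cases follow the declared contracts", {
  fs <- 1000
  x <- seq(10, 0, length.out = 300)    # strictly linear descent
  sh <- detect_shoulder("Fs", 250L, x, fs)
  expect_true(sh$low_confidence)
  expect_equal(sh$sample, 250L - round(0.06 * fs) + 1L)
  # valley at the record start: window cannot fit
  expect_warning(sh0 <- detect_shoulder("Fs", 5L, x, fs), "outside")
  expect_true(is.na(sh0$sample))
})

test_that("full delineation of a clean beat yields all 11 labels", {
  s <- clean_synth(duration = 8, fs = 1000, seed = 2, resp = 0)
  maps <- encode_segmaps(s$truth, length(s$clean), 1000)
  det <- delineate_recording(maps, s$recording, bandlimit_first = FALSE)
  for (b in unique(s$truth$beat))
    expect_setequal(det$label[det$beat == b], fiducial_labels())
})

test_that("empty complex maps give an empty result", {
  fs <- 1000
  rec <- scg_recording(rnorm(2000), fs)
  maps <- prob_maps(2000, fs, rows = list("19" = rep(1, 2000)))
  det <- delineate_recording(maps, rec, bandlimit_first = FALSE)
  expect_equal(nrow(det), 0L)
})

test_that("encode -> filter -> extract recovers every encoded fiducial exactly", {
  # round trip at 0 ms tolerance over noise-free subjects
  encoded <- setdiff(fiducial_labels(), c("Es", "Bd"))
  for (seed in c(4, 29)) {
    p <- sample_subject(default_population(cd_fraction = 0), seed = seed)
    p$noise_sd <- 0
    s <- synthesize(p, 15, fs = 800, seed = seed + 1)
    maps <- encode_segmaps(s$truth, length(s$clean), 800)
    det <- delineate_recording(maps, s$recording, bandlimit_first = FALSE)
    rep_df <- match_fiducials(s$truth, det, 800,
                              match_config(tolerance = 0.5),
                              labels = encoded)
    expect_true(all(rep_df$FP == 0))
    expect_true(all(rep_df$FN == 0))
    pairs <- attr(rep_df, "pairs")
    for (lab in encoded)
      expect_true(all(pairs[[lab]]$error_ms == 0))
  }
})
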