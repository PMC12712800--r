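test_that("PPV and sensitivity follow their defining ratios", {
  expect_equal(ppv(2, 1), 2 / 3)
  expect_equal(sensitivity(2, 1), 2 / 3)
  expect_equal(ppv(5, 0), 1)
  expect_equal(sensitivity(0, 4), 0)
  expect_true(is.na(ppv(0, 0)))
  expect_true(is.na(sensitivity(0, 0)))
  expect_error(ppv(-1, 2))
})

test_that("matching within 10 ms is one-to-one and inclusive", {
  fs <- 5000
  truth <- data.frame(label = "Fs", sample = c(1000L, 2000L))
  pred <- data.frame(label = "Fs", sample = c(1030L, 2100L))
  rep_df <- match_fiducials(truth, pred, fs)
  expect_equal(rep_df$TP, 1L)  # 1030 is 6 ms from 1000; 2100 is 20 ms off
  expect_equal(rep_df$FP, 1L)
  expect_equal(rep_df$FN, 1L)
  # identity
  idm <- match_fiducials(truth, truth, fs)
  expect_equal(idm$TP, 2L)
  expect_equal(idm$FP + idm$FN, 0L)
  # exactly 10 ms counts (inclusive)
  atol <- match_fiducials(data.frame(label = "Fs", sample = 1000L),
                          data.frame(label = "Fs", sample = 1050L), fs)
  expect_equal(atol$TP, 1L)
})

test_that("two predictions near one truth give one TP and one FP", {
  fs <- 1000
  truth <- data.frame(label = "Cs", sample = 500L)
  pred <- data.frame(label = "Cs", sample = c(498L, 503L))
  rep_df <- match_fiducials(truth, pred, fs)
  expect_equal(c(rep_df$TP, rep_df$FP, rep_df$FN), c(1L, 1L, 0L))
})

test_that("greedy matching agrees with exhaustive optimal on small sets", {
  # oracle: maximum-cardinality one-to-one matching by exhaustive search
  brute_tp <- function(truth, pred, tol) {
    recur <- function(ti, used) {
      if (ti > length(truth)) return(0L)
      best <- recur(ti + 1L, used)  # leave truth[ti] unmatched
      for (j in setdiff(seq_along(pred), used))
        if (abs(truth[ti] - pred[j]) <= tol)
          best <- max(best, 1L + recur(ti + 1L, c(used, j)))
      best
    }
    recur(1L, integer(0))
  }
  set.seed(31)
  for (rep in 1:25) {
    # within each set, points sit further apart than twice the tolerance
    # (beats are far apart relative to 10 ms), so a unique best matching
    # exists and greedy must find it
    truth <- cumsum(sample(25:80, sample(1:5, 1)))
    pred <- cumsum(sample(25:80, sample(1:5, 1)))
    m <- scgdelin:::match_points(truth, pred, tol_samples = 10, fs = 1000)
    expect_equal(m$TP, brute_tp(truth, pred, 10))
  }
})

test_that("counts are conserved and TP is monotone in the tolerance", {
  set.seed(8)
  fs <- 1000
  for (rep in 1:10) {
    truth <- data.frame(label = "Ks", sample = sort(sample(1:3000, 12)))
    pred <- data.frame(label = "Ks",
                       sample = sort(sample(1:3000, 10)))
    prev_tp <- Inf
    for (tol in c(50, 20, 10, 5)) {
      r <- match_fiducials(truth, pred, fs,
                           match_config(tolerance = tol))
      expect_equal(r$TP + r$FN, nrow(truth))
      expect_equal(r$TP + r$FP, nrow(pred))
      expect_lte(r$TP, prev_tp)
      prev_tp <- r$TP
    }
  }
})

test_that("metrics are invariant to a uniform time shift", {
  fs <- 1000
  truth <- data.frame(label = "Gs", sample = c(300L, 900L, 1500L))
  pred <- data.frame(label = "Gs", sample = c(303L, 940L, 1502L))
  a <- match_fiducials(truth, pred, fs)
  truth$sample <- truth$sample + 777L
  pred$sample <- pred$sample + 777L
  b <- match_fiducials(truth, pred, fs)
  expect_equal(a[, c("TP", "FP", "FN")], b[, c("TP", "FP", "FN")])
})

test_that("aggregation summarizes across subjects, not pooled beats", {
  one <- data.frame(subject = "A", label = "Fs", ppv = 0.9,
                    sensitivity = 0.8)
  s1 <- aggregate_metrics(one)
  expect_equal(s1$median[s1$metric == "ppv"], 0.9)
  expect_equal(s1$mean[s1$metric == "ppv"], 0.9)
  expect_equal(s1$iqr[s1$metric == "ppv"], 0)
  expect_equal(s1$sd[s1$metric == "ppv"], 0)
  three <- data.frame(subject = c("A", "B", "C"), label = "Fs",
                      ppv = c(0.8, 0.9, 1.0),
                      sensitivity = c(0.7, 0.8, 0.9))
  s3 <- aggregate_metrics(three)
  expect_equal(s3$median[s3$metric == "ppv"], 0.9)
  expect_equal(s3$mean[s3$metric == "ppv"], 0.9)
  # constructed counterexample: pooled-beat PPV differs from the
  # subject-level median (subjects weigh equally regardless of beats)
  counts <- data.frame(subject = c("A", "B"), label = "Fs",
                       TP = c(90, 1), FP = c(10, 9))
  pooled <- sum(counts$TP) / sum(counts$TP + counts$FP)
  per_subj <- ppv(counts$TP, counts$FP)
  expect_false(isTRUE(all.equal(pooled, median(per_subj))))
  # NA (0/0) subjects are excluded, not coerced
  with_na <- data.frame(subject = c("A", "B"), label = "Fs",
                        ppv = c(NA, 0.8), sensitivity = c(0.5, NA))
  sna <- aggregate_metrics(with_na)
  expect_equal(sna$n_subjects[sna$metric == "ppv"], 1L)
  expect_equal(sna$median[sna$metric == "ppv"], 0.8)
  expect_error(aggregate_metrics(with_na[0, ]))
})

test_that("SM-center evaluation matches run midpoints within tolerance", {
  n <- 2000; fs <- 1000
  truth <- prob_maps(n, fs, rows = list(
    "5" = runs_vec(n, list(c(100, 151), c(800, 900)))))
  expect_equal(scgdelin:::run_centers(truth$maps[5, ]), c(125L, 850L))
  identical_eval <- sm_center_eval(truth, truth)
  expect_equal(identical_eval$ppv[5], 1)
  expect_equal(identical_eval$sensitivity[5], 1)
  # a shift beyond tolerance gives FP + FN for that run
  shifted <- prob_maps(n, fs, rows = list(
    "5" = runs_vec(n, list(c(120, 171), c(800, 900)))))
  ev <- sm_center_eval(truth, shifted, match_config(center_tolerance = 10))
  expect_equal(ev$TP[5], 1L)
  expect_equal(ev$FP[5], 1L)
  expect_equal(ev$FN[5], 1L)
})

test_that("sample accuracy is the per-map agreement fraction", {
  n <- 100; fs <- 100
  a <- prob_maps(n, fs, rows = list("1" = runs_vec(n, list(c(1, 50)))))
  expect_equal(unname(sample_accuracy(a, a)["SM01"]), 1)
  b <- prob_maps(n, fs, rows = list("1" = runs_vec(n, list(c(51, 100)))))
  expect_equal(unname(sample_accuracy(a, b)["SM01"]), 0)
  c2 <- prob_maps(n, fs, rows = list("1" = runs_vec(n, list(c(26, 75)))))
  expect_equal(unname(sample_accuracy(a, c2)["SM01"]), 0.5)
  short <- prob_maps(50, fs)
  expect_error(sample_accuracy(a, short), "length")
})
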