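test_that("the built network matches the declared architecture", {
  model <- unet_build(seed = 1)
  inv <- model$inventory
  enc_convs <- inv[grepl("^enc\\d_c1$", inv$layer), ]
  expect_equal(enc_convs$out_ch, c(4L, 8L, 16L, 32L))
  expect_equal(inv$out_ch[inv$layer == "bot_c1"], 64L)
  dec_convs <- inv[grepl("^dec\\d_c1$", inv$layer), ]
  expect_equal(dec_convs$out_ch, c(32L, 16L, 8L, 4L))
  expect_equal(inv$out_ch[inv$layer == "out"], 19L)
  # dilation inventory 1,2,4,8,16,8,4,2,1 across the nine blocks
  dil <- inv$dilation[inv$layer %in% c(sprintf("enc%d_c1", 1:4), "bot_c1",
                                       sprintf("dec%d_c1", 1:4))]
  expect_equal(dil, c(1L, 2L, 4L, 8L, 16L, 8L, 4L, 2L, 1L))
  # 9 blocks x 2 subblocks of conv+bn, 4 upsamplers, 1 output projection
  expect_equal(sum(inv$type == "conv"), 19L)
  expect_equal(sum(inv$type == "bn"), 18L)
  expect_equal(sum(inv$type == "upconv"), 4L)
  expect_gt(model$n_params, 0)
  expect_equal(model$n_params,
               sum(vapply(model$params, length, integer(1))))
})

test_that("forward pass has the contracted shape and range", {
  model <- unet_build(seed = 2)
  seg <- list(samples = runif(1600), fs = 256)
  pred <- unet_predict(model, seg)
  expect_s3_class(pred, "scg_segmaps")
  expect_equal(dim(pred$maps), c(19L, 1600L))
  expect_true(all(is.finite(pred$maps)))
  expect_true(all(pred$maps >= 0 & pred$maps <= 1))
  bad <- list(samples = runif(1000), fs = 100)
  expect_error(unet_predict(model, bad), "divisible by 16")
})

test_that("analytic gradients agree with numerical differentiation", {
  model <- unet_build(seed = 3)
  set.seed(5)
  L <- 64; N <- 2
  x <- array(rnorm(L * N), c(1, L, N))
  y <- array(rbinom(19 * L * N, 1, 0.3), c(19, L, N))
  loss_at <- function() {
    fw <- scgdelin:::unet_forward(model, x, training = TRUE)
    scgdelin:::bce_with_logits(fw$logits, y)
  }
  fw <- scgdelin:::unet_forward(model, x, training = TRUE)
  gz <- (scgdelin:::sigmoid(fw$logits) - y) / length(y)
  grads <- scgdelin:::unet_backward(model, gz, fw$cache)
  eps <- 1e-6
  for (nm in c("enc1_c1_W", "enc3_bn2_g", "bot_c2_W", "up2_W1",
               "dec4_c1_W", "out_W", "dec1_bn1_b")) {
    i <- 1L
    p0 <- model$params[[nm]][i]
    model$params[[nm]][i] <- p0 + eps; lp <- loss_at()
    model$params[[nm]][i] <- p0 - eps; lm <- loss_at()
    model$params[[nm]][i] <- p0
    num <- (lp - lm) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("loss on perfect clipped predictions approaches zero", {
  y <- array(rbinom(19 * 32, 1, 0.4), c(19, 32, 1))
  z <- (2 * y - 1) * 20  # logits saturated toward the targets
  expect_lt(scgdelin:::bce_with_logits(z, y), 1e-6)
})

test_that("a one-epoch run selects epoch 1 and training is seeded", {
  s <- clean_synth(duration = 21, fs = 256, seed = 1)
  segs <- window_recording(s$recording, s$truth)
  va_syn <- clean_synth(duration = 11, fs = 256, seed = 2)
  va_syn$recording$subject_id <- "other"
  va <- window_recording(va_syn$recording, va_syn$truth)
  m1 <- unet_build(seed = 7)
  fit1 <- unet_train(m1, segs, va, train_config(max_epochs = 1, seed = 5))
  expect_equal(fit1$best_epoch, 1L)
  m2 <- unet_build(seed = 7)
  fit2 <- unet_train(m2, segs, va, train_config(max_epochs = 1, seed = 5))
  expect_identical(fit1$train_loss, fit2$train_loss)
  expect_identical(fit1$val_loss, fit2$val_loss)
  expect_error(unet_train(unet_build(seed = 1), segs, list(),
                          train_config(max_epochs = 1)), "validation")
  expect_error(unet_train(unet_build(seed = 1), segs, segs,
                          train_config(max_epochs = 1)), "share subjects")
})

test_that("training reduces the validation loss on a small fixture", {
  set.seed(0)
  tr <- list(); va <- list()
  for (i in 1:4) {
    syn <- clean_synth(duration = 11, fs = 256, seed = 30 + i)
    syn$recording$subject_id <- paste0("T", i)
    tr <- c(tr, window_recording(syn$recording, syn$truth))
  }
  for (i in 1:2) {
    syn <- clean_synth(duration = 11, fs = 256, seed = 40 + i)
    syn$recording$subject_id <- paste0("V", i)
    va <- c(va, window_recording(syn$recording, syn$truth))
  }
  model <- unet_build(seed = 11)
  fit <- unet_train(model, tr, va,
                    train_config(max_epochs = 12, batch_size = 2,
                                 seed = 3))
  expect_equal(fit$val_loss[fit$best_epoch], min(fit$val_loss))
  expect_lte(fit$val_loss[fit$best_epoch], fit$val_loss[1])
})

test_that("checkpoints restore an identical model", {
  model <- unet_build(seed = 9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path, seed = 9L)
  loaded <- load_checkpoint(path)
  seg <- list(samples = runif(320), fs = 32)
  expect_identical(unet_predict(model, seg)$maps,
                   unet_predict(loaded, seg)$maps)
  unlink(path)
})

test_that("overlap merging averages the covering windows", {
  fs <- 100
  rec <- scg_recording(rnorm(18 * fs), fs)
  # recording exactly one window long: merged = single prediction
  one <- scg_recording(rnorm(10 * fs), fs)
  const2 <- function(seg) matrix(0.3, 19, length(seg$samples))
  m_one <- predict_full(const2, one)
  expect_true(all(m_one$maps == 0.3))
  # constant mock stays constant under any overlap pattern
  m_const <- predict_full(const2, rec)
  expect_true(all(abs(m_const$maps - 0.3) < 1e-12))
  # two overlapping windows with values 0.2 and 0.6 average to 0.4
  calls <- new.env(); calls$n <- 0
  stepped <- function(seg) {
    calls$n <- calls$n + 1
    matrix(if (calls$n == 1) 0.2 else 0.6, 19, length(seg$samples))
  }
  rec2 <- scg_recording(rnorm(18 * fs), fs)   # windows at 1 and 801
  m <- predict_full(stepped, rec2)
  expect_true(all(m$maps[, 1:800] == 0.2))
  expect_true(all(m$maps[, 801:1000] == 0.4))  # overlap region
  expect_true(all(m$maps[, 1001:1800] == 0.6))
})
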