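#' U-Net architecture configuration
#'
#' Four encoder levels (4, 8, 16, 32 filters), a 64-filter bottleneck,
#' four decoder levels (32, 16, 8, 4), and a 19-channel sigmoid output.
#' Each level is a block of two subblocks: dilated convolution, batch
#' normalization, LeakyReLU (negative slope 0.01).  Dilation runs
#' 1, 2, 4, 8 down the encoder, 16 in the bottleneck, and 8, 4, 2, 1 up
#' the decoder.  Max pooling (factor 2) downsamples between encoder
#' blocks; stride-2 transposed convolutions upsample between decoder
#' blocks; skip connections concatenate each encoder block's output onto
#' its mirror decoder level.
#'
#' @param encoder_filters,bottleneck_filters,decoder_filters Filter counts.
#' @param out_channels Number of output maps (changing this detaches the
#'   model from the fixed [sm_index()] and is almost never wanted).
#' @param kernel_size Odd convolution kernel length (the padding accounts
#'   for dilation so every layer preserves length).
#' @param leaky_slope Negative slope of the LeakyReLU.
#' @param in_channels Input channels (single-axis SCG: 1).
#' @return A `unet_config` list.
#' @export
unet_config <- function(encoder_filters = c(4L, 8L, 16L, 32L),
                        bottleneck_filters = 64L,
                        decoder_filters = c(32L, 16L, 8L, 4L),
                        out_channels = 19L, kernel_size = 3L,
                        leaky_slope = 0.01, in_channels = 1L) {
  stopifnot(length(encoder_filters) == 4L, length(decoder_filters) == 4L,
            kernel_size %% 2L == 1L, kernel_size >= 1L,
            bottleneck_filters >= 1L, out_channels >= 1L)
  structure(list(encoder_filters = as.integer(encoder_filters),
                 bottleneck_filters = as.integer(bottleneck_filters),
                 decoder_filters = as.integer(decoder_filters),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 leaky_slope = leaky_slope,
                 in_channels = as.integer(in_channels),
                 dilation_schedule = c(1L, 2L, 4L, 8L, 16L, 8L, 4L, 2L, 1L),
                 pool_factor = 2L),
            class = "unet_config")
}

#' Training configuration
#'
#' Adam with learning rate 0.001 and element-wise binary cross-entropy
#' averaged over channels, samples and batch; the epoch with the minimum
#' validation loss is kept.  `gap_ceiling` optionally restricts the
#' selection to epochs whose (validation - training) loss gap does not
#' exceed the ceiling, the operational reading of "no dispersion between
#' the curves"; the default `Inf` is a pure argmin and the gap is always
#' reported.
#'
#' @param learning_rate Adam step size.
#' @param max_epochs Number of epochs (the study default is 100; the
#'   package's test fixtures use far fewer).
#' @param batch_size Segments per minibatch.
#' @param seed Integer seed driving initialization and shuffling.
#' @param gap_ceiling Maximum allowed validation-training gap at the
#'   selected epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 100L,
                         batch_size = 8L, seed = 1L, gap_ceiling = Inf) {
  stopifnot(learning_rate > 0, max_epochs >= 1L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), gap_ceiling = gap_ceiling),
            class = "train_config")
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

add_conv <- function(env, name, cin, cout, k, dil) {
  env$params[[paste0(name, "_W")]] <- he_init(cout, cin * k, cin * k)
  env$params[[paste0(name, "_b")]] <- numeric(cout)
  env$meta[[name]] <- list(type = "conv", k = k, dil = dil,
                           cin = cin, cout = cout)
}

add_bn <- function(env, name, c) {
  env$params[[paste0(name, "_g")]] <- rep(1, c)
  env$params[[paste0(name, "_b")]] <- numeric(c)
  env$rstats[[paste0(name, "_mean")]] <- numeric(c)
  env$rstats[[paste0(name, "_var")]] <- rep(1, c)
  env$meta[[name]] <- list(type = "bn", c = c)
}

add_upconv <- function(env, name, cin, cout) {
  env$params[[paste0(name, "_W0")]] <- he_init(cout, cin, cin)
  env$params[[paste0(name, "_W1")]] <- he_init(cout, cin, cin)
  env$params[[paste0(name, "_b")]] <- numeric(cout)
  env$meta[[name]] <- list(type = "upconv", cin = cin, cout = cout)
}

#' Build the 1-D U-Net
#'
#' Allocates and initializes all parameters (fan-in-scaled normal weights,
#' unit-gain batch norm) and returns the model together with an
#' inspectable layer inventory and the trainable-parameter count.
#'
#' @param config A [unet_config].
#' @param seed Seed for weight initialization.
#' @return A `unet_model` (environment) with fields `params`, `rstats`,
#'   `meta`, `config`, `inventory`, `n_params`.
#' @export
unet_build <- function(config = unet_config(), seed = 1L) {
  env <- new.env(parent = emptyenv())
  env$params <- list(); env$rstats <- list(); env$meta <- list()
  env$config <- config
  k <- config$kernel_size
  ef <- config$encoder_filters; df <- config$decoder_filters
  dil <- config$dilation_schedule
  with_seed(seed, {
    cin <- config$in_channels
    for (i in 1:4) {
      for (s in 1:2) {
        nm <- sprintf("enc%d_c%d", i, s)
        add_conv(env, nm, if (s == 1) cin else ef[i], ef[i], k, dil[i])
        add_bn(env, sprintf("enc%d_bn%d", i, s), ef[i])
      }
      cin <- ef[i]
    }
    for (s in 1:2) {
      add_conv(env, sprintf("bot_c%d", s),
               if (s == 1) ef[4] else config$bottleneck_filters,
               config$bottleneck_filters, k, dil[5])
      add_bn(env, sprintf("bot_bn%d", s), config$bottleneck_filters)
    }
    cprev <- config$bottleneck_filters
    for (j in 1:4) {
      add_upconv(env, sprintf("up%d", j), cprev, df[j])
      skip_c <- ef[5 - j]
      for (s in 1:2) {
        nm <- sprintf("dec%d_c%d", j, s)
        add_conv(env, nm, if (s == 1) df[j] + skip_c else df[j], df[j],
                 k, dil[5 + j])
        add_bn(env, sprintf("dec%d_bn%d", j, s), df[j])
      }
      cprev <- df[j]
    }
    add_conv(env, "out", df[4], config$out_channels, 1L, 1L)
  })
  env$inventory <- do.call(rbind, lapply(names(env$meta), function(nm) {
    m <- env$meta[[nm]]
    data.frame(layer = nm, type = m$type,
               in_ch = m$cin %||% m$c, out_ch = m$cout %||% m$c,
               kernel = if (m$type == "conv") m$k else
                 if (m$type == "upconv") 2L else NA_integer_,
               dilation = if (m$type == "conv") m$dil else NA_integer_)
  }))
  env$n_params <- sum(vapply(env$params, length, integer(1)))
  class(env) <- "unet_model"
  env
}

#' @export
print.unet_model <- function(x, ...) {
  cat("<unet_model>", nrow(x$inventory), "layers,", x$n_params,
      "trainable parameters\n")
  cat("  encoder", paste(x$config$encoder_filters, collapse = "/"),
      "- bottleneck", x$config$bottleneck_filters,
      "- decoder", paste(x$config$decoder_filters, collapse = "/"),
      "- out", x$config$out_channels, "\n")
  invisible(x)
}

check_input_len <- function(L) {
  if (L %% 16L != 0L)
    stop("input length (", L, ") must be divisible by 16 ",
         "(four factor-2 pooling levels)")
}

# --- layer forward/backward helpers -------------------------------------

lrelu_fwd <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
lrelu_bwd <- function(g, x, slope) g * ((x > 0) + slope * (x <= 0))

bn_fwd <- function(model, x, name, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x); C <- d[1]; M <- d[2] * d[3]
  xm <- x; dim(xm) <- c(C, M)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    rm_nm <- paste0(name, "_mean"); rv_nm <- paste0(name, "_var")
    model$rstats[[rm_nm]] <- (1 - momentum) * model$rstats[[rm_nm]] +
      momentum * mu
    model$rstats[[rv_nm]] <- (1 - momentum) * model$rstats[[rv_nm]] +
      momentum * v * M / max(M - 1, 1)
  } else {
    mu <- model$rstats[[paste0(name, "_mean")]]
    v <- model$rstats[[paste0(name, "_var")]]
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * invstd
  y <- model$params[[paste0(name, "_g")]] * xhat +
    model$params[[paste0(name, "_b")]]
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d,
                           name = name, training = training))
}

bn_bwd <- function(model, g, cache, grads) {
  d <- cache$d; C <- d[1]; M <- d[2] * d[3]
  gm <- g; dim(gm) <- c(C, M)
  gamma <- model$params[[paste0(cache$name, "_g")]]
  grads[[paste0(cache$name, "_g")]] <- rowSums(gm * cache$xhat)
  grads[[paste0(cache$name, "_b")]] <- rowSums(gm)
  if (cache$training) {
    dxhat <- gm * gamma
    gx <- (dxhat - rowMeans(dxhat) -
             cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$invstd
  } else {
    gx <- gm * gamma * cache$invstd
  }
  dim(gx) <- d
  list(gx = gx, grads = grads)
}

conv_fwd <- function(model, x, name) {
  m <- model$meta[[name]]
  y <- cpp_conv1d_fwd(x, model$params[[paste0(name, "_W")]],
                      model$params[[paste0(name, "_b")]], m$k, m$dil)
  list(y = y, cache = list(x = x, name = name))
}

conv_bwd <- function(model, g, cache, grads) {
  m <- model$meta[[cache$name]]
  out <- cpp_conv1d_bwd(cache$x, model$params[[paste0(cache$name, "_W")]],
                        g, m$k, m$dil)
  grads[[paste0(cache$name, "_W")]] <- out$gW
  grads[[paste0(cache$name, "_b")]] <- out$gb
  list(gx = out$gx, grads = grads)
}

block_fwd <- function(model, x, prefix, training) {
  slope <- model$config$leaky_slope
  cache <- list()
  for (s in 1:2) {
    cv <- conv_fwd(model, x, sprintf("%s_c%d", prefix, s))
    bn <- bn_fwd(model, cv$y, sprintf("%s_bn%d", prefix, s), training)
    cache[[s]] <- list(conv = cv$cache, bn = bn$cache, pre_act = bn$y)
    x <- lrelu_fwd(bn$y, slope)
  }
  list(y = x, cache = cache)
}

block_bwd <- function(model, g, cache, grads) {
  slope <- model$config$leaky_slope
  for (s in 2:1) {
    g <- lrelu_bwd(g, cache[[s]]$pre_act, slope)
    bb <- bn_bwd(model, g, cache[[s]]$bn, grads); grads <- bb$grads
    cb <- conv_bwd(model, bb$gx, cache[[s]]$conv, grads); grads <- cb$grads
    g <- cb$gx
  }
  list(gx = g, grads = grads)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1] + db[1], da[2], da[3]))
  y[seq_len(da[1]), , ] <- a
  y[da[1] + seq_len(db[1]), , ] <- b
  y
}

# Full forward pass; x has dims (in_channels, L, N).
unet_forward <- function(model, x, training = FALSE) {
  check_input_len(dim(x)[2])
  cache <- list()
  skips <- list()
  h <- x
  for (i in 1:4) {
    blk <- block_fwd(model, h, sprintf("enc%d", i), training)
    skips[[i]] <- blk$y
    pl <- cpp_pool2_fwd(blk$y)
    cache[[sprintf("enc%d", i)]] <- list(block = blk$cache, pool = pl$idx)
    h <- pl$y
  }
  blk <- block_fwd(model, h, "bot", training)
  cache$bot <- blk$cache
  h <- blk$y
  for (j in 1:4) {
    nm <- sprintf("up%d", j)
    u <- cpp_upconv2_fwd(h, model$params[[paste0(nm, "_W0")]],
                         model$params[[paste0(nm, "_W1")]],
                         model$params[[paste0(nm, "_b")]])
    skip <- skips[[5 - j]]
    cat_in <- concat_ch(u, skip)
    blk <- block_fwd(model, cat_in, sprintf("dec%d", j), training)
    cache[[sprintf("dec%d", j)]] <-
      list(up_x = h, up_cout = dim(u)[1], block = blk$cache)
    h <- blk$y
  }
  cv <- conv_fwd(model, h, "out")
  cache$out <- cv$cache
  list(logits = cv$y, cache = cache)
}

unet_backward <- function(model, g, cache) {
  grads <- list()
  cb <- conv_bwd(model, g, cache$out, grads); grads <- cb$grads
  g <- cb$gx
  for (j in 4:1) {
    cc <- cache[[sprintf("dec%d", j)]]
    bb <- block_bwd(model, g, cc$block, grads); grads <- bb$grads
    cu <- cc$up_cout
    g_up <- bb$gx[seq_len(cu), , , drop = FALSE]
    g_skip <- bb$gx[-seq_len(cu), , , drop = FALSE]
    nm <- sprintf("up%d", j)
    ub <- cpp_upconv2_bwd(cc$up_x, model$params[[paste0(nm, "_W0")]],
                          model$params[[paste0(nm, "_W1")]], g_up)
    grads[[paste0(nm, "_W0")]] <- ub$gW0
    grads[[paste0(nm, "_W1")]] <- ub$gW1
    grads[[paste0(nm, "_b")]] <- ub$gb
    g <- ub$gx
    # stash skip gradients to add after the mirrored encoder pool
    attr(g, "skip_grad") <- NULL
    assign(sprintf("gskip%d", 5 - j), g_skip, envir = environment())
  }
  bb <- block_bwd(model, g, cache$bot, grads); grads <- bb$grads
  g <- bb$gx
  for (i in 4:1) {
    cc <- cache[[sprintf("enc%d", i)]]
    g <- cpp_pool2_bwd(g, cc$pool)
    g <- g + get(sprintf("gskip%d", i), envir = environment())
    bb <- block_bwd(model, g, cc$block, grads); grads <- bb$grads
    g <- bb$gx
  }
  grads
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable element-wise binary cross-entropy from logits.
bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Train the U-Net on annotated segments
#'
#' Minimizes element-wise binary cross-entropy between the 19 predicted
#' probability maps and the binary ground-truth maps with Adam, shuffling
#' segments every epoch with a seeded RNG.  After the final epoch the
#' parameters are restored to the selected (lowest-validation-loss) epoch.
#'
#' @param model A [unet_build()] model (modified in place and returned).
#' @param train_segments,val_segments Lists of `scg_segment`s carrying
#'   `sm_truth`; train and validation must be subject-disjoint.
#' @param config A [train_config].
#' @param verbose Print one line per epoch.
#' @return A `unet_train_result`: `model`, `train_loss`, `val_loss`,
#'   `best_epoch`, `gap` (val - train at best epoch).
#' @export
unet_train <- function(model, train_segments, val_segments,
                       config = train_config(), verbose = FALSE) {
  if (!length(val_segments))
    stop("validation set is empty; epoch selection is undefined")
  stopifnot(length(train_segments) >= 1L)
  ids <- function(segs) unique(vapply(segs, function(s)
    s$origin$subject_id, character(1)))
  if (length(intersect(ids(train_segments), ids(val_segments))))
    stop("training and validation segments share subjects")
  get_xy <- function(seg) {
    L <- length(seg$samples)
    check_input_len(L)
    list(x = seg$samples, y = seg$sm_truth$maps)
  }
  tr <- lapply(train_segments, get_xy)
  va <- lapply(val_segments, get_xy)
  L <- length(tr[[1]]$x)
  make_batch <- function(data, idx) {
    x <- array(0, c(1, L, length(idx)))
    y <- array(0, c(model$config$out_channels, L, length(idx)))
    for (q in seq_along(idx)) {
      x[1, , q] <- data[[idx[q]]]$x
      y[, , q] <- data[[idx[q]]]$y
    }
    list(x = x, y = y)
  }
  eval_loss <- function(data) {
    tot <- 0
    idx <- seq_along(data)
    for (chunk in split(idx, ceiling(idx / config$batch_size))) {
      b <- make_batch(data, chunk)
      fw <- unet_forward(model, b$x, training = FALSE)
      tot <- tot + bce_with_logits(fw$logits, b$y) * length(chunk)
    }
    tot / length(data)
  }
  opt <- list(m = list(), v = list(), t = 0)
  adam_step <- function(grads) {
    opt$t <<- opt$t + 1
    lr <- config$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (nm in names(grads)) {
      g <- grads[[nm]]
      if (is.null(opt$m[[nm]])) {
        opt$m[[nm]] <<- g * 0; opt$v[[nm]] <<- g * 0
      }
      opt$m[[nm]] <<- b1 * opt$m[[nm]] + (1 - b1) * g
      opt$v[[nm]] <<- b2 * opt$v[[nm]] + (1 - b2) * g^2
      mhat <- opt$m[[nm]] / (1 - b1^opt$t)
      vhat <- opt$v[[nm]] / (1 - b2^opt$t)
      model$params[[nm]] <- model$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  train_loss <- numeric(config$max_epochs)
  val_loss <- numeric(config$max_epochs)
  best <- list(epoch = NA_integer_, loss = Inf, params = NULL,
               rstats = NULL)
  with_seed(config$seed, {
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample(length(tr))
      ep_loss <- 0
      for (chunk in split(ord, ceiling(seq_along(ord) /
                                         config$batch_size))) {
        b <- make_batch(tr, chunk)
        fw <- unet_forward(model, b$x, training = TRUE)
        loss <- bce_with_logits(fw$logits, b$y)
        ep_loss <- ep_loss + loss * length(chunk)
        gz <- (sigmoid(fw$logits) - b$y) / length(b$y)
        grads <- unet_backward(model, gz, fw$cache)
        adam_step(grads)
      }
      train_loss[ep] <- ep_loss / length(tr)
      val_loss[ep] <- eval_loss(va)
      gap <- val_loss[ep] - train_loss[ep]
      if (val_loss[ep] < best$loss && gap <= config$gap_ceiling) {
        best <- list(epoch = ep, loss = val_loss[ep],
                     params = model$params, rstats = model$rstats)
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                        train_loss[ep], val_loss[ep]))
    }
  })
  if (is.na(best$epoch))
    stop("no epoch satisfied the validation-gap ceiling")
  model$params <- best$params
  model$rstats <- best$rstats
  structure(list(model = model, train_loss = train_loss,
                 val_loss = val_loss, best_epoch = best$epoch,
                 gap = val_loss[best$epoch] - train_loss[best$epoch]),
            class = "unet_train_result")
}

#' @export
print.unet_train_result <- function(x, ...) {
  cat("<unet_train_result>", length(x$train_loss), "epochs, best epoch",
      x$best_epoch, sprintf("(val loss %.5f)\n", x$val_loss[x$best_epoch]))
  invisible(x)
}

#' Predict the 19 probability maps for one segment
#'
#' @param model A trained `unet_model`.
#' @param segment An `scg_segment` (normalized, length divisible by 16).
#' @return An `scg_segmaps` of per-sample probabilities aligned with the
#'   input.
#' @export
unet_predict <- function(model, segment) {
  x <- array(segment$samples, c(1, length(segment$samples), 1))
  fw <- unet_forward(model, x, training = FALSE)
  probs <- sigmoid(fw$logits[, , 1])
  new_segmaps(probs, segment$fs)
}

#' Predict probability maps over a whole recording
#'
#' Windows the recording (see [window_recording()]), predicts each window
#' and merges overlapping predictions by the arithmetic mean of the
#' probabilities over all windows covering each sample.
#'
#' @param model A trained `unet_model`, or a function
#'   `segment -> 19 x L probability matrix` (useful for mocks and tests).
#' @param recording An [scg_recording] (band-limit it first if the model
#'   was trained on band-limited input).
#' @param config A [preprocess_config].
#' @return A full-length `scg_segmaps` of probabilities.
#' @export
predict_full <- function(model, recording, config = preprocess_config()) {
  segs <- window_recording(recording, truth = NULL, config = config)
  if (!length(segs)) stop("recording shorter than one window")
  n <- length(recording$samples)
  acc <- matrix(0, 19L, n)
  cnt <- numeric(n)
  for (seg in segs) {
    probs <- if (is.function(model)) model(seg)
      else unet_predict(model, seg)$maps
    idx <- seg$origin$start:(seg$origin$start + length(seg$samples) - 1L)
    acc[, idx] <- acc[, idx] + probs
    cnt[idx] <- cnt[idx] + 1
  }
  covered <- cnt > 0
  acc[, covered] <- sweep(acc[, covered, drop = FALSE], 2L,
                          cnt[covered], "/")
  new_segmaps(acc, recording$fs)
}
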