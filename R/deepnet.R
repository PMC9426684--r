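# Deep-learning module: a trainable scaled-down UNet for 4-class
# segmentation wired to the channel-weighted Dice loss, a small sigmoid-head
# CNN classifier wired to the class-weighted cross-entropy, and a canonical
# ResNet50 architecture audit with exact parameter accounting.

#' UNet configuration
#'
#' The package builds a compact encoder-decoder UNet (two pooling levels)
#' sized for desk-scale experiments; the clinical-scale configuration of the
#' same family (224 x 224 inputs, ~75M parameters) is out of the training
#' scope of this package. Dropout is applied in the first three
#' decoder ("up-sampling") convolutional blocks.
#'
#' @param input_channels cine frames stacked as input channels (default 32).
#' @param base_filters filters of the first encoder block (scaled default 8).
#' @param image_size square input size; must be divisible by 4 (two pooling
#'   levels). Scaled default 64.
#' @param dropout_rate dropout in the first three decoder conv blocks
#'   (default 0.3).
#' @param batch_norm batch normalization after every convolution
#'   (default TRUE).
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(input_channels = 32L, base_filters = 8L,
                        image_size = 64L, dropout_rate = 0.3,
                        batch_norm = TRUE) {
  if (image_size %% 4 != 0) stopf("image_size must be divisible by 4")
  structure(list(input_channels = as.integer(input_channels),
                 base_filters = as.integer(base_filters),
                 image_size = as.integer(image_size),
                 output_channels = 4L,
                 dropout_rate = dropout_rate,
                 batch_norm = isTRUE(batch_norm)),
            class = "unet_config")
}

# conv layer descriptors of the compact UNet: name, kernel, in, out
unet_layer_table <- function(cfg) {
  f <- cfg$base_filters
  data.frame(
    name = paste0("conv", 1:11),
    k = c(rep(3L, 10), 1L),
    cin = c(cfg$input_channels, f, f, 2L * f, 2L * f, 4L * f,
            4L * f, 4L * f, 2L * f, 2L * f, f),
    cout = c(f, f, 2L * f, 2L * f, 4L * f, 4L * f,
             2L * f, 2L * f, f, f, 4L),
    stringsAsFactors = FALSE)
}

#' Build the compact UNet
#'
#' Encoder-decoder with skip connections: two encoder blocks (each two 3x3
#' convolutions, batch norm, ReLU, then 2x2 max pooling), a bottleneck, and
#' two decoder blocks (nearest-neighbour upsampling, convolution, skip
#' concatenation, convolution) with 30% dropout in the first three decoder
#' convolutions; a 1x1 convolution and per-pixel softmax produce the 4
#' normalized output channels (background, myocardium, LV cavity, scar).
#' Weight initialization is seeded (He normal).
#'
#' @param cfg a [unet_config()].
#' @param seed initialization seed.
#' @return Object of class `scar_unet` with `params`, `bn_state`, `cfg` and
#'   `param_count` (list: total, trainable, non_trainable).
#' @export
build_unet <- function(cfg = unet_config(), seed = 0L) {
  lt <- unet_layer_table(cfg)
  params <- list()
  bn_state <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(lt))) {
      init <- nn_init_conv(lt$k[i], lt$cin[i], lt$cout[i])
      params[[paste0(lt$name[i], "_W")]] <- init$W
      params[[paste0(lt$name[i], "_b")]] <- init$b
      if (cfg$batch_norm && i < nrow(lt)) {  # no BN on the output conv
        params[[paste0("bn", i, "_gamma")]] <- rep(1, lt$cout[i])
        params[[paste0("bn", i, "_beta")]] <- rep(0, lt$cout[i])
        bn_state[[paste0("bn", i)]] <- list(mean = rep(0, lt$cout[i]),
                                            var = rep(1, lt$cout[i]))
      }
    }
  })
  n_conv <- sum(lt$k^2 * lt$cin * lt$cout + lt$cout)
  n_bn_train <- if (cfg$batch_norm) 2L * sum(lt$cout[-nrow(lt)]) else 0L
  n_bn_moving <- if (cfg$batch_norm) 2L * sum(lt$cout[-nrow(lt)]) else 0L
  structure(list(kind = "unet", cfg = cfg, params = params,
                 bn_state = bn_state, layer_table = lt,
                 param_count = list(total = n_conv + n_bn_train + n_bn_moving,
                                    trainable = n_conv + n_bn_train,
                                    non_trainable = n_bn_moving)),
            class = "scar_unet")
}

# One conv + (BN) + ReLU step; returns output, caches and updated bn state.
unet_step <- function(model, x, i, training, act = TRUE) {
  lt <- model$layer_table
  p <- model$params
  cv <- nn_conv_fwd(x, p[[paste0(lt$name[i], "_W")]],
                    p[[paste0(lt$name[i], "_b")]], lt$k[i])
  out <- cv$y
  bn_cache <- NULL
  if (model$cfg$batch_norm && i < nrow(lt)) {
    nm <- paste0("bn", i)
    bn <- nn_bn_fwd(out, p[[paste0(nm, "_gamma")]], p[[paste0(nm, "_beta")]],
                    model$bn_state[[nm]], training)
    out <- bn$y; bn_cache <- bn$cache
    model$bn_state[[nm]] <- bn$state
  }
  relu_cache <- NULL
  if (act) {
    r <- nn_relu_fwd(out)
    out <- r$y; relu_cache <- r$cache
  }
  list(y = out, conv_cache = cv$cache, bn_cache = bn_cache,
       relu_cache = relu_cache, model = model)
}

unet_step_bwd <- function(model, dy, i, caches, grads) {
  lt <- model$layer_table
  if (!is.null(caches$relu_cache)) dy <- nn_relu_bwd(dy, caches$relu_cache)
  if (!is.null(caches$bn_cache)) {
    nm <- paste0("bn", i)
    bb <- nn_bn_bwd(dy, model$params[[paste0(nm, "_gamma")]], caches$bn_cache)
    grads[[paste0(nm, "_gamma")]] <- bb$dgamma
    grads[[paste0(nm, "_beta")]] <- bb$dbeta
    dy <- bb$dx
  }
  cb <- nn_conv_bwd(dy, model$params[[paste0(lt$name[i], "_W")]],
                    caches$conv_cache)
  grads[[paste0(lt$name[i], "_W")]] <- cb$dW
  grads[[paste0(lt$name[i], "_b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

#' Forward pass of the compact UNet
#'
#' @param model a `scar_unet` from [build_unet()].
#' @param x input batch, array `(H, W, input_channels, N)` (a single
#'   `(H, W, C)` sample is promoted to a batch of one).
#' @param training logical; enables batch statistics and dropout.
#' @return List with `p` (softmax probabilities `(H, W, 4, N)`), `cache`
#'   (for backprop) and `model` (updated running BN statistics when
#'   training).
#' @export
unet_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  ch <- list()
  s1 <- unet_step(model, x, 1, training); model <- s1$model
  s2 <- unet_step(model, s1$y, 2, training); model <- s2$model
  e1 <- s2$y
  p1 <- nn_maxpool_fwd(e1)
  s3 <- unet_step(model, p1$y, 3, training); model <- s3$model
  s4 <- unet_step(model, s3$y, 4, training); model <- s4$model
  e2 <- s4$y
  p2 <- nn_maxpool_fwd(e2)
  s5 <- unet_step(model, p2$y, 5, training); model <- s5$model
  s6 <- unet_step(model, s5$y, 6, training); model <- s6$model
  u1 <- nn_upsample_fwd(s6$y)
  s7 <- unet_step(model, u1, 7, training); model <- s7$model
  d7 <- nn_dropout_fwd(s7$y, model$cfg$dropout_rate, training)
  k1 <- nn_concat(d7$y, e2)
  s8 <- unet_step(model, k1, 8, training); model <- s8$model
  d8 <- nn_dropout_fwd(s8$y, model$cfg$dropout_rate, training)
  u2 <- nn_upsample_fwd(d8$y)
  s9 <- unet_step(model, u2, 9, training); model <- s9$model
  d9 <- nn_dropout_fwd(s9$y, model$cfg$dropout_rate, training)
  k2 <- nn_concat(d9$y, e1)
  s10 <- unet_step(model, k2, 10, training); model <- s10$model
  s11 <- unet_step(model, s10$y, 11, training, act = FALSE)
  p <- nn_softmax_channels(s11$y)
  cache <- list(steps = list(s1, s2, s3, s4, s5, s6, s7, s8, s9, s10, s11),
                pools = list(p1, p2), drops = list(d7, d8, d9), p = p)
  list(p = p, cache = cache, model = model)
}

# Backward pass from dL/dp; returns flat gradient list over model$params.
unet_backward <- function(model, cache, dp) {
  st <- cache$steps
  grads <- list()
  dz <- nn_softmax_bwd(dp, cache$p)
  b11 <- unet_step_bwd(model, dz, 11, st[[11]], grads); grads <- b11$grads
  b10 <- unet_step_bwd(model, b11$dx, 10, st[[10]], grads); grads <- b10$grads
  f <- model$cfg$base_filters
  da9 <- b10$dx[, , seq_len(f), , drop = FALSE]
  de1_a <- b10$dx[, , f + seq_len(f), , drop = FALSE]
  da9 <- nn_dropout_bwd(da9, cache$drops[[3]]$cache)
  b9 <- unet_step_bwd(model, da9, 9, st[[9]], grads); grads <- b9$grads
  da8 <- nn_upsample_bwd(b9$dx)
  da8 <- nn_dropout_bwd(da8, cache$drops[[2]]$cache)
  b8 <- unet_step_bwd(model, da8, 8, st[[8]], grads); grads <- b8$grads
  da7 <- b8$dx[, , seq_len(2 * f), , drop = FALSE]
  de2_a <- b8$dx[, , 2 * f + seq_len(2 * f), , drop = FALSE]
  da7 <- nn_dropout_bwd(da7, cache$drops[[1]]$cache)
  b7 <- unet_step_bwd(model, da7, 7, st[[7]], grads); grads <- b7$grads
  da6 <- nn_upsample_bwd(b7$dx)
  b6 <- unet_step_bwd(model, da6, 6, st[[6]], grads); grads <- b6$grads
  b5 <- unet_step_bwd(model, b6$dx, 5, st[[5]], grads); grads <- b5$grads
  de2_b <- nn_maxpool_bwd(b5$dx, cache$pools[[2]]$cache)
  b4 <- unet_step_bwd(model, de2_a + de2_b, 4, st[[4]], grads); grads <- b4$grads
  b3 <- unet_step_bwd(model, b4$dx, 3, st[[3]], grads); grads <- b3$grads
  de1_b <- nn_maxpool_bwd(b3$dx, cache$pools[[1]]$cache)
  b2 <- unet_step_bwd(model, de1_a + de1_b, 2, st[[2]], grads); grads <- b2$grads
  b1 <- unet_step_bwd(model, b2$dx, 1, st[[1]], grads); grads <- b1$grads
  grads
}

#' Build a compact CNN classifier with a sigmoid head
#'
#' Two conv-pool blocks, global average pooling and a single fully connected
#' output unit with sigmoid activation — the desk-scale counterpart of the
#' residual classifier, used to exercise the class-weighted cross-entropy
#' training path on phantoms.
#'
#' @param input_channels input channels (cine frames).
#' @param base_filters filters of the first block (default 8).
#' @param image_size square input size divisible by 4.
#' @param batch_norm batch normalization after convolutions.
#' @param seed initialization seed.
#' @return Object of class `scar_cnn` with `params`, `bn_state` and
#'   `param_count`.
#' @export
build_cnn_classifier <- function(input_channels = 32L, base_filters = 8L,
                                 image_size = 64L, batch_norm = TRUE,
                                 seed = 0L) {
  if (image_size %% 4 != 0) stopf("image_size must be divisible by 4")
  f <- as.integer(base_filters)
  params <- list(); bn_state <- list()
  with_seed(seed, {
    i1 <- nn_init_conv(3, input_channels, f)
    i2 <- nn_init_conv(3, f, 2 * f)
    params$conv1_W <- i1$W; params$conv1_b <- i1$b
    params$conv2_W <- i2$W; params$conv2_b <- i2$b
    if (batch_norm) {
      params$bn1_gamma <- rep(1, f); params$bn1_beta <- rep(0, f)
      params$bn2_gamma <- rep(1, 2 * f); params$bn2_beta <- rep(0, 2 * f)
      bn_state$bn1 <- list(mean = rep(0, f), var = rep(1, f))
      bn_state$bn2 <- list(mean = rep(0, 2 * f), var = rep(1, 2 * f))
    }
    params$fc_W <- matrix(stats::rnorm(2 * f, sd = sqrt(1 / (2 * f))), 2 * f, 1)
    params$fc_b <- 0
  })
  n <- sum(vapply(params, length, numeric(1)))
  n_moving <- if (batch_norm) 2L * (f + 2L * f) else 0L
  structure(list(kind = "cnn", params = params, bn_state = bn_state,
                 batch_norm = batch_norm,
                 cfg = list(input_channels = input_channels,
                            base_filters = f, image_size = image_size),
                 param_count = list(total = n + n_moving, trainable = n,
                                    non_trainable = n_moving)),
            class = "scar_cnn")
}

#' Forward pass of the compact classifier
#'
#' @param model a `scar_cnn`.
#' @param x batch array `(H, W, C, N)` or single sample.
#' @param training logical.
#' @return List with `p` (class-1 probabilities, length N), `cache`,
#'   `model`.
#' @export
cnn_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  p <- model$params
  c1 <- nn_conv_fwd(x, p$conv1_W, p$conv1_b, 3)
  h <- c1$y
  bn1c <- NULL
  if (model$batch_norm) {
    bn <- nn_bn_fwd(h, p$bn1_gamma, p$bn1_beta, model$bn_state$bn1, training)
    h <- bn$y; bn1c <- bn$cache; model$bn_state$bn1 <- bn$state
  }
  r1 <- nn_relu_fwd(h)
  pl1 <- nn_maxpool_fwd(r1$y)
  c2 <- nn_conv_fwd(pl1$y, p$conv2_W, p$conv2_b, 3)
  h2 <- c2$y
  bn2c <- NULL
  if (model$batch_norm) {
    bn <- nn_bn_fwd(h2, p$bn2_gamma, p$bn2_beta, model$bn_state$bn2, training)
    h2 <- bn$y; bn2c <- bn$cache; model$bn_state$bn2 <- bn$state
  }
  r2 <- nn_relu_fwd(h2)
  pl2 <- nn_maxpool_fwd(r2$y)
  d <- dim(pl2$y)
  gap <- apply(pl2$y, c(3, 4), mean)  # (C, N)
  z <- drop(t(gap) %*% p$fc_W) + p$fc_b
  prob <- 1 / (1 + exp(-z))
  list(p = prob, cache = list(c1 = c1$cache, bn1 = bn1c, r1 = r1$cache,
                              pl1 = pl1$cache, c2 = c2$cache, bn2 = bn2c,
                              r2 = r2$cache, pl2 = pl2$cache, gap = gap,
                              gap_dim = d, z = z),
       model = model)
}

# Backward from dL/dz (logit gradient, length N).
cnn_backward <- function(model, cache, dz) {
  p <- model$params
  grads <- list()
  grads$fc_W <- cache$gap %*% matrix(dz, ncol = 1)
  grads$fc_b <- sum(dz)
  dgap <- p$fc_W %*% matrix(dz, nrow = 1)  # (C, N)
  d <- cache$gap_dim
  dpool <- array(0, d)
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    dpool[, , c, n] <- dgap[c, n] / (d[1] * d[2])
  }
  dr2 <- nn_maxpool_bwd(dpool, cache$pl2)
  dh2 <- nn_relu_bwd(dr2, cache$r2)
  if (!is.null(cache$bn2)) {
    bb <- nn_bn_bwd(dh2, p$bn2_gamma, cache$bn2)
    grads$bn2_gamma <- bb$dgamma; grads$bn2_beta <- bb$dbeta
    dh2 <- bb$dx
  }
  cb2 <- nn_conv_bwd(dh2, p$conv2_W, cache$c2)
  grads$conv2_W <- cb2$dW; grads$conv2_b <- cb2$db
  dr1 <- nn_maxpool_bwd(cb2$dx, cache$pl1)
  dh1 <- nn_relu_bwd(dr1, cache$r1)
  if (!is.null(cache$bn1)) {
    bb <- nn_bn_bwd(dh1, p$bn1_gamma, cache$bn1)
    grads$bn1_gamma <- bb$dgamma; grads$bn1_beta <- bb$dbeta
    dh1 <- bb$dx
  }
  cb1 <- nn_conv_bwd(dh1, p$conv1_W, cache$c1)
  grads$conv1_W <- cb1$dW; grads$conv1_b <- cb1$db
  grads
}

#' Canonical ResNet50 binary classifier: architecture and parameter audit
#'
#' Builds the layer table of the canonical 50-layer residual classifier with
#' a configurable number of input channels: a 7x7/64 stem convolution, four
#' bottleneck stages of (3, 4, 6, 3) blocks with filter triples
#' (64,64,256), (128,128,512), (256,256,1024), (512,512,2048) and projection
#' shortcuts on each stage's first block, global average pooling and a
#' single fully connected sigmoid output unit. Convolutions carry biases and
#' every convolution is followed by batch normalization whose moving mean
#' and variance are counted as non-trainable parameters. With 32 input
#' channels the audit reports 23,680,705 total and 23,627,585 trainable
#' parameters; only the stem convolution depends on the input channel count
#' (`(c - 3) * 7 * 7 * 64` parameters relative to an RGB stem).
#'
#' @param input_channels input planes of the stem convolution (default 32).
#' @return Object of class `resnet50_spec`: `layers` (data frame with
#'   per-layer parameter counts), `total`, `trainable`, `non_trainable`,
#'   `input_channels`. This is an architecture specification and parameter
#'   audit; training at this scale is outside the package's scope.
#' @examples
#' build_resnet50_classifier(32)$total  # 23680705
#' @export
build_resnet50_classifier <- function(input_channels = 32L) {
  if (input_channels < 1) stopf("input_channels must be >= 1")
  rows <- list()
  add <- function(name, type, params, trainable, non_trainable = 0) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, type = type, params = params,
      trainable = trainable, non_trainable = non_trainable)
  }
  conv <- function(name, k, cin, cout) {
    n <- k * k * cin * cout + cout
    add(name, "conv", n, n)
  }
  bn <- function(name, c) add(name, "batch_norm", 4 * c, 2 * c, 2 * c)

  conv("stem_conv", 7, input_channels, 64)
  bn("stem_bn", 64)
  stages <- list(
    list(name = "conv2", blocks = 3, f = c(64, 64, 256), cin = 64),
    list(name = "conv3", blocks = 4, f = c(128, 128, 512), cin = 256),
    list(name = "conv4", blocks = 6, f = c(256, 256, 1024), cin = 512),
    list(name = "conv5", blocks = 3, f = c(512, 512, 2048), cin = 1024))
  for (st in stages) {
    cin <- st$cin
    for (blk in seq_len(st$blocks)) {
      pre <- sprintf("%s_block%d", st$name, blk)
      if (blk == 1) {
        conv(paste0(pre, "_proj"), 1, cin, st$f[3])
        bn(paste0(pre, "_proj_bn"), st$f[3])
      }
      conv(paste0(pre, "_1"), 1, cin, st$f[1])
      bn(paste0(pre, "_1_bn"), st$f[1])
      conv(paste0(pre, "_2"), 3, st$f[1], st$f[2])
      bn(paste0(pre, "_2_bn"), st$f[2])
      conv(paste0(pre, "_3"), 1, st$f[2], st$f[3])
      bn(paste0(pre, "_3_bn"), st$f[3])
      cin <- st$f[3]
    }
  }
  add("fc", "dense", 2048 + 1, 2048 + 1)
  layers <- do.call(rbind, rows)
  structure(list(layers = layers,
                 total = sum(layers$params),
                 trainable = sum(layers$trainable),
                 non_trainable = sum(layers$non_trainable),
                 input_channels = as.integer(input_channels)),
            class = "resnet50_spec")
}

#' @export
print.resnet50_spec <- function(x, ...) {
  cat(sprintf("ResNet50 classifier spec: %d input channels, %d layers\n",
              x$input_channels, nrow(x$layers)))
  cat(sprintf("  total parameters:     %s\n", format(x$total, big.mark = ",")))
  cat(sprintf("  trainable:            %s\n", format(x$trainable, big.mark = ",")))
  cat(sprintf("  non-trainable (BN):   %s\n", format(x$non_trainable, big.mark = ",")))
  invisible(x)
}

#' Training configuration
#'
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param learning_rate initial learning rate (segmentation default 1e-3;
#'   the classification counterpart conventionally uses 1e-4 with RMSProp).
#' @param decay_rate exponential decay rate per epoch (default 0.1: the
#'   learning rate is multiplied by `exp(-0.1)` each epoch after the warm
#'   period).
#' @param decay_after warm epochs before decay starts (default 5).
#' @param patience early-stopping patience in epochs (default 30); the
#'   weights of the best epoch are restored.
#' @param max_epochs training budget (default 100).
#' @param batch_size samples per gradient step (default 32).
#' @param monitor `"train"` (stop on the training loss, the default) or
#'   `"val"` (requires validation data).
#' @param augment logical; enable rotation + percentile-normalization
#'   augmentation.
#' @param rotation_range_deg augmentation rotation range (default 60,
#'   meaning angles drawn uniformly in +/-60 degrees).
#' @param seed training seed (shuffling, dropout, augmentation).
#' @return Object of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "rmsprop"),
                         learning_rate = 1e-3, decay_rate = 0.1,
                         decay_after = 5L, patience = 30L, max_epochs = 100L,
                         batch_size = 32L, monitor = c("train", "val"),
                         augment = FALSE, rotation_range_deg = 60,
                         seed = 0L) {
  if (patience > max_epochs) stopf("patience must be <= max_epochs")
  structure(list(optimizer = match.arg(optimizer),
                 learning_rate = learning_rate, decay_rate = decay_rate,
                 decay_after = as.integer(decay_after),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 monitor = match.arg(monitor),
                 augment = isTRUE(augment),
                 rotation_range_deg = rotation_range_deg,
                 seed = as.integer(seed)),
            class = "train_config")
}

# learning rate at 1-based epoch e
lr_at_epoch <- function(cfg, epoch) {
  cfg$learning_rate * exp(-cfg$decay_rate * max(0, epoch - cfg$decay_after))
}

#' Rotation and intensity augmentation of a batch
#'
#' Each sample is rotated by an angle drawn uniformly from the configured
#' range (image channels bilinear, mask channels nearest-neighbour, so label
#' values are preserved) and its intensities are clipped at the 1st/99th
#' percentiles and scaled to (0, 1).
#'
#' @param x batch array `(H, W, C, N)` of images.
#' @param y optional mask batch `(H, W, 4, N)` (one-hot), rotated jointly.
#' @param rotation_range_deg rotation half-range in degrees.
#' @return List with `x`, `y` (NULL when not given) and `angles`.
#' @export
augment_batch <- function(x, y = NULL, rotation_range_deg = 60) {
  d <- dim(x); N <- d[4]
  angles <- stats::runif(N, -rotation_range_deg, rotation_range_deg)
  for (n in seq_len(N)) {
    pr <- affine_params(rotation = angles[n])
    for (c in seq_len(d[3])) {
      x[, , c, n] <- apply_affine(matrix(x[, , c, n], d[1], d[2]), pr, "linear")
    }
    q <- stats::quantile(x[, , , n], c(0.01, 0.99), names = FALSE)
    if (q[2] > q[1]) {
      x[, , , n] <- (pmin(pmax(x[, , , n], q[1]), q[2]) - q[1]) / (q[2] - q[1])
    }
    if (!is.null(y)) {
      # rotate hard labels, re-encode one-hot so channels stay normalized
      lab <- matrix(0L, d[1], d[2])
      for (c in 1:4) lab[y[, , c, n] > 0.5] <- c - 1L
      lab <- apply_affine(lab, pr, "nearest")
      for (c in 1:4) y[, , c, n] <- (lab == c - 1L) * 1
    }
  }
  list(x = x, y = y, angles = angles)
}

#' Train a model with the pipeline's weighted losses
#'
#' Mini-batch gradient training with the configured optimizer, the
#' exponential learning-rate schedule (rate multiplied by `exp(-decay_rate)`
#' per epoch after `decay_after` warm epochs) and early stopping that
#' restores the best-epoch weights. Segmentation models (`scar_unet`) train
#' against the channel-weighted Dice loss; classifiers (`scar_cnn`) against
#' the class-weighted cross-entropy whose weights are recomputed from the
#' actual training-label counts (never hard-coded), unless `class_weights`
#' is supplied.
#'
#' @param model a `scar_unet` or `scar_cnn`.
#' @param data for UNet: `list(x = (H,W,C,N) array, y = (H,W,4,N) one-hot)`;
#'   for the classifier: `list(x = ..., labels = 0/1 vector)`.
#' @param loss `"weighted_dice"` or `"weighted_cross_entropy"` (must match
#'   the model head).
#' @param cfg a [train_config()].
#' @param dice_w a [dice_weights()] (UNet loss weights).
#' @param class_weights optional [compute_class_weights()] override.
#' @return List with `model` (best weights restored), `history` (data frame
#'   epoch/loss/lr), `best_epoch`, `stopped_early`.
#' @export
train_model <- function(model, data,
                        loss = c("weighted_dice", "weighted_cross_entropy"),
                        cfg = train_config(), dice_w = dice_weights(),
                        class_weights = NULL) {
  loss <- match.arg(loss)
  is_unet <- inherits(model, "scar_unet")
  if (is_unet && loss != "weighted_dice") {
    stopf("the 4-channel softmax head trains with the weighted Dice loss")
  }
  if (!is_unet && loss != "weighted_cross_entropy") {
    stopf("the sigmoid head trains with the weighted cross-entropy loss")
  }
  x <- data$x
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  N <- dim(x)[4]
  if (N < 1) stopf("empty dataset")
  if (!is_unet) {
    labels <- as.integer(data$labels)
    if (is.null(class_weights)) {
      counts <- c(sum(labels == 0), sum(labels == 1))
      class_weights <- if (all(counts > 0)) compute_class_weights(counts)
                       else compute_class_weights(c(1, 1))
    }
    lambda <- class_weights$lambda
  }
  opt_state <- list()
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  best_loss <- Inf; best_params <- model$params; best_epoch <- 0L
  stopped_early <- FALSE
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- lr_at_epoch(cfg, epoch)
      order_idx <- sample.int(N)
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1, N, by = cfg$batch_size)) {
        idx <- order_idx[start:min(start + cfg$batch_size - 1, N)]
        xb <- x[, , , idx, drop = FALSE]
        if (is_unet) {
          yb <- data$y[, , , idx, drop = FALSE]
          if (cfg$augment) {
            aug <- augment_batch(xb, yb, cfg$rotation_range_deg)
            xb <- aug$x; yb <- aug$y
          }
          fw <- unet_forward(model, xb, training = TRUE)
          model <- fw$model
          ls <- nn_weighted_dice(fw$p, yb, dice_w)
          grads <- unet_backward(model, fw$cache, ls$dp)
          batch_loss <- ls$loss
        } else {
          yb <- labels[idx]
          if (cfg$augment) {
            aug <- augment_batch(xb, NULL, cfg$rotation_range_deg)
            xb <- aug$x
          }
          fw <- cnn_forward(model, xb, training = TRUE)
          model <- fw$model
          batch_loss <- weighted_cross_entropy(yb, fw$p, lambda)
          nb <- length(idx)
          p1 <- pmin(pmax(fw$p, 1e-7), 1 - 1e-7)
          dz <- ifelse(yb == 1, -lambda[2] * (1 - p1), lambda[1] * p1) / nb
          grads <- cnn_backward(model, fw$cache, dz)
        }
        stepped <- nn_opt_step(model$params, grads, opt_state, lr,
                               cfg$optimizer)
        model$params <- stepped$params
        opt_state <- stepped$opt_state
        epoch_loss <- epoch_loss + batch_loss
        n_batches <- n_batches + 1L
      }
      epoch_loss <- epoch_loss / n_batches
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = epoch_loss, lr = lr))
      if (epoch_loss < best_loss) {
        best_loss <- epoch_loss
        best_params <- model$params
        best_epoch <- epoch
      } else if (epoch - best_epoch >= cfg$patience) {
        stopped_early <- TRUE
        break
      }
    }
  })
  model$params <- best_params
  list(model = model, history = history, best_epoch = best_epoch,
       stopped_early = stopped_early)
}
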