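test_that("the residual classifier audit reports the canonical parameter counts", {
  rs <- build_resnet50_classifier(32)
  expect_identical(rs$total, 23680705)
  expect_identical(rs$trainable, 23627585)
  expect_identical(rs$total - rs$trainable, rs$non_trainable)

  # RGB stem + the canonical 1000-way head reproduces the published reference
  # total of the same topology (head swap is exactly 2048*1000+1000 vs 2048+1)
  rs3 <- build_resnet50_classifier(3)
  expect_identical(rs3$total - (2048 + 1) + (2048 * 1000 + 1000), 25636712)

  # only the stem convolution depends on the input channel count
  for (c in c(1, 3, 8, 32)) {
    expect_identical(build_resnet50_classifier(c)$total - rs3$total,
                     (c - 3) * 7 * 7 * 64)
  }
  expect_error(build_resnet50_classifier(0), "input_channels")
})

test_that("the compact UNet parameter count equals the hand-derived layer sum", {
  cfg <- unet_config(input_channels = 8, base_filters = 8, image_size = 32)
  m <- build_unet(cfg, seed = 1)
  f <- 8; cin <- 8
  conv <- function(k, a, b) k * k * a * b + b
  hand <- conv(3, cin, f) + conv(3, f, f) +            # encoder 1
    conv(3, f, 2 * f) + conv(3, 2 * f, 2 * f) +        # encoder 2
    conv(3, 2 * f, 4 * f) + conv(3, 4 * f, 4 * f) +    # bottleneck
    conv(3, 4 * f, 2 * f) + conv(3, 4 * f, 2 * f) +    # decoder 1 (+skip)
    conv(3, 2 * f, f) + conv(3, 2 * f, f) +            # decoder 2 (+skip)
    conv(1, f, 4)                                      # output head
  bn_channels <- f + f + 2 * f + 2 * f + 4 * f + 4 * f + 2 * f + 2 * f + f + f
  expect_identical(m$param_count$trainable, hand + 2L * bn_channels)
  expect_identical(m$param_count$total, hand + 4L * bn_channels)
  expect_identical(sum(vapply(m$params, length, numeric(1))),
                   as.numeric(m$param_count$trainable))
  expect_error(unet_config(image_size = 30), "divisible")
})

test_that("UNet forward produces normalized 4-channel output of the input shape", {
  cfg <- unet_config(input_channels = 3, base_filters = 4, image_size = 16)
  m <- build_unet(cfg, seed = 2)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  out <- unet_forward(m, x)
  expect_identical(dim(out$p), c(16L, 16L, 4L, 2L))
  sums <- apply(out$p, c(1, 2, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(61)
  cfg <- unet_config(input_channels = 2, base_filters = 2, image_size = 8,
                     dropout_rate = 0, batch_norm = TRUE)
  model <- build_unet(cfg, seed = 1)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  lab <- array(sample(0:3, 8 * 8 * 2, TRUE), c(8, 8, 2))
  y <- array(0, c(8, 8, 4, 2))
  for (c in 1:4) y[, , c, ] <- (lab == c - 1) * 1
  w <- dice_weights()
  loss_of <- function(m) {
    fw <- unet_forward(m, x, training = TRUE)
    cinescar:::nn_weighted_dice(fw$p, y, w)$loss
  }
  fw <- unet_forward(model, x, training = TRUE)
  ls <- cinescar:::nn_weighted_dice(fw$p, y, w)
  grads <- cinescar:::unet_backward(model, fw$cache, ls$dp)
  eps <- 1e-5
  for (nm in c("conv1_W", "conv6_W", "conv11_W", "bn4_gamma", "bn9_beta")) {
    for (i in sample(length(grads[[nm]]), 2)) {
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_lt(abs(fd - grads[[nm]][i]) / max(abs(fd) + abs(grads[[nm]][i]), 1e-6),
                1e-4)
    }
  }
})

test_that("the learning-rate schedule decays exponentially after the warm period", {
  cfg <- train_config(learning_rate = 1e-3, decay_rate = 0.1, decay_after = 5)
  lr <- cinescar:::lr_at_epoch
  expect_equal(lr(cfg, 3), 1e-3)
  expect_equal(lr(cfg, 5), 1e-3)
  expect_equal(lr(cfg, 6), 1e-3 * exp(-0.1))
  expect_equal(lr(cfg, 7), 1e-3 * exp(-0.2))
  expect_error(train_config(patience = 40, max_epochs = 30), "patience")
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  set.seed(62)
  X <- array(0, c(16, 16, 2, 4)); Y <- array(0, c(16, 16, 4, 4))
  for (i in 1:4) {
    ph <- generate_cine_phantom(
      phantom_config(image_size = 16, n_frames = 4, cavity_radius_px = 3,
                     myo_thickness_px = 2, scar_present = i <= 2, seed = i))
    for (f in 1:2) X[, , f, i] <- ph$cine$frames[[f]] / 255
    for (c in 1:4) Y[, , c, i] <- (ph$masks[[2]] == c - 1) * 1
  }
  m <- build_unet(unet_config(input_channels = 2, base_filters = 4,
                              image_size = 16), seed = 3)
  cfg <- train_config(learning_rate = 3e-3, decay_rate = 0, max_epochs = 30,
                      patience = 30, batch_size = 4, seed = 5)
  r1 <- train_model(m, list(x = X, y = Y), "weighted_dice", cfg)
  expect_lt(tail(r1$history$loss, 1), r1$history$loss[1])
  r2 <- train_model(m, list(x = X, y = Y), "weighted_dice", cfg)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_error(train_model(m, list(x = X, y = Y), "weighted_cross_entropy"),
               "Dice")
})

test_that("the scaled UNet overfits four phantom pairs to a small Dice loss", {
  losses <- vapply(1:3, function(seed) {
    X <- array(0, c(32, 32, 8, 4)); Y <- array(0, c(32, 32, 4, 4))
    for (i in 1:4) {
      ph <- generate_cine_phantom(
        phantom_config(image_size = 32, n_frames = 8, cavity_radius_px = 6,
                       myo_thickness_px = 4, scar_present = i <= 2,
                       seed = 10 * seed + i))
      for (f in 1:8) X[, , f, i] <- ph$cine$frames[[f]] / 255
      for (c in 1:4) Y[, , c, i] <- (ph$masks[[4]] == c - 1) * 1
    }
    m <- build_unet(unet_config(input_channels = 8, base_filters = 8,
                                image_size = 32), seed = seed)
    res <- train_model(m, list(x = X, y = Y), "weighted_dice",
                       train_config(learning_rate = 5e-3, decay_rate = 0,
                                    max_epochs = 200, patience = 200,
                                    batch_size = 4, seed = seed))
    min(res$history$loss)
  }, numeric(1))
  expect_true(all(losses < 0.2))
})

test_that("the classifier head trains with class weights from its own labels", {
  set.seed(63)
  N <- 10
  labs <- rep(c(1, 0), c(4, 6))
  X <- array(0, c(16, 16, 2, N))
  for (i in 1:N) {
    ph <- generate_cine_phantom(
      phantom_config(image_size = 16, n_frames = 4, cavity_radius_px = 3,
                     myo_thickness_px = 2, scar_present = labs[i] == 1,
                     seed = 50 + i))
    for (f in 1:2) X[, , f, i] <- ph$cine$frames[[f]] / 255
  }
  m <- build_cnn_classifier(input_channels = 2, base_filters = 4,
                            image_size = 16, seed = 1)
  res <- train_model(m, list(x = X, labels = labs), "weighted_cross_entropy",
                     train_config(optimizer = "rmsprop", learning_rate = 1e-3,
                                  decay_rate = 0, max_epochs = 40,
                                  patience = 40, batch_size = 5, seed = 2))
  expect_lt(tail(res$history$loss, 1), res$history$loss[1])
  # Eq.-5-style weights recomputed from the training labels (4 vs 6)
  w <- compute_class_weights(c(6, 4))
  expect_equal(w$lambda, c(10 / 12, 10 / 8))
})

test_that("augmentation preserves label sets and normalizes intensities", {
  set.seed(64)
  x <- array(runif(16 * 16 * 2 * 3, 0, 200), c(16, 16, 2, 3))
  lab <- array(sample(0:3, 16 * 16 * 3, TRUE), c(16, 16, 3))
  y <- array(0, c(16, 16, 4, 3))
  for (c in 1:4) y[, , c, ] <- (lab == c - 1) * 1
  aug <- augment_batch(x, y, rotation_range_deg = 60)
  expect_gte(min(aug$x), 0); expect_lte(max(aug$x), 1)
  sums <- apply(aug$y, c(1, 2, 4), sum)
  expect_true(all(sums == 1))                 # still one-hot after rotation

  # zero rotation range leaves geometry untouched
  aug0 <- augment_batch(x, y, rotation_range_deg = 0)
  expect_identical(aug0$y, y)
})
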