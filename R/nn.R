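# Minimal CNN engine used by the deep-learning module: batched 4D tensors
# (H, W, C, N), im2col convolutions, batch normalization, 2x2 max pooling,
# nearest-neighbour upsampling, dropout, softmax/sigmoid heads, manual
# backpropagation and Adam / RMSProp optimizers. Written for desk-scale
# networks (small images, few filters); correctness is guarded by a
# finite-difference gradient check in the test suite.

nn_pad_half <- function(k) (k - 1L) %/% 2L

# im2col for stride-1 same-padding convolution of one sample (H, W, C):
# rows = output pixels (column-major), cols = k*k offset blocks of C channels.
nn_im2col <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  h <- nn_pad_half(k)
  xp <- array(0, c(H + 2 * h, W + 2 * h, C))
  xp[h + seq_len(H), h + seq_len(W), ] <- x
  out <- matrix(0, H * W, k * k * C)
  o <- 0L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    blk <- xp[di + seq_len(H), dj + seq_len(W), , drop = FALSE]
    out[, o * C + seq_len(C)] <- matrix(blk, H * W, C)
    o <- o + 1L
  }
  out
}

nn_col2im <- function(dcol, H, W, C, k) {
  h <- nn_pad_half(k)
  dxp <- array(0, c(H + 2 * h, W + 2 * h, C))
  o <- 0L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    blk <- array(dcol[, o * C + seq_len(C)], c(H, W, C))
    dxp[di + seq_len(H), dj + seq_len(W), ] <-
      dxp[di + seq_len(H), dj + seq_len(W), , drop = FALSE] + blk
    o <- o + 1L
  }
  dxp[h + seq_len(H), h + seq_len(W), , drop = FALSE]
}

# Convolution over a batch. W: (k*k*Cin) x F matrix, b: length-F.
nn_conv_fwd <- function(x, W, b, k) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[4]
  f <- length(b)
  y <- array(0, c(H, Wd, f, N))
  cols <- vector("list", N)
  for (n in seq_len(N)) {
    col <- nn_im2col(array(x[, , , n], d[1:3]), k)
    cols[[n]] <- col
    y[, , , n] <- array(col %*% W + rep(b, each = H * Wd), c(H, Wd, f))
  }
  list(y = y, cache = list(cols = cols, dim_in = d, k = k))
}

nn_conv_bwd <- function(dy, W, cache) {
  d <- cache$dim_in; H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  k <- cache$k
  f <- ncol(W)
  dW <- matrix(0, nrow(W), f); db <- numeric(f)
  dx <- array(0, d)
  for (n in seq_len(N)) {
    dyn <- matrix(dy[, , , n], H * Wd, f)
    dW <- dW + crossprod(cache$cols[[n]], dyn)
    db <- db + colSums(dyn)
    dx[, , , n] <- nn_col2im(dyn %*% t(W), H, Wd, C, k)
  }
  list(dx = dx, dW = dW, db = db)
}

# Spatial batch normalization over (H, W, N) per channel.
nn_bn_fwd <- function(x, gamma, beta, state, training, momentum = 0.9,
                      eps = 1e-5) {
  d <- dim(x); C <- d[3]
  y <- array(0, d)
  xhat <- array(0, d)
  mu <- numeric(C); va <- numeric(C)
  for (c in seq_len(C)) {
    xc <- x[, , c, , drop = FALSE]
    if (training) {
      mu[c] <- mean(xc)
      va[c] <- mean((xc - mu[c])^2)
    } else {
      mu[c] <- state$mean[c]; va[c] <- state$var[c]
    }
    xh <- (xc - mu[c]) / sqrt(va[c] + eps)
    xhat[, , c, ] <- xh
    y[, , c, ] <- gamma[c] * xh + beta[c]
  }
  if (training) {
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  }
  list(y = y, cache = list(xhat = xhat, var = va, eps = eps), state = state)
}

nn_bn_bwd <- function(dy, gamma, cache) {
  d <- dim(dy); C <- d[3]
  dx <- array(0, d)
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dyc <- dy[, , c, , drop = FALSE]
    xh <- cache$xhat[, , c, , drop = FALSE]
    dgamma[c] <- sum(dyc * xh)
    dbeta[c] <- sum(dyc)
    m <- length(dyc)
    dx[, , c, ] <- gamma[c] / sqrt(cache$var[c] + cache$eps) *
      (dyc - mean(dyc) - xh * mean(dyc * xh))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

nn_relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
nn_relu_bwd <- function(dy, cache) dy * cache

nn_maxpool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  oi <- seq(1, H, 2); ei <- seq(2, H, 2)
  oj <- seq(1, W, 2); ej <- seq(2, W, 2)
  a <- x[oi, oj, , , drop = FALSE]; b <- x[ei, oj, , , drop = FALSE]
  cc <- x[oi, ej, , , drop = FALSE]; dd <- x[ei, ej, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  sa <- a == m; sb <- b == m & !sa; sc <- cc == m & !sa & !sb
  sd_ <- !sa & !sb & !sc
  list(y = m, cache = list(sa = sa, sb = sb, sc = sc, sd = sd_, dim_in = d))
}

nn_maxpool_bwd <- function(dy, cache) {
  d <- cache$dim_in
  dx <- array(0, d)
  oi <- seq(1, d[1], 2); ei <- seq(2, d[1], 2)
  oj <- seq(1, d[2], 2); ej <- seq(2, d[2], 2)
  dx[oi, oj, , ] <- dy * cache$sa
  dx[ei, oj, , ] <- dy * cache$sb
  dx[oi, ej, , ] <- dy * cache$sc
  dx[ei, ej, , ] <- dy * cache$sd
  dx
}

nn_upsample_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  oi <- seq(1, 2 * d[1], 2); ei <- oi + 1
  oj <- seq(1, 2 * d[2], 2); ej <- oj + 1
  y[oi, oj, , ] <- x; y[ei, oj, , ] <- x
  y[oi, ej, , ] <- x; y[ei, ej, , ] <- x
  y
}

nn_upsample_bwd <- function(dy) {
  d <- dim(dy)
  oi <- seq(1, d[1], 2); ei <- oi + 1
  oj <- seq(1, d[2], 2); ej <- oj + 1
  dy[oi, oj, , , drop = FALSE] + dy[ei, oj, , , drop = FALSE] +
    dy[oi, ej, , , drop = FALSE] + dy[ei, ej, , , drop = FALSE]
}

nn_dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(y = x * mask, cache = mask)
}

nn_dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

nn_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

nn_softmax_channels <- function(z) {
  d <- dim(z); C <- d[3]
  mx <- z[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1]) mx <- pmax(mx, z[, , c, , drop = FALSE])
  e <- array(0, d)
  for (c in seq_len(C)) e[, , c, ] <- exp(z[, , c, , drop = FALSE] - mx)
  s <- e[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1]) s <- s + e[, , c, , drop = FALSE]
  p <- array(0, d)
  for (c in seq_len(C)) p[, , c, ] <- e[, , c, , drop = FALSE] / s
  p
}

# dL/dz for a softmax given dL/dp.
nn_softmax_bwd <- function(dp, p) {
  d <- dim(p); C <- d[3]
  inner <- p[, , 1, , drop = FALSE] * dp[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1]) {
    inner <- inner + p[, , c, , drop = FALSE] * dp[, , c, , drop = FALSE]
  }
  dz <- array(0, d)
  for (c in seq_len(C)) {
    dz[, , c, ] <- p[, , c, , drop = FALSE] *
      (dp[, , c, , drop = FALSE] - inner)
  }
  dz
}

# Mean (over batch) weighted Dice loss of softmax output p vs one-hot y,
# and its gradient dL/dp.
nn_weighted_dice <- function(p, y, w) {
  d <- dim(p); N <- d[4]
  loss <- 0
  dp <- array(0, d)
  for (n in seq_len(N)) {
    for (c in 1:4) {
      yc <- y[, , c, n]; pc <- p[, , c, n]
      A <- sum(yc * pc); B <- sum(yc) + sum(pc)
      dsc <- (2 * A + w$epsilon) / (B + w$epsilon)
      loss <- loss + w$beta[c] * (1 - dsc) / N
      dp[, , c, n] <- -w$beta[c] / N *
        (2 * yc * (B + w$epsilon) - (2 * A + w$epsilon)) / (B + w$epsilon)^2
    }
  }
  list(loss = loss, dp = dp)
}

nn_init_conv <- function(k, cin, cout, gain = 2) {
  W <- matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(gain / (k * k * cin))),
              k * k * cin, cout)
  list(W = W, b = numeric(cout))
}

nn_zeros_like <- function(params) lapply(params, function(p) p * 0)

# One optimizer step over flat named parameter/gradient lists.
nn_opt_step <- function(params, grads, opt_state, lr, optimizer = "adam",
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(opt_state$m)) {
    opt_state$m <- nn_zeros_like(params)
    opt_state$v <- nn_zeros_like(params)
    opt_state$t <- 0
  }
  opt_state$t <- opt_state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (optimizer == "adam") {
      opt_state$m[[nm]] <- beta1 * opt_state$m[[nm]] + (1 - beta1) * g
      opt_state$v[[nm]] <- beta2 * opt_state$v[[nm]] + (1 - beta2) * g^2
      mhat <- opt_state$m[[nm]] / (1 - beta1^opt_state$t)
      vhat <- opt_state$v[[nm]] / (1 - beta2^opt_state$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    } else {  # rmsprop
      opt_state$v[[nm]] <- 0.9 * opt_state$v[[nm]] + 0.1 * g^2
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(opt_state$v[[nm]]) + eps)
    }
  }
  list(params = params, opt_state = opt_state)
}
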