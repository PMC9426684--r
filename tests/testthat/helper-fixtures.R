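# Shared fixtures, built in code and cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, fast phantom: 32 px, 12 frames
tiny_phantom_config <- function(seed = 1L, scar = FALSE, ...) {
  phantom_config(image_size = 32L, n_frames = 12L, cavity_radius_px = 6,
                 myo_thickness_px = 4, scar_present = scar, seed = seed, ...)
}

tiny_phantom <- function(seed = 1L, scar = FALSE, ...) {
  cached(sprintf("tiny-%d-%d", seed, scar), {
    generate_cine_phantom(tiny_phantom_config(seed, scar, ...))
  })
}

default_phantom <- function(seed = 1L, scar = FALSE) {
  cached(sprintf("default-%d-%d", seed, scar), {
    generate_cine_phantom(phantom_config(scar_present = scar, seed = seed))
  })
}

# mean radius of myocardium boundary pixels inside an angular sector,
# per frame -- an oracle for contraction measured from masks alone
sector_mean_radius <- function(mask, sector_deg) {
  n <- nrow(mask)
  ctr <- (n - 1) / 2
  idx <- which(mask == 1L | mask == 3L, arr.ind = TRUE)
  dr <- idx[, 1] - 1 - ctr; dc <- idx[, 2] - 1 - ctr
  theta <- atan2(dc, dr) * 180 / pi
  insec <- ((theta - sector_deg[1]) %% 360) < sector_deg[2]
  if (!any(insec)) return(NA_real_)
  mean(sqrt(dr[insec]^2 + dc[insec]^2))
}

# total absolute excursion of the sector mean radius over the cycle
sector_excursion <- function(masks, sector_deg) {
  r <- vapply(masks, sector_mean_radius, numeric(1), sector_deg = sector_deg)
  sum(abs(r - r[1]))
}

# independent GLRLM oracle: explicit run scanning with plain loops,
# sharing no code with the package implementation
oracle_glrlm <- function(levels, mask, angle) {
  nr <- nrow(levels); nc <- ncol(levels)
  step <- switch(as.character(angle),
                 "0" = c(0, 1), "90" = c(1, 0),
                 "45" = c(-1, 1), "135" = c(1, 1))
  starts <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    pi_ <- i - step[1]; pj <- j - step[2]
    if (pi_ < 1 || pi_ > nr || pj < 1 || pj > nc) {
      starts[[length(starts) + 1]] <- c(i, j)
    }
  }
  runs <- list()
  for (s in starts) {
    i <- s[1]; j <- s[2]
    cur_g <- NA; cur_l <- 0
    while (i >= 1 && i <= nr && j >= 1 && j <= nc) {
      inmask <- mask[i, j] > 0
      g <- levels[i, j]
      if (inmask && !is.na(cur_g) && g == cur_g) {
        cur_l <- cur_l + 1
      } else {
        if (cur_l > 0) runs[[length(runs) + 1]] <- c(cur_g, cur_l)
        if (inmask) { cur_g <- g; cur_l <- 1 } else { cur_g <- NA; cur_l <- 0 }
      }
      i <- i + step[1]; j <- j + step[2]
    }
    if (cur_l > 0) runs[[length(runs) + 1]] <- c(cur_g, cur_l)
  }
  rm_ <- do.call(rbind, runs)
  nz <- nrow(rm_)
  rg <- tapply(rep(1, nz), rm_[, 1], sum)
  rl <- tapply(rep(1, nz), rm_[, 2], sum)
  p <- as.numeric(table(rm_[, 1], rm_[, 2])) / nz
  p <- p[p > 0]
  c(gln = sum(rg^2) / nz, rln = sum(rl^2) / nz, rlnn = sum(rl^2) / nz^2,
    run_entropy = -sum(p * log2(p)))
}

# smooth, textured test image for optical flow (superposed Gaussians)
textured_image <- function(n = 64, seed = 1) {
  set.seed(seed)
  img <- matrix(0, n, n)
  for (b in 1:25) {
    cx <- runif(1, 8, n - 8); cy <- runif(1, 8, n - 8)
    amp <- runif(1, 30, 90); sig <- runif(1, 2, 4)
    img <- img + amp * outer(seq_len(n), seq_len(n), function(i, j)
      exp(-((i - cx)^2 + (j - cy)^2) / (2 * sig^2)))
  }
  img
}

# subpixel translation by Fourier-free bilinear sampling of the same field
translate_image <- function(img, dr, dc) {
  apply_affine(img, affine_params(translation = c(dr, dc)), "linear")
}
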