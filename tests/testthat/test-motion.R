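test_that("flow is zero for identical frames and undefined on flat images", {
  img <- textured_image(48, seed = 1)
  f0 <- lucas_kanade_flow(img, img)
  expect_true(all(f0$vx == 0) && all(f0$vy == 0))

  flat <- matrix(7, 32, 32)
  ff <- lucas_kanade_flow(flat, flat + 0)
  expect_false(any(ff$confident))
  expect_true(all(ff$vx == 0))
  expect_error(lucas_kanade_flow(img, img[1:10, 1:10]), "dimensions")
})

test_that("a one-pixel translation is recovered by the flow", {
  n <- 64; ctr <- (n - 1) / 2
  blob <- function(dx) 100 * outer(0:(n - 1), 0:(n - 1), function(i, j)
    exp(-((i - ctr - dx)^2 + (j - ctr)^2) / (2 * 6^2)))
  fl <- lucas_kanade_flow(blob(0), blob(1))
  sel <- fl$confident & blob(0) > 10
  expect_gt(sum(sel), 100)
  expect_lt(abs(median(fl$vx[sel]) - 1), 0.2)
  expect_lt(abs(median(fl$vy[sel])), 0.1)
})

test_that("rigid translation of a textured scene is recovered with subpixel accuracy", {
  img <- textured_image(64, seed = 3)
  for (shift in list(c(1, 0), c(0, -1.5), c(1.2, 0.8))) {
    moved <- translate_image(img, shift[1], shift[2])
    fl <- lucas_kanade_flow(img, moved)
    inner <- matrix(FALSE, 64, 64); inner[9:56, 9:56] <- TRUE
    sel <- fl$confident & inner
    err <- sqrt((fl$vx[sel] - shift[1])^2 + (fl$vy[sel] - shift[2])^2)
    expect_lt(median(err), 0.3)
  }
})

test_that("displacement magnitude follows r = v k dt and both magnitude conventions", {
  f <- list(vx = matrix(3, 4, 4), vy = matrix(4, 4, 4))
  d <- displacement_magnitude(f, dt_ms = 1, k = 1)
  expect_equal(d$v[1, 1], 5)
  expect_equal(d$r[1, 1], 5)
  expect_equal(displacement_magnitude(f, 1, 1, magnitude = "sum")$v[1, 1], 7)

  zero <- list(vx = matrix(0, 3, 3), vy = matrix(0, 3, 3))
  expect_true(all(displacement_magnitude(zero, 30, 3)$r == 0))
  expect_error(displacement_magnitude(f, dt_ms = 0), "dt_ms")

  # linear scaling across a dt x k grid
  for (dt in c(10, 25)) for (k in 1:3) {
    expect_equal(displacement_magnitude(f, dt, k)$r[1, 1], 5 * k * dt)
  }
})

test_that("frame-pair enumeration yields the canonical counts", {
  expect_equal(nrow(enumerate_frame_pairs(32, 3)), 11)
  expect_equal(unname(enumerate_frame_pairs(2, 1)), cbind(0L, 1L),
               ignore_attr = TRUE)
  p73 <- enumerate_frame_pairs(7, 3)
  expect_equal(nrow(p73), 2)
  expect_equal(unname(p73[, 1]), c(0L, 3L))
  expect_equal(unname(p73[, 2]), c(3L, 6L))
  # last pair of the 32/3 enumeration is clipped to the final frame
  p <- enumerate_frame_pairs(32, 3)
  expect_equal(unname(p[11, ]), c(30L, 31L))
  expect_error(enumerate_frame_pairs(1, 3), "n_frames")
})

test_that("flow PCA projects deterministically and orders variance", {
  set.seed(31)
  maps <- lapply(1:30, function(i) matrix(rnorm(64, sd = 10 / i), 8, 8))
  proj <- fit_flow_pca(maps, n_components = 5)
  expect_true(all(diff(proj$sdev) <= 1e-9))       # non-increasing variance

  v <- flow_feature_vector(maps[1:3], proj)
  expect_length(v, 15)
  expect_match(names(v)[1], "flow_pc_01_1")
  # identical maps give identical sub-vectors
  v2 <- flow_feature_vector(list(maps[[4]], maps[[4]]), proj)
  expect_equal(unname(v2[1:5]), unname(v2[6:10]))
  expect_error(flow_feature_vector(maps[1:2], structure(list(), class = "x")),
               "flow_pca")

  # full-rank projection is invertible
  full <- fit_flow_pca(maps, n_components = 29)
  sc <- flow_feature_vector(maps[1], full)
  recon <- as.vector(full$rotation %*% sc) + full$center
  expect_equal(recon, as.vector(maps[[1]]), tolerance = 1e-8)
})

test_that("area-change series follows the canonical pair enumeration", {
  ph <- default_phantom(seed = 1)
  s <- area_change_series(ph$masks, ph$cine$trigger_times_ms, k = 3)
  expect_length(s$values, 11)
  expect_false(any(s$flagged))

  const <- rep(list(matrix(1L, 6, 6)), 10)
  s0 <- area_change_series(const, seq(0, 270, by = 30), k = 3)
  expect_true(all(s0$values == 0))

  # A decreasing by 10 px^2 per frame, dt = 1 ms
  masks <- lapply(0:9, function(i) {
    m <- matrix(0L, 20, 20); m[seq_len(200 - 10 * i)] <- 1L; m
  })
  s1 <- area_change_series(masks, 0:9, k = 3)
  expect_true(all(abs(s1$values + 10) < 1e-12))

  nomyo <- const; nomyo[[4]] <- matrix(0L, 6, 6)
  s2 <- area_change_series(nomyo, seq(0, 270, by = 30), k = 3)
  expect_true(any(s2$flagged))
  expect_true(all(is.na(s2$values[s2$flagged])))
})

test_that("scar sectors move less than remote myocardium across seeded phantoms", {
  set.seed(33)
  diffs <- vapply(1:20, function(i) {
    sector <- c(-45, 90)
    cfg <- tiny_phantom_config(seed = 100 + i, scar = TRUE,
                               scar_sector_deg = sector,
                               scar_contraction_factor = 0.35)
    ph <- generate_cine_phantom(cfg)
    pairs <- enumerate_frame_pairs(length(ph$cine$frames), 3)
    scar_disp <- 0; remote_disp <- 0
    for (p in seq_len(nrow(pairs))) {
      i0 <- pairs[p, 1] + 1; j0 <- pairs[p, 2] + 1
      fl <- lucas_kanade_flow(ph$cine$frames[[i0]], ph$cine$frames[[j0]])
      r <- displacement_magnitude(fl, dt_ms = 1, k = 1)$r
      m <- ph$masks[[i0]]
      scar_px <- m == 3L
      remote_px <- m == 1L
      if (any(scar_px) && any(remote_px)) {
        scar_disp <- scar_disp + mean(r[scar_px])
        remote_disp <- remote_disp + mean(r[remote_px])
      }
    }
    remote_disp - scar_disp
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.9)       # one-sided: scar moves less
  expect_gt(mean(diffs), 0)
})
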