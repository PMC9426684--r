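test_that("in-plane area resampling preserves constants and conserves intensity", {
  img <- outer(1:40, 1:40, function(i, j) 50 + 20 * sin(i / 6) * cos(j / 9))
  same <- resample_inplane(img, NULL, spacing_mm = 1.9, target_mm = 1.9)
  expect_lt(max(abs(same$image - img)), 1e-6)

  const <- resample_inplane(matrix(7, 30, 30), NULL, 1.3, 1.9)
  expect_lt(max(abs(const$image - 7)), 1e-9)

  # integrated intensity conserved when the extents divide evenly
  rs <- resample_inplane(img, NULL, spacing_mm = 1, target_mm = 2)
  expect_lt(abs(sum(rs$image) * 4 - sum(img)) / sum(img), 0.005)
  expect_error(resample_inplane(img, NULL, 1, target_mm = 0), "> 0")

  # nearest-neighbour masks keep their label set
  msk <- matrix(sample(0:3, 40 * 40, TRUE), 40, 40)
  rs2 <- resample_inplane(img, msk, spacing_mm = 1.4, target_mm = 1.9)
  expect_true(all(unique(as.vector(rs2$mask)) %in% 0:3))
  expect_identical(dim(rs2$mask), dim(rs2$image))
})

test_that("percentile normalization spans the level range and flags degeneracy", {
  img <- matrix(seq(0, 100, length.out = 100), 10, 10)
  mk <- matrix(1, 10, 10)
  nq <- normalize_intensity(img, mk)
  expect_identical(range(nq$levels), c(0L, 255L))
  expect_false(nq$degenerate)

  flat <- normalize_intensity(matrix(4, 5, 5), matrix(1, 5, 5))
  expect_true(flat$degenerate)
  expect_true(all(flat$levels == 0L))

  # invariant to positive affine rescaling of the intensities
  nq2 <- normalize_intensity(3.7 * img + 11, mk)
  expect_identical(nq$levels, nq2$levels)
  expect_error(normalize_intensity(img, matrix(0, 10, 10)), "empty")
})

test_that("shape features hit their analytic limits", {
  disk <- outer(1:61, 1:61, function(i, j) (i - 31)^2 + (j - 31)^2 <= 20^2) * 1
  sh <- shape2d_features(disk)
  expect_gt(sh["sphericity"], 0.95); expect_lte(sh["sphericity"], 1)
  expect_lt(abs(sh["major_axis_length"] / sh["minor_axis_length"] - 1), 0.02)

  rect <- matrix(0, 60, 60); rect[11:20, 11:50] <- 1
  shr <- shape2d_features(rect)
  expect_lt(abs(shr["major_axis_length"] / shr["minor_axis_length"] - 4), 0.2)
  expect_lt(abs(shr["maximum_diameter"] - sqrt(10^2 + 40^2)), 1.5)

  single <- matrix(0, 9, 9); single[5, 5] <- 1
  shs <- shape2d_features(single)
  expect_gt(shs["perimeter"], 0)
  expect_true(is.finite(shs["sphericity"]))
  expect_error(shape2d_features(matrix(0, 4, 4)), "empty")
})

test_that("shape features are translation- and 90-degree-rotation-invariant", {
  m <- matrix(0, 80, 80); m[21:30, 21:60] <- 1
  a <- shape2d_features(m)
  shifted <- matrix(0, 80, 80); shifted[41:50, 11:50] <- 1
  expect_equal(shape2d_features(shifted), a, tolerance = 1e-9)
  rotated <- t(m)
  b <- shape2d_features(rotated)
  expect_equal(unname(b[c("major_axis_length", "minor_axis_length",
                          "maximum_diameter", "perimeter", "sphericity")]),
               unname(a[c("major_axis_length", "minor_axis_length",
                          "maximum_diameter", "perimeter", "sphericity")]),
               tolerance = 1e-9)
})

test_that("first-order features match closed forms and the percentile oracle", {
  fo <- firstorder_features(matrix(3, 10, 10), matrix(1, 10, 10),
                            pixel_area_mm2 = 3.61)
  expect_equal(unname(fo["energy"]), 900)
  expect_equal(unname(fo["total_energy"]), 3249)
  expect_equal(unname(fo["mean"]), 3)
  expect_equal(unname(fo["range"]), 0)
  expect_equal(unname(fo["rms"]), 3)

  vals <- matrix(1:100, 10, 10)
  fo2 <- firstorder_features(vals, matrix(1, 10, 10))
  expect_equal(unname(fo2["median"]), 50.5)
  expect_equal(unname(fo2["p90"]), unname(quantile(1:100, 0.9, type = 7)))
  expect_equal(unname(fo2["p10"]), unname(quantile(1:100, 0.1, type = 7)))

  # mask locality: only masked values matter
  half <- matrix(0, 10, 10); half[, 1:5] <- 1
  fo3 <- firstorder_features(vals, half)
  fo4 <- firstorder_features(ifelse(half > 0, vals, 999), half)
  expect_equal(fo3, fo4)
})

test_that("GLRLM features match hand enumeration and the brute-force oracle", {
  row3 <- matrix(c(5, 5, 5), 1, 3)
  r <- glrlm_features(row3, matrix(1, 1, 3), angles = 0)
  expect_equal(unname(r$features["gln"]), 1)
  expect_equal(unname(r$features["rln"]), 1)
  expect_equal(unname(r$features["run_entropy"]), 0)

  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  r2 <- glrlm_features(cb, matrix(1, 4, 4), angles = 0)
  expect_equal(unname(r2$features["gln"]), 8)   # (8^2 + 8^2) / 16

  set.seed(41)
  lv <- matrix(sample(0:4, 15 * 15, TRUE), 15, 15)
  mk <- matrix(rbinom(225, 1, 0.8), 15, 15)
  for (ang in c(0, 45, 90, 135)) {
    mine <- glrlm_features(lv, mk, angles = ang)$features
    orc <- oracle_glrlm(lv, mk, ang)
    expect_equal(unname(mine), unname(orc[names(mine)]), tolerance = 1e-6)
  }
  expect_error(glrlm_features(lv, matrix(0, 15, 15)), "empty")
})

test_that("GLRLM runs cover every masked pixel exactly once per direction", {
  set.seed(42)
  for (i in 1:5) {
    lv <- matrix(sample(0:3, 12 * 12, TRUE), 12, 12)
    mk <- matrix(rbinom(144, 1, runif(1, 0.4, 0.95)), 12, 12)
    if (!any(mk > 0)) next
    res <- glrlm_features(lv, mk)
    expect_true(all(res$per_angle$pixels_covered == sum(mk > 0)))
  }
})

test_that("ED, ES and the middle frame are located by cavity area", {
  ph <- default_phantom(seed = 4)
  sel <- select_frames_ed_es_mid(ph$masks)
  areas <- sel$cavity_areas
  expect_equal(sel$i_ed, which.max(areas))
  expect_equal(sel$i_es, which.min(areas))
  expect_false(sel$ambiguous)

  # floor rule on the 0-based index path
  fake <- function(a) {
    m <- matrix(0L, 8, 8); m[seq_len(a)] <- 2L; m
  }
  masks <- lapply(c(12, 11, 10, 9, 8, 7, 6, 5, 4, 3, 2, 1), fake)
  s2 <- select_frames_ed_es_mid(masks)   # ED index 1 (0-based 0), ES index 12 (0-based 11)
  expect_equal(s2$i_ed, 1); expect_equal(s2$i_es, 12)
  expect_equal(s2$i_mid, floor((0 + 11) / 2) + 1)  # rounds toward ED

  amb <- select_frames_ed_es_mid(rep(list(fake(5)), 4))
  expect_true(amb$ambiguous)
  expect_equal(amb$i_ed, 1)
})

test_that("redundancy filter keeps one representative per correlated group", {
  set.seed(43)
  n <- 200
  a <- rnorm(n)
  tbl <- data.frame(col_a = a, col_b = rnorm(n), col_c = a + rnorm(n, sd = 0.01),
                    col_dup = a, col_const = rep(1, n))
  sel <- redundancy_filter(tbl, r_threshold = 0.9)
  expect_true("col_a" %in% sel$kept_names)
  expect_false(any(c("col_c", "col_dup") %in% sel$kept_names))
  expect_true(all(sel$dropped_redundant$partner == "col_a"))
  expect_gt(min(abs(sel$dropped_redundant$r)), 0.99)
  expect_identical(sel$dropped_constant, "col_const")

  # mutually independent columns all survive
  ind <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  expect_length(redundancy_filter(ind)$kept_names, 6)
  expect_error(redundancy_filter(tbl[1:2, ]), ">= 3 rows")
})

test_that("no kept pair exceeds the correlation threshold after filtering", {
  set.seed(44)
  X <- matrix(rnorm(150 * 8), 150, 8)
  X <- cbind(X, X[, 1] * 0.99 + rnorm(150, sd = 0.05),
             X[, 2] + rnorm(150, sd = 0.01))
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  sel <- redundancy_filter(X, r_threshold = 0.9)
  kept <- X[, sel$kept_names, drop = FALSE]
  cors <- cor(kept); diag(cors) <- 0
  expect_lt(max(abs(cors)), 0.9)
})

test_that("significance filter keeps label-linked features and drops noise", {
  set.seed(45)
  n <- 100
  labels <- rep(c(0, 1), each = n / 2)
  tbl <- data.frame(signal = labels + rnorm(n, sd = 0.01),
                    noise = rnorm(n),
                    flat = rep(2, n))
  sel <- significance_filter(tbl, labels, alpha = 0.001)
  expect_true("signal" %in% sel$kept_names)
  expect_false("noise" %in% sel$kept_names)
  expect_identical(sel$dropped_constant, "flat")
  expect_lt(sel$p_values["signal"], 1e-10)
  expect_error(significance_filter(tbl, rep(1, n)), "both classes")
})

test_that("the full radiomics vector is bit-stable across runs", {
  ph <- tiny_phantom(seed = 11, scar = TRUE)
  v1 <- extract_radiomics(ph$cine$frames, ph$masks, 1.9)
  v2 <- extract_radiomics(ph$cine$frames, ph$masks, 1.9)
  expect_identical(v1, v2)
  expect_length(v1, 54)
  expect_true(all(c("ed_shape_sphericity", "es_fo_energy", "mid_glrlm_gln")
                  %in% names(v1)))
})
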