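test_that("phantom returns the requested number of frames and masks", {
  ph <- default_phantom(seed = 1)
  expect_length(ph$cine$frames, 32)
  expect_length(ph$masks, 32)
  expect_true(all(diff(ph$cine$trigger_times_ms) > 0))
  expect_true(all(vapply(ph$masks, function(m) all(m %in% 0:3), logical(1))))
})

test_that("the same seed reproduces the phantom bit for bit", {
  a <- generate_cine_phantom(tiny_phantom_config(seed = 9, scar = TRUE))
  b <- generate_cine_phantom(tiny_phantom_config(seed = 9, scar = TRUE))
  expect_identical(a$cine$frames, b$cine$frames)
  expect_identical(a$masks, b$masks)
})

test_that("invalid geometry is rejected", {
  expect_error(phantom_config(image_size = 32, cavity_radius_px = 12,
                              myo_thickness_px = 6), "geometry")
  expect_error(phantom_config(n_frames = 1), "n_frames")
  expect_error(phantom_config(scar_contraction_factor = 1), "scar_contraction_factor")
})

test_that("the cardiac cycle closes: cavity area returns to baseline", {
  ph <- default_phantom(seed = 2)
  areas <- vapply(ph$masks, function(m) sum(m == 2L), numeric(1))
  expect_lt(abs(areas[32] - areas[1]) / areas[1], 0.05)
  # and mid-cycle contraction is substantial
  expect_lt(min(areas), 0.75 * areas[1])
})

test_that("myocardium intensities separate from background beyond the noise", {
  cfg <- phantom_config(seed = 3)
  ph <- generate_cine_phantom(cfg)
  f <- ph$cine$frames[[1]]; m <- ph$masks[[1]]
  expect_gt(mean(f[m == 1L]) - mean(f[m == 0L]), 3 * cfg$noise_sd)
})

test_that("reduced scar contraction shrinks sector boundary displacement monotonically", {
  sector <- c(-45, 90)
  exc <- vapply(c(0.2, 0.5, 0.8), function(scf) {
    cfg <- tiny_phantom_config(seed = 5, scar = TRUE,
                               scar_contraction_factor = scf,
                               scar_sector_deg = sector, noise_sd = 0)
    sector_excursion(generate_cine_phantom(cfg)$masks, sector)
  }, numeric(1))
  healthy <- sector_excursion(
    generate_cine_phantom(tiny_phantom_config(seed = 5, scar = FALSE,
                                              noise_sd = 0))$masks, sector)
  expect_true(all(diff(exc) > 0))   # monotone in the contraction factor
  expect_lt(exc[1], healthy)        # scar sector moves less than healthy tissue
})

test_that("identity-misaligned LGE mask matches the chosen cine phase exactly", {
  cfg <- tiny_phantom_config(seed = 4, scar = TRUE,
                             lge_misalignment = affine_params())
  ph <- generate_cine_phantom(cfg)
  lge <- generate_lge_from_phantom(ph$cine, ph$masks, cfg)
  expect_identical(lge$true_mask, ph$masks[[cfg$lge_phase]])
  # LGE trigger time falls strictly between two cine trigger times
  tt <- ph$cine$trigger_times_ms
  expect_true(lge$trigger_time_ms > tt[cfg$lge_phase] &&
                lge$trigger_time_ms < tt[cfg$lge_phase + 1])
  expect_equal(match_frame_by_trigger_time(ph$cine, lge$trigger_time_ms),
               cfg$lge_phase)
})

test_that("healthy LGE has no scar label and scar is hyperintense when present", {
  cfg <- tiny_phantom_config(seed = 6, scar = FALSE)
  ph <- generate_cine_phantom(cfg)
  lge <- generate_lge_from_phantom(ph$cine, ph$masks, cfg)
  expect_false(any(lge$true_mask == 3L))

  cfg2 <- tiny_phantom_config(seed = 6, scar = TRUE,
                              lge_misalignment = affine_params())
  ph2 <- generate_cine_phantom(cfg2)
  lge2 <- generate_lge_from_phantom(ph2$cine, ph2$masks, cfg2)
  expect_gt(mean(lge2$image[lge2$true_mask == 3L]),
            mean(lge2$image[lge2$true_mask == 1L]) + 0.5 * cfg2$scar_intensity_delta)
})

test_that("pure translation of the LGE shifts the myocardium centroid accordingly", {
  cfg <- tiny_phantom_config(seed = 7, scar = FALSE,
                             lge_misalignment = affine_params(translation = c(5, -3)))
  ph <- generate_cine_phantom(cfg)
  lge <- generate_lge_from_phantom(ph$cine, ph$masks, cfg)
  centroid <- function(m) colMeans(which(m == 1L, arr.ind = TRUE))
  shift <- centroid(lge$true_mask) - centroid(ph$masks[[cfg$lge_phase]])
  expect_lt(abs(shift[1] - 5), 0.5)
  expect_lt(abs(shift[2] + 3), 0.5)
})

test_that("cohort generation respects counts, labels and seeding", {
  tmpl <- tiny_phantom_config()
  ch <- generate_cohort(0, 5, tmpl, seed = 3)
  expect_length(ch$studies, 5)
  expect_identical(ch$labels, rep(0L, 5))

  ch2 <- generate_cohort(3, 2, tmpl, seed = 3)
  expect_identical(sum(ch2$labels == 1L), 3L)
  expect_identical(vapply(ch2$studies, `[[`, integer(1), "label"), ch2$labels)

  ch3 <- generate_cohort(3, 2, tmpl, seed = 3)
  expect_identical(ch2$studies[[1]]$cine$frames, ch3$studies[[1]]$cine$frames)
  expect_identical(ch2$studies[[5]]$config$lge_misalignment,
                   ch3$studies[[5]]$config$lge_misalignment)
})

test_that("studies round-trip through the on-disk container", {
  ch <- generate_cohort(1, 0, tiny_phantom_config(), seed = 8)
  dir <- file.path(tempdir(), "study-roundtrip")
  write_study(ch$studies[[1]], dir)
  back <- read_study(dir)
  expect_equal(back$cine$frames, ch$studies[[1]]$cine$frames, tolerance = 1e-6)
  expect_identical(back$masks, ch$studies[[1]]$masks)
  expect_equal(back$label, 1)
  expect_equal(back$lge$true_misalignment$translation,
               ch$studies[[1]]$lge$true_misalignment$translation)
  unlink(dir, recursive = TRUE)
})
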