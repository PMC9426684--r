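# Synthetic cine/LGE phantom: a contracting annular myocardium around an LV
# cavity, with an optional hypokinetic scar sector, known segmentation masks
# and a known affine misalignment between the cine and LGE acquisitions.

#' Phantom configuration
#'
#' Parameters of the synthetic short-axis study generator. The phantom is an
#' annulus (myocardium) around a disk (LV cavity) that contracts and relaxes
#' radially over one cardiac cycle following `(1 - cos(2*pi*f/n_frames))/2`,
#' so the cycle closes (frame 0 and the final frame nearly coincide). When a
#' scar is present, contraction inside the scar sector is multiplied by
#' `scar_contraction_factor`, emulating the reduced regional wall motion of an
#' infarct. A fixed intensity texture is attached to material coordinates so
#' tissue motion is visible to optical flow.
#'
#' @param image_size pixels per side (square frames).
#' @param n_frames frames per cardiac cycle (default 32, >= 2).
#' @param pixel_spacing_mm in-plane pixel spacing (default 1.9 mm).
#' @param frame_interval_ms trigger-time spacing between frames (default 30).
#' @param cavity_radius_px end-diastolic endocardial radius.
#' @param myo_thickness_px end-diastolic myocardial wall thickness.
#' @param contraction_amplitude peak radial contraction as a fraction of the
#'   resting radius (default 0.25).
#' @param scar_present logical; render a hypokinetic scar sector.
#' @param scar_sector_deg `(start, extent)` of the scar sector in degrees.
#' @param scar_contraction_factor multiplier in `[0, 1)` applied to the local
#'   contraction inside the scar sector (smaller = more akinetic).
#' @param scar_intensity_delta additive hyperintensity of scar in the LGE
#'   image (intensity units).
#' @param noise_sd additive Gaussian noise SD (intensities clipped at 0).
#' @param lge_misalignment [affine_params()] applied to the LGE acquisition
#'   relative to the cine coordinate system (the ground-truth misalignment the
#'   registration step must undo).
#' @param lge_phase 1-based cine phase rendered as the LGE image; default
#'   `round(0.3 * n_frames)`.
#' @param seed integer seed; all phantom randomness flows from it.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64L, n_frames = 32L,
                           pixel_spacing_mm = 1.9, frame_interval_ms = 30,
                           cavity_radius_px = 10, myo_thickness_px = 6,
                           contraction_amplitude = 0.25,
                           scar_present = FALSE,
                           scar_sector_deg = c(-45, 90),
                           scar_contraction_factor = 0.4,
                           scar_intensity_delta = 80,
                           noise_sd = 4,
                           lge_misalignment = affine_params(
                             translation = c(3, -2), rotation = 4,
                             scale = c(1.02, 0.98), shear = 0.02),
                           lge_phase = NULL,
                           seed = 1L) {
  if (n_frames < 2) stopf("n_frames must be >= 2")
  if (scar_contraction_factor < 0 || scar_contraction_factor >= 1) {
    stopf("scar_contraction_factor must be in [0, 1)")
  }
  if (cavity_radius_px + myo_thickness_px >= image_size / 2) {
    stopf("geometry too large: cavity_radius_px + myo_thickness_px must be < image_size / 2")
  }
  if (contraction_amplitude < 0 || contraction_amplitude >= 1) {
    stopf("contraction_amplitude must be in [0, 1)")
  }
  structure(list(image_size = as.integer(image_size),
                 n_frames = as.integer(n_frames),
                 pixel_spacing_mm = pixel_spacing_mm,
                 frame_interval_ms = frame_interval_ms,
                 cavity_radius_px = cavity_radius_px,
                 myo_thickness_px = myo_thickness_px,
                 contraction_amplitude = contraction_amplitude,
                 scar_present = isTRUE(scar_present),
                 scar_sector_deg = scar_sector_deg,
                 scar_contraction_factor = scar_contraction_factor,
                 scar_intensity_delta = scar_intensity_delta,
                 noise_sd = noise_sd,
                 lge_misalignment = lge_misalignment,
                 lge_phase = lge_phase %||% max(1L, round(0.3 * n_frames)),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Cine sequence container
#'
#' Ordered 2D frames of one slice location with strictly increasing trigger
#' times and a common shape.
#'
#' @param frames list of equal-shape numeric matrices.
#' @param trigger_times_ms numeric, strictly increasing, one per frame.
#' @param pixel_spacing_mm length-2 in-plane spacing (mm).
#' @param subject_id,slice_id identifiers.
#' @return Object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, trigger_times_ms, pixel_spacing_mm,
                          subject_id = "subj", slice_id = "slice") {
  if (length(frames) != length(trigger_times_ms)) {
    stopf("one trigger time per frame required")
  }
  if (length(trigger_times_ms) > 1 && any(diff(trigger_times_ms) <= 0)) {
    stopf("trigger times must be strictly increasing")
  }
  dims <- lapply(frames, dim)
  if (length(unique(dims)) > 1) stopf("all frames must have the same shape")
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  structure(list(frames = frames, trigger_times_ms = trigger_times_ms,
                 pixel_spacing_mm = pixel_spacing_mm,
                 subject_id = subject_id, slice_id = slice_id),
            class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  cat(sprintf("cine_sequence: %d frames of %dx%d, TT %.0f..%.0f ms, spacing %.2f mm (%s/%s)\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              min(x$trigger_times_ms), max(x$trigger_times_ms),
              x$pixel_spacing_mm[1], x$subject_id, x$slice_id))
  invisible(x)
}

# Per-pixel geometry shared by all frames of one phantom: polar coordinates
# about the image centre and scar-sector membership.
phantom_grid <- function(config) {
  n <- config$image_size
  ctr <- (n - 1) / 2
  rows <- matrix(rep(seq_len(n) - 1, times = n), n, n) - ctr
  cols <- matrix(rep(seq_len(n) - 1, each = n), n, n) - ctr
  r <- sqrt(rows^2 + cols^2)
  theta <- atan2(cols, rows) * 180 / pi  # degrees in (-180, 180]
  start <- config$scar_sector_deg[1]
  extent <- config$scar_sector_deg[2]
  in_sector <- ((theta - start) %% 360) < extent
  grid <- list(r = r, theta = theta, in_sector = in_sector)
  grid$bg <- background_anatomy(config, grid)
  grid
}

# Cardiac-cycle contraction envelope for 0-based frame f: 0 at frame 0,
# peaking mid-cycle, closing at frame n (so frame n-1 is nearly closed).
contraction_envelope <- function(f, n_frames) {
  (1 - cos(2 * pi * f / n_frames)) / 2
}

# Fixed intensity texture in material coordinates (rho = resting radius,
# theta), so tissue displacement advects the texture. Incommensurate angular
# frequencies avoid rotational symmetry.
myo_texture <- function(rho, theta_deg) {
  th <- theta_deg * pi / 180
  # spatial periods of 5-7 px: coarse enough to survive bilinear resampling
  12 * sin(0.9 * rho + 3 * th) + 12 * cos(1.3 * rho - 2 * th) +
    8 * sin(th + 0.7)
}

# Static background anatomy shared by cine and LGE renders: a smooth
# intensity gradient (coil-profile-like) and a bright vessel cross-section,
# which anchor rotation during registration.
background_anatomy <- function(config, grid) {
  n <- config$image_size
  ctr <- (n - 1) / 2
  rows <- matrix(rep(seq_len(n) - 1, times = n), n, n)
  cols <- matrix(rep(seq_len(n) - 1, each = n), n, n)
  grad <- 0.25 * (rows - ctr) + 0.1 * (cols - ctr)
  vr <- 0.72 * n / 2
  va <- 150 * pi / 180
  vrow <- ctr + vr * cos(va); vcol <- ctr + vr * sin(va)
  blob <- 70 * exp(-((rows - vrow)^2 + (cols - vcol)^2) / (2 * 2.5^2))
  grad + blob
}

# Render geometry of one frame: local contraction, label mask and noiseless
# intensity. Intensity tiers: background 40, myocardium 110 + texture,
# cavity (blood pool, bright in cine) 190.
render_phantom_frame <- function(config, grid, f, lge = FALSE) {
  bg <- grid$bg
  g <- contraction_envelope(f, config$n_frames)
  s <- rep(1, length(grid$r))
  if (config$scar_present) {
    s[grid$in_sector] <- config$scar_contraction_factor
  }
  ctf <- 1 - config$contraction_amplitude * s * g
  endo <- config$cavity_radius_px * ctf
  epi <- (config$cavity_radius_px + config$myo_thickness_px) * ctf
  rvec <- as.vector(grid$r)
  lab <- integer(length(rvec))
  lab[rvec < endo] <- 2L
  myo <- rvec >= endo & rvec < epi
  lab[myo] <- 1L
  if (config$scar_present) {
    lab[myo & as.vector(grid$in_sector)] <- 3L
  }
  rho <- rvec / ctf
  if (lge) {
    img <- 40 + as.vector(bg)
    img[lab == 2L] <- 150
    img[lab == 1L | lab == 3L] <- 70 + myo_texture(rho, as.vector(grid$theta))[lab == 1L | lab == 3L]
    img[lab == 3L] <- img[lab == 3L] + config$scar_intensity_delta
  } else {
    img <- 40 + as.vector(bg)
    img[lab == 2L] <- 190
    sel <- lab == 1L | lab == 3L
    img[sel] <- 110 + myo_texture(rho, as.vector(grid$theta))[sel]
  }
  n <- config$image_size
  list(image = matrix(img, n, n), mask = matrix(lab, n, n))
}

#' Generate a synthetic cine sequence with per-frame ground-truth masks
#'
#' Renders `n_frames` frames of a cyclically contracting annular myocardium
#' around an LV cavity, with additive Gaussian noise (clipped at zero). When
#' `config$scar_present`, pixels in the scar sector contract with their
#' amplitude multiplied by `scar_contraction_factor`. Per-frame label masks
#' use 0 = background, 1 = myocardium, 2 = LV cavity, 3 = scar.
#'
#' @param config a [phantom_config()].
#' @return List with `cine` (a [cine_sequence()]) and `masks` (list of
#'   integer matrices, one per frame).
#' @export
generate_cine_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) stopf("config must be a phantom_config")
  grid <- phantom_grid(config)
  n <- config$image_size
  frames <- vector("list", config$n_frames)
  masks <- vector("list", config$n_frames)
  with_seed(config$seed, {
    for (f in seq_len(config$n_frames)) {
      fr <- render_phantom_frame(config, grid, f - 1)
      img <- fr$image + matrix(stats::rnorm(n * n, sd = config$noise_sd), n, n)
      frames[[f]] <- pmax(img, 0)
      masks[[f]] <- fr$mask
    }
  })
  tt <- (seq_len(config$n_frames) - 1) * config$frame_interval_ms
  list(cine = cine_sequence(frames, tt, config$pixel_spacing_mm,
                            subject_id = sprintf("phantom-%d", config$seed)),
       masks = masks)
}

#' Generate the LGE image of a phantom study
#'
#' Renders one cardiac phase with LGE contrast (nulled myocardium, bright
#' blood pool, scar hyperintense by `scar_intensity_delta`), applies the
#' configured affine misalignment to the image (bilinear) and to its label
#' mask (nearest-neighbour), and records the applied transform as ground
#' truth. The LGE trigger time is placed 40% of a frame interval after the
#' chosen phase's trigger time, so it falls strictly between two cine trigger
#' times and trigger-time matching is nontrivial.
#'
#' @param cine a [cine_sequence()] from [generate_cine_phantom()].
#' @param masks per-frame mask list from [generate_cine_phantom()].
#' @param config the [phantom_config()] used to generate them.
#' @return Object of class `lge_record` with fields `image`,
#'   `trigger_time_ms`, `true_mask` and `true_misalignment`.
#' @export
generate_lge_from_phantom <- function(cine, masks, config) {
  grid <- phantom_grid(config)
  phase <- config$lge_phase
  fr <- render_phantom_frame(config, grid, phase - 1, lge = TRUE)
  n <- config$image_size
  img <- with_seed(derive_seed(config$seed, "lge"),
                   pmax(fr$image + matrix(stats::rnorm(n * n, sd = config$noise_sd), n, n), 0))
  img <- apply_affine(img, config$lge_misalignment, "linear")
  msk <- apply_affine(fr$mask, config$lge_misalignment, "nearest")
  structure(list(image = img,
                 trigger_time_ms = cine$trigger_times_ms[phase] +
                   0.4 * config$frame_interval_ms,
                 true_mask = msk,
                 true_misalignment = config$lge_misalignment,
                 phase = phase),
            class = "lge_record")
}

#' Generate a cohort of phantom studies
#'
#' Draws `n_scar + n_healthy` studies whose geometric and acquisition
#' parameters are jittered deterministically from `seed` around
#' `config_template`: resting radius and wall thickness, contraction
#' amplitude, scar sector placement/extent/severity, and a random LGE
#' misalignment per study (|translation| <= 5 px, |rotation| <= 8 degrees,
#' scale between 0.95 and 1.05, |shear| <= 0.04).
#'
#' @param n_scar,n_healthy study counts (>= 0).
#' @param config_template a [phantom_config()] supplying defaults.
#' @param seed integer cohort seed.
#' @return List with `studies` (each a list of `config`, `cine`, `masks`,
#'   `lge`, `label`, `id`) and `labels` (0 = healthy, 1 = scar).
#' @export
generate_cohort <- function(n_scar, n_healthy,
                            config_template = phantom_config(), seed = 1L) {
  if (n_scar < 0 || n_healthy < 0) stopf("counts must be >= 0")
  n_total <- n_scar + n_healthy
  labels <- c(rep(1L, n_scar), rep(0L, n_healthy))
  draws <- with_seed(seed, lapply(seq_len(n_total), function(i) {
    list(cavity = config_template$cavity_radius_px + stats::runif(1, -2, 2),
         thick = config_template$myo_thickness_px + stats::runif(1, -1, 1),
         amp = config_template$contraction_amplitude + stats::runif(1, -0.04, 0.04),
         sector_start = stats::runif(1, 0, 360),
         sector_extent = stats::runif(1, 60, 120),
         scar_factor = stats::runif(1, 0.3, 0.55),
         mis = affine_params(translation = stats::runif(2, -5, 5),
                             rotation = stats::runif(1, -8, 8),
                             scale = stats::runif(2, 0.95, 1.05),
                             shear = stats::runif(1, -0.04, 0.04)),
         study_seed = derive_seed(seed, sprintf("study-%d", i)))
  }))
  studies <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    d <- draws[[i]]
    cfg <- phantom_config(
      image_size = config_template$image_size,
      n_frames = config_template$n_frames,
      pixel_spacing_mm = config_template$pixel_spacing_mm,
      frame_interval_ms = config_template$frame_interval_ms,
      cavity_radius_px = d$cavity, myo_thickness_px = d$thick,
      contraction_amplitude = d$amp,
      scar_present = labels[i] == 1L,
      scar_sector_deg = c(d$sector_start, d$sector_extent),
      scar_contraction_factor = d$scar_factor,
      scar_intensity_delta = config_template$scar_intensity_delta,
      noise_sd = config_template$noise_sd,
      lge_misalignment = d$mis,
      seed = d$study_seed)
    ph <- generate_cine_phantom(cfg)
    lge <- generate_lge_from_phantom(ph$cine, ph$masks, cfg)
    studies[[i]] <- list(config = cfg, cine = ph$cine, masks = ph$masks,
                         lge = lge, label = labels[i],
                         id = sprintf("study-%03d", i))
  }
  list(studies = studies, labels = labels)
}
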