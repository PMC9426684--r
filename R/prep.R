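# Ground-truth preparation: trigger-time matching, mutual-information affine
# registration of the LGE image onto its cine frame, fixed-length stacking and
# automated alignment QC.

#' Registration configuration
#'
#' Settings for the mutual-information metric and the (1+1) evolutionary
#' optimizer used by [register_affine_mi()]. The optimizer perturbs the six
#' affine parameters (translation px, rotation degrees, scale and shear in
#' 0.02-unit steps) with an adaptive radius: grown by `growth_factor` on an
#' accepted step, shrunk by `growth_factor^-0.25` on rejection, stopping when
#' the radius falls below `epsilon` or after `max_iterations` candidates.
#'
#' @param histogram_bins joint-histogram bins per axis (>= 8).
#' @param sample_fraction fraction of pixels entering the metric, in (0, 1].
#' @param growth_factor radius growth on acceptance (> 1).
#' @param epsilon radius at which the search is declared converged.
#' @param initial_radius initial perturbation radius in natural units
#'   (1.0 corresponds to 1 px / 1 degree / 0.02 scale-shear steps).
#' @param max_iterations candidate evaluations budget.
#' @param init_grid_px half-range of the coarse translation grid (step 3 px)
#'   searched before the evolutionary refinement to secure the capture
#'   range; 0 disables the initialization.
#' @param seed integer seed for the evolutionary search.
#' @return Object of class `registration_config`.
#' @export
registration_config <- function(histogram_bins = 50, sample_fraction = 1,
                                growth_factor = 1.05, epsilon = 1.5e-6,
                                initial_radius = 1.0, max_iterations = 600,
                                init_grid_px = 12, seed = 0L) {
  if (histogram_bins < 8) stopf("histogram_bins must be >= 8")
  if (max_iterations < 1) stopf("max_iterations must be >= 1")
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stopf("sample_fraction must be in (0, 1]")
  }
  structure(list(histogram_bins = as.integer(histogram_bins),
                 sample_fraction = sample_fraction,
                 growth_factor = growth_factor, epsilon = epsilon,
                 initial_radius = initial_radius,
                 max_iterations = as.integer(max_iterations),
                 init_grid_px = init_grid_px,
                 seed = as.integer(seed)),
            class = "registration_config")
}

#' Match the cine frame closest in trigger time to an LGE image
#'
#' Each cine frame carries a trigger time (TT, ms after the ECG R-wave); the
#' LGE image of the same slice location carries one TT. The frame whose TT is
#' nearest to the LGE TT is selected, so the myocardium is at approximately
#' the same cardiac phase in both images. Ties break toward the earlier frame.
#'
#' @param cine a [cine_sequence()] (or any list with `trigger_times_ms`).
#' @param lge_tt_ms LGE trigger time in ms.
#' @return 1-based index of the matched frame.
#' @examples
#' cine <- list(trigger_times_ms = c(0, 40, 80))
#' match_frame_by_trigger_time(cine, 75)  # 3
#' @export
match_frame_by_trigger_time <- function(cine, lge_tt_ms) {
  tt <- cine$trigger_times_ms
  if (is.null(tt) || length(tt) < 1) stopf("cine sequence has no frames")
  which.min(abs(tt - lge_tt_ms))  # which.min breaks ties toward earlier index
}

# Quantize intensities into `bins` levels spanning the image's own range.
bin_image <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  idx <- floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(as.integer(idx), bins)
}

#' Mutual information between two images
#'
#' Joint-histogram (Mattes-style binned) estimate of the mutual information
#' between `fixed` and `moving`, in nats. Each image is quantized into
#' `cfg$histogram_bins` equal-width bins over its own intensity range;
#' MI = H(fixed) + H(moving) - H(fixed, moving). Images with fewer than two
#' distinct intensities have MI defined as 0.
#'
#' @param fixed,moving numeric matrices of equal shape.
#' @param cfg a [registration_config()].
#' @return Mutual information in nats (>= 0 up to floating error).
#' @export
mattes_mutual_information <- function(fixed, moving,
                                      cfg = registration_config()) {
  check_matrix(fixed); check_matrix(moving)
  check_same_shape(fixed, moving)
  if (length(unique(as.vector(fixed))) < 2 ||
      length(unique(as.vector(moving))) < 2) {
    return(0)
  }
  bins <- cfg$histogram_bins
  fi <- bin_image(as.vector(fixed), bins)
  mi <- bin_image(as.vector(moving), bins)
  if (cfg$sample_fraction < 1) {
    keep <- with_seed(cfg$seed, sample.int(length(fi),
                                           max(2, round(cfg$sample_fraction * length(fi)))))
    fi <- fi[keep]; mi <- mi[keep]
  }
  joint <- tabulate((fi - 1L) * bins + mi, nbins = bins * bins)
  p <- joint / sum(joint)
  pj <- p[p > 0]
  px <- tabulate(fi, nbins = bins) / length(fi)
  py <- tabulate(mi, nbins = bins) / length(mi)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy <- -sum(pj * log(pj))
  max(hx + hy - hxy, 0)
}

#' Affine registration by mutual-information maximization
#'
#' Registers `moving` onto `fixed` over translation, rotation, scale and shear
#' using a (1+1) evolutionary strategy: starting from the identity, candidate
#' parameter vectors are drawn from a Gaussian around the current best with an
#' adaptive radius (grown on acceptance, shrunk on rejection) and accepted iff
#' the mutual information of the resampled moving image improves. The metric
#' never decreases below its starting value, so the returned alignment is at
#' least as good as the input alignment. Non-convergence within the iteration
#' budget is not an error; the best parameters found are returned together
#' with the iteration count.
#'
#' @param fixed,moving numeric matrices of equal shape.
#' @param cfg a [registration_config()].
#' @return List with `params` ([affine_params()]), `resampled` (moving image
#'   in fixed coordinates), `mi_before`, `mi_after`, `iterations`, `accepted`
#'   and `converged`.
#' @export
register_affine_mi <- function(fixed, moving, cfg = registration_config()) {
  check_matrix(fixed); check_matrix(moving)
  check_same_shape(fixed, moving)
  # natural-unit scales: px, px, degrees, and 0.02 per unit for scale/shear
  scales <- c(1, 1, 1, 1, 1, 1)
  par_to_affine <- function(p) {
    affine_params(translation = p[1:2], rotation = p[3],
                  scale = pmax(1 + p[4:5] * 0.02, 0.05), shear = p[6] * 0.02)
  }
  # precomputed fixed-grid quantities for the metric evaluations
  nr <- nrow(fixed); nc <- ncol(fixed)
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  grid_r <- rep(seq_len(nr) - 1, times = nc)
  grid_c <- rep(seq_len(nc) - 1, each = nr)
  bins <- cfg$histogram_bins
  fix_bin <- bin_image(as.vector(fixed), bins)
  px_f <- tabulate(fix_bin, nbins = bins) / length(fix_bin)
  h_fixed <- -sum(px_f[px_f > 0] * log(px_f[px_f > 0]))
  mi_of <- function(p) {
    pa <- par_to_affine(p)
    Ainv <- solve(affine_linear_part(pa))
    dr <- grid_r - ctr[1] - pa$translation[1]
    dc <- grid_c - ctr[2] - pa$translation[2]
    vals <- bilinear_gather(moving,
                            Ainv[1, 1] * dr + Ainv[1, 2] * dc + ctr[1],
                            Ainv[2, 1] * dr + Ainv[2, 2] * dc + ctr[2])
    if (length(unique(vals)) < 2) return(0)
    mov_bin <- bin_image(vals, bins)
    joint <- tabulate((fix_bin - 1L) * bins + mov_bin, nbins = bins * bins)
    pj <- joint / length(fix_bin)
    pj <- pj[pj > 0]
    py <- tabulate(mov_bin, nbins = bins) / length(mov_bin)
    py <- py[py > 0]
    max(h_fixed - sum(py * log(py)) + sum(pj * log(pj)), 0)
  }
  best <- rep(0, 6)
  mi_before <- mi_of(best)
  best_mi <- mi_before
  if (cfg$init_grid_px > 0) {
    # coarse translation sweep to land inside the capture range
    for (dx in seq(-cfg$init_grid_px, cfg$init_grid_px, by = 3)) {
      for (dy in seq(-cfg$init_grid_px, cfg$init_grid_px, by = 3)) {
        if (dx == 0 && dy == 0) next
        m <- mi_of(c(dx, dy, 0, 0, 0, 0))
        if (m > best_mi) {
          best <- c(dx, dy, 0, 0, 0, 0); best_mi <- m
        }
      }
    }
    # then a coarse rotation sweep about the best translation, which removes
    # the rotational local optima of near-annular anatomy
    for (rot in seq(-12, 12, by = 3)) {
      if (rot == 0) next
      cand <- best; cand[3] <- rot
      m <- mi_of(cand)
      if (m > best_mi) { best <- cand; best_mi <- m }
    }
  }
  radius <- cfg$initial_radius
  shrink <- cfg$growth_factor^(-0.25)
  accepted <- 0L
  iter <- 0L
  with_seed(cfg$seed, {
    while (iter < cfg$max_iterations && radius > cfg$epsilon) {
      iter <- iter + 1L
      cand <- best + radius * scales * stats::rnorm(6)
      mi_c <- mi_of(cand)
      if (mi_c > best_mi) {
        best <- cand
        best_mi <- mi_c
        radius <- radius * cfg$growth_factor
        accepted <- accepted + 1L
      } else {
        radius <- radius * shrink
      }
    }
  })
  params <- par_to_affine(best)
  list(params = params,
       resampled = apply_affine(moving, params),
       mi_before = mi_before, mi_after = best_mi,
       iterations = iter, accepted = accepted,
       converged = radius <= cfg$epsilon)
}

#' Pad or truncate a cine stack to a fixed number of frames
#'
#' Slice stacks hold up to 32 phases; shorter stacks are padded with empty
#' (all-zero) frames appended at the end, longer stacks are truncated after
#' the first `target` frames.
#'
#' @param frames list of equal-shape numeric matrices (>= 1 frame).
#' @param target stack length (default 32).
#' @return List of exactly `target` matrices.
#' @export
stack_to_fixed_length <- function(frames, target = 32L) {
  if (!is.list(frames) || length(frames) < 1) stopf("need at least one frame")
  target <- as.integer(target)
  n <- length(frames)
  if (n >= target) return(frames[seq_len(target)])
  zero <- matrix(0, nrow(frames[[1]]), ncol(frames[[1]]))
  c(frames, rep(list(zero), target - n))
}

#' Automated alignment quality control
#'
#' Scores the agreement between a cine frame and the registered LGE image by
#' normalized cross-correlation of intensities restricted to the myocardium
#' band (optionally dilated by `band_radius` pixels; the default undilated
#' band is the most sensitive to residual misalignment because the
#' surrounding cavity/background edges are rotation-invariant for an annular
#' ventricle). Scar pixels are best excluded from the mask: scar enhancement
#' is a true cine-LGE contrast difference, not a misalignment. This is an
#' automated proxy for visual inspection of spatial mismatch; pairs are
#' flagged, never deleted.
#'
#' @param cine_frame,registered_lge numeric matrices of equal shape.
#' @param myocardium_mask logical/0-1 matrix marking the myocardium.
#' @param threshold pass threshold on the score (default 0.5).
#' @param band_radius dilation radius in pixels (default 0).
#' @return List with `qc_score`, `qc_pass` and `reason` (NA when scoreable).
#' @export
qc_alignment <- function(cine_frame, registered_lge, myocardium_mask,
                         threshold = 0.5, band_radius = 0L) {
  check_same_shape(cine_frame, registered_lge)
  check_same_shape(cine_frame, myocardium_mask)
  mk <- myocardium_mask > 0
  if (!any(mk)) {
    return(list(qc_score = NA_real_, qc_pass = FALSE, reason = "empty ROI"))
  }
  band <- if (band_radius > 0) dilate_square(mk, as.integer(band_radius)) else mk
  a <- cine_frame[band]; b <- registered_lge[band]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(qc_score = NA_real_, qc_pass = FALSE, reason = "constant intensities"))
  }
  score <- stats::cor(a, b)
  list(qc_score = score, qc_pass = score >= threshold, reason = NA_character_)
}
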