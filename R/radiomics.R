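# Radiomics over the myocardium mask at end-diastolic, end-systolic and
# middle frames: in-plane area resampling, percentile intensity
# normalization, 2D shape / first-order / gray-level run-length features,
# and redundancy + significance feature filtering.

#' Radiomics configuration
#'
#' @param target_spacing_mm in-plane spacing images are resampled to
#'   (default 1.9 mm).
#' @param norm_percentiles `(low, high)` percentiles for intensity clipping
#'   (default `c(1, 99)`).
#' @param n_levels quantization levels (default 256).
#' @param glrlm_angles run directions in degrees, subset of
#'   `c(0, 45, 90, 135)`.
#' @return Object of class `radiomics_config`.
#' @export
radiomics_config <- function(target_spacing_mm = 1.9,
                             norm_percentiles = c(1, 99),
                             n_levels = 256L,
                             glrlm_angles = c(0, 45, 90, 135)) {
  if (norm_percentiles[1] >= norm_percentiles[2]) stopf("low percentile must be < high")
  if (n_levels < 2) stopf("n_levels must be >= 2")
  if (!all(glrlm_angles %in% c(0, 45, 90, 135))) stopf("angles must be in {0,45,90,135}")
  structure(list(target_spacing_mm = target_spacing_mm,
                 norm_percentiles = norm_percentiles,
                 n_levels = as.integer(n_levels),
                 glrlm_angles = glrlm_angles),
            class = "radiomics_config")
}

# Row-space area-interpolation weight matrix mapping n_in pixels of width
# s_in onto output pixels of width s_out. Weights per output pixel sum to 1
# (constants are preserved); interior output pixels conserve integrated
# intensity.
area_weights_1d <- function(n_in, s_in, s_out) {
  n_out <- max(1L, round(n_in * s_in / s_out))
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    lo <- (j - 1) * s_out; hi <- j * s_out
    i0 <- max(1L, floor(lo / s_in) + 1L)
    i1 <- min(n_in, ceiling(hi / s_in))
    for (i in i0:i1) {
      ov <- min(hi, i * s_in) - max(lo, (i - 1) * s_in)
      if (ov > 0) W[j, i] <- ov
    }
    s <- sum(W[j, ])
    if (s > 0) W[j, ] <- W[j, ] / s
  }
  W
}

#' Resample an image/mask pair to a target in-plane spacing
#'
#' Separable one-dimensional area (box) interpolation along each in-plane
#' axis for the image — each output pixel is the overlap-weighted average of
#' the input pixels it covers, so constants are preserved and integrated
#' intensity is conserved away from the border — and nearest-neighbour
#' sampling for the label mask.
#'
#' @param image numeric matrix.
#' @param mask label matrix of the same shape (or NULL).
#' @param spacing_mm current spacing (scalar or length-2, row/col).
#' @param target_mm target spacing (scalar or length-2, > 0).
#' @return List with `image`, `mask` and `spacing_mm` (the achieved spacing,
#'   equal to `target_mm`).
#' @export
resample_inplane <- function(image, mask = NULL, spacing_mm, target_mm = 1.9) {
  check_matrix(image)
  if (any(target_mm <= 0)) stopf("target spacing must be > 0")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  if (length(target_mm) == 1) target_mm <- rep(target_mm, 2)
  if (all(spacing_mm == target_mm)) {
    return(list(image = image, mask = mask, spacing_mm = target_mm))
  }
  Wr <- area_weights_1d(nrow(image), spacing_mm[1], target_mm[1])
  Wc <- area_weights_1d(ncol(image), spacing_mm[2], target_mm[2])
  out <- Wr %*% image %*% t(Wc)
  out_mask <- NULL
  if (!is.null(mask)) {
    ri <- pmin(pmax(floor(((seq_len(nrow(Wr)) - 0.5) * target_mm[1]) / spacing_mm[1]) + 1, 1), nrow(image))
    ci <- pmin(pmax(floor(((seq_len(nrow(Wc)) - 0.5) * target_mm[2]) / spacing_mm[2]) + 1, 1), ncol(image))
    out_mask <- mask[ri, ci, drop = FALSE]
  }
  list(image = out, mask = out_mask, spacing_mm = target_mm)
}

#' Percentile intensity normalization and quantization
#'
#' Clips intensities to the masked `(low, high)` percentiles and linearly
#' maps them to integer levels `0 .. n_levels - 1`. A degenerate window
#' (low percentile equal to high) maps every pixel to level 0 and sets the
#' `degenerate` flag. The mapping is invariant to affine rescaling
#' `a * x + b` (a > 0) of the input because percentiles are equivariant.
#'
#' @param image numeric matrix.
#' @param mask non-empty mask over which percentiles are computed.
#' @param cfg a [radiomics_config()].
#' @return List with `levels` (integer matrix), `bounds` (the percentile
#'   pair) and `degenerate` flag.
#' @export
normalize_intensity <- function(image, mask, cfg = radiomics_config()) {
  check_matrix(image)
  mk <- mask > 0
  if (!any(mk)) stopf("empty mask")
  q <- stats::quantile(image[mk], probs = cfg$norm_percentiles / 100,
                       names = FALSE, type = 7)
  if (q[1] == q[2]) {
    return(list(levels = matrix(0L, nrow(image), ncol(image)),
                bounds = q, degenerate = TRUE))
  }
  x <- pmin(pmax(image, q[1]), q[2])
  lv <- round((x - q[1]) / (q[2] - q[1]) * (cfg$n_levels - 1))
  list(levels = matrix(as.integer(lv), nrow(image), ncol(image)),
       bounds = q, degenerate = FALSE)
}

#' Two-dimensional shape features of a mask
#'
#' Major/minor axis lengths follow the second-central-moment convention
#' (4 * sqrt of the covariance eigenvalues of foreground coordinates);
#' maximum diameter is the largest pairwise distance between foreground
#' pixel corners (convex hull); perimeter is the length of the 0.5-level
#' boundary contour; sphericity is `2 * sqrt(pi * A) / P` with `A` the
#' contour-enclosed area, so a disk scores close to 1 and no shape exceeds 1.
#'
#' @param mask logical/0-1 matrix with at least one foreground pixel.
#' @param spacing_mm pixel spacing (scalar or length-2).
#' @return Named vector: `major_axis_length`, `minor_axis_length`,
#'   `maximum_diameter`, `perimeter`, `sphericity` (lengths in mm when
#'   spacing is given, else pixels).
#' @export
shape2d_features <- function(mask, spacing_mm = 1) {
  mk <- mask > 0
  if (!any(mk)) stopf("empty mask")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  idx <- which(mk, arr.ind = TRUE)
  pts <- cbind(idx[, 1] * spacing_mm[1], idx[, 2] * spacing_mm[2])
  # axis lengths from coordinate covariance eigenvalues
  if (nrow(pts) > 1) {
    ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0)
  }
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  # maximum diameter over pixel-corner convex hull
  corners <- rbind(
    pts + rep(c(-0.5, -0.5) * spacing_mm, each = nrow(pts)),
    pts + rep(c(-0.5, 0.5) * spacing_mm, each = nrow(pts)),
    pts + rep(c(0.5, -0.5) * spacing_mm, each = nrow(pts)),
    pts + rep(c(0.5, 0.5) * spacing_mm, each = nrow(pts)))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  maxdiam <- if (nrow(hull) > 1) max(stats::dist(hull)) else max(spacing_mm)
  # boundary contour (0.5 level on a zero-padded grid); a light Gaussian
  # smoothing removes the staircase bias of the binary contour, with a raw
  # fallback for masks too small to survive the smoothing
  padded <- matrix(0, nrow(mask) + 4, ncol(mask) + 4)
  padded[2 + seq_len(nrow(mask)), 2 + seq_len(ncol(mask))] <- as.numeric(mk)
  contour_of <- function(z) grDevices::contourLines(
    x = (seq_len(nrow(z)) - 1) * spacing_mm[1],
    y = (seq_len(ncol(z)) - 1) * spacing_mm[2],
    z = z, levels = 0.5)
  cl <- contour_of(separable_filter(padded, gaussian_kernel_1d(5, 0.8)))
  if (length(cl) == 0) cl <- contour_of(padded)
  perim <- 0; area <- 0
  for (cc in cl) {
    xs <- cc$x; ys <- cc$y
    if (xs[1] != xs[length(xs)] || ys[1] != ys[length(ys)]) {
      xs <- c(xs, xs[1]); ys <- c(ys, ys[1])
    }
    perim <- perim + sum(sqrt(diff(xs)^2 + diff(ys)^2))
    area <- area + abs(sum(xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)])) / 2
  }
  sph <- if (perim > 0) 2 * sqrt(pi * area) / perim else NA_real_
  c(major_axis_length = major, minor_axis_length = minor,
    maximum_diameter = maxdiam, perimeter = perim, sphericity = sph)
}

#' First-order intensity features over a mask
#'
#' Computed on the quantized level values inside the mask. Energy is the sum
#' of squared values; total energy scales energy by the pixel area in mm^2;
#' RMS is `sqrt(energy / n)`. Percentiles use the linear-interpolation
#' convention between closest ranks (R quantile type 7).
#'
#' @param levels numeric/integer matrix of intensity levels.
#' @param mask non-empty mask.
#' @param pixel_area_mm2 area of one pixel (default 1).
#' @return Named vector: `energy`, `total_energy`, `mean`, `median`,
#'   `maximum`, `range`, `rms`, `p10`, `p90`.
#' @export
firstorder_features <- function(levels, mask, pixel_area_mm2 = 1) {
  x <- as.numeric(levels[mask > 0])
  if (length(x) == 0) stopf("empty mask")
  energy <- sum(x^2)
  qs <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  c(energy = energy,
    total_energy = energy * pixel_area_mm2,
    mean = mean(x), median = stats::median(x),
    maximum = max(x), range = max(x) - min(x),
    rms = sqrt(energy / length(x)),
    p10 = qs[1], p90 = qs[2])
}

# Extract the pixel sequences (values + mask flags) of all lines of `m`
# along one direction.
glrlm_lines <- function(m, mask, angle) {
  nr <- nrow(m); nc <- ncol(m)
  switch(as.character(angle),
    "0" = lapply(seq_len(nr), function(i) list(v = m[i, ], k = mask[i, ])),
    "90" = lapply(seq_len(nc), function(j) list(v = m[, j], k = mask[, j])),
    "45" = {  # anti-diagonals: row + col constant
      key <- outer(seq_len(nr), seq_len(nc), `+`)
      lapply(split(seq_along(m), as.vector(key)),
             function(ii) list(v = m[ii], k = mask[ii]))
    },
    "135" = {  # main diagonals: col - row constant
      key <- outer(seq_len(nr), seq_len(nc), function(i, j) j - i)
      lapply(split(seq_along(m), as.vector(key)),
             function(ii) list(v = m[ii], k = mask[ii]))
    },
    stopf("unsupported angle %s", angle))
}

# Run-length matrix for one direction: maximal runs of equal gray level
# within the mask (pixels outside the mask break runs).
glrlm_matrix <- function(levels, mask, angle) {
  runs_g <- integer(0); runs_l <- integer(0)
  for (ln in glrlm_lines(levels, mask > 0, angle)) {
    key <- ifelse(ln$k, as.numeric(ln$v), -Inf)
    r <- rle(key)
    keep <- is.finite(r$values)
    runs_g <- c(runs_g, as.integer(r$values[keep]))
    runs_l <- c(runs_l, r$lengths[keep])
  }
  list(g = runs_g, l = runs_l)
}

#' Gray-level run-length (GLRLM) texture features
#'
#' For each direction, maximal runs of equal quantized gray level inside the
#' mask are counted into the run-length matrix `P(g, l)`; features follow the
#' standard definitions — gray-level non-uniformity
#' `GLN = sum_g (sum_l P)^2 / Nz`, run-length non-uniformity
#' `RLN = sum_l (sum_g P)^2 / Nz`, its normalized form `RLNN = RLN / Nz`,
#' and run entropy `-sum p log2 p` over `p = P / Nz` — and are averaged over
#' the configured angles.
#'
#' @param levels quantized integer matrix (e.g. from
#'   [normalize_intensity()]).
#' @param mask non-empty mask; out-of-mask pixels break runs.
#' @param angles directions in degrees, subset of `c(0, 45, 90, 135)`.
#' @return List with `features` (named vector `gln`, `rln`, `rlnn`,
#'   `run_entropy`, angle-averaged) and `per_angle` (data frame with the
#'   per-angle features, run counts `n_runs` and `pixels_covered`).
#' @export
glrlm_features <- function(levels, mask, angles = c(0, 45, 90, 135)) {
  if (!any(mask > 0)) stopf("empty mask")
  per <- lapply(angles, function(a) {
    rl <- glrlm_matrix(levels, mask, a)
    nz <- length(rl$l)
    r_g <- tapply(rep(1L, nz), rl$g, sum)
    r_l <- tapply(rep(1L, nz), rl$l, sum)
    # P(g, l) cell counts
    cell <- table(rl$g, rl$l)
    p <- as.numeric(cell) / nz
    p <- p[p > 0]
    data.frame(angle = a,
               gln = sum(r_g^2) / nz,
               rln = sum(r_l^2) / nz,
               rlnn = sum(r_l^2) / nz^2,
               run_entropy = -sum(p * log2(p)),
               n_runs = nz,
               pixels_covered = sum(rl$l))
  })
  per <- do.call(rbind, per)
  feats <- colMeans(per[, c("gln", "rln", "rlnn", "run_entropy")])
  list(features = feats, per_angle = per)
}

#' Locate end-diastolic, end-systolic and middle frames
#'
#' ED is the frame with the largest LV-cavity area, ES the smallest; the
#' middle frame lies halfway along the index path from ED to ES, rounding
#' toward ED (floor of the 0-based index average). If every frame has the
#' same cavity area the result is flagged ambiguous (ED = first frame).
#'
#' @param masks per-frame label masks (cavity label 2).
#' @return List with 1-based `i_ed`, `i_es`, `i_mid`, the per-frame
#'   `cavity_areas` and an `ambiguous` flag.
#' @export
select_frames_ed_es_mid <- function(masks) {
  areas <- vapply(masks, function(m) sum(m == 2L), numeric(1))
  if (all(areas == 0)) stopf("cavity label absent from all frames")
  i_ed <- which.max(areas)
  i_es <- which.min(areas)
  ambiguous <- max(areas) == min(areas)
  i_mid <- floor(((i_ed - 1) + (i_es - 1)) / 2) + 1L
  list(i_ed = i_ed, i_es = i_es, i_mid = as.integer(i_mid),
       cavity_areas = areas, ambiguous = ambiguous)
}

#' Drop mutually redundant features
#'
#' Greedy pass over columns in canonical (sorted-name) order: a column is
#' dropped iff its absolute Pearson correlation with an already-kept column
#' exceeds `r_threshold`; exactly one representative of each correlated
#' group survives, deterministically. Zero-variance columns are dropped with
#' reason "constant".
#'
#' @param table data frame or matrix of features (>= 3 rows).
#' @param r_threshold correlation threshold (default 0.9).
#' @return Object of class `selected_features`: `kept_names`,
#'   `dropped_redundant` (data frame name/partner/r), `dropped_constant`,
#'   `r_threshold`.
#' @export
redundancy_filter <- function(table, r_threshold = 0.9) {
  X <- as.matrix(table)
  if (nrow(X) < 3) stopf("need >= 3 rows to estimate correlations")
  nms <- sort(colnames(X))
  kept <- character(0)
  drop_red <- data.frame(name = character(0), partner = character(0), r = numeric(0))
  drop_const <- character(0)
  for (nm in nms) {
    x <- X[, nm]
    if (stats::sd(x) == 0) {
      drop_const <- c(drop_const, nm)
      next
    }
    partner <- NA_character_; rmax <- 0
    for (k in kept) {
      r <- stats::cor(x, X[, k])
      if (abs(r) > r_threshold) { partner <- k; rmax <- r; break }
    }
    if (!is.na(partner)) {
      drop_red <- rbind(drop_red, data.frame(name = nm, partner = partner, r = rmax))
    } else {
      kept <- c(kept, nm)
    }
  }
  structure(list(kept_names = kept, dropped_redundant = drop_red,
                 dropped_constant = drop_const, r_threshold = r_threshold),
            class = "selected_features")
}

#' Keep features significantly associated with the binary outcome
#'
#' Point-biserial correlation (Pearson correlation of each feature with the
#' 0/1 outcome) tested against the t distribution with n - 2 degrees of
#' freedom; features are kept iff `p < alpha` (no multiple-testing
#' correction, matching the raw threshold convention). Zero-variance
#' features are dropped with reason "zero variance".
#'
#' @param table feature data frame or matrix.
#' @param labels binary 0/1 outcome, both classes present.
#' @param alpha significance level (default 0.001).
#' @return Object of class `selected_features`: `kept_names`, `p_values`
#'   (all testable features), `dropped_insignificant` (data frame name/p),
#'   `dropped_constant`, `alpha`.
#' @export
significance_filter <- function(table, labels, alpha = 0.001) {
  X <- as.matrix(table)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) stopf("labels must contain both classes")
  n <- nrow(X)
  kept <- character(0); drop_const <- character(0)
  pvals <- stats::setNames(numeric(0), character(0))
  drop_insig <- data.frame(name = character(0), p = numeric(0))
  for (nm in colnames(X)) {
    x <- X[, nm]
    if (stats::sd(x) == 0) {
      drop_const <- c(drop_const, nm)
      next
    }
    r <- stats::cor(x, labels)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    pvals[nm] <- p
    if (p < alpha) kept <- c(kept, nm) else {
      drop_insig <- rbind(drop_insig, data.frame(name = nm, p = p))
    }
  }
  structure(list(kept_names = kept, p_values = pvals,
                 dropped_insignificant = drop_insig,
                 dropped_constant = drop_const, alpha = alpha),
            class = "selected_features")
}

#' Radiomics feature row for one study
#'
#' Convenience wrapper: selects the ED, ES and middle frames, restricts to
#' the myocardium (labels 1 and 3), resamples image and mask to the target
#' spacing, normalizes/quantizes intensities and extracts the shape,
#' first-order and GLRLM families, named `<frame>_<family>_<feature>`
#' (frames `ed`, `es`, `mid`).
#'
#' @param frames cine frame list.
#' @param masks per-frame label masks.
#' @param spacing_mm acquisition pixel spacing.
#' @param cfg a [radiomics_config()].
#' @return Named numeric row vector (54 features).
#' @export
extract_radiomics <- function(frames, masks, spacing_mm,
                              cfg = radiomics_config()) {
  sel <- select_frames_ed_es_mid(masks)
  idx <- c(ed = sel$i_ed, es = sel$i_es, mid = sel$i_mid)
  out <- list()
  for (tag in names(idx)) {
    i <- idx[[tag]]
    myo <- (masks[[i]] == 1L | masks[[i]] == 3L) * 1L
    rs <- resample_inplane(frames[[i]], myo, spacing_mm, cfg$target_spacing_mm)
    if (!any(rs$mask > 0)) stopf("myocardium mask empty after resampling (frame %d)", i)
    nq <- normalize_intensity(rs$image, rs$mask, cfg)
    px_area <- prod(rs$spacing_mm)
    sh <- shape2d_features(rs$mask, rs$spacing_mm)
    fo <- firstorder_features(nq$levels, rs$mask, px_area)
    gl <- glrlm_features(nq$levels, rs$mask, cfg$glrlm_angles)$features
    v <- c(sh, fo, gl)
    names(v) <- c(paste0(tag, "_shape_", names(sh)),
                  paste0(tag, "_fo_", names(fo)),
                  paste0(tag, "_glrlm_", names(gl)))
    out[[tag]] <- v
  }
  unlist(unname(out))
}
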