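# Motion features: dense Lucas-Kanade optical flow between frame pairs,
# displacement magnitude over a skip interval, PCA-compressed flow features
# and the rate-of-myocardial-area-change series.

#' Optical flow configuration
#'
#' @param window side of the square least-squares neighbourhood Omega
#'   (default 8).
#' @param gaussian_kernel side of the Gaussian weighting kernel (odd,
#'   default 5).
#' @param gaussian_sigma Gaussian SD along each axis (default 3).
#' @param skip_interval frame gap `k` of a pair (default 3).
#' @param eigenvalue_floor aperture guard: pixels whose structure-tensor
#'   minimum eigenvalue is at or below `eigenvalue_floor * range(frame)^2`
#'   are flagged low-confidence and assigned zero velocity (default 1e-3,
#'   relative so the guard is invariant to intensity rescaling).
#' @param magnitude `"euclidean"` (default) for `sqrt(vx^2 + vy^2)` or
#'   `"sum"` for the literal component sum `vx + vy`.
#' @return Object of class `flow_config`.
#' @export
flow_config <- function(window = 8L, gaussian_kernel = 5L, gaussian_sigma = 3,
                        skip_interval = 3L, eigenvalue_floor = 1e-3,
                        magnitude = c("euclidean", "sum")) {
  if (window < 2) stopf("window must be >= 2")
  if (gaussian_kernel %% 2 == 0) stopf("gaussian_kernel must be odd")
  if (gaussian_sigma <= 0) stopf("gaussian_sigma must be > 0")
  if (skip_interval < 1) stopf("skip_interval must be >= 1")
  structure(list(window = as.integer(window),
                 gaussian_kernel = as.integer(gaussian_kernel),
                 gaussian_sigma = gaussian_sigma,
                 skip_interval = as.integer(skip_interval),
                 eigenvalue_floor = eigenvalue_floor,
                 magnitude = match.arg(magnitude)),
            class = "flow_config")
}

#' Dense Lucas-Kanade optical flow between two frames
#'
#' Solves, at every pixel, the 2x2 weighted least-squares normal equations of
#' the brightness-constancy constraint over the Omega window: spatial
#' gradients by central differences, temporal gradient `frame_b - frame_a`,
#' with the gradient products Gaussian-weighted (`gaussian_kernel`,
#' `gaussian_sigma`) and summed over the `window` x `window` neighbourhood.
#' Pixels failing the aperture guard (minimum structure-tensor eigenvalue at
#' or below the floor) receive zero velocity and a low-confidence flag.
#' Velocities are in pixels per frame; time scaling is applied by
#' [displacement_magnitude()].
#'
#' @param frame_a,frame_b numeric matrices of equal shape.
#' @param cfg a [flow_config()].
#' @return Object of class `flow_field`: `vx`, `vy` (row/col velocity
#'   components, px/frame), `confident` (logical matrix).
#' @export
lucas_kanade_flow <- function(frame_a, frame_b, cfg = flow_config()) {
  check_matrix(frame_a); check_matrix(frame_b)
  check_same_shape(frame_a, frame_b)
  gk <- gaussian_kernel_1d(cfg$gaussian_kernel, cfg$gaussian_sigma)
  a <- separable_filter(frame_a, gk)
  b <- separable_filter(frame_b, gk)
  # central differences; vx along rows, vy along cols
  ix <- (shift_edge(a, -1L, 0L) - shift_edge(a, 1L, 0L)) / 2
  iy <- (shift_edge(a, 0L, -1L) - shift_edge(a, 0L, 1L)) / 2
  it <- b - a
  w <- cfg$window
  sxx <- box_sum(ix * ix, w); syy <- box_sum(iy * iy, w)
  sxy <- box_sum(ix * iy, w)
  sxt <- box_sum(ix * it, w); syt <- box_sum(iy * it, w)
  det <- sxx * syy - sxy * sxy
  trace <- sxx + syy
  min_eig <- trace / 2 - sqrt(pmax(trace^2 / 4 - det, 0))
  rng <- diff(range(frame_a))
  floor_abs <- cfg$eigenvalue_floor * rng^2
  confident <- min_eig > floor_abs
  vx <- matrix(0, nrow(a), ncol(a)); vy <- vx
  ok <- confident & abs(det) > .Machine$double.eps
  # solve [sxx sxy; sxy syy] v = -[sxt; syt]
  vx[ok] <- (-sxt[ok] * syy[ok] + syt[ok] * sxy[ok]) / det[ok]
  vy[ok] <- (-syt[ok] * sxx[ok] + sxt[ok] * sxy[ok]) / det[ok]
  structure(list(vx = vx, vy = vy, confident = confident & ok),
            class = "flow_field")
}

#' Displacement magnitude of a flow field over a skip interval
#'
#' Velocity magnitude `v` per pixel (Euclidean by default, or the literal
#' component sum when configured) scaled by the elapsed time:
#' the displacement is \eqn{r = v k \Delta t}. When velocities are expressed per frame, pass
#' `dt_ms = 1` to obtain displacement in pixels; with per-ms velocities pass
#' the trigger-time difference of adjacent frames.
#'
#' @param field a `flow_field` from [lucas_kanade_flow()].
#' @param dt_ms time between adjacent frames (must be > 0).
#' @param k skip interval of the frame pair.
#' @param magnitude `"euclidean"` or `"sum"`.
#' @return List with `v` (velocity magnitude) and `r` (displacement) matrices.
#' @export
displacement_magnitude <- function(field, dt_ms, k = 1L,
                                   magnitude = c("euclidean", "sum")) {
  if (dt_ms <= 0) stopf("dt_ms must be > 0")
  magnitude <- match.arg(magnitude)
  v <- if (magnitude == "euclidean") sqrt(field$vx^2 + field$vy^2) else field$vx + field$vy
  list(v = v, r = v * k * dt_ms)
}

#' Canonical frame-pair enumeration for a skip interval
#'
#' Start indices step by `k` from 0 while `i <= n_frames - 2`; the partner
#' frame is `min(i + k, n_frames - 1)` (clipped to the last frame). This is
#' the rule under which 32 frames at `k = 3` yield 11 pairs.
#'
#' @param n_frames number of frames (>= 2).
#' @param k skip interval (>= 1).
#' @return Two-column matrix of 0-based `(i, j)` frame indices.
#' @examples
#' nrow(enumerate_frame_pairs(32, 3))  # 11
#' @export
enumerate_frame_pairs <- function(n_frames, k) {
  if (n_frames < 2) stopf("n_frames must be >= 2")
  if (k < 1) stopf("k must be >= 1")
  starts <- seq(0L, n_frames - 2L, by = as.integer(k))
  cbind(i = starts, j = pmin(starts + as.integer(k), n_frames - 1L))
}

#' Fit the PCA projector for flow displacement maps
#'
#' Fits a principal-component projector on vectorized displacement maps from
#' the training samples only (to avoid information leakage into held-out
#' evaluation). All maps of all training studies are pooled as observations.
#'
#' @param train_maps list (over studies) of lists of displacement matrices,
#'   or a single list of matrices.
#' @param n_components leading components to retain (default 8).
#' @return Object of class `flow_pca` with the centering vector, rotation and
#'   per-component variances.
#' @export
fit_flow_pca <- function(train_maps, n_components = 8L) {
  if (is.list(train_maps) && length(train_maps) && is.list(train_maps[[1]])) {
    train_maps <- unlist(train_maps, recursive = FALSE)
  }
  mat <- do.call(rbind, lapply(train_maps, as.vector))
  n_components <- min(n_components, nrow(mat) - 1L, ncol(mat))
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE, rank. = n_components)
  structure(list(center = pc$center, rotation = pc$rotation,
                 sdev = pc$sdev[seq_len(n_components)],
                 n_components = n_components),
            class = "flow_pca")
}

#' Project displacement maps into a flow feature row
#'
#' Each displacement map is projected onto the leading principal components
#' of the fitted projector; the per-map score vectors are concatenated into a
#' single named row vector of length `n_maps * n_components`
#' (`flow_pc_<pair>_<comp>`).
#'
#' @param displacement_maps list of displacement matrices (one per frame
#'   pair, in enumeration order).
#' @param projector a fitted `flow_pca` from [fit_flow_pca()]; projecting
#'   with an unfitted object is an error.
#' @return Named numeric row vector.
#' @export
flow_feature_vector <- function(displacement_maps, projector) {
  if (!inherits(projector, "flow_pca")) {
    stopf("projector must be a fitted flow_pca (call fit_flow_pca first)")
  }
  out <- lapply(seq_along(displacement_maps), function(p) {
    v <- as.vector(displacement_maps[[p]]) - projector$center
    sc <- drop(v %*% projector$rotation)
    names(sc) <- sprintf("flow_pc_%02d_%d", p, seq_along(sc))
    sc
  })
  unlist(out)
}

#' Rate of myocardial area change across the cycle
#'
#' Myocardial cross-sectional area per frame is the count of myocardium
#' pixels (labels 1 and 3, i.e., including scarred myocardium) times the
#' pixel area; the rate for the canonical frame pair `(i, j)` is
#' `a = (A_j - A_i) / (k * dt)`, the same pair enumeration as the optical
#' flow. Frames missing a myocardium label yield `NA` with a flag.
#'
#' @param masks per-frame label masks (0/1/2/3).
#' @param trigger_times_ms per-frame trigger times.
#' @param k skip interval (default 3).
#' @param spacing_mm pixel spacing; scalar or length-2. Default 1 gives
#'   px^2/ms; pass the true spacing for mm^2/ms.
#' @return List with `values` (named `area_rate_<pair>`), `areas`,
#'   `frame_pairs` and `flagged` (logical, pairs with undefined values).
#' @export
area_change_series <- function(masks, trigger_times_ms, k = 3L, spacing_mm = 1) {
  if (length(masks) != length(trigger_times_ms)) stopf("masks/trigger time mismatch")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  px_area <- prod(spacing_mm)
  areas <- vapply(masks, function(m) sum(m == 1L | m == 3L) * px_area, numeric(1))
  has_myo <- vapply(masks, function(m) any(m == 1L | m == 3L), logical(1))
  pairs <- enumerate_frame_pairs(length(masks), k)
  values <- numeric(nrow(pairs))
  flagged <- logical(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1] + 1L; j <- pairs[p, 2] + 1L
    if (!has_myo[i] || !has_myo[j]) {
      values[p] <- NA_real_; flagged[p] <- TRUE
      next
    }
    dt <- (trigger_times_ms[j] - trigger_times_ms[i])
    values[p] <- (areas[j] - areas[i]) / dt
  }
  names(values) <- sprintf("area_rate_%02d", seq_len(nrow(pairs)))
  list(values = values, areas = areas, frame_pairs = pairs, flagged = flagged)
}
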