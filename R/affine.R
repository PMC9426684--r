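#' Affine transform parameters
#'
#' Parameterizes a 2D affine map consisting of translation, rotation, scale
#' and shear, the transform family used to register a late gadolinium
#' enhancement (LGE) image onto its matching cine frame. The convention used
#' throughout the package: parameters map moving-image coordinates into
#' fixed-image coordinates; coordinates are 0-based `(row, col)`; rotation is
#' about the image centre with positive angles counter-clockwise; resampling
#' pulls intensities from the moving image through the inverse map.
#'
#' @param translation numeric length-2, `(d_row, d_col)` in pixels.
#' @param rotation rotation angle in degrees.
#' @param scale numeric length-2 `(s_row, s_col)`, both strictly positive.
#' @param shear unitless shear coefficient.
#' @return An object of class `affine_params`.
#' @examples
#' affine_params(translation = c(5, -3), rotation = 10)
#' @export
affine_params <- function(translation = c(0, 0), rotation = 0,
                          scale = c(1, 1), shear = 0) {
  translation <- as.numeric(translation)
  scale <- as.numeric(scale)
  if (length(scale) == 1) scale <- rep(scale, 2)
  if (length(translation) != 2 || length(scale) != 2) {
    stopf("translation and scale must have length 2")
  }
  if (any(scale <= 0)) stopf("scale components must be > 0")
  structure(list(translation = translation, rotation = as.numeric(rotation),
                 scale = scale, shear = as.numeric(shear)),
            class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf("affine: t = (%.3f, %.3f) px, rot = %.3f deg, scale = (%.4f, %.4f), shear = %.4f\n",
              x$translation[1], x$translation[2], x$rotation,
              x$scale[1], x$scale[2], x$shear))
  invisible(x)
}

is_identity_affine <- function(p) {
  all(p$translation == 0) && p$rotation == 0 && all(p$scale == 1) && p$shear == 0
}

# 2x2 linear part: rotation %*% shear %*% scale acting on (row, col).
affine_linear_part <- function(p) {
  th <- p$rotation * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sh <- matrix(c(1, 0, p$shear, 1), 2, 2)
  sc <- diag(p$scale)
  rot %*% sh %*% sc
}

#' Apply an affine transform to an image or label mask
#'
#' Resamples `image` under `params` (moving-to-fixed convention): the output
#' grid is scanned and intensities are pulled from the input through the
#' inverse map. Label masks must use `"nearest"` so no new label values are
#' created; intensity images use `"linear"` (bilinear). Samples falling
#' outside the input grid take the value `fill`.
#'
#' @param image numeric matrix (image or integer label mask).
#' @param params an [affine_params()] object.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill out-of-bounds fill value (default 0, the background label).
#' @return Transformed matrix of the same shape.
#' @export
apply_affine <- function(image, params, interpolation = c("linear", "nearest"),
                         fill = 0) {
  check_matrix(image)
  interpolation <- match.arg(interpolation)
  if (!inherits(params, "affine_params")) stopf("params must be affine_params")
  if (is_identity_affine(params)) return(image)

  nr <- nrow(image); nc <- ncol(image)
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  A <- affine_linear_part(params)
  Ainv <- solve(A)

  # fixed-grid coordinates (0-based), mapped back into the moving image
  rows <- rep(seq_len(nr) - 1, times = nc)
  cols <- rep(seq_len(nc) - 1, each = nr)
  dr <- rows - ctr[1] - params$translation[1]
  dc <- cols - ctr[2] - params$translation[2]
  src_r <- Ainv[1, 1] * dr + Ainv[1, 2] * dc + ctr[1]
  src_c <- Ainv[2, 1] * dr + Ainv[2, 2] * dc + ctr[2]

  out <- rep(fill, nr * nc)
  if (interpolation == "nearest") {
    ri <- round(src_r); ci <- round(src_c)
    ok <- ri >= 0 & ri <= nr - 1 & ci >= 0 & ci <= nc - 1
    out[ok] <- image[cbind(ri[ok] + 1, ci[ok] + 1)]
  } else {
    out <- bilinear_gather(image, src_r, src_c, fill)
  }
  matrix(out, nr, nc)
}

# Bilinear sampling of `image` at 0-based coordinates, fill outside; the
# base index is clamped so exact hits on the last row/column stay in bounds.
bilinear_gather <- function(image, src_r, src_c, fill = 0) {
  nr <- nrow(image); nc <- ncol(image)
  sel <- src_r >= 0 & src_r <= nr - 1 & src_c >= 0 & src_c <= nc - 1
  out <- rep(fill, length(src_r))
  r0 <- pmin(floor(src_r[sel]), nr - 2)
  c0 <- pmin(floor(src_c[sel]), nc - 2)
  fr <- src_r[sel] - r0; fc <- src_c[sel] - c0
  i00 <- r0 + 1 + (c0) * nr  # column-major linear index
  v00 <- image[i00]; v10 <- image[i00 + 1]
  v01 <- image[i00 + nr]; v11 <- image[i00 + nr + 1]
  out[sel] <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
  out
}

# homogeneous 3x3 matrix of an affine_params map (0-based coords, centre C)
affine_homogeneous <- function(p, shape) {
  ctr <- (shape - 1) / 2
  A <- affine_linear_part(p)
  b <- ctr + p$translation - A %*% ctr
  rbind(cbind(A, b), c(0, 0, 1))
}

#' Residual error of a recovered registration transform
#'
#' Composes the recovered transform with the true misalignment; a perfect
#' registration yields the identity. Reports the residual displacement of
#' the image centre (px) and the residual rotation angle (degrees) of the
#' composite map — the target-registration-error convention, which accounts
#' for the interaction of rotation and translation in the inverse map.
#'
#' @param recovered,true_params [affine_params()] objects (recovered maps
#'   moving to fixed, `true_params` is the misalignment that was applied).
#' @param shape image dimensions (length-2).
#' @return List with `translation_px` and `rotation_deg`.
#' @export
registration_error <- function(recovered, true_params, shape) {
  E <- affine_homogeneous(recovered, shape) %*%
    affine_homogeneous(true_params, shape)
  ctr_full <- (shape - 1) / 2
  moved <- E %*% c(ctr_full, 1)
  list(translation_px = sqrt(sum((moved[1:2] - ctr_full)^2)),
       rotation_deg = abs(atan2(E[2, 1] - E[1, 2], E[1, 1] + E[2, 2])) * 180 / pi)
}
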