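# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. All package-level randomness flows through this helper.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and a stage name, so every pipeline
# stage is independently reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  chars <- utf8ToInt(as.character(stage))
  h <- 0
  for (ch in chars) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 7919 + h + 1) %% 2147480009)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("'%s' must be a numeric matrix", name)
  }
  invisible(x)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stopf("%s must have identical dimensions (got %s vs %s)", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  }
  invisible(NULL)
}

# 1D Gaussian kernel of odd length `size`, unit sum.
gaussian_kernel_1d <- function(size, sigma) {
  if (size %% 2 == 0) stopf("Gaussian kernel size must be odd (got %d)", size)
  half <- (size - 1) / 2
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Shift a matrix by integer offsets, padding with edge replication.
shift_edge <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Separable convolution of a matrix with a symmetric odd 1D kernel applied
# along rows then columns; edge-replicated borders.
separable_filter <- function(m, k) {
  half <- (length(k) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_edge(m, 0L, as.integer(i - half - 1L))
  res <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) res <- res + k[i] * shift_edge(out, as.integer(i - half - 1L), 0L)
  res
}

# Sum of values over a w x w window centred (floor convention) on each pixel,
# computed with an integral image. Used for the optical-flow structure tensor.
box_sum <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 1, nc + 1)
  pad[-1, -1] <- m
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  lo <- floor((w - 1) / 2); hi <- ceiling((w - 1) / 2)
  r0 <- pmax(seq_len(nr) - lo - 1L, 0L); r1 <- pmin(seq_len(nr) + hi, nr)
  c0 <- pmax(seq_len(nc) - lo - 1L, 0L); c1 <- pmin(seq_len(nc) + hi, nc)
  ii[r1 + 1L, c1 + 1L, drop = FALSE] - ii[r0 + 1L, c1 + 1L, drop = FALSE] -
    ii[r1 + 1L, c0 + 1L, drop = FALSE] + ii[r0 + 1L, c0 + 1L, drop = FALSE]
}

# Binary dilation of a logical matrix with a square structuring element of
# radius `r` (side 2r + 1).
dilate_square <- function(mask, r) {
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_edge(mask, dr, dc)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
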