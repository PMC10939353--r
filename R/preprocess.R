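# Background subtraction ahead of spot localization. Two stages, both
# subtractive and clipped at zero: a rolling-ball estimate removes the
# smooth extracellular/illumination background, then subtracting the
# median-filtered image flattens the cytoplasmic signal and cell-edge
# gradients while diffraction-limited spots (smaller than the median
# window) survive.

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball structuring element of the given radius (the classic rolling-ball
#' formulation: the ball is rolled under the intensity surface and the
#' background is the surface it touches), and subtracts it. For speed the
#' ball is rolled on a block-minimum-shrunken copy of the image and the
#' background is enlarged back by bilinear interpolation, the same strategy
#' ImageJ uses for large radii. Output is clipped at zero.
#'
#' @param image 2D numeric matrix, nonnegative.
#' @param radius_px ball radius in pixels; must be smaller than the image.
#' @return background-subtracted image (same dimensions), everywhere in
#'   `[0, image]`.
#' @export
rolling_ball_subtract <- function(image, radius_px = 70) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a numeric matrix", call. = FALSE)
  }
  stopifnot_scalar_pos(radius_px, "radius_px")
  if (radius_px >= min(dim(image))) {
    stop("'radius_px' must be smaller than the smallest image dimension",
         call. = FALSE)
  }
  s <- max(1L, floor(radius_px / 10))
  small <- if (s > 1L) block_min(image, s) else image
  r_small <- radius_px / s
  bg_small <- ball_opening(small, r_small)
  bg <- if (s > 1L) {
    Wr <- upsample_weights(nrow(image), nrow(small), s)
    Wc <- upsample_weights(ncol(image), ncol(small), s)
    Wr %*% bg_small %*% t(Wc)
  } else {
    bg_small
  }
  bg <- pmin(bg, image)   # interpolation must never overshoot the data
  pmax(image - bg, 0)
}

# Block minimum over s x s tiles (edge tiles may be smaller).
block_min <- function(image, s) {
  nr <- nrow(image); nc <- ncol(image)
  nrs <- ceiling(nr / s); ncs <- ceiling(nc / s)
  out <- matrix(Inf, nrs, ncs)
  ri <- rep(seq_len(nrs), each = s, length.out = nr)
  ci <- rep(seq_len(ncs), each = s, length.out = nc)
  for (j in seq_len(nc)) {
    col_min <- tapply(image[, j], ri, min)
    out[, ci[j]] <- pmin(out[, ci[j]], col_min)
  }
  out
}

# Grayscale opening with a (non-flat) ball structuring element of radius r:
# erosion e(p) = min_q f(p+q) - z(q), then dilation max_q e(p-q) + z(q),
# with z the ball height profile. Borders use edge replication.
ball_opening <- function(f, r) {
  ir <- floor(r)
  offs <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  keep <- offs$dr^2 + offs$dc^2 <= r^2
  offs <- offs[keep, ]
  z <- sqrt(pmax(r^2 - offs$dr^2 - offs$dc^2, 0))
  ero <- shift_reduce(f, offs$dr, offs$dc, -z, pmin, Inf)
  shift_reduce(ero, -offs$dr, -offs$dc, z, pmax, -Inf)
}

# Reduce over shifted copies: out(p) = reduce_q (f(p + (dr,dc)_q) + add_q),
# with edge replication for out-of-range shifts.
shift_reduce <- function(f, dr, dc, add, reduce, init) {
  nr <- nrow(f); nc <- ncol(f)
  out <- matrix(init, nr, nc)
  for (q in seq_along(dr)) {
    ri <- pmin(pmax(seq_len(nr) + dr[q], 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc[q], 1L), nc)
    out <- reduce(out, f[ri, ci, drop = FALSE] + add[q])
  }
  out
}

#' Median-filter subtraction
#'
#' Subtracts the median-filtered image (square window of side
#' `diameter_px`) from the image and clips at zero. With the window set to
#' twice the diffraction limit the filter erases diffraction-limited spots
#' from its output, so the subtraction preserves spots while removing the
#' cell-scale structure (cytoplasmic signal, cell contour gradients).
#'
#' @param image 2D numeric matrix.
#' @param diameter_px window side in pixels; odd, >= 3.
#' @return filtered image, everywhere in `[0, image]`.
#' @export
median_subtract <- function(image, diameter_px = 11) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a numeric matrix", call. = FALSE)
  }
  diameter_px <- as.integer(diameter_px)
  if (diameter_px < 3L || diameter_px %% 2L == 0L) {
    stop("'diameter_px' must be odd and >= 3", call. = FALSE)
  }
  mx <- max(image)
  if (mx <= 0) return(pmax(image, 0))
  med <- EBImage::medianFilter(image / mx, (diameter_px - 1L) %/% 2L) * mx
  pmax(image - med, 0)
}

#' Full image pre-processing
#'
#' Applies [rolling_ball_subtract()] then [median_subtract()] with the
#' parameters of a [preprocess_config()].
#'
#' @param image 2D numeric matrix.
#' @param pre a [preprocess_config()].
#' @return pre-processed image.
#' @export
preprocess_image <- function(image, pre = preprocess_config()) {
  stopifnot(inherits(pre, "preprocess_config"))
  median_subtract(rolling_ball_subtract(image, pre$rolling_ball_radius_px),
                  pre$median_diameter_px)
}
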