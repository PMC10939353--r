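#' Affine registration map
#'
#' The chromatic-aberration registration map: a 2x2 linear part plus a
#' translation, mapping channel-1 (row, col) pixel coordinates onto the
#' channel-2 reference frame.
#'
#' @param linear 2x2 matrix (dimensionless); must be invertible.
#' @param translation length-2 numeric, in pixels.
#' @param n_points_fit number of bead correspondences the map was fitted on
#'   (0 for a hand-constructed map).
#' @return an object of class `affine_map`.
#' @examples
#' identity_map <- affine_map()
#' shift <- affine_map(translation = c(-1.5, 0.75))
#' apply_affine(shift, cbind(0, 0))
#' @export
affine_map <- function(linear = diag(2), translation = c(0, 0),
                       n_points_fit = 0L) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (!all(is.finite(linear)) || abs(det(linear)) < 1e-12) {
    stop("'linear' must be a finite, invertible 2x2 matrix", call. = FALSE)
  }
  translation <- as.numeric(translation)
  if (length(translation) != 2L || !all(is.finite(translation))) {
    stop("'translation' must be a finite length-2 vector", call. = FALSE)
  }
  structure(list(linear = linear, translation = translation,
                 n_points_fit = as.integer(n_points_fit)),
            class = "affine_map")
}

#' Apply an affine map to points
#'
#' @param map an [affine_map()].
#' @param pts n x 2 matrix of (row, col) positions in pixels.
#' @return n x 2 matrix of mapped positions.
#' @export
apply_affine <- function(map, pts) {
  stopifnot(inherits(map, "affine_map"))
  pts <- matrix(as.numeric(pts), ncol = 2)
  sweep(pts %*% t(map$linear), 2, map$translation, "+")
}

#' Invert an affine map
#'
#' @param map an [affine_map()].
#' @return the inverse `affine_map`.
#' @export
invert_affine <- function(map) {
  stopifnot(inherits(map, "affine_map"))
  Ainv <- solve(map$linear)
  affine_map(Ainv, -as.vector(Ainv %*% map$translation), map$n_points_fit)
}

#' Fit an affine map by least squares
#'
#' Solves for the affine transform minimizing the mean squared residual of
#' `map(moving) - reference` over matched point pairs, on homogeneous
#' coordinates. With exactly three non-collinear pairs the fit interpolates
#' them exactly. No robust reweighting is applied: bead correspondences are
#' expected to be pre-filtered for aggregates.
#'
#' @param moving n x 2 matrix of channel-1 (row, col) centroids.
#' @param reference n x 2 matrix of matched channel-2 centroids.
#' @return an [affine_map()] with `n_points_fit = n`.
#' @export
fit_affine <- function(moving, reference) {
  moving <- matrix(as.numeric(moving), ncol = 2)
  reference <- matrix(as.numeric(reference), ncol = 2)
  n <- nrow(moving)
  if (nrow(reference) != n) {
    stop("'moving' and 'reference' must have the same number of points",
         call. = FALSE)
  }
  if (n < 3L) {
    stop("affine registration needs at least 3 point correspondences",
         call. = FALSE)
  }
  X <- cbind(1, moving)
  if (qr(X)$rank < 3L) {
    stop("degenerate (collinear) point configuration: cannot fit an affine ",
         "map; spread beads across the field of view", call. = FALSE)
  }
  beta <- qr.coef(qr(X), reference)           # 3 x 2: intercept + linear
  affine_map(t(beta[2:3, , drop = FALSE]), beta[1, ], n)
}

#' @export
print.affine_map <- function(x, digits = 6, ...) {
  cat("Affine registration map (row, col convention)\n")
  cat("  linear:\n")
  print(round(x$linear, digits))
  cat("  translation (px):", paste(round(x$translation, digits),
                                   collapse = ", "), "\n")
  if (x$n_points_fit > 0) {
    cat("  fitted on", x$n_points_fit, "bead correspondences\n")
  }
  invisible(x)
}

#' Write / read a registration map as structured text
#'
#' The map is serialized as JSON (matrix, translation, metadata) so it can
#' be inspected and versioned alongside the imaging data.
#'
#' @param map an [affine_map()].
#' @param path file path.
#' @return `write_affine` returns `path` invisibly; `read_affine` the map.
#' @export
write_affine <- function(map, path) {
  stopifnot(inherits(map, "affine_map"))
  jsonlite::write_json(
    list(linear = map$linear, translation = map$translation,
         n_points_fit = map$n_points_fit),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lin <- x$linear
  if (!is.matrix(lin)) lin <- do.call(rbind, lapply(lin, unlist))
  affine_map(lin, x$translation, x$n_points_fit)
}
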