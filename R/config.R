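#' Optical configuration of the imaging setup
#'
#' Collects the physical constants of the microscope that parameterize the
#' whole pipeline. The defaults describe a wide-field setup with a x100
#' objective and a 6.45 um camera sensor, i.e. a sample-plane pixel of
#' 64.5 nm, and a diffraction limit of 5.5 px. Every default filter radius
#' downstream derives from these two numbers (see [selection_config()] and
#' [preprocess_config()]).
#'
#' @param pixel_size_nm physical sample-plane pixel size in nm per pixel.
#' @param diffraction_limit_px diffraction limit expressed in pixels.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels. The default
#'   ties the PSF FWHM to the diffraction limit
#'   (`diffraction_limit_px / 2.355`).
#' @param image_shape integer vector `c(rows, cols)` of a field of view.
#' @return an object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' cfg$pixel_size_nm
#' @export
optical_config <- function(pixel_size_nm = 64.5,
                           diffraction_limit_px = 5.5,
                           psf_sigma_px = diffraction_limit_px / 2.355,
                           image_shape = c(256L, 256L)) {
  stopifnot_scalar_pos(pixel_size_nm, "pixel_size_nm")
  stopifnot_scalar_pos(diffraction_limit_px, "diffraction_limit_px")
  stopifnot_scalar_pos(psf_sigma_px, "psf_sigma_px")
  if (length(image_shape) != 2L || any(image_shape < 16)) {
    stop("'image_shape' must be c(rows, cols) with both >= 16", call. = FALSE)
  }
  structure(list(pixel_size_nm = pixel_size_nm,
                 diffraction_limit_px = diffraction_limit_px,
                 psf_sigma_px = psf_sigma_px,
                 image_shape = as.integer(image_shape)),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  pixel size:        %.2f nm/px\n", x$pixel_size_nm))
  cat(sprintf("  diffraction limit: %.2f px\n", x$diffraction_limit_px))
  cat(sprintf("  PSF sigma:         %.3f px\n", x$psf_sigma_px))
  cat(sprintf("  image shape:       %d x %d px\n",
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

# Odd detection/median window derived from the diffraction limit:
# twice the diffraction limit, rounded to the nearest odd integer.
median_diameter_from <- function(cfg) {
  d <- 2 * cfg$diffraction_limit_px
  2L * as.integer(round((d - 1) / 2)) + 1L
}

#' Background-subtraction parameters
#'
#' Defaults derive from the optical configuration: the median window is
#' twice the diffraction limit (rounded to odd, 11 px for the default setup)
#' so it erases diffraction-limited spots but preserves the cell contour,
#' and the rolling-ball radius is slightly larger than a yeast cell
#' (70 px by default).
#'
#' @param cfg an [optical_config()].
#' @param rolling_ball_radius_px rolling-ball background radius in pixels.
#' @param median_diameter_px median filter window diameter (odd, >= 3).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(cfg = optical_config(),
                              rolling_ball_radius_px = 70,
                              median_diameter_px = median_diameter_from(cfg)) {
  stopifnot_scalar_pos(rolling_ball_radius_px, "rolling_ball_radius_px")
  median_diameter_px <- as.integer(median_diameter_px)
  if (median_diameter_px < 3L || median_diameter_px %% 2L == 0L) {
    stop("'median_diameter_px' must be odd and >= 3", call. = FALSE)
  }
  structure(list(rolling_ball_radius_px = rolling_ball_radius_px,
                 median_diameter_px = median_diameter_px),
            class = "preprocess_config")
}

#' Spot-pair selection thresholds
#'
#' Defaults reproduce the recommended thresholds for the example setup with
#' an 11 px twice-diffraction-limit window: closest-neighbour isolation at
#' twice the diffraction limit minus one pixel (10 px), distance to the cell
#' contour at twice the diffraction limit plus two pixels (13 px), a
#' feature-density probability cut-off of 0.5 (the densest 50% of spot pairs
#' are retained) and a 2D-Gaussian goodness-of-fit threshold of 0.35.
#'
#' @param cfg an [optical_config()].
#' @param max_closest_neighbour_px isolation radius in pixels.
#' @param max_contour_dist_px maximum centroid distance to the cell contour.
#' @param density_cutoff retained fraction of the feature-density filter,
#'   in (0, 1).
#' @param r2_threshold minimum Gaussian-fit R-squared, in \[0, 1\].
#' @param segmentation_backend `"threshold"` (Otsu-based fallback bundled
#'   with the package) or `"external_mask"` (a label mask supplied by any
#'   external segmentation tool).
#' @return an object of class `selection_config`.
#' @examples
#' sel <- selection_config()
#' sel$max_closest_neighbour_px  # 10 for the default 5.5 px setup
#' sel$max_contour_dist_px      # 13
#' @export
selection_config <- function(cfg = optical_config(),
                             max_closest_neighbour_px =
                               round(2 * cfg$diffraction_limit_px) - 1,
                             max_contour_dist_px =
                               round(2 * cfg$diffraction_limit_px) + 2,
                             density_cutoff = 0.5,
                             r2_threshold = 0.35,
                             segmentation_backend = c("threshold",
                                                      "external_mask")) {
  stopifnot_scalar_pos(max_closest_neighbour_px, "max_closest_neighbour_px")
  stopifnot_scalar_pos(max_contour_dist_px, "max_contour_dist_px")
  if (!is.numeric(density_cutoff) || density_cutoff <= 0 ||
      density_cutoff >= 1) {
    stop("'density_cutoff' must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(r2_threshold) || r2_threshold < 0 || r2_threshold > 1) {
    stop("'r2_threshold' must be in [0, 1]", call. = FALSE)
  }
  structure(list(max_closest_neighbour_px = max_closest_neighbour_px,
                 max_contour_dist_px = max_contour_dist_px,
                 density_cutoff = density_cutoff,
                 r2_threshold = r2_threshold,
                 segmentation_backend = match.arg(segmentation_backend)),
            class = "selection_config")
}
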