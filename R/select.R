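# The spot-pair quality cascade: isolation -> cell contour -> feature
# density -> 2D-Gaussian goodness of fit. Each filter appends a pass_*
# flag column; a pair failing stage k is not evaluated at stage k+1
# (its later flags stay NA), so each stage returns a subset of the
# previous one.

pairs_active <- function(pairs) {
  flags <- grep("^pass_", names(pairs), value = TRUE)
  if (length(flags) == 0L) return(rep(TRUE, nrow(pairs)))
  Reduce(`&`, lapply(flags, function(f) {
    v <- pairs[[f]]
    is.na(v) | v
  }))
}

#' Isolation filter: reject pairs with close neighbouring spots
#'
#' A pair fails when any other detected spot of the field of view (either
#' channel, its own two members excluded) lies within
#' `max_closest_neighbour_px` of either member centroid. Overlapping spots
#' bias the intensity-weighted centroids, so such pairs are unreliable.
#'
#' @param pairs pair table from [link_pairs()] (one field of view).
#' @param ch1_spots,ch2_spots all detected spots of that field of view,
#'   including unpaired ones.
#' @param max_closest_neighbour_px isolation radius, px.
#' @return `pairs` with a `pass_isolation` logical column.
#' @export
isolation_filter <- function(pairs, ch1_spots, ch2_spots,
                             max_closest_neighbour_px = 10) {
  stopifnot_scalar_pos(max_closest_neighbour_px, "max_closest_neighbour_px")
  n <- nrow(pairs)
  pairs$pass_isolation <- rep(NA, n)
  if (n == 0L) return(pairs)
  pts <- rbind(cbind(ch1_spots$row, ch1_spots$col),
               cbind(ch2_spots$row, ch2_spots$col))
  chan <- rep(1:2, c(nrow(ch1_spots), nrow(ch2_spots)))
  idx <- c(seq_len(nrow(ch1_spots)), seq_len(nrow(ch2_spots)))
  a_row <- if ("row1_raw" %in% names(pairs)) pairs$row1_raw else pairs$row1
  a_col <- if ("col1_raw" %in% names(pairs)) pairs$col1_raw else pairs$col1
  for (i in seq_len(n)) {
    own <- (chan == 1 & idx == pairs$idx1[i]) |
      (chan == 2 & idx == pairs$idx2[i])
    others <- pts[!own, , drop = FALSE]
    if (nrow(others) == 0L) {
      pairs$pass_isolation[i] <- TRUE
      next
    }
    d1 <- sqrt((others[, 1] - a_row[i])^2 +
                 (others[, 2] - a_col[i])^2)
    d2 <- sqrt((others[, 1] - pairs$row2[i])^2 +
                 (others[, 2] - pairs$col2[i])^2)
    pairs$pass_isolation[i] <- min(d1, d2) >= max_closest_neighbour_px
  }
  pairs
}

#' Segment cells into a label mask
#'
#' The segmentation contract of the pipeline: any integer label image
#' (0 = background, k = cell k) of the same shape as the channel image is
#' accepted, so an externally produced mask (e.g. from a neural-network
#' segmentation tool) plugs in directly. The bundled fallback backend
#' thresholds a Gaussian-smoothed copy of the raw image with Otsu's
#' method, fills holes and labels connected components.
#'
#' @param image raw (not pre-processed) channel image; used by the
#'   threshold backend and for shape validation.
#' @param backend `"threshold"` or `"external_mask"`.
#' @param mask label matrix or path to a 16-bit label TIFF (required for
#'   the external backend).
#' @param smooth_sigma_px Gaussian smoothing before thresholding, px.
#' @param spot_erase_radius_px median-filter radius used to erase
#'   diffraction-limited spots before thresholding (bright spots would
#'   otherwise dominate the intensity histogram and bulge the mask).
#' @param min_area_px minimum component area kept, px^2.
#' @return integer label matrix.
#' @export
segment_cells <- function(image, backend = c("threshold", "external_mask"),
                          mask = NULL, smooth_sigma_px = 3,
                          spot_erase_radius_px = 8, min_area_px = 100) {
  backend <- match.arg(backend)
  if (backend == "external_mask") {
    if (is.null(mask)) {
      stop("external_mask backend needs a 'mask'", call. = FALSE)
    }
    if (is.character(mask)) mask <- read_mask_tiff(mask)
    if (!all(dim(mask) == dim(image))) {
      stop("external mask shape ", paste(dim(mask), collapse = "x"),
           " does not match image shape ", paste(dim(image), collapse = "x"),
           call. = FALSE)
    }
    return(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  }
  mx <- max(image)
  if (mx <= min(image)) {
    return(matrix(0L, nrow(image), ncol(image)))   # blank image
  }
  # erase the diffraction-limited spots first (median over a window wider
  # than a spot), then smooth: Otsu must separate cytoplasm from
  # extracellular background, and bright spots would otherwise dominate
  # the histogram
  sm <- EBImage::medianFilter(image / mx, spot_erase_radius_px)
  sm <- EBImage::gblur(sm, sigma = smooth_sigma_px)
  thr <- EBImage::otsu(EBImage::Image(sm), range = range(sm))
  fg <- EBImage::fillHull(sm > thr)
  lab <- EBImage::bwlabel(fg)
  # drop specks
  tab <- table(lab[lab > 0])
  small <- as.integer(names(tab)[tab < min_area_px])
  m <- matrix(as.integer(lab), nrow(image), ncol(image))
  m[m %in% small] <- 0L
  # relabel compactly
  ids <- sort(unique(m[m > 0]))
  if (length(ids)) m <- matrix(match(m, c(0L, ids)) - 1L, nrow(m), ncol(m))
  m
}

#' Cell-contour proximity filter
#'
#' The anchor platforms sit on the plasma membrane, so genuine spot pairs
#' lie at the edge of the cell equatorial section. The contour is the
#' boundary pixel set of the labelled cells; a pair passes iff both member
#' centroids are within `max_contour_dist_px` of some contour pixel
#' (Euclidean distance transform). Spots slightly outside the cell are
#' allowed, as the anchor straddles the membrane.
#'
#' @param pairs pair table (one field of view).
#' @param mask label mask from [segment_cells()].
#' @param max_contour_dist_px maximum centroid-to-contour distance, px.
#' @return `pairs` with a `pass_contour` logical column.
#' @export
contour_filter <- function(pairs, mask, max_contour_dist_px = 13) {
  stopifnot_scalar_pos(max_contour_dist_px, "max_contour_dist_px")
  active <- pairs_active(pairs)
  pairs$pass_contour <- rep(NA, nrow(pairs))
  if (nrow(pairs) == 0L) return(pairs)
  fg <- mask > 0
  if (!any(fg)) {
    warning("all-zero segmentation mask: every pair fails the contour filter")
    pairs$pass_contour[active] <- FALSE
    return(pairs)
  }
  eroded <- EBImage::erode(fg * 1, EBImage::makeBrush(3, "box")) > 0.5
  contour <- fg & !eroded
  # distance of every pixel to the nearest contour pixel
  dist <- EBImage::distmap(1 - contour)
  d_at <- function(r, c) {
    i <- pmin(pmax(round(r), 0), nrow(dist) - 1) + 1
    j <- pmin(pmax(round(c), 0), ncol(dist) - 1) + 1
    dist[cbind(i, j)]
  }
  a_row <- if ("row1_raw" %in% names(pairs)) pairs$row1_raw else pairs$row1
  a_col <- if ("col1_raw" %in% names(pairs)) pairs$col1_raw else pairs$col1
  ok <- d_at(a_row, a_col) <= max_contour_dist_px &
    d_at(pairs$row2, pairs$col2) <= max_contour_dist_px
  pairs$pass_contour[active] <- ok[active]
  pairs
}

#' Feature-density filter on (second momentum, eccentricity)
#'
#' Genuine anchored spot pairs share similar brightness structure and
#' roundness, so they form the densest cloud in feature space. Per
#' channel, a Gaussian kernel density estimate (Scott's-rule bandwidth on
#' standardized features) is evaluated over the paired spots'
#' (second momentum, eccentricity); each pair is scored by the lower of
#' its two channels' density percentile ranks and the densest
#' `round(n * cutoff)` pairs pass — with the default cutoff of 0.5 the
#' densest ~50% of the population is retained.
#'
#' Needs a minimal population for the density estimate to mean anything;
#' below `min_pairs` the filter is skipped (pairs flagged pass-by-default
#' with an NA flag and a warning).
#'
#' @param pairs pair table (pooled over fields of view is fine).
#' @param density_cutoff retained fraction, in (0, 1).
#' @param min_pairs minimum active pairs for the filter to run.
#' @return `pairs` with a `pass_density` logical column.
#' @export
density_filter <- function(pairs, density_cutoff = 0.5, min_pairs = 20) {
  if (density_cutoff <= 0 || density_cutoff >= 1) {
    stop("'density_cutoff' must be in (0, 1)", call. = FALSE)
  }
  active <- which(pairs_active(pairs))
  pairs$pass_density <- rep(NA, nrow(pairs))
  n <- length(active)
  if (n < min_pairs) {
    warning("only ", n, " active pairs (< ", min_pairs,
            "): density filter skipped, pairs pass by default")
    return(pairs)
  }
  dens_rank <- function(m2, ecc) {
    f <- cbind(scale_safe(m2), scale_safe(ecc))
    h <- n^(-1 / 6)   # Scott's rule in 2D on standardized features
    dens <- vapply(seq_len(n), function(i) {
      u <- (f[, 1] - f[i, 1]) / h
      v <- (f[, 2] - f[i, 2]) / h
      mean(exp(-0.5 * (u^2 + v^2)))
    }, numeric(1))
    list(rank = rank(dens, ties.method = "first") / n, dens = dens)
  }
  k1 <- dens_rank(pairs$m2_1[active], pairs$ecc1[active])
  k2 <- dens_rank(pairs$m2_2[active], pairs$ecc2[active])
  score <- pmin(k1$rank, k2$rank)
  n_keep <- max(0L, min(n, as.integer(floor(n * density_cutoff + 0.5))))
  ord <- order(-score, -(k1$dens + k2$dens), seq_len(n))
  pass <- logical(n)
  if (n_keep > 0) pass[ord[seq_len(n_keep)]] <- TRUE
  pairs$pass_density[active] <- pass
  pairs
}

scale_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) s <- 1
  (x - mean(x)) / s
}

#' 2D-Gaussian goodness-of-fit filter
#'
#' Fits an isotropic 2D Gaussian plus constant offset over each member
#' spot's detection window by nonlinear least squares and computes
#' R^2 = 1 - SS_res / SS_tot. Out-of-focus or artefactual spots (double
#' lobes, flat blobs) fit poorly; a pair passes iff both members reach
#' `r2_threshold`. A non-converged fit scores -Inf and fails.
#'
#' @param pairs pair table (one field of view).
#' @param image1,image2 the pre-processed channel images the spots were
#'   detected in.
#' @param r2_threshold minimum R^2, in \[0, 1\].
#' @param diameter_px fitting window diameter, odd (the detection window).
#' @return `pairs` with `r2_1`, `r2_2` and `pass_gauss` columns.
#' @export
gaussian_fit_filter <- function(pairs, image1, image2, r2_threshold = 0.35,
                                diameter_px = 11) {
  w <- (as.integer(diameter_px) - 1L) %/% 2L
  active <- pairs_active(pairs)
  n <- nrow(pairs)
  pairs$r2_1 <- rep(NA_real_, n)
  pairs$r2_2 <- rep(NA_real_, n)
  pairs$pass_gauss <- rep(NA, n)
  a_row <- if ("row1_raw" %in% names(pairs)) pairs$row1_raw else pairs$row1
  a_col <- if ("col1_raw" %in% names(pairs)) pairs$col1_raw else pairs$col1
  for (i in which(active)) {
    g1 <- fit_spot_gaussian(image1, round(c(a_row[i], a_col[i])),
                            w)
    g2 <- fit_spot_gaussian(image2, round(c(pairs$row2[i], pairs$col2[i])),
                            w)
    r1 <- if (is.null(g1)) -Inf else g1$r2
    r2 <- if (is.null(g2)) -Inf else g2$r2
    pairs$r2_1[i] <- r1
    pairs$r2_2[i] <- r2
    pairs$pass_gauss[i] <- is.finite(r1) && is.finite(r2) &&
      r1 >= r2_threshold && r2 >= r2_threshold
  }
  pairs
}
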