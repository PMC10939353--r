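# Sub-pixel spot localization and cross-channel pair linking.
#
# Localization follows the Crocker-Grier convention: candidate local
# maxima above a brightness percentile are refined by iterative
# intensity-weighted centroiding over a circular window. The refinement
# recentres the window at fractional positions (window pixels resampled by
# bilinear interpolation), which removes the integer-window truncation
# bias that plain recentring leaves behind. Per-spot shape features (mass,
# second momentum, eccentricity) are computed from the same window.

circle_offsets <- function(w) {
  offs <- expand.grid(dr = -w:w, dc = -w:w)
  offs[offs$dr^2 + offs$dc^2 <= w^2, ]
}

# Iterative centroid refinement at fractional window positions. The
# centroid weights are soft-thresholded at clip_frac of the window peak:
# residual background plateaus (e.g. the one-sided cytoplasm remnant at a
# cell edge) otherwise drag the centroid, while for an isolated symmetric
# spot the soft threshold is symmetric and leaves the position untouched.
refine_centroid <- function(image, start, offs, max_iter = 20,
                            tol = 1e-4, clip_frac = 0.1) {
  nr <- nrow(image); nc <- ncol(image)
  w <- max(offs$dr)
  centre <- start
  for (it in seq_len(max_iter)) {
    rows <- centre[1] + offs$dr
    cols <- centre[2] + offs$dc
    if (min(rows) < 0 || min(cols) < 0 ||
        max(rows) > nr - 1 || max(cols) > nc - 1) {
      return(NULL)   # window fell off the image
    }
    vals <- pmax(bilinear_sample(image, rows, cols), 0)
    wts <- pmax(vals - clip_frac * max(vals), 0)
    tot <- sum(wts)
    if (tot <= 0) return(NULL)
    shift <- c(sum(offs$dr * wts), sum(offs$dc * wts)) / tot
    # limit the step so one noisy iteration cannot escape the spot
    shift <- pmin(pmax(shift, -1), 1)
    centre <- centre + shift
    if (max(abs(shift)) < tol) break
  }
  list(centre = centre, vals = vals)
}

spot_features <- function(vals, offs) {
  tot <- sum(vals)
  m2 <- sum(vals * (offs$dr^2 + offs$dc^2)) / tot
  srr <- sum(vals * offs$dr^2) / tot
  scc <- sum(vals * offs$dc^2) / tot
  src <- sum(vals * offs$dr * offs$dc) / tot
  tr <- srr + scc
  disc <- sqrt(max((srr - scc)^2 + 4 * src^2, 0))
  lam_max <- (tr + disc) / 2
  lam_min <- (tr - disc) / 2
  ecc <- if (lam_max <= 0) 0 else sqrt(max(1 - lam_min / lam_max, 0))
  c(mass = tot, m2 = m2, ecc = ecc)
}

# Isotropic 2D Gaussian + offset fit over an integer window centred at
# (r0, c0) (0-based). Returns NULL when the fit fails to converge.
fit_spot_gaussian <- function(image, centre_int, w) {
  nr <- nrow(image); nc <- ncol(image)
  r0 <- centre_int[1]; c0 <- centre_int[2]
  if (r0 - w < 0 || c0 - w < 0 || r0 + w > nr - 1 || c0 + w > nc - 1) {
    return(NULL)
  }
  dr <- rep(-w:w, times = 2 * w + 1)
  dc <- rep(-w:w, each = 2 * w + 1)
  vals <- as.vector(image[(r0 - w):(r0 + w) + 1L, (c0 - w):(c0 + w) + 1L])
  lo <- min(vals); amp <- max(vals) - lo
  if (amp <= 0) return(NULL)
  df <- data.frame(v = vals, dr = dr, dc = dc)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A * exp(-((dr - mr)^2 + (dc - mc)^2) / (2 * s^2)) + B,
      data = df,
      start = list(A = amp, B = lo, mr = 0, mc = 0, s = max(w / 2.5, 1)),
      lower = c(0, -Inf, -w, -w, 0.3),
      upper = c(Inf, Inf, w, w, 4 * w),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL, warning = function(w2) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((vals - mean(vals))^2)
  r2 <- if (ss_tot <= 0) -Inf else 1 - ss_res / ss_tot
  list(centre = c(r0 + p[["mr"]], c0 + p[["mc"]]), sigma = p[["s"]],
       amplitude = p[["A"]], offset = p[["B"]], r2 = r2)
}

#' Detect diffraction-limited spots with sub-pixel precision
#'
#' Candidate local maxima above the given brightness percentile are
#' refined to sub-pixel centroids by iterative intensity-weighted
#' centroiding over a circular window of the given diameter; total mass,
#' second momentum (intensity-weighted mean squared radius, px^2) and
#' eccentricity (from the intensity covariance eigenvalues) are computed
#' from the same window. `refine = "gaussian"` additionally replaces each
#' centroid by an isotropic 2D-Gaussian least-squares position, which is
#' the right choice for bright beads where sub-nm accuracy matters.
#'
#' @param image pre-processed (background-subtracted) channel image.
#' @param diameter_px detection window diameter, odd.
#' @param min_mass minimum integrated window intensity for a spot to be
#'   kept.
#' @param percentile brightness percentile (0-100) a candidate local
#'   maximum must exceed.
#' @param refine `"centroid"` (default) or `"gaussian"`.
#' @return a `data.frame` with one row per spot: `row`, `col` (0-based,
#'   sub-pixel), `mass`, `m2`, `ecc`, `peak` and, for Gaussian refinement,
#'   `gauss_r2`. Empty (zero-row) for a blank image.
#' @export
detect_spots <- function(image, diameter_px = 11, min_mass = 0,
                         percentile = 99.5,
                         refine = c("centroid", "gaussian")) {
  refine <- match.arg(refine)
  diameter_px <- as.integer(diameter_px)
  if (diameter_px < 3L || diameter_px %% 2L == 0L) {
    stop("'diameter_px' must be odd and >= 3", call. = FALSE)
  }
  w <- (diameter_px - 1L) %/% 2L
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      mass = numeric(0), m2 = numeric(0), ecc = numeric(0),
                      peak = numeric(0), gauss_r2 = numeric(0))
  if (max(image) <= 0) return(empty)

  thr <- stats::quantile(image, percentile / 100, names = FALSE)
  dil <- EBImage::dilate(image, EBImage::makeBrush(diameter_px, "box"))
  cand <- which(image >= dil & image > max(thr, 0), arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  # window must fit the frame
  nr <- nrow(image); nc <- ncol(image)
  keep <- cand[, 1] > w & cand[, 1] <= nr - w &
    cand[, 2] > w & cand[, 2] <= nc - w
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(image[cand], decreasing = TRUE), , drop = FALSE]

  offs <- circle_offsets(w)
  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    start <- c(cand[i, 1] - 1, cand[i, 2] - 1)   # to 0-based
    ref <- refine_centroid(image, start, offs)
    if (is.null(ref)) next
    centre <- ref$centre
    feats <- spot_features(ref$vals, offs)
    g_r2 <- NA_real_
    if (refine == "gaussian") {
      gf <- fit_spot_gaussian(image, round(centre), w)
      if (!is.null(gf)) {
        centre <- gf$centre
        g_r2 <- gf$r2
      }
    }
    out[[i]] <- c(centre[1], centre[2], feats, image[cand[i, 1], cand[i, 2]],
                  g_r2)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  spots <- data.frame(row = out[, 1], col = out[, 2], mass = out[, 3],
                      m2 = out[, 4], ecc = out[, 5], peak = out[, 6],
                      gauss_r2 = out[, 7])
  # merge refinements that converged onto the same spot: keep the brighter
  if (nrow(spots) > 1L) {
    o <- order(spots$mass, decreasing = TRUE)
    spots <- spots[o, ]
    keep <- rep(TRUE, nrow(spots))
    for (i in seq_len(nrow(spots))[-1]) {
      prev <- which(keep[seq_len(i - 1)])
      dd <- sqrt((spots$row[prev] - spots$row[i])^2 +
                   (spots$col[prev] - spots$col[i])^2)
      if (any(dd < w)) keep[i] <- FALSE
    }
    spots <- spots[keep, ]
  }
  spots <- spots[spots$mass >= min_mass, , drop = FALSE]
  rownames(spots) <- NULL
  spots
}

#' Link channel-1 and channel-2 spots into pairs
#'
#' Mutual-nearest-neighbour matching between the two channels of one field
#' of view; only pairs with centroid separation at most `max_sep_px` are
#' kept and each spot joins at most one pair. When two candidates are
#' exactly equidistant the brighter channel-2 spot wins (deterministic).
#'
#' @param ch1_spots,ch2_spots spot tables from [detect_spots()] for the
#'   same field of view.
#' @param max_sep_px maximum centroid separation, px (2-3 px recommended:
#'   2 for intra-assembly, 3 for inter-assembly measurements).
#' @return a `data.frame` with one row per pair: `pair_id`, member indices
#'   `idx1`, `idx2` into the input tables, per-member positions/features
#'   (`row1`, `col1`, `mass1`, `m2_1`, `ecc1`, ... and the channel-2
#'   equivalents), and `distance_px` (uncorrected separation).
#' @export
link_pairs <- function(ch1_spots, ch2_spots, max_sep_px = 2) {
  stopifnot_scalar_pos(max_sep_px, "max_sep_px")
  n1 <- nrow(ch1_spots); n2 <- nrow(ch2_spots)
  empty <- cbind(data.frame(pair_id = integer(0), idx1 = integer(0),
                            idx2 = integer(0)),
                 pair_cols(ch1_spots[0, ], ch2_spots[0, ]),
                 data.frame(distance_px = numeric(0)))
  if (n1 == 0L || n2 == 0L) return(empty)
  D <- outer(ch1_spots$row, ch2_spots$row, "-")^2 +
    outer(ch1_spots$col, ch2_spots$col, "-")^2
  # nearest ch2 for each ch1; equidistant ties -> brighter ch2 spot
  best2 <- apply(D, 1, function(dd) {
    cands <- which(dd == min(dd))
    cands[order(-ch2_spots$mass[cands], cands)][1]
  })
  best1 <- apply(D, 2, function(dd) {
    cands <- which(dd == min(dd))
    cands[order(-ch1_spots$mass[cands], cands)][1]
  })
  mutual <- which(best1[best2] == seq_len(n1))
  if (length(mutual) == 0L) return(empty)
  i1 <- mutual
  i2 <- best2[mutual]
  sep <- sqrt(D[cbind(i1, i2)])
  ok <- sep <= max_sep_px
  i1 <- i1[ok]; i2 <- i2[ok]; sep <- sep[ok]
  if (length(i1) == 0L) return(empty)
  out <- cbind(data.frame(pair_id = seq_along(i1), idx1 = i1, idx2 = i2),
               pair_cols(ch1_spots[i1, , drop = FALSE],
                         ch2_spots[i2, , drop = FALSE]),
               data.frame(distance_px = sep))
  rownames(out) <- NULL
  out
}

pair_cols <- function(s1, s2) {
  data.frame(row1 = s1$row, col1 = s1$col, mass1 = s1$mass, m2_1 = s1$m2,
             ecc1 = s1$ecc,
             row2 = s2$row, col2 = s2$col, mass2 = s2$mass, m2_2 = s2$m2,
             ecc2 = s2$ecc)
}

#' Correct spot pairs for chromatic aberration
#'
#' Replaces the channel-1 (anchor) centroids by their image under the
#' registration map and recomputes the pair separation in nm. Correction
#' is a mandatory pipeline stage; `map = NULL` is accepted only as an
#' explicit debugging bypass and is logged loudly.
#'
#' @param pairs pair table from [link_pairs()].
#' @param map an [affine_map()] from the registration stage, or `NULL` to
#'   skip correction (debug only).
#' @param pixel_size_nm sample-plane pixel size, nm.
#' @return the pair table with corrected `row1`, `col1`, `distance_px` and
#'   a `distance_nm` column.
#' @export
correct_chromatic <- function(pairs, map, pixel_size_nm = 64.5) {
  stopifnot_scalar_pos(pixel_size_nm, "pixel_size_nm")
  if (is.null(map)) {
    warning("NO chromatic-aberration correction applied (map = NULL): ",
            "distances are only valid for debugging", call. = FALSE)
  } else {
    stopifnot(inherits(map, "affine_map"))
    if (!"row1_raw" %in% names(pairs)) {
      # keep the image-frame anchor coordinates: window-based filters
      # (Gaussian fit, isolation against raw detections) need them
      pairs$row1_raw <- pairs$row1
      pairs$col1_raw <- pairs$col1
    }
    if (nrow(pairs) > 0L) {
      corr <- apply_affine(map, cbind(pairs$row1_raw, pairs$col1_raw))
      pairs$row1 <- corr[, 1]
      pairs$col1 <- corr[, 2]
    }
  }
  pairs$distance_px <- sqrt((pairs$row1 - pairs$row2)^2 +
                              (pairs$col1 - pairs$col2)^2)
  pairs$distance_nm <- pairs$distance_px * pixel_size_nm
  pairs
}
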