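# Chromatic-aberration registration from multicolour bead fields:
# detect bead centroids in both channels, match them, split the FOV set
# into a fit half and a held-out validation half, fit the affine map on
# the fit half and quantify its accuracy (TRE) on the validation half.

#' Detect calibration beads in one channel
#'
#' A bead-tuned call to [detect_spots()]: Gaussian-refined centroids
#' (bright beads support localization far below the camera pixel) with an
#' isolation step that discards bead aggregates and near neighbours — any
#' centroid whose nearest neighbour lies within `isolation_px` is dropped
#' together with that neighbour. The default isolation radius of 1.5
#' detection windows keeps a neighbouring bead's PSF tail out of the
#' fitting window: tail contamination at closer spacings biases the
#' position by 0.01 px and more, which a sub-nm registration cannot
#' afford.
#'
#' @param image single-channel bead image (raw; beads sit on a flat
#'   background so no pre-processing is required).
#' @param cfg an [optical_config()].
#' @param diameter_px detection window diameter, odd.
#' @param percentile brightness percentile for candidate maxima.
#' @param min_mass minimum integrated intensity.
#' @param isolation_px aggregate-rejection radius, px.
#' @param max_ecc maximum eccentricity: beads are round, and a pair of
#'   beads too close to resolve merges into one elongated blob that the
#'   neighbour-distance rule cannot see.
#' @return a spot `data.frame` (see [detect_spots()]).
#' @export
detect_beads <- function(image, cfg = optical_config(),
                         diameter_px = median_diameter_from(cfg),
                         percentile = 99, min_mass = 0,
                         isolation_px = 1.5 * diameter_px,
                         max_ecc = 0.2) {
  spots <- detect_spots(image, diameter_px = diameter_px,
                        min_mass = min_mass, percentile = percentile,
                        refine = "gaussian")
  if (nrow(spots) >= 2L) {
    D <- as.matrix(stats::dist(cbind(spots$row, spots$col)))
    diag(D) <- Inf
    spots <- spots[apply(D, 1, min) >= isolation_px, , drop = FALSE]
  }
  # after isolation an elongated blob can only be an unresolved aggregate
  # (a close neighbour would have inflated the ecc of a genuine bead too,
  # but such beads are already gone)
  spots <- spots[spots$ecc <= max_ecc, , drop = FALSE]
  rownames(spots) <- NULL
  spots
}

#' Match bead centroids across channels and split FOVs in two halves
#'
#' Channel-1/channel-2 correspondences are formed per field of view by
#' mutual nearest neighbour within `match_tol_px` (ambiguous, non-mutual
#' candidates are dropped). The FOV set is then partitioned into two
#' halves — one to fit the registration map, one held out to validate it —
#' at the FOV level so fit and validation beads are independent. The split
#' alternates even/odd positions in the (optionally seed-permuted) FOV
#' order; with an odd FOV count the fit half receives the extra FOV.
#'
#' @param ch1_centroids,ch2_centroids data.frames with columns `fov`,
#'   `row`, `col`, pooled across fields of view.
#' @param match_tol_px matching tolerance, px (must exceed the largest
#'   expected chromatic displacement).
#' @param seed optional seed permuting the FOV order before the
#'   alternating split.
#' @return a list with `fit` and `validation` data.frames (columns `fov`,
#'   `row1`, `col1`, `row2`, `col2`) and the `fit_fovs` / `validation_fovs`
#'   id vectors.
#' @export
match_and_split <- function(ch1_centroids, ch2_centroids, match_tol_px = 2,
                            seed = NULL) {
  stopifnot_scalar_pos(match_tol_px, "match_tol_px")
  fovs <- sort(unique(c(ch1_centroids$fov, ch2_centroids$fov)))
  matched <- lapply(fovs, function(f) {
    s1 <- ch1_centroids[ch1_centroids$fov == f, , drop = FALSE]
    s2 <- ch2_centroids[ch2_centroids$fov == f, , drop = FALSE]
    if (nrow(s1) == 0L || nrow(s2) == 0L) return(NULL)
    m <- mutual_nn(cbind(s1$row, s1$col), cbind(s2$row, s2$col),
                   match_tol_px)
    if (nrow(m) == 0L) return(NULL)
    data.frame(fov = f,
               row1 = s1$row[m[, 1]], col1 = s1$col[m[, 1]],
               row2 = s2$row[m[, 2]], col2 = s2$col[m[, 2]])
  })
  matched <- do.call(rbind, matched)
  if (is.null(matched) || nrow(matched) == 0L) {
    stop("no bead correspondences found within the matching tolerance",
         call. = FALSE)
  }
  ord <- if (is.null(seed)) fovs else with_seed(seed, sample(fovs))
  fit_fovs <- ord[seq_along(ord) %% 2L == 1L]
  val_fovs <- ord[seq_along(ord) %% 2L == 0L]
  fit <- matched[matched$fov %in% fit_fovs, , drop = FALSE]
  validation <- matched[matched$fov %in% val_fovs, , drop = FALSE]
  if (nrow(fit) < 3L) {
    stop("fewer than 3 bead correspondences in the fit half: cannot ",
         "compute a registration map", call. = FALSE)
  }
  rownames(fit) <- rownames(validation) <- NULL
  list(fit = fit, validation = validation,
       fit_fovs = sort(fit_fovs), validation_fovs = sort(val_fovs))
}

# Mutual nearest-neighbour index pairs within tol; returns a 2-column
# matrix of (i1, i2).
mutual_nn <- function(p1, p2, tol) {
  D2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
  b2 <- apply(D2, 1, which.min)
  b1 <- apply(D2, 2, which.min)
  i1 <- which(b1[b2] == seq_len(nrow(p1)))
  i2 <- b2[i1]
  ok <- D2[cbind(i1, i2)] <= tol^2
  cbind(i1[ok], i2[ok])
}

#' Target registration error on held-out beads
#'
#' Applies the registration map to the validation-half channel-1 centroids
#' and reports the mean deviation from the channel-2 centroids: per-axis
#' mean absolute deviations and, as the scalar gate value, the mean
#' Euclidean residual norm (`tre_nm`). The pre-correction mean deviation
#' is reported alongside for the before/after contrast. Proceed to
#' distance measurements only when the TRE is below 1 nm.
#'
#' @param map an [affine_map()].
#' @param validation validation data.frame from [match_and_split()].
#' @param pixel_size_nm sample-plane pixel size, nm.
#' @return an object of class `registration_report`: `tre_nm`,
#'   `mean_dev_x_nm`, `mean_dev_y_nm` (row/col axes), `pre_tre_nm`,
#'   `n_validation_beads`.
#' @export
compute_tre <- function(map, validation, pixel_size_nm = 64.5) {
  stopifnot(inherits(map, "affine_map"))
  if (is.null(validation) || nrow(validation) == 0L) {
    stop("empty validation set: cannot compute a TRE", call. = FALSE)
  }
  p1 <- cbind(validation$row1, validation$col1)
  p2 <- cbind(validation$row2, validation$col2)
  res_pre <- (p1 - p2) * pixel_size_nm
  res_post <- (apply_affine(map, p1) - p2) * pixel_size_nm
  structure(list(
    tre_nm = mean(sqrt(rowSums(res_post^2))),
    mean_dev_y_nm = mean(abs(res_post[, 1])),
    mean_dev_x_nm = mean(abs(res_post[, 2])),
    pre_tre_nm = mean(sqrt(rowSums(res_pre^2))),
    n_validation_beads = nrow(validation),
    pixel_size_nm = pixel_size_nm), class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat("Registration validation on", x$n_validation_beads, "held-out beads\n")
  cat(sprintf("  TRE (mean Euclidean residual): %.4f nm\n", x$tre_nm))
  cat(sprintf("  per-axis mean |dev|: y %.4f nm, x %.4f nm\n",
              x$mean_dev_y_nm, x$mean_dev_x_nm))
  cat(sprintf("  before correction: %.2f nm\n", x$pre_tre_nm))
  if (x$tre_nm >= 1) {
    cat("  WARNING: TRE >= 1 nm — distance measurements not recommended\n")
  }
  invisible(x)
}

#' Full registration stage: bead images to validated map
#'
#' Detects beads in every field of view of a bead dataset, matches and
#' splits them, fits the affine map on the fit half and computes the TRE
#' on the validation half.
#'
#' @param beads a `bead_dataset` (from [make_bead_dataset()]) or a list of
#'   `list(ch1, ch2)` image pairs.
#' @param cfg an [optical_config()].
#' @param match_tol_px matching tolerance, px.
#' @param seed optional seed for the FOV permutation of the split.
#' @param ... passed to [detect_beads()].
#' @return a list of class `registration`: `map` ([affine_map()]),
#'   `report` ([compute_tre()]), `split`, and the pooled centroid tables.
#' @export
register_beads <- function(beads, cfg = optical_config(), match_tol_px = 2,
                           seed = NULL, ...) {
  images <- if (inherits(beads, "bead_dataset")) beads$images else beads
  cents <- lapply(seq_along(images), function(f) {
    s1 <- detect_beads(images[[f]]$ch1, cfg, ...)
    s2 <- detect_beads(images[[f]]$ch2, cfg, ...)
    list(ch1 = if (nrow(s1)) cbind(fov = f, s1) else NULL,
         ch2 = if (nrow(s2)) cbind(fov = f, s2) else NULL)
  })
  ch1 <- do.call(rbind, lapply(cents, `[[`, "ch1"))
  ch2 <- do.call(rbind, lapply(cents, `[[`, "ch2"))
  split <- match_and_split(ch1, ch2, match_tol_px = match_tol_px,
                           seed = seed)
  map <- fit_affine(cbind(split$fit$row1, split$fit$col1),
                    cbind(split$fit$row2, split$fit$col2))
  report <- compute_tre(map, split$validation, cfg$pixel_size_nm)
  structure(list(map = map, report = report, split = split,
                 ch1_centroids = ch1, ch2_centroids = ch2),
            class = "registration")
}

#' @export
print.registration <- function(x, ...) {
  print(x$map)
  print(x$report)
  invisible(x)
}
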