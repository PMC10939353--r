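# Synthetic-scene generator: bead calibration fields with a known affine
# inter-channel distortion, and yeast-like cell scenes with membrane-
# anchored spot pairs at a known true separation. Every downstream stage
# is testable against the ground truth these emit.
#
# Camera model: expected photon counts are rendered from pixel-integrated
# Gaussian PSFs on top of the structured background, then Poisson shot
# noise plus additive Gaussian read noise is applied (the standard
# wide-field camera model; amplitudes configurable, noise can be disabled).

# Render 2D Gaussian spots (pixel-integrated) onto an image. pos is an
# n x 2 matrix of 0-based (row, col) centres; photons the total count per
# spot. Stamp-based: each spot only touches a (2*halo+1)^2 neighbourhood.
render_spots <- function(shape, pos, photons, sigma_px) {
  img <- matrix(0, shape[1], shape[2])
  if (is.null(pos) || nrow(pos) == 0L) return(img)
  halo <- ceiling(4.5 * sigma_px)
  for (i in seq_len(nrow(pos))) {
    r <- pos[i, 1]; c <- pos[i, 2]
    ri <- max(0L, floor(r) - halo):min(shape[1] - 1L, ceiling(r) + halo)
    ci <- max(0L, floor(c) - halo):min(shape[2] - 1L, ceiling(c) + halo)
    if (length(ri) == 0L || length(ci) == 0L) next
    wr <- stats::pnorm((ri + 0.5 - r) / sigma_px) -
      stats::pnorm((ri - 0.5 - r) / sigma_px)
    wc <- stats::pnorm((ci + 0.5 - c) / sigma_px) -
      stats::pnorm((ci - 0.5 - c) / sigma_px)
    img[ri + 1L, ci + 1L] <- img[ri + 1L, ci + 1L] +
      photons[i] * outer(wr, wc)
  }
  img
}

add_camera_noise <- function(img, read_noise_sd = 2) {
  noisy <- matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img))
  if (read_noise_sd > 0) {
    noisy <- noisy + stats::rnorm(length(img), 0, read_noise_sd)
  }
  noisy
}

# Uniform positions with a minimum pairwise spacing, by rejection sampling
# with bounded retries.
sample_spaced_positions <- function(n, shape, margin, min_spacing,
                                    max_tries = 200L) {
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- c(stats::runif(1, margin, shape[1] - 1 - margin),
             stats::runif(1, margin, shape[2] - 1 - margin))
      if (i == 1L ||
          min(sqrt(rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE],
                                 2, p)^2))) >= min_spacing) {
        pos[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("bead density too high to satisfy the minimum spacing of ",
           signif(min_spacing, 3), " px after ", max_tries, " retries",
           call. = FALSE)
    }
  }
  pos
}

#' Simulate a multicolour bead calibration dataset
#'
#' Generates a grid of two-channel bead fields with a known affine
#' inter-channel distortion, emulating the low-density calibration
#' acquisition used for chromatic-aberration registration: 25-75 beads per
#' field of view across a grid of FOVs. Channel-2 bead positions are drawn
#' uniformly with a minimum spacing of 4 PSF sigmas (so aggregates are
#' negligible); channel-1 positions are the distortion applied to the
#' channel-2 positions plus isotropic Gaussian localization noise.
#'
#' @param cfg an [optical_config()].
#' @param n_fov number of fields of view (the recommended acquisition is a
#'   10 x 10 grid, i.e. 100).
#' @param beads_per_fov integer range `c(min, max)`; the per-FOV count is
#'   drawn uniformly from it.
#' @param distortion an [affine_map()] applied to channel-2 truth positions
#'   to produce channel-1 positions (must be invertible).
#' @param loc_noise_nm isotropic per-axis localization noise added to the
#'   channel-1 truth positions, in nm.
#' @param bead_photons expected photons per bead (calibration beads are
#'   bright; the default reflects that).
#' @param background constant background level, counts.
#' @param read_noise_sd Gaussian read noise s.d., counts.
#' @param noise logical; `FALSE` renders noise-free expected counts.
#' @param seed integer seed; the dataset is bit-for-bit reproducible given
#'   `(cfg, seed)`.
#' @return a list of class `bead_dataset`: `images` (list of
#'   `list(ch1, ch2)` matrices), `truth` (data.frame with columns `fov`,
#'   `bead`, `row1`, `col1`, `row2`, `col2`; 0-based px), `distortion`,
#'   `cfg`.
#' @export
make_bead_dataset <- function(cfg = optical_config(), n_fov = 100,
                              beads_per_fov = c(25, 75),
                              distortion = affine_map(),
                              loc_noise_nm = 0.2,
                              bead_photons = 5e5, background = 100,
                              read_noise_sd = 2, noise = TRUE, seed = 1) {
  stopifnot(inherits(cfg, "optical_config"),
            inherits(distortion, "affine_map"))
  if (length(beads_per_fov) != 2L || beads_per_fov[1] > beads_per_fov[2] ||
      beads_per_fov[1] < 1) {
    stop("'beads_per_fov' must be a valid range c(min, max)", call. = FALSE)
  }
  shape <- cfg$image_shape
  loc_noise_px <- loc_noise_nm / cfg$pixel_size_nm
  min_spacing <- 4 * cfg$psf_sigma_px
  margin <- ceiling(4.5 * cfg$psf_sigma_px) + 2
  with_seed(seed, {
    images <- vector("list", n_fov)
    truth <- vector("list", n_fov)
    for (f in seq_len(n_fov)) {
      nb <- sample(beads_per_fov[1]:beads_per_fov[2], 1L)
      p2 <- sample_spaced_positions(nb, shape, margin, min_spacing)
      p1 <- apply_affine(distortion, p2) +
        matrix(stats::rnorm(2 * nb, 0, loc_noise_px), nb, 2)
      ch1 <- background + render_spots(shape, p1, rep(bead_photons, nb),
                                       cfg$psf_sigma_px)
      ch2 <- background + render_spots(shape, p2, rep(bead_photons, nb),
                                       cfg$psf_sigma_px)
      if (noise) {
        ch1 <- add_camera_noise(ch1, read_noise_sd)
        ch2 <- add_camera_noise(ch2, read_noise_sd)
      }
      images[[f]] <- list(ch1 = ch1, ch2 = ch2)
      truth[[f]] <- data.frame(fov = f, bead = seq_len(nb),
                               row1 = p1[, 1], col1 = p1[, 2],
                               row2 = p2[, 1], col2 = p2[, 2])
    }
    structure(list(images = images, truth = do.call(rbind, truth),
                   distortion = distortion, cfg = cfg),
              class = "bead_dataset")
  })
}

#' Simulate a PICT-like two-channel cell field of view
#'
#' Renders yeast-like cells as disks with elevated cytoplasmic background
#' and a brighter membrane rim, and places anchor/prey spot pairs on the
#' disk boundary (the cell equatorial contour). The channel-2 (prey) truth
#' position is the channel-1 (anchor) truth position plus a displacement of
#' length `true_sep_nm` in a uniform direction; each channel's rendered
#' position additionally carries independent per-axis Gaussian jitter of
#' s.d. `loc_noise_nm`, so measured 2D distances follow
#' Rice(`true_sep_nm`, sqrt(2) * `loc_noise_nm`).
#'
#' @param cfg an [optical_config()].
#' @param n_cells number of cells (0 gives a background-only scene).
#' @param pairs_per_cell anchor/prey pairs per cell, spread around the rim.
#' @param true_sep_nm true anchor-to-prey separation, nm.
#' @param loc_noise_nm per-channel, per-axis localization jitter, nm.
#' @param distortion optional [affine_map()] applied to channel-1 render
#'   positions (same convention as [make_bead_dataset()]): emulates the
#'   chromatic aberration the registration map must undo. `NULL` renders
#'   both channels in the same frame.
#' @param cell_radius_px cell disk radius, px.
#' @param spot_photons expected photons per spot.
#' @param background extracellular background level, counts.
#' @param cyto_extra additional cytoplasmic level inside cells, counts.
#' @param rim_extra peak additional level of the membrane rim, counts.
#' @param rim_sigma_px radial Gaussian width of the rim profile, px.
#' @param read_noise_sd Gaussian read noise s.d., counts.
#' @param noise logical; `FALSE` renders noise-free expected counts.
#' @param seed integer seed.
#' @return a list of class `pict_fov`: `ch1`, `ch2` (matrices), `truth`
#'   (data.frame: `cell`, `pair_id`, rendered anchor position `row1`,
#'   `col1` (channel-1 frame), anchor reference-frame position `row1_ref`,
#'   `col1_ref`, prey `row2`, `col2`, `true_sep_nm`), `mask` (integer label
#'   image of the cell disks), `cells` (centres and radii), `cfg`.
#' @export
make_pict_fov <- function(cfg = optical_config(), n_cells = 9,
                          pairs_per_cell = 2, true_sep_nm = 20,
                          loc_noise_nm = 7, distortion = NULL,
                          cell_radius_px = 25, spot_photons = 15000,
                          background = 100, cyto_extra = 25, rim_extra = 30,
                          rim_sigma_px = 3, read_noise_sd = 2, noise = TRUE,
                          seed = 1) {
  stopifnot(inherits(cfg, "optical_config"))
  if (true_sep_nm < 0) stop("'true_sep_nm' must be >= 0", call. = FALSE)
  shape <- cfg$image_shape
  sep_px <- true_sep_nm / cfg$pixel_size_nm
  jit_px <- loc_noise_nm / cfg$pixel_size_nm

  with_seed(seed, {
    # cells on a jittered grid so disks never overlap
    mask <- matrix(0L, shape[1], shape[2])
    cells <- NULL
    centres <- NULL
    if (n_cells > 0) {
      k <- ceiling(sqrt(n_cells))
      spacing <- floor(min(shape) / k)
      if (spacing < 2 * cell_radius_px + 14) {
        stop("impossible geometry: ", n_cells, " cells of radius ",
             cell_radius_px, " px do not fit a ", shape[1], "x", shape[2],
             " frame without overlap", call. = FALSE)
      }
      grid_pos <- expand.grid(gr = seq_len(k), gc = seq_len(k))
      grid_pos <- grid_pos[seq_len(n_cells), , drop = FALSE]
      jmax <- (spacing - 2 * cell_radius_px - 14) / 2
      centres <- cbind(
        (grid_pos$gr - 0.5) * spacing +
          stats::runif(n_cells, -jmax, jmax) - 1,
        (grid_pos$gc - 0.5) * spacing +
          stats::runif(n_cells, -jmax, jmax) - 1)
      cells <- data.frame(cell = seq_len(n_cells),
                          row = centres[, 1], col = centres[, 2],
                          radius = cell_radius_px)
    }

    rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
    cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
    cellbg <- matrix(0, shape[1], shape[2])
    rim <- matrix(0, shape[1], shape[2])
    if (n_cells > 0) {
      for (i in seq_len(n_cells)) {
        rad <- sqrt((rr - centres[i, 1])^2 + (cc - centres[i, 2])^2)
        inside <- rad <= cell_radius_px
        mask[inside] <- i
        # smooth cytoplasm edge (2 px roll-off) + Gaussian rim profile
        cellbg <- cellbg +
          cyto_extra * stats::plogis((cell_radius_px - rad) / 1.5)
        rim <- rim +
          rim_extra * exp(-(rad - cell_radius_px)^2 / (2 * rim_sigma_px^2))
      }
    }

    # spot pairs on the rims, spread in angle so truth pairs stay isolated
    truth <- NULL
    anchors_render <- NULL
    preys_render <- NULL
    if (n_cells > 0 && pairs_per_cell > 0) {
      rows <- vector("list", n_cells)
      for (i in seq_len(n_cells)) {
        base <- stats::runif(1, 0, 2 * pi)
        ang <- base + (seq_len(pairs_per_cell) - 1) * 2 * pi /
          pairs_per_cell +
          stats::runif(pairs_per_cell, -0.15, 0.15)
        anchor_true <- cbind(centres[i, 1] + cell_radius_px * cos(ang),
                             centres[i, 2] + cell_radius_px * sin(ang))
        phi <- stats::runif(pairs_per_cell, 0, 2 * pi)
        prey_true <- anchor_true + sep_px * cbind(cos(phi), sin(phi))
        a_obs <- anchor_true + matrix(stats::rnorm(2 * pairs_per_cell, 0,
                                                   jit_px),
                                      pairs_per_cell, 2)
        p_obs <- prey_true + matrix(stats::rnorm(2 * pairs_per_cell, 0,
                                                 jit_px),
                                    pairs_per_cell, 2)
        a_render <- if (is.null(distortion)) a_obs else
          apply_affine(distortion, a_obs)
        rows[[i]] <- data.frame(cell = i, pair_id = NA_integer_,
                                row1 = a_render[, 1], col1 = a_render[, 2],
                                row1_ref = a_obs[, 1], col1_ref = a_obs[, 2],
                                row2 = p_obs[, 1], col2 = p_obs[, 2],
                                true_sep_nm = true_sep_nm)
      }
      truth <- do.call(rbind, rows)
      truth$pair_id <- seq_len(nrow(truth))
      anchors_render <- as.matrix(truth[, c("row1", "col1")])
      preys_render <- as.matrix(truth[, c("row2", "col2")])
    } else {
      truth <- data.frame(cell = integer(0), pair_id = integer(0),
                          row1 = numeric(0), col1 = numeric(0),
                          row1_ref = numeric(0), col1_ref = numeric(0),
                          row2 = numeric(0), col2 = numeric(0),
                          true_sep_nm = numeric(0))
    }

    n_spots <- nrow(truth)
    ch1 <- background + cellbg + rim +
      render_spots(shape, anchors_render, rep(spot_photons, n_spots),
                   cfg$psf_sigma_px)
    ch2 <- background + cellbg +
      render_spots(shape, preys_render, rep(spot_photons, n_spots),
                   cfg$psf_sigma_px)
    if (noise) {
      ch1 <- add_camera_noise(ch1, read_noise_sd)
      ch2 <- add_camera_noise(ch2, read_noise_sd)
    }
    structure(list(ch1 = ch1, ch2 = ch2, truth = truth, mask = mask,
                   cells = cells, cfg = cfg),
              class = "pict_fov")
  })
}

#' Write and read two-channel fields of view as multi-page TIFF
#'
#' Channel 1 is stored as the first page, channel 2 as the second. Pixel
#' counts are stored divided by 65535 (the `tiff` writer stores values in
#' \[0, 1\]); `read_fov_tiff` undoes the scaling, so the round trip
#' preserves counts up to float precision.
#'
#' @param fov a `pict_fov`, or a `list(ch1, ch2)` of matrices.
#' @param path TIFF file path.
#' @return `write_fov_tiff` returns `path` invisibly; `read_fov_tiff` a
#'   `list(ch1, ch2)`.
#' @export
write_fov_tiff <- function(fov, path) {
  scale <- 65535
  tiff::writeTIFF(list(pmin(pmax(fov$ch1, 0), scale) / scale,
                       pmin(pmax(fov$ch2, 0), scale) / scale),
                  path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_fov_tiff
#' @export
read_fov_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) {
    stop("expected a two-page (two-channel) TIFF: ", path, call. = FALSE)
  }
  list(ch1 = pages[[1]] * 65535, ch2 = pages[[2]] * 65535)
}

#' Write / read a 16-bit label mask TIFF
#'
#' @param mask integer label matrix (0 = background).
#' @param path TIFF file path.
#' @return `write_mask_tiff` returns `path` invisibly; `read_mask_tiff`
#'   an integer matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
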