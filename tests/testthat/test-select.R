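# The spot-pair selection cascade.

fake_spots <- function(pos, mass = 10) {
  data.frame(row = pos[, 1], col = pos[, 2], mass = mass,
             m2 = 1, ecc = 0.1)
}
fake_pairs <- function(s1, s2, idx = seq_len(nrow(s1))) {
  data.frame(pair_id = seq_along(idx), idx1 = idx, idx2 = idx,
             row1 = s1$row[idx], col1 = s1$col[idx],
             mass1 = s1$mass[idx], m2_1 = s1$m2[idx], ecc1 = s1$ecc[idx],
             row2 = s2$row[idx], col2 = s2$col[idx],
             mass2 = s2$mass[idx], m2_2 = s2$m2[idx], ecc2 = s2$ecc[idx],
             distance_px = 0.5, distance_nm = 32)
}

test_that("isolation keeps well-separated pairs and drops crowded ones", {
  s1 <- fake_spots(rbind(c(20, 20), c(80, 80)))
  s2 <- fake_spots(rbind(c(20, 21), c(80, 81)))
  pairs <- fake_pairs(s1, s2)
  out <- isolation_filter(pairs, s1, s2, 10)
  expect_true(all(out$pass_isolation))
  # a stray channel-2 spot 5 px from the first anchor
  s2b <- rbind(s2, fake_spots(cbind(20, 25)))
  out2 <- isolation_filter(pairs, s1, s2b, 10)
  expect_false(out2$pass_isolation[1])
  expect_true(out2$pass_isolation[2])
})

test_that("isolation agrees exactly with the brute-force oracle", {
  for (rep in 1:3) {
    set.seed(60 + rep)
    n1 <- 70; n2 <- 80
    s1 <- fake_spots(cbind(stats::runif(n1, 0, 150),
                           stats::runif(n1, 0, 150)),
                     mass = stats::runif(n1, 1, 5))
    s2 <- fake_spots(cbind(stats::runif(n2, 0, 150),
                           stats::runif(n2, 0, 150)),
                     mass = stats::runif(n2, 1, 5))
    pairs <- link_pairs(s1, s2, 4)
    out <- isolation_filter(pairs, s1, s2, 10)
    expect_identical(out$pass_isolation, isolation_oracle(pairs, s1, s2, 10))
  }
})

test_that("threshold segmentation recovers disk cells with IoU >= 0.9", {
  fov <- make_pict_fov(cfg_default, n_cells = 5, pairs_per_cell = 0,
                       seed = 7)
  mask <- segment_cells(fov$ch2, "threshold")
  expect_identical(max(mask), 5L)
  for (i in 1:5) expect_gte(mask_iou(mask, fov$mask, i), 0.9)
})

test_that("external masks pass through with shape validation", {
  img <- matrix(0, 64, 64)
  m <- matrix(0L, 64, 64); m[20:30, 20:30] <- 1L
  expect_identical(segment_cells(img, "external_mask", mask = m), m)
  mf <- tempfile(fileext = ".tif")
  write_mask_tiff(m, mf)
  expect_identical(segment_cells(img, "external_mask", mask = mf), m)
  expect_error(segment_cells(matrix(0, 32, 32), "external_mask", mask = m),
               "does not match")
  expect_error(segment_cells(img, "external_mask"), "needs a 'mask'")
})

test_that("blank images segment to an all-zero mask", {
  expect_true(all(segment_cells(matrix(5, 64, 64), "threshold") == 0L))
})

test_that("contour filter keeps rim spots and drops interior ones", {
  mask <- matrix(0L, 100, 100)
  rr <- matrix(0:99, 100, 100); cc <- t(rr)
  mask[(rr - 50)^2 + (cc - 50)^2 <= 40^2] <- 1L
  s_rim <- fake_spots(cbind(50, 90))     # exactly on the boundary
  s_ctr <- fake_spots(cbind(50, 50))     # disk centre, 40 px from contour
  pairs <- rbind(fake_pairs(s_rim, s_rim), fake_pairs(s_ctr, s_ctr))
  pairs$pair_id <- 1:2
  out <- contour_filter(pairs, mask, 13)
  expect_true(out$pass_contour[1])
  expect_false(out$pass_contour[2])
  out0 <- contour_filter(pairs[1, ], mask, 0.51)
  expect_true(out0$pass_contour[1])   # on-contour spot passes any threshold
  expect_warning(out_empty <- contour_filter(pairs, matrix(0L, 100, 100), 13),
                 "all-zero")
  expect_true(all(!out_empty$pass_contour))
})

test_that("fixture rim pairs all pass the contour filter at 13 px", {
  fov <- make_pict_fov(cfg_default, seed = 15)
  tr <- fov$truth
  pairs <- data.frame(pair_id = tr$pair_id, idx1 = tr$pair_id,
                      idx2 = tr$pair_id,
                      row1 = tr$row1_ref, col1 = tr$col1_ref,
                      mass1 = 1, m2_1 = 1, ecc1 = 0.1,
                      row2 = tr$row2, col2 = tr$col2,
                      mass2 = 1, m2_2 = 1, ecc2 = 0.1,
                      distance_px = 0.3, distance_nm = 20)
  out <- contour_filter(pairs, fov$mask, 13)
  expect_true(all(out$pass_contour))
})

make_feature_pairs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(pair_id = seq_len(n), idx1 = seq_len(n), idx2 = seq_len(n),
             row1 = 0, col1 = 0, mass1 = 1,
             m2_1 = stats::rnorm(n, 4, 0.5),
             ecc1 = stats::rnorm(n, 0.3, 0.05),
             row2 = 0, col2 = 0, mass2 = 1,
             m2_2 = stats::rnorm(n, 4, 0.5),
             ecc2 = stats::rnorm(n, 0.3, 0.05),
             distance_px = 0.5, distance_nm = 32)
}

test_that("density filter retains the cutoff fraction on unimodal clouds", {
  pairs <- make_feature_pairs(1000)
  out <- density_filter(pairs, 0.5)
  expect_identical(sum(out$pass_density), 500L)
  for (cutoff in c(0.3, 0.7)) {
    kept <- sum(density_filter(pairs, cutoff)$pass_density)
    expect_lte(abs(kept / 1000 - cutoff), 2 / 1000)
  }
  # rank semantics at the extremes: the retained fraction follows the
  # cutoff, so a vanishing cutoff keeps (almost) nothing and a cutoff
  # near 1 keeps (almost) everything
  expect_lte(sum(density_filter(pairs, 0.001)$pass_density), 1)
  expect_gte(sum(density_filter(pairs, 0.999)$pass_density), 998)
})

test_that("a planted sparse outlier cluster is rejected at cutoff 0.5", {
  pairs <- make_feature_pairs(950)
  outliers <- make_feature_pairs(50, seed = 2)
  outliers$m2_1 <- outliers$m2_1 + 20    # far from the bulk in channel 1
  outliers$pair_id <- outliers$idx1 <- outliers$idx2 <- 951:1000
  all_pairs <- rbind(pairs, outliers)
  out <- density_filter(all_pairs, 0.5)
  expect_true(all(!out$pass_density[951:1000]))
})

test_that("density filter skips tiny populations with a warning", {
  pairs <- make_feature_pairs(10)
  expect_warning(out <- density_filter(pairs, 0.5), "skipped")
  expect_true(all(is.na(out$pass_density)))
  # pass-by-default: downstream selection still sees the pairs
  expect_identical(nrow(pictdist:::selected_pairs(out)), 10L)
})

test_that("Gaussian goodness-of-fit separates spots from junk", {
  img <- matrix(0, 64, 64)
  img <- img + pictdist:::render_spots(c(64, 64), cbind(20.2, 20.7),
                                       1e4, 2.335)
  set.seed(3)
  noise_img <- matrix(abs(stats::rnorm(64 * 64, 0, 5)), 64, 64)
  lobes <- pictdist:::render_spots(c(64, 64), rbind(c(37, 45), c(43, 45)),
                                   c(8e3, 8e3), 1.6)
  test_img <- img + noise_img / 10 + lobes
  pairs <- data.frame(pair_id = 1:3, idx1 = 1:3, idx2 = 1:3,
                      row1 = c(20.2, 50, 40), col1 = c(20.7, 10, 45),
                      mass1 = 1, m2_1 = 1, ecc1 = 0.1,
                      row2 = c(20.2, 50, 40), col2 = c(20.7, 10, 45),
                      mass2 = 1, m2_2 = 1, ecc2 = 0.1,
                      distance_px = 0, distance_nm = 0)
  out <- gaussian_fit_filter(pairs, test_img, test_img, 0.35)
  expect_gt(out$r2_1[1], 0.999)      # clean rendered Gaussian
  expect_true(out$pass_gauss[1])
  expect_false(out$pass_gauss[2])    # noise-only window
  expect_false(out$pass_gauss[3])    # double-lobe artefact
})

test_that("the cascade is monotone: every stage returns a subset", {
  fov <- make_pict_fov(cfg_default, seed = 16)
  p1 <- preprocess_image(fov$ch1)
  p2 <- preprocess_image(fov$ch2)
  s1 <- detect_spots(p1, min_mass = 1000)
  s2 <- detect_spots(p2, min_mass = 1000)
  pairs <- link_pairs(s1, s2, 2)
  pairs <- correct_chromatic(pairs, affine_map(), 64.5)
  n0 <- nrow(pairs)
  pairs <- isolation_filter(pairs, s1, s2, 10)
  n1 <- sum(pairs$pass_isolation, na.rm = TRUE)
  mask <- segment_cells(fov$ch2, "threshold")
  pairs <- contour_filter(pairs, mask, 13)
  n2 <- sum(pictdist:::pairs_active(pairs))
  suppressWarnings(pairs <- density_filter(pairs, 0.5))
  n3 <- sum(pictdist:::pairs_active(pairs))
  pairs <- gaussian_fit_filter(pairs, p1, p2, 0.35)
  n4 <- sum(pictdist:::pairs_active(pairs))
  expect_true(n0 >= n1 && n1 >= n2 && n2 >= n3 && n3 >= n4)
  expect_gt(n4, 0)
  # a pair failing stage k is not evaluated at stage k+1
  failed_iso <- which(!pairs$pass_isolation)
  if (length(failed_iso)) {
    expect_true(all(is.na(pairs$pass_contour[failed_iso])))
  }
})
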