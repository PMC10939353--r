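# Sub-pixel spot detection, linking and chromatic correction.

test_that("a single rendered spot is localized to 0.05 px and is round", {
  img <- pictdist:::render_spots(c(64, 64), cbind(20.3, 41.7), 1e4, 2.335)
  s <- detect_spots(img, min_mass = 100)
  expect_identical(nrow(s), 1L)
  expect_lt(sqrt((s$row - 20.3)^2 + (s$col - 41.7)^2), 0.05)
  expect_lt(s$ecc, 0.05)
  expect_gt(s$m2, 0)
})

test_that("blank images give an empty spot table", {
  s <- detect_spots(matrix(0, 64, 64))
  expect_identical(nrow(s), 0L)
  expect_named(s, c("row", "col", "mass", "m2", "ecc", "peak", "gauss_r2"))
})

test_that("window diameter must be odd", {
  expect_error(detect_spots(matrix(0, 32, 32), diameter_px = 10), "odd")
})

test_that("linking respects the separation cap", {
  s1 <- data.frame(row = 10, col = 10, mass = 5, m2 = 1, ecc = 0.1)
  s2 <- data.frame(row = 10, col = 11.5, mass = 4, m2 = 1, ecc = 0.1)
  p <- link_pairs(s1, s2, max_sep_px = 2)
  expect_identical(nrow(p), 1L)
  expect_equal(p$distance_px, 1.5)
  expect_identical(nrow(link_pairs(s1, s2, max_sep_px = 1)), 0L)
})

test_that("linking is mutual, exclusive and symmetric", {
  set.seed(17)
  n <- 12
  base <- cbind(stats::runif(n, 15, 110), stats::runif(n, 15, 110))
  s1 <- data.frame(row = base[, 1], col = base[, 2],
                   mass = stats::runif(n, 1, 2), m2 = 1, ecc = 0.1)
  s2 <- data.frame(row = base[, 1] + stats::rnorm(n, 0, 0.4),
                   col = base[, 2] + stats::rnorm(n, 0, 0.4),
                   mass = stats::runif(n, 1, 2), m2 = 1, ecc = 0.1)
  p12 <- link_pairs(s1, s2, 2)
  p21 <- link_pairs(s2, s1, 2)
  expect_identical(nrow(p12), nrow(p21))
  expect_setequal(paste(p12$idx1, p12$idx2), paste(p21$idx2, p21$idx1))
  expect_identical(anyDuplicated(p12$idx1), 0L)
  expect_identical(anyDuplicated(p12$idx2), 0L)
  expect_true(all(p12$distance_px <= 2))
})

test_that("all truth pairs in a synthetic FOV are recovered exactly", {
  fov <- make_pict_fov(cfg_default, n_cells = 4, pairs_per_cell = 2,
                       loc_noise_nm = 0, noise = FALSE, seed = 8)
  p1 <- preprocess_image(fov$ch1)
  p2 <- preprocess_image(fov$ch2)
  s1 <- detect_spots(p1, min_mass = 1000)
  s2 <- detect_spots(p2, min_mass = 1000)
  pairs <- link_pairs(s1, s2, 2)
  # recall and precision both 1: 8 truth pairs, 8 recovered, 1:1
  expect_identical(nrow(pairs), 8L)
  d1 <- truth_errors(data.frame(row = pairs$row1, col = pairs$col1),
                     cbind(fov$truth$row1, fov$truth$col1))
  d2 <- truth_errors(data.frame(row = pairs$row2, col = pairs$col2),
                     cbind(fov$truth$row2, fov$truth$col2))
  expect_lt(max(c(d1, d2)), 0.15)
  # each truth pair claimed exactly once
  nearest <- apply(outer(pairs$row1, fov$truth$row1, "-")^2 +
                     outer(pairs$col1, fov$truth$col1, "-")^2, 1,
                   which.min)
  expect_setequal(nearest, seq_len(8))
})

test_that("chromatic correction recomputes distances", {
  pairs <- data.frame(pair_id = 1, idx1 = 1, idx2 = 1,
                      row1 = 20, col1 = 30, mass1 = 1, m2_1 = 1, ecc1 = 0,
                      row2 = 20, col2 = 30, mass2 = 1, m2_2 = 1, ecc2 = 0,
                      distance_px = 0)
  ident <- correct_chromatic(pairs, affine_map(), 64.5)
  expect_equal(ident$distance_nm, 0)
  shift <- correct_chromatic(pairs, affine_map(translation = c(1, 0)), 64.5)
  expect_equal(shift$distance_nm, 64.5)
  expect_warning(correct_chromatic(pairs, NULL, 64.5), "NO chromatic")
})

test_that("correction with the fitted map shrinks pair distances", {
  distortion <- affine_map(diag(2) * 1.003, c(1.5, 0.7))
  fov <- make_pict_fov(cfg_default, distortion = distortion,
                       loc_noise_nm = 2, seed = 12)
  p1 <- preprocess_image(fov$ch1)
  p2 <- preprocess_image(fov$ch2)
  s1 <- detect_spots(p1, min_mass = 1000)
  s2 <- detect_spots(p2, min_mass = 1000)
  pairs <- link_pairs(s1, s2, 3)
  expect_gt(nrow(pairs), 10)
  before <- correct_chromatic(pairs, NULL, 64.5) |> suppressWarnings()
  after <- correct_chromatic(pairs, invert_affine(distortion), 64.5)
  expect_lt(mean(after$distance_nm), mean(before$distance_nm))
  # raw channel-1 coordinates are preserved for image-space filters
  expect_true(all(c("row1_raw", "col1_raw") %in% names(after)))
  expect_identical(after$row1_raw, pairs$row1)
})
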