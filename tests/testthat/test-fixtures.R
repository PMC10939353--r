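# Synthetic-scene generators: ground truth, geometry, reproducibility.

test_that("bead counts respect the configured range", {
  ds <- make_bead_dataset(cfg_default, n_fov = 6, seed = 1)
  counts <- table(ds$truth$fov)
  expect_true(all(counts >= 25 & counts <= 75))
  expect_length(ds$images, 6)
})

test_that("identity distortion with zero noise gives identical channels", {
  ds <- make_bead_dataset(cfg_default, n_fov = 2, distortion = affine_map(),
                          loc_noise_nm = 0, seed = 2)
  expect_equal(ds$truth$row1, ds$truth$row2, tolerance = 1e-12)
  expect_equal(ds$truth$col1, ds$truth$col2, tolerance = 1e-12)
})

test_that("a pure translation shifts channel-1 truth by that amount", {
  ds <- make_bead_dataset(cfg_default, n_fov = 2,
                          distortion = affine_map(translation = c(2, 0)),
                          loc_noise_nm = 0, seed = 3)
  expect_equal(ds$truth$row1, ds$truth$row2 + 2, tolerance = 1e-12)
  expect_equal(ds$truth$col1, ds$truth$col2, tolerance = 1e-12)
})

test_that("rendered datasets are bit-for-bit reproducible given the seed", {
  a <- make_bead_dataset(cfg_default, n_fov = 2, seed = 7)
  b <- make_bead_dataset(cfg_default, n_fov = 2, seed = 7)
  expect_identical(a$images, b$images)
  expect_identical(a$truth, b$truth)
  f1 <- make_pict_fov(cfg_default, seed = 7)
  f2 <- make_pict_fov(cfg_default, seed = 7)
  expect_identical(f1$ch1, f2$ch1)
  expect_identical(f1$truth, f2$truth)
})

test_that("impossible bead density fails after bounded retries", {
  small <- optical_config(image_shape = c(64, 64))
  expect_error(
    make_bead_dataset(small, n_fov = 1, beads_per_fov = c(500, 500),
                      seed = 1),
    "density too high")
})

test_that("rendered spot centroids sit on their truth positions", {
  # noise-free render; intensity-weighted centroid over a 7x7 window
  # centred on the truth position (bilinear-resampled, so the check sees
  # the renderer's mass placement rather than window truncation)
  pos <- rbind(c(40.3, 52.8), c(70.45, 31.2), c(20.0, 90.62))
  img <- pictdist:::render_spots(c(128, 128), pos, rep(1e4, 3), 2.335)
  offs <- expand.grid(dr = -3:3, dc = -3:3)
  for (i in seq_len(nrow(pos))) {
    vals <- pictdist:::bilinear_sample(img, pos[i, 1] + offs$dr,
                                       pos[i, 2] + offs$dc)
    cr <- pos[i, 1] + sum(offs$dr * vals) / sum(vals)
    cc <- pos[i, 2] + sum(offs$dc * vals) / sum(vals)
    expect_lt(sqrt((cr - pos[i, 1])^2 + (cc - pos[i, 2])^2), 0.2)
  }
})

test_that("empty cell scene renders background only", {
  fov <- make_pict_fov(cfg_default, n_cells = 0, seed = 1)
  expect_identical(nrow(fov$truth), 0L)
  expect_true(all(fov$mask == 0L))
  # no structure beyond camera noise around the background level
  expect_lt(abs(mean(fov$ch1) - 100), 1)
  expect_lt(max(fov$ch1), 100 + 8 * sqrt(100))
})

test_that("zero separation and zero jitter make the pair truth coincide", {
  fov <- make_pict_fov(cfg_default, true_sep_nm = 0, loc_noise_nm = 0,
                       seed = 4)
  expect_equal(fov$truth$row1, fov$truth$row2, tolerance = 1e-12)
  expect_equal(fov$truth$col1, fov$truth$col2, tolerance = 1e-12)
})

test_that("pairs are placed on the cell rim", {
  fov <- make_pict_fov(cfg_default, n_cells = 5, pairs_per_cell = 2,
                       seed = 5)
  expect_identical(nrow(fov$truth), 10L)
  for (i in seq_len(10)) {
    ctr <- unlist(fov$cells[fov$truth$cell[i], c("row", "col")])
    rad <- sqrt((fov$truth$row1_ref[i] - ctr[1])^2 +
                  (fov$truth$col1_ref[i] - ctr[2])^2)
    expect_lt(abs(rad - fov$cells$radius[1]), 1)
  }
  expect_identical(sort(unique(as.vector(fov$mask))), 0:5)
})

test_that("impossible cell geometry is an error", {
  small <- optical_config(image_shape = c(96, 96))
  expect_error(make_pict_fov(small, n_cells = 9, seed = 1),
               "impossible geometry")
})

test_that("two-channel TIFF and label-mask round trips preserve data", {
  fov <- make_pict_fov(cfg_default, n_cells = 2, seed = 6)
  tf <- tempfile(fileext = ".tif")
  write_fov_tiff(fov, tf)
  back <- read_fov_tiff(tf)
  expect_equal(back$ch1, fov$ch1, tolerance = 1e-3)
  mf <- tempfile(fileext = ".tif")
  write_mask_tiff(fov$mask, mf)
  expect_identical(read_mask_tiff(mf), fov$mask)
})
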