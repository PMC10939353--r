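# Affine registration: bead detection, matching/splitting, map fitting,
# target registration error.

test_that("noise-free beads are detected completely and accurately", {
  ds <- make_bead_dataset(cfg_default, n_fov = 1, noise = FALSE,
                          loc_noise_nm = 0, seed = 10)
  tr <- ds$truth
  s <- detect_beads(ds$images[[1]]$ch2, cfg_default)
  # the generator's 4-sigma spacing keeps some close neighbours that the
  # aggregate rejection discards; every kept centroid must be accurate
  expect_gt(nrow(s), 0)
  expect_lte(nrow(s), nrow(tr))
  expect_lt(max(truth_errors(s, cbind(tr$row2, tr$col2))), 0.1)
})

test_that("blank images yield no beads", {
  expect_identical(nrow(detect_beads(matrix(0, 64, 64), cfg_default)), 0L)
})

test_that("bead aggregates are rejected", {
  img <- pictdist:::render_spots(c(64, 64), rbind(c(30, 30), c(30, 31)),
                                 c(1e5, 1e5), 2.335)
  s <- detect_beads(img, cfg_default)
  expect_identical(nrow(s), 0L)
})

test_that("affine fit is exact on noiseless transforms", {
  set.seed(31)
  p <- cbind(stats::runif(40, 0, 200), stats::runif(40, 0, 200))
  shift <- sweep(p, 2, c(-1.5, 0.75), "+")
  m1 <- fit_affine(shift, p)   # moving = shifted, reference = p
  expect_equal(m1$linear, diag(2), tolerance = 1e-9)
  expect_equal(m1$translation, c(1.5, -0.75), tolerance = 1e-9)
  m2 <- fit_affine(p * 1.001, p)
  expect_equal(m2$linear, diag(2) / 1.001, tolerance = 1e-9)
  expect_equal(m2$translation, c(0, 0), tolerance = 1e-7)
})

test_that("affine fit recovers a known map from noisy correspondences", {
  set.seed(32)
  truth <- affine_map(matrix(c(1.003, 2e-4, -1e-4, 0.998), 2, 2),
                      c(1.2, -0.8))
  p <- cbind(stats::runif(200, 0, 250), stats::runif(200, 0, 250))
  moving <- p
  reference <- apply_affine(truth, p) +
    matrix(stats::rnorm(400, 0, 0.01), 200, 2)
  fit <- fit_affine(moving, reference)
  # noise 0.01 px over 200 spread points: parameter SEs ~1e-5 (linear)
  expect_lt(max(abs(fit$linear - truth$linear)), 5e-5)
  expect_lt(max(abs(fit$translation - truth$translation)), 8e-3)
})

test_that("degenerate configurations are rejected", {
  line <- cbind(1:10, 2 * (1:10) + 3)
  expect_error(fit_affine(line, line), "collinear")
  expect_error(fit_affine(cbind(1, 1), cbind(1, 1)), "at least 3")
})

test_that("apply/invert behave as a group", {
  m <- affine_map(matrix(c(1.01, 0.002, -0.001, 0.99), 2, 2), c(1.5, -2))
  p <- cbind(c(0, 10, 200.5), c(5, -3, 100))
  expect_identical(apply_affine(affine_map(), p), p)
  round_trip <- apply_affine(invert_affine(m), apply_affine(m, p))
  expect_equal(round_trip, p, tolerance = 1e-9)
})

test_that("affine fitting is rotation-equivariant", {
  set.seed(33)
  p1 <- cbind(stats::runif(50, 0, 100), stats::runif(50, 0, 100))
  truth <- affine_map(matrix(c(1.002, 1e-4, -2e-4, 0.997), 2, 2), c(2, -1))
  p2 <- apply_affine(truth, p1)
  theta <- 0.3
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  m0 <- fit_affine(p1, p2)
  mr <- fit_affine(p1 %*% t(R), p2 %*% t(R))
  expect_equal(mr$linear, R %*% m0$linear %*% solve(R), tolerance = 1e-9)
  expect_equal(mr$translation, as.vector(R %*% m0$translation),
               tolerance = 1e-8)
})

test_that("map serialization round-trips", {
  m <- affine_map(matrix(c(1.01, 0.002, -0.001, 0.99), 2, 2), c(1.5, -2), 42L)
  f <- tempfile(fileext = ".json")
  write_affine(m, f)
  back <- read_affine(f)
  expect_equal(back$linear, m$linear, tolerance = 1e-12)
  expect_equal(back$translation, m$translation, tolerance = 1e-12)
  expect_identical(back$n_points_fit, 42L)
})

make_centroid_tables <- function(n_fov, beads = 3, shift = 0.5) {
  set.seed(1)
  tabs <- lapply(seq_len(n_fov), function(f) {
    p <- cbind(stats::runif(beads, 10, 90), stats::runif(beads, 10, 90))
    list(ch1 = data.frame(fov = f, row = p[, 1] + shift, col = p[, 2]),
         ch2 = data.frame(fov = f, row = p[, 1], col = p[, 2]))
  })
  list(ch1 = do.call(rbind, lapply(tabs, `[[`, "ch1")),
       ch2 = do.call(rbind, lapply(tabs, `[[`, "ch2")))
}

test_that("the FOV split is half/half, disjoint and exhaustive", {
  tabs <- make_centroid_tables(100)
  sp <- match_and_split(tabs$ch1, tabs$ch2, match_tol_px = 2)
  expect_length(sp$fit_fovs, 50)
  expect_length(sp$validation_fovs, 50)
  expect_length(intersect(sp$fit_fovs, sp$validation_fovs), 0)
  expect_setequal(c(sp$fit_fovs, sp$validation_fovs), 1:100)

  sp9 <- match_and_split(make_centroid_tables(9)$ch1,
                         make_centroid_tables(9)$ch2, match_tol_px = 2)
  expect_length(sp9$fit_fovs, 5)   # fit gets the extra FOV
  expect_length(sp9$validation_fovs, 4)
})

test_that("centroids without a counterpart within tolerance stay unmatched", {
  tabs <- make_centroid_tables(4, beads = 4, shift = 0.5)
  # plant one channel-1 centroid with no channel-2 partner within 2 px
  stray <- data.frame(fov = 1, row = 5, col = 5)
  sp <- match_and_split(rbind(tabs$ch1, stray), tabs$ch2, match_tol_px = 2)
  all_pairs <- rbind(sp$fit, sp$validation)
  expect_identical(nrow(all_pairs), 16L)    # the stray is excluded
  expect_false(any(all_pairs$row1 == 5 & all_pairs$col1 == 5))
})

test_that("TRE is exact for noiseless distortions and zero for identity", {
  tabs <- make_centroid_tables(10, beads = 6, shift = 0)
  truth <- affine_map(diag(2) * 1.002, c(1.5, 0.7))
  ch1 <- tabs$ch1
  ch1[, c("row", "col")] <- apply_affine(truth, as.matrix(ch1[, c("row",
                                                                  "col")]))
  sp <- match_and_split(ch1, tabs$ch2, match_tol_px = 3)
  map <- fit_affine(as.matrix(sp$fit[, c("row1", "col1")]),
                    as.matrix(sp$fit[, c("row2", "col2")]))
  rep1 <- compute_tre(map, sp$validation, 64.5)
  expect_lt(rep1$tre_nm, 1e-3)
  expect_lt(rep1$tre_nm, rep1$pre_tre_nm)

  sp0 <- match_and_split(tabs$ch1, tabs$ch2, match_tol_px = 2)
  rep0 <- compute_tre(affine_map(), sp0$validation, 64.5)
  expect_identical(rep0$tre_nm, 0)
  expect_error(compute_tre(affine_map(), sp0$validation[0, ], 64.5),
               "empty validation")
})

test_that("registration on a rendered bead grid reaches sub-nm TRE", {
  ds <- make_bead_dataset(cfg_default, n_fov = 16,
                          distortion = affine_map(diag(2) * 1.003,
                                                  c(1.5, 0.7)),
                          loc_noise_nm = 0.2, seed = 40)
  reg <- register_beads(ds, cfg_default, match_tol_px = 3)
  expect_lt(reg$report$tre_nm, 1)
  expect_lt(reg$report$tre_nm, reg$report$pre_tre_nm)
  # recovered map is the inverse of the planted distortion
  expect_equal(reg$map$linear, diag(2) / 1.003, tolerance = 1e-4)
})
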