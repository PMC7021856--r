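test_that("volume primary rate divides summed counts by total projection time", {
  v <- uniform_volume(value = 9600 / 256, dims = c(8, 8, 4),
                      n_proj = 96, t_proj = 10)
  expect_equal(volume_primary_rate(v), 10)
  empty <- array(FALSE, dim = c(8, 8, 4))
  expect_equal(volume_primary_rate(v, empty), 0)
  expect_error(volume_primary_rate(v, array(TRUE, dim = c(4, 4, 4))),
               "dimensions")
})

test_that("threshold mask keeps voxels at or above the fraction of the maximum", {
  v <- count_volume(array(c(0, 5, 100, rep(0, 5)), dim = c(2, 2, 2)),
                    4.8, 96, 10)
  m <- threshold_mask(v, 0.01)           # threshold = 1.0
  expect_equal(sum(m), 2)
  expect_true(all(v$voxels[m] %in% c(5, 100)))
  expect_true(all(threshold_mask(v, 0)))  # degenerate: keeps everything
  # ties at the threshold are included
  vt <- count_volume(array(c(1, 100, rep(0, 6)), dim = c(2, 2, 2)), 4.8, 1, 1)
  expect_true(vt$voxels[1] %in% vt$voxels[threshold_mask(vt, 0.01)])
  expect_error(threshold_mask(count_volume(array(0, dim = c(2, 2, 2)),
                                           4.8, 1, 1)),
               "all-zero")
})

test_that("threshold segmentation is idempotent", {
  set.seed(11)
  v <- count_volume(array(rpois(512, 20), dim = c(8, 8, 8)), 4.8, 96, 5)
  m1 <- threshold_mask(v, 0.5)
  v2 <- v
  v2$voxels[!m1] <- 0
  expect_identical(threshold_mask(v2, 0.5), m1)
})

test_that("ROI discs match a brute-force rasterization oracle", {
  v <- uniform_volume(dims = c(32, 32, 8), voxel = 4.8)
  set.seed(21)
  for (i in 1:5) {
    centre <- runif(2, 40, 32 * 4.8 - 40)
    diam <- runif(1, 10, 70)
    roi <- roi_spec(centre, diam, c(2, 5))
    m <- roi_mask(v, roi)
    oracle <- array(FALSE, dim = dim(v$voxels))
    for (ix in 1:32) for (iy in 1:32) for (iz in 2:5) {
      cx <- (ix - 0.5) * 4.8
      cy <- (iy - 0.5) * 4.8
      oracle[ix, iy, iz] <-
        (cx - centre[1])^2 + (cy - centre[2])^2 <= (diam / 2)^2
    }
    expect_identical(m, oracle)
  }
})

test_that("disjoint ROIs union and out-of-bounds ROIs are rejected", {
  v <- uniform_volume(dims = c(32, 32, 8), voxel = 4.8)
  r1 <- roi_spec(c(40, 40), 20, c(1, 3))
  r2 <- roi_spec(c(110, 110), 20, c(1, 3))
  m <- roi_mask(v, list(r1, r2))
  expect_equal(sum(m), sum(roi_mask(v, r1)) + sum(roi_mask(v, r2)))
  expect_error(roi_mask(v, roi_spec(c(5, 5), 30, c(1, 3))), "outside")
  expect_error(roi_mask(v, roi_spec(c(40, 40), 20, c(7, 9))), "slice")
})

test_that("a 23-cm disc on a coarse grid covers close to its analytic area", {
  v <- uniform_volume(dims = c(128, 128, 4), voxel = 4.8)
  centre <- c(64, 64) * 4.8
  m <- roi_mask(v, roi_spec(centre, 230, c(1, 1)))
  expected <- pi * (230 / 2 / 4.8)^2
  expect_equal(sum(m), expected, tolerance = 0.02)
})

test_that("segmented rates never exceed the whole-volume rate", {
  set.seed(31)
  v <- count_volume(array(rpois(2048, 5), dim = c(16, 16, 8)), 4.8, 96, 5)
  whole <- volume_primary_rate(v)
  expect_lte(volume_primary_rate(v, threshold_mask(v, 0.5)), whole)
  # equality when the mask covers every non-zero voxel
  expect_equal(volume_primary_rate(v, v$voxels > 0), whole)
})

test_that("count volumes round-trip through NIfTI with their sidecar", {
  v <- count_volume(array(rpois(512, 30), dim = c(8, 8, 8)),
                    voxel_size = c(4.8, 4.8, 4.8),
                    n_projections = 96, t_projection = 12)
  path <- tempfile(fileext = ".nii.gz")
  write_count_volume(v, path)
  back <- read_count_volume(path)
  expect_equal(back$voxels, v$voxels)
  expect_equal(back$voxel_size, v$voxel_size, tolerance = 1e-6)
  expect_equal(back$n_projections, 96)
  expect_equal(back$t_projection, 12)
  unlink(c(path, paste0(path, ".json")))
})

test_that("simulated volumes keep their primary-count bookkeeping", {
  cam <- camera_truth()
  ph <- phantom_truth("CTDI-16")
  plan <- acquisition_plan(500, frame_duration = 8, mode = "tomo",
                           seed = 1, noise = FALSE)
  v <- generate_volume(ph, 500, cam, plan)
  injected <- attr(v, "injected_primary")
  total_t <- v$n_projections * v$t_projection
  # whole volume = primary + spurious background
  expect_equal(volume_primary_rate(v),
               (injected + attr(v, "background_counts")) / total_t)
  # threshold segmentation recovers the injected primary counts
  m <- threshold_mask(v, 0.01)
  expect_equal(volume_primary_rate(v, m), injected / total_t,
               tolerance = 1e-10)
  expect_equal(injected / total_t, attr(v, "r_po"), tolerance = 1e-10)
  # with no background, whole-volume and threshold rates coincide
  ph0 <- phantom_truth("CTDI-16", background_level = 0)
  v0 <- generate_volume(ph0, 500, cam, plan)
  expect_equal(volume_primary_rate(v0),
               volume_primary_rate(v0, threshold_mask(v0, 0.01)))
})

test_that("Jaszczak-style sphere shows its 6:1 concentration ratio", {
  cam <- camera_truth()
  ph <- phantom_truth("Jaszczak")
  plan <- acquisition_plan(1000, frame_duration = 10, mode = "tomo",
                           seed = 1, noise = FALSE)
  v <- generate_volume(ph, 1000, cam, plan, grid = c(64, 64, 32))
  vox <- v$voxels
  sphere_level <- max(vox)
  body <- vox[vox > 0 & vox < sphere_level * 0.9]
  expect_equal(sphere_level / stats::median(body), 6, tolerance = 0.01)
})
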