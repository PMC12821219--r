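# Image stack IO, resampling, smoothing, thresholding, mask cleaning.

test_that("TIFF round trip preserves voxels, spacing and overrides", {
  set.seed(5)
  st <- image_stack(array(runif(64 * 64 * 10, 0, 500), c(64, 64, 10)),
                    c(1, 1, 3))
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, f)
  st2 <- read_stack(f)
  expect_identical(dim(st2$voxels), dim(st$voxels))
  expect_lt(max(abs(st2$voxels - st$voxels)), 1e-4)   # float32 storage
  expect_equal(st2$spacing, c(1, 1, 3))
  # explicit override wins
  st3 <- read_stack(f, spacing = c(0.9, 0.9, 2.0))
  expect_equal(st3$spacing, c(0.9, 0.9, 2.0))
  # missing spacing and no override is an explicit error
  f2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:3, function(k) matrix(runif(16), 4, 4)), f2)
  expect_error(read_stack(f2), "spacing")
  expect_error(read_stack(file.path(tempdir(), "does-not-exist.tif")),
               "not found")
})

test_that("resampling to isotropic voxels preserves physical extent", {
  set.seed(1)
  st <- image_stack(array(runif(64 * 64 * 10), c(64, 64, 10)), c(1, 1, 3))
  rs <- resample_isotropic(st)
  expect_equal(rs$spacing, c(1, 1, 1))
  extent_in <- dim(st$voxels) * st$spacing
  extent_out <- dim(rs$voxels) * rs$spacing
  expect_true(all(abs(extent_in - extent_out) <= rs$spacing[1]))
  # already-isotropic input returns voxel-identical data
  iso <- image_stack(array(runif(8^3), c(8, 8, 8)), 1)
  expect_identical(resample_isotropic(iso)$voxels, iso$voxels)
  # constant stays constant
  cst <- resample_isotropic(image_stack(array(5, c(10, 10, 4)), c(1, 1, 2)))
  expect_true(all(cst$voxels == 5))
  expect_error(resample_isotropic(st, target = -1), "> 0")
})

test_that("Gaussian smoothing is physical-unit, identity at 0, exact at a
           point source", {
  set.seed(2)
  st <- image_stack(array(runif(20^3), c(20, 20, 20)), 1)
  expect_identical(gaussian_smooth(st, 0)$voxels, st$voxels)
  cst <- gaussian_smooth(image_stack(array(3, c(16, 16, 16)), 1), 2)
  expect_equal(max(abs(cst$voxels - 3)), 0, tolerance = 1e-12)
  # single bright voxel: peak equals the 3D kernel center weight
  pt <- array(0, c(21, 21, 21)); pt[11, 11, 11] <- 1
  gp <- gaussian_smooth(image_stack(pt, 1), 2)
  w <- dnorm(seq(-6, 6), sd = 2); w <- w / sum(w)
  expect_equal(gp$voxels[11, 11, 11], w[7]^3, tolerance = 1e-12)
  expect_error(gaussian_smooth(st, -1), "sigma")
})

test_that("global and adaptive thresholding separate vessels from background", {
  # two-level stack: global threshold recovers the vessels exactly
  vox <- array(10, c(24, 24, 24))
  vox[8:16, 8:16, ] <- 200
  st <- image_stack(vox, 1)
  bw <- binarize(st, "global", threshold = 100)
  expect_identical(bw$voxels, vox > 100)
  expect_equal(attr(bw, "provenance")$threshold, 100)
  # all-background input warns and yields an empty mask
  expect_warning(b0 <- binarize(image_stack(array(1, c(8, 8, 8)), 1),
                                "global", threshold = 10), "empty")
  expect_false(any(b0$voxels))
  expect_error(binarize(st, "adaptive", window = 2L), "window")
  # adaptive thresholding on a noisy synthetic tube: Dice >= 0.95
  cfg <- synth_config(seed = 3L, block = c(200, 80, 80), n_links = 1L,
                      radius_range = c(10, 10))
  g <- random_vessel_graph(cfg)
  rz <- rasterize_graph(g, cfg, spacing = 1)
  sm <- gaussian_smooth(rz$stack, 1)
  bw2 <- clean_mask(binarize(sm, "adaptive", window = 32L, offset = 0.2),
                    500L)
  expect_gte(dice_coefficient(bw2, rz$mask), 0.95)
})

test_that("clean_mask fills cavities and applies the strict <500 voxel rule", {
  d <- c(60L, 40L, 20L)
  vox <- array(FALSE, d)
  vox[2:21, 2:21, 2:11] <- TRUE               # large block (kept)
  vox[30:39, 25:34, 2:6] <- TRUE              # exactly 10*10*5 = 500: kept
  vox[45:54, 2:11, 2:6] <- TRUE               # 500 ...
  vox[45, 2, 2] <- FALSE                      # ... minus 1 = 499: removed
  cleaned <- clean_mask(binary_mask(vox, 1), 500L)
  expect_equal(sum(cleaned$voxels), sum(vox) - 499L)
  expect_true(all(cleaned$voxels[30:39, 25:34, 2:6]))
  expect_false(any(cleaned$voxels[45:54, 2:11, 2:6]))
  # hollow shell becomes solid
  shell <- array(FALSE, c(30, 30, 30))
  ax <- seq_len(30) - 15.5
  rr <- sqrt(outer(ax^2, ax^2, "+"))
  for (k in 1:30) {
    rad <- sqrt(rr^2 + ax[k]^2)
    shell[, , k] <- rad <= 10 & rad >= 7
  }
  filled <- clean_mask(binary_mask(shell, 1), 10L)
  for (k in 1:30) {
    rad <- sqrt(rr^2 + ax[k]^2)
    expect_true(all(filled$voxels[, , k][rad <= 10]))
  }
  # a solid tube passes through unchanged
  tube <- cylinder_mask(radius = 6, length = 40)
  expect_identical(clean_mask(tube, 500L)$voxels, tube$voxels)
})

test_that("level-set refinement is optional, stable on sharp edges, and
           recovers an eroded tube", {
  cfg <- synth_config(seed = 2L, block = c(120, 60, 60), n_links = 1L,
                      radius_range = c(10, 10), blur_sigma = 1.5,
                      noise_sd = 0)
  g <- random_vessel_graph(cfg)
  rz <- rasterize_graph(g, cfg, spacing = 1)
  truth <- rz$mask
  # 0 iterations: identity
  m0 <- refine_levelset(truth, rz$stack, iterations = 0L)
  expect_identical(m0$voxels, truth$voxels)
  expect_error(refine_levelset(truth, rz$stack, iterations = -1L), ">= 0")
  # a sharp-edged correct mask is a near fixed point
  m1 <- refine_levelset(truth, rz$stack, iterations = 5L)
  expect_gte(dice_coefficient(m1, truth), 0.99)
  # an eroded mask grows back toward the edge
  er <- truth$voxels
  dt <- array(vesselflow:::.edt(as.logical(er), dim(er), c(1, 1, 1)), dim(er))
  eroded <- binary_mask(dt > 1.5, 1)
  d0 <- dice_coefficient(eroded, truth)
  m2 <- refine_levelset(eroded, rz$stack, iterations = 25L)
  expect_gt(dice_coefficient(m2, truth), d0)
})
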