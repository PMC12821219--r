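# Synthetic-data generators: determinism, ground truth contracts, realism
# bounds.

test_that("generators are pure functions of (config, seed)", {
  cfg <- synth_config(seed = 42L, block = c(240, 160, 160), n_links = 6L,
                      radius_range = c(8, 16))
  g1 <- random_vessel_graph(cfg)
  g2 <- random_vessel_graph(cfg)
  expect_identical(g1$polylines, g2$polylines)
  expect_identical(g1$links, g2$links)
  r1 <- rasterize_graph(g1, cfg, spacing = 2)
  r2 <- rasterize_graph(g2, cfg, spacing = 2)
  expect_identical(r1$stack$voxels, r2$stack$voxels)
  expect_identical(r1$mask$voxels, r2$mask$voxels)
  t1 <- synth_permeability_timelapse(1e-8, 80, 1000, noise_sd = 0.05,
                                     seed = 3)
  t2 <- synth_permeability_timelapse(1e-8, 80, 1000, noise_sd = 0.05,
                                     seed = 3)
  expect_identical(t1$frames, t2$frames)
  # the generators do not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(random_vessel_graph(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("n_links = 1 gives a single straight spanning link", {
  cfg <- synth_config(seed = 1L, block = c(200, 100, 100), n_links = 1L,
                      radius_range = c(10, 10))
  g <- random_vessel_graph(cfg)
  expect_equal(nrow(g$links), 1L)
  expect_equal(g$links$tortuosity, 1, tolerance = 1e-9)
  expect_equal(g$polylines[[1]][1, 1], 0)
  expect_equal(g$polylines[[1]][nrow(g$polylines[[1]]), 1], 200)
})

test_that("trees satisfy the radius, connectivity and span contracts", {
  for (sd in c(1L, 2L)) {
    cfg <- synth_config(seed = sd)
    g <- random_vessel_graph(cfg)
    expect_equal(nrow(g$links), 20L)
    expect_true(all(g$links$radius >= cfg$radius_range[1] - 1e-9))
    expect_true(all(g$links$radius <= cfg$radius_range[2] + 1e-9))
    # parent radius never smaller than either child radius
    deg <- table(factor(c(g$links$node_a, g$links$node_b),
                        seq_len(nrow(g$nodes))))
    for (nd in which(deg >= 3)) {
      inc <- which(g$links$node_a == nd | g$links$node_b == nd)
      rmax_child <- sort(g$links$radius[inc], decreasing = TRUE)
      expect_gte(rmax_child[1], rmax_child[2])
    }
    # single connected tree spanning inlet to outlet
    adj <- cbind(g$links$node_a, g$links$node_b)
    seen <- 1L
    repeat {
      grow <- unique(c(adj[adj[, 1] %in% seen, 2], adj[adj[, 2] %in% seen, 1]))
      nxt <- union(seen, grow)
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    expect_setequal(seen, unique(c(adj)))
    xs <- do.call(rbind, g$polylines)
    expect_equal(min(xs[, 1]), 0)
    expect_equal(max(xs[, 1]), cfg$block[1])
    # realism: tortuosity mild, all inside the block
    expect_true(all(g$links$tortuosity < 1.35))
    expect_true(all(xs[, 2] >= 0 & xs[, 2] <= cfg$block[2]))
  }
})

test_that("rasterization matches its ground truth and stays thresholdable", {
  cfg0 <- synth_config(seed = 5L, block = c(200, 120, 120), n_links = 4L,
                       radius_range = c(8, 14), blur_sigma = 0, noise_sd = 0)
  g <- random_vessel_graph(cfg0)
  rz <- rasterize_graph(g, cfg0, spacing = 1)
  # zero blur, zero noise: thresholding at 0.5 IS the ground-truth mask
  expect_identical(rz$stack$voxels > 0.5, rz$mask$voxels)
  expect_error(rasterize_graph(g, cfg0, spacing = 20), "coarser")
})

test_that("the permeability timelapse encodes its stated slope", {
  tl <- synth_permeability_timelapse(1e-8, 80, 1000,
                                     times = seq(0, 120, by = 10))
  gel <- vapply(seq_along(tl$frames),
                function(k) mean(tl$frames[[k]][tl$gel_mask]), numeric(1))
  slope <- coef(lm(gel ~ tl$times))[[2]]
  expect_equal(slope, 2 * 1e-8 / 80e-6 * 1000, tolerance = 1e-9)
  expect_equal(attr(tl, "Pd_true"), 1e-8)
  # zero permeability: flat gel
  tl0 <- synth_permeability_timelapse(0, 80, 1000)
  gel0 <- vapply(seq_along(tl0$frames),
                 function(k) mean(tl0$frames[[k]][tl0$gel_mask]), numeric(1))
  expect_equal(diff(range(gel0)), 0)
})

test_that("bead movies advect beads through the field with exact truth", {
  field <- slab_channel_field()
  mv <- synth_bead_movie(field, n_beads = 12, dt = 0.1, n_frames = 5,
                         pixel_size = 2, seed = 2)
  expect_length(mv$frames, 5)
  expect_length(mv$truth$tracks, 12)
  # determinism
  mv2 <- synth_bead_movie(field, n_beads = 12, dt = 0.1, n_frames = 5,
                          pixel_size = 2, seed = 2)
  expect_identical(mv$trajectories, mv2$trajectories)
  # ground-truth displacement agrees with the local field velocity
  tr <- mv$truth$tracks[[1]]
  v0 <- sample_velocity(field, matrix(c(tr$x[1], tr$y[1],
                                        mv$trajectories[1, 3, 1]), 1)) * 1e6
  step <- c(tr$x[2] - tr$x[1], tr$y[2] - tr$y[1]) / 0.1
  expect_lt(sqrt(sum((step - v0[1:2])^2)), 0.05 * max(sqrt(sum(v0^2)), 1))
  expect_error(synth_bead_movie(field, 0, 0.1, 5), "positive")
})
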