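# Skeletonization, node-link graph extraction, link measures, subdivision,
# radius estimation, network metrics and the CSV round trip.

test_that("a solid cylinder thins to a single open centerline curve", {
  m <- cylinder_mask(radius = 6, length = 60)
  sk <- skeletonize(m)
  expect_true(all(m$voxels[sk$voxels]))          # skeleton subset of mask
  expect_equal(count_components(sk$voxels), count_components(m))
  # exactly 2 endpoint voxels (one skeleton neighbor each)
  d <- dim(sk$voxels)
  vox <- which(sk$voxels, arr.ind = TRUE)
  n26 <- vapply(seq_len(nrow(vox)), function(r) {
    p <- vox[r, ]
    s <- 0L
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      i <- p[1] + dx; j <- p[2] + dy; k <- p[3] + dz
      if (i >= 1 && j >= 1 && k >= 1 && i <= d[1] && j <= d[2] &&
          k <= d[3] && sk$voxels[i, j, k]) s <- s + 1L
    }
    s
  }, integer(1))
  expect_equal(sum(n26 == 1L), 2L)
  expect_true(all(n26 <= 2L))                    # open curve, no branches
  g <- skeleton_to_graph(sk)
  expect_equal(nrow(g$links), 1L)
  expect_equal(sum(g$nodes$kind == "terminal"), 2L)
})

test_that("a solid torus thins to one closed loop with a single cycle", {
  m <- torus_mask()
  sk <- skeletonize(m)
  expect_equal(count_components(sk$voxels), 1L)
  g <- skeleton_to_graph(sk)
  # one self-loop link, no endpoints, Euler cycle count 1
  expect_equal(nrow(g$links), 1L)
  expect_equal(g$links$node_a, g$links$node_b)
  expect_equal(sum(g$nodes$kind == "terminal"), 0L)
  cycles <- nrow(g$links) - nrow(g$nodes) + 1L
  expect_equal(cycles, 1L)
  g <- measure_links(g)
  expect_true(g$links$flagged[1])                # degenerate closed link
  expect_true(is.infinite(g$links$tortuosity[1]))
})

test_that("two disjoint tubes keep two skeleton components", {
  m1 <- cylinder_mask(radius = 5, length = 30)
  d <- dim(m1$voxels)
  vox <- array(FALSE, d + c(30L, 0L, 0L))
  vox[seq_len(d[1]), , ] <- m1$voxels
  vox[d[1] + 10 + seq_len(d[1]), , ] <- m1$voxels
  m <- binary_mask(vox, 1)
  expect_equal(count_components(m), 2L)
  sk <- skeletonize(m)
  expect_equal(count_components(sk$voxels), 2L)
})

test_that("a Y-shaped skeleton yields one branch node, three terminals,
           three links", {
  d <- c(40L, 40L, 5L)
  y <- array(FALSE, d)
  y[5:20, 20, 3] <- TRUE
  for (s in 1:12) { y[20 + s, 20 + s, 3] <- TRUE; y[20 + s, 20 - s, 3] <- TRUE }
  sk <- structure(list(voxels = y, spacing = c(1, 1, 1)), class = "skeleton")
  g <- skeleton_to_graph(sk)
  expect_equal(sum(g$nodes$kind == "branch"), 1L)
  expect_equal(sum(g$nodes$kind == "terminal"), 3L)
  expect_equal(nrow(g$links), 3L)
  # the branch node has graph degree 3
  deg <- table(c(g$links$node_a, g$links$node_b))
  expect_equal(max(deg), 3L)
  # branch/terminal ratio for the metrics contract
  met <- network_metrics(measure_links(g),
                         binary_mask(y, 1), chamber_volume = 1e-3)
  expect_equal(met$branch_terminal_ratio, 1 / 3)
})

test_that("a binary tree with three bifurcations is recovered exactly", {
  d <- c(64L, 64L, 5L)
  tr <- array(FALSE, d)
  tr[4:16, 32, 3] <- TRUE
  for (s in 1:8) { tr[16 + s, 32 + s, 3] <- TRUE; tr[16 + s, 32 - s, 3] <- TRUE }
  for (s in 1:6) {   # second level: arms stay well separated
    tr[24 + s, 40 + s, 3] <- TRUE; tr[24 + s, 40 - s, 3] <- TRUE
    tr[24 + s, 24 + s, 3] <- TRUE; tr[24 + s, 24 - s, 3] <- TRUE
  }
  sk <- structure(list(voxels = tr, spacing = c(1, 1, 1)), class = "skeleton")
  g <- skeleton_to_graph(sk)
  # 3 bifurcations: 3 branch nodes, 5 terminals (root + 4 leaves), 7 links
  expect_equal(sum(g$nodes$kind == "branch"), 3L)
  expect_equal(sum(g$nodes$kind == "terminal"), 5L)
  expect_equal(nrow(g$links), 7L)
  met <- network_metrics(measure_links(g), binary_mask(tr, 1), 1e-3)
  expect_equal(met$branch_terminal_ratio, 3 / 5)
})

test_that("link measures: straight, semicircular and stretched polylines", {
  mk <- function(pl) {
    nodes <- data.frame(id = 1:2, x = pl[c(1, nrow(pl)), 1],
                        y = pl[c(1, nrow(pl)), 2], z = pl[c(1, nrow(pl)), 3],
                        kind = "terminal")
    measure_links(vessel_graph(nodes,
                               data.frame(id = 1L, node_a = 1L, node_b = 2L),
                               list(pl)))
  }
  straight <- mk(cbind(seq(0, 10, 1), 0, 0))
  expect_equal(straight$links$tortuosity, 1.0)
  # discretized semicircle: tortuosity -> pi/2 with refinement
  for (n in c(20, 200)) {
    th <- seq(0, pi, length.out = n)
    semi <- mk(cbind(50 * cos(th), 50 * sin(th), 0))
    expect_equal(semi$links$tortuosity, pi / 2,
                 tolerance = if (n == 20) 1e-2 else 1e-4)
  }
  # path 1.2 L over chord L
  zig <- mk(rbind(c(0, 0, 0), c(0.5, sqrt(0.36^2 - 0.1^2 - 0), 0),
                  c(1, 0, 0)))
  expect_equal(zig$links$euclidean_length, 1)
  expect_equal(zig$links$tortuosity, zig$links$path_length)
  expect_error(measure_links(vessel_graph(
    data.frame(id = 1, x = 0, y = 0, z = 0, kind = "terminal"),
    data.frame(id = 1L, node_a = 1L, node_b = 1L),
    list(matrix(0, 1, 3)))), "n >= 2")
})

test_that("subdivision splits strictly-tortuous links into five conserving
           parts", {
  th <- seq(0, pi * 0.9, length.out = 41)
  pl <- cbind(30 * cos(th) + 40, 30 * sin(th) + 5, 3)
  nodes <- data.frame(id = 1:2, x = pl[c(1, 41), 1], y = pl[c(1, 41), 2],
                      z = 3, kind = "terminal")
  g <- measure_links(vessel_graph(nodes,
                                  data.frame(id = 1L, node_a = 1L,
                                             node_b = 2L), list(pl)))
  g$links$radius <- 5
  expect_gt(g$links$tortuosity, 1.15)
  parent_len <- g$links$path_length
  sub <- subdivide_tortuous(g, threshold = 1.15, parts = 5L)
  expect_equal(nrow(sub$links), 5L)
  expect_equal(sum(sub$nodes$kind == "passthrough"), 4L)
  # exact conservation of total path length, equal arc fractions
  expect_equal(sum(sub$links$path_length), parent_len, tolerance = 1e-12)
  expect_equal(sub$links$path_length, rep(parent_len / 5, 5),
               tolerance = 1e-9)
  # concatenation of child polylines equals the parent polyline
  cat_pl <- do.call(rbind, lapply(seq_along(sub$polylines), function(i) {
    p <- sub$polylines[[i]]
    if (i == 1) p else p[-1, , drop = FALSE]
  }))
  # child polylines contain the parent's vertices (plus the cut points)
  expect_true(all(apply(pl, 1, function(q)
    min(sqrt(colSums((t(cat_pl) - q)^2))) < 1e-9)))
  # boundary semantics: exactly at the threshold means untouched
  g2 <- g
  g2$links$tortuosity <- 1.15
  expect_equal(nrow(subdivide_tortuous(g2)$links), 1L)
  expect_error(subdivide_tortuous(g, parts = 1L), ">= 2")
  # a graph with no tortuous links is returned unchanged
  straight <- measure_links(vessel_graph(
    data.frame(id = 1:2, x = c(0, 60), y = 3, z = 3, kind = "terminal"),
    data.frame(id = 1L, node_a = 1L, node_b = 2L),
    list(cbind(c(0, 30, 60), 3, 3))))
  expect_identical(nrow(subdivide_tortuous(straight)$links), 1L)
})

test_that("radius estimation: cylinder, cone taper and one-voxel line", {
  m <- cylinder_mask(radius = 10, length = 50, pad = 4)
  sk <- skeletonize(m)
  # perimeter-association estimator: robust to the lattice-aligned axis,
  # where the minimum-distance convention clips by half a diagonal
  g <- estimate_radii(measure_links(skeleton_to_graph(sk)), m,
                      method = "perimeter")
  expect_gte(g$links$radius, 9.5)
  expect_lte(g$links$radius, 10.5)
  # the distance-transform default agrees within the digital half-diagonal
  g0 <- estimate_radii(measure_links(skeleton_to_graph(sk)), m)
  expect_lt(abs(g0$links$radius - 10), 1)
  # cone: per-point radii monotone after 3-point median smoothing
  d <- c(40L, 40L, 60L)
  vox <- array(FALSE, d)
  ax <- seq_len(40) - 20.5
  rr <- sqrt(outer(ax^2, ax^2, "+"))
  for (k in 3:58) vox[, , k] <- rr <= 5 + 10 * (k - 3) / 55
  cone <- binary_mask(vox, 1)
  gc <- estimate_radii(measure_links(skeleton_to_graph(skeletonize(cone))),
                       cone)
  pr <- gc$point_radii[[which.max(gc$links$path_length)]]
  pl <- gc$polylines[[which.max(gc$links$path_length)]]
  if (pl[1, 3] > pl[nrow(pl), 3]) pr <- rev(pr)
  sm3 <- stats::runmed(pr, 3)
  expect_true(all(diff(sm3) >= -0.75))   # non-decreasing up to voxel noise
  expect_gt(mean(tail(sm3, 5)), mean(head(sm3, 5)))
  # one-voxel-wide line: sub-voxel convention, radius about one voxel
  d2 <- c(9L, 9L, 30L)
  line <- array(FALSE, d2); line[5, 5, 3:28] <- TRUE
  lm <- binary_mask(line, 1)
  gl <- estimate_radii(measure_links(skeleton_to_graph(skeletonize(lm))), lm)
  expect_gte(gl$links$radius, 0.5)
  expect_lte(gl$links$radius, 1.2)
})

test_that("network metrics compute coverage, density and handle an empty
           graph", {
  d <- c(100L, 100L, 10L)
  vox <- array(FALSE, d)
  vox[1:100, 1:100, 1:10] <- FALSE
  vox[seq_len(100), seq_len(100), 1] <- TRUE    # 1e4 voxels of (1 um)^3
  vox[, , 2:10] <- FALSE
  m <- binary_mask(vox, 1)
  g <- measure_links(vessel_graph(
    data.frame(id = 1:2, x = c(0, 99), y = 50, z = 1, kind = "terminal"),
    data.frame(id = 1L, node_a = 1L, node_b = 2L),
    list(cbind(c(0, 99), 50, 1))))
  met <- network_metrics(g, m, chamber_volume = 1e-4)
  expect_equal(met$volumetric_coverage, 1e4 * 1e-9 / 1e-4)
  expect_equal(met$vessel_density, 1 / 1e-4)
  expect_error(network_metrics(g, m, 0), "positive")
  # graph with no terminals: ratio NaN with warning
  loop <- measure_links(vessel_graph(
    data.frame(id = 1L, x = 5, y = 5, z = 1, kind = "passthrough"),
    data.frame(id = 1L, node_a = 1L, node_b = 1L),
    list(rbind(c(5, 5, 1), c(6, 6, 1), c(5, 5, 1)))))
  expect_warning(m2 <- network_metrics(loop, m, 1e-4), "undefined")
  expect_true(is.nan(m2$branch_terminal_ratio))
})

test_that("graph CSV export round-trips losslessly", {
  cfg <- synth_config(seed = 9L, block = c(240, 160, 160), n_links = 7L,
                      radius_range = c(8, 16))
  g <- random_vessel_graph(cfg)
  path <- file.path(tempdir(), "net")
  files <- export_graph_csv(g, path)
  g2 <- read_graph_csv(path)
  expect_equal(nrow(g2$links), nrow(g$links))
  expect_equal(g2$links$radius, g$links$radius, tolerance = 1e-9)
  expect_equal(g2$nodes$x, g$nodes$x, tolerance = 1e-4)
  # positions round-trip to < 1e-4 um
  for (t in seq_along(g$polylines))
    expect_lt(max(abs(g2$polylines[[t]] - g$polylines[[t]])), 1e-4)
  expect_equal(g2$links$path_length, g$links$path_length, tolerance = 1e-7)
  file.remove(paste0(path, c("_nodes.csv", "_links.csv")))
})
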