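# Label-field construction, iso-surfacing, registration, deviation.

test_that("a single capsule labels lumen, shell and interstitium exactly", {
  nodes <- data.frame(id = 1:2, x = c(20, 180), y = 50, z = 50,
                      kind = "terminal")
  links <- data.frame(id = 1L, node_a = 1L, node_b = 2L, radius = 10)
  g <- measure_links(vessel_graph(nodes, links,
                                  list(rbind(c(20, 50, 50), c(180, 50, 50)))))
  g$links$radius <- 10
  f <- build_label_field(g, block = c(200, 100, 100), t_endo = 5,
                         resolution = 1)
  set.seed(3)
  d <- dim(f$labels)
  ii <- cbind(sample.int(d[1], 4000, TRUE), sample.int(d[2], 4000, TRUE),
              sample.int(d[3], 4000, TRUE))
  ctr <- ii - 0.5
  t <- pmin(pmax((ctr[, 1] - 20) / 160, 0), 1)
  dd <- sqrt((ctr[, 1] - (20 + 160 * t))^2 + (ctr[, 2] - 50)^2 +
             (ctr[, 3] - 50)^2)
  want <- ifelse(dd <= 10, LUMEN, ifelse(dd <= 15, ENDOTHELIUM, INTERSTITIUM))
  expect_identical(f$labels[ii], want)
  # partition invariant: every voxel exactly one known label
  expect_true(all(f$labels %in% c(EXTERIOR, LUMEN, ENDOTHELIUM,
                                  INTERSTITIUM)))
  # monotonicity in shell thickness
  f2 <- build_label_field(g, block = c(200, 100, 100), t_endo = 8,
                          resolution = 1)
  expect_gt(sum(f2$labels == ENDOTHELIUM), sum(f$labels == ENDOTHELIUM))
  expect_equal(sum(f2$labels == LUMEN), sum(f$labels == LUMEN))
  # resolution coarser than the smallest radius errors out
  expect_error(build_label_field(g, c(200, 100, 100), 5, resolution = 12),
               "coarser")
})

test_that("collinear links sharing a node leave no seam inside the union", {
  nodes <- data.frame(id = 1:3, x = c(20, 100, 180), y = 50, z = 50,
                      kind = c("terminal", "passthrough", "terminal"))
  links <- data.frame(id = 1:2, node_a = c(1L, 2L), node_b = c(2L, 3L),
                      radius = 10)
  g <- measure_links(vessel_graph(nodes, links,
         list(rbind(c(20, 50, 50), c(100, 50, 50)),
              rbind(c(100, 50, 50), c(180, 50, 50)))))
  g$links$radius <- c(10, 10)
  f <- build_label_field(g, block = c(200, 100, 100), t_endo = 5,
                         resolution = 1)
  # scan the junction slab: everything within the union must be lumen
  slab <- f$labels[95:105, , ]
  ctr_y <- rep(seq_len(100) - 50.5, times = 100)
  ctr_z <- rep(seq_len(100) - 50.5, each = 100)
  inside <- sqrt(ctr_y^2 + ctr_z^2) <= 9.4   # strictly inside, half-voxel in
  for (s in 1:11)
    expect_true(all(slab[s, , ][inside] == LUMEN))
  # empty graph: all interstitium
  ge <- vessel_graph(nodes[0, ], links[0, ], list())
  fe <- build_label_field(ge, block = c(40, 40, 40), t_endo = 5,
                          resolution = 2)
  expect_true(all(fe$labels == INTERSTITIUM))
})

test_that("iso-surfaces have correct area, topology and handle tiny input", {
  fs <- sphere_field(radius = 20, side = 100)
  ms <- extract_surface(fs, LUMEN)
  expect_lt(abs(mesh_area(ms) / (4 * pi * 20^2) - 1), 0.05)
  expect_true(mesh_is_watertight(ms))
  expect_equal(mesh_euler_characteristic(ms), 2L)      # genus 0
  # capsule: also genus-0 watertight
  nodes <- data.frame(id = 1:2, x = c(30, 90), y = 40, z = 40,
                      kind = "terminal")
  links <- data.frame(id = 1L, node_a = 1L, node_b = 2L, radius = 12)
  g <- measure_links(vessel_graph(nodes, links,
                                  list(rbind(c(30, 40, 40), c(90, 40, 40)))))
  g$links$radius <- 12
  fc <- build_label_field(g, block = c(120, 80, 80), t_endo = 5,
                          resolution = 1)
  mc <- extract_surface(fc, LUMEN)
  expect_true(mesh_is_watertight(mc))
  expect_equal(mesh_euler_characteristic(mc), 2L)
  # single-voxel label: small closed mesh, no crash
  lf <- fc
  lf$labels[] <- EXTERIOR
  lf$labels[60, 40, 40] <- LUMEN
  m1 <- extract_surface(lf, LUMEN, smooth_sigma = 0)
  expect_gt(nrow(m1$faces), 0)
  expect_true(mesh_is_watertight(m1))
  expect_error(extract_surface(lf, ENDOTHELIUM), "not present")
})

test_that("rigid ICP recovers identity, translation and rotation", {
  fs <- sphere_field(radius = 20, side = 100)
  # an asymmetric two-sphere compound so rotations are observable
  nodes <- data.frame(id = 1:2, x = c(35, 70), y = c(40, 55), z = 50,
                      kind = "terminal")
  links <- data.frame(id = 1L, node_a = 1L, node_b = 2L, radius = 10)
  g <- measure_links(vessel_graph(nodes, links,
                                  list(rbind(c(35, 40, 50), c(70, 55, 50)))))
  g$links$radius <- 10
  f <- build_label_field(g, block = c(100, 100, 100), t_endo = 5,
                         resolution = 1)
  mesh <- extract_surface(f, LUMEN)
  P <- mesh$vertices
  # identity
  tr0 <- register_rigid(P, mesh)
  expect_lt(tr0$rms, 1e-6)
  # known translation
  Q <- P + matrix(c(5, 0, 0), nrow(P), 3, byrow = TRUE)
  tr1 <- register_rigid(Q, mesh, rms_tol = 1e-9)
  expect_lt(max(abs(tr1$t - c(-5, 0, 0))), 0.1)
  # known rotation about z (10 degrees about the centroid)
  th <- 10 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- colMeans(P)
  Q2 <- sweep(sweep(P, 2, ctr) %*% t(Rz), 2, ctr, "+")
  tr2 <- register_rigid(Q2, mesh, rms_tol = 1e-9)
  ang <- acos(min(max((sum(diag(tr2$R %*% Rz)) - 1) / 2, -1), 1)) * 180 / pi
  expect_lt(ang, 0.5)
  expect_lt(tr2$rms, 0.05)
  expect_error(register_rigid(matrix(numeric(0), 0, 3), mesh), "nonempty")
})

test_that("cloud-to-mesh deviation matches concentric-sphere analytics", {
  m20 <- extract_surface(sphere_field(radius = 20, side = 100), LUMEN)
  m25 <- extract_surface(sphere_field(radius = 25, side = 100), LUMEN)
  set.seed(4)
  # points on the mesh itself: all distances tiny
  on <- sample_mesh_points(m25, 1500)
  dev0 <- cloud_to_mesh_deviation(on, m25, thresholds = c(25))
  expect_lt(dev0$max, 1.5)                       # below mesh edge length
  expect_equal(unname(dev0$fraction_within[1]), 1.0)
  # concentric radius-20 cloud vs radius-25 mesh: distances ~ 5
  cl <- sample_mesh_points(m20, 1500)
  dev <- cloud_to_mesh_deviation(cl, m25, thresholds = c(4, 25))
  expect_equal(dev$mean, 5, tolerance = 0.05)
  expect_equal(unname(dev$fraction_within), c(0, 1), tolerance = 1e-6)
  # fraction_within monotone in the threshold
  dev2 <- cloud_to_mesh_deviation(cl, m25, thresholds = c(1, 4.9, 5.1, 10))
  expect_true(all(diff(dev2$fraction_within) >= 0))
  expect_error(cloud_to_mesh_deviation(matrix(numeric(0), 0, 3), m25),
               "empty")
})

test_that("ASCII STL export round-trips a mesh", {
  mesh <- extract_surface(sphere_field(radius = 12, side = 60), LUMEN)
  f <- file.path(tempdir(), "m.stl")
  write_stl(mesh, f)
  m2 <- read_stl(f)
  expect_equal(nrow(m2$faces), nrow(mesh$faces))
  expect_equal(mesh_area(m2), mesh_area(mesh), tolerance = 1e-5)
  file.remove(f)
})

test_that("lumen volume matches the analytic capsule union within 5%", {
  # well-separated capsules at resolution r/10
  nodes <- data.frame(id = 1:4, x = c(20, 160, 20, 160), y = c(30, 30, 90, 90),
                      z = 40, kind = "terminal")
  links <- data.frame(id = 1:2, node_a = c(1L, 3L), node_b = c(2L, 4L),
                      radius = c(10, 14))
  g <- measure_links(vessel_graph(nodes, links,
         list(rbind(c(20, 30, 40), c(160, 30, 40)),
              rbind(c(20, 90, 40), c(160, 90, 40)))))
  g$links$radius <- c(10, 14)
  f <- build_label_field(g, block = c(180, 120, 80), t_endo = 5,
                         resolution = 1)
  vol <- sum(f$labels == LUMEN)      # (1 um)^3 voxels
  capsule_vol <- function(r, l) pi * r^2 * l + 4 / 3 * pi * r^3
  want <- capsule_vol(10, 140) + capsule_vol(14, 140)
  expect_lt(abs(vol / want - 1), 0.05)
})
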