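# Shared fixtures, all generated in code.

# solid cylinder mask along z, axis between voxel centers
cylinder_mask <- function(radius = 6, length = 60, pad = 4) {
  side <- 2L * as.integer(ceiling(radius + pad))
  d <- c(side, side, as.integer(length + 2 * pad))
  ax <- seq_len(side) - 0.5 - side / 2
  rr <- outer(ax^2, ax^2, "+")
  vox <- array(FALSE, d)
  for (k in (pad + 1):(pad + length)) vox[, , k] <- rr <= radius^2
  binary_mask(vox, 1)
}

# solid torus mask in the z mid-plane
torus_mask <- function(R = 14, r = 4) {
  side <- 2L * as.integer(ceiling(R + r + 4))
  nz <- 2L * as.integer(ceiling(r + 4))
  vox <- array(FALSE, c(side, side, nz))
  cx <- side / 2; cz <- nz / 2
  for (k in seq_len(nz)) for (j in seq_len(side)) {
    x <- seq_len(side) - 0.5 - cx
    y <- j - 0.5 - cx
    z <- k - 0.5 - cz
    rho <- sqrt(x^2 + y^2)
    vox[, j, k] <- (rho - R)^2 + z^2 <= r^2
  }
  binary_mask(vox, 1)
}

# straight-tube label field with pressure tags on the z faces
tube_field <- function(h, R = 20, L = 400, t_endo = 5, pad = 1,
                       lumen_only = TRUE) {
  w <- 2 * (R + t_endo + pad)
  nodes <- data.frame(id = 1:2, x = w / 2, y = w / 2,
                      z = c(-10, L + 10), kind = "terminal")
  links <- data.frame(id = 1L, node_a = 1L, node_b = 2L, radius = R)
  g <- measure_links(vessel_graph(nodes, links,
         list(rbind(c(w / 2, w / 2, -10), c(w / 2, w / 2, L + 10)))))
  g$links$radius <- R
  f <- build_label_field(g, block = c(w, w, L), t_endo = t_endo,
                         resolution = h,
                         face_tags = list("z-" = list(LUMEN = "inlet"),
                                          "z+" = list(LUMEN = "outlet")))
  if (lumen_only) f$labels[f$labels == INTERSTITIUM] <- EXTERIOR
  list(graph = g, field = f)
}

# all-interstitium Darcy slab with pressure tags on the x faces
darcy_slab <- function(nx = 100L, ny = 8L, nz = 8L, h_um = 10) {
  dims <- c(nx, ny, nz)
  structure(list(labels = array(INTERSTITIUM, dims),
                 spacing = rep(h_um, 3), origin = c(0, 0, 0),
                 face_tags = list("x-" = list(INTERSTITIUM = "in"),
                                  "x+" = list(INTERSTITIUM = "out")),
                 link_id = array(0L, dims), gdist = NULL, t_endo = 5),
            class = "label_field")
}

# plane-Poiseuille slab channel along x (used for bead movies)
slab_channel_field <- function(vmax = 150e-6, blk = c(400, 160, 48), h = 4) {
  dims <- as.integer(round(blk / h))
  labels <- array(EXTERIOR, dims)
  labels[, , 2:(dims[3] - 1)] <- LUMEN
  f <- structure(list(labels = labels, spacing = rep(h, 3),
                      origin = c(0, 0, 0),
                      face_tags = list("x-" = list(LUMEN = "in"),
                                       "x+" = list(LUMEN = "out")),
                      link_id = array(1L, dims), gdist = NULL, t_endo = 5),
                 class = "label_field")
  b <- (dims[3] - 2) * h * 1e-6
  L <- blk[1] * 1e-6
  dP <- vmax * 8 * 1.002e-3 * L / b^2
  props <- material_props(kappa_endo = 0)
  solve_flow(assemble_problem(f, props,
                              boundary_conditions(c(`in` = dP, out = 0))))
}

# sphere label field (single zero-length link)
sphere_field <- function(radius = 20, side = 100, t_endo = 5, resolution = 1) {
  c0 <- side / 2
  nodes <- data.frame(id = 1:2, x = c(c0, c0 + 1e-3), y = c0, z = c0,
                      kind = "terminal")
  links <- data.frame(id = 1L, node_a = 1L, node_b = 2L, radius = radius)
  g <- measure_links(vessel_graph(nodes, links,
         list(rbind(c(c0, c0, c0), c(c0 + 1e-3, c0, c0)))))
  g$links$radius <- radius
  build_label_field(g, block = rep(side, 3), t_endo = t_endo,
                    resolution = resolution)
}

# match each true link to an extracted link via the closest centerline point
# at the true link's midpoint; returns extracted per-link radii
match_link_radii <- function(truth, extracted) {
  midpt <- function(pl) {
    cum <- c(0, cumsum(sqrt(rowSums(diff(pl)^2))))
    pl[which.min(abs(cum - cum[length(cum)] / 2)), ]
  }
  Mt <- t(vapply(truth$polylines, midpt, numeric(3)))
  allpts <- do.call(rbind, lapply(seq_len(nrow(extracted$links)), function(t)
    cbind(extracted$polylines[[t]], t)))
  nn <- vesselflow:::.nn_index(Mt, allpts[, 1:3])
  extracted$links$radius[allpts[nn, 4]]
}

# full extraction pipeline on a synthetic stack (smooth, threshold at half
# contrast, clean, skeletonize, graph, radii with known-blur correction)
extract_network <- function(rz, cfg) {
  sm <- gaussian_smooth(rz$stack, 1)
  bw <- clean_mask(binarize(sm, "global", threshold = 0.5), 500L)
  sk <- skeletonize(bw)
  g <- estimate_radii(measure_links(skeleton_to_graph(sk)), bw,
                      blur_sigma = sqrt(cfg$blur_sigma^2 + 1))
  list(graph = g, mask = bw, skeleton = sk)
}
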