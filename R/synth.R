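# Synthetic data generators: procedural vessel trees, rasterized noisy image
# stacks, permeability timelapses with known ground truth, and bead movies
# advected through solved flow fields. Every generator is deterministic
# given (config, seed) and returns its ground truth alongside the data.

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Configuration for synthetic vessel networks
#'
#' @param seed integer seed; fixed seed implies identical output.
#' @param block block extents `c(Lx, Ly, Lz)` in micrometers (default
#'   400 x 260 x 260, comparable to one field of view of an imaged device).
#' @param n_links number of links to grow.
#' @param radius_range link radius range in micrometers (default 5-20;
#'   the imaged networks have vessel diameters of roughly 20-40 um, i.e.
#'   radii 10-20 um, and smaller branches reach down to ~5 um).
#' @param tortuosity_amplitude transverse wiggle amplitude as a fraction of
#'   link length (default 0.08, giving tortuosities ~1.0-1.3).
#' @param blur_sigma imaging blur in micrometers (default 2).
#' @param noise_sd additive Gaussian noise as a fraction of the vessel /
#'   background contrast (default 0.05).
#' @param shot_noise add Poisson shot noise on top (default FALSE).
#' @export
synth_config <- function(seed = 1L, block = c(400, 260, 260), n_links = 20L,
                         radius_range = c(5, 20),
                         tortuosity_amplitude = 0.08,
                         blur_sigma = 2, noise_sd = 0.05,
                         shot_noise = FALSE) {
  stopifnot(all(radius_range > 0), diff(radius_range) >= 0, n_links >= 1)
  structure(list(seed = as.integer(seed), block = block,
                 n_links = as.integer(n_links),
                 radius_range = radius_range,
                 tortuosity_amplitude = tortuosity_amplitude,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 shot_noise = shot_noise),
            class = "synth_config")
}

rotate_toward <- function(dir, angle, axis_seedvec) {
  # rotate `dir` by `angle` around a random axis perpendicular to it
  perp <- axis_seedvec - sum(axis_seedvec * dir) * dir
  if (sqrt(sum(perp^2)) < 1e-9) perp <- c(-dir[2], dir[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  d <- dir * cos(angle) + perp * sin(angle)
  d / sqrt(sum(d^2))
}

#' Generate a random branching vessel tree
#'
#' Grows a breadth-first bifurcating tree from the inlet face (`x = 0`)
#' toward the outlet face (`x = Lx`): each link is a gently wiggled
#' polyline, children never exceed the parent radius, sibling subtrees fan
#' out in alternating lateral directions, and candidate links that would
#' collide with existing vessels are re-drawn (space-colonization-style
#' exclusion), so vessels only touch at their shared junctions. The trunk
#' pierces the inlet face and tips that approach the far side pierce the
#' outlet face. With `n_links = 1` the result is a single straight link
#' spanning the block (tortuosity 1).
#'
#' @param config a [synth_config()].
#' @return a measured [vessel_graph()] with radii (the ground truth).
#' @export
random_vessel_graph <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  blk <- config$block
  rmin <- config$radius_range[1]; rmax <- config$radius_range[2]
  margin <- rmax + 5
  if (any(blk < 4 * margin))
    stop("block too small for the requested radii")
  mid_r <- (rmin + rmax) / 2
  if (config$n_links == 1L) {
    p0 <- c(0, blk[2] / 2, blk[3] / 2)
    p1 <- c(blk[1], blk[2] / 2, blk[3] / 2)
    nodes <- data.frame(id = 1:2, x = c(p0[1], p1[1]), y = c(p0[2], p1[2]),
                        z = c(p0[3], p1[3]), kind = "terminal",
                        stringsAsFactors = FALSE)
    links <- data.frame(id = 1L, node_a = 1L, node_b = 2L, radius = mid_r)
    pl <- unname(rbind(p0, (p0 + p1) / 2, p1))
    g <- vessel_graph(nodes, links, list(pl))
    return(measure_links(g))
  }
  with_seed(config$seed, {
    nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0), kind = character(0),
                        stringsAsFactors = FALSE)
    add_node <- function(p) {
      id <- nrow(nodes) + 1L
      nodes[id, ] <<- list(id, p[1], p[2], p[3], "terminal")
      id
    }
    links <- list(); polylines <- list()
    occ <- matrix(numeric(0), 0, 4)   # centerline samples (x, y, z, r)
    wig <- config$tortuosity_amplitude
    seg_len <- blk[1] / 4.5
    make_polyline <- function(pos, target) {
      npts <- 9L
      s <- seq(0, 1, length.out = npts)
      base <- sweep(outer(s, target - pos), 2, pos, "+")
      len <- sqrt(sum((target - pos)^2))
      dir <- (target - pos) / max(len, 1e-9)
      amp <- min(wig * len, margin / 3)
      if (amp > 0) {
        e1 <- rotate_toward(dir, pi / 2, c(runif(3) - 0.5))
        # two-arch transverse wiggle, zero at both ends
        ph <- runif(1, 0, 2 * pi)
        base <- base + outer(amp * sin(2 * pi * s) * sin(pi * s + ph), e1)
      }
      base
    }
    collides <- function(pl, r, junction, parent_r) {
      if (!nrow(occ)) return(FALSE)
      # exempt only the shared junction blob itself
      zone <- r + parent_r + 3
      for (q in seq_len(nrow(pl))) {
        p <- pl[q, ]
        excl <- sqrt((occ[, 1] - p[1])^2 + (occ[, 2] - p[2])^2 +
                     (occ[, 3] - p[3])^2) - occ[, 4] - r
        near_junction <- sqrt(sum((p - junction)^2)) < zone
        ok <- if (near_junction) {
          # near the junction, only samples of the same blob may touch
          all(excl >= 3 |
              sqrt((occ[, 1] - junction[1])^2 + (occ[, 2] - junction[2])^2 +
                   (occ[, 3] - junction[3])^2) < zone)
        } else all(excl >= 3)
        if (!ok) return(TRUE)
      }
      FALSE
    }
    # try to place one link from `pos` heading along `dir`; returns the
    # polyline or NULL. Links approaching the far side run to the outlet.
    try_place <- function(pos, dir, radius, parent_radius, fan) {
      to_outlet <- pos[1] + 1.35 * seg_len >= blk[1] - margin
      for (try in 1:30) {
        len <- runif(1, 0.85, 1.25) * seg_len
        target <- pos + dir * len
        if (try > 1) target[2:3] <- target[2:3] + runif(2, -1, 1) * fan * 0.5
        if (to_outlet) target <- c(blk[1], target[2], target[3])
        target[2] <- min(max(target[2], margin), blk[2] - margin)
        target[3] <- min(max(target[3], margin), blk[3] - margin)
        pl <- make_polyline(pos, target)
        if (!collides(pl, radius, pos, parent_radius))
          return(list(pl = pl, to_outlet = to_outlet))
      }
      NULL
    }
    commit_link <- function(from_node, pl, radius) {
      end_id <- add_node(pl[nrow(pl), ])
      links[[length(links) + 1L]] <<- data.frame(
        id = length(links) + 1L, node_a = from_node, node_b = end_id,
        radius = radius)
      polylines[[length(polylines) + 1L]] <<- pl
      occ <<- rbind(occ, cbind(pl, radius))
      end_id
    }
    p0 <- c(0, blk[2] / 2, blk[3] / 2)
    root <- add_node(p0)
    trunk <- try_place(p0, c(1, 0, 0), rmax, rmax, 0.45 * blk[2])
    if (is.null(trunk)) stop("could not place the trunk link")
    root_end <- commit_link(root, trunk$pl, rmax)
    # queue of link ends eligible to bifurcate (breadth-first). Bifurcations
    # are committed atomically (both children or neither), so every internal
    # node of the ground truth is a genuine degree-3 branch point; if only
    # one link remains in the budget, a single child continues at the SAME
    # radius (extraction merges it into its parent without information loss).
    tips <- list(list(node = root_end, pl = trunk$pl, radius = rmax,
                      depth = 0L, fan = 0.45 * blk[2],
                      at_outlet = trunk$to_outlet))
    while (length(tips) && length(links) < config$n_links) {
      tip <- tips[[1]]; tips <- tips[-1]
      if (tip$at_outlet) next
      budget <- config$n_links - length(links)
      end <- tip$pl[nrow(tip$pl), ]
      newdir <- end - tip$pl[1, ]
      newdir <- newdir / sqrt(sum(newdir^2))
      lat_ax <- if (tip$depth %% 2 == 0) c(0, 1, 0) else c(0, 0, 1)
      other_ax <- if (tip$depth %% 2 == 0) c(0, 0, 1) else c(0, 1, 0)
      child_dir <- function(sgn) {
        cd <- newdir + sgn * runif(1, 0.5, 0.95) * lat_ax +
          runif(1, -0.25, 0.25) * other_ax
        cd <- cd / sqrt(sum(cd^2))
        if (cd[1] < 0.3) { cd[1] <- 0.3; cd <- cd / sqrt(sum(cd^2)) }
        cd
      }
      if (budget == 1L) {
        # straight continuation at the parent radius
        res <- try_place(end, newdir, tip$radius, tip$radius, tip$fan)
        if (!is.null(res)) commit_link(tip$node, res$pl, tip$radius)
        next
      }
      r1 <- max(rmin, min(tip$radius * runif(1, 0.62, 0.82), tip$radius))
      r2 <- max(rmin, min(tip$radius * runif(1, 0.62, 0.82), tip$radius))
      for (attempt in 1:6) {   # fresh direction draws per attempt
        res1 <- try_place(end, child_dir(1), r1, tip$radius, tip$fan)
        if (is.null(res1)) next
        occ_rows <- nrow(occ)
        n1 <- commit_link(tip$node, res1$pl, r1)
        res2 <- try_place(end, child_dir(-1), r2, tip$radius, tip$fan)
        if (is.null(res2)) {
          # roll the first child back: bifurcate fully or not at all
          occ <- occ[seq_len(occ_rows), , drop = FALSE]
          links[[length(links)]] <- NULL
          polylines[[length(polylines)]] <- NULL
          nodes <- nodes[-nrow(nodes), ]
          next
        }
        n2 <- commit_link(tip$node, res2$pl, r2)
        tips[[length(tips) + 1L]] <- list(node = n1, pl = res1$pl,
                                          radius = r1,
                                          depth = tip$depth + 1L,
                                          fan = tip$fan * 0.55,
                                          at_outlet = res1$to_outlet)
        tips[[length(tips) + 1L]] <- list(node = n2, pl = res2$pl,
                                          radius = r2,
                                          depth = tip$depth + 1L,
                                          fan = tip$fan * 0.55,
                                          at_outlet = res2$to_outlet)
        break
      }
    }
    links_df <- do.call(rbind, links)
    deg <- tabulate(c(links_df$node_a, links_df$node_b), nbins = nrow(nodes))
    nodes$kind <- ifelse(deg >= 3, "branch",
                         ifelse(deg == 2, "passthrough", "terminal"))
    g <- vessel_graph(nodes, links_df, polylines)
    measure_links(g)
  })
}

#' Rasterize a vessel graph into a synthetic fluorescence stack
#'
#' Capsule-union occupancy (vessel intensity 1, background 0), Gaussian
#' blur, then additive Gaussian noise (a fraction of the vessel/background
#' contrast) and optional Poisson shot noise. The noiseless ground-truth
#' occupancy mask is returned alongside.
#'
#' @param graph a measured [vessel_graph()] with radii.
#' @param config the [synth_config()] (block, blur, noise, seed).
#' @param spacing isotropic voxel size in micrometers (default 1).
#' @return list with `stack` (an [image_stack()]) and `mask` (the
#'   ground-truth [binary_mask()]).
#' @export
rasterize_graph <- function(graph, config, spacing = 1) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(config, "synth_config"))
  if (spacing > min(graph$links$radius))
    stop("spacing coarser than the smallest link radius")
  dims <- pmax(1L, as.integer(round(config$block / spacing)))
  segs <- graph_segments(graph)
  cf <- .capsule_field(dims, rep(spacing, 3), segs, pad = 2 * spacing)
  occ <- array(as.numeric(cf$g <= 0), dims)
  gt <- binary_mask(array(cf$g <= 0, dims), spacing)
  stack <- image_stack(occ, rep(spacing, 3))
  if (config$blur_sigma > 0)
    stack <- gaussian_smooth(stack, config$blur_sigma)
  vox <- stack$voxels
  with_seed(config$seed + 7L, {
    if (config$noise_sd > 0)
      vox <- vox + rnorm(length(vox), sd = config$noise_sd)
    if (config$shot_noise) {
      photons <- 200
      vox <- rpois(length(vox), lambda = pmax(vox, 0) * photons) / photons
    }
  })
  list(stack = image_stack(array(vox, dims), rep(spacing, 3)), mask = gt)
}

#' Synthetic dextran permeability timelapse
#'
#' Frames contain a vessel strip at constant intensity `I_vessel` and a gel
#' region whose mean intensity ramps linearly at the slope implied by the
#' ground-truth diffusive permeability, `dI_gel/dt = (2 Pd / r) * I_vessel`,
#' plus optional Gaussian noise (fraction of `I_vessel`).
#'
#' @param Pd_true ground-truth diffusive permeability, m/s.
#' @param r_vessel vessel radius, micrometers.
#' @param I_vessel vessel intensity, a.u.
#' @param times frame times in seconds (default every 10 s for 2 min).
#' @param noise_sd relative intensity noise (default 0).
#' @param seed RNG seed for the noise.
#' @param dims frame size in pixels.
#' @return a [timelapse_stack()] with a `Pd_true` attribute.
#' @export
synth_permeability_timelapse <- function(Pd_true, r_vessel = 80,
                                         I_vessel = 1000,
                                         times = seq(0, 120, by = 10),
                                         noise_sd = 0, seed = 1L,
                                         dims = c(64, 64)) {
  stopifnot(Pd_true >= 0, length(times) >= 3)
  r_m <- r_vessel * 1e-6
  slope <- 2 * Pd_true / r_m * I_vessel
  vw <- max(4L, round(dims[1] / 4))
  vessel_mask <- matrix(FALSE, dims[1], dims[2]); vessel_mask[1:vw, ] <- TRUE
  gel_mask <- matrix(FALSE, dims[1], dims[2])
  gel_mask[(vw + 8):dims[1], ] <- TRUE
  frames <- with_seed(seed, lapply(times, function(t) {
    fr <- matrix(0, dims[1], dims[2])
    fr[vessel_mask] <- I_vessel
    fr[gel_mask] <- slope * t
    if (noise_sd > 0)
      fr <- fr + rnorm(length(fr), sd = noise_sd * I_vessel)
    fr
  }))
  out <- timelapse_stack(frames, times, vessel_mask, gel_mask, r_vessel)
  attr(out, "Pd_true") <- Pd_true
  out
}

#' Synthetic bead-perfusion movie through a solved flow field
#'
#' Beads are seeded in lumen voxels, advected by RK4 through the
#' interpolated velocity field, and rendered as Gaussian blobs of the bead
#' diameter on a 2D (maximum-projection-style) pixel grid. Ground-truth
#' tracks are returned with the frames.
#'
#' @param field a solved `flow_field`.
#' @param n_beads number of beads (> 0).
#' @param dt frame interval, seconds.
#' @param n_frames number of frames.
#' @param loc_noise localization noise added to the rendered bead centers,
#'   micrometers (default 0).
#' @param pixel_size rendering pixel size, micrometers.
#' @param diameter bead diameter, micrometers (default 10).
#' @param seed RNG seed.
#' @param substeps RK4 substeps per frame.
#' @param seed_region optional predicate `function(x, y, z)` (micrometers)
#'   restricting where beads are seeded inside the lumen, e.g. a central
#'   sheet of a channel for velocimetry calibration.
#' @param min_separation minimum initial projected (x-y) distance between
#'   beads, micrometers (0 = none): greedy rejection sampling, so rendered
#'   beads start resolvable.
#' @return list with `frames` (list of matrices), `pixel_size`, and
#'   `truth` (a `track_set` of ground-truth 2D positions).
#' @export
synth_bead_movie <- function(field, n_beads, dt, n_frames, loc_noise = 0,
                             pixel_size = 2, diameter = 10, seed = 1L,
                             substeps = 4L, seed_region = NULL,
                             min_separation = 0) {
  stopifnot(inherits(field, "flow_field"), n_frames >= 2)
  if (n_beads <= 0) stop("n_beads must be positive")
  problem <- field$problem
  lf <- problem$field
  h_um <- lf$spacing[1]
  dims <- problem$dims
  lumen_cells <- which(lf$labels == LUMEN & problem$fluid)
  if (!is.null(seed_region)) {
    idx0 <- lumen_cells - 1L
    cx <- ((idx0 %% dims[1]) + 0.5) * h_um
    cy <- (((idx0 %/% dims[1]) %% dims[2]) + 0.5) * h_um
    cz <- ((idx0 %/% (dims[1] * dims[2])) + 0.5) * h_um
    lumen_cells <- lumen_cells[seed_region(cx, cy, cz)]
  }
  if (!length(lumen_cells)) stop("field has no lumen to seed beads in")
  extent <- dims * h_um
  with_seed(seed, {
    # seed beads preferentially where flow is present
    cc <- cell_velocity(list(u = field$u, v = field$v, w = field$w), dims)
    spd <- sqrt(cc$u^2 + cc$v^2 + cc$w^2)[lumen_cells]
    wts <- spd + 1e-3 * max(spd, 0)
    if (max(wts) <= 0) wts <- rep(1, length(lumen_cells))
    n_cand <- if (min_separation > 0) 40L * n_beads else n_beads
    cells <- sample(lumen_cells, n_cand, replace = TRUE, prob = wts)
    idx0 <- cells - 1L
    pos <- cbind(((idx0 %% dims[1]) + runif(n_cand)) * h_um,
                 (((idx0 %/% dims[1]) %% dims[2]) + runif(n_cand)) * h_um,
                 ((idx0 %/% (dims[1] * dims[2])) + runif(n_cand)) * h_um)
    if (min_separation > 0) {
      keep <- 1L
      for (cand in 2:n_cand) {
        if (length(keep) >= n_beads) break
        dmin <- min(sqrt((pos[keep, 1] - pos[cand, 1])^2 +
                         (pos[keep, 2] - pos[cand, 2])^2))
        if (dmin >= min_separation) keep <- c(keep, cand)
      }
      if (length(keep) < n_beads)
        stop("could not place ", n_beads, " beads at the requested separation")
      pos <- pos[keep, , drop = FALSE]
    } else {
      pos <- pos[seq_len(n_beads), , drop = FALSE]
    }
    traj <- array(NA_real_, c(n_beads, 3, n_frames))
    traj[, , 1] <- pos
    alive <- rep(TRUE, n_beads)
    hsub <- dt / substeps
    for (f in 2:n_frames) {
      for (s in seq_len(substeps)) {
        v1 <- sample_velocity(field, pos) * 1e6      # m/s -> um/s
        v2 <- sample_velocity(field, pos + hsub / 2 * v1) * 1e6
        v3 <- sample_velocity(field, pos + hsub / 2 * v2) * 1e6
        v4 <- sample_velocity(field, pos + hsub * v3) * 1e6
        pos <- pos + hsub / 6 * (v1 + 2 * v2 + 2 * v3 + v4)
        # beads reaching the block boundary leave the device
        out <- pos[, 1] < 0 | pos[, 1] > extent[1] |
               pos[, 2] < 0 | pos[, 2] > extent[2] |
               pos[, 3] < 0 | pos[, 3] > extent[3]
        alive[out] <- FALSE
        pos[, 1] <- pmin(pmax(pos[, 1], 0), extent[1])
        pos[, 2] <- pmin(pmax(pos[, 2], 0), extent[2])
        pos[, 3] <- pmin(pmax(pos[, 3], 0), extent[3])
      }
      traj[alive, , f] <- pos[alive, , drop = FALSE]
    }
    # render frames (x-y projection)
    nr <- ceiling(extent[1] / pixel_size)
    nc <- ceiling(extent[2] / pixel_size)
    sig_px <- diameter / 2.355 / pixel_size
    rad_px <- ceiling(3 * sig_px)
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      img <- matrix(0, nr, nc)
      for (bd in seq_len(n_beads)) {
        if (is.na(traj[bd, 1, f])) next          # bead has left the device
        cx <- traj[bd, 1, f] / pixel_size + 0.5
        cy <- traj[bd, 2, f] / pixel_size + 0.5
        if (loc_noise > 0) {
          cx <- cx + rnorm(1, sd = loc_noise / pixel_size)
          cy <- cy + rnorm(1, sd = loc_noise / pixel_size)
        }
        i0 <- max(1L, floor(cx - rad_px)); i1 <- min(nr, ceiling(cx + rad_px))
        j0 <- max(1L, floor(cy - rad_px)); j1 <- min(nc, ceiling(cy + rad_px))
        if (i0 > i1 || j0 > j1) next
        gx <- exp(-((i0:i1) - cx)^2 / (2 * sig_px^2))
        gy <- exp(-((j0:j1) - cy)^2 / (2 * sig_px^2))
        img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + outer(gx, gy)
      }
      frames[[f]] <- img
    }
    truth <- structure(list(
      tracks = lapply(seq_len(n_beads), function(bd) {
        ok <- which(!is.na(traj[bd, 1, ]))
        data.frame(frame = ok, t = (ok - 1) * dt,
                   x = traj[bd, 1, ok], y = traj[bd, 2, ok])
      }),
      frame_interval = dt), class = "track_set")
    list(frames = frames, pixel_size = pixel_size, truth = truth,
         trajectories = traj)
  })
}
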