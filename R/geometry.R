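# Bottom-up domain reconstruction and surface-deviation validation.

# Segment table (one row per polyline segment) for the implicit capsule
# union. Constant per-link radius by default; tapered = per-point radii.
graph_segments <- function(graph, tapered = FALSE) {
  segs <- list()
  for (t in seq_len(nrow(graph$links))) {
    pl <- graph$polylines[[t]]
    r <- graph$links$radius[t]
    n <- nrow(pl)
    pr <- if (tapered && !is.null(graph$point_radii) &&
              length(graph$point_radii[[t]]) == n)
      graph$point_radii[[t]] else rep(r, n)
    segs[[t]] <- cbind(pl[-n, , drop = FALSE], pl[-1, , drop = FALSE],
                       pr[-n], pr[-1], graph$links$id[t])
  }
  do.call(rbind, segs)
}

#' Build the labeled computational domain from a vessel graph
#'
#' Implicit signed-distance construction equivalent to Boolean solid
#' modeling: the lumen is the union of capsules (a cylinder per centerline
#' segment with spheres at segment ends, which removes seams at branch
#' points); the endothelium is the same union grown by `t_endo` minus the
#' lumen; everything else inside the block is interstitium. Link ends lying
#' within one radius of a tagged block face are extended through that face so
#' the vessel opens into the boundary (no endothelial cap).
#'
#' @param graph a measured [vessel_graph()] with radii (micrometers).
#' @param block block extents `c(Lx, Ly, Lz)` in micrometers.
#' @param t_endo uniform endothelial shell thickness in micrometers
#'   (default 5).
#' @param resolution isotropic voxel size in micrometers.
#' @param face_tags named list mapping block faces (`"x-", "x+", "y-", "y+",
#'   "z-", "z+"`) to a list with per-label boundary tags, e.g.
#'   `list("x-" = list(LUMEN = "vessel_inlet", INTERSTITIUM =
#'   "interstitial_inlet"))`. Untagged faces are walls.
#' @param tapered sweep per-point radii along each link instead of the
#'   constant per-link radius.
#' @return a `label_field`: integer label array (`EXTERIOR`, `LUMEN`,
#'   `ENDOTHELIUM`, `INTERSTITIUM`), spacing, per-voxel owning link id,
#'   the signed capsule distance (micrometers, negative inside the lumen),
#'   and the face tags.
#' @export
build_label_field <- function(graph, block, t_endo = 5, resolution = 1,
                              face_tags = list(), tapered = FALSE) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (is.null(graph$links$radius)) stop("graph has no radii")
  if (t_endo <= 0) stop("t_endo must be > 0")
  if (resolution <= 0) stop("resolution must be > 0")
  rmin <- suppressWarnings(min(graph$links$radius))
  if (nrow(graph$links) > 0 && resolution > rmin) {
    bad <- graph$links$id[which.min(graph$links$radius)]
    stop(sprintf(paste0("resolution %.3g um is coarser than the smallest link ",
                        "radius %.3g um (link %s): its lumen would vanish"),
                 resolution, rmin, bad))
  }
  dims <- pmax(1L, as.integer(round(block / resolution)))
  sp <- rep(resolution, 3)
  graph <- open_boundary_links(graph, block, face_tags, t_endo)
  if (nrow(graph$links) > 0) {
    segs <- graph_segments(graph, tapered = tapered)
    # junction spheres sized by the measured junction radius (extracted
    # graphs carry it from the distance transform), refining the paper-style
    # sphere-at-link-ends construction where several vessels meet
    jr <- graph$nodes$junction_radius
    if (!is.null(jr)) {
      jn <- which(graph$nodes$kind == "branch" & is.finite(jr) & jr > 0)
      if (length(jn)) {
        pts <- as.matrix(graph$nodes[jn, c("x", "y", "z")])
        segs <- rbind(segs, cbind(pts, pts, jr[jn], jr[jn], 0))
      }
    }
    cf <- .capsule_field(dims, sp, segs, pad = t_endo + 2 * resolution)
    g <- array(cf$g, dims)
    link_id <- array(cf$link_id, dims)
  } else {
    g <- array(1e30, dims)
    link_id <- array(0L, dims)
  }
  labels <- array(INTERSTITIUM, dims)
  labels[g <= t_endo] <- ENDOTHELIUM
  labels[g <= 0] <- LUMEN
  link_id[labels != LUMEN] <- 0L
  structure(list(labels = labels, spacing = sp, origin = c(0, 0, 0),
                 face_tags = face_tags, link_id = link_id, gdist = g,
                 t_endo = t_endo),
            class = "label_field")
}

# Extend link end segments through tagged faces when the end lies within one
# radius of the face, so the lumen is open there (no endothelial cap).
open_boundary_links <- function(graph, block, face_tags, t_endo) {
  if (!length(face_tags) || nrow(graph$links) == 0L) return(graph)
  faces <- names(face_tags)
  for (t in seq_len(nrow(graph$links))) {
    r <- graph$links$radius[t]
    for (end in c(1L, 2L)) {
      pl <- graph$polylines[[t]]
      p <- if (end == 1L) pl[1, ] else pl[nrow(pl), ]
      for (f in faces) {
        ax <- match(substr(f, 1, 1), c("x", "y", "z"))
        lo <- substr(f, 2, 2) == "-"
        dist <- if (lo) p[ax] else block[ax] - p[ax]
        if (dist <= r) {
          q <- p
          q[ax] <- if (lo) -(t_endo + r) else block[ax] + t_endo + r
          graph$polylines[[t]] <- if (end == 1L) rbind(q, pl) else rbind(pl, q)
        }
      }
    }
  }
  graph
}

#' @export
print.label_field <- function(x, ...) {
  d <- dim(x$labels)
  counts <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf(paste0("label_field %d x %d x %d @ %.3g um: ",
                     "%d lumen, %d endothelium, %d interstitium, %d exterior\n"),
              d[1], d[2], d[3], x$spacing[1],
              counts[LUMEN + 1L], counts[ENDOTHELIUM + 1L],
              counts[INTERSTITIUM + 1L], counts[EXTERIOR + 1L]))
  invisible(x)
}

#' Triangle mesh
#' @param vertices n x 3 matrix (micrometers).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @export
tri_mesh <- function(vertices, faces) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3L,
            ncol(faces) == 3L)
  storage.mode(faces) <- "integer"
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces),
              format(mesh_is_watertight(x))))
  invisible(x)
}

#' Mesh surface area, edge census and watertightness
#' @param mesh a [tri_mesh()].
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @rdname mesh_area
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' @rdname mesh_area
#' @export
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  length(unique(as.vector(f))) - length(key) + nrow(f)
}

#' Extract an iso-surface mesh of one label region
#'
#' Marching-tetrahedra iso-surfacing of the (optionally smoothed) 0/1
#' occupancy of the requested label at iso-level 0.5, with vertices in
#' physical micrometers. The occupancy grid is zero-padded so regions
#' touching the block boundary still yield closed meshes.
#'
#' @param field a `label_field` or a [binary_mask()] (the segmented network,
#'   iso-surfaced directly).
#' @param label one of [LUMEN], [ENDOTHELIUM], [INTERSTITIUM]; `LUMEN`
#'   selects lumen, and `"vessel"` selects lumen plus endothelium (the
#'   solid vessel, useful for deviation checks). Ignored for masks.
#' @param smooth_sigma occupancy smoothing before iso-surfacing, in voxels
#'   (default 1; reduces voxel staircase bias in areas and distances).
#' @return a [tri_mesh()].
#' @export
extract_surface <- function(field, label = LUMEN, smooth_sigma = 1) {
  if (inherits(field, "binary_mask")) {
    field <- structure(list(labels = array(ifelse(field$voxels, LUMEN,
                                                  EXTERIOR),
                                           dim(field$voxels)),
                            spacing = field$spacing, origin = c(0, 0, 0)),
                       class = "label_field")
    label <- LUMEN
  }
  stopifnot(inherits(field, "label_field"))
  occ <- if (identical(label, "vessel"))
    field$labels == LUMEN | field$labels == ENDOTHELIUM
  else field$labels == label
  if (!any(occ)) stop("label not present in field")
  d <- dim(occ)
  vol <- array(0, d + 2L)
  vol[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(occ)
  if (smooth_sigma > 0) {
    w <- gauss_kernel(smooth_sigma)
    for (a in 1:3) vol <- conv_axis(vol, w, a)
  }
  sp <- field$spacing
  mt <- .march_tets(as.numeric(vol), dim(vol), 0.5, sp,
                    field$origin - sp)   # padded grid shifts origin one voxel
  tri_mesh(mt$vertices, mt$faces)
}

#' Rigid registration by iterative closest point
#'
#' Aligns `source` onto `reference` with rigid (rotation + translation)
#' iterative closest point: nearest-neighbor correspondences against the
#' reference vertices (or a point cloud), Kabsch SVD update, repeated until
#' the RMS improvement drops below `rms_tol`. An optional isotropic
#' `prescale` is applied to the source first (known unit conversions).
#'
#' @param source a [tri_mesh()] or n x 3 point matrix.
#' @param reference a [tri_mesh()] or n x 3 point matrix.
#' @param rms_tol stop when RMS improves by less than this (default 1e-5).
#' @param max_iter iteration cap (default 100).
#' @param prescale optional isotropic scale applied to source first.
#' @return a `rigid_transform`: rotation `R`, translation `t`, `prescale`,
#'   final `rms`, iteration count and a `converged` flag. Apply with
#'   [apply_transform()].
#' @export
register_rigid <- function(source, reference, rms_tol = 1e-5,
                           max_iter = 100L, prescale = NULL) {
  P <- if (inherits(source, "tri_mesh")) source$vertices else as.matrix(source)
  Q <- if (inherits(reference, "tri_mesh")) reference$vertices else
    as.matrix(reference)
  if (!nrow(P) || !nrow(Q)) stop("both shapes must be nonempty")
  s <- if (is.null(prescale)) 1 else prescale
  P0 <- P * s
  R <- diag(3); tr <- c(0, 0, 0)
  rms_prev <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    Pt <- P0 %*% t(R) + matrix(tr, nrow(P0), 3, byrow = TRUE)
    nn <- .nn_index(Pt, Q)
    M <- Q[nn, , drop = FALSE]
    rms <- sqrt(mean(rowSums((Pt - M)^2)))
    if (is.finite(rms_prev) && rms_prev - rms < rms_tol) {
      converged <- TRUE
      rms_prev <- rms
      break
    }
    rms_prev <- rms
    # Kabsch on current correspondences
    cp <- colMeans(Pt); cm <- colMeans(M)
    H <- t(sweep(Pt, 2, cp)) %*% sweep(M, 2, cm)
    sv <- svd(H)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    Rstep <- sv$v %*% D %*% t(sv$u)
    tstep <- cm - as.vector(Rstep %*% cp)
    R <- Rstep %*% R
    tr <- as.vector(Rstep %*% tr) + tstep
  }
  if (!converged)
    warning("ICP did not converge within max_iter; returning best transform")
  structure(list(R = R, t = tr, prescale = s, rms = rms_prev,
                 iterations = it, converged = converged),
            class = "rigid_transform")
}

#' @rdname register_rigid
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix (or [tri_mesh()]) to transform.
#' @export
apply_transform <- function(transform, points) {
  if (inherits(points, "tri_mesh")) {
    points$vertices <- apply_transform(transform, points$vertices)
    return(points)
  }
  P <- as.matrix(points) * transform$prescale
  P %*% t(transform$R) + matrix(transform$t, nrow(P), 3, byrow = TRUE)
}

#' Cloud-to-mesh deviation report
#'
#' Unsigned distance from every source point to the nearest point on the
#' reference mesh surface (exact point-triangle distances), plus the
#' fraction of points within each requested threshold.
#'
#' @param source_points n x 3 matrix of (registered) points, micrometers.
#' @param reference a [tri_mesh()].
#' @param thresholds distances (micrometers) at which to report
#'   `fraction_within`.
#' @return a `deviation_report`: per-point `distances`, named
#'   `fraction_within`, and summary stats.
#' @export
cloud_to_mesh_deviation <- function(source_points, reference,
                                    thresholds = c(25)) {
  P <- if (inherits(source_points, "tri_mesh")) source_points$vertices else
    as.matrix(source_points)
  if (!nrow(P)) stop("empty point cloud")
  d <- .point_mesh_dist(P, reference$vertices, reference$faces)
  fw <- vapply(thresholds, function(th) mean(d <= th), numeric(1))
  names(fw) <- paste0("within_", format(thresholds, trim = TRUE))
  structure(list(distances = d, fraction_within = fw,
                 thresholds = thresholds,
                 mean = mean(d), max = max(d),
                 q95 = unname(quantile(d, 0.95))),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("deviation: mean %.3g um, 95%% quantile %.3g um, max %.3g um\n",
              x$mean, x$q95, x$max))
  for (t in seq_along(x$thresholds))
    cat(sprintf("  within %.3g um: %.1f%%\n", x$thresholds[t],
                100 * x$fraction_within[t]))
  invisible(x)
}

#' Sample points uniformly on a mesh surface
#'
#' Area-weighted triangle sampling with uniform barycentric coordinates.
#'
#' @param mesh a [tri_mesh()].
#' @param n number of points.
#' @export
sample_mesh_points <- function(mesh, n) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  w <- sqrt(rowSums(cr^2))
  tri <- sample.int(nrow(f), n, replace = TRUE, prob = w)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  u <- 1 - r1; vv <- r1 * (1 - r2); ww <- r1 * r2
  v[f[tri, 1], , drop = FALSE] * u + v[f[tri, 2], , drop = FALSE] * vv +
    v[f[tri, 3], , drop = FALSE] * ww
}

#' Write / read an ASCII STL surface
#'
#' @param mesh a [tri_mesh()] (vertex units recorded in the solid name).
#' @param path file path.
#' @param unit unit label recorded in the header (default "um").
#' @export
write_stl <- function(mesh, path, unit = "um") {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid vesselflow_%s", unit), con)
  for (t in seq_len(nrow(f))) {
    p1 <- v[f[t, 1], ]; p2 <- v[f[t, 2], ]; p3 <- v[f[t, 3], ]
    nrm <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
             (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
             (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    nl <- sqrt(sum(nrm^2)); if (nl > 0) nrm <- nrm / nl
    writeLines(c(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", p1[1], p1[2], p1[3]),
                 sprintf("      vertex %.9g %.9g %.9g", p2[1], p2[2], p2[3]),
                 sprintf("      vertex %.9g %.9g %.9g", p3[1], p3[2], p3[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid vesselflow_%s", unit), con)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  ln <- readLines(path)
  vx <- grep("^\\s*vertex ", ln, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"),
                                  function(p) as.numeric(p[2:4])))
  key <- apply(coords, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  vid <- match(key, key[uk])
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}
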