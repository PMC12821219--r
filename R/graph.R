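# Vessel graph extraction: skeletonization, node-link graph, link measures,
# radius estimation, network metrics, CSV round-trip.

#' Construct a vessel graph
#'
#' @param nodes data frame with columns `id, x, y, z, kind`
#'   (`kind` in `"branch"`, `"terminal"`, `"passthrough"`); coordinates in
#'   micrometers.
#' @param links data frame with columns `id, node_a, node_b` and optionally
#'   `radius, path_length, euclidean_length, tortuosity`.
#' @param polylines list (one entry per link) of n x 3 matrices of centerline
#'   points in micrometers; first/last rows coincide with the endpoint node
#'   positions.
#' @param point_radii optional list of per-centerline-point radii.
#' @export
vessel_graph <- function(nodes, links, polylines, point_radii = NULL) {
  stopifnot(is.data.frame(nodes), is.data.frame(links),
            is.list(polylines), nrow(links) == length(polylines))
  if (!all(links$node_a %in% nodes$id) || !all(links$node_b %in% nodes$id))
    stop("link endpoints must reference existing nodes")
  for (i in seq_along(polylines)) {
    pl <- polylines[[i]]
    if (!is.matrix(pl) || ncol(pl) != 3L || nrow(pl) < 2L)
      stop("each polyline must be an n x 3 matrix with n >= 2 (link ", i, ")")
  }
  structure(list(nodes = nodes, links = links, polylines = polylines,
                 point_radii = point_radii),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind,
                        c("branch", "terminal", "passthrough")))
  cat(sprintf("vessel_graph: %d nodes (%d branch, %d terminal), %d links\n",
              nrow(x$nodes), kinds[["branch"]], kinds[["terminal"]],
              nrow(x$links)))
  invisible(x)
}

# Voxel linear index (1-based) -> center coordinates in micrometers.
voxel_centers <- function(idx, dims, spacing) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind((i + 0.5) * spacing[1], (j + 0.5) * spacing[2], (k + 0.5) * spacing[3])
}

#' Skeletonize a binary mask
#'
#' Topology-preserving homotopic thinning to a one-voxel-wide medial curve
#' skeleton: only simple points are removed (sequentially, outside-in by
#' distance to the boundary, in six directional subiterations), so component
#' and loop counts of the mask are preserved. Terminal side chains shorter
#' than the vessel radius at their base (pure artifacts of thinning a thick
#' tube) are pruned afterwards unless `prune = FALSE`.
#'
#' @param mask a cleaned [binary_mask()].
#' @param prune prune distance-transform-short terminal spurs (default TRUE).
#' @return a `skeleton` object (logical voxel grid + spacing).
#' @export
skeletonize <- function(mask, prune = TRUE) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("cannot skeletonize an empty mask")
  d <- dim(mask$voxels)
  sk <- array(.thin3d(as.logical(mask$voxels), d), d)
  if (prune) sk <- prune_spur_voxels(sk, mask)
  # local vessel radius (physical units) for radius-aware graph cleaning
  edt <- array(.edt(as.logical(mask$voxels), d, mask$spacing), d)
  structure(list(voxels = sk, spacing = mask$spacing, edt = edt),
            class = "skeleton")
}

# Remove terminal chains rooted at a branch node whose length is below the
# local vessel radius (distance-transform value at the base): such chains lie
# entirely inside the parent vessel and carry no centerline information.
prune_spur_voxels <- function(sk, mask) {
  d <- dim(sk)
  dt <- array(.edt(as.logical(mask$voxels), d, c(1, 1, 1)), d)  # voxel units
  repeat {
    gr <- .skel_graph(as.logical(sk), d)
    n_nodes <- length(gr$node_voxels)
    if (!length(gr$link_a)) return(sk)
    deg <- tabulate(c(gr$link_a, gr$link_b), nbins = n_nodes)
    nvox <- lengths(gr$node_voxels)
    is_branch <- deg >= 3L | nvox > 1L
    is_tip <- deg == 1L & nvox == 1L
    removed <- FALSE
    for (t in seq_along(gr$link_a)) {
      a <- gr$link_a[t]; b <- gr$link_b[t]
      if (a == b) next
      tip <- if (is_tip[a] && is_branch[b]) a
             else if (is_tip[b] && is_branch[a]) b
             else next
      base <- if (tip == a) b else a
      chain <- gr$link_paths[[t]]
      spur_len <- length(chain) + 1L            # chain plus the tip voxel
      base_r <- max(dt[gr$node_voxels[[base]]])
      if (spur_len < max(1.5 * base_r, 4)) {
        sk[gr$node_voxels[[tip]]] <- FALSE
        # direct node-node adjacencies carry node voxels in their path
        sk[setdiff(chain, gr$node_voxels[[base]])] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) return(sk)
  }
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d voxels on a %s grid\n", sum(x$voxels),
              paste(dim(x$voxels), collapse = " x ")))
  invisible(x)
}

#' Convert a skeleton to a node-link vessel graph
#'
#' Skeleton voxels with three or more neighbors cluster (26-connectivity)
#' into branch nodes placed at the cluster centroid; voxels with one
#' neighbor become terminal nodes; maximal degree-2 chains become links with
#' ordered centerline polylines in physical micrometers whose first and last
#' points coincide with the endpoint node positions. Pure cycles receive an
#' anchor node and a self-loop link.
#'
#' @param skel a `skeleton` from [skeletonize()].
#' @return an unmeasured [vessel_graph()] (run [measure_links()] next).
#' @export
skeleton_to_graph <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  if (!any(skel$voxels)) stop("skeleton has no voxels")
  d <- dim(skel$voxels)
  sp <- skel$spacing
  gr <- .skel_graph(as.logical(skel$voxels), d)
  n_nodes <- length(gr$node_voxels)
  pos <- matrix(0, n_nodes, 3)
  nvox <- integer(n_nodes)
  for (t in seq_len(n_nodes)) {
    ctr <- voxel_centers(gr$node_voxels[[t]], d, sp)
    pos[t, ] <- colMeans(ctr)
    nvox[t] <- nrow(ctr)
  }
  n_links <- length(gr$link_paths)
  node_a <- gr$link_a; node_b <- gr$link_b
  polylines <- vector("list", n_links)
  for (t in seq_len(n_links)) {
    chain <- gr$link_paths[[t]]
    mid <- if (length(chain)) voxel_centers(chain, d, sp) else
      matrix(numeric(0), 0, 3)
    polylines[[t]] <- rbind(pos[node_a[t], , drop = FALSE], mid,
                            pos[node_b[t], , drop = FALSE])
  }
  # --- graph-level cleaning. The one-voxel-wide digital curve carries
  # small decorations (diagonal duplicate voxels, two-wide zigzags) that are
  # locally non-simple and so survive homotopic thinning; at graph level
  # they show up as tiny self-loops, short parallel edges, short terminal
  # stubs and short branch-branch links. Everything below the local vessel
  # radius (distance-transform) scale is sub-resolution and is consolidated
  # here, mirroring the junction handling of standard skeleton-to-graph
  # converters.
  alive_node <- rep(TRUE, n_nodes)
  alive_link <- rep(TRUE, n_links)
  plen <- vapply(polylines, polyline_length, numeric(1))
  node_edt <- rep(max(sp), n_nodes)
  if (!is.null(skel$edt)) {
    for (t in seq_len(n_nodes))
      node_edt[t] <- max(skel$edt[gr$node_voxels[[t]]], max(sp))
  }
  repeat {
    changed <- FALSE
    # self-loops shorter than the local junction girth
    drop <- which(alive_link & node_a == node_b &
                  plen < 3 * node_edt[node_a])
    if (length(drop)) { alive_link[drop] <- FALSE; changed <- TRUE }
    # short parallel duplicates between the same node pair: keep the shortest
    live <- which(alive_link & node_a != node_b)
    key <- paste(pmin(node_a[live], node_b[live]),
                 pmax(node_a[live], node_b[live]))
    for (k in unique(key[duplicated(key)])) {
      grp <- live[key == k]
      lim <- 3 * pmin(node_edt[node_a[grp]], node_edt[node_b[grp]])
      short <- grp[plen[grp] < lim]
      if (length(short) >= 1 && length(grp) >= 2) {
        keep1 <- grp[which.min(plen[grp])]
        kill <- setdiff(short, keep1)
        if (length(kill)) { alive_link[kill] <- FALSE; changed <- TRUE }
      }
    }
    deg <- tabulate(c(node_a[alive_link], node_b[alive_link]),
                    nbins = n_nodes)
    # terminal stubs shorter than the radius at their base
    live <- which(alive_link & node_a != node_b)
    for (l in live) {
      a <- node_a[l]; b <- node_b[l]
      tipn <- if (deg[a] == 1L && deg[b] >= 3L) a
              else if (deg[b] == 1L && deg[a] >= 3L) b else next
      basen <- if (tipn == a) b else a
      if (plen[l] < 1.5 * node_edt[basen]) {
        alive_link[l] <- FALSE
        alive_node[tipn] <- FALSE
        deg[a] <- deg[a] - 1L; deg[b] <- deg[b] - 1L
        changed <- TRUE
      }
    }
    # contract links joining two branch nodes closer than the vessel radius
    # (adjacent junction clusters belong to one anatomical bifurcation)
    cl <- which(alive_link & node_a != node_b &
                plen < 1.5 * pmax(node_edt[node_a], node_edt[node_b]) &
                deg[node_a] >= 3L & deg[node_b] >= 3L)
    if (length(cl)) {
      l <- cl[1]
      a <- node_a[l]; b <- node_b[l]
      node_edt[a] <- max(node_edt[a], node_edt[b])
      alive_link[l] <- FALSE
      alive_node[b] <- FALSE
      # links attached at b are routed through the contracted link's own
      # path (b -> a), preserving the centerline geometry exactly
      path_ba <- polylines[[l]][nrow(polylines[[l]]):1, , drop = FALSE]
      rel <- which(alive_link & (node_a == b | node_b == b))
      for (t in rel) {
        if (node_a[t] == b) {
          # new path: a -> b along the contracted link, then onward
          polylines[[t]] <- rbind(polylines[[l]],
                                  polylines[[t]][-1, , drop = FALSE])
          node_a[t] <- a
        }
        if (node_b[t] == b) {
          polylines[[t]] <- rbind(polylines[[t]],
                                  path_ba[-1, , drop = FALSE])
          node_b[t] <- a
        }
        plen[t] <- polyline_length(polylines[[t]])
      }
      changed <- TRUE
    }
    if (!changed) break
  }
  # drop nodes stranded by the cleaning (not original isolated voxels)
  if (any(alive_link)) {
    deg <- tabulate(c(node_a[alive_link], node_b[alive_link]),
                    nbins = n_nodes)
    alive_node[alive_node & deg == 0L] <- FALSE
    if (!any(alive_node)) alive_node[node_a[which(alive_link)[1]]] <- TRUE
  }
  # splice spurious pass-through nodes: junction clusters with exactly two
  # incident links arise from diagonal duplicate voxels riding beside the
  # digital curve, not from real bifurcations
  repeat {
    deg <- tabulate(c(node_a[alive_link], node_b[alive_link]),
                    nbins = n_nodes)
    selfloop <- unique(node_a[alive_link & node_a == node_b])
    cand <- which(alive_node & deg == 2L &
                  !(seq_len(n_nodes) %in% selfloop))
    if (!length(cand)) break
    u <- cand[1]
    inc <- which(alive_link & (node_a == u | node_b == u))
    l1 <- inc[1]; l2 <- inc[2]
    p1 <- polylines[[l1]]
    if (node_b[l1] != u) { p1 <- p1[nrow(p1):1, , drop = FALSE] }
    x <- if (node_b[l1] != u) node_b[l1] else node_a[l1]
    p2 <- polylines[[l2]]
    if (node_a[l2] != u) { p2 <- p2[nrow(p2):1, , drop = FALSE] }
    y <- if (node_a[l2] != u) node_a[l2] else node_b[l2]
    polylines[[l1]] <- rbind(p1, p2[-1, , drop = FALSE])
    node_a[l1] <- x; node_b[l1] <- y
    alive_link[l2] <- FALSE
    alive_node[u] <- FALSE
  }
  # renumber surviving nodes and links
  new_id <- cumsum(alive_node)
  keep_l <- which(alive_link)
  node_a <- new_id[node_a[keep_l]]
  node_b <- new_id[node_b[keep_l]]
  polylines <- polylines[keep_l]
  pos <- pos[alive_node, , drop = FALSE]
  n_nodes <- sum(alive_node)
  deg <- tabulate(c(node_a, node_b), nbins = n_nodes)
  kind <- ifelse(deg >= 3L, "branch",
                 ifelse(deg == 2L, "passthrough", "terminal"))
  nodes <- data.frame(id = seq_len(n_nodes), x = pos[, 1], y = pos[, 2],
                      z = pos[, 3], kind = kind,
                      junction_radius = node_edt[alive_node],
                      stringsAsFactors = FALSE)
  links <- data.frame(id = seq_along(keep_l),
                      node_a = if (length(keep_l)) node_a else integer(0),
                      node_b = if (length(keep_l)) node_b else integer(0))
  g <- vessel_graph(nodes, links, polylines)
  attr(g, "grid") <- list(dims = d, spacing = sp)
  g
}

polyline_length <- function(pl) {
  if (nrow(pl) < 2L) return(0)
  sum(sqrt(rowSums((pl[-1, , drop = FALSE] -
                    pl[-nrow(pl), , drop = FALSE])^2)))
}

#' Measure link lengths and tortuosity
#'
#' `path_length` is the summed polyline segment length, `euclidean_length`
#' the endpoint distance, and tortuosity their ratio. Degenerate closed
#' links (coincident endpoints) get `tortuosity = Inf` and `flagged = TRUE`.
#'
#' @param graph a [vessel_graph()] with polylines.
#' @export
measure_links <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  n <- nrow(graph$links)
  pl_len <- numeric(n); eu_len <- numeric(n)
  for (t in seq_len(n)) {
    pl <- graph$polylines[[t]]
    if (nrow(pl) < 2L) stop("polyline with fewer than 2 points (link ", t, ")")
    pl_len[t] <- polyline_length(pl)
    eu_len[t] <- sqrt(sum((pl[nrow(pl), ] - pl[1, ])^2))
  }
  graph$links$path_length <- pl_len
  graph$links$euclidean_length <- eu_len
  graph$links$tortuosity <- ifelse(eu_len > 1e-9, pl_len / eu_len, Inf)
  graph$links$flagged <- !is.finite(graph$links$tortuosity)
  graph
}

# Resample a polyline at given cumulative path-length fractions; returns the
# split sub-polylines (splits exactly at the requested arc positions).
split_polyline <- function(pl, fractions) {
  seg <- sqrt(rowSums((pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  cuts <- fractions * total
  pieces <- list()
  pts <- pl[1, , drop = FALSE]
  ci <- 1L
  for (s in seq_along(seg)) {
    a <- pl[s, ]; b <- pl[s + 1, ]
    while (ci <= length(cuts) && cuts[ci] <= cum[s + 1] + 1e-12 &&
           cuts[ci] > cum[s] + 1e-12) {
      f <- (cuts[ci] - cum[s]) / max(seg[s], 1e-300)
      q <- a + f * (b - a)
      pts <- rbind(pts, q)
      pieces[[length(pieces) + 1L]] <- pts
      pts <- matrix(q, 1, 3)
      ci <- ci + 1L
    }
    pts <- rbind(pts, b)
  }
  pieces[[length(pieces) + 1L]] <- pts
  pieces
}

#' Subdivide tortuous links
#'
#' Every link with tortuosity strictly greater than `threshold` is replaced
#' by `parts` child links that split its polyline at equal path-length
#' fractions, inserting pass-through nodes; the concatenation of the child
#' polylines equals the parent polyline and total path length is conserved
#' exactly. Children are re-measured but not recursively subdivided.
#'
#' @param graph a measured [vessel_graph()].
#' @param threshold tortuosity threshold (default 1.15; strict `>`).
#' @param parts number of child links per subdivided parent (default 5).
#' @export
subdivide_tortuous <- function(graph, threshold = 1.15, parts = 5L) {
  stopifnot(inherits(graph, "vessel_graph"))
  parts <- as.integer(parts)
  if (parts < 2L) stop("parts must be >= 2")
  if (is.null(graph$links$tortuosity))
    stop("run measure_links() before subdividing")
  tosplit <- which(is.finite(graph$links$tortuosity) &
                   graph$links$tortuosity > threshold)
  if (!length(tosplit)) return(graph)
  nodes <- graph$nodes
  keep <- setdiff(seq_len(nrow(graph$links)), tosplit)
  new_links <- graph$links[keep, c("id", "node_a", "node_b"), drop = FALSE]
  new_poly <- graph$polylines[keep]
  new_pr <- if (!is.null(graph$point_radii)) graph$point_radii[keep] else NULL
  has_radius <- !is.null(graph$links$radius)
  new_radius <- if (has_radius) graph$links$radius[keep] else NULL
  next_node <- max(nodes$id) + 1L
  for (t in tosplit) {
    pl <- graph$polylines[[t]]
    pieces <- split_polyline(pl, seq_len(parts - 1L) / parts)
    a <- graph$links$node_a[t]
    prev_node <- a
    for (s in seq_along(pieces)) {
      pc <- pieces[[s]]
      if (s < length(pieces)) {
        newrow <- nodes[1, , drop = FALSE]
        newrow[1, ] <- NA
        newrow$id <- next_node
        newrow$x <- pc[nrow(pc), 1]
        newrow$y <- pc[nrow(pc), 2]
        newrow$z <- pc[nrow(pc), 3]
        newrow$kind <- "passthrough"
        nodes <- rbind(nodes, newrow)
        end_node <- next_node
        next_node <- next_node + 1L
      } else end_node <- graph$links$node_b[t]
      new_links <- rbind(new_links,
                         data.frame(id = NA_integer_, node_a = prev_node,
                                    node_b = end_node))
      new_poly[[length(new_poly) + 1L]] <- pc
      if (has_radius) new_radius <- c(new_radius, graph$links$radius[t])
      if (!is.null(new_pr)) new_pr[[length(new_pr) + 1L]] <- NULL
      prev_node <- end_node
    }
  }
  new_links$id <- seq_len(nrow(new_links))
  g <- vessel_graph(nodes, new_links, new_poly, new_pr)
  if (has_radius) g$links$radius <- new_radius
  measure_links(g)
}

#' Estimate per-link radii from the mask distance transform
#'
#' The Euclidean distance transform of the mask is evaluated at each
#' centerline voxel; the per-link radius is the mean (or median) of these
#' per-point radii. For tubular shapes this equals the average
#' skeleton-to-perimeter distance. A one-voxel-wide line yields about one
#' voxel (distance to the nearest background voxel center), the documented
#' sub-voxel convention.
#'
#' @param graph a [vessel_graph()] from [skeleton_to_graph()].
#' @param mask the [binary_mask()] the skeleton came from.
#' @param summary `"mean"` (default) or `"median"` per-link aggregation.
#' @param recenter number of medial hill-climb steps: each per-point radius
#'   is read at the cross-sectional distance-transform maximum reachable
#'   within this many unit steps of the centerline point, compensating the
#'   off-axis bias of digital skeletons. 0 disables.
#' @param blur_sigma known acquisition blur (micrometers). The half-level
#'   surface of a Gaussian-blurred cylinder of radius r sits about
#'   sigma^2 / (2 r) inside the true surface; when the blur is known this
#'   curvature shrinkage is added back. 0 (default) disables.
#' @param method `"edt"` (default): the distance-transform value at the
#'   (re-centered) centerline point. `"perimeter"`: the average distance
#'   from each centerline point to its associated mask perimeter voxels
#'   (nearest-centerline-point assignment); unlike the minimum-distance
#'   convention this does not clip on lattice-aligned tubes.
#' @return the graph with `links$radius` and `point_radii` filled in.
#' @export
estimate_radii <- function(graph, mask, summary = c("mean", "median"),
                           recenter = 3, blur_sigma = 0,
                           method = c("edt", "perimeter")) {
  summary <- match.arg(summary)
  method <- match.arg(method)
  stopifnot(inherits(graph, "vessel_graph"), inherits(mask, "binary_mask"))
  d <- dim(mask$voxels)
  dt <- .edt(as.logical(mask$voxels), d, mask$spacing)
  dt <- array(dt, d)
  sp <- mask$spacing
  perim_mean <- NULL
  if (method == "perimeter") {
    # mask perimeter voxels: foreground with a background 6-neighbor
    fg <- mask$voxels
    border <- array(FALSE, d)
    for (ax in 1:3) for (s in c(-1L, 1L))
      border <- border | !shift_array(fg, ax, s, fill = FALSE)
    perim <- which(fg & border)
    pctr <- voxel_centers(perim, d, sp)
    allpts <- do.call(rbind, lapply(seq_len(nrow(graph$links)), function(t)
      cbind(graph$polylines[[t]], t, seq_len(nrow(graph$polylines[[t]])))))
    nn <- .nn_index(pctr, allpts[, 1:3, drop = FALSE])
    dists <- sqrt(rowSums((pctr - allpts[nn, 1:3, drop = FALSE])^2))
    key <- paste(allpts[nn, 4], allpts[nn, 5])
    perim_mean <- tapply(dists, key, mean)
  }
  # unit-step offsets for the medial hill climb
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offnorm <- sqrt(rowSums(offs^2))
  agg <- if (summary == "mean") mean else stats::median
  n <- nrow(graph$links)
  radii <- numeric(n)
  prad <- vector("list", n)
  for (t in seq_len(n)) {
    pl <- graph$polylines[[t]]
    ij <- cbind(pmin(pmax(ceiling(pl[, 1] / sp[1]), 1L), d[1]),
                pmin(pmax(ceiling(pl[, 2] / sp[2]), 1L), d[2]),
                pmin(pmax(ceiling(pl[, 3] / sp[3]), 1L), d[3]))
    vals <- dt[ij]
    if (recenter > 0 && nrow(pl) >= 2) {
      # unit tangents at each point (forward/backward differences)
      tg <- rbind(pl[2, ] - pl[1, ],
                  if (nrow(pl) > 2)
                    pl[3:nrow(pl), , drop = FALSE] -
                    pl[1:(nrow(pl) - 2), , drop = FALSE],
                  pl[nrow(pl), ] - pl[nrow(pl) - 1, ])
      tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
      # bounded hill climb on the distance transform, restricted to
      # cross-sectional (near-perpendicular) unit steps
      cur_ij <- ij
      for (step in seq_len(max(1L, as.integer(recenter) + 2L))) {
        best <- vals
        best_ij <- cur_ij
        for (o in seq_len(nrow(offs))) {
          off <- offs[o, ]
          cosang <- abs(tg %*% (off * sp)) / (offnorm[o] * max(sp))
          qi <- cbind(pmin(pmax(cur_ij[, 1] + off[1], 1L), d[1]),
                      pmin(pmax(cur_ij[, 2] + off[2], 1L), d[2]),
                      pmin(pmax(cur_ij[, 3] + off[3], 1L), d[3]))
          cand <- dt[qi]
          use <- cosang <= 0.6 & cand > best
          if (any(use)) {
            best[use] <- cand[use]
            best_ij[use, ] <- qi[use, , drop = FALSE]
          }
        }
        moved <- best > vals
        if (!any(moved)) break
        vals <- best
        cur_ij <- best_ij
      }
    }
    # endpoint polyline points are node centroids and may fall just outside
    # the mask for irregular junction clusters; interior points must be in
    inner <- vals[-c(1L, length(vals))]
    if (length(inner) && any(inner <= 0))
      stop("centerline point outside mask (link ", t, ")")
    if (all(vals <= 0))
      stop("centerline point outside mask (link ", t, ")")
    # node-centroid endpoints may fall just outside the mask for irregular
    # junction clusters: carry the adjacent value so per-point radii stay
    # aligned with the polyline rows (needed for tapered reconstruction)
    if (vals[1] <= 0) vals[1] <- vals[min(2L, length(vals))]
    nv <- length(vals)
    if (vals[nv] <= 0) vals[nv] <- vals[max(nv - 1L, 1L)]
    if (method == "perimeter") {
      pm <- perim_mean[paste(t, seq_len(nv))]
      vals <- ifelse(is.na(pm), vals, pm)   # fallback: distance transform
    }
    if (blur_sigma > 0)
      vals <- vals + pmin(blur_sigma^2 / (2 * vals), 0.5 * vals)
    if (nv >= 3) vals <- stats::runmed(vals, 3)   # 3-point median smoothing
    prad[[t]] <- vals
    # per-link radius: skip points within one local radius of either link
    # end, where the distance transform is limited by the end cap or reads
    # the junction blob instead of this link's cross-section
    arc <- c(0, cumsum(sqrt(rowSums(diff(pl)^2))))
    keep <- arc >= vals & (arc[nv] - arc) >= vals
    radii[t] <- if (any(keep)) agg(vals[keep]) else agg(vals)
  }
  graph$links$radius <- radii
  graph$point_radii <- prad
  graph
}

#' Summary metrics of an extracted network
#'
#' @param graph a measured [vessel_graph()].
#' @param mask the source [binary_mask()].
#' @param chamber_volume reference chamber volume in cubic millimeters.
#' @return a `network_metrics` list: volumetric coverage, vessel density
#'   (links per mm^3), length/diameter distribution summaries, and the
#'   branch-to-terminal node ratio.
#' @export
network_metrics <- function(graph, mask, chamber_volume) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(mask, "binary_mask"))
  if (!is.finite(chamber_volume) || chamber_volume <= 0)
    stop("chamber volume must be positive")
  voxel_mm3 <- prod(mask$spacing) * 1e-9       # um^3 -> mm^3
  coverage <- sum(mask$voxels) * voxel_mm3 / chamber_volume
  n_branch <- sum(graph$nodes$kind == "branch")
  n_term <- sum(graph$nodes$kind == "terminal")
  ratio <- if (n_term > 0) n_branch / n_term else {
    warning("no terminal nodes; branch/terminal ratio undefined")
    NaN
  }
  if (nrow(graph$links) == 0L) warning("empty graph: zero vessel density")
  summarize <- function(v) {
    if (!length(v)) return(c(min = NA, median = NA, mean = NA, max = NA))
    c(min = min(v), median = stats::median(v), mean = mean(v), max = max(v))
  }
  structure(list(
    volumetric_coverage = coverage,
    vessel_density = nrow(graph$links) / chamber_volume,
    length_distribution = summarize(graph$links$path_length),
    diameter_distribution = summarize(2 * graph$links$radius),
    branch_terminal_ratio = ratio,
    n_branch = n_branch, n_terminal = n_term
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("network metrics: coverage %.3f, density %.1f links/mm^3, ",
                     "branch/terminal %.3f\n"),
              x$volumetric_coverage, x$vessel_density,
              x$branch_terminal_ratio))
  invisible(x)
}

#' Export / import a vessel graph as CSV tables
#'
#' Writes `<path>_nodes.csv` (`id,x,y,z,kind`) and `<path>_links.csv`
#' (`id,node_a,node_b,radius,path_length,tortuosity` plus the centerline
#' encoded as a `;`-separated polyline column) in micrometers with full
#' double precision, so the pair round-trips losslessly through
#' [read_graph_csv()].
#'
#' @param graph a measured [vessel_graph()] with radii.
#' @param path output path prefix.
#' @return invisibly, the two file paths.
#' @export
export_graph_csv <- function(graph, path) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (is.null(graph$links$radius)) stop("graph has no radii; run estimate_radii()")
  nodes_file <- paste0(path, "_nodes.csv")
  links_file <- paste0(path, "_links.csv")
  fmt <- function(x) sprintf("%.12g", x)
  nd <- graph$nodes
  nd$x <- fmt(nd$x); nd$y <- fmt(nd$y); nd$z <- fmt(nd$z)
  ok <- tryCatch({
    write.csv(nd, nodes_file, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ", nodes_file)
  poly_str <- vapply(graph$polylines, function(pl) {
    paste(apply(pl, 1, function(p) paste(fmt(p), collapse = " ")),
          collapse = ";")
  }, character(1))
  lk <- graph$links
  out <- data.frame(id = lk$id, node_a = lk$node_a, node_b = lk$node_b,
                    radius = fmt(lk$radius),
                    path_length = fmt(lk$path_length),
                    tortuosity = fmt(lk$tortuosity),
                    polyline = poly_str, stringsAsFactors = FALSE)
  write.csv(out, links_file, row.names = FALSE, quote = FALSE)
  invisible(c(nodes = nodes_file, links = links_file))
}

#' @rdname export_graph_csv
#' @export
read_graph_csv <- function(path) {
  nodes <- read.csv(paste0(path, "_nodes.csv"), stringsAsFactors = FALSE)
  lk <- read.csv(paste0(path, "_links.csv"), stringsAsFactors = FALSE)
  polylines <- lapply(lk$polyline, function(s) {
    pts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], " ", fixed = TRUE)
    do.call(rbind, lapply(pts, as.numeric))
  })
  links <- lk[, c("id", "node_a", "node_b", "radius", "path_length",
                  "tortuosity")]
  g <- vessel_graph(nodes, links, polylines)
  measure_links(g)
}
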