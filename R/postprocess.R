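# Post-processing of solved flow fields: wall shear stress, per-link flow
# statistics, streamline tracing, and the WSS multivariate regression.

# cell-centered velocity gradient tensor component d(comp)/d(axis), with
# one-sided stencils against the no-slip wall at solid interfaces. Where the
# signed wall distance `adist` (distance from the cell center to the true
# wall along each axis, in meters) is supplied, the stencil is the quadratic
# through (wall, 0), the cell and its fluid neighbor, evaluated AT THE WALL:
# exact for a parabolic profile, so the wall shear of developed tube flow is
# recovered without the half-voxel cell-center bias.
cc_gradients <- function(field, adist = NULL) {
  problem <- field$problem
  dims <- problem$dims
  h <- field$h
  cc <- cell_velocity(list(u = field$u, v = field$v, w = field$w), dims)
  fluid <- problem$fluid
  grads <- array(0, c(dims, 3, 3))   # [.., comp, axis]
  for (comp in 1:3) {
    f <- cc[[comp]]
    f[!fluid] <- 0
    for (axis in 1:3) {
      fp <- shift_array(f, axis, 1L, fill = 0)
      fm <- shift_array(f, axis, -1L, fill = 0)
      okp <- shift_array(fluid, axis, 1L, fill = FALSE)
      okm <- shift_array(fluid, axis, -1L, fill = FALSE)
      g <- array(0, dims)
      both <- okp & okm
      g[both] <- (fp[both] - fm[both]) / (2 * h)
      a <- if (is.null(adist)) array(h / 2, dims) else
        pmin(pmax(adist[, , , axis, drop = TRUE], 0), h)
      # wall on one side: quadratic through the discrete wall (zero at h/2
      # beyond the cell, where the solver imposed no-slip) and the two cell
      # values, with its derivative evaluated at the true wall position `a`
      # from the capsule distance field -- removes the cell-center bias of
      # one-sided wall gradients
      onlyp <- okp & !okm
      aa <- a[onlyp]
      g[onlyp] <- f[onlyp] * (4 * aa + h) / h^2 +
        fp[onlyp] * (h - 4 * aa) / (3 * h^2)
      onlym <- okm & !okp
      aa <- a[onlym]
      g[onlym] <- -(f[onlym] * (4 * aa + h) / h^2 +
                    fm[onlym] * (h - 4 * aa) / (3 * h^2))
      # isolated along this axis: walls on both sides -- gradient ~ 0
      grads[, , , comp, axis] <- g
    }
  }
  grads
}

#' Wall shear stress on the lumen wall
#'
#' For every lumen cell adjacent to the endothelium (or to a solid wall),
#' the full viscous traction is evaluated from the cell-centered velocity
#' gradient tensor (one-sided first-order differences against the no-slip
#' interface value at solid walls) and the local surface normal estimated
#' from the smooth capsule distance field; the reported WSS is the magnitude
#' of the tangential component of `mu (grad v + grad v^T) n`. Values are in
#' Pa (multiply by 10 for dyn/cm^2).
#'
#' @param field a solved `flow_field`.
#' @return a `wss_field`: data frame of wall-adjacent lumen cells with
#'   position (micrometers), WSS (Pa and dyn/cm^2), owning link id, and the
#'   wall-face area-weight (number of wall faces of that cell).
#' @export
wall_shear_stress <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  problem <- field$problem
  lf <- problem$field
  labels <- lf$labels
  dims <- problem$dims
  h_um <- lf$spacing[1]
  mu <- problem$props$mu
  lumen <- labels == LUMEN & problem$fluid
  wallish <- labels == ENDOTHELIUM | labels == EXTERIOR | !problem$fluid
  nwall <- array(0L, dims)
  for (axis in 1:3) for (s in c(-1L, 1L))
    nwall <- nwall + (shift_array(wallish, axis, s, fill = TRUE) & lumen)
  sel <- which(lumen & nwall > 0L)
  if (!length(sel)) stop("no lumen wall cells in field")
  # surface normal from the capsule signed distance (fallback: smoothed
  # lumen occupancy)
  if (!is.null(lf$gdist)) {
    phi <- lf$gdist
  } else {
    phi <- -as.numeric(lumen)
    dim(phi) <- dims
    w <- gauss_kernel(1)
    for (a in 1:3) phi <- conv_axis(phi, w, a)
  }
  nx <- grad_axis(phi, 1); ny <- grad_axis(phi, 2); nz <- grad_axis(phi, 3)
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nx <- nx / pmax(nn, 1e-12); ny <- ny / pmax(nn, 1e-12)
  nz <- nz / pmax(nn, 1e-12)
  # distance from each cell center to the true wall along each grid axis
  # (normal distance from the capsule field divided by the normal component)
  adist <- NULL
  if (!is.null(lf$gdist)) {
    h <- field$h
    dn <- pmax(-lf$gdist, 0.05) * 1e-6          # um -> m, inside lumen
    adist <- array(0, c(dims, 3))
    adist[, , , 1] <- dn / pmax(abs(nx), 1e-3)
    adist[, , , 2] <- dn / pmax(abs(ny), 1e-3)
    adist[, , , 3] <- dn / pmax(abs(nz), 1e-3)
  }
  grads <- cc_gradients(field, adist)
  # traction t = mu (grad v + grad v^T) n, in m/s per m (gradients already /m)
  tx <- ty <- tz <- numeric(length(sel))
  nvec <- cbind(nx[sel], ny[sel], nz[sel])
  gd <- function(comp, axis) grads[, , , comp, axis][sel]
  tr <- matrix(0, length(sel), 3)
  for (i_comp in 1:3) {
    acc <- numeric(length(sel))
    for (j_ax in 1:3)
      acc <- acc + (gd(i_comp, j_ax) + gd(j_ax, i_comp)) * nvec[, j_ax]
    tr[, i_comp] <- mu * acc
  }
  tn <- rowSums(tr * nvec)
  tt <- tr - tn * nvec
  wss <- sqrt(rowSums(tt^2))
  idx0 <- sel - 1L
  i <- idx0 %% dims[1]; j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  out <- data.frame(
    x = (i + 0.5) * h_um, y = (j + 0.5) * h_um, z = (k + 0.5) * h_um,
    wss_pa = wss, wss_dyn_cm2 = wss * 10,
    link_id = if (!is.null(lf$link_id)) lf$link_id[sel] else NA_integer_,
    n_wall_faces = nwall[sel])
  structure(list(cells = out,
                 mean_wss_pa = sum(out$wss_pa * out$n_wall_faces) /
                   sum(out$n_wall_faces),
                 face_area_m2 = (field$h)^2),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("wss_field: %d wall cells, mean WSS %.4g Pa (%.4g dyn/cm^2)\n",
              nrow(x$cells), x$mean_wss_pa, 10 * x$mean_wss_pa))
  invisible(x)
}

# polyline tangents at the nearest centerline point for a set of positions
nearest_tangent <- function(polyline, pts) {
  n <- nrow(polyline)
  segs <- diff(polyline)
  lens <- sqrt(rowSums(segs^2))
  tang <- segs / pmax(lens, 1e-12)
  mid <- (polyline[-n, , drop = FALSE] + polyline[-1, , drop = FALSE]) / 2
  nn <- .nn_index(pts, mid)
  tang[nn, , drop = FALSE]
}

#' Per-link flow statistics
#'
#' For every link of the graph used to build the label field: mean axial
#' velocity (cell-mean of the velocity component along the local centerline
#' tangent over the link's lumen voxels), volumetric inflow and outflow
#' through its junction/boundary cross-sections, transmural leakage through
#' its lumen-endothelium interface, mean WSS over its wall cells, and its
#' radius. `inflow - outflow - leakage = 0` holds to the solver's
#' divergence tolerance.
#'
#' @param field a solved `flow_field`.
#' @param graph the measured [vessel_graph()] the label field was built from.
#' @param wss optionally, a precomputed [wall_shear_stress()] result.
#' @return a data frame, one row per link.
#' @export
link_statistics <- function(field, graph, wss = NULL) {
  stopifnot(inherits(field, "flow_field"), inherits(graph, "vessel_graph"))
  problem <- field$problem
  lf <- problem$field
  if (is.null(lf$link_id)) stop("label field has no link ownership")
  dims <- problem$dims
  h <- field$h
  h_um <- lf$spacing[1]
  lumen <- lf$labels == LUMEN & problem$fluid
  owner <- lf$link_id
  owner[!lumen] <- 0L
  if (is.null(wss)) wss <- wall_shear_stress(field)
  cc <- cell_velocity(list(u = field$u, v = field$v, w = field$w), dims)
  varr <- list(field$u, field$v, field$w)
  out <- list()
  for (t in seq_len(nrow(graph$links))) {
    lid <- graph$links$id[t]
    cells <- which(owner == lid)
    if (!length(cells)) {
      warning("link ", lid, " has no lumen voxels at this resolution")
      next
    }
    idx0 <- cells - 1L
    pos <- cbind(((idx0 %% dims[1]) + 0.5) * h_um,
                 (((idx0 %/% dims[1]) %% dims[2]) + 0.5) * h_um,
                 ((idx0 %/% (dims[1] * dims[2])) + 0.5) * h_um)
    tang <- nearest_tangent(graph$polylines[[t]], pos)
    vax <- cc$u[cells] * tang[, 1] + cc$v[cells] * tang[, 2] +
      cc$w[cells] * tang[, 3]
    mean_axial <- mean(vax)
    # face fluxes out of this link's lumen voxel set
    inflow <- outflow <- leak <- 0
    for (a in 1:3) {
      ax <- problem$axes[[a]]
      own_f <- array(0L, ax$fd)
      na <- dims[a]
      ownW <- array(0L, ax$fd); ownE <- array(0L, ax$fd)
      labW <- array(EXTERIOR, ax$fd); labE <- array(EXTERIOR, ax$fd)
      if (a == 1) {
        ownW[2:(na + 1), , ] <- owner; ownE[1:na, , ] <- owner
        labW[2:(na + 1), , ] <- lf$labels; labE[1:na, , ] <- lf$labels
      } else if (a == 2) {
        ownW[, 2:(na + 1), ] <- owner; ownE[, 1:na, ] <- owner
        labW[, 2:(na + 1), ] <- lf$labels; labE[, 1:na, ] <- lf$labels
      } else {
        ownW[, , 2:(na + 1)] <- owner; ownE[, , 1:na] <- owner
        labW[, , 2:(na + 1)] <- lf$labels; labE[, , 1:na] <- lf$labels
      }
      vA <- varr[[a]]
      # faces where exactly one side belongs to this link's lumen
      selW <- which(ownW == lid & ownE != lid)   # link on lower side: outward = +v
      selE <- which(ownE == lid & ownW != lid)   # link on upper side: outward = -v
      for (sgn in c(1, -1)) {
        ss <- if (sgn > 0) selW else selE
        if (!length(ss)) next
        olab <- if (sgn > 0) labE[ss] else labW[ss]
        oown <- if (sgn > 0) ownE[ss] else ownW[ss]
        q <- sgn * vA[ss] * h^2           # outward volumetric flux
        is_leak <- olab == ENDOTHELIUM | olab == INTERSTITIUM
        is_thru <- !is_leak                # other link's lumen or boundary
        leak <- leak + sum(q[is_leak])
        outflow <- outflow + sum(pmax(q[is_thru], 0))
        inflow <- inflow + sum(pmax(-q[is_thru], 0))
      }
    }
    wcells <- wss$cells[wss$cells$link_id == lid, , drop = FALSE]
    mwss <- if (nrow(wcells))
      sum(wcells$wss_pa * wcells$n_wall_faces) / sum(wcells$n_wall_faces)
    else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      link_id = lid, radius = graph$links$radius[t],
      n_lumen_cells = length(cells),
      mean_axial_velocity = mean_axial,
      inflow = inflow, outflow = outflow, leakage = leak,
      closure = inflow - outflow - leak,
      mean_wss_pa = mwss)
  }
  do.call(rbind, out)
}

# trilinear interpolation of one staggered component at physical positions
interp_staggered <- function(arr, axis, pts_um, h_um) {
  # component `axis` lives at face centers: coordinate along `axis` is i*h,
  # others at (i+0.5)*h. Convert to 1-based fractional array indices.
  xi <- pts_um[, 1] / h_um + if (axis == 1) 1 else 0.5
  yi <- pts_um[, 2] / h_um + if (axis == 2) 1 else 0.5
  zi <- pts_um[, 3] / h_um + if (axis == 3) 1 else 0.5
  trilinear_sample(arr, xi, yi, zi)
}

#' Sample the interpolated velocity vector (m/s) at physical points
#'
#' @param field a solved `flow_field`.
#' @param pts n x 3 matrix of positions in micrometers.
#' @export
sample_velocity <- function(field, pts) {
  h_um <- field$h * 1e6
  pts <- matrix(pts, ncol = 3)
  cbind(interp_staggered(field$u, 1, pts, h_um),
        interp_staggered(field$v, 2, pts, h_um),
        interp_staggered(field$w, 3, pts, h_um))
}

#' Trace streamlines through a solved field
#'
#' Fourth-order Runge-Kutta advection of massless tracers through the
#' trilinearly interpolated velocity field until the tracer leaves the
#' domain, stagnates (`|v| < v_min`), or exceeds `max_len`.
#'
#' @param field a solved `flow_field`.
#' @param seeds n x 3 matrix of seed points, micrometers.
#' @param step integration step in micrometers (default: one voxel).
#' @param max_len maximum path length in micrometers.
#' @param v_min stagnation speed, m/s.
#' @return list of polyline matrices (micrometers), one per seed.
#' @export
streamlines <- function(field, seeds, step = NULL, max_len = 5000,
                        v_min = 1e-12) {
  seeds <- matrix(seeds, ncol = 3)
  h_um <- field$h * 1e6
  if (is.null(step)) step <- h_um
  extent <- field$dims * h_um
  inside <- function(p) all(p >= 0) && all(p <= extent)
  lapply(seq_len(nrow(seeds)), function(s) {
    p <- seeds[s, ]
    if (!inside(p)) stop("seed outside domain")
    path <- matrix(p, 1, 3)
    travelled <- 0
    repeat {
      vel <- function(q) as.vector(sample_velocity(field, matrix(q, 1, 3)))
      v1 <- vel(p)
      sp <- sqrt(sum(v1^2))
      if (sp < v_min || travelled >= max_len) break
      dirstep <- function(v) step * v / sqrt(sum(v^2))
      k1 <- dirstep(v1)
      q2 <- p + k1 / 2; if (!inside(q2)) break
      v2 <- vel(q2); if (sqrt(sum(v2^2)) < v_min) break
      k2 <- dirstep(v2)
      q3 <- p + k2 / 2; if (!inside(q3)) break
      v3 <- vel(q3); if (sqrt(sum(v3^2)) < v_min) break
      k3 <- dirstep(v3)
      q4 <- p + k3; if (!inside(q4)) break
      v4 <- vel(q4); if (sqrt(sum(v4^2)) < v_min) break
      k4 <- dirstep(v4)
      p <- p + (k1 + 2 * k2 + 2 * k3 + k4) / 6
      if (!inside(p)) break
      path <- rbind(path, p)
      travelled <- travelled + step
    }
    path
  })
}

#' Multivariate regression of wall shear stress
#'
#' Ordinary least squares of per-link mean WSS on mean axial velocity,
#' transmural (vessel-wall) outflow, and vessel radius. Reports
#' coefficients, R-squared, per-predictor F-test p-values, variance
#' inflation factors, and the predicted-versus-actual table.
#'
#' @param stats a [link_statistics()] data frame (>= 5 complete links).
#' @return a `wss_regression` list.
#' @export
wss_regression <- function(stats) {
  df <- stats[stats$n_lumen_cells > 0 & is.finite(stats$mean_wss_pa), ,
              drop = FALSE]
  df <- data.frame(wss = df$mean_wss_pa,
                   axial_velocity = df$mean_axial_velocity,
                   wall_outflow = df$leakage,
                   radius = df$radius)
  if (nrow(df) < 5L) stop("need at least 5 links with complete statistics")
  fit <- lm(wss ~ axial_velocity + wall_outflow + radius, data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear predictors: ",
         paste(bad, collapse = ", "))
  }
  sm <- suppressWarnings(summary(fit))
  # per-predictor F tests (equal to squared t in this full model)
  tv <- sm$coefficients[-1, "t value"]
  dfres <- fit$df.residual
  pvals <- pf(tv^2, 1, dfres, lower.tail = FALSE)
  preds <- c("axial_velocity", "wall_outflow", "radius")
  vif <- vapply(preds, function(p) {
    r2 <- summary(lm(stats::reformulate(setdiff(preds, p), p),
                     data = df))$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1))
  structure(list(fit = fit,
                 coefficients = coef(fit),
                 r_squared = sm$r.squared,
                 p_values = pvals,
                 vif = vif,
                 predicted_vs_actual = data.frame(
                   predicted = predict(fit), actual = df$wss)),
            class = "wss_regression")
}

#' @export
print.wss_regression <- function(x, ...) {
  cat(sprintf("WSS regression: R^2 = %.3f\n", x$r_squared))
  print(round(x$coefficients, 6))
  cat("VIF:\n"); print(round(x$vif, 3))
  invisible(x)
}

#' Device hydraulic conductance from a solved field
#'
#' Total volumetric inflow divided by the driving pressure (largest tagged
#' inlet pressure minus the outlet pressure), m^3 s^-1 Pa^-1. Used by the
#' finite-reservoir protocol ([reservoir_pressure()]).
#'
#' @param field a solved `flow_field`.
#' @export
device_conductance <- function(field) {
  bf <- field$boundary_flux
  dp <- max(bf$pressure) - min(bf$pressure)
  if (dp <= 0) stop("no pressure difference across tagged boundaries")
  sum(bf$flux[bf$flux > 0]) / dp
}
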