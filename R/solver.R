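# Steady incompressible flow over a label field: Navier-Stokes in the lumen,
# Brinkman (optionally with Forchheimer and convective terms) in the porous
# endothelium and interstitium, discretized on a MAC staggered grid as one
# unified momentum/continuity system and solved with an augmented-Lagrangian
# Uzawa iteration around a sparse Cholesky factorization.

label_name <- function(label) {
  c("EXTERIOR", "LUMEN", "ENDOTHELIUM", "INTERSTITIUM")[label + 1L]
}

# shift an array by `s` along `axis`, filling vacated entries with `fill`
shift_array <- function(arr, axis, s, fill = NA) {
  d <- dim(arr)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) (1 + s):n else 1:(n + s)
  dst <- if (s > 0) 1:(n - s) else (1 - s):n
  ix <- function(a, idx) switch(a, arr[idx, , , drop = FALSE],
                                arr[, idx, , drop = FALSE],
                                arr[, , idx, drop = FALSE])
  if (axis == 1) out[dst, , ] <- ix(1, src)
  else if (axis == 2) out[, dst, ] <- ix(2, src)
  else out[, , dst] <- ix(3, src)
  out
}

face_dims <- function(dims, axis) {
  fd <- dims
  fd[axis] <- fd[axis] + 1L
  fd
}

#' Assemble the discrete flow problem
#'
#' Builds the staggered-grid saddle-point system for the label field:
#' one momentum equation per unknown face velocity (viscous term
#' `mu_region / eps_p` Laplacian, Darcy drag `mu/kappa` averaged across
#' region interfaces as resistivities, pressure gradient) and one continuity
#' equation per fluid cell. Regions with `kappa = 0` and `EXTERIOR` voxels
#' are no-slip solids. Boundary faces whose region carries a pressure tag
#' get that pressure imposed in the ghost cell; all other domain boundaries
#' are no-slip walls.
#'
#' @param field a `label_field` from [build_label_field()].
#' @param props a [material_props()].
#' @param bcs a [boundary_conditions()].
#' @param slip_walls treat untagged domain boundaries as free-slip symmetry
#'   planes instead of no-slip walls (default FALSE: chamber walls are
#'   physical). Interior solid interfaces are always no-slip.
#' @return a `flow_problem` for [solve_flow()].
#' @export
assemble_problem <- function(field, props, bcs, slip_walls = FALSE) {
  stopifnot(inherits(field, "label_field"), inherits(props, "material_props"),
            inherits(bcs, "boundary_conditions"))
  if (!spacing_isotropic(field$spacing))
    stop("label field must have isotropic spacing")
  labels <- field$labels
  dims <- dim(labels)
  h <- field$spacing[1] * 1e-6           # um -> m
  reg <- props$regions
  # per-cell material arrays
  eps_c <- array(NA_real_, dims)
  muv_c <- array(NA_real_, dims)         # effective viscosity mu_region/eps
  drag_c <- array(NA_real_, dims)        # Darcy resistivity mu_region/kappa
  kap_c <- array(NA_real_, dims)
  cf_c <- array(NA_real_, dims)
  solid <- labels == EXTERIOR
  for (t in seq_len(nrow(reg))) {
    sel <- labels == reg$label[t]
    if (!any(sel)) next
    if (reg$label[t] != LUMEN && !is.na(reg$kappa[t]) && reg$kappa[t] == 0) {
      solid[sel] <- TRUE
      next
    }
    if (reg$label[t] != LUMEN && is.na(reg$kappa[t]))
      stop("porous region ", reg$name[t], " has no permeability")
    eps_c[sel] <- reg$eps[t]
    muv_c[sel] <- reg$mu[t] / reg$eps[t]
    drag_c[sel] <- if (reg$label[t] == LUMEN) 0 else reg$mu[t] / reg$kappa[t]
    kap_c[sel] <- if (reg$label[t] == LUMEN) NA_real_ else reg$kappa[t]
    cf_c[sel] <- reg$Cf[t]
  }
  fluid <- !solid & labels != EXTERIOR
  n_fluid <- sum(fluid)
  if (n_fluid == 0L) stop("no fluid cells in domain")
  cid <- array(0L, dims)
  cid[fluid] <- seq_len(n_fluid)

  sides <- matrix(c("x-", "x+", "y-", "y+", "z-", "z+"), nrow = 2)
  axes <- list()
  fid_counter <- 0L
  for (a in 1:3) {
    fd <- face_dims(dims, a)
    na <- dims[a]
    pad_lo <- function(arr, fill = NA) {   # value of lower (W) cell per face
      out <- array(fill, fd)
      if (a == 1) out[2:(na + 1), , ] <- arr
      else if (a == 2) out[, 2:(na + 1), ] <- arr
      else out[, , 2:(na + 1)] <- arr
      out
    }
    pad_hi <- function(arr, fill = NA) {   # value of upper (E) cell per face
      out <- array(fill, fd)
      if (a == 1) out[1:na, , ] <- arr
      else if (a == 2) out[, 1:na, ] <- arr
      else out[, , 1:na] <- arr
      out
    }
    Wfluid <- pad_lo(fluid, FALSE); Efluid <- pad_hi(fluid, FALSE)
    Wcid <- pad_lo(cid, 0L); Ecid <- pad_hi(cid, 0L)
    unknown <- Wfluid & Efluid
    # tagged pressure boundary faces (tbc: index into names(bcs$pressures))
    pbc <- array(NA_real_, fd)
    tbc <- array(NA_integer_, fd)
    slice_assign <- function(arr, idx, vals) {
      if (a == 1) arr[idx, , ] <- vals
      else if (a == 2) arr[, idx, ] <- vals
      else arr[, , idx] <- vals
      arr
    }
    slice_get <- function(arr, idx) {
      if (a == 1) arr[idx, , ] else if (a == 2) arr[, idx, ] else arr[, , idx]
    }
    for (end in 1:2) {
      side <- sides[end, a]
      tags <- field$face_tags[[side]]
      if (is.null(tags)) next
      fidx <- if (end == 1) 1L else na + 1L
      cidx <- if (end == 1) 1L else na
      lab_slice <- slice_get(labels, cidx)
      fl_slice <- slice_get(fluid, cidx)
      lid_slice <- if (!is.null(field$link_id)) slice_get(field$link_id, cidx)
      pb <- array(NA_real_, dim(as.array(lab_slice)))
      tg <- array(NA_integer_, dim(as.array(lab_slice)))
      for (nm in names(tags)) {
        tag <- tags[[nm]]
        if (!tag %in% names(bcs$pressures)) next
        if (grepl("^link_", nm)) {
          # tag applies to the lumen of one specific link (distinguishes
          # several vessels piercing the same block face)
          if (is.null(lid_slice)) next
          sel <- lid_slice == as.integer(sub("^link_", "", nm)) & fl_slice
        } else {
          lab_code <- match(nm, c("EXTERIOR", "LUMEN", "ENDOTHELIUM",
                                  "INTERSTITIUM")) - 1L
          sel <- lab_slice == lab_code & fl_slice
        }
        pb[sel] <- bcs$pressures[[tag]]
        tg[sel] <- match(tag, names(bcs$pressures))
      }
      cur <- slice_get(pbc, fidx)
      curt <- slice_get(tbc, fidx)
      cur[!is.na(pb)] <- pb[!is.na(pb)]
      curt[!is.na(tg)] <- tg[!is.na(tg)]
      pbc <- slice_assign(pbc, fidx, cur)
      tbc <- slice_assign(tbc, fidx, curt)
    }
    unknown <- unknown | !is.na(pbc)
    fid <- array(0L, fd)
    nf_a <- sum(unknown)
    fid[unknown] <- fid_counter + seq_len(nf_a)
    fid_counter <- fid_counter + nf_a
    # wall weight of known (zero) faces: 1 if the face borders a fluid cell
    # (no-slip value at distance h), 2 if it lies inside solid or outside the
    # domain (wall plane halfway)
    wallw <- array(2, fd)
    wallw[Wfluid | Efluid] <- 1
    wallw[unknown] <- 0
    mean2 <- function(A, B) {
      out <- (A + B) / 2
      out[is.na(A)] <- B[is.na(A)]
      out[is.na(B)] <- A[is.na(B)]
      out
    }
    axes[[a]] <- list(
      fd = fd, unknown = unknown, fid = fid, wallw = wallw,
      Wcid = Wcid, Ecid = Ecid, pbc = pbc, tbc = tbc,
      drag = mean2(pad_lo(drag_c), pad_hi(drag_c)),
      muf = mean2(pad_lo(muv_c), pad_hi(muv_c)),
      epsf = mean2(pad_lo(eps_c), pad_hi(eps_c)),
      kapf = mean2(pad_lo(kap_c), pad_hi(kap_c)),
      cff = mean2(pad_lo(cf_c), pad_hi(cf_c)))
  }
  n_face <- fid_counter

  # ---- momentum rows (A triplets), pressure gradient RHS, D triplets
  Ai <- list(); Aj <- list(); Ax <- list()
  b <- numeric(n_face)
  drag0 <- numeric(n_face)
  face_meta <- vector("list", 3)
  Di <- list(); Dj <- list(); Dx <- list()
  push <- function(lst, v) { lst[[length(lst) + 1L]] <- v; lst }
  for (a in 1:3) {
    ax <- axes[[a]]
    uf <- which(ax$unknown)
    fids <- ax$fid[uf]
    muf <- ax$muf[uf]
    drag0[fids] <- ax$drag[uf]
    diag_acc <- ax$drag[uf]
    for (d in 1:3) {
      for (s in c(-1L, 1L)) {
        qfid <- shift_array(ax$fid, d, s, fill = -1L)[uf]
        qwall <- shift_array(ax$wallw, d, s, fill = -1)[uf]
        qmu <- shift_array(ax$muf, d, s, fill = NA)[uf]
        mu_cpl <- ifelse(is.na(qmu), muf, (muf + qmu) / 2)
        outside <- qfid < 0
        isunk <- qfid > 0
        iszero <- !outside & !isunk
        # unknown neighbor: symmetric coupling
        if (any(isunk)) {
          Ai <- push(Ai, fids[isunk]); Aj <- push(Aj, qfid[isunk])
          Ax <- push(Ax, -mu_cpl[isunk] / h^2)
          diag_acc[isunk] <- diag_acc[isunk] + mu_cpl[isunk] / h^2
        }
        # zero-velocity neighbor face: diag only (weight 2 = wall halfway)
        if (any(iszero)) {
          diag_acc[iszero] <- diag_acc[iszero] +
            qwall[iszero] * mu_cpl[iszero] / h^2
        }
        # outside the face array: tangential -> wall halfway (or symmetry
        # plane when slip_walls); normal -> free
        if (any(outside) && d != a && !slip_walls) {
          diag_acc[outside] <- diag_acc[outside] + 2 * muf[outside] / h^2
        }
      }
    }
    Ai <- push(Ai, fids); Aj <- push(Aj, fids); Ax <- push(Ax, diag_acc)
    # pressure coupling and RHS
    Wc <- ax$Wcid[uf]; Ec <- ax$Ecid[uf]
    pb <- ax$pbc[uf]
    hasW <- Wc > 0L; hasE <- Ec > 0L
    # D rows: +1/h on a cell's upper face, -1/h on its lower face
    Di <- push(Di, Wc[hasW]); Dj <- push(Dj, fids[hasW])
    Dx <- push(Dx, rep(1 / h, sum(hasW)))
    Di <- push(Di, Ec[hasE]); Dj <- push(Dj, fids[hasE])
    Dx <- push(Dx, rep(-1 / h, sum(hasE)))
    # ghost-side boundary pressures
    gW <- !hasW & !is.na(pb)     # ghost below: +pb/h to RHS
    gE <- !hasE & !is.na(pb)
    b[fids[gW]] <- b[fids[gW]] + pb[gW] / h
    b[fids[gE]] <- b[fids[gE]] - pb[gE] / h
    face_meta[[a]] <- list(uf = uf, fid = fids, ghostW = gW, ghostE = gE,
                           pb = pb, tag = ax$tbc[uf])
  }
  A <- Matrix::sparseMatrix(i = unlist(Ai), j = unlist(Aj), x = unlist(Ax),
                            dims = c(n_face, n_face))
  D <- Matrix::sparseMatrix(i = unlist(Di), j = unlist(Dj), x = unlist(Dx),
                            dims = c(n_fluid, n_face))
  if (!any(!is.na(unlist(lapply(axes, function(ax) ax$pbc))))) {
    stop("no reachable pressure boundary: tag at least one face")
  }
  # face-level Forchheimer coefficient rho * eps * Cf / sqrt(kappa)
  ffc <- numeric(n_face)
  epsf <- numeric(n_face)
  for (a in 1:3) {
    ax <- axes[[a]]
    uf <- which(ax$unknown)
    fids <- ax$fid[uf]
    kv <- ax$kapf[uf]
    ev <- ax$epsf[uf]
    cv <- ax$cff[uf]
    f <- props$rho * ev * cv / sqrt(kv)
    f[!is.finite(f)] <- 0      # lumen faces: no Forchheimer drag
    ffc[fids] <- f
    epsf[fids] <- ifelse(is.na(ev), 1, ev)
  }
  structure(list(A = A, D = D, b = b, drag = drag0, forch_coef = ffc,
                 eps_face = epsf,
                 axes = lapply(axes, function(ax)
                   ax[c("fd", "fid", "unknown", "Wcid", "Ecid", "pbc")]),
                 face_meta = face_meta,
                 n_face = n_face, n_cell = n_fluid,
                 h = h, dims = dims, cid = cid, fluid = fluid,
                 field = field, props = props, bcs = bcs),
            class = "flow_problem")
}

# scatter the face-velocity solution vector into staggered arrays (m/s)
faces_to_arrays <- function(problem, v) {
  out <- vector("list", 3)
  for (a in 1:3) {
    ax <- problem$axes[[a]]
    arr <- array(0, ax$fd)
    arr[ax$unknown] <- v[ax$fid[ax$unknown]]
    out[[a]] <- arr
  }
  names(out) <- c("u", "v", "w")
  out
}

# cell-centered velocity components from staggered arrays
cell_velocity <- function(uvw, dims) {
  ucc <- (uvw$u[1:dims[1], , , drop = FALSE] +
          uvw$u[2:(dims[1] + 1), , , drop = FALSE]) / 2
  vcc <- (uvw$v[, 1:dims[2], , drop = FALSE] +
          uvw$v[, 2:(dims[2] + 1), , drop = FALSE]) / 2
  wcc <- (uvw$w[, , 1:dims[3], drop = FALSE] +
          uvw$w[, , 2:(dims[3] + 1), drop = FALSE]) / 2
  list(u = ucc, v = vcc, w = wcc)
}

solve_linear_inner <- function(problem, drag_total, rhs, tol, max_uzawa = 200L,
                               gamma = 1e3) {
  A <- problem$A
  n_face <- problem$n_face
  # replace drag diagonal: A was built with drag0 on the diagonal
  dd <- drag_total - problem$drag
  if (any(dd != 0)) A <- A + Matrix::Diagonal(n_face, dd)
  D <- problem$D
  h <- problem$h
  diagA <- Matrix::diag(A)
  # per-cell augmentation weight ~ gamma * h^2 * local momentum diagonal,
  # so the grad-div term scales with the local operator (robust across
  # permeability jumps of many decades)
  absD <- abs(D)
  cnt <- pmax(Matrix::rowSums(absD > 0), 1)
  mean_diag <- as.vector(absD %*% diagA) * h / cnt
  wc <- gamma * h^2 * pmax(mean_diag, min(diagA[diagA > 0]))
  K <- A + Matrix::crossprod(D, Matrix::Diagonal(problem$n_cell, wc) %*% D)
  ch <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = FALSE, perm = TRUE,
                     super = TRUE),
    error = function(e)   # very large factors: fall back to simplicial
      Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = FALSE, perm = TRUE,
                       super = FALSE))
  p <- numeric(problem$n_cell)
  v <- numeric(n_face)
  div_hist <- numeric(0)
  for (it in seq_len(max_uzawa)) {
    rhs_v <- rhs + as.vector(Matrix::crossprod(D, p))
    v <- as.vector(Matrix::solve(ch, rhs_v))
    dv <- as.vector(D %*% v)
    p <- p - wc * dv
    mdv <- max(abs(dv))
    div_hist <- c(div_hist, mdv)
    vmax <- max(abs(v), 1e-300)
    if (mdv <= 1e-10 * vmax / h) break
    if (it > 20 && mdv > 0.5 * div_hist[it - 10]) break  # numerical floor
  }
  list(v = v, p = p, div = dv, div_hist = div_hist, uzawa_iter = it)
}

#' Solve the assembled flow problem
#'
#' `mode = "stokes_brinkman_linear"` (default) drops the convective and
#' Forchheimer terms -- valid at the device Reynolds numbers of order 1e-3 --
#' and solves a single sparse saddle-point system (augmented-Lagrangian
#' Uzawa around a Cholesky factorization, deterministic ordering).
#' `mode = "picard_full"` honors the full equations by lagging `|v|` in the
#' Forchheimer drag and the advecting velocity in the convective term,
#' iterating until the relative velocity change drops below `tol`.
#'
#' @param problem a `flow_problem` from [assemble_problem()].
#' @param mode `"stokes_brinkman_linear"` or `"picard_full"`.
#' @param tol relative Picard tolerance (default 1e-8).
#' @param max_iter Picard iteration cap.
#' @return a `flow_field`: staggered velocity arrays `u, v, w` (m/s), cell
#'   pressures `p` (Pa, `NA` outside fluid), divergence residual, boundary
#'   flux table, and an iteration log.
#' @export
solve_flow <- function(problem, mode = c("stokes_brinkman_linear",
                                         "picard_full"),
                       tol = 1e-8, max_iter = 30L) {
  mode <- match.arg(mode)
  stopifnot(inherits(problem, "flow_problem"))
  log <- list()
  if (mode == "stokes_brinkman_linear") {
    sol <- solve_linear_inner(problem, problem$drag, problem$b, tol)
    log$uzawa_iterations <- sol$uzawa_iter
    converged <- TRUE
  } else {
    v_prev <- NULL
    sol <- solve_linear_inner(problem, problem$drag, problem$b, tol)
    converged <- FALSE
    for (pic in seq_len(max_iter)) {
      speed <- face_speed(problem, sol$v)
      drag_tot <- problem$drag + problem$forch_coef * speed
      rhs <- problem$b - convective_term(problem, sol$v)
      sol <- solve_linear_inner(problem, drag_tot, rhs, tol)
      if (!is.null(v_prev)) {
        rel <- max(abs(sol$v - v_prev)) / max(abs(sol$v), 1e-300)
        log$picard_residual <- c(log$picard_residual, rel)
        if (rel < tol) { converged <- TRUE; break }
      }
      v_prev <- sol$v
    }
    if (!converged)
      warning("Picard iteration did not reach tol; returning best iterate")
    log$picard_iterations <- pic
  }
  uvw <- faces_to_arrays(problem, sol$v)
  p <- array(NA_real_, problem$dims)
  p[problem$fluid] <- sol$p
  bf <- boundary_flux_table(problem, sol$v)
  structure(list(u = uvw$u, v = uvw$v, w = uvw$w, p = p,
                 h = problem$h, dims = problem$dims,
                 max_div = max(abs(sol$div)),
                 boundary_flux = bf,
                 converged = converged, log = log,
                 problem = problem),
            class = "flow_field")
}

# face speed magnitude |v| for the Forchheimer term: own normal component
# plus cell-centered tangential components averaged onto the face
face_speed <- function(problem, v) {
  uvw <- faces_to_arrays(problem, v)
  cc <- cell_velocity(uvw, problem$dims)
  sp_cell <- sqrt(cc$u^2 + cc$v^2 + cc$w^2)
  out <- numeric(problem$n_face)
  for (a in 1:3) {
    ax <- problem$axes[[a]]
    lo <- array(0, ax$fd); hi <- array(0, ax$fd)
    na <- problem$dims[a]
    if (a == 1) { lo[2:(na + 1), , ] <- sp_cell; hi[1:na, , ] <- sp_cell }
    else if (a == 2) { lo[, 2:(na + 1), ] <- sp_cell; hi[, 1:na, ] <- sp_cell }
    else { lo[, , 2:(na + 1)] <- sp_cell; hi[, , 1:na] <- sp_cell }
    cntW <- (ax$Wcid > 0) + (ax$Ecid > 0)
    sp_face <- (lo * (ax$Wcid > 0) + hi * (ax$Ecid > 0)) / pmax(cntW, 1)
    uf <- which(ax$unknown)
    out[ax$fid[uf]] <- sp_face[uf]
  }
  out
}

# explicit convective term rho/eps^2 (v . grad) v_a per unknown face
convective_term <- function(problem, v) {
  uvw <- faces_to_arrays(problem, v)
  h <- problem$h
  rho <- problem$props$rho
  cc <- cell_velocity(uvw, problem$dims)
  out <- numeric(problem$n_face)
  comp <- list(uvw$u, uvw$v, uvw$w)
  for (a in 1:3) {
    ax <- problem$axes[[a]]
    va <- comp[[a]]
    # advecting velocity at this face: averaged cell-centered components
    adv <- vector("list", 3)
    na <- problem$dims[a]
    for (d in 1:3) {
      f <- cc[[d]]
      lo <- array(0, ax$fd); hi <- array(0, ax$fd)
      if (a == 1) { lo[2:(na + 1), , ] <- f; hi[1:na, , ] <- f }
      else if (a == 2) { lo[, 2:(na + 1), ] <- f; hi[, 1:na, ] <- f }
      else { lo[, , 2:(na + 1)] <- f; hi[, , 1:na] <- f }
      cnt <- (ax$Wcid > 0) + (ax$Ecid > 0)
      adv[[d]] <- (lo * (ax$Wcid > 0) + hi * (ax$Ecid > 0)) / pmax(cnt, 1)
    }
    conv <- array(0, ax$fd)
    for (d in 1:3) {
      gp <- shift_array(va, d, 1L, fill = NA)
      gm <- shift_array(va, d, -1L, fill = NA)
      g <- (gp - gm) / (2 * h)
      one <- (gp - va) / h; two <- (va - gm) / h
      g[is.na(g)] <- one[is.na(g)]
      g[is.na(g)] <- two[is.na(g)]
      g[is.na(g)] <- 0
      conv <- conv + adv[[d]] * g
    }
    uf <- which(ax$unknown)
    fids <- ax$fid[uf]
    out[fids] <- rho / problem$eps_face[fids]^2 * conv[uf]
  }
  out
}

# signed volumetric flux (m^3/s) through every tagged boundary face
boundary_flux_table <- function(problem, v) {
  h <- problem$h
  rows <- list()
  sides <- matrix(c("x-", "x+", "y-", "y+", "z-", "z+"), nrow = 2)
  for (a in 1:3) {
    fm <- problem$face_meta[[a]]
    ax <- problem$axes[[a]]
    for (ghost in c("W", "E")) {
      sel <- if (ghost == "W") fm$ghostW else fm$ghostE
      if (!any(sel)) next
      fids <- fm$fid[sel]
      sign_in <- if (ghost == "W") 1 else -1   # + = flow into the domain
      tagnames <- names(problem$bcs$pressures)[fm$tag[sel]]
      rows[[length(rows) + 1L]] <- data.frame(
        axis = a, side = sides[if (ghost == "W") 1 else 2, a],
        fid = fids, tag = tagnames,
        flux = sign_in * v[fids] * h^2,
        pressure = fm$pb[sel], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Global mass-conservation summary of a solved field
#'
#' @param field a `flow_field`.
#' @return list with total inflow/outflow (m^3/s), the signed imbalance and
#'   its value relative to the total inflow, and the maximum cell divergence.
#' @export
mass_balance <- function(field) {
  bf <- field$boundary_flux
  total_in <- sum(bf$flux[bf$flux > 0])
  total_out <- -sum(bf$flux[bf$flux < 0])
  imb <- sum(bf$flux)
  list(inflow = total_in, outflow = total_out, imbalance = imb,
       relative_imbalance = abs(imb) / max(total_in, 1e-300),
       max_divergence = field$max_div)
}

#' @export
print.flow_field <- function(x, ...) {
  mb <- mass_balance(x)
  cat(sprintf(paste0("flow_field %s cells @ %.3g um: max |v| %.3g m/s, ",
                     "inflow %.3g m^3/s, rel. imbalance %.2g\n"),
              paste(x$dims, collapse = "x"), x$h * 1e6,
              max(abs(x$u), abs(x$v), abs(x$w)), mb$inflow,
              mb$relative_imbalance))
  invisible(x)
}
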