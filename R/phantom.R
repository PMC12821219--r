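# Two-channel grid phantom: the device-scale fixture used to compare the
# control and cytokine-treated (IL-1b) conditions on identical geometry.

#' Two-parent-channel grid phantom
#'
#' A reduced model of the microfluidic device: two parallel parent channels
#' spanning the block along y, connected by a square-grid array of smaller
#' network vessels along x, embedded in a fibrin interstitium with a uniform
#' endothelial shell on every vessel. Parent channel 1 (link 1) is tagged
#' `vessel_inlet` where it pierces the y faces, parent channel 2 (link 2)
#' `vessel_outlet`; the interstitium is tagged `interstitial_inlet` /
#' `interstitial_outlet` on the x faces.
#'
#' @param block block extents in micrometers (default `c(320, 240, 70)`, a
#'   scaled-down, quasi-planar tissue chamber).
#' @param parent_radius parent channel radius, micrometers (default 20; the
#'   devices use needle-molded channels of a few hundred micrometers, scaled
#'   here with the chamber).
#' @param vessel_radius grid vessel radius, micrometers (default 10,
#'   matching the 20-40 um diameters of self-assembled vessels).
#' @param n_cross number of grid vessels connecting the channels (default 3).
#' @param t_endo endothelial shell thickness, micrometers.
#' @param resolution voxel size, micrometers.
#' @return list with the `graph`, the `label_field`, and the face tags used.
#' @export
two_channel_phantom <- function(block = c(320, 240, 70), parent_radius = 20,
                                vessel_radius = 10, n_cross = 3L,
                                t_endo = 5, resolution = 5) {
  x1 <- 0.2 * block[1]; x2 <- 0.8 * block[1]
  zc <- block[3] / 2
  ys <- seq(0.2, 0.8, length.out = n_cross) * block[2]
  nodes <- list(); links <- list(); poly <- list()
  nid <- 0L
  add_node <- function(p) {
    nid <<- nid + 1L
    nodes[[nid]] <<- data.frame(id = nid, x = p[1], y = p[2], z = p[3],
                                kind = "terminal")
    nid
  }
  # parent channels pierce the y faces
  c1a <- add_node(c(x1, 0, zc)); c1b <- add_node(c(x1, block[2], zc))
  c2a <- add_node(c(x2, 0, zc)); c2b <- add_node(c(x2, block[2], zc))
  links[[1]] <- data.frame(id = 1L, node_a = c1a, node_b = c1b,
                           radius = parent_radius)
  poly[[1]] <- rbind(c(x1, 0, zc), c(x1, block[2], zc))
  links[[2]] <- data.frame(id = 2L, node_a = c2a, node_b = c2b,
                           radius = parent_radius)
  poly[[2]] <- rbind(c(x2, 0, zc), c(x2, block[2], zc))
  for (t in seq_len(n_cross)) {
    na <- add_node(c(x1, ys[t], zc)); nb <- add_node(c(x2, ys[t], zc))
    links[[2 + t]] <- data.frame(id = 2L + t, node_a = na, node_b = nb,
                                 radius = vessel_radius)
    poly[[2 + t]] <- rbind(c(x1, ys[t], zc), c(x2, ys[t], zc))
  }
  g <- measure_links(vessel_graph(do.call(rbind, nodes),
                                  do.call(rbind, links), poly))
  tags <- list(
    "y-" = list(link_1 = "vessel_inlet", link_2 = "vessel_outlet"),
    "y+" = list(link_1 = "vessel_inlet", link_2 = "vessel_outlet"),
    "x-" = list(INTERSTITIUM = "interstitial_inlet"),
    "x+" = list(INTERSTITIUM = "interstitial_outlet"))
  field <- build_label_field(g, block, t_endo = t_endo,
                             resolution = resolution, face_tags = tags)
  list(graph = g, field = field, face_tags = tags)
}

#' Signed volumetric flux through one boundary tag
#'
#' @param field a solved `flow_field`.
#' @param tag boundary tag name; positive = into the domain, m^3/s.
#' @export
tag_flux <- function(field, tag) {
  bf <- field$boundary_flux
  sum(bf$flux[bf$tag == tag])
}

#' Solve both cytokine scenarios on the same phantom
#'
#' Assembles and solves the control and IL-1b-treated conditions (identical
#' geometry, endothelial permeability tenfold higher when treated) on a
#' [two_channel_phantom()], at either the per-scenario printed inlet
#' pressures or a common fixed pressure set.
#'
#' @param phantom result of [two_channel_phantom()].
#' @param fixed_pressures if not NULL, a named pressure vector used for BOTH
#'   scenarios (isolates the permeability effect from the inlet-pressure
#'   difference).
#' @return named list of solved `flow_field`s (`control`, `il1b`).
#' @export
solve_scenarios <- function(phantom, fixed_pressures = NULL) {
  out <- list()
  for (sc in c("control", "il1b")) {
    par <- scenario_parameters(sc)
    bcs <- if (is.null(fixed_pressures)) par$bcs else
      boundary_conditions(fixed_pressures)
    prob <- assemble_problem(phantom$field, par$props, bcs)
    out[[sc]] <- solve_flow(prob)
  }
  out
}
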