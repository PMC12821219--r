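# Stokes-Brinkman solver: material bookkeeping, closed-form oracles at coarse
# resolution (the acceptance suite runs the finer ones), conservation,
# linearity, Picard consistency, post-processing.

test_that("friction factor follows the porosity formula and is monotone", {
  expect_equal(friction_factor(0.265), 1.75 / sqrt(150 * 0.265^3),
               tolerance = 1e-12)
  expect_equal(friction_factor(1), 1.75 / sqrt(150), tolerance = 1e-12)
  eps <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(friction_factor(eps)) < 0))
  expect_error(friction_factor(0), "porosity")
  expect_error(friction_factor(1.2), "porosity")
})

test_that("assembly bookkeeping: boundary tags, pure-Brinkman domains,
           missing permeability", {
  tf <- tube_field(h = 5, R = 20, L = 100)
  props <- material_props(kappa_endo = 0)
  bcs <- boundary_conditions(c(inlet = 1, outlet = 0))
  prob <- assemble_problem(tf$field, props, bcs)
  tags <- unique(prob$face_meta[[3]]$tag)
  expect_setequal(names(bcs$pressures)[tags[!is.na(tags)]],
                  c("inlet", "outlet"))
  # an all-interstitium block assembles as a pure Brinkman system
  slab <- darcy_slab(nx = 20L, ny = 6L, nz = 6L)
  ps <- assemble_problem(slab, material_props(kappa_inter = 1e-12),
                         boundary_conditions(c(`in` = 1, out = 0)))
  expect_true(all(ps$drag > 0))
  # lumen needs no kappa; a porous region without one errors
  badprops <- material_props()
  badprops$regions$kappa[badprops$regions$label == INTERSTITIUM] <- NA
  expect_error(assemble_problem(slab, badprops,
                                boundary_conditions(c(`in` = 1, out = 0))),
               "permeability")
  # no tagged pressure boundary is an explicit error
  notags <- slab
  notags$face_tags <- list()
  expect_error(assemble_problem(notags, material_props(kappa_inter = 1e-12),
                                boundary_conditions(c(`in` = 1))),
               "pressure")
})

test_that("coarse Poiseuille flow approaches the closed form and conserves
           mass", {
  tf <- tube_field(h = 5, R = 20, L = 100)    # 8 cells/diameter
  props <- material_props(kappa_endo = 0)
  sol <- solve_flow(assemble_problem(tf$field, props,
                                     boundary_conditions(c(inlet = 1,
                                                           outlet = 0))))
  st <- link_statistics(sol, tf$graph)
  mu <- 1.002e-3
  v_true <- 1 * (20e-6)^2 / (8 * mu * 100e-6)
  expect_lt(abs(st$mean_axial_velocity / v_true - 1), 0.10)
  expect_equal(st$leakage, 0)
  expect_lt(abs(st$inflow - st$outflow) / st$inflow, 1e-6)
  mb <- mass_balance(sol)
  expect_lt(mb$relative_imbalance, 1e-6)
  # equal boundary pressures: identically zero flow
  s0 <- solve_flow(assemble_problem(tf$field, props,
                                    boundary_conditions(c(inlet = 2,
                                                          outlet = 2))))
  expect_equal(max(abs(s0$u), abs(s0$v), abs(s0$w)), 0, tolerance = 1e-18)
  w0 <- wall_shear_stress(s0)
  expect_equal(max(w0$cells$wss_pa), 0, tolerance = 1e-12)
})

test_that("Darcy slab reproduces the superficial velocity and uniform flow", {
  slab <- darcy_slab(nx = 50L, ny = 6L, nz = 6L, h_um = 20)
  props <- material_props(kappa_inter = 1e-12)
  sol <- solve_flow(assemble_problem(slab, props,
                                     boundary_conditions(c(`in` = 1,
                                                           out = 0)),
                                     slip_walls = TRUE))
  mb <- mass_balance(sol)
  A <- 36 * (20e-6)^2
  v_sup <- mb$inflow / A
  v_true <- 1e-12 * 1 / (1.002e-3 * 1e-3)
  expect_lt(abs(v_sup / v_true - 1), 0.05)
  mid <- sol$u[25, , ]
  expect_lt(sd(mid) / mean(mid), 1e-6)
  expect_lt(mb$relative_imbalance, 1e-6)
})

test_that("the linear field scales exactly with boundary pressures", {
  tf <- tube_field(h = 5, R = 20, L = 100)
  props <- material_props(kappa_endo = 0)
  s1 <- solve_flow(assemble_problem(tf$field, props,
                                    boundary_conditions(c(inlet = 1,
                                                          outlet = 0))))
  s2 <- solve_flow(assemble_problem(tf$field, props,
                                    boundary_conditions(c(inlet = 2,
                                                          outlet = 0))))
  expect_lt(max(abs(s2$w - 2 * s1$w)) / max(abs(s1$w)), 1e-10)
  w1 <- wall_shear_stress(s1); w2 <- wall_shear_stress(s2)
  expect_equal(w2$mean_wss_pa / w1$mean_wss_pa, 2, tolerance = 1e-9)
})

test_that("the Picard solution reduces to the linear one at creeping flow", {
  tf <- tube_field(h = 5, R = 20, L = 100)
  props <- material_props(kappa_endo = 0)
  bcs <- boundary_conditions(c(inlet = 1, outlet = 0))
  s_lin <- solve_flow(assemble_problem(tf$field, props, bcs))
  s_pic <- solve_flow(assemble_problem(tf$field, props, bcs),
                      mode = "picard_full", tol = 1e-10)
  expect_true(s_pic$converged)
  expect_lt(max(abs(s_pic$w - s_lin$w)) / max(abs(s_lin$w)), 1e-6)
  # and with rho -> 0 the convective/Forchheimer terms vanish identically
  props0 <- material_props(kappa_endo = 0)
  props0$rho <- 1e-6
  s_pic0 <- solve_flow(assemble_problem(tf$field, props0, bcs),
                       mode = "picard_full", tol = 1e-10)
  expect_lt(max(abs(s_pic0$w - s_lin$w)) / max(abs(s_lin$w)), 1e-6)
})

test_that("a permeable endothelium leaks and per-link closure holds", {
  h <- 5; R <- 20; L <- 150; w <- 2 * (R + 5 + 10)
  nodes <- data.frame(id = 1:2, x = w / 2, y = w / 2, z = c(-10, L + 10),
                      kind = "terminal")
  links <- data.frame(id = 1L, node_a = 1L, node_b = 2L, radius = R)
  g <- measure_links(vessel_graph(nodes, links,
         list(rbind(c(w / 2, w / 2, -10), c(w / 2, w / 2, L + 10)))))
  g$links$radius <- R
  f <- build_label_field(g, block = c(w, w, L), t_endo = 5, resolution = h,
         face_tags = list("z-" = list(LUMEN = "inlet"),
                          "z+" = list(LUMEN = "outlet",
                                      INTERSTITIUM = "ioutlet")))
  sol <- solve_flow(assemble_problem(f, material_props(),
                      boundary_conditions(c(inlet = 3.15, outlet = 0,
                                            ioutlet = 0))))
  st <- link_statistics(sol, g)
  expect_gt(st$leakage, 0)
  expect_lt(abs(st$closure) / st$inflow, 1e-3)
  expect_lt(mass_balance(sol)$relative_imbalance, 1e-6)
})

test_that("streamlines follow the flow and stop on stagnation", {
  tf <- tube_field(h = 5, R = 20, L = 100)
  props <- material_props(kappa_endo = 0)
  sol <- solve_flow(assemble_problem(tf$field, props,
                                     boundary_conditions(c(inlet = 1,
                                                           outlet = 0))))
  w <- dim(tf$field$labels)[1] * tf$field$spacing[1]
  sl <- streamlines(sol, matrix(c(w / 2, w / 2, 3), 1), step = 2,
                    max_len = 300)[[1]]
  # traverses the tube along the axis
  expect_gt(max(sl[, 3]) - min(sl[, 3]), 90)
  expect_lt(max(abs(sl[, 1] - w / 2)), 1)
  expect_lt(max(abs(sl[, 2] - w / 2)), 1)
  # zero field: a single point
  s0 <- solve_flow(assemble_problem(tf$field, props,
                                    boundary_conditions(c(inlet = 0,
                                                          outlet = 0))))
  expect_equal(nrow(streamlines(s0, matrix(c(w / 2, w / 2, 50), 1))[[1]]), 1L)
  expect_error(streamlines(sol, matrix(c(-5, 0, 0), 1)), "outside")
})

test_that("the WSS regression recovers coefficients, p-values and VIFs", {
  set.seed(7)
  n <- 30
  df <- data.frame(link_id = 1:n, radius = runif(n, 5, 20),
                   n_lumen_cells = 100,
                   mean_axial_velocity = runif(n, 1e-5, 3e-4),
                   inflow = 0, outflow = 0,
                   leakage = runif(n, 0, 1e-13), closure = 0,
                   mean_wss_pa = NA)
  df$mean_wss_pa <- 1.5 * df$mean_axial_velocity + 2e9 * df$leakage +
    1e-4 * df$radius + rnorm(n, sd = 1e-5)
  reg <- wss_regression(df)
  # coefficients recovered within 3 standard errors
  se <- suppressWarnings(summary(reg$fit))$coefficients[-1, "Std. Error"]
  expect_lt(abs(reg$coefficients["axial_velocity"] - 1.5), 3 * se[1])
  expect_lt(abs(reg$coefficients["wall_outflow"] - 2e9), 3 * se[2])
  expect_lt(abs(reg$coefficients["radius"] - 1e-4), 3 * se[3])
  expect_true(all(reg$vif < 2))
  expect_true(all(reg$p_values < 0.05))
  # exact linear data: R^2 = 1, velocity coefficient exact, others ~ 0
  df2 <- df
  df2$mean_wss_pa <- 2 * df2$mean_axial_velocity
  reg2 <- wss_regression(df2)
  expect_equal(reg2$r_squared, 1)
  expect_equal(unname(reg2$coefficients["axial_velocity"]), 2,
               tolerance = 1e-9)
  expect_lt(abs(reg2$coefficients["radius"]), 1e-9)
  # mutually orthogonal standardized predictors: all VIF = 1
  v <- rep(c(-1, 1), length.out = 8)
  r <- rep(c(-1, -1, 1, 1), 2)
  l <- rep(c(-1, 1, 1, -1), 2)
  df3 <- data.frame(link_id = 1:8, radius = r, n_lumen_cells = 100,
                    mean_axial_velocity = v, inflow = 0, outflow = 0,
                    leakage = l, closure = 0,
                    mean_wss_pa = v + 0.5 * r + 0.25 * l + c(0.01, -0.02,
                                                             0.03, 0.015,
                                                             -0.01, 0.02,
                                                             -0.03, 0.005))
  reg3 <- wss_regression(df3)
  expect_equal(unname(reg3$vif), rep(1, 3), tolerance = 1e-9)
  # rank-deficient design errors with the collinear predictor named
  df4 <- df
  df4$radius <- 2 * df4$mean_axial_velocity
  df4$leakage <- df4$mean_axial_velocity
  expect_error(wss_regression(df4), "collinear")
  expect_error(wss_regression(df[1:4, ]), "at least 5")
})

test_that("the finite-reservoir head decays exponentially with conductance", {
  dp0 <- 1000 * 9.81 * 0.004
  expect_equal(reservoir_pressure(G = 0, t = 100, dp0 = dp0), dp0)
  expect_equal(reservoir_pressure(G = 1e-12, t = 0, dp0 = dp0), dp0)
  p1 <- reservoir_pressure(1e-12, 5, dp0, well_area = 2e-5)
  p2 <- reservoir_pressure(2e-12, 5, dp0, well_area = 2e-5)
  expect_lt(p2, p1)            # leakier device equilibrates faster
  expect_equal(p2 / dp0, (p1 / dp0)^2, tolerance = 1e-12)
})
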