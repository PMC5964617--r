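test_that("bioheat element stiffness matches brute-force quadrature", {
  mesh <- one_triangle_mesh()
  bas <- mwablate:::tri_basis(mesh)
  p <- mesh$nodes
  k <- 0.42
  vals <- mwablate:::elem_vals(bas, k, "grad")
  for (i in 1:3) for (j in 1:3) {
    grad <- bas$b[1, i] * bas$b[1, j] + bas$c[1, i] * bas$c[1, j]
    dense <- k * grad * brute_tri_integral(p[1, ], p[2, ], p[3, ],
                                           function(r, z, l) r)
    expect_equal(vals[[(i - 1) * 3 + j]], dense, tolerance = 1e-10)
  }
})

test_that("equilibrium is preserved: no source means 37 degC everywhere", {
  mesh <- default_mesh()
  sys <- assemble_bioheat_operator(mesh, default_materials(), qext = NULL,
                                   boundary_temperature = 37)
  steady <- solve_steady_bioheat(sys)
  # Q_met = 3.9 W/m^3 is a femto-scale perturbation; equilibrium to < 0.01 C
  expect_equal(max(abs(steady$values - 37)), 0, tolerance = 0.01)
  tr <- run_transient_bioheat(sys, duration = 5, dt = 1, initial_temperature = 37)
  expect_equal(max(abs(tr$values - 37)), 0, tolerance = 0.01)
})

test_that("steady response is linear in the source", {
  mesh <- generate_mesh(rectangle_geometry(1e-3, 20e-3, 0, 20e-3), 2e-3)
  mats <- list(tissue = material_registry()$breast)
  q1 <- rep(1e5, nrow(mesh$tri))
  s0 <- solve_steady_bioheat(assemble_bioheat_operator(mesh, mats))
  s1 <- solve_steady_bioheat(assemble_bioheat_operator(mesh, mats, qext = q1))
  s2 <- solve_steady_bioheat(assemble_bioheat_operator(mesh, mats, qext = 2 * q1))
  expect_equal(s2$values - s0$values, 2 * (s1$values - s0$values), tolerance = 1e-9)
})

test_that("pure conduction with fixed end temperatures gives the linear profile", {
  # no perfusion, sides held at the same linear profile as the ends
  mesh <- generate_mesh(rectangle_geometry(10, 10.01, 0, 1), 0.1e-1)
  mats <- list(tissue = material_properties("solid", thermal_conductivity = 1,
                                            density = 1, specific_heat = 1))
  lin <- function(r, z) 30 + 20 * z
  sys <- assemble_bioheat_operator(mesh, mats, dirichlet_fun = lin,
                                   dirichlet_tags = "outer_boundary")
  steady <- solve_steady_bioheat(sys)
  expect_equal(steady$values[, 1], lin(mesh$nodes[, 1], mesh$nodes[, 2]),
               tolerance = 1e-9)
})

test_that("pure-Neumann zero-perfusion stationary problems are rejected", {
  mesh <- generate_mesh(rectangle_geometry(1, 2, 0, 1), 0.25)
  mats <- list(tissue = material_properties("solid", thermal_conductivity = 1,
                                            density = 1, specific_heat = 1))
  sys <- assemble_bioheat_operator(mesh, mats, boundary_temperature = NULL)
  expect_error(solve_steady_bioheat(sys), class = "mwablate_solver_error")
})

test_that("the steady solver reproduces the perfused-slab cosh profile", {
  # plane slab emulated at large radius so curvature is negligible;
  # exact profile imposed on the boundary, interior must follow it
  k <- 0.42; Tb <- 37; q <- 1e5; L <- 1e-2
  beta <- 1000 * 3639 * perfusion_to_volumetric_rate(33, 1020)
  R0 <- 50
  mesh <- generate_mesh(rectangle_geometry(R0, R0 + 4e-3, 0, 2 * L), 0.4e-3)
  mats <- list(tissue = material_registry()$breast)
  mats$tissue$thermal_conductivity <- k
  profile <- function(r, z) perfused_slab_analytic(k, beta, q, Tb, L, z - L)
  sys <- assemble_bioheat_operator(mesh, mats,
                                   qext = rep(q, nrow(mesh$tri)),
                                   dirichlet_fun = profile,
                                   dirichlet_tags = "outer_boundary")
  steady <- solve_steady_bioheat(sys)
  exact <- profile(mesh$nodes[, 1], mesh$nodes[, 2])
  expect_lt(max(abs(steady$values[, 1] - exact)), 0.1)
  # and the analytic oracle itself matches an independent finite-difference solve
  x <- seq(-L, L, length.out = 10001); h <- x[2] - x[1]; n <- length(x)
  d <- rep(2 * k / h^2 + beta, n); d[c(1, n)] <- 1
  lo <- rep(-k / h^2, n - 1); lo[n - 1] <- 0
  up <- rep(-k / h^2, n - 1); up[1] <- 0
  rhs <- rep(beta * Tb + q, n); rhs[c(1, n)] <- Tb
  A <- Matrix::bandSparse(n, k = c(-1, 0, 1), diagonals = list(lo, d, up))
  Tfd <- as.vector(Matrix::solve(A, rhs))
  expect_lt(max(abs(Tfd - perfused_slab_analytic(k, beta, q, Tb, L, x))), 1e-4)
})

test_that("manufactured bioheat solutions converge at second order", {
  case <- manufactured_solution_pair("bioheat")
  expect_lt(verify_manufactured(case), 1e-8)
  conv <- manufactured_convergence(case, c(8, 16, 32))
  expect_true(all(conv$order[-1] >= 1.8))
})

test_that("transient stepping is stable, conservative and converges to steady", {
  # lumped perfused body with uniform source: exponential approach with
  # time constant rho C / beta
  rho <- 1000; C <- 4000; k <- 0.5; Tb <- 37; q <- 2e5
  perf <- 600  # mL/min/kg
  beta <- 1000 * 3639 * perfusion_to_volumetric_rate(perf, rho)
  mesh <- generate_mesh(rectangle_geometry(1, 1.2, 0, 0.2), 0.05)
  mats <- list(tissue = material_properties("body", thermal_conductivity = k,
                                            density = rho, specific_heat = C,
                                            perfusion_rate = perf))
  sys <- assemble_bioheat_operator(mesh, mats, qext = rep(q, nrow(mesh$tri)),
                                   boundary_temperature = NULL)
  tau <- rho * C / beta
  dt <- tau / 200
  tr <- run_transient_bioheat(sys, duration = tau, dt = dt,
                              initial_temperature = Tb)
  sensor <- sensor_trace(tr, data.frame(r = 1.1, z = 0.1, name = "s"))
  exact <- Tb + (q / beta) * (1 - exp(-sensor$time / tau))
  expect_lt(max(abs(sensor$temperature - exact)) / (q / beta), 0.01)

  # zero source from equilibrium: nothing moves
  sys0 <- assemble_bioheat_operator(mesh, mats, boundary_temperature = NULL)
  st <- advance_transient_bioheat(rep(Tb, nrow(mesh$nodes)), sys0, 1)
  expect_equal(st, rep(Tb, nrow(mesh$nodes)), tolerance = 1e-12)

  # energy consistency on an insulated, non-perfused domain:
  # each implicit step adds exactly dt * integral(q) to the heat content
  mats_np <- list(tissue = material_properties("inert", thermal_conductivity = k,
                                               density = rho, specific_heat = C))
  sysn <- assemble_bioheat_operator(mesh, mats_np, qext = rep(q, nrow(mesh$tri)),
                                    boundary_temperature = NULL)
  T0 <- rep(20, nrow(mesh$nodes))
  T1 <- advance_transient_bioheat(T0, sysn, 0.25)
  ones <- rep(1, nrow(mesh$nodes))
  dH <- sum(sysn$Mc %*% (T1 - T0))
  expect_equal(dH, 0.25 * sum(sysn$F), tolerance = 1e-10)

  # long-time transient approaches the stationary solution
  mesh2 <- generate_mesh(rectangle_geometry(1e-3, 30e-3, 0, 30e-3), 3e-3)
  mats2 <- list(tissue = material_registry()$breast)
  sys2 <- assemble_bioheat_operator(mesh2, mats2,
                                    qext = rep(5e4, nrow(mesh2$tri)),
                                    boundary_temperature = 37)
  steady <- solve_steady_bioheat(sys2)
  tr2 <- run_transient_bioheat(sys2, duration = 20000, dt = 100,
                               initial_temperature = 37)
  expect_lt(max(abs(tr2$values[, ncol(tr2$values)] - steady$values[, 1])), 0.1)
  expect_error(advance_transient_bioheat(rep(NaN, nrow(mesh2$nodes)), sys2, 1),
               class = "mwablate_numerical_error")
})

test_that("the maximum principle holds for the heated scenario", {
  res <- preset_result(1)
  expect_gte(min(res$field$values), 37 - 1e-6)
})

test_that("sensor traces interpolate exactly and extract maxima by definition", {
  mesh <- generate_mesh(rectangle_geometry(1, 2, 0, 1), 0.25)
  vals <- matrix(seq_len(nrow(mesh$nodes)) + 0.5, ncol = 1)
  f <- mwablate:::new_temperature_field(cbind(vals, vals * 2), c(0, 1), mesh)
  node <- 7
  tr <- sensor_trace(f, data.frame(r = mesh$nodes[node, 1], z = mesh$nodes[node, 2],
                                   name = "n7"))
  expect_equal(tr$temperature, c(vals[node], 2 * vals[node]))
  # co-located sensors give identical traces
  tr2 <- sensor_trace(f, data.frame(r = rep(1.3, 2), z = rep(0.4, 2),
                                    name = c("a", "b")))
  expect_equal(tr2$temperature[tr2$sensor == "a"],
               tr2$temperature[tr2$sensor == "b"])
  # the reported maximum is the maximum of the trace
  res <- preset_result(1)
  slot_trace <- res$traces[res$traces$sensor == "slot", ]
  expect_equal(res$max_temperatures$max_temperature[
    res$max_temperatures$sensor == "slot"], max(slot_trace$temperature))
})

test_that("isotherm area integrates a synthetic hot disk correctly", {
  # all cold: zero area
  mesh <- generate_mesh(rectangle_geometry(0, 2e-2, 0, 4e-2), 1e-3)
  cold <- mwablate:::new_temperature_field(matrix(37, nrow(mesh$nodes)), NULL, mesh)
  expect_equal(ablation_area(cold), 0)
  # hot half-disk of radius 0.5 cm on the axis: mirrored area -> pi R^2
  R <- 0.5e-2; zc <- 2e-2
  for (h in c(1e-3, 0.5e-3, 0.25e-3)) {
    m <- generate_mesh(rectangle_geometry(0, 2e-2, 0, 4e-2), h)
    Tn <- ifelse(m$nodes[, 1]^2 + (m$nodes[, 2] - zc)^2 < R^2, 100, 37)
    f <- mwablate:::new_temperature_field(matrix(Tn, ncol = 1), NULL, m)
    a <- ablation_area(f, 60)
    expect_equal(a, pi * 0.5^2, tolerance = 3 * h / R)
  }
  # sharper check at the finest level
  m <- generate_mesh(rectangle_geometry(0, 2e-2, 0, 4e-2), 0.25e-3)
  Tn <- ifelse(m$nodes[, 1]^2 + (m$nodes[, 2] - zc)^2 < R^2, 100, 37)
  f <- mwablate:::new_temperature_field(matrix(Tn, ncol = 1), NULL, m)
  expect_equal(ablation_area(f, 60), pi * 0.5^2, tolerance = 0.05)
})

test_that("ablation area grows with power at fixed duration", {
  areas <- vapply(c(10, 20, 30, 50), function(p) {
    cfg <- scenario_config(p, 30, 40e-3)
    run_scenario(cfg, check = FALSE, keep_fields = FALSE)$ablation_area_cm2
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("peak sensor temperature is mesh-stable near the slot", {
  # the sensor sits 0.19 mm from a field-singular slot edge; successive
  # refinements move the slot maximum by only a few percent of the rise
  g1 <- glance(run_scenario(scenario_presets(1, mesh_min_size = 0.3e-3)[[1]],
                            check = FALSE, keep_fields = FALSE))
  g2 <- glance(preset_result(1))
  expect_lt(abs(g2$max_slot_C - g1$max_slot_C), 3)
})
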