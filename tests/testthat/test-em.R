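test_that("coax impedance formula reproduces the 50-ohm UT-085 line", {
  expect_equal(coax_characteristic_impedance(0.255e-3, 0.84e-3, 2.03), 50.1,
               tolerance = 0.2 / 50.1)
  expect_equal(coax_characteristic_impedance(1e-3, 1e-3, 1), 0)
  # logarithm property: squaring b/a doubles the impedance
  z1 <- coax_characteristic_impedance(1e-3, 3e-3, 1)
  z2 <- coax_characteristic_impedance(1e-3, 9e-3, 1)
  expect_equal(z2, 2 * z1)
  expect_error(coax_characteristic_impedance(2e-3, 1e-3, 1),
               class = "mwablate_invalid_parameter")
})

test_that("SWR closed form is exact and rejects total reflection", {
  expect_equal(swr_from_reflection(0), 1)
  expect_equal(swr_from_reflection(1 / 3), 2)
  expect_equal(swr_from_reflection(0.0371), 1.077, tolerance = 1e-3)
  g <- runif(20)
  expect_true(all(swr_from_reflection(g * 0.99) >= 1))
  expect_error(swr_from_reflection(1), class = "mwablate_invalid_parameter")
  expect_error(swr_from_reflection(-0.1), class = "mwablate_invalid_parameter")
})

test_that("element matrices match brute-force quadrature on one triangle", {
  mesh <- one_triangle_mesh()
  bas <- mwablate:::tri_basis(mesh)
  p <- mesh$nodes
  # EM operator on the scaled variable: (grad_i . grad_j) Int 1/r  (3-pt rule)
  vals <- mwablate:::elem_vals(bas, 1, "grad_invr")
  rq <- bas$rq[1, ]
  dense_invr <- brute_tri_integral(p[1, ], p[2, ], p[3, ],
                                   function(r, z, l) 1 / r)
  # the documented 3-point rule is within quadrature error of a dense integral
  expect_equal(bas$area[1] / 3 * sum(1 / rq), dense_invr, tolerance = 1e-3)
  for (i in 1:3) for (j in 1:3) {
    grad <- bas$b[1, i] * bas$b[1, j] + bas$c[1, i] * bas$c[1, j]
    expect_equal(vals[[(i - 1) * 3 + j]],
                 grad * bas$area[1] / 3 * sum(1 / rq), tolerance = 1e-13)
  }
  # mass with r-weight against dense integration of phi_i phi_j r
  mv <- mwablate:::elem_vals(bas, 1, "mass")
  for (i in 1:3) for (j in 1:3) {
    dense <- brute_tri_integral(p[1, ], p[2, ], p[3, ],
                                function(r, z, l) l[, i] * l[, j] * r)
    # the documented rule is degree-2; phi_i phi_j r is cubic, so allow its
    # small quadrature error against the dense reference
    expect_equal(mv[[(i - 1) * 3 + j]], dense, tolerance = 1e-2)
  }
})

test_that("lossless media give a complex-symmetric (non-Hermitian) system", {
  mesh <- generate_mesh(rectangle_geometry(0.5e-3, 2e-3, 0, 5e-3), 0.5e-3)
  mat <- list(tissue = material_properties("lossless", relative_permittivity = 2))
  sys <- assemble_em_system(mesh, mat, 2.45e9)
  expect_lt(Matrix::norm(sys$A$re - Matrix::t(sys$A$re), "M") /
              Matrix::norm(sys$A$re, "M"), 1e-12)
  expect_lt(Matrix::norm(sys$A$im - Matrix::t(sys$A$im), "M"), 1e-12)
  expect_error(assemble_em_system(mesh, list(), 2.45e9),
               class = "mwablate_config_error")
})

test_that("a matched uniform coax line reflects almost nothing", {
  reg <- material_registry()
  a <- 0.255e-3; b <- 0.84e-3; L <- 20e-3
  mesh <- generate_mesh(rectangle_geometry(a, b, 0, L, region = "coax_dielectric"),
                        0.1e-3)
  n1 <- mesh$nodes[mesh$edges$n1, ]; n2 <- mesh$nodes[mesh$edges$n2, ]
  top <- n1[, 2] < 1e-12 & n2[, 2] < 1e-12
  bot <- abs(n1[, 2] - L) < 1e-12 & abs(n2[, 2] - L) < 1e-12
  mesh$edges$tag <- ifelse(top, "port", ifelse(bot, "outer_boundary", "pec"))
  sys <- assemble_em_system(mesh, list(coax_dielectric = reg$coax_dielectric), 2.45e9)
  em <- solve_em(sys, 10)
  expect_lt(abs(em$s11), 0.05)
  # the TEM field is H ~ 1/r with the analytic amplitude
  C <- sqrt(10 / (pi * (physical_constants()$eta0 / sqrt(2.03)) * log(b / a)))
  mid <- which(abs(mesh$nodes[, 2] - 10e-3) < 1e-9)
  expect_equal(Mod(em$h_phi[mid]), C / mesh$nodes[mid, 1], tolerance = 1e-3)
})

test_that("EM solution scales linearly with input power", {
  mats <- default_materials()
  mesh <- default_mesh()
  sys <- assemble_em_system(mesh, mats, 2.45e9)
  em1 <- solve_em(sys, 10)
  em2 <- solve_em(sys, 20)
  expect_equal(em2$qext, 2 * em1$qext, tolerance = 1e-12)
  expect_equal(abs(em2$E_r), sqrt(2) * abs(em1$E_r), tolerance = 1e-12)
  expect_equal(abs(em2$s11), abs(em1$s11), tolerance = 1e-12)
})

test_that("zero-conductivity tissue deposits nothing; the boundary takes it all", {
  mats <- default_materials()
  mats$tissue <- material_properties("lossless_tissue", relative_permittivity = 5.14,
                                     electric_conductivity = 0,
                                     thermal_conductivity = 0.42, density = 1020,
                                     specific_heat = 3000)
  mesh <- default_mesh()
  em <- solve_em(assemble_em_system(mesh, mats, 2.45e9), 10)
  expect_equal(max(em$qext), 0)
  expect_equal(em$power_balance$deposited, 0)
  expect_equal(em$power_balance$radiated, em$power_balance$expected,
               tolerance = 0.02 * 10 / em$power_balance$expected)
})

test_that("qext is non-negative, zero without loss, and phase-invariant", {
  res <- preset_result(1)
  em <- res$em
  expect_true(all(em$qext >= 0))
  # global phase rotation leaves qext unchanged
  rot <- em
  rot$E_r <- em$E_r * exp(1i * 0.7); rot$E_z <- em$E_z * exp(1i * 0.7)
  expect_equal(compute_qext(rot, default_materials()), em$qext, tolerance = 1e-12)
  # sigma = 0 map: no deposition despite nonzero fields
  mats0 <- default_materials()
  mats0$tissue <- material_properties("s0", relative_permittivity = 5.14)
  expect_equal(max(compute_qext(em, mats0)), 0)
  # uniform-field arithmetic: |E| = 100 V/m in breast gives 700 W/m^3
  u <- em; u$E_r <- rep(100 + 0i, length(em$E_r)); u$E_z <- rep(0i, length(em$E_z))
  q <- compute_qext(u, default_materials())
  expect_equal(unique(round(q[u$mesh$region == "tissue"], 9)), 700)
})

test_that("manufactured EM solutions converge at second order", {
  case <- manufactured_solution_pair("em")
  expect_lt(verify_manufactured(case), 1e-8)
  conv <- manufactured_convergence(case, c(16, 32, 64))
  expect_true(all(conv$order[-1] >= 1.8))
})

test_that("slot mirror symmetry holds in the geometry and the solved S11 is stable", {
  geom <- build_scenario_geometry(domain_spec(insertion_depth = 40e-3))
  # the two slots are mirror images about the midpoint plane
  D <- 40e-3; rs <- 0.95e-3
  dz <- seq(0.05e-3, 0.4e-3, by = 0.05e-3)
  expect_identical(geom$classify(rep(rs, length(dz)), D + dz),
                   geom$classify(rep(rs, length(dz)), D - dz))
  # repeated assembly/solve is bit-stable
  res1 <- preset_result(1)
  mesh <- res1$field$mesh
  em2 <- solve_em(assemble_em_system(mesh, default_materials(), 2.45e9), 10)
  expect_identical(abs(em2$s11), abs(res1$s11))
})
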