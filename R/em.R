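# Axisymmetric frequency-domain EM solver, azimuthal magnetic field
# formulation in the scaled variable v = r * H_phi (time convention
# exp(+j omega t)). Weak form:
#
#   a(v, w) = Int (1/eps_c) (grad v . grad w) (1/r) dr dz
#             - k0^2 Int v w (1/r) dr dz,
#
# with eps_c = eps_r - j sigma/(omega eps0) per region. The scaling matters:
# the coaxial TEM mode is H_phi ~ 1/r, i.e. v = const, which P1 elements
# represent exactly; the unscaled field cannot propagate on a nodal mesh.
# Metal surfaces are natural boundaries (tangential E = 0, i.e. PEC). The
# coaxial port carries a unit-amplitude incident TEM mode through a
# first-order matched condition; the outer boundary carries a first-order
# absorbing condition matched to the local medium. v vanishes on the
# symmetry axis (essential condition; H_phi is finite there).

#' Characteristic impedance of a coaxial line
#'
#' `Z0 = eta0 / (2 pi sqrt(eps_r)) * ln(b/a)`; a consistency check that the
#' modelled cable (UT-085 radii with its PTFE dielectric) is the expected
#' 50-Ohm line, and the normalization behind the port's TEM mode.
#'
#' @param inner_radius,outer_radius Conductor radii, m (`outer > inner > 0`).
#' @param relative_permittivity Dielectric relative permittivity (>= 1).
#' @return Impedance, Ohm.
#' @examples
#' coax_characteristic_impedance(0.255e-3, 0.84e-3, 2.03)
#' @export
coax_characteristic_impedance <- function(inner_radius, outer_radius,
                                          relative_permittivity) {
  if (any(inner_radius <= 0) || any(outer_radius < inner_radius)) {
    abort_param("radii must satisfy outer_radius >= inner_radius > 0")
  }
  if (any(relative_permittivity < 1)) abort_param("relative_permittivity must be >= 1")
  physical_constants()$eta0 / (2 * pi * sqrt(relative_permittivity)) *
    log(outer_radius / inner_radius)
}

#' Standing wave ratio from a reflection magnitude
#'
#' `SWR = (1 + |Gamma|) / (1 - |Gamma|)`.
#'
#' @param reflection_magnitude `|Gamma| = |S11|`, in `[0, 1)`.
#' @return SWR (>= 1).
#' @examples
#' swr_from_reflection(1 / 3)
#' @export
swr_from_reflection <- function(reflection_magnitude) {
  if (any(reflection_magnitude < 0) || any(reflection_magnitude >= 1)) {
    abort_param("|Gamma| must lie in [0, 1) (total reflection is not a matched state)")
  }
  (1 + reflection_magnitude) / (1 - reflection_magnitude)
}

#' Assemble the axisymmetric frequency-domain EM system
#'
#' Builds the complex sparse system for the azimuthal magnetic field with the
#' complex effective permittivity of each region, an inhomogeneous coaxial TEM
#' port condition (tag `port`), first-order absorbing conditions on
#' `absorbing_tags` (impedance-matched to the adjacent element's medium), the
#' essential `H_phi = 0` condition on the axis, and natural (PEC) conditions
#' on all remaining boundary edges.
#'
#' @param mesh An `mwa_mesh`.
#' @param materials Named list of [material_properties()] keyed by the mesh's
#'   region tags.
#' @param frequency Operating frequency, Hz.
#' @param absorbing_tags Edge tags carrying the absorbing condition.
#' @param dirichlet Optional list `list(tags =, fun = function(r, z))` imposing
#'   essential values on the nodes of the tagged edges (used by the
#'   manufactured-solution harness; overrides port/absorbing on those edges).
#' @param source Optional volume source `s(r, z)` (complex ok) added to the
#'   right-hand side (manufactured solutions).
#' @return An `mwa_em_system` list; pass to [solve_em()].
#' @export
assemble_em_system <- function(mesh, materials, frequency,
                               absorbing_tags = "outer_boundary",
                               dirichlet = NULL, source = NULL) {
  stopifnot(inherits(mesh, "mwa_mesh"))
  if (frequency <= 0) abort_param("frequency must be positive")
  tags <- unique(mesh$region)
  missing <- setdiff(tags, names(materials))
  if (length(missing)) {
    rlang::abort(paste0("no material assigned to region tag(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mwablate_config_error")
  }
  cst <- physical_constants()
  omega <- 2 * pi * frequency
  k0 <- omega / cst$speed_of_light

  eps_by_tag <- vapply(tags, function(tg)
    complex_effective_permittivity(materials[[tg]], frequency), complex(1))
  names(eps_by_tag) <- tags
  eps_tri <- eps_by_tag[mesh$region]

  bas <- tri_basis(mesh)
  A_curl <- assemble_sparse(mesh, elem_vals(bas, 1 / eps_tri, "grad_invr"))
  A_mass <- assemble_sparse(mesh, elem_vals(bas, rep(-k0^2 + 0i, nrow(mesh$tri)), "mass_invr"))
  A <- list(re = A_curl$re + A_mass$re, im = A_curl$im + A_mass$im)

  n <- nrow(mesh$nodes)
  rhs0 <- rep(0 + 0i, n)

  dir_tags <- if (!is.null(dirichlet)) dirichlet$tags else character(0)

  # port: first-order matched condition with unit incident TEM amplitude
  port_edges <- mesh$edges[mesh$edges$tag == "port" & !(mesh$edges$tag %in% dir_tags), ]
  port <- NULL
  if (nrow(port_edges) > 0) {
    port_reg <- unique(mesh$region[port_edges$tri])
    eps_p <- eps_by_tag[port_reg[1]]
    if (abs(Im(eps_p)) > 1e-9) {
      rlang::abort("port medium must be lossless", class = "mwablate_config_error")
    }
    eps_p <- unname(Re(eps_p))
    gam <- 1i * k0 / sqrt(eps_p)
    Mp <- edge_mass(mesh, port_edges, rep(gam + 0i, nrow(port_edges)), weight = "invr")
    A$re <- A$re + Mp$re; A$im <- A$im + Mp$im
    rhs0 <- rhs0 + 2 * gam *
      edge_load(mesh, port_edges, function(r, z) rep(1 + 0i, length(r)),
                weight = "invr")
    pn <- unique(c(port_edges$n1, port_edges$n2))
    port <- list(edges = port_edges, eps_r = eps_p,
                 a = min(mesh$nodes[pn, 1]), b = max(mesh$nodes[pn, 1]),
                 eta = cst$eta0 / sqrt(eps_p))
  }

  # absorbing outer boundary, matched to the adjacent element's medium
  abs_edges <- mesh$edges[mesh$edges$tag %in% setdiff(absorbing_tags, dir_tags), ]
  abs_eps <- NULL
  if (nrow(abs_edges) > 0) {
    abs_eps <- eps_by_tag[mesh$region[abs_edges$tri]]
    gam_e <- 1i * k0 / sqrt(abs_eps)
    Ma <- edge_mass(mesh, abs_edges, gam_e, weight = "invr")
    A$re <- A$re + Ma$re; A$im <- A$im + Ma$im
  }

  if (!is.null(source)) {
    # the test functions are phi/r, so the source load carries unit weight
    rhs0 <- rhs0 + load_vector(mesh, bas, function(r, z) source(r, z) + 0i,
                               weight = "one")
  }

  # essential conditions: axis (v = 0) plus any user Dirichlet (given as
  # H_phi values; scaled to v = r * H_phi here)
  fixed <- which(mesh$nodes[, 1] < 1e-12)
  fixed_val <- rep(0 + 0i, length(fixed))
  if (!is.null(dirichlet)) {
    de <- mesh$edges[mesh$edges$tag %in% dirichlet$tags, ]
    dn <- setdiff(unique(c(de$n1, de$n2)), fixed)
    fixed <- c(fixed, dn)
    fixed_val <- c(fixed_val,
                   mesh$nodes[dn, 1] *
                     dirichlet$fun(mesh$nodes[dn, 1], mesh$nodes[dn, 2]) + 0i)
  }

  structure(list(
    A = A, rhs0 = rhs0, mesh = mesh, bas = bas,
    frequency = frequency, omega = omega, k0 = k0,
    eps_tri = eps_tri, materials = materials,
    port = port, abs_edges = abs_edges, abs_eps = abs_eps,
    fixed = fixed, fixed_val = fixed_val
  ), class = "mwa_em_system")
}

#' Solve the assembled EM system
#'
#' Scales the incident coaxial TEM mode so that it carries exactly
#' `input_power` forward watts, solves the complex sparse system (as the
#' equivalent real block system, sparse LU), extracts the reflection
#' coefficient S11 by overlap of the scattered port field with the TEM mode,
#' and evaluates the electric field and the volumetric heat source
#' `qext = 1/2 sigma |E|^2` per triangle. The returned solution carries a
#' power-balance diagnostic: deposited + radiated power versus
#' `P_in (1 - |S11|^2)`.
#'
#' @param system An `mwa_em_system` from [assemble_em_system()].
#' @param input_power Forward (incident) power at the port, W.
#' @return An `mwa_em_solution`: nodal complex `H_phi` (A/m), per-triangle
#'   `E_r`, `E_z` (V/m), `qext` (W/m^3), `s11` (complex), `swr`,
#'   `power_balance` list, and references to mesh/frequency.
#' @export
solve_em <- function(system, input_power = 1) {
  stopifnot(inherits(system, "mwa_em_system"))
  if (!is.null(system$port) && input_power <= 0) {
    abort_param("input_power must be positive")
  }
  mesh <- system$mesh; n <- nrow(mesh$nodes)
  C <- 1
  if (!is.null(system$port)) {
    p <- system$port
    C <- sqrt(input_power / (pi * p$eta * log(p$b / p$a)))
  }
  rhs <- system$rhs0 * C

  free <- setdiff(seq_len(n), system$fixed)
  u <- rep(0 + 0i, n)
  if (length(system$fixed)) {
    u[system$fixed] <- system$fixed_val
    bf <- rhs[free] -
      (as.vector(system$A$re[free, system$fixed, drop = FALSE] %*% Re(system$fixed_val)) -
       as.vector(system$A$im[free, system$fixed, drop = FALSE] %*% Im(system$fixed_val))) -
      1i * (as.vector(system$A$re[free, system$fixed, drop = FALSE] %*% Im(system$fixed_val)) +
            as.vector(system$A$im[free, system$fixed, drop = FALSE] %*% Re(system$fixed_val)))
  } else {
    bf <- rhs[free]
  }
  Aff <- list(re = system$A$re[free, free, drop = FALSE],
              im = system$A$im[free, free, drop = FALSE])
  uf <- tryCatch(solve_complex_sparse(Aff, bf), error = function(e) {
    rlang::abort(paste0("EM system solve failed (possibly a lossless closed cavity ",
                        "at resonance; check losses/geometry): ", conditionMessage(e)),
                 class = "mwablate_solver_error")
  })
  u[free] <- uf
  v <- u   # scaled unknown v = r * H_phi

  # S11: overlap of (v - v_inc) with the TEM mode (v_inc = C) over the port
  s11 <- NA_complex_
  if (!is.null(system$port)) {
    pe <- system$port$edges
    num <- sum(edge_port_integral(mesh, pe, v, C))
    den <- C * sum(edge_ds_over_r(mesh, pe))
    s11 <- unname(num / den)
  }

  # nodal H_phi (zero on the axis by regularity)
  h_phi <- v / pmax(mesh$nodes[, 1], 1e-300)
  h_phi[mesh$nodes[, 1] < 1e-12] <- 0 + 0i

  # fields and heat source per triangle (centroid values)
  bas <- system$bas
  cst <- physical_constants()
  jweps <- 1i * system$omega * cst$vacuum_permittivity * system$eps_tri
  v1 <- v[mesh$tri[, 1]]; v2 <- v[mesh$tri[, 2]]; v3 <- v[mesh$tri[, 3]]
  vz <- v1 * bas$c[, 1] + v2 * bas$c[, 2] + v3 * bas$c[, 3]
  vr <- v1 * bas$b[, 1] + v2 * bas$b[, 2] + v3 * bas$b[, 3]
  rc <- rowMeans(bas$rv)
  Er <- -(vz / rc) / jweps
  Ez <- (vr / rc) / jweps
  sigma_tri <- vapply(mesh$region, function(tg)
    system$materials[[tg]]$electric_conductivity, numeric(1))
  qext <- 0.5 * sigma_tri * (abs(Er)^2 + abs(Ez)^2)

  # power bookkeeping (true watts: 2*pi azimuthal factor)
  p_dep <- 2 * pi * sum(qext * bas$area * rc)
  p_out <- 0
  if (!is.null(system$abs_edges) && nrow(system$abs_edges) > 0) {
    p_out <- 2 * pi * sum(edge_outflow(mesh, system$abs_edges, system$abs_eps, v,
                                       cst$eta0))
  }
  pb <- NULL
  if (!is.null(system$port)) {
    p_net <- input_power * (1 - abs(s11)^2)
    pb <- list(deposited = p_dep, radiated = p_out, expected = p_net,
               relative_error = (p_dep + p_out - p_net) / input_power)
  }

  structure(list(
    h_phi = h_phi, v = v, E_r = Er, E_z = Ez, qext = qext,
    s11 = s11, swr = if (is.na(s11)) NA_real_ else swr_from_reflection(abs(s11)),
    input_power = input_power, omega = system$omega, frequency = system$frequency,
    power_balance = pb, mesh = mesh
  ), class = "mwa_em_solution")
}

#' @export
print.mwa_em_solution <- function(x, ...) {
  cat(sprintf("<mwa_em_solution> f=%.4g GHz P_in=%.3g W |S11|=%.4g SWR=%.4g\n",
              x$frequency / 1e9, x$input_power, abs(x$s11), x$swr))
  if (!is.null(x$power_balance)) {
    cat(sprintf("  power: deposited %.4g W + radiated %.4g W vs expected %.4g W (rel err %.3g)\n",
                x$power_balance$deposited, x$power_balance$radiated,
                x$power_balance$expected, x$power_balance$relative_error))
  }
  invisible(x)
}

#' Volumetric heat source from a solved EM field
#'
#' `qext = 1/2 sigma |E|^2` per triangle; for the purely conductive losses of
#' the model's media this is the full SAR density. Returns zero where the
#' material is lossless regardless of the local field.
#'
#' @param em An `mwa_em_solution`.
#' @param materials Named list of materials keyed by region tag (defaults to
#'   recomputing with the conductivities used at solve time via the stored
#'   field; pass explicitly to evaluate alternative loss maps).
#' @return Per-triangle heat source, W/m^3.
#' @export
compute_qext <- function(em, materials = NULL) {
  stopifnot(inherits(em, "mwa_em_solution"))
  if (is.null(materials)) return(em$qext)
  sigma_tri <- vapply(em$mesh$region, function(tg)
    materials[[tg]]$electric_conductivity, numeric(1))
  0.5 * sigma_tri * (abs(em$E_r)^2 + abs(em$E_z)^2)
}

# ---- edge quadrature helpers for port/power bookkeeping -------------------

# integral over edges of (v - C)/r ds, 2-point Gauss with P1 interpolation
edge_port_integral <- function(mesh, edges, v, C) {
  n1 <- edges$n1; n2 <- edges$n2
  r1 <- mesh$nodes[n1, 1]; r2 <- mesh$nodes[n2, 1]
  z1 <- mesh$nodes[n1, 2]; z2 <- mesh$nodes[n2, 2]
  L <- sqrt((r2 - r1)^2 + (z2 - z1)^2)
  tg <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))
  acc <- 0 + 0i
  for (t in tg) {
    rt <- r1 + t * (r2 - r1)
    vt <- (1 - t) * v[n1] + t * v[n2]
    acc <- acc + 0.5 * L * (vt - C) / rt
  }
  acc
}

edge_ds_over_r <- function(mesh, edges) {
  n1 <- edges$n1; n2 <- edges$n2
  r1 <- mesh$nodes[n1, 1]; r2 <- mesh$nodes[n2, 1]
  z1 <- mesh$nodes[n1, 2]; z2 <- mesh$nodes[n2, 2]
  L <- sqrt((r2 - r1)^2 + (z2 - z1)^2)
  tg <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))
  acc <- 0
  for (t in tg) acc <- acc + 0.5 * L / (r1 + t * (r2 - r1))
  acc
}

# outgoing Poynting flux (per radian) through absorbing edges:
# 1/2 eta0 Re(1/sqrt(eps_c)) |H_phi|^2 r = ... |v|^2 / r
edge_outflow <- function(mesh, edges, eps_edge, v, eta0) {
  n1 <- edges$n1; n2 <- edges$n2
  r1 <- mesh$nodes[n1, 1]; r2 <- mesh$nodes[n2, 1]
  z1 <- mesh$nodes[n1, 2]; z2 <- mesh$nodes[n2, 2]
  L <- sqrt((r2 - r1)^2 + (z2 - z1)^2)
  coef <- 0.5 * eta0 * Re(1 / sqrt(eps_edge))
  tg <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))
  acc <- 0
  for (t in tg) {
    rt <- r1 + t * (r2 - r1)
    vt <- (1 - t) * v[n1] + t * v[n2]
    acc <- acc + 0.5 * L * coef * abs(vt)^2 / rt
  }
  acc
}
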