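# Verification fixtures: closed-form oracles, manufactured solutions for both
# PDE solvers, and synthetic "experimental" sensor traces. Everything here is
# self-validating and seeded; no measurement data is required anywhere in the
# test suite.

#' Steady perfused-slab temperature profile (closed form)
#'
#' 1D stationary Pennes problem `-k T'' = beta (T_b - T) + q` on
#' `[-L, L]` with both walls held at `T_b`:
#' `T(x) = T_b + (q/beta) (1 - cosh(x/delta)/cosh(L/delta))`,
#' `delta = sqrt(k/beta)`. Used as the analytic oracle for the steady solver.
#'
#' @param k Thermal conductivity, W/(m K) (> 0).
#' @param beta Volumetric perfusion coefficient `rho_b C_b w_b`, W/(m^3 K) (> 0).
#' @param qext Uniform source, W/m^3.
#' @param t_b Arterial/wall temperature, deg C.
#' @param half_width Slab half width `L`, m.
#' @param x Evaluation points, m.
#' @return Temperatures, deg C.
#' @export
perfused_slab_analytic <- function(k, beta, qext, t_b, half_width, x) {
  if (k <= 0) abort_param("k must be positive")
  if (beta <= 0) abort_param("beta must be positive (pure-Neumann slab has no unique solution)")
  delta <- sqrt(k / beta)
  t_b + (qext / beta) * (1 - cosh(x / delta) / cosh(half_width / delta))
}

#' Construct a manufactured solution for the EM or bioheat operator
#'
#' Prescribes a smooth trigonometric field on the rectangle
#' `[0, R] x [0, H]` and computes the exact source that makes it a solution
#' of the corresponding axisymmetric operator, so the solver can be verified
#' against a known answer under mesh refinement. The fields are regular on the
#' axis (the `1/r` terms of both operators stay finite as `r -> 0`).
#'
#' * `bioheat`: `T = T_b + A cos(pi r / 2R) cos(pi z / H)` under
#'   `-k Lap(T) + beta (T - T_b) = Q`.
#' * `em`: `u = U sin(pi r / R) sin(pi z / H)` under
#'   `-(1/eps)(u_rr + u_r/r - u/r^2 + u_zz) - k0^2 u = s`, with a lossy
#'   permittivity so the Dirichlet problem is never at a real resonance.
#'
#' @param pde `"em"` or `"bioheat"`.
#' @param R,H Rectangle extent, m.
#' @param amplitude Field amplitude (`A` or `U`); must be nonzero.
#' @param k,beta,t_b Bioheat constants.
#' @param eps_c,k0 EM constants (complex permittivity, free-space wavenumber).
#' @return An object of class `mwa_manufactured`: `pde`, `field(r, z)`,
#'   `source(r, z)`, the constants, and the domain.
#' @export
manufactured_solution_pair <- function(pde = c("bioheat", "em"),
                                       R = 1, H = 1, amplitude = 1,
                                       k = 0.5, beta = 2000, t_b = 37,
                                       eps_c = 2 - 0.5i, k0 = 2) {
  pde <- match.arg(pde)
  if (amplitude == 0) {
    abort_param("constant (zero-amplitude) fields do not exercise the operator")
  }
  if (pde == "bioheat") {
    a <- pi / (2 * R); b <- pi / H; A <- amplitude
    field <- function(r, z) t_b + A * cos(a * r) * cos(b * z)
    source <- function(r, z) {
      sinc <- ifelse(abs(r) < 1e-12, a, sin(a * r) / r)
      g <- cos(b * z)
      A * g * (k * (a^2 * cos(a * r) + a * sinc + b^2 * cos(a * r)) +
                 beta * cos(a * r))
    }
    case <- list(pde = pde, field = field, source = source, R = R, H = H,
                 k = k, beta = beta, t_b = t_b)
  } else {
    a <- pi / R; b <- pi / H; U <- amplitude
    field <- function(r, z) U * sin(a * r) * sin(b * z)
    # (a r cos(ar) - sin(ar)) / r^2, with its series value near the axis
    axial <- function(r) {
      out <- (a * r * cos(a * r) - sin(a * r)) / r^2
      small <- abs(a * r) < 1e-6
      out[small] <- -a^3 * r[small] / 3
      out
    }
    source <- function(r, z) {
      u <- U * sin(a * r) * sin(b * z)
      lap_extra <- U * sin(b * z) * axial(r)
      -(1 / eps_c) * (-a^2 * u + lap_extra - b^2 * u) - k0^2 * u
    }
    case <- list(pde = pde, field = field, source = source, R = R, H = H,
                 eps_c = eps_c, k0 = k0)
  }
  structure(case, class = "mwa_manufactured")
}

#' Verify a manufactured case by independent numeric differentiation
#'
#' Applies the PDE operator to the prescribed field with Richardson-
#' extrapolated central differences at random interior points and compares
#' against the stored analytic source. Returns the maximum residual relative
#' to the source scale; a valid case stays below ~1e-8.
#'
#' @param case An `mwa_manufactured`.
#' @param n Number of random check points.
#' @param seed RNG seed for the check points.
#' @param h Base finite-difference step.
#' @return Maximum relative residual (numeric scalar).
#' @export
verify_manufactured <- function(case, n = 100, seed = 1, h = 1e-3) {
  stopifnot(inherits(case, "mwa_manufactured"))
  rng <- local_seed(seed)
  r <- stats::runif(n, 0.05 * case$R, 0.95 * case$R)
  z <- stats::runif(n, 0.05 * case$H, 0.95 * case$H)
  d2 <- function(f, x, hh) (f(x + hh) - 2 * f(x) + f(x - hh)) / hh^2
  d1 <- function(f, x, hh) (f(x + hh) - f(x - hh)) / (2 * hh)
  rich <- function(g, x) (4 * g(x, h / 2) - g(x, h)) / 3
  fr <- function(rr) case$field(rr, z)
  fz <- function(zz) case$field(r, zz)
  u_rr <- rich(function(x, hh) d2(fr, x, hh), r)
  u_zz <- rich(function(x, hh) d2(fz, x, hh), z)
  u_r  <- rich(function(x, hh) d1(fr, x, hh), r)
  u    <- case$field(r, z)
  if (case$pde == "bioheat") {
    lhs <- -case$k * (u_rr + u_r / r + u_zz) + case$beta * (u - case$t_b)
  } else {
    lhs <- -(1 / case$eps_c) * (u_rr + u_r / r - u / r^2 + u_zz) - case$k0^2 * u
  }
  s <- case$source(r, z)
  max(abs(lhs - s)) / max(abs(s))
}

#' Mesh-refinement convergence study for a manufactured case
#'
#' Solves the case on uniformly refined rectangle meshes with exact Dirichlet
#' data and reports the L2 field error per level and the observed order
#' between consecutive levels (expected ~2 for P1 elements; the acceptance
#' bar is >= 1.8).
#'
#' @param case An `mwa_manufactured`.
#' @param n_levels Cells per side at each refinement level.
#' @return Tibble with columns `n`, `h`, `l2_error`, `order`.
#' @export
manufactured_convergence <- function(case, n_levels = c(8, 16, 32)) {
  stopifnot(inherits(case, "mwa_manufactured"))
  errs <- vapply(n_levels, function(nn) {
    geom <- rectangle_geometry(0, case$R, 0, case$H)
    mesh <- generate_mesh(geom, case$R / nn)
    bas <- tri_basis(mesh)
    if (case$pde == "bioheat") {
      # with unit blood density/heat and unit tissue density, a perfusion of
      # beta * 60e6 mL/min/kg makes the reaction coefficient exactly beta
      rate_mat <- list(tissue = material_properties(
        "mms", thermal_conductivity = case$k, density = 1, specific_heat = 1,
        perfusion_rate = case$beta * 60 * 1e6))
      sys <- assemble_bioheat_operator(
        mesh, rate_mat, blood = list(density = 1, specific_heat = 1, temperature = case$t_b),
        dirichlet_tags = c("outer_boundary", "axis"),
        dirichlet_fun = case$field, source_fun = case$source)
      sol <- solve_steady_bioheat(sys)
      uh <- sol$values[, 1]
    } else {
      freq <- case$k0 * physical_constants()$speed_of_light / (2 * pi)
      mat <- list(tissue = material_em_from_eps(case$eps_c, freq))
      sysE <- assemble_em_system(
        mesh, mat, freq, absorbing_tags = character(0),
        dirichlet = list(tags = c("outer_boundary", "axis"), fun = case$field),
        source = case$source)
      uh <- solve_em(sysE)$h_phi
    }
    l2_error_field(mesh, uh, case$field)
  }, numeric(1))
  h <- case$R / n_levels
  ord <- c(NA, log(errs[-length(errs)] / errs[-1]) / log(n_levels[-1] / n_levels[-length(n_levels)]))
  tibble::tibble(n = n_levels, h = h, l2_error = errs, order = ord)
}

# material whose complex effective permittivity at `freq` equals eps_c
material_em_from_eps <- function(eps_c, freq) {
  cst <- physical_constants()
  material_properties("mms_em",
                      relative_permittivity = Re(eps_c),
                      electric_conductivity = -Im(eps_c) * 2 * pi * freq * cst$vacuum_permittivity)
}

# L2 error of a nodal field against an exact field, r-weighted quadrature
l2_error_field <- function(mesh, uh, exact) {
  bas <- tri_basis(mesh)
  err2 <- 0; nrm2 <- 0
  for (q in 1:3) {
    rq <- bas$rq[, q]; zq <- bas$zq[, q]
    uq <- QPTS[q, 1] * uh[mesh$tri[, 1]] + QPTS[q, 2] * uh[mesh$tri[, 2]] +
      QPTS[q, 3] * uh[mesh$tri[, 3]]
    ex <- exact(rq, zq)
    err2 <- err2 + sum(bas$area / 3 * rq * abs(uq - ex)^2)
    nrm2 <- nrm2 + sum(bas$area / 3 * rq * abs(ex)^2)
  }
  sqrt(err2 / max(nrm2, .Machine$double.eps))
}

#' Synthetic experimental sensor trace
#'
#' Emulates a fibre-optic sensor recording during heating: a saturating
#' exponential rise from `baseline` toward the perfusion-limited `plateau`
#' with time constant `time_constant`, sampled at 1 s, plus i.i.d. Gaussian
#' noise. Exists to exercise the model-versus-measurement comparison
#' machinery without any real recordings; it is reproducible from its seed.
#'
#' @param baseline Initial temperature, deg C.
#' @param plateau Asymptotic temperature, deg C.
#' @param time_constant Rise time constant, s (> 0).
#' @param duration Recording length, s (>= 1).
#' @param noise_sd Noise standard deviation, deg C (>= 0).
#' @param seed RNG seed.
#' @return A tibble (class `mwa_synthetic_trace`) with columns `time`,
#'   `temperature`; generating parameters are stored as attributes.
#' @export
synthetic_sensor_trace <- function(baseline, plateau, time_constant,
                                   duration, noise_sd = 0, seed = 1) {
  if (noise_sd < 0) abort_param("noise_sd must be non-negative")
  if (time_constant <= 0) abort_param("time_constant must be positive")
  if (duration < 1) abort_param("duration must be at least 1 s")
  local_seed(seed)
  t <- seq(0, duration, by = 1)
  temp <- baseline + (plateau - baseline) * (1 - exp(-t / time_constant)) +
    stats::rnorm(length(t), 0, noise_sd)
  out <- tibble::tibble(time = t, temperature = temp)
  attr(out, "params") <- list(baseline = baseline, plateau = plateau,
                              time_constant = time_constant,
                              noise_sd = noise_sd, seed = seed)
  class(out) <- c("mwa_synthetic_trace", class(out))
  out
}

# set the RNG seed for the current call only, restoring the caller's state
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  invisible(seed)
}
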