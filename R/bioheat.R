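# Pennes bioheat solver on the axisymmetric mesh:
#   rho C dT/dt - div(k grad T) = rho_b C_b w_b (T_b - T) + Q_met + Q_ext
# The stationary form drops the capacity term; the transient solver uses
# backward Euler (unconditionally stable) with a factorization reused across
# steps. All integrals carry the cylindrical r weight.

#' Assemble the Pennes bioheat operator
#'
#' Builds stiffness (thermal conduction), perfusion reaction mass, capacity
#' mass and load (perfusion at arterial temperature + metabolic heat +
#' external EM heat source) for every meshed region. Metal interfaces and any
#' untagged boundary are natural (insulated); the edges in `dirichlet_tags`
#' are held at `boundary_temperature` (far-field condition).
#'
#' @param mesh An `mwa_mesh`.
#' @param materials Named list of [material_properties()] keyed by region tag.
#' @param qext Per-triangle external heat source, W/m^3 (`NULL` for none).
#' @param blood Blood parameters, see [blood_parameters()].
#' @param boundary_temperature Dirichlet value on `dirichlet_tags`, deg C. Use
#'   `NULL` for a pure natural-boundary (insulated) problem.
#' @param dirichlet_tags Edge tags held at `boundary_temperature`.
#' @param source_fun Optional extra volumetric source `f(r, z)` in W/m^3
#'   (manufactured-solution harness).
#' @param dirichlet_fun Optional function `f(r, z)` giving spatially varying
#'   Dirichlet values (overrides `boundary_temperature`).
#' @return An `mwa_bioheat_system`.
#' @export
assemble_bioheat_operator <- function(mesh, materials, qext = NULL,
                                      blood = blood_parameters(),
                                      boundary_temperature = 37,
                                      dirichlet_tags = "outer_boundary",
                                      source_fun = NULL,
                                      dirichlet_fun = NULL) {
  stopifnot(inherits(mesh, "mwa_mesh"))
  tags <- unique(mesh$region)
  missing <- setdiff(tags, names(materials))
  if (length(missing)) {
    rlang::abort(paste0("no thermal properties for region tag(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mwablate_config_error")
  }
  get_prop <- function(field) {
    by_tag <- vapply(tags, function(tg) materials[[tg]][[field]], numeric(1))
    unname(by_tag[mesh$region])
  }
  k_tri    <- get_prop("thermal_conductivity")
  rhoC_tri <- get_prop("density") * get_prop("specific_heat")
  beta_tri <- blood$density * blood$specific_heat *
    perfusion_to_volumetric_rate(get_prop("perfusion_rate"), get_prop("density"))
  qmet_tri <- get_prop("metabolic_heat")
  q_tri <- if (is.null(qext)) rep(0, nrow(mesh$tri)) else qext
  if (length(q_tri) != nrow(mesh$tri)) {
    rlang::abort("qext must have one value per triangle", class = "mwablate_config_error")
  }

  bas <- tri_basis(mesh)
  K <- assemble_sparse(mesh, elem_vals(bas, k_tri, "grad")) +
       assemble_sparse(mesh, elem_vals(bas, beta_tri, "mass"))
  Mc <- assemble_sparse(mesh, elem_vals(bas, rhoC_tri, "mass"))
  FF <- load_vector(mesh, bas, beta_tri * blood$temperature + qmet_tri + q_tri)
  if (!is.null(source_fun)) FF <- FF + load_vector(mesh, bas, source_fun)

  fixed <- integer(0); fixed_val <- numeric(0)
  if (!is.null(boundary_temperature) || !is.null(dirichlet_fun)) {
    de <- mesh$edges[mesh$edges$tag %in% dirichlet_tags, ]
    fixed <- unique(c(de$n1, de$n2))
    fixed_val <- if (!is.null(dirichlet_fun)) {
      dirichlet_fun(mesh$nodes[fixed, 1], mesh$nodes[fixed, 2])
    } else rep(boundary_temperature, length(fixed))
  }

  structure(list(
    K = K, Mc = Mc, F = FF, mesh = mesh, bas = bas,
    beta = beta_tri, blood = blood,
    fixed = fixed, fixed_val = fixed_val,
    cache = new.env(parent = emptyenv())
  ), class = "mwa_bioheat_system")
}

#' Solve the stationary bioheat problem
#'
#' Solves `K T = F` with the assembled Dirichlet data. Errors if the operator
#' is singular (no Dirichlet boundary and no perfusion anywhere: the pure
#' Neumann conduction problem has no unique steady state).
#'
#' @param system An `mwa_bioheat_system`.
#' @return An `mwa_temperature` with a single field.
#' @export
solve_steady_bioheat <- function(system) {
  stopifnot(inherits(system, "mwa_bioheat_system"))
  n <- nrow(system$mesh$nodes)
  if (length(system$fixed) == 0 && all(system$beta == 0)) {
    rlang::abort(paste0("stationary operator is singular: no Dirichlet boundary and ",
                        "zero perfusion; fix a boundary temperature or add perfusion"),
                 class = "mwablate_solver_error")
  }
  free <- setdiff(seq_len(n), system$fixed)
  T <- numeric(n)
  T[system$fixed] <- system$fixed_val
  rhs <- system$F[free]
  if (length(system$fixed)) {
    rhs <- rhs - as.vector(system$K[free, system$fixed, drop = FALSE] %*% system$fixed_val)
  }
  T[free] <- as.vector(Matrix::solve(system$K[free, free, drop = FALSE], rhs))
  new_temperature_field(matrix(T, ncol = 1), NULL, system$mesh)
}

new_temperature_field <- function(values, times, mesh) {
  structure(list(values = values, times = times, mesh = mesh),
            class = "mwa_temperature")
}

#' @export
print.mwa_temperature <- function(x, ...) {
  if (is.null(x$times)) {
    cat(sprintf("<mwa_temperature> steady field, %d nodes, range %.2f..%.2f degC\n",
                nrow(x$values), min(x$values), max(x$values)))
  } else {
    cat(sprintf("<mwa_temperature> %d nodes x %d times (0..%g s), final max %.2f degC\n",
                nrow(x$values), length(x$times), max(x$times),
                max(x$values[, ncol(x$values)])))
  }
  invisible(x)
}

transient_factor <- function(system, dt) {
  key <- sprintf("chol_%.12g", dt)
  if (!is.null(system$cache[[key]])) return(system$cache[[key]])
  n <- nrow(system$mesh$nodes)
  free <- setdiff(seq_len(n), system$fixed)
  A <- system$Mc / dt + system$K
  entry <- list(
    free = free,
    Afd = A[free, system$fixed, drop = FALSE],
    Mff = system$Mc[free, , drop = FALSE],
    chol = Matrix::Cholesky(Matrix::forceSymmetric(A[free, free, drop = FALSE]),
                            LDL = FALSE)
  )
  system$cache[[key]] <- entry
  entry
}

#' Advance the transient bioheat solution by one implicit step
#'
#' Backward-Euler update of the capacity-augmented system
#' `(Mc/dt + K) T_next = Mc/dt T + F`; unconditionally stable, and for a fixed
#' source the iterates converge to the stationary solution. The sparse
#' Cholesky factorization is computed once per time-step size and reused.
#'
#' @param state An `mwa_temperature` (last field is used) or numeric vector of
#'   nodal temperatures.
#' @param system An `mwa_bioheat_system`.
#' @param dt Time step, s (> 0).
#' @return Numeric vector of nodal temperatures after the step.
#' @export
advance_transient_bioheat <- function(state, system, dt) {
  stopifnot(inherits(system, "mwa_bioheat_system"))
  if (dt <= 0) abort_param("dt must be positive")
  T <- if (inherits(state, "mwa_temperature")) state$values[, ncol(state$values)] else state
  if (any(!is.finite(T))) {
    rlang::abort("non-finite temperature state: transient solve aborted",
                 class = "mwablate_numerical_error")
  }
  fac <- transient_factor(system, dt)
  rhs <- as.vector(fac$Mff %*% T) / dt + system$F[fac$free]
  if (length(system$fixed)) {
    rhs <- rhs - as.vector(fac$Afd %*% system$fixed_val)
  }
  Tn <- numeric(length(T))
  Tn[system$fixed] <- system$fixed_val
  Tn[fac$free] <- as.vector(Matrix::solve(fac$chol, rhs, system = "A"))
  Tn
}

#' Run a transient bioheat simulation
#'
#' Repeated backward-Euler steps from a uniform (or supplied) initial field.
#'
#' @param system An `mwa_bioheat_system`.
#' @param duration Total simulated time, s.
#' @param dt Time step, s.
#' @param initial_temperature Uniform initial value, deg C, or a length-N
#'   vector.
#' @return An `mwa_temperature` with `values` (N x (steps + 1)) and `times`.
#' @export
run_transient_bioheat <- function(system, duration, dt = 0.5,
                                  initial_temperature = 37) {
  stopifnot(inherits(system, "mwa_bioheat_system"))
  n <- nrow(system$mesh$nodes)
  T0 <- if (length(initial_temperature) == 1) rep(initial_temperature, n) else initial_temperature
  nt <- max(1L, as.integer(ceiling(duration / dt - 1e-9)))
  out <- matrix(NA_real_, n, nt + 1L)
  out[, 1] <- T0
  Tcur <- T0
  for (s in seq_len(nt)) {
    Tcur <- advance_transient_bioheat(Tcur, system, dt)
    out[, s + 1L] <- Tcur
  }
  new_temperature_field(out, seq(0, by = dt, length.out = nt + 1L), system$mesh)
}

#' Sample sensor temperature traces from a temperature field
#'
#' Barycentric interpolation of the nodal field(s) at the sensor locations.
#'
#' @param field An `mwa_temperature` (steady or time series).
#' @param sensors A matrix/data frame with columns `r`, `z` (m) and optionally
#'   `name`.
#' @return A tibble with columns `time` (s; 0 for a steady field), `sensor`,
#'   `temperature` (deg C).
#' @export
sensor_trace <- function(field, sensors) {
  stopifnot(inherits(field, "mwa_temperature"))
  sensors <- as.data.frame(sensors)
  if (is.null(sensors$name)) sensors$name <- paste0("sensor", seq_len(nrow(sensors)))
  loc <- point_locate(field$mesh, as.matrix(sensors[, c("r", "z")]))
  times <- if (is.null(field$times)) 0 else field$times
  out <- lapply(seq_len(nrow(sensors)), function(i) {
    v <- field$mesh$tri[loc$triangle[i], ]
    w <- c(loc$w1[i], loc$w2[i], loc$w3[i])
    tibble::tibble(
      time = times,
      sensor = sensors$name[i],
      temperature = as.vector(w[1] * field$values[v[1], ] +
                              w[2] * field$values[v[2], ] +
                              w[3] * field$values[v[3], ]))
  })
  dplyr::bind_rows(out)
}

#' Cross-sectional area above a temperature threshold
#'
#' Area of the region `{T >= threshold}` in the full mirrored 2D cross
#' section (twice the meshed half-plane area), restricted to the given region
#' tags, with the isotherm located by linear interpolation inside each
#' element. This is a plane area of the 2D temperature map (the convention of
#' lesion maps drawn on the axial cross section), not a volume.
#'
#' @param field An `mwa_temperature`; the final time (or steady) field is used.
#' @param threshold Temperature threshold, deg C (default 60, the coagulative
#'   necrosis level).
#' @param regions Region tags included in the measurement.
#' @return Area, cm^2.
#' @export
ablation_area <- function(field, threshold = 60, regions = "tissue") {
  stopifnot(inherits(field, "mwa_temperature"))
  mesh <- field$mesh
  Tn <- field$values[, ncol(field$values)]
  sel <- which(mesh$region %in% regions)
  if (!length(sel)) return(0)
  v <- mesh$tri[sel, , drop = FALSE]
  A <- triangle_areas(mesh)[sel]
  T1 <- Tn[v[, 1]]; T2 <- Tn[v[, 2]]; T3 <- Tn[v[, 3]]
  above <- (T1 >= threshold) + (T2 >= threshold) + (T3 >= threshold)
  area <- sum(A[above == 3])
  mixed <- which(above == 1 | above == 2)
  for (m in mixed) {
    vals <- c(T1[m], T2[m], T3[m])
    hot <- vals >= threshold
    if (sum(hot) == 1) {
      a <- which(hot); bc <- which(!hot)
      t1 <- (vals[a] - threshold) / (vals[a] - vals[bc[1]])
      t2 <- (vals[a] - threshold) / (vals[a] - vals[bc[2]])
      area <- area + A[m] * t1 * t2
    } else {
      c_ <- which(!hot); ab <- which(hot)
      s1 <- (threshold - vals[c_]) / (vals[ab[1]] - vals[c_])
      s2 <- (threshold - vals[c_]) / (vals[ab[2]] - vals[c_])
      area <- area + A[m] * (1 - s1 * s2)
    }
  }
  2 * area * 1e4   # mirrored cross-section, m^2 -> cm^2
}
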