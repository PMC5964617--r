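# Scenario orchestration: geometry -> mesh -> EM solve -> SAR -> transient
# bioheat -> sensor traces and lesion metrics, for the four published
# power/time/insertion protocols and for user configurations.

#' Build a scenario configuration
#'
#' @param input_power Forward microwave power at the port, W (0 < P <= 200).
#' @param heating_duration Heating time, s (> 0).
#' @param insertion_depth Slot-midpoint depth below the tissue surface, m.
#' @param mode `"in_vivo"` (perfused breast tissue at 37 deg C) or
#'   `"phantom"` (tissue-mimicking phantom: no perfusion, no metabolism,
#'   room-temperature start at 25 deg C).
#' @param frequency Operating frequency, Hz.
#' @param antenna [antenna_geometry()] of the applicator.
#' @param tissue_radius,tissue_height Modelled tissue block, m.
#' @param material_overrides Named list of material property overrides (see
#'   [resolve_materials()]).
#' @param mesh_min_size,mesh_max_size,mesh_growth Mesh sizing: minimum element
#'   size at the slots, far-field cap, geometric growth factor.
#' @param dt Transient time step, s.
#' @param sensors Optional data frame of sensor locations (`r`, `z`, `name`);
#'   default: one sensor at the slot midpoint on the catheter surface and one
#'   1.0 cm proximal along the antenna axis direction.
#' @param initial_temperature Initial/boundary temperature, deg C; default 37
#'   (in vivo) or 25 (phantom).
#' @param seed Seed recorded for fixture generation (the model itself is
#'   deterministic).
#' @return An object of class `mwa_scenario_config`.
#' @export
scenario_config <- function(input_power, heating_duration, insertion_depth,
                            mode = c("in_vivo", "phantom"),
                            frequency = 2.45e9,
                            antenna = antenna_geometry(),
                            tissue_radius = 30e-3, tissue_height = 80e-3,
                            material_overrides = NULL,
                            mesh_min_size = 0.15e-3, mesh_max_size = 3e-3,
                            mesh_growth = 1.3,
                            dt = 0.5, sensors = NULL,
                            initial_temperature = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(input_power) || input_power <= 0 || input_power > 200) {
    abort_param("input_power must lie in (0, 200] W")
  }
  if (!is.finite(heating_duration) || heating_duration <= 0) {
    abort_param("heating_duration must be positive")
  }
  if (is.null(initial_temperature)) {
    initial_temperature <- if (mode == "phantom") 25 else 37
  }
  if (is.null(sensors)) {
    sensors <- data.frame(
      r = c(antenna$catheter_radius, antenna$catheter_radius),
      z = c(insertion_depth, insertion_depth - 1.0e-2),
      name = c("slot", "1cm"))
  }
  structure(list(
    input_power = input_power, heating_duration = heating_duration,
    insertion_depth = insertion_depth, mode = mode, frequency = frequency,
    antenna = antenna, tissue_radius = tissue_radius,
    tissue_height = tissue_height, material_overrides = material_overrides,
    mesh_min_size = mesh_min_size, mesh_max_size = mesh_max_size,
    mesh_growth = mesh_growth, dt = dt, sensors = sensors,
    initial_temperature = initial_temperature, seed = seed
  ), class = "mwa_scenario_config")
}

#' The four published ablation protocols
#'
#' Power/time/insertion presets: (10 W, 120 s, 4 cm), (20 W, 40 s, 5 cm),
#' (30 W, 30 s, 4.5 cm) and (50 W, 15 s, 6 cm).
#'
#' @param which Preset numbers, subset of 1:4.
#' @param mode,... Passed to [scenario_config()].
#' @return A list of `mwa_scenario_config`.
#' @export
scenario_presets <- function(which = 1:4, mode = "in_vivo", ...) {
  tab <- data.frame(power = c(10, 20, 30, 50),
                    time = c(120, 40, 30, 15),
                    insertion = c(4, 5, 4.5, 6) * 1e-2)
  if (!all(which %in% 1:4)) abort_param("presets are numbered 1 to 4")
  lapply(which, function(i) {
    scenario_config(tab$power[i], tab$time[i], tab$insertion[i], mode = mode, ...)
  })
}

scenario_materials <- function(config) {
  mats <- resolve_materials(config$material_overrides)
  tissue_name <- if (config$mode == "phantom") "phantom" else "breast"
  map <- c(tissue = tissue_name, coax_dielectric = "coax_dielectric",
           slot = "coax_dielectric", catheter = "catheter")
  out <- lapply(map, function(nm) mats[[nm]])
  names(out) <- names(map)
  out
}

#' Run one ablation scenario end to end
#'
#' Builds the antenna-in-tissue geometry, meshes it, solves the 2.45 GHz EM
#' problem with the configured forward power, converts the field to the
#' volumetric SAR source, runs the transient Pennes solve for the heating
#' duration, and extracts sensor traces, maxima, S11/SWR and the 60 deg C
#' lesion area. Deterministic given the configuration.
#'
#' @param config An [scenario_config()].
#' @param check If `TRUE` (default), abort when the EM power balance error
#'   exceeds 2% or the 60 deg C isotherm touches the outer boundary.
#' @param keep_fields Keep the final temperature field, the EM solution and
#'   the mesh in the result (default `TRUE`; set `FALSE` to slim the object).
#' @return An object of class `mwa_scenario_result`.
#' @export
run_scenario <- function(config, check = TRUE, keep_fields = TRUE) {
  stopifnot(inherits(config, "mwa_scenario_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("[%s] %s", what, conditionMessage(e)),
                   class = "mwablate_stage_error", parent = e)
    })
  }
  mats <- scenario_materials(config)
  domain <- stage("geometry", domain_spec(
    tissue_radius = config$tissue_radius, tissue_height = config$tissue_height,
    insertion_depth = config$insertion_depth, antenna = config$antenna))
  geom <- stage("geometry", build_scenario_geometry(domain))
  mesh <- stage("mesh", generate_mesh(geom, config$mesh_min_size,
                                      config$mesh_max_size, config$mesh_growth))
  emsys <- stage("em_assemble", assemble_em_system(mesh, mats, config$frequency))
  em <- stage("em_solve", solve_em(emsys, config$input_power))
  if (check && abs(em$power_balance$relative_error) > 0.02) {
    rlang::abort(sprintf(
      "[em_solve] power balance violated: relative error %.3g exceeds 2%%",
      em$power_balance$relative_error), class = "mwablate_stage_error")
  }
  bsys <- stage("bioheat_assemble", assemble_bioheat_operator(
    mesh, mats, qext = em$qext,
    boundary_temperature = config$initial_temperature))
  field <- stage("bioheat_solve", run_transient_bioheat(
    bsys, config$heating_duration, dt = config$dt,
    initial_temperature = config$initial_temperature))
  traces <- stage("metrics", sensor_trace(field, config$sensors))
  area <- stage("metrics", ablation_area(field, 60))
  if (check) {
    bn <- unique(unlist(mesh$edges[mesh$edges$tag == "outer_boundary", c("n1", "n2")]))
    if (max(field$values[bn, ncol(field$values)]) >= 60) {
      rlang::abort("[metrics] 60 degC isotherm reached the outer boundary; enlarge the tissue block",
                   class = "mwablate_stage_error")
    }
  }
  maxima <- traces |>
    dplyr::group_by(.data$sensor) |>
    dplyr::summarise(
      max_temperature = max(.data$temperature),
      time_of_max = .data$time[which.max(.data$temperature)],
      crossing_60s = if (any(.data$temperature >= 60)) {
        min(.data$time[.data$temperature >= 60])
      } else NA_real_,
      .groups = "drop")
  res <- structure(list(
    config = config,
    traces = traces,
    max_temperatures = maxima,
    s11 = em$s11, swr = em$swr,
    ablation_area_cm2 = area,
    power_balance = em$power_balance,
    mesh_stats = list(nodes = nrow(mesh$nodes), triangles = nrow(mesh$tri),
                      min_element_size = config$mesh_min_size),
    provenance = list(config_hash = config_hash(config),
                      solver = "P1 FEM, backward Euler",
                      dt = config$dt,
                      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    field = if (keep_fields) new_temperature_field(
      field$values[, ncol(field$values), drop = FALSE], NULL, mesh) else NULL,
    em = if (keep_fields) em else NULL
  ), class = "mwa_scenario_result")
  res
}

#' Canonical configuration hash
#'
#' Hashes a canonical serialization of the configuration (sorted fields,
#' numeric values formatted at full precision) so provenance is stable across
#' platforms.
#' @param config An `mwa_scenario_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$sensors <- as.list(as.data.frame(x$sensors))
  x$antenna <- unclass(x$antenna)
  canon <- jsonlite::toJSON(x[order(names(x))], digits = NA, auto_unbox = TRUE,
                            null = "null", force = TRUE)
  rlang::hash(as.character(canon))
}

#' @export
print.mwa_scenario_result <- function(x, ...) {
  cat(sprintf("<mwa_scenario_result> %g W for %g s at %.1f cm (%s)\n",
              x$config$input_power, x$config$heating_duration,
              x$config$insertion_depth * 100, x$config$mode))
  cat(sprintf("  SWR %.3f | 60C area %.3f cm^2 | power balance err %.2g\n",
              x$swr, x$ablation_area_cm2, x$power_balance$relative_error))
  print(x$max_temperatures)
  invisible(x)
}

#' Absolute model-versus-reference temperature difference
#'
#' The Delta-T bookkeeping of a model/experiment comparison table:
#' `|model - reference|`, vectorised.
#'
#' @param model_max,reference_max Maximum temperatures, deg C (finite).
#' @return Absolute differences, deg C.
#' @examples
#' compare_model_experiment(92.11, 89.37)
#' @export
compare_model_experiment <- function(model_max, reference_max) {
  if (any(!is.finite(model_max)) || any(!is.finite(reference_max))) {
    abort_param("temperatures must be finite")
  }
  abs(model_max - reference_max)
}

#' Pairwise Delta-T comparison table
#'
#' Builds the three pairwise comparison columns (model vs phantom, model vs
#' in vivo, phantom vs in vivo) from per-scenario maxima.
#'
#' @param model,phantom,in_vivo Numeric vectors of maximum temperatures.
#' @param label Optional scenario labels.
#' @return Tibble with the three `|Delta T|` columns.
#' @export
delta_t_table <- function(model, phantom, in_vivo, label = NULL) {
  tibble::tibble(
    scenario = label %||% seq_along(model),
    model = model, phantom = phantom, in_vivo = in_vivo,
    dT_model_phantom = compare_model_experiment(model, phantom),
    dT_model_in_vivo = compare_model_experiment(model, in_vivo),
    dT_phantom_in_vivo = compare_model_experiment(phantom, in_vivo))
}

#' Run a suite of scenarios
#'
#' Executes each configuration, collecting one result row per scenario;
#' failures are recorded per row (column `error`) and the suite continues.
#'
#' @param configs List of [scenario_config()] objects.
#' @param check,keep_fields Passed to [run_scenario()].
#' @return A list with `results` (list of `mwa_scenario_result` or `NULL`)
#'   and `table` (tibble, one row per scenario).
#' @export
run_suite <- function(configs, check = TRUE, keep_fields = FALSE) {
  if (!length(configs)) {
    abort_param("run_suite needs at least one scenario configuration")
  }
  rows <- list(); results <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    res <- tryCatch(run_scenario(cfg, check = check, keep_fields = keep_fields),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- tibble::tibble(
        scenario = i, power_W = cfg$input_power, duration_s = cfg$heating_duration,
        insertion_cm = cfg$insertion_depth * 100, mode = cfg$mode,
        swr = NA_real_, max_slot_C = NA_real_, max_1cm_C = NA_real_,
        crossing_60s_slot = NA_real_, area60_cm2 = NA_real_,
        error = conditionMessage(res))
    } else {
      results[[i]] <- res
      g <- glance(res)
      rows[[i]] <- dplyr::bind_cols(tibble::tibble(scenario = i), g,
                                    tibble::tibble(error = NA_character_))
    }
  }
  list(results = results, table = dplyr::bind_rows(rows))
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a scenario result
#'
#' @param x An `mwa_scenario_result`.
#' @param ... Unused.
#' @return A one-row tibble: protocol, SWR, sensor maxima, 60 deg C crossing
#'   time at the slot sensor, lesion area.
#' @method glance mwa_scenario_result
#' @export
glance.mwa_scenario_result <- function(x, ...) {
  mx <- x$max_temperatures
  slot <- mx[mx$sensor == "slot", ]; cm <- mx[mx$sensor == "1cm", ]
  tibble::tibble(
    power_W = x$config$input_power,
    duration_s = x$config$heating_duration,
    insertion_cm = x$config$insertion_depth * 100,
    mode = x$config$mode,
    swr = x$swr,
    max_slot_C = if (nrow(slot)) slot$max_temperature else NA_real_,
    max_1cm_C = if (nrow(cm)) cm$max_temperature else NA_real_,
    crossing_60s_slot = if (nrow(slot)) slot$crossing_60s else NA_real_,
    area60_cm2 = x$ablation_area_cm2)
}

#' Per-sensor summary of a scenario result
#'
#' @param x An `mwa_scenario_result`.
#' @param ... Unused.
#' @return Tibble with one row per sensor: maximum temperature, time of the
#'   maximum, and first 60 deg C crossing time.
#' @method tidy mwa_scenario_result
#' @export
tidy.mwa_scenario_result <- function(x, ...) {
  x$max_temperatures
}

#' Serialize a scenario result to plain-text files
#'
#' Writes `result.json` (configuration, metrics, provenance) and `traces.csv`
#' (long sensor trace table) into `dir`. [read_scenario_result()] restores the
#' same summary structure losslessly.
#'
#' @param x An `mwa_scenario_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_result <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    config = jsonlite::fromJSON(as.character(jsonlite::toJSON(
      local({
        cfg <- unclass(x$config)
        cfg$antenna <- unclass(cfg$antenna)
        cfg$sensors <- as.list(as.data.frame(cfg$sensors))
        cfg
      }), digits = NA, auto_unbox = TRUE, null = "null", force = TRUE))),
    metrics = list(
      s11_re = Re(x$s11), s11_im = Im(x$s11), swr = x$swr,
      ablation_area_cm2 = x$ablation_area_cm2,
      max_temperatures = as.list(x$max_temperatures),
      power_balance = x$power_balance),
    mesh_stats = x$mesh_stats,
    provenance = x$provenance)
  jsonlite::write_json(summary, file.path(dir, "result.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  utils::write.csv(x$traces, file.path(dir, "traces.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read back a serialized scenario result summary
#'
#' @param dir Directory written by [write_scenario_result()].
#' @return List with `summary` (parsed JSON) and `traces` (tibble).
#' @export
read_scenario_result <- function(dir) {
  list(summary = jsonlite::fromJSON(file.path(dir, "result.json"),
                                    simplifyVector = TRUE),
       traces = tibble::as_tibble(utils::read.csv(file.path(dir, "traces.csv"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
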