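#' Define the physical properties of one material region
#'
#' Bundles the electromagnetic (relative permittivity, conductivity) and
#' thermal (conductivity, density, specific heat, blood perfusion, metabolic
#' heat) constants of a homogeneous region. Perfusion is given in the
#' physiological unit mL/min/kg and converted to a volumetric coefficient by
#' [perfusion_to_volumetric_rate()] where the bioheat operator needs it.
#'
#' @param name Region label.
#' @param relative_permittivity Dimensionless relative permittivity (>= 1).
#' @param electric_conductivity Electrical conductivity, S/m (>= 0).
#' @param thermal_conductivity Thermal conductivity, W/(m K).
#' @param density Mass density, kg/m^3.
#' @param specific_heat Specific heat capacity, J/(kg K).
#' @param perfusion_rate Blood perfusion, mL/min/kg (0 for non-perfused media).
#' @param metabolic_heat Volumetric metabolic heat source, W/m^3.
#'
#' @return An object of class `mwa_material` (a named list).
#' @seealso [material_registry()]
#' @export
material_properties <- function(name,
                                relative_permittivity = 1,
                                electric_conductivity = 0,
                                thermal_conductivity = 0.5,
                                density = 1000,
                                specific_heat = 4000,
                                perfusion_rate = 0,
                                metabolic_heat = 0) {
  vals <- c(relative_permittivity, electric_conductivity, thermal_conductivity,
            density, specific_heat, perfusion_rate, metabolic_heat)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort_param("all material properties must be finite and non-negative")
  }
  if (relative_permittivity < 1) {
    abort_param("relative_permittivity must be >= 1 for a physical medium")
  }
  structure(
    list(
      name = as.character(name),
      relative_permittivity = relative_permittivity,
      electric_conductivity = electric_conductivity,
      thermal_conductivity = thermal_conductivity,
      density = density,
      specific_heat = specific_heat,
      perfusion_rate = perfusion_rate,
      metabolic_heat = metabolic_heat
    ),
    class = "mwa_material"
  )
}

#' @export
print.mwa_material <- function(x, ...) {
  cat(sprintf(
    "<mwa_material> %s: eps_r=%.4g sigma=%.4g S/m | k=%.4g W/mK rho=%.4g kg/m3 C=%.4g J/kgK omega_b=%.4g mL/min/kg Qmet=%.4g W/m3\n",
    x$name, x$relative_permittivity, x$electric_conductivity,
    x$thermal_conductivity, x$density, x$specific_heat,
    x$perfusion_rate, x$metabolic_heat))
  invisible(x)
}

#' Built-in material registry
#'
#' Returns the published dielectric and thermal constants for the regions of
#' the breast ablation model: breast tissue, blood (carried on the breast
#' entry as perfusion parameters), the coaxial cable dielectric, the PTFE
#' catheter, and the tissue-mimicking phantom. Breast specific heat is not
#' published for this model; a representative literature value of
#' 3000 J/(kg K) is used and can be overridden per scenario. The phantom
#' carries its measured dielectric constants (eps_r 5.38, sigma 0.16 S/m) with
#' breast thermal constants but no perfusion and no metabolism.
#'
#' @param as_tibble If `TRUE`, return a tibble with one row per material
#'   instead of a named list of [material_properties()] objects.
#' @return Named list of `mwa_material` objects (default) or a tibble.
#' @examples
#' material_registry(as_tibble = TRUE)
#' @export
material_registry <- function(as_tibble = FALSE) {
  reg <- list(
    breast = material_properties(
      "breast",
      relative_permittivity = 5.14,
      electric_conductivity = 0.14,
      thermal_conductivity  = 0.42,
      density               = 1020,
      specific_heat         = 3000,  # unpublished for this model; literature default
      perfusion_rate        = 33,
      metabolic_heat        = 3.9
    ),
    blood = material_properties(
      "blood",
      relative_permittivity = 58,
      electric_conductivity = 2.54,
      thermal_conductivity  = 0.52,
      density               = 1000,
      specific_heat         = 3639,
      perfusion_rate        = 0,
      metabolic_heat        = 0
    ),
    coax_dielectric = material_properties(
      "coax_dielectric",
      relative_permittivity = 2.03,
      electric_conductivity = 0,
      thermal_conductivity  = 0.25,   # PTFE
      density               = 2200,
      specific_heat         = 1050
    ),
    catheter = material_properties(
      "catheter",
      relative_permittivity = 2.60,
      electric_conductivity = 0,
      thermal_conductivity  = 0.25,   # PTFE
      density               = 2200,
      specific_heat         = 1050
    ),
    phantom = material_properties(
      "phantom",
      relative_permittivity = 5.38,
      electric_conductivity = 0.16,
      thermal_conductivity  = 0.42,
      density               = 1020,
      specific_heat         = 3000,
      perfusion_rate        = 0,
      metabolic_heat        = 0
    )
  )
  if (as_tibble) {
    return(dplyr::bind_rows(lapply(reg, function(m) tibble::as_tibble(unclass(m)))))
  }
  reg
}

#' Arterial blood parameters for the Pennes perfusion sink
#'
#' @return Named list with blood density (kg/m^3), blood specific heat
#'   (J/(kg K)) and arterial blood temperature (deg C).
#' @export
blood_parameters <- function() {
  list(density = 1000, specific_heat = 3639, temperature = 37)
}

#' Effective wavelength in a dielectric medium
#'
#' `lambda_eff = c / (f sqrt(eps_r))` — the design rule that sizes the slot
#' spacing of the interstitial applicator relative to the wavelength in
#' tissue at the operating frequency.
#'
#' @param frequency Operating frequency, Hz (> 0).
#' @param relative_permittivity Relative permittivity of the medium (>= 1).
#' @return Wavelength in metres.
#' @examples
#' effective_wavelength(2.45e9, 5.15)
#' @export
effective_wavelength <- function(frequency, relative_permittivity) {
  if (any(frequency <= 0)) abort_param("frequency must be positive")
  if (any(relative_permittivity < 1)) abort_param("relative_permittivity must be >= 1")
  physical_constants()$speed_of_light / (frequency * sqrt(relative_permittivity))
}

#' Electrical conductivity from the dielectric loss factor
#'
#' `sigma = eps'' * eps0 * omega` with `omega = 2 pi f`; the conversion used
#' to derive a medium's conductivity from a measured imaginary permittivity.
#'
#' @param loss_factor Imaginary relative permittivity eps'' (>= 0).
#' @param frequency Measurement frequency, Hz (> 0).
#' @return Conductivity, S/m.
#' @examples
#' conductivity_from_loss_factor(1.0, 2.45e9)
#' @export
conductivity_from_loss_factor <- function(loss_factor, frequency) {
  if (any(loss_factor < 0)) abort_param("loss_factor must be non-negative")
  if (any(frequency <= 0)) abort_param("frequency must be positive")
  loss_factor * physical_constants()$vacuum_permittivity * 2 * pi * frequency
}

#' Convert physiological perfusion to a volumetric rate
#'
#' Normalizes a perfusion given in mL of blood per minute per kg of tissue
#' into the 1/s volumetric coefficient the Pennes sink term
#' `rho_b C_b omega_b (T_b - T)` requires:
#' `rate = perfusion * 1e-6 (m^3/mL) / 60 (s/min) * rho_tissue`.
#'
#' @param perfusion Perfusion, mL/min/kg (>= 0).
#' @param tissue_density Tissue density, kg/m^3 (>= 0).
#' @return Volumetric perfusion rate, 1/s.
#' @examples
#' perfusion_to_volumetric_rate(33, 1020)
#' @export
perfusion_to_volumetric_rate <- function(perfusion, tissue_density) {
  if (any(perfusion < 0) || any(tissue_density < 0)) {
    abort_param("perfusion and tissue_density must be non-negative")
  }
  perfusion * 1e-6 / 60 * tissue_density
}

#' Complex effective relative permittivity
#'
#' `eps_c = eps_r - j sigma/(omega eps0)`, the combined polarization and
#' conduction loss term that enters the frequency-domain wave equation and
#' the SAR expression. The imaginary part is non-positive for passive media
#' (time convention `exp(+j omega t)`).
#'
#' @param props An [material_properties()] object (or any list with
#'   `relative_permittivity` and `electric_conductivity`).
#' @param frequency Frequency, Hz (> 0).
#' @return A complex scalar.
#' @export
complex_effective_permittivity <- function(props, frequency) {
  if (any(frequency <= 0)) abort_param("frequency must be positive")
  eps0 <- physical_constants()$vacuum_permittivity
  omega <- 2 * pi * frequency
  complex(real = props$relative_permittivity,
          imaginary = -props$electric_conductivity / (omega * eps0))
}

#' Read a material block list from a configuration list
#'
#' Accepts the `materials:` section of a YAML scenario configuration — a named
#' list of blocks, each holding any subset of the [material_properties()]
#' fields — and merges it over the built-in registry.
#' @param overrides Named list of material override blocks (may be `NULL`).
#' @return Named list of `mwa_material` objects.
#' @keywords internal
resolve_materials <- function(overrides = NULL) {
  reg <- material_registry()
  if (is.null(overrides)) return(reg)
  for (nm in names(overrides)) {
    base <- if (nm %in% names(reg)) unclass(reg[[nm]]) else list(name = nm)
    ov <- overrides[[nm]]
    base[names(ov)] <- ov
    base$name <- nm
    reg[[nm]] <- do.call(material_properties, base)
  }
  reg
}
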