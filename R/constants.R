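#' Physical constants used by the solvers
#'
#' Fixed CODATA values for the speed of light, vacuum permittivity and vacuum
#' permeability, plus the free-space wave impedance derived from them.
#' `c = 1/sqrt(mu0 * eps0)` holds to relative error below 1e-9.
#'
#' @return A named list with elements `speed_of_light` (m/s),
#'   `vacuum_permittivity` (F/m), `vacuum_permeability` (H/m) and
#'   `eta0` (Ohm, free-space impedance).
#' @examples
#' physical_constants()$speed_of_light
#' @export
physical_constants <- function() {
  c0   <- 299792458            # m/s, exact
  mu0  <- 4e-7 * pi            # H/m (classical value; within CODATA uncertainty)
  eps0 <- 1 / (mu0 * c0^2)     # F/m, so c = 1/sqrt(mu0*eps0) exactly
  list(
    speed_of_light      = c0,
    vacuum_permittivity = eps0,
    vacuum_permeability = mu0,
    eta0                = sqrt(mu0 / eps0)
  )
}

abort_param <- function(msg) {
  rlang::abort(msg, class = "mwablate_invalid_parameter")
}
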