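# Physical constants (CODATA 2018), SI
.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  NA_  = 6.02214076e23      # Avogadro number, 1/mol
)

#' Bjerrum length
#'
#' Distance at which the Coulomb energy of two elementary charges in a
#' dielectric medium equals the thermal energy `kB*T`:
#' \deqn{\lambda_B = e^2 / (4\pi \epsilon \epsilon_0 k_B T)}
#' For water at room temperature (`T = 298` K, `epsilon = 80`) this is
#' approximately 0.70 nm.
#'
#' @param T temperature in kelvin.
#' @param epsilon relative dielectric permittivity (default 80, water).
#' @return Bjerrum length in nm.
#' @examples
#' bjerrum_length(298)      # ~0.70 nm
#' bjerrum_length(310, 80)
#' @export
bjerrum_length <- function(T, epsilon = 80) {
  if (!is.numeric(T) || any(T <= 0)) abort("`T` must be a positive temperature in kelvin.")
  if (!is.numeric(epsilon) || any(epsilon <= 0)) abort("`epsilon` must be positive.")
  lb_m <- .const$e^2 / (4 * pi * epsilon * .const$eps0 * .const$kB * T)
  lb_m * 1e9
}

#' Thermal voltage kB*T/e in millivolts
#'
#' Conversion factor between the dimensionless potential `e*Psi/(kB*T)` and a
#' physical potential in mV.
#'
#' @param T temperature in kelvin.
#' @return kB*T/e in millivolts.
#' @export
thermal_voltage_mV <- function(T) {
  if (any(T <= 0)) abort("`T` must be positive.")
  .const$kB * T / .const$e * 1000
}

# canonical group tags used throughout the package
.group_levels <- c("core", "backbone", "inner_ch2", "terminal_ch2", "side_ch2",
                   "innerGly_ch2", "terminal_N", "donor", "hydrogen",
                   "acceptor", "counterion", "other")
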