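#' International Standard Atmosphere constants
#'
#' Sea-level constants of the ISA model (ISO 2533:1975) used to convert
#' logger pressure records to altitude: temperature `T0` (K), temperature
#' lapse rate `L` (K m^-1), sea-level pressure `P0` (hPa), gravitational
#' acceleration `g` (m s^-2), and the specific gas constant of dry air `R0`
#' (J kg^-1 K^-1). Override individual values only if you know why.
#'
#' @param T0,L,P0,g,R0 optional overrides of the standard values.
#' @return named list of class `isa_constants`.
#' @export
#' @examples
#' isa_constants()$P0  # 1013.25 hPa
isa_constants <- function(T0 = 288.15, L = -0.0065, P0 = 1013.25,
                          g = 9.81, R0 = 287.053) {
  structure(list(T0 = T0, L = L, P0 = P0, g = g, R0 = R0),
            class = "isa_constants")
}

#' Barometric altitude from ambient pressure (ISA)
#'
#' Closed-form inversion of the standard-atmosphere pressure profile:
#' \deqn{z = \frac{T_0}{L}\left(\left(\frac{P_0}{P}\right)^{L R_0 / g} - 1\right)}
#' Altitudes are standard-atmosphere values, not corrected for local
#' atmospheric conditions; near sea level a 1 hPa change corresponds to
#' roughly 8 m.
#'
#' @param pressure_hpa ambient pressure, hPa (vectorised, must be > 0).
#' @param const constants from [isa_constants()].
#' @return altitude above sea level, m.
#' @export
#' @examples
#' pressure_to_altitude(1013.25)  # 0
#' pressure_to_altitude(850)      # about 1457 m
pressure_to_altitude <- function(pressure_hpa, const = isa_constants()) {
  if (any(!is.finite(pressure_hpa)) || any(pressure_hpa <= 0))
    stop("pressure must be positive and finite")
  with(const, T0 / L * ((P0 / pressure_hpa)^(L * R0 / g) - 1))
}

#' Ambient pressure at a given altitude (inverse ISA)
#'
#' Exact inverse of [pressure_to_altitude()]; used by the synthetic sensor
#' generator so that the round trip altitude -> pressure -> altitude is the
#' identity in the absence of noise.
#'
#' @param altitude_m altitude above sea level, m.
#' @inheritParams pressure_to_altitude
#' @return pressure, hPa.
#' @export
altitude_to_pressure <- function(altitude_m, const = isa_constants()) {
  with(const, {
    base <- 1 + altitude_m * L / T0
    if (any(base <= 0)) stop("altitude outside the validity of the ISA troposphere")
    P0 * base^(-g / (L * R0))
  })
}
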