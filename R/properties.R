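# Air transport properties and material property containers.

# Specific gas constant of dry air, J/(kg K)
.R_AIR <- 287.0
# Specific heat of air, J/(kg K); varies by <1% over 250-320 K, held constant
.CP_AIR <- 1006

#' Dry-air density from the ideal-gas law
#'
#' @param T Gas temperature, K.
#' @param p Pressure, Pa.
#' @return Density, kg/m^3.
#' @examples
#' air_density(277, 1e5)
#' @export
air_density <- function(T, p) {
  if (any(T <= 0) || any(p <= 0)) {
    stop("air_density: temperature and pressure must be strictly positive",
         call. = FALSE)
  }
  p / (.R_AIR * T)
}

#' Dry-air dynamic viscosity (Sutherland's law)
#'
#' Sutherland's correlation with reference viscosity 1.716e-5 Pa s at
#' 273.15 K and Sutherland constant 110.4 K.
#'
#' @param T Gas temperature, K.
#' @return Dynamic viscosity, Pa s.
#' @export
air_viscosity <- function(T) {
  if (any(T <= 0)) {
    stop("air_viscosity: temperature must be strictly positive", call. = FALSE)
  }
  1.716e-5 * (T / 273.15)^1.5 * (273.15 + 110.4) / (T + 110.4)
}

#' Dry-air thermal conductivity (Sutherland form)
#'
#' Sutherland-type correlation with reference conductivity 0.0241 W/(m K)
#' at 273.15 K and effective Sutherland constant 194 K.
#'
#' @param T Gas temperature, K.
#' @return Thermal conductivity, W/(m K).
#' @export
air_conductivity <- function(T) {
  if (any(T <= 0)) {
    stop("air_conductivity: temperature must be strictly positive",
         call. = FALSE)
  }
  0.0241 * (T / 273.15)^1.5 * (273.15 + 194) / (T + 194)
}

#' Assemble the full air state at a temperature and pressure
#'
#' Combines the ideal-gas density and the Sutherland correlations with a
#' constant specific heat of 1006 J/(kg K) and the derived Prandtl number
#' Pr = cp * mu / k.
#'
#' @param T Gas temperature, K.
#' @param p Pressure, Pa.
#' @return An object of class `air_state`: a list with fields `T`, `p`,
#'   `rho_a` (kg/m^3), `mu_a` (Pa s), `k_a` (W/(m K)), `cp_a` (J/(kg K))
#'   and `Pr`.
#' @examples
#' air_state(277, 1e5)$Pr  # about 0.715
#' @export
air_state <- function(T, p) {
  mu <- air_viscosity(T)
  k <- air_conductivity(T)
  structure(
    list(T = T, p = p, rho_a = air_density(T, p), mu_a = mu, k_a = k,
         cp_a = .CP_AIR, Pr = .CP_AIR * mu / k),
    class = "air_state"
  )
}

#' Thermophysical properties of a solidifying material
#'
#' Container for the constant solid/liquid properties used by the staged
#' model. The phase change is spread over the interval from `T_freeze`
#' (onset, the temperature at which crystallization starts) down to
#' `T_solidus` (the temperature at which the droplet is taken to be fully
#' solid).
#'
#' @param rho Density, kg/m^3 (constant across phases; the droplet neither
#'   shrinks nor loses mass).
#' @param cp_liquid Specific heat of the liquid, J/(kg K).
#' @param cp_solid Specific heat of the solid, J/(kg K).
#' @param latent_heat Latent heat of crystallization, J/kg.
#' @param T_freeze Phase-change onset temperature, K.
#' @param T_solidus Phase-change end temperature, K (must be below
#'   `T_freeze`).
#' @param k_thermal Thermal conductivity of the material, W/(m K). Used only
#'   for the Biot-number diagnostic, never in the lumped energy balance.
#' @return An object of class `material_properties`.
#' @seealso [cocoa_butter()] for the packaged default.
#' @export
material_properties <- function(rho, cp_liquid, cp_solid, latent_heat,
                                T_freeze, T_solidus, k_thermal) {
  fields <- list(rho = rho, cp_liquid = cp_liquid, cp_solid = cp_solid,
                 latent_heat = latent_heat, T_freeze = T_freeze,
                 T_solidus = T_solidus, k_thermal = k_thermal)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("material_properties: '%s' must be a finite number", nm),
           call. = FALSE)
    }
  }
  # latent_heat = 0 is admitted (a material with no phase-change enthalpy);
  # everything else must be strictly positive
  if (latent_heat < 0) {
    stop("material_properties: 'latent_heat' must be non-negative",
         call. = FALSE)
  }
  for (nm in setdiff(names(fields), "latent_heat")) {
    if (fields[[nm]] <= 0) {
      stop(sprintf("material_properties: '%s' must be strictly positive", nm),
           call. = FALSE)
    }
  }
  if (T_freeze <= T_solidus) {
    stop("material_properties: 'T_freeze' must exceed 'T_solidus'",
         call. = FALSE)
  }
  structure(fields, class = "material_properties")
}

#' Cocoa butter property set
#'
#' The packaged default material: pure cocoa butter with constant
#' properties in each phase. Crystallization starts at 291 K and the
#' droplet is treated as fully solid at 273 K. The thermal conductivity of
#' cocoa butter is not part of the published property table; the default
#' 0.18 W/(m K) is back-derived from the reported Biot number of
#' approximately 0.18 for a 2 mm droplet and is used only for the Biot
#' diagnostic.
#'
#' @return A [material_properties()] object.
#' @examples
#' cocoa_butter()
#' @export
cocoa_butter <- function() {
  material_properties(rho = 894, cp_liquid = 2200, cp_solid = 1250,
                      latent_heat = 157000, T_freeze = 291, T_solidus = 273,
                      k_thermal = 0.18)
}

#' @export
print.material_properties <- function(x, ...) {
  cat("Material properties\n")
  cat(sprintf("  density          %8.1f kg/m^3\n", x$rho))
  cat(sprintf("  cp (liquid)      %8.1f J/(kg K)\n", x$cp_liquid))
  cat(sprintf("  cp (solid)       %8.1f J/(kg K)\n", x$cp_solid))
  cat(sprintf("  latent heat      %8.0f J/kg\n", x$latent_heat))
  cat(sprintf("  freeze onset     %8.1f K\n", x$T_freeze))
  cat(sprintf("  solidus          %8.1f K\n", x$T_solidus))
  cat(sprintf("  k (diagnostic)   %8.3f W/(m K)\n", x$k_thermal))
  invisible(x)
}
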