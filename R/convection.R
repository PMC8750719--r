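# Dimensionless groups and the convective heat-transfer coefficient.

#' Film temperature
#'
#' Arithmetic mean of the droplet surface and ambient temperatures, the
#' standard evaluation temperature for gas transport properties in external
#' convection.
#'
#' @param Td Droplet (surface) temperature, K.
#' @param Ta Ambient gas temperature, K.
#' @return Temperature, K.
#' @export
film_temperature <- function(Td, Ta) {
  if (any(Td <= 0) || any(Ta <= 0)) {
    stop("film_temperature: temperatures must be strictly positive",
         call. = FALSE)
  }
  (Td + Ta) / 2
}

#' Droplet Reynolds number
#'
#' Re = d * rho_a * Vdg / mu_a for flow of the ambient gas past the droplet.
#'
#' @param d Droplet diameter, m.
#' @param Vdg Relative drop-gas speed, m/s (non-negative).
#' @param air An [air_state()] supplying `rho_a` and `mu_a`.
#' @return Reynolds number (dimensionless).
#' @export
reynolds <- function(d, Vdg, air) {
  if (any(d <= 0)) stop("reynolds: diameter must be positive", call. = FALSE)
  if (any(Vdg < 0)) {
    stop("reynolds: relative speed must be non-negative", call. = FALSE)
  }
  d * air$rho_a * Vdg / air$mu_a
}

#' Ranz-Marshall Nusselt number
#'
#' Nu = 2 + 0.6 Pr^(1/3) Re^(1/2), the standard correlation for convective
#' heat transfer to a sphere; the floor of 2 is the stagnant-gas conduction
#' limit.
#'
#' @param Re Reynolds number (non-negative).
#' @param Pr Prandtl number of the gas (positive).
#' @return Nusselt number (dimensionless), always >= 2.
#' @export
nusselt <- function(Re, Pr) {
  if (any(Re < 0)) stop("nusselt: Re must be non-negative", call. = FALSE)
  if (any(Pr <= 0)) stop("nusselt: Pr must be positive", call. = FALSE)
  2 + 0.6 * Pr^(1 / 3) * sqrt(Re)
}

#' Heat-transfer coefficient from the Nusselt number
#'
#' @param Nu Nusselt number.
#' @param ka Gas thermal conductivity, W/(m K).
#' @param d Droplet diameter, m.
#' @return h, W/(m^2 K).
#' @export
htc <- function(Nu, ka, d) {
  if (any(d <= 0)) stop("htc: diameter must be positive", call. = FALSE)
  Nu * ka / d
}

#' Biot number of a sphere
#'
#' Bi = h l / k with the characteristic length l = V/A = d/6 of a sphere.
#' Bi below about 0.1 justifies the spatially uniform droplet temperature
#' that the lumped model assumes.
#'
#' @param h Heat-transfer coefficient, W/(m^2 K).
#' @param d Droplet diameter, m.
#' @param k_material Thermal conductivity of the droplet material, W/(m K).
#' @return Biot number (dimensionless).
#' @export
biot <- function(h, d, k_material) {
  if (any(h < 0) || any(d <= 0)) {
    stop("biot: h must be non-negative and d positive", call. = FALSE)
  }
  if (any(k_material <= 0)) {
    stop("biot: material conductivity must be positive", call. = FALSE)
  }
  h * (d / 6) / k_material
}

#' Convective transfer state of a droplet
#'
#' Evaluates the full chain Re -> Nu -> h -> Bi for a droplet of diameter
#' `d` at temperature `Td` in gas at `Ta` and pressure `p`. The gas
#' viscosity, conductivity and Prandtl number are evaluated at the film
#' temperature (Td + Ta)/2; the gas density entering Re is the far-field
#' density at (`Ta`, `p`), i.e. the density of the chamber gas the droplet
#' actually moves through.
#'
#' All arguments are vectorized over `Td`.
#'
#' @param d Droplet diameter, m.
#' @param Td Droplet temperature, K.
#' @param Ta Ambient gas temperature, K.
#' @param Vdg Relative drop-gas speed, m/s.
#' @param p Pressure, Pa.
#' @param k_material Optional material conductivity for the Biot number;
#'   `NA` suppresses the Bi field.
#' @return An object of class `transfer_state`: list with `Re`, `Pr`, `Nu`,
#'   `h` (W/(m^2 K)), `Bi` (NA when `k_material` is NA), and the film
#'   temperature `T_film` and conductivity `ka` used.
#' @export
transfer_state <- function(d, Td, Ta, Vdg, p, k_material = NA_real_) {
  T_film <- film_temperature(Td, Ta)
  mu <- air_viscosity(T_film)
  ka <- air_conductivity(T_film)
  Pr <- .CP_AIR * mu / ka
  rho_far <- air_density(Ta, p)
  Re <- d * rho_far * Vdg / mu
  if (any(Vdg < 0)) {
    stop("transfer_state: relative speed must be non-negative", call. = FALSE)
  }
  Nu <- nusselt(Re, Pr)
  h <- htc(Nu, ka, d)
  Bi <- if (all(is.na(k_material))) NA_real_ else biot(h, d, k_material)
  structure(list(Re = Re, Pr = Pr, Nu = Nu, h = h, Bi = Bi,
                 T_film = T_film, ka = ka),
            class = "transfer_state")
}
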