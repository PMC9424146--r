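#' Body radiation parameters for flux-based mean radiant temperature
#'
#' Bundles the constants of the flux-based MRT equation: the solar
#' absorption coefficient of the irradiated body surface (`alpha_ir`,
#' standard value 0.7), the emissivity of the clothed human body (`eps_p`,
#' standard value 0.97) and the angle factor (`f_a`, 0.5, i.e. the
#' surroundings reduced to a ground hemisphere and a sky hemisphere).
#'
#' @param alpha_ir Solar absorption coefficient, in (0, 1].
#' @param eps_p Body emissivity, in (0, 1].
#' @param f_a Angle factor, in (0, 1].
#' @return A list of class `body_radiation_params`.
#' @export
body_radiation_params <- function(alpha_ir = 0.7, eps_p = 0.97, f_a = 0.5) {
  stopifnot(alpha_ir > 0, alpha_ir <= 1, eps_p > 0, eps_p <= 1, f_a > 0, f_a <= 1)
  structure(list(alpha_ir = alpha_ir, eps_p = eps_p, f_a = f_a),
            class = "body_radiation_params")
}

#' Globe thermometer parameters
#'
#' @param diameter Globe diameter in metres (default 0.05, a 50-mm globe).
#' @param emissivity Globe emissivity (default 0.95 for a gray-painted
#'   copper globe).
#' @return A list of class `globe_params`.
#' @export
globe_params <- function(diameter = 0.05, emissivity = 0.95) {
  stopifnot(diameter > 0, emissivity > 0, emissivity <= 1)
  structure(list(diameter = diameter, emissivity = emissivity),
            class = "globe_params")
}

#' Mean radiant temperature from a globe thermometer
#'
#' ISO 7726 forced-convection estimator:
#' `Tmrt = [(Tg + 273.15)^4 + 1.1e8 * va^0.6 / (eps * D^0.4) * (Tg - Ta)]^0.25 - 273.15`.
#'
#' @param tg Globe temperature, degC.
#' @param ta Air temperature, degC.
#' @param va Wind speed at sensor height, m/s (>= 0).
#' @param gp A [globe_params()] object.
#' @return Mean radiant temperature, degC. Equals `tg` in the isothermal
#'   case `tg == ta` and whenever `va = 0`.
#' @examples
#' mrt_from_globe(30, 25, 1.0) # ~45.9 degC
#' @export
mrt_from_globe <- function(tg, ta, va, gp = globe_params()) {
  if (any(va < 0, na.rm = TRUE)) abort("`va` must be >= 0.")
  conv <- 1.1e8 * va^0.6 / (gp$emissivity * gp$diameter^0.4)
  inner <- (tg + T_KELVIN)^4 + conv * (tg - ta)
  if (any(inner <= 0, na.rm = TRUE)) {
    abort("non-physical globe reading: radiant balance is not positive.")
  }
  inner^0.25 - T_KELVIN
}

#' Projected area factor of a standing person
#'
#' Fraction of the body surface exposed to the direct solar beam for a
#' rotationally symmetric standing or walking person, as a function of
#' solar elevation `gamma` (degrees):
#' `f_p = 0.308 * cos(gamma * (0.998 - gamma^2 / 50000))` with the cosine
#' taken in degrees. Maximal (0.308) at the horizon, ~0.079 at the zenith.
#' Elevations at or below 0 return 0 (no direct beam at night).
#'
#' @param solar_elev_deg Solar elevation angle, degrees (values > 90 are
#'   rejected).
#' @return Dimensionless projected area factor in \[0, 0.308\].
#' @export
projected_area_factor <- function(solar_elev_deg) {
  if (any(solar_elev_deg > 90, na.rm = TRUE)) {
    abort("`solar_elev_deg` must be <= 90.")
  }
  g <- pmax(solar_elev_deg, 0)
  fp <- 0.308 * cos(pi / 180 * (g * (0.998 - g^2 / 50000)))
  ifelse(solar_elev_deg <= 0, 0, fp)
}

#' Mean radiant temperature from radiation fluxes
#'
#' Computes MRT from the four radiation components used when deriving the
#' UTCI from gridded radiation data: downwelling (`l_dn`) and upwelling
#' (`l_up`) thermal fluxes, isotropic diffuse (`s_diffuse`) and
#' surface-reflected (`s_up`) solar fluxes, and the direct solar flux on a
#' surface perpendicular to the beam (`i_star`), weighted by the angle
#' factor, the body absorption/emissivity ratio and the projected area
#' factor:
#' \deqn{T_{mrt} = \left\{\frac{1}{\sigma}\left[f_a L^{dn} + f_a L^{up} +
#'   \frac{\alpha_{ir}}{\epsilon_p}\left(f_a S^{dn,diff} + f_a S^{up} +
#'   f_p I^*\right)\right]\right\}^{0.25}}
#'
#' @param l_dn,l_up Thermal fluxes, W/m2 (>= 0).
#' @param s_diffuse,s_up Diffuse and reflected solar fluxes, W/m2 (>= 0).
#' @param i_star Direct solar flux perpendicular to the beam, W/m2; forced
#'   to 0 when the sun is below the horizon.
#' @param solar_elev_deg Solar elevation, degrees.
#' @param bp A [body_radiation_params()] object.
#' @return Mean radiant temperature, degC.
#' @examples
#' # isothermal blackbody enclosure at 300 K
#' mrt_from_fluxes(459.3, 459.3, 0, 0, 0, -10) # ~26.85 degC
#' @export
mrt_from_fluxes <- function(l_dn, l_up, s_diffuse, s_up, i_star,
                            solar_elev_deg, bp = body_radiation_params()) {
  fluxes_ok <- c(l_dn, l_up, s_diffuse, s_up, i_star)
  if (any(fluxes_ok < 0, na.rm = TRUE)) abort("radiation fluxes must be >= 0.")
  if (any(abs(solar_elev_deg) > 90, na.rm = TRUE)) {
    abort("`solar_elev_deg` must lie in [-90, 90].")
  }
  i_star <- ifelse(solar_elev_deg <= 0, 0, i_star)
  fp <- projected_area_factor(solar_elev_deg)
  total <- bp$f_a * l_dn + bp$f_a * l_up +
    (bp$alpha_ir / bp$eps_p) * (bp$f_a * s_diffuse + bp$f_a * s_up + fp * i_star)
  if (any(total <= 0, na.rm = TRUE)) {
    abort("radiant flux sum must be positive to define a mean radiant temperature.")
  }
  (total / SIGMA_SB)^0.25 - T_KELVIN
}
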