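#' Saturation vapour pressure over water
#'
#' Computes the saturation vapour pressure `es(Ta)` in hPa from air
#' temperature using the ITS-90-based formulation of Hardy, the same
#' formulation employed by the operational UTCI procedure to convert
#' relative humidity into the vapour-pressure input of the polynomial.
#'
#' @param ta_c Air temperature in degrees Celsius. Must lie in
#'   \[-60, 60\], the range over which the formulation is intended.
#' @return Saturation vapour pressure in hPa (same length as `ta_c`);
#'   strictly increasing in temperature.
#' @examples
#' saturation_vapour_pressure(0)   # ~6.11 hPa
#' saturation_vapour_pressure(20)  # ~23.4 hPa
#' @export
saturation_vapour_pressure <- function(ta_c) {
  if (any(!is.finite(ta_c))) abort("`ta_c` must be finite.")
  if (any(ta_c < -60 | ta_c > 60)) {
    abort("`ta_c` out of range: saturation_vapour_pressure requires -60 <= ta_c <= 60 degC.")
  }
  tk <- ta_c + T_KELVIN
  g <- c(-2836.5744, -6028.076559, 19.54263612, -0.02737830188,
         1.6261698e-05, 7.0229056e-10, -1.8680009e-13)
  lp <- 2.7150305 * log(tk)
  for (i in seq_along(g)) lp <- lp + g[i] * tk^(i - 3)
  exp(lp) / 100 # Pa -> hPa
}

#' Convert relative humidity to vapour pressure
#'
#' @param ta_c Air temperature, degC.
#' @param rh_pct Relative humidity, percent (0-100).
#' @return Water vapour pressure in hPa.
#' @export
vapour_pressure <- function(ta_c, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE)) {
    abort("`rh_pct` must lie in [0, 100].")
  }
  saturation_vapour_pressure(ta_c) * rh_pct / 100
}

#' Scale wind speed to the 10-m reference height
#'
#' Extrapolates a wind-speed measurement to the 10 m above ground required
#' by the UTCI, assuming a neutral logarithmic profile
#' `va10 = va * log(10 / z0) / log(z_wind / z0)`.
#'
#' @param va Measured wind speed, m/s (>= 0).
#' @param z_wind Measurement height above ground, m. Typical survey
#'   anemometer height is 2.1 m.
#' @param z0 Aerodynamic roughness length, m (default 0.01).
#' @return Wind speed at 10 m, m/s. Identity when `z_wind = 10`; linear in
#'   `va`.
#' @examples
#' scale_wind_to_10m(1.0, z_wind = 2.1) # ~1.29
#' @export
scale_wind_to_10m <- function(va, z_wind, z0 = 0.01) {
  if (any(va < 0, na.rm = TRUE)) abort("`va` must be >= 0.")
  if (any(z0 <= 0)) abort("`z0` must be > 0.")
  if (any(z_wind <= z0)) abort("`z_wind` must exceed the roughness length `z0`.")
  va * log(10 / z0) / log(z_wind / z0)
}
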