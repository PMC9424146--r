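#' Add thermal indices to a meteorological data frame
#'
#' Data-frame-first wrapper over the thermal kernels: computes 10-m wind,
#' mean radiant temperature (from globe thermometry or from radiation
#' fluxes), UTCI, DTS, the thermal-stress category and comfort-zone flags,
#' and returns the input tibble with the derived columns appended.
#'
#' With `mrt = "globe"` the data must contain `ta_c`, `rh_pct`, `wind_ms`,
#' `wind_height_m` and `globe_c`; the globe equation uses the wind speed at
#' sensor height. With `mrt = "fluxes"` the data must contain `ta_c`,
#' `rh_pct`, `wind_ms` (already at 10 m, as in gridded products), `l_dn`,
#' `l_up`, `s_diffuse`, `s_up`, `i_star` and `solar_elev_deg`.
#'
#' @param data A data frame of meteorological records.
#' @param mrt Which MRT estimator to use: `"globe"` or `"fluxes"`.
#' @param z0 Roughness length for the wind profile, m.
#' @param gp [globe_params()] used when `mrt = "globe"`.
#' @param bp [body_radiation_params()] used when `mrt = "fluxes"`.
#' @param dts_table DTS conversion table.
#' @param scale Stress-category scale.
#' @param strict Passed to [utci()].
#' @return The input as a tibble with columns `va10_ms`, `tmrt_c`,
#'   `utci_c`, `dts`, `stress_category`, `in_tcz`, `in_adjusted_tcz`
#'   appended.
#' @export
add_thermal_indices <- function(data, mrt = c("globe", "fluxes"), z0 = 0.01,
                                gp = globe_params(),
                                bp = body_radiation_params(),
                                dts_table = dts_conversion_table(),
                                scale = utci_stress_scale(),
                                strict = FALSE) {
  mrt <- match.arg(mrt)
  data <- as_tibble(data)
  need <- if (mrt == "globe") {
    c("ta_c", "rh_pct", "wind_ms", "wind_height_m", "globe_c")
  } else {
    c("ta_c", "rh_pct", "wind_ms", "l_dn", "l_up", "s_diffuse", "s_up",
      "i_star", "solar_elev_deg")
  }
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` is missing required columns: ",
                 paste(missing_cols, collapse = ", "), "."))
  }

  if (mrt == "globe") {
    va10 <- scale_wind_to_10m(data$wind_ms, data$wind_height_m, z0 = z0)
    tmrt <- mrt_from_globe(data$globe_c, data$ta_c, data$wind_ms, gp = gp)
  } else {
    va10 <- data$wind_ms
    tmrt <- mrt_from_fluxes(data$l_dn, data$l_up, data$s_diffuse, data$s_up,
                            data$i_star, data$solar_elev_deg, bp = bp)
  }
  u <- utci(data$ta_c, tmrt, va10, rh = data$rh_pct, strict = strict)
  data |>
    mutate(
      va10_ms = va10,
      tmrt_c = tmrt,
      utci_c = u,
      dts = dts_from_utci(u, table = dts_table),
      stress_category = utci_category(u, scale = scale),
      in_tcz = in_tcz(u, scale = scale),
      in_adjusted_tcz = in_adjusted_tcz(u, scale = scale)
    )
}

# Southern-Hemisphere meteorological season from a timestamp
#' Season label (Southern-Hemisphere convention)
#'
#' Maps timestamps to meteorological seasons with the Southern-Hemisphere
#' convention: Dec-Feb summer, Mar-May fall, Jun-Aug winter, Sep-Nov
#' spring.
#'
#' @param timestamp POSIXct (or Date) vector.
#' @return A factor with levels summer, fall, winter, spring.
#' @export
season_of <- function(timestamp) {
  m <- as.integer(format(timestamp, "%m"))
  lab <- dplyr::case_when(
    m %in% c(12L, 1L, 2L) ~ "summer",
    m %in% 3:5 ~ "fall",
    m %in% 6:8 ~ "winter",
    TRUE ~ "spring"
  )
  factor(lab, levels = c("summer", "fall", "winter", "spring"))
}
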