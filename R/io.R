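time_col <- function() {
  readr::col_datetime(format = "")
}

#' Read a survey-response CSV
#'
#' Expects columns `id`, `timestamp` (ISO-8601, one fixed offset per
#' dataset — no daylight-saving logic), `location_id`, `morphology`,
#' `tsv`. Votes must be integers on the 7-point scale; rows with votes
#' outside \{-3..+3\} (or unparseable) are collected and reported in a
#' single error naming the offending rows. Seasons are derived from the
#' timestamps (Southern-Hemisphere convention).
#'
#' @param path Path to the CSV file.
#' @return A tibble of survey responses with a derived `season` column.
#' @export
read_survey_csv <- function(path) {
  dat <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_integer(),
    timestamp = time_col(),
    location_id = readr::col_character(),
    morphology = readr::col_character(),
    tsv = readr::col_double()
  ))
  missing_cols <- setdiff(c("id", "timestamp", "morphology", "tsv"), names(dat))
  if (length(missing_cols)) {
    abort(paste0("survey CSV is missing columns: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(dat) == 0) {
    warn("survey CSV contains a header but no responses.")
    dat$season <- factor(character(), levels = levels(season_of(Sys.time())))
    return(dat)
  }
  bad <- which(is.na(dat$tsv) | dat$tsv != round(dat$tsv) |
                 dat$tsv < -3 | dat$tsv > 3)
  if (length(bad)) {
    abort(paste0("invalid thermal sensation vote(s) outside {-3..+3} in row(s): ",
                 paste(bad, collapse = ", "), "."))
  }
  dat$tsv <- as.integer(dat$tsv)
  dat$season <- season_of(dat$timestamp)
  dat
}

#' Read an in-situ meteorological CSV
#'
#' Expects columns `timestamp`, `ta_c`, `rh_pct`, `wind_ms`,
#' `wind_height_m`, `globe_c`, `solar_wm2` (the last two may be empty).
#'
#' @param path Path to the CSV file.
#' @return A tibble of meteorological records.
#' @export
read_meteo_csv <- function(path) {
  dat <- readr::read_csv(path, col_types = readr::cols(
    timestamp = time_col(),
    ta_c = readr::col_double(),
    rh_pct = readr::col_double(),
    wind_ms = readr::col_double(),
    wind_height_m = readr::col_double(),
    globe_c = readr::col_double(),
    solar_wm2 = readr::col_double()
  ))
  if (any(dat$rh_pct < 0 | dat$rh_pct > 100, na.rm = TRUE)) {
    abort("meteo CSV: `rh_pct` outside [0, 100].")
  }
  if (any(dat$wind_ms < 0, na.rm = TRUE)) abort("meteo CSV: negative wind speed.")
  dat
}

#' Read a radiation-flux CSV
#'
#' Expects columns `timestamp`, `l_dn`, `l_up`, `s_diffuse`, `s_up`,
#' `i_star`, `solar_elev_deg`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of radiation fluxes.
#' @export
read_flux_csv <- function(path) {
  dat <- readr::read_csv(path, col_types = readr::cols(
    timestamp = time_col(),
    l_dn = readr::col_double(), l_up = readr::col_double(),
    s_diffuse = readr::col_double(), s_up = readr::col_double(),
    i_star = readr::col_double(), solar_elev_deg = readr::col_double()
  ))
  fluxes <- c("l_dn", "l_up", "s_diffuse", "s_up", "i_star")
  if (any(unlist(dat[fluxes]) < 0, na.rm = TRUE)) {
    abort("flux CSV: radiation fluxes must be >= 0.")
  }
  dat
}

#' Read an hourly proxy-UTCI CSV
#'
#' Accepts either a precomputed series (`timestamp`, `utci_c`) or raw
#' hourly meteorology plus fluxes (`timestamp`, `ta_c`, `rh_pct`,
#' `wind_ms` at 10 m, `l_dn`, `l_up`, `s_diffuse`, `s_up`, `i_star`,
#' `solar_elev_deg`), in which case the UTCI is computed through the
#' flux-based MRT path.
#'
#' @param path Path to the CSV file.
#' @param ... Passed to [add_thermal_indices()] when the UTCI has to be
#'   computed.
#' @return A tibble with at least `timestamp` and `utci_c`.
#' @export
read_proxy_csv <- function(path, ...) {
  dat <- readr::read_csv(path, col_types = readr::cols(
    timestamp = time_col(), .default = readr::col_double()
  ))
  if ("utci_c" %in% names(dat)) {
    return(dat)
  }
  flux_cols <- c("ta_c", "rh_pct", "wind_ms", "l_dn", "l_up", "s_diffuse",
                 "s_up", "i_star", "solar_elev_deg")
  if (all(flux_cols %in% names(dat))) {
    return(add_thermal_indices(dat, mrt = "fluxes", ...))
  }
  abort("proxy CSV must contain `utci_c` or the full meteorology + flux columns.")
}

#' Write a synthetic campaign to CSV files
#'
#' Writes the campaign in the same schemas the readers expect:
#' `survey.csv`, `meteo.csv`, `proxy.csv` and `fluxes.csv`.
#'
#' @param campaign A campaign from [simulate_campaign()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_campaign_csvs <- function(campaign, dir) {
  stopifnot(inherits(campaign, "utci_campaign"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    survey = file.path(dir, "survey.csv"),
    meteo = file.path(dir, "meteo.csv"),
    proxy = file.path(dir, "proxy.csv"),
    fluxes = file.path(dir, "fluxes.csv")
  )
  resp <- campaign$responses
  readr::write_csv(
    tibble(id = resp$id, timestamp = resp$timestamp,
           location_id = paste0("P", match(resp$morphology,
                                           sort(unique(resp$morphology)))),
           morphology = resp$morphology, tsv = resp$tsv),
    paths[["survey"]]
  )
  readr::write_csv(
    tibble(timestamp = resp$timestamp, ta_c = resp$ta_c,
           rh_pct = resp$rh_pct, wind_ms = resp$wind_ms,
           wind_height_m = resp$wind_height_m, globe_c = resp$globe_c,
           solar_wm2 = NA_real_),
    paths[["meteo"]]
  )
  readr::write_csv(campaign$proxy, paths[["proxy"]])
  readr::write_csv(
    campaign$reference |>
      select("timestamp", "l_dn", "l_up", "s_diffuse", "s_up", "i_star",
             "solar_elev_deg"),
    paths[["fluxes"]]
  )
  invisible(paths)
}
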