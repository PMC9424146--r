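#' Configuration of the synthetic survey-campaign generator
#'
#' Bundles every parameter of the seeded synthetic generator that emulates
#' the statistical structure of a subtropical outdoor-thermal-comfort
#' campaign: a January-August study period with surveys between 10:00 and
#' 15:00 local standard time, a seasonal + diurnal harmonic temperature
#' climate with AR(1) weather noise, morphology-dependent microclimate
#' offsets, an hourly proxy series that damps extremes relative to the
#' in-situ series, and thermal votes linearly related to in-situ UTCI with
#' integer rounding.
#'
#' @param seed Master seed; split into independent per-generator streams
#'   (weather, surveys, votes, proxy) so consuming more draws in one
#'   stream never perturbs another.
#' @param start,end Study period (dates, local standard time).
#' @param window_hours Daily survey window, decimal hours (surveys drawn
#'   uniformly in `[window_hours[1], window_hours[2])`).
#' @param latitude Site latitude in degrees (negative south) for solar
#'   geometry.
#' @param mean_c,annual_amp_c,diurnal_amp_c Mean air temperature and the
#'   amplitudes of the annual and diurnal harmonics, degC.
#' @param peak_doy,peak_hour Day-of-year and local hour of the annual and
#'   diurnal temperature maxima.
#' @param ar1_phi,ar1_sd AR(1) weather-noise persistence and innovation SD
#'   (degC).
#' @param rh_mean,rh_per_degc,rh_sd Relative-humidity model: mean level,
#'   anticorrelation slope with the temperature anomaly (% per degC) and
#'   noise SD; values clipped to \[5, 100\].
#' @param wind_meanlog,wind_sdlog Lognormal parameters of the 10-m wind.
#' @param tau Broadband atmospheric transmittance of clear days, in
#'   (0, 1\].
#' @param tau_overcast Transmittance of overcast days, in (0, `tau`\].
#' @param clear_fraction Probability that a day is clear; the two-state
#'   daily cloud regime produces the right-skewed UTCI distribution of
#'   sunny versus overcast survey days.
#' @param eps_atm Effective atmospheric emissivity for downwelling thermal
#'   flux on clear days.
#' @param eps_atm_overcast Atmospheric emissivity on overcast days.
#' @param ground_warm_k Peak ground-surface warming over air temperature at
#'   full sun, K.
#' @param albedo,diffuse_frac Surface albedo and diffuse fraction of the
#'   direct beam.
#' @param morphologies Data frame with columns `morphology`, `offset_c`
#'   (additive in-situ microclimate offset, degC) and `prob` (sampling
#'   weight).
#' @param clear_wind_factor Multiplicative wind reduction on clear days
#'   (fair-weather days are typically calmer, compounding their radiant
#'   heat load).
#' @param survey_clear_weight Relative propensity to hold a survey
#'   campaign on a clear day versus an overcast one (field campaigns
#'   favour fair weather); 1 samples days uniformly.
#' @param micro_sd Microscale noise SD added to in-situ temperature and
#'   radiant temperature, degC.
#' @param micro_rh_sd Microscale noise SD for in-situ relative humidity, %.
#' @param micro_wind_lnsd Lognormal SD of the multiplicative microscale
#'   wind jitter at the in-situ sensor.
#' @param survey_on_hour If `TRUE`, survey timestamps are snapped to exact
#'   clock hours inside the window (campaigns run at fixed times); useful
#'   for controlled experiments with no within-hour drift.
#' @param wind_height_m In-situ anemometer height, m.
#' @param proxy_gain Extreme-damping gain g in \[0, 1): the proxy series is
#'   `centre + (1 - g) * (utci - centre)` plus seasonal offset and noise,
#'   so the proxy under-represents both heat and cold extremes.
#' @param proxy_centre_c Pivot of the damping transform, degC UTCI.
#' @param proxy_season_offsets Named numeric vector of additive proxy
#'   offsets per season, degC UTCI.
#' @param proxy_noise_sd Proxy noise SD, degC UTCI.
#' @param vote_slope,vote_intercept,vote_sd Vote model: the thermal
#'   sensation vote is `round(vote_slope * utci_insitu + vote_intercept +
#'   e)` with `e ~ N(0, vote_sd)`, clamped to \[-3, 3\].
#' @param n_responses Number of survey responses to draw.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             start = "2009-01-01", end = "2009-08-31",
                             window_hours = c(10, 15),
                             latitude = -25.43,
                             mean_c = 17, annual_amp_c = 3.8,
                             diurnal_amp_c = 2.5, peak_doy = 15, peak_hour = 14,
                             ar1_phi = 0.8, ar1_sd = 1.2,
                             rh_mean = 78, rh_per_degc = 3, rh_sd = 5,
                             wind_meanlog = log(3.5), wind_sdlog = 0.45,
                             tau = 0.85, tau_overcast = 0.25,
                             clear_fraction = 0.4,
                             eps_atm = 0.78, eps_atm_overcast = 0.95,
                             ground_warm_k = 2,
                             albedo = 0.2, diffuse_frac = 0.25,
                             morphologies = tibble(
                               morphology = c("canyon", "crossroads", "square"),
                               offset_c = c(0.9, -0.2, 1.5),
                               prob = c(0.4, 0.4, 0.2)
                             ),
                             survey_clear_weight = 2,
                             clear_wind_factor = 0.45,
                             micro_sd = 1.0, micro_rh_sd = 3,
                             micro_wind_lnsd = 0.1,
                             survey_on_hour = FALSE,
                             wind_height_m = 2.1,
                             proxy_gain = 0.3, proxy_centre_c = 20,
                             proxy_season_offsets = c(summer = -3.65,
                                                      fall = -0.84,
                                                      winter = 1.10),
                             proxy_noise_sd = 1.5,
                             vote_slope = 0.10, vote_intercept = -2.02,
                             vote_sd = 0.8,
                             n_responses = 1640L) {
  cfg <- as.list(environment())
  cfg$start <- as.Date(start); cfg$end <- as.Date(end)
  if (cfg$end < cfg$start) abort("`end` must not precede `start`.")
  if (ar1_phi < 0 || ar1_phi >= 1) abort("`ar1_phi` must lie in [0, 1).")
  if (ar1_sd < 0 || vote_sd < 0 || proxy_noise_sd < 0 || micro_sd < 0) {
    abort("noise standard deviations must be >= 0.")
  }
  if (proxy_gain < 0 || proxy_gain >= 1) abort("`proxy_gain` must lie in [0, 1).")
  if (n_responses <= 0) abort("`n_responses` must be positive.")
  if (window_hours[2] <= window_hours[1]) abort("`window_hours` must be increasing.")
  if (tau <= 0 || tau > 1) abort("`tau` must lie in (0, 1].")
  if (tau_overcast <= 0 || tau_overcast > tau) {
    abort("`tau_overcast` must lie in (0, tau].")
  }
  if (clear_fraction < 0 || clear_fraction > 1) {
    abort("`clear_fraction` must lie in [0, 1].")
  }
  cfg$n_responses <- as.integer(n_responses)
  cfg$morphologies <- as_tibble(morphologies)
  structure(cfg, class = "synthetic_config")
}

# solar elevation (degrees) from a simple declination / hour-angle formula
solar_elevation <- function(doy, hour, latitude) {
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365)
  hour_angle <- 15 * (hour - 12)
  lat <- latitude * pi / 180; dec <- decl * pi / 180; ha <- hour_angle * pi / 180
  sin_el <- sin(lat) * sin(dec) + cos(lat) * cos(dec) * cos(ha)
  asin(pmin(pmax(sin_el, -1), 1)) * 180 / pi
}

#' Generate the hourly reference weather and radiation series
#'
#' Produces the deterministic (given the seed) hourly series from which
#' both the proxy series and the in-situ observations are derived: air
#' temperature as mean + annual harmonic + diurnal harmonic + AR(1) noise,
#' relative humidity anticorrelated with the temperature anomaly and
#' clipped to \[5, 100\], lognormal 10-m wind, and a clear-sky radiation
#' model (direct beam `S0 * max(0, sin(elev)) * tau`, isotropic diffuse
#' and surface-reflected shortwave, gray-body longwave up/down).
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble with one row per hour: `timestamp`, `ta_c`, `rh_pct`,
#'   `wind_ms` (10 m), `clear_day`, `solar_elev_deg`, `i_star`,
#'   `s_diffuse`, `s_up`, `l_dn`, `l_up`.
#' @export
generate_reference_series <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seeds <- split_seed(cfg$seed, c("weather", "surveys", "votes", "proxy"))
  ts <- seq(as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(cfg$end, "23:00:00"), tz = "UTC"),
            by = "hour")
  doy <- as.integer(format(ts, "%j"))
  hour <- as.integer(format(ts, "%H"))
  n <- length(ts)

  day_index <- as.integer(as.Date(ts, tz = "UTC") - cfg$start) + 1L
  n_days <- max(day_index)

  with_seed(seeds[["weather"]], {
    innov <- rnorm(n, 0, cfg$ar1_sd)
    ar <- as.numeric(stats::filter(innov, cfg$ar1_phi, method = "recursive"))
    ta <- cfg$mean_c +
      cfg$annual_amp_c * cos(2 * pi * (doy - cfg$peak_doy) / 365) +
      cfg$diurnal_amp_c * cos(2 * pi * (hour - cfg$peak_hour) / 24) +
      ar
    rh <- cfg$rh_mean - cfg$rh_per_degc * (ta - cfg$mean_c) + rnorm(n, 0, cfg$rh_sd)
    rh <- pmin(pmax(rh, 5), 100)
    wind <- rlnorm(n, cfg$wind_meanlog, cfg$wind_sdlog)
    # two-state daily cloud regime: clear days carry the full beam and a
    # drier atmosphere, overcast days a weak beam and a warmer sky
    clear_day <- runif(n_days) < cfg$clear_fraction
  })
  clear <- clear_day[day_index]
  tau_h <- ifelse(clear, cfg$tau, cfg$tau_overcast)
  eps_h <- ifelse(clear, cfg$eps_atm, cfg$eps_atm_overcast)
  wind <- wind * ifelse(clear, cfg$clear_wind_factor, 1)

  elev <- solar_elevation(doy, hour, cfg$latitude)
  sin_el <- pmax(sin(elev * pi / 180), 0)
  i_star <- 1361 * sin_el * tau_h
  i_star[elev <= 0] <- 0
  s_diffuse <- cfg$diffuse_frac * i_star
  s_up <- cfg$albedo * (i_star * sin_el + s_diffuse)
  l_dn <- eps_h * SIGMA_SB * (ta + T_KELVIN)^4
  l_up <- SIGMA_SB * (ta + cfg$ground_warm_k * sin_el * tau_h / cfg$tau + T_KELVIN)^4

  tibble(timestamp = ts, ta_c = ta, rh_pct = rh, wind_ms = wind,
         clear_day = clear,
         solar_elev_deg = elev, i_star = i_star, s_diffuse = s_diffuse,
         s_up = s_up, l_dn = l_dn, l_up = l_up)
}

# linear interpolation of a reference column at arbitrary times
interp_ref <- function(ref, col, at) {
  out <- approx(as.numeric(ref$timestamp), ref[[col]], xout = as.numeric(at),
                rule = 1)$y
  if (any(is.na(out))) abort("timestamp outside the reference series range.")
  out
}

# invert the ISO 7726 forced-convection globe equation: find the globe
# temperature whose MRT equals `tmrt` at the given air temperature and wind
globe_from_mrt <- function(tmrt, ta, va, gp = globe_params()) {
  conv <- 1.1e8 * va^0.6 / (gp$emissivity * gp$diameter^0.4)
  target <- (tmrt + T_KELVIN)^4
  tg <- tmrt # Newton iterations; f is strictly increasing in tg
  for (i in 1:50) {
    f <- (tg + T_KELVIN)^4 + conv * (tg - ta) - target
    fp <- 4 * (tg + T_KELVIN)^3 + conv
    step <- f / fp
    tg <- tg - step
    if (max(abs(step)) < 1e-10) break
  }
  tg
}

#' Generate in-situ survey observations
#'
#' Draws survey timestamps uniformly over the study days and the daily
#' survey window, assigns an urban-morphology label per response, and
#' synthesises the portable-station record: in-situ air temperature and
#' radiant temperature equal the time-interpolated reference plus the
#' morphology offset plus microscale noise; the globe temperature is
#' obtained by inverting the forced-convection globe equation so that
#' [mrt_from_globe()] recovers the intended radiant temperature exactly.
#'
#' @param ref Hourly reference series from [generate_reference_series()].
#' @param cfg A [synthetic_config()].
#' @return A tibble with one row per response: `id`, `timestamp`,
#'   `morphology`, `season`, `ta_c`, `rh_pct`, `wind_ms` (sensor height),
#'   `wind_height_m`, `globe_c`.
#' @export
generate_insitu_observations <- function(ref, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seeds <- split_seed(cfg$seed, c("weather", "surveys", "votes", "proxy"))
  n <- cfg$n_responses
  days <- seq(cfg$start, cfg$end, by = "day")

  day_clear <- ref |>
    group_by(day = as.Date(.data$timestamp, tz = "UTC")) |>
    summarise(clear = any(.data$clear_day), .groups = "drop")
  w <- ifelse(day_clear$clear[match(days, day_clear$day)], cfg$survey_clear_weight, 1)
  with_seed(seeds[["surveys"]], {
    day <- sample(days, n, replace = TRUE, prob = w)
    hour <- runif(n, cfg$window_hours[1], cfg$window_hours[2])
    if (cfg$survey_on_hour) hour <- floor(hour)
    ts <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC") +
      round(hour * 60) * 60 # minute resolution
    morph <- sample(cfg$morphologies$morphology, n, replace = TRUE,
                    prob = cfg$morphologies$prob)
    off <- cfg$morphologies$offset_c[match(morph, cfg$morphologies$morphology)]

    ta_ref <- interp_ref(ref, "ta_c", ts)
    rh_ref <- interp_ref(ref, "rh_pct", ts)
    va10_ref <- interp_ref(ref, "wind_ms", ts)

    # intended radiant temperature: reference flux-based MRT + local effects
    tmrt_ref <- mrt_from_fluxes(
      interp_ref(ref, "l_dn", ts), interp_ref(ref, "l_up", ts),
      interp_ref(ref, "s_diffuse", ts), interp_ref(ref, "s_up", ts),
      interp_ref(ref, "i_star", ts), interp_ref(ref, "solar_elev_deg", ts)
    )

    ta <- ta_ref + off + rnorm(n, 0, cfg$micro_sd)
    tmrt <- tmrt_ref + off + rnorm(n, 0, cfg$micro_sd)
    rh <- pmin(pmax(rh_ref + rnorm(n, 0, cfg$micro_rh_sd), 5), 100)
    va_sensor <- va10_ref * log(cfg$wind_height_m / 0.01) / log(10 / 0.01) *
      exp(rnorm(n, 0, cfg$micro_wind_lnsd))
  })

  globe <- globe_from_mrt(tmrt, ta, va_sensor)
  ord <- order(ts)
  tibble(
    id = seq_len(n),
    timestamp = ts,
    morphology = morph,
    season = season_of(ts),
    ta_c = ta, rh_pct = rh,
    wind_ms = va_sensor, wind_height_m = cfg$wind_height_m,
    globe_c = globe
  )[ord, ] |> mutate(id = seq_len(n))
}

#' Generate thermal sensation votes from in-situ UTCI
#'
#' Votes follow the linear vote model
#' `tsv = clamp(round(a * utci + b + e), -3, 3)` with `e ~ N(0, s)`,
#' deterministic given the configuration seed. The default slope and
#' intercept (0.10 and -2.02 MTSV per degC UTCI) reproduce the linear
#' vote-UTCI structure typical of subtropical survey campaigns.
#'
#' @param utci_insitu Numeric vector of in-situ UTCI values, degC.
#' @param cfg A [synthetic_config()].
#' @return Integer votes in \{-3, ..., +3\}.
#' @export
generate_votes <- function(utci_insitu, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seeds <- split_seed(cfg$seed, c("weather", "surveys", "votes", "proxy"))
  with_seed(seeds[["votes"]], {
    e <- rnorm(length(utci_insitu), 0, cfg$vote_sd)
  })
  raw <- round(cfg$vote_slope * utci_insitu + cfg$vote_intercept + e)
  as.integer(pmin(pmax(raw, -3), 3))
}

#' Derive the hourly proxy UTCI series
#'
#' Applies the extreme-damping divergence model to an hourly UTCI series:
#' `utci_proxy = centre + (1 - gain) * (utci - centre) + season_offset +
#' noise`. With `gain > 0` the proxy under-represents both heat and cold
#' extremes relative to the input series, the qualitative signature of a
#' grid-cell average compared against point measurements.
#'
#' @param hourly A tibble with columns `timestamp` and `utci_c` (the
#'   reference hourly UTCI).
#' @param cfg A [synthetic_config()].
#' @return A tibble `timestamp`, `utci_c` holding the proxy series.
#' @export
make_proxy_series <- function(hourly, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"),
            all(c("timestamp", "utci_c") %in% names(hourly)))
  seeds <- split_seed(cfg$seed, c("weather", "surveys", "votes", "proxy"))
  season <- as.character(season_of(hourly$timestamp))
  off <- cfg$proxy_season_offsets[season]
  off[is.na(off)] <- 0
  with_seed(seeds[["proxy"]], {
    noise <- rnorm(nrow(hourly), 0, cfg$proxy_noise_sd)
  })
  tibble(
    timestamp = hourly$timestamp,
    utci_c = cfg$proxy_centre_c +
      (1 - cfg$proxy_gain) * (hourly$utci_c - cfg$proxy_centre_c) +
      unname(off) + noise
  )
}

#' Simulate a complete synthetic survey campaign
#'
#' Chains the generators: hourly reference weather, the hourly proxy UTCI
#' series (reference UTCI passed through the extreme-damping divergence
#' model), per-response in-situ observations with thermal indices, and
#' thermal sensation votes. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `utci_campaign` with elements `reference`
#'   (hourly meteorology, fluxes and UTCI), `proxy` (hourly proxy UTCI),
#'   and `responses` (per-response in-situ record, thermal indices and
#'   vote `tsv`).
#' @export
simulate_campaign <- function(cfg = synthetic_config()) {
  ref <- generate_reference_series(cfg)
  ref_idx <- ref |>
    mutate(tmrt_c = mrt_from_fluxes(.data$l_dn, .data$l_up, .data$s_diffuse,
                                    .data$s_up, .data$i_star,
                                    .data$solar_elev_deg),
           utci_c = utci(.data$ta_c, .data$tmrt_c, .data$wind_ms,
                         rh = .data$rh_pct))
  proxy <- make_proxy_series(ref_idx, cfg)

  obs <- generate_insitu_observations(ref, cfg)
  obs_idx <- add_thermal_indices(obs, mrt = "globe")
  obs_idx$tsv <- generate_votes(obs_idx$utci_c, cfg)

  structure(list(reference = ref_idx, proxy = proxy, responses = obs_idx,
                 config = cfg),
            class = "utci_campaign")
}
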