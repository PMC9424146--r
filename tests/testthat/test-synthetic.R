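test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 11)
  a <- generate_reference_series(cfg)
  b <- generate_reference_series(cfg)
  expect_identical(a, b)
  oa <- generate_insitu_observations(a, cfg)
  ob <- generate_insitu_observations(a, cfg)
  expect_identical(oa, ob)
  expect_identical(generate_votes(oa_u <- seq(10, 30, length.out = 50), cfg),
                   generate_votes(oa_u, cfg))
  expect_identical(make_proxy_series(tibble::tibble(timestamp = a$timestamp,
                                                    utci_c = a$ta_c), cfg),
                   make_proxy_series(tibble::tibble(timestamp = a$timestamp,
                                                    utci_c = a$ta_c), cfg))
})

test_that("the hourly series covers the study period exactly", {
  cfg <- synthetic_config(seed = 1) # Jan 1 - Aug 31, 2009 (non-leap)
  ref <- generate_reference_series(cfg)
  expect_identical(nrow(ref), 243L * 24L) # 5832 hours
  expect_true(all(ref$rh_pct >= 0 & ref$rh_pct <= 100))
  expect_true(all(ref$wind_ms >= 0))
  expect_true(all(ref[c("i_star", "s_diffuse", "s_up", "l_dn", "l_up")] >= 0))
  expect_true(all(ref$i_star[ref$solar_elev_deg <= 0] == 0))
})

test_that("noise-free temperature is a pure annual cosine", {
  cfg <- synthetic_config(seed = 3, ar1_phi = 0, ar1_sd = 0,
                          diurnal_amp_c = 0)
  ref <- generate_reference_series(cfg)
  expect_equal(max(ref$ta_c), cfg$mean_c + cfg$annual_amp_c, tolerance = 1e-3)
  doy <- as.integer(format(ref$timestamp, "%j"))
  expect_equal(ref$ta_c,
               cfg$mean_c + cfg$annual_amp_c * cos(2 * pi * (doy - 15) / 365),
               tolerance = 1e-9)
})

test_that("survey timestamps respect the daily window and date range", {
  cfg <- tiny_config(seed = 5, n = 400L)
  ref <- generate_reference_series(cfg)
  obs <- generate_insitu_observations(ref, cfg)
  h <- as.integer(format(obs$timestamp, "%H")) +
    as.integer(format(obs$timestamp, "%M")) / 60
  expect_true(all(h >= 10 & h <= 15))
  expect_true(all(as.Date(obs$timestamp, tz = "UTC") >= cfg$start))
  expect_true(all(as.Date(obs$timestamp, tz = "UTC") <= cfg$end))
  expect_setequal(as.character(unique(obs$season)), c("fall"))
})

test_that("zero offsets and zero noise reproduce the interpolated reference", {
  cfg <- controlled_config(seed = 9, n = 200L)
  ref <- generate_reference_series(cfg)
  obs <- generate_insitu_observations(ref, cfg)
  at <- match(obs$timestamp, ref$timestamp) # surveys on the hour
  expect_false(anyNA(at))
  expect_equal(obs$ta_c, ref$ta_c[at], tolerance = 1e-9)
  expect_equal(obs$rh_pct, ref$rh_pct[at], tolerance = 1e-9)
  # sensor wind scales back up to the reference 10-m wind exactly
  expect_equal(scale_wind_to_10m(obs$wind_ms, obs$wind_height_m),
               ref$wind_ms[at], tolerance = 1e-9)
})

test_that("globe synthesis inverts the forced-convection equation", {
  # with local effects switched off, the globe reading must reproduce the
  # reference flux-based radiant temperature exactly
  cfg <- controlled_config(seed = 13, n = 150L)
  ref <- generate_reference_series(cfg)
  obs <- generate_insitu_observations(ref, cfg)
  tmrt <- mrt_from_globe(obs$globe_c, obs$ta_c, obs$wind_ms)
  at <- match(obs$timestamp, ref$timestamp)
  tmrt_ref <- mrt_from_fluxes(ref$l_dn[at], ref$l_up[at], ref$s_diffuse[at],
                              ref$s_up[at], ref$i_star[at],
                              ref$solar_elev_deg[at])
  expect_equal(tmrt, tmrt_ref, tolerance = 1e-6)
  # under the noisy defaults the inversion still returns finite values
  noisy <- generate_insitu_observations(ref, tiny_config(seed = 13, n = 150L))
  expect_true(all(is.finite(mrt_from_globe(noisy$globe_c, noisy$ta_c,
                                           noisy$wind_ms))))
})

test_that("morphology offsets shift the in-situ record by their set value", {
  off <- 2
  cfg <- synthetic_config(
    seed = 21, n_responses = 1500L,
    morphologies = tibble::tibble(morphology = "square", offset_c = off,
                                  prob = 1),
    micro_sd = 0.5, micro_rh_sd = 0, micro_wind_lnsd = 0,
    survey_on_hour = TRUE
  )
  ref <- generate_reference_series(cfg)
  obs <- generate_insitu_observations(ref, cfg)
  at <- match(obs$timestamp, ref$timestamp)
  delta <- obs$ta_c - ref$ta_c[at]
  expect_lt(abs(mean(delta) - off), 3 * sd(delta) / sqrt(length(delta)))
})

test_that("votes follow the clamped rounded linear rule", {
  cfg <- synthetic_config(seed = 2, vote_sd = 0)
  # round(0.10 * 20.2 - 2.02) = round(0) = 0
  expect_identical(generate_votes(20.2, cfg), 0L)
  expect_identical(generate_votes(60, cfg), 3L)   # clamped hot
  expect_identical(generate_votes(-60, cfg), -3L) # clamped cold
  v <- generate_votes(runif(500, -20, 60), synthetic_config(seed = 3))
  expect_true(all(v >= -3L & v <= 3L))
})

test_that("mean vote matches the discretised-normal expectation", {
  u0 <- 24; s <- 0.8
  cfg <- synthetic_config(seed = 17, vote_sd = s, n_responses = 10000L)
  v <- generate_votes(rep(u0, 10000), cfg)
  # brute-force expectation of clamp(round(mu + e)) over the normal density
  mu <- cfg$vote_slope * u0 + cfg$vote_intercept
  k <- -3:3
  lo <- ifelse(k == -3, -Inf, k - 0.5); hi <- ifelse(k == 3, Inf, k + 0.5)
  p <- pnorm(hi, mu, s) - pnorm(lo, mu, s)
  expected <- sum(k * p)
  se <- sqrt(sum(k^2 * p) - expected^2) / sqrt(10000)
  expect_lt(abs(mean(v) - expected), 3 * se)
})

test_that("the full pipeline yields finite UTCI for every generated record", {
  camp <- suppressMessages(simulate_campaign(tiny_config(seed = 29, n = 300L)))
  expect_true(all(is.finite(camp$responses$utci_c)))
  expect_true(all(is.finite(camp$reference$utci_c)))
  expect_true(all(is.finite(camp$proxy$utci_c)))
  expect_true(all(camp$responses$tsv %in% -3:3))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(ar1_phi = 1), "0, 1")
  expect_error(synthetic_config(proxy_gain = 1), "0, 1")
  expect_error(synthetic_config(n_responses = 0), "positive")
  expect_error(synthetic_config(start = "2009-06-01", end = "2009-01-01"),
               "precede")
  expect_error(synthetic_config(tau = 0), "0, 1")
  cfg <- tiny_config()
  ref <- generate_reference_series(cfg)
  outside <- cfg; outside$start <- as.Date("2008-01-01")
  expect_error(interp_ref_test(ref, as.POSIXct("2008-01-01 12:00:00",
                                               tz = "UTC")),
               "outside")
})
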