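# small deterministic campaigns for module tests
tiny_config <- function(seed = 7L, n = 120L, ...) {
  synthetic_config(seed = seed, n_responses = n,
                   start = "2009-03-01", end = "2009-04-30", ...)
}

# a controlled configuration in which the proxy-in-situ bias is exactly
# season offset + hourly proxy noise (no damping, no morphology or
# microscale effects, surveys on the hour)
controlled_config <- function(seed, n = 1640L, proxy_noise_sd = 2,
                              survey_on_hour = TRUE, ...) {
  synthetic_config(
    seed = seed, n_responses = n,
    proxy_gain = 0, proxy_noise_sd = proxy_noise_sd,
    morphologies = tibble::tibble(
      morphology = c("canyon", "crossroads", "square"),
      offset_c = c(0, 0, 0), prob = c(0.4, 0.4, 0.2)
    ),
    micro_sd = 0, micro_rh_sd = 0, micro_wind_lnsd = 0,
    survey_on_hour = survey_on_hour, ...
  )
}

paired_campaign <- function(cfg) {
  camp <- suppressMessages(simulate_campaign(cfg))
  pairs <- suppressMessages(match_to_hourly(camp$responses, camp$proxy))
  pairs$dts_proxy <- dts_from_utci(pairs$utci_proxy)
  pairs$bias <- pairs$utci_proxy - pairs$utci_insitu
  pairs
}

SIGMA_SB_TEST <- 5.67e-8

interp_ref_test <- function(ref, at) utciproxy:::interp_ref(ref, "ta_c", at)
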