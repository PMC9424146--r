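# utciproxy

Can an hourly gridded thermal-index product stand in for on-site weather
measurements during outdoor thermal comfort (OTC) surveys? Field campaigns
pair each pedestrian's thermal sensation vote (TSV, 7-point scale from −3
*cold* to +3 *hot*) with the microclimate measured next to the respondent;
when those measurements are flawed or missing, an hourly proxy series of
the **Universal Thermal Climate Index (UTCI)** is the natural backup.
`utciproxy` implements the full evaluation of that idea for researchers in
human biometeorology and urban climate: it computes the thermal indices
from raw meteorology, aligns survey votes with hourly proxy values,
quantifies proxy-versus-in-situ agreement, and derives comfort ranges from
binned votes — plus a seeded synthetic-campaign generator so the whole
pipeline is testable without any field dataset.

## The model in brief

* **UTCI** — the operational sixth-order polynomial approximation
  `UTCI = Ta + Σ c_ijkl · Ta^i · va^j · ΔTmrt^k · pa^l` in air temperature
  (°C), 10-m wind (m/s), radiant excess `ΔTmrt = Tmrt − Ta` (K) and vapour
  pressure (kPa); 210 coefficients shipped as a checksummed text table.
* **Mean radiant temperature** — from globe thermometry (ISO 7726 forced
  convection, 50-mm gray globe) for the in-situ path, or from solar and
  thermal radiation fluxes with angle factor 0.5, absorption coefficient
  0.7, body emissivity 0.97 and the standing-person projected area factor
  `f_p(γ) = 0.308·cos[γ(0.998 − γ²/50000)]` for the gridded path.
* **Alignment** — responses pair with the proxy value at the nearest clock
  hour; the interval analysis keeps pairs within `interval/2` minutes of
  the hour (60/30/15/10 min).
* **Agreement** — mean bias (proxy − in situ), SD, Pearson's r with exact
  p, extreme offsets; balanced-subset ANOVA by season and urban
  morphology; stratification by UTCI stress category and the thermal
  comfort zones (18–26 °C; adjusted 15–27 °C).
* **Comfort** — mean votes in 1-°C UTCI bins (MTSV), unweighted OLS trend
  `MTSV = a·UTCI + b`, neutral UTCI `−b/a`, comfort range at
  `MTSV = ±0.5`, thermal sensitivity `1/a`.

## Worked example

```r
library(utciproxy)

# a hot sunny street: Ta 28 degC, Tmrt 52 degC, light wind, 55 % rh
utci(ta = 28, tmrt = 52, va10 = 1.4, rh = 55)
#> [1] 34.29414        # "strong heat stress" on the assessment scale

# a full synthetic campaign: 1640 votes, Jan-Aug, surveys 10:00-15:00
camp  <- simulate_campaign(synthetic_config(seed = 2025))
pairs <- match_to_hourly(camp$responses, camp$proxy)

agreement_metrics(pairs)
#>      n mean_bias sd_bias pearson_r p_value max_positive_offset max_negative_offset
#> 1 1640    -2.233   3.675      0.83       0               9.071             -12.225

fit_comfort_model(bin_mtsv(pairs, "utci_insitu"))
#> Comfort model: MTSV = 0.1020 * UTCI -2.0437  (r = 0.987, 31 bins, 1637 votes)
#>   neutral UTCI 20.04 degC, comfort range [15.14, 24.95] degC, sensitivity 9.81 degC/MTSV
```

The agreement row reads: across 1640 paired votes the hourly proxy runs
2.2 °C UTCI cool of the in-situ record on average (its damped extremes
under-represent the hot survey hours), with a 3.7 °C spread and r = 0.83.
The comfort model recovers the vote-generating line (slope 0.10, intercept
−2.02): thermal neutrality near 20 °C UTCI, a comfort range of roughly
15–25 °C, and one full vote unit per ~10 °C UTCI.

`run_pipeline(pipeline_config(seed = 1))` chains everything and writes the
agreement-by-interval, season/morphology ANOVA, stratified-DTS and
comfort-model tables as CSV plus a JSON run manifest.

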