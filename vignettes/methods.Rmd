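---
title: "Methods: evaluating hourly proxy UTCI against in-situ thermal comfort surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating hourly proxy UTCI against in-situ thermal comfort surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utciproxy)
library(dplyr)
```

## The problem

Outdoor thermal comfort (OTC) surveys link a pedestrian's reported thermal
sensation vote (TSV, on the 7-point scale from $-3$ cold to $+3$ hot) to the
microclimate measured next to the respondent at the moment of the interview.
Portable stations fail, records go missing, and measurement protocols differ
between campaigns, so a natural question is whether an *hourly gridded proxy*
— a reanalysis-style historical reconstruction that reports the Universal
Thermal Climate Index (UTCI) for every hour at a grid cell — can stand in
for the on-site record.

`utciproxy` implements that evaluation end to end:

1. **thermal kernels** — UTCI, mean radiant temperature ($T_{mrt}$) by two
   estimators, Dynamic Thermal Sensation (DTS), stress categories;
2. **a synthetic campaign generator** — seeded, with the statistical
   structure such an evaluation assumes, so the whole pipeline is testable
   without the (unavailable) original survey data;
3. **alignment** of per-minute survey responses to hourly proxy values;
4. **agreement statistics** — bias, spread, correlation, balanced-subset
   ANOVA, thermal-stress stratification;
5. **comfort modelling** — neutral UTCI and comfort ranges from binned mean
   thermal sensation votes (MTSV).

## Thermal kernels

### UTCI

The UTCI is an equivalent temperature: the air temperature of a reference
environment that would provoke the same dynamic physiological response as
the actual environment. Operationally it is evaluated by a sixth-order
polynomial in air temperature $T_a$ (°C), 10-m wind speed $v_a$ (m/s),
radiant excess $\Delta T_{mrt} = T_{mrt} - T_a$ (K) and water vapour
pressure $p_a$ (kPa):

$$\mathrm{UTCI} = T_a + \sum_{i+j+k+l \le 6} c_{ijkl}\,
T_a^i\, v_a^j\, \Delta T_{mrt}^k\, p_a^l .$$

The 210 published coefficients ship as a plain-text exponent table
(`inst/extdata/utci_polynomial.tsv`) whose md5 checksum is verified at
load. The test suite cross-checks the table evaluator against a second,
independently hand-typed transcription of the same coefficient set written
as one explicit 210-term expression; the two agree to well below 0.01 °C on
a 336-point grid spanning the validity domain. Behavioural checks (the
index stays within 1.5 °C of $T_a$ under reference conditions — wind
0.5 m/s, $T_{mrt}=T_a$, 50 % relative humidity with vapour pressure capped
at 20 hPa — and is monotone in $T_a$ and $T_{mrt}$) guard against errors
that a duplicated typo could in principle share.

Validity handling: the polynomial is defined for $T_a \in [-50, 50]$ °C,
$\Delta T_{mrt} \in [-30, 70]$ K and $v_a \in [0.5, 17]$ m/s. Temperatures
and radiant excess outside their ranges always raise an error; wind is
clamped into its range by default (the behaviour of operational
implementations, where calm air is evaluated at the 0.5 m/s floor) and
raises only in `strict = TRUE` mode. We enforce the asymmetric
$[-30, 70]$ K radiant-excess range of the operational procedure rather
than a symmetric $\pm 70$ K band, because the approximation was never
fitted below $-30$ K.

Humidity enters through the saturation vapour pressure, computed with the
ITS-90-based formulation of Hardy — the formulation used by the operational
procedure itself (6.112 hPa at 0 °C, 23.39 hPa at 20 °C).

### Mean radiant temperature

Two estimators are provided, matching the two data sources:

* **Globe thermometry** (in-situ path): the ISO 7726 forced-convection
  equation for a globe of diameter $D$ and emissivity $\varepsilon$,
  $T_{mrt} = [(T_g+273.15)^4 + \frac{1.1\times10^8\, v_a^{0.6}}
  {\varepsilon D^{0.4}}(T_g-T_a)]^{1/4} - 273.15$, with defaults
  $D = 0.05$ m (a 50-mm globe) and $\varepsilon = 0.95$, a standard value
  for a gray-painted copper globe; both are configurable since gray paints
  vary.
* **Radiation fluxes** (gridded path): the body-centred combination of
  downwelling/upwelling thermal fluxes and diffuse/reflected/direct solar
  fluxes with angle factor $f_a = 0.5$, absorption coefficient
  $\alpha_{ir} = 0.7$, body emissivity $\varepsilon_p = 0.97$ and the
  standing-person projected area factor
  $f_p(\gamma) = 0.308\cos[\gamma(0.998-\gamma^2/50000)]$ (cosine in
  degrees), zeroed below the horizon.

All Kelvin conversions use 273.15 (some printed forms of the flux equation
write 273; the difference is below 0.15 K and we prefer the physically
exact constant).

Wind measured at sensor height (2.1 m for the emulated survey stations) is
scaled to 10 m with a neutral logarithmic profile and default roughness
length $z_0 = 0.01$ m — an open, short-grass value; urban canopy profiles
are deliberately not modelled because the survey anemometer sits in the
street canyon where any similarity profile is dubious anyway, and the same
scaling is what UTCI practice prescribes.

### DTS and stress categories

The DTS maps UTCI to a predicted vote on the same 7-point scale via
piecewise-linear interpolation of a conversion table, with clamped
extrapolation. **The shipped default table is a constructed one**
(`dts_conversion_synthetic.csv`): its nodes are anchored at the UTCI
assessment-scale category boundaries and chosen monotone in $[-3, 3]$. It
stands in for a published conversion table that we could not transcribe
verbatim; any two-column table can be supplied instead, and no quantitative
result in the package's tests depends on its exact node values.

Stress categories follow the standard UTCI assessment scale (no thermal
stress 9–26 °C, moderate heat 26–32 °C, strong heat 32–38 °C, …),
implemented as contiguous half-open intervals $[l, u)$ so every value has
exactly one category. The Thermal Comfort Zone (TCZ) is the closed interval
18–26 °C UTCI, with a locally adjusted variant 15–27 °C; both are
configurable.

## The synthetic campaign generator

The generator replaces an unavailable subtropical field dataset of 1640
responses over 14 campaigns (January–August, surveys 10:00–15:00 local
standard time, latitude $-25.43^\circ$). It is a first-class, tested module
— every study condition the original setting states is a default, and the
remaining choices were made once, on meteorological grounds:

* **Air temperature**: annual mean 17 °C with amplitude 3.8 °C (matching
  13.5–21 °C monthly means), diurnal amplitude 2.5 °C peaking at 14:00,
  plus AR(1) weather noise ($\phi = 0.8$, innovation sd 1.2 °C).
* **Cloud regime**: days are clear with probability 0.4 (broadband
  transmittance 0.85, sky emissivity 0.78, winds reduced by factor 0.45 —
  fair-weather days are calmer) or overcast (transmittance 0.25, sky
  emissivity 0.95). This two-state regime, together with a modest
  fair-weather preference in scheduling survey days (weight 2:1), produces
  the right-skewed survey UTCI distribution characteristic of urban
  campaigns: a majority of no-thermal-stress responses alongside a
  noticeable strong-heat tail (defaults give roughly 57 % / 34 % / 9 %
  none / moderate / strong heat and < 1 % cold stress).
* **Radiation**: direct beam $S_0 \tau \max(0, \sin\gamma)$ with
  $S_0 = 1361$ W/m², isotropic diffuse fraction 0.25, albedo 0.2,
  gray-body longwave up/down with ground warming up to 2 K at full sun;
  solar elevation from a declination/hour-angle formula.
* **Microclimate**: morphology offsets (canyon $+0.9$, crossroads $-0.2$,
  square $+1.5$ °C) and microscale noise (sd 1 °C) added to the in-situ
  air and radiant temperatures; the globe temperature is synthesised by
  *inverting* the forced-convection equation so the globe path recovers
  the intended $T_{mrt}$ exactly.
* **Proxy divergence**: the hourly proxy is
  $c + (1-g)(\mathrm{UTCI}-c) + \delta_{season} + \epsilon$ with damping
  gain $g = 0.3$ about $c = 20$ °C, seasonal offsets
  $(-3.65, -0.84, +1.10)$ °C for summer/fall/winter and noise sd 1.5 °C.
  The damping dominates the noise by design — that is what makes the proxy
  under-represent both heat and cold extremes, and (because the vote axis
  is compressed) steepens the proxy-based MTSV trend line relative to the
  in-situ one in the large majority of seeds.
* **Votes**: $\mathrm{tsv} = \mathrm{clamp}(\mathrm{round}(0.10\,
  \mathrm{UTCI} - 2.02 + e), -3, 3)$, $e \sim N(0, 0.8)$.

One RNG stream per generator (weather, surveys, votes, proxy) is split from
the master seed, so drawing more surveys never perturbs the weather.

**What passing tests do and do not show.** The generator emulates harmonic
climate + AR(1) noise, a two-state sky, and a linear vote model; it has no
fronts, no rain, no autocorrelated survey behaviour, no respondent
covariates, and a single grid cell. Green tests therefore demonstrate that
the *statistical machinery* recovers known structure under realistic noise
— not that any real proxy product has these error characteristics.

## Alignment

Responses are paired with the proxy value at the nearest clock hour (no
interpolation); an exact half-hour rounds up, deterministically. Responses
whose nearest hour is missing from the proxy series are dropped and
counted. The interval analysis keeps pairs with
$|\text{minutes to hour}| \le \mathrm{interval}/2$ with the boundary
included, so the 60-minute interval is exactly "all data" and subsets nest:
under uniformly distributed survey minutes the expected retained fractions
at 60/30/15/10 minutes are $1, 1/2, 1/4, 1/6$.

## Agreement statistics

The metric set per paired dataset: $n$, mean bias (**proxy minus in situ,
everywhere in this package**, asserted by a canary test), sample SD of the
bias, Pearson's $r$ between the two series with its exact two-sided
$t$-test $p$-value, and the maximum positive/negative offsets. A
zero-variance series yields an *undefined* correlation, reported as `NA`
rather than 0.

Seasonal and morphology effects on the bias are tested with a
fixed-effects ANOVA after balancing: every group is randomly subsampled
(seeded, without replacement) to the smallest group's size. The original
"two-factor" construction with an "interaction against the pooled sample"
row cannot be reproduced as printed — a pooled-vs-subset contrast is not an
interaction in a standard two-way layout — so the package reports (a) the
one-way ANOVA across the primary factor and (b) an ordinary two-way
season × morphology ANOVA with interaction when a second factor is given.
Raw $p$-values are always reported; significance thresholds are a
presentation choice.

Stratification of the DTS comparison uses the *in-situ* UTCI to define the
stratum (the proxy-based alternative is a flag), because the in-situ value
is the reference measurement; strata with fewer than `min_n` pairs are
flagged rather than suppressed.

In controlled recovery experiments the proxy noise is drawn once per clock
hour, so responses within the same hour share a draw; standard errors in
those experiments are computed over hour-level means, the actual
independent unit.

## Comfort model

Votes are grouped into half-open 1-°C UTCI bins $[k, k+1)$ anchored at
integer degrees; bins with fewer than 3 votes are dropped (all three
choices are configurable; the origin and the half-open convention are
arbitrary but fixed, and `min_count = 3` keeps the tail bins that carry
the heat-stress information while discarding singletons). The mean vote
per bin (MTSV) is regressed on the bin centre by unweighted ordinary least
squares — unweighted because the method being emulated fits a trend line
to the binned points as such; count-weighted OLS and the vote-weighted bin
mean are available behind flags. From $\mathrm{MTSV} = a\,\mathrm{UTCI} +
b$:

* neutral UTCI $= -b/a$;
* comfort range: solutions of $\mathrm{MTSV} = \mp 0.5$, hence exactly
  $\mathrm{neutral} \mp 0.5/a$;
* thermal sensitivity $= 1/a$ °C per MTSV unit.

Thresholds are withheld (returned `NA`) unless the slope is positive and
significant at the one-sided 5 % level; an exact fit with zero residual
variance counts as significant since its slope is not in doubt.

## Numerical choices and degenerate inputs

* Globe-equation inversion uses damped-free Newton iterations on a
  strictly increasing quartic; 50 iterations at tolerance $10^{-10}$ K.
* `round()` ties in the vote model occur with probability zero under
  continuous noise; the noise-free edge case follows R's default rounding.
* Empty strata are reported with $n = 0$; ANOVA on identical group
  distributions returns $F = 0$, $p = 1$; correlation on fewer than two
  pairs is an error, on constant series `NA`.
* All timestamps are fixed-offset local standard time (no daylight-saving
  logic — appropriate for the emulated setting and documented for users
  elsewhere).

## Problem sizes

The shipped tests and the acceptance script use the sizes the analysis
naturally needs: full 5832-hour reference series, campaigns of 1600–1640
responses, 50-seed recovery ensembles for the comfort model, 100-replicate
power and 1000-replicate type-I checks for the ANOVA, and a 336-point grid
for the polynomial cross-check. A complete end-to-end pipeline run takes a
few seconds on one CPU.

## Known limitations

* The default DTS table is constructed, not transcribed; DTS-level numbers
  change (monotonically) under a different table.
* The polynomial cross-check is a dual transcription, not a comparison
  against an external implementation; an identical digit error in both
  transcriptions would evade it (behavioural tests reduce, but cannot
  eliminate, that risk).
* The generator's proxy error model is stationary within seasons; real
  gridded products have flow-dependent error structure.
* No Bland–Altman limits of agreement, no probit comfort-zone estimation —
  natural extensions outside the emulated method set.
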