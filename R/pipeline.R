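#' Pipeline configuration
#'
#' Collects every option of the end-to-end evaluation: the input source
#' (CSV paths, or a [synthetic_config()] when no paths are given), the
#' rounding intervals, the balancing seed for the ANOVA subsets, the
#' category scale, the DTS table and the comfort-fit options.
#'
#' @param seed Master seed; also the default seed of the synthetic
#'   campaign and the balancing procedure.
#' @param out_dir Output directory for the report files.
#' @param survey_csv,meteo_csv,proxy_csv Optional input paths; when `NULL`
#'   a synthetic campaign is generated from `synthetic`.
#' @param synthetic A [synthetic_config()] used when no input paths are
#'   given.
#' @param intervals Rounding intervals in minutes for the interval
#'   analysis.
#' @param balance_seed Seed of the subset-balancing randomisation.
#' @param scale Stress-category scale.
#' @param dts_table DTS conversion table.
#' @param bin_min_count Minimum votes per retained MTSV bin.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("utciproxy-run-"),
                            survey_csv = NULL, meteo_csv = NULL,
                            proxy_csv = NULL,
                            synthetic = synthetic_config(seed = seed),
                            intervals = c(60, 30, 15, 10),
                            balance_seed = seed,
                            scale = utci_stress_scale(),
                            dts_table = dts_conversion_table(),
                            bin_min_count = 3L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full proxy-evaluation pipeline
#'
#' Chains simulate (or read) -> compute thermal indices -> align to the
#' hourly proxy -> agreement by rounding interval -> balanced-subset
#' ANOVAs by season and morphology -> stratified DTS report -> comfort
#' models, and writes one CSV per report table plus a JSON run manifest
#' (seeds, configuration hash, dropped-response counts, versions) to
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with elements `pairs`,
#'   `agreement_by_interval`, `anova_seasons`, `anova_morphology`,
#'   `dts_stratified`, `comfort_models` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  # --- inputs -------------------------------------------------------------
  if (is.null(config$survey_csv)) {
    campaign <- simulate_campaign(config$synthetic)
    responses <- campaign$responses
    proxy <- campaign$proxy
  } else {
    survey <- read_survey_csv(config$survey_csv)
    meteo <- read_meteo_csv(config$meteo_csv)
    joined <- left_join(survey, meteo, by = "timestamp")
    if (any(is.na(joined$ta_c))) {
      abort("stage input: some survey timestamps have no meteorological record.")
    }
    responses <- add_thermal_indices(joined, mrt = "globe",
                                     dts_table = config$dts_table,
                                     scale = config$scale)
    proxy <- read_proxy_csv(config$proxy_csv)
  }

  # --- alignment ----------------------------------------------------------
  pairs <- match_to_hourly(responses, proxy)
  pairs$dts_proxy <- dts_from_utci(pairs$utci_proxy, table = config$dts_table)
  pairs$bias <- pairs$utci_proxy - pairs$utci_insitu
  n_dropped <- attr(pairs, "n_dropped") %||% 0L

  # --- agreement across rounding intervals (interval-analysis table) ------
  agreement_by_interval <- map_dfr(config$intervals, function(iv) {
    sub <- subset_by_interval(pairs, iv)
    bind_cols(tibble(interval_min = iv), agreement_metrics(sub))
  })

  # --- balanced-subset ANOVAs (season / morphology tables) ----------------
  tidy_anova <- function(av) {
    bind_rows(
      av$group_means |>
        mutate(term = as.character(.data$group), .keep = "unused") |>
        select("term", "n", "mean_bias", "sd_bias"),
      av$anova_table |>
        select("term", statistic_f = "statistic", p_value = "p_value")
    )
  }
  bal_season <- balance_subsets(pairs, "season", seed = config$balance_seed)
  anova_seasons <- anova_bias(bal_season, "season")
  bal_morph <- balance_subsets(pairs, "morphology", seed = config$balance_seed)
  anova_morphology <- anova_bias(bal_morph, "morphology")

  # --- stratified DTS report ----------------------------------------------
  dts_stratified <- stratified_dts_report(pairs, scale = config$scale)

  # --- comfort models ------------------------------------------------------
  comfort_models <- map_dfr(c(insitu = "utci_insitu", proxy = "utci_proxy"),
                            function(col) {
    bins <- bin_mtsv(pairs, utci_col = col, min_count = config$bin_min_count)
    glance(fit_comfort_model(bins))
  }, .id = "dataset")

  # --- outputs -------------------------------------------------------------
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  outs <- list(
    agreement_by_interval = agreement_by_interval,
    anova_seasons = tidy_anova(anova_seasons),
    anova_morphology = tidy_anova(anova_morphology),
    dts_stratified = dts_stratified,
    comfort_models = comfort_models
  )
  for (nm in names(outs)) {
    readr::write_csv(outs[[nm]], file.path(config$out_dir, paste0(nm, ".csv")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("utciproxy")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    balance_seed = config$balance_seed,
    synthetic_seed = if (is.null(config$survey_csv)) config$synthetic$seed else NULL,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_responses = nrow(responses),
    n_pairs = nrow(pairs),
    n_dropped_missing_hour = n_dropped,
    intervals = config$intervals
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(c(list(pairs = pairs), outs,
              list(anova_seasons_fit = anova_seasons,
                   anova_morphology_fit = anova_morphology,
                   manifest = manifest)))
}
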