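#' Pair survey responses with an hourly proxy series
#'
#' Rounds each response timestamp to the nearest clock hour (an exact
#' half-hour rounds up to the later hour) and attaches the proxy value at
#' that hour — no temporal interpolation. Responses whose nearest hour is
#' absent from the proxy series are dropped; the number dropped is
#' recorded in the `n_dropped` attribute and reported via a message.
#'
#' @param responses A data frame with a `timestamp` column (plus any
#'   response-level columns to carry through, e.g. `tsv`, `utci_c`).
#' @param proxy An hourly proxy series with columns `timestamp` and
#'   `utci_c`.
#' @return A tibble: all columns of `responses` (with the in-situ UTCI
#'   column, if named `utci_c`, renamed to `utci_insitu`), plus
#'   `minutes_from_hour` (absolute distance to the nearest hour, 0-30),
#'   `nearest_hour` and `utci_proxy`.
#' @export
match_to_hourly <- function(responses, proxy) {
  if (nrow(proxy) == 0) abort("the proxy series is empty.")
  if (!all(c("timestamp", "utci_c") %in% names(proxy))) {
    abort("`proxy` must have columns `timestamp` and `utci_c`.")
  }
  responses <- as_tibble(responses)
  secs <- as.numeric(responses$timestamp)
  within <- secs %% 3600
  # round-half-up: exactly 30 minutes past goes to the later hour
  nearest <- ifelse(within < 1800, secs - within, secs - within + 3600)
  minutes_from_hour <- pmin(within, 3600 - within) / 60

  out <- responses
  if ("utci_c" %in% names(out)) {
    out <- rename(out, utci_insitu = "utci_c")
  }
  if ("dts" %in% names(out)) {
    out <- rename(out, dts_insitu = "dts")
  }
  out$minutes_from_hour <- minutes_from_hour
  out$nearest_hour <- as.POSIXct(nearest, origin = "1970-01-01", tz = "UTC")

  prox <- tibble(nearest_hour = proxy$timestamp, utci_proxy = proxy$utci_c)
  out <- left_join(out, prox, by = "nearest_hour")
  n_dropped <- sum(is.na(out$utci_proxy))
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " response(s) dropped: nearest hour missing from the proxy series."))
    out <- filter(out, !is.na(.data$utci_proxy))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Subset paired samples by distance to the clock hour
#'
#' Keeps pairs whose timestamp lies within `interval_minutes / 2` of the
#' nearest hour (boundary included), mirroring the gradual reduction of a
#' survey sample to responses taken close to the hour. The 60-minute
#' interval keeps all pairs; the canonical intervals are 60, 30, 15 and
#' 10 minutes, but any positive interval is accepted with a warning.
#'
#' @param pairs Output of [match_to_hourly()].
#' @param interval_minutes Rounding interval, minutes.
#' @return The filtered tibble; subsets are nested across decreasing
#'   intervals.
#' @export
subset_by_interval <- function(pairs, interval_minutes) {
  if (!is.numeric(interval_minutes) || length(interval_minutes) != 1 ||
      interval_minutes <= 0) {
    abort("`interval_minutes` must be a single positive number.")
  }
  if (!interval_minutes %in% c(60, 30, 15, 10)) {
    warn(paste0("non-canonical rounding interval ", interval_minutes,
                " min (canonical: 60, 30, 15, 10)."))
  }
  filter(pairs, .data$minutes_from_hour <= interval_minutes / 2)
}
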