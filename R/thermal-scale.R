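#' UTCI thermal-stress assessment scale
#'
#' Returns the ordered category scale used to stratify UTCI values, as a
#' tibble of contiguous half-open intervals `[lower, upper)` covering the
#' real line, together with the Thermal Comfort Zone (TCZ) bounds carried
#' as attributes. Defaults follow the standard UTCI assessment scale
#' (extreme cold below -40 degC up to extreme heat above +46 degC) with a
#' TCZ of 18-26 degC UTCI and a locally adjusted TCZ of 15-27 degC.
#'
#' @param boundaries Numeric vector of interior category boundaries, degC,
#'   strictly increasing, one fewer than `labels`.
#' @param labels Category labels, ordered cold to hot.
#' @param tcz Length-2 numeric, TCZ bounds (closed interval), degC.
#' @param tcz_adjusted Length-2 numeric, adjusted TCZ bounds, degC.
#' @return A tibble with columns `lower`, `upper`, `label`; attributes
#'   `tcz` and `tcz_adjusted`.
#' @export
utci_stress_scale <- function(boundaries = c(-40, -27, -13, 0, 9, 26, 32, 38, 46),
                              labels = c("extreme cold stress",
                                         "very strong cold stress",
                                         "strong cold stress",
                                         "moderate cold stress",
                                         "slight cold stress",
                                         "no thermal stress",
                                         "moderate heat stress",
                                         "strong heat stress",
                                         "very strong heat stress",
                                         "extreme heat stress"),
                              tcz = c(18, 26),
                              tcz_adjusted = c(15, 27)) {
  if (length(labels) != length(boundaries) + 1L) {
    abort("`labels` must have exactly one more element than `boundaries`.")
  }
  if (any(diff(boundaries) <= 0)) abort("`boundaries` must be strictly increasing.")
  scale <- tibble(
    lower = c(-Inf, boundaries),
    upper = c(boundaries, Inf),
    label = labels
  )
  attr(scale, "tcz") <- sort(tcz)
  attr(scale, "tcz_adjusted") <- sort(tcz_adjusted)
  scale
}

#' Classify UTCI values into thermal-stress categories
#'
#' Each value falls in exactly one half-open interval `[lower, upper)` of
#' the scale.
#'
#' @param u UTCI values, degC.
#' @param scale A scale from [utci_stress_scale()].
#' @return A factor with the scale's labels as ordered levels.
#' @export
utci_category <- function(u, scale = utci_stress_scale()) {
  idx <- findInterval(u, c(scale$lower[1], scale$upper))
  idx[idx == 0L] <- 1L # -Inf lower edge
  factor(scale$label[idx], levels = scale$label)
}

#' Thermal Comfort Zone membership
#'
#' Closed-interval membership tests for the Thermal Comfort Zone
#' (default 18-26 degC UTCI) and a locally adjusted comfort zone
#' (default 15-27 degC UTCI).
#'
#' @param u UTCI values, degC.
#' @param scale A scale from [utci_stress_scale()] carrying the zone
#'   bounds.
#' @return Logical vector.
#' @export
in_tcz <- function(u, scale = utci_stress_scale()) {
  b <- attr(scale, "tcz")
  u >= b[1] & u <= b[2]
}

#' @rdname in_tcz
#' @export
in_adjusted_tcz <- function(u, scale = utci_stress_scale()) {
  b <- attr(scale, "tcz_adjusted")
  u >= b[1] & u <= b[2]
}
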