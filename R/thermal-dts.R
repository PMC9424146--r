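#' UTCI-to-DTS conversion table
#'
#' The Dynamic Thermal Sensation (DTS) translates a UTCI value into a
#' predicted thermal vote on the 7-point (-3..+3) scale. The package maps
#' UTCI to DTS by piecewise-linear interpolation between the nodes of a
#' conversion table.
#'
#' The default table shipped in
#' `inst/extdata/dts_conversion_synthetic.csv` is a constructed
#' (synthetic) monotone table anchored at the boundaries of the UTCI
#' assessment scale — it is a package default standing in for a published
#' conversion table and can be replaced by any user-supplied table with
#' the same two-column layout.
#'
#' @param path Optional path to a CSV with columns `utci_c`, `dts`
#'   (UTCI nodes strictly increasing, DTS nondecreasing in \[-3, 3\]).
#' @return A tibble with columns `utci_c` and `dts`.
#' @export
dts_conversion_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dts_conversion_synthetic.csv",
                        package = "utciproxy")
  }
  tab <- readr::read_csv(path, col_types = readr::cols(
    utci_c = readr::col_double(), dts = readr::col_double()
  ))
  validate_dts_table(tab)
  tab
}

validate_dts_table <- function(tab) {
  if (!all(c("utci_c", "dts") %in% names(tab)) || nrow(tab) < 2) {
    abort("DTS conversion table needs >= 2 rows with columns `utci_c`, `dts`.")
  }
  if (any(diff(tab$utci_c) <= 0)) {
    abort("DTS conversion table: `utci_c` nodes must be strictly increasing.")
  }
  if (any(diff(tab$dts) < 0)) {
    abort("DTS conversion table: `dts` values must be nondecreasing.")
  }
  if (any(tab$dts < -3 | tab$dts > 3)) {
    abort("DTS conversion table: `dts` must lie in [-3, 3].")
  }
  invisible(tab)
}

#' Dynamic Thermal Sensation from UTCI
#'
#' Piecewise-linear interpolation of the conversion table; outside the
#' node range the endpoint DTS is carried forward (clamped
#' extrapolation). Output always lies in \[-3, 3\].
#'
#' @param u UTCI values, degC.
#' @param table Conversion table, see [dts_conversion_table()].
#' @return DTS values on the continuous -3..+3 scale.
#' @export
dts_from_utci <- function(u, table = dts_conversion_table()) {
  validate_dts_table(table)
  approx(table$utci_c, table$dts, xout = u, rule = 2)$y
}
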