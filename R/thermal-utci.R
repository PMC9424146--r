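# cache for the polynomial coefficient table
.utci_env <- new.env(parent = emptyenv())

# md5 of the shipped coefficient file; guards against accidental edits
UTCI_COEF_MD5 <- "572c734bc01ccb11abd1845e37174b81"

#' Coefficients of the operational UTCI polynomial
#'
#' Loads (and caches) the 210-term sixth-order polynomial approximation of
#' the UTCI offset, shipped as a plain-text exponent table. Each row gives
#' the exponents of air temperature (`ta`, degC), 10-m wind speed (`va`,
#' m/s), the radiant excess `dtmrt = Tmrt - Ta` (K) and water vapour
#' pressure (`pa`, kPa), plus the term coefficient. The file's md5 checksum
#' is verified on first load.
#'
#' @return A data frame with columns `ta`, `va`, `dtmrt`, `pa`, `coef`.
#' @export
utci_coefficients <- function() {
  if (is.null(.utci_env$coefs)) {
    path <- system.file("extdata", "utci_polynomial.tsv", package = "utciproxy")
    if (!nzchar(path)) abort("UTCI coefficient file not found in the installed package.")
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, UTCI_COEF_MD5)) {
      abort(paste0("UTCI coefficient file checksum mismatch (", md5, ")."))
    }
    tab <- read.table(path, header = TRUE, colClasses = "numeric")
    stopifnot(nrow(tab) == 210L)
    .utci_env$coefs <- tab
  }
  .utci_env$coefs
}

#' Universal Thermal Climate Index (operational approximation)
#'
#' Evaluates the sixth-order polynomial approximation of the UTCI from air
#' temperature, mean radiant temperature, 10-m wind speed and humidity
#' (given either as relative humidity or directly as vapour pressure).
#'
#' The approximation is defined for `ta` in \[-50, 50\] degC,
#' `tmrt - ta` in \[-30, 70\] K and `va10` in \[0.5, 17\] m/s. By default
#' (`strict = FALSE`) wind speeds are clamped into that interval — the
#' behaviour of operational implementations — while air temperature and
#' radiant excess outside their ranges raise an error in either mode.
#' With `strict = TRUE` out-of-range wind also raises.
#'
#' @param ta Air temperature, degC.
#' @param tmrt Mean radiant temperature, degC.
#' @param va10 Wind speed at 10 m, m/s.
#' @param rh Relative humidity, percent. Exactly one of `rh`/`pa_hpa` must
#'   be supplied.
#' @param pa_hpa Water vapour pressure, hPa.
#' @param strict If `TRUE`, out-of-range wind raises instead of clamping.
#' @return UTCI, degC (equivalent temperature).
#' @examples
#' utci(ta = 25, tmrt = 25, va10 = 1, rh = 50) # ~24.6
#' @export
utci <- function(ta, tmrt, va10, rh = NULL, pa_hpa = NULL, strict = FALSE) {
  if (is.null(rh) == is.null(pa_hpa)) {
    abort("supply exactly one of `rh` or `pa_hpa`.")
  }
  if (is.null(pa_hpa)) pa_hpa <- vapour_pressure(ta, rh)

  if (any(ta < -50 | ta > 50, na.rm = TRUE)) {
    abort("`ta` outside the UTCI validity range [-50, 50] degC.")
  }
  d <- tmrt - ta
  if (any(d < -30 | d > 70, na.rm = TRUE)) {
    abort("`tmrt - ta` outside the UTCI validity range [-30, 70] K.")
  }
  if (strict) {
    if (any(va10 < 0.5 | va10 > 17, na.rm = TRUE)) {
      abort("`va10` outside the UTCI validity range [0.5, 17] m/s (strict mode).")
    }
  } else {
    va10 <- pmin(pmax(va10, 0.5), 17)
  }

  pa_kpa <- pa_hpa / 10
  tab <- utci_coefficients()

  n <- max(length(ta), length(d), length(va10), length(pa_kpa))
  ta <- rep_len(ta, n); d <- rep_len(d, n)
  va10 <- rep_len(va10, n); pa_kpa <- rep_len(pa_kpa, n)

  # powers 0..6 of each regressor, reused across the 210 terms
  pow <- function(x) lapply(0:6, function(k) x^k)
  p_ta <- pow(ta); p_va <- pow(va10); p_d <- pow(d); p_pa <- pow(pa_kpa)

  offset <- numeric(n)
  for (r in seq_len(nrow(tab))) {
    offset <- offset + tab$coef[r] *
      p_ta[[tab$ta[r] + 1L]] * p_va[[tab$va[r] + 1L]] *
      p_d[[tab$dtmrt[r] + 1L]] * p_pa[[tab$pa[r] + 1L]]
  }
  ta + offset
}
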