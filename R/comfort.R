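#' Bin thermal sensation votes by UTCI
#'
#' Groups votes into half-open 1-degC UTCI bins `[k, k+1)` (origin at an
#' integer degC by default) and computes the mean thermal sensation vote
#' (MTSV) per bin. Bins with fewer than `min_count` votes are dropped and
#' reported via a message.
#'
#' @param pairs A data frame with a vote column `tsv` and a UTCI column.
#' @param utci_col Name of the UTCI column to bin on (e.g. `utci_insitu`
#'   or `utci_proxy`).
#' @param bin_width Bin width in degC (default 1).
#' @param origin Bin origin, degC (default 0: bins at integer degC).
#' @param min_count Minimum votes for a bin to be retained (default 3).
#' @return A tibble `bin_lower`, `bin_centre`, `bin_mean_utci`
#'   (vote-weighted mean UTCI within the bin), `n`, `mtsv`, ordered by
#'   bin.
#' @export
bin_mtsv <- function(pairs, utci_col = "utci_insitu", bin_width = 1,
                     origin = 0, min_count = 3L) {
  if (nrow(pairs) == 0) abort("`pairs` is empty.")
  if (!utci_col %in% names(pairs)) {
    abort(paste0("no column `", utci_col, "` in `pairs`."))
  }
  u <- pairs[[utci_col]]
  bins <- tibble(u = u, tsv = pairs$tsv,
                 bin_lower = origin + bin_width * floor((u - origin) / bin_width)) |>
    group_by(.data$bin_lower) |>
    summarise(n = n(), mtsv = mean(.data$tsv), bin_mean_utci = mean(.data$u),
              .groups = "drop") |>
    mutate(bin_centre = .data$bin_lower + bin_width / 2) |>
    arrange(.data$bin_lower) |>
    select("bin_lower", "bin_centre", "bin_mean_utci", "n", "mtsv")
  dropped <- sum(bins$n < min_count)
  if (dropped > 0) {
    inform(paste0(dropped, " bin(s) dropped with fewer than ", min_count,
                  " votes."))
  }
  filter(bins, .data$n >= min_count)
}

#' Fit the linear comfort model to binned votes
#'
#' Ordinary least squares of mean thermal sensation vote on UTCI
#' (unweighted over bins by default, reflecting a trend line fitted to
#' binned MTSV points). From the fitted line `MTSV = a * UTCI + b` the
#' model derives the neutral UTCI (`-b/a`, where the line crosses
#' MTSV = 0), the comfort-range thresholds solving `MTSV = -0.5` and
#' `MTSV = +0.5`, and the thermal sensitivity `1/a` — the change in degC
#' UTCI needed for one unit change in MTSV.
#'
#' Thresholds are only derived when the slope is positive and
#' statistically distinguishable from zero (one-sided t-test at
#' `alpha`); otherwise they are `NA` and the model is marked degenerate.
#'
#' @param bins Output of [bin_mtsv()] (>= 3 retained bins).
#' @param x Which x to regress on: `"bin_centre"` (default) or
#'   `"bin_mean_utci"` (vote-weighted bin mean).
#' @param weighted If `TRUE`, weight bins by their vote count.
#' @param alpha Significance level for the positive-slope requirement.
#' @return An object of class `comfort_model` with elements `slope`,
#'   `intercept`, `pearson_r`, `neutral_utci`, `lower_threshold`,
#'   `upper_threshold`, `thermal_sensitivity`, `n_bins`, `n_votes`,
#'   `thresholds_defined` and the underlying `fit`.
#' @examples
#' bins <- tibble::tibble(bin_centre = c(15.5, 18.5, 21.5, 24.5),
#'                        bin_mean_utci = c(15.5, 18.5, 21.5, 24.5),
#'                        n = c(10, 10, 10, 10),
#'                        mtsv = 0.2 * c(15.5, 18.5, 21.5, 24.5) - 4)
#' fit_comfort_model(bins) # neutral 20, thresholds 17.5 / 22.5
#' @export
fit_comfort_model <- function(bins, x = c("bin_centre", "bin_mean_utci"),
                              weighted = FALSE, alpha = 0.05) {
  x <- match.arg(x)
  if (nrow(bins) < 3) abort("at least 3 retained bins are required.")
  d <- tibble(x = bins[[x]], y = bins$mtsv, w = bins$n)
  fit <- if (weighted) lm(y ~ x, data = d, weights = w) else lm(y ~ x, data = d)
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  r <- if (sd(d$x) == 0 || sd(d$y) == 0) NA_real_ else cor(d$x, d$y)

  # one-sided test of slope > 0; an exact fit (zero residual variance with a
  # positive slope) counts as significant
  sm <- suppressWarnings(summary(fit))$coefficients # exact fits warn
  se <- sm[2, 2]
  p_pos <- if (!is.finite(se) || se == 0) {
    if (a > 0) 0 else 1
  } else {
    pt(a / se, df = fit$df.residual, lower.tail = FALSE)
  }
  ok <- is.finite(a) && a > 0 && p_pos < alpha

  neutral <- if (a != 0) -b / a else NA_real_
  structure(list(
    slope = a, intercept = b, pearson_r = r,
    neutral_utci = neutral,
    lower_threshold = if (ok) (-0.5 - b) / a else NA_real_,
    upper_threshold = if (ok) (0.5 - b) / a else NA_real_,
    thermal_sensitivity = if (ok) 1 / a else NA_real_,
    thresholds_defined = ok,
    slope_p_one_sided = p_pos,
    n_bins = nrow(bins), n_votes = sum(bins$n),
    x_var = x, weighted = weighted,
    fit = fit
  ), class = "comfort_model")
}

#' @export
print.comfort_model <- function(x, ...) {
  cat(sprintf("Comfort model: MTSV = %.4f * UTCI %+.4f  (r = %.3f, %d bins, %d votes)\n",
              x$slope, x$intercept, x$pearson_r, x$n_bins, x$n_votes))
  if (x$thresholds_defined) {
    cat(sprintf("  neutral UTCI %.2f degC, comfort range [%.2f, %.2f] degC, sensitivity %.2f degC/MTSV\n",
                x$neutral_utci, x$lower_threshold, x$upper_threshold,
                x$thermal_sensitivity))
  } else {
    cat("  thresholds undefined (slope not significantly positive)\n")
  }
  invisible(x)
}

#' @method tidy comfort_model
#' @export
tidy.comfort_model <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = c("(Intercept)", "utci"),
         estimate = unname(sm[, 1]),
         std_error = unname(sm[, 2]),
         statistic = unname(sm[, 3]),
         p_value = unname(sm[, 4]))
}

#' @method glance comfort_model
#' @export
glance.comfort_model <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, pearson_r = x$pearson_r,
         neutral_utci = x$neutral_utci,
         lower_threshold = x$lower_threshold,
         upper_threshold = x$upper_threshold,
         thermal_sensitivity = x$thermal_sensitivity,
         thresholds_defined = x$thresholds_defined,
         n_bins = x$n_bins, n_votes = x$n_votes)
}

#' @method autoplot comfort_model
#' @export
autoplot.comfort_model <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::geom_hline(yintercept = c(-0.5, 0, 0.5), linetype = "dotted") +
    ggplot2::labs(x = "UTCI (degC)", y = "MTSV",
                  title = sprintf("MTSV = %.2f UTCI %+.2f", object$slope,
                                  object$intercept)) +
    ggplot2::theme_minimal()
}
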