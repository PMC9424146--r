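#' Proxy-versus-in-situ agreement metrics
#'
#' Computes the evaluation-metric set for one paired dataset (or stratum):
#' sample size, mean bias (proxy minus in situ, by convention,
#' everywhere in this package), the sample standard deviation of the bias,
#' Pearson's r between proxy and in-situ values with its exact two-sided
#' t-test p-value, and the maximum positive and negative offsets.
#'
#' @param pairs A data frame of paired samples.
#' @param insitu_col,proxy_col Names of the in-situ and proxy value
#'   columns (defaults `utci_insitu`, `utci_proxy`).
#' @return A one-row tibble: `n`, `mean_bias`, `sd_bias`, `pearson_r`,
#'   `p_value`, `max_positive_offset`, `max_negative_offset`. When either
#'   series has zero variance the correlation is undefined and reported as
#'   `NA` (not 0).
#' @examples
#' pairs <- tibble::tibble(utci_insitu = c(20, 25, 30),
#'                         utci_proxy = c(19, 24, 32))
#' agreement_metrics(pairs)
#' @export
agreement_metrics <- function(pairs, insitu_col = "utci_insitu",
                              proxy_col = "utci_proxy") {
  x <- pairs[[insitu_col]]; y <- pairs[[proxy_col]]
  if (is.null(x) || is.null(y)) {
    abort("`pairs` must contain the in-situ and proxy value columns.")
  }
  if (length(x) < 2) abort("at least 2 paired samples are required.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("paired values must be finite.")
  }
  bias <- y - x
  if (sd(x) == 0 || sd(y) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(y, x, method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  tibble(
    n = length(bias),
    mean_bias = mean(bias),
    sd_bias = sd(bias),
    pearson_r = r,
    p_value = p,
    max_positive_offset = max(bias),
    max_negative_offset = min(bias)
  )
}

#' Balance groups by random subsampling to the smallest group
#'
#' Reduces every group to the size of the smallest one by seeded random
#' subsampling without replacement, producing the balanced design required
#' by a fixed-effects ANOVA on unequal survey subsets. The input rows are
#' never modified — only a subset is returned.
#'
#' @param data A data frame.
#' @param group Name of the grouping column.
#' @param seed Integer balancing seed; the selection is deterministic
#'   given the seed.
#' @return A tibble in which every group has exactly
#'   `min(table(data[[group]]))` rows; attribute `balance_seed` records
#'   the seed.
#' @export
balance_subsets <- function(data, group, seed = 1L) {
  if (!group %in% names(data)) abort(paste0("no column `", group, "` in `data`."))
  counts <- table(as.character(data[[group]]))
  if (length(counts) < 2) abort("at least 2 non-empty groups are required.")
  if (any(counts == 0)) {
    abort(paste0("empty group: ", names(counts)[counts == 0][1], "."))
  }
  target <- min(counts)
  data <- as_tibble(data)
  idx_by_group <- split(seq_len(nrow(data)), as.character(data[[group]]))
  keep <- with_seed(seed, {
    unlist(lapply(idx_by_group, function(ix) {
      if (length(ix) == target) ix else sort(sample(ix, target))
    }), use.names = FALSE)
  })
  out <- data[sort(keep), ]
  attr(out, "balance_seed") <- as.integer(seed)
  out
}

#' ANOVA on the proxy-minus-in-situ bias across groups
#'
#' Fits a fixed-effects analysis of variance on the per-response bias.
#' With one factor this is a one-way ANOVA across its levels; with a
#' second factor a standard two-way ANOVA with interaction
#' (`bias ~ f1 * f2`) is fitted. Per-group sample sizes and mean biases
#' are reported alongside the F table. Intended to be run on the output of
#' [balance_subsets()] so the design is balanced.
#'
#' @param data A data frame of paired samples carrying a bias column.
#' @param factor1 Name of the primary factor column.
#' @param factor2 Optional name of a second factor column.
#' @param bias_col Name of the bias column; if absent and both UTCI
#'   columns are present the bias (proxy minus in situ) is computed.
#' @return An object of class `bias_anova`: a list with `group_means`
#'   (tibble of n and mean bias per level of `factor1`), `anova_table`
#'   (tidy F table), `formula`, and `balance_seed` (carried over from
#'   [balance_subsets()], if any).
#' @export
anova_bias <- function(data, factor1, factor2 = NULL, bias_col = "bias") {
  if (!factor1 %in% names(data)) abort(paste0("no column `", factor1, "`."))
  if (!is.null(factor2) && !factor2 %in% names(data)) {
    abort(paste0("no column `", factor2, "`."))
  }
  if (!bias_col %in% names(data)) {
    if (all(c("utci_insitu", "utci_proxy") %in% names(data))) {
      data[[bias_col]] <- data$utci_proxy - data$utci_insitu
    } else {
      abort("no bias column and no UTCI column pair to derive it from.")
    }
  }
  if (length(unique(data[[factor1]])) < 2) {
    abort("`factor1` must have at least 2 levels.")
  }
  d <- tibble(
    bias = data[[bias_col]],
    f1 = factor(as.character(data[[factor1]]))
  )
  form <- bias ~ f1
  if (!is.null(factor2)) {
    d$f2 <- factor(as.character(data[[factor2]]))
    form <- bias ~ f1 * f2
  }
  fit <- aov(form, data = d)
  st <- summary(fit)[[1]]
  terms <- trimws(rownames(st))
  terms[terms == "f1"] <- factor1
  if (!is.null(factor2)) {
    terms[terms == "f2"] <- factor2
    terms[terms == "f1:f2"] <- paste0(factor1, ":", factor2)
  }
  anova_table <- tibble(
    term = terms,
    df = st$Df,
    sumsq = st$`Sum Sq`,
    meansq = st$`Mean Sq`,
    statistic = st$`F value`,
    p_value = st$`Pr(>F)`
  )
  group_means <- d |>
    group_by(group = .data$f1) |>
    summarise(n = n(), mean_bias = mean(.data$bias), sd_bias = sd(.data$bias),
              .groups = "drop")
  structure(list(group_means = group_means, anova_table = anova_table,
                 formula = form,
                 balance_seed = attr(data, "balance_seed")),
            class = "bias_anova")
}

#' @method tidy bias_anova
#' @export
tidy.bias_anova <- function(x, ...) x$anova_table

#' @method glance bias_anova
#' @export
glance.bias_anova <- function(x, ...) {
  main <- x$anova_table[1, ]
  tibble(statistic = main$statistic, p_value = main$p_value,
         df = main$df, n_groups = nrow(x$group_means),
         n_total = sum(x$group_means$n))
}

#' @export
print.bias_anova <- function(x, ...) {
  cat("Bias ANOVA (", deparse(x$formula), ")\n", sep = "")
  print(x$group_means)
  print(x$anova_table)
  invisible(x)
}

#' Stratified DTS agreement report
#'
#' Agreement between proxy and in-situ Dynamic Thermal Sensation,
#' stratified by the thermal-stress category of the in-situ UTCI value and
#' by the two comfort zones (which overlap the category strata by design).
#' Reports per stratum the sample size, mean reported vote, mean in-situ
#' and proxy DTS, mean bias (proxy DTS minus in-situ DTS), its SD, and
#' Pearson's r; strata with fewer than `min_n` pairs are flagged as too
#' small for a meaningful correlation.
#'
#' @param pairs Paired samples with columns `tsv`, `dts_insitu`,
#'   `dts_proxy` and `utci_insitu` (or `utci_proxy` with
#'   `stratify_on = "proxy"`).
#' @param scale Stress-category scale, see [utci_stress_scale()].
#' @param stratify_on Which UTCI series defines the stratum: `"insitu"`
#'   (default) or `"proxy"`.
#' @param min_n Minimum stratum size below which the `flagged` column is
#'   `TRUE`.
#' @return A tibble with one row per non-empty category stratum plus the
#'   TCZ and adjusted-TCZ strata.
#' @export
stratified_dts_report <- function(pairs, scale = utci_stress_scale(),
                                  stratify_on = c("insitu", "proxy"),
                                  min_n = 10L) {
  stratify_on <- match.arg(stratify_on)
  ucol <- if (stratify_on == "insitu") "utci_insitu" else "utci_proxy"
  need <- c("tsv", "dts_insitu", "dts_proxy", ucol)
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols)) {
    abort(paste0("`pairs` is missing: ", paste(missing_cols, collapse = ", "), "."))
  }
  u <- pairs[[ucol]]

  strat_stats <- function(sub, label) {
    if (nrow(sub) == 0) {
      return(tibble(stratum = label, n = 0L, mean_tsv = NA_real_,
                    mean_dts_insitu = NA_real_, mean_dts_proxy = NA_real_,
                    mean_bias = NA_real_, sd_bias = NA_real_,
                    pearson_r = NA_real_))
    }
    bias <- sub$dts_proxy - sub$dts_insitu
    r <- if (nrow(sub) >= 2 && sd(sub$dts_insitu) > 0 && sd(sub$dts_proxy) > 0) {
      cor(sub$dts_proxy, sub$dts_insitu)
    } else {
      NA_real_
    }
    tibble(stratum = label, n = nrow(sub), mean_tsv = mean(sub$tsv),
           mean_dts_insitu = mean(sub$dts_insitu),
           mean_dts_proxy = mean(sub$dts_proxy),
           mean_bias = mean(bias),
           sd_bias = if (nrow(sub) > 1) sd(bias) else NA_real_,
           pearson_r = r)
  }

  cats <- utci_category(u, scale = scale)
  cat_rows <- map_dfr(levels(cats)[levels(cats) %in% as.character(cats)],
                      function(lab) strat_stats(pairs[cats == lab, ], lab))
  tcz_rows <- bind_rows(
    strat_stats(pairs[in_tcz(u, scale), ], "TCZ"),
    strat_stats(pairs[in_adjusted_tcz(u, scale), ], "TCZ adjusted")
  )
  bind_rows(cat_rows, tcz_rows) |>
    mutate(flagged = .data$n < min_n)
}
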