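test_that("agreement metrics match hand arithmetic on three pairs", {
  pairs <- tibble::tibble(utci_insitu = c(20, 25, 30),
                          utci_proxy = c(19, 24, 32))
  m <- agreement_metrics(pairs)
  expect_equal(m$mean_bias, 0)
  expect_equal(m$max_positive_offset, 2)
  expect_equal(m$max_negative_offset, -1)
  expect_equal(m$n, 3L)
  expect_equal(m$sd_bias, sd(c(-1, -1, 2)))
})

test_that("identical and affinely shifted series behave as expected", {
  x <- c(18, 22, 27, 31)
  ident <- agreement_metrics(tibble::tibble(utci_insitu = x, utci_proxy = x))
  expect_equal(ident$mean_bias, 0)
  expect_equal(ident$sd_bias, 0)
  expect_equal(ident$max_positive_offset, 0)
  expect_equal(ident$max_negative_offset, 0)
  expect_equal(ident$pearson_r, 1)

  # constant shift: bias 1, zero spread, correlation preserved
  shift <- agreement_metrics(tibble::tibble(utci_insitu = x,
                                            utci_proxy = x + 1))
  expect_equal(shift$mean_bias, 1)
  expect_equal(shift$sd_bias, 0)
  expect_equal(shift$pearson_r, 1)
})

test_that("zero-variance series report an undefined correlation, not zero", {
  m <- agreement_metrics(tibble::tibble(utci_insitu = c(20, 20, 20),
                                        utci_proxy = c(19, 21, 23)))
  expect_true(is.na(m$pearson_r))
  expect_true(is.na(m$p_value))
  expect_error(agreement_metrics(tibble::tibble(utci_insitu = 1,
                                                utci_proxy = 1)), "at least 2")
  expect_error(agreement_metrics(tibble::tibble(utci_insitu = c(1, NA),
                                                utci_proxy = c(1, 2))),
               "finite")
})

test_that("the bias sign convention is proxy minus in situ", {
  # canary: proxy warmer by exactly +1 must give mean bias +1
  pairs <- tibble::tibble(utci_insitu = runif(50, 10, 30))
  pairs$utci_proxy <- pairs$utci_insitu + 1
  expect_equal(agreement_metrics(pairs)$mean_bias, 1)
})

test_that("constant injected bias is recovered within 3 sd/sqrt(n)", {
  for (s in c(2, 23, 404)) {
    delta <- c(-2.5, 1.3)[s %% 2 + 1]
    n <- 600L
    pairs <- withr::with_seed(s, tibble::tibble(
      utci_insitu = runif(n, 10, 30)
    ))
    pairs$utci_proxy <- withr::with_seed(s + 1, {
      pairs$utci_insitu + delta + rnorm(n, 0, 2)
    })
    m <- agreement_metrics(pairs)
    expect_lt(abs(m$mean_bias - delta), 3 * m$sd_bias / sqrt(n))
  }
})

test_that("balancing subsamples every group to the smallest one", {
  make_groups <- function(sizes) {
    tibble::tibble(
      g = rep(names(sizes), sizes),
      v = seq_len(sum(sizes))
    )
  }
  # seasonal subset sizes: smallest 171 gives pooled N = 513
  seasons <- make_groups(c(summer = 171, fall = 540, winter = 602))
  bal <- balance_subsets(seasons, "g", seed = 4)
  expect_identical(nrow(bal), 513L)
  expect_true(all(table(bal$g) == 171))
  # morphology subset sizes: smallest 221 gives pooled N = 663
  morph <- make_groups(c(canyon = 480, crossroads = 455, square = 221))
  expect_identical(nrow(balance_subsets(morph, "g", seed = 4)), 663L)
  # deterministic given the seed, and a subset of the original rows
  b1 <- balance_subsets(seasons, "g", seed = 99)
  b2 <- balance_subsets(seasons, "g", seed = 99)
  expect_identical(b1, b2)
  expect_true(all(b1$v %in% seasons$v))
  # already-equal groups are passed through whole
  eq <- make_groups(c(a = 50, b = 50))
  expect_identical(sort(balance_subsets(eq, "g", seed = 1)$v), eq$v)
  expect_error(balance_subsets(seasons[seasons$g == "summer", ], "g"),
               "2 non-empty")
})

test_that("one-way bias ANOVA degenerates correctly and detects separation", {
  # identical bias values in every group: no between-group variance
  same <- tibble::tibble(g = rep(c("a", "b", "c"), each = 5),
                         bias = rep(c(1, 2, 3, 4, 5), 3))
  av <- anova_bias(same, "g")
  expect_equal(av$anova_table$statistic[1], 0, tolerance = 1e-10)
  expect_equal(av$anova_table$p_value[1], 1, tolerance = 1e-10)
  expect_identical(nrow(av$group_means), 3L)

  # a five-sigma separation at n = 171 is detected essentially always
  detected <- vapply(1:10, function(s) {
    d <- withr::with_seed(s, tibble::tibble(
      g = rep(c("a", "b"), each = 171),
      bias = c(rnorm(171, 0, 1), rnorm(171, 5, 1))
    ))
    anova_bias(d, "g")$anova_table$p_value[1] < 0.001
  }, logical(1))
  expect_true(all(detected))
  expect_error(anova_bias(same[same$g == "a", ], "g"), "2 levels")
})

test_that("two-way ANOVA reports main effects and the interaction", {
  d <- withr::with_seed(8, tibble::tibble(
    season = rep(c("summer", "winter"), each = 40),
    morphology = rep(c("canyon", "square"), times = 40),
    bias = rnorm(80)
  ))
  av <- anova_bias(d, "season", "morphology")
  expect_identical(av$anova_table$term,
                   c("season", "morphology", "season:morphology", "Residuals"))
  expect_true(all(is.finite(av$anova_table$statistic[1:3])))
  td <- tidy(av)
  expect_identical(td, av$anova_table)
  expect_identical(glance(av)$n_total, 80L)
})

test_that("bias ANOVA derives the bias from UTCI columns when absent", {
  pairs <- paired_campaign(tiny_config(seed = 41, n = 300L))
  pairs$bias <- NULL
  av <- anova_bias(pairs, "morphology")
  expect_identical(sum(av$group_means$n), 300L)
})

test_that("stratified DTS report partitions by category plus comfort zones", {
  pairs <- tibble::tibble(
    tsv = c(0L, 1L, 0L, -1L, 2L, 1L),
    utci_insitu = c(20, 30, 25, 16, 33, 28),
    dts_insitu = c(0.1, 0.8, 0.4, -0.4, 1.2, 0.7),
    dts_proxy = c(0.0, 0.5, 0.3, -0.2, 0.8, 0.6)
  )
  rep <- stratified_dts_report(pairs, min_n = 3)
  # brute-force partition: categories from in-situ UTCI
  expect_identical(rep$n[rep$stratum == "no thermal stress"], 3L)
  expect_identical(rep$n[rep$stratum == "moderate heat stress"], 2L)
  expect_identical(rep$n[rep$stratum == "strong heat stress"], 1L)
  # TCZ 18-26 closed: 20 and 25; adjusted adds 16
  expect_identical(rep$n[rep$stratum == "TCZ"], 2L)
  expect_identical(rep$n[rep$stratum == "TCZ adjusted"], 3L)
  # a pair at 30 degC sits in moderate heat, not in the TCZ
  expect_false(30 %in% pairs$utci_insitu[in_tcz(pairs$utci_insitu)])
  # small strata are flagged
  expect_true(rep$flagged[rep$stratum == "strong heat stress"])
  expect_false(rep$flagged[rep$stratum == "no thermal stress"])
  # bias convention: proxy DTS minus in-situ DTS
  expect_equal(rep$mean_bias[rep$stratum == "strong heat stress"], -0.4)
})

test_that("all pairs inside the comfort zone give a TCZ stratum of full size", {
  pairs <- tibble::tibble(
    tsv = rep(0L, 5),
    utci_insitu = c(19, 20, 22, 24, 25.5),
    dts_insitu = runif(5, -0.3, 0.3),
    dts_proxy = runif(5, -0.3, 0.3)
  )
  rep <- stratified_dts_report(pairs)
  expect_identical(rep$n[rep$stratum == "TCZ"], 5L)
})
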