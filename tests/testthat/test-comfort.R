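line_bins <- function(slope, intercept, centres, n = 10L) {
  tibble::tibble(
    bin_lower = centres - 0.5,
    bin_centre = centres,
    bin_mean_utci = centres,
    n = n,
    mtsv = slope * centres + intercept
  )
}

test_that("votes are grouped into half-open integer-degree bins", {
  pairs <- tibble::tibble(utci_insitu = c(20.2, 20.9), tsv = c(0L, 1L))
  bins <- bin_mtsv(pairs, min_count = 1)
  expect_identical(nrow(bins), 1L)
  expect_equal(bins$bin_lower, 20)
  expect_equal(bins$mtsv, 0.5)
  # exactly 21.0 belongs to [21, 22), not [20, 21)
  b2 <- bin_mtsv(tibble::tibble(utci_insitu = 21.0, tsv = 2L), min_count = 1)
  expect_equal(b2$bin_lower, 21)
  expect_error(bin_mtsv(tibble::tibble(utci_insitu = numeric(), tsv = integer())),
               "empty")
})

test_that("sparse bins are dropped with a message", {
  pairs <- tibble::tibble(utci_insitu = c(rep(20.5, 5), 25.5),
                          tsv = c(rep(0L, 5), 2L))
  expect_message(bins <- bin_mtsv(pairs, min_count = 3), "dropped")
  expect_identical(bins$bin_lower, 20)
})

test_that("noise-free votes on an exact line give exact bin means", {
  u <- withr::with_seed(1, runif(1000, 10, 30))
  cfg <- synthetic_config(seed = 1, vote_sd = 0, vote_slope = 0.2,
                          vote_intercept = -4)
  pairs <- tibble::tibble(utci_insitu = u, tsv = generate_votes(u, cfg))
  bins <- bin_mtsv(pairs)
  # brute force per retained bin
  for (i in seq_len(nrow(bins))) {
    inb <- u >= bins$bin_lower[i] & u < bins$bin_lower[i] + 1
    expect_equal(bins$mtsv[i], mean(round(0.2 * u[inb] - 4)))
  }
})

test_that("comfort model inverts an exact trend line in closed form", {
  m <- fit_comfort_model(line_bins(0.2, -4, centres = c(15.5, 18.5, 21.5, 24.5)))
  expect_equal(m$slope, 0.2)
  expect_equal(m$neutral_utci, 20.0)
  expect_equal(m$lower_threshold, 17.5)
  expect_equal(m$upper_threshold, 22.5)
  expect_equal(m$thermal_sensitivity, 5.0)
  expect_equal(m$pearson_r, 1)
})

test_that("the printed in-situ trend line inverts to its comfort range", {
  # MTSV = 0.10 * UTCI - 2.02 crosses zero at 20.2 with sensitivity 10
  m <- fit_comfort_model(line_bins(0.10, -2.02, centres = seq(12.5, 27.5, 1)))
  expect_equal(m$neutral_utci, 20.2, tolerance = 1e-9)
  expect_equal(m$lower_threshold, 15.2, tolerance = 1e-9)
  expect_equal(m$upper_threshold, 25.2, tolerance = 1e-9)
  expect_equal(m$thermal_sensitivity, 10.0, tolerance = 1e-9)
})

test_that("flat or negative trends withhold the thresholds", {
  flat <- fit_comfort_model(line_bins(0, 0.2, centres = c(15.5, 18.5, 21.5)))
  expect_false(flat$thresholds_defined)
  expect_true(is.na(flat$lower_threshold))
  expect_true(is.na(flat$thermal_sensitivity))
  neg <- fit_comfort_model(line_bins(-0.1, 2, centres = c(15.5, 18.5, 21.5)))
  expect_false(neg$thresholds_defined)
  expect_error(fit_comfort_model(line_bins(0.1, 0, centres = c(15.5, 18.5))),
               "3 retained bins")
})

test_that("comfort thresholds are symmetric about the neutral point", {
  for (s in 1:5) {
    pairs <- paired_campaign(tiny_config(seed = s, n = 800L))
    m <- fit_comfort_model(suppressMessages(bin_mtsv(pairs)))
    if (!m$thresholds_defined) next
    expect_equal(m$upper_threshold - m$neutral_utci, 0.5 / m$slope,
                 tolerance = 1e-9)
    expect_equal(m$neutral_utci - m$lower_threshold, 0.5 / m$slope,
                 tolerance = 1e-9)
  }
})

test_that("tidy, glance and autoplot expose the fitted model", {
  m <- fit_comfort_model(line_bins(0.2, -4, centres = c(15.5, 18.5, 21.5, 24.5)))
  td <- tidy(m)
  expect_identical(td$term, c("(Intercept)", "utci"))
  gl <- glance(m)
  expect_identical(gl$n_bins, 4L)
  expect_equal(gl$neutral_utci, 20)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})

test_that("proxy damping steepens the proxy trend line in most campaigns", {
  steeper <- 0L
  for (s in 1:7) {
    pairs <- paired_campaign(synthetic_config(seed = s, n_responses = 1200L))
    mi <- fit_comfort_model(suppressMessages(bin_mtsv(pairs, "utci_insitu")))
    mp <- fit_comfort_model(suppressMessages(bin_mtsv(pairs, "utci_proxy")))
    steeper <- steeper + (mp$slope > mi$slope)
  }
  expect_gte(steeper, 4L)
})
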