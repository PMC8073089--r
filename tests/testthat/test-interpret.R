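test_that("minimum read count derivation reproduces the published default", {
  # mean 34, SD 30, k = 1 -> 64 (observations with those exact moments)
  obs2 <- c(4, 34, 64)
  expect_equal(mean(obs2), 34)
  expect_equal(sd(obs2), 30)
  expect_equal(derive_min_read_count(obs2, k = 1), 64L)
  expect_equal(derive_min_read_count(c(10, 20, 30), k = 2), 40L)
  expect_equal(derive_min_read_count(rep(0, 50), k = 3), 0L)
  expect_error(derive_min_read_count(numeric(), 1), "no background")
})

test_that("analytical threshold derivation follows both rounding modes", {
  # observation pairs constructed to have exact mean 0.7 and SD 1.0 / 0.5
  y <- 0.7 + c(-1, 1) / sqrt(2)
  expect_equal(mean(y), 0.7)
  expect_equal(sd(y), 1.0)
  expect_equal(derive_at(y, k = 3, "one-decimal")$custom_at, 3.7)
  z <- 0.7 + c(-1, 1) * 0.5 / sqrt(2)
  expect_equal(sd(z), 0.5)
  expect_equal(derive_at(z, k = 3, "ceil-to-integer")$custom_at, 3)
  expect_equal(derive_at(rep(0, 10))$custom_at, 0)
  s <- derive_at(y, k = 3)
  expect_named(s$summary,
               c("mean", "sd", "k", "percentile95", "max", "n",
                 "excluded_hotspots"))
})

test_that("derived thresholds are monotone in k and in the observations", {
  set.seed(4)
  obs <- pmax(rnorm(100, 34, 30), 0)
  v <- vapply(c(0, 0.5, 1, 2, 3), function(k)
    derive_min_read_count(obs, k), integer(1))
  expect_true(all(diff(v) >= 0))
  obs_hi <- obs + 10
  expect_gte(derive_min_read_count(obs_hi, 1), derive_min_read_count(obs, 1))
})

test_that("expected mixture ratios match the published table", {
  expect_equal(expected_mixture_ratio(1, 1), list(minor = 50L, major = 50L))
  expect_equal(expected_mixture_ratio(1, 3), list(minor = 25L, major = 75L))
  expect_equal(expected_mixture_ratio(1, 5), list(minor = 17L, major = 83L))
  expect_equal(expected_mixture_ratio(1, 9), list(minor = 10L, major = 90L))
  expect_equal(expected_mixture_ratio(1, 15), list(minor = 6L, major = 94L))
  for (m in 1:4) for (M in 1:16) {
    r <- expected_mixture_ratio(m, M)
    expect_equal(r$minor + r$major, 100L)
  }
  expect_error(expected_mixture_ratio(0, 3), "> 0")
})

test_that("detection rates print at one decimal, half-up", {
  expect_equal(detection_rate(15, 27), 55.6)
  expect_equal(detection_rate(7, 27), 25.9)
  expect_equal(detection_rate(8, 10), 80)
  expect_equal(detection_rate(10, 10), 100)
  for (e in c(1, 3, 10, 27)) expect_equal(detection_rate(e, e), 100)
  expect_error(detection_rate(1, 0), "> 0")
})

test_that("mixture flagging uses the mixed-base majority rule", {
  mk <- function(s) structure(list(haplotype = parse_haplotype(s)),
                              class = "sample_result")
  # 6 mixed of 10 calls: 0.6 > 0.5 -> flagged
  r <- flag_mixture(mk("73Y 150Y 152Y 263Y 295Y 315Y 489G 490G 491G 492G"))
  expect_true(r$flagged_mixture)
  expect_equal(r$mixed_base_fraction, 0.6)
  # exactly half is not flagged (strict majority)
  half <- flag_mixture(mk("73Y 150Y 152C 263G"))
  expect_false(half$flagged_mixture)
  # 0 mixed of 11 -> not flagged
  expect_false(flag_mixture(
    mk("73G 150T 152C 263G 295T 315.1C 489C 16069T 16193T 16278T 16362C")
  )$flagged_mixture)
  empty <- flag_mixture(mk(""))
  expect_false(empty$flagged_mixture)
  expect_equal(empty$mixed_base_fraction, 0)
})

test_that("NTC depth estimate divides paired reads over the panel", {
  expect_equal(ntc_depth_estimate(900, 18), 100)
  expect_equal(ntc_depth_estimate(0, 18), 0)
  expect_equal(ntc_depth_estimate(18, 18), 2)
  expect_error(ntc_depth_estimate(10, 0), "amplicon")
})

test_that("precision metric follows the two-tier printed precision", {
  expect_equal(precision_metric(356, 16569), 97.9)
  expect_equal(precision_metric(4, 16569), 99.98)
  expect_equal(precision_metric(0, 16569), 100)
  expect_error(precision_metric(-1, 10), "within")
  expect_error(precision_metric(5, 0), "> 0")
})

test_that("crosstalk candidates link NTC calls to co-indexed samples", {
  mk <- function(hap, i7, i5, reads = 100) {
    r <- structure(list(haplotype = parse_haplotype(hap)),
                   class = "sample_result")
    r$index_i7 <- i7; r$index_i5 <- i5; r$total_reads <- reads
    r
  }
  samples <- list(X = mk("73G 263G", "AAAAAAAA", "CCCCCCCC"),
                  Y = mk("152C", "GGGGGGGG", "TTTTTTTT"))
  # NTC sharing X's i7 and matching X's calls
  ntcs <- list(ntc1 = mk("73G 263G", "AAAAAAAA", "GGGGTTTT"))
  out <- crosstalk_candidates(samples, ntcs)
  expect_equal(out$source_sample, "X")
  expect_equal(out$shared_index, "i7")
  # NTC with zero reads -> empty table
  ntc0 <- list(ntc2 = mk("", "AAAAAAAA", "GGGGTTTT", reads = 0))
  expect_equal(nrow(crosstalk_candidates(samples, ntc0)), 0L)
  # NTC whose calls match no co-indexed sample -> unexplained
  ntcx <- list(ntc3 = mk("16069T", "AAAAAAAA", "GGGGTTTT"))
  outx <- crosstalk_candidates(samples, ntcx)
  expect_equal(outx$note, "unexplained")
})

test_that("threshold report YAML round-trips", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  at <- derive_at(c(0.2, 0.7, 1.2), k = 3)
  write_threshold_report(list(mean = 34, sd = 30, k = 1, value = 64), at, tmp)
  y <- yaml::read_yaml(tmp)
  expect_equal(y$minimum_read_count$value, 64)
  expect_equal(y$analytical_threshold$custom_at, at$custom_at)
})
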