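# A miniature hand-built ledger with two classes over two days; every
# metric below is checkable by hand.
mini_ledger <- function() {
  data.frame(
    day = 1:2,
    donations = c(10, 10), demand = c(8, 8),
    shipped_young = 0, shipped_restock = 0,
    expired_collector = c(1, 3), expired_hospital = c(0, 2),
    collector_end = c(100, 90), hospital_end = c(50, 60),
    `demand.HRG-TM7` = c(3, 1), `transfused.HRG-TM7` = c(3, 1),
    `agesum.HRG-TM7` = c(24, 12), `unmet.HRG-TM7` = c(0, 0),
    `unmet_by_age.HRG-TM7` = c(1, 0),
    `demand.BBR` = c(5, 7), `transfused.BBR` = c(4, 6),
    `agesum.BBR` = c(40, 60), `unmet.BBR` = c(1, 1),
    `unmet_by_age.BBR` = c(0, 0),
    check.names = FALSE
  )
}

test_that("annual average daily values are horizon means", {
  expect_equal(aad(rep(100, 365)), 100)
  expect_equal(aad(c(0, 10)), 5)
  expect_error(aad(numeric(0)), "at least one day")
  set.seed(12)
  x <- rpois(365, 50)
  expect_lt(abs(aad(x) - 50), 4 * sqrt(50 / 365))
})

test_that("weighted transfused age pools unit-days over the horizon", {
  l <- mini_ledger()
  # HRG: ages {8:3 on day 1, 12:1 on day 2} -> (24 + 12) / 4 = 9
  expect_equal(weighted_age_of_transfused(l, "HRG-TM7"), 9)
  expect_equal(weighted_age_of_transfused(l, "BBR"), 10)
  expect_equal(weighted_age_of_transfused(l), (36 + 100) / 14)
  none <- l; none$`transfused.BBR` <- 0; none$`agesum.BBR` <- 0
  expect_true(is.na(weighted_age_of_transfused(none, "BBR")))
})

test_that("percent unmet-by-age is unmet over demanded", {
  l <- mini_ledger()
  expect_equal(pct_unmet_by_age(l, "HRG-TM7"), 100 * 1 / 4)
  expect_equal(pct_unmet_by_age(l, "BBR"), 0)
  zero <- l; zero$`demand.BBR` <- 0
  expect_true(is.na(pct_unmet_by_age(zero, "BBR")))
})

test_that("efficiency complements percent unmet in every summary", {
  l <- mini_ledger()
  m <- replicate_metrics(l)
  expect_equal(m$`efficiency.HRG-TM7` + m$`pct_unmet_by_age.HRG-TM7`, 100)
  expect_equal(m$efficiency + m$pct_unmet_by_age, 100)
  expect_equal(m$aad_total_supply, mean(c(150, 150)))
  expect_equal(m$aad_expired, mean(c(1, 5)))
  expect_equal(m$aad_expired_collector, 2)
})

test_that("the 95% interval is mean plus/minus 1.96 standard errors", {
  ci <- ci95(c(0, 10))
  expect_equal(unname(ci["point"]), 5)
  expect_equal(unname(ci["low"]), 5 - 1.96 * 5)
  expect_equal(unname(ci["high"]), 5 + 1.96 * 5)
  same <- ci95(rep(4.2, 10))
  expect_equal(unname(same["low"]), unname(same["high"]))
  expect_true(is.na(ci95(3)["low"]))
  ci2 <- ci95(rnorm(50))
  expect_true(ci2["low"] <= ci2["point"] && ci2["point"] <= ci2["high"])
})

test_that("baseline comparison is zero against itself and sorts by supply", {
  l <- mini_ledger()
  summaries <- list(
    baseline = summarize_scenario(list(l, l)),
    lower = summarize_scenario(list(within(l, {
      collector_end <- collector_end - 30
    })))
  )
  cmp <- compare_to_baseline(summaries, "baseline")
  expect_equal(cmp$pct_reduction_supply[cmp$scenario == "baseline"], 0)
  expect_equal(cmp$pct_reduction_supply[cmp$scenario == "lower"], 20)
  expect_equal(cmp$scenario, c("baseline", "lower"))  # descending supply
  expect_error(compare_to_baseline(summaries, "nope"), "not found")
})

test_that("report regeneration from the same ledgers is identical", {
  l <- mini_ledger()
  s1 <- summarize_scenario(list(l, l))
  s2 <- summarize_scenario(list(l, l))
  expect_identical(s1, s2)
})

test_that("metrics CSV export writes one row per scenario and metric", {
  l <- mini_ledger()
  summaries <- list(a = summarize_scenario(list(l, l)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(summaries, path)
  df <- utils::read.csv(path)
  expect_true(all(c("scenario", "metric", "point") %in% names(df)))
  expect_equal(unique(df$scenario), "a")
})
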