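test_that("day-of-year conversion honours leap years", {
  expect_identical(dayOfYear("2016-02-08"), 39L)
  expect_identical(dayOfYear("2016-01-16"), 16L)
  expect_identical(dayOfYear("2016-03-01"), 61L)
  expect_identical(dayOfYear("2015-03-01"), 60L)
  expect_error(dayOfYear("not-a-date"), "invalid date")
})

test_that("break search equals the exhaustive formula-interface oracle", {
  set.seed(101)
  days <- 16:44
  for (i in 1:50) {
    y <- if (i %% 2 == 0) rpois(29, 5) else step_series(sample(30:41, 1))
    got <- zaBreakSearch(y, days)
    want <- naive_za(y, days)
    expect_identical(got$tp_day, want$tp_day, info = paste("series", i))
    expect_equal(got$t_min, want$t_min, tolerance = 1e-10,
                 info = paste("series", i))
  }
})

test_that("break search is invariant to adding a constant", {
  set.seed(7)
  y <- step_series(39)
  a <- zaBreakSearch(y, 16:44)
  b <- zaBreakSearch(y + 100, 16:44)
  expect_identical(a$tp_day, b$tp_day)
  expect_equal(a$t_min, b$t_min, tolerance = 1e-9)
})

test_that("the detected break stays inside the trimmed candidate window", {
  set.seed(42)
  days <- 16:44
  k <- ceiling(0.15 * 29)
  for (i in 1:30) {
    y <- rpois(29, 8)
    tp <- zaBreakSearch(y, days)$tp_day
    expect_gte(tp, days[1 + k])
    expect_lte(tp, days[29 - k])
  }
})

test_that("degenerate and too-short series raise the documented errors", {
  expect_error(zaBreakSearch(rep(5, 29)), "degenerate")
  # a clean two-level series has zero residual variance at the true break
  expect_error(zaBreakSearch(c(rep(5, 15), rep(15, 14))), "degenerate")
  expect_error(zaBreakSearch(rpois(5, 5)), "too short")
})

test_that("cell analysis flags constant series as no-break", {
  r <- analyzeCell(rep(4, 29), 16:44)
  expect_true(r$no_break)
  expect_identical(r$mean_before, r$mean_after)
})

test_that("an implanted upward step is detected and confirmed", {
  set.seed(9)
  y <- step_series(39, mu1 = 5, mu2 = 15)
  r <- analyzeCell(y, 16:44)
  expect_false(r$no_break)
  expect_gt(r$mean_after, r$mean_before)
  expect_lt(r$p_value, 0.05)
  expect_lte(abs(r$tp_day - 39), 2)
})

test_that("analysis skips absent days without imputing them", {
  set.seed(10)
  y <- step_series(39)
  y[c(3, 20)] <- NA
  r <- analyzeCell(y, 16:44)
  expect_false(r$no_break)
  expect_equal(r$mean_before, mean(y[16:44 < r$tp_day], na.rm = TRUE))
})

test_that("Mann-Whitney size at the fixed New-Year split is near nominal", {
  # null Poisson cells, split days <39 vs >=39; size should be close to
  # alpha = 0.05 (slightly conservative from the continuity correction)
  set.seed(12)
  days <- 16:44
  rej <- 0L
  n <- 2000L
  for (i in seq_len(n)) {
    y <- rpois(29, 5)
    p <- mannWhitneyU(y[days < 39], y[days >= 39])$p
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n, 0.03)
  expect_lt(rej / n, 0.065)
})

test_that("batch detection matches per-cell analysis and carries domains", {
  g <- partitionGrid(filterLowActivity(
    simulateMobilityGrid(generatorConfig(seed = 2))))
  small <- g[1:20, ]
  tp <- detectTurningPoints(small)
  expect_identical(nrow(tp), 20L)
  one <- analyzeCell(cellCounts(small)[7, ], julianDays(small))
  expect_identical(tp$tp_day[7], as.integer(one$tp_day))
  expect_equal(tp$p_value[7], one$p_value)
  expect_true(all(tp$domain %in% c("urban", "rural")))
  expect_true(all(tp$p_value[!tp$no_break] > 0 &
                    tp$p_value[!tp$no_break] <= 1))
})
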