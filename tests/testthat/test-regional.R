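test_that("net increase and relative rate follow their definitions", {
  r <- S4Vectors::DataFrame(mean_before = c(2, 4, 0), mean_after = c(5, 4, 3))
  expect_equal(cellNetIncrease(r), c(3, 0, 3))
  expect_equal(cellRelativeRate(r), c(1.5, 0, NA))
})

test_that("regional aggregation is additive and computes PR", {
  results <- S4Vectors::DataFrame(
    cell_id = paste0("c", 1:6),
    tp_day = 38L, t_min = -5,
    mean_before = c(2, 3, 5, 5, 10, 8),
    mean_after = c(5, 5, 4, 5.5, 4, 9),
    u_stat = 1, p_value = 0.01, no_break = FALSE,
    domain = c("rural", "rural", "rural", "rural", "urban", "rural"))
  region_map <- data.frame(cell_id = paste0("c", 1:6),
                           county_id = c("A", "A", "A", "B", "B", "B"),
                           city_id = "M", province_id = "P")
  s <- aggregateRegions(results, region_map, level = "county_id")
  sA <- s[s$region_id == "A", ]
  expect_equal(sA$net_increase, 3 + 2)
  expect_equal(sA$PR, 2 / 3)
  # merged region equals the sum of its parts
  m <- aggregateRegions(results, region_map, level = "city_id")
  expect_equal(m$net_increase, sum(s$net_increase))
  expect_equal(m$net_decrease, sum(s$net_decrease))
  # share bookkeeping
  expect_equal(sum(s$rural_share), 1)
  expect_equal(sum(s$urban_share), 1)
  # unmapped cell is an integrity error
  expect_error(aggregateRegions(results, region_map[-2, ], "county_id"),
               "unmapped")
})

test_that("country series shares sum to one and flag all-zero days", {
  counts <- rbind(r1 = c(398L, 0L), r2 = c(0L, 0L), u1 = c(500L, 0L),
                  e1 = c(102L, 0L))
  g <- MobilityGrid(counts, julianDays = 39:40,
                    cellInfo = data.frame(grid_row = 0:3, grid_col = 0L,
                                          domain = c("rural", "rural",
                                                     "urban", NA)))
  cs <- countrySeries(g)
  expect_identical(sort(setdiff(names(cs), "julian_day")),
                   c("excluded", "rural", "urban"))
  pr <- domainProportions(cs)
  expect_equal(pr$rural[1], 0.398)
  expect_equal(pr$rural[1] + pr$urban[1] + pr$excluded[1], 1)
  expect_true(pr$all_zero[2])
  expect_true(is.na(pr$rural[2]))
})

test_that("the urban return fraction reproduces the published arithmetic", {
  expect_equal(round(urbanReturnFraction(0.398, 0.184), 3), 0.262)
  expect_equal(urbanReturnFraction(0.3, 0.3), 0)
  expect_equal(urbanReturnFraction(1.0, 0.5), 1)
  expect_error(urbanReturnFraction(1.2, 1.0), "p_base")
})

test_that("Kendall tau equals the O(n^2) pair-count oracle", {
  expect_equal(kendallTau(1:10)$tau, 1)
  expect_equal(kendallTau(10:1)$tau, -1)
  set.seed(61)
  for (i in 1:10) {
    x <- rpois(29, 6)  # ties likely
    got <- kendallTau(x)
    want <- kendall_pairs(seq_along(x), x)
    expect_equal(got$tau, want$tau, tolerance = 1e-12)
  }
  # tie-free case: the normal-approximation p matches the closed form
  x <- rnorm(29)
  expect_equal(kendallTau(x)$p, kendall_pairs(seq_along(x), x)$p_noties,
               tolerance = 1e-12)
  expect_true(kendallTau(rep(2, 10))$constant)
})

test_that("log-log and semi-log fits recover noiseless coefficients", {
  x <- c(10, 100, 1000, 5000)
  y <- exp(1 + 2 * log(x))
  f <- fitLogLog(x, y)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  g <- fitLog(x, 0.1 + 0.2 * log(x))
  expect_equal(g$a, 0.1)
  expect_equal(g$b, 0.2)
  expect_equal(g$r_squared, 1)
  # nonpositive rows are dropped and counted
  f2 <- fitLogLog(c(x, -5), c(y, 10))
  expect_identical(f2$n_dropped, 1L)
  expect_error(fitLogLog(rep(7, 4), rep(3, 4)), "degenerate")
  expect_error(fitLogLog(1:2, 1:2), "fewer than 3")
})

test_that("log-log slope recovery stays inside its own 95% CI", {
  set.seed(71)
  x <- exp(runif(50, log(1e3), log(1e6)))
  y <- exp(1 + 2 * log(x) + rnorm(50, 0, 0.5))
  f <- fitLogLog(x, y)
  expect_gt(2, f$slope_ci[1])
  expect_lt(2, f$slope_ci[2])
})

test_that("source/sink labels follow the deviation-multiple rule", {
  expect_identical(classifySourceSink(0.06, 0.01), "source")
  expect_identical(classifySourceSink(0.01, 0.06), "sink")
  expect_identical(classifySourceSink(0.02, 0.02), "balanced")
  # symmetry: swapping the shares swaps the label
  set.seed(81)
  a <- runif(20)
  b <- runif(20)
  l1 <- classifySourceSink(a, b)
  l2 <- classifySourceSink(b, a)
  expect_identical(l1 == "source", l2 == "sink")
  expect_identical(l1 == "balanced", l2 == "balanced")
})

test_that("county selection applies both strict criteria", {
  cen <- data.frame(agri_share = c(0.6, 0.4, 0.6, 0.51),
                    nonhukou_ratio = c(0.05, 0.05, 0.10, 0.099))
  sel <- selectCounties(cen)
  expect_identical(rownames(sel), c("1", "4"))
  expect_error(selectCounties(data.frame(agri_share = 1)), "nonhukou")
})

test_that("out-migrant inference is a signed difference with inflow flag", {
  r <- inferOutMigrants(c(100000, 50000, 80000), c(80000, 50000, 100000))
  expect_identical(r$out_migrants, c(20000, 0, -20000))
  expect_identical(r$net_inflow, c(FALSE, FALSE, TRUE))
})

test_that("census validation recovers the implanted coupling", {
  g <- simulateMobilityGrid(generatorConfig(seed = 37))
  f <- partitionGrid(filterLowActivity(g))
  tp <- detectTurningPoints(f)
  region_map <- data.frame(cell_id = cellIds(f),
                           county_id = cellInfo(f)$county_id,
                           city_id = cellInfo(f)$city_id,
                           province_id = cellInfo(f)$province_id)
  s <- aggregateRegions(tp, region_map, "county_id")
  cen <- simulateCensus(g, noise_sd = 0.1)
  om <- cbind(cen, inferOutMigrants(cen$registered_pop,
                                    cen$resident_hukou_pop))
  v <- validateAgainstCensus(s, om)
  expect_gt(v$slope, 0)
  expect_lt(v$p_value, 0.05)
  # perfectly proportional data give R^2 = 1
  s2 <- s[1:5, ]
  s2$net_increase <- 1:5
  om2 <- data.frame(county_id = s2$region_id, out_migrants = (1:5) * 100)
  expect_equal(validateAgainstCensus(s2, om2)$r_squared, 1)
})

test_that("slope is null-calibrated when the census is decoupled", {
  # out-migrants independent of the regional signal: the validation slope
  # should rarely look significant
  set.seed(91)
  frac <- mean(replicate(300, {
    s <- data.frame(region_id = sprintf("c%02d", 1:30),
                    level = "county_id",
                    net_increase = rlnorm(30, 3, 1))
    om <- data.frame(county_id = s$region_id,
                     out_migrants = runif(30, 0, 1e5))
    v <- validateAgainstCensus(s, om)
    # |t| < 2 on 28 df is equivalent to p above the matching two-sided tail
    v$p_value > 2 * pt(-2, df = 28)
  }))
  expect_gte(frac, 0.9)
})

test_that("z-scoring normalizes and is affine invariant", {
  z <- zscoreSeries(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  x <- rnorm(20)
  expect_equal(zscoreSeries(3 * x + 7), zscoreSeries(x))
  expect_error(zscoreSeries(rep(1, 5)), "constant")
  # z-scored coupled visitor/N pair stays tightly correlated
  v <- simulateVisitorSeries(62, coupling = 1, noise_sd = 0.1, seed = 3)
  expect_gt(cor(zscoreSeries(v$visitors), zscoreSeries(v$N)), 0.9)
})
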