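test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- generatorConfig(seed = 11)
  g1 <- simulateMobilityGrid(cfg)
  g2 <- simulateMobilityGrid(cfg)
  expect_identical(cellCounts(g1), cellCounts(g2))
  expect_identical(as.data.frame(gridTruth(g1)), as.data.frame(gridTruth(g2)))
  expect_identical(S4Vectors::metadata(g1)$settlementPoints,
                   S4Vectors::metadata(g2)$settlementPoints)
  expect_identical(S4Vectors::metadata(g1)$regionTruth,
                   S4Vectors::metadata(g2)$regionTruth)
})

test_that("generator honours configured class sizes and affected fraction", {
  cfg <- generatorConfig(n_rows = 25, n_cols = 40, n_urban = 200,
                         n_rural = 700, n_empty = 100,
                         frac_affected_rural = 0.7, n_counties = 25,
                         counties_per_city = 5, cities_per_province = 5,
                         seed = 3)
  g <- simulateMobilityGrid(cfg)
  tr <- gridTruth(g)
  expect_equal(as.vector(table(tr$true_domain)[c("urban", "rural",
                                                 "empty")]),
               c(200, 700, 100))
  # exactly round(0.7 * 700) rural cells carry a truth break
  expect_identical(sum(tr$true_domain == "rural" & !is.na(tr$true_break_day)),
                   490L)  # exactly round(0.7 * 700)
  # every cell has exactly one truth record; counts are integers >= 0
  expect_identical(nrow(tr), nrow(g))
  expect_true(all(cellCounts(g) >= 0))
  expect_true(all(cellCounts(g) == round(cellCounts(g))))
  expect_true(all(cellInfo(g)$radiance >= 0))
})

test_that("implanted break days stay within the configured jitter window", {
  g <- simulateMobilityGrid(generatorConfig(seed = 5))
  tr <- gridTruth(g)
  bd <- tr$true_break_day[!is.na(tr$true_break_day)]
  expect_true(all(bd >= 39 - 2 & bd <= 39 + 2))
})

test_that("rural radiance sample mean matches the class statistics", {
  # 10,000 rural-class draws; clamping at 0 biases the mean upward by
  # E[max(0,-X)] = sd*dnorm(m/sd) - m*pnorm(-m/sd), which the bound must
  # include alongside 3 standard errors
  cfg <- generatorConfig(n_rows = 100, n_cols = 100, n_urban = 0,
                         n_rural = 10000, n_empty = 0, n_counties = 25,
                         counties_per_city = 5, cities_per_province = 5,
                         seed = 13)
  g <- simulateMobilityGrid(cfg)
  rad <- cellInfo(g)$radiance
  m <- 0.377; s <- 0.27
  clamp_bias <- s * dnorm(m / s) - m * pnorm(-m / s)
  se <- s / sqrt(10000)
  expect_lt(abs(mean(rad) - (m + clamp_bias)), 3 * se)
})

test_that("census accounting is exact at zero noise and coupled to effects", {
  g <- simulateMobilityGrid(generatorConfig(seed = 17))
  rt <- S4Vectors::metadata(g)$regionTruth
  cen0 <- simulateCensus(g, noise_sd = 0)
  expect_identical(cen0$registered_pop - cen0$resident_hukou_pop,
                   rt$true_out_migrants)
  # counties without affected cells have zero out-migrants
  expect_true(all(rt$true_out_migrants[rt$implanted_effect_mass == 0] == 0))
  # positive coupling between implanted effect mass and noisy out-migrants
  cen <- simulateCensus(g, noise_sd = 0.1, seed = 99)
  om <- cen$registered_pop - cen$resident_hukou_pop
  expect_gte(nrow(rt), 20)
  expect_gt(cor(rt$implanted_effect_mass, om), 0)
})

test_that("visitor series coupling behaves across the coupling range", {
  v1 <- simulateVisitorSeries(n_days = 62, coupling = 1, noise_sd = 0,
                              seed = 2)
  expect_identical(nrow(v1), 62L)
  expect_equal(cor(v1$visitors, v1$N), 1)
  v0 <- simulateVisitorSeries(n_days = 62, coupling = 0, noise_sd = 0.1,
                              seed = 2)
  expect_lt(abs(cor(v0$visitors, v0$N)), 0.2)
  expect_error(simulateVisitorSeries(n_days = 2), "n_days")
})

test_that("invalid generator configurations are rejected", {
  expect_error(generatorConfig(n_urban = 100), "must equal")
  expect_error(generatorConfig(effect_rural = 0), "strictly positive")
  expect_error(generatorConfig(frac_affected_rural = 1.2), "\\[0, 1\\]")
  expect_error(generatorConfig(cny_day = 50), "cover cny_day")
  expect_error(generatorConfig(baseline_rate = c(urban = 50, rural = -1,
                                                 empty = 0.8)),
               "positive")
})

test_that("region tables partition the cell set", {
  g <- simulateMobilityGrid(generatorConfig(seed = 23))
  info <- cellInfo(g)
  expect_false(any(is.na(info$county_id)))
  sizes <- table(info$county_id)
  expect_identical(length(sizes), 30L)
  expect_true(all(sizes == nrow(g) / 30))
})
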