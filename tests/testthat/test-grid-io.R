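make_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("a well-formed long CSV yields one series per cell", {
  days <- 16:44
  df <- expand.grid(julian_day = days, cell_id = c("a", "b", "c"),
                    stringsAsFactors = FALSE)
  df$row <- match(df$cell_id, c("a", "b", "c")) - 1L
  df$col <- 0L
  df$N <- 5L
  g <- readGridCSV(make_long_csv(df[, c("cell_id", "row", "col",
                                        "julian_day", "N")]))
  expect_identical(dim(cellCounts(g)), c(3L, 29L))
  expect_identical(julianDays(g), days)
  expect_false(anyNA(cellCounts(g)))
})

test_that("duplicate cell-day rows raise an integrity error", {
  df <- data.frame(cell_id = c("a", "a"), row = 0L, col = 0L,
                   julian_day = c(16L, 16L), N = c(1L, 2L))
  expect_error(readGridCSV(make_long_csv(df)), "integrity")
})

test_that("grid write then read round-trips, keeping absent days absent", {
  g <- simulateMobilityGrid(generatorConfig(seed = 4))
  # punch a hole: drop one cell-day to exercise absence handling
  counts <- cellCounts(g)
  counts[3, 5] <- NA_integer_
  g2 <- MobilityGrid(counts, julianDays(g), cellInfo(g)[, c("grid_row",
                                                            "grid_col")])
  p <- tempfile(fileext = ".csv")
  writeGridCSV(g2, p)
  g3 <- readGridCSV(p)
  expect_identical(cellCounts(g3)[rownames(g2), ], cellCounts(g2))
  expect_true(is.na(cellCounts(g3)[rownames(g2)[3], 5]))
})

test_that("activity filter applies a strict < cutoff on the observed mean", {
  counts <- rbind(all_ones = rep(1L, 10),     # mean 1 -> excluded
                  exactly2 = rep(2L, 10),     # mean exactly 2 -> retained
                  gappy = c(rep(5L, 5), rep(NA, 5)))  # observed mean 5
  g <- MobilityGrid(counts, julianDays = 16:25,
                    cellInfo = data.frame(grid_row = 0:2, grid_col = 0L))
  f <- filterLowActivity(g)
  expect_identical(rownames(f), c("exactly2", "gappy"))
  meta <- S4Vectors::metadata(f)$low_activity
  expect_identical(meta$n_excluded, 1L)
  expect_identical(meta$excluded_ids, "all_ones")
  # idempotent; retained + excluded = input
  f2 <- filterLowActivity(f)
  expect_identical(rownames(f2), rownames(f))
  expect_identical(nrow(f) + meta$n_excluded, nrow(g))
})

test_that("empty input passes through the filter without error", {
  g <- simulateMobilityGrid(generatorConfig(seed = 4))
  empty <- g[integer(0), ]
  expect_identical(nrow(filterLowActivity(empty)), 0L)
})

test_that("settlement indexing uses half-open cell intervals", {
  counts <- matrix(5L, 4, 10,
                   dimnames = list(paste0("c", 1:4), NULL))
  g <- MobilityGrid(counts, julianDays = 16:25,
                    cellInfo = data.frame(grid_row = c(0L, 0L, 1L, 1L),
                                          grid_col = c(0L, 1L, 0L, 1L)))
  pts <- data.frame(id = c("corner", "inner1", "inner2", "outer_edge",
                           "outside"),
                    x = c(0, 1.5, 1.7, 2.0, 5.0),
                    y = c(0, 1.5, 1.2, 1.0, 0.5))
  idx <- indexSettlements(pts, g)
  # lower-left corner belongs to its cell; two points in cell (1,1)
  expect_identical(unname(idx$counts["c1"]), 1L)
  expect_identical(unname(idx$counts["c4"]), 2L)
  # the grid's outer max edge is not contained (half-open convention)
  expect_identical(idx$n_unassigned, 2L)
  expect_setequal(idx$unassigned_ids, c("outer_edge", "outside"))
  expect_identical(idx$n_assigned + idx$n_unassigned, nrow(pts))
  expect_identical(sum(idx$counts), idx$n_assigned)
})

test_that("settlement points round-trip through GeoJSON and CSV", {
  pts <- data.frame(id = c("s1", "s2"), x = c(0.25, 3.5), y = c(1.5, 0.125))
  pj <- tempfile(fileext = ".geojson")
  writeSettlementsGeoJSON(pts, pj)
  back <- readSettlementsGeoJSON(pj)
  expect_equal(back, pts)
  pc <- tempfile(fileext = ".csv")
  writeSettlementsCSV(pts, pc)
  expect_equal(readSettlementsCSV(pc), pts)
})

test_that("raster export rescales values recoverably", {
  g <- simulateMobilityGrid(generatorConfig(seed = 4))
  v <- setNames(rnorm(nrow(g)), cellIds(g))
  p <- tempfile(fileext = ".tif")
  writeRasterTIFF(v, g, p)
  side <- jsonlite::read_json(paste0(p, ".json"))
  img <- tiff::readTIFF(p)
  info <- cellInfo(g)
  rec <- side$offset + side$scale * img[cbind(info$grid_row + 1L,
                                              info$grid_col + 1L)]
  expect_equal(rec, unname(v), tolerance = 1e-6)
})
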