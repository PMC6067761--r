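#' Read a long-format grid CSV into a MobilityGrid
#'
#' The long format has one row per observed cell-day with columns
#' \code{cell_id,row,col,julian_day,N}. Days absent from the file are kept
#' as \code{NA} in the assembled count matrix and are never imputed.
#'
#' @param path CSV file path
#' @return a \linkS4class{MobilityGrid}
#' @export
readGridCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "row", "col", "julian_day", "N")
  if (!all(need %in% names(df)))
    stop("grid CSV must have columns ", paste(need, collapse = ","))
  bad <- which(is.na(df$julian_day) | is.na(df$N) | !nzchar(df$cell_id))
  if (length(bad))
    stop("malformed grid CSV row(s) at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  if (any(df$N < 0)) stop("negative counts in grid CSV")
  key <- paste(df$cell_id, df$julian_day)
  if (anyDuplicated(key))
    stop("integrity error: duplicated (cell_id, julian_day) pair(s), e.g. ",
         key[which(duplicated(key))[1]])
  days <- sort(unique(df$julian_day))
  cells <- unique(df$cell_id)
  counts <- matrix(NA_integer_, nrow = length(cells), ncol = length(days),
                   dimnames = list(cells, NULL))
  counts[cbind(match(df$cell_id, cells), match(df$julian_day, days))] <-
    as.integer(df$N)
  first <- !duplicated(df$cell_id)
  info <- S4Vectors::DataFrame(grid_row = as.integer(df$row[first]),
                               grid_col = as.integer(df$col[first]),
                               row.names = df$cell_id[first])
  MobilityGrid(counts, julianDays = days, cellInfo = info[cells, ,
                                                          drop = FALSE])
}

#' Write a MobilityGrid as a long-format CSV
#'
#' Inverse of \code{\link{readGridCSV}}; absent (\code{NA}) cell-days are
#' omitted from the file.
#'
#' @param grid a \linkS4class{MobilityGrid}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeGridCSV <- function(grid, path) {
  n <- cellCounts(grid)
  info <- cellInfo(grid)
  long <- data.frame(
    cell_id = rep(rownames(n), times = ncol(n)),
    row = rep(info$grid_row, times = ncol(n)),
    col = rep(info$grid_col, times = ncol(n)),
    julian_day = rep(julianDays(grid), each = nrow(n)),
    N = as.vector(n))
  long <- long[!is.na(long$N), ]
  long <- long[order(long$cell_id, long$julian_day), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude low-activity grid cells
#'
#' Applies the activity filter used to reduce noise from remote lands:
#' cells whose arithmetic mean daily count over their observed days is
#' below \code{min_mean} are dropped. The criterion is a strict \code{<},
#' so a cell with mean exactly \code{min_mean} is retained. The mean is
#' computed over observed days only (absent days are not imputed as 0).
#'
#' @param grid a \linkS4class{MobilityGrid}
#' @param min_mean exclusion cutoff in counts/day (default 2)
#' @return the retained subset, with \code{metadata()$low_activity}
#'   recording the excluded cell ids and count
#' @export
filterLowActivity <- function(grid, min_mean = 2) {
  if (nrow(grid) == 0) return(grid)
  m <- rowMeans(cellCounts(grid), na.rm = TRUE)
  keep <- m >= min_mean
  out <- grid[keep, ]
  S4Vectors::metadata(out)$low_activity <- list(
    min_mean = min_mean,
    n_excluded = sum(!keep),
    excluded_ids = rownames(grid)[!keep])
  out
}

#' Assign settlement points to grid cells
#'
#' Cells are axis-aligned unit squares with half-open extents
#' \code{[col, col+1) x [row, row+1)} in the grid's planar frame, so a
#' point on a cell's lower-left corner belongs to that cell and a point on
#' the grid's outer maximum edge belongs to no cell. Points falling outside
#' the grid (or on a (row, col) not present in it) are counted as
#' unassigned and reported, not dropped silently.
#'
#' @param points data.frame with columns \code{id}, \code{x}, \code{y}
#' @param grid a \linkS4class{MobilityGrid} providing the cell geometry
#' @return list with \code{counts} (named integer vector, one entry per
#'   grid cell, zeros included), \code{n_assigned}, \code{n_unassigned}
#'   and \code{unassigned_ids}
#' @export
indexSettlements <- function(points, grid) {
  stopifnot(all(c("id", "x", "y") %in% names(points)))
  info <- cellInfo(grid)
  key <- paste(info$grid_row, info$grid_col)
  pcell <- match(paste(floor(points$y), floor(points$x)), key)
  counts <- integer(nrow(grid))
  names(counts) <- rownames(grid)
  tab <- table(pcell)
  counts[as.integer(names(tab))] <- as.integer(tab)
  unassigned <- is.na(pcell)
  list(counts = counts,
       n_assigned = sum(!unassigned),
       n_unassigned = sum(unassigned),
       unassigned_ids = points$id[unassigned])
}

#' Read / write auxiliary tables
#'
#' \code{readRadianceCSV} reads a per-cell radiance table
#' (\code{cell_id,radiance}) as a named vector. \code{readSettlementsCSV}
#' and \code{writeSettlementsCSV} handle settlement point tables
#' (\code{id,x,y}); \code{writeSettlementsGeoJSON} and
#' \code{readSettlementsGeoJSON} do the same as a GeoJSON point
#' FeatureCollection. \code{readRegionMapCSV} reads the cell-to-region map
#' (\code{cell_id,county_id,city_id,province_id}).
#'
#' @param path file path
#' @param points data.frame with \code{id,x,y}
#' @name aux-io
NULL

#' @rdname aux-io
#' @export
readRadianceCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "radiance") %in% names(df)))
  stats::setNames(df$radiance, df$cell_id)
}

#' @rdname aux-io
#' @export
readSettlementsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "x", "y") %in% names(df)))
  df
}

#' @rdname aux-io
#' @export
writeSettlementsCSV <- function(points, path) {
  utils::write.csv(points[, c("id", "x", "y")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname aux-io
#' @export
writeSettlementsGeoJSON <- function(points, path) {
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         properties = list(id = points$id[i]),
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname aux-io
#' @export
readSettlementsGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  do.call(rbind, lapply(gj$features, function(f) {
    data.frame(id = f$properties$id,
               x = as.numeric(f$geometry$coordinates[[1]]),
               y = as.numeric(f$geometry$coordinates[[2]]),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname aux-io
#' @export
readRegionMapCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "county_id", "city_id", "province_id") %in%
                  names(df)))
  df
}

#' Export a per-cell scalar as a single-band TIFF raster
#'
#' Writes one value per grid cell (e.g. net increase or relative rate) as
#' a single-band TIFF laid out on the cell grid. TIFF sample values are
#' confined to [0, 1], so the values are rescaled affinely and the
#' transform (\code{offset}, \code{scale}, i.e.
#' \code{value = offset + scale * sample}) is recorded in a JSON sidecar
#' \code{<path>.json} together with the cells lacking a value (written as
#' sample 0). The grid lives in an abstract planar frame, so no
#' geospatial tags are written. Requires the suggested \pkg{tiff} package.
#'
#' @param values named numeric vector (names = cell ids)
#' @param grid a \linkS4class{MobilityGrid}
#' @param path output .tif path
#' @return \code{path}, invisibly
#' @export
writeRasterTIFF <- function(values, grid, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for raster export")
  info <- cellInfo(grid)
  nr <- max(info$grid_row) + 1L
  nc <- max(info$grid_col) + 1L
  img <- matrix(NA_real_, nr, nc)
  img[cbind(info$grid_row + 1L, info$grid_col + 1L)] <-
    values[rownames(grid)]
  fin <- is.finite(img)
  rng <- if (any(fin)) range(img[fin]) else c(0, 1)
  scale <- max(rng[2] - rng[1], .Machine$double.eps)
  samp <- (img - rng[1]) / scale
  samp[!fin] <- 0
  tiff::writeTIFF(samp, path, bits.per.sample = 32, reduce = TRUE)
  jsonlite::write_json(list(offset = rng[1], scale = scale,
                            n_missing = sum(!fin),
                            nrow = nr, ncol = nc),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
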