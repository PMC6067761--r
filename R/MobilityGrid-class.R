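#' MobilityGrid: gridded daily location-request counts
#'
#' An S4 container for the central data object of the package: a grid of
#' ~1 km cells observed over a window of consecutive Julian days, holding
#' the daily aggregate count of mobile location requests (\code{N}) per
#' cell. The class extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: rows are grid cells,
#' columns are days, and the single assay \code{"N"} is an integer matrix
#' (with \code{NA} for cell-days absent from the source feed, which are
#' never imputed).
#'
#' Row metadata (\code{rowData}) carries per-cell attributes as they become
#' available along the pipeline: grid indices (\code{grid_row},
#' \code{grid_col}), nightlight \code{radiance}, \code{settlements} (count
#' of rural settlement points contained in the cell), region membership
#' (\code{county_id}, \code{city_id}, \code{province_id}) and, after
#' partitioning, \code{domain} (\code{"urban"} or \code{"rural"}). Column
#' metadata carries \code{julian_day}. Simulated objects additionally store
#' ground truth under \code{metadata()}: \code{truth} (per-cell true
#' domain, break day and step factor), \code{regionTruth} (per-county
#' hukou-accounting truth) and \code{settlementPoints}.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#'
#' @seealso \code{\link{simulateMobilityGrid}}, \code{\link{readGridCSV}},
#'   \code{\link{filterLowActivity}}, \code{\link{detectTurningPoints}}
#' @importFrom methods setClass setMethod setValidity validObject is new callNextMethod
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass MobilityGrid
setClass("MobilityGrid", contains = "SummarizedExperiment")

setValidity("MobilityGrid", function(object) {
  msg <- character()
  if (!"N" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'N' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"julian_day" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain 'julian_day'")
  } else {
    jd <- cd$julian_day
    if (length(jd) > 1 && any(diff(jd) <= 0))
      msg <- c(msg, "julian_day must be strictly increasing")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("grid_row", "grid_col") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'grid_row' and 'grid_col'")
  if ("N" %in% SummarizedExperiment::assayNames(object)) {
    n <- SummarizedExperiment::assay(object, "N")
    if (any(n < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MobilityGrid
#'
#' @param counts integer matrix of daily counts, cells in rows (rownames =
#'   cell ids), days in columns; \code{NA} marks absent cell-days.
#' @param julianDays integer vector of Julian days (1-based day-of-year),
#'   strictly increasing, one per column of \code{counts}.
#' @param cellInfo data.frame or DataFrame of per-cell metadata; must
#'   contain \code{grid_row} and \code{grid_col} (0-based grid indices).
#' @param metadata optional list stored in \code{metadata()}.
#' @return a \linkS4class{MobilityGrid}
#' @examples
#' m <- matrix(rpois(6, 5), nrow = 2,
#'             dimnames = list(c("c1", "c2"), NULL))
#' mg <- MobilityGrid(m, julianDays = 16:18,
#'                    cellInfo = data.frame(grid_row = c(0, 0),
#'                                          grid_col = c(0, 1)))
#' @export
MobilityGrid <- function(counts, julianDays, cellInfo, metadata = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("'counts' must have rownames (cell ids)")
  if (ncol(counts) != length(julianDays))
    stop("length(julianDays) must equal ncol(counts)")
  colnames(counts) <- paste0("d", julianDays)
  cd <- S4Vectors::DataFrame(julian_day = as.integer(julianDays),
                             row.names = colnames(counts))
  rd <- S4Vectors::DataFrame(cellInfo, row.names = rownames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(N = counts), rowData = rd, colData = cd,
    metadata = metadata)
  obj <- methods::new("MobilityGrid", se)
  methods::validObject(obj)
  obj
}

#' @describeIn MobilityGrid compact display
#' @param object a MobilityGrid
#' @export
setMethod("show", "MobilityGrid", function(object) {
  jd <- julianDays(object)
  cat("MobilityGrid:", nrow(object), "cells x", ncol(object), "days",
      sprintf("(Julian days %d..%d)\n", min(jd), max(jd)))
  rd <- SummarizedExperiment::rowData(object)
  if ("domain" %in% colnames(rd)) {
    tab <- table(rd$domain, useNA = "ifany")
    cat("  domains:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(S4Vectors::metadata(object)$truth))
    cat("  simulated object with recorded ground truth\n")
  invisible(NULL)
})

#' Accessors for MobilityGrid
#'
#' \code{cellCounts} returns the cells x days count matrix (assay
#' \code{"N"}); \code{julianDays} the Julian day of each column;
#' \code{cellIds} the cell identifiers; \code{cellInfo} the per-cell
#' metadata (\code{rowData}); \code{gridTruth} the generator's per-cell
#' ground truth (or \code{NULL} for observed data).
#'
#' @param x a \linkS4class{MobilityGrid}
#' @return see individual descriptions
#' @name MobilityGrid-accessors
#' @aliases cellCounts julianDays cellIds cellInfo gridTruth
NULL

#' @rdname MobilityGrid-accessors
#' @export
cellCounts <- function(x) SummarizedExperiment::assay(x, "N")

#' @rdname MobilityGrid-accessors
#' @export
julianDays <- function(x) SummarizedExperiment::colData(x)$julian_day

#' @rdname MobilityGrid-accessors
#' @export
cellIds <- function(x) rownames(x)

#' @rdname MobilityGrid-accessors
#' @export
cellInfo <- function(x) SummarizedExperiment::rowData(x)

#' @rdname MobilityGrid-accessors
#' @export
gridTruth <- function(x) S4Vectors::metadata(x)$truth
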