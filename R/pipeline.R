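#' Pipeline configuration
#'
#' Collects every tunable of the full analysis in one validated object.
#' All published constants are named defaults here rather than being
#' hard-coded in stage code: the activity cutoff (2 counts/day), the
#' rural radiance threshold (0.738), the significance level (0.05), the
#' New Year Julian day (39), the break-search trimming (0.15) and the
#' source/sink deviation multiple (k = 2).
#'
#' @param generator a \code{\link{generatorConfig}} (used when
#'   \code{grid_csv} is NULL)
#' @param grid_csv,radiance_csv,settlements_csv,region_map_csv,census_csv
#'   optional input file paths; when \code{grid_csv} is given the pipeline
#'   ingests files instead of simulating
#' @param min_mean activity-filter cutoff (counts/day)
#' @param threshold rural radiance boundary
#' @param alpha significance level
#' @param cny_day Julian day of the New Year
#' @param trim break-search trimming fraction
#' @param lags break-search lag order
#' @param tier tier used for regional aggregation maps
#' @param k source/sink deviation multiple
#' @param census_noise_sd noise on the simulated census
#' @param outdir output directory
#' @param seed master seed (propagated into the generator)
#' @param verbose log stage progress to stderr
#' @return list of class \code{"PipelineConfig"}
#' @export
pipelineConfig <- function(generator = generatorConfig(),
                           grid_csv = NULL, radiance_csv = NULL,
                           settlements_csv = NULL, region_map_csv = NULL,
                           census_csv = NULL,
                           min_mean = 2, threshold = 0.738, alpha = 0.05,
                           cny_day = 39, trim = 0.15, lags = 0,
                           tier = "medium", k = 2, census_noise_sd = 0.1,
                           outdir = tempfile("ruralflight_run_"),
                           seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) {
    generator$seed <- as.integer(seed)
    generator <- do.call(generatorConfig, unclass(generator))
  }
  cfg <- list(generator = generator, grid_csv = grid_csv,
              radiance_csv = radiance_csv,
              settlements_csv = settlements_csv,
              region_map_csv = region_map_csv, census_csv = census_csv,
              min_mean = min_mean, threshold = threshold, alpha = alpha,
              cny_day = as.integer(cny_day), trim = trim,
              lags = as.integer(lags), tier = tier, k = k,
              census_noise_sd = census_noise_sd,
              outdir = outdir, verbose = isTRUE(verbose))
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(cfg$grid_csv)) {
    dr <- cfg$generator$day_range
    if (cfg$cny_day < dr[1] || cfg$cny_day > dr[2])
      stop("cny_day must lie within the generator day range")
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{pipelineConfig}};
#' a \code{generator:} mapping mirrors \code{\link{generatorConfig}}.
#'
#' @param path YAML file
#' @return a \code{PipelineConfig}
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  y$generator <- NULL
  gen <- if (is.null(gen_args)) generatorConfig() else {
    if (!is.null(gen_args$baseline_rate))
      gen_args$baseline_rate <- unlist(gen_args$baseline_rate)
    if (!is.null(gen_args$day_range))
      gen_args$day_range <- as.integer(unlist(gen_args$day_range))
    if (!is.null(gen_args$nightlight_stats))
      gen_args$nightlight_stats <-
        as.data.frame(lapply(gen_args$nightlight_stats, unlist),
                      stringsAsFactors = FALSE)
    do.call(generatorConfig, gen_args)
  }
  do.call(pipelineConfig, c(list(generator = gen), y))
}

#' Run the full analysis pipeline
#'
#' Orchestrates: data acquisition (simulate, or ingest the CSV inputs)
#' -> activity filter -> nightlight partition -> per-cell turning-point
#' detection -> tier assignment and urban decline flags -> regional and
#' country-level statistics -> census validation. All stage outputs are
#' written under \code{config$outdir} together with a JSON manifest
#' recording the configuration hash, seed, stage row counts and package
#' version; re-running the same configuration reproduces identical
#' outputs.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return the manifest, invisibly; stage results are attached as
#'   attribute \code{"results"}
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(...) if (config$verbose) message("[ruralflight] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- acquire -------------------------------------------------------
  simulated <- is.null(config$grid_csv)
  grid <- stage("acquire", {
    if (simulated) {
      log_("simulating grid (seed ", config$generator$seed, ")")
      g <- simulateMobilityGrid(config$generator)
      writeGridCSV(g, file.path(config$outdir, "grid.csv"))
      utils::write.csv(
        data.frame(cell_id = cellIds(g),
                   radiance = cellInfo(g)$radiance),
        file.path(config$outdir, "radiance.csv"), row.names = FALSE,
        quote = FALSE)
      writeSettlementsCSV(S4Vectors::metadata(g)$settlementPoints,
                          file.path(config$outdir, "settlements.csv"))
      utils::write.csv(
        data.frame(cell_id = cellIds(g),
                   county_id = cellInfo(g)$county_id,
                   city_id = cellInfo(g)$city_id,
                   province_id = cellInfo(g)$province_id),
        file.path(config$outdir, "region_map.csv"), row.names = FALSE,
        quote = FALSE)
      utils::write.csv(as.data.frame(gridTruth(g)),
                       file.path(config$outdir, "truth_cells.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(S4Vectors::metadata(g)$regionTruth,
                       file.path(config$outdir, "truth_regions.csv"),
                       row.names = FALSE, quote = FALSE)
      g
    } else {
      log_("reading grid from ", config$grid_csv)
      g <- readGridCSV(config$grid_csv)
      if (!is.null(config$radiance_csv)) {
        rad <- readRadianceCSV(config$radiance_csv)
        SummarizedExperiment::rowData(g)$radiance <-
          unname(rad[cellIds(g)])
      }
      if (!is.null(config$region_map_csv)) {
        rm_ <- readRegionMapCSV(config$region_map_csv)
        m <- match(cellIds(g), rm_$cell_id)
        SummarizedExperiment::rowData(g)$county_id <- rm_$county_id[m]
        SummarizedExperiment::rowData(g)$city_id <- rm_$city_id[m]
        SummarizedExperiment::rowData(g)$province_id <- rm_$province_id[m]
      }
      g
    }
  })

  # --- filter --------------------------------------------------------
  filtered <- stage("filter", filterLowActivity(grid, config$min_mean))
  n_excluded <- S4Vectors::metadata(filtered)$low_activity$n_excluded
  log_("activity filter: ", nrow(filtered), " retained, ", n_excluded,
       " excluded")

  # --- settlements ---------------------------------------------------
  settle <- stage("settlements", {
    pts <- if (simulated) S4Vectors::metadata(grid)$settlementPoints
    else if (!is.null(config$settlements_csv))
      readSettlementsCSV(config$settlements_csv)
    else NULL
    if (is.null(pts)) NULL else indexSettlements(pts, filtered)
  })
  settlement_counts <- if (is.null(settle))
    stats::setNames(integer(nrow(filtered)), cellIds(filtered))
  else settle$counts
  total_sites_all <- if (is.null(settle)) 0L else
    settle$n_assigned + settle$n_unassigned

  # --- partition -----------------------------------------------------
  filtered <- stage("partition", partitionGrid(filtered, config$threshold))
  part <- table(cellInfo(filtered)$domain)
  log_("partition: ", paste(names(part), part, sep = "=", collapse = ", "))
  utils::write.csv(
    data.frame(cell_id = cellIds(filtered),
               label = cellInfo(filtered)$domain),
    file.path(config$outdir, "partition.csv"), row.names = FALSE,
    quote = FALSE)

  # --- detect --------------------------------------------------------
  tp <- stage("detect", detectTurningPoints(filtered, trim = config$trim,
                                            lags = config$lags,
                                            verbose = config$verbose))
  utils::write.csv(as.data.frame(tp),
                   file.path(config$outdir, "turning_points.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- tiers ---------------------------------------------------------
  rural_tp <- tp[!is.na(tp$domain) & tp$domain == "rural", ]
  urban_tp <- tp[!is.na(tp$domain) & tp$domain == "urban", ]
  tiers <- stage("tiers", assignTiers(rural_tp,
                                      settlement_counts[rural_tp$cell_id],
                                      cny_day = config$cny_day,
                                      alpha = config$alpha))
  urban_decline <- flagUrbanDecline(urban_tp, alpha = config$alpha)
  utils::write.csv(as.data.frame(tiers),
                   file.path(config$outdir, "tiers.csv"),
                   row.names = FALSE, quote = FALSE)
  tier_summary <- summarizeTiers(tiers)
  tier_summary_all <- summarizeTiers(tiers, total_sites = total_sites_all)

  # --- regions -------------------------------------------------------
  region_map <- data.frame(cell_id = cellIds(filtered),
                           county_id = cellInfo(filtered)$county_id,
                           city_id = cellInfo(filtered)$city_id,
                           province_id = cellInfo(filtered)$province_id,
                           stringsAsFactors = FALSE)
  have_regions <- !any(is.na(region_map$county_id))
  summaries <- NULL
  validation <- NULL
  if (have_regions) {
    summaries <- stage("regions", do.call(rbind, lapply(
      c("county_id", "city_id", "province_id"), function(lev)
        aggregateRegions(tp, region_map, level = lev,
                         assignments = tiers, tier = config$tier,
                         k = config$k))))
    for (lev in unique(summaries$level))
      utils::write.csv(summaries[summaries$level == lev, ],
                       file.path(config$outdir,
                                 paste0("region_summary_", sub("_id$", "",
                                                               lev),
                                        ".csv")),
                       row.names = FALSE, quote = FALSE)
    census <- if (simulated)
      simulateCensus(grid, noise_sd = config$census_noise_sd)
    else if (!is.null(config$census_csv))
      utils::read.csv(config$census_csv, stringsAsFactors = FALSE)
    else NULL
    if (!is.null(census)) {
      selected <- selectCounties(census)
      om <- cbind(selected,
                  inferOutMigrants(selected$registered_pop,
                                   selected$resident_hukou_pop))
      validation <- stage("validate",
                          validateAgainstCensus(summaries[
                            summaries$level == "county_id", ], om))
      utils::write.csv(census, file.path(config$outdir, "census.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }

  # --- country series ------------------------------------------------
  cs <- stage("country", countrySeries(filtered))
  props <- domainProportions(cs)
  utils::write.csv(cs, file.path(config$outdir, "country_series.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- optional raster export (abstract planar frame, no geo tags) ---
  if (requireNamespace("tiff", quietly = TRUE)) {
    net <- stats::setNames(cellNetIncrease(tp), tp$cell_id)
    writeRasterTIFF(net, filtered, file.path(config$outdir,
                                             "net_increase.tif"))
    rate <- stats::setNames(cellRelativeRate(tp), tp$cell_id)
    writeRasterTIFF(rate, filtered, file.path(config$outdir,
                                              "relative_rate.tif"))
  }

  # --- manifest ------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("ruralflight")),
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      c("outdir",
                                                        "verbose"))]),
    seed = if (simulated) config$generator$seed else NA,
    stages = list(
      input_cells = nrow(grid),
      retained_cells = nrow(filtered),
      excluded_cells = n_excluded,
      urban_cells = sum(cellInfo(filtered)$domain == "urban"),
      rural_cells = sum(cellInfo(filtered)$domain == "rural"),
      settlement_sites = total_sites_all,
      tier_cells = stats::setNames(as.list(tier_summary$n_cells),
                                   tier_summary$tier),
      urban_decline_cells = sum(urban_decline)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  summary_json <- list(
    tiers = tier_summary, tiers_vs_all_sites = tier_summary_all,
    rural_peak = attr(props, "rural_peak"),
    validation = validation)
  jsonlite::write_json(summary_json, file.path(config$outdir,
                                               "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  attr(manifest, "results") <- list(
    grid = grid, filtered = filtered, turning_points = tp,
    tiers = tiers, urban_decline = urban_decline,
    tier_summary = tier_summary, tier_summary_all_sites = tier_summary_all,
    summaries = summaries, validation = validation,
    country_series = cs, proportions = props)
  invisible(manifest)
}

#' Write a small demo dataset and its expected summaries
#'
#' Simulates the default 1,200-cell configuration, writes all its input
#' files and the full pipeline outputs under \code{outdir}, and returns
#' the manifest. The fixture is small enough for interactive use and the
#' test suite.
#'
#' @param outdir output directory
#' @param seed master seed
#' @return the pipeline manifest, invisibly
#' @export
makeDemo <- function(outdir = tempfile("ruralflight_demo_"), seed = 1L) {
  cfg <- pipelineConfig(generator = generatorConfig(seed = as.integer(seed)),
                        outdir = outdir)
  runPipeline(cfg)
}
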