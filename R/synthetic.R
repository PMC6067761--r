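#' Configuration for the synthetic grid generator
#'
#' Builds and validates the parameter set for
#' \code{\link{simulateMobilityGrid}}. The defaults describe the study
#' window the analysis targets: a 29-day observation window (Julian days
#' 16--44 of 2016, i.e. Jan 16 -- Feb 13) spanning the Chunyun travel
#' season, with the Chinese New Year on Julian day 39 (Feb 8). Daily counts
#' are Poisson with a piecewise-constant mean: rural cells carrying an
#' implanted migration effect step up by \code{effect_rural} at a break day
#' drawn uniformly from \code{cny_day +/- break_day_jitter}; urban cells
#' step down by \code{effect_urban}; "empty" cells keep a constant mean
#' below 2 counts/day so that the low-activity filter has work to do.
#'
#' Nightlight radiance is drawn per true class from a normal distribution
#' truncated (clamped) at 0, with the three class parameterisations
#' (large cities 48.82 +/- 22.73, small cities and townships 11.71 +/- 7.97,
#' rural villages 0.377 +/- 0.27, in 1e-9 W cm-2 sr-1); urban cells sample
#' from an even mixture of the two city classes, rural and empty cells from
#' the village class.
#'
#' @param n_rows,n_cols grid dimensions; \code{n_rows * n_cols} must equal
#'   \code{n_urban + n_rural + n_empty}.
#' @param day_range inclusive Julian-day span of the window.
#' @param cny_day Julian day of the Chinese New Year.
#' @param n_urban,n_rural,n_empty cell counts per true class.
#' @param baseline_rate named vector of mean daily counts per class.
#' @param effect_rural multiplicative step factor for affected rural cells
#'   (> 1).
#' @param effect_urban step factor for urban cells (< 1).
#' @param frac_affected_rural fraction of rural cells carrying an implanted
#'   step; exactly \code{round(frac * n_rural)} cells are affected.
#' @param break_day_jitter max |offset| of an implanted break from
#'   \code{cny_day}, in days. The default of 2 keeps every implanted break
#'   within 2 days of a reachable candidate of the trimmed break search
#'   (candidate days 21..39 under the default window and 15\% trimming).
#' @param nightlight_stats data.frame with columns \code{label},
#'   \code{mean}, \code{sd} for the three radiance classes.
#' @param settlements_per_rural_cell Poisson mean of settlement points per
#'   rural cell.
#' @param n_counties,counties_per_city,cities_per_province region layout;
#'   counties are contiguous equal-sized strips of cells, merged upward
#'   into cities and provinces.
#' @param persons_per_unit out-migrants per unit of implanted daily net
#'   increase, coupling the census tables to the implanted effects.
#' @param seed master seed; all sub-streams derive from it.
#' @return a validated list of class \code{"GeneratorConfig"}
#' @export
generatorConfig <- function(n_rows = 30, n_cols = 40,
                            day_range = c(16L, 44L), cny_day = 39L,
                            n_urban = 350, n_rural = 700, n_empty = 150,
                            baseline_rate = c(urban = 50, rural = 5,
                                              empty = 0.8),
                            effect_rural = 3, effect_urban = 0.5,
                            frac_affected_rural = 0.6,
                            break_day_jitter = 2,
                            nightlight_stats = nightlightClassStats(),
                            settlements_per_rural_cell = 1.0,
                            n_counties = 30, counties_per_city = 2,
                            cities_per_province = 3,
                            persons_per_unit = 30,
                            seed = 1L) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              day_range = as.integer(day_range), cny_day = as.integer(cny_day),
              n_urban = as.integer(n_urban), n_rural = as.integer(n_rural),
              n_empty = as.integer(n_empty), baseline_rate = baseline_rate,
              effect_rural = effect_rural, effect_urban = effect_urban,
              frac_affected_rural = frac_affected_rural,
              break_day_jitter = as.integer(break_day_jitter),
              nightlight_stats = nightlight_stats,
              settlements_per_rural_cell = settlements_per_rural_cell,
              n_counties = as.integer(n_counties),
              counties_per_city = as.integer(counties_per_city),
              cities_per_province = as.integer(cities_per_province),
              persons_per_unit = persons_per_unit,
              seed = as.integer(seed))
  n_cells <- cfg$n_rows * cfg$n_cols
  if (n_cells < 1)
    stop("empty grid: n_rows * n_cols must be >= 1")
  if (cfg$n_urban + cfg$n_rural + cfg$n_empty != n_cells)
    stop("n_urban + n_rural + n_empty must equal n_rows * n_cols")
  if (any(cfg$n_urban < 0, cfg$n_rural < 0, cfg$n_empty < 0))
    stop("class cell counts must be non-negative")
  if (!all(c("urban", "rural", "empty") %in% names(cfg$baseline_rate)))
    stop("baseline_rate must name 'urban', 'rural' and 'empty'")
  if (any(cfg$baseline_rate <= 0))
    stop("baseline rates must be strictly positive")
  if (cfg$effect_rural <= 0 || cfg$effect_urban <= 0)
    stop("effect factors must be strictly positive")
  if (cfg$frac_affected_rural < 0 || cfg$frac_affected_rural > 1)
    stop("frac_affected_rural must lie in [0, 1]")
  if (cfg$day_range[1] > cfg$day_range[2])
    stop("day_range must be an inclusive span")
  if (cfg$cny_day < cfg$day_range[1] || cfg$cny_day > cfg$day_range[2])
    stop("day_range must cover cny_day")
  if (cfg$break_day_jitter < 0)
    stop("break_day_jitter must be >= 0")
  if (cfg$settlements_per_rural_cell < 0)
    stop("settlements_per_rural_cell must be >= 0")
  if (n_cells %% cfg$n_counties != 0)
    stop("n_counties must divide the number of cells")
  if (cfg$n_counties %% cfg$counties_per_city != 0)
    stop("counties_per_city must divide n_counties")
  n_cities <- cfg$n_counties / cfg$counties_per_city
  if (n_cities %% cfg$cities_per_province != 0)
    stop("cities_per_province must divide the number of cities")
  st <- cfg$nightlight_stats
  if (!all(c("label", "mean", "sd") %in% names(st)) || any(st$sd <= 0))
    stop("nightlight_stats needs label/mean/sd with sd > 0")
  class(cfg) <- "GeneratorConfig"
  cfg
}

#' @export
print.GeneratorConfig <- function(x, ...) {
  cat("GeneratorConfig:", x$n_rows, "x", x$n_cols, "grid,",
      sprintf("days %d..%d (CNY day %d)\n", x$day_range[1], x$day_range[2],
              x$cny_day))
  cat(sprintf("  classes: urban %d, rural %d, empty %d; affected rural %.0f%%\n",
              x$n_urban, x$n_rural, x$n_empty, 100 * x$frac_affected_rural))
  cat(sprintf("  effects: rural x%.2f, urban x%.2f; break jitter +/-%d days\n",
              x$effect_rural, x$effect_urban, x$break_day_jitter))
  invisible(x)
}

#' Simulate a gridded location-request dataset with ground truth
#'
#' Generates a complete synthetic input set for the pipeline: daily Poisson
#' counts per cell with implanted step changes around the New Year,
#' per-cell nightlight radiance, rural settlement points, a contiguous
#' county/city/province region layout, and per-county hukou-accounting
#' truth coupled to the implanted rural effects. All ground truth is stored
#' in \code{metadata()} of the returned object. Identical \code{config}
#' (including its \code{seed}) gives bit-identical output.
#'
#' @param config a \code{\link{generatorConfig}}
#' @return a \linkS4class{MobilityGrid} with metadata elements
#'   \code{truth}, \code{regionTruth}, \code{settlementPoints} and
#'   \code{config}
#' @examples
#' g <- simulateMobilityGrid(generatorConfig(seed = 7))
#' g
#' @export
simulateMobilityGrid <- function(config = generatorConfig()) {
  if (!inherits(config, "GeneratorConfig"))
    config <- do.call(generatorConfig, config)
  set.seed(config$seed)
  n_cells <- config$n_rows * config$n_cols
  days <- seq(config$day_range[1], config$day_range[2])
  n_days <- length(days)

  # cell geometry, column-major so county strips are contiguous blocks
  grid_col <- rep(seq_len(config$n_cols) - 1L, each = config$n_rows)
  grid_row <- rep(seq_len(config$n_rows) - 1L, times = config$n_cols)
  cell_id <- sprintf("cell_%05d", seq_len(n_cells))

  # true class assignment, random across the grid
  domain <- sample(rep(c("urban", "rural", "empty"),
                       times = c(config$n_urban, config$n_rural,
                                 config$n_empty)))

  # region layout: equal contiguous strips of cells
  cells_per_county <- n_cells / config$n_counties
  county <- (seq_len(n_cells) - 1L) %/% cells_per_county + 1L
  city <- (county - 1L) %/% config$counties_per_city + 1L
  province <- (city - 1L) %/% config$cities_per_province + 1L
  county_id <- sprintf("county_%03d", county)
  city_id <- sprintf("city_%03d", city)
  province_id <- sprintf("province_%02d", province)

  # implanted breaks: exactly round(frac * n_rural) rural cells; all urban
  rural_idx <- which(domain == "rural")
  n_affected <- round(config$frac_affected_rural * length(rural_idx))
  affected_rural <- sort(sample(rural_idx, n_affected))
  urban_idx <- which(domain == "urban")
  jit <- config$break_day_jitter
  break_choices <- seq(config$cny_day - jit, config$cny_day + jit)
  true_break <- rep(NA_integer_, n_cells)
  true_break[affected_rural] <- sample(break_choices, n_affected,
                                       replace = TRUE)
  true_break[urban_idx] <- sample(break_choices, length(urban_idx),
                                  replace = TRUE)
  true_effect <- rep(1, n_cells)
  true_effect[affected_rural] <- config$effect_rural
  true_effect[urban_idx] <- config$effect_urban

  # Poisson counts with piecewise-constant mean
  base <- config$baseline_rate[domain]
  mu <- matrix(rep(base, n_days), nrow = n_cells)
  has_break <- !is.na(true_break)
  post <- outer(true_break[has_break], days, function(b, d) d >= b)
  mu[has_break, ][post] <- (base[has_break] * true_effect[has_break])[
    row(post)[post]]
  counts <- matrix(stats::rpois(n_cells * n_days, mu), nrow = n_cells,
                   dimnames = list(cell_id, NULL))

  # nightlight radiance: urban = even large/small city mixture
  st <- config$nightlight_stats
  stat_of <- function(lab) st[st$label == lab, , drop = FALSE]
  radiance <- numeric(n_cells)
  rv <- stat_of("rural")
  nr <- sum(domain != "urban")
  radiance[domain != "urban"] <- stats::rnorm(nr, rv$mean, rv$sd)
  if (length(urban_idx)) {
    pick_large <- stats::runif(length(urban_idx)) < 0.5
    lc <- stat_of("large_city"); sc <- stat_of("small_city")
    m <- ifelse(pick_large, lc$mean, sc$mean)
    s <- ifelse(pick_large, lc$sd, sc$sd)
    radiance[urban_idx] <- stats::rnorm(length(urban_idx), m, s)
  }
  radiance[radiance < 0] <- 0

  # settlement points: uniform within unit cells, rural cells only
  k <- integer(n_cells)
  k[rural_idx] <- stats::rpois(length(rural_idx),
                               config$settlements_per_rural_cell)
  tot <- sum(k)
  settlements <- data.frame(
    id = sprintf("site_%06d", seq_len(tot)),
    x = rep(grid_col, k) + stats::runif(tot),
    y = rep(grid_row, k) + stats::runif(tot),
    cell_id = rep(cell_id, k),
    stringsAsFactors = FALSE)

  # per-county hukou accounting coupled to implanted rural effect mass
  rural_rate <- config$baseline_rate[["rural"]]
  implant <- ifelse(domain == "rural" & has_break,
                    rural_rate * (true_effect - 1), 0)
  eff_mass <- as.vector(tapply(implant, county, sum))
  n_rural_c <- as.vector(tapply(domain == "rural", county, sum))
  n_urban_c <- as.vector(tapply(domain == "urban", county, sum))
  n_cells_c <- as.vector(table(county))
  out_mig <- round(config$persons_per_unit * eff_mass)
  resident <- round((n_rural_c * 1000 + n_urban_c * 3000) *
                      stats::runif(config$n_counties, 0.8, 1.2))
  agri <- pmin(pmax(n_rural_c / n_cells_c *
                      stats::runif(config$n_counties, 0.9, 1.15), 0), 1)
  nonhukou <- stats::runif(config$n_counties, 0, 0.15)
  region_truth <- data.frame(
    county_id = sprintf("county_%03d", seq_len(config$n_counties)),
    city_id = sprintf("city_%03d",
                      (seq_len(config$n_counties) - 1L) %/%
                        config$counties_per_city + 1L),
    province_id = sprintf("province_%02d",
                          ((seq_len(config$n_counties) - 1L) %/%
                             config$counties_per_city) %/%
                            config$cities_per_province + 1L),
    true_out_migrants = out_mig,
    registered_pop = resident + out_mig,
    resident_hukou_pop = resident,
    agri_share = agri,
    nonhukou_ratio = nonhukou,
    implanted_effect_mass = eff_mass,
    stringsAsFactors = FALSE)

  truth <- S4Vectors::DataFrame(
    cell_id = cell_id, true_domain = domain,
    true_break_day = true_break, true_effect = true_effect,
    row.names = cell_id)

  info <- S4Vectors::DataFrame(
    grid_row = grid_row, grid_col = grid_col,
    radiance = radiance, settlements = k,
    county_id = county_id, city_id = city_id, province_id = province_id,
    row.names = cell_id)

  MobilityGrid(counts, julianDays = days, cellInfo = info,
               metadata = list(truth = truth, regionTruth = region_truth,
                               settlementPoints = settlements,
                               config = config))
}

#' Simulate a county census table from generator truth
#'
#' Emulates the hukou accounting used to infer out-migrants: the observed
#' registered population minus the population still resident with local
#' hukou equals the true out-migrant count up to multiplicative noise
#' (exactly, at \code{noise_sd = 0}).
#'
#' @param grid a simulated \linkS4class{MobilityGrid} (its metadata must
#'   contain \code{regionTruth})
#' @param noise_sd multiplicative noise sd on the out-migrant difference
#' @param seed seed for the noise stream (default derived from the
#'   generator's master seed)
#' @return data.frame with one row per county: region ids, observed
#'   \code{registered_pop} and \code{resident_hukou_pop}, \code{agri_share}
#'   and \code{nonhukou_ratio}
#' @export
simulateCensus <- function(grid, noise_sd = 0.1, seed = NULL) {
  rt <- S4Vectors::metadata(grid)$regionTruth
  if (is.null(rt))
    stop("grid carries no region truth; was it simulated?")
  if (is.null(seed)) {
    cfg <- S4Vectors::metadata(grid)$config
    seed <- if (is.null(cfg)) 1L else (cfg$seed + 1013L) %% .Machine$integer.max
  }
  set.seed(seed)
  eps <- stats::rnorm(nrow(rt), 0, noise_sd)
  observed_out <- round(rt$true_out_migrants * (1 + eps))
  data.frame(county_id = rt$county_id, city_id = rt$city_id,
             province_id = rt$province_id,
             registered_pop = rt$resident_hukou_pop + observed_out,
             resident_hukou_pop = rt$resident_hukou_pop,
             agri_share = rt$agri_share,
             nonhukou_ratio = rt$nonhukou_ratio,
             stringsAsFactors = FALSE)
}

#' Simulate a paired visitor / location-request series
#'
#' Emulates the calibration comparison of the local sum of location
#' requests against independently counted visitors at a park over a 62-day
#' window: the count series is a noisy affine transform of the visitor
#' series, with configurable coupling.
#'
#' @param n_days series length (the reference comparison uses 62 days)
#' @param coupling coefficient linking N to the visitor series; 0 decouples
#'   them entirely
#' @param noise_sd sd of the additive noise, as a fraction of the visitor
#'   series' sd
#' @param baseline mean visitor level
#' @param amplitude relative amplitude of the weekly/holiday fluctuation
#' @param seed integer seed
#' @return data.frame with columns \code{day}, \code{visitors}, \code{N}
#' @export
simulateVisitorSeries <- function(n_days = 62, coupling = 1, noise_sd = 0.1,
                                  baseline = 1000, amplitude = 0.5,
                                  seed = 1L) {
  if (n_days < 3) stop("n_days must be >= 3")
  set.seed(seed)
  t <- seq_len(n_days)
  shape <- 1 + amplitude * sin(2 * pi * t / 7) +
    amplitude * exp(-((t - n_days / 2)^2) / (2 * (n_days / 10)^2))
  visitors <- stats::rpois(n_days, baseline * shape)
  sv <- stats::sd(visitors)
  N <- 50 + coupling * visitors + stats::rnorm(n_days, 0, noise_sd * sv)
  data.frame(day = t, visitors = visitors, N = N)
}
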