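#' Per-cell net increase and relative rate
#'
#' The net increase in N is NR_a - NR_b; the relative increase rate is
#' (NR_a - NR_b) / NR_b, undefined (NA) when the before-mean is 0.
#'
#' @param results turning-point results (data.frame-like with
#'   \code{mean_before}, \code{mean_after})
#' @return numeric vector
#' @name cell-changes
NULL

#' @rdname cell-changes
#' @export
cellNetIncrease <- function(results) {
  unname(results$mean_after - results$mean_before)
}

#' @rdname cell-changes
#' @export
cellRelativeRate <- function(results) {
  net <- results$mean_after - results$mean_before
  rate <- ifelse(results$mean_before > 0, net / results$mean_before,
                 NA_real_)
  unname(rate)
}

#' Aggregate cell results into regional summaries
#'
#' For each region at a given level, sums the per-cell net increase over
#' qualifying rural cells and computes the prevalence PR, the proportion
#' of the region's rural cells whose N increased. The qualifying set is by
#' default all rural cells with net increase > 0; passing \code{tier}
#' together with tier \code{assignments} restricts it to a tier
#' (e.g. the medium estimate). Urban cells contribute the regional net
#' decrease (sum of NU_b - NU_a over urban cells with a decline). Regional
#' shares of the nationwide rural increase / urban decrease and the
#' source/sink label (\code{\link{classifySourceSink}}) are attached.
#'
#' Additivity holds exactly: a merged region's net increase is the sum of
#' its parts', since regions partition the cells.
#'
#' @param results turning-point results with a \code{domain} column
#' @param region_map data.frame mapping \code{cell_id} to the region id
#'   columns; every cell in \code{results} must be mapped exactly once
#' @param level which id column of \code{region_map} to aggregate by
#' @param assignments optional tier assignments
#'   (\code{\link{assignTiers}})
#' @param tier optional tier name (\code{"lower"}, \code{"medium"},
#'   \code{"upper"}) selecting the qualifying rural set
#' @param k deviation multiple for the source/sink rule
#' @return data.frame, one row per region: \code{region_id},
#'   \code{level}, \code{n_rural_cells}, \code{n_increased},
#'   \code{net_increase}, \code{PR}, \code{net_decrease},
#'   \code{rural_share}, \code{urban_share}, \code{label}
#' @export
aggregateRegions <- function(results, region_map,
                             level = c("county_id", "city_id",
                                       "province_id"),
                             assignments = NULL, tier = NULL, k = 2) {
  level <- match.arg(level)
  idx <- match(results$cell_id, region_map$cell_id)
  if (any(is.na(idx)))
    stop("integrity error: unmapped cell(s), e.g. ",
         results$cell_id[which(is.na(idx))[1]])
  region <- region_map[[level]][idx]
  net <- cellNetIncrease(results)
  is_rural <- results$domain == "rural"
  is_urban <- results$domain == "urban"
  qualify <- is_rural & net > 0 & !results$no_break
  if (!is.null(tier)) {
    if (is.null(assignments))
      stop("tier filtering needs 'assignments'")
    col <- paste0("in_", match.arg(tier, c("lower", "medium", "upper")))
    member <- stats::setNames(assignments[[col]], assignments$cell_id)
    qualify <- is_rural & !is.na(member[results$cell_id]) &
      member[results$cell_id]
  }
  decline <- is_urban & net < 0 & !results$no_break
  regs <- sort(unique(region_map[[level]]))
  f <- factor(region, levels = regs)
  sum_by <- function(v, sel) {
    x <- tapply(ifelse(sel, v, 0), f, sum, default = 0)
    as.numeric(ifelse(is.na(x), 0, x))
  }
  n_rural <- sum_by(rep(1, length(net)), is_rural)
  n_inc <- sum_by(rep(1, length(net)), qualify)
  net_inc <- sum_by(net, qualify)
  net_dec <- sum_by(-net, decline)
  out <- data.frame(region_id = regs, level = level,
                    n_rural_cells = as.integer(n_rural),
                    n_increased = as.integer(n_inc),
                    net_increase = net_inc,
                    PR = ifelse(n_rural > 0, n_inc / n_rural, NA_real_),
                    net_decrease = net_dec,
                    stringsAsFactors = FALSE)
  tot_inc <- sum(out$net_increase)
  tot_dec <- sum(out$net_decrease)
  out$rural_share <- if (tot_inc > 0) out$net_increase / tot_inc else NA_real_
  out$urban_share <- if (tot_dec > 0) out$net_decrease / tot_dec else NA_real_
  out$label <- classifySourceSink(out$rural_share, out$urban_share, k = k)
  out
}

#' Country-level daily series per domain
#'
#' \code{countrySeries} sums the daily counts over all cells of each
#' domain (cells without a domain label are grouped as
#' \code{"excluded"}). \code{domainProportions} converts the sums into
#' daily shares of the country-level total, which sum to 1 on every day
#' with a positive total (all-zero days get NA shares and a flag), and
#' reports the peak day and peak share of the rural domain.
#'
#' @param grid a \linkS4class{MobilityGrid} whose rowData has
#'   \code{domain} (NA allowed)
#' @return \code{countrySeries}: data.frame \code{julian_day} x domain
#'   columns of daily sums
#' @name country-series
NULL

#' @rdname country-series
#' @export
countrySeries <- function(grid) {
  info <- cellInfo(grid)
  dom <- if ("domain" %in% colnames(info)) info$domain else
    rep(NA_character_, nrow(grid))
  dom[is.na(dom)] <- "excluded"
  counts <- cellCounts(grid)
  sums <- rowsum(ifelse(is.na(counts), 0, counts), dom)
  out <- data.frame(julian_day = julianDays(grid), t(sums))
  rownames(out) <- NULL
  out
}

#' @rdname country-series
#' @param series output of \code{countrySeries}
#' @export
domainProportions <- function(series) {
  domains <- setdiff(names(series), "julian_day")
  total <- rowSums(series[domains])
  shares <- series
  for (d in domains)
    shares[[d]] <- ifelse(total > 0, series[[d]] / total, NA_real_)
  shares$all_zero <- total == 0
  peak <- NULL
  if ("rural" %in% domains && any(total > 0)) {
    i <- which.max(shares$rural)
    peak <- list(day = series$julian_day[i], share = shares$rural[i])
  }
  attr(shares, "rural_peak") <- peak
  shares
}

#' Fraction of the urban population returning to the countryside
#'
#' From the rural share of the country-level total before the travel
#' season (\code{p_base}) and its New-Year's-Day peak (\code{p_peak}),
#' the fraction of the population usually living in cities that returned
#' to the countryside is \code{(p_peak - p_base) / (1 - p_base)}. With
#' the published shares 39.8\% and 18.4\% this gives 26.2\%.
#'
#' @param p_peak peak rural share, in [0, 1)
#' @param p_base baseline rural share, \code{0 <= p_base < 1} and
#'   \code{p_peak >= p_base}
#' @return the return fraction
#' @examples
#' urbanReturnFraction(0.398, 0.184)  # ~0.262
#' @export
urbanReturnFraction <- function(p_peak, p_base) {
  if (any(p_base < 0) || any(p_base >= 1))
    stop("p_base must lie in [0, 1)")
  if (any(p_peak < p_base))
    stop("p_peak must be >= p_base")
  (p_peak - p_base) / (1 - p_base)
}

#' Kendall rank-correlation trend test
#'
#' Trend of a daily series against time: tau-b with tie correction, with
#' the p-value from the normal approximation (via
#' \code{stats::cor.test}). A constant series has no defined tau and is
#' flagged.
#'
#' @param x the series
#' @param t time index (defaults to observation order)
#' @return list with \code{tau}, \code{p}, \code{constant}
#' @export
kendallTau <- function(x, t = seq_along(x)) {
  if (length(x) < 3) stop("series too short (need >= 3)")
  if (length(unique(x)) == 1)
    return(list(tau = NA_real_, p = NA_real_, constant = TRUE))
  ct <- suppressWarnings(stats::cor.test(t, x, method = "kendall",
                                         exact = FALSE, continuity = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value, constant = FALSE)
}

#' Log-log and semi-log least-squares fits
#'
#' \code{fitLogLog} regresses \code{log(y)} on \code{log(x)} (the
#' relationship between regional net increase and source population size,
#' which spans orders of magnitude); \code{fitLog} regresses \code{y} on
#' \code{log(x)} (prevalence PR against out-migrant magnitude). Pairs with
#' a nonpositive value on any logged axis are dropped and counted. Natural
#' logarithms throughout.
#'
#' @param x,y numeric vectors
#' @return list with coefficients (\code{slope}/\code{intercept} for
#'   log-log, \code{a}/\code{b} for \code{y = a + b ln x}),
#'   \code{r_squared}, \code{slope_ci} (95\%), \code{n_used},
#'   \code{n_dropped}
#' @name log-fits
NULL

#' @rdname log-fits
#' @export
fitLogLog <- function(x, y) {
  ok <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  if (sum(ok) < 3) stop("fit error: fewer than 3 usable pairs")
  if (stats::sd(log(x[ok])) == 0) stop("fit error: degenerate predictor")
  fit <- stats::lm(log(y[ok]) ~ log(x[ok]))
  s <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  ci <- suppressWarnings(stats::confint(fit))[2, ]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared, slope_ci = unname(ci),
       n_used = sum(ok), n_dropped = sum(!ok))
}

#' @rdname log-fits
#' @export
fitLog <- function(x, y) {
  ok <- !is.na(x) & !is.na(y) & x > 0
  if (sum(ok) < 3) stop("fit error: fewer than 3 usable pairs")
  if (stats::sd(log(x[ok])) == 0) stop("fit error: degenerate predictor")
  fit <- stats::lm(y[ok] ~ log(x[ok]))
  s <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit))[2, ]
  list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
       r_squared = s$r.squared, slope_ci = unname(ci),
       n_used = sum(ok), n_dropped = sum(!ok))
}

#' Source / sink classification of regions
#'
#' With y the region's share of the nationwide rural net increase and x
#' its share of the nationwide urban net decrease, a region is a
#' \code{source} of migrants iff \code{y > (k + 1) x} (its rural return
#' signal dominates), a \code{sink} iff \code{x > (k + 1) y}, and
#' \code{balanced} otherwise. The default deviation multiple \code{k = 2}
#' corresponds to the deviation lines y = 2x + x and x = 2y + y around
#' the balanced diagonal.
#'
#' @param rural_share,urban_share non-negative shares
#' @param k deviation multiple
#' @return character vector of labels
#' @examples
#' classifySourceSink(0.06, 0.01)  # source
#' @export
classifySourceSink <- function(rural_share, urban_share, k = 2) {
  if (any(rural_share < 0, na.rm = TRUE) ||
      any(urban_share < 0, na.rm = TRUE))
    stop("shares must be non-negative")
  ifelse(is.na(rural_share) | is.na(urban_share), NA_character_,
         ifelse(rural_share > (k + 1) * urban_share, "source",
                ifelse(urban_share > (k + 1) * rural_share, "sink",
                       "balanced")))
}

#' Select counties suitable for census validation
#'
#' Keeps county rows whose resident agricultural population share exceeds
#' 50\% (removing urbanized areas) and whose ratio of inhabitants without
#' local hukou to those with it is below 0.10 (removing areas with
#' notable in-migration). Both criteria are strict.
#'
#' @param census data.frame with \code{agri_share} and
#'   \code{nonhukou_ratio}
#' @return the qualifying subset
#' @export
selectCounties <- function(census) {
  if (!all(c("agri_share", "nonhukou_ratio") %in% names(census)))
    stop("census table needs 'agri_share' and 'nonhukou_ratio'")
  census[census$agri_share > 0.5 & census$nonhukou_ratio < 0.10, ,
         drop = FALSE]
}

#' Infer regional out-migrants from hukou accounting
#'
#' Out-migrants = registered population minus the population holding
#' local hukou and still resident. A negative difference (net inflow) is
#' reported as-is with a flag.
#'
#' @param registered,resident_hukou person counts (>= 0)
#' @return data.frame with \code{out_migrants} and \code{net_inflow}
#' @examples
#' inferOutMigrants(100000, 80000)  # 20000
#' @export
inferOutMigrants <- function(registered, resident_hukou) {
  if (any(registered < 0) || any(resident_hukou < 0))
    stop("population counts must be >= 0")
  d <- registered - resident_hukou
  data.frame(out_migrants = d, net_inflow = d < 0)
}

#' Validate regional net increases against census out-migrants
#'
#' OLS of the regional net increase in N on the census-inferred
#' out-migrant count, per region level.
#'
#' @param summaries output of \code{\link{aggregateRegions}} (one level,
#'   or rbind of several)
#' @param out_migrants data.frame with the region id column matching
#'   \code{summaries$level} and an \code{out_migrants} column
#' @return data.frame per level: \code{level}, \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{p_value}, \code{n}
#' @export
validateAgainstCensus <- function(summaries, out_migrants) {
  do.call(rbind, lapply(split(summaries, summaries$level), function(s) {
    lev <- s$level[1]
    m <- match(s$region_id, out_migrants[[lev]])
    ok <- !is.na(m)
    if (sum(ok) < 3) stop("fit error: fewer than 3 regions at level ", lev)
    x <- out_migrants$out_migrants[m[ok]]
    y <- s$net_increase[ok]
    fit <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(fit))
    data.frame(level = lev,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4],
               n = sum(ok), stringsAsFactors = FALSE)
  }))
}

#' Standard-score normalization
#'
#' Centers and scales a series to mean 0 and sd 1, as used when comparing
#' the local sum of N against independent visitor counts.
#'
#' @param x numeric series with sd > 0
#' @return the z-scored series
#' @export
zscoreSeries <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) stop("constant series cannot be z-scored")
  (x - mean(x)) / s
}
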