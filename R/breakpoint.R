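#' Julian day of a calendar date
#'
#' 1-based day-of-year, honoring leap years. The New Year's Day of the
#' 2016 observation window, Feb 8, is Julian day 39.
#'
#' @param date a Date, or anything \code{as.Date} accepts
#' @return integer day(s) of year
#' @examples
#' dayOfYear("2016-02-08")  # 39
#' dayOfYear("2016-03-01")  # 61: 2016 is a leap year
#' @export
dayOfYear <- function(date) {
  d <- as.Date(date, optional = TRUE)
  if (any(is.na(d))) stop("invalid date: ",
                          paste(date[is.na(d)], collapse = ", "))
  as.integer(as.POSIXlt(d)$yday + 1L)
}

#' Minimum-t structural-break search for the turning point
#'
#' Locates the day at which a cell's count series shifts regime, in the
#' spirit of the Zivot-Andrews unit-root test with a one-time intercept
#' break. For every candidate break \code{b} in the trimmed interior of
#' the series, the test regression
#' \deqn{\Delta y_t = \mu + \theta 1[t \ge b] + \beta t + \alpha y_{t-1}
#'   + \sum_{j=1}^{lags} c_j \Delta y_{t-j} + e_t}
#' is fit by OLS, and the candidate minimizing the t-statistic of
#' \eqn{\alpha} is returned (ties broken toward the earliest candidate).
#' The returned day is the first day of the post-break regime. Candidate
#' positions run from \code{1 + ceiling(trim * n)} to
#' \code{n - ceiling(trim * n)}.
#'
#' Degenerate series (all values identical, or a zero-residual exact fit
#' at some candidate, where the t-statistic is unbounded) raise an error
#' of class \code{"ruralflight_degenerate"};
#' series shorter than 10 observed days raise a length error.
#'
#' @param counts non-negative count series (missing days already removed)
#' @param days Julian day of each observation (defaults to positions)
#' @param trim trimming fraction of the candidate window (default 0.15)
#' @param lags number of lagged-difference terms (default 0; a 29-day
#'   window cannot support much more)
#' @return list with \code{tp_day} (Julian day of the break) and
#'   \code{t_min} (the minimized t-statistic)
#' @export
zaBreakSearch <- function(counts, days = seq_along(counts), trim = 0.15,
                          lags = 0) {
  ok <- !is.na(counts)
  y <- as.numeric(counts[ok])
  d <- days[ok]
  n <- length(y)
  if (n < 10) stop("series too short for the break search (need >= 10 days)")
  if (length(unique(y)) == 1)
    stop(structure(class = c("ruralflight_degenerate", "error", "condition"),
                   list(message = "degenerate series: all values identical",
                        call = sys.call(-1))))
  k <- ceiling(trim * n)
  cand <- seq(1 + k, n - k)
  if (length(cand) == 0) stop("trimming leaves no candidate breaks")
  dy <- diff(y)
  tt <- seq(2, n)
  X0 <- cbind(mu = 1, du = 0, trend = tt, ylag = y[-n])
  resp <- dy
  if (lags > 0) {
    lagmat <- sapply(seq_len(lags), function(j)
      c(rep(NA, j), dy)[seq_along(dy)])
    X0 <- cbind(X0, lagmat)
    keep <- seq(lags + 1, length(dy))
    X0 <- X0[keep, , drop = FALSE]
    resp <- dy[keep]
    tt <- tt[keep]
  }
  npar <- ncol(X0)
  best_t <- Inf
  best_b <- NA_integer_
  for (b in cand) {
    X <- X0
    X[, "du"] <- as.numeric(tt >= b)
    fit <- tryCatch(stats::lm.fit(X, resp), error = function(e) NULL)
    if (is.null(fit) || fit$rank < npar) next
    dfree <- length(resp) - npar
    if (dfree <= 0) next
    s2 <- sum(fit$residuals^2) / dfree
    if (s2 < 1e-12)  # exact fit: the t-statistic is unbounded there
      stop(structure(class = c("ruralflight_degenerate", "error",
                               "condition"),
                     list(message = paste("degenerate series: exact fit at",
                                          "candidate break", d[b]),
                          call = sys.call(-1))))
    xtxinv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
    if (is.null(xtxinv)) next
    tstat <- fit$coefficients["ylag"] / sqrt(s2 * xtxinv[4, 4])
    if (is.finite(tstat) && tstat < best_t) {
      best_t <- tstat
      best_b <- b
    }
  }
  if (is.na(best_b))
    stop(structure(class = c("ruralflight_degenerate", "error", "condition"),
                   list(message = "degenerate series: no valid candidate fit",
                        call = sys.call(-1))))
  list(tp_day = d[best_b], t_min = unname(best_t))
}

#' Analyze one cell: turning point, sub-series means and shift test
#'
#' Runs \code{\link{zaBreakSearch}}, splits the series at the detected
#' turning point (the TP day opens the "after" regime: before = days <
#' TP, after = days >= TP), and confirms the shift between the two
#' sub-series with \code{\link{mannWhitneyU}}. For a rural cell the two
#' means are the quantities written NR_b and NR_a; for an urban cell NU_b
#' and NU_a. A degenerate series yields a result flagged \code{no_break}
#' with both means equal to the overall mean.
#'
#' @param counts count series (may contain NA for absent days)
#' @param days Julian days of the observations
#' @param trim,lags passed to \code{\link{zaBreakSearch}}
#' @param mw_mode passed to \code{\link{mannWhitneyU}}
#' @return list with \code{tp_day}, \code{t_min}, \code{mean_before},
#'   \code{mean_after}, \code{u_stat}, \code{p_value}, \code{no_break}
#' @export
analyzeCell <- function(counts, days = seq_along(counts), trim = 0.15,
                        lags = 0, mw_mode = "auto") {
  ok <- !is.na(counts)
  y <- as.numeric(counts[ok])
  d <- days[ok]
  res <- tryCatch(zaBreakSearch(y, d, trim = trim, lags = lags),
                  ruralflight_degenerate = function(e) NULL)
  if (is.null(res)) {
    m <- mean(y)
    return(list(tp_day = NA_integer_, t_min = NA_real_,
                mean_before = m, mean_after = m,
                u_stat = NA_real_, p_value = NA_real_, no_break = TRUE))
  }
  before <- y[d < res$tp_day]
  after <- y[d >= res$tp_day]
  mw <- mannWhitneyU(before, after, mode = mw_mode)
  list(tp_day = res$tp_day, t_min = res$t_min,
       mean_before = mean(before), mean_after = mean(after),
       u_stat = mw$U, p_value = mw$p, no_break = FALSE)
}

#' Batch turning-point detection over a grid
#'
#' Applies \code{\link{analyzeCell}} to every cell of a (filtered)
#' \linkS4class{MobilityGrid}, with progress logging every 10,000 cells.
#'
#' @param grid a \linkS4class{MobilityGrid}
#' @param trim,lags,mw_mode passed to \code{\link{analyzeCell}}
#' @param verbose emit progress messages
#' @return a \link[S4Vectors]{DataFrame} with one row per cell:
#'   \code{cell_id}, \code{tp_day}, \code{t_min}, \code{mean_before},
#'   \code{mean_after}, \code{u_stat}, \code{p_value}, \code{no_break},
#'   plus the grid's \code{domain} column if present
#' @export
detectTurningPoints <- function(grid, trim = 0.15, lags = 0,
                                mw_mode = "auto", verbose = FALSE) {
  counts <- cellCounts(grid)
  days <- julianDays(grid)
  n <- nrow(counts)
  cols <- c("tp_day", "t_min", "mean_before", "mean_after", "u_stat",
            "p_value", "no_break")
  out <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    r <- analyzeCell(counts[i, ], days, trim = trim, lags = lags,
                     mw_mode = mw_mode)
    out[i, ] <- c(r$tp_day, r$t_min, r$mean_before, r$mean_after,
                  r$u_stat, r$p_value, as.numeric(r$no_break))
    if (verbose && i %% 10000 == 0)
      message("detectTurningPoints: ", i, "/", n, " cells")
  }
  res <- S4Vectors::DataFrame(cell_id = rownames(counts),
                              tp_day = as.integer(out[, "tp_day"]),
                              t_min = out[, "t_min"],
                              mean_before = out[, "mean_before"],
                              mean_after = out[, "mean_after"],
                              u_stat = out[, "u_stat"],
                              p_value = out[, "p_value"],
                              no_break = out[, "no_break"] > 0,
                              row.names = rownames(counts))
  info <- cellInfo(grid)
  if ("domain" %in% colnames(info)) res$domain <- info$domain
  res
}
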