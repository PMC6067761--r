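#' Assign rural cells to the nested depopulation estimate tiers
#'
#' Applies the determinative rulebook for the grid cell-level rural
#' depopulation estimate and its bounds. For a rural cell with before/after
#' means NR_b / NR_a:
#' \itemize{
#'   \item \strong{upper}: NR_b < NR_a (the basic direction rule);
#'   \item \strong{medium}: additionally the Mann-Whitney test is
#'     significant (p < \code{alpha});
#'   \item \strong{lower}: additionally TP is no larger than
#'     \code{cny_day} (the first day of the Chinese New Year, inclusive)
#'     and the cell contains at least one rural settlement site.
#' }
#' The tiers are nested by construction: lower implies medium implies
#' upper. Cells flagged \code{no_break} belong to no tier.
#'
#' @param results turning-point results (\link[S4Vectors]{DataFrame} or
#'   data.frame from \code{\link{detectTurningPoints}}) for rural cells
#' @param settlement_count integer vector of settlement sites per cell,
#'   aligned with \code{results} (or named by cell id)
#' @param cny_day Julian day of the New Year (default 39)
#' @param alpha significance level (default 0.05)
#' @return \link[S4Vectors]{DataFrame}: \code{cell_id}, \code{in_upper},
#'   \code{in_medium}, \code{in_lower}, \code{settlement_count}
#' @export
assignTiers <- function(results, settlement_count, cny_day = 39,
                        alpha = 0.05) {
  if (!is.null(names(settlement_count)))
    settlement_count <- settlement_count[results$cell_id]
  if (length(settlement_count) != nrow(results))
    stop("settlement_count must align with results")
  settlement_count[is.na(settlement_count)] <- 0L
  ok <- !results$no_break
  upper <- ok & results$mean_before < results$mean_after
  medium <- upper & !is.na(results$p_value) & results$p_value < alpha
  lower <- medium & !is.na(results$tp_day) & results$tp_day <= cny_day &
    settlement_count >= 1
  S4Vectors::DataFrame(cell_id = results$cell_id,
                       in_upper = unname(upper),
                       in_medium = unname(medium),
                       in_lower = unname(lower),
                       settlement_count = as.integer(settlement_count),
                       row.names = results$cell_id)
}

#' Flag urban cells with a significant decline
#'
#' An urban cell is flagged iff its mean N decreased across the turning
#' point (NU_b > NU_a) and the Mann-Whitney test is significant.
#'
#' @param results turning-point results for urban cells
#' @param alpha significance level (default 0.05)
#' @return logical vector
#' @export
flagUrbanDecline <- function(results, alpha = 0.05) {
  ok <- !results$no_break
  unname(ok & results$mean_before > results$mean_after &
           !is.na(results$p_value) & results$p_value < alpha)
}

#' Summarize tier membership and settlement coverage
#'
#' @param assignments output of \code{\link{assignTiers}}
#' @param total_sites total number of rural settlement sites the coverage
#'   share is computed against; defaults to the sum of
#'   \code{settlement_count} over the supplied (filtered) cells. Supplying
#'   the unfiltered total instead reports coverage against the full
#'   settlement universe, including sites in cells dropped by the
#'   activity filter.
#' @return data.frame with one row per tier: \code{tier}, \code{n_cells},
#'   \code{n_settlements}, \code{settlement_share}
#' @export
summarizeTiers <- function(assignments, total_sites = NULL) {
  if (is.null(total_sites))
    total_sites <- sum(assignments$settlement_count)
  one <- function(tier, member) {
    data.frame(tier = tier,
               n_cells = sum(member),
               n_settlements = sum(assignments$settlement_count[member]),
               settlement_share = if (total_sites > 0)
                 sum(assignments$settlement_count[member]) / total_sites
               else NA_real_)
  }
  if (nrow(assignments) == 0) {
    return(data.frame(tier = c("lower", "medium", "upper"),
                      n_cells = 0L, n_settlements = 0L,
                      settlement_share = if (is.null(total_sites) ||
                                             total_sites == 0) NA_real_
                      else 0))
  }
  rbind(one("lower", assignments$in_lower),
        one("medium", assignments$in_medium),
        one("upper", assignments$in_upper))
}
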