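#' Aggregate a flowering survey into a flowering series
#'
#' Collapses per-census presence/absence observations of flowering into
#' per-period counts of distinct trees in flower for each of two populations,
#' plus census totals (distinct trees ever surveyed per population). A tree
#' counts as flowering in a period if it was flagged flowering in at least
#' one census of that period; trees without a record in a period are treated
#' as not flowering. The default period is the calendar month (the temporal
#' RI index is defined on monthly counts while surveys are typically
#' biweekly); `period = "census"` keeps each census date as its own period.
#'
#' @param survey data.frame with columns `date` (ISO-8601 or `Date`),
#'   `tree_id`, `population`, `flowering` (0/1 or logical). Exactly two
#'   population labels must be present.
#' @param period `"month"` (default) or `"census"`.
#' @return An object of class `"flowering_series"`: list with `periods`
#'   (labels), `counts` (matrix, one row per population), `totals` (named
#'   census sizes), `populations`.
#' @export
aggregate_survey <- function(survey, period = c("month", "census")) {
  period <- match.arg(period)
  need <- c("date", "tree_id", "population", "flowering")
  stopifnot(is.data.frame(survey), all(need %in% names(survey)))
  if (!nrow(survey)) stop("survey is empty")
  pops <- sort(unique(as.character(survey$population)))
  if (length(pops) != 2L)
    stop("survey must contain exactly two population labels, found: ",
         paste(pops, collapse = ", "))
  date <- as.Date(survey$date)
  if (anyNA(date)) stop("unparseable dates in survey")
  key <- paste(date, survey$tree_id)
  if (anyDuplicated(key))
    stop("each (census_date, tree_id) may appear at most once")
  per <- if (period == "month") format(date, "%Y-%m") else format(date)
  periods <- sort(unique(per))
  fl <- survey$flowering %in% c(1, TRUE, "1", "TRUE", "true")
  counts <- matrix(0L, nrow = 2L, ncol = length(periods),
                   dimnames = list(pops, periods))
  for (p in pops) {
    sel <- survey$population == p & fl
    if (any(sel)) {
      tally <- tapply(survey$tree_id[sel], per[sel],
                      function(id) length(unique(id)))
      counts[p, names(tally)] <- as.integer(tally)
    }
  }
  totals <- vapply(pops, function(p)
    length(unique(survey$tree_id[survey$population == p])), integer(1))
  structure(list(periods = periods, counts = counts, totals = totals,
                 populations = pops),
            class = "flowering_series")
}

#' @export
print.flowering_series <- function(x, ...) {
  cat(sprintf("flowering_series: %d periods, populations %s (n = %d) and %s (n = %d)\n",
              length(x$periods), x$populations[1], x$totals[1],
              x$populations[2], x$totals[2]))
  invisible(x)
}

#' Directional phenological reproductive isolation
#'
#' Computes the abundance-weighted temporal RI ([ri_temporal()]) in both
#' directions of a flowering series: for each population as focal, with the
#' other providing the heterospecific counts. With identical per-capita
#' phenology, the population with the smaller census total receives the
#' smaller (possibly negative) RI, because its flowers are outnumbered by
#' heterospecific flowers whenever both are in bloom.
#'
#' @param series A `flowering_series` from [aggregate_survey()], or a list
#'   with `counts` (2 x n matrix) and `totals` (length-2 named vector).
#' @return Named numeric vector of length 2: the RI of each population as
#'   the focal direction.
#' @export
ri_phenology <- function(series) {
  counts <- series$counts
  totals <- series$totals
  stopifnot(nrow(counts) == 2L, length(totals) == 2L)
  ri <- c(
    ri_temporal(counts[1, ], counts[2, ], totals[1], totals[2]),
    ri_temporal(counts[2, ], counts[1, ], totals[2], totals[1])
  )
  names(ri) <- rownames(counts)
  ri
}

#' Read a flowering survey CSV
#'
#' Expects columns `date` (ISO-8601), `tree_id`, `population`,
#' `flowering` (0/1).
#'
#' @param file Path to the CSV.
#' @return The survey data.frame (validated lazily by [aggregate_survey()]).
#' @export
read_phenology_survey <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Export per-period flowering proportions
#'
#' Writes (or returns) the proportion of each population in flower per
#' period — the standard flowering-curve summary plotted in phenology
#' studies.
#'
#' @param series A `flowering_series`.
#' @param file Optional path; if given, written as CSV.
#' @return data.frame with `period` and one proportion column per population.
#' @export
flowering_proportions <- function(series, file = NULL) {
  out <- data.frame(period = series$periods,
                    t(series$counts / series$totals),
                    check.names = FALSE)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
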