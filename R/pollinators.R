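#' Bray-Curtis dissimilarity between two count vectors
#'
#' Computes \eqn{1 - 2\sum_k \min(x_k, y_k) / (\sum x + \sum y)} on two
#' non-negative abundance vectors (0 = identical communities, 1 = no shared
#' taxa), delegating to [vegan::vegdist()], the standard community-ecology
#' implementation.
#'
#' @param x,y Non-negative count vectors of equal length (one entry per
#'   taxon / morphospecies).
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (sum(x) + sum(y) == 0)
    stop("both communities are empty: dissimilarity undefined")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Construct / read a pollinator visitation table
#'
#' A visitation table records the number of visits by each insect
#' morphospecies to each of two ecotypes (antagonistic episodes such as
#' nectar robbing excluded upstream; counts pooled over male and female
#' trees). `read_visitation_table()` expects a CSV whose first column is the
#' morphospecies label and whose remaining two columns are the per-ecotype
#' visit counts.
#'
#' @param counts A matrix or data.frame of non-negative integer counts with
#'   two columns (ecotypes) and one row per morphospecies.
#' @return An object of class `"visitation_table"`: the validated count
#'   matrix with morphospecies rownames.
#' @export
visitation_table <- function(counts) {
  m <- as.matrix(counts)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("visitation table must have exactly two ecotype columns")
  if (nrow(m) < 1L) stop("visitation table needs at least one morphospecies")
  if (any(m < 0) || any(m != round(m))) stop("visit counts must be non-negative integers")
  if (any(colSums(m) == 0))
    stop("each ecotype column must contain at least one visit")
  structure(m, class = c("visitation_table", "matrix"))
}

#' @rdname visitation_table
#' @param file Path to a CSV (morphospecies, then two count columns).
#' @export
read_visitation_table <- function(file) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("expected columns: morphospecies + two count columns")
  m <- as.matrix(raw[, 2:3])
  rownames(m) <- raw[[1]]
  visitation_table(m)
}

#' Pollinator-assemblage reproductive isolation
#'
#' The Bray-Curtis dissimilarity d between the two ecotypes' visitation
#' profiles is taken as the unshared proportion U and 1 - d as the shared
#' proportion S of the co-occurrence index, so
#' `ri_cooccurrence(S = 1 - d, U = d) = d`: the RI equals the dissimilarity
#' and is identical in both directions.
#'
#' @param table A `visitation_table` (or 2-column count matrix).
#' @return A single numeric RI value in \[0, 1\].
#' @examples
#' tab <- visitation_table(cbind(white_sand = c(22, 6, 9), brown_sand = c(4, 4, 84)))
#' ri_pollinator(tab)
#' @export
ri_pollinator <- function(table) {
  m <- as.matrix(table)
  d <- bray_curtis(m[, 1], m[, 2])
  ri_cooccurrence(S = 1 - d, U = d)
}

#' Rank-based comparison of visitation between ecotypes
#'
#' Tests whether per-morphospecies visit counts differ between the two
#' ecotypes. The default treats the two columns as independent samples
#' (two-sample Wilcoxon rank-sum / Mann-Whitney U, midranks for ties,
#' tie-corrected normal approximation); `paired = TRUE` runs the
#' signed-rank variant across morphospecies instead.
#'
#' @param table A `visitation_table` (or 2-column count matrix) with >= 2
#'   rows.
#' @param paired Logical; pair counts by morphospecies (default `FALSE`).
#' @return A list with `statistic` (U, or V if paired), `z` (signed normal
#'   deviate), `p_value` (two-sided), and `method`.
#' @export
visitation_rank_test <- function(table, paired = FALSE) {
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop("need at least two morphospecies")
  if (all(m[, 1] == m[, 2]))
    return(list(statistic = if (paired) 0 else nrow(m)^2 / 2, z = 0,
                p_value = 1,
                method = if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum"))
  wt <- suppressWarnings(
    stats::wilcox.test(m[, 1], m[, 2], paired = paired,
                       exact = FALSE, correct = FALSE)
  )
  # recover the signed normal deviate from the two-sided p and the direction
  # of the statistic around its null mean
  mu <- if (paired) sum(m[, 1] != m[, 2]) * (sum(m[, 1] != m[, 2]) + 1) / 4
        else nrow(m)^2 / 2
  z <- sign(unname(wt$statistic) - mu) * stats::qnorm(1 - wt$p.value / 2)
  list(statistic = unname(wt$statistic), z = z, p_value = wt$p.value,
       method = if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum")
}
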