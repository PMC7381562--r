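#' Reproductive isolation from shared vs unshared co-occurrence (RI4C)
#'
#' Computes the co-occurrence form of the Sobel-Chen RI4 index,
#' \deqn{RI_{4C} = 1 - S / (S + U),}
#' where \code{S} is the shared quantity (habitat pixels, proportion of
#' pollinators, or time shared with the other ecotype) and \code{U} the
#' unshared quantity, in the same units. The result lies in \[0, 1\]: 0 means
#' complete overlap (no isolation), 1 complete isolation.
#'
#' @param S Shared quantity, a single non-negative finite number.
#' @param U Unshared quantity, a single non-negative finite number.
#' @return A single numeric RI value in \[0, 1\].
#' @examples
#' ri_cooccurrence(S = 504, U = 2485) # ecogeographic isolation, one direction
#' ri_cooccurrence(S = 0, U = 7)      # disjoint ranges -> 1
#' @seealso [ri_mating()], [ri_temporal()], [ri_4e()]
#' @export
ri_cooccurrence <- function(S, U) {
  stopifnot(length(S) == 1L, length(U) == 1L)
  if (!is.finite(S) || !is.finite(U) || S < 0 || U < 0)
    stop("S and U must be finite and non-negative")
  if (S + U == 0)
    stop("S + U must be positive: RI4C is undefined when nothing co-occurs")
  1 - S / (S + U)
}

#' Reproductive isolation from heterospecific vs conspecific mating (RI4A)
#'
#' Computes the mating form of the Sobel-Chen RI4 index,
#' \deqn{RI_{4A} = 1 - 2H / (H + C),}
#' where \code{H} is the heterospecific mating quantity (a count, mean, or
#' rate) and \code{C} the conspecific quantity in identical units. The result
#' lies in \[-1, 1\]: 1 means no heterospecific success, 0 random mating, and
#' negative values disassortative mating (heterospecific success exceeds
#' conspecific).
#'
#' @param H Heterospecific mating quantity (non-negative, finite).
#' @param C Conspecific mating quantity, same units as \code{H}.
#' @return A single numeric RI value in \[-1, 1\].
#' @examples
#' ri_mating(H = 0.164, C = 0.39) # seed-set rates -> 0.408
#' ri_mating(H = 112, C = 159)    # adhered-grain means -> 0.173
#' @export
ri_mating <- function(H, C) {
  stopifnot(length(H) == 1L, length(C) == 1L)
  if (!is.finite(H) || !is.finite(C) || H < 0 || C < 0)
    stop("H and C must be finite and non-negative")
  if (H + C == 0)
    stop("H + C must be positive: RI4A is undefined with no matings")
  1 - 2 * H / (H + C)
}

#' Abundance-weighted temporal reproductive isolation (RI4S2)
#'
#' Computes the temporal form of the Sobel-Chen RI4 index over a flowering
#' series. For each period \eqn{i} the expected heterospecific and conspecific
#' pollen-transfer terms for the focal population A are
#' \deqn{H_i = \frac{A_i}{A_{tot}} \cdot \frac{B_i}{A_i + B_i} \cdot
#'   \frac{B_{tot}}{A_{tot} + B_{tot}}, \qquad
#'   C_i = \frac{A_i}{A_{tot}} \cdot \frac{A_i}{A_i + B_i} \cdot
#'   \frac{A_{tot}}{A_{tot} + B_{tot}},}
#' and \eqn{RI_{4S2} = 1 - 2\sum_i H_i / (\sum_i H_i + \sum_i C_i)}. Periods
#' in which neither population flowers (\eqn{A_i + B_i = 0}) contribute zero
#' to both sums. The index is 1 when the focal population never flowers
#' together with the other, 0 under identical proportional flowering with
#' equal census sizes, and negative when heterospecific transfer dominates
#' (e.g. a rare focal population swamped by an abundant one).
#'
#' @param A Integer-like vector: number of focal-population individuals in
#'   flower in each period.
#' @param B Number of other-population individuals in flower per period; same
#'   length as \code{A}.
#' @param A_total,B_total Census sizes (total individuals monitored) of the
#'   focal and other population.
#' @return A single numeric RI value in \[-1, 1\].
#' @examples
#' ri_temporal(A = c(3, 2, 0), B = c(1, 4, 2), A_total = 5, B_total = 8)
#' @export
ri_temporal <- function(A, B, A_total, B_total) {
  stopifnot(length(A) == length(B), length(A) >= 1L,
            length(A_total) == 1L, length(B_total) == 1L)
  if (A_total <= 0 || B_total <= 0)
    stop("census totals must be positive")
  if (any(A < 0) || any(B < 0) || any(A > A_total) || any(B > B_total))
    stop("flowering counts must satisfy 0 <= A_i <= A_total, 0 <= B_i <= B_total")
  active <- (A + B) > 0
  share_other <- ifelse(active, B / (A + B), 0)
  share_self  <- ifelse(active, A / (A + B), 0)
  H <- (A / A_total) * share_other * (B_total / (A_total + B_total))
  C <- (A / A_total) * share_self  * (A_total / (A_total + B_total))
  sH <- sum(H)
  sC <- sum(C)
  if (sH + sC == 0)
    stop("focal population never flowers: RI4S2 undefined")
  1 - 2 * sH / (sH + sC)
}

#' Invert RI4A to a heterospecific:conspecific success ratio
#'
#' Given an RI value on the mating scale, returns the ratio
#' \eqn{r = H/C = (1 - RI) / (1 + RI)} such that
#' \code{ri_mating(H = r, C = 1)} recovers the RI. Used to translate barrier
#' strengths into conditional gene-flow probabilities for [ri_4e()].
#'
#' @param ri RI value in (-1, 1].
#' @return The implied heterospecific:conspecific success ratio (>= 0).
#' @export
ri_to_mating_ratio <- function(ri) {
  stopifnot(length(ri) == 1L, is.finite(ri))
  if (ri <= -1 || ri > 1)
    stop("ri must lie in (-1, 1]: the implied ratio is infinite at ri = -1")
  (1 - ri) / (1 + ri)
}

#' Co-occurrence-conditioned total reproductive isolation (RI4E)
#'
#' Computes the Sobel-Chen RI4E total-isolation form, which conditions gene
#' flow on whether the two taxa co-occur:
#' \deqn{RI_{4E} = 1 - \frac{2\,(S_{tot} P(H|S) + U_{tot} P(H|U))}
#'   {S_{tot} P(H|S) + U_{tot} P(H|U) + S_{tot} P(C|S) + U_{tot} P(C|U)}}
#' with \eqn{S_{tot}} the shared and \eqn{U_{tot}} the unshared habitat
#' fraction and \eqn{P(\cdot|\cdot)} the conditional probabilities of
#' heterospecific / conspecific gene flow in shared / unshared habitat.
#'
#' @param S_total,U_total Shared and unshared habitat fractions; must sum to 1.
#' @param p_H_S,p_H_U Probability of heterospecific gene flow given shared /
#'   unshared habitat.
#' @param p_C_S,p_C_U Probability of conspecific gene flow given shared /
#'   unshared habitat.
#' @return A single numeric RI value.
#' @seealso [ri_4e_from_barriers()] for the default mapping from a barrier
#'   cascade to these probabilities.
#' @export
ri_4e <- function(S_total, U_total, p_H_S, p_H_U, p_C_S, p_C_U) {
  probs <- c(p_H_S, p_H_U, p_C_S, p_C_U)
  stopifnot(length(probs) == 4L, all(is.finite(probs)))
  if (any(probs < 0) || any(probs > 1))
    stop("conditional gene-flow probabilities must lie in [0, 1]")
  if (abs(S_total + U_total - 1) > 1e-9)
    stop("S_total + U_total must equal 1")
  het <- S_total * p_H_S + U_total * p_H_U
  con <- S_total * p_C_S + U_total * p_C_U
  if (het + con == 0)
    stop("all gene-flow probabilities are zero: RI4E undefined")
  1 - 2 * het / (het + con)
}
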