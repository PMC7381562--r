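#' @importFrom stats setNames
NULL

# Canonical life-cycle order of the barriers this pipeline measures, with the
# stage and RI method each one uses. Order is fixed: earlier-acting barriers
# limit what later ones can contribute.
.barrier_registry <- data.frame(
  barrier = c("ecogeography", "phenology", "pollinators",
              "pollen_adhesion", "pollen_germination", "seed_development"),
  stage   = c("prepollination", "prepollination", "prepollination",
              "postpollination_prezygotic", "postpollination_prezygotic",
              "postzygotic"),
  method  = c("RI4C", "RI4S2", "RI4C", "RI4A", "RI4A", "RI4A"),
  stringsAsFactors = FALSE
)

.method_range <- function(method) {
  if (method == "RI4C") c(0, 1) else c(-1, 1)
}

#' Construct one barrier-strength record
#'
#' A light constructor for a single barrier's isolation estimate, carrying its
#' life-cycle stage, estimation method, and the direction (focal ecotype) it
#' was measured for. Rows from several calls can be bound together into the
#' barrier table consumed by [ri_cascade()].
#'
#' @param barrier One of `"ecogeography"`, `"phenology"`, `"pollinators"`,
#'   `"pollen_adhesion"`, `"pollen_germination"`, `"seed_development"`.
#' @param value The RI estimate. Must lie in \[0,1\] for RI4C barriers and
#'   \[-1,1\] for RI4S2/RI4A barriers.
#' @param focal Label of the ecotype the estimate is directed at.
#' @param available Logical; `FALSE` marks a barrier that could not be
#'   measured in this direction (its `value` may be `NA`). Unavailable
#'   barriers are skipped by the cascade, never imputed as zero.
#' @return A one-row `data.frame` with columns `barrier`, `stage`, `focal`,
#'   `method`, `value`, `available`.
#' @examples
#' rbind(
#'   barrier_strength("ecogeography", 0.45, focal = "brown_sand"),
#'   barrier_strength("phenology", 0.69, focal = "brown_sand")
#' )
#' @export
barrier_strength <- function(barrier, value, focal = "focal",
                             available = !is.na(value)) {
  barrier <- match.arg(barrier, .barrier_registry$barrier)
  reg <- .barrier_registry[.barrier_registry$barrier == barrier, ]
  if (available) {
    stopifnot(length(value) == 1L)
    if (!is.finite(value))
      stop("value must be finite for an available barrier")
    rng <- .method_range(reg$method)
    if (value < rng[1] || value > rng[2])
      stop(sprintf("%s uses %s: value must lie in [%g, %g]",
                   barrier, reg$method, rng[1], rng[2]))
  } else {
    value <- NA_real_
  }
  data.frame(barrier = barrier, stage = reg$stage, focal = focal,
             method = reg$method, value = as.numeric(value),
             available = available, stringsAsFactors = FALSE)
}

# Validate a barrier table and return it ordered by life-cycle stage.
.validate_barrier_table <- function(barriers) {
  need <- c("barrier", "value")
  if (!is.data.frame(barriers) || !all(need %in% names(barriers)))
    stop("barriers must be a data.frame with at least columns 'barrier' and 'value'")
  if (!"available" %in% names(barriers))
    barriers$available <- !is.na(barriers$value)
  unknown <- setdiff(barriers$barrier, .barrier_registry$barrier)
  if (length(unknown))
    stop("unknown barrier(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(barriers[, intersect(c("barrier", "focal"), names(barriers))]))
    stop("each barrier may appear at most once per direction")
  idx <- match(barriers$barrier, .barrier_registry$barrier)
  barriers$stage <- .barrier_registry$stage[idx]
  barriers$method <- .barrier_registry$method[idx]
  barriers <- barriers[order(idx), , drop = FALSE]
  for (i in seq_len(nrow(barriers))) {
    if (!barriers$available[i]) next
    v <- barriers$value[i]
    rng <- .method_range(barriers$method[i])
    if (!is.finite(v) || v < rng[1] || v > rng[2])
      stop(sprintf("barrier '%s' (%s): value %s outside [%g, %g]",
                   barriers$barrier[i], barriers$method[i],
                   format(v), rng[1], rng[2]))
  }
  rownames(barriers) <- NULL
  barriers
}

#' Combine barrier strengths into total isolation and contributions
#'
#' Fits the sequential multiplicative cascade over a set of per-barrier RI
#' estimates ordered by life-cycle stage (ecogeography, phenology,
#' pollinators, pollen adhesion, pollen-tube germination, seed development).
#' Total isolation is \eqn{RI_{total} = 1 - \prod_k (1 - RI_k)} over the
#' available barriers; the absolute contribution of barrier \eqn{k} is
#' \eqn{AC_k = RI_k \prod_{j<k} (1 - RI_j)} (the isolation it adds given that
#' gene flow already blocked by earlier barriers cannot be blocked again), and
#' the relative contribution is \eqn{RC_k = AC_k / RI_{total}}. Absolute
#' contributions sum exactly to the total. Negative barrier strengths
#' (disassortative barriers) propagate through factors \eqn{(1 - RI_k) > 1}.
#'
#' A sympatric total (the cascade excluding ecogeography, i.e. isolation at a
#' contact zone where the taxa co-occur) is always reported when the
#' remaining barriers allow it, and the co-occurrence-conditioned RI4E total
#' (see [ri_4e_from_barriers()]) is reported when an ecogeographic barrier is
#' present.
#'
#' @param barriers Either a barrier table (`data.frame` as returned by
#'   [barrier_strength()] / [read_barrier_table()], possibly filtered to one
#'   `focal` direction) or a named numeric vector of RI values whose names are
#'   barrier identifiers.
#' @param focal Optional ecotype label; if the table carries a `focal` column
#'   with several directions, selects one.
#' @param include_ecogeography Logical; if `FALSE` the ecogeographic barrier
#'   is dropped before fitting (contact-zone analysis).
#' @param baseline_gene_flow Baseline probability of gene flow given contact,
#'   used by the RI4E mapping; 0.5 assumes random mating.
#' @return An object of class `"ri_cascade"`: a list with elements
#'   `barriers` (the table used, in order), `total`, `total_sympatry`,
#'   `total_ri4e`, `contributions` (data.frame with `value`,
#'   `absolute_contribution`, `relative_contribution`), and
#'   `baseline_gene_flow`. Methods: `print`, `summary`, `coef`, `plot`,
#'   `as.data.frame`.
#' @examples
#' bs <- c(ecogeography = 0.45, phenology = 0.69, pollinators = 0.82,
#'         pollen_adhesion = 0.18, pollen_germination = 0.02,
#'         seed_development = 0.40)
#' fit <- ri_cascade(bs)
#' fit$total       # 0.985
#' coef(fit)
#' summary(fit)
#' @export
ri_cascade <- function(barriers, focal = NULL, include_ecogeography = TRUE,
                       baseline_gene_flow = 0.5) {
  if (is.numeric(barriers) && !is.null(names(barriers))) {
    barriers <- do.call(rbind, lapply(names(barriers), function(b)
      barrier_strength(b, barriers[[b]],
                       focal = if (is.null(focal)) "focal" else focal)))
  }
  barriers <- .validate_barrier_table(barriers)
  if (!is.null(focal) && "focal" %in% names(barriers))
    barriers <- barriers[barriers$focal == focal, , drop = FALSE]
  if ("focal" %in% names(barriers) && length(unique(barriers$focal)) > 1L)
    stop("barrier table mixes directions; pass focal= to select one")
  if (baseline_gene_flow <= 0 || baseline_gene_flow >= 1)
    stop("baseline_gene_flow must lie in (0, 1)")

  used <- barriers[barriers$available, , drop = FALSE]
  if (!include_ecogeography)
    used <- used[used$barrier != "ecogeography", , drop = FALSE]
  if (nrow(used) == 0L)
    stop("no available barriers to combine")

  seq_fit <- .cascade_sequential(used$value)
  contributions <- data.frame(
    barrier = used$barrier,
    stage = used$stage,
    value = used$value,
    absolute_contribution = seq_fit$ac,
    relative_contribution = seq_fit$rc,
    stringsAsFactors = FALSE
  )

  symp <- used[used$barrier != "ecogeography", , drop = FALSE]
  total_sympatry <- if (nrow(symp) > 0L) .cascade_sequential(symp$value)$total else NA_real_

  total_ri4e <- if ("ecogeography" %in% used$barrier)
    ri_4e_from_barriers(used, baseline_gene_flow = baseline_gene_flow)
  else NA_real_

  structure(
    list(barriers = barriers, contributions = contributions,
         total = seq_fit$total, total_sympatry = total_sympatry,
         total_ri4e = total_ri4e,
         include_ecogeography = include_ecogeography,
         baseline_gene_flow = baseline_gene_flow,
         focal = if ("focal" %in% names(barriers) && nrow(barriers))
           barriers$focal[1] else NA_character_),
    class = "ri_cascade"
  )
}

.cascade_sequential <- function(ri) {
  remaining <- cumprod(1 - ri)
  total <- 1 - remaining[length(remaining)]
  ac <- ri * c(1, remaining[-length(remaining)])
  rc <- if (total != 0) ac / total else rep(NA_real_, length(ac))
  list(total = total, ac = ac, rc = rc)
}

#' Total isolation under the RI4E co-occurrence mapping
#'
#' Maps a barrier table onto the inputs of [ri_4e()]: the shared habitat
#' fraction is \eqn{S_{tot} = 1 - RI_{eco}} and the unshared fraction
#' \eqn{U_{tot} = RI_{eco}}; heterospecific gene flow is impossible in
#' unshared habitat (\eqn{P(H|U) = 0}); conspecific gene flow occurs at the
#' baseline probability everywhere; and in shared habitat the heterospecific
#' probability is the baseline discounted by the product of the
#' heterospecific:conspecific success ratios implied by each remaining
#' barrier, \eqn{P(H|S) = p_0 \prod_k (1 - RI_k)/(1 + RI_k)}.
#'
#' @param barriers Barrier table (or named numeric vector) including an
#'   ecogeographic barrier; remaining available barriers feed the success
#'   ratios.
#' @param baseline_gene_flow Baseline gene-flow probability given contact.
#' @return A single numeric RI value.
#' @export
ri_4e_from_barriers <- function(barriers, baseline_gene_flow = 0.5) {
  if (is.numeric(barriers) && !is.null(names(barriers))) {
    barriers <- do.call(rbind, lapply(names(barriers), function(b)
      barrier_strength(b, barriers[[b]])))
  }
  barriers <- .validate_barrier_table(barriers)
  barriers <- barriers[barriers$available, , drop = FALSE]
  eco <- barriers$value[barriers$barrier == "ecogeography"]
  if (length(eco) != 1L)
    stop("ri_4e_from_barriers requires an available ecogeographic barrier")
  rest <- barriers$value[barriers$barrier != "ecogeography"]
  ratio <- if (length(rest)) prod(vapply(rest, ri_to_mating_ratio, numeric(1))) else 1
  # RI4E is invariant to a joint rescaling of the conditional probabilities,
  # so when strongly disassortative barriers push the implied heterospecific
  # probability above 1 the whole set is scaled back into [0, 1]
  p_h_s <- baseline_gene_flow * ratio
  scale <- max(1, p_h_s)
  ri_4e(S_total = 1 - eco, U_total = eco,
        p_H_S = p_h_s / scale, p_H_U = 0,
        p_C_S = baseline_gene_flow / scale, p_C_U = baseline_gene_flow / scale)
}

#' @export
print.ri_cascade <- function(x, digits = 3, ...) {
  cat("Reproductive isolation cascade")
  if (!is.na(x$focal)) cat(" (focal: ", x$focal, ")", sep = "")
  cat("\n\nBarriers (life-cycle order):\n")
  tab <- x$contributions
  tab$value <- round(tab$value, digits)
  tab$absolute_contribution <- round(tab$absolute_contribution, digits)
  tab$relative_contribution <- round(tab$relative_contribution, digits)
  print(tab, row.names = FALSE)
  cat("\nTotal RI:          ", format(round(x$total, digits)), "\n")
  if (!is.na(x$total_sympatry))
    cat("Total RI (sympatry):", format(round(x$total_sympatry, digits)), "\n")
  if (!is.na(x$total_ri4e))
    cat("Total RI (RI4E):   ", format(round(x$total_ri4e, digits)), "\n")
  invisible(x)
}

#' @export
summary.ri_cascade <- function(object, ...) {
  structure(list(fit = object), class = "summary.ri_cascade")
}

#' @export
print.summary.ri_cascade <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  n_unavail <- sum(!x$fit$barriers$available)
  if (n_unavail > 0)
    cat("\n", n_unavail, " barrier(s) unmeasured in this direction (skipped, not imputed)\n",
        sep = "")
  cat("\nAbsolute contributions sum to the total; relative contributions to 1.\n")
  invisible(x)
}

#' @export
coef.ri_cascade <- function(object, ...) {
  setNames(object$contributions$value, object$contributions$barrier)
}

#' @export
as.data.frame.ri_cascade <- function(x, ...) x$contributions

#' Barplot of per-barrier contributions to total isolation
#'
#' @param x An `ri_cascade` fit.
#' @param which `"relative"` (default) or `"absolute"` contributions.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted heights.
#' @importFrom graphics barplot
#' @importFrom grDevices hcl.colors
#' @export
plot.ri_cascade <- function(x, which = c("relative", "absolute"), ...) {
  which <- match.arg(which)
  h <- if (which == "relative") x$contributions$relative_contribution
       else x$contributions$absolute_contribution
  names(h) <- x$contributions$barrier
  barplot(h, las = 2, col = hcl.colors(length(h), "Teal"),
          ylab = paste(which, "contribution"),
          main = sprintf("Total RI = %.2f", x$total), ...)
  invisible(h)
}

#' Read or write a barrier table as CSV
#'
#' The barrier table mirrors the per-ecotype barrier-strength summary of a
#' multi-barrier isolation study: one row per barrier and direction, columns
#' `barrier_name`, `stage`, `focal`, `method`, `value`, `available`.
#' Unavailable barriers (unmeasured in a direction) carry an empty `value`
#' and `available = FALSE`.
#'
#' @param file Path to a CSV file.
#' @return `read_barrier_table()`: a validated `data.frame` in life-cycle
#'   order with the columns above (named `barrier`, not `barrier_name`,
#'   internally).
#' @export
read_barrier_table <- function(file) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  if ("barrier_name" %in% names(raw))
    names(raw)[names(raw) == "barrier_name"] <- "barrier"
  if (!"available" %in% names(raw))
    raw$available <- !is.na(raw$value)
  raw$available <- as.logical(raw$available)
  raw$value <- as.numeric(raw$value)
  out <- lapply(split(raw, if ("focal" %in% names(raw)) raw$focal else 1),
                .validate_barrier_table)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname read_barrier_table
#' @param barriers A barrier table `data.frame`.
#' @export
write_barrier_table <- function(barriers, file) {
  barriers <- do.call(rbind, lapply(
    split(barriers, if ("focal" %in% names(barriers)) barriers$focal else 1),
    .validate_barrier_table))
  out <- barriers
  names(out)[names(out) == "barrier"] <- "barrier_name"
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
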