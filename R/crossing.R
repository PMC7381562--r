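.cross_stages <- c("adhesion", "germination", "seed_set")

#' Validate hand-pollination cross records
#'
#' Checks a table of per-flower hand-pollination outcomes and derives the
#' treatment: `parental` when pollen and maternal ecotype match, `hybrid`
#' otherwise. Rules enforced: `germinated <= adhered` wherever both were
#' counted; control flowers carry no pollen ecotype; and a negative control
#' that set seed is invalid input (pollination without pollen cannot produce
#' seed — a contaminated or mislabelled record).
#'
#' @param records data.frame with columns `flower_id`, `maternal_ecotype`,
#'   `pollen_ecotype`, and any of `adhered`, `germinated`, `seed_set`,
#'   `control_type` (`none`/`negative`/`positive`), `inflorescence_id`.
#' @return The records with a derived `treatment` column, classed
#'   `"cross_records"`.
#' @export
cross_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("flower_id", "maternal_ecotype", "pollen_ecotype")
                %in% names(records)))
  if (!"control_type" %in% names(records)) records$control_type <- "none"
  records$control_type[is.na(records$control_type) |
                         records$control_type == ""] <- "none"
  bad_ct <- setdiff(unique(records$control_type),
                    c("none", "negative", "positive"))
  if (length(bad_ct))
    stop("unknown control_type value(s): ", paste(bad_ct, collapse = ", "))
  for (col in c("adhered", "germinated"))
    if (!col %in% names(records)) records[[col]] <- NA_real_
  if (!"seed_set" %in% names(records)) records$seed_set <- NA
  records$seed_set <- as.logical(records$seed_set)

  is_ctrl <- records$control_type != "none"
  has_pollen <- !is.na(records$pollen_ecotype) & records$pollen_ecotype != ""
  if (any(is_ctrl & has_pollen))
    stop("control flowers must not carry a pollen ecotype: ",
         paste(records$flower_id[is_ctrl & has_pollen], collapse = ", "))
  if (any(!is_ctrl & !has_pollen))
    stop("non-control flowers must carry a pollen ecotype: ",
         paste(records$flower_id[!is_ctrl & !has_pollen], collapse = ", "))

  both <- !is.na(records$adhered) & !is.na(records$germinated)
  viol <- both & records$germinated > records$adhered
  if (any(viol))
    stop("germinated exceeds adhered for flower(s): ",
         paste(records$flower_id[viol], collapse = ", "))
  neg_seed <- records$control_type == "negative" & records$seed_set %in% TRUE
  if (any(neg_seed))
    stop("negative control(s) recorded as setting seed: ",
         paste(records$flower_id[neg_seed], collapse = ", "))

  records$treatment <- ifelse(
    is_ctrl, paste0("control_", records$control_type),
    ifelse(records$maternal_ecotype == records$pollen_ecotype,
           "parental", "hybrid"))
  class(records) <- c("cross_records", "data.frame")
  records
}

#' @rdname cross_records
#' @param file Path to a CSV of cross records.
#' @export
read_cross_records <- function(file) {
  cross_records(utils::read.csv(file, stringsAsFactors = FALSE))
}

# Per-flower values for a stage, restricted to one treatment.
.stage_values <- function(records, stage, treatment) {
  r <- records[records$treatment == treatment, , drop = FALSE]
  v <- switch(stage,
    adhesion = r$adhered,
    germination = ifelse(!is.na(r$adhered) & r$adhered > 0,
                         r$germinated / r$adhered, NA_real_),
    seed_set = as.numeric(r$seed_set)
  )
  v[!is.na(v)]
}

#' Per-treatment success metrics for one crossing stage
#'
#' Summarises the hand-pollination outcome at one stage for the parental and
#' hybrid treatments: mean adhered pollen grains per flower (adhesion), mean
#' per-flower proportion of adhered grains that germinated (germination), or
#' the proportion of flowers that set seed (seed set). Standard errors are
#' the usual mean SE for adhesion/germination and the binomial SE for seed
#' set.
#'
#' @param records A `cross_records` table (see [cross_records()]).
#' @param stage One of `"adhesion"`, `"germination"`, `"seed_set"`.
#' @return An object of class `"stage_summary"`: stage, per-treatment metric,
#'   SE and n.
#' @export
stage_metrics <- function(records, stage = .cross_stages) {
  stage <- match.arg(stage)
  records <- if (inherits(records, "cross_records")) records
             else cross_records(records)
  out <- list(stage = stage)
  for (tr in c("parental", "hybrid")) {
    v <- .stage_values(records, stage, tr)
    if (!length(v))
      stop("stage '", stage, "' is unmeasured in the ", tr, " treatment")
    m <- mean(v)
    se <- if (stage == "seed_set") sqrt(m * (1 - m) / length(v))
          else stats::sd(v) / sqrt(length(v))
    out[[paste0(tr, "_metric")]] <- m
    out[[paste0(tr, "_se")]] <- se
    out[[paste0("n_", tr)]] <- length(v)
  }
  structure(out, class = "stage_summary")
}

#' @export
print.stage_summary <- function(x, ...) {
  cat(sprintf("stage '%s': parental %.4g (SE %.3g, n=%d) vs hybrid %.4g (SE %.3g, n=%d)\n",
              x$stage, x$parental_metric, x$parental_se, x$n_parental,
              x$hybrid_metric, x$hybrid_se, x$n_hybrid))
  if (!is.null(x$ri)) cat(sprintf("  RI4A = %.4f\n", x$ri))
  if (!is.null(x$test))
    cat(sprintf("  %s: statistic %.4g, p = %.4g\n",
                x$test$method, x$test$statistic, x$test$p_value))
  invisible(x)
}

#' Compare parental vs hybrid success at one crossing stage
#'
#' Adhesion and germination use a two-sample Mann-Whitney U test on the
#' per-flower values (midranks, tie-corrected normal approximation); seed set
#' uses the two-sided Fisher exact test on the 2 x 2 treatment-by-outcome
#' table (p as the sum of hypergeometric probabilities of all tables at most
#' as probable as the observed one).
#'
#' @inheritParams stage_metrics
#' @return A list with `statistic`, `p_value`, `method`, and for rank tests
#'   `z`; for seed set also the 2 x 2 `table`.
#' @export
compare_stage <- function(records, stage = .cross_stages) {
  stage <- match.arg(stage)
  records <- if (inherits(records, "cross_records")) records
             else cross_records(records)
  vp <- .stage_values(records, stage, "parental")
  vh <- .stage_values(records, stage, "hybrid")
  if (length(vp) < 2L || length(vh) < 2L)
    stop("need at least 2 observations per treatment")
  if (stage == "seed_set") {
    tab <- rbind(parental = c(yes = sum(vp == 1), no = sum(vp == 0)),
                 hybrid = c(yes = sum(vh == 1), no = sum(vh == 0)))
    ft <- stats::fisher.test(tab)
    return(list(statistic = unname(ft$estimate), p_value = ft$p.value,
                method = "fisher_exact", table = tab))
  }
  if (all(c(vp, vh) == c(vp, vh)[1]))
    return(list(statistic = length(vp) * length(vh) / 2, z = 0, p_value = 1,
                method = "mann_whitney_u"))
  wt <- suppressWarnings(
    stats::wilcox.test(vp, vh, exact = FALSE, correct = FALSE))
  mu <- length(vp) * length(vh) / 2
  z <- sign(unname(wt$statistic) - mu) * stats::qnorm(1 - wt$p.value / 2)
  list(statistic = unname(wt$statistic), z = z, p_value = wt$p.value,
       method = "mann_whitney_u")
}

#' Stage-wise reproductive isolation from a stage summary
#'
#' Fills the RI of a crossing stage by applying the mating index with
#' H = the hybrid treatment's metric and C = the parental treatment's:
#' `ri = ri_mating(H = hybrid, C = parental)`. Zero when the treatments do
#' equally well, positive when hybrid crosses underperform.
#'
#' @param summary A `stage_summary` from [stage_metrics()].
#' @return The `stage_summary` with `$ri` filled.
#' @export
ri_stage <- function(summary) {
  stopifnot(inherits(summary, "stage_summary"))
  summary$ri <- ri_mating(H = summary$hybrid_metric,
                          C = summary$parental_metric)
  summary
}

#' Full crossing-stage analysis
#'
#' Runs [stage_metrics()], [compare_stage()] and [ri_stage()] for every
#' measurable stage (adhesion, germination, seed set) and returns the stage
#' summaries, ready to feed the barrier cascade. Because hand crosses are
#' typically made on one maternal ecotype only, these RIs are directional
#' (maternal ecotype as focal).
#'
#' @param records A `cross_records` table or raw data.frame.
#' @return Named list of `stage_summary` objects (stages with no data in one
#'   treatment are omitted with a message).
#' @export
crossing_isolation <- function(records) {
  records <- if (inherits(records, "cross_records")) records
             else cross_records(records)
  out <- list()
  for (stage in .cross_stages) {
    s <- tryCatch(stage_metrics(records, stage), error = function(e) NULL)
    if (is.null(s)) {
      message("stage '", stage, "' skipped: unmeasured in one treatment")
      next
    }
    s$test <- tryCatch(compare_stage(records, stage), error = function(e) NULL)
    out[[stage]] <- ri_stage(s)
  }
  out
}
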