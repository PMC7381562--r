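#' Pipeline run configuration
#'
#' Bundles the input paths and analysis options of a full multi-barrier run.
#' Any input may be omitted (`NULL`); the corresponding barrier is then
#' skipped and reported as unavailable. Configurations can also be read from
#' a YAML file with the same field names via [read_run_config()]; values
#' passed directly override the file.
#'
#' @param rasters Named character vector/list: one suitability raster path
#'   per ecotype (names are the ecotype labels).
#' @param occurrences CSV path (`x`, `y`, `ecotype`).
#' @param phenology CSV path (`date`, `tree_id`, `population`, `flowering`).
#' @param visitation CSV path (morphospecies + two count columns).
#' @param crosses CSV path of hand-pollination records.
#' @param focal,other The two ecotype labels; `focal` should be the maternal
#'   ecotype of the crossing experiment if one is supplied.
#' @param radius_m Dispersal radius in metres (default 500).
#' @param element Buffer structuring element, `"square"` or `"disk"`.
#' @param period Phenology aggregation period, `"month"` or `"census"`.
#' @param baseline_gene_flow Baseline gene-flow probability for RI4E.
#' @param n_background Background pixels per ecotype for the ETSS threshold.
#' @param seed Integer seed for the background sampling (and anything else
#'   stochastic in a run).
#' @param out_dir Output directory for the report bundle (`NULL` = don't
#'   write).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(rasters = NULL, occurrences = NULL, phenology = NULL,
                       visitation = NULL, crosses = NULL,
                       focal = "brown_sand", other = "white_sand",
                       radius_m = 500, element = "square", period = "month",
                       baseline_gene_flow = 0.5, n_background = 10000,
                       seed = 1, out_dir = NULL) {
  structure(list(rasters = rasters, occurrences = occurrences,
                 phenology = phenology, visitation = visitation,
                 crosses = crosses, focal = focal, other = other,
                 radius_m = radius_m, element = element, period = period,
                 baseline_gene_flow = baseline_gene_flow,
                 n_background = n_background, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param file Path to a YAML configuration file.
#' @param ... Overrides for individual fields.
#' @export
read_run_config <- function(file, ...) {
  raw <- yaml::read_yaml(file)
  dots <- list(...)
  raw[names(dots)] <- dots
  do.call(run_config, raw[names(raw) %in% names(formals(run_config))])
}

#' Validate the input files of a run configuration
#'
#' Schema-checks every input the configuration names: required columns,
#' parseable dates and numbers, `germinated <= adhered` per flower, the
#' negative-control sanity rule (a negative control must not set seed),
#' ecotype labels cross-referenced against `focal`/`other`, and raster
#' alignment. Issues are reported per file with row numbers where
#' applicable.
#'
#' @param config A [run_config()].
#' @return A list with `ok` (logical) and `issues` (data.frame `file`,
#'   `row`, `message`; zero rows when everything passes).
#' @export
validate_inputs <- function(config) {
  issues <- list()
  add <- function(file, row, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, row = row, message = message, stringsAsFactors = FALSE)
  need_file <- function(path) {
    if (!file.exists(path)) { add(path, NA, "file does not exist"); FALSE }
    else TRUE
  }
  labels <- c(config$focal, config$other)

  if (!is.null(config$rasters)) {
    grids <- list()
    for (e in names(config$rasters)) {
      if (!e %in% labels) add(config$rasters[[e]], NA,
                              paste0("raster ecotype '", e, "' not in focal/other labels"))
      if (need_file(config$rasters[[e]]))
        grids[[e]] <- tryCatch(read_raster(config$rasters[[e]]),
                               error = function(err) {
                                 add(config$rasters[[e]], NA, conditionMessage(err))
                                 NULL
                               })
    }
    if (length(grids) == 2L && !is.null(grids[[1]]) && !is.null(grids[[2]])) {
      if (!identical(dim(grids[[1]]$values), dim(grids[[2]]$values)))
        add(config$rasters[[1]], NA, "suitability rasters are not aligned")
    }
  }
  if (!is.null(config$occurrences) && need_file(config$occurrences)) {
    occ <- utils::read.csv(config$occurrences, stringsAsFactors = FALSE)
    miss <- setdiff(c("x", "y", "ecotype"), names(occ))
    if (length(miss)) add(config$occurrences, NA,
                          paste("missing column(s):", paste(miss, collapse = ", ")))
    else {
      bad <- which(!occ$ecotype %in% labels)
      for (i in bad) add(config$occurrences, i,
                         paste0("unknown ecotype label '", occ$ecotype[i], "'"))
    }
  }
  if (!is.null(config$phenology) && need_file(config$phenology)) {
    ph <- utils::read.csv(config$phenology, stringsAsFactors = FALSE)
    miss <- setdiff(c("date", "tree_id", "population", "flowering"), names(ph))
    if (length(miss)) add(config$phenology, NA,
                          paste("missing column(s):", paste(miss, collapse = ", ")))
    else {
      bad <- which(is.na(as.Date(ph$date, optional = TRUE)))
      for (i in utils::head(bad, 5)) add(config$phenology, i, "unparseable date")
      if (length(unique(ph$population)) != 2L)
        add(config$phenology, NA, "survey must contain exactly two populations")
    }
  }
  if (!is.null(config$visitation) && need_file(config$visitation)) {
    vt <- tryCatch(read_visitation_table(config$visitation),
                   error = function(err) {
                     add(config$visitation, NA, conditionMessage(err)); NULL
                   })
  }
  if (!is.null(config$crosses) && need_file(config$crosses)) {
    cr <- utils::read.csv(config$crosses, stringsAsFactors = FALSE)
    miss <- setdiff(c("flower_id", "maternal_ecotype", "pollen_ecotype"),
                    names(cr))
    if (length(miss)) add(config$crosses, NA,
                          paste("missing column(s):", paste(miss, collapse = ", ")))
    else {
      if (!"control_type" %in% names(cr)) cr$control_type <- "none"
      cr$control_type[is.na(cr$control_type) | cr$control_type == ""] <- "none"
      if (all(c("adhered", "germinated") %in% names(cr))) {
        bad <- which(!is.na(cr$adhered) & !is.na(cr$germinated) &
                       cr$germinated > cr$adhered)
        for (i in bad) add(config$crosses, i,
                           paste0("germinated > adhered for flower '",
                                  cr$flower_id[i], "'"))
      }
      if ("seed_set" %in% names(cr)) {
        bad <- which(cr$control_type == "negative" &
                       as.logical(cr$seed_set) %in% TRUE)
        for (i in bad) add(config$crosses, i,
                           paste0("negative control '", cr$flower_id[i],
                                  "' recorded as setting seed"))
      }
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues)
            else data.frame(file = character(), row = integer(),
                            message = character())
  list(ok = nrow(issues) == 0L, issues = issues)
}

#' Run the full multi-barrier isolation pipeline
#'
#' Executes every barrier stage for which the configuration names inputs,
#' assembles the per-direction barrier table, fits the sequential cascade
#' with and without ecogeography, and (optionally) writes a report bundle:
#' `barrier_table.csv`, `cascade.json`, `intermediates.json` and
#' `manifest.json` under `config$out_dir`. Stages without inputs are skipped
#' and marked unavailable (never imputed as zero). Crossing-stage RIs are
#' only attributed to the maternal (focal) ecotype's direction.
#'
#' @param config A [run_config()].
#' @return A list of class `"ri_pipeline"`: `barriers` (the two-direction
#'   barrier table), `cascades` (named list of [ri_cascade()] fits),
#'   `intermediates` (per-stage raw results), `config`, `skipped`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  val <- validate_inputs(config)
  if (!val$ok) {
    msg <- paste(sprintf("%s [row %s]: %s", val$issues$file,
                         ifelse(is.na(val$issues$row), "-", val$issues$row),
                         val$issues$message), collapse = "\n  ")
    stop("input validation failed:\n  ", msg)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  focal <- config$focal; other <- config$other
  inter <- list()
  skipped <- character()
  ri <- list()  # ri[[direction]][[barrier]]
  ri[[focal]] <- list(); ri[[other]] <- list()

  if (!is.null(config$rasters) && !is.null(config$occurrences) &&
      all(c(focal, other) %in% names(config$rasters))) {
    occ <- utils::read.csv(config$occurrences, stringsAsFactors = FALSE)
    eco <- eco_isolation(read_raster(config$rasters[[focal]]),
                         read_raster(config$rasters[[other]]),
                         occ, focal, other,
                         radius_m = config$radius_m, element = config$element,
                         n_background = config$n_background)
    cl <- eco$classification
    inter$ecogeography <- list(
      counts = list(focal_only = cl$focal_only, other_only = cl$other_only,
                    shared = cl$shared,
                    shared_from_model = cl$shared_from_model,
                    shared_from_buffer = cl$shared_from_buffer),
      thresholds = as.list(eco$thresholds), ri = as.list(eco$ri))
    inter$eco_classification <- cl
    ri[[focal]]$ecogeography <- eco$ri[[focal]]
    ri[[other]]$ecogeography <- eco$ri[[other]]
  } else skipped <- c(skipped, "ecogeography")

  if (!is.null(config$phenology)) {
    survey <- read_phenology_survey(config$phenology)
    series <- aggregate_survey(survey, period = config$period)
    phen <- ri_phenology(series)
    inter$phenology <- list(periods = series$periods,
                            counts = series$counts,
                            totals = as.list(series$totals),
                            ri = as.list(phen))
    for (d in c(focal, other))
      if (d %in% names(phen)) ri[[d]]$phenology <- phen[[d]]
  } else skipped <- c(skipped, "phenology")

  if (!is.null(config$visitation)) {
    vt <- read_visitation_table(config$visitation)
    d <- bray_curtis(vt[, 1], vt[, 2])
    test <- visitation_rank_test(vt)
    poll <- ri_pollinator(vt)
    inter$pollinators <- list(bray_curtis = d, rank_test = test, ri = poll)
    ri[[focal]]$pollinators <- poll
    ri[[other]]$pollinators <- poll
  } else skipped <- c(skipped, "pollinators")

  if (!is.null(config$crosses)) {
    records <- read_cross_records(config$crosses)
    maternal <- unique(records$maternal_ecotype)
    if (length(maternal) != 1L || !maternal %in% c(focal, other))
      stop("cross records must have one maternal ecotype matching focal/other")
    stages <- crossing_isolation(records)
    inter$crossing <- lapply(stages, function(s) {
      s_clean <- unclass(s)
      s_clean$test <- if (!is.null(s$test))
        s$test[setdiff(names(s$test), "table")] else NULL
      s_clean
    })
    map <- c(adhesion = "pollen_adhesion", germination = "pollen_germination",
             seed_set = "seed_development")
    for (st in names(stages))
      ri[[maternal]][[map[[st]]]] <- stages[[st]]$ri
  } else skipped <- c(skipped, "crossing")

  barriers <- do.call(rbind, unlist(lapply(c(focal, other), function(d) {
    lapply(.barrier_registry$barrier, function(b) {
      if (!is.null(ri[[d]][[b]]))
        barrier_strength(b, ri[[d]][[b]], focal = d)
      else
        barrier_strength(b, NA_real_, focal = d, available = FALSE)
    })
  }), recursive = FALSE))

  cascades <- list()
  for (d in c(focal, other)) {
    sub <- barriers[barriers$focal == d & barriers$available, , drop = FALSE]
    if (nrow(sub))
      cascades[[d]] <- ri_cascade(sub, baseline_gene_flow = config$baseline_gene_flow)
  }

  result <- structure(
    list(barriers = barriers, cascades = cascades, intermediates = inter,
         skipped = skipped, config = config),
    class = "ri_pipeline")
  if (!is.null(config$out_dir)) write_report_bundle(result, config$out_dir)
  result
}

#' @export
print.ri_pipeline <- function(x, ...) {
  cat("Multi-barrier reproductive isolation pipeline run\n")
  if (length(x$skipped))
    cat("Skipped stages (no input):", paste(x$skipped, collapse = ", "), "\n")
  for (d in names(x$cascades)) {
    cat("\n--- direction:", d, "---\n")
    print(x$cascades[[d]])
  }
  invisible(x)
}

#' Write the report bundle of a pipeline run
#'
#' Emits `barrier_table.csv` (per-direction barrier strengths),
#' `cascade.json` (totals and contributions under the sequential cascade and
#' RI4E, with and without ecogeography), `intermediates.json` (pixel counts,
#' dissimilarity, stage metrics, test results), an optional classified
#' habitat raster, and `manifest.json` (inputs, their MD5 hashes, options,
#' package version).
#'
#' @param result An `ri_pipeline` result.
#' @param dir Output directory.
#' @param classified_raster Logical; write the 0/1/2/3-coded overlap raster
#'   if the ecogeographic stage ran.
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(result, dir, classified_raster = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(barrier_table = file.path(dir, "barrier_table.csv"),
                cascade = file.path(dir, "cascade.json"),
                intermediates = file.path(dir, "intermediates.json"),
                manifest = file.path(dir, "manifest.json"))
  write_barrier_table(result$barriers, paths$barrier_table)
  cascade_out <- lapply(result$cascades, function(cc) list(
    total = cc$total,
    total_sympatry = cc$total_sympatry,
    total_ri4e = cc$total_ri4e,
    barriers = cc$contributions))
  jsonlite::write_json(cascade_out, paths$cascade, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  inter <- result$intermediates
  inter$eco_classification <- NULL # matrix payload stays out of the JSON
  jsonlite::write_json(inter, paths$intermediates, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  if (classified_raster && !is.null(result$intermediates$eco_classification)) {
    cl <- result$intermediates$eco_classification
    paths$classified_raster <- file.path(dir, "habitat_classification.asc")
    # codes 0 none / 1 focal-only / 2 other-only / 3 shared
    code_grid <- structure(list(values = cl$codes, pixel_size = cl$pixel_size,
                                origin = cl$origin, crs_label = ""),
                           class = "suitability_grid")
    write_esri_ascii(code_grid, paths$classified_raster)
  }
  cfg <- result$config
  input_paths <- c(unlist(cfg$rasters), cfg$occurrences, cfg$phenology,
                   cfg$visitation, cfg$crosses)
  manifest <- list(
    package = "ribarriers",
    version = as.character(utils::packageVersion("ribarriers")),
    seed = cfg$seed,
    options = cfg[c("focal", "other", "radius_m", "element", "period",
                    "baseline_gene_flow", "n_background")],
    inputs = lapply(input_paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    skipped = result$skipped)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
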