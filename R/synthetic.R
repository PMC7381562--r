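#' Simulation configuration for the synthetic input generators
#'
#' Collects every tunable of the four input generators with defaults sized
#' like the field study the pipeline is designed around: two anti-correlated
#' habitat types on a 250 m grid, 103 white-sand and 76 brown-sand
#' occurrences, a biweekly flowering survey of 12 white-sand and 39
#' brown-sand trees over three years, a 15-morphospecies visitation table
#' with 40 and 177 visits per ecotype, and hand-pollination arms of 38
#' parental and 104 hybrid flowers with adhesion means 159/112,
#' germination probabilities 0.46/0.44 and seed-set rates 0.39/0.164.
#' Identical configurations (including `seed`) yield identical outputs; each
#' generator consumes its own substream of the root seed, so modules can be
#' regenerated independently.
#'
#' @param seed Root integer seed.
#' @param grid List: `rows`, `cols`, `pixel_size` (m), `correlation_length`
#'   (pixels, Gaussian smoothing SD of the latent soil field), `contrast`
#'   (logistic steepness mapping the field to suitability; larger = closer to
#'   binary, 0 = both ecotypes identical at 0.5), `offset` (named per-ecotype
#'   latent cutoffs controlling how much habitat each gets), `n_occurrences`
#'   (named, per ecotype).
#' @param phenology List: `n_trees` (named per population), `n_months`,
#'   `start` (first census month, `"YYYY-MM-01"`), `peak_prob` (named
#'   per-population peak monthly flowering probability; the seasonal shape is
#'   shared, so populations differ in flowering abundance, not timing),
#'   `season_shape` (optional function month-index -> \[0,1\]).
#' @param pollinators List: `proportions` (2-column matrix of community
#'   proportions, defaults to the observed study community), `totals` (named
#'   visits per ecotype), `concentration` (Dirichlet concentration for
#'   jittering the proportions; `NULL` = fixed).
#' @param crossing List: `n_flowers` (named per treatment), `adhesion_mean`,
#'   `adhesion_dispersion` (d in var = mu + d mu^2; 0 = counts constant at
#'   the mean), `germination_p`, `seed_rate` (all named per treatment),
#'   `n_negative_controls`, `maternal` and `paternal` ecotype labels.
#' @param ecotypes Character vector of the two ecotype labels.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1,
                              grid = list(), phenology = list(),
                              pollinators = list(), crossing = list(),
                              ecotypes = c("white_sand", "brown_sand")) {
  ws <- ecotypes[1]; bs <- ecotypes[2]
  def_grid <- list(rows = 120, cols = 120, pixel_size = 250,
                   correlation_length = 8, contrast = 6,
                   offset = stats::setNames(c(0, 1.2), ecotypes),
                   n_occurrences = stats::setNames(c(103, 76), ecotypes))
  def_phen <- list(n_trees = stats::setNames(c(12, 39), ecotypes),
                   n_months = 36, start = "2006-01-01",
                   peak_prob = stats::setNames(c(0.3, 0.7), ecotypes),
                   season_shape = NULL)
  def_poll <- list(proportions = .study_community(ws, bs),
                   totals = stats::setNames(c(40, 177), ecotypes),
                   concentration = NULL)
  def_cross <- list(
    n_flowers = c(parental = 38, hybrid = 104),
    adhesion_mean = c(parental = 159, hybrid = 112),
    adhesion_dispersion = c(parental = 0.34, hybrid = 0.34),
    germination_p = c(parental = 0.46, hybrid = 0.44),
    seed_rate = c(parental = 0.39, hybrid = 0.164),
    n_negative_controls = 30,
    maternal = bs, paternal = ws)
  cfg <- list(seed = as.integer(seed), ecotypes = ecotypes,
              grid = utils::modifyList(def_grid, grid),
              phenology = utils::modifyList(def_phen, phenology),
              pollinators = utils::modifyList(def_poll, pollinators),
              crossing = utils::modifyList(def_cross, crossing))
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

# Visitation-community proportions shaped like the observed study community:
# one dominant shared bee morphospecies heavily biased to brown sand, a few
# shared minor species, and a tail of singletons exclusive to one ecotype.
.study_community <- function(ws, bs) {
  counts <- cbind(c(22, 6, 9, 0, 0, 0, 0, 0, 2, 0, 0, 0, 0, 0, 1),
                  c(4, 4, 84, 2, 9, 10, 7, 1, 34, 10, 2, 8, 1, 1, 0))
  colnames(counts) <- c(ws, bs)
  rownames(counts) <- paste0("morphospecies_", LETTERS[seq_len(nrow(counts))])
  sweep(counts, 2, colSums(counts), "/")
}

.validate_sim_config <- function(cfg) {
  probs <- c(cfg$phenology$peak_prob, cfg$crossing$germination_p,
             cfg$crossing$seed_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(cfg$grid$n_occurrences, cfg$phenology$n_trees,
              cfg$pollinators$totals, cfg$crossing$n_flowers)
  if (any(counts < 1)) stop("counts must be >= 1")
  if (any(abs(colSums(cfg$pollinators$proportions) - 1) > 1e-8))
    stop("community proportion columns must sum to 1")
  invisible(cfg)
}

# Deterministic per-generator substreams of the root seed, so each generator
# is reproducible on its own. Kept below 2^31.
.substream <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

# Smooth a white-noise matrix with a separable Gaussian kernel under
# circular (torus) boundary conditions, then standardise.
.gaussian_field <- function(rows, cols, sd_pixels) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (sd_pixels > 0) {
    half <- max(1L, ceiling(3 * sd_pixels))
    k <- stats::dnorm(-half:half, sd = sd_pixels)
    k <- k / sum(k)
    smooth_vec <- function(v) {
      n <- length(v)
      idx <- outer(seq_len(n), -half:half, function(i, d) ((i + d - 1) %% n) + 1)
      as.numeric(matrix(v[idx], n) %*% k)
    }
    z <- apply(z, 2, smooth_vec)
    z <- t(apply(z, 1, smooth_vec))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate an anti-correlated pair of suitability grids with occurrences
#'
#' Simulates a smooth latent soil field (kernel-smoothed Gaussian white
#' noise) and maps it monotonically to habitat suitability for the first
#' ecotype and anti-monotonically for the second:
#' `plogis(contrast * (z - offset_1))` and `plogis(-contrast * (z + offset_2))`.
#' With `contrast = 0` the two surfaces are identical (0.5 everywhere); as
#' contrast grows the niches become binary and disjoint wherever the offsets
#' separate the cutoffs. Occurrence points are sampled across pixels with
#' probability proportional to suitability and placed at pixel centres.
#'
#' @param config A [simulation_config()].
#' @return List with `grids` (named list of two [suitability_grid()]s) and
#'   `occurrences` (data.frame `x`, `y`, `ecotype`).
#' @export
make_suitability_pair <- function(config) {
  g <- config$grid
  set.seed(.substream(config$seed, 1L))
  z <- .gaussian_field(g$rows, g$cols, g$correlation_length)
  e1 <- config$ecotypes[1]; e2 <- config$ecotypes[2]
  suit <- list(
    stats::plogis(g$contrast * (z - g$offset[[e1]])),
    stats::plogis(-g$contrast * (z + g$offset[[e2]]))
  )
  names(suit) <- config$ecotypes
  grids <- lapply(suit, suitability_grid, pixel_size = g$pixel_size)
  occ <- do.call(rbind, lapply(config$ecotypes, function(e) {
    w <- as.numeric(grids[[e]]$values)
    pick <- sample.int(length(w), g$n_occurrences[[e]],
                       replace = TRUE, prob = w)
    row <- (pick - 1) %% g$rows + 1
    col <- (pick - 1) %/% g$rows + 1
    data.frame(
      x = grids[[e]]$origin[1] + (col - 0.5) * g$pixel_size,
      y = grids[[e]]$origin[2] - (row - 0.5) * g$pixel_size,
      ecotype = e, stringsAsFactors = FALSE)
  }))
  list(grids = grids, occurrences = occ)
}

#' Generate a biweekly flowering survey
#'
#' Each tree is in flower (or not) for whole calendar months, drawn
#' independently per month with its population's monthly probability
#' `peak_prob * season_shape(month)`; both biweekly censuses of a month
#' record the month's state. The default seasonal shape is a smooth annual
#' cycle shared by both populations, so the populations differ in flowering
#' abundance but not timing — the regime under which the abundance-weighted
#' temporal index rewards the common population and penalises the rare one.
#'
#' @param config A [simulation_config()].
#' @return A survey data.frame (`date`, `tree_id`, `population`,
#'   `flowering`) suitable for [aggregate_survey()].
#' @export
make_phenology <- function(config) {
  ph <- config$phenology
  set.seed(.substream(config$seed, 2L))
  shape <- ph$season_shape
  if (is.null(shape))
    shape <- function(m) 0.5 + 0.5 * sin(2 * pi * (m - 2) / 12)
  months <- seq(as.Date(ph$start), by = "month", length.out = ph$n_months)
  rows <- list()
  for (pop in names(ph$n_trees)) {
    n <- ph$n_trees[[pop]]
    ids <- sprintf("%s_tree_%02d", pop, seq_len(n))
    p <- pmin(1, pmax(0, ph$peak_prob[[pop]] * shape(seq_len(ph$n_months))))
    state <- matrix(stats::rbinom(n * ph$n_months, 1, rep(p, each = n)),
                    nrow = n)
    for (m in seq_len(ph$n_months)) {
      for (day in c(1, 15)) {
        rows[[length(rows) + 1L]] <- data.frame(
          date = format(months[m] + (day - 1)),
          tree_id = ids, population = pop,
          flowering = state[, m], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a pollinator visitation table
#'
#' Draws each ecotype's visit counts from a multinomial over morphospecies
#' with the configured community proportions and per-ecotype totals. If a
#' Dirichlet `concentration` is set, the proportions are first jittered
#' around the configured vectors (larger concentration = less jitter); by
#' default they are fixed, so the expected dissimilarity is controlled by
#' the overlap of the two proportion vectors alone.
#'
#' @param config A [simulation_config()].
#' @return A [visitation_table()].
#' @export
make_visitation <- function(config) {
  po <- config$pollinators
  set.seed(.substream(config$seed, 3L))
  p <- po$proportions
  if (!is.null(po$concentration)) {
    p <- apply(p, 2, function(col) {
      a <- po$concentration * col + 1e-8
      draw <- stats::rgamma(length(a), shape = a)
      draw / sum(draw)
    })
  }
  counts <- vapply(seq_len(2L), function(j)
    as.numeric(stats::rmultinom(1, po$totals[[j]], p[, j])),
    numeric(nrow(p)))
  dimnames(counts) <- dimnames(po$proportions)
  visitation_table(counts)
}

#' Generate hand-pollination cross records
#'
#' Per flower and treatment: adhered pollen grains are negative-binomial
#' with the treatment mean and dispersion d (var = mu + d mu^2; d = 0 gives
#' counts constant at the mean — the study's standard errors imply clear
#' overdispersion relative to Poisson, hence the negative binomial default);
#' germinated grains are binomial(adhered, p); and seed set is Bernoulli with
#' the treatment rate. Negative-control flowers (no pollen applied) never set
#' seed.
#'
#' @param config A [simulation_config()].
#' @return A `cross_records` data.frame (see [cross_records()]).
#' @export
make_crosses <- function(config) {
  cr <- config$crossing
  set.seed(.substream(config$seed, 4L))
  recs <- list()
  for (tr in c("parental", "hybrid")) {
    n <- cr$n_flowers[[tr]]
    mu <- cr$adhesion_mean[[tr]]
    d <- cr$adhesion_dispersion[[tr]]
    adhered <- if (d <= 0) rep(round(mu), n)
               else stats::rnbinom(n, mu = mu, size = 1 / d)
    germ <- stats::rbinom(n, adhered, cr$germination_p[[tr]])
    seed_set <- stats::rbinom(n, 1, cr$seed_rate[[tr]]) == 1
    recs[[tr]] <- data.frame(
      flower_id = sprintf("%s_%03d", tr, seq_len(n)),
      inflorescence_id = sprintf("%s_infl_%d", tr, (seq_len(n) - 1) %/% 10 + 1),
      maternal_ecotype = cr$maternal,
      pollen_ecotype = if (tr == "parental") cr$maternal else cr$paternal,
      adhered = adhered, germinated = germ, seed_set = seed_set,
      control_type = "none", stringsAsFactors = FALSE)
  }
  if (cr$n_negative_controls > 0) {
    n <- cr$n_negative_controls
    recs$control <- data.frame(
      flower_id = sprintf("negctrl_%03d", seq_len(n)),
      inflorescence_id = sprintf("negctrl_infl_%d", (seq_len(n) - 1) %/% 10 + 1),
      maternal_ecotype = cr$maternal, pollen_ecotype = "",
      adhered = NA_real_, germinated = NA_real_, seed_set = FALSE,
      control_type = "negative", stringsAsFactors = FALSE)
  }
  cross_records(do.call(rbind, recs))
}

#' Write a full synthetic input bundle to disk
#'
#' Runs all four generators and writes the pipeline's input files into a run
#' directory: two suitability rasters (ESRI ASCII), `occurrences.csv`,
#' `phenology.csv`, `visitation.csv`, `crosses.csv`, and a `manifest.json`
#' recording the seed, configuration and package version.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths written.
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- make_suitability_pair(config)
  paths <- list()
  for (e in config$ecotypes) {
    paths[[paste0("raster_", e)]] <- file.path(dir, paste0("suitability_", e, ".asc"))
    write_esri_ascii(sp$grids[[e]], paths[[paste0("raster_", e)]])
  }
  paths$occurrences <- file.path(dir, "occurrences.csv")
  utils::write.csv(sp$occurrences, paths$occurrences, row.names = FALSE, quote = FALSE)
  paths$phenology <- file.path(dir, "phenology.csv")
  utils::write.csv(make_phenology(config), paths$phenology, row.names = FALSE, quote = FALSE)
  paths$visitation <- file.path(dir, "visitation.csv")
  vt <- make_visitation(config)
  utils::write.csv(data.frame(morphospecies = rownames(vt),
                              as.data.frame.matrix(unclass(vt)),
                              check.names = FALSE),
                   paths$visitation, row.names = FALSE, quote = FALSE)
  paths$crosses <- file.path(dir, "crosses.csv")
  utils::write.csv(make_crosses(config), paths$crosses, row.names = FALSE, quote = FALSE)
  paths$manifest <- file.path(dir, "manifest.json")
  manifest <- list(
    seed = config$seed,
    package = "ribarriers",
    version = as.character(utils::packageVersion("ribarriers")),
    ecotypes = config$ecotypes,
    files = lapply(paths[names(paths) != "manifest"], basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
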