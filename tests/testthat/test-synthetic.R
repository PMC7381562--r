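# Small configs keep the generator tests fast; the study-scale defaults are
# exercised in the pipeline and acceptance suites.
small_config <- function(seed = 1, grid = list(), phenology = list(), ...) {
  simulation_config(
    seed = seed,
    grid = utils::modifyList(
      list(rows = 40, cols = 40, correlation_length = 4,
           n_occurrences = c(white_sand = 30, brown_sand = 25)), grid),
    phenology = utils::modifyList(list(n_months = 12), phenology),
    ...)
}

test_that("identical configurations produce identical outputs", {
  c1 <- small_config(seed = 7)
  c2 <- small_config(seed = 7)
  expect_identical(make_suitability_pair(c1), make_suitability_pair(c2))
  expect_identical(make_phenology(c1), make_phenology(c2))
  expect_identical(make_visitation(c1), make_visitation(c2))
  expect_identical(make_crosses(c1), make_crosses(c2))
  # and a different seed changes them
  c3 <- small_config(seed = 8)
  expect_false(identical(make_visitation(c1), make_visitation(c3)))
})

test_that("generators can be regenerated independently of one another", {
  cfg <- small_config(seed = 3)
  v1 <- make_visitation(cfg)
  make_phenology(cfg) # consuming another substream must not disturb the next
  v2 <- make_visitation(cfg)
  expect_identical(v1, v2)
})

test_that("suitability contrast controls niche overlap", {
  # zero contrast: both surfaces identical at 0.5 -> RI_eco ~ 0
  flat <- small_config(seed = 2, grid = list(contrast = 0))
  sp <- make_suitability_pair(flat)
  expect_equal(sp$grids[[1]]$values, sp$grids[[2]]$values)
  cl <- classify_overlap(binarize(sp$grids[[1]], 0.5, "a"),
                         binarize(sp$grids[[2]], 0.5, "b"), radius_m = 500)
  expect_equal(ri_ecogeographic(cl), 0)
  # extreme contrast and separated cutoffs: model-level shared pixels vanish
  sharp <- simulation_config(seed = 2, grid = list(
    rows = 40, cols = 40, correlation_length = 4, contrast = 400,
    offset = c(white_sand = 0.5, brown_sand = 0.5),
    n_occurrences = c(white_sand = 30, brown_sand = 25)))
  sp2 <- make_suitability_pair(sharp)
  cl2 <- classify_overlap(binarize(sp2$grids[[1]], 0.5, "a"),
                          binarize(sp2$grids[[2]], 0.5, "b"), radius_m = 0)
  expect_equal(cl2$shared_from_model, 0)
})

test_that("occurrences land on suitable habitat within the grid", {
  cfg <- small_config(seed = 5)
  sp <- make_suitability_pair(cfg)
  for (e in cfg$ecotypes) {
    pts <- sp$occurrences[sp$occurrences$ecotype == e, ]
    expect_equal(nrow(pts), cfg$grid$n_occurrences[[e]])
    sc <- extract_scores(sp$grids[[e]], pts$x, pts$y)
    expect_true(all(!is.na(sc)))
    # sampling is suitability-weighted, so scores should be high on average
    expect_gt(mean(sc), mean(sp$grids[[e]]$values))
  }
})

test_that("phenology generator reproduces the directional abundance asymmetry", {
  # identical curves and equal census sizes: the temporal index carries a
  # positive O(1/n) small-sample bias (the conspecific term is quadratic in
  # the focal counts), so the mean RI converges to 0 as censuses grow
  mean_ri_at <- function(n, reps = 40) {
    set.seed(77)
    mean(replicate(reps, {
      cfg <- simulation_config(seed = sample.int(1e6, 1), phenology = list(
        n_trees = c(white_sand = n, brown_sand = n),
        peak_prob = c(white_sand = 0.5, brown_sand = 0.5), n_months = 12))
      ri_phenology(aggregate_survey(make_phenology(cfg)))
    }))
  }
  b_small <- mean_ri_at(20)
  b_large <- mean_ri_at(100)
  expect_lt(abs(b_large), abs(b_small))  # error shrinks with census size
  expect_lt(abs(b_large), 0.03)          # and is already small at n = 100
  # non-overlapping seasons: RI = 1 both directions
  cfg_disj <- simulation_config(seed = 4, phenology = list(
    n_trees = c(white_sand = 10, brown_sand = 10), n_months = 12,
    peak_prob = c(white_sand = 1, brown_sand = 1),
    season_shape = NULL))
  surv <- make_phenology(cfg_disj)
  # force disjoint flowering by population-specific halves of the year
  month <- as.integer(format(as.Date(surv$date), "%m"))
  surv$flowering <- ifelse(surv$population == "white_sand",
                           surv$flowering * (month <= 6),
                           surv$flowering * (month > 6))
  expect_equal(unname(ri_phenology(aggregate_survey(surv))), c(1, 1))
  # study-sized censuses (12 vs 39 trees), shared curve: rare population
  # negative, common population positive
  set.seed(78)
  ri_asym <- rowMeans(replicate(40, {
    cfg <- simulation_config(seed = sample.int(1e6, 1), phenology = list(
      peak_prob = c(white_sand = 0.5, brown_sand = 0.5), n_months = 24))
    ri_phenology(aggregate_survey(make_phenology(cfg)))
  }))
  expect_lt(ri_asym[["white_sand"]], 0)
  expect_gt(ri_asym[["brown_sand"]], 0)
})

test_that("visitation generator hits its analytic expected dissimilarity", {
  cfg <- small_config(seed = 1)
  p <- cfg$pollinators$proportions
  totals <- cfg$pollinators$totals
  expected <- oracle_expected_bray(p[, 1], p[, 2], totals[[1]], totals[[2]])
  sims <- vapply(1:500, function(i) {
    tab <- make_visitation(small_config(seed = 1000 + i))
    bray_curtis(tab[, 1], tab[, 2])
  }, numeric(1))
  expect_lt(abs(mean(sims) - expected), 0.02)
  # disjoint support proportions give dissimilarity exactly 1
  disjoint <- simulation_config(seed = 6, pollinators = list(
    proportions = cbind(white_sand = c(0.5, 0.5, 0, 0),
                        brown_sand = c(0, 0, 0.3, 0.7)),
    totals = c(white_sand = 50, brown_sand = 50)))
  tab <- make_visitation(disjoint)
  expect_equal(bray_curtis(tab[, 1], tab[, 2]), 1)
  # identical proportions with large totals: dissimilarity near sampling floor
  same <- simulation_config(seed = 6, pollinators = list(
    proportions = cbind(white_sand = rep(0.2, 5), brown_sand = rep(0.2, 5)),
    totals = c(white_sand = 5000, brown_sand = 5000)))
  tab2 <- make_visitation(same)
  expect_lt(bray_curtis(tab2[, 1], tab2[, 2]), 0.05)
})

test_that("crossing generator respects its parameters", {
  cfg <- small_config(seed = 11)
  recs <- make_crosses(cfg)
  expect_s3_class(recs, "cross_records")
  expect_equal(sum(recs$treatment == "parental"), 38)
  expect_equal(sum(recs$treatment == "hybrid"), 104)
  expect_true(all(recs$germinated[!is.na(recs$germinated)] <=
                    recs$adhered[!is.na(recs$adhered)]))
  expect_true(all(!recs$seed_set[recs$control_type == "negative"]))
  # zero dispersion: adhered counts constant at the treatment mean
  cfg0 <- simulation_config(seed = 11, crossing = list(
    adhesion_dispersion = c(parental = 0, hybrid = 0)))
  r0 <- make_crosses(cfg0)
  expect_equal(unique(r0$adhered[r0$treatment == "parental"]), 159)
  expect_equal(unique(r0$adhered[r0$treatment == "hybrid"]), 112)
  # equal parameters across treatments: stage RIs scatter around zero
  set.seed(79)
  ri_eq <- replicate(40, {
    cfg_eq <- simulation_config(seed = sample.int(1e6, 1), crossing = list(
      n_flowers = c(parental = 60, hybrid = 60),
      adhesion_mean = c(parental = 120, hybrid = 120),
      germination_p = c(parental = 0.45, hybrid = 0.45),
      seed_rate = c(parental = 0.3, hybrid = 0.3)))
    vapply(crossing_isolation(make_crosses(cfg_eq)), `[[`, numeric(1), "ri")
  })
  for (stage in rownames(ri_eq))
    expect_lt(abs(mean(ri_eq[stage, ])),
              3 * sd(ri_eq[stage, ]) / sqrt(ncol(ri_eq)))
})

test_that("generated input bundles validate and feed the pipeline", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 13)
  paths <- simulate_inputs(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  rc <- run_config(
    rasters = list(white_sand = paths$raster_white_sand,
                   brown_sand = paths$raster_brown_sand),
    occurrences = paths$occurrences, phenology = paths$phenology,
    visitation = paths$visitation, crosses = paths$crosses,
    focal = "brown_sand", other = "white_sand", out_dir = NULL)
  v <- validate_inputs(rc)
  expect_true(v$ok)
  # byte-identical regeneration under the same config
  dir2 <- withr::local_tempdir()
  paths2 <- simulate_inputs(small_config(seed = 13), dir2)
  for (nm in setdiff(names(paths), "manifest"))
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]))
})
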