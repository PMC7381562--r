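make_map <- function(m, pixel_size = 250, ecotype = "a") {
  binarize(suitability_grid(m * 1, pixel_size = pixel_size), 0.5, ecotype)
}

test_that("ETSS threshold handles separable and uninformative scores", {
  # perfectly separable: smallest candidate achieving sens = spec = 1
  expect_equal(etss_threshold(c(0.9, 0.8), c(0.1, 0.2)), 0.8)
  # presence == background (uninformative scores): sens + spec = 1 at every
  # candidate, so the gap is minimised where sensitivity is nearest 0.5
  sc <- c(0.2, 0.5, 0.7)
  expect_equal(etss_threshold(sc, sc), 0.5)
  # exact ties in the gap break toward the smallest candidate
  tied <- c(0.1, 0.5, 0.5, 0.9)
  expect_equal(etss_threshold(tied, tied), 0.5)
  expect_error(etss_threshold(numeric(0), c(0.1)), "non-empty")
})

test_that("ETSS threshold equals the exhaustive-scan oracle", {
  set.seed(7)
  for (i in 1:20) {
    presence <- rbeta(50, 4, 2)
    background <- rbeta(200, 2, 3)
    expect_equal(etss_threshold(presence, background),
                 oracle_etss(presence, background))
  }
  # heavy ties (discretised scores)
  for (i in 1:10) {
    presence <- sample(seq(0, 1, 0.1), 40, replace = TRUE)
    background <- sample(seq(0, 1, 0.1), 100, replace = TRUE)
    expect_equal(etss_threshold(presence, background),
                 oracle_etss(presence, background))
  }
})

test_that("binarisation respects threshold and missingness", {
  vals <- matrix(c(0.1, 0.6, NA, 0.9, 0.5, 0.2, 0.7, 0.4, 0.3,
                   NA, 0.8, 0.05, 0.55, 0.45, 0.65, 0.35, 0.15, 0.95,
                   0.25, 0.5, 0.75, 0.85, 0.05, 0.6, 0.4), 5, 5)
  g <- suitability_grid(vals)
  expect_equal(sum(binarize(g, 0, "x")$suitable), sum(!is.na(vals)))
  expect_equal(sum(binarize(g, 1, "x")$suitable), sum(vals == 1, na.rm = TRUE))
  b <- binarize(g, 0.7, "x")
  expect_equal(sum(b$suitable), sum(vals >= 0.7, na.rm = TRUE))
  expect_false(any(b$suitable & is.na(vals)))
})

test_that("dilation matches hand enumeration and the brute-force oracle", {
  # single pixel, 500 m radius on 250 m pixels -> ceil(2) = 2 -> 5x5 block
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  d <- dilate(make_map(m), 500)
  expect_equal(sum(d$suitable), 25)
  expect_true(all(d$suitable[3:7, 3:7]))
  # radius 0 is the identity; full map is a fixed point
  expect_equal(dilate(make_map(m), 0)$suitable, m)
  full <- matrix(TRUE, 4, 4)
  expect_equal(dilate(make_map(full), 1000)$suitable, full)
  # random maps vs oracle, both elements
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(runif(15 * 12) < 0.15, 15, 12)
    for (el in c("square", "disk")) {
      r <- sample(1:3, 1)
      got <- dilate(make_map(m), r * 250, element = el)$suitable
      expect_equal(got, oracle_dilate(m, r, el))
    }
  }
})

test_that("dilation is extensive and monotone", {
  set.seed(8)
  m <- matrix(runif(20 * 20) < 0.1, 20, 20)
  d1 <- dilate(make_map(m), 250)$suitable
  d2 <- dilate(make_map(m), 750)$suitable
  expect_true(all(m <= d1))       # output contains input
  expect_true(all(d1 <= d2))      # monotone in radius
  m2 <- m; m2[1, 1] <- TRUE
  expect_true(all(dilate(make_map(m), 500)$suitable <=
                    dilate(make_map(m2), 500)$suitable)) # monotone in input
})

test_that("overlap classification matches the brute-force oracle on random maps", {
  set.seed(21)
  for (i in 1:15) {
    f <- matrix(runif(400) < 0.12, 20, 20)
    o <- matrix(runif(400) < 0.12, 20, 20)
    if (!any(f) || !any(o)) next
    r <- sample(1:3, 1)
    cl <- classify_overlap(make_map(f), make_map(o), radius_m = r * 250)
    orc <- oracle_classify(f, o, r)
    expect_equal(cl$shared, orc$shared)
    expect_equal(cl$focal_only, orc$focal_only)
    expect_equal(cl$other_only, orc$other_only)
    expect_equal(cl$shared_from_model, orc$shared_from_model)
    expect_equal(cl$shared_from_buffer, cl$shared - cl$shared_from_model)
    # count conservation: union size is label-invariant
    swapped <- classify_overlap(make_map(o), make_map(f), radius_m = r * 250)
    expect_equal(swapped$shared, cl$shared)
    expect_equal(swapped$focal_only, cl$other_only)
    expect_equal(cl$focal_only + cl$other_only + cl$shared,
                 swapped$focal_only + swapped$other_only + swapped$shared)
  }
})

test_that("shared habitat grows and exclusive habitat shrinks with radius", {
  set.seed(4)
  f <- matrix(runif(625) < 0.1, 25, 25)
  o <- matrix(runif(625) < 0.1, 25, 25)
  prev_shared <- -1; prev_focal <- Inf
  for (r in c(0, 250, 500, 1000, 2000)) {
    cl <- classify_overlap(make_map(f), make_map(o), radius_m = r)
    expect_gte(cl$shared, prev_shared)
    expect_lte(cl$focal_only, prev_focal)
    prev_shared <- cl$shared; prev_focal <- cl$focal_only
  }
})

test_that("degenerate overlap cases classify correctly", {
  f <- matrix(FALSE, 20, 20); f[2:3, 2:3] <- TRUE
  o <- matrix(FALSE, 20, 20); o[15:16, 15:16] <- TRUE
  cl <- classify_overlap(make_map(f), make_map(o), radius_m = 500)
  expect_equal(cl$shared, 0)   # separated by far more than the buffer
  ident <- classify_overlap(make_map(f), make_map(f), radius_m = 500)
  expect_equal(ident$focal_only, 0)
  expect_equal(ident$other_only, 0)
  expect_equal(ident$shared, sum(f))
  g1 <- make_map(matrix(TRUE, 3, 3))
  g2 <- make_map(matrix(TRUE, 4, 4))
  expect_error(classify_overlap(g1, g2), "aligned")
})

test_that("ecogeographic RI uses shared vs focal-exclusive pixels", {
  cl <- list(shared = 504, focal_only = 2485, other_only = 424)
  expect_equal(round(ri_ecogeographic(cl), 4), 0.8314)
  expect_equal(round(ri_ecogeographic(cl, direction = "other"), 4), 0.4569)
  expect_equal(ri_ecogeographic(list(shared = 5, focal_only = 0)), 0)
})

test_that("occurrence points map to pixels by half-open intervals", {
  g <- suitability_grid(matrix(seq(0.01, 0.12, le = 12), 3, 4),
                        pixel_size = 100, origin = c(1000, 2000))
  # top-left pixel covers x in [1000,1100), y in (1900,2000]
  expect_equal(extract_scores(g, 1000, 2000 - 1e-9), g$values[1, 1])
  expect_equal(extract_scores(g, 1099.99, 1901), g$values[1, 1])
  expect_equal(extract_scores(g, 1100, 1901), g$values[1, 2])
  expect_equal(extract_scores(g, 1250, 1750), g$values[3, 3])
  expect_error(extract_scores(g, 999, 1950), "outside")
})

test_that("ESRI ASCII rasters round-trip", {
  vals <- matrix(round(runif(30), 6), 5, 6)
  vals[2, 3] <- NA
  g <- suitability_grid(vals, pixel_size = 250, origin = c(500, 3000))
  f <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, f)
  back <- read_esri_ascii(f)
  expect_equal(back$values, vals, tolerance = 1e-9)
  expect_equal(back$pixel_size, 250)
  expect_equal(back$origin, c(500, 3000))
  # binary maps write as 0/1
  b <- binarize(g, 0.5, "x")
  write_esri_ascii(b, f)
  back2 <- read_esri_ascii(f)
  expect_equal(back2$values == 1, unname(b$suitable))
})

test_that("dilation agrees with an independent image-processing implementation", {
  skip_if_not_installed("EBImage")
  set.seed(19)
  m <- matrix(runif(900) < 0.1, 30, 30)
  for (r in 1:3) {
    ours <- dilate(make_map(m), r * 250)$suitable
    brush <- EBImage::makeBrush(2 * r + 1, shape = "box")
    theirs <- EBImage::dilate(m * 1, brush) > 0
    expect_equal(ours, unname(theirs))
  }
})
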