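#' Equal training sensitivity and specificity (ETSS) threshold
#'
#' Scans candidate thresholds (the sorted unique pooled scores) and returns
#' the one minimising |sensitivity - specificity|, where sensitivity is the
#' fraction of presence scores >= t and specificity the fraction of
#' background scores < t. Ties are broken toward the smallest threshold. This
#' is the standard cutoff for binarising a continuous habitat-suitability
#' model into a presence/absence range map.
#'
#' @param presence_scores Suitability scores at occurrence pixels.
#' @param background_scores Suitability scores at background pixels.
#' @return The selected threshold (one of the observed scores).
#' @export
etss_threshold <- function(presence_scores, background_scores) {
  presence_scores <- presence_scores[!is.na(presence_scores)]
  background_scores <- background_scores[!is.na(background_scores)]
  if (!length(presence_scores) || !length(background_scores))
    stop("presence and background score sets must be non-empty")
  cand <- sort(unique(c(presence_scores, background_scores)))
  # findInterval(..., left.open = TRUE) counts scores strictly below each
  # candidate, so sensitivity/specificity are exact even under heavy ties
  sens <- 1 - findInterval(cand, sort(presence_scores), left.open = TRUE) /
    length(presence_scores)
  spec <- findInterval(cand, sort(background_scores), left.open = TRUE) /
    length(background_scores)
  gap <- abs(sens - spec)
  # ties (within floating-point noise) break toward the smallest candidate
  cand[which(gap <= min(gap) + 1e-12)[1]]
}

#' Binarise a suitability grid into a habitat map
#'
#' @param grid A [suitability_grid()].
#' @param threshold Score cutoff in \[0, 1\]; pixels with score >= threshold
#'   are suitable. Missing pixels are always unsuitable.
#' @param ecotype Label carried on the resulting map.
#' @return An object of class `"habitat_map"`: logical matrix `suitable`
#'   plus `threshold`, `ecotype`, `pixel_size`, `origin`.
#' @export
binarize <- function(grid, threshold, ecotype = "") {
  stopifnot(inherits(grid, "suitability_grid"),
            length(threshold) == 1L, threshold >= 0, threshold <= 1)
  suitable <- !is.na(grid$values) & grid$values >= threshold
  structure(list(suitable = suitable, threshold = threshold,
                 ecotype = ecotype, pixel_size = grid$pixel_size,
                 origin = grid$origin),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("habitat_map '%s': %d x %d pixels, %d suitable (threshold %.4g)\n",
              x$ecotype, nrow(x$suitable), ncol(x$suitable),
              sum(x$suitable), x$threshold))
  invisible(x)
}

# Morphological dilation of a logical matrix by a structuring element of
# radius r pixels: square (Chebyshev) or disk (Euclidean).
.dilate_matrix <- function(m, r, element = "square") {
  if (r <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (dy in -r:r) {
    if (dy >= nr || dy <= -nr) next
    for (dx in -r:r) {
      if (dx >= nc || dx <= -nc) next
      if (element == "disk" && dy * dy + dx * dx > r * r + 1e-9) next
      rs <- max(1, 1 - dy):min(nr, nr - dy)
      cs <- max(1, 1 - dx):min(nc, nc - dx)
      out[rs, cs] <- out[rs, cs] | m[rs + dy, cs + dx]
    }
  }
  out
}

#' Add a dispersal boundary around suitable habitat
#'
#' Expands a binary habitat map by a pollen-dispersal radius: a pixel becomes
#' suitable if any suitable source pixel lies within
#' `ceiling(radius_m / pixel_size)` pixels. The default structuring element is
#' the square (Chebyshev metric), the plainest raster reading of "a buffer of
#' r metres around a pixel"; a Euclidean disk is available for sensitivity
#' analysis. Dilation is extensive (output contains input) and radius 0 is
#' the identity.
#'
#' @param map A `habitat_map`.
#' @param radius_m Dispersal radius in metres (>= 0); the study default is
#'   500 m on 250 m pixels, i.e. a 2-pixel buffer.
#' @param element `"square"` (default) or `"disk"`.
#' @return A `habitat_map` with the buffered suitability mask.
#' @export
dilate <- function(map, radius_m, element = c("square", "disk")) {
  stopifnot(inherits(map, "habitat_map"), radius_m >= 0)
  element <- match.arg(element)
  r <- ceiling(radius_m / map$pixel_size)
  map$suitable <- .dilate_matrix(map$suitable, r, element)
  map
}

.check_aligned <- function(a, b) {
  if (!identical(dim(a$suitable), dim(b$suitable)) ||
      !isTRUE(all.equal(a$pixel_size, b$pixel_size)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop("habitat maps are not aligned (shape, pixel size and origin must match)")
}

#' Classify pixels as focal-only, other-only, or shared habitat
#'
#' A pixel is shared habitat if it is suitable for both ecotypes under the
#' binary models, or if the dispersal boundary of one ecotype's habitat
#' reaches a pixel suitable for the other: shared =
#' (F & O) | (dilate(F) & O) | (F & dilate(O)). Remaining suitable pixels are
#' focal-only / other-only. The classification records how many shared pixels
#' came from model overlap versus buffer reclassification.
#'
#' @param map_focal,map_other Aligned `habitat_map`s for the two ecotypes.
#' @param radius_m Dispersal radius in metres (default 500).
#' @param element Structuring element, see [dilate()].
#' @return An object of class `"overlap_classification"`: counts
#'   `focal_only`, `other_only`, `shared`, `shared_from_model`,
#'   `shared_from_buffer`, plus the classified code matrix `codes`
#'   (0 none, 1 focal-only, 2 other-only, 3 shared) and map metadata.
#' @export
classify_overlap <- function(map_focal, map_other, radius_m = 500,
                             element = c("square", "disk")) {
  stopifnot(inherits(map_focal, "habitat_map"),
            inherits(map_other, "habitat_map"))
  element <- match.arg(element)
  .check_aligned(map_focal, map_other)
  f <- map_focal$suitable
  o <- map_other$suitable
  fd <- dilate(map_focal, radius_m, element)$suitable
  od <- dilate(map_other, radius_m, element)$suitable
  shared <- (f & o) | (fd & o) | (f & od)
  focal_only <- f & !shared
  other_only <- o & !shared
  codes <- matrix(0L, nrow(f), ncol(f))
  codes[focal_only] <- 1L
  codes[other_only] <- 2L
  codes[shared] <- 3L
  structure(list(
    focal_only = sum(focal_only),
    other_only = sum(other_only),
    shared = sum(shared),
    shared_from_model = sum(f & o),
    shared_from_buffer = sum(shared) - sum(f & o),
    codes = codes,
    radius_m = radius_m,
    element = element,
    pixel_size = map_focal$pixel_size,
    origin = map_focal$origin,
    focal = map_focal$ecotype,
    other = map_other$ecotype
  ), class = "overlap_classification")
}

#' @export
print.overlap_classification <- function(x, ...) {
  cat(sprintf("habitat overlap ('%s' vs '%s', %g m buffer, %s element):\n",
              x$focal, x$other, x$radius_m, x$element))
  cat(sprintf("  focal-only %d | other-only %d | shared %d (%d model + %d buffer)\n",
              x$focal_only, x$other_only, x$shared,
              x$shared_from_model, x$shared_from_buffer))
  invisible(x)
}

#' Ecogeographic reproductive isolation from an overlap classification
#'
#' Applies [ri_cooccurrence()] with S = shared pixels and U = the focal
#' ecotype's exclusive pixels. The two directions of the estimate use the
#' same shared count but each ecotype's own exclusive count.
#'
#' @param classification An `overlap_classification`, or a list/counts with
#'   elements `shared` and `focal_only`.
#' @param direction `"focal"` (default) or `"other"`: which ecotype's
#'   exclusive pixel count to use as U.
#' @return A single numeric RI value in \[0, 1\].
#' @examples
#' cl <- list(shared = 504, focal_only = 2485, other_only = 424)
#' ri_ecogeographic(cl)                      # white-sand direction: 0.831
#' ri_ecogeographic(cl, direction = "other") # brown-sand direction: 0.457
#' @export
ri_ecogeographic <- function(classification, direction = c("focal", "other")) {
  direction <- match.arg(direction)
  u <- if (direction == "focal") classification$focal_only
       else classification$other_only
  ri_cooccurrence(S = classification$shared, U = u)
}

#' Map occurrence points to pixels and extract suitability scores
#'
#' Points are assigned to pixels by `col = floor((x - x0)/pixel) + 1`,
#' `row = floor((y0 - y)/pixel) + 1` (row-major, origin top-left, half-open
#' pixel intervals). Points outside the grid extent are an error.
#'
#' @param grid A `suitability_grid`.
#' @param x,y Projected point coordinates.
#' @return Numeric vector of suitability scores at the points' pixels.
#' @export
extract_scores <- function(grid, x, y) {
  stopifnot(inherits(grid, "suitability_grid"), length(x) == length(y))
  col <- floor((x - grid$origin[1]) / grid$pixel_size) + 1L
  row <- floor((grid$origin[2] - y) / grid$pixel_size) + 1L
  bad <- col < 1L | col > ncol(grid$values) | row < 1L | row > nrow(grid$values)
  if (any(bad))
    stop(sum(bad), " occurrence point(s) fall outside the grid extent")
  grid$values[cbind(row, col)]
}

#' Sample background suitability scores
#'
#' Draws scores from uniformly random non-missing pixels, the conventional
#' pseudo-absence background for threshold selection. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param grid A `suitability_grid`.
#' @param n Number of background pixels (default 10000), sampled with
#'   replacement.
#' @return Numeric vector of `n` scores.
#' @export
sample_background <- function(grid, n = 10000) {
  ok <- which(!is.na(grid$values))
  if (!length(ok)) stop("grid has no non-missing pixels")
  grid$values[sample(ok, n, replace = TRUE)]
}

#' Ecogeographic isolation from grids and occurrences, end to end
#'
#' Convenience wrapper running the full ecogeographic stage: ETSS threshold
#' per ecotype (presence scores at occurrence pixels vs sampled background),
#' binarisation, dispersal-boundary overlap classification, and directional
#' RI values.
#'
#' @param grid_focal,grid_other Suitability grids for the two ecotypes.
#' @param occ Occurrence data.frame with columns `x`, `y`, `ecotype`.
#' @param focal,other Ecotype labels matching `occ$ecotype`.
#' @param radius_m Dispersal radius in metres.
#' @param element Structuring element for the buffer.
#' @param n_background Background pixels per ecotype for ETSS.
#' @return A list with `classification` (an `overlap_classification`),
#'   `ri` (named vector: focal and other direction), and the two thresholds.
#' @export
eco_isolation <- function(grid_focal, grid_other, occ, focal, other,
                          radius_m = 500, element = c("square", "disk"),
                          n_background = 10000) {
  element <- match.arg(element)
  stopifnot(all(c("x", "y", "ecotype") %in% names(occ)))
  pf <- occ[occ$ecotype == focal, , drop = FALSE]
  po <- occ[occ$ecotype == other, , drop = FALSE]
  if (!nrow(pf) || !nrow(po))
    stop("occurrences must include both ecotype labels: ", focal, ", ", other)
  thr_f <- etss_threshold(extract_scores(grid_focal, pf$x, pf$y),
                          sample_background(grid_focal, n_background))
  thr_o <- etss_threshold(extract_scores(grid_other, po$x, po$y),
                          sample_background(grid_other, n_background))
  cl <- classify_overlap(binarize(grid_focal, thr_f, focal),
                         binarize(grid_other, thr_o, other),
                         radius_m = radius_m, element = element)
  ri <- c(ri_ecogeographic(cl, "focal"), ri_ecogeographic(cl, "other"))
  names(ri) <- c(focal, other)
  list(classification = cl, ri = ri,
       thresholds = stats::setNames(c(thr_f, thr_o), c(focal, other)))
}
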