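#' Construct a habitat-suitability grid
#'
#' A minimal in-memory raster: a numeric matrix of suitability scores in
#' \[0, 1\] (NA = missing), square pixels of known size, and the projected
#' coordinate of the top-left pixel corner. Rows run north to south
#' (row-major, origin top-left), matching the usual raster convention.
#'
#' @param values Numeric matrix of suitability scores in \[0, 1\]; `NA`
#'   allowed.
#' @param pixel_size Side length of a pixel in metres (default 250, the
#'   resolution of gridded soil-property products).
#' @param origin Projected (x, y) of the top-left corner of the top-left
#'   pixel. Defaults to (0, nrow * pixel_size) so the lower-left corner is
#'   the coordinate origin.
#' @param crs_label Free-text projection tag carried through I/O.
#' @return An object of class `"suitability_grid"`.
#' @export
suitability_grid <- function(values, pixel_size = 250, origin = NULL,
                             crs_label = "") {
  stopifnot(is.matrix(values), pixel_size > 0)
  rng <- range(values, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 1))
    stop("suitability scores must lie in [0, 1]")
  if (is.null(origin)) origin <- c(0, nrow(values) * pixel_size)
  structure(list(values = values, pixel_size = pixel_size,
                 origin = origin, crs_label = crs_label),
            class = "suitability_grid")
}

#' @export
print.suitability_grid <- function(x, ...) {
  cat(sprintf("suitability_grid: %d x %d pixels of %g m, %d missing\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              sum(is.na(x$values))))
  invisible(x)
}

#' Read and write rasters
#'
#' `read_raster()` reads a single-band raster into a [suitability_grid()].
#' ESRI ASCII grids (`.asc`/`.txt`) are parsed directly; TIFF (`.tif`/
#' `.tiff`) requires the \pkg{tiff} package and, since plain TIFF carries no
#' georeferencing, the pixel size (and optionally origin) must be supplied.
#' `write_esri_ascii()` writes a grid or binary habitat map as an ESRI ASCII
#' grid (binary maps as 0/1).
#'
#' @param file Path to the raster file.
#' @param pixel_size,origin,crs_label Overrides / metadata for formats that
#'   do not carry them (TIFF); ignored for ESRI ASCII, which encodes them.
#' @return `read_raster()`: a `suitability_grid`.
#' @export
read_raster <- function(file, pixel_size = 250, origin = NULL,
                        crs_label = "") {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    vals <- tiff::readTIFF(file)
    if (length(dim(vals)) == 3L) vals <- vals[, , 1]
    return(suitability_grid(vals, pixel_size = pixel_size, origin = origin,
                            crs_label = crs_label))
  }
  read_esri_ascii(file)
}

#' @rdname read_raster
#' @export
read_esri_ascii <- function(file) {
  lines <- readLines(file, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("ESRI ASCII header missing ", k)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(file, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ESRI ASCII grid: cell count does not match header")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  suitability_grid(m, pixel_size = hdr$cellsize,
                   origin = c(xll, yll + hdr$nrows * hdr$cellsize))
}

#' @rdname read_raster
#' @param x A `suitability_grid`, `habitat_map`, or numeric/logical matrix.
#' @export
write_esri_ascii <- function(x, file) {
  if (inherits(x, "habitat_map")) {
    m <- x$suitable * 1L
    px <- x$pixel_size; origin <- x$origin
  } else if (inherits(x, "suitability_grid")) {
    m <- x$values; px <- x$pixel_size; origin <- x$origin
  } else {
    m <- x * 1; px <- 250; origin <- c(0, nrow(m) * px)
  }
  nodata <- -9999
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", origin[1]),
    sprintf("yllcorner %.10g", origin[2] - nrow(m) * px),
    sprintf("cellsize %.10g", px),
    sprintf("NODATA_value %d", nodata)
  )
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), file)
  invisible(file)
}
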