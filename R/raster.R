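#' Lightweight single-band raster
#'
#' An `esp_raster` wraps a numeric matrix together with the minimal
#' georeference used throughout the package: a square cell size in km and the
#' (x, y) coordinate of the lower-left corner of the grid.  Matrix row 1 is
#' the *top* (northern) row, matching the order in which ESRI ASCII grids and
#' GeoTIFF strips store their data.  Missing cells are held as `NA`
#' internally; the `nodata` sentinel is only materialised at I/O time.
#'
#' @param values numeric matrix (row 1 = northern row).
#' @param cell_size edge length of a cell in km (> 0).
#' @param origin numeric length-2, (x, y) of the lower-left corner.
#' @param nodata sentinel written to files for `NA` cells.
#' @return An object of class `esp_raster`.
#' @examples
#' r <- esp_raster(matrix(1:12, 3, 4), cell_size = 0.5)
#' cell_area(r)
#' @export
esp_raster <- function(values, cell_size = 1, origin = c(0, 0), nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(length(cell_size) == 1L, is.finite(cell_size), cell_size > 0,
            length(origin) == 2L, all(is.finite(origin)))
  if (any(is.infinite(values), na.rm = TRUE))
    stop("raster values must be finite or NA")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "esp_raster")
}

#' Categorical (graded) raster
#'
#' Integer class codes `1..length(labels)` per cell, `NA` for nodata.  Used
#' for every graded surface: erosion intensity, the five-level importance /
#' sensitivity / connectivity / security maps, and land use.
#'
#' @param values integer matrix of class codes (or `NA`).
#' @param labels ordered character vector of class names.
#' @inheritParams esp_raster
#' @return An object of class `esp_classes` (inherits `esp_raster`).
#' @export
esp_classes <- function(values, labels, cell_size = 1, origin = c(0, 0),
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  codes <- values[!is.na(values)]
  if (length(codes) && (min(codes) < 1L || max(codes) > length(labels)))
    stop("class codes must lie in 1..length(labels)")
  r <- esp_raster(values + 0, cell_size, origin, nodata)
  r$values <- values
  r$labels <- as.character(labels)
  class(r) <- c("esp_classes", "esp_raster")
  r
}

#' @export
dim.esp_raster <- function(x) dim(x$values)

#' @export
as.matrix.esp_raster <- function(x, ...) x$values

#' Cell area in km^2
#' @param x an `esp_raster`.
#' @export
cell_area <- function(x) x$cell_size^2

#' Test or assert that rasters share a grid
#'
#' Two rasters are aligned iff their shape, cell size and origin agree; every
#' multi-raster operation in the package requires alignment.
#' @param ... rasters to compare.
#' @return `is_aligned` returns a logical; `check_aligned` errors on mismatch.
#' @export
is_aligned <- function(...) {
  rs <- list(...)
  if (length(rs) < 2L) return(TRUE)
  ref <- rs[[1L]]
  all(vapply(rs[-1L], function(r) {
    identical(dim(r$values), dim(ref$values)) &&
      isTRUE(all.equal(r$cell_size, ref$cell_size)) &&
      isTRUE(all.equal(r$origin, ref$origin))
  }, logical(1L)))
}

#' @rdname is_aligned
#' @export
check_aligned <- function(...) {
  if (!is_aligned(...)) stop("rasters are not aligned (shape/cell_size/origin)")
  invisible(TRUE)
}

#' Build a raster on the same grid as a template
#' @param template an `esp_raster` supplying shape and georeference.
#' @param values matrix or scalar recycled over the grid.
#' @export
raster_like <- function(template, values) {
  if (length(values) == 1L)
    values <- matrix(values, nrow(template$values), ncol(template$values))
  esp_raster(values, template$cell_size, template$origin, template$nodata)
}

# x/y coordinates of cell centres; row 1 is the northern row
cell_xy <- function(r, rows, cols) {
  nr <- nrow(r$values)
  cbind(x = r$origin[1L] + (cols - 0.5) * r$cell_size,
        y = r$origin[2L] + (nr - rows + 0.5) * r$cell_size)
}

# inverse of cell_xy: map coordinates to (row, col), clamped to the grid
xy_cell <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- pmin(pmax(ceiling((x - r$origin[1L]) / r$cell_size), 1L), nc)
  row <- pmin(pmax(nr - ceiling((y - r$origin[2L]) / r$cell_size) + 1L, 1L), nr)
  cbind(row = as.integer(row), col = as.integer(col))
}

in_extent <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  x >= r$origin[1L] & x <= r$origin[1L] + nc * r$cell_size &
    y >= r$origin[2L] & y <= r$origin[2L] + nr * r$cell_size
}

#' @export
print.esp_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<%s> %d x %d cells, %.4g km cells, origin (%.4g, %.4g)\n",
              class(x)[1L], nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1L], x$origin[2L]))
  if (!is.null(x$labels))
    cat("  classes:", paste(x$labels, collapse = ", "), "\n")
  else if (length(v))
    cat(sprintf("  range [%.6g, %.6g], %d nodata\n", min(v), max(v),
                sum(is.na(x$values))))
  invisible(x)
}

#' @export
plot.esp_raster <- function(x, main = NULL, ...) {
  # image() wants [col, rev(row)] orientation
  z <- t(x$values[nrow(x$values):1L, , drop = FALSE])
  graphics::image(z, main = main, axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}

# elementwise helper: apply f over aligned rasters, NA (nodata) propagates
raster_map <- function(f, ...) {
  rs <- list(...)
  do.call(check_aligned, rs)
  vals <- do.call(f, lapply(rs, function(r) r$values))
  out <- rs[[1L]]
  out$values <- vals
  out$labels <- NULL
  class(out) <- "esp_raster"
  out
}

#' Min-max normalize a raster to [0, 1]
#'
#' A constant layer (zero range) maps to 0.5 everywhere with a warning, so a
#' degenerate input still contributes a neutral value to composites.
#' @param r an `esp_raster`.
#' @export
normalize_raster <- function(r) {
  v <- r$values
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1L])) stop("all-nodata raster cannot be normalized")
  if (rng[1L] == rng[2L]) {
    warning("constant layer: normalized to 0.5 everywhere")
    v[!is.na(v)] <- 0.5
  } else {
    v <- (v - rng[1L]) / (rng[2L] - rng[1L])
  }
  out <- r
  out$values <- v
  out
}
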