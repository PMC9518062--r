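#' Read and write rasters
#'
#' Two plain interchange formats are supported: ESRI ASCII grid (`.asc`) and
#' single-band baseline GeoTIFF (`.tif`, uncompressed, strip-organised,
#' float32 on write).  The GeoTIFF codec is deliberately minimal — enough to
#' exchange analysis grids with GDAL-based tooling — and carries the cell
#' size, lower-left corner and nodata value via the ModelPixelScale,
#' ModelTiepoint and GDAL nodata tags.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"ascii"` or `"geotiff"`.
#' @param raster an [esp_raster].
#' @return `read_raster` returns an [esp_raster]; `write_raster` returns
#'   `path` invisibly.  Round-trips are value-identical within float32
#'   precision for GeoTIFF and exact for ASCII at the written precision.
#' @export
read_raster <- function(path, format = c("auto", "ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format, ascii = read_ascii_grid(path), geotiff = read_geotiff(path))
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path, format = c("auto", "ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         ascii = write_ascii_grid(raster, path),
         geotiff = write_geotiff(raster, path))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("asc", "txt", "grd")) "ascii"
  else if (ext %in% c("tif", "tiff")) "geotiff"
  else stop("cannot guess raster format from extension: ", path)
}

# ---- ESRI ASCII grid ------------------------------------------------------

read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) < 2L || suppressWarnings(is.na(as.numeric(parts[2L]))))
      stop("malformed ASCII grid header line: ", ln)
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing: ", paste(setdiff(need, names(hdr)), collapse = ", "))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = length(lines), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d", length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # stored north-first
  m[m == nodata] <- NA_real_
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  esp_raster(m, cell_size = hdr$cellsize, origin = c(xll, yll), nodata = nodata)
}

write_ascii_grid <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$origin[1L]),
    sprintf("yllcorner %.10g", raster$origin[2L]),
    sprintf("cellsize %.10g", raster$cell_size),
    sprintf("NODATA_value %.10g", raster$nodata)), con)
  write.table(format(v, trim = TRUE, digits = 10, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
}

# ---- minimal baseline GeoTIFF --------------------------------------------
# byte width of each TIFF field type 1..12 (BYTE..DOUBLE)
TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

# Single-band, uncompressed, strip-organised TIFF with the three GeoTIFF
# tags GDAL needs (ModelPixelScale 33550, ModelTiepoint 33922,
# GeoKeyDirectory 34735) and the GDAL nodata tag 42113.

write_geotiff <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  nr <- nrow(v); nc <- ncol(v)
  data <- writeBin(as.numeric(t(v)), raw(), size = 4L, endian = "little")
  data_off <- 8L
  ifd_off <- data_off + length(data)
  if (ifd_off %% 2L == 1L) { data <- c(data, as.raw(0L)); ifd_off <- ifd_off + 1L }

  scale <- c(raster$cell_size, raster$cell_size, 0)
  # tiepoint: raster (0,0) [top-left corner] maps to model (xll, ytop)
  tie <- c(0, 0, 0, raster$origin[1L], raster$origin[2L] + nr * raster$cell_size, 0)
  geokeys <- as.integer(c(1, 1, 0, 1, 1024, 0, 1, 1))  # GTModelType = user-defined
  nodata_str <- c(charToRaw(format(raster$nodata, scientific = FALSE)), as.raw(0L))

  entries <- list(
    tiff_entry(256L, 3L, 1L, nc),                 # ImageWidth
    tiff_entry(257L, 3L, 1L, nr),                 # ImageLength
    tiff_entry(258L, 3L, 1L, 32L),                # BitsPerSample
    tiff_entry(259L, 3L, 1L, 1L),                 # Compression = none
    tiff_entry(262L, 3L, 1L, 1L),                 # Photometric = min-is-black
    tiff_entry(273L, 4L, 1L, data_off),           # StripOffsets
    tiff_entry(277L, 3L, 1L, 1L),                 # SamplesPerPixel
    tiff_entry(278L, 4L, 1L, nr),                 # RowsPerStrip (one strip)
    tiff_entry(279L, 4L, 1L, 4L * nr * nc),       # StripByteCounts
    tiff_entry(339L, 3L, 1L, 3L))                 # SampleFormat = IEEE float
  # out-of-line payloads appended after the IFD, offsets patched below
  ext <- list(
    list(tag = 33550L, type = 12L, values = scale),
    list(tag = 33922L, type = 12L, values = tie),
    list(tag = 34735L, type = 3L, values = geokeys),
    list(tag = 42113L, type = 2L, values = nodata_str))
  n_entries <- length(entries) + length(ext)
  ifd_bytes <- 2L + 12L * n_entries + 4L
  payload_off <- ifd_off + ifd_bytes
  for (i in seq_along(ext)) {
    e <- ext[[i]]
    cnt <- length(e$values)
    entries[[length(entries) + 1L]] <- tiff_entry(e$tag, e$type, cnt, payload_off)
    payload_off <- payload_off + cnt * TIFF_TYPE_SIZE[e$type]
  }
  # entries must be sorted by tag
  entries <- entries[order(vapply(entries, function(e) e$tag, numeric(1L)))]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_off, con, size = 4L, endian = "little")
  writeBin(data, con)
  writeBin(n_entries, con, size = 2L, endian = "little")
  for (e in entries) {
    writeBin(e$tag, con, size = 2L, endian = "little")
    writeBin(e$type, con, size = 2L, endian = "little")
    writeBin(e$count, con, size = 4L, endian = "little")
    writeBin(e$value_raw, con)
  }
  writeBin(0L, con, size = 4L, endian = "little")
  for (e in ext) {
    if (e$type == 12L) writeBin(as.numeric(e$values), con, size = 8L, endian = "little")
    else if (e$type == 3L) writeBin(as.integer(e$values), con, size = 2L, endian = "little")
    else writeBin(as.raw(e$values), con)
  }
}

tiff_entry <- function(tag, type, count, value) {
  # inline value field is always 4 bytes, left-justified
  vraw <- switch(as.character(type),
    `3` = c(writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
            as.raw(c(0L, 0L))),
    `4` = writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
    writeBin(as.integer(value), raw(), size = 4L, endian = "little"))
  list(tag = as.integer(tag), type = as.integer(type),
       count = as.integer(count), value_raw = vraw[1:4])
}

read_geotiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  endian <- if (raw[1L] == charToRaw("I")) "little"
            else if (raw[1L] == charToRaw("M")) "big"
            else stop("not a TIFF file: ", path)
  rd_u <- function(off, size, n = 1L) {
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size > 2L, endian = endian)
  }
  if (rd_u(2L, 2L) != 42L) stop("bad TIFF magic in ", path)
  ifd <- rd_u(4L, 4L)
  n_ent <- rd_u(ifd, 2L)
  tags <- list()
  type_size <- TIFF_TYPE_SIZE
  for (i in seq_len(n_ent)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- rd_u(off, 2L); type <- rd_u(off + 2L, 2L); cnt <- rd_u(off + 4L, 4L)
    nbytes <- type_size[type] * cnt
    voff <- if (nbytes > 4L) rd_u(off + 8L, 4L) else off + 8L
    vals <- switch(as.character(type),
      `3` = rd_u(voff, 2L, cnt),
      `4` = rd_u(voff, 4L, cnt),
      `12` = readBin(raw[(voff + 1L):(voff + 8L * cnt)], "double", n = cnt,
                     size = 8L, endian = endian),
      `11` = readBin(raw[(voff + 1L):(voff + 4L * cnt)], "double", n = cnt,
                     size = 4L, endian = endian),
      `2` = rawToChar(raw[(voff + 1L):(voff + cnt)] [
              raw[(voff + 1L):(voff + cnt)] != as.raw(0L)]),
      rd_u(voff, type_size[type], cnt))
    tags[[as.character(tag)]] <- vals
  }
  need <- c("256", "257", "273", "279")
  if (!all(need %in% names(tags))) stop("TIFF missing required tags: ", path)
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
    stop("only uncompressed TIFF supported")
  nc <- tags[["256"]]; nr <- tags[["257"]]
  bits <- if (is.null(tags[["258"]])) 8L else tags[["258"]][1L]
  fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1L]
  offs <- tags[["273"]]; counts <- tags[["279"]]
  pix <- do.call(c, lapply(seq_along(offs), function(i) {
    chunk <- raw[(offs[i] + 1L):(offs[i] + counts[i])]
    if (fmt == 3L)
      readBin(chunk, "double", n = counts[i] %/% (bits %/% 8L),
              size = bits %/% 8L, endian = endian)
    else
      readBin(chunk, "integer", n = counts[i] %/% (bits %/% 8L),
              size = bits %/% 8L, signed = fmt == 2L || bits > 16L, endian = endian)
  }))
  if (length(pix) != nr * nc) stop("TIFF pixel count mismatch in ", path)
  m <- matrix(as.numeric(pix), nrow = nr, ncol = nc, byrow = TRUE)
  cell <- if (!is.null(tags[["33550"]])) tags[["33550"]][1L] else 1
  tie <- tags[["33922"]]
  origin <- if (!is.null(tie) && length(tie) >= 5L)
    c(tie[4L] - tie[1L] * cell, tie[5L] + tie[2L] * cell - nr * cell)
  else c(0, 0)
  nodata <- if (!is.null(tags[["42113"]]))
    suppressWarnings(as.numeric(tags[["42113"]])) else NA_real_
  if (is.finite(nodata)) {
    # float32 round-trip can perturb the sentinel in the last ulp
    m[abs(m - nodata) <= abs(nodata) * 1e-6] <- NA_real_
  }
  esp_raster(m, cell_size = cell, origin = origin,
             nodata = if (is.finite(nodata)) nodata else -9999)
}

# ---- GeoJSON --------------------------------------------------------------

#' Read and write point/polyline sets as GeoJSON
#'
#' Feature collections of `Point` and `LineString` geometries, with feature
#' properties preserved as a data frame.  Coordinates are in the raster
#' georeference (km), not geographic degrees.
#'
#' @param path file path.
#' @param vectors an [esp_vectors] set.
#' @return `read_geojson` returns an [esp_vectors]; `write_geojson` returns
#'   `path` invisibly.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  geoms <- list(); props <- list(); kind <- NULL
  for (f in gj$features) {
    g <- f$geometry
    if (g$type == "Point") {
      kind <- union(kind, "points")
      geoms[[length(geoms) + 1L]] <- matrix(unlist(g$coordinates), ncol = 2L,
                                            byrow = TRUE)
    } else if (g$type == "LineString") {
      kind <- union(kind, "polylines")
      geoms[[length(geoms) + 1L]] <- do.call(rbind, lapply(g$coordinates,
                                                           function(p) unlist(p)[1:2]))
    } else stop("unsupported GeoJSON geometry: ", g$type)
    props[[length(props) + 1L]] <- if (is.null(f$properties)) list() else f$properties
  }
  if (length(kind) > 1L) stop("mixed geometry kinds in ", path)
  attrs <- rbind_props(props)
  esp_vectors(kind = if (is.null(kind)) "points" else kind,
              geoms = geoms, attributes = attrs)
}

#' @rdname read_geojson
#' @export
write_geojson <- function(vectors, path) {
  gtype <- switch(vectors$kind, points = "Point", polylines = "LineString",
                  stop("unsupported geometry kind: ", vectors$kind))
  feats <- lapply(seq_along(vectors$geoms), function(i) {
    m <- vectors$geoms[[i]]
    coords <- if (gtype == "Point") as.numeric(m[1L, 1:2])
              else lapply(seq_len(nrow(m)), function(k) as.numeric(m[k, 1:2]))
    pr <- if (nrow(vectors$attributes))
      as.list(vectors$attributes[i, , drop = FALSE]) else structure(list(), names = character())
    list(type = "Feature", geometry = list(type = gtype, coordinates = coords),
         properties = pr)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

rbind_props <- function(props) {
  keys <- unique(unlist(lapply(props, names)))
  if (!length(keys)) return(data.frame(row.names = seq_along(props))[, 0, drop = FALSE])
  as.data.frame(lapply(stats::setNames(keys, keys), function(k) {
    vapply(props, function(p) {
      v <- p[[k]]
      if (is.null(v)) NA else v
    }, vector(mode = if (all(vapply(props, function(p)
      is.null(p[[k]]) || is.numeric(p[[k]]), logical(1L)))) "numeric" else "character", 1L))
  }), stringsAsFactors = FALSE)
}

#' Write a class table as CSV
#' @param tab a class table (data frame) from [class_area_table] and friends.
#' @param path output CSV path.
#' @export
write_class_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
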