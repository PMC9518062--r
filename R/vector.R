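#' Point / polyline feature sets
#'
#' A thin container for vector features in the raster georeference: a
#' geometry kind, a list of coordinate matrices (one per feature, columns
#' x, y) and a data frame of per-feature attributes.
#'
#' @param kind `"points"`, `"polylines"` or `"polygons"`.
#' @param geoms list of numeric matrices with columns x, y (one row for a
#'   point feature).
#' @param attributes data frame with one row per feature.
#' @export
esp_vectors <- function(kind = c("points", "polylines", "polygons"),
                        geoms = list(), attributes = NULL) {
  kind <- match.arg(kind)
  geoms <- lapply(geoms, function(g) {
    g <- matrix(as.numeric(g), ncol = 2L,
                dimnames = list(NULL, c("x", "y")))
    g
  })
  if (is.null(attributes))
    attributes <- data.frame(row.names = seq_along(geoms))[, 0, drop = FALSE]
  stopifnot(nrow(attributes) == length(geoms))
  structure(list(kind = kind, geoms = geoms, attributes = attributes),
            class = "esp_vectors")
}

#' @export
print.esp_vectors <- function(x, ...) {
  cat(sprintf("<esp_vectors> %d %s, %d attribute column(s)\n",
              length(x$geoms), x$kind, ncol(x$attributes)))
  invisible(x)
}

#' @export
length.esp_vectors <- function(x) length(x$geoms)

#' Flag features outside a raster extent
#' @param vectors an [esp_vectors].
#' @param template an [esp_raster] supplying the extent.
#' @return Logical vector, `TRUE` when every vertex lies inside the extent.
#' @export
within_extent <- function(vectors, template) {
  vapply(vectors$geoms, function(g)
    all(in_extent(template, g[, 1L], g[, 2L])), logical(1L))
}

#' Burn vector features into a binary mask
#'
#' Points mark their containing cell; polylines are traced cell-by-cell with
#' a supercover Bresenham walk so the burned path is 8-connected and covers
#' every cell the segment passes through.
#'
#' @param vectors an [esp_vectors].
#' @param template an [esp_raster] supplying grid and georeference.
#' @return An [esp_raster] with 1 on touched cells and 0 elsewhere.
#' @export
rasterize_vectors <- function(vectors, template) {
  if (!length(vectors$geoms)) stop("empty vector set")
  m <- matrix(0, nrow(template$values), ncol(template$values))
  for (g in vectors$geoms) {
    rc <- xy_cell(template, g[, 1L], g[, 2L])
    if (vectors$kind == "points" || nrow(rc) == 1L) {
      m[rc] <- 1
    } else {
      for (k in seq_len(nrow(rc) - 1L)) {
        seg <- bresenham_cells(rc[k, 1L], rc[k, 2L], rc[k + 1L, 1L], rc[k + 1L, 2L])
        m[seg] <- 1
      }
    }
  }
  raster_like(template, m)
}

# integer cell walk between two cells (inclusive), 8-connected
bresenham_cells <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc)
  if (n == 0L) return(cbind(r0, c0))
  err <- dc - dr
  rows <- integer(0); cols <- integer(0)
  r <- r0; c <- c0
  repeat {
    rows <- c(rows, r); cols <- c(cols, c)
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  cbind(rows, cols)
}

#' Euclidean distance to the nearest feature cell
#'
#' Exact Euclidean distance transform (two-pass separable lower-envelope
#' algorithm) from every cell to the nearest cell touched by the vector set,
#' in km.  Cells on the features themselves are at distance 0.
#'
#' @inheritParams rasterize_vectors
#' @return An [esp_raster] of distances (km).
#' @export
burn_distance <- function(vectors, template) {
  mask <- rasterize_vectors(vectors, template)
  mask_distance(mask)
}

#' Distance to the nearest 1-cell of a binary mask
#' @param mask an [esp_raster] of 0/1 values.
#' @return An [esp_raster] of Euclidean distances in km.
#' @export
mask_distance <- function(mask) {
  m <- mask$values
  if (!any(m == 1, na.rm = TRUE)) stop("mask has no feature cells")
  f <- ifelse(!is.na(m) & m == 1, 0, Inf)
  d2 <- edt_squared(f)
  raster_like(mask, sqrt(d2) * mask$cell_size)
}

# Felzenszwalb & Huttenlocher squared distance transform over a matrix of
# 0/Inf seeds, in cell units
edt_squared <- function(f) {
  g <- f
  for (j in seq_len(ncol(f))) g[, j] <- edt_1d(f[, j])   # within columns
  for (i in seq_len(nrow(f))) g[i, ] <- edt_1d(g[i, ])   # then within rows
  g
}

edt_1d <- function(f) {
  n <- length(f)
  d <- rep(Inf, n)
  idx <- which(is.finite(f))          # only finite parabolas participate
  if (!length(idx)) return(d)
  v <- integer(length(idx)); z <- numeric(length(idx) + 1L)
  k <- 1L; v[1L] <- idx[1L]; z[1L] <- -Inf; z[2L] <- Inf
  for (q in idx[-1L]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + q^2) - (f[p] + p^2)) / (2 * q - 2 * p)
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Intersection points of two polyline sets
#'
#' Exact segment-segment intersection over all segment pairs (vectorised
#' with a bounding-box prefilter).  Touching endpoints and collinear
#' overlaps count as intersections; for overlaps the segment midpoint is
#' reported.
#'
#' @param a,b [esp_vectors] polyline sets.
#' @return A two-column matrix of intersection coordinates (possibly empty).
#' @export
segment_intersections <- function(a, b) {
  segs <- function(v) do.call(rbind, lapply(v$geoms, function(g) {
    if (nrow(g) < 2L) return(NULL)
    cbind(g[-nrow(g), 1L], g[-nrow(g), 2L], g[-1L, 1L], g[-1L, 2L])
  }))
  A <- segs(a); B <- segs(b)
  if (is.null(A) || is.null(B)) return(matrix(numeric(0), 0L, 2L))
  n <- nrow(A); m <- nrow(B)
  # bounding-box prefilter
  ax0 <- pmin(A[, 1L], A[, 3L]); ax1 <- pmax(A[, 1L], A[, 3L])
  ay0 <- pmin(A[, 2L], A[, 4L]); ay1 <- pmax(A[, 2L], A[, 4L])
  bx0 <- pmin(B[, 1L], B[, 3L]); bx1 <- pmax(B[, 1L], B[, 3L])
  by0 <- pmin(B[, 2L], B[, 4L]); by1 <- pmax(B[, 2L], B[, 4L])
  cand <- which(outer(ax0, bx1, `<=`) & outer(ax1, bx0, `>=`) &
                outer(ay0, by1, `<=`) & outer(ay1, by0, `>=`), arr.ind = TRUE)
  if (!nrow(cand)) return(matrix(numeric(0), 0L, 2L))
  i <- cand[, 1L]; j <- cand[, 2L]
  px <- A[i, 1L]; py <- A[i, 2L]; rx <- A[i, 3L] - px; ry <- A[i, 4L] - py
  qx <- B[j, 1L]; qy <- B[j, 2L]; sx <- B[j, 3L] - qx; sy <- B[j, 4L] - qy
  denom <- rx * sy - ry * sx
  dqpx <- qx - px; dqpy <- qy - py
  t <- (dqpx * sy - dqpy * sx) / denom
  u <- (dqpx * ry - dqpy * rx) / denom
  hit <- is.finite(t) & is.finite(u) & t >= 0 & t <= 1 & u >= 0 & u <= 1
  pts <- cbind(px[hit] + t[hit] * rx[hit], py[hit] + t[hit] * ry[hit])
  # collinear overlaps: denom == 0 and cross(q-p, r) == 0
  coll <- denom == 0 & abs(dqpx * ry - dqpy * rx) < 1e-12
  if (any(coll)) {
    k <- which(coll)
    pts <- rbind(pts, cbind((pmax(pmin(px[k], px[k] + rx[k]), pmin(qx[k], qx[k] + sx[k])) +
                             pmin(pmax(px[k], px[k] + rx[k]), pmax(qx[k], qx[k] + sx[k]))) / 2,
                            (pmax(pmin(py[k], py[k] + ry[k]), pmin(qy[k], qy[k] + sy[k])) +
                             pmin(pmax(py[k], py[k] + ry[k]), pmax(qy[k], qy[k] + sy[k]))) / 2))
  }
  pts
}
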