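# Terrain primitives: Horn slope/aspect, D8 flow direction and accumulation.
# Elevations are in metres, cell_size in km (converted internally).

# 8-neighbour offsets, row/col, in D8 order E, SE, S, SW, W, NW, N, NE
D8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

pad_edge <- function(m) {
  m2 <- rbind(m[1L, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m2[, 1L, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

#' Slope and aspect from a DEM
#'
#' Horn's third-order finite differences on the 3x3 window, with edge rows
#' and columns replicated.  Slope is returned in radians; aspect in radians
#' clockwise from north (`NA` on flat cells).
#'
#' @param dem an [esp_raster] of elevations in metres.
#' @return A list of two aligned rasters, `slope` and `aspect`.
#' @export
slope_aspect <- function(dem) {
  z <- pad_edge(dem$values)
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  cs_m <- dem$cell_size * 1000
  i <- 2:(nr + 1L); j <- 2:(nc + 1L)
  # Horn kernel; matrix row 1 is north, so +row is south
  dzdx <- ((z[i - 1L, j + 1L] + 2 * z[i, j + 1L] + z[i + 1L, j + 1L]) -
           (z[i - 1L, j - 1L] + 2 * z[i, j - 1L] + z[i + 1L, j - 1L])) / (8 * cs_m)
  dzdy <- ((z[i - 1L, j - 1L] + 2 * z[i - 1L, j] + z[i - 1L, j + 1L]) -
           (z[i + 1L, j - 1L] + 2 * z[i + 1L, j] + z[i + 1L, j + 1L])) / (8 * cs_m)
  slope <- atan(sqrt(dzdx^2 + dzdy^2))
  aspect <- atan2(dzdx, dzdy)          # clockwise from north
  aspect[slope == 0] <- NA_real_
  aspect <- (aspect + 2 * pi) %% (2 * pi)
  list(slope = raster_like(dem, slope), aspect = raster_like(dem, aspect))
}

#' D8 flow direction
#'
#' Each cell drains to its steepest-descent 8-neighbour (distance-weighted
#' drop; diagonals divided by sqrt(2)).  Cells with no lower neighbour
#' (pits, flats, nodata) get direction 0.
#'
#' @param surface an [esp_raster]; any scalar field works (DEM or a
#'   resistance surface).
#' @return Integer matrix of directions 1..8 (E, SE, S, SW, W, NW, N, NE) or
#'   0 for sinks.
#' @export
d8_directions <- function(surface) {
  z <- surface$values
  nr <- nrow(z); nc <- ncol(z)
  best_drop <- matrix(0, nr, nc)
  dir <- matrix(0L, nr, nc)
  for (k in 1:8) {
    dr <- D8_DR[k]; dc <- D8_DC[k]
    dist <- if (dr != 0L && dc != 0L) sqrt(2) else 1
    rs <- seq_len(nr); cs <- seq_len(nc)
    rs_src <- rs[(rs + dr) >= 1L & (rs + dr) <= nr]
    cs_src <- cs[(cs + dc) >= 1L & (cs + dc) <= nc]
    drop <- matrix(-Inf, nr, nc)
    drop[rs_src, cs_src] <- (z[rs_src, cs_src] - z[rs_src + dr, cs_src + dc]) / dist
    upd <- !is.na(drop) & drop > best_drop
    best_drop[upd] <- drop[upd]
    dir[upd] <- k
  }
  dir[is.na(z)] <- 0L
  dir
}

#' D8 flow accumulation
#'
#' Number of upstream cells draining through each cell (the cell itself
#' excluded), obtained by pushing counts down the D8 directions in
#' decreasing elevation order.
#'
#' @param surface an [esp_raster].
#' @param directions optional precomputed [d8_directions] matrix.
#' @return An [esp_raster] of upstream cell counts.
#' @export
d8_accumulation <- function(surface, directions = NULL) {
  if (is.null(directions)) directions <- d8_directions(surface)
  z <- surface$values
  nr <- nrow(z); nc <- ncol(z)
  acc <- matrix(0, nr, nc)
  ord <- order(z, decreasing = TRUE, na.last = NA)
  for (idx in ord) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    k <- directions[r, c]
    if (k > 0L) {
      r2 <- r + D8_DR[k]; c2 <- c + D8_DC[k]
      acc[r2, c2] <- acc[r2, c2] + acc[r, c] + 1
    }
  }
  acc[is.na(z)] <- NA_real_
  raster_like(surface, acc)
}

#' Ridge and valley lines of a surface
#'
#' Hydrological extraction on the surface itself: ridge cells are those that
#' receive no D8 inflow (zero upstream contribution) when water runs downhill
#' on the surface; valley cells are the same on the sign-inverted surface.
#' On smooth surfaces the zero-inflow set forms thin lines along crests and
#' troughs, since every cell adjacent to a crest receives inflow from it.
#'
#' @param surface an [esp_raster] (here: the corrected resistance surface).
#' @return List of two 0/1 [esp_raster] masks, `ridge` and `valley`.
#' @export
ridge_valley_lines <- function(surface) {
  ridge <- zero_inflow_mask(surface)
  inv <- surface
  inv$values <- -inv$values
  valley <- zero_inflow_mask(inv)
  list(ridge = raster_like(surface, ridge),
       valley = raster_like(surface, valley))
}

zero_inflow_mask <- function(surface) {
  acc <- d8_accumulation(surface)$values
  m <- ifelse(!is.na(acc) & acc == 0, 1, 0)
  m[is.na(surface$values)] <- 0
  m
}
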