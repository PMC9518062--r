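#' Configuration for a synthetic mountainous scene
#'
#' Collects every knob of the generator with defaults describing a desk-scale
#' alpine-valley landscape: a 200 x 200 grid of 0.1 km cells (20 x 20 km,
#' 400 km^2), ~3000 m of relief, monsoonal rainfall concentrated in summer,
#' settlement and farmland on valley floors, and a hazard inventory whose
#' intensity rises with slope and river proximity.
#'
#' @param nrows,ncols grid shape.
#' @param cell_size cell edge in km.
#' @param seed integer master seed; each layer derives its own stream from it.
#' @param min_elev,relief elevation floor and amplitude in m.
#' @param roughness fractal roughness of the DEM in (0, 1]; smaller = smoother.
#' @param landuse_fractions named targets for forest, grassland, farmland,
#'   unutilized and construction as shares of non-water cells (normalised to
#'   sum to 1); water is carved from the river network.
#' @param river_quantile flow-accumulation quantile above which a cell is a
#'   river (0.98 keeps ~2 % of cells).
#' @param rain_monthly_mean,rain_sd_frac 12 monthly rainfall means (mm) and
#'   the relative interannual/spatial sd.
#' @param n_years years of monthly rainfall to simulate.
#' @param npp_mean,npp_sd NPP field moments (g C m^-2 a^-1).
#' @param nightlight_scale e-folding distance (km) of nightlight away from
#'   construction.
#' @param field_range_km correlation range of the Gaussian random fields.
#' @param hazard_intercept logistic intercept for per-cell hazard occurrence;
#'   when `NULL` it is calibrated so the expected count is `hazard_target_n`.
#' @param hazard_w_slope,hazard_w_river logistic weights on standardised
#'   slope and (negative) standardised river distance.
#' @param hazard_target_n expected number of hazard points when
#'   `hazard_intercept` is `NULL`.
#' @return A `scene_config` list.
#' @export
scene_config <- function(nrows = 200L, ncols = 200L, cell_size = 0.1,
                         seed = 1L,
                         min_elev = 800, relief = 3000, roughness = 0.55,
                         landuse_fractions = c(forest = 0.55, grassland = 0.14,
                                               farmland = 0.14, unutilized = 0.09,
                                               construction = 0.08),
                         river_quantile = 0.98,
                         rain_monthly_mean = c(20, 25, 35, 60, 100, 180,
                                               220, 200, 140, 90, 40, 20),
                         rain_sd_frac = 0.25,
                         n_years = 5L,
                         npp_mean = 600, npp_sd = 150,
                         nightlight_scale = 0.5,
                         field_range_km = 2,
                         hazard_intercept = NULL,
                         hazard_w_slope = 1.2,
                         hazard_w_river = 0.8,
                         hazard_target_n = 2000L) {
  stopifnot(nrows > 2L, ncols > 2L, cell_size > 0, relief >= 0,
            length(rain_monthly_mean) == 12L, all(rain_monthly_mean >= 0),
            n_years >= 1L, npp_mean > 0, nightlight_scale > 0,
            field_range_km > 0, hazard_target_n > 0)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "scene_config"
  cfg
}

# deterministic per-layer seed derived from the master seed and layer name,
# kept inside the 32-bit signed range
layer_seed <- function(seed, layer) {
  h <- 0
  for (ch in utf8ToInt(layer)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.double(seed) * 48271 + h) %% 2147483629)
}

# stationary Gaussian random field, mean 0 sd 1, via FFT smoothing of white
# noise with a Gaussian kernel of the given range (cells)
gaussian_field <- function(nr, nc, range_cells) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  fx <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fy <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  # Gaussian transfer function in frequency space
  h <- exp(-2 * pi^2 * range_cells^2 * outer(fx^2, fy^2, `+`))
  sm <- Re(stats::fft(stats::fft(noise) * h, inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Fractal DEM by midpoint displacement
#'
#' Diamond-square on the smallest enclosing (2^k + 1) square, cropped to the
#' requested shape and rescaled to `[min_elev, min_elev + relief]`.
#' Deterministic for a fixed config seed.
#'
#' @param config a [scene_config].
#' @return An [esp_raster] of elevations (m).
#' @export
generate_dem <- function(config) {
  set.seed(layer_seed(config$seed, "dem"))
  n <- 2L^ceiling(log2(max(config$nrows, config$ncols) - 1L)) + 1L
  z <- matrix(0, n, n)
  z[c(1L, n), c(1L, n)] <- stats::rnorm(4)
  step <- n - 1L
  amp <- 1
  while (step > 1L) {
    half <- step %/% 2L
    # diamond
    for (r in seq(half + 1L, n, by = step)) {
      for (c in seq(half + 1L, n, by = step)) {
        z[r, c] <- mean(z[c(r - half, r + half), c(c - half, c + half)]) +
          stats::rnorm(1L, sd = amp)
      }
    }
    # square
    for (r in seq(1L, n, by = half)) {
      shift <- if (((r - 1L) %/% half) %% 2L == 0L) half + 1L else 1L
      for (c in seq(shift, n, by = step)) {
        nb <- rbind(c(r - half, c), c(r + half, c), c(r, c - half), c(r, c + half))
        nb <- nb[nb[, 1L] >= 1L & nb[, 1L] <= n & nb[, 2L] >= 1L & nb[, 2L] <= n, ,
                 drop = FALSE]
        z[r, c] <- mean(z[nb]) + stats::rnorm(1L, sd = amp)
      }
    }
    step <- half
    amp <- amp * config$roughness
  }
  z <- z[seq_len(config$nrows), seq_len(config$ncols), drop = FALSE]
  rng <- range(z)
  z <- if (config$relief == 0 || rng[1L] == rng[2L])
    matrix(config$min_elev, config$nrows, config$ncols)
  else config$min_elev + (z - rng[1L]) / (rng[2L] - rng[1L]) * config$relief
  esp_raster(z, cell_size = config$cell_size)
}

#' River network from the DEM
#'
#' D8 flow accumulation above `river_quantile`, returned as a binary mask
#' plus downstream-traced polylines (hydrologically consistent with the DEM
#' by construction).
#'
#' @param config a [scene_config].
#' @param dem the scene DEM.
#' @return List with `mask` (0/1 raster) and `lines` ([esp_vectors]).
#' @export
generate_rivers <- function(config, dem) {
  dirs <- d8_directions(dem)
  acc <- d8_accumulation(dem, dirs)$values
  thr <- stats::quantile(acc, config$river_quantile, na.rm = TRUE, names = FALSE)
  mask <- ifelse(acc >= thr, 1, 0)
  lines <- trace_streams(mask, dirs, dem)
  list(mask = raster_like(dem, mask), lines = lines)
}

# follow D8 downstream from river heads, emitting cell-centre polylines
trace_streams <- function(mask, dirs, dem) {
  nr <- nrow(mask); nc <- ncol(mask)
  inflow <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- dirs[r, c]
    if (mask[r, c] == 1 && k > 0L) {
      r2 <- r + D8_DR[k]; c2 <- c + D8_DC[k]
      if (mask[r2, c2] == 1) inflow[r2, c2] <- inflow[r2, c2] + 1L
    }
  }
  heads <- which(mask == 1 & inflow == 0L)
  visited <- matrix(FALSE, nr, nc)
  geoms <- list()
  for (h in heads) {
    r <- ((h - 1L) %% nr) + 1L; c <- ((h - 1L) %/% nr) + 1L
    rows <- integer(0); cols <- integer(0)
    while (mask[r, c] == 1 && !visited[r, c]) {
      visited[r, c] <- TRUE
      rows <- c(rows, r); cols <- c(cols, c)
      k <- dirs[r, c]
      if (k == 0L) break
      r2 <- r + D8_DR[k]; c2 <- c + D8_DC[k]
      if (mask[r2, c2] != 1) break
      r <- r2; c <- c2
    }
    if (length(rows) >= 2L)
      geoms[[length(geoms) + 1L]] <- cell_xy(dem, rows, cols)
  }
  if (!length(geoms)) # degenerate flat DEM: one nominal channel
    geoms <- list(cell_xy(dem, rep(nr %/% 2L, nc), seq_len(nc)))
  esp_vectors("polylines", geoms,
              data.frame(id = seq_along(geoms)))
}

#' Land-use map with elevation/valley structure
#'
#' Water follows the river mask; construction and farmland claim the lowest,
#' most river-accessible cells; unutilized land the highest and steepest;
#' grassland the remaining high ground; forest everything else.  Class
#' targets are met exactly on the non-water domain (so realised fractions
#' deviate from targets only by the water share).
#'
#' Class codes follow the resistance-table order: 1 forest, 2 grassland,
#' 3 farmland, 4 water, 5 unutilized, 6 construction.
#'
#' @param config a [scene_config].
#' @param dem the scene DEM.
#' @param rivers optional result of [generate_rivers]; `NULL` for no water.
#' @return An [esp_classes] raster with the six land-use labels.
#' @export
generate_landuse <- function(config, dem, rivers = NULL) {
  set.seed(layer_seed(config$seed, "landuse"))
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  labels <- c("forest", "grassland", "farmland", "water", "unutilized",
              "construction")
  code <- matrix(NA_integer_, nr, nc)
  water <- if (is.null(rivers)) matrix(0, nr, nc) else rivers$mask$values
  code[water == 1] <- 4L
  free <- which(is.na(code))
  fr <- config$landuse_fractions
  fr <- fr[c("forest", "grassland", "farmland", "unutilized", "construction")]
  fr[is.na(fr)] <- 0
  fr <- fr / sum(fr)
  n_free <- length(free)
  elev <- (dem$values - min(dem$values)) / max(1e-9, diff(range(dem$values)))
  slope <- slope_aspect(dem)$slope$values
  slope_n <- slope / max(slope, 1e-9)
  rivd <- if (is.null(rivers)) matrix(0.5, nr, nc)
          else mask_distance(rivers$mask)$values
  rivd_n <- rivd / max(rivd, 1e-9)
  noise <- gaussian_field(nr, nc, config$field_range_km / config$cell_size / 2)
  # class-specific suitability; higher = more likely claimed
  suit <- list(
    construction = -(0.55 * elev + 0.35 * rivd_n + 0.10 * slope_n) + 0.10 * noise,
    farmland = -(0.45 * elev + 0.25 * rivd_n + 0.30 * slope_n) + 0.15 * noise,
    unutilized = 0.7 * elev + 0.3 * slope_n + 0.10 * noise,
    grassland = 0.6 * elev - 0.1 * slope_n + 0.25 * noise)
  claim_order <- c("construction", "farmland", "unutilized", "grassland")
  n_target <- round(fr * n_free)
  for (cls in claim_order) {
    n_cls <- min(n_target[[cls]], sum(is.na(code[free])))
    if (n_cls <= 0L) next
    cand <- free[is.na(code[free])]
    take <- cand[order(suit[[cls]][cand], decreasing = TRUE)[seq_len(n_cls)]]
    code[take] <- match(cls, labels)
  }
  code[is.na(code)] <- 1L  # forest fills the remainder
  esp_classes(code, labels, dem$cell_size, dem$origin, dem$nodata)
}

#' Continuous environmental fields
#'
#' Smoothed Gaussian random fields with configured moments, physically
#' clipped: monthly rainfall (mm, >= 0) with optional orographic
#' enhancement, NPP (>= 0), NDVI in [-1, 1], nightlight decaying with
#' distance from construction, and soil texture fractions summing to 100
#' plus an organic-carbon percentage.  With zero sd every field is exactly
#' constant at its configured mean.
#'
#' @param config a [scene_config].
#' @param dem scene DEM (orographic modulation; optional).
#' @param landuse land-use raster (nightlight source cells; optional).
#' @return List: `rainfall` (list of `n_years` lists of 12 rasters), `npp`,
#'   `ndvi`, `nightlight`, `soil` (list `Wg`, `Wp`, `Wc`, `Wo`).
#' @export
generate_fields <- function(config, dem = NULL, landuse = NULL) {
  nr <- config$nrows; nc <- config$ncols
  rng_cells <- config$field_range_km / config$cell_size
  template <- if (!is.null(dem)) dem
              else esp_raster(matrix(0, nr, nc), config$cell_size)
  elev <- if (!is.null(dem))
    (dem$values - min(dem$values)) / max(1e-9, diff(range(dem$values)))
  else matrix(0.5, nr, nc)

  set.seed(layer_seed(config$seed, "rainfall"))
  rainfall <- vector("list", config$n_years)
  sdf <- config$rain_sd_frac
  orog <- if (sdf > 0) 0.3 * (elev - mean(elev)) else 0
  for (y in seq_len(config$n_years)) {
    rainfall[[y]] <- lapply(seq_len(12L), function(m) {
      mu <- config$rain_monthly_mean[m]
      f <- if (sdf > 0) gaussian_field(nr, nc, rng_cells) else 0
      v <- mu * (1 + orog + sdf * f)
      raster_like(template, pmax(v, 0))
    })
  }

  set.seed(layer_seed(config$seed, "npp"))
  npp_v <- config$npp_mean * (1 - if (config$npp_sd > 0) 0.4 * (elev - mean(elev)) else 0) +
    if (config$npp_sd > 0) config$npp_sd * gaussian_field(nr, nc, rng_cells) else 0
  npp <- raster_like(template, pmax(npp_v, 0))

  set.seed(layer_seed(config$seed, "ndvi"))
  npp_n <- (npp$values - min(npp$values)) / max(1e-9, diff(range(npp$values)))
  ndvi_v <- 0.15 + 0.65 * npp_n +
    if (config$npp_sd > 0) 0.08 * gaussian_field(nr, nc, rng_cells) else 0
  ndvi <- raster_like(template, pmin(pmax(ndvi_v, -1), 1))

  set.seed(layer_seed(config$seed, "nightlight"))
  if (!is.null(landuse) && any(landuse$values == 6L, na.rm = TRUE)) {
    constr <- raster_like(template,
                          ifelse(!is.na(landuse$values) & landuse$values == 6L, 1, 0))
    d <- mask_distance(constr)$values
    nl_v <- 63 * exp(-d / config$nightlight_scale) *
      (1 + 0.2 * gaussian_field(nr, nc, rng_cells / 2))
  } else {
    nl_v <- matrix(1, nr, nc)
  }
  nightlight <- raster_like(template, pmax(nl_v, 0.01))

  set.seed(layer_seed(config$seed, "soil"))
  sd_on <- config$rain_sd_frac > 0 || config$npp_sd > 0
  e1 <- exp(0.9 + if (sd_on) 0.35 * gaussian_field(nr, nc, rng_cells) else 0) # sand
  e2 <- exp(0.8 + if (sd_on) 0.35 * gaussian_field(nr, nc, rng_cells) else 0) # silt
  e3 <- exp(0.4 + if (sd_on) 0.35 * gaussian_field(nr, nc, rng_cells) else 0) # clay
  tot <- e1 + e2 + e3
  soil <- list(
    Wg = raster_like(template, 100 * e1 / tot),
    Wp = raster_like(template, 100 * e2 / tot),
    Wc = raster_like(template, 100 * e3 / tot),
    Wo = raster_like(template,
                     pmin(pmax(1.5 + if (sd_on) 0.8 * gaussian_field(nr, nc, rng_cells)
                               else 0, 0.1), 4)))
  list(rainfall = rainfall, npp = npp, ndvi = ndvi, nightlight = nightlight,
       soil = soil)
}

#' Hazard-point inventory driven by slope and river proximity
#'
#' Each land cell is an independent Bernoulli trial with probability
#' `plogis(b0 + w_s * z_slope - w_r * z_riverdist)` on standardised
#' predictors, so hazard intensity rises with slope and falls with distance
#' from rivers.  When the intercept is unset it is calibrated so the
#' expected count equals `hazard_target_n`.  Ground-truth coefficients are
#' attached for parameter-recovery tests.
#'
#' @param config a [scene_config].
#' @param dem scene DEM.
#' @param rivers result of [generate_rivers].
#' @return An [esp_vectors] point set with attribute `cell` and attributes
#'   `ground_truth` (list of coefficients) and `probability` raster attached
#'   as attributes.
#' @export
generate_hazards <- function(config, dem, rivers) {
  set.seed(layer_seed(config$seed, "hazards"))
  slope <- slope_aspect(dem)$slope$values
  rivd <- mask_distance(rivers$mask)$values
  zs <- as.vector(scale(as.vector(slope)))
  zd <- as.vector(scale(as.vector(rivd)))
  if (any(is.na(zs))) zs[] <- 0
  if (any(is.na(zd))) zd[] <- 0
  eta0 <- config$hazard_w_slope * zs - config$hazard_w_river * zd
  land <- as.vector(rivers$mask$values != 1) & !is.na(as.vector(dem$values))
  b0 <- config$hazard_intercept
  if (is.null(b0)) {
    # expected count cannot exceed the land-cell count; cap so the
    # calibration stays solvable on small grids
    target <- min(config$hazard_target_n, 0.5 * sum(land))
    f <- function(b) sum(stats::plogis(b + eta0[land])) - target
    b0 <- stats::uniroot(f, c(-50, 50))$root
  }
  p <- stats::plogis(b0 + eta0)
  p[!land] <- 0
  hit <- which(stats::runif(length(p)) < p)
  nr <- nrow(dem$values)
  rows <- ((hit - 1L) %% nr) + 1L
  cols <- ((hit - 1L) %/% nr) + 1L
  xy <- cell_xy(dem, rows, cols)
  pts <- esp_vectors("points",
                     geoms = lapply(seq_along(hit), function(i) xy[i, , drop = FALSE]),
                     attributes = data.frame(cell = hit))
  attr(pts, "ground_truth") <- list(intercept = b0,
                                    w_slope = config$hazard_w_slope,
                                    w_river = config$hazard_w_river)
  attr(pts, "probability") <- raster_like(dem, matrix(p, nrow = nr))
  pts
}

# simple valley roads: connect the centroids of the largest construction
# clusters (fallback: a straight east-west road through the domain middle)
generate_roads <- function(config, dem, landuse) {
  constr <- ifelse(!is.na(landuse$values) & landuse$values == 6L, 1, 0)
  comp <- label_components(constr, connectivity = 8L)
  geoms <- list()
  if (comp$n >= 2L) {
    sizes <- tabulate(comp$labels[comp$labels > 0L], nbins = comp$n)
    keep <- order(sizes, decreasing = TRUE)[seq_len(min(4L, comp$n))]
    cent <- t(vapply(keep, function(k) {
      cells <- which(comp$labels == k)
      nr <- nrow(constr)
      r <- mean(((cells - 1L) %% nr) + 1L); c <- mean(((cells - 1L) %/% nr) + 1L)
      cell_xy(dem, round(r), round(c))[1L, ]
    }, numeric(2L)))
    ord <- order(cent[, 1L])
    geoms[[1L]] <- cent[ord, , drop = FALSE]
  } else {
    nr <- nrow(dem$values); nc <- ncol(dem$values)
    geoms[[1L]] <- cell_xy(dem, rep(nr %/% 2L, 2L), c(1L, nc))
  }
  esp_vectors("polylines", geoms, data.frame(id = seq_along(geoms)))
}

#' Generate a complete synthetic scene
#'
#' Runs every layer generator with per-layer seeded streams and returns an
#' aligned stack: DEM, rivers, land use, roads, environmental fields and the
#' hazard inventory, plus the ground-truth hazard coefficients.
#'
#' @param config a [scene_config].
#' @return A `synthetic_scene` list.
#' @export
generate_scene <- function(config = scene_config()) {
  dem <- generate_dem(config)
  rivers <- generate_rivers(config, dem)
  landuse <- generate_landuse(config, dem, rivers)
  fields <- generate_fields(config, dem, landuse)
  hazards <- generate_hazards(config, dem, rivers)
  roads <- generate_roads(config, dem, landuse)
  structure(list(config = config, dem = dem, rivers = rivers,
                 landuse = landuse, roads = roads,
                 rainfall = fields$rainfall, npp = fields$npp,
                 ndvi = fields$ndvi, nightlight = fields$nightlight,
                 soil = fields$soil, hazards = hazards,
                 ground_truth = attr(hazards, "ground_truth")),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d cells (%.3g km), seed %d, %d hazard points\n",
              x$config$nrows, x$config$ncols, x$config$cell_size,
              x$config$seed, length(x$hazards)))
  invisible(x)
}

#' Write every scene layer to a directory
#'
#' Rasters go out in the requested grid format, vectors as GeoJSON, and the
#' ground-truth hazard coefficients as `ground_truth.json`.
#'
#' @param scene a `synthetic_scene`.
#' @param outdir output directory (created if missing).
#' @param format raster format passed to [write_raster].
#' @export
write_scene <- function(scene, outdir, format = "ascii") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "geotiff") "tif" else "asc"
  wr <- function(r, name)
    write_raster(r, file.path(outdir, paste0(name, ".", ext)), format)
  wr(scene$dem, "dem")
  wr(scene$rivers$mask, "rivers_mask")
  lu <- scene$landuse; lu$values <- lu$values + 0  # codes as numbers
  wr(esp_raster(lu$values, lu$cell_size, lu$origin, lu$nodata), "landuse")
  wr(scene$npp, "npp"); wr(scene$ndvi, "ndvi"); wr(scene$nightlight, "nightlight")
  for (nm in names(scene$soil)) wr(scene$soil[[nm]], paste0("soil_", nm))
  for (y in seq_along(scene$rainfall))
    for (m in seq_len(12L))
      wr(scene$rainfall[[y]][[m]], sprintf("rain_y%02d_m%02d", y, m))
  write_geojson(scene$rivers$lines, file.path(outdir, "rivers.geojson"))
  write_geojson(scene$roads, file.path(outdir, "roads.geojson"))
  write_geojson(scene$hazards, file.path(outdir, "hazards.geojson"))
  jsonlite::write_json(scene$ground_truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
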