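# Eco-environmental sensitivity: RUSLE soil erosion, certainty-factor (CF)
# geohazard susceptibility, and their weighted fusion.

#' Rainfall erosivity factor R
#'
#' Monthly-rainfall estimator
#' `R = 0.1833 * [ (1/N) * sum_i (sum_j P_ij^2) / (sum_j P_ij) ]^1.9957`
#' in MJ mm / (hm^2 h a), where `P_ij` is rainfall (mm) of month `j` in
#' year `i`.  Cells with zero annual rainfall in every year get `R = 0`.
#'
#' @param monthly list of years, each a list of 12 aligned rainfall rasters,
#'   or a single year's list of 12 rasters.
#' @param coef,expo estimator constants.
#' @return An [esp_raster] of R values.
#' @export
rainfall_erosivity <- function(monthly, coef = 0.1833, expo = 1.9957) {
  if (length(monthly) == 12L && inherits(monthly[[1L]], "esp_raster"))
    monthly <- list(monthly)
  n_years <- length(monthly)
  template <- monthly[[1L]][[1L]]
  inner <- matrix(0, nrow(template$values), ncol(template$values))
  for (y in seq_len(n_years)) {
    stopifnot(length(monthly[[y]]) == 12L)
    s1 <- s2 <- matrix(0, nrow(inner), ncol(inner))
    for (m in seq_len(12L)) {
      check_aligned(template, monthly[[y]][[m]])
      p <- monthly[[y]][[m]]$values
      if (any(p < 0, na.rm = TRUE)) stop("negative precipitation")
      s1 <- s1 + p
      s2 <- s2 + p^2
    }
    ratio <- ifelse(s1 > 0, s2 / s1, 0)
    inner <- inner + ratio
  }
  raster_like(template, coef * (inner / n_years)^expo)
}

#' Soil erodibility factor K (EPIC)
#'
#' Williams' texture/organic-carbon estimator:
#' `K = [0.2 + 0.3 exp(-0.0256 Wg (1 - Wp/100))] * [Wp/(Wc+Wp)]^0.3 *
#' [1 - 0.25 Wo/(Wo + exp(3.72 - 2.95 Wo))] *
#' [1 - 0.7 b/(b + exp(22.9 b - 5.51))]`, `b = 1 - Wg/100`,
#' in t h / (MJ mm).  `Wg`, `Wp`, `Wc`, `Wo` are percent sand, silt, clay
#' and organic carbon.
#'
#' @param wg,wp,wc,wo aligned percent-content rasters.
#' @return An [esp_raster] of K values (> 0 whenever silt + clay > 0).
#' @export
soil_erodibility <- function(wg, wp, wc, wo) {
  check_aligned(wg, wp, wc, wo)
  f <- function(g, p, c, o) {
    if (any(p + c <= 0, na.rm = TRUE)) stop("silt + clay must be positive")
    b <- 1 - g / 100
    (0.2 + 0.3 * exp(-0.0256 * g * (1 - p / 100))) *
      (p / (c + p))^0.3 *
      (1 - 0.25 * o / (o + exp(3.72 - 2.95 * o))) *
      (1 - 0.7 * b / (b + exp(22.9 * b - 5.51)))
  }
  raster_map(f, wg, wp, wc, wo)
}

#' Slope length-steepness factor LS
#'
#' Raster LS in the McCool/Moore style used for mountainous RUSLE mapping:
#' slope length `lambda` accumulates along D8 flow
#' (`lambda = (acc + 1) * cell`, capped), `L = (lambda / 22.13)^m` with the
#' slope-dependent exponent m (0.2/0.3/0.4/0.5 below 1/3/5 degrees and
#' above), and the steep-slope S:
#' `S = 10.8 sin(t) + 0.03` (t < 5 deg), `16.8 sin(t) - 0.5` (5-10 deg),
#' `21.9 sin(t) - 0.96` (>= 10 deg).  Flat terrain gives the minimum
#' `S = 0.03` everywhere.
#'
#' @param dem an [esp_raster] of elevations (m).
#' @param max_length cap on slope length in m (default 300).
#' @param use_accumulation use D8 flow accumulation for slope length;
#'   `FALSE` uses one cell length everywhere.
#' @return An [esp_raster] of LS values (>= 0).
#' @export
ls_factor <- function(dem, max_length = 300, use_accumulation = TRUE) {
  slope <- slope_aspect(dem)$slope$values
  cell_m <- dem$cell_size * 1000
  lambda <- if (use_accumulation)
    pmin((d8_accumulation(dem)$values + 1) * cell_m, max_length)
  else matrix(pmin(cell_m, max_length), nrow(slope), ncol(slope))
  deg <- slope * 180 / pi
  m <- ifelse(deg < 1, 0.2, ifelse(deg < 3, 0.3, ifelse(deg < 5, 0.4, 0.5)))
  L <- (lambda / 22.13)^m
  S <- ifelse(deg < 5, 10.8 * sin(slope) + 0.03,
              ifelse(deg < 10, 16.8 * sin(slope) - 0.5,
                     21.9 * sin(slope) - 0.96))
  raster_like(dem, L * S)
}

#' Erosion-intensity grading bounds
#'
#' The six hydraulic-erosion intensity classes in t/(km^2 a): micro
#' (0-500), mild (500-2500), moderate (2500-5000), serious (5000-8000),
#' polar (8000-15000) and severe (> 15000).
#' @export
erosion_breaks <- function() c(0, 500, 2500, 5000, 8000, 15000, Inf)

#' @rdname erosion_breaks
#' @export
erosion_labels <- function() c("Micro erosion", "Mild erosion",
                               "Moderate erosion", "Serious erosion",
                               "Polar erosion", "Severe erosion")

#' RUSLE soil loss and its intensity grading
#'
#' `A = R * K * LS * C * P` in t/(hm^2 a); multiplied by 100 to the
#' t/(km^2 a) scale (1 km^2 = 100 hm^2) before grading with the six
#' intensity bounds.
#'
#' @param r,k,ls,c,p aligned factor rasters (`c`, `p` in [0, 1]).
#' @return List with `modulus` (t/(km^2 a) raster) and `classes`
#'   (six-level [esp_classes]).
#' @export
soil_loss <- function(r, k, ls, c, p) {
  for (f in list(r, k, ls, c, p))
    if (any(f$values < 0, na.rm = TRUE)) stop("RUSLE factors must be non-negative")
  a_hm2 <- raster_map(function(...) Reduce(`*`, list(...)), r, k, ls, c, p)
  modulus <- raster_map(function(v) v * 100, a_hm2)
  list(modulus = modulus,
       classes = classify_raster(modulus, erosion_breaks(), erosion_labels()))
}

#' Cover-management and practice factors from land use
#'
#' Standard RUSLE lookup: dense natural cover gives low C, farmland high C;
#' P defaults to 1 (no conservation practice) except farmland.
#'
#' @param landuse an [esp_classes] land-use raster.
#' @param c_table,p_table named per-class values.
#' @return List of two rasters, `c` and `p`.
#' @export
cp_factors <- function(landuse,
                       c_table = c(forest = 0.003, grassland = 0.05,
                                   farmland = 0.25, water = 0,
                                   unutilized = 0.45, construction = 0.2),
                       p_table = c(forest = 1, grassland = 1, farmland = 0.5,
                                   water = 1, unutilized = 1, construction = 1)) {
  labs <- landuse$labels
  if (!all(labs %in% names(c_table)) || !all(labs %in% names(p_table)))
    stop("C/P table missing land-use classes")
  lu <- landuse$values
  cmat <- matrix(c_table[labs][lu], nrow(lu), ncol(lu))
  pmat <- matrix(p_table[labs][lu], nrow(lu), ncol(lu))
  list(c = raster_like(landuse, cmat), p = raster_like(landuse, pmat))
}

# ---- certainty-factor (CF) geohazard model --------------------------------

#' Certainty factor from conditional and prior probabilities
#'
#' `CF = (Pa - Ps) / (Pa (1 - Ps))` when `Pa >= Ps`, and
#' `(Pa - Ps) / (Ps (1 - Pa))` when `Pa < Ps`; always in [-1, 1] for
#' probabilities in [0, 1].  Positive values flag hazard-prone bins.
#'
#' @param pa conditional event probability in the factor bin.
#' @param ps prior event probability over the whole domain.
#' @return CF value(s) in [-1, 1].
#' @export
certainty_factor <- function(pa, ps) {
  stopifnot(all(pa >= 0 & pa <= 1), all(ps > 0 & ps < 1))
  ifelse(pa >= ps, (pa - ps) / (pa * (1 - ps)), (pa - ps) / (ps * (1 - pa)))
}

#' Per-bin certainty factors for one conditioning factor
#'
#' Bins a factor raster (quantile bins for continuous factors, native codes
#' for categorical ones), counts hazard points per bin and converts bin
#' event rates into certainty factors.  Rates are expressed per cell
#' (count / cells in bin, capped at 1), which keeps both probabilities
#' inside [0, 1] regardless of the grid's physical cell size.
#'
#' @param hazard_points an [esp_vectors] point set.
#' @param factor_raster an [esp_raster] (continuous) or [esp_classes]
#'   (categorical).
#' @param bins number of quantile bins for continuous factors, or an
#'   explicit vector of break values.
#' @return A `cf_factor` object: per-bin table (bin, from, to, cells,
#'   area, count, pa, cf), the prior `ps`, and enough metadata to map cells
#'   to bins.
#' @export
cf_factor <- function(hazard_points, factor_raster, bins = 8L) {
  if (!length(hazard_points$geoms)) stop("need at least one hazard point")
  v <- factor_raster$values
  ok <- !is.na(v)
  categorical <- inherits(factor_raster, "esp_classes")
  if (categorical) {
    bin_of <- v
    breaks <- NULL
    bin_ids <- seq_along(factor_raster$labels)
    bin_names <- factor_raster$labels
  } else {
    breaks <- if (length(bins) > 1L) as.numeric(bins)
    else unique(stats::quantile(v[ok], probs = seq(0, 1, length.out = bins + 1L),
                                names = FALSE))
    breaks[1L] <- -Inf; breaks[length(breaks)] <- Inf
    bin_of <- matrix(NA_integer_, nrow(v), ncol(v))
    bin_of[ok] <- findInterval(v[ok], breaks, rightmost.closed = TRUE)
    bin_ids <- seq_len(length(breaks) - 1L)
    bin_names <- paste0("bin", bin_ids)
  }
  pts_xy <- do.call(rbind, hazard_points$geoms)
  rc <- xy_cell(factor_raster, pts_xy[, 1L], pts_xy[, 2L])
  pt_bins <- bin_of[rc]
  cells <- vapply(bin_ids, function(b) sum(bin_of == b, na.rm = TRUE), numeric(1L))
  counts <- vapply(bin_ids, function(b) sum(pt_bins == b, na.rm = TRUE), numeric(1L))
  if (any(cells == 0 & counts > 0)) stop("hazard points fall in an empty bin")
  total_cells <- sum(cells)
  ps <- min(sum(counts) / total_cells, 1 - 1e-12)
  pa <- ifelse(cells > 0, pmin(counts / cells, 1), 0)
  cf <- ifelse(cells > 0, certainty_factor(pa, ps), 0)
  tab <- data.frame(bin = bin_names,
                    from = if (is.null(breaks)) NA_real_ else breaks[-length(breaks)],
                    to = if (is.null(breaks)) NA_real_ else breaks[-1L],
                    cells = cells,
                    area_km2 = cells * cell_area(factor_raster),
                    count = counts, pa = pa, cf = cf,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, ps = ps, breaks = breaks,
                 categorical = categorical, bin_of = bin_of),
            class = "cf_factor")
}

#' @export
print.cf_factor <- function(x, ...) {
  cat(sprintf("<cf_factor> %d bins, prior %.4g\n", nrow(x$table), x$ps))
  print(x$table[, c("bin", "cells", "count", "pa", "cf")], row.names = FALSE)
  invisible(x)
}

#' Geohazard sensitivity from a set of CF factor layers
#'
#' The per-cell score is the unweighted sum over factors of the certainty
#' factor of the cell's bin; the score is graded into five sensitivity
#' levels.
#'
#' @param cf_models list of `cf_factor` objects (one per conditioning
#'   factor), all on aligned grids.
#' @param template an [esp_raster] supplying the grid.
#' @param method classification method for [grade_raster].
#' @return List with `score` raster and five-level `classes`.
#' @export
geohazard_sensitivity <- function(cf_models, template, method = "jenks") {
  score <- matrix(0, nrow(template$values), ncol(template$values))
  for (cfm in cf_models) {
    if (!identical(dim(cfm$bin_of), dim(score)))
      stop("cf model grid does not match the template")
    cfv <- cfm$table$cf[cfm$bin_of]
    if (any(is.na(cfv) & !is.na(cfm$bin_of)))
      stop("cell with unbinned factor value")
    cfv[is.na(cfv)] <- 0
    score <- score + matrix(cfv, nrow(score))
  }
  score[is.na(template$values)] <- NA_real_
  sr <- raster_like(template, score)
  labels <- c("least sensitive", "less sensitive", "medium sensitivity",
              "more sensitive", "most sensitive")
  cls <- if (diff(range(score, na.rm = TRUE)) == 0)
    esp_classes(matrix(1L, nrow(score), ncol(score)), labels,
                template$cell_size, template$origin)
  else grade_raster(sr, labels, method)
  list(score = sr, classes = cls)
}

#' Fuse erosion and geohazard gradings into eco-environmental sensitivity
#'
#' Class ranks are normalised to [0, 1] (`(rank - 1) / (K - 1)`), combined
#' as a weighted mean, and re-graded into five equal-interval levels
#' (Jenks would be degenerate on the small set of combined rank values).
#'
#' @param erosion_class graded erosion [esp_classes] (6 levels).
#' @param geohazard_class graded geohazard [esp_classes] (5 levels).
#' @param weights length-2 weights summing to 1.
#' @return List with `score` raster and five-level `classes`.
#' @export
combined_sensitivity <- function(erosion_class, geohazard_class,
                                 weights = c(0.5, 0.5)) {
  check_aligned(erosion_class, geohazard_class)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  norm_rank <- function(cls) {
    k <- length(cls$labels)
    (cls$values - 1) / max(k - 1, 1)
  }
  score <- weights[1L] * norm_rank(erosion_class) +
    weights[2L] * norm_rank(geohazard_class)
  sr <- esp_raster(score, erosion_class$cell_size, erosion_class$origin)
  labels <- c("least sensitive", "less sensitive", "medium sensitivity",
              "more sensitive", "most sensitive")
  cls <- classify_raster(sr, seq(0, 1, length.out = 6L), labels)
  list(score = sr, classes = cls)
}
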