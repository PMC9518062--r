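# Comprehensive ecological security, source/point identification, the
# corrected resistance surface, MCR cost distances / least-cost corridors,
# and typed ecological nodes.

SECURITY_LABELS <- c("lowest", "lower", "medium", "higher", "highest")

#' Comprehensive ecological-security surface
#'
#' Per-cell weighted combination of the three five-level evaluations with
#' sensitivity entering with reversed polarity (high sensitivity lowers
#' security): `score = w1 * n(imp) + w2 * (1 - n(sens)) + w3 * n(conn)`
#' where `n(r) = (r - 1) / (K - 1)` normalises class ranks to [0, 1].  The
#' score is graded into five equal-interval security levels.
#'
#' @param importance,sensitivity,connectivity aligned [esp_classes] inputs.
#' @param weights length-3 non-negative weights summing to 1 (default
#'   equal).
#' @return List with `score` raster and five-level `classes`.
#' @export
security_index <- function(importance, sensitivity, connectivity,
                           weights = rep(1 / 3, 3)) {
  check_aligned(importance, sensitivity, connectivity)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  nr <- function(cls) (cls$values - 1) / max(length(cls$labels) - 1, 1)
  score <- weights[1L] * nr(importance) + weights[2L] * (1 - nr(sensitivity)) +
    weights[3L] * nr(connectivity)
  sr <- esp_raster(score, importance$cell_size, importance$origin)
  cls <- classify_raster(sr, seq(0, 1, length.out = 6L), SECURITY_LABELS)
  list(score = sr, classes = cls)
}

#' Identify ecological sources and points
#'
#' Primary sources are the connected components of the highest security
#' class, secondary sources those of the next ("higher") class, each
#' filtered by a minimum patch area.  One ecological point is extracted per
#' retained patch: the patch centroid, snapped to the nearest in-patch cell
#' when it falls outside a concave patch.
#'
#' @param security five-level [esp_classes] from [security_index].
#' @param min_area minimum source-patch area in km^2 (default 10).
#' @return A `source_set`: `primary` and `secondary` `patch_set`s (or
#'   `NULL` when empty) and `points` ([esp_vectors] with `level` and
#'   `patch` attributes).
#' @export
identify_sources <- function(security, min_area = 10) {
  lvl <- function(code) {
    mask <- raster_like(security,
                        ifelse(!is.na(security$values) & security$values == code, 1, 0))
    if (!any(mask$values == 1)) return(NULL)
    tryCatch(extract_patches(mask, min_area = min_area),
             error = function(e) NULL)
  }
  primary <- lvl(5L)
  secondary <- lvl(4L)
  if (is.null(primary) && is.null(secondary))
    stop("no source patch survives the min_area threshold")
  pts <- list(); lev <- character(0); pid <- integer(0)
  add_points <- function(ps, level) {
    if (is.null(ps)) return()
    for (p in ps$patches) {
      xy <- p$centroid
      cxy <- cell_xy(security, p$rows, p$cols)
      d2 <- (cxy[, 1L] - xy[1L])^2 + (cxy[, 2L] - xy[2L])^2
      snap <- which.min(d2)
      pts[[length(pts) + 1L]] <<- cxy[snap, , drop = FALSE]
      lev <<- c(lev, level)
      pid <<- c(pid, p$id)
    }
  }
  add_points(primary, "primary")
  add_points(secondary, "secondary")
  points <- esp_vectors("points", pts,
                        data.frame(level = lev, patch = pid,
                                   stringsAsFactors = FALSE))
  structure(list(primary = primary, secondary = secondary, points = points,
                 min_area = min_area),
            class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  np <- if (is.null(x$primary)) 0L else length(x$primary$patches)
  ns <- if (is.null(x$secondary)) 0L else length(x$secondary$patches)
  cat(sprintf("<source_set> %d primary + %d secondary patches (min area %.3g km^2)\n",
              np, ns, x$min_area))
  invisible(x)
}

#' Land-use resistance surface with nightlight and elevation corrections
#'
#' Base resistance from the land-use lookup (forest 1, grassland 10,
#' farmland 30, water 50, unutilized 300, construction 500); then
#' `R_i = (NL_i / NL_a) * R` using the mean nightlight `NL_a` of the cell's
#' land-use class, and `R_j = (DEM_i / DEM_a) * R_i` analogously for
#' elevation.  A class with zero mean nightlight (or elevation) leaves the
#' previous coefficient unchanged, since the ratio is undefined.
#'
#' @param landuse an [esp_classes] land-use raster.
#' @param nightlight,dem aligned correction rasters (`NULL` skips that
#'   correction).
#' @param coefficients named base resistance per land-use class.
#' @return A `resistance_surface`: rasters `base`, `nightlight_adj`,
#'   `elevation_adj` (the final surface) plus the per-class means used.
#' @export
resistance_surface <- function(landuse, nightlight = NULL, dem = NULL,
                               coefficients = c(forest = 1, grassland = 10,
                                                farmland = 30, water = 50,
                                                unutilized = 300,
                                                construction = 500)) {
  labs <- landuse$labels
  if (!all(labs %in% names(coefficients)))
    stop("resistance coefficients missing for: ",
         paste(setdiff(labs, names(coefficients)), collapse = ", "))
  lu <- landuse$values
  base <- matrix(coefficients[labs][lu], nrow(lu), ncol(lu))
  class_ratio <- function(field) {
    means <- vapply(seq_along(labs), function(k)
      mean(field[lu == k], na.rm = TRUE), numeric(1L))
    ratio <- field / matrix(means[lu], nrow(lu), ncol(lu))
    ratio[!is.finite(ratio)] <- 1    # zero-mean class: keep coefficient
    list(ratio = ratio, means = means)
  }
  ri <- base; nl_means <- NULL
  if (!is.null(nightlight)) {
    check_aligned(landuse, nightlight)
    cr <- class_ratio(nightlight$values)
    ri <- cr$ratio * base
    nl_means <- stats::setNames(cr$means, labs)
  }
  rj <- ri; dem_means <- NULL
  if (!is.null(dem)) {
    check_aligned(landuse, dem)
    cr <- class_ratio(dem$values)
    rj <- cr$ratio * ri
    dem_means <- stats::setNames(cr$means, labs)
  }
  structure(list(base = raster_like(landuse, base),
                 nightlight_adj = raster_like(landuse, ri),
                 elevation_adj = raster_like(landuse, rj),
                 nl_means = nl_means, dem_means = dem_means),
            class = "resistance_surface")
}

# grid graph over traversable cells: 8-neighbour edges, edge weight =
# mean(resistance of the two cells) * step length (km, sqrt(2) on diagonals)
resistance_graph <- function(resistance) {
  z <- resistance$values
  if (any(z[!is.na(z)] <= 0)) stop("resistance must be positive everywhere traversable")
  nr <- nrow(z); nc <- ncol(z)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  cs <- resistance$cell_size
  for (k in c(1L, 2L, 3L, 8L)) {  # E, SE, S, NE cover each pair once
    dr <- D8_DR[k]; dc <- D8_DC[k]
    rs <- seq_len(nr); cols <- seq_len(nc)
    rs <- rs[rs + dr >= 1L & rs + dr <= nr]
    cols <- cols[cols + dc >= 1L & cols + dc <= nc]
    a <- as.vector(idx[rs, cols]); b <- as.vector(idx[rs + dr, cols + dc])
    step <- if (dr != 0L && dc != 0L) sqrt(2) * cs else cs
    wt <- (as.vector(z[rs, cols]) + as.vector(z[rs + dr, cols + dc])) / 2 * step
    ok <- !is.na(wt)
    from <- c(from, a[ok]); to <- c(to, b[ok]); w <- c(w, wt[ok])
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  g
}

#' Minimum-cumulative-resistance cost distance
#'
#' Accumulated `sum(D_ij * R_i)` cost from the nearest source cell to every
#' cell, on the 8-neighbour grid graph (step cost = mean resistance of the
#' two cells x step length; the identity is used for the outer monotone
#' function).  Implemented as a single multi-source shortest-path run via a
#' zero-cost virtual source.
#'
#' @param resistance an [esp_raster] of positive resistance values.
#' @param source_cells integer cell indices (column-major) of the source
#'   set.
#' @param graph optional precomputed [resistance_graph] (saves rebuilds).
#' @return An [esp_raster] of accumulated costs (0 on sources).
#' @export
cost_distance <- function(resistance, source_cells, graph = NULL) {
  if (!length(source_cells)) stop("no source cells")
  if (is.null(graph)) graph <- resistance_graph(resistance)
  n <- nrow(resistance$values) * ncol(resistance$values)
  g2 <- igraph::add_vertices(graph, 1L)
  g2 <- igraph::add_edges(g2, rbind(n + 1L, source_cells),
                          weight = rep(0, length(source_cells)))
  d <- as.vector(igraph::distances(g2, v = n + 1L, algorithm = "dijkstra"))[-(n + 1L)]
  raster_like(resistance, matrix(d, nrow(resistance$values)))
}

#' Least-cost ecological corridors between source points
#'
#' Minimum-cost paths on the resistance grid between point pairs.  Pairing
#' rules: `"pairs"` joins every pair within a level; `"nearest"` joins each
#' point to its `m` nearest neighbours by cost.  Corridors sharing more
#' than `dedup_share` of their cells with an already accepted corridor are
#' dropped (near-duplicate routes through the same valley).
#'
#' @param resistance an [esp_raster].
#' @param points an [esp_vectors] point set; a `level` attribute column, if
#'   present, is copied to the corridors and pairing is within/between
#'   levels as described in Details.
#' @param pairing `"pairs"` or `"nearest"`.
#' @param m neighbours per point for `"nearest"`.
#' @param dedup_share cell-overlap share above which a corridor is dropped.
#' @param graph optional precomputed [resistance_graph].
#' @return A `corridor_set`: list of corridors (cells, polyline, endpoints,
#'   level, `mcr` cost, length in km).
#' @details With levels present, primary-primary pairs use `"pairs"` and
#'   every secondary point connects to its nearest (by cost) neighbour of
#'   any level, mirroring a trunk-and-feeder corridor hierarchy.
#' @export
least_cost_corridors <- function(resistance, points, pairing = c("level", "pairs", "nearest"),
                                 m = 1L, dedup_share = 0.8, graph = NULL) {
  pairing <- match.arg(pairing)
  if (is.null(graph)) graph <- resistance_graph(resistance)
  xy <- do.call(rbind, points$geoms)
  rc <- xy_cell(resistance, xy[, 1L], xy[, 2L])
  nr <- nrow(resistance$values)
  cells <- (rc[, 2L] - 1L) * nr + rc[, 1L]
  n <- length(cells)
  lev <- if ("level" %in% names(points$attributes))
    points$attributes$level else rep("primary", n)
  if (pairing == "level" && !any(lev == "secondary")) pairing <- "pairs"
  cost <- igraph::distances(graph, v = cells, to = cells, algorithm = "dijkstra")
  if (any(!is.finite(cost))) stop("some source points are mutually unreachable")
  pairs <- switch(pairing,
    pairs = t(utils::combn(seq_len(n), 2L)),
    nearest = do.call(rbind, lapply(seq_len(n), function(i) {
      ord <- order(cost[i, ])[-1L]
      cbind(i, ord[seq_len(min(m, n - 1L))])
    })),
    level = {
      pr <- which(lev == "primary"); se <- which(lev == "secondary")
      pp <- if (length(pr) > 1L) t(utils::combn(pr, 2L)) else NULL
      sp <- if (length(se)) do.call(rbind, lapply(se, function(i) {
        ord <- order(cost[i, ])[-1L]
        cbind(i, ord[seq_len(min(m, n - 1L))])
      })) else NULL
      rbind(pp, sp)
    })
  if (is.null(pairs) || !nrow(pairs)) stop("no point pairs to connect")
  pairs <- unique(t(apply(pairs, 1L, sort)))
  # cheapest corridors first so dedup keeps the best route in a valley
  pairs <- pairs[order(cost[pairs]), , drop = FALSE]
  corridors <- list()
  seen_cells <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    vp <- igraph::shortest_paths(graph, from = cells[i], to = cells[j],
                                 output = "vpath")$vpath[[1L]]
    path_cells <- as.integer(vp)
    dup <- FALSE
    for (sc in seen_cells) {
      if (length(intersect(path_cells, sc)) / length(path_cells) > dedup_share) {
        dup <- TRUE; break
      }
    }
    if (dup) next
    rows <- ((path_cells - 1L) %% nr) + 1L
    cols <- ((path_cells - 1L) %/% nr) + 1L
    pxy <- cell_xy(resistance, rows, cols)
    steps <- sqrt(diff(rows)^2 + diff(cols)^2) * resistance$cell_size
    level <- if (lev[i] == "primary" && lev[j] == "primary") "primary" else "secondary"
    corridors[[length(corridors) + 1L]] <- list(
      id = length(corridors) + 1L, from = i, to = j, level = level,
      cells = path_cells, polyline = pxy, mcr = cost[i, j],
      length_km = sum(steps))
    seen_cells[[length(seen_cells) + 1L]] <- path_cells
  }
  structure(list(corridors = corridors, points = points,
                 cell_size = resistance$cell_size, dim = dim(resistance$values)),
            class = "corridor_set")
}

#' @export
print.corridor_set <- function(x, ...) {
  lv <- vapply(x$corridors, `[[`, character(1L), "level")
  cat(sprintf("<corridor_set> %d corridors (%d primary, %d secondary)\n",
              length(x$corridors), sum(lv == "primary"), sum(lv == "secondary")))
  invisible(x)
}

#' Corridors as a vector set
#' @param corridors a `corridor_set`.
#' @return An [esp_vectors] of polylines with level, cost and length.
#' @export
corridors_as_vectors <- function(corridors) {
  esp_vectors("polylines",
              lapply(corridors$corridors, `[[`, "polyline"),
              data.frame(
                id = vapply(corridors$corridors, `[[`, integer(1L), "id"),
                level = vapply(corridors$corridors, `[[`, character(1L), "level"),
                mcr = vapply(corridors$corridors, `[[`, numeric(1L), "mcr"),
                length_km = vapply(corridors$corridors, `[[`, numeric(1L),
                                   "length_km"),
                stringsAsFactors = FALSE))
}

#' Typed ecological nodes on the corridors
#'
#' Strategic points: corridor cells on the resistance ridge lines; breaking
#' points: geometric crossings of corridor polylines with roads or rivers
#' (computed by segment intersection, so a corridor slipping diagonally
#' "between" the cells of a diagonal river line is still caught); respite
#' points ("stepping stones"): corridor cells on the valley lines.
#' Adjacent intersection cells (8-connected) merge into a single node
#' placed at the member cell nearest the component centroid.
#'
#' @param corridors a `corridor_set`.
#' @param ridge_mask,valley_mask 0/1 rasters from [ridge_valley_lines].
#' @param roads,rivers [esp_vectors] polylines (either may be `NULL`).
#' @param template an [esp_raster] supplying the grid for node merging.
#' @return An [esp_vectors] point set with `type` and `corridor` attributes.
#' @export
ecological_nodes <- function(corridors, ridge_mask, valley_mask,
                             roads = NULL, rivers = NULL, template = NULL) {
  if (is.null(template)) template <- ridge_mask
  nr <- corridors$dim[1L]; ncl <- corridors$dim[2L]
  cor_mask <- matrix(0, nr, ncl)
  cor_id <- matrix(0L, nr, ncl)
  for (co in corridors$corridors) {
    cor_mask[co$cells] <- 1
    cor_id[co$cells] <- co$id
  }
  mask_nodes <- function(inter, type) {
    if (!any(inter)) return(NULL)
    comp <- label_components(ifelse(inter, 1, 0))
    out <- list()
    for (k in seq_len(comp$n)) {
      cells <- which(comp$labels == k)
      rows <- ((cells - 1L) %% nr) + 1L
      cols <- ((cells - 1L) %/% nr) + 1L
      cen <- c(mean(rows), mean(cols))
      pick <- which.min((rows - cen[1L])^2 + (cols - cen[2L])^2)
      out[[k]] <- list(xy = cell_xy(template, rows[pick], cols[pick]),
                       type = type, corridor = cor_id[cells[pick]])
    }
    out
  }
  cor_lines <- corridors_as_vectors(corridors)
  cross_pts <- matrix(numeric(0), 0L, 2L)
  for (v in list(roads, rivers))
    if (!is.null(v) && length(v$geoms))
      cross_pts <- rbind(cross_pts, segment_intersections(cor_lines, v))
  cross_inter <- matrix(FALSE, nr, ncl)
  if (nrow(cross_pts)) {
    rc <- xy_cell(template, cross_pts[, 1L], cross_pts[, 2L])
    cross_inter[rc] <- TRUE
  }
  nodes <- c(mask_nodes(cor_mask == 1 & ridge_mask$values == 1, "strategic"),
             mask_nodes(cross_inter, "breaking"),
             mask_nodes(cor_mask == 1 & valley_mask$values == 1, "respite"))
  if (!length(nodes))
    return(esp_vectors("points", list(),
                       data.frame(type = character(0), corridor = integer(0))))
  esp_vectors("points", lapply(nodes, `[[`, "xy"),
              data.frame(type = vapply(nodes, `[[`, character(1L), "type"),
                         corridor = vapply(nodes, `[[`, numeric(1L), "corridor"),
                         stringsAsFactors = FALSE))
}
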