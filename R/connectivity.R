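# Habitat patches and Conefor-style connectivity indices (IIC, PC, dIIC,
# dPC, PI).  Patches are connected components of a binary habitat raster;
# links are thresholded edge-to-edge distances; dispersal probabilities use a
# negative-exponential kernel.

#' Label connected components of a binary mask
#'
#' Iterative flood fill under 4- or 8-connectivity.
#'
#' @param mask numeric/integer matrix; cells with value 1 are foreground.
#' @param connectivity 4 or 8.
#' @return List with `labels` (integer matrix, 0 = background) and `n`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- !is.na(mask) & mask == 1
  labels <- matrix(0L, nr, nc)
  dr <- if (connectivity == 8L) D8_DR else c(0L, 1L, 0L, -1L)
  dc <- if (connectivity == 8L) D8_DC else c(1L, 0L, -1L, 0L)
  n <- 0L
  stack <- integer(nr * nc)
  for (start in which(fg & labels == 0L)) {
    if (labels[start] != 0L) next
    n <- n + 1L
    top <- 1L; stack[1L] <- start; labels[start] <- n
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- ((cur - 1L) %% nr) + 1L; c <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- c + dc[k]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          idx <- (c2 - 1L) * nr + r2
          if (fg[idx] && labels[idx] == 0L) {
            labels[idx] <- n
            top <- top + 1L; stack[top] <- idx
          }
        }
      }
    }
  }
  list(labels = labels, n = n)
}

#' Extract habitat patches
#'
#' Connected components of a binary habitat raster, filtered by a minimum
#' area.  Each patch records its cells, area, centroid and boundary cells
#' (used for edge-to-edge distances).
#'
#' @param habitat an [esp_raster] with 1 = habitat (anything else or `NA` =
#'   matrix).
#' @param min_area smallest retained patch area in km^2.
#' @param connectivity_rule 8 (default, diagonal neighbours join) or 4.
#' @return A `patch_set`: list of patches plus the shared template info.
#' @export
extract_patches <- function(habitat, min_area = 0, connectivity_rule = 8L) {
  m <- habitat$values
  if (!any(m == 1, na.rm = TRUE)) stop("empty habitat raster")
  comp <- label_components(m, connectivity_rule)
  nr <- nrow(m)
  ca <- cell_area(habitat)
  patches <- list()
  for (k in seq_len(comp$n)) {
    cells <- which(comp$labels == k)
    area <- length(cells) * ca
    if (area < min_area) next
    rows <- ((cells - 1L) %% nr) + 1L
    cols <- ((cells - 1L) %/% nr) + 1L
    boundary <- is_boundary_cell(comp$labels, k, rows, cols)
    xy <- cell_xy(habitat, rows, cols)
    patches[[length(patches) + 1L]] <- list(
      id = length(patches) + 1L, cells = cells, rows = rows, cols = cols,
      boundary = cells[boundary], area = area,
      centroid = c(mean(xy[, 1L]), mean(xy[, 2L])))
  }
  if (!length(patches)) stop("no patch survives the min_area threshold")
  structure(list(patches = patches, cell_size = habitat$cell_size,
                 origin = habitat$origin, dim = dim(m)),
            class = "patch_set")
}

is_boundary_cell <- function(labels, k, rows, cols) {
  nr <- nrow(labels); nc <- ncol(labels)
  vapply(seq_along(rows), function(i) {
    r <- rows[i]; c <- cols[i]
    if (r == 1L || r == nr || c == 1L || c == nc) return(TRUE)
    any(labels[(r - 1L):(r + 1L), (c - 1L):(c + 1L)] != k)
  }, logical(1L))
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, total area %.4g km^2\n",
              length(x$patches), sum(vapply(x$patches, `[[`, numeric(1L), "area"))))
  invisible(x)
}

# minimum cell-centre distance between the boundary cells of two patches (km)
patch_distance <- function(ps, i, j) {
  nr <- ps$dim[1L]; cs <- ps$cell_size
  bi <- ps$patches[[i]]$boundary; bj <- ps$patches[[j]]$boundary
  ri <- ((bi - 1L) %% nr) + 1L; ci <- ((bi - 1L) %/% nr) + 1L
  rj <- ((bj - 1L) %% nr) + 1L; cj <- ((bj - 1L) %/% nr) + 1L
  sqrt(min(outer(ri, rj, `-`)^2 + outer(ci, cj, `-`)^2)) * cs
}

#' Build the patch graph
#'
#' Patches are linked when their edge-to-edge distance is at most
#' `threshold`; the direct dispersal probability is `p = exp(-k d)` with `k`
#' calibrated so that `p = p_median` at `d = d_median`.  `l_ij` counts links
#' on the shortest topological path; `p*_ij` is the maximum product
#' probability over all paths (self pairs: `l_ii = 0`, `p*_ii = 1`;
#' disconnected pairs: `Inf` and 0).
#'
#' @param ps a `patch_set` from [extract_patches], or a list with `patches`
#'   entries carrying `area` and precomputed distances (see `dist_matrix`).
#' @param A_L total landscape area in km^2.
#' @param threshold maximum link distance in km (> 0).
#' @param d_median,p_median dispersal-kernel calibration pair.
#' @param dist_matrix optional precomputed symmetric distance matrix (km);
#'   when supplied, `ps` only needs patch areas.
#' @return A `patch_graph`.
#' @export
build_graph <- function(ps, A_L, threshold, d_median = threshold / 2,
                        p_median = 0.5, dist_matrix = NULL) {
  stopifnot(threshold > 0, A_L > 0, p_median > 0, p_median < 1, d_median > 0)
  n <- length(ps$patches)
  areas <- vapply(ps$patches, `[[`, numeric(1L), "area")
  d <- dist_matrix
  if (is.null(d)) {
    d <- matrix(0, n, n)
    if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- patch_distance(ps, i, j)
  }
  k <- -log(p_median) / d_median
  linked <- d <= threshold
  diag(linked) <- FALSE
  p <- ifelse(linked, exp(-k * d), 0)
  diag(p) <- 1
  l <- hop_distances(linked)
  pstar <- max_product_probability(linked, p)
  structure(list(areas = areas, d = d, linked = linked, l = l, p = p,
                 pstar = pstar, A_L = A_L, k = k, threshold = threshold),
            class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("<patch_graph> %d patches, %d links, A_L = %.4g km^2\n",
              length(x$areas), sum(x$linked) / 2, x$A_L))
  invisible(x)
}

#' Integral index of connectivity
#'
#' `IIC = sum_ij a_i a_j / (1 + l_ij) / A_L^2`; self pairs contribute with
#' `l_ii = 0`, disconnected pairs contribute nothing.
#' @param graph a `patch_graph`.
#' @export
iic <- function(graph) {
  term <- outer(graph$areas, graph$areas) / (1 + graph$l)
  term[!is.finite(graph$l)] <- 0
  sum(term) / graph$A_L^2
}

#' Probability of connectivity
#'
#' `PC = sum_ij a_i a_j p*_ij / A_L^2` with `p*_ii = 1` and 0 for
#' disconnected pairs.
#' @param graph a `patch_graph`.
#' @export
pc <- function(graph) {
  sum(outer(graph$areas, graph$areas) * graph$pstar) / graph$A_L^2
}

# unweighted shortest-path hop counts on the link matrix
hop_distances <- function(linked) {
  g <- igraph::graph_from_adjacency_matrix(linked * 1, mode = "undirected",
                                           diag = FALSE)
  igraph::distances(g)
}

# maximum product probability over all paths = exp(-shortest path on -log p);
# a tiny floor keeps zero-weight edges (p = 1) in the graph
max_product_probability <- function(linked, p) {
  w <- ifelse(linked, pmax(-log(pmax(p, 1e-300)), 1e-12), 0)
  gw <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  pstar <- exp(-igraph::distances(gw))
  diag(pstar) <- 1
  pstar
}

# rebuild the graph without patch i (links and distances are inherited,
# paths through i disappear)
drop_patch <- function(graph, i) {
  keep <- setdiff(seq_along(graph$areas), i)
  linked <- graph$linked[keep, keep, drop = FALSE]
  p <- graph$p[keep, keep, drop = FALSE]
  l <- hop_distances(linked)
  pstar <- max_product_probability(linked, p)
  out <- graph
  out$areas <- graph$areas[keep]
  out$d <- graph$d[keep, keep, drop = FALSE]
  out$linked <- linked; out$l <- l; out$p <- p; out$pstar <- pstar
  out
}

#' Per-patch importance (dIIC, dPC, PI)
#'
#' Leave-one-out percentage drop of each index when a patch is removed:
#' `dX = 100 (X - X_remove) / X`, and `PI = (dIIC + dPC) / 2`.  Removing the
#' sole patch empties the landscape, giving 100 %.
#'
#' @param graph a `patch_graph`.
#' @return Data frame with `patch`, `dIIC`, `dPC`, `PI`.
#' @export
patch_importance <- function(graph) {
  n <- length(graph$areas)
  iic0 <- iic(graph); pc0 <- pc(graph)
  res <- t(vapply(seq_len(n), function(i) {
    if (n == 1L) return(c(100, 100))
    sub <- drop_patch(graph, i)
    c(100 * (iic0 - iic(sub)) / iic0, 100 * (pc0 - pc(sub)) / pc0)
  }, numeric(2L)))
  data.frame(patch = seq_len(n), dIIC = res[, 1L], dPC = res[, 2L],
             PI = (res[, 1L] + res[, 2L]) / 2)
}

#' Rasterize patch importance into a graded connectivity surface
#'
#' Every cell of a patch carries the patch's PI value; non-habitat cells
#' carry 0 (and therefore fall in the lowest class).  Graded into five
#' levels by Jenks breaks.
#'
#' @param ps a `patch_set`.
#' @param pi_values per-patch PI (same order as `ps$patches`).
#' @param template an [esp_raster] giving the output grid.
#' @param labels five class names, lowest first.
#' @return List with `surface` (PI raster) and `classes` ([esp_classes]).
#' @export
connectivity_surface <- function(ps, pi_values, template,
                                 labels = c("lowest", "lower", "medium",
                                            "higher", "highest")) {
  stopifnot(length(pi_values) == length(ps$patches))
  m <- matrix(0, ps$dim[1L], ps$dim[2L])
  for (i in seq_along(ps$patches)) m[ps$patches[[i]]$cells] <- pi_values[i]
  m[is.na(template$values)] <- NA_real_
  surf <- raster_like(template, m)
  list(surface = surf, classes = grade_raster(surf, labels))
}
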