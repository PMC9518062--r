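#' Classify a continuous raster into graded intervals
#'
#' Intervals follow the left-closed, right-open convention `[a, b)`; the last
#' class is closed on both ends, so the upper bound itself belongs to the top
#' class.  Pass `-Inf`/`Inf` as outer breaks for open-ended gradings (e.g. a
#' "> 15000" top class).
#'
#' @param raster an [esp_raster].
#' @param breaks strictly increasing numeric vector of length
#'   `length(labels) + 1`.
#' @param labels class names, lowest first.
#' @return An [esp_classes] raster.
#' @examples
#' r <- esp_raster(matrix(c(100, 600, 20000, 499), 2, 2))
#' classify_raster(r, c(0, 500, 2500, Inf), c("micro", "mild", "severe"))
#' @export
classify_raster <- function(raster, breaks, labels) {
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  if (length(breaks) != length(labels) + 1L)
    stop("need length(labels) + 1 breaks")
  v <- raster$values
  ok <- !is.na(v)
  if (any(v[ok] < breaks[1L] | v[ok] > breaks[length(breaks)]))
    stop("values outside the classification range and no open-ended class")
  code <- matrix(NA_integer_, nrow(v), ncol(v))
  # [a, b) everywhere, but the global maximum closes the last class
  idx <- findInterval(v[ok], breaks, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx > length(labels)] <- length(labels)
  code[ok] <- idx
  esp_classes(code, labels, raster$cell_size, raster$origin, raster$nodata)
}

#' Jenks natural-breaks class limits
#'
#' Fisher's exact dynamic programme on (a sample of) the data: minimises
#' within-class sum of squared deviations.  Used as the default grading for
#' the five-level importance / sensitivity / connectivity / security maps.
#'
#' @param values numeric vector (NAs dropped).
#' @param k number of classes.
#' @param sample_n cap on the number of sorted values entering the O(k n^2)
#'   programme; larger inputs are quantile-thinned first.
#' @return Numeric vector of `k + 1` break values spanning the data range.
#' @export
jenks_breaks <- function(values, k = 5L, sample_n = 1500L) {
  x <- sort(values[!is.na(values)])
  if (!length(x)) stop("no data to classify")
  if (length(unique(x)) <= k) {
    u <- unique(x)
    # degenerate: fewer distinct values than classes — midpoint breaks
    br <- c(u[1L], (u[-1L] + u[-length(u)]) / 2, u[length(u)])
    while (length(br) < k + 1L) br <- c(br, br[length(br)])
    return(br[1:(k + 1L)])
  }
  if (length(x) > sample_n)
    x <- stats::quantile(x, probs = seq(0, 1, length.out = sample_n),
                         names = FALSE, type = 7)
  n <- length(x)
  csum <- cumsum(x); csum2 <- cumsum(x^2)
  ssq <- function(i, j) { # within-class SSE for x[i..j]
    s <- csum[j] - if (i > 1L) csum[i - 1L] else 0
    s2 <- csum2[j] - if (i > 1L) csum2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  cost <- matrix(Inf, k, n); from <- matrix(1L, k, n)
  for (j in seq_len(n)) cost[1L, j] <- ssq(1L, j)
  for (c in 2:k) {
    for (j in c:n) {
      best <- Inf; arg <- c
      for (i in c:j) {
        v <- cost[c - 1L, i - 1L] + ssq(i, j)
        if (v < best) { best <- v; arg <- i }
      }
      cost[c, j] <- best; from[c, j] <- arg
    }
  }
  cuts <- integer(k - 1L); j <- n
  for (c in k:2) { i <- from[c, j]; cuts[c - 1L] <- i - 1L; j <- i - 1L }
  # break between last member of one class and first of the next
  c(x[1L], (x[cuts] + x[cuts + 1L]) / 2, x[n])
}

#' Classify into k graded levels
#'
#' Convenience wrapper: computes breaks by Jenks (default) or quantiles and
#' applies [classify_raster].
#' @param raster an [esp_raster].
#' @param labels class names (their number sets `k`).
#' @param method `"jenks"` or `"quantile"`.
#' @export
grade_raster <- function(raster, labels, method = c("jenks", "quantile")) {
  method <- match.arg(method)
  v <- raster$values[!is.na(raster$values)]
  br <- if (method == "jenks") jenks_breaks(v, length(labels))
        else unique(stats::quantile(v, seq(0, 1, length.out = length(labels) + 1L),
                                    names = FALSE))
  br <- unique(br)
  if (length(br) < length(labels) + 1L) {
    # collapse of distinct breaks: pad with epsilon steps to keep k classes
    eps <- diff(range(v)) * 1e-9 + 1e-12
    while (length(br) < length(labels) + 1L)
      br <- sort(c(br, br[length(br)] + eps * (length(br))))
  }
  classify_raster(raster, br, labels)
}

#' Class area accounting
#'
#' The bread-and-butter reporting table: per-class area in km^2 and share of
#' the total, the layout of the paper-style graded-area tables.
#'
#' @param categorical an [esp_classes] raster, or `NULL` when `areas` are
#'   supplied directly.
#' @param total_area domain total in km^2; defaults to the summed class areas.
#' @param areas optional externally supplied per-class areas (named or in
#'   label order) replacing the cell count.
#' @param labels class labels when `areas` are supplied without a raster.
#' @param digits rounding for the printed columns (areas and shares).
#' @return Data frame with columns `label`, `area_km2`, `share_pct`.
#' @export
class_area_table <- function(categorical = NULL, total_area = NULL,
                             areas = NULL, labels = NULL, digits = 2L) {
  if (is.null(areas)) {
    stopifnot(inherits(categorical, "esp_classes"))
    labels <- categorical$labels
    counts <- tabulate(categorical$values[!is.na(categorical$values)],
                       nbins = length(labels))
    areas <- counts * cell_area(categorical)
  } else {
    if (is.null(labels)) labels <- names(areas)
    if (is.null(labels)) labels <- paste0("class_", seq_along(areas))
  }
  if (is.null(total_area)) total_area <- sum(areas)
  if (total_area <= 0) stop("total area must be positive")
  data.frame(label = labels,
             area_km2 = round(areas, digits),
             share_pct = round(100 * areas / total_area, digits),
             stringsAsFactors = FALSE)
}

#' Count shares and densities per class
#'
#' For event inventories (e.g. geological-hazard points) tabulated against
#' graded class areas: per-class count share (% of all events) and density
#' (events per km^2).
#'
#' @param counts_per_class integer event counts, one per class.
#' @param areas_per_class class areas in km^2.
#' @param labels optional class labels.
#' @param digits rounding for percentage columns; densities keep 4 decimals.
#' @return Data frame with `label`, `area_km2`, `count`, `count_share_pct`,
#'   `density_per_km2`.
#' @export
rate_statistics <- function(counts_per_class, areas_per_class, labels = NULL,
                            digits = 2L) {
  stopifnot(length(counts_per_class) == length(areas_per_class))
  if (any(areas_per_class == 0 & counts_per_class > 0))
    stop("nonzero count in a zero-area class")
  if (is.null(labels)) labels <- paste0("class_", seq_along(counts_per_class))
  total <- sum(counts_per_class)
  share <- if (total > 0) 100 * counts_per_class / total else rep(0, length(counts_per_class))
  dens <- ifelse(areas_per_class > 0, counts_per_class / areas_per_class, 0)
  data.frame(label = labels,
             area_km2 = round(areas_per_class, digits),
             count = counts_per_class,
             count_share_pct = round(share, digits),
             density_per_km2 = round(dens, 4L),
             stringsAsFactors = FALSE)
}

#' Erosion amount budget per intensity class
#'
#' Amount per class = class area (km^2) x mean erosion modulus
#' (t/(km^2 a)); shares are against the summed total.
#'
#' @param areas_per_class km^2 per class.
#' @param mean_modulus_per_class t/(km^2 a) per class.
#' @param labels optional class labels.
#' @return Data frame with `label`, `area_km2`, `mean_modulus`, `amount_t`,
#'   `amount_share_pct`, plus a `total_t` attribute.
#' @export
erosion_budget <- function(areas_per_class, mean_modulus_per_class,
                           labels = NULL) {
  stopifnot(length(areas_per_class) == length(mean_modulus_per_class))
  if (any(areas_per_class < 0) || any(mean_modulus_per_class < 0))
    stop("areas and moduli must be non-negative")
  if (is.null(labels)) labels <- paste0("class_", seq_along(areas_per_class))
  amount <- areas_per_class * mean_modulus_per_class
  total <- sum(amount)
  out <- data.frame(label = labels,
                    area_km2 = round(areas_per_class, 2L),
                    mean_modulus = round(mean_modulus_per_class, 2L),
                    amount_t = round(amount, 2L),
                    amount_share_pct = round(if (total > 0) 100 * amount / total
                                             else rep(0, length(amount)), 2L),
                    stringsAsFactors = FALSE)
  attr(out, "total_t") <- total
  out
}
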