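# The four ecosystem-service layers (water conservation, soil conservation,
# carbon sequestration, habitat quality) and their fusion into the
# five-level importance surface.

check_unit_interval <- function(r, name) {
  v <- r$values
  if (any(v[!is.na(v)] < 0 | v[!is.na(v)] > 1))
    stop(name, " must lie in [0, 1]")
  invisible(TRUE)
}

#' Water conservation capacity
#'
#' `WC = NPP_mean * F_sic * F_pre * (1 - F_slo)`: productivity scaled by
#' soil infiltration, normalised precipitation and the complement of the
#' slope factor (steeper slopes hold less water).
#'
#' @param npp_mean annual mean NPP raster.
#' @param f_sic soil-infiltration factor raster in [0, 1].
#' @param f_pre normalised annual-precipitation factor raster in [0, 1].
#' @param f_slo slope factor raster in [0, 1].
#' @return An [esp_raster], non-negative.
#' @export
water_conservation <- function(npp_mean, f_sic, f_pre, f_slo) {
  check_unit_interval(f_sic, "F_sic"); check_unit_interval(f_pre, "F_pre")
  check_unit_interval(f_slo, "F_slo")
  raster_map(function(n, si, pr, sl) n * si * pr * (1 - sl),
             npp_mean, f_sic, f_pre, f_slo)
}

#' Soil conservation capacity
#'
#' `SC = NPP_mean * (1 - K) * (1 - F_slo)` with the erodibility factor K
#' min-max normalised to [0, 1] first (pass `normalize = FALSE` if K is
#' already normalised).
#'
#' @param npp_mean annual mean NPP raster.
#' @param k soil-erodibility raster.
#' @param f_slo slope factor raster in [0, 1].
#' @param normalize min-max normalise `k` before use.
#' @return An [esp_raster], non-negative.
#' @export
soil_conservation <- function(npp_mean, k, f_slo, normalize = TRUE) {
  check_unit_interval(f_slo, "F_slo")
  if (normalize) k <- suppressWarnings(normalize_raster(k))
  check_unit_interval(k, "K (after normalization)")
  raster_map(function(n, kk, sl) n * (1 - kk) * (1 - sl), npp_mean, k, f_slo)
}

#' Carbon sequestration capacity
#'
#' Dry matter production is `NPP / 0.45` (carbon is ~45 % of dry matter);
#' each gram of dry matter fixes 1.63 g CO2 and releases 1.2 g O2, so
#' `CS = NPP / 0.45 * (1.2 + 1.63)`.
#'
#' @param npp_mean annual mean NPP raster (g C), non-negative.
#' @param carbon_fraction carbon share of dry matter (default 0.45).
#' @param gas_constant CO2 + O2 mass per g dry matter (default 1.2 + 1.63).
#' @return An [esp_raster].
#' @export
carbon_sequestration <- function(npp_mean, carbon_fraction = 0.45,
                                 gas_constant = 1.2 + 1.63) {
  if (any(npp_mean$values < 0, na.rm = TRUE)) stop("NPP must be non-negative")
  raster_map(function(n) n / carbon_fraction * gas_constant, npp_mean)
}

#' Habitat-threat model
#'
#' Parameters of the half-saturation habitat-quality model: suitability
#' `H_j` per land-use class, threat sources with maximum impact distance
#' (km), weight and linear distance decay, the half-saturation constant `k`,
#' and per-habitat sensitivity to each threat.  Defaults treat construction
#' (strong, far-reaching) and farmland (weaker, shorter) as threats, natural
#' covers as habitat.
#'
#' @param h named habitat suitability per land-use class, in [0, 1].
#' @param threats data frame with columns `source` (land-use label),
#'   `max_dist` (km) and `weight` in [0, 1].
#' @param k half-saturation constant (> 0).
#' @param sensitivity matrix [habitat class x threat] in [0, 1]; default 1
#'   for every natural class.
#' @export
habitat_model <- function(h = c(forest = 1, grassland = 0.8, farmland = 0.4,
                                water = 0.9, unutilized = 0.3,
                                construction = 0),
                          threats = data.frame(
                            source = c("construction", "farmland"),
                            max_dist = c(3, 1.5),
                            weight = c(1, 0.6)),
                          k = 0.5,
                          sensitivity = NULL) {
  stopifnot(all(h >= 0 & h <= 1), k > 0, all(threats$max_dist > 0),
            all(threats$weight >= 0 & threats$weight <= 1))
  if (is.null(sensitivity)) {
    sensitivity <- matrix(1, length(h), nrow(threats),
                          dimnames = list(names(h), threats$source))
    sensitivity[names(h) %in% threats$source, ] <- 0  # sources unthreatened
  }
  structure(list(h = h, threats = threats, k = k, sensitivity = sensitivity),
            class = "habitat_model")
}

#' Habitat quality (half-saturation decay)
#'
#' `Q = H_j * (1 - D^2 / (D^2 + k^2))` where the threat level `D` is the
#' weighted, linearly distance-decayed, sensitivity-scaled sum over threat
#' sources: `D = sum_t w_t * max(0, 1 - d_t / maxdist_t) * s(j, t)`.
#' `Q = H_j` where no threat reaches; `Q = H_j / 2` exactly at `D = k`.
#'
#' @param landuse an [esp_classes] land-use raster.
#' @param model a [habitat_model].
#' @return List with `quality` and `threat` rasters.
#' @export
habitat_quality <- function(landuse, model) {
  labs <- landuse$labels
  if (!all(labs %in% names(model$h)))
    stop("habitat model lacks suitability for: ",
         paste(setdiff(labs, names(model$h)), collapse = ", "))
  lu <- landuse$values
  d_total <- matrix(0, nrow(lu), ncol(lu))
  for (t in seq_len(nrow(model$threats))) {
    src <- model$threats$source[t]
    code <- match(src, labs)
    src_mask <- raster_like(landuse, ifelse(!is.na(lu) & lu == code, 1, 0))
    if (!any(src_mask$values == 1)) next
    d <- mask_distance(src_mask)$values
    decay <- pmax(0, 1 - d / model$threats$max_dist[t])
    sens <- model$sensitivity[labs, src][lu]
    sens <- matrix(sens, nrow(lu), ncol(lu))
    d_total <- d_total + model$threats$weight[t] * decay * sens
  }
  hmap <- matrix(model$h[labs][lu], nrow(lu), ncol(lu))
  q <- hmap * (1 - d_total^2 / (d_total^2 + model$k^2))
  q[is.na(lu)] <- NA_real_
  d_total[is.na(lu)] <- NA_real_
  list(quality = raster_like(landuse, q),
       threat = raster_like(landuse, d_total))
}

#' Fuse the four service layers into the importance surface
#'
#' Each layer is min-max normalised to [0, 1]; the composite is their
#' weighted mean (equal weights by default) and is graded into five
#' importance levels.
#'
#' @param wc,sc,cs,hq the four aligned service rasters.
#' @param weights length-4 non-negative weights, normalised internally.
#' @param method classification method for [grade_raster].
#' @return List with `composite` raster, `classes` five-level
#'   [esp_classes], and the normalised `layers`.
#' @export
importance_index <- function(wc, sc, cs, hq, weights = rep(1, 4),
                             method = "jenks") {
  check_aligned(wc, sc, cs, hq)
  stopifnot(length(weights) == 4L, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  layers <- lapply(list(wc = wc, sc = sc, cs = cs, hq = hq), normalize_raster)
  comp <- raster_map(function(a, b, c, d)
    weights[1L] * a + weights[2L] * b + weights[3L] * c + weights[4L] * d,
    layers$wc, layers$sc, layers$cs, layers$hq)
  labels <- c("least important", "less important", "medium importance",
              "more important", "most important")
  list(composite = comp, classes = grade_raster(comp, labels, method),
       layers = layers)
}
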