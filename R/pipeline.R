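#' Run the full ecological-security-pattern pipeline on a scene
#'
#' Chains every stage on an aligned raster stack (typically a
#' [generate_scene] result): ecosystem-service importance, eco-environmental
#' sensitivity (RUSLE + CF), landscape connectivity, the comprehensive
#' security surface, source/point identification, the corrected resistance
#' surface, MCR corridors and typed ecological nodes, plus the summary
#' tables behind each stage.
#'
#' @param scene a `synthetic_scene` (or any list with the same layers).
#' @param security_weights length-3 weights for importance / sensitivity /
#'   connectivity (default equal).
#' @param min_source_area minimum source-patch area in km^2; the default
#'   (0.5 % of the domain) scales the threshold to the scene instead of
#'   assuming a prefecture-sized domain.
#' @param habitat_classes land-use labels forming habitat patches.
#' @param link_threshold patch-link distance threshold in km.
#' @param sic_table per-class soil-infiltration factors.
#' @param verbose log stage boundaries with `message()`.
#' @return An `esp_result` list with every intermediate surface, the
#'   corridor and node sets, and `tables` (class areas, corridor and node
#'   accounting).
#' @export
esp_pipeline <- function(scene,
                         security_weights = rep(1 / 3, 3),
                         min_source_area = NULL,
                         habitat_classes = c("forest", "grassland"),
                         link_threshold = 2,
                         sic_table = c(forest = 0.9, grassland = 0.7,
                                       farmland = 0.5, water = 0.8,
                                       unutilized = 0.3, construction = 0.1),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dem <- scene$dem; landuse <- scene$landuse
  domain_area <- sum(!is.na(dem$values)) * cell_area(dem)
  if (is.null(min_source_area)) min_source_area <- 0.005 * domain_area
  say("ESP pipeline: %d x %d cells (%.4g km^2), seed %s",
      nrow(dem$values), ncol(dem$values), domain_area,
      if (!is.null(scene$config$seed)) scene$config$seed else "unknown")

  # --- stage 1: ecosystem-service importance ------------------------------
  say("stage 1/6: ecosystem-service importance")
  slope <- slope_aspect(dem)$slope
  f_slo <- normalize_raster(slope)
  annual_rain <- raster_like(dem, Reduce(`+`, lapply(scene$rainfall, function(y)
    Reduce(`+`, lapply(y, as.matrix)))) / length(scene$rainfall))
  f_pre <- normalize_raster(annual_rain)
  lu <- landuse$values
  f_sic <- raster_like(dem, matrix(sic_table[landuse$labels][lu], nrow(lu)))
  k_fac <- soil_erodibility(scene$soil$Wg, scene$soil$Wp, scene$soil$Wc,
                            scene$soil$Wo)
  wc <- water_conservation(scene$npp, f_sic, f_pre, f_slo)
  sc <- soil_conservation(scene$npp, k_fac, f_slo)
  cs <- carbon_sequestration(scene$npp)
  hq <- habitat_quality(landuse, habitat_model())$quality
  importance <- importance_index(wc, sc, cs, hq)

  # --- stage 2: eco-environmental sensitivity -----------------------------
  say("stage 2/6: eco-environmental sensitivity (RUSLE + CF)")
  r_fac <- rainfall_erosivity(scene$rainfall)
  ls <- ls_factor(dem)
  cp <- cp_factors(landuse)
  erosion <- soil_loss(r_fac, k_fac, ls, cp$c, cp$p)
  river_dist <- mask_distance(scene$rivers$mask)
  road_dist <- burn_distance(scene$roads, dem)
  aspect <- slope_aspect(dem)$aspect
  aspect$values[is.na(aspect$values)] <- 0
  cf_layers <- list(
    slope = cf_factor(scene$hazards, slope),
    aspect = cf_factor(scene$hazards, aspect),
    elevation = cf_factor(scene$hazards, dem),
    river_dist = cf_factor(scene$hazards, river_dist),
    ndvi = cf_factor(scene$hazards, scene$ndvi),
    road_dist = cf_factor(scene$hazards, road_dist),
    landuse = cf_factor(scene$hazards, landuse),
    rainfall = cf_factor(scene$hazards, annual_rain))
  geohazard <- geohazard_sensitivity(cf_layers, dem)
  sensitivity <- combined_sensitivity(erosion$classes, geohazard$classes)

  # --- stage 3: landscape connectivity ------------------------------------
  say("stage 3/6: landscape connectivity")
  hab_codes <- match(habitat_classes, landuse$labels)
  habitat <- raster_like(dem, ifelse(!is.na(lu) & lu %in% hab_codes, 1, 0))
  patches <- extract_patches(habitat, min_area = 4 * cell_area(dem))
  graph <- build_graph(patches, A_L = domain_area, threshold = link_threshold)
  imp_tab <- patch_importance(graph)
  connectivity <- connectivity_surface(patches, imp_tab$PI, dem)

  # --- stage 4: comprehensive security + sources --------------------------
  say("stage 4/6: security surface and ecological sources")
  security <- security_index(importance$classes, sensitivity$classes,
                             connectivity$classes, security_weights)
  sources <- identify_sources(security$classes, min_area = min_source_area)

  # --- stage 5: resistance surface + corridors ----------------------------
  say("stage 5/6: resistance surface and MCR corridors")
  resist <- resistance_surface(landuse, scene$nightlight, dem)
  rgraph <- resistance_graph(resist$elevation_adj)
  src_cells <- unlist(lapply(c(sources$primary$patches,
                               sources$secondary$patches),
                             `[[`, "cells"))
  costdist <- cost_distance(resist$elevation_adj, src_cells, graph = rgraph)
  corridors <- least_cost_corridors(resist$elevation_adj, sources$points,
                                    graph = rgraph)

  # --- stage 6: ecological nodes ------------------------------------------
  say("stage 6/6: ridge/valley lines and ecological nodes")
  rv <- ridge_valley_lines(resist$elevation_adj)
  nodes <- ecological_nodes(corridors, rv$ridge, rv$valley,
                            roads = scene$roads, rivers = scene$rivers$lines,
                            template = dem)

  tables <- esp_tables(importance, sensitivity, erosion, geohazard,
                       connectivity, security, sources, corridors, nodes,
                       domain_area)
  structure(list(importance = importance, erosion = erosion,
                 geohazard = geohazard, sensitivity = sensitivity,
                 cf_layers = cf_layers, patches = patches,
                 patch_graph = graph, patch_importance = imp_tab,
                 connectivity = connectivity, security = security,
                 sources = sources, resistance = resist,
                 cost_distance = costdist, corridors = corridors,
                 ridge_valley = rv, nodes = nodes, tables = tables,
                 domain_area = domain_area),
            class = "esp_result")
}

esp_tables <- function(importance, sensitivity, erosion, geohazard,
                       connectivity, security, sources, corridors, nodes,
                       domain_area) {
  lv <- vapply(corridors$corridors, `[[`, character(1L), "level")
  len <- vapply(corridors$corridors, `[[`, numeric(1L), "length_km")
  corridor_tab <- data.frame(
    level = c("primary", "secondary"),
    n = c(sum(lv == "primary"), sum(lv == "secondary")),
    total_length_km = c(round(sum(len[lv == "primary"]), 2L),
                        round(sum(len[lv == "secondary"]), 2L)))
  node_tab <- as.data.frame(table(factor(nodes$attributes$type,
                                         levels = c("strategic", "breaking",
                                                    "respite"))),
                            stringsAsFactors = FALSE)
  names(node_tab) <- c("type", "n")
  src_area <- function(ps) if (is.null(ps)) 0 else
    sum(vapply(ps$patches, `[[`, numeric(1L), "area"))
  source_tab <- data.frame(
    level = c("primary", "secondary"),
    area_km2 = round(c(src_area(sources$primary), src_area(sources$secondary)), 2L))
  source_tab$share_pct <- round(100 * source_tab$area_km2 / domain_area, 2L)
  list(importance = class_area_table(importance$classes, domain_area),
       erosion = class_area_table(erosion$classes, domain_area),
       geohazard = class_area_table(geohazard$classes, domain_area),
       sensitivity = class_area_table(sensitivity$classes, domain_area),
       connectivity = class_area_table(connectivity$classes, domain_area),
       security = class_area_table(security$classes, domain_area),
       sources = source_tab, corridors = corridor_tab, nodes = node_tab)
}

#' @export
print.esp_result <- function(x, ...) {
  cat("<esp_result>\n")
  cat("  sources:\n"); print(x$tables$sources)
  cat("  corridors:\n"); print(x$tables$corridors)
  cat("  nodes:\n"); print(x$tables$nodes)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Rasters (security score/classes, base and corrected resistance, cost
#' distance) in the chosen grid format, sources/points/corridors/nodes as
#' GeoJSON, and every summary table as CSV.
#'
#' @param result an `esp_result`.
#' @param outdir output directory.
#' @param format raster format for [write_raster].
#' @export
write_esp_result <- function(result, outdir, format = "ascii") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "geotiff") "tif" else "asc"
  wr <- function(r, name)
    write_raster(r, file.path(outdir, paste0(name, ".", ext)), format)
  wr(result$security$score, "security_score")
  cls <- result$security$classes
  wr(esp_raster(cls$values + 0, cls$cell_size, cls$origin), "security_class")
  wr(result$resistance$base, "resistance_base")
  wr(result$resistance$nightlight_adj, "resistance_nightlight")
  wr(result$resistance$elevation_adj, "resistance_elevation")
  wr(result$cost_distance, "cost_distance")
  write_geojson(result$sources$points, file.path(outdir, "points.geojson"))
  write_geojson(corridors_as_vectors(result$corridors),
                file.path(outdir, "corridors.geojson"))
  if (length(result$nodes$geoms))
    write_geojson(result$nodes, file.path(outdir, "nodes.geojson"))
  for (nm in names(result$tables))
    write_class_table(result$tables[[nm]],
                      file.path(outdir, paste0("table_", nm, ".csv")))
  invisible(outdir)
}
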