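five <- c("lowest", "lower", "medium", "higher", "highest")
cls5 <- function(v, nr = 2, cell = 1) esp_classes(matrix(v, nr, length(v) / nr),
                                                  five, cell_size = cell)

test_that("security index: extremes, polarity symmetry, per-cell oracle", {
  best <- security_index(cls5(rep(5L, 4)), cls5(rep(1L, 4)), cls5(rep(5L, 4)))
  expect_true(all(best$score$values == 1))
  expect_true(all(best$classes$values == 5L))
  # flipping the sensitivity rank r -> 6 - r with polarity flipped is identity
  set.seed(61)
  s <- matrix(sample(1:5, 36, TRUE), 6)
  i <- matrix(sample(1:5, 36, TRUE), 6)
  c_ <- matrix(sample(1:5, 36, TRUE), 6)
  a <- security_index(esp_classes(i, five), esp_classes(s, five),
                      esp_classes(c_, five))$score$values
  # oracle: direct weighted sum with reversed sensitivity polarity
  oracle <- ((i - 1) / 4 + (1 - (s - 1) / 4) + (c_ - 1) / 4) / 3
  expect_equal(a, oracle, tolerance = 1e-12)
  b <- security_index(esp_classes(i, five), esp_classes(6L - s, five),
                      esp_classes(c_, five))$score$values
  expect_equal(b, ((i - 1) / 4 + ((s - 1) / 4) + (c_ - 1) / 4) / 3,
               tolerance = 1e-12)
  expect_error(security_index(cls5(rep(1L, 4)), cls5(rep(1L, 4)),
                              cls5(rep(1L, 4)), weights = c(1, 1, 1)),
               "sum to 1")
})

test_that("source identification: centroids, guard, threshold monotonicity", {
  m <- matrix(1L, 12, 12)
  m[3:7, 3:7] <- 5L
  sec <- esp_classes(m, five, cell_size = 1)
  src <- identify_sources(sec, min_area = 4)
  expect_length(src$primary$patches, 1)
  expect_null(src$secondary)
  # centroid of the 5x5 block at rows/cols 3..7 -> cell (5, 5)
  expect_equal(src$points$geoms[[1]][1, ], c(x = 4.5, y = 7.5))
  expect_identical(src$points$attributes$level, "primary")
  expect_error(identify_sources(sec, min_area = 100), "threshold")
  # patch count never increases as the threshold grows
  sc <- small_scene()
  res <- esp_pipeline(sc, verbose = FALSE)
  counts <- vapply(c(0.1, 0.5, 1, 2, 5), function(thr) {
    s <- tryCatch(identify_sources(res$security$classes, min_area = thr),
                  error = function(e) NULL)
    if (is.null(s)) 0L
    else length(s$primary$patches) + length(s$secondary$patches)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  # points lie inside their patches (concave-safe snapping)
  pts <- res$sources$points
  for (idx in seq_along(pts$geoms)) {
    lvl <- pts$attributes$level[idx]
    ps <- if (lvl == "primary") res$sources$primary else res$sources$secondary
    patch <- ps$patches[[which(vapply(ps$patches, `[[`, integer(1), "id") ==
                               pts$attributes$patch[idx])[1]]]
    rc <- espattern:::xy_cell(sc$dem, pts$geoms[[idx]][1, 1],
                              pts$geoms[[idx]][1, 2])
    cell <- (rc[1, 2] - 1L) * nrow(sc$dem$values) + rc[1, 1]
    expect_true(cell %in% patch$cells)
  }
})

test_that("resistance surface: lookup, correction identities and ratios", {
  labs <- c("forest", "grassland", "farmland", "water", "unutilized",
            "construction")
  lu <- esp_classes(matrix(c(1L, 6L, 3L, 3L), 2, 2), labs)
  base_only <- resistance_surface(lu)
  expect_equal(base_only$elevation_adj$values,
               matrix(c(1, 500, 30, 30), 2, 2))
  # NL_i = NL_a and DEM_i = DEM_a (uniform per class): corrections are identity
  nl <- raster_like(base_only$base, matrix(c(3, 8, 5, 5), 2, 2))
  dem <- raster_like(base_only$base, matrix(c(900, 1200, 700, 700), 2, 2))
  rs <- resistance_surface(lu, nl, dem)
  expect_equal(rs$elevation_adj$values, base_only$base$values)
  # NL_i = 2 NL_a on farmland (values 4 and 0 -> class mean 2): R_i = 60
  nl2 <- raster_like(base_only$base, matrix(c(3, 8, 4, 0), 2, 2))
  rs2 <- resistance_surface(lu, nl2)
  expect_equal(rs2$nightlight_adj$values[1, 2], 2 * 30)
  expect_equal(rs2$nightlight_adj$values[2, 2], 0)
  # zero-mean class keeps the base coefficient (unlit-class guard)
  nl3 <- raster_like(base_only$base, matrix(c(0, 8, 4, 4), 2, 2))
  rs3 <- resistance_surface(lu, nl3)
  expect_equal(rs3$nightlight_adj$values[1, 1], 1)
  expect_error(resistance_surface(esp_classes(matrix(1L, 1, 1), "swamp")),
               "missing")
})

test_that("cost distance: closed form, Dijkstra oracle, metric properties", {
  # uniform resistance, two points 4 cardinal cells apart
  r <- esp_raster(matrix(3, 7, 7), cell_size = 0.5)
  cd <- cost_distance(r, source_cells = (3 - 1) * 7 + 4)  # row 4, col 3
  expect_equal(cd$values[4, 7], 4 * 3 * 0.5)
  expect_equal(cd$values[4, 3], 0)
  # random grids vs the textbook oracle
  set.seed(71)
  for (i in 1:5) {
    rm <- matrix(runif(100, 0.5, 10), 10, 10)
    rr <- esp_raster(rm, cell_size = 0.2)
    src <- c(sample(10, 1), sample(10, 1))
    cd2 <- cost_distance(rr, source_cells = (src[2] - 1) * 10 + src[1])
    oracle <- dijkstra_oracle(rm, 0.2, src)
    expect_equal(cd2$values, oracle, tolerance = 1e-10)
  }
  # metric: non-negative, zero exactly on sources, triangle inequality
  rm <- matrix(runif(64, 1, 5), 8, 8)
  rr <- esp_raster(rm, cell_size = 1)
  g <- espattern:::resistance_graph(rr)
  pts <- c(3, 30, 55)
  dmat <- igraph::distances(g, v = pts, to = pts)
  expect_true(all(dmat >= 0))
  expect_equal(unname(diag(dmat)), rep(0, 3))
  expect_lte(dmat[1, 3], dmat[1, 2] + dmat[2, 3] + 1e-12)
  expect_equal(dmat, t(dmat))   # endpoint symmetry
})

test_that("corridors: obstacle avoidance, dedup and resistance monotonicity", {
  # high-resistance wall with one gap: the corridor threads the gap
  rm <- matrix(1, 9, 9)
  rm[, 5] <- 1000
  rm[5, 5] <- 1
  rr <- esp_raster(rm, cell_size = 1)
  pts <- esp_vectors("points", list(cbind(2.5, 4.5), cbind(8.5, 4.5)))
  cset <- least_cost_corridors(rr, pts, pairing = "pairs")
  expect_length(cset$corridors, 1)
  path_rc <- cbind(((cset$corridors[[1]]$cells - 1) %% 9) + 1,
                   ((cset$corridors[[1]]$cells - 1) %/% 9) + 1)
  expect_true(any(path_rc[, 1] == 5 & path_rc[, 2] == 5))
  # lowering any cell's resistance never increases the corridor cost
  set.seed(73)
  rm2 <- matrix(runif(49, 1, 8), 7, 7)
  rr2 <- esp_raster(rm2, cell_size = 1)
  p2 <- esp_vectors("points", list(cbind(0.5, 0.5), cbind(6.5, 6.5)))
  base_cost <- least_cost_corridors(rr2, p2, pairing = "pairs")$corridors[[1]]$mcr
  for (k in sample(49, 8)) {
    rm3 <- rm2; rm3[k] <- rm3[k] * 0.3
    cost3 <- least_cost_corridors(esp_raster(rm3, cell_size = 1), p2,
                                  pairing = "pairs")$corridors[[1]]$mcr
    expect_lte(cost3, base_cost + 1e-12)
  }
  # corridor cost equals the pairwise cost-distance (consistency invariant)
  co <- least_cost_corridors(rr2, p2, pairing = "pairs")$corridors[[1]]
  cd <- cost_distance(rr2, source_cells = co$cells[1])
  expect_equal(cd$values[co$cells[length(co$cells)]], co$mcr,
               tolerance = 1e-10)
})

test_that("ridge and valley lines: tent profiles and inflow oracle", {
  # 1-D tent: crest column is a ridge, trough of the inverted tent a valley
  prof <- c(1, 2, 3, 4, 5, 4, 3, 2, 1)
  tent <- esp_raster(matrix(rep(prof, each = 7), 7, 9), cell_size = 1)
  rv <- ridge_valley_lines(tent)
  expect_true(all(rv$ridge$values[, 5] == 1))
  expect_true(all(rv$ridge$values[, c(2, 8)] == 0))
  inv <- esp_raster(-tent$values, cell_size = 1)
  rv2 <- ridge_valley_lines(inv)
  expect_true(all(rv2$valley$values[, 5] == 1))
  # duality: ridge of f == valley of -f
  expect_identical(rv$ridge$values, rv2$valley$values)
  # random smooth surface: ridge cells receive no inflow under an
  # independently recomputed steepest-descent assignment
  set.seed(79)
  z <- matrix(rnorm(15 * 15), 15, 15)
  z <- (z + z[c(1, 1:14), ] + z[, c(1, 1:14)] + z[c(2:15, 15), ] +
        z[, c(2:15, 15)]) / 5
  zr <- esp_raster(z, cell_size = 1)
  ridge <- ridge_valley_lines(zr)$ridge$values
  dr <- c(0, 1, 1, 1, 0, -1, -1, -1); dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  receives <- matrix(FALSE, 15, 15)
  for (r in 1:15) for (c in 1:15) {
    best <- 0; arg <- 0
    for (k in 1:8) {
      r2 <- r + dr[k]; c2 <- c + dc[k]
      if (r2 < 1 || r2 > 15 || c2 < 1 || c2 > 15) next
      drop <- (z[r, c] - z[r2, c2]) / ifelse(dr[k] != 0 & dc[k] != 0, sqrt(2), 1)
      if (drop > best) { best <- drop; arg <- k }
    }
    if (arg > 0) receives[r + dr[arg], c + dc[arg]] <- TRUE
  }
  expect_identical(ridge == 1, !receives)
})

test_that("ecological nodes: typed intersections with merging", {
  tpl <- esp_raster(matrix(1, 10, 10), cell_size = 1)
  empty_mask <- raster_like(tpl, 0)
  # hand-built corridor: straight horizontal path through row 5
  corridor <- structure(list(corridors = list(list(
    id = 1L, from = 1L, to = 2L, level = "primary",
    cells = (0:9) * 10 + 5,
    polyline = cbind(0.5 + 0:9, 5.5), mcr = 1, length_km = 9)),
    cell_size = 1, dim = c(10L, 10L)), class = "corridor_set")
  # one vertical road crossing once -> exactly one breaking point
  road <- esp_vectors("polylines", list(cbind(c(4.2, 4.2), c(0, 10))))
  nodes <- ecological_nodes(corridor, empty_mask, empty_mask, roads = road,
                            template = tpl)
  expect_identical(nodes$attributes$type, "breaking")
  expect_equal(nrow(nodes$attributes), 1)
  # two crossings -> two breaking points (geometric oracle: count = k)
  zig <- esp_vectors("polylines",
                     list(cbind(c(2.2, 2.2), c(0, 10)),
                          cbind(c(7.7, 7.7), c(0, 10))))
  n2 <- ecological_nodes(corridor, empty_mask, empty_mask, roads = zig,
                         template = tpl)
  expect_equal(sum(n2$attributes$type == "breaking"), 2)
  # corridor disjoint from all masks and lines -> empty node set
  far <- esp_vectors("polylines", list(cbind(c(0, 10), c(9.5, 9.5))))
  n3 <- ecological_nodes(corridor, empty_mask, empty_mask, roads = far,
                         template = tpl)
  expect_length(n3$geoms, 0)
  # ridge mask intersection yields strategic points; adjacency merges cells
  ridge <- raster_like(tpl, 0)
  ridge$values[5, 6:7] <- 1   # two adjacent corridor cells on the ridge
  n4 <- ecological_nodes(corridor, ridge, empty_mask, template = tpl)
  expect_identical(n4$attributes$type, "strategic")
  expect_equal(nrow(n4$attributes), 1)
})
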