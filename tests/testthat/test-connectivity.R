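habitat_raster <- function(m, cell = 1) esp_raster(m, cell_size = cell)

test_that("patch extraction: blocks, connectivity rules, flood-fill oracle", {
  m <- matrix(0, 8, 8)
  m[2:4, 2:4] <- 1
  ps <- extract_patches(habitat_raster(m, cell = 0.5))
  expect_length(ps$patches, 1)
  expect_equal(ps$patches[[1]]$area, 9 * 0.25)
  # diagonal-only touch: one patch under 8-connectivity, two under 4
  m2 <- matrix(0, 6, 6)
  m2[2, 2] <- 1; m2[3, 3] <- 1
  expect_length(extract_patches(habitat_raster(m2), connectivity_rule = 8L)$patches, 1)
  expect_length(extract_patches(habitat_raster(m2), connectivity_rule = 4L)$patches, 2)
  # random rasters vs recursive flood-fill oracle, both rules
  set.seed(51)
  for (i in 1:5) {
    mr <- matrix(rbinom(400, 1, 0.35), 20, 20)
    if (!any(mr == 1)) next
    for (rule in c(4L, 8L)) {
      expect_length(extract_patches(habitat_raster(mr),
                                    connectivity_rule = rule)$patches,
                    flood_fill_count(mr, rule)$n)
    }
  }
  expect_error(extract_patches(habitat_raster(matrix(0, 3, 3))), "empty")
  # min_area filter
  m3 <- matrix(0, 10, 10); m3[1:3, 1:3] <- 1; m3[9, 9] <- 1
  expect_length(extract_patches(habitat_raster(m3), min_area = 2)$patches, 1)
})

test_that("patch graph: links, kernel calibration, topological distances", {
  # three patches on a line, 3 cells between neighbours, 7 between the ends
  m <- matrix(0, 3, 11)
  m[2, c(1, 5, 9)] <- 1
  ps <- extract_patches(habitat_raster(m))
  g <- build_graph(ps, A_L = 33, threshold = 5, d_median = 4, p_median = 0.5)
  expect_true(g$linked[1, 2] && g$linked[2, 3] && !g$linked[1, 3])
  expect_equal(g$p[1, 2], exp(log(0.5) / 4 * 4))  # p = 0.5 at the median distance
  # chain probability: p*_AC = p_AB * p_BC
  expect_equal(g$pstar[1, 3], g$p[1, 2] * g$p[2, 3], tolerance = 1e-12)
  expect_equal(g$l[1, 3], 2)
  # two patches beyond threshold: no link, l = Inf, p* = 0
  m2 <- matrix(0, 3, 11); m2[2, c(1, 11)] <- 1
  g2 <- build_graph(extract_patches(habitat_raster(m2)), A_L = 33, threshold = 5)
  expect_false(g2$linked[1, 2])
  expect_true(is.infinite(g2$l[1, 2]))
  expect_equal(g2$pstar[1, 2], 0)
  # 4-patch chain: l_14 = 3
  m3 <- matrix(0, 3, 15); m3[2, c(1, 5, 9, 13)] <- 1
  g3 <- build_graph(extract_patches(habitat_raster(m3)), A_L = 45, threshold = 4.5)
  expect_equal(g3$l[1, 4], 3)
})

test_that("IIC and PC closed forms on tiny configurations", {
  one <- list(ps = list(patches = list(list(area = 10))))
  g1 <- build_graph(one$ps, A_L = 100, threshold = 1,
                    dist_matrix = matrix(0, 1, 1))
  expect_equal(iic(g1), 0.01)
  expect_equal(pc(g1), 0.01)
  # two disconnected equal patches
  d2 <- matrix(c(0, 9, 9, 0), 2)
  ps2 <- list(patches = list(list(area = 10), list(area = 10)))
  gd <- build_graph(ps2, A_L = 100, threshold = 5, dist_matrix = d2)
  expect_equal(iic(gd), 0.02)
  expect_equal(pc(gd), 0.02)
  # same two patches linked with l = 1 -> IIC = 0.03
  gl <- build_graph(ps2, A_L = 100, threshold = 10, dist_matrix = d2,
                    d_median = 9, p_median = 0.5)
  expect_equal(iic(gl), (100 + 100 + 2 * 100 / 2) / 1e4)
  expect_equal(pc(gl), (100 + 100 + 2 * 100 * 0.5) / 1e4)
  # p* -> 1 limit: PC -> (sum a)^2 / A_L^2
  gp <- build_graph(ps2, A_L = 100, threshold = 10, dist_matrix = d2,
                    d_median = 1e9, p_median = 0.5)
  expect_equal(pc(gp), (20 / 100)^2, tolerance = 1e-6)
})

test_that("IIC/PC match exhaustive enumeration oracles on random graphs", {
  for (case in 1:12) {
    n <- 2 + (case %% 5)   # 2..6 patches
    rg <- random_graph_case(n, seed = 600 + case)
    thr <- stats::median(rg$d[upper.tri(rg$d)])
    g <- build_graph(rg$ps, A_L = 200, threshold = thr, d_median = thr / 2,
                     p_median = 0.4, dist_matrix = rg$d)
    expect_equal(iic(g), iic_oracle(rg$areas, g$linked, 200),
                 tolerance = 1e-12)
    expect_equal(pc(g), pc_oracle(rg$areas, g$linked, g$p, 200),
                 tolerance = 1e-12)
  }
})

test_that("patch importance equals brute-force leave-one-out", {
  # closed forms first
  solo <- build_graph(list(patches = list(list(area = 5))), A_L = 50,
                      threshold = 1, dist_matrix = matrix(0, 1, 1))
  expect_equal(patch_importance(solo)$dIIC, 100)
  d2 <- matrix(c(0, 9, 9, 0), 2)
  two <- build_graph(list(patches = list(list(area = 10), list(area = 10))),
                     A_L = 100, threshold = 5, dist_matrix = d2)
  expect_equal(patch_importance(two)$dIIC, c(50, 50))
  # random graphs vs full recomputation through the oracles
  for (case in 1:6) {
    n <- 3 + (case %% 4)
    rg <- random_graph_case(n, seed = 700 + case)
    thr <- stats::median(rg$d[upper.tri(rg$d)])
    g <- build_graph(rg$ps, A_L = 300, threshold = thr, d_median = thr / 2,
                     p_median = 0.5, dist_matrix = rg$d)
    imp <- patch_importance(g)
    iic0 <- iic_oracle(rg$areas, g$linked, 300)
    pc0 <- pc_oracle(rg$areas, g$linked, g$p, 300)
    for (i in seq_len(n)) {
      keep <- setdiff(seq_len(n), i)
      diic <- 100 * (iic0 - iic_oracle(rg$areas[keep],
                                       g$linked[keep, keep, drop = FALSE],
                                       300)) / iic0
      dpc <- 100 * (pc0 - pc_oracle(rg$areas[keep],
                                    g$linked[keep, keep, drop = FALSE],
                                    g$p[keep, keep, drop = FALSE], 300)) / pc0
      expect_equal(imp$dIIC[i], diic, tolerance = 1e-10)
      expect_equal(imp$dPC[i], dpc, tolerance = 1e-10)
      expect_equal(imp$PI[i], (diic + dpc) / 2, tolerance = 1e-10)
    }
  }
})

test_that("adding a link never decreases IIC or PC", {
  for (case in 1:8) {
    n <- 3 + (case %% 6)  # up to 8 patches
    rg <- random_graph_case(n, seed = 800 + case)
    thr <- stats::quantile(rg$d[upper.tri(rg$d)], 0.4, names = FALSE)
    g <- build_graph(rg$ps, A_L = 300, threshold = thr, d_median = thr / 2,
                     p_median = 0.5, dist_matrix = rg$d)
    un <- which(!g$linked & upper.tri(g$linked), arr.ind = TRUE)
    if (!nrow(un)) next
    pick <- un[1, ]
    d2 <- rg$d
    d2[pick[1], pick[2]] <- d2[pick[2], pick[1]] <- thr * 0.9
    g2 <- build_graph(rg$ps, A_L = 300, threshold = thr, d_median = thr / 2,
                      p_median = 0.5, dist_matrix = d2)
    expect_gte(iic(g2), iic(g) - 1e-14)
    expect_gte(pc(g2), pc(g) - 1e-14)
  }
})

test_that("a stepping-stone patch outranks an equal-area terminal patch", {
  # chain A - B - C, equal areas, only consecutive links
  d <- matrix(c(0, 2, 4,
                2, 0, 2,
                4, 2, 0), 3, byrow = TRUE)
  ps <- list(patches = list(list(area = 10), list(area = 10), list(area = 10)))
  g <- build_graph(ps, A_L = 100, threshold = 3, d_median = 2, p_median = 0.5,
                   dist_matrix = d)
  imp <- patch_importance(g)
  expect_gt(imp$dPC[2], imp$dPC[1])   # connector beats terminal
  expect_gt(imp$PI[2], imp$PI[3])
})

test_that("connectivity surface: per-patch values, partition, lowest class", {
  m <- matrix(0, 12, 12)
  m[2:4, 2:4] <- 1; m[8:11, 8:11] <- 1
  hab <- habitat_raster(m, cell = 0.5)
  ps <- extract_patches(hab)
  g <- build_graph(ps, A_L = 36, threshold = 10)
  imp <- patch_importance(g)
  cs <- connectivity_surface(ps, imp$PI, hab)
  # all cells of one patch share one class
  for (p in ps$patches)
    expect_length(unique(cs$classes$values[p$cells]), 1)
  # non-habitat cells carry 0 and the lowest class
  expect_true(all(cs$surface$values[m == 0] == 0))
  expect_true(all(cs$classes$values[m == 0] == 1L))
  # class areas sum to domain area
  tab <- class_area_table(cs$classes)
  expect_equal(sum(tab$area_km2), 144 * 0.25)
})
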