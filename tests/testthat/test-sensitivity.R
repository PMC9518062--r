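test_that("rainfall erosivity: zero-rain convention, direct value, homogeneity", {
  tpl <- esp_raster(matrix(0, 2, 2))
  zero <- rainfall_erosivity(lapply(1:12, function(m) const_like(tpl, 0)))
  expect_true(all(zero$values == 0))
  ten <- rainfall_erosivity(lapply(1:12, function(m) const_like(tpl, 10)))
  expect_equal(ten$values[1, 1], 0.1833 * 10^1.9957, tolerance = 1e-12)
  twenty <- rainfall_erosivity(lapply(1:12, function(m) const_like(tpl, 20)))
  expect_equal(twenty$values[1, 1], ten$values[1, 1] * 2^1.9957,
               tolerance = 1e-12)
  # multi-year: mean of annual ratios before the exponent
  yrs <- list(lapply(1:12, function(m) const_like(tpl, 10)),
              lapply(1:12, function(m) const_like(tpl, 30)))
  expect_equal(rainfall_erosivity(yrs)$values[1, 1],
               0.1833 * ((10 + 30) / 2)^1.9957, tolerance = 1e-12)
  expect_error(rainfall_erosivity(lapply(1:12, function(m) const_like(tpl, -1))),
               "negative")
})

test_that("soil erodibility matches an independent transcription of the formula", {
  # literal second transcription, scalar form
  k_oracle <- function(wg, wp, wc, wo) {
    beta <- 1 - wg / 100
    (0.2 + 0.3 * exp(-0.0256 * wg * (1 - wp / 100))) *
      (wp / (wc + wp))^0.3 *
      (1 - 0.25 * wo / (wo + exp(3.72 - 2.95 * wo))) *
      (1 - 0.7 * beta / (beta + exp(22.9 * beta - 5.51)))
  }
  tpl <- esp_raster(matrix(0, 1, 1))
  k <- soil_erodibility(const_like(tpl, 40), const_like(tpl, 30),
                        const_like(tpl, 30), const_like(tpl, 2))
  expect_equal(k$values[1, 1], k_oracle(40, 30, 30, 2), tolerance = 1e-14)
  # beta = 0 at pure sand: last bracket collapses to 1
  k100 <- soil_erodibility(const_like(tpl, 100), const_like(tpl, 0.001),
                           const_like(tpl, 0.001), const_like(tpl, 1))
  expect_equal(k100$values[1, 1], k_oracle(100, 0.001, 0.001, 1),
               tolerance = 1e-14)
  # strictly decreasing in organic carbon over [0.1, 4] (grid scan oracle)
  kk <- vapply(seq(0.1, 4, length.out = 20), function(wo)
    soil_erodibility(const_like(tpl, 40), const_like(tpl, 30),
                     const_like(tpl, 30), const_like(tpl, wo))$values[1, 1],
    numeric(1))
  expect_true(all(diff(kk) < 0))
  expect_error(soil_erodibility(const_like(tpl, 100), const_like(tpl, 0),
                                const_like(tpl, 0), const_like(tpl, 1)),
               "silt \\+ clay")
})

test_that("LS factor: flat minimum, slope monotonicity, ramp gradient", {
  flat <- ls_factor(esp_raster(matrix(500, 10, 10), cell_size = 0.1))
  expect_true(all(abs(flat$values - flat$values[1, 1]) < 1e-12))
  expect_equal(min(flat$values), flat$values[5, 5])  # uniform = its minimum
  # monotone non-decreasing in slope at fixed (unit) slope length
  grads <- seq(0, 0.5, length.out = 12)   # dz per cell over 100 m cells
  ls_at <- vapply(grads, function(g) {
    dem <- esp_raster(outer(rep(1, 6), 0:5) * g * 100, cell_size = 0.1)
    ls_factor(dem, use_accumulation = FALSE)$values[3, 3]
  }, numeric(1))
  expect_true(all(diff(ls_at) >= -1e-12))
  # a uniform ramp's Horn slope equals atan(dz / cell)
  dem <- esp_raster(outer(rep(1, 8), 0:7) * 20, cell_size = 0.1)
  sl <- slope_aspect(dem)$slope$values
  expect_equal(sl[4, 4], atan(20 / 100), tolerance = 1e-12)
})

test_that("soil loss: product, unit conversion, grading", {
  tpl <- esp_raster(matrix(0, 3, 3))
  res <- soil_loss(const_like(tpl, 100), const_like(tpl, 0.3),
                   const_like(tpl, 2), const_like(tpl, 0.5),
                   const_like(tpl, 1))
  # 30 t/(hm2 a) -> 3000 t/(km2 a) -> Moderate
  expect_equal(res$modulus$values[1, 1], 3000)
  expect_identical(res$classes$labels[res$classes$values[1, 1]],
                   "Moderate erosion")
  zero <- soil_loss(const_like(tpl, 0), const_like(tpl, 0.3),
                    const_like(tpl, 2), const_like(tpl, 0.5),
                    const_like(tpl, 1))
  expect_true(all(zero$modulus$values == 0))
  expect_identical(zero$classes$labels[zero$classes$values[1, 1]],
                   "Micro erosion")
  expect_error(soil_loss(const_like(tpl, -1), const_like(tpl, 1),
                         const_like(tpl, 1), const_like(tpl, 1),
                         const_like(tpl, 1)), "non-negative")
})

test_that("per-class budget accounting agrees with the cell-level modulus", {
  sc <- small_scene()
  k <- soil_erodibility(sc$soil$Wg, sc$soil$Wp, sc$soil$Wc, sc$soil$Wo)
  r <- rainfall_erosivity(sc$rainfall)
  cp <- cp_factors(sc$landuse)
  res <- soil_loss(r, k, ls_factor(sc$dem), cp$c, cp$p)
  cls <- res$classes$values
  mod <- res$modulus$values
  ca <- cell_area(sc$dem)
  present <- sort(unique(as.vector(cls)))
  areas <- vapply(present, function(g) sum(cls == g) * ca, numeric(1))
  means <- vapply(present, function(g) mean(mod[cls == g]), numeric(1))
  budget <- erosion_budget(areas, means)
  # sum over classes of area x mean modulus == total modulus integral
  expect_equal(attr(budget, "total_t"), sum(mod) * ca, tolerance = 1e-9)
  # partition: six-class areas sum to the domain area
  tab <- class_area_table(res$classes)
  expect_equal(sum(tab$area_km2), prod(dim(cls)) * ca, tolerance = 1e-9)
  # permuting cell order cannot change the table
  perm <- cls[sample(length(cls))]
  expect_equal(sort(tabulate(perm, 6)), sort(tabulate(cls, 6)))
})

test_that("certainty factor: branch values and bounds", {
  expect_equal(certainty_factor(0.5, 0.5), 0)
  expect_equal(certainty_factor(1, 0.5), 1)
  expect_equal(certainty_factor(0, 0.5), -1)
  # generic branch checks
  expect_equal(certainty_factor(0.8, 0.2), (0.8 - 0.2) / (0.8 * 0.8))
  expect_equal(certainty_factor(0.1, 0.4), (0.1 - 0.4) / (0.4 * 0.9))
  set.seed(31)
  pa <- runif(200); ps <- runif(200, 0.01, 0.99)
  cf <- certainty_factor(pa, ps)
  expect_true(all(cf >= -1 & cf <= 1))
})

test_that("cf_factor: count conservation and per-bin probabilities", {
  sc <- small_scene()
  slope <- slope_aspect(sc$dem)$slope
  cfm <- cf_factor(sc$hazards, slope, bins = 6L)
  # conservation of hazard counts across bins
  expect_equal(sum(cfm$table$count), length(sc$hazards$geoms))
  expect_equal(sum(cfm$table$cells), length(slope$values))
  expect_equal(cfm$table$pa, pmin(cfm$table$count / cfm$table$cells, 1))
  expect_true(all(cfm$table$cf >= -1 & cfm$table$cf <= 1))
  # categorical factor uses native classes
  cfl <- cf_factor(sc$hazards, sc$landuse)
  expect_identical(cfl$table$bin, sc$landuse$labels)
  expect_error(cf_factor(esp_vectors("points"), slope), "at least one")
})

test_that("geohazard scores sum per-cell CF values (hand oracle)", {
  # two hand-built factor models on a 2x2 grid
  mk <- function(bin_of, cf) {
    structure(list(table = data.frame(bin = paste0("b", seq_along(cf)),
                                      cf = cf),
                   bin_of = bin_of), class = "cf_factor")
  }
  tpl <- esp_raster(matrix(0, 2, 2))
  f1 <- mk(matrix(c(1L, 2L, 1L, 2L), 2), c(0.5, -0.5))
  f2 <- mk(matrix(c(1L, 1L, 2L, 2L), 2), c(0.2, 0.9))
  res <- geohazard_sensitivity(list(f1, f2), tpl)
  expect_equal(res$score$values,
               matrix(c(0.7, -0.3, 1.4, 0.4), 2))
  # all-zero CF: uniform zero score, single class
  z <- mk(matrix(1L, 2, 2), 0)
  u <- geohazard_sensitivity(list(z), tpl)
  expect_true(all(u$score$values == 0))
  expect_true(all(u$classes$values == 1L))
})

test_that("slope-bin CF recovers the ground-truth hazard preference", {
  sc <- small_scene()   # w_slope > 0 in the generator
  slope <- slope_aspect(sc$dem)$slope
  cfm <- cf_factor(sc$hazards, slope)
  rho <- stats::cor(seq_len(nrow(cfm$table)), cfm$table$cf,
                    method = "spearman")
  expect_gt(rho, 0)
})

test_that("combined sensitivity: symmetry, extremes, per-cell oracle", {
  labs6 <- erosion_labels()
  labs5 <- c("a", "b", "c", "d", "e")
  mk6 <- function(v) esp_classes(matrix(v, 2, 2), labs6)
  mk5 <- function(v) esp_classes(matrix(v, 2, 2), labs5)
  top <- combined_sensitivity(mk6(6L), mk5(5L))
  expect_true(all(top$classes$values == 5L))
  # rank symmetry under equal weights: (1,5) and (5,1) score identically
  a <- combined_sensitivity(mk5(1L), mk5(5L))$score$values[1, 1]
  b <- combined_sensitivity(mk5(5L), mk5(1L))$score$values[1, 1]
  expect_equal(a, b)
  expect_equal(a, 0.5)
  # random rasters vs per-cell arithmetic oracle
  set.seed(41)
  e <- matrix(sample(1:6, 100, TRUE), 10)
  g <- matrix(sample(1:5, 100, TRUE), 10)
  res <- combined_sensitivity(esp_classes(e, labs6), esp_classes(g, labs5),
                              weights = c(0.3, 0.7))
  oracle <- 0.3 * (e - 1) / 5 + 0.7 * (g - 1) / 4
  expect_equal(res$score$values, oracle, tolerance = 1e-12)
  expect_error(combined_sensitivity(mk6(1L), mk5(1L), weights = c(0.5, 0.6)),
               "sum to 1")
})
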