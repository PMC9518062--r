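# Shared fixtures.  Scenes are generated once per test run and cached; the
# small scene keeps most tests fast, the full default scene is reserved for
# the acceptance suite.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_scene <- function() {
  cached("small_scene",
         generate_scene(scene_config(nrows = 80L, ncols = 80L, seed = 42L,
                                     n_years = 2L, hazard_target_n = 500L)))
}

default_scene <- function() {
  cached("default_scene", generate_scene(scene_config(seed = 42L)))
}

# simple aligned raster filled with given values
r_of <- function(values, nr = NULL, cell = 1) {
  if (is.matrix(values)) esp_raster(values, cell_size = cell)
  else esp_raster(matrix(values, nr, length(values) / nr), cell_size = cell)
}

# constant raster on a template grid
const_like <- function(template, value) raster_like(template, value)
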