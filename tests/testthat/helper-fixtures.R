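# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# a realistic 80-nm phantom image with default optics and its thickness map
fixture_phantom <- function() memo("phantom", {
  make_phantom(radius_um = 1.2, length_um = 4, thickness_nm = 80)
})

fixture_image <- function() memo("image", {
  render_image(fixture_phantom(), imaging_spec(seed = 42))
})

fixture_map <- function() memo("map", {
  map_thickness(fixture_image(), pipeline_config())
})

# noise-free, shift-free rendering of the same phantom
fixture_clean_image <- function() memo("clean_image", {
  render_image(fixture_phantom(),
               imaging_spec(noise = FALSE, chromatic_shift_nm = c(0, 0)))
})

fixture_clean_map <- function() memo("clean_map", {
  map_thickness(fixture_clean_image(),
                pipeline_config(chromatic_shift_nm = c(0, 0)))
})

# brute-force thickness oracle: nearest distance from each inner-face point
# to the dense outer-face polyline (independent of rendering and fitting)
curve_distance_oracle <- function(geom, s_query_um, ds_um = 0.005) {
  cv <- phantom_curves(geom, ds_um = ds_um)
  vapply(s_query_um, function(s) {
    i <- which.min(abs(cv$s_um - s))
    min(sqrt((cv$xo_um - cv$xi_um[i])^2 + (cv$yo_um - cv$yi_um[i])^2)) * 1e3
  }, numeric(1))
}

canonical_params <- function() memo("params", default_params())
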