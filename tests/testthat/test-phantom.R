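test_that("phantom outer face sits at h(s) along the normal (offset-curve)", {
  # constant thickness
  g <- make_phantom(radius_um = 1, length_um = 4, thickness_nm = 80)
  d <- curve_distance_oracle(g, seq(0, g$s_max_um, length.out = 40))
  expect_true(all(abs(d - 80) < 1))
  # Gaussian bump of +40 nm at the tip
  gb <- make_phantom(1, 4, thickness_nm = function(s)
    80 + 40 * exp(-s^2 / (2 * 0.5^2)))
  cv <- phantom_curves(gb, ds_um = 0.01)
  dist <- sqrt((cv$xo_um - cv$xi_um)^2 + (cv$yo_um - cv$yi_um)^2) * 1e3
  expect_equal(max(dist), 120, tolerance = 1e-6)
  expect_equal(cv$s_um[which.max(dist)], 0)
  # sinusoidal profile: per-point normal distance equals h(s) within 1 nm
  gs <- make_phantom(1.2, 5, thickness_nm = function(s)
    80 + 20 * sin(2 * pi * s / 3))
  sq <- seq(0.2, gs$s_max_um - 0.2, length.out = 25)
  d <- curve_distance_oracle(gs, sq)
  expect_true(all(abs(d - gs$thickness_fun(sq)) < 1))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(make_phantom(-1, 4, 80), "radius")
  expect_error(make_phantom(1, 4, -5), "thickness")
  expect_error(make_phantom(1, 4, function(s) 80 - 30 * s), "positive")
})

test_that("rendering is seed-deterministic and linear in photon_scale", {
  g <- fixture_phantom()
  s1 <- imaging_spec(seed = 7)
  expect_identical(render_image(g, s1)$channels,
                   render_image(g, s1)$channels)
  s2 <- imaging_spec(seed = 8)
  expect_false(identical(render_image(g, s1)$channels[[1]],
                         render_image(g, s2)$channels[[1]]))
  # linearity on noise-free expectation images
  a <- render_image(g, imaging_spec(noise = FALSE, photon_scale = 200))
  b <- render_image(g, imaging_spec(noise = FALSE, photon_scale = 400))
  for (k in 1:2)
    expect_equal(b$channels[[k]], 2 * a$channels[[k]], tolerance = 1e-12)
})

test_that("delta-PSF rendering puts the two channels h apart", {
  g <- make_phantom(1, 3, 130)
  spec <- imaging_spec(psf_sigma_nm = c(0, 0), noise = FALSE,
                       chromatic_shift_nm = c(0, 0))
  img <- render_image(g, spec)
  # cross-wall profile along the vertical through the midline centre
  xc <- 1.5
  j <- which.min(abs(img$x0_um + (seq_len(img$nx) - 1) * img$pixel_um - xc))
  y <- img$y0_um + (seq_len(img$ny) - 1) * img$pixel_um
  up <- y > 0.2  # upper wall only
  p1 <- y[up][which.max(img$channels[[1]][up, j])]
  p2 <- y[up][which.max(img$channels[[2]][up, j])]
  expect_lt(abs((p2 - p1) * 1e3 - 130), spec$pixel_size_nm + 1e-9)
})

test_that("a known chromatic shift moves the channel-2 peak accordingly", {
  g <- make_phantom(1, 3, 100)
  base <- imaging_spec(noise = FALSE, chromatic_shift_nm = c(0, 0))
  shft <- imaging_spec(noise = FALSE, chromatic_shift_nm = c(0, 130))
  i0 <- render_image(g, base)
  i1 <- render_image(g, shft, raster = list(x0_um = i0$x0_um, y0_um = i0$y0_um,
                                            nx = i0$nx, ny = i0$ny))
  xc <- 1.5
  j <- which.min(abs(i0$x0_um + (seq_len(i0$nx) - 1) * i0$pixel_um - xc))
  y <- i0$y0_um + (seq_len(i0$ny) - 1) * i0$pixel_um
  up <- y > 0.2
  fit_c <- function(img) {
    pr <- img$channels[[2]][up, j]
    fit_peak((y[up] - 1) * 1e3, pr, 200)$center_nm
  }
  # shift projects fully on the (vertical) normal of the upper wall
  expect_equal(fit_c(i1) - fit_c(i0), 130, tolerance = 8)
})

test_that("rendering outside an explicit raster names the overflow", {
  g <- make_phantom(1, 6, 80)
  expect_error(render_image(g, imaging_spec(),
                            raster = list(x0_um = 0, y0_um = -2, nx = 40,
                                          ny = 60)),
               "exceeds raster bounds.*right")
})

test_that("deflation pair inverts the requested strains exactly", {
  g <- make_phantom(1.0, 4, 80)
  dp <- make_deflation_pair(g, list(radial = 0.1, longitudinal = 0.05),
                            imaging_spec(noise = FALSE))
  expect_equal(dp$geometry_after$radius_um, 1 / 1.1, tolerance = 1e-12)
  expect_equal(dp$geometry_after$mid_len_um, 4 / 1.05, tolerance = 1e-12)
  # zero strain reproduces the geometry
  dp0 <- make_deflation_pair(g, list(radial = 0, longitudinal = 0),
                             imaging_spec(noise = FALSE))
  expect_equal(dp0$geometry_after$radius_um, g$radius_um)
  expect_equal(dp0$geometry_after$mid_len_um, g$mid_len_um)
  expect_identical(dp0$before$channels, dp0$after$channels)
  expect_error(make_deflation_pair(g, list(radial = -0.2, longitudinal = 0)),
               ">= 0")
})

test_that("trace pairs carry the constructed lag", {
  tp0 <- make_trace_pair(60, lag = 0, noise_sd = 0, seed = 2)
  expect_equal(tp0$a, tp0$b)
  tp <- make_trace_pair(120, lag = 5, noise_sd = 0, seed = 3)
  cc <- cross_correlation(tp$a, tp$b, max_lag = 20)
  expect_equal(cc$lag[which.max(cc$r)], 5)
  expect_gt(max(cc$r), 0.99)
  expect_error(make_trace_pair(10, lag = 4), "n > 3")
  # reproducible
  expect_identical(make_trace_pair(50, 3, 0.1, seed = 11),
                   make_trace_pair(50, 3, 0.1, seed = 11))
})

test_that("independent white-noise pairs stay inside the 2/sqrt(n) envelope", {
  set.seed(1405)
  n <- 100; nl <- 10; nseed <- 200
  inside <- matrix(FALSE, nseed, 2 * nl + 1)
  for (s in seq_len(nseed)) {
    cc <- cross_correlation(stats::rnorm(n), stats::rnorm(n), nl)
    inside[s, ] <- abs(cc$r) < 2 / sqrt(n)
  }
  # ~95% of values fall inside the white-noise envelope
  expect_gte(mean(inside), 0.93)
  expect_true(all(colMeans(inside) >= 0.85))
})
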