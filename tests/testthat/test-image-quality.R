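test_that("NPS of a noise-free volume is zero and white noise integrates to its variance", {
  quiet <- voxel_grid(array(5, c(40, 40, 40)), c(0.5, 0.5, 0.5))
  nps0 <- estimate_nps(quiet, roi_size = 16)
  expect_true(all(abs(nps0$values) < 1e-18))

  set.seed(21)
  vol <- voxel_grid(array(rnorm(80^3, sd = 10), c(80, 80, 80)), c(0.5, 0.5, 0.5))
  nps <- estimate_nps(vol, roi_size = 32)
  expect_gte(attr(nps, "n_roi"), 64)
  expect_equal(riemann_integral(nps), 100, tolerance = 0.1)
})

test_that("difference-pair mode recovers the single-image NPS from two repeats", {
  set.seed(22)
  a <- voxel_grid(array(rnorm(64^3, sd = 10), c(64, 64, 64)), c(0.5, 0.5, 0.5))
  b <- voxel_grid(array(rnorm(64^3, sd = 10), c(64, 64, 64)), c(0.5, 0.5, 0.5))
  nps <- estimate_nps(list(a, b), mode = "difference_pair", roi_size = 32)
  expect_equal(riemann_integral(nps), 100, tolerance = 0.1)

  expect_error(estimate_nps(list(a), mode = "difference_pair"), "exactly two")
  bb <- voxel_grid(b$values, c(0.5, 0.5, 1))
  expect_error(estimate_nps(list(a, bb), mode = "difference_pair"), "identical grids")
})

test_that("few ROIs warn and linear detrend removes a plane", {
  set.seed(23)
  base <- array(rnorm(32^3, sd = 5), c(32, 32, 32))
  ramp <- outer(outer(seq_len(32) * 2, rep(1, 32)), rep(1, 32))
  vol <- voxel_grid(base + ramp, c(0.5, 0.5, 0.5))
  expect_warning(nps <- estimate_nps(vol, roi_size = 32, detrend = "linear"),
                 "fewer than 4")
  expect_equal(riemann_integral(nps), 25, tolerance = 0.2)
})

test_that("TTF estimation recovers a Gaussian blur and is flat for a sharp edge", {
  ep <- render_edge_phantom(c(64, 64, 16), c(0.5, 0.5, 2), contrast = 1000,
                            sigma_xy = 1, orientation = "x")
  tp <- estimate_ttf(ep, attr(ep, "edge"), contrast = 1000, axis = "inplane")
  expect_equal(tp$value[tp$freq == 0], 1) # normalization contract
  f50_analytic <- sqrt(log(2) / (2 * pi^2 * 1^2))
  expect_equal(f50(tp), f50_analytic, tolerance = 0.1)
  analytic <- exp(-2 * pi^2 * 1^2 * tp$freq^2)
  sel <- analytic >= 0.1
  expect_lt(max(abs(tp$value[sel] - analytic[sel])), 0.05)

  ep0 <- render_edge_phantom(c(64, 64, 16), c(0.5, 0.5, 2), contrast = 1000,
                             orientation = "x")
  tp0 <- estimate_ttf(ep0, attr(ep0, "edge"), contrast = 1000, axis = "inplane")
  nyq <- 1 / (2 * 0.5)
  expect_gte(min(tp0$value[tp0$freq <= 0.8 * nyq]), 0.95)
})

test_that("axial TTF comes from an axial edge and low contrast warns", {
  ep <- render_edge_phantom(c(32, 32, 64), c(0.5, 0.5, 0.625), contrast = 1000,
                            sigma_xy = 0.6, sigma_z = 0.8, orientation = "z")
  tp <- estimate_ttf(ep, attr(ep, "edge"), contrast = 1000, axis = "axial")
  f50_analytic <- sqrt(log(2) / (2 * pi^2 * 0.8^2))
  expect_equal(f50(tp), f50_analytic, tolerance = 0.1)

  epn <- render_edge_phantom(c(64, 64, 16), c(0.5, 0.5, 2), contrast = 30,
                             sigma_xy = 1, orientation = "x",
                             noise = list(type = "white", variance = 100),
                             seed = 4)
  expect_warning(estimate_ttf(epn, attr(epn, "edge"), contrast = 30,
                              axis = "inplane"),
                 "noise level")
})

test_that("a non-edge input fails ESF estimation rather than returning garbage", {
  flat <- voxel_grid(array(0, c(16, 16, 8)), c(0.5, 0.5, 2))
  expect_error(
    estimate_ttf(flat, list(type = "plane", axis = 1L, position = 4),
                 contrast = 100, axis = "inplane"),
    "estimation-failed"
  )
})

test_that("separable 3-D TTF composition multiplies profiles and is 1 at DC", {
  g <- make_frequency_grid(c(16, 16, 8), c(0.5, 0.5, 1.25))
  inpl <- tibble::tibble(freq = seq(0, 2, by = 0.05),
                         value = exp(-2 * pi^2 * 0.6^2 * seq(0, 2, by = 0.05)^2))
  axial <- tibble::tibble(freq = seq(0, 2, by = 0.05),
                          value = exp(-2 * pi^2 * 0.9^2 * seq(0, 2, by = 0.05)^2))
  t3 <- ttf_separable(inpl, axial, g)
  dc <- dc_index(g)
  expect_equal(t3$values[dc[1], dc[2], dc[3]], 1)
  ## matches the parametric construction on the same grid
  ref <- gaussian_ttf(g, 0.6, 0.9)
  expect_lt(max(abs(t3$values - ref$values)), 0.01)
})

test_that("NPS magnitude rescaling preserves shape exactly", {
  g <- make_frequency_grid(c(12, 12, 12), c(0.5, 0.5, 0.5))
  nps <- shaped_nps(g, 50, "lowpass")
  same <- rescale_nps_magnitude(nps, riemann_integral(nps))
  expect_equal(same$values, nps$values, tolerance = 1e-14)

  x4 <- rescale_nps_magnitude(nps, 200)
  expect_equal(x4$values, 4 * nps$values, tolerance = 1e-12)
  expect_equal(riemann_integral(x4), 200, tolerance = 1e-12)

  expect_equal(x4$values / riemann_integral(x4),
               nps$values / riemann_integral(nps), tolerance = 1e-12)

  zero <- spectral_function(array(0, g$shape), g)
  expect_error(rescale_nps_magnitude(zero, 10), "zero-integral")
})

test_that("library lookups are exact at keys and linear along continuous axes", {
  lib <- tiny_library()
  ## exact hit returns the stored entry bitwise
  e1 <- lib$entries[[1]]
  hit <- interpolate_library(lib, recon = e1$recon, thickness_mm = e1$thickness_mm,
                             dose_fraction = e1$dose_fraction,
                             contrast_hu = e1$contrast_hu)
  expect_identical(hit$nps$values, e1$nps$values)
  expect_identical(hit$ttf$values, e1$ttf$values)

  ## NPS midway in variance between two entries of identical shape
  g <- make_frequency_grid(c(8, 8, 8), c(0.5, 0.5, 0.5))
  ttf <- gaussian_ttf(g, 0.5, 0.5)
  mk <- function(dose, var) iq_entry("fbp", 1.25, dose, 80,
                                     shaped_nps(g, var, "white"), ttf)
  lib2 <- iq_library(list(mk(1, 50), mk(0.5, 100)))
  mid <- interpolate_library(lib2, "fbp", 1.25, noise_variance = 75,
                             contrast_hu = 80)
  expect_equal(mid$variance, 75, tolerance = 1e-6)

  ## TTF betweenness along contrast
  lib3 <- iq_library(list(
    iq_entry("fbp", 1.25, 1, 100, shaped_nps(g, 50, "white"), gaussian_ttf(g, 0.8, 0.8)),
    iq_entry("fbp", 1.25, 1, 1000, shaped_nps(g, 50, "white"), gaussian_ttf(g, 0.5, 0.5))
  ))
  q <- interpolate_library(lib3, "fbp", 1.25, dose_fraction = 1, contrast_hu = 300)
  lo <- gaussian_ttf(g, 0.5, 0.5)$values
  hi <- gaussian_ttf(g, 0.8, 0.8)$values
  expect_true(all(q$ttf$values >= pmin(lo, hi) - 1e-12 &
                    q$ttf$values <= pmax(lo, hi) + 1e-12))
})

test_that("library queries outside the hull fail naming the offending axis", {
  lib <- tiny_library()
  expect_error(interpolate_library(lib, "mbir", 1.25, dose_fraction = 1,
                                   contrast_hu = 80),
               "reconstruction")
  expect_error(interpolate_library(lib, "fbp", 5, dose_fraction = 1,
                                   contrast_hu = 80),
               "slice_thickness")
  expect_error(interpolate_library(lib, "fbp", 1.25, dose_fraction = 0.01,
                                   contrast_hu = 80),
               "dose_fraction")
  expect_error(interpolate_library(lib, "fbp", 1.25, dose_fraction = 1,
                                   contrast_hu = 5000),
               "contrast_hu")
})

test_that("libraries round-trip through the plain-text directory format", {
  lib <- iq_library(list(
    iq_entry("fbp", 1.25, 1, 80,
             shaped_nps(make_frequency_grid(c(6, 6, 6), c(0.5, 0.5, 1.25)), 40, "white"),
             gaussian_ttf(make_frequency_grid(c(6, 6, 6), c(0.5, 0.5, 1.25)), 0.6, 0.8))
  ), metadata = list(source = "test"))
  dir <- tempfile("lib")
  write_iq_library(lib, dir)
  rt <- read_iq_library(dir)
  expect_equal(length(rt$entries), 1L)
  expect_equal(rt$entries[[1]]$nps$values, lib$entries[[1]]$nps$values,
               tolerance = 1e-12)
  expect_equal(rt$entries[[1]]$variance, lib$entries[[1]]$variance,
               tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
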