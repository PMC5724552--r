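test_that("e' equals a brute-force triple-loop evaluation on random fields", {
  set.seed(31)
  for (n in c(6, 10)) {
    g <- make_frequency_grid(c(n, n, n), c(0.5, 0.5, 1.25))
    nps <- spectral_function(array(rexp(n^3), g$shape), g, "HU^2.mm^3")
    ttf <- spectral_function(array(runif(n^3), g$shape), g)
    wa <- spectral_function(array(runif(n^3), g$shape), g)
    wb <- spectral_function(array(runif(n^3), g$shape), g)
    res <- estimability_index(nps, ttf, wa, wb)
    ref <- loop_eprime(nps$values, ttf$values, wa$values, wb$values,
                       g$deltas, dc = dc_index(g))
    expect_equal(res$e_prime, ref, tolerance = 1e-10)
    ## the result invariant ties e', numerator and denominator together
    expect_equal(1 / res$e_prime^2,
                 res$numerator_integral / res$denominator_integral^2,
                 tolerance = 1e-12)
  }
})

test_that("white noise with unit TTF reduces to the closed form sqrt(S/N0)", {
  tk <- task_function(rasterize_nodule(nodule_48(), spacing = 0.5))
  g <- tk$grid
  n0 <- 7.5
  res <- estimability_index(flat_sf(g, n0, "HU^2.mm^3"), flat_sf(g, 1), tk, tk)
  dc <- dc_index(g)
  s <- (sum(tk$values^2) - tk$values[dc[1], dc[2], dc[3]]^2) * prod(g$deltas)
  expect_equal(res$e_prime, sqrt(s / n0), tolerance = 1e-10)
})

test_that("e' follows the exact scaling laws in NPS and TTF", {
  tk <- task_function(rasterize_nodule(nodule_95(), spacing = 0.5))
  g <- tk$grid
  nps <- shaped_nps(g, 40, "lowpass")
  ttf <- gaussian_ttf(g, 0.6, 0.8)
  base <- estimability_index(nps, ttf, tk, tk)$e_prime
  for (k in c(0.25, 0.5, 2, 4)) {
    scaled <- spectral_function(nps$values * k, g, nps$units)
    expect_equal(estimability_index(scaled, ttf, tk, tk)$e_prime,
                 base / sqrt(k), tolerance = 1e-12)
  }
  for (t in c(0.25, 0.5, 2, 4)) {
    scaled <- spectral_function(ttf$values * t, g, "1")
    expect_equal(estimability_index(nps, scaled, tk, tk)$e_prime,
                 base * t, tolerance = 1e-12)
  }
})

test_that("e' scales linearly with nodule contrast under a matched template", {
  g <- make_frequency_grid(c(32, 32, 32), c(0.5, 0.5, 0.5))
  nps <- shaped_nps(g, 40, "lowpass")
  ttf <- gaussian_ttf(g, 0.6, 0.8)
  ep <- function(contrast) {
    tk <- task_function(rasterize_nodule(nodule_model(6, contrast),
                                         shape = g$shape, spacing = g$spacing))
    estimability_index(nps, ttf, tk, tk)$e_prime
  }
  expect_equal(ep(160) / ep(80), 2, tolerance = 1e-8)
})

test_that("degenerate tasks and mismatched grids are rejected", {
  g <- make_frequency_grid(c(8, 8, 8), c(1, 1, 1))
  nps <- flat_sf(g, 1, "HU^2.mm^3")
  zero <- flat_sf(g, 0)
  expect_error(estimability_index(nps, flat_sf(g, 1), zero, zero), "degenerate")

  g2 <- make_frequency_grid(c(8, 8, 8), c(0.5, 0.5, 0.5))
  expect_error(
    estimability_index(nps, flat_sf(g2, 1), flat_sf(g, 1), flat_sf(g, 1),
                       resample = FALSE),
    "not on the NPS"
  )
})

test_that("e' is invariant to in-plane axis relabeling for symmetric inputs", {
  tk <- task_function(rasterize_nodule(nodule_48(), spacing = 0.5))
  g <- tk$grid
  nps <- shaped_nps(g, 25, "ridge")
  ttf <- gaussian_ttf(g, 0.7, 0.9)
  swap <- function(sf) spectral_function(aperm(sf$values, c(2, 1, 3)), g, sf$units)
  a <- estimability_index(nps, ttf, tk, tk)$e_prime
  b <- estimability_index(swap(nps), swap(ttf), swap(tk), swap(tk))$e_prime
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("a mismatched raw-power template predicts worse precision than matched", {
  g <- make_frequency_grid(c(40, 40, 40), c(0.5, 0.5, 0.5))
  nps <- shaped_nps(g, 60, "lowpass")
  ttf <- gaussian_ttf(g, 0.6, 0.8)
  tk <- task_function(rasterize_nodule(nodule_95(), shape = g$shape,
                                       spacing = g$spacing))
  tm7 <- task_function(rasterize_nodule(nodule_model(7, 80), shape = g$shape,
                                        spacing = g$spacing))
  matched <- estimability_index(nps, ttf, tk, tk)
  mis <- estimability_index(nps, ttf, tk, tm7)
  expect_gt(mis$inv_e_prime, matched$inv_e_prime)
})

test_that("the matched diameter is optimal in a fixed-energy template sweep", {
  g <- make_frequency_grid(c(40, 40, 40), c(0.5, 0.5, 0.5))
  nps <- shaped_nps(g, 60, "lowpass")
  ttf <- gaussian_ttf(g, 0.6, 0.8)
  sw <- template_sweep(nps, ttf, nodule_95(), seq(4.5, 15.5, by = 1))
  expect_gte(nrow(sw), 11)
  best <- sw$template_diameter_mm[which.min(sw$inv_e_prime)]
  expect_equal(best, 9.5)
  expect_true(all(sw$inv_e_prime[!sw$matched] > sw$inv_e_prime[sw$matched]))
})

test_that("protocol evaluation produces ordered rows with dose-monotone e'", {
  lib <- tiny_library()
  grid <- protocol_grid(c(1, 0.5, 0.1), c(0.625, 1.25), c("fbp", "asir"))
  res <- evaluate_protocols(lib, list(nodule_95(), nodule_48()), grid)
  expect_s3_class(res, "eprime_results")
  expect_equal(nrow(res), 3 * 2 * 2 * 2)

  ## single protocol, single nodule
  one <- evaluate_protocols(lib, nodule_95(),
                            protocol_grid(1, 1.25, "fbp"))
  expect_equal(nrow(one), 1L)

  ## within (recon, thickness, nodule): variance decreasing => e' increasing
  by_grp <- split(res, list(res$recon, res$thickness_mm, res$nodule))
  for (grp in by_grp) {
    grp <- grp[order(-grp$dose_fraction), ]
    expect_true(all(diff(grp$e_prime) < 0)) # dose descending => e' decreasing
  }
})

test_that("lung-region variance rescaling propagates into protocol e'", {
  lib <- tiny_library()
  grid <- protocol_grid(1, 1.25, "fbp")
  base <- evaluate_protocols(lib, nodule_95(), grid)
  iq <- interpolate_library(lib, "fbp", 1.25, dose_fraction = 1, contrast_hu = 80)
  lung <- data.frame(recon = "fbp", thickness_mm = 1.25, dose_fraction = 1,
                     variance_hu2 = 4 * iq$variance)
  res <- evaluate_protocols(lib, nodule_95(), grid, lung_variances = lung)
  expect_equal(res$e_prime, base$e_prime / 2, tolerance = 1e-9)
})

test_that("design bookkeeping reproduces factorial counts", {
  d <- enumerate_design(dose_levels = 6, repeats = 5, reconstructions = 3,
                        thicknesses = 3, nodules_per_dataset = 35,
                        softwares = 2, nodule_sizes = 2)
  expect_equal(d$scans, 30)
  expect_equal(d$datasets, 270)
  expect_equal(d$protocols, 54)
  expect_equal(d$prc_values, 108)
  expect_equal(d$segmentations, 18900)

  ones <- enumerate_design(1, 1, 1, 1, 1, 1, 1)
  expect_true(all(unlist(ones) == 1))
  expect_error(enumerate_design(0, 1, 1, 1, 1, 1), "positive integers")
})
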