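test_that("the stand-in segmenter recovers sphere volumes and is deterministic", {
  r95 <- rasterize_nodule(nodule_95(), spacing = 0.25)
  expect_equal(segment_volume(r95, 80), 4 / 3 * pi * 4.75^3, tolerance = 0.02)

  expect_error(segment_volume(voxel_grid(array(0, c(8, 8, 8)), c(1, 1, 1)), 80),
               "segmentation-failed")

  sc <- scene_spec(nodule_95(), sigma_xy = 0.6, sigma_z = 0.8,
                   nps = list(type = "lowpass", variance = 50, corr_mm = 0.6),
                   seed = 99)
  v1 <- segment_volume(render_scene(sc, shape = 36, spacing = 0.5), 80)
  v2 <- segment_volume(render_scene(sc, shape = 36, spacing = 0.5), 80)
  expect_identical(v1, v2)
})

test_that("negative-contrast lesions segment downward", {
  nod <- nodule_model(8, -100)
  rg <- rasterize_nodule(nod, spacing = 0.5)
  expect_equal(segment_volume(rg, -100), 4 / 3 * pi * 4^3, tolerance = 0.05)
})

test_that("PRC is zero for identical repeats and exact for hand-pooled cases", {
  ident <- data.frame(case_id = rep(1:3, each = 4), volume_mm3 = rep(250, 12))
  expect_equal(percent_repeatability_coefficient(ident)$prc_pct, 0)

  ## two cases: sigma_w = 0 and sigma_w = 10% (sample variance exactly 100)
  devs <- c(-0.1, -0.1, 0, 0.1, 0.1) # percent/100 deviations, var = 100 %^2
  two <- data.frame(
    case_id = rep(c("a", "b"), each = 5),
    volume_mm3 = c(rep(100, 5), 200 * (1 + devs))
  )
  out <- percent_repeatability_coefficient(two)
  expect_equal(out$prc_pct, 1.96 * sqrt(2) * sqrt(50), tolerance = 1e-12)
  expect_equal(out$prc_pct, 2.77 * 10 / sqrt(2), tolerance = 0.01)
})

test_that("PRC matches the 2.77 sigma_w closed form on Gaussian simulation", {
  set.seed(42)
  n_cases <- 200; n_rep <- 5; sw <- 5
  df <- data.frame(
    case_id = rep(seq_len(n_cases), each = n_rep),
    volume_mm3 = 100 * (1 + stats::rnorm(n_cases * n_rep, sd = sw / 100))
  )
  out <- percent_repeatability_coefficient(df)
  expect_equal(out$prc_pct, 1.96 * sqrt(2) * sw, tolerance = 0.5 / 13.86)
})

test_that("PRC is scale invariant and drops under-replicated cases", {
  set.seed(43)
  df <- data.frame(case_id = rep(1:20, each = 4),
                   volume_mm3 = 100 * (1 + rnorm(80, sd = 0.03)))
  base <- percent_repeatability_coefficient(df)
  df2 <- df
  sel <- df2$case_id <= 10
  df2$volume_mm3[sel] <- df2$volume_mm3[sel] * 37.5
  expect_equal(percent_repeatability_coefficient(df2)$prc_pct, base$prc_pct,
               tolerance = 1e-12)

  df3 <- rbind(df, data.frame(case_id = 99, volume_mm3 = 100))
  expect_warning(out <- percent_repeatability_coefficient(df3), "dropped")
  expect_equal(out$n_cases, 20L)
  expect_equal(out$prc_pct, base$prc_pct, tolerance = 1e-12)

  single <- data.frame(case_id = 1:3, volume_mm3 = c(10, 20, 30))
  expect_warning(expect_error(percent_repeatability_coefficient(single),
                              ">= 2 repeated"))
  expect_error(percent_repeatability_coefficient(
    data.frame(case_id = c(1, 1), volume_mm3 = c(-5, 10))
  ), "> 0")
})

test_that("calibration recovers known parameters from noise-free data", {
  x <- exp(seq(log(0.1), log(10), length.out = 20))
  df <- data.frame(pred = x, resp = 10 * log(2 * x^1 + 1))
  fit <- fit_calibration(df, x = pred, y = resp)
  expect_equal(fit$a, 10, tolerance = 1e-4)
  expect_equal(fit$b, 2, tolerance = 1e-4)
  expect_equal(fit$c, 1, tolerance = 1e-4)
  expect_gte(fit$r_squared, 1 - 1e-10)
  ## round trip through prediction reproduces the fitted values
  expect_equal(predict_prc(x, fit), fit$data$fitted, tolerance = 1e-12)
})

test_that("calibration recovers parameters within 10% under 5% noise", {
  ## predictor spans four decades so the large-x logarithmic regime
  ## separates b from a (identifiability by design)
  set.seed(42)
  x <- exp(seq(log(0.02), log(50), length.out = 100))
  y <- 10 * log(2 * x + 1) * (1 + rnorm(100, sd = 0.05))
  fit <- fit_calibration(data.frame(x = x, y = y), x = x, y = y)
  expect_equal(fit$a, 10, tolerance = 0.1)
  expect_equal(fit$b, 2, tolerance = 0.1)
  expect_equal(fit$c, 1, tolerance = 0.1)
  expect_gt(fit$r_squared, 0.98)
})

test_that("degenerate calibration inputs fail loudly", {
  flat <- data.frame(x = 1:10, y = rep(5, 10))
  expect_error(fit_calibration(flat, x = x, y = y), "fit-failed")
  short <- data.frame(x = 1:5, y = 1:5)
  expect_error(fit_calibration(short, x = x, y = y), "at least 6")
  neg <- data.frame(x = c(-1, 1:9), y = 0:9)
  expect_error(fit_calibration(neg, x = x, y = y), "positive")
})

test_that("prediction follows the model form and rejects negative input", {
  fit <- structure(list(a = 10, b = 2, c = 1, converged = TRUE),
                   class = "prc_calibration")
  expect_equal(predict_prc(0, fit), 0)
  expect_equal(predict_prc(1, fit), 10 * log(3), tolerance = 1e-12)
  xs <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(predict_prc(xs, fit)) > 0))
  expect_error(predict_prc(-0.1, fit), ">= 0")
})

test_that("calibration models round-trip through JSON and expose tidy/glance", {
  x <- exp(seq(log(0.2), log(5), length.out = 12))
  fit <- fit_calibration(data.frame(x = x, y = 4 * log(1.5 * x + 1)),
                         x = x, y = y, software = "standin-A")
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "c"))
  gl <- glance(fit)
  expect_equal(gl$software, "standin-A")
  expect_s3_class(autoplot(fit), "ggplot")

  path <- tempfile(fileext = ".json")
  write_calibration(fit, path)
  rt <- read_calibration(path)
  expect_equal(rt$a, fit$a, tolerance = 1e-12)
  expect_equal(rt$n, fit$n)
  expect_equal(predict_prc(2, rt), predict_prc(2, fit), tolerance = 1e-12)
  unlink(path)
})
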