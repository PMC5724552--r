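## Morphology and labeling helpers for the stand-in segmenter. Binary
## dilation/erosion use a 3x3x3 box applied separably; connected components
## use 26-connectivity via frontier-vectorized flood fill on a padded array.

shift_or <- function(m, axis) {
  n <- dim(m)
  out <- m
  idx <- function(a, from, to) {
    ix <- list(seq_len(n[1]), seq_len(n[2]), seq_len(n[3]))
    ix[[a]] <- from:to
    ix
  }
  up <- idx(axis, 1, n[axis] - 1); dn <- idx(axis, 2, n[axis])
  out[up[[1]], up[[2]], up[[3]]] <- out[up[[1]], up[[2]], up[[3]]] |
    m[dn[[1]], dn[[2]], dn[[3]]]
  out[dn[[1]], dn[[2]], dn[[3]]] <- out[dn[[1]], dn[[2]], dn[[3]]] |
    m[up[[1]], up[[2]], up[[3]]]
  out
}

dilate_box <- function(m) {
  for (a in 1:3) m <- shift_or(m, a)
  m
}

erode_box <- function(m) !dilate_box(!m)

close_box <- function(m) erode_box(dilate_box(m))

label_components_26 <- function(mask) {
  n <- dim(mask)
  np <- n + 2L
  mp <- array(FALSE, np)
  mp[2:(np[1] - 1), 2:(np[2] - 1), 2:(np[3] - 1)] <- mask
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  loff <- offs[, 1] + offs[, 2] * np[1] + offs[, 3] * np[1] * np[2]
  lab <- integer(prod(np))
  todo <- which(mp)
  current <- 0L
  sizes <- integer(0)
  unvisited <- rep(TRUE, prod(np))
  for (seed in todo) {
    if (!unvisited[seed] || !mp[seed]) next
    current <- current + 1L
    frontier <- seed
    unvisited[seed] <- FALSE
    size <- 0L
    while (length(frontier)) {
      lab[frontier] <- current
      size <- size + length(frontier)
      nb <- unique(as.vector(outer(frontier, loff, "+")))
      nb <- nb[nb >= 1 & nb <= length(lab)]
      nb <- nb[mp[nb] & unvisited[nb]]
      unvisited[nb] <- FALSE
      frontier <- nb
    }
    sizes[current] <- size
  }
  lab_arr <- array(lab, np)[2:(np[1] - 1), 2:(np[2] - 1), 2:(np[3] - 1)]
  list(labels = lab_arr, sizes = sizes)
}

#' Threshold-based stand-in volume segmentation
#'
#' A deliberately simple, fully deterministic surrogate for semiautomatic
#' clinical segmentation software: threshold at half the expected contrast
#' above the local background (estimated as the median of the one-voxel
#' border shell), keep the largest 26-connected component after one binary
#' closing pass, and report its volume. For negative-contrast lesions the
#' threshold is applied downward. It is not a model of any commercial tool.
#'
#' @param vg a `voxel_grid`.
#' @param expected_contrast expected lesion contrast (HU), nonzero.
#' @return segmented volume in mm^3 (scalar).
#' @export
segment_volume <- function(vg, expected_contrast) {
  stopifnot(inherits(vg, "voxel_grid"))
  if (expected_contrast == 0) stop("expected_contrast must be nonzero", call. = FALSE)
  v <- vg$values
  n <- dim(v)
  shell <- array(FALSE, n)
  shell[c(1, n[1]), , ] <- TRUE
  shell[, c(1, n[2]), ] <- TRUE
  shell[, , c(1, n[3])] <- TRUE
  background <- stats::median(v[shell])
  mask <- if (expected_contrast > 0) {
    v >= background + expected_contrast / 2
  } else {
    v <= background + expected_contrast / 2
  }
  if (!any(mask)) stop("segmentation-failed: no above-threshold component", call. = FALSE)
  mask <- close_box(mask)
  lab <- label_components_26(mask)
  if (!length(lab$sizes)) {
    stop("segmentation-failed: no connected component", call. = FALSE)
  }
  max(lab$sizes) * voxel_volume(vg)
}

#' Percent repeatability coefficient from repeated volume measurements
#'
#' PRC is the expected percent difference between any two repeated
#' quantifications of the same case, for 95% of cases:
#' `PRC = 1.96 * sqrt(2) * sigma_w` (about `2.77 sigma_w`), where `sigma_w`
#' is the within-case standard deviation of percent deviations from each
#' case's mean. The within-case variance is pooled as the mean of the
#' per-case unbiased variances; because deviations are percentages of the
#' case mean, the statistic is invariant to rescaling any case's volumes.
#' Smaller PRC means better precision.
#'
#' @param data data frame of repeated measurements.
#' @param case column identifying the case (default `case_id`).
#' @param volume column of measured volumes, mm^3, > 0 (default `volume_mm3`).
#' @return one-row tibble: `prc_pct`, `sigma_w_pct`, `n_cases`,
#'   `n_measurements`, `n_dropped_cases`.
#' @export
percent_repeatability_coefficient <- function(data, case = case_id,
                                              volume = volume_mm3) {
  df <- dplyr::transmute(data, case = {{ case }}, volume = {{ volume }})
  if (any(!is.finite(df$volume)) || any(df$volume <= 0)) {
    stop("volumes must be finite and > 0", call. = FALSE)
  }
  per_case <- df |>
    dplyr::summarise(
      n = dplyr::n(),
      s2 = stats::var(100 * (.data$volume - mean(.data$volume)) / mean(.data$volume)),
      .by = "case"
    )
  dropped <- sum(per_case$n < 2)
  if (dropped > 0) {
    warning(sprintf("%d case(s) with < 2 repeats dropped", dropped), call. = FALSE)
  }
  kept <- per_case[per_case$n >= 2, ]
  if (!nrow(kept)) stop("no case has >= 2 repeated measurements", call. = FALSE)
  pooled <- mean(kept$s2)
  sigma_w <- sqrt(pooled)
  tibble::tibble(
    prc_pct = 1.96 * sqrt(2) * sigma_w,
    sigma_w_pct = sigma_w,
    n_cases = nrow(kept),
    n_measurements = sum(kept$n),
    n_dropped_cases = dropped
  )
}

## ---- calibration ----------------------------------------------------------

calib_fn <- function(x, a, b, c) a * log(b * x^c + 1)

#' Fit the logarithmic precision calibration
#'
#' Fits `y = a * ln(b * x^c + 1)` with `a, b, c > 0` by nonlinear least
#' squares, the asymptotic-logarithmic form relating the imprecision
#' predictor derived from the estimability index to empirical PRC.
#' Residuals are weighted by `1/y^2` (relative least squares), since the
#' sampling uncertainty of a repeatability coefficient is proportional to
#' its value; positivity is enforced by fitting on the log scale, and the
#' optimizer is multi-started from a log-spaced grid of shape parameters
#' (with `a` given a closed-form least-squares start at each grid point).
#' The best converged start wins. `r_squared` is reported on the
#' unweighted scale.
#'
#' @param data data frame holding predictor and response columns.
#' @param x predictor column (default `inv_e_prime`, the Fig.-5-style axis).
#' @param y response column (default `prc_pct`), >= 0.
#' @param software free-form label; calibrations are software-specific.
#' @return a `prc_calibration`: `a`, `b`, `c`, `r_squared`, `fitted`,
#'   `residuals`, `converged`, `n`, `software`.
#' @export
fit_calibration <- function(data, x = inv_e_prime, y = prc_pct,
                            software = "generic") {
  df <- dplyr::transmute(data, x = {{ x }}, y = {{ y }})
  if (nrow(df) < 6) stop("need at least 6 (x, y) pairs", call. = FALSE)
  if (any(df$x <= 0) || any(!is.finite(df$x))) {
    stop("predictor values must be positive and finite", call. = FALSE)
  }
  if (any(df$y < 0) || any(!is.finite(df$y))) {
    stop("response values must be non-negative and finite", call. = FALSE)
  }
  if (stats::sd(df$y) < 1e-12) {
    stop("fit-failed: response is constant, no relationship to fit", call. = FALSE)
  }
  df$w <- 1 / pmax(df$y, 1e-3 * max(df$y))^2
  starts <- expand.grid(lb = log(c(0.2, 1, 5)), lc = log(c(0.5, 1, 2)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    g <- calib_fn(df$x, 1, exp(starts$lb[i]), exp(starts$lc[i]))
    a0 <- sum(df$y * g) / sum(g^2)
    if (!is.finite(a0) || a0 <= 0) a0 <- max(df$y) / log(2)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ exp(la) * log(exp(lb) * x^exp(lc) + 1),
        data = df,
        start = list(la = log(a0), lb = starts$lb[i], lc = starts$lc[i]),
        weights = df$w,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ss <- sum(df$w * stats::resid(fit)^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) {
    stop("fit-failed: no starting point converged", call. = FALSE)
  }
  th <- exp(stats::coef(best$fit))
  names(th) <- c("a", "b", "c")
  fitted <- calib_fn(df$x, th["a"], th["b"], th["c"])
  ss_res <- sum((df$y - fitted)^2)
  ss_tot <- sum((df$y - mean(df$y))^2)
  structure(
    list(a = unname(th["a"]), b = unname(th["b"]), c = unname(th["c"]),
         r_squared = 1 - ss_res / ss_tot,
         data = tibble::tibble(x = df$x, y = df$y, fitted = fitted,
                               residual = df$y - fitted),
         converged = TRUE, n = nrow(df), software = software),
    class = "prc_calibration"
  )
}

#' @export
print.prc_calibration <- function(x, ...) {
  cat(sprintf(
    "<prc_calibration> [%s] PRC = %.4g * ln(%.4g * x^%.4g + 1), R^2 = %.4f (n = %d)\n",
    x$software, x$a, x$b, x$c, x$r_squared, x$n
  ))
  invisible(x)
}

#' @method tidy prc_calibration
#' @export
tidy.prc_calibration <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @method glance prc_calibration
#' @export
glance.prc_calibration <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n, converged = x$converged,
                 software = x$software)
}

#' @method autoplot prc_calibration
#' @export
autoplot.prc_calibration <- function(object, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
                                 length.out = 200))
  grid$y <- calib_fn(grid$x, object$a, object$b, object$c)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "imprecision predictor (1/e')", y = "PRC (%)",
                  title = sprintf("PRC = %.3g ln(%.3g x^%.3g + 1), R^2 = %.3f",
                                  object$a, object$b, object$c, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Predict PRC from the estimability-derived predictor
#'
#' Evaluates the fitted `a * ln(b * x^c + 1)`; strictly increasing in `x` and
#' 0 at `x = 0`.
#'
#' @param x predictor values (the same quantity the model was fitted
#'   against), >= 0.
#' @param model a converged `prc_calibration`.
#' @return predicted PRC (%), same length as `x`.
#' @export
predict_prc <- function(x, model) {
  stopifnot(inherits(model, "prc_calibration"))
  if (!isTRUE(model$converged)) stop("calibration model did not converge", call. = FALSE)
  if (any(x < 0)) stop("predictor values must be >= 0", call. = FALSE)
  calib_fn(x, model$a, model$b, model$c)
}

#' Write / read a calibration model as JSON
#' @param model a `prc_calibration`.
#' @param path JSON path.
#' @return `path` invisibly; `read_calibration()` returns the model (without
#'   the per-point fit table).
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(
    list(software = model$software, a = model$a, b = model$b, c = model$c,
         r_squared = model$r_squared, n_points = model$n),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(a = m$a, b = m$b, c = m$c, r_squared = m$r_squared,
         data = NULL, converged = TRUE, n = m$n_points, software = m$software),
    class = "prc_calibration"
  )
}
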