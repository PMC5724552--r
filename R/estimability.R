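#' Estimability index of a volumetry task
#'
#' The Fourier-domain precision surrogate
#' \deqn{1/e'^2 = \frac{\iiint NPS \, TTF^2 |W_{task}| |W_{temp}| \, du\,dv\,dw}
#'                    {\left(\iiint TTF^2 |W_{task}| |W_{temp}| \, du\,dv\,dw\right)^2},}
#' the nonprewhitening-matched-filter form: the numerator is the fluctuation
#' of the nodule–template cross correlation due to image noise, the
#' denominator its strength. Under this definition e' behaves like a
#' detectability index — more noise, poorer resolution or a worse template
#' match all reduce e' — and its reciprocal `1/e'` is the imprecision
#' predictor that repeatability (PRC) is calibrated against.
#'
#' All four fields must share one frequency grid; when they do not and
#' `resample = TRUE`, the TTF and the task/template spectra are explicitly
#' resampled (trilinear in frequency) onto the NPS grid. The DC bin is
#' excluded from both integrals by default: the NPS at DC depends on the
#' detrending choice and the task spectrum at DC on the edge-profile
#' normalization, so neither carries task information.
#'
#' @param nps,ttf,wtask,wtemp `spectral_function`s.
#' @param exclude_dc drop the DC bin from both integrals (default `TRUE`).
#' @param resample resample `ttf`, `wtask`, `wtemp` onto the NPS grid when
#'   grids differ; with `FALSE`, mismatched grids are an error.
#' @param protocol,nodule,template optional labels carried into the result.
#' @return an `estimability_result`: list with `e_prime`, `inv_e_prime`,
#'   `numerator_integral` (the numerator), `denominator_integral` (the
#'   *unsquared* denominator integral) and the labels.
#' @export
estimability_index <- function(nps, ttf, wtask, wtemp, exclude_dc = TRUE,
                               resample = TRUE, protocol = NA_character_,
                               nodule = NA_character_, template = "matched") {
  stopifnot(inherits(nps, "spectral_function"))
  fields <- list(ttf = ttf, wtask = wtask, wtemp = wtemp)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(inherits(f, "spectral_function"))
    if (!same_grid(f$grid, nps$grid)) {
      if (!resample) {
        stop("`", nm, "` is not on the NPS frequency grid", call. = FALSE)
      }
      fields[[nm]] <- resample_spectral(f, nps$grid)
    }
  }
  g <- nps$grid
  cross <- fields$ttf$values^2 * fields$wtask$values * fields$wtemp$values
  if (exclude_dc) {
    dc <- dc_index(g)
    cross[dc[1], dc[2], dc[3]] <- 0
  }
  dudvdw <- prod(g$deltas)
  den_int <- sum(cross) * dudvdw
  if (den_int <= 0) {
    stop("degenerate task: the template/task cross-correlation integral is zero",
         call. = FALSE)
  }
  num <- sum(nps$values * cross) * dudvdw
  e_prime <- den_int / sqrt(num)
  structure(
    list(e_prime = e_prime, inv_e_prime = 1 / e_prime,
         numerator_integral = num, denominator_integral = den_int,
         protocol = protocol, nodule = nodule, template = template),
    class = "estimability_result"
  )
}

#' @export
print.estimability_result <- function(x, ...) {
  cat(sprintf(
    "<estimability_result> e' = %.4g (1/e' = %.4g)  [nodule %s, template %s]\n",
    x$e_prime, x$inv_e_prime, x$nodule, x$template
  ))
  invisible(x)
}

#' @method tidy estimability_result
#' @export
tidy.estimability_result <- function(x, ...) {
  tibble::tibble(
    protocol = x$protocol, nodule = x$nodule, template = x$template,
    e_prime = x$e_prime, inv_e_prime = x$inv_e_prime,
    num = x$numerator_integral, den = x$denominator_integral
  )
}

#' Acquisition protocol grid
#'
#' The factorial of dose fractions, slice thicknesses and reconstruction
#' labels over which e' (and empirically, PRC) is evaluated.
#'
#' @param dose_fractions numeric in (0, 1].
#' @param thicknesses_mm slice thicknesses (mm).
#' @param recons reconstruction labels.
#' @return tibble with one row per protocol, ordered by (recon, thickness,
#'   dose).
#' @export
protocol_grid <- function(dose_fractions, thicknesses_mm, recons) {
  if (!length(dose_fractions) || !length(thicknesses_mm) || !length(recons)) {
    stop("protocol grid axes must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(dose_fractions) || anyDuplicated(thicknesses_mm) ||
      anyDuplicated(recons)) {
    stop("protocol grid axes must not contain duplicates", call. = FALSE)
  }
  g <- tidyr::expand_grid(recon = recons, thickness_mm = thicknesses_mm,
                          dose_fraction = dose_fractions)
  dplyr::arrange(g, .data$recon, .data$thickness_mm, dplyr::desc(.data$dose_fraction))
}

#' Evaluate e' across a protocol grid and a set of nodules
#'
#' For each protocol x nodule: interpolate (NPS, TTF) from the library at the
#' nodule's contrast, optionally rescale the NPS to a structured-region
#' (lung) noise variance, build the task function on the NPS grid, and
#' evaluate [estimability_index()] with a matched template (or a supplied
#' one). Row order is deterministic: (recon, thickness, dose descending,
#' nodule label).
#'
#' @param lib an [iq_library()].
#' @param nodules list of [nodule_model()]s.
#' @param grid a [protocol_grid()] tibble.
#' @param templates `NULL` for matched templates, a single `nodule_model`, or
#'   a named list keyed by nodule label.
#' @param lung_variances optional data frame (`recon`, `thickness_mm`,
#'   `dose_fraction`, `variance_hu2`) giving structured-region noise variances
#'   used to rescale the uniform-region NPS before e' evaluation.
#' @param exclude_dc passed to [estimability_index()].
#' @return an `eprime_results` tibble: recon, thickness_mm, dose_fraction,
#'   nodule, template, e_prime, inv_e_prime, num, den.
#' @export
evaluate_protocols <- function(lib, nodules, grid, templates = NULL,
                               lung_variances = NULL, exclude_dc = TRUE) {
  stopifnot(inherits(lib, "iq_library"))
  if (inherits(nodules, "nodule_model")) nodules <- list(nodules)
  labels <- vapply(nodules, `[[`, character(1), "label")
  ord <- order(labels)
  nodules <- nodules[ord]; labels <- labels[ord]
  rows <- purrr::pmap_dfr(grid, function(recon, thickness_mm, dose_fraction) {
    iq <- tryCatch(
      interpolate_library(lib, recon = recon, thickness_mm = thickness_mm,
                          dose_fraction = dose_fraction,
                          contrast_hu = nodules[[1]]$contrast_hu),
      error = function(e) {
        stop(sprintf("library lookup failed for (%s, %g mm, dose %g): %s",
                     recon, thickness_mm, dose_fraction, conditionMessage(e)),
             call. = FALSE)
      }
    )
    nps <- iq$nps
    if (!is.null(lung_variances)) {
      hit <- lung_variances$recon == recon &
        abs(lung_variances$thickness_mm - thickness_mm) < 1e-9 &
        abs(lung_variances$dose_fraction - dose_fraction) < 1e-9
      if (any(hit)) {
        nps <- rescale_nps_magnitude(nps, lung_variances$variance_hu2[which(hit)[1]])
      }
    }
    fg <- nps$grid
    purrr::map_dfr(seq_along(nodules), function(i) {
      nod <- nodules[[i]]
      wtask <- task_function(rasterize_nodule(nod, shape = fg$shape,
                                              spacing = fg$spacing))
      tmpl <- if (is.null(templates)) {
        NULL
      } else if (inherits(templates, "nodule_model")) {
        templates
      } else {
        templates[[nod$label]]
      }
      if (is.null(tmpl)) {
        wtemp <- wtask
        tlabel <- "matched"
      } else {
        wtemp <- task_function(rasterize_nodule(tmpl, shape = fg$shape,
                                                spacing = fg$spacing))
        tlabel <- tmpl$label
      }
      res <- estimability_index(nps, iq$ttf, wtask, wtemp,
                                exclude_dc = exclude_dc,
                                protocol = sprintf("%s|%g|%g", recon,
                                                   thickness_mm, dose_fraction),
                                nodule = nod$label, template = tlabel)
      tibble::tibble(
        recon = recon, thickness_mm = thickness_mm, dose_fraction = dose_fraction,
        nodule = nod$label, template = tlabel,
        e_prime = res$e_prime, inv_e_prime = res$inv_e_prime,
        num = res$numerator_integral, den = res$denominator_integral
      )
    })
  })
  class(rows) <- c("eprime_results", class(rows))
  rows
}

#' @method autoplot eprime_results
#' @export
autoplot.eprime_results <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_fraction, y = .data$e_prime,
                                       colour = .data$nodule,
                                       linetype = factor(.data$thickness_mm))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$recon)) +
    ggplot2::scale_x_continuous(trans = "log10") +
    ggplot2::labs(x = "dose fraction", y = "estimability index e'",
                  linetype = "slice (mm)") +
    ggplot2::theme_minimal()
}

#' Sweep template diameters against a fixed nodule at fixed image quality
#'
#' Evaluates e' for sphere templates of varying diameter against one nodule,
#' at fixed NPS and TTF. Because Eq.-(3)-style indices scale with the overall
#' magnitude of the template spectrum, a raw sweep confounds template *shape*
#' with template *energy*; matched-filter optimality is a fixed-energy
#' statement. Each template spectrum is therefore rescaled so its effective
#' energy under the system resolution, `integral(TTF^2 |Wtemp|^2)`, equals
#' the task's — after which, for white noise, the matched diameter maximizes
#' e' (minimizes predicted imprecision) by Cauchy–Schwarz.
#'
#' @param nps,ttf `spectral_function`s defining the image quality.
#' @param nodule a `nodule_model`; the task (and matched template) object.
#' @param template_diameters_mm diameters to sweep; the nodule's own diameter
#'   is added if absent.
#' @param exclude_dc passed to [estimability_index()].
#' @return tibble: template_diameter_mm, matched, e_prime, inv_e_prime.
#' @export
template_sweep <- function(nps, ttf, nodule, template_diameters_mm,
                           exclude_dc = TRUE) {
  fg <- nps$grid
  wtask <- task_function(rasterize_nodule(nodule, shape = fg$shape,
                                          spacing = fg$spacing))
  if (!any(abs(template_diameters_mm - nodule$diameter_mm) < 1e-9)) {
    template_diameters_mm <- c(template_diameters_mm, nodule$diameter_mm)
  }
  template_diameters_mm <- sort(template_diameters_mm)
  t2 <- ttf$values^2
  task_energy <- sum(t2 * wtask$values^2)
  purrr::map_dfr(template_diameters_mm, function(d) {
    matched <- abs(d - nodule$diameter_mm) < 1e-9
    if (matched) {
      wtemp <- wtask
    } else {
      tm <- nodule_model(d, nodule$contrast_hu, nodule$edge_width_mm)
      wt <- task_function(rasterize_nodule(tm, shape = fg$shape,
                                           spacing = fg$spacing))
      scale <- sqrt(task_energy / sum(t2 * wt$values^2))
      wtemp <- spectral_function(wt$values * scale, fg, wt$units)
    }
    res <- estimability_index(nps, ttf, wtask, wtemp, exclude_dc = exclude_dc,
                              nodule = nodule$label,
                              template = sprintf("d%.3gmm", d))
    tibble::tibble(template_diameter_mm = d, matched = matched,
                   e_prime = res$e_prime, inv_e_prime = res$inv_e_prime)
  })
}

#' Bookkeeping for a factorial repeatability study design
#'
#' Pure design arithmetic: number of scans, reconstructed datasets, distinct
#' protocols, PRC values and individual segmentations implied by a factorial
#' precision experiment (dose levels x repeats, reconstruction algorithms x
#' slice thicknesses per scan, nodules per dataset, segmentation softwares).
#'
#' @param dose_levels,repeats,reconstructions,thicknesses positive integers.
#' @param nodules_per_dataset nodules embedded in each dataset.
#' @param softwares segmentation software count.
#' @param nodule_sizes distinct nodule sizes (PRC is pooled per size).
#' @return one-row tibble: scans, datasets, protocols, prc_values,
#'   segmentations.
#' @export
enumerate_design <- function(dose_levels, repeats, reconstructions, thicknesses,
                             nodules_per_dataset, softwares, nodule_sizes = 2) {
  args <- c(dose_levels = dose_levels, repeats = repeats,
            reconstructions = reconstructions, thicknesses = thicknesses,
            nodules_per_dataset = nodules_per_dataset, softwares = softwares,
            nodule_sizes = nodule_sizes)
  if (any(args != round(args)) || any(args < 1)) {
    stop("all design factors must be positive integers", call. = FALSE)
  }
  scans <- dose_levels * repeats
  datasets <- scans * reconstructions * thicknesses
  protocols <- dose_levels * reconstructions * thicknesses
  tibble::tibble(
    scans = scans,
    datasets = datasets,
    protocols = protocols,
    prc_values = protocols * nodule_sizes,
    nodules_per_dataset = nodules_per_dataset,
    segmentations = datasets * nodules_per_dataset * softwares
  )
}
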