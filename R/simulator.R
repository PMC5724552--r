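#' Parametric NPS models for the simulator
#'
#' Builds a target noise power spectrum of the requested total variance on a
#' frequency grid. `"white"` is flat; `"lowpass"` is an isotropic Gaussian
#' falling with frequency (the waxy texture of iterative reconstruction);
#' `"ridge"` rises linearly with in-plane radial frequency before an
#' apodizing Gaussian roll-off (the classic filtered-back-projection
#' texture).
#'
#' @param fgrid a `frequency_grid`.
#' @param variance total noise variance (HU^2), >= 0.
#' @param type `"white"`, `"lowpass"` or `"ridge"`.
#' @param corr_mm correlation length (mm) setting the roll-off of the shaped
#'   types.
#' @return a `spectral_function` (HU^2 mm^3) whose [riemann_integral()] is
#'   `variance`.
#' @export
shaped_nps <- function(fgrid, variance, type = c("white", "lowpass", "ridge"),
                       corr_mm = 1) {
  type <- match.arg(type)
  if (variance < 0) stop("`variance` must be >= 0", call. = FALSE)
  shape <- switch(type,
    white = array(1, fgrid$shape),
    lowpass = {
      u <- fgrid$freqs[[1]]; v <- fgrid$freqs[[2]]; w <- fgrid$freqs[[3]]
      r2p <- outer(u^2, v^2, "+")
      vals <- exp(-2 * pi^2 * corr_mm^2 * outer(as.vector(r2p), w^2, "+"))
      dim(vals) <- fgrid$shape
      vals
    },
    ridge = {
      u <- fgrid$freqs[[1]]; v <- fgrid$freqs[[2]]; w <- fgrid$freqs[[3]]
      r <- sqrt(outer(u^2, v^2, "+"))
      inpl <- r * exp(-(r * corr_mm * 2)^2)
      ax <- exp(-2 * pi^2 * corr_mm^2 * w^2)
      vals <- outer(as.vector(inpl), ax)
      dim(vals) <- fgrid$shape
      vals
    }
  )
  tot <- sum(shape) * prod(fgrid$deltas)
  if (variance == 0 || tot == 0) {
    return(spectral_function(array(0, fgrid$shape), fgrid, "HU^2.mm^3"))
  }
  spectral_function(shape * (variance / tot), fgrid, "HU^2.mm^3")
}

#' Spectrally shaped Gaussian noise volume
#'
#' Filters a seeded white Gaussian field in the frequency domain by
#' `sqrt(NPS / voxel_volume)`, so the ensemble noise power spectrum of the
#' generated volumes equals the target: the exact inverse of the
#' periodogram-average NPS estimator. Mean zero in expectation.
#'
#' @param nps_target a `spectral_function` (HU^2 mm^3); its grid defines the
#'   output shape and spacing.
#' @param seed integer; identical seeds give bitwise-identical volumes.
#' @param spacing optional override check: if given, must match the spacing
#'   that generated the NPS grid.
#' @return a `voxel_grid` of pure noise (HU).
#' @export
shaped_noise_volume <- function(nps_target, seed, spacing = NULL) {
  stopifnot(inherits(nps_target, "spectral_function"))
  g <- nps_target$grid
  if (!is.null(spacing) && any(abs(g$spacing - spacing) > 1e-9)) {
    stop("requested spacing is incompatible with the NPS grid", call. = FALSE)
  }
  n <- g$shape
  dv <- prod(g$spacing)
  h <- ifftshift3(sqrt(nps_target$values / dv))
  white <- with_seed(seed, array(stats::rnorm(prod(n)), n))
  vals <- Re(stats::fft(stats::fft(white) * h, inverse = TRUE)) / prod(n)
  voxel_grid(vals, g$spacing)
}

#' Synthetic edge phantom with Gaussian blur and shaped noise
#'
#' A slightly slanted half-space step of the given contrast (the standard
#' slanted-edge trick, so voxel centres sample the edge spread at dense
#' sub-voxel phases). The Gaussian-blurred profile is rendered analytically
#' (error-function edge spread along the plane normal), avoiding periodic
#' wrap-around; shaped noise is added on top. The edge geometry is attached
#' as an attribute so [estimate_ttf()] can consume the volume directly.
#'
#' @param shape,spacing grid geometry.
#' @param contrast step height (HU), nonzero.
#' @param sigma_xy,sigma_z Gaussian blur SD (mm) in-plane / axial.
#' @param orientation `"x"` (in-plane edge, normal mostly along x) or `"z"`
#'   (axial edge, normal mostly along the slice direction).
#' @param tilt tangent of the slant angle between the edge normal and the
#'   main axis (default 0.13, about 7 degrees).
#' @param noise `NULL`, or a `spectral_function` NPS, or
#'   `list(type =, variance =, corr_mm =)` passed to [shaped_nps()].
#' @param seed noise seed (required when noise is requested).
#' @return a `voxel_grid` with attribute `edge` (geometry metadata).
#' @export
render_edge_phantom <- function(shape, spacing, contrast, sigma_xy = 0,
                                sigma_z = 0, orientation = c("x", "z"),
                                tilt = 0.13, noise = NULL, seed = NULL) {
  orientation <- match.arg(orientation)
  if (contrast == 0) stop("`contrast` must be nonzero", call. = FALSE)
  shape <- as.integer(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  nv <- if (orientation == "x") c(1, tilt, 0) else c(tilt, 0, 1)
  nv <- nv / sqrt(sum(nv^2))
  co <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
  point <- vapply(co, function(x) mean(range(x)), numeric(1)) +
    spacing / 2 * nv  # keep voxel centres off the plane
  ## effective blur SD along the plane normal
  sig <- c(sigma_xy, sigma_xy, sigma_z)
  sigma_eff <- sqrt(sum(sig^2 * nv^2))
  dxy <- outer((co[[1]] - point[1]) * nv[1], (co[[2]] - point[2]) * nv[2], "+")
  d <- outer(as.vector(dxy), (co[[3]] - point[3]) * nv[3], "+")
  dim(d) <- shape
  vals <- if (sigma_eff > 0) {
    contrast * stats::pnorm(-d / sigma_eff)
  } else {
    contrast * ((d < 0) + 0)
  }
  vg <- voxel_grid(vals, spacing)
  if (!is.null(noise)) {
    if (is.null(seed)) stop("`seed` required when adding noise", call. = FALSE)
    nps <- if (inherits(noise, "spectral_function")) {
      noise
    } else {
      shaped_nps(make_frequency_grid(shape, spacing), noise$variance,
                 type = noise$type %||% "white", corr_mm = noise$corr_mm %||% 1)
    }
    vg <- voxel_grid(vg$values + shaped_noise_volume(nps, seed)$values, spacing)
  }
  attr(vg, "edge") <- list(type = "plane", normal = nv, point = point)
  vg
}

#' Scene specification for the nodule simulator
#'
#' Everything needed to render one synthetic "scan": the nodule, a constant
#' background, the system blur (parametric Gaussian or an explicit TTF), the
#' noise model (parametric or an explicit NPS), and the seed. An identical
#' spec with an identical seed renders a bitwise-identical volume; repeat
#' scans differ only by seed.
#'
#' @param nodule a [nodule_model()].
#' @param background constant background (HU).
#' @param sigma_xy,sigma_z Gaussian blur SD (mm), used when `ttf` is `NULL`.
#' @param ttf optional explicit `spectral_function` TTF.
#' @param nps `list(type =, variance =, corr_mm =)` or an explicit
#'   `spectral_function`.
#' @param seed integer noise seed.
#' @return a `scene_spec`.
#' @export
scene_spec <- function(nodule, background = -800, sigma_xy = 0, sigma_z = 0,
                       ttf = NULL, nps = list(type = "white", variance = 0),
                       seed = 1L) {
  stopifnot(inherits(nodule, "nodule_model"))
  if (sigma_xy < 0 || sigma_z < 0) stop("blur SD must be >= 0", call. = FALSE)
  if (!inherits(nps, "spectral_function") && (nps$variance %||% 0) < 0) {
    stop("noise variance must be >= 0", call. = FALSE)
  }
  structure(
    list(nodule = nodule, background = background, sigma_xy = sigma_xy,
         sigma_z = sigma_z, ttf = ttf, nps = nps, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Render a nodule scene
#'
#' Rasterizes the nodule, applies the system blur as multiplication by the
#' TTF in the frequency domain (the linear-shift-invariant approximation),
#' adds the constant background, then adds seeded spectrally shaped noise.
#'
#' @param spec a [scene_spec()].
#' @param shape grid shape (default 96^3).
#' @param spacing voxel spacing mm (default 0.5 isotropic).
#' @return a `voxel_grid`.
#' @export
render_scene <- function(spec, shape = c(96, 96, 96), spacing = c(0.5, 0.5, 0.5)) {
  stopifnot(inherits(spec, "scene_spec"))
  shape <- as.integer(if (length(shape) == 1) rep(shape, 3) else shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  nod <- rasterize_nodule(spec$nodule, shape = shape, spacing = spacing)
  fgrid <- make_frequency_grid(shape, spacing)
  vals <- nod$values
  if (!is.null(spec$ttf) || spec$sigma_xy > 0 || spec$sigma_z > 0) {
    ttf <- spec$ttf %||% gaussian_ttf(fgrid, spec$sigma_xy, spec$sigma_z)
    if (!same_grid(ttf$grid, fgrid)) ttf <- resample_spectral(ttf, fgrid)
    f <- fft_volume(nod) * ttf$values
    vals <- ifft_volume(f, spacing)$values
  }
  vals <- vals + spec$background
  nps <- if (inherits(spec$nps, "spectral_function")) {
    spec$nps
  } else if ((spec$nps$variance %||% 0) > 0) {
    shaped_nps(fgrid, spec$nps$variance, type = spec$nps$type %||% "white",
               corr_mm = spec$nps$corr_mm %||% 1)
  } else {
    NULL
  }
  if (!is.null(nps) && riemann_integral(nps) > 0) {
    vals <- vals + shaped_noise_volume(nps, spec$seed)$values
  }
  voxel_grid(vals, spacing)
}

#' Synthetic image-quality library over a protocol grid
#'
#' Builds a parametric (NPS, TTF) library emulating the qualitative behaviour
#' of the three reconstruction families: `fbp` with a ridge-shaped NPS and
#' dose-independent resolution, `asir` and `mbir` with low-pass NPS of
#' reduced magnitude and resolution that improves with dose and contrast.
#' Noise variance scales as `ref_variance / (dose_fraction * thickness /
#' 0.625 mm)`. Not a model of any vendor implementation — a plausible,
#' fully-specified operating space for exercising the method end to end.
#'
#' @param dose_fractions,thicknesses_mm,recons protocol axes; recons from
#'   `"fbp"`, `"asir"`, `"mbir"`.
#' @param contrasts_hu TTF contrast keys (HU).
#' @param shape spectral grid shape per entry.
#' @param inplane_mm in-plane voxel pitch of the emulated reconstructions.
#' @param ref_variance uniform-region noise variance (HU^2) at 100% dose,
#'   0.625 mm slices, FBP.
#' @return an [iq_library()].
#' @export
build_synthetic_library <- function(dose_fractions = c(1, 0.75, 0.5, 0.25, 0.1, 0.03),
                                    thicknesses_mm = c(0.625, 1.25, 2.5),
                                    recons = c("fbp", "asir", "mbir"),
                                    contrasts_hu = c(80, 1000),
                                    shape = c(24, 24, 24), inplane_mm = 0.5,
                                    ref_variance = 100) {
  params <- list(
    fbp = list(mult = 1, sigma0 = 0.70, nps_type = "ridge", dose_sharp = 0),
    asir = list(mult = 0.55, sigma0 = 0.60, nps_type = "lowpass", dose_sharp = 0.15),
    mbir = list(mult = 0.30, sigma0 = 0.50, nps_type = "lowpass", dose_sharp = 0.30)
  )
  entries <- list()
  for (rc in recons) {
    p <- params[[rc]]
    if (is.null(p)) stop("unknown reconstruction label: ", rc, call. = FALSE)
    for (th in thicknesses_mm) {
      spacing <- c(inplane_mm, inplane_mm, th)
      fgrid <- make_frequency_grid(shape, spacing)
      for (dd in dose_fractions) {
        variance <- ref_variance * p$mult / (dd * th / 0.625)
        nps <- shaped_nps(fgrid, variance, type = p$nps_type, corr_mm = 1)
        for (cc in contrasts_hu) {
          ## IR resolution improves with dose and with contrast; FBP does not.
          sig <- p$sigma0 * (1 + p$dose_sharp * (1 - dd)) *
            (1 - 0.05 * p$dose_sharp * log10(cc / 80))
          ttf <- gaussian_ttf(fgrid, sigma_xy = sig, sigma_z = max(sig, th / 2))
          entries[[length(entries) + 1L]] <- iq_entry(
            recon = rc, thickness_mm = th, dose_fraction = dd,
            contrast_hu = cc, nps = nps, ttf = ttf
          )
        }
      }
    }
  }
  iq_library(entries, metadata = list(source = "synthetic parametric library"))
}

#' Desk-scale virtual precision experiment (noise ladder)
#'
#' The simulated analogue of a factorial repeatability study: over a ladder
#' of dose fractions (noise variance proportional to 1/dose) and a set of
#' nodules, render `n_cases` independent nodule instances per condition, each
#' "scanned" `n_repeats` times with fresh noise seeds, segment every volume
#' with [segment_volume()], and pool the percent repeatability coefficient
#' per condition. Alongside, e' for each condition is computed analytically
#' from the same NPS and Gaussian TTF the simulator used. The returned
#' summary is the raw material for the PRC-vs-1/e' calibration.
#'
#' The default noise model is band-limited ("lowpass") with a correlation
#' length matching the system blur, as reconstructed CT noise is; the
#' default full-dose variance keeps even the noisiest rung of the ladder
#' inside the threshold segmenter's tracking regime (background exceedance
#' of the threshold stays below the 26-connectivity percolation level, so
#' the largest component remains the nodule).
#'
#' @param nodules list of [nodule_model()]s.
#' @param dose_fractions noise ladder, in (0, 1].
#' @param full_dose_variance noise variance (HU^2) at dose fraction 1.
#' @param nps_type,corr_mm noise texture passed to [shaped_nps()].
#' @param n_cases nodule instances per condition.
#' @param n_repeats repeat scans per instance.
#' @param sigma_xy,sigma_z system blur (mm).
#' @param shape,spacing scene grid.
#' @param background scene background (HU).
#' @param seed master seed; every scene seed derives from it.
#' @return list with `summary` (one row per dose x nodule: variance, e_prime,
#'   inv_e_prime, prc_pct, ...) and `measurements` (per-scan volumes).
#' @export
virtual_precision_experiment <- function(nodules,
                                         dose_fractions = c(1, 0.75, 0.5, 0.25, 0.1, 0.03),
                                         full_dose_variance = 6.25,
                                         nps_type = "lowpass", corr_mm = 0.6,
                                         n_cases = 50, n_repeats = 5,
                                         sigma_xy = 0.6, sigma_z = 0.8,
                                         shape = c(36, 36, 36),
                                         spacing = c(0.5, 0.5, 0.5),
                                         background = -800, seed = 42) {
  if (inherits(nodules, "nodule_model")) nodules <- list(nodules)
  shape <- as.integer(if (length(shape) == 1) rep(shape, 3) else shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  fgrid <- make_frequency_grid(shape, spacing)
  ttf <- gaussian_ttf(fgrid, sigma_xy, sigma_z)
  meas <- list()
  summ <- list()
  cond <- 0L
  for (ni in seq_along(nodules)) {
    nod <- nodules[[ni]]
    wtask <- task_function(rasterize_nodule(nod, shape = shape, spacing = spacing))
    for (di in seq_along(dose_fractions)) {
      dd <- dose_fractions[di]
      variance <- full_dose_variance / dd
      nps <- shaped_nps(fgrid, variance, type = nps_type, corr_mm = corr_mm)
      res <- estimability_index(nps, ttf, wtask, wtask,
                                protocol = sprintf("dose%g", dd),
                                nodule = nod$label)
      cond <- cond + 1L
      vols <- tidyr::expand_grid(case_id = seq_len(n_cases),
                                 repeat_idx = seq_len(n_repeats))
      vols$volume_mm3 <- purrr::map2_dbl(vols$case_id, vols$repeat_idx, function(cs, rp) {
        sseed <- derive_seed(seed, ((ni * 1009 + di) * 131 + cs) * 17 + rp)
        sc <- scene_spec(nod, background = background, sigma_xy = sigma_xy,
                         sigma_z = sigma_z,
                         nps = list(type = nps_type, variance = variance,
                                    corr_mm = corr_mm),
                         seed = sseed)
        segment_volume(render_scene(sc, shape = shape, spacing = spacing),
                       expected_contrast = nod$contrast_hu)
      })
      prc <- percent_repeatability_coefficient(vols)
      meas[[cond]] <- dplyr::mutate(vols, nodule = nod$label, dose_fraction = dd,
                                    .before = 1)
      summ[[cond]] <- tibble::tibble(
        nodule = nod$label, diameter_mm = nod$diameter_mm, dose_fraction = dd,
        variance_hu2 = variance, e_prime = res$e_prime,
        inv_e_prime = res$inv_e_prime, prc_pct = prc$prc_pct,
        sigma_w_pct = prc$sigma_w_pct, n_cases = prc$n_cases
      )
    }
  }
  list(summary = dplyr::bind_rows(summ), measurements = dplyr::bind_rows(meas))
}
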