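#' Estimate the 3-D noise power spectrum from uniform-region volumes
#'
#' Ensemble-averaged periodogram over overlapping cubic ROIs: each ROI is
#' detrended, Fourier transformed, and `|DFT|^2 * voxel_volume / n_voxels`
#' is averaged across ROIs (and volumes). Under the package's transform
#' convention the frequency integral of the result is the noise variance
#' (HU^2). In `difference_pair` mode the two co-registered repeats are
#' subtracted — the standard trick to remove structure (e.g. lung vessels)
#' before noise measurement — and the periodogram is halved, since the
#' difference of two independent realizations carries twice the noise power.
#'
#' @param volumes a `voxel_grid` or list of them; exactly two in
#'   `difference_pair` mode, on identical grids.
#' @param mode `"single"` or `"difference_pair"`.
#' @param roi_size ROI edge length in voxels (scalar or length-3).
#' @param detrend `"mean"` removes each ROI's mean; `"linear"` removes a
#'   least-squares first-order polynomial (plane) per ROI.
#' @param stride ROI start step in voxels; default half-overlapping.
#' @return a `spectral_function` (HU^2 mm^3) on the ROI's frequency grid,
#'   with attribute `n_roi`.
#' @export
estimate_nps <- function(volumes, mode = c("single", "difference_pair"),
                         roi_size = 32, detrend = c("mean", "linear"),
                         stride = NULL) {
  mode <- match.arg(mode)
  detrend <- match.arg(detrend)
  if (inherits(volumes, "voxel_grid")) volumes <- list(volumes)
  stopifnot(all(vapply(volumes, inherits, logical(1), "voxel_grid")))
  if (mode == "difference_pair") {
    if (length(volumes) != 2) {
      stop("difference_pair mode needs exactly two repeat volumes", call. = FALSE)
    }
    a <- volumes[[1]]; b <- volumes[[2]]
    if (!identical(dim(a$values), dim(b$values)) ||
        any(abs(a$spacing - b$spacing) > 1e-9)) {
      stop("repeat volumes are not on identical grids", call. = FALSE)
    }
    volumes <- list(voxel_grid(a$values - b$values, a$spacing, a$origin))
  }
  roi <- as.integer(if (length(roi_size) == 1) rep(roi_size, 3) else roi_size)
  spacing <- volumes[[1]]$spacing
  if (any(dim(volumes[[1]]$values) < roi)) {
    stop("ROI does not fit inside the volume", call. = FALSE)
  }
  stride <- as.integer(stride %||% pmax(roi %/% 2L, 1L))
  if (length(stride) == 1) stride <- rep(stride, 3L)
  fgrid <- make_frequency_grid(roi, spacing)
  nvox <- prod(roi)
  dv <- prod(spacing)

  plane_qr <- NULL
  if (detrend == "linear") {
    ijk <- expand.grid(i = seq_len(roi[1]), j = seq_len(roi[2]), k = seq_len(roi[3]))
    plane_qr <- qr(cbind(1, ijk$i, ijk$j, ijk$k))
  }

  acc <- array(0, roi)
  n_roi <- 0L
  for (vol in volumes) {
    nd <- dim(vol$values)
    starts <- lapply(1:3, function(a) unique(c(seq(1L, nd[a] - roi[a] + 1L, by = stride[a]),
                                               nd[a] - roi[a] + 1L)))
    for (i0 in starts[[1]]) for (j0 in starts[[2]]) for (k0 in starts[[3]]) {
      blk <- vol$values[i0:(i0 + roi[1] - 1L), j0:(j0 + roi[2] - 1L),
                        k0:(k0 + roi[3] - 1L)]
      blk <- if (detrend == "mean") {
        blk - mean(blk)
      } else {
        array(qr.resid(plane_qr, as.vector(blk)), roi)
      }
      acc <- acc + Mod(stats::fft(blk))^2
      n_roi <- n_roi + 1L
    }
  }
  if (n_roi < 4L) {
    warning("fewer than 4 ROIs; NPS estimate will be high-variance", call. = FALSE)
  }
  nps <- fftshift3(acc / n_roi) * dv / nvox
  if (mode == "difference_pair") nps <- nps / 2
  out <- spectral_function(nps, fgrid, units = "HU^2.mm^3")
  attr(out, "n_roi") <- n_roi
  out
}

#' Rescale an NPS to a target noise variance
#'
#' Multiplies the spectrum by `target_variance / integral(nps)`, changing the
#' noise magnitude while leaving the frequency dependence (texture) untouched.
#' This is how a uniform-region NPS is adjusted to the noise level measured in
#' a structured region such as lung parenchyma, under the assumption that
#' structure changes only the magnitude of the noise.
#'
#' @param nps a `spectral_function` with positive integral.
#' @param target_variance desired variance (HU^2).
#' @return a rescaled `spectral_function`.
#' @export
rescale_nps_magnitude <- function(nps, target_variance) {
  stopifnot(inherits(nps, "spectral_function"))
  cur <- riemann_integral(nps)
  if (cur <= 0) {
    if (target_variance == 0) return(nps)
    stop("cannot rescale a zero-integral NPS to a nonzero variance", call. = FALSE)
  }
  spectral_function(nps$values * (target_variance / cur), nps$grid, nps$units)
}

## ---- TTF ------------------------------------------------------------------

#' Estimate a task transfer function from an edge volume
#'
#' Classic edge technique: every voxel's signed distance to the stated edge
#' surface is computed, the edge spread function (ESF) is assembled by binning
#' those distances at a fine sub-voxel pitch, smoothed and forced monotone,
#' differentiated to the line spread function (LSF), Hann-windowed about its
#' peak, and the magnitude of its 1-D Fourier transform — normalized to 1 at
#' zero frequency — is the TTF along the probed direction.
#'
#' @param edge_volume a `voxel_grid` containing the edge.
#' @param edge edge geometry: `list(type = "plane", axis = 1|2|3,
#'   position = <mm>)` for a flat interface with normal along `axis`;
#'   `list(type = "plane", normal = c(nx, ny, nz), point = c(x, y, z))` for a
#'   slanted plane (the slanted-edge technique, which samples the ESF at
#'   dense sub-voxel phases); or `list(type = "cylinder", center = c(x, y),
#'   radius = <mm>)` for a rod probed radially in-plane.
#' @param contrast nominal edge contrast (HU), used only for the noise-level
#'   adequacy warning.
#' @param axis `"inplane"` or `"axial"`; recorded on the output and checked
#'   against the geometry.
#' @param bin_frac ESF bin pitch as a fraction of the voxel pitch along the
#'   probed direction (default 0.1).
#' @param smooth_bins width (bins) of the moving-average pre-smoother; kept
#'   narrow (3 bins = 0.3 voxel) so an unblurred edge keeps a near-flat TTF.
#' @param max_freq truncate the returned profile at this frequency (mm^-1);
#'   default the Nyquist frequency of the probed direction.
#' @return a `ttf_profile`: tibble with columns `freq` (mm^-1) and `value`,
#'   `value[freq == 0] == 1`, plus attributes `axis` and `pitch`.
#' @export
estimate_ttf <- function(edge_volume, edge, contrast, axis = c("inplane", "axial"),
                         bin_frac = 0.1, smooth_bins = 3, max_freq = NULL) {
  axis <- match.arg(axis)
  stopifnot(inherits(edge_volume, "voxel_grid"))
  co <- voxel_coords(edge_volume)
  n <- dim(edge_volume$values)
  if (edge$type == "plane" && !is.null(edge$normal)) {
    nv <- edge$normal / sqrt(sum(edge$normal^2))
    dx <- outer(co[[1]] - edge$point[1], rep(1, n[2])) * nv[1] +
      outer(rep(1, n[1]), co[[2]] - edge$point[2]) * nv[2]
    d <- outer(as.vector(dx), (co[[3]] - edge$point[3]) * nv[3], "+")
    dim(d) <- n
    ax <- which.max(abs(nv))
    pitch_vox <- edge_volume$spacing[ax]
    if (axis == "axial" && ax != 3L) {
      stop("axial TTF needs a plane with normal along the slice axis", call. = FALSE)
    }
  } else if (edge$type == "plane") {
    ax <- edge$axis
    d1 <- co[[ax]] - edge$position
    d <- switch(ax,
      array(d1, n),
      aperm(array(d1, n[c(2, 1, 3)]), c(2, 1, 3)),
      aperm(array(d1, n[c(3, 1, 2)]), c(2, 3, 1))
    )
    pitch_vox <- edge_volume$spacing[ax]
    if (axis == "axial" && ax != 3L) {
      stop("axial TTF needs a plane with normal along the slice axis", call. = FALSE)
    }
  } else if (edge$type == "cylinder") {
    rr <- sqrt(outer((co[[1]] - edge$center[1])^2, (co[[2]] - edge$center[2])^2, "+"))
    d <- array(rep(rr - edge$radius, n[3]), n)
    pitch_vox <- max(edge_volume$spacing[1:2])
    if (axis != "inplane") {
      stop("a cylinder edge probes the in-plane direction", call. = FALSE)
    }
  } else {
    stop("unknown edge geometry type", call. = FALSE)
  }

  pitch <- bin_frac * pitch_vox
  span <- min(max(abs(range(d))), 40 * pitch_vox)
  keep <- abs(d) <= span
  db <- round(d[keep] / pitch)
  vv <- edge_volume$values[keep]
  esf_raw <- tapply(vv, db, mean)
  pos <- as.integer(names(esf_raw))
  full <- seq(min(pos), max(pos))
  esf <- stats::approx(pos, esf_raw, xout = full, rule = 2)$y

  far_lo <- vv[d[keep] < -0.6 * span]
  far_hi <- vv[d[keep] > 0.6 * span]
  noise_sd <- stats::sd(c(far_lo - mean(far_lo), far_hi - mean(far_hi)))
  if (is.finite(noise_sd) && abs(contrast) < 10 * noise_sd) {
    warning(sprintf(
      "edge contrast (%.3g HU) is < 10x the noise level (%.3g HU); TTF estimate may be unstable",
      abs(contrast), noise_sd
    ), call. = FALSE)
  }

  if (smooth_bins > 1) {
    kern <- rep(1 / smooth_bins, smooth_bins)
    esf <- stats::filter(esf, kern, sides = 2)
    ok <- !is.na(esf)
    esf <- as.numeric(esf[ok]); full <- full[ok]
  }
  rise <- mean(utils::tail(esf, 5)) - mean(utils::head(esf, 5))
  if (abs(rise) < 1e-9) stop("estimation-failed: ESF is flat", call. = FALSE)
  oriented <- if (rise > 0) esf else rev(esf)
  iso <- stats::isoreg(oriented)$yf
  resid_frac <- max(abs(iso - oriented)) / abs(rise)
  if (resid_frac > 0.2) {
    stop("estimation-failed: ESF is not monotone after smoothing", call. = FALSE)
  }
  esf_mono <- if (rise > 0) iso else rev(iso)

  lsf <- diff(esf_mono) / pitch
  peak <- which.max(abs(lsf))
  m <- length(lsf)
  half <- max(peak - 1, m - peak)
  hann <- 0.5 * (1 + cos(pi * (seq_len(m) - peak) / half))
  lsf_w <- lsf * hann

  nfft <- stats::nextn(2 * m, 2)
  spec <- Mod(stats::fft(c(lsf_w, rep(0, nfft - m))))
  freq <- (seq_len(nfft) - 1) / (nfft * pitch)
  half_n <- floor(nfft / 2)
  ttf <- spec[seq_len(half_n)] / spec[1]
  freq <- freq[seq_len(half_n)]
  fmax <- max_freq %||% (1 / (2 * pitch_vox))
  keep_f <- freq <= fmax + 1e-12
  out <- tibble::tibble(freq = freq[keep_f], value = ttf[keep_f])
  class(out) <- c("ttf_profile", class(out))
  attr(out, "axis") <- axis
  attr(out, "pitch") <- pitch
  out
}

#' Frequency at which a transfer-function profile falls to 0.5
#' @param profile a tibble with `freq` and `value` columns (e.g. a
#'   `ttf_profile`).
#' @return scalar frequency (mm^-1), or `NA` if the profile never crosses 0.5.
#' @export
f50 <- function(profile) {
  f <- profile$freq; v <- profile$value
  below <- which(v < 0.5)
  if (!length(below) || below[1] == 1) return(NA_real_)
  i <- below[1]
  f[i - 1] + (0.5 - v[i - 1]) * (f[i] - f[i - 1]) / (v[i] - v[i - 1])
}

#' Compose a 3-D TTF from in-plane and axial profiles (separable model)
#'
#' The in-plane profile is applied at the radial frequency
#' `sqrt(u^2 + v^2)` and the axial profile at `|w|`; the 3-D TTF is their
#' product. Separability is a modeling choice: in-plane and axial resolution
#' are measured independently and no cross term is available.
#'
#' @param inplane,axial `ttf_profile`s (or any tibble with `freq`, `value`).
#' @param fgrid target `frequency_grid`.
#' @return a `spectral_function` (dimensionless) with value 1 at DC.
#' @export
ttf_separable <- function(inplane, axial, fgrid) {
  interp <- function(prof, x) {
    stats::approx(prof$freq, prof$value, xout = x, rule = 2)$y
  }
  u <- fgrid$freqs[[1]]; v <- fgrid$freqs[[2]]; w <- fgrid$freqs[[3]]
  r <- sqrt(outer(u^2, v^2, "+"))
  tr <- array(interp(inplane, as.vector(r)), dim = c(length(u), length(v)))
  ta <- interp(axial, abs(w))
  vals <- outer(as.vector(tr), ta)
  dim(vals) <- fgrid$shape
  vals <- pmin(pmax(vals, 0), Inf)
  dc <- dc_index(fgrid)
  if (vals[dc[1], dc[2], dc[3]] > 0) vals <- vals / vals[dc[1], dc[2], dc[3]]
  spectral_function(vals, fgrid, units = "1")
}

#' Parametric Gaussian 3-D TTF
#'
#' `exp(-2 pi^2 (sigma_xy^2 (u^2 + v^2) + sigma_z^2 w^2))` — the transfer
#' function of an anisotropic Gaussian blur with the given standard
#' deviations (mm).
#'
#' @param fgrid a `frequency_grid`.
#' @param sigma_xy,sigma_z blur SD in mm (>= 0).
#' @return a `spectral_function` (dimensionless).
#' @export
gaussian_ttf <- function(fgrid, sigma_xy, sigma_z = sigma_xy) {
  u <- fgrid$freqs[[1]]; v <- fgrid$freqs[[2]]; w <- fgrid$freqs[[3]]
  rp <- exp(-2 * pi^2 * sigma_xy^2 * outer(u^2, v^2, "+"))
  az <- exp(-2 * pi^2 * sigma_z^2 * w^2)
  vals <- outer(as.vector(rp), az)
  dim(vals) <- fgrid$shape
  spectral_function(vals, fgrid, units = "1")
}

## ---- protocol-indexed library ---------------------------------------------

#' One image-quality library entry
#'
#' @param recon reconstruction label (e.g. `"fbp"`, `"asir"`, `"mbir"`).
#' @param thickness_mm slice thickness (mm).
#' @param dose_fraction fraction of reference dose, in (0, 1].
#' @param contrast_hu contrast (HU) at which the TTF was measured.
#' @param nps,ttf `spectral_function`s on a shared grid convention;
#'   `ttf` must be 1 at DC.
#' @return an `iq_entry`.
#' @export
iq_entry <- function(recon, thickness_mm, dose_fraction, contrast_hu, nps, ttf) {
  stopifnot(inherits(nps, "spectral_function"), inherits(ttf, "spectral_function"))
  if (dose_fraction <= 0 || dose_fraction > 1) {
    stop("dose_fraction must be in (0, 1]", call. = FALSE)
  }
  dc <- dc_index(ttf$grid)
  if (abs(ttf$values[dc[1], dc[2], dc[3]] - 1) > 1e-6) {
    stop("TTF must equal 1 at zero frequency", call. = FALSE)
  }
  structure(
    list(recon = recon, thickness_mm = thickness_mm,
         dose_fraction = dose_fraction, contrast_hu = contrast_hu,
         nps = nps, ttf = ttf, variance = riemann_integral(nps)),
    class = "iq_entry"
  )
}

#' Image-quality library: (NPS, TTF) indexed by acquisition protocol
#'
#' Keys are reconstruction label and slice thickness (categorical) plus dose
#' fraction / noise variance and contrast (continuous, interpolable). The dose
#' axis is keyed by the measured noise variance of each entry, since it is the
#' noise magnitude — not the nominal dose — that determines the working point.
#'
#' @param entries list of [iq_entry()] objects.
#' @param metadata optional provenance strings.
#' @return an `iq_library`.
#' @export
iq_library <- function(entries, metadata = list()) {
  stopifnot(length(entries) > 0, all(vapply(entries, inherits, logical(1), "iq_entry")))
  key <- vapply(entries, function(e) {
    sprintf("%s|%g|%g|%g", e$recon, e$thickness_mm, e$dose_fraction, e$contrast_hu)
  }, character(1))
  if (anyDuplicated(key)) stop("duplicate library keys", call. = FALSE)
  structure(list(entries = entries, metadata = metadata), class = "iq_library")
}

#' @export
print.iq_library <- function(x, ...) {
  cat(sprintf("<iq_library> %d entries\n", length(x$entries)))
  print(library_index(x))
  invisible(x)
}

#' Tabular index of an image-quality library
#' @param lib an `iq_library`.
#' @return tibble with one row per entry (recon, thickness, dose, contrast,
#'   noise variance).
#' @export
library_index <- function(lib) {
  purrr::map_dfr(lib$entries, function(e) {
    tibble::tibble(recon = e$recon, thickness_mm = e$thickness_mm,
                   dose_fraction = e$dose_fraction, contrast_hu = e$contrast_hu,
                   variance_hu2 = e$variance)
  })
}

blend_spectral <- function(a, b, t, units) {
  stopifnot_same_grid(a, b)
  spectral_function(a$values * (1 - t) + b$values * t, a$grid, units)
}

#' Interpolate (NPS, TTF) for a protocol from an image-quality library
#'
#' Reconstruction and slice thickness must match stored entries exactly.
#' Along the continuous axes the rule is value-wise linear interpolation
#' between the two bracketing entries: the NPS along dose — with the weight
#' computed in noise variance when `noise_variance` is given, else in dose
#' fraction — and the TTF along contrast (then dose). Queries outside the
#' library's hull raise an error naming the offending axis; exact key hits
#' return the stored objects unchanged.
#'
#' @param lib an `iq_library`.
#' @param recon,thickness_mm categorical keys (exact match).
#' @param dose_fraction,noise_variance working point on the dose axis; give
#'   one of the two.
#' @param contrast_hu contrast (HU) for the TTF lookup.
#' @return list with elements `nps`, `ttf` (spectral functions) and
#'   `variance` (HU^2 integral of the returned NPS).
#' @export
interpolate_library <- function(lib, recon, thickness_mm, dose_fraction = NULL,
                                noise_variance = NULL, contrast_hu) {
  stopifnot(inherits(lib, "iq_library"))
  ent <- lib$entries
  sub <- ent[vapply(ent, function(e) identical(e$recon, recon), logical(1))]
  if (!length(sub)) stop("reconstruction not in library: ", recon, call. = FALSE)
  sub <- sub[vapply(sub, function(e) abs(e$thickness_mm - thickness_mm) < 1e-9,
                    logical(1))]
  if (!length(sub)) {
    stop("slice_thickness not in library: ", thickness_mm, " mm", call. = FALSE)
  }
  if (is.null(dose_fraction) && is.null(noise_variance)) {
    stop("give `dose_fraction` or `noise_variance`", call. = FALSE)
  }

  doses <- sort(unique(vapply(sub, `[[`, numeric(1), "dose_fraction")))
  at_dose <- function(d) sub[vapply(sub, function(e) abs(e$dose_fraction - d) < 1e-12,
                                    logical(1))]
  dose_variance <- vapply(doses, function(d) at_dose(d)[[1]]$variance, numeric(1))

  bracket <- function(x, grid, axis) {
    if (x < min(grid) - 1e-9 || x > max(grid) + 1e-9) {
      stop(sprintf("%s = %g outside library range [%g, %g]",
                   axis, x, min(grid), max(grid)), call. = FALSE)
    }
    hi <- which(grid >= x - 1e-12)[1]
    lo <- max(hi - 1, 1)
    if (abs(grid[hi] - x) < 1e-12) lo <- hi
    t <- if (lo == hi) 0 else (x - grid[lo]) / (grid[hi] - grid[lo])
    list(lo = lo, hi = hi, t = t)
  }

  ## --- dose axis ---
  if (!is.null(noise_variance)) {
    ord <- order(dose_variance)
    bk <- bracket(noise_variance, dose_variance[ord], "noise_variance")
    d_lo <- doses[ord][bk$lo]; d_hi <- doses[ord][bk$hi]; tdose <- bk$t
  } else {
    bk <- bracket(dose_fraction, doses, "dose_fraction")
    d_lo <- doses[bk$lo]; d_hi <- doses[bk$hi]; tdose <- bk$t
  }

  ## --- contrast axis (TTF only), within each bracketing dose ---
  ttf_at_dose <- function(d) {
    es <- at_dose(d)
    cons <- sort(vapply(es, `[[`, numeric(1), "contrast_hu"))
    bc <- bracket(contrast_hu, cons, "contrast_hu")
    pick <- function(cv) es[[which(vapply(es, function(e) abs(e$contrast_hu - cv) < 1e-12,
                                          logical(1)))[1]]]
    lo <- pick(cons[bc$lo]); hi <- pick(cons[bc$hi])
    if (bc$lo == bc$hi) lo$ttf else blend_spectral(lo$ttf, hi$ttf, bc$t, "1")
  }
  nps_at_dose <- function(d) at_dose(d)[[1]]$nps

  if (d_lo == d_hi) {
    nps <- nps_at_dose(d_lo)
    ttf <- ttf_at_dose(d_lo)
  } else {
    nps <- blend_spectral(nps_at_dose(d_lo), nps_at_dose(d_hi), tdose, "HU^2.mm^3")
    ttf <- blend_spectral(ttf_at_dose(d_lo), ttf_at_dose(d_hi), tdose, "1")
  }
  list(nps = nps, ttf = ttf, variance = riemann_integral(nps))
}

#' Write / read an image-quality library as a plain-text directory
#'
#' `index.json` records the keys; each entry's NPS and TTF are stored with
#' [write_spectral_csv()].
#'
#' @param lib an `iq_library`.
#' @param dir directory path (created if needed).
#' @return `dir` invisibly; `read_iq_library()` returns the library.
#' @export
write_iq_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- library_index(lib)
  idx$id <- seq_len(nrow(idx))
  jsonlite::write_json(list(metadata = lib$metadata, entries = idx),
                       file.path(dir, "index.json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_along(lib$entries)) {
    write_spectral_csv(lib$entries[[i]]$nps, file.path(dir, sprintf("nps_%03d.csv", i)))
    write_spectral_csv(lib$entries[[i]]$ttf, file.path(dir, sprintf("ttf_%03d.csv", i)))
  }
  invisible(dir)
}

#' @rdname write_iq_library
#' @export
read_iq_library <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"), simplifyVector = TRUE)
  ent <- idx$entries
  entries <- lapply(seq_len(nrow(ent)), function(i) {
    iq_entry(
      recon = ent$recon[i], thickness_mm = ent$thickness_mm[i],
      dose_fraction = ent$dose_fraction[i], contrast_hu = ent$contrast_hu[i],
      nps = read_spectral_csv(file.path(dir, sprintf("nps_%03d.csv", ent$id[i]))),
      ttf = read_spectral_csv(file.path(dir, sprintf("ttf_%03d.csv", ent$id[i])))
    )
  })
  iq_library(entries, metadata = as.list(idx$metadata))
}
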