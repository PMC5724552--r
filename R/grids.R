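#' Voxel grid: a 3-D scalar field with physical spacing
#'
#' The common currency of the package: a 3-D array of intensities (HU) on an
#' anisotropic voxel lattice. Spacing is in mm and strictly positive; slice
#' thickness routinely differs from in-plane pitch, so nothing downstream ever
#' assumes cubic voxels.
#'
#' @param values 3-D numeric array of intensities (HU); all finite.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm.
#' @param origin numeric length-3, position of the first voxel centre in mm.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (any(dim(values) < 2L)) {
    stop("each dimension of a voxel grid must have at least 2 voxels", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive finite values (mm)", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("voxel values must all be finite", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %s voxels, spacing %s mm, range [%.2f, %.2f] HU\n",
    paste(dim(x$values), collapse = "x"),
    paste(format(x$spacing, digits = 4), collapse = "x"),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' Volume of one voxel in mm^3
#' @param x a `voxel_grid`
#' @return scalar, `dx*dy*dz` in mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Spatial coordinate vectors of a voxel grid (mm)
#' @param x a `voxel_grid`
#' @return list of three numeric vectors (voxel-centre coordinates per axis).
#' @export
voxel_coords <- function(x) {
  n <- dim(x$values)
  lapply(1:3, function(a) x$origin[a] + (seq_len(n[a]) - 1) * x$spacing[a])
}

#' DFT frequency grid matched to a voxel grid
#'
#' Frequencies are DC-centred: along an axis with `n` samples at spacing `d`
#' mm the bins are `(k - floor(n/2)) / (n d)` mm^-1 for `k = 0, ..., n-1`,
#' so the bin step is `1/(n d)` and the extreme bin reaches the Nyquist
#' frequency `1/(2 d)`. The DC bin sits at index `floor(n/2) + 1` on every
#' axis.
#'
#' @param shape integer length-3, samples per axis (each >= 2).
#' @param spacing_mm numeric length-3, voxel spacing in mm.
#' @return An object of class `frequency_grid` with elements `shape`,
#'   `spacing` (the generating voxel spacing), `deltas` (bin widths, mm^-1)
#'   and `freqs` (list of three DC-centred frequency vectors).
#' @export
make_frequency_grid <- function(shape, spacing_mm) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(shape) != 3L || any(shape < 2L)) {
    stop("`shape` must be 3 integers, each >= 2", call. = FALSE)
  }
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 strictly positive values", call. = FALSE)
  }
  deltas <- 1 / (shape * spacing_mm)
  freqs <- lapply(1:3, function(a) {
    (seq_len(shape[a]) - 1 - floor(shape[a] / 2)) * deltas[a]
  })
  structure(
    list(shape = shape, spacing = spacing_mm, deltas = deltas, freqs = freqs),
    class = "frequency_grid"
  )
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf(
    "<frequency_grid> %s bins, deltas (%s) mm^-1, Nyquist (%s) mm^-1\n",
    paste(x$shape, collapse = "x"),
    paste(format(x$deltas, digits = 4), collapse = ", "),
    paste(format(1 / (2 * x$spacing), digits = 4), collapse = ", ")
  ))
  invisible(x)
}

#' Index of the DC bin on each axis of a frequency grid
#' @param fgrid a `frequency_grid`
#' @return integer length-3.
#' @export
dc_index <- function(fgrid) floor(fgrid$shape / 2) + 1L

#' Spectral function: a non-negative 3-D field over spatial frequency
#'
#' Houses the NPS (HU^2 mm^3), TTF (dimensionless, 1 at DC) and the
#' task/template magnitude spectra. Values live on a DC-centred
#' [make_frequency_grid()] lattice.
#'
#' @param values 3-D numeric array, same shape as `fgrid`; non-negative.
#' @param fgrid a `frequency_grid`.
#' @param units unit string, e.g. `"HU^2.mm^3"` or `"1"`.
#' @return An object of class `spectral_function`.
#' @export
spectral_function <- function(values, fgrid, units = "1") {
  values <- as.array(values)
  if (!inherits(fgrid, "frequency_grid")) {
    stop("`fgrid` must be a frequency_grid", call. = FALSE)
  }
  if (!identical(dim(values), as.integer(fgrid$shape))) {
    stop("`values` shape does not match the frequency grid", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < -1e-12)) {
    stop("spectral values must be finite and non-negative", call. = FALSE)
  }
  values[values < 0] <- 0
  structure(
    list(values = values, grid = fgrid, units = units),
    class = "spectral_function"
  )
}

#' @export
print.spectral_function <- function(x, ...) {
  cat(sprintf(
    "<spectral_function> %s bins [%s], integral %.4g\n",
    paste(x$grid$shape, collapse = "x"), x$units, riemann_integral(x)
  ))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(as.integer(a$shape), as.integer(b$shape)) &&
    all(abs(a$deltas - b$deltas) <= tol * pmax(a$deltas, b$deltas))
}

stopifnot_same_grid <- function(...) {
  sfs <- list(...)
  g <- sfs[[1]]$grid
  for (s in sfs[-1]) {
    if (!same_grid(g, s$grid)) {
      stop("spectral functions are not on identical frequency grids", call. = FALSE)
    }
  }
  invisible(g)
}

## ---- transform conventions ------------------------------------------------

## Circular shifts that move the DC component between DFT order (index 1)
## and centred order (index floor(n/2)+1). Identical for even n; they differ
## for odd n, and fftshift3/ifftshift3 are exact inverses of each other.
shift_idx_fwd <- function(n) c((n - floor(n / 2) + 1):n, seq_len(n - floor(n / 2)))
shift_idx_inv <- function(n) c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))

fftshift3 <- function(x) {
  d <- dim(x)
  x[shift_idx_fwd(d[1]), shift_idx_fwd(d[2]), shift_idx_fwd(d[3]), drop = FALSE]
}

ifftshift3 <- function(x) {
  d <- dim(x)
  x[shift_idx_inv(d[1]), shift_idx_inv(d[2]), shift_idx_inv(d[3]), drop = FALSE]
}

#' Forward 3-D Fourier transform of a voxel grid (continuous convention)
#'
#' The discrete transform is multiplied by the voxel volume `dx dy dz`, so it
#' approximates the continuous Fourier integral and spectral quantities carry
#' physical units (an NPS in HU^2 mm^3, a task spectrum in HU mm^3). Under
#' this normalization Parseval's identity reads
#' `sum(|F|^2) du dv dw = sum(f^2) dx dy dz`. This convention is the contract
#' every module shares; [ifft_volume()] inverts it exactly.
#'
#' @param vg a `voxel_grid`.
#' @return complex 3-D array in DC-centred order, on the grid returned by
#'   `make_frequency_grid(dim(vg), vg$spacing)`.
#' @export
fft_volume <- function(vg) {
  stopifnot(inherits(vg, "voxel_grid"))
  fftshift3(stats::fft(vg$values)) * voxel_volume(vg)
}

#' Inverse of [fft_volume()]
#' @param fvals complex 3-D array, DC-centred order.
#' @param spacing voxel spacing (mm) of the target grid.
#' @param origin origin of the target grid.
#' @return a `voxel_grid` (real part; the imaginary residue of a transform of
#'   a real field is at machine-epsilon level and is dropped).
#' @export
ifft_volume <- function(fvals, spacing, origin = c(0, 0, 0)) {
  n <- prod(dim(fvals))
  vals <- Re(stats::fft(ifftshift3(fvals), inverse = TRUE)) / (n * prod(spacing))
  voxel_grid(vals, spacing, origin)
}

## ---- integration and radial averaging ------------------------------------

#' Riemann integral of a spectral function over frequency
#'
#' Sum of sample values times the frequency-bin volume `du dv dw`. For an NPS
#' this is the noise variance (HU^2); for a task function it is the object
#' power used in the normalization contract.
#'
#' @param sf a `spectral_function` (or bare 3-D array with `deltas` given).
#' @param deltas bin widths; taken from `sf` when it is a spectral function.
#' @param exclude_dc drop the DC bin from the sum.
#' @return scalar.
#' @export
riemann_integral <- function(sf, deltas = NULL, exclude_dc = FALSE) {
  if (inherits(sf, "spectral_function")) {
    vals <- sf$values
    deltas <- sf$grid$deltas
    dc <- dc_index(sf$grid)
  } else {
    vals <- as.array(sf)
    if (is.null(deltas)) stop("`deltas` required for a bare array", call. = FALSE)
    dc <- floor(dim(vals) / 2) + 1L
  }
  if (any(!is.finite(vals))) stop("spectral values must be finite", call. = FALSE)
  s <- sum(vals)
  if (exclude_dc) s <- s - vals[dc[1], dc[2], dc[3]]
  s * prod(deltas)
}

#' In-plane radial average of a spectral function
#'
#' Averages over bins of radial frequency `r = sqrt(u^2 + v^2)`, the standard
#' presentation of a CT noise power spectrum. Bin width is the larger of the
#' two in-plane frequency steps; the value in a bin is the mean of the samples
#' that fall in it, and empty bins are reported as `NA`, never as zero.
#'
#' @param sf a `spectral_function`.
#' @param collapse_axial average over all axial planes (default); otherwise one
#'   profile per axial frequency `w`.
#' @return a tibble with columns `freq` (bin-centre radial frequency, mm^-1),
#'   `value`, `n` (samples per bin) and, when `collapse_axial = FALSE`, `w`.
#' @export
radial_average_inplane <- function(sf, collapse_axial = TRUE) {
  stopifnot(inherits(sf, "spectral_function"))
  g <- sf$grid
  u <- g$freqs[[1]]; v <- g$freqs[[2]]
  r <- sqrt(outer(u^2, v^2, "+"))
  width <- max(g$deltas[1:2])
  bin <- as.integer(floor(r / width + 0.5))
  nbins <- max(bin) + 1L
  one_plane <- function(plane) {
    sums <- tapply(as.vector(plane), bin, sum)
    cnts <- tapply(rep(1, length(bin)), bin, sum)
    idx <- as.integer(names(sums)) + 1L
    value <- rep(NA_real_, nbins); n <- rep(0L, nbins)
    value[idx] <- sums / cnts
    n[idx] <- as.integer(cnts)
    tibble::tibble(freq = (seq_len(nbins) - 1) * width, value = value, n = n)
  }
  if (collapse_axial) {
    plane <- apply(sf$values, c(1, 2), mean)
    one_plane(plane)
  } else {
    w <- g$freqs[[3]]
    purrr::map_dfr(seq_along(w), function(k) {
      dplyr::mutate(one_plane(sf$values[, , k]), w = w[k], .before = 1)
    })
  }
}

#' Resample a spectral function onto another frequency grid
#'
#' Trilinear interpolation in frequency. Used to bring task/template spectra
#' onto the NPS grid before evaluating the estimability integrals; frequencies
#' outside the source grid get zero.
#'
#' @param sf a `spectral_function`.
#' @param target a `frequency_grid`.
#' @return a `spectral_function` on `target`.
#' @export
resample_spectral <- function(sf, target) {
  stopifnot(inherits(sf, "spectral_function"), inherits(target, "frequency_grid"))
  if (same_grid(sf$grid, target)) {
    return(spectral_function(sf$values, target, sf$units))
  }
  src <- sf$grid
  ax <- lapply(1:3, function(a) {
    f <- target$freqs[[a]]
    s <- src$freqs[[a]]
    pos <- (f - s[1]) / src$deltas[a] + 1
    i0 <- floor(pos)
    t <- pos - i0
    inside <- i0 >= 1 & i0 <= length(s) & (i0 < length(s) | t < 1e-9)
    i1 <- pmin(pmax(i0 + 1, 1), length(s))
    i0 <- pmin(pmax(i0, 1), length(s))
    list(i0 = i0, i1 = i1, t = t, inside = inside)
  })
  vals <- sf$values
  ## separable gather: interpolate axis by axis
  gather <- function(arr, axinfo, axis) {
    d <- dim(arr)
    pick <- function(i) {
      switch(axis,
        arr[i, , , drop = FALSE],
        arr[, i, , drop = FALSE],
        arr[, , i, drop = FALSE]
      )
    }
    lo <- pick(axinfo$i0); hi <- pick(axinfo$i1)
    tt <- axinfo$t
    shp <- dim(lo)
    ## broadcast the per-index weight along `axis`
    tarr <- switch(axis,
      array(tt, dim = shp),
      aperm(array(tt, dim = shp[c(2, 1, 3)]), c(2, 1, 3)),
      aperm(array(tt, dim = shp[c(3, 1, 2)]), c(2, 3, 1))
    )
    res <- lo * (1 - tarr) + hi * tarr
    mask <- switch(axis,
      array(axinfo$inside, dim = shp),
      aperm(array(axinfo$inside, dim = shp[c(2, 1, 3)]), c(2, 1, 3)),
      aperm(array(axinfo$inside, dim = shp[c(3, 1, 2)]), c(2, 3, 1))
    )
    res * mask
  }
  out <- gather(vals, ax[[1]], 1L)
  out <- gather(out, ax[[2]], 2L)
  out <- gather(out, ax[[3]], 3L)
  spectral_function(out, target, sf$units)
}

## ---- I/O ------------------------------------------------------------------

#' Read a NIfTI-1 volume as a voxel grid
#' @param path NIfTI file (`.nii` / `.nii.gz`); spacing comes from the header.
#' @return a `voxel_grid`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  spc <- RNifti::pixdim(img)[1:3]
  voxel_grid(array(as.numeric(img), dim = dim(img)[1:3]), spc)
}

#' Write a voxel grid to NIfTI-1
#' @param vg a `voxel_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vg, path) {
  img <- RNifti::asNifti(vg$values)
  RNifti::pixdim(img) <- vg$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a spectral function as plain text
#'
#' Long-format CSV (`u,v,w,value` in mm^-1) with a JSON sidecar (`<path>.json`)
#' recording shape, deltas, generating voxel spacing and units, so the object
#' round-trips exactly.
#'
#' @param sf a `spectral_function`.
#' @param path CSV path.
#' @return `path` invisibly; `read_spectral_csv()` returns the object.
#' @export
write_spectral_csv <- function(sf, path) {
  stopifnot(inherits(sf, "spectral_function"))
  g <- sf$grid
  df <- expand.grid(u = g$freqs[[1]], v = g$freqs[[2]], w = g$freqs[[3]],
                    KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(sf$values)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(shape = g$shape, spacing = g$spacing, deltas = g$deltas,
               units = sf$units)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectral_csv
#' @export
read_spectral_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  g <- make_frequency_grid(meta$shape, meta$spacing)
  spectral_function(array(df$value, dim = g$shape), g, meta$units)
}

#' Write a 1-D spectral profile (e.g. a radial NPS or a TTF) as CSV
#' @param profile tibble with columns `freq` and `value`.
#' @param path output CSV; columns are named `freq_mm^-1`, `value`.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  out <- data.frame(`freq_mm^-1` = profile$freq, value = profile$value,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
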