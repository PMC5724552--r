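#' Parametric spherical nodule model
#'
#' A homogeneous sphere of given diameter and contrast with an optional linear
#' edge ramp: intensity is `contrast` up to `diameter/2 - edge_width/2` from
#' the centre, falls linearly over `edge_width`, and is 0 outside. This is the
#' idealized lesion whose edge profile defines the volumetry task.
#'
#' @param diameter_mm sphere diameter (mm), > 0.
#' @param contrast_hu lesion-to-background contrast (HU); may be negative.
#' @param edge_width_mm width of the linear edge ramp (mm); 0 = hard edge.
#'   Must be smaller than the radius.
#' @param center_mm centre position (mm); `NULL` centres the nodule on
#'   whatever grid it is rasterized into.
#' @param label optional label carried into results tables.
#' @return An object of class `nodule_model`.
#' @export
nodule_model <- function(diameter_mm, contrast_hu, edge_width_mm = 0,
                         center_mm = NULL, label = NULL) {
  if (!is.numeric(diameter_mm) || diameter_mm <= 0) {
    stop("`diameter_mm` must be > 0", call. = FALSE)
  }
  if (edge_width_mm < 0 || edge_width_mm >= diameter_mm / 2) {
    stop("`edge_width_mm` must be in [0, diameter/2)", call. = FALSE)
  }
  structure(
    list(
      diameter_mm = diameter_mm, contrast_hu = contrast_hu,
      edge_width_mm = edge_width_mm, center_mm = center_mm,
      label = label %||% sprintf("d%.3gmm_c%.3gHU", diameter_mm, contrast_hu)
    ),
    class = "nodule_model"
  )
}

#' @export
print.nodule_model <- function(x, ...) {
  cat(sprintf(
    "<nodule_model> %s: diameter %.3g mm, contrast %.3g HU, edge %.3g mm\n",
    x$label, x$diameter_mm, x$contrast_hu, x$edge_width_mm
  ))
  invisible(x)
}

#' Analytic volume of a nodule model (mm^3)
#'
#' For the linear-ramp profile the half-intensity surface sits at the nominal
#' radius, so the nominal sphere volume `4/3 pi r^3` is the reference value.
#'
#' @param model a `nodule_model`.
#' @return scalar mm^3.
#' @export
nodule_volume <- function(model) {
  4 / 3 * pi * (model$diameter_mm / 2)^3
}

#' Read a nodule/template specification from YAML or JSON
#'
#' Expected fields: `diameter_mm`, `contrast_hu`, and optionally
#' `edge_width_mm`, `center_mm`, `label`.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a `nodule_model`.
#' @export
read_nodule_spec <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  nodule_model(
    diameter_mm = spec$diameter_mm,
    contrast_hu = spec$contrast_hu,
    edge_width_mm = spec$edge_width_mm %||% 0,
    center_mm = spec$center_mm,
    label = spec$label
  )
}

#' Default raster shape for a nodule (padded to twice its extent)
#' @param model a `nodule_model`.
#' @param spacing voxel spacing (mm).
#' @param pad linear padding factor relative to the nodule diameter.
#' @return integer length-3 shape.
#' @export
nodule_grid_shape <- function(model, spacing, pad = 2) {
  pmax(as.integer(ceiling(pad * model$diameter_mm / spacing)), 8L)
}

radial_profile_value <- function(d, r, w) {
  if (w <= 0) {
    (d <= r) + 0  # keeps dim attributes, unlike as.numeric()
  } else {
    ## array-first argument order so pmin/pmax preserve dim attributes
    pmin(pmax((r + w / 2 - d) / w, 0), 1)
  }
}

#' Rasterize a nodule model onto a voxel grid
#'
#' Voxel values are `contrast` times the partial-volume fraction. Voxels whose
#' centre is within half a voxel diagonal of the edge shell are supersampled
#' 3x per axis (27 sub-samples) so the discrete volume converges to the
#' analytic sphere volume; all other voxels are trivially inside or outside.
#'
#' @param model a `nodule_model`.
#' @param shape integer length-3 grid shape; default pads to twice the nodule
#'   extent.
#' @param spacing voxel spacing (mm).
#' @param origin grid origin (mm).
#' @return a `voxel_grid`; background is exactly 0.
#' @export
rasterize_nodule <- function(model, shape = NULL, spacing, origin = c(0, 0, 0)) {
  stopifnot(inherits(model, "nodule_model"))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  shape <- if (is.null(shape)) nodule_grid_shape(model, spacing) else as.integer(shape)
  r <- model$diameter_mm / 2
  w <- model$edge_width_mm
  coords <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
  center <- model$center_mm %||%
    vapply(1:3, function(a) mean(range(coords[[a]])), numeric(1))
  r_out <- r + w / 2
  lo <- vapply(1:3, function(a) coords[[a]][1] + 2 * spacing[a], numeric(1))
  hi <- vapply(1:3, function(a) coords[[a]][shape[a]] - 2 * spacing[a], numeric(1))
  if (any(center - r_out < lo) || any(center + r_out > hi)) {
    stop("nodule does not fit inside the grid with a 2-voxel margin", call. = FALSE)
  }
  dx2 <- outer((coords[[1]] - center[1])^2, (coords[[2]] - center[2])^2, "+")
  d <- sqrt(outer(as.vector(dx2), (coords[[3]] - center[3])^2, "+"))
  dim(d) <- shape
  halfdiag <- sqrt(sum((spacing / 2)^2))
  vals <- radial_profile_value(d, r, w)
  shell <- abs(d - r) <= (w / 2 + halfdiag)
  idx <- which(shell)
  if (length(idx)) {
    ijk <- arrayInd(idx, shape)
    sub <- (-1:1) / 3
    acc <- numeric(length(idx))
    cx <- coords[[1]][ijk[, 1]] - center[1]
    cy <- coords[[2]][ijk[, 2]] - center[2]
    cz <- coords[[3]][ijk[, 3]] - center[3]
    for (sx in sub) for (sy in sub) for (sz in sub) {
      ds <- sqrt((cx + sx * spacing[1])^2 + (cy + sy * spacing[2])^2 +
                   (cz + sz * spacing[3])^2)
      acc <- acc + radial_profile_value(ds, r, w)
    }
    vals[idx] <- acc / 27
  }
  voxel_grid(vals * model$contrast_hu, spacing, origin)
}

#' Spacing-aware discrete Laplacian (7-point stencil)
#'
#' Second differences along each axis divided by the squared spacing; exact
#' for quadratic fields. Boundary voxels, where the stencil is incomplete,
#' are set to 0.
#'
#' @param vg a `voxel_grid` with at least 3 voxels per axis.
#' @return a `voxel_grid` holding the Laplacian (HU/mm^2).
#' @export
laplacian_edge <- function(vg) {
  stopifnot(inherits(vg, "voxel_grid"))
  n <- dim(vg$values)
  if (any(n < 3L)) stop("laplacian_edge needs >= 3 voxels per axis", call. = FALSE)
  v <- vg$values
  h <- vg$spacing
  out <- array(0, n)
  i <- 2:(n[1] - 1); j <- 2:(n[2] - 1); k <- 2:(n[3] - 1)
  out[i, j, k] <-
    (v[i + 1, j, k] - 2 * v[i, j, k] + v[i - 1, j, k]) / h[1]^2 +
    (v[i, j + 1, k] - 2 * v[i, j, k] + v[i, j - 1, k]) / h[2]^2 +
    (v[i, j, k + 1] - 2 * v[i, j, k] + v[i, j, k - 1]) / h[3]^2
  voxel_grid(out, vg$spacing, vg$origin)
}

#' Task function of a voxelized nodule
#'
#' The volumetry task is edge detection: the nodule is differentiated with the
#' discrete Laplacian, Fourier transformed in 3-D, and the magnitude spectrum
#' is rescaled by a scalar so that its frequency-domain integral (the power of
#' the task) equals the power of the nodule in the spatial domain (the
#' absolute spatial integral of its intensity, HU mm^3). The resulting
#' `|Wtask|` encodes the lesion's size, contrast and edge profile.
#'
#' @param vg a `voxel_grid` holding the (background-free) nodule.
#' @param normalization `"power"` (default): integral of `|W|` equals the
#'   spatial integral of the nodule. `"parseval"`: integral of `|W|^2` equals
#'   the spatial integral of the squared nodule (both via the shared transform
#'   convention).
#' @return a `spectral_function` (units HU mm^3). An all-zero input yields an
#'   all-zero spectrum with attribute `degenerate = TRUE`.
#' @export
task_function <- function(vg, normalization = c("power", "parseval")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(vg, "voxel_grid"))
  fgrid <- make_frequency_grid(dim(vg$values), vg$spacing)
  lap <- laplacian_edge(vg)
  w <- Mod(fft_volume(lap))
  dv <- voxel_volume(vg)
  target <- if (normalization == "power") {
    abs(sum(vg$values)) * dv
  } else {
    sum(vg$values^2) * dv
  }
  raw <- if (normalization == "power") {
    riemann_integral(w, deltas = fgrid$deltas)
  } else {
    riemann_integral(w^2, deltas = fgrid$deltas)
  }
  if (raw <= 0 || target <= 0) {
    out <- spectral_function(array(0, dim(w)), fgrid, units = "HU.mm^3")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  s <- if (normalization == "power") target / raw else sqrt(target / raw)
  spectral_function(w * s, fgrid, units = "HU.mm^3")
}

#' Template function of a segmentation model
#'
#' The segmentation software's expectation of the lesion, expressed in the
#' Fourier domain. It is built exactly as a task function of the rasterized
#' template model, so a template identical to the nodule yields a spectrum
#' identical to the nodule's task function — the appropriate choice for
#' perfectly spherical lesions — while a mismatched template penalizes the
#' estimability index downstream.
#'
#' @param template_model a `nodule_model` describing the template.
#' @inheritParams rasterize_nodule
#' @inheritParams task_function
#' @return a `spectral_function` (units HU mm^3).
#' @export
template_function <- function(template_model, shape = NULL, spacing,
                              origin = c(0, 0, 0),
                              normalization = c("power", "parseval")) {
  task_function(
    rasterize_nodule(template_model, shape = shape, spacing = spacing,
                     origin = origin),
    normalization = normalization
  )
}
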