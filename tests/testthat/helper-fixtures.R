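## Shared fixtures and independent oracles, all built in code.

## Flat (white) spectral function with the given constant value.
flat_sf <- function(fgrid, value, units = "1") {
  spectral_function(array(value, fgrid$shape), fgrid, units)
}

## Independent triple-nested-loop oracle for the frequency-domain Riemann sum.
loop_integral <- function(values, deltas) {
  acc <- 0
  d <- dim(values)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        acc <- acc + values[i, j, k]
      }
    }
  }
  acc * prod(deltas)
}

## Independent brute-force evaluation of the estimability index: explicit
## triple loops over the frequency lattice, no shared code with the package
## implementation beyond the input arrays.
loop_eprime <- function(nps, ttf, wtask, wtemp, deltas, dc = NULL) {
  d <- dim(nps)
  num <- 0
  den <- 0
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        if (!is.null(dc) && i == dc[1] && j == dc[2] && k == dc[3]) next
        x <- ttf[i, j, k]^2 * wtask[i, j, k] * wtemp[i, j, k]
        num <- num + nps[i, j, k] * x
        den <- den + x
      }
    }
  }
  num <- num * prod(deltas)
  den <- den * prod(deltas)
  den / sqrt(num)
}

## Small reference nodules (sizes and contrast of the acrylic phantom
## inserts: 9.5 / 4.8 mm at 80 HU).
nodule_95 <- function() nodule_model(9.5, 80, label = "9.5mm")
nodule_48 <- function() nodule_model(4.8, 80, label = "4.8mm")

## A small two-recon synthetic library for lookup tests.
tiny_library <- function() {
  build_synthetic_library(
    dose_fractions = c(1, 0.5, 0.1),
    thicknesses_mm = c(0.625, 1.25),
    recons = c("fbp", "asir"),
    shape = c(24, 24, 24)
  )
}
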