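# Single-level separable 3D Haar decomposition. Orthonormal filters
# (L = (a+b)/sqrt(2), H = (a-b)/sqrt(2)) so total coefficient energy equals
# input energy on even-sized grids; odd axes are symmetrically padded by
# replicating the final slice.

haar_pair <- function(vol, axis) {
  d <- dim(vol)
  n <- d[axis]
  if (n %% 2 == 1) {
    # replicate last slice
    idx <- c(seq_len(n), n)
    vol <- switch(axis,
                  vol[idx, , , drop = FALSE],
                  vol[, idx, , drop = FALSE],
                  vol[, , idx, drop = FALSE])
    n <- n + 1
  }
  odd <- seq(1, n, by = 2)
  even <- odd + 1
  a <- switch(axis, vol[odd, , , drop = FALSE], vol[, odd, , drop = FALSE],
              vol[, , odd, drop = FALSE])
  b <- switch(axis, vol[even, , , drop = FALSE], vol[, even, , drop = FALSE],
              vol[, , even, drop = FALSE])
  list(L = (a + b) / sqrt(2), H = (a - b) / sqrt(2))
}

#' Single-level 3D Haar wavelet decomposition
#'
#' Applies the low/high-pass Haar filter pair along each axis in turn,
#' producing the eight decimated sub-band volumes LLL, HLL, LHL, HHL, LLH,
#' HLH, LHH, HHH, where letter k gives the filter applied along axis k
#' (L = low-pass, H = high-pass).
#'
#' @param values 3D numeric array (or `volume_image`).
#' @return named list of 8 sub-band arrays in canonical order.
#' @export
wavelet_decompose <- function(values) {
  if (inherits(values, "volume_image")) values <- values$values
  stopifnot(length(dim(values)) == 3L, all(dim(values) >= 2L))
  ax1 <- haar_pair(values, 1L)
  out <- list()
  for (f1 in c("L", "H")) {
    ax2 <- haar_pair(ax1[[f1]], 2L)
    for (f2 in c("L", "H")) {
      ax3 <- haar_pair(ax2[[f2]], 3L)
      for (f3 in c("L", "H")) {
        out[[paste0(f1, f2, f3)]] <- ax3[[f3]]
      }
    }
  }
  out[wavelet_band_names()]
}

#' Canonical order of the 8 wavelet sub-band keys
#' @export
wavelet_band_names <- function() {
  c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")
}

# Mask on the decimated lattice: nearest-neighbor, band voxel m maps to
# input voxel 2m-1.
decimate_mask <- function(mask) {
  d <- dim(mask)
  idx <- lapply(d, function(n) seq(1, n, by = 2))
  mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
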