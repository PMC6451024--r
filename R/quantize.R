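#' Gray-level quantization of a masked region
#'
#' Equal-width binning of the within-mask intensities into `n_levels` levels
#' from the within-mask minimum to maximum; bins are half-open
#' `[edge_i, edge_{i+1})` with the top bin closed. A constant region maps
#' every voxel to level 1. Quantization is invariant under affine rescaling
#' of the masked intensities.
#'
#' @param values 3D numeric array.
#' @param mask logical array of the same shape.
#' @param n_levels number of gray levels (default 32).
#' @return a `quantized_volume`: list with `values` (integer array,
#'   1..n_levels inside the mask, 0 outside) and `n_levels`.
#' @export
gray_level_quantize <- function(values, mask, n_levels = 32) {
  stopifnot(identical(dim(values), dim(mask)), n_levels >= 1)
  lev <- array(0L, dim = dim(values))
  v <- values[mask]
  if (length(v) == 0) stop("empty mask")
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) {
    lev[mask] <- 1L
  } else {
    w <- (hi - lo) / n_levels
    q <- floor((v - lo) / w) + 1
    lev[mask] <- as.integer(pmin(q, n_levels))
  }
  structure(list(values = lev, n_levels = as.integer(n_levels)),
            class = "quantized_volume")
}
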