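# Gaussian random fields and Gaussian smoothing, both by FFT on the periodic
# grid. Used by the phantom generator (class-specific texture) and the
# protocol-shift transform (acquisition blur).

fft_gaussian_kernel <- function(dims, sigma_vox) {
  # frequency response of a periodized Gaussian, separable per axis
  resp <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dims[ax]
    s <- sigma_vox[ax]
    if (s <= 0) {
      resp[[ax]] <- rep(1, n)
    } else {
      k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[1:n]
      omega <- 2 * pi * k / n
      resp[[ax]] <- exp(-0.5 * (s * omega)^2)
    }
  }
  outer(outer(resp[[1]], resp[[2]]), resp[[3]])
}

gauss_smooth <- function(vol, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  if (all(sigma_vox <= 0)) return(vol)
  dims <- dim(vol)
  ker <- fft_gaussian_kernel(dims, sigma_vox)
  Re(fft(fft(vol) * ker, inverse = TRUE)) / prod(dims)
}

#' Stationary Gaussian random field on a 3D grid
#'
#' Spectral synthesis: white Gaussian noise is smoothed with a Gaussian of
#' standard deviation `corr_length` voxels (the correlation length) and
#' re-standardized to zero mean and unit variance over the grid. Deterministic
#' for a fixed seed.
#'
#' @param dims integer length-3 grid shape.
#' @param corr_length correlation length in voxels (0 gives white noise).
#' @param seed integer seed.
#' @return a 3D array with mean 0 and SD 1.
#' @export
gaussian_random_field <- function(dims, corr_length, seed) {
  dims <- as.integer(rep_len(dims, 3L))
  w <- with_seed(seed, array(rnorm(prod(dims)), dim = dims))
  g <- if (corr_length > 0) gauss_smooth(w, rep(corr_length, 3L)) else w
  s <- sd(as.vector(g))
  if (s == 0) return(array(0, dim = dims))
  (g - mean(g)) / s
}
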