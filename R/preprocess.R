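#' Masked z-normalization of CE-T1W intensities
#'
#' Brings subjects onto a comparable intensity scale: the affine map that
#' gives the within-mask voxels mean 0 and unit (sample) variance is applied
#' to the whole volume. This is a simplified stand-in for histogram-based
#' white-matter normalization; it preserves the contract that downstream
#' features see a common scale.
#'
#' @param img a `volume_image` of modality CE-T1W.
#' @param brain_mask a `tumor_mask`-like binary mask (the normalization
#'   region, typically the brain).
#' @return the normalized `volume_image`.
#' @export
normalize_intensity <- function(img, brain_mask) {
  stopifnot_same_grid(img, brain_mask)
  v <- img$values[brain_mask$values]
  if (length(v) < 2) stop("brain mask must contain at least 2 voxels")
  m <- mean(v)
  s <- sd(v)
  if (s == 0) stop("constant image within mask: zero variance")
  volume_image((img$values - m) / s, img$voxel_size_mm, img$modality)
}

#' Brain mask from the b=0 diffusion volume
#'
#' Voxels above `frac` of the volume maximum; on phantoms this separates
#' tissue from zero-signal air.
#' @param b0 `volume_image`.
#' @param frac threshold fraction of the maximum (default 0.1).
#' @export
brain_mask_from_b0 <- function(b0, frac = 0.1) {
  tumor_mask(b0$values > frac * max(b0$values), b0$voxel_size_mm)
}

#' Two-point ADC map
#'
#' `ADC = ln(S0 / Sb) / b` per voxel from the diffusion signal at b = 0 and
#' b = `b` s/mm^2. Voxels with non-positive signal in either volume are
#' flagged invalid (NaN value, TRUE in `invalid_mask`), never silently
#' zeroed.
#'
#' @param b0,b1000 `volume_image`s on the same grid.
#' @param b diffusion weighting of the second volume, s/mm^2.
#' @return an `adc_map`: list with `values` (`volume_image`, mm^2/s),
#'   `b_value`, `invalid_mask` (`tumor_mask`).
#' @export
compute_adc_map <- function(b0, b1000, b = 1000) {
  stopifnot(b > 0)
  stopifnot_same_grid(b0, b1000)
  s0 <- b0$values
  sb <- b1000$values
  invalid <- (s0 <= 0) | (sb <= 0)
  adc <- array(NaN, dim = dim(s0))
  ok <- !invalid
  adc[ok] <- log(s0[ok] / sb[ok]) / b
  structure(list(values = volume_image(adc, b0$voxel_size_mm, "ADC"),
                 b_value = b,
                 invalid_mask = tumor_mask(invalid, b0$voxel_size_mm)),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("<adc_map> b=%g s/mm^2, %d invalid voxels\n", x$b_value,
              mask_count(x$invalid_mask)))
  invisible(x)
}

#' Flag ADC outliers beyond 3 SD of the ROI mean
#'
#' Mean and SD (sample, n-1) are computed once over the valid ROI voxels;
#' voxels farther than `k` SD from the mean are added to the invalid mask.
#' Values themselves are untouched.
#'
#' @param adc an `adc_map`.
#' @param roi `tumor_mask` region over which statistics are taken.
#' @param k SD multiplier (default 3).
#' @return the `adc_map` with an enlarged `invalid_mask`.
#' @export
clip_adc_outliers <- function(adc, roi, k = 3) {
  stopifnot(inherits(adc, "adc_map"))
  stopifnot_same_grid(adc$values, roi)
  valid_roi <- roi$values & !adc$invalid_mask$values
  if (!any(valid_roi)) stop("no valid voxels in ROI")
  v <- adc$values$values[valid_roi]
  m <- mean(v)
  s <- sd(v)
  out <- valid_roi & abs(adc$values$values - m) > k * s
  out[is.na(out)] <- FALSE
  adc$invalid_mask$values <- adc$invalid_mask$values | out
  adc
}

# Trilinear resampling of a bare array between voxel grids. Output voxel
# centers are placed on the shared physical extent; edge samples clamp.
resample_trilinear <- function(vol, spacing_in, spacing_out, out_dims = NULL) {
  dims <- dim(vol)
  if (is.null(out_dims)) {
    out_dims <- as.integer(ceiling(dims * spacing_in / spacing_out - 1e-9))
  }
  axinfo <- lapply(1:3, function(ax) {
    pos <- (seq_len(out_dims[ax]) - 0.5) * spacing_out[ax]
    xi <- pos / spacing_in[ax] + 0.5
    xi <- pmin(pmax(xi, 1), dims[ax])
    i0 <- pmin(floor(xi), dims[ax] - 1L)
    if (dims[ax] == 1L) i0 <- rep(1L, length(xi))
    f <- xi - i0
    if (dims[ax] == 1L) f <- rep(0, length(xi))
    list(i0 = as.integer(i0), f = f)
  })
  n1 <- out_dims[1]; n2 <- out_dims[2]; n3 <- out_dims[3]
  i0 <- axinfo[[1]]$i0; j0 <- axinfo[[2]]$i0; k0 <- axinfo[[3]]$i0
  fx <- axinfo[[1]]$f;  fy <- axinfo[[2]]$f;  fz <- axinfo[[3]]$f
  d1 <- dims[1]; d12 <- dims[1] * dims[2]
  # linear indices of the lower corner for the whole output grid
  I <- rep(i0, times = n2 * n3)
  J <- rep(rep(j0, each = n1), times = n3)
  K <- rep(k0, each = n1 * n2)
  FX <- rep(fx, times = n2 * n3)
  FY <- rep(rep(fy, each = n1), times = n3)
  FZ <- rep(fz, each = n1 * n2)
  base <- I + (J - 1L) * d1 + (K - 1L) * d12
  dx <- 1L; dy <- d1; dz <- d12
  out <-
    vol[base]                * (1 - FX) * (1 - FY) * (1 - FZ) +
    vol[base + dx]           * FX       * (1 - FY) * (1 - FZ) +
    vol[base + dy]           * (1 - FX) * FY       * (1 - FZ) +
    vol[base + dx + dy]      * FX       * FY       * (1 - FZ) +
    vol[base + dz]           * (1 - FX) * (1 - FY) * FZ +
    vol[base + dx + dz]      * FX       * (1 - FY) * FZ +
    vol[base + dy + dz]      * (1 - FX) * FY       * FZ +
    vol[base + dx + dy + dz] * FX       * FY       * FZ
  array(out, dim = out_dims)
}

resample_nearest <- function(vol, spacing_in, spacing_out, out_dims = NULL) {
  dims <- dim(vol)
  if (is.null(out_dims)) {
    out_dims <- as.integer(ceiling(dims * spacing_in / spacing_out - 1e-9))
  }
  idx <- lapply(1:3, function(ax) {
    pos <- (seq_len(out_dims[ax]) - 0.5) * spacing_out[ax]
    xi <- pos / spacing_in[ax] + 0.5
    as.integer(pmin(pmax(round(xi), 1), dims[ax]))
  })
  vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Resample a volume or mask to isotropic voxels
#'
#' Output spacing is `target_mm` per axis and the output shape is
#' `ceiling(extent / target_mm)`. Images are tri-linearly interpolated; masks
#' use nearest-neighbor so they stay binary. Resampling to the native spacing
#' is an exact identity.
#'
#' @param img a `volume_image` or `tumor_mask`.
#' @param target_mm target isotropic spacing, mm.
#' @export
resample_isotropic <- function(img, target_mm = 1) {
  stopifnot(target_mm > 0)
  tgt <- rep(target_mm, 3L)
  if (inherits(img, "tumor_mask")) {
    v <- resample_nearest(img$values + 0, img$voxel_size_mm, tgt)
    return(tumor_mask(v > 0.5, tgt))
  }
  if (max(abs(img$voxel_size_mm - tgt)) < 1e-12) return(img)
  v <- resample_trilinear(img$values, img$voxel_size_mm, tgt)
  volume_image(v, tgt, img$modality)
}

#' Full per-subject preprocessing
#'
#' Normalizes CE-T1W within the brain mask, computes the two-point ADC map,
#' flags within-ROI outliers beyond 3 SD, and resamples everything to
#' `target_mm` isotropic voxels. Co-registration is a no-op hook: synthetic
#' subjects are generated aligned.
#'
#' @param subject a `subject_record`.
#' @param b diffusion weighting, s/mm^2.
#' @param target_mm target isotropic spacing.
#' @return list with `ce_norm` (`volume_image`), `adc` (`adc_map`, outlier
#'   flagged), `mask` (`tumor_mask`), `brain_mask`.
#' @export
preprocess_subject <- function(subject, b = 1000, target_mm = 1) {
  brain <- brain_mask_from_b0(subject$dw_b0)
  ce <- normalize_intensity(subject$ce_t1w, brain)
  adc <- compute_adc_map(subject$dw_b0, subject$dw_b1000, b = b)
  adc <- clip_adc_outliers(adc, subject$mask_truth)
  ce <- resample_isotropic(ce, target_mm)
  mask <- resample_isotropic(subject$mask_truth, target_mm)
  adc$values <- resample_isotropic(adc$values, target_mm)
  adc$invalid_mask <- resample_isotropic(adc$invalid_mask, target_mm)
  list(ce_norm = ce, adc = adc, mask = mask, brain_mask = brain)
}
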