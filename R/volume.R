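#' 3D scalar volumes and binary masks
#'
#' `volume_image()` wraps a 3D numeric array together with its voxel spacing
#' (mm) and a modality tag; it is the unit every imaging stage consumes and
#' produces. `tumor_mask()` is the binary counterpart defined on the same
#' grid. Both are plain S3 objects around base arrays so that all of base R's
#' array machinery applies.
#'
#' @param values 3D numeric array.
#' @param voxel_size_mm numeric length-3 spacing per axis, strictly positive.
#' @param modality one of `"CE-T1W"`, `"DW-b0"`, `"DW-b1000"`, `"ADC"`,
#'   `"derived"`.
#' @return an object of class `volume_image` (resp. `tumor_mask`).
#' @export
volume_image <- function(values, voxel_size_mm = c(1, 1, 1),
                         modality = c("derived", "CE-T1W", "DW-b0",
                                      "DW-b1000", "ADC")) {
  modality <- match.arg(modality)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0)) {
    stop("voxel spacing must be strictly positive")
  }
  structure(
    list(values = values, voxel_size_mm = voxel_size_mm, modality = modality),
    class = "volume_image"
  )
}

#' @rdname volume_image
#' @export
tumor_mask <- function(values, voxel_size_mm = c(1, 1, 1)) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  storage.mode(values) <- "logical"
  values[is.na(values)] <- FALSE
  structure(
    list(values = values, voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L)),
    class = "tumor_mask"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s, %s voxels @ %s mm\n", x$modality,
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> %d voxels set, grid %s\n", sum(x$values),
              paste(dim(x$values), collapse = "x")))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$values)

#' @export
dim.tumor_mask <- function(x) dim(x$values)

#' Number of voxels set in a mask
#' @param mask a `tumor_mask`.
#' @export
mask_count <- function(mask) sum(mask$values)

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) {
    stop("grids do not match: ", paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"))
  }
  if (max(abs(a$voxel_size_mm - b$voxel_size_mm)) > 1e-9) {
    stop("voxel spacings do not match")
  }
  invisible(TRUE)
}

nifti_affine <- function(voxel_size_mm) {
  diag(c(voxel_size_mm, 1))
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] carrying
#' the voxel spacing through the NIfTI header. Masks are written as uint8.
#'
#' @param img a `volume_image` or `tumor_mask`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality modality tag to attach on read.
#' @export
write_volume_nifti <- function(img, path) {
  vals <- img$values
  hdr <- list(pixdim = c(-1, img$voxel_size_mm, 0, 0, 0, 0))
  if (inherits(img, "tumor_mask")) {
    storage.mode(vals) <- "integer"
    nim <- RNifti::asNifti(vals, reference = hdr, datatype = "uint8")
  } else {
    nim <- RNifti::asNifti(vals, reference = hdr, datatype = "double")
  }
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, modality = "derived") {
  nim <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(nim)[1:3]
  volume_image(array(as.numeric(nim), dim = dim(nim)[1:3]),
               voxel_size_mm = sp, modality = modality)
}

#' @rdname write_volume_nifti
#' @export
read_mask_nifti <- function(path) {
  nim <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(nim)[1:3]
  tumor_mask(array(as.numeric(nim) > 0.5, dim = dim(nim)[1:3]),
             voxel_size_mm = sp)
}
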