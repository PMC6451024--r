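#' Phantom specification for one synthetic subject
#'
#' Defines the geometry, class-conditional appearance and noise level of a
#' synthetic brain-tumor phantom. The two classes emulate the qualitative
#' radiological contrast the classifiers must learn: glioblastomas are
#' rim-enhancing with a darker core, fine-grained heterogeneous texture and
#' higher diffusivity (ADC about 1.0e-3 mm^2/s); PCNSLs enhance homogeneously
#' with a longer texture correlation length, lower within-tumor variance and
#' lower ADC (about 0.7e-3 mm^2/s).
#'
#' @param grid_shape voxels per axis (default 64^3).
#' @param voxel_size_mm spacing per axis in mm (default 1 mm isotropic).
#' @param tumor_radius_range tumor semi-axis range in voxels (default 8-14).
#' @param class_label `"glioblastoma"` or `"pcnsl"`.
#' @param gbm_params list: `rim_intensity`, `core_intensity`,
#'   `texture_corr_length` (voxels), `adc_mean` (mm^2/s), `heterogeneity_sd`.
#' @param pcnsl_params list: `enh_intensity`, `texture_corr_length`,
#'   `adc_mean`, `heterogeneity_sd`.
#' @param noise_sd additive Gaussian noise SD on all acquired volumes.
#' @param atypical whether a PCNSL subject is rendered atypical (necrotic
#'   darker core and inflated heterogeneity); no quantitative reference
#'   exists, so the default keeps every subject typical.
#' @param seed integer seed; the subject is a pure function of the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size_mm = c(1, 1, 1),
                         tumor_radius_range = c(8, 14),
                         class_label = c("glioblastoma", "pcnsl"),
                         gbm_params = list(rim_intensity = 100,
                                           core_intensity = 45,
                                           texture_corr_length = 2,
                                           adc_mean = 1.0e-3,
                                           heterogeneity_sd = 15),
                         pcnsl_params = list(enh_intensity = 95,
                                             texture_corr_length = 4,
                                             adc_mean = 0.7e-3,
                                             heterogeneity_sd = 4),
                         noise_sd = 2,
                         atypical = FALSE,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape <= 0)) stop("grid_shape must be positive")
  if (any(tumor_radius_range <= 0) || tumor_radius_range[2] < tumor_radius_range[1]) {
    stop("invalid tumor_radius_range")
  }
  # tumor (with boundary perturbation headroom) must fit with a 2-voxel margin
  max_extent <- max(tumor_radius_range) * 1.15 + 2
  if (any(max_extent > grid_shape / 2)) {
    stop(sprintf(paste0("tumor radius up to %.1f voxels cannot fit a %s grid ",
                        "with a 2-voxel margin"),
                 max(tumor_radius_range), paste(grid_shape, collapse = "x")))
  }
  if (any(gbm_params$adc_mean <= 0, pcnsl_params$adc_mean <= 0)) {
    stop("adc_mean must be strictly positive")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 class_label = class_label,
                 gbm_params = gbm_params, pcnsl_params = pcnsl_params,
                 noise_sd = noise_sd, atypical = isTRUE(atypical),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

radial_coordinate <- function(dims, center, semiaxes) {
  x <- (seq_len(dims[1]) - center[1]) / semiaxes[1]
  y <- (seq_len(dims[2]) - center[2]) / semiaxes[2]
  z <- (seq_len(dims[3]) - center[3]) / semiaxes[3]
  sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
}

#' Generate one synthetic subject
#'
#' Produces paired CE-T1W, DW b=0 and DW b=1000 volumes, the ground-truth
#' tumor mask, the true ADC map and a seed point inside the tumor. The DW
#' pair satisfies `dw_b1000 = dw_b0 * exp(-b * adc_true)` exactly, voxel-wise,
#' so the two-point ADC estimate recovers `adc_true` on every voxel with
#' positive signal.
#'
#' @param spec a [phantom_spec()].
#' @return a `subject_record`: list with `subject_id`, `class_label`,
#'   `ce_t1w`, `dw_b0`, `dw_b1000`, `adc_true`, `mask_truth`, `seed_point`.
#' @export
generate_subject <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$voxel_size_mm
  n <- prod(dims)
  is_gbm <- spec$class_label == "glioblastoma"
  par <- if (is_gbm) spec$gbm_params else spec$pcnsl_params

  # geometry: ellipsoid with smoothly perturbed boundary
  geo <- with_seed(derive_seed(spec$seed, 1), {
    list(semiaxes = runif(3, spec$tumor_radius_range[1], spec$tumor_radius_range[2]),
         jitter = runif(3, -2, 2))
  })
  center <- dims / 2 + 0.5 + geo$jitter
  u <- radial_coordinate(dims, center, geo$semiaxes)
  pert <- gaussian_random_field(dims, 6, derive_seed(spec$seed, 2))
  u_eff <- u * (1 + 0.06 * pert)
  mask <- u_eff <= 1
  if (!any(mask)) stop("degenerate phantom: empty tumor mask")

  # brain: sphere of background tissue; air outside is zero-signal
  brain <- radial_coordinate(dims, dims / 2 + 0.5, rep(0.46 * min(dims), 3)) <= 1
  bg_field <- gaussian_random_field(dims, 8, derive_seed(spec$seed, 3))

  het <- gaussian_random_field(dims, par$texture_corr_length,
                               derive_seed(spec$seed, 4))
  het_sd <- par$heterogeneity_sd
  necrotic <- !is_gbm && spec$atypical
  if (necrotic) het_sd <- het_sd * 2.5

  ce <- array(0, dim = dims)
  ce[brain] <- 30 + 2.5 * bg_field[brain]
  if (is_gbm) {
    rim <- mask & u_eff > 0.70
    core <- mask & !rim
    ce[rim] <- par$rim_intensity
    ce[core] <- par$core_intensity
  } else {
    ce[mask] <- par$enh_intensity
    if (necrotic) ce[mask & u_eff <= 0.5] <- 0.5 * par$enh_intensity
  }
  ce[mask] <- ce[mask] + het_sd * het[mask]

  # true diffusivity, strictly positive (mm^2/s)
  adc_fluct <- (het_sd / 100) * par$adc_mean
  adc <- array(2.0e-3, dim = dims)
  adc[brain] <- 0.80e-3 + 0.03e-3 * bg_field[brain]
  adc[mask] <- par$adc_mean + adc_fluct * het[mask]
  adc <- pmax(adc, 1e-5)

  b0 <- array(2, dim = dims)
  b0[brain] <- 400 + 10 * bg_field[brain]
  b0[mask] <- 380 + 4 * het[mask]

  if (spec$noise_sd > 0) {
    noise <- with_seed(derive_seed(spec$seed, 5),
                       array(rnorm(2 * n, sd = spec$noise_sd), dim = c(dims, 2)))
    ce <- ce + noise[, , , 1]
    b0 <- b0 + noise[, , , 2]
  }
  b0 <- pmax(b0, 1)
  b1000 <- b0 * exp(-1000 * adc)

  mk <- tumor_mask(mask, sp)
  # seed point: in-mask voxel closest to the tumor center
  idx <- which(mask)
  seed_point <- arrayInd(idx[which.min(u_eff[idx])], dims)[1, ]

  structure(list(
    subject_id = sprintf("s%08d", spec$seed %% 100000000L),
    class_label = spec$class_label,
    ce_t1w = volume_image(ce, sp, "CE-T1W"),
    dw_b0 = volume_image(b0, sp, "DW-b0"),
    dw_b1000 = volume_image(b1000, sp, "DW-b1000"),
    adc_true = volume_image(adc, sp, "ADC"),
    mask_truth = mk,
    seed_point = as.integer(seed_point)
  ), class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s [%s], tumor %d voxels\n", x$subject_id,
              x$class_label, mask_count(x$mask_truth)))
  invisible(x)
}

#' Generate a seeded two-class cohort
#'
#' Subjects are ordered glioblastoma first, then PCNSL; per-subject seeds are
#' spawned deterministically from the cohort seed, so the cohort is a pure
#' function of its arguments. `atypical_fraction` renders the stated leading
#' fraction of PCNSL subjects atypical.
#'
#' @param n_gbm,n_pcnsl subject counts per class (each >= 1).
#' @param spec_template a [phantom_spec()] providing everything but the class
#'   label and seed.
#' @param seed cohort master seed.
#' @param atypical_fraction fraction of PCNSL subjects with atypical
#'   (necrotic, heterogeneous) appearance.
#' @return list of `subject_record`s with unique ids.
#' @export
generate_cohort <- function(n_gbm, n_pcnsl, spec_template = phantom_spec(),
                            seed = 1L, atypical_fraction = 0) {
  stopifnot(n_gbm >= 1, n_pcnsl >= 1)
  labels <- c(rep("glioblastoma", n_gbm), rep("pcnsl", n_pcnsl))
  n_atyp <- floor(atypical_fraction * n_pcnsl)
  lapply(seq_along(labels), function(i) {
    sp <- spec_template
    sp$class_label <- labels[i]
    sp$atypical <- labels[i] == "pcnsl" && (i - n_gbm) <= n_atyp
    sp$seed <- derive_seed(seed, i)
    subj <- generate_subject(sp)
    subj$subject_id <- sprintf("%s_%03d", ifelse(labels[i] == "pcnsl", "pcnsl", "gbm"), i)
    subj
  })
}

#' Acquisition protocol shift
#'
#' Parameterizes the systematic differences between the training-site and an
#' external-site acquisition: global intensity scaling, extra noise, scanner
#' blur, thicker slices (resampled back to the native grid, emulating the
#' external diffusion protocol's 3-5 mm slices) and a nuisance intensity
#' drift from differing TE/TR. The identity shift leaves volumes
#' bit-identical.
#'
#' @param intensity_scale multiplicative intensity factor.
#' @param extra_noise_sd additive noise SD.
#' @param blur_fwhm_mm Gaussian blur FWHM in mm.
#' @param slice_thickness_mm acquired slice thickness along the third axis.
#' @param te_tr_jitter SD of a per-volume global intensity offset.
#' @return an object of class `protocol_shift`.
#' @export
protocol_shift <- function(intensity_scale = 1, extra_noise_sd = 0,
                           blur_fwhm_mm = 0, slice_thickness_mm = 1,
                           te_tr_jitter = 0) {
  stopifnot(intensity_scale > 0, extra_noise_sd >= 0, blur_fwhm_mm >= 0,
            slice_thickness_mm > 0, te_tr_jitter >= 0)
  structure(list(intensity_scale = intensity_scale,
                 extra_noise_sd = extra_noise_sd,
                 blur_fwhm_mm = blur_fwhm_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 te_tr_jitter = te_tr_jitter),
            class = "protocol_shift")
}

#' Default external-site shift used by the experiment orchestrator
#' @export
default_external_shift <- function() {
  protocol_shift(intensity_scale = 1.1, extra_noise_sd = 3,
                 blur_fwhm_mm = 2, slice_thickness_mm = 4,
                 te_tr_jitter = 2)
}

shift_is_identity <- function(shift) {
  shift$intensity_scale == 1 && shift$extra_noise_sd == 0 &&
    shift$blur_fwhm_mm == 0 && shift$te_tr_jitter == 0
}

shift_one_volume <- function(img, shift, seed) {
  v <- img$values
  sp <- img$voxel_size_mm
  if (shift$slice_thickness_mm > sp[3] + 1e-12) {
    thick <- resample_trilinear(v, sp, c(sp[1], sp[2], shift$slice_thickness_mm))
    v <- resample_trilinear(thick, c(sp[1], sp[2], shift$slice_thickness_mm),
                            sp, out_dims = dim(img$values))
  }
  if (shift$blur_fwhm_mm > 0) {
    v <- gauss_smooth(v, shift$blur_fwhm_mm / 2.354820045 / sp)
  }
  if (shift$intensity_scale != 1) v <- v * shift$intensity_scale
  if (shift$te_tr_jitter > 0) {
    v <- v + with_seed(derive_seed(seed, 91), rnorm(1, sd = shift$te_tr_jitter))
  }
  if (shift$extra_noise_sd > 0) {
    v <- v + with_seed(derive_seed(seed, 92),
                       array(rnorm(length(v), sd = shift$extra_noise_sd), dim = dim(v)))
  }
  volume_image(v, sp, img$modality)
}

#' Apply a protocol shift to a subject
#'
#' Image volumes are degraded (thick-slice resampling, blur, scaling, drift,
#' noise, in that order); the truth mask, true ADC and label are never
#' touched. Deterministic given the seed; the identity shift returns the
#' subject unchanged.
#'
#' @param subject a `subject_record`.
#' @param shift a [protocol_shift()].
#' @param seed integer seed for the stochastic parts.
#' @export
apply_protocol_shift <- function(subject, shift, seed = 1L) {
  stopifnot(inherits(shift, "protocol_shift"))
  sp <- subject$ce_t1w$voxel_size_mm
  if (shift$slice_thickness_mm < sp[3] - 1e-12) {
    stop("slice_thickness_mm must be >= the native slice spacing")
  }
  if (shift_is_identity(shift) && shift$slice_thickness_mm <= sp[3] + 1e-12) {
    return(subject)
  }
  out <- subject
  out$ce_t1w <- shift_one_volume(subject$ce_t1w, shift, derive_seed(seed, 1))
  out$dw_b0 <- shift_one_volume(subject$dw_b0, shift, derive_seed(seed, 2))
  out$dw_b1000 <- shift_one_volume(subject$dw_b1000, shift, derive_seed(seed, 3))
  out$dw_b0$values <- pmax(out$dw_b0$values, 1)
  out$dw_b1000$values <- pmax(out$dw_b1000$values, 1e-3)
  out
}

#' Write a subject's volumes as NIfTI plus return manifest row
#'
#' @param subject a `subject_record`.
#' @param dir output directory (created if needed).
#' @return (invisibly) a one-row data.frame manifest entry.
#' @export
write_subject <- function(subject, dir) {
  sd <- file.path(dir, subject$subject_id)
  dir.create(sd, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ce_t1w = file.path(sd, "ce_t1w.nii.gz"),
             dw_b0 = file.path(sd, "dw_b0.nii.gz"),
             dw_b1000 = file.path(sd, "dw_b1000.nii.gz"),
             mask = file.path(sd, "mask.nii.gz"))
  write_volume_nifti(subject$ce_t1w, paths["ce_t1w"])
  write_volume_nifti(subject$dw_b0, paths["dw_b0"])
  write_volume_nifti(subject$dw_b1000, paths["dw_b1000"])
  write_volume_nifti(subject$mask_truth, paths["mask"])
  invisible(data.frame(subject_id = subject$subject_id,
                       label = subject$class_label,
                       seed_i = subject$seed_point[1],
                       seed_j = subject$seed_point[2],
                       seed_k = subject$seed_point[3],
                       ce_t1w = paths[["ce_t1w"]], dw_b0 = paths[["dw_b0"]],
                       dw_b1000 = paths[["dw_b1000"]], mask = paths[["mask"]],
                       stringsAsFactors = FALSE))
}

#' @rdname write_subject
#' @param cohort list of subjects.
#' @export
write_cohort <- function(cohort, dir) {
  rows <- lapply(cohort, write_subject, dir = dir)
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Class labels of a cohort
#' @param cohort list of `subject_record`s.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort, `[[`, character(1), "class_label")
}
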