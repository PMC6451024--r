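#' The canonical 936-feature manifest
#'
#' Defines the name, source image and group of every radiomic feature
#' extracted per image channel: 17 first-order + 87 texture (22 GLCM
#' descriptors at each of 3 pair distances, direction-averaged over the 13
#' unique 3D directions, plus 21 direction-averaged GLRLM descriptors) on the
#' original image, and the same 104 on each of the 8 Haar wavelet sub-bands,
#' for 104 + 832 = 936 features. The arithmetic (17 + 87 = 104,
#' 104 x 8 = 832, total 936) is asserted at construction.
#'
#' @return a data.frame with columns `name`, `source`, `group`, `feature`.
#' @export
feature_manifest <- function() {
  per_image <- rbind(
    data.frame(group = "firstorder", feature = first_order_names(),
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(1:3, function(d) {
      data.frame(group = paste0("glcm_d", d), feature = glcm_feature_names(),
                 stringsAsFactors = FALSE)
    })),
    data.frame(group = "glrlm", feature = glrlm_feature_names(),
               stringsAsFactors = FALSE)
  )
  stopifnot(nrow(per_image) == 104L,
            sum(per_image$group == "firstorder") == 17L,
            sum(per_image$group != "firstorder") == 87L)
  sources <- c("original", wavelet_band_names())
  man <- do.call(rbind, lapply(sources, function(src) {
    data.frame(source = src, group = per_image$group,
               feature = per_image$feature, stringsAsFactors = FALSE)
  }))
  man$name <- paste(man$source, man$group, man$feature, sep = ":")
  stopifnot(nrow(man) == 936L, !anyDuplicated(man$name),
            sum(man$source != "original") == 832L)
  man[, c("name", "source", "group", "feature")]
}

# 104 features (17 first-order + 87 texture) for one image/mask pair
features_one_image <- function(values, mask, n_levels = 32) {
  if (!any(mask)) {
    warning("empty mask on sub-band; features set to 0")
    nm <- c(first_order_names(),
            unlist(lapply(1:3, function(d) glcm_feature_names()), use.names = FALSE),
            glrlm_feature_names())
    return(stats::setNames(numeric(104), nm))
  }
  # texture depends only on in-mask voxels: crop to the mask bounding box
  bb <- lapply(1:3, function(ax) {
    r <- range(which(apply(mask, ax, any)))
    r[1]:r[2]
  })
  values <- values[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  mask <- mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  fo <- first_order_features(values, mask, n_bins = n_levels)
  q <- gray_level_quantize(values, mask, n_levels)
  q$values <- array(as.integer(q$values), dim = dim(q$values))
  dirs <- glcm_directions()
  glcm_by_d <- lapply(1:3, function(d) {
    acc <- matrix(0, nrow(dirs), 22)
    empty <- 0L
    for (r in seq_len(nrow(dirs))) {
      g <- compute_glcm(q, dirs[r, ], d)
      if (g$n_pairs == 0) empty <- empty + 1L
      acc[r, ] <- suppressWarnings(glcm_features(g))
    }
    if (empty == nrow(dirs)) {
      warning(sprintf("no voxel pairs at distance %d; GLCM features 0", d))
    }
    colMeans(acc)
  })
  glr <- colMeans(do.call(rbind, lapply(seq_len(nrow(dirs)), function(r) {
    glrlm_features(compute_glrlm(q, dirs[r, ]))
  })))
  out <- c(fo, unlist(glcm_by_d, use.names = FALSE), glr)
  names(out) <- c(first_order_names(),
                  unlist(lapply(1:3, function(d) {
                    paste0("d", d, ":", glcm_feature_names())
                  }), use.names = FALSE),
                  glrlm_feature_names())
  out
}

#' Extract the full 936-feature vector for one image channel
#'
#' Computes the manifest's 104 first-order + texture features on the original
#' (preprocessed) image and on each of its 8 single-level Haar sub-bands,
#' with the tumor mask carried to each sub-band grid by nearest-neighbor on
#' the decimated lattice. Deterministic given its inputs.
#'
#' @param img `volume_image` (or bare 3D array), already preprocessed.
#' @param mask `tumor_mask` (or logical array) on the same grid, nonempty.
#' @param manifest the [feature_manifest()] (computed if omitted).
#' @param n_levels gray levels for quantization (default 32).
#' @return named numeric vector of length 936 in manifest order.
#' @export
extract_all_features <- function(img, mask, manifest = feature_manifest(),
                                 n_levels = 32) {
  values <- if (inherits(img, "volume_image")) img$values else img
  mvals <- if (inherits(mask, "tumor_mask")) mask$values else mask
  stopifnot(identical(dim(values), dim(mvals)))
  if (!any(mvals)) stop("empty mask")
  bands <- wavelet_decompose(values)
  bmask <- decimate_mask(mvals)
  blocks <- c(list(original = features_one_image(values, mvals, n_levels)),
              lapply(bands, features_one_image, mask = bmask,
                     n_levels = n_levels))
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- manifest$name
  stopifnot(length(out) == 936L)
  out
}

#' Feature table for a cohort
#'
#' Runs preprocessing and per-channel feature extraction for every subject.
#' Channel `"ce"` uses the normalized CE-T1W volume, `"adc"` the computed ADC
#' map (outlier-flagged voxels replaced by the within-ROI mean of the valid
#' voxels), and `"ce+adc"` the 1872-column concatenation.
#'
#' @param cohort list of `subject_record`s.
#' @param channels `"ce"`, `"adc"` or `"ce+adc"`.
#' @param manifest the [feature_manifest()].
#' @return list with `features` (matrix subjects x features), `labels`
#'   (character), `subject_ids`.
#' @export
cohort_feature_table <- function(cohort, channels = c("ce+adc", "ce", "adc"),
                                 manifest = feature_manifest()) {
  channels <- match.arg(channels)
  rows <- lapply(cohort, function(subj) {
    pp <- preprocess_subject(subj)
    mask <- pp$mask
    out <- NULL
    if (channels %in% c("ce", "ce+adc")) {
      fe <- extract_all_features(pp$ce_norm, mask, manifest)
      names(fe) <- paste0("ce:", names(fe))
      out <- c(out, fe)
    }
    if (channels %in% c("adc", "ce+adc")) {
      adcv <- pp$adc$values$values
      bad <- pp$adc$invalid_mask$values & mask$values
      good <- mask$values & !pp$adc$invalid_mask$values
      if (any(bad)) adcv[bad] <- mean(adcv[good])
      fe <- extract_all_features(adcv, mask$values, manifest)
      names(fe) <- paste0("adc:", names(fe))
      out <- c(out, fe)
    }
    out
  })
  feats <- do.call(rbind, rows)
  rownames(feats) <- vapply(cohort, `[[`, character(1), "subject_id")
  list(features = feats, labels = cohort_labels(cohort),
       subject_ids = rownames(feats))
}

#' Z-transform a feature table against a training subset
#'
#' Per-feature standardization `(x - mean_fit) / sd_fit` with mean and sample
#' SD estimated on the `fit_rows` only; the same affine map is applied to all
#' rows, so validation rows never leak into the scaler. Features constant on
#' the fit rows are mapped to 0 with a warning.
#'
#' @param table numeric matrix, subjects x features.
#' @param fit_rows integer/logical row index of the fitting (training)
#'   subset, at least 2 rows.
#' @return list with `table` (standardized), `center`, `scale`.
#' @export
z_transform_features <- function(table, fit_rows = seq_len(nrow(table))) {
  fit <- table[fit_rows, , drop = FALSE]
  stopifnot(nrow(fit) >= 2)
  ctr <- colMeans(fit)
  scl <- apply(fit, 2, sd)
  flat <- scl == 0 | !is.finite(scl)
  if (any(flat)) {
    warning(sprintf("%d constant feature(s) in fit rows mapped to 0", sum(flat)))
    scl[flat] <- 1
  }
  out <- sweep(sweep(table, 2, ctr, `-`), 2, scl, `/`)
  list(table = out, center = ctr, scale = scl)
}
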