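vol3 <- function(v, sp = c(1, 1, 1), modality = "derived") {
  volume_image(array(v, dim = c(length(v), 1, 1)), sp, modality)
}

test_that("masked z-normalization maps {10,20,30} to {-1,0,1}", {
  img <- vol3(c(10, 20, 30), modality = "CE-T1W")
  msk <- tumor_mask(array(TRUE, dim = c(3, 1, 1)))
  out <- normalize_intensity(img, msk)
  expect_equal(as.vector(out$values), c(-1, 0, 1))
  again <- normalize_intensity(out, msk)
  expect_equal(again$values, out$values, tolerance = 1e-12)
  one <- tumor_mask(array(c(TRUE, FALSE, FALSE), dim = c(3, 1, 1)))
  expect_error(normalize_intensity(img, one), "2 voxels")
  flat <- vol3(c(5, 5, 5), modality = "CE-T1W")
  expect_error(normalize_intensity(flat, msk), "zero variance")
})

test_that("two-point ADC matches the closed form and flags bad voxels", {
  b0 <- vol3(c(500, 1000, 1000), modality = "DW-b0")
  b1 <- vol3(c(500, 100, 0), modality = "DW-b1000")
  adc <- compute_adc_map(b0, b1, b = 1000)
  expect_equal(adc$values$values[1, 1, 1], 0)
  expect_equal(adc$values$values[2, 1, 1], log(10) / 1000, tolerance = 1e-12)
  expect_true(adc$invalid_mask$values[3, 1, 1])
  expect_false(any(adc$invalid_mask$values[1:2, 1, 1]))
  b1_bad <- vol3(c(500, 100), modality = "DW-b1000")
  expect_error(compute_adc_map(b0, b1_bad), "grids do not match")
})

test_that("regenerating the diffusion signal from ADC round-trips", {
  s <- generate_subject(small_spec(seed = 8))
  adc <- compute_adc_map(s$dw_b0, s$dw_b1000)
  sb <- s$dw_b0$values * exp(-1000 * adc$values$values)
  rel <- abs(sb - s$dw_b1000$values) / pmax(abs(s$dw_b1000$values), 1e-300)
  expect_lt(max(rel), 1e-9)
})

test_that("3-SD outlier clipping flags exactly the planted outlier", {
  set.seed(123)
  vals <- c(rnorm(1000), 10)
  n <- length(vals)
  b0 <- vol3(rep(exp(1), n), modality = "DW-b0") # ADC = 1 - vals/1000... build directly
  adc <- compute_adc_map(b0, vol3(exp(1 - vals)), b = 1000)
  # adc values = vals/1000; statistics scale with them
  roi <- tumor_mask(array(TRUE, dim = c(n, 1, 1)))
  out <- clip_adc_outliers(adc, roi)
  flagged <- which(out$invalid_mask$values)
  m <- mean(vals)
  sdev <- sd(vals)
  expected <- which(abs(vals - m) > 3 * sdev) # direct computation oracle
  expect_identical(flagged, expected)
  expect_true(n %in% flagged)
})

test_that("outlier clipping is single-pass, monotone, and guards edge cases", {
  sym <- vol3(rep(c(-1, 1), 10) / 1000 + 2e-3)
  adc <- compute_adc_map(vol3(rep(1, 20), modality = "DW-b0"),
                         vol3(exp(-(rep(c(-1, 1), 10) / 1000 + 2e-3) * 1000)))
  roi <- tumor_mask(array(TRUE, dim = c(20, 1, 1)))
  expect_equal(mask_count(clip_adc_outliers(adc, roi)$invalid_mask), 0)
  # equal values: nothing removed
  adc_flat <- compute_adc_map(vol3(rep(2, 5), modality = "DW-b0"),
                              vol3(rep(1, 5)))
  roi5 <- tumor_mask(array(TRUE, dim = c(5, 1, 1)))
  expect_equal(mask_count(clip_adc_outliers(adc_flat, roi5)$invalid_mask), 0)
  # removal set shrinks as the multiplier grows
  set.seed(4)
  vals <- c(rnorm(200), 6, 8)
  adc2 <- compute_adc_map(vol3(rep(1, 202), modality = "DW-b0"),
                          vol3(exp(-vals)))
  roi2 <- tumor_mask(array(TRUE, dim = c(202, 1, 1)))
  sizes <- vapply(c(2, 3, 4, 5), function(k) {
    mask_count(clip_adc_outliers(adc2, roi2, k = k)$invalid_mask)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("isotropic resampling obeys shape arithmetic and identities", {
  arr <- array(rnorm(32^3), dim = c(32, 32, 32))
  img <- volume_image(arr, c(2, 2, 2))
  out <- resample_isotropic(img, 1)
  expect_identical(dim(out$values), c(64L, 64L, 64L))
  expect_equal(out$voxel_size_mm, c(1, 1, 1))
  # constant stays constant at any target
  cim <- volume_image(array(7, dim = c(10, 10, 10)), c(1.7, 1.7, 1.7))
  for (t in c(0.8, 1, 2.5)) {
    expect_equal(range(resample_isotropic(cim, t)$values), c(7, 7))
  }
  # native spacing is an exact identity
  nat <- resample_isotropic(volume_image(arr, c(1, 1, 1)), 1)
  expect_equal(nat$values, arr, tolerance = 1e-12)
  # masks stay binary under nearest-neighbor
  mk <- tumor_mask(array(runif(8^3) > 0.5, dim = c(8, 8, 8)), c(2, 2, 2))
  rmk <- resample_isotropic(mk, 1)
  expect_type(rmk$values, "logical")
  expect_identical(dim(rmk$values), c(16L, 16L, 16L))
})

test_that("resampling preserves within-tumor mean of smooth phantoms to 2%", {
  # smooth intensity field + ellipsoidal mask
  vol <- 100 + 20 * gaussian_random_field(c(32, 32, 32), 4, seed = 17)
  ctr <- c(16.5, 16.5, 16.5)
  dist <- sqrt(outer(outer((seq_len(32) - ctr[1])^2,
                           (seq_len(32) - ctr[2])^2, `+`),
                     (seq_len(32) - ctr[3])^2, `+`))
  mk <- dist <= 10
  for (target in c(0.5, 2)) {
    up <- radiomlp:::resample_trilinear(vol, c(1, 1, 1), rep(target, 3))
    mk_up <- radiomlp:::resample_nearest(mk + 0, c(1, 1, 1),
                                         rep(target, 3)) > 0.5
    expect_lt(abs(mean(up[mk_up]) - mean(vol[mk])) / abs(mean(vol[mk])), 0.02)
  }
})

test_that("full preprocessing yields a normalized CE and valid ADC", {
  s <- generate_subject(small_spec(seed = 23))
  pp <- preprocess_subject(s)
  brain <- brain_mask_from_b0(s$dw_b0)
  v <- pp$ce_norm$values[brain$values]
  expect_lt(abs(mean(v)), 1e-8)
  expect_equal(sd(v), 1, tolerance = 1e-8)
  expect_equal(dim(pp$adc$values$values), dim(s$ce_t1w$values))
  tum <- pp$adc$values$values[pp$mask$values & !pp$adc$invalid_mask$values]
  expect_true(all(tum > 0))
})
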