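test_that("the feature manifest arithmetic holds", {
  man <- feature_manifest()
  expect_identical(nrow(man), 936L)
  expect_identical(anyDuplicated(man$name), 0L)
  expect_identical(sum(man$source == "original" & man$group == "firstorder"), 17L)
  expect_identical(sum(man$source == "original" & man$group != "firstorder"), 87L)
  expect_identical(sum(man$source != "original"), 832L)
  expect_identical(length(unique(man$source)), 9L)
  expect_identical(length(wavelet_band_names()), 8L)
})

test_that("quantization maps intensities to monotone levels", {
  d <- c(4, 4, 2)
  const <- gray_level_quantize(array(5, dim = d), array(TRUE, dim = d), 32)
  expect_true(all(const$values == 1L))
  vals <- array(seq(0, 31.999, length.out = 32), dim = c(32, 1, 1))
  q <- gray_level_quantize(vals, array(TRUE, dim = c(32, 1, 1)), 32)
  expect_identical(as.vector(q$values), as.integer(floor(vals) + 1))
  # affine rescaling of masked values leaves levels unchanged
  for (seed in 1:3) {
    set.seed(seed)
    v <- array(rnorm(5^3), dim = c(5, 5, 5))
    m <- array(runif(5^3) > 0.3, dim = c(5, 5, 5))
    q1 <- gray_level_quantize(v, m, 16)
    q2 <- gray_level_quantize(3.7 * v + 11, m, 16)
    expect_identical(q1$values, q2$values)
  }
})

test_that("there are exactly 13 sign-deduplicated 3D directions", {
  dirs <- glcm_directions()
  expect_identical(nrow(dirs), 13L)
  has <- function(v) any(apply(dirs, 1, function(r) all(r == v)))
  expect_true(has(c(1, 0, 0)))
  expect_false(has(c(-1, 0, 0)))
  # exhaustive oracle: {-1,0,1}^3 minus origin, modulo negation
  all26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  all26 <- all26[rowSums(abs(all26)) > 0, ]
  canon <- unique(t(apply(all26, 1, function(v) {
    if (v[which(v != 0)[1]] < 0) -v else v
  })))
  expect_identical(nrow(canon), 13L)
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(dirs), key(canon))
})

test_that("GLCM matches hand examples and stays symmetric", {
  lv <- as_quantized(array(c(1, 2, 3, 4), dim = c(2, 2, 1)), 4)
  g <- compute_glcm(lv, c(1, 0, 0), 1)
  expect_equal(g$p[1, 2], 0.25)
  expect_equal(g$p[2, 1], 0.25)
  expect_equal(g$p[3, 4], 0.25)
  expect_equal(g$p[4, 3], 0.25)
  expect_equal(sum(g$p), 1)
  # constant region: single diagonal entry
  cl <- as_quantized(array(1, dim = c(3, 3, 1)), 4)
  gc <- compute_glcm(cl, c(1, 0, 0), 1)
  expect_equal(gc$p[1, 1], 1)
  # symmetry on random content
  set.seed(2)
  rl <- as_quantized(array(sample(0:4, 6^3, replace = TRUE), dim = c(6, 6, 6)), 4)
  for (d in 1:3) {
    gr <- compute_glcm(rl, c(1, 1, 0), d)
    expect_identical(gr$counts, t(gr$counts))
  }
})

test_that("GLCM counts equal brute-force pair enumeration on small masks", {
  dirs <- glcm_directions()
  for (seed in 1:3) {
    set.seed(seed)
    d <- sample(3:6, 3, replace = TRUE)
    lv <- array(sample(0:4, prod(d), replace = TRUE), dim = d)
    q <- as_quantized(lv, 4)
    for (r in seq_len(nrow(dirs))) {
      for (dist in 1:3) {
        expect_equal(compute_glcm(q, dirs[r, ], dist)$counts,
                     oracle_glcm(lv, dirs[r, ], dist, 4))
      }
    }
  }
})

test_that("GLCM descriptors match hand computations", {
  cl <- as_quantized(array(1, dim = c(3, 3, 1)), 4)
  f <- glcm_features(compute_glcm(cl, c(1, 0, 0), 1))
  expect_length(f, 22)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["correlation"]), 0) # zero-variance guard
  lv <- as_quantized(array(c(1, 2, 3, 4), dim = c(2, 2, 1)), 4)
  f2 <- glcm_features(compute_glcm(lv, c(1, 0, 0), 1))
  expect_equal(unname(f2["contrast"]), 1) # 4 * 0.25 * (i-j)^2 with |i-j|=1
  expect_equal(unname(f2["dissimilarity"]), 1)
  expect_equal(unname(f2["maximum_probability"]), 0.25)
  # checkerboard: dissimilarity against the pair-enumeration oracle
  cb <- array(rep(c(1, 2), 8), dim = c(4, 4, 1))
  qcb <- as_quantized(cb, 2)
  g <- compute_glcm(qcb, c(1, 0, 0), 1)
  o <- oracle_glcm(cb, c(1, 0, 0), 1, 2)
  op <- o / sum(o)
  odis <- sum(abs(row(op) - col(op)) * op)
  expect_equal(unname(glcm_features(g)["dissimilarity"]), odis)
})

test_that("GLRLM matches hand enumerations and the run oracle", {
  row3 <- as_quantized(array(c(1, 1, 2), dim = c(3, 1, 1)), 2)
  r <- compute_glrlm(row3, c(1, 0, 0))
  expect_equal(r$n_runs, 2)
  expect_equal(r$counts[1, 2], 1)
  expect_equal(r$counts[2, 1], 1)
  # all-distinct levels: n runs of length 1
  rowd <- as_quantized(array(1:5, dim = c(5, 1, 1)), 5)
  rd <- compute_glrlm(rowd, c(1, 0, 0))
  expect_equal(rd$n_runs, 5)
  expect_true(all(rd$counts[, 1] == 1))
  # constant row: one run of length n
  rowc <- as_quantized(array(1, dim = c(6, 1, 1)), 2)
  rc <- compute_glrlm(rowc, c(1, 0, 0))
  expect_equal(rc$n_runs, 1)
  expect_equal(rc$counts[1, 6], 1)
  # oracle equivalence on random small masks, all 13 directions
  dirs <- glcm_directions()
  for (seed in 1:3) {
    set.seed(seed)
    d <- sample(3:6, 3, replace = TRUE)
    lv <- array(sample(0:3, prod(d), replace = TRUE), dim = d)
    q <- as_quantized(lv, 3)
    for (r_i in seq_len(nrow(dirs))) {
      got <- compute_glrlm(q, dirs[r_i, ])$counts
      want <- oracle_glrlm(lv, dirs[r_i, ], 3)
      nc <- max(ncol(got), ncol(want))
      pad <- function(m) cbind(m, matrix(0, nrow(m), nc - ncol(m)))
      expect_equal(pad(got), pad(want))
    }
  }
})

test_that("GLRLM descriptors match closed forms", {
  rowd <- as_quantized(array(c(1, 2, 1, 2), dim = c(4, 1, 1)), 2)
  f <- glrlm_features(compute_glrlm(rowd, c(1, 0, 0)))
  expect_length(f, 21)
  expect_equal(unname(f["sre"]), 1)
  expect_equal(unname(f["lre"]), 1)
  # runs {(level 1, len 2), (level 2, len 1)}
  mix <- as_quantized(array(c(1, 1, 2), dim = c(3, 1, 1)), 2)
  f2 <- glrlm_features(compute_glrlm(mix, c(1, 0, 0)))
  expect_equal(unname(f2["sre"]), 0.625)
  # single run
  one <- as_quantized(array(1, dim = c(4, 1, 1)), 2)
  f3 <- glrlm_features(compute_glrlm(one, c(1, 0, 0)))
  expect_equal(unname(f3["rln"]), 1)
  expect_equal(unname(f3["gln"]), 1)
  expect_error(glrlm_features(matrix(0, 2, 2)), "empty")
})

test_that("first-order features match hand values", {
  d <- c(3, 1, 1)
  f <- first_order_features(array(c(1, 2, 3), dim = d), array(TRUE, dim = d))
  expect_length(f, 17)
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["median"]), 2)
  expect_equal(unname(f["maximum"]), 3)
  expect_equal(unname(f["variance"]), 1)
  expect_equal(unname(f["energy"]), 14)
  const <- first_order_features(array(4, dim = d), array(TRUE, dim = d))
  expect_equal(unname(const["range"]), 0)
  expect_equal(unname(const["variance"]), 0)
  expect_equal(unname(const["entropy"]), 0)
  expect_equal(unname(const["uniformity"]), 1)
  expect_error(first_order_features(array(1, dim = d), array(FALSE, dim = d)),
               "empty")
})

test_that("the Haar decomposition has 8 bands and conserves energy", {
  bands <- wavelet_decompose(array(3, dim = c(8, 8, 8)))
  expect_identical(names(bands), wavelet_band_names())
  expect_length(bands, 8)
  for (nm in setdiff(names(bands), "LLL")) {
    expect_equal(max(abs(bands[[nm]])), 0)
  }
  set.seed(6)
  v <- array(rnorm(8^3), dim = c(8, 8, 8))
  b <- wavelet_decompose(v)
  e_in <- sum(v^2)
  e_out <- sum(vapply(b, function(x) sum(x^2), numeric(1)))
  expect_lt(abs(e_out - e_in) / e_in, 1e-8)
  # odd dims handled by padding
  odd <- wavelet_decompose(array(rnorm(7 * 6 * 5), dim = c(7, 6, 5)))
  expect_identical(dim(odd$LLL), c(4L, 3L, 3L))
})

test_that("extraction yields 936 deterministic features per channel", {
  s <- generate_subject(small_spec(seed = 31))
  pp <- preprocess_subject(s)
  f1 <- extract_all_features(pp$ce_norm, pp$mask)
  f2 <- extract_all_features(pp$ce_norm, pp$mask)
  expect_identical(f1, f2)
  expect_length(f1, 936)
  man <- feature_manifest()
  expect_identical(names(f1), man$name)
  expect_identical(sum(man$source != "original"), 832L)
  expect_true(all(is.finite(f1)))
})

test_that("texture separates the heterogeneous class from the homogeneous", {
  # gray-level spread (GLCM sum of squares) and run statistics (GLRLM
  # gray-level variance, run entropy) should stochastically dominate for
  # the rim-enhancing heterogeneous class
  pull <- function(cls, seedbase) {
    vapply(1:8, function(i) {
      s <- generate_subject(small_spec(cls, seed = derive_seed(seedbase, i)))
      pp <- preprocess_subject(s)
      q <- gray_level_quantize(pp$ce_norm$values, pp$mask$values, 32)
      c(unname(glcm_features(compute_glcm(q, c(1, 0, 0), 1))["sum_of_squares"]),
        unname(glrlm_features(compute_glrlm(q, c(1, 0, 0)))[c("glv",
                                                              "run_entropy")]))
    }, numeric(3))
  }
  gbm <- pull("glioblastoma", 60)
  pcnsl <- pull("pcnsl", 61)
  for (r in 1:3) {
    expect_lt(wilcox.test(gbm[r, ], pcnsl[r, ],
                          alternative = "greater")$p.value, 0.01)
  }
})

test_that("z-transform standardizes on the fit rows only", {
  tab <- rbind(matrix(c(1, 2, 3, 10, 20, 30), 3, 2), c(2, 20))
  colnames(tab) <- c("a", "b")
  zt <- z_transform_features(tab, fit_rows = 1:3)
  expect_equal(zt$table[1:3, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(zt$table[1:3, ]), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(zt$table[1:3, ], 2, sd), c(a = 1, b = 1),
               tolerance = 1e-10)
  # validation row equal to the training mean maps to 0
  expect_equal(unname(zt$table[4, ]), c(0, 0), tolerance = 1e-12)
  flat <- cbind(tab, c = rep(5, 4))
  expect_warning(z2 <- z_transform_features(flat, 1:3), "constant")
  expect_equal(unname(z2$table[, "c"]), rep(0, 4))
})
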