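# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (no shifting tricks, no rank formulas): plain loops
# and direct definitions.

# all voxel pairs at displacement dist*dir, both in mask (level > 0)
oracle_glcm <- function(levels, dir, dist, nlevels) {
  d <- dim(levels)
  out <- matrix(0, nlevels, nlevels)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- levels[i, j, k]
    if (a == 0) next
    ii <- i + dir[1] * dist; jj <- j + dir[2] * dist; kk <- k + dir[3] * dist
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
    b <- levels[ii, jj, kk]
    if (b == 0) next
    out[a, b] <- out[a, b] + 1
    out[b, a] <- out[b, a] + 1
  }
  out
}

# enumerate maximal runs by walking every line in the direction
oracle_glrlm <- function(levels, dir, nlevels) {
  d <- dim(levels)
  counts <- list()
  bump <- function(a, len) {
    key <- paste(a, len)
    counts[[key]] <<- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- levels[i, j, k]
    if (a == 0) next
    pi <- i - dir[1]; pj <- j - dir[2]; pk <- k - dir[3]
    prev_same <- pi >= 1 && pi <= d[1] && pj >= 1 && pj <= d[2] &&
      pk >= 1 && pk <= d[3] && levels[pi, pj, pk] == a
    if (prev_same) next
    len <- 1
    ci <- i + dir[1]; cj <- j + dir[2]; ck <- k + dir[3]
    while (ci >= 1 && ci <= d[1] && cj >= 1 && cj <= d[2] &&
           ck >= 1 && ck <= d[3] && levels[ci, cj, ck] == a) {
      len <- len + 1
      ci <- ci + dir[1]; cj <- cj + dir[2]; ck <- ck + dir[3]
    }
    bump(a, len)
  }
  maxlen <- 0
  for (key in names(counts)) {
    maxlen <- max(maxlen, as.integer(strsplit(key, " ")[[1]][2]))
  }
  out <- matrix(0, nlevels, max(maxlen, 1))
  for (key in names(counts)) {
    al <- as.integer(strsplit(key, " ")[[1]])
    out[al[1], al[2]] <- counts[[key]]
  }
  out
}

# probability a random positive outscores a random negative, ties half
oracle_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# connected in-band region by iterative label propagation (not BFS)
oracle_flood <- function(eligible, start) {
  d <- dim(eligible)
  lab <- array(FALSE, dim = d)
  lab[start[1], start[2], start[3]] <- TRUE
  repeat {
    changed <- FALSE
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (lab[i, j, k] || !eligible[i, j, k]) next
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if ((di | dj | dk) && ii >= 1 && ii <= d[1] && jj >= 1 &&
            jj <= d[2] && kk >= 1 && kk <= d[3] && lab[ii, jj, kk]) {
          lab[i, j, k] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# entropy-based mutual information (bits) from a plain contingency table
oracle_mi <- function(a, b) {
  H <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  Hab <- {
    p <- table(paste(a, b)) / length(a)
    -sum(p * log2(p))
  }
  H(a) + H(b) - Hab
}

as_quantized <- function(values, n_levels) {
  structure(list(values = array(as.integer(values), dim = dim(values)),
                 n_levels = as.integer(n_levels)),
            class = "quantized_volume")
}

# small fast phantom spec for pipeline tests
small_spec <- function(class_label = "glioblastoma", seed = 1, ...) {
  phantom_spec(grid_shape = c(32, 32, 32), tumor_radius_range = c(6, 9),
               class_label = class_label, seed = seed, ...)
}

# well-separated two-class Gaussian feature matrix
separable_features <- function(n_per_class, p = 12, shift = 3, seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  y <- rep(c("glioblastoma", "pcnsl"), each = n_per_class)
  x[y == "pcnsl", 1:4] <- x[y == "pcnsl", 1:4] + shift
  colnames(x) <- sprintf("f%03d", seq_len(p))
  list(x = x, y = y)
}
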