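# 26-connectivity neighbor offsets in linear index space, with bounds kept
# explicit via (i,j,k) arithmetic.
neighbor_offsets_26 <- function() {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
}

# Vectorized frontier BFS over an eligibility array.
flood_fill_26 <- function(eligible, start_idx) {
  dims <- dim(eligible)
  nb <- neighbor_offsets_26()
  visited <- array(FALSE, dim = dims)
  visited[start_idx] <- TRUE
  frontier <- start_idx
  while (length(frontier) > 0) {
    fi <- arrayInd(frontier, dims)
    cand <- integer(0)
    for (r in seq_len(nrow(nb))) {
      i <- fi[, 1] + nb$di[r]
      j <- fi[, 2] + nb$dj[r]
      k <- fi[, 3] + nb$dk[r]
      ok <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] & k >= 1 & k <= dims[3]
      if (any(ok)) {
        cand <- c(cand, i[ok] + (j[ok] - 1L) * dims[1] + (k[ok] - 1L) * dims[1] * dims[2])
      }
    }
    cand <- unique(cand)
    cand <- cand[eligible[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

#' Threshold + region-growing segmentation
#'
#' Returns the maximal 26-connected set of voxels containing the seed whose
#' intensities lie in `[low, high]`, mimicking interactive threshold /
#' region-growing tools. The result is invariant to the choice of seed within
#' the same connected in-band region.
#'
#' @param img `volume_image`.
#' @param seed integer length-3 voxel index (1-based) inside the grid.
#' @param low,high intensity band (inclusive).
#' @return a `tumor_mask`.
#' @export
region_grow <- function(img, seed, low, high = Inf) {
  dims <- dim(img$values)
  seed <- as.integer(seed)
  stopifnot(length(seed) == 3L, all(seed >= 1), all(seed <= dims))
  sval <- img$values[seed[1], seed[2], seed[3]]
  if (is.na(sval) || sval < low || sval > high) {
    stop(sprintf("seed intensity %.6g outside threshold band [%g, %g]",
                 sval, low, high))
  }
  eligible <- !is.na(img$values) & img$values >= low & img$values <= high
  lin <- seed[1] + (seed[2] - 1L) * dims[1] + (seed[3] - 1L) * dims[1] * dims[2]
  tumor_mask(flood_fill_26(eligible, lin), img$voxel_size_mm)
}

#' Largest 26-connected component of a mask
#'
#' Ties between equally sized components are broken toward the component
#' containing the lexicographically smallest voxel index.
#'
#' @param mask `tumor_mask` (nonempty).
#' @return a `tumor_mask` with a single connected component.
#' @export
largest_component <- function(mask) {
  if (mask_count(mask) == 0) stop("empty mask")
  dims <- dim(mask$values)
  remaining <- mask$values
  best <- NULL
  best_n <- -1L
  while (any(remaining)) {
    start <- which(remaining)[1] # smallest linear index = lexicographic min
    comp <- flood_fill_26(remaining, start)
    n <- sum(comp)
    if (n > best_n) { # strict: first (lexicographically smallest) wins ties
      best <- comp
      best_n <- n
    }
    remaining <- remaining & !comp
  }
  tumor_mask(best, mask$voxel_size_mm)
}

#' Summary statistics of an image over a mask
#'
#' @param mask `tumor_mask` (nonempty).
#' @param img `volume_image` on the same grid.
#' @return list with `volume_mm3`, `mean`, `sd` (sample), `min`, `max`,
#'   `voxel_count`.
#' @export
mask_stats <- function(mask, img) {
  stopifnot_same_grid(mask, img)
  n <- mask_count(mask)
  if (n == 0) stop("empty mask")
  v <- img$values[mask$values]
  list(volume_mm3 = n * prod(mask$voxel_size_mm),
       mean = mean(v), sd = if (n > 1) sd(v) else 0,
       min = min(v), max = max(v), voxel_count = n)
}
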