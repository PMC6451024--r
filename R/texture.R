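#' The 13 unique 3D texture directions
#'
#' The 26-neighborhood offsets of a voxel, deduplicated up to sign (a
#' direction and its negation index the same voxel pairs), in canonical
#' lexicographic order with the first nonzero component positive.
#'
#' @return a 13 x 3 integer matrix of offsets.
#' @export
glcm_directions <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1, function(v) v[which(v != 0)[1]] > 0)
  g <- g[keep, , drop = FALSE]
  g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
}

#' Gray-level co-occurrence matrix for one direction and distance
#'
#' Counts pairs of in-mask voxels separated by `distance * direction`, with
#' symmetric accumulation (each pair contributes to both matrix cells), so
#' the matrix equals its transpose; the normalized form sums to 1.
#'
#' @param q a `quantized_volume` from [gray_level_quantize()].
#' @param direction integer length-3 offset (one row of [glcm_directions()]).
#' @param distance pair distance in voxels (1, 2 or 3).
#' @return list with `counts`, `p` (normalized; all-zero if no valid pair)
#'   and `n_pairs`.
#' @export
compute_glcm <- function(q, direction, distance = 1) {
  stopifnot(inherits(q, "quantized_volume"), distance >= 1)
  cnt <- cpp_glcm_counts(as.integer(q$values), dim(q$values),
                         as.integer(direction), as.integer(distance),
                         q$n_levels)
  s <- sum(cnt)
  p <- if (s > 0) cnt / s else cnt
  list(counts = cnt, p = p, n_pairs = s / 2)
}

#' GLCM texture descriptors
#'
#' The 22-descriptor set computed from a normalized co-occurrence matrix:
#' autocorrelation, cluster prominence/shade/tendency, contrast, correlation,
#' difference average/entropy/variance, dissimilarity, energy (angular second
#' moment), entropy, homogeneity (inverse difference), inverse difference
#' moment, the two informational measures of correlation, inverse variance,
#' maximum probability, sum average/entropy/variance and variance (sum of
#' squares). Logs are base 2. Degenerate matrices (zero marginal variance)
#' return correlation and the informational measures as 0.
#'
#' @param g result of [compute_glcm()] (or a normalized matrix).
#' @return named numeric vector of length 22.
#' @export
glcm_features <- function(g) {
  p <- if (is.list(g)) g$p else g
  nm <- glcm_feature_names()
  out <- stats::setNames(numeric(length(nm)), nm)
  s <- sum(p)
  if (s == 0) {
    warning("empty co-occurrence matrix; features set to 0")
    return(out)
  }
  p <- p / s
  n <- nrow(p)
  ix <- glcm_index_cache(n)
  i <- ix$i
  j <- ix$j
  pi_m <- rowSums(p) # symmetric: row marginal = column marginal
  mu <- sum(seq_len(n) * pi_m)
  sig2 <- sum((seq_len(n) - mu)^2 * pi_m)

  plog <- function(x) {
    out <- numeric(length(x))
    nz <- x > 0
    out[nz] <- log2(x[nz])
    out
  }
  ent <- -sum(p * plog(p))

  # sum / difference distributions via grouped sums
  k_sum <- 2:(2 * n)
  p_sum <- as.vector(rowsum(as.vector(p), ix$sum_group))
  k_diff <- 0:(n - 1)
  p_diff <- as.vector(rowsum(as.vector(p), ix$diff_group))
  sa <- sum(k_sum * p_sum)
  da <- sum(k_diff * p_diff)

  hx <- -sum(pi_m * plog(pi_m))
  pxy <- outer(pi_m, pi_m)
  hxy1 <- -sum(p * plog(pxy))
  hxy2 <- -sum(pxy * plog(pxy))

  out["autocorrelation"] <- sum(i * j * p)
  out["cluster_prominence"] <- sum((i + j - 2 * mu)^4 * p)
  out["cluster_shade"] <- sum((i + j - 2 * mu)^3 * p)
  out["cluster_tendency"] <- sum((i + j - 2 * mu)^2 * p)
  out["contrast"] <- sum((i - j)^2 * p)
  out["correlation"] <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0
  out["difference_average"] <- da
  out["difference_entropy"] <- -sum(p_diff * plog(p_diff))
  out["difference_variance"] <- sum((k_diff - da)^2 * p_diff)
  out["dissimilarity"] <- sum(abs(i - j) * p)
  out["energy"] <- sum(p^2)
  out["entropy"] <- ent
  out["homogeneity"] <- sum(p / (1 + abs(i - j)))
  out["idm"] <- sum(p / (1 + (i - j)^2))
  out["imc1"] <- if (hx > 0) (ent - hxy1) / hx else 0
  out["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  out["inverse_variance"] <- sum(p[i != j] / (i[i != j] - j[i != j])^2)
  out["maximum_probability"] <- max(p)
  out["sum_average"] <- sa
  out["sum_entropy"] <- -sum(p_sum * plog(p_sum))
  out["sum_variance"] <- sum((k_sum - sa)^2 * p_sum)
  out["sum_of_squares"] <- sum((i - mu)^2 * p)
  out
}

.glcm_ix_env <- new.env(parent = emptyenv())
glcm_index_cache <- function(n) {
  key <- as.character(n)
  if (!exists(key, envir = .glcm_ix_env, inherits = FALSE)) {
    i <- matrix(seq_len(n), n, n)
    j <- t(i)
    assign(key, list(i = i, j = j, sum_group = as.vector(i + j),
                     diff_group = as.vector(abs(i - j))),
           envir = .glcm_ix_env)
  }
  get(key, envir = .glcm_ix_env)
}

glcm_feature_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "dissimilarity", "energy",
    "entropy", "homogeneity", "idm", "imc1", "imc2", "inverse_variance",
    "maximum_probability", "sum_average", "sum_entropy", "sum_variance",
    "sum_of_squares")
}

#' Gray-level run-length matrix for one direction
#'
#' Counts maximal runs of equal gray level along the direction, restricted
#' to in-mask voxels; runs break at the mask boundary. Rows index gray
#' levels, columns run lengths; the counts sum to the number of runs.
#'
#' @inheritParams compute_glcm
#' @return list with `counts` and `n_runs`.
#' @export
compute_glrlm <- function(q, direction) {
  stopifnot(inherits(q, "quantized_volume"))
  cnt <- cpp_glrlm_counts(as.integer(q$values), dim(q$values),
                          as.integer(direction), q$n_levels)
  list(counts = cnt, n_runs = sum(cnt))
}

#' GLRLM run-length descriptors
#'
#' A 21-descriptor set: the 16 standard run-length statistics (short/long run
#' emphasis, gray-level and run-length nonuniformity with normalized
#' variants, run percentage, low/high gray-level run emphasis and their four
#' short/long combinations, gray-level and run-length variance, run entropy)
#' plus five distributional summaries declared in the manifest: mean run
#' length, mean gray level of runs, marginal gray-level entropy, marginal
#' run-length entropy and maximum run length.
#'
#' @param r result of [compute_glrlm()] (or a counts matrix).
#' @return named numeric vector of length 21.
#' @export
glrlm_features <- function(r) {
  cnt <- if (is.list(r)) r$counts else r
  nr <- sum(cnt)
  if (nr == 0) stop("empty run-length matrix")
  p <- cnt / nr
  i <- matrix(seq_len(nrow(cnt)), nrow(cnt), ncol(cnt))
  j <- matrix(seq_len(ncol(cnt)), nrow(cnt), ncol(cnt), byrow = TRUE)
  ri <- rowSums(p)
  rj <- colSums(p)
  np <- sum(cnt * j) # voxels covered by runs
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  plog <- function(x) ifelse(x > 0, log2(x), 0)
  nm <- glrlm_feature_names()
  out <- stats::setNames(numeric(length(nm)), nm)
  out["sre"] <- sum(p / j^2)
  out["lre"] <- sum(p * j^2)
  out["gln"] <- sum(rowSums(cnt)^2) / nr
  out["glnn"] <- sum(ri^2)
  out["rln"] <- sum(colSums(cnt)^2) / nr
  out["rlnn"] <- sum(rj^2)
  out["rp"] <- nr / np
  out["lglre"] <- sum(p / i^2)
  out["hglre"] <- sum(p * i^2)
  out["srlgle"] <- sum(p / (i^2 * j^2))
  out["srhgle"] <- sum(p * i^2 / j^2)
  out["lrlgle"] <- sum(p * j^2 / i^2)
  out["lrhgle"] <- sum(p * i^2 * j^2)
  out["glv"] <- sum(p * (i - mu_i)^2)
  out["rlv"] <- sum(p * (j - mu_j)^2)
  out["run_entropy"] <- -sum(p * plog(p))
  out["run_length_mean"] <- mu_j
  out["gray_level_mean"] <- mu_i
  out["gray_level_entropy"] <- -sum(ri * plog(ri))
  out["run_length_entropy"] <- -sum(rj * plog(rj))
  out["max_run_length"] <- max(j[cnt > 0])
  out
}

glrlm_feature_names <- function() {
  c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "lglre", "hglre",
    "srlgle", "srhgle", "lrlgle", "lrhgle", "glv", "rlv", "run_entropy",
    "run_length_mean", "gray_level_mean", "gray_level_entropy",
    "run_length_entropy", "max_run_length")
}
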