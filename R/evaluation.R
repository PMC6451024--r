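label_to_binary <- function(labels, positive = NULL) {
  lab <- as.character(labels)
  lv <- sort(unique(lab))
  if (length(lv) < 2) stop("both classes must be present")
  if (length(lv) > 2) stop("more than two classes")
  if (is.null(positive)) positive <- lv[2]
  as.integer(lab == positive)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney statistic: the probability that a random positive scores
#' above a random negative, with ties counted one half. Equals brute-force
#' all-pairs counting and is invariant under strictly monotone score
#' transforms.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels two-class labels; the positive class defaults to the
#'   second sorted level (`"pcnsl"` against `"glioblastoma"`).
#' @param positive positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels, positive = NULL) {
  y <- label_to_binary(labels, positive)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal operating threshold
#'
#' Scans midpoints between adjacent unique scores (plus the two infinite
#' endpoints), predicting positive when `score > threshold`, and returns the
#' threshold maximizing Youden's J = sensitivity + specificity - 1. Ties in
#' J resolve toward higher specificity, then toward the higher threshold.
#'
#' @inheritParams compute_auc
#' @return list with `threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `j`.
#' @export
youden_threshold <- function(scores, labels, positive = NULL) {
  y <- label_to_binary(labels, positive)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    pred <- scores > t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (spec > best$specificity + 1e-12 ||
          (abs(spec - best$specificity) <= 1e-12 && t > best$threshold)))) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   accuracy = mean(pred == (y == 1)), j = j)
    }
  }
  best
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples positives and negatives separately (so every resample holds
#' both classes) and returns the percentile interval of the resampled AUCs.
#' Seeded and deterministic.
#'
#' @inheritParams compute_auc
#' @param n_boot bootstrap resamples (>= 100; default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                         seed = 1L, positive = NULL) {
  stopifnot(n_boot >= 100)
  y <- label_to_binary(labels, positive)
  pos <- which(y == 1)
  neg <- which(y == 0)
  aucs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      compute_auc(scores[i], y[i], positive = 1)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  unname(quantile(aucs, c(alpha, 1 - alpha), type = 7))
}

#' Relative standard deviation of a set of AUCs
#'
#' The stability measure `100 * SD / mean` (sample SD), scale-invariant by
#' construction.
#'
#' @param aucs numeric vector of at least 2 AUCs with positive mean.
#' @return list with `auc_mean`, `auc_sd`, `rsd_percent`.
#' @export
rsd_stability <- function(aucs) {
  stopifnot(length(aucs) >= 2)
  m <- mean(aucs)
  if (m <= 0) stop("mean AUC must be positive")
  s <- sd(aucs)
  list(auc_mean = m, auc_sd = s, rsd_percent = 100 * s / m)
}

#' Full ROC summary for one model on one dataset
#'
#' AUC with stratified-bootstrap CI and the Youden-threshold operating point.
#'
#' @inheritParams bootstrap_ci
#' @return a `roc_result` list: `auc`, `ci_low`, `ci_high`, `threshold`,
#'   `sensitivity`, `specificity`, `accuracy`, `n_pos`, `n_neg`.
#' @export
roc_result <- function(scores, labels, n_boot = 2000, seed = 1L,
                       positive = NULL) {
  y <- label_to_binary(labels, positive)
  auc <- compute_auc(scores, y, positive = 1)
  ci <- bootstrap_ci(scores, y, n_boot = n_boot, seed = seed, positive = 1)
  yt <- youden_threshold(scores, y, positive = 1)
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 threshold = yt$threshold, sensitivity = yt$sensitivity,
                 specificity = yt$specificity, accuracy = yt$accuracy,
                 n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f-%.3f), sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
              x$auc, x$ci_low, x$ci_high, 100 * x$sensitivity,
              100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

#' Export the selector x classifier heat-map tables
#'
#' Writes one CSV per metric (mean AUC and RSD), selectors in rows and
#' classifiers in columns, preserving the labels from the grid result.
#'
#' @param grid the `grid` data.frame of [train_classifier_grid()] (9 rows).
#' @param dir output directory.
#' @return (invisibly) named list of the two matrices.
#' @export
grid_heatmap_export <- function(grid, dir) {
  sel <- unique(grid$selector)
  cls <- unique(grid$classifier)
  need <- expand.grid(selector = sel, classifier = cls,
                      stringsAsFactors = FALSE)
  have <- paste(grid$selector, grid$classifier)
  missing <- setdiff(paste(need$selector, need$classifier), have)
  if (length(missing)) {
    stop("missing grid cell(s): ", paste(missing, collapse = "; "))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (metric in c("mean_auc", "rsd")) {
    m <- matrix(NA_real_, length(sel), length(cls),
                dimnames = list(sel, cls))
    for (r in seq_len(nrow(grid))) {
      m[grid$selector[r], grid$classifier[r]] <- grid[[metric]][r]
    }
    write.csv(m, file.path(dir, paste0("heatmap_", metric, ".csv")))
    out[[metric]] <- m
  }
  invisible(out)
}
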