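# Feature selection: mRMR (greedy MID criterion), CFS (best-first subset
# merit) and backward elimination (model-based recursive elimination scored
# by inner CV AUC). All three are pure functions of (table, labels, config,
# seed), with ties broken by manifest (column) order.

selection_result <- function(method, selected, trace, seed = NA_integer_) {
  structure(list(method = method, selected = selected, trace = trace,
                 seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d feature(s)\n", x$method,
              length(x$selected)))
  invisible(x)
}

# Equal-frequency discretization into (up to) n_bins levels; ties can merge
# bins, a constant column collapses to a single level.
discretize_ef <- function(x, n_bins = 4) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

# Mutual information (bits) between two small-alphabet integer vectors.
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}

# MI (bits) between one integer vector and every column of an integer matrix
# sharing the alphabet 1..ka / 1..kb; vectorized over columns.
mi_vector <- function(s, bins, ka, kb) {
  n <- length(s)
  p_b <- t(vapply(seq_len(kb), function(v) colMeans(bins == v),
                  numeric(ncol(bins))))  # kb x p
  mi <- numeric(ncol(bins))
  for (u in seq_len(ka)) {
    rows <- s == u
    pu <- mean(rows)
    if (pu == 0) next
    cnt <- t(vapply(seq_len(kb), function(v) {
      if (sum(rows) == 0) numeric(ncol(bins)) else colSums(bins[rows, , drop = FALSE] == v)
    }, numeric(ncol(bins)))) / n  # kb x p joint probs for this u
    for (v in seq_len(kb)) {
      pj <- cnt[v, ]
      denom <- pu * p_b[v, ]
      nz <- pj > 0
      mi[nz] <- mi[nz] + pj[nz] * log2(pj[nz] / denom[nz])
    }
  }
  mi
}

#' Minimum-redundancy maximum-relevance selection (greedy MID)
#'
#' Features are discretized into 4 equal-frequency bins; relevance and
#' redundancy are mutual information (bits). At each step the feature
#' maximizing `I(f; y) - mean_{s in S} I(f; s)` is added, with ties broken by
#' column order. The first pick always maximizes marginal relevance.
#'
#' @param table numeric matrix, subjects x features (named columns).
#' @param labels two-class character/factor vector.
#' @param k number of features to select.
#' @param n_bins discretization bins (default 4).
#' @return a `selection_result`; the trace holds each step's criterion value.
#' @export
select_mrmr <- function(table, labels, k, n_bins = 4) {
  stopifnot(k >= 1)
  if (k > ncol(table)) stop("k exceeds the number of features")
  y <- as.integer(factor(labels))
  if (length(unique(y)) < 2) stop("need two classes")
  bins <- apply(table, 2, discretize_ef, n_bins = n_bins)
  kb <- max(bins)
  relevance <- mi_vector(y, bins, max(y), kb)
  selected <- integer(0)
  trace <- numeric(0)
  red_sum <- numeric(ncol(table))
  for (step in seq_len(k)) {
    crit <- relevance - if (step == 1) 0 else red_sum / length(selected)
    crit[selected] <- -Inf
    pick <- which.max(crit)
    selected <- c(selected, pick)
    trace <- c(trace, crit[pick])
    if (step < k) {
      red_sum <- red_sum + mi_vector(bins[, pick], bins, kb, kb)
    }
  }
  selection_result("mrmr", colnames(table)[selected], trace)
}

cfs_merit <- function(subset, rcf, rff) {
  k <- length(subset)
  if (k == 0) return(0)
  mean_rcf <- mean(rcf[subset])
  if (k == 1) return(mean_rcf)
  mean_rff <- mean(rff[subset, subset][upper.tri(diag(k))])
  k * mean_rcf / sqrt(k + k * (k - 1) * mean_rff)
}

#' Correlation-based feature selection (best-first search)
#'
#' Maximizes the subset merit
#' `k * mean|r_cf| / sqrt(k + k(k-1) * mean|r_ff|)` where `r_cf` is the
#' point-biserial feature-class correlation and `r_ff` the feature-feature
#' Pearson correlation. Forward best-first search from the empty set,
#' stopping after `stall` consecutive expansions that fail to improve the
#' best merit; each expansion queues its 40 best-merit children (a beam that
#' keeps the search tractable at radiomic dimensionality while leaving the
#' greedy path and its local improvements intact). Zero-variance features
#' are skipped with a warning.
#'
#' @inheritParams select_mrmr
#' @param stall non-improving expansions before stopping (default 5).
#' @param max_size cap on subset size (default 50).
#' @return a `selection_result`; the trace holds the best merit after each
#'   expansion.
#' @export
select_cfs <- function(table, labels, stall = 5, max_size = 50) {
  stopifnot(ncol(table) >= 2)
  y01 <- as.numeric(factor(labels)) - 1
  sds <- apply(table, 2, sd)
  usable <- which(sds > 0)
  if (length(usable) < ncol(table)) {
    warning(sprintf("%d zero-variance feature(s) skipped",
                    ncol(table) - length(usable)))
  }
  x <- table[, usable, drop = FALSE]
  rcf <- abs(as.vector(cor(x, y01)))
  rcf[is.na(rcf)] <- 0
  rff <- abs(cor(x))
  rff[is.na(rff)] <- 0

  key <- function(s) {
    if (length(s) == 0) "<empty>" else paste(sort(s), collapse = ",")
  }
  open <- list(list(set = integer(0), merit = 0,
                    sum_rcf = 0, sum_rff = 0))
  visited <- new.env(hash = TRUE)
  assign(key(integer(0)), TRUE, envir = visited)
  best_set <- integer(0)
  best_merit <- 0
  stalled <- 0
  trace <- numeric(0)
  beam <- 40 # children queued per expansion, best-merit first
  while (length(open) > 0 && stalled < stall) {
    merits <- vapply(open, `[[`, numeric(1), "merit")
    at <- which.max(merits)
    node <- open[[at]]
    open[[at]] <- NULL
    improved <- FALSE
    k <- length(node$set)
    if (k < max_size) {
      cand <- setdiff(seq_len(ncol(x)), node$set)
      # incremental merit for every candidate child at once
      s_rcf <- node$sum_rcf + rcf[cand]
      s_rff <- node$sum_rff +
        if (k == 0) numeric(length(cand)) else colSums(rff[node$set, cand, drop = FALSE])
      kk <- k + 1
      m_all <- if (kk == 1) s_rcf else {
        kk * (s_rcf / kk) / sqrt(kk + 2 * s_rff)
      }
      ord <- order(m_all, decreasing = TRUE)
      for (oi in head(ord, beam)) {
        f <- cand[oi]
        child <- c(node$set, f)
        ck <- key(child)
        if (exists(ck, envir = visited, inherits = FALSE)) next
        assign(ck, TRUE, envir = visited)
        open[[length(open) + 1]] <- list(set = child, merit = m_all[oi],
                                         sum_rcf = s_rcf[oi],
                                         sum_rff = s_rff[oi])
        if (m_all[oi] > best_merit + 1e-12) {
          best_merit <- m_all[oi]
          best_set <- child
          improved <- TRUE
        }
      }
    }
    stalled <- if (improved) 0 else stalled + 1
    trace <- c(trace, best_merit)
    if (length(open) > 2000) { # keep the frontier bounded
      merits <- vapply(open, `[[`, numeric(1), "merit")
      open <- open[order(merits, decreasing = TRUE)[1:1000]]
    }
  }
  sel <- sort(best_set)
  selection_result("cfs", colnames(x)[sel], trace)
}

# Univariate AUC of each column for the two-class labels (positive = second
# factor level); separation strength is |AUC - 0.5|.
univariate_auc <- function(table, labels) {
  y <- as.integer(factor(labels)) - 1L
  apply(table, 2, function(x) compute_auc(x, y))
}

#' Backward feature elimination with a model-based scorer
#'
#' Features are prefiltered to the `prefilter` strongest by univariate AUC
#' separation, then recursively eliminated: at each step the inner model
#' (componentwise GLM boosting by default) is fitted on the current set, the
#' feature with the smallest importance is dropped, and every visited set is
#' scored by stratified `inner_folds`-fold CV AUC. The best-scoring set is
#' returned (earliest, i.e. largest, set on ties). Fully seeded.
#'
#' @inheritParams select_mrmr
#' @param inner_model `"glm_boost"` (componentwise boosting importance).
#' @param seed integer seed for the inner CV folds.
#' @param prefilter univariate prefilter size (default 100).
#' @param inner_folds inner CV folds (default 5).
#' @return a `selection_result`; the trace is a data.frame of step, set size
#'   and inner CV AUC.
#' @export
select_backward_elimination <- function(table, labels,
                                        inner_model = "glm_boost",
                                        seed = 1L, prefilter = 100,
                                        inner_folds = 5) {
  stopifnot(ncol(table) >= 2, inner_model == "glm_boost")
  y <- factor(labels)
  auc1 <- univariate_auc(table, labels)
  strength <- abs(auc1 - 0.5)
  keep <- head(order(strength, decreasing = TRUE), prefilter)
  keep <- sort(keep) # manifest order within the prefiltered set
  x <- table[, keep, drop = FALSE]

  score_set <- function(cols, fold_seed) {
    folds <- make_folds(y, inner_folds, fold_seed)
    scores <- numeric(length(y))
    for (f in seq_along(folds)) {
      tr <- setdiff(seq_along(y), folds[[f]])
      fit <- glm_boost_fit(x[tr, cols, drop = FALSE], y[tr])
      scores[folds[[f]]] <- glm_boost_score(fit, x[folds[[f]], cols, drop = FALSE])
    }
    compute_auc(scores, y)
  }

  cols <- seq_len(ncol(x))
  best_cols <- cols
  best_auc <- score_set(cols, derive_seed(seed, 0))
  steps <- data.frame(step = 0L, n_features = length(cols), cv_auc = best_auc)
  step <- 0L
  while (length(cols) >= 2) {
    step <- step + 1L
    fit <- glm_boost_fit(x[, cols, drop = FALSE], y)
    imp <- glm_boost_importance(fit)
    drop_at <- which.min(imp) # ties: first = manifest order
    cols <- cols[-drop_at]
    auc <- score_set(cols, derive_seed(seed, step))
    steps <- rbind(steps, data.frame(step = step, n_features = length(cols),
                                     cv_auc = auc))
    if (auc > best_auc + 1e-12) {
      best_auc <- auc
      best_cols <- cols
    }
  }
  res <- selection_result("backward_elimination",
                          colnames(x)[best_cols], steps[-1, ], seed)
  res$cv_auc <- best_auc
  res
}
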