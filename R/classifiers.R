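# Metric-1 classifiers behind a single fit/score interface. The continuous
# score is always oriented so that larger means more PCNSL-like (the second
# factor level when labels are "glioblastoma" < "pcnsl").

class_levels <- function(labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("need exactly two classes")
  lv
}

#' Stratified cross-validation folds
#'
#' Partitions subjects into `n_folds` folds preserving the class ratio
#' within one subject per class; deterministic for a fixed seed.
#'
#' @param labels class labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return list of validation-row index vectors that partition the subjects.
#' @export
make_folds <- function(labels, n_folds, seed = 1L) {
  folds <- vector("list", n_folds)
  with_seed(seed, {
    for (cl in unique(as.character(labels))) {
      rows <- sample(which(labels == cl))
      grp <- rep_len(seq_len(n_folds), length(rows))
      for (f in seq_len(n_folds)) {
        folds[[f]] <- c(folds[[f]], rows[grp == f])
      }
    }
  })
  lapply(folds, sort)
}

#' Cross-validation scheme
#'
#' @param n_folds folds (default 10).
#' @param n_repeats repeats of the whole CV (default 10, giving the 100-run
#'   scheme; the ensemble uses 1).
#' @param seed integer seed.
#' @export
cv_scheme <- function(n_folds = 10, n_repeats = 10, seed = 1L) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Classifier specification
#'
#' @param kind `"rbf_svm"`, `"glm_boost"`, `"regularized_rf"` or
#'   `"logistic"`.
#' @param ... hyper-parameter overrides: SVM `cost_grid`, `gamma_factors`;
#'   boosting `mstop` (default 100), `nu` (default 0.1); RF `n_trees`
#'   (default 500), `penalty` (default 0.8); logistic `lambda`.
#' @export
classifier_spec <- function(kind = c("rbf_svm", "glm_boost", "regularized_rf",
                                     "logistic"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    rbf_svm = list(cost_grid = c(0.1, 1, 10), gamma_factors = c(0.5, 1, 2)),
    glm_boost = list(mstop = 100L, nu = 0.1),
    regularized_rf = list(n_trees = 500L, penalty = 0.8),
    logistic = list(lambda = 1e-3))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown hyper-parameters: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  if (any(unlist(defaults[vapply(defaults, is.numeric, TRUE)]) <= 0)) {
    stop("hyper-parameters must be positive")
  }
  structure(c(list(kind = kind), defaults), class = "classifier_spec")
}

# ---- componentwise GLM boosting (logit loss, linear base learners) --------

#' Componentwise gradient boosting for the binomial GLM
#'
#' Linear base learners on standardized columns, logit loss, `mstop`
#' iterations with step length `nu`: each iteration fits every column to the
#' current negative gradient and updates only the best-fitting one, giving a
#' sparse additive linear model on the logit scale. Importance of a feature
#' is the absolute value of its accumulated standardized coefficient.
#'
#' @param x numeric matrix.
#' @param y two-class factor/character labels.
#' @param mstop boosting iterations (default 100).
#' @param nu step length (default 0.1).
#' @return a `glm_boost` model.
#' @export
glm_boost_fit <- function(x, y, mstop = 100L, nu = 0.1) {
  lv <- class_levels(y)
  yb <- as.numeric(as.character(y) == lv[2])
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, ctr, `-`), 2, scl, `/`)
  n <- nrow(xs)
  p <- ncol(xs)
  ssq <- colSums(xs^2)
  ssq[ssq == 0] <- Inf
  f0 <- log(mean(yb) / (1 - mean(yb) + 1e-12) + 1e-12)
  f <- rep(f0, n)
  coefs <- numeric(p)
  for (m in seq_len(mstop)) {
    prob <- 1 / (1 + exp(-f))
    u <- yb - prob
    b <- as.vector(crossprod(xs, u)) / ssq
    sse_red <- b^2 * ssq # squared-error reduction per base learner
    j <- which.max(sse_red)
    coefs[j] <- coefs[j] + nu * b[j]
    f <- f + nu * b[j] * xs[, j]
  }
  structure(list(coefs = coefs, center = ctr, scale = scl, offset = f0,
                 levels = lv), class = "glm_boost")
}

#' @rdname glm_boost_fit
#' @param fit a `glm_boost` model.
#' @param newx matrix of new rows.
#' @export
glm_boost_score <- function(fit, newx) {
  xs <- sweep(sweep(newx, 2, fit$center, `-`), 2, fit$scale, `/`)
  eta <- fit$offset + as.vector(xs %*% fit$coefs)
  1 / (1 + exp(-eta))
}

glm_boost_importance <- function(fit) abs(fit$coefs)

# ---- fit / score dispatch -------------------------------------------------

#' Fit one Metric-1 classifier
#'
#' @param spec a [classifier_spec()].
#' @param x training matrix (rows = subjects).
#' @param y two-class labels.
#' @param seed integer seed (forest bootstrap, inner tuning folds).
#' @return a `fitted_classifier`.
#' @export
fit_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  lv <- class_levels(y)
  yf <- factor(as.character(y), levels = lv)
  model <- switch(spec$kind,
    rbf_svm = fit_rbf_svm(x, yf, spec, seed),
    glm_boost = glm_boost_fit(x, yf, mstop = spec$mstop, nu = spec$nu),
    regularized_rf = fit_regularized_rf(x, yf, spec, seed),
    logistic = fit_ridge_logistic(x, yf, spec))
  structure(list(kind = spec$kind, model = model, levels = lv,
                 features = colnames(x)), class = "fitted_classifier")
}

#' @rdname fit_classifier
#' @param fit a `fitted_classifier`.
#' @param newx matrix with the training feature columns.
#' @return numeric score per row, increasing toward the second class level
#'   (PCNSL).
#' @export
score_classifier <- function(fit, newx) {
  newx <- newx[, fit$features, drop = FALSE]
  switch(fit$kind,
    rbf_svm = {
      dv <- attr(predict(fit$model$svm, newx, decision.values = TRUE),
                 "decision.values")
      orient <- if (startsWith(colnames(dv)[1], fit$levels[2])) 1 else -1
      as.vector(dv) * orient
    },
    glm_boost = glm_boost_score(fit$model, newx),
    regularized_rf = {
      pr <- predict(fit$model$forest,
                    data = newx[, fit$model$admitted, drop = FALSE],
                    num.threads = 1)$predictions
      pr[, fit$levels[2]]
    },
    logistic = as.vector(predict(fit$model$fit, newx, s = fit$model$lambda,
                                 type = "response")))
}

fit_rbf_svm <- function(x, y, spec, seed) {
  gamma0 <- 1 / ncol(x)
  grid <- expand.grid(cost = spec$cost_grid,
                      gamma = gamma0 * spec$gamma_factors)
  inner <- make_folds(y, 5, derive_seed(seed, 17))
  perf <- vapply(seq_len(nrow(grid)), function(g) {
    sc <- numeric(length(y))
    for (f in seq_along(inner)) {
      tr <- setdiff(seq_along(y), inner[[f]])
      if (length(unique(y[tr])) < 2) return(0.5)
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = grid$cost[g], gamma = grid$gamma[g], scale = FALSE)
      dv <- attr(predict(m, x[inner[[f]], , drop = FALSE],
                         decision.values = TRUE), "decision.values")
      orient <- if (startsWith(colnames(dv)[1], levels(y)[2])) 1 else -1
      sc[inner[[f]]] <- as.vector(dv) * orient
    }
    compute_auc(sc, y)
  }, numeric(1))
  best <- which.max(perf)
  svm <- e1071::svm(x, y, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], scale = FALSE)
  list(svm = svm, cost = grid$cost[best], gamma = grid$gamma[best],
       tuning_auc = perf[best])
}

fit_regularized_rf <- function(x, y, spec, seed) {
  pilot <- ranger::ranger(x = x, y = y, num.trees = spec$n_trees,
                          importance = "impurity", probability = TRUE,
                          seed = derive_seed(seed, 31), num.threads = 1)
  imp <- pilot$variable.importance
  # penalized admission: a feature enters only if its importance reaches
  # (1 - penalty) of the best feature's importance
  admitted <- names(imp)[imp >= (1 - spec$penalty) * max(imp)]
  if (length(admitted) == 0) admitted <- names(which.max(imp))
  forest <- ranger::ranger(x = x[, admitted, drop = FALSE], y = y,
                           num.trees = spec$n_trees, probability = TRUE,
                           seed = derive_seed(seed, 32), num.threads = 1)
  list(forest = forest, admitted = admitted, importance = imp)
}

fit_ridge_logistic <- function(x, y, spec) {
  # ridge-stabilized logistic: identifiable for p >~ n and under separation
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = c(1, 0.1, spec$lambda), standardize = TRUE)
  list(fit = fit, lambda = spec$lambda)
}

# ---- Metric-1 grid --------------------------------------------------------

run_selector <- function(selector, table, labels, seed, k_mrmr = 15) {
  switch(selector,
    mrmr = select_mrmr(table, labels, k = min(k_mrmr, ncol(table))),
    cfs = select_cfs(table, labels),
    backward_elimination = select_backward_elimination(table, labels,
                                                       seed = seed),
    stop("unknown selector: ", selector))
}

#' Train and cross-validate the selector x classifier grid
#'
#' The Metric-1 design: every combination of feature-selection method and
#' classifier is scored by repeated stratified k-fold cross-validation
#' (10 repeats x 10 folds = up to 100 runs per model by default). With
#' `nested = TRUE` (the leakage-safe default) selection is re-run inside
#' every training fold; `nested = FALSE` reproduces the variant where
#' selection is run once on the full training set before CV. Final models
#' are refitted on all rows with selection on all rows.
#'
#' @param features standardized feature matrix (rows = subjects).
#' @param labels two-class labels.
#' @param selectors character vector of selector ids (default the three
#'   methods `"mrmr"`, `"cfs"`, `"backward_elimination"`).
#' @param classifiers named list of [classifier_spec()]s (default RBF SVM,
#'   GLM boosting, regularized RF).
#' @param cv a [cv_scheme()].
#' @param nested logical; see above.
#' @param k_mrmr mRMR subset size (default 15).
#' @return a `classifier_grid`: data.frame `grid` (selector, classifier,
#'   mean AUC, RSD), `auc_runs` (matrix model x run), `final_models`,
#'   `final_selections`.
#' @export
train_classifier_grid <- function(features, labels,
                                  selectors = c("mrmr", "cfs",
                                                "backward_elimination"),
                                  classifiers = default_classifier_grid(),
                                  cv = cv_scheme(), nested = TRUE,
                                  k_mrmr = 15) {
  lv <- class_levels(labels)
  n_models <- length(selectors) * length(classifiers)
  run_auc <- matrix(NA_real_, n_models, cv$n_repeats * cv$n_folds)
  model_id <- function(s, c) paste(s, c, sep = "|")
  ids <- as.vector(outer(selectors, names(classifiers), model_id))
  rownames(run_auc) <- ids

  presel <- NULL
  if (!nested) {
    presel <- lapply(selectors, function(s) {
      run_selector(s, features, labels, derive_seed(cv$seed, 999))$selected
    })
    names(presel) <- selectors
  }

  run <- 0L
  for (r in seq_len(cv$n_repeats)) {
    folds <- make_folds(labels, cv$n_folds, derive_seed(cv$seed, r))
    for (f in seq_len(cv$n_folds)) {
      run <- run + 1L
      val <- folds[[f]]
      tr <- setdiff(seq_along(labels), val)
      if (length(unique(labels[val])) < 2 || length(unique(labels[tr])) < 2) {
        stop(sprintf("degenerate fold (single class) at repeat %d fold %d", r, f))
      }
      for (s in selectors) {
        sel <- if (nested) {
          run_selector(s, features[tr, , drop = FALSE], labels[tr],
                       derive_seed(cv$seed, r, f), k_mrmr)$selected
        } else {
          presel[[s]]
        }
        xs_tr <- features[tr, sel, drop = FALSE]
        xs_val <- features[val, sel, drop = FALSE]
        for (cn in names(classifiers)) {
          fit <- fit_classifier(classifiers[[cn]], xs_tr, labels[tr],
                                seed = derive_seed(cv$seed, r, f))
          sc <- score_classifier(fit, xs_val)
          run_auc[model_id(s, cn), run] <- compute_auc(sc, labels[val])
        }
      }
    }
  }

  final_selections <- lapply(selectors, function(s) {
    run_selector(s, features, labels, derive_seed(cv$seed, 0), k_mrmr)
  })
  names(final_selections) <- selectors
  final_models <- list()
  for (s in selectors) {
    sel <- final_selections[[s]]$selected
    for (cn in names(classifiers)) {
      final_models[[model_id(s, cn)]] <-
        fit_classifier(classifiers[[cn]], features[, sel, drop = FALSE],
                       labels, seed = derive_seed(cv$seed, 0))
    }
  }
  grid <- do.call(rbind, lapply(selectors, function(s) {
    do.call(rbind, lapply(names(classifiers), function(cn) {
      aucs <- run_auc[model_id(s, cn), ]
      data.frame(selector = s, classifier = cn,
                 mean_auc = mean(aucs),
                 rsd = rsd_stability(aucs)$rsd_percent,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(grid = grid, auc_runs = run_auc,
                 final_models = final_models,
                 final_selections = final_selections,
                 levels = lv, cv = cv, nested = nested),
            class = "classifier_grid")
}

#' The default three-classifier bank
#' @export
default_classifier_grid <- function() {
  list(rbf_svm = classifier_spec("rbf_svm"),
       glm_boost = classifier_spec("glm_boost"),
       regularized_rf = classifier_spec("regularized_rf"))
}
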