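test_that("stratified folds partition subjects and preserve class ratio", {
  y <- rep(c("glioblastoma", "pcnsl"), c(21, 14))
  folds <- make_folds(y, 5, seed = 3)
  expect_length(folds, 5)
  expect_identical(sort(unlist(folds)), seq_along(y))
  for (f in folds) {
    expect_equal(sum(y[f] == "glioblastoma"), 21 / 5, tolerance = 0.5)
    expect_equal(sum(y[f] == "pcnsl"), 14 / 5, tolerance = 0.5)
  }
  expect_identical(folds, make_folds(y, 5, seed = 3))
})

test_that("every classifier separates well-separated Gaussian classes", {
  sep <- separable_features(30, seed = 7)
  hold <- separable_features(20, seed = 8)
  for (kind in c("rbf_svm", "glm_boost", "regularized_rf", "logistic")) {
    fit <- fit_classifier(classifier_spec(kind), sep$x, sep$y, seed = 5)
    auc <- compute_auc(score_classifier(fit, hold$x), hold$y)
    expect_gt(auc, 0.95)
    # determinism of fit + score
    fit2 <- fit_classifier(classifier_spec(kind), sep$x, sep$y, seed = 5)
    expect_equal(score_classifier(fit, hold$x),
                 score_classifier(fit2, hold$x))
  }
  expect_error(classifier_spec("glm_boost", bogus = 1), "unknown")
})

test_that("the selector x classifier grid yields 9 scored models", {
  sep <- separable_features(30, p = 16, seed = 7)
  cv <- cv_scheme(n_folds = 5, n_repeats = 2, seed = 9)
  grid <- train_classifier_grid(sep$x, sep$y, cv = cv)
  expect_identical(nrow(grid$grid), 9L)
  expect_identical(dim(grid$auc_runs), c(9L, 10L))
  expect_length(grid$final_models, 9)
  expect_true(all(grid$grid$mean_auc >= 0.95))
  expect_true(all(grid$grid$rsd >= 0))
  # scheme arithmetic: the default protocol allows 100 runs per model
  dflt <- cv_scheme()
  expect_identical(dflt$n_folds * dflt$n_repeats, 100L)
})

test_that("non-nested selection reproduces the single-selection variant", {
  sep <- separable_features(24, p = 10, seed = 17)
  cv <- cv_scheme(n_folds = 4, n_repeats = 1, seed = 2)
  g1 <- train_classifier_grid(sep$x, sep$y, selectors = "mrmr",
                              classifiers = list(glm_boost = classifier_spec("glm_boost")),
                              cv = cv, nested = FALSE)
  expect_identical(nrow(g1$grid), 1L)
  expect_false(g1$nested)
  expect_true(all(is.finite(g1$auc_runs)))
})

test_that("selection fitted on training rows ignores a validation canary", {
  # canary equals the labels on validation rows but is noise on training
  # rows: a leakage-safe selector fitted on training rows must not rank it
  set.seed(31)
  n_tr <- 40; n_val <- 20
  y <- rep(c("glioblastoma", "pcnsl"), each = (n_tr + n_val) / 2)
  x <- matrix(rnorm((n_tr + n_val) * 8), n_tr + n_val, 8)
  colnames(x) <- sprintf("f%02d", 1:8)
  train_rows <- c(1:20, 31:50)
  val_rows <- setdiff(seq_along(y), train_rows)
  x[val_rows, 8] <- as.numeric(factor(y[val_rows])) # canary
  x[, 2] <- x[, 2] + 2 * (y == "pcnsl")
  res <- select_mrmr(x[train_rows, ], y[train_rows], k = 2)
  expect_false("f08" %in% res$selected)
})

test_that("MLP architectures parse the full sweep plus deeper variants", {
  archs <- default_mlp_architectures()
  expect_length(archs, 4)
  parsed <- lapply(archs, mlp_architecture)
  expect_identical(parsed[[1]]$hidden, c(100L, 10L))
  expect_identical(parsed[[4]]$hidden, c(500L, 250L, 100L, 50L, 10L))
  deep <- mlp_architecture("750-500-250-100-50-10")
  expect_identical(deep$hidden, c(750L, 500L, 250L, 100L, 50L, 10L))
  expect_error(mlp_architecture("100-0-10"), "positive")
  expect_error(mlp_architecture("abc"), "positive")
})

test_that("training config carries the study hyper-parameters", {
  cfg <- training_config()
  expect_identical(cfg$batch_size, 32L)
  expect_equal(cfg$momentum, 0.25)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_equal(cfg$weight_decay, 0)
  expect_equal(cfg$class_weight_pcnsl, 1.467)
})

test_that("class weight 1 reduces the loss to the unweighted form", {
  set.seed(5)
  prob <- cbind(runif(30, 0.1, 0.9))
  prob <- cbind(1 - prob, prob)
  y01 <- rbinom(30, 1, 0.5)
  w1 <- radiomlp:::mlp_loss(prob, y01, 1)
  plain <- -mean(log(ifelse(y01 == 1, prob[, 2], prob[, 1])))
  expect_equal(w1, plain, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(radiomlp:::mlp_loss(prob, y01, 1.467), w1)))
})

test_that("the MLP fits separable data and is seed-reproducible", {
  sep <- separable_features(30, p = 10, shift = 4, seed = 23)
  y01 <- as.numeric(sep$y == "pcnsl")
  cfg <- training_config(max_epochs = 400, patience = 60, seed = 11)
  m1 <- mlp_train(sep$x, y01, "16-4", cfg)
  m2 <- mlp_train(sep$x, y01, "16-4", cfg)
  expect_identical(m1$layers, m2$layers)
  pr <- mlp_predict_prob(m1, sep$x)
  expect_gt(compute_auc(pr, sep$y), 0.99)
  # smoothed training loss decreases overall
  h <- m1$loss_history
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))
  expect_error(mlp_predict_prob(m1, sep$x[, 1:3]), "dimension mismatch")
})

test_that("the ensemble has 10 members and classifies separable data", {
  sep <- separable_features(30, p = 10, shift = 4, seed = 29)
  cfg <- training_config(max_epochs = 800, patience = 100, seed = 13)
  ens <- train_mlp_ensemble(sep$x, sep$y, "16-4", cfg,
                            cv = cv_scheme(n_folds = 10, n_repeats = 1,
                                           seed = 13))
  expect_length(ens$members, 10)
  # members trained with disjoint validation folds
  expect_identical(sort(unlist(ens$folds)), seq_along(sep$y))
  pr <- predict_ensemble(ens, sep$x)
  expect_equal(mean(pr$label == sep$y), 1.0)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
})

test_that("majority voting matches direct counting, ties go by mean prob", {
  # engineered members with constant outputs: logit pairs force the votes
  const_member <- function(p_pcnsl, d = 3) {
    logit <- log(p_pcnsl / (1 - p_pcnsl))
    structure(list(layers = list(list(W = matrix(0, d, 2),
                                      b = c(0, logit)))),
              class = "mlp_model")
  }
  mk_ens <- function(probs) {
    structure(list(members = lapply(probs, const_member),
                   folds = as.list(seq_along(probs)),
                   levels = c("glioblastoma", "pcnsl"),
                   arch = mlp_architecture("1-1"),
                   fold_auc = rep(0.5, length(probs))),
              class = "trained_ensemble")
  }
  x <- matrix(0, 2, 3)
  # 7 GBM votes vs 3 PCNSL votes -> glioblastoma
  ens <- mk_ens(c(rep(0.2, 7), rep(0.8, 3)))
  pr <- predict_ensemble(ens, x)
  expect_identical(pr$label, rep("glioblastoma", 2))
  expect_identical(unname(rowSums(t(pr$votes))), rep(3, 2))
  # 5-5 tie with mean probability 0.62 -> pcnsl
  probs <- c(rep(0.95, 5), rep(0.29, 5))
  expect_equal(mean(probs), 0.62)
  pr2 <- predict_ensemble(mk_ens(probs), x)
  expect_identical(pr2$label, rep("pcnsl", 2))
  # all members identical: ensemble equals the single member
  pr3 <- predict_ensemble(mk_ens(rep(0.8, 10)), x)
  expect_identical(pr3$label, rep("pcnsl", 2))
  expect_equal(pr3$score, rep(0.8, 2), tolerance = 1e-12)
})

test_that("the logistic baseline behaves at the two extremes", {
  # a feature equal to the label: perfect CV AUC
  set.seed(41)
  n <- 60
  y <- rep(c("glioblastoma", "pcnsl"), each = n / 2)
  x <- cbind(lab = as.numeric(factor(y)) + 0, noise = rnorm(n))
  base <- train_logistic_baseline(x, y, cv = cv_scheme(5, 1, seed = 5))
  expect_equal(mean(base$fold_auc), 1.0)
  # pure noise: CV AUC near chance
  set.seed(3)
  n2 <- 200
  y2 <- rep(c("glioblastoma", "pcnsl"), each = n2 / 2)
  x2 <- matrix(rnorm(n2 * 5), n2, 5)
  colnames(x2) <- sprintf("n%d", 1:5)
  b2 <- train_logistic_baseline(x2, y2, cv = cv_scheme(5, 1, seed = 3))
  expect_gt(mean(b2$fold_auc), 0.35)
  expect_lt(mean(b2$fold_auc), 0.65)
  # deterministic given seed
  b3 <- train_logistic_baseline(x2, y2, cv = cv_scheme(5, 1, seed = 3))
  expect_identical(b2$fold_auc, b3$fold_auc)
})
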