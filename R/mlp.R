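#' MLP architecture from a dash string
#'
#' `"100-10"` denotes the hidden-layer widths only; the 2-unit softmax output
#' layer is implicit. The default sweep covers 100-10, 500-100-10,
#' 500-100-50-10 and 500-250-100-50-10; deeper strings such as
#' "750-500-250-100-50-10" parse as further valid variants.
#'
#' @param arch dash-separated hidden widths, e.g. `"500-100-10"`.
#' @return an `mlp_architecture`: list with `hidden` (integer vector) and
#'   `label`.
#' @export
mlp_architecture <- function(arch) {
  hidden <- suppressWarnings(as.integer(strsplit(arch, "-", fixed = TRUE)[[1]]))
  if (length(hidden) < 1 || anyNA(hidden) || any(hidden <= 0)) {
    stop("architecture must be a dash string of positive widths")
  }
  structure(list(hidden = hidden, label = arch), class = "mlp_architecture")
}

#' The default architecture sweep
#' @export
default_mlp_architectures <- function() {
  c("100-10", "500-100-10", "500-100-50-10", "500-250-100-50-10")
}

#' MLP training configuration
#'
#' Defaults follow the study protocol: minibatch SGD with batch size 32,
#' momentum 0.25, learning rate 1e-3, no weight decay, and class weight
#' 1.467 multiplying the PCNSL terms of the cross-entropy loss (compensating
#' the 73:50 class imbalance). Training runs up to `max_epochs` with early
#' stopping on held-out fold loss.
#'
#' @param batch_size minibatch size.
#' @param momentum SGD momentum.
#' @param learning_rate SGD step size.
#' @param weight_decay L2 penalty (0 = none).
#' @param class_weight_pcnsl loss weight on PCNSL samples.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param seed integer seed for initialization and shuffling.
#' @export
training_config <- function(batch_size = 32, momentum = 0.25,
                            learning_rate = 1e-3, weight_decay = 0,
                            class_weight_pcnsl = 1.467, max_epochs = 500,
                            patience = 50, seed = 1L) {
  structure(list(batch_size = as.integer(batch_size), momentum = momentum,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 class_weight_pcnsl = class_weight_pcnsl,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "training_config")
}

mlp_init <- function(n_in, hidden, seed) {
  sizes <- c(n_in, hidden, 2L)
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(l) {
      list(W = matrix(rnorm(sizes[l] * sizes[l + 1],
                            sd = sqrt(2 / sizes[l])),
                      sizes[l], sizes[l + 1]),
           b = numeric(sizes[l + 1]))
    })
  })
}

mlp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- x
  a <- x
  for (l in seq_along(layers)) {
    z <- sweep(a %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    a <- if (l < length(layers)) pmax(z, 0) else z # ReLU, linear logits out
    acts[[l + 1]] <- a
  }
  acts
}

softmax2 <- function(z) {
  m <- pmax(z[, 1], z[, 2])
  e1 <- exp(z[, 1] - m)
  e2 <- exp(z[, 2] - m)
  cbind(e1 / (e1 + e2), e2 / (e1 + e2))
}

# mean class-weighted cross-entropy; column 2 = PCNSL
mlp_loss <- function(prob, y01, w_pcnsl) {
  p <- ifelse(y01 == 1, prob[, 2], prob[, 1])
  w <- ifelse(y01 == 1, w_pcnsl, 1)
  -sum(w * log(pmax(p, 1e-12))) / sum(w)
}

#' Train one multilayer perceptron
#'
#' ReLU hidden layers, 2-unit softmax output, class-weighted cross-entropy
#' minimized by minibatch SGD with momentum. Deterministic for a fixed
#' config seed. Fails if the loss diverges to NaN.
#'
#' @param x standardized feature matrix.
#' @param y01 0/1 vector (1 = PCNSL).
#' @param arch an [mlp_architecture()] or dash string.
#' @param cfg a [training_config()].
#' @param val_x,val_y01 optional held-out rows for early stopping.
#' @return an `mlp_model` with weights, loss history and `n_epochs`.
#' @export
mlp_train <- function(x, y01, arch, cfg = training_config(),
                      val_x = NULL, val_y01 = NULL) {
  if (is.character(arch)) arch <- mlp_architecture(arch)
  n <- nrow(x)
  layers <- mlp_init(ncol(x), arch$hidden, derive_seed(cfg$seed, 1))
  vel <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  w_pcnsl <- cfg$class_weight_pcnsl
  tgt <- cbind(1 - y01, y01)
  wts <- ifelse(y01 == 1, w_pcnsl, 1)
  best <- list(layers = layers, loss = Inf, epoch = 0L)
  history <- numeric(0)
  stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 2, epoch), sample.int(n))
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      acts <- mlp_forward(layers, x[idx, , drop = FALSE])
      prob <- softmax2(acts[[length(acts)]])
      bw <- wts[idx]
      delta <- (prob - tgt[idx, , drop = FALSE]) * bw / sum(bw)
      for (l in rev(seq_along(layers))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (cfg$weight_decay > 0) gW <- gW + cfg$weight_decay * layers[[l]]$W
        vel[[l]]$W <- cfg$momentum * vel[[l]]$W - cfg$learning_rate * gW
        vel[[l]]$b <- cfg$momentum * vel[[l]]$b - cfg$learning_rate * gb
        if (l > 1) {
          delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
        }
        layers[[l]]$W <- layers[[l]]$W + vel[[l]]$W
        layers[[l]]$b <- layers[[l]]$b + vel[[l]]$b
      }
    }
    monitor_x <- if (is.null(val_x)) x else val_x
    monitor_y <- if (is.null(val_x)) y01 else val_y01
    prob <- softmax2(mlp_forward(layers, monitor_x)[[length(layers) + 1]])
    loss <- mlp_loss(prob, monitor_y, w_pcnsl)
    if (!is.finite(loss)) stop("MLP training diverged (loss not finite)")
    history <- c(history, loss)
    if (loss < best$loss - 1e-7) {
      best <- list(layers = layers, loss = loss, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  structure(list(layers = best$layers, arch = arch, cfg = cfg,
                 loss_history = history, n_epochs = length(history),
                 best_epoch = best$epoch),
            class = "mlp_model")
}

#' @rdname mlp_train
#' @param model an `mlp_model`.
#' @param newx matrix with training feature dimension.
#' @return probability of PCNSL per row.
#' @export
mlp_predict_prob <- function(model, newx) {
  if (ncol(newx) != nrow(model$layers[[1]]$W)) {
    stop("feature dimension mismatch: model expects ",
         nrow(model$layers[[1]]$W), ", got ", ncol(newx))
  }
  softmax2(mlp_forward(model$layers, newx)[[length(model$layers) + 1]])[, 2]
}

#' Train the 10-member MLP ensemble
#'
#' One member per cross-validation fold: each member trains on the other 9
#' folds with the member's fold held out for early stopping, so the members
#' see disjoint validation folds. Members are combined by majority voting
#' with the mean PCNSL probability as the continuous score.
#'
#' @param features standardized feature matrix.
#' @param labels two-class labels (`"glioblastoma"` / `"pcnsl"`).
#' @param arch dash string or [mlp_architecture()].
#' @param cfg a [training_config()].
#' @param cv a [cv_scheme()] (its `n_folds` sets the member count, 10 by
#'   default; `n_repeats` is ignored here).
#' @return a `trained_ensemble`.
#' @export
train_mlp_ensemble <- function(features, labels, arch = "100-10",
                               cfg = training_config(),
                               cv = cv_scheme(n_repeats = 1)) {
  lv <- class_levels(labels)
  y01 <- as.numeric(as.character(labels) == lv[2])
  folds <- make_folds(labels, cv$n_folds, derive_seed(cv$seed, 77))
  members <- vector("list", cv$n_folds)
  fold_auc <- numeric(cv$n_folds)
  for (f in seq_len(cv$n_folds)) {
    tr <- setdiff(seq_along(labels), folds[[f]])
    cfg_f <- cfg
    cfg_f$seed <- derive_seed(cfg$seed, f)
    members[[f]] <- mlp_train(features[tr, , drop = FALSE], y01[tr], arch,
                              cfg_f,
                              val_x = features[folds[[f]], , drop = FALSE],
                              val_y01 = y01[folds[[f]]])
    fold_auc[f] <- if (length(unique(labels[folds[[f]]])) < 2) NA_real_ else {
      compute_auc(
        mlp_predict_prob(members[[f]], features[folds[[f]], , drop = FALSE]),
        labels[folds[[f]]])
    }
  }
  structure(list(members = members, folds = folds, levels = lv,
                 arch = if (is.character(arch)) mlp_architecture(arch) else arch,
                 fold_auc = fold_auc),
            class = "trained_ensemble")
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat(sprintf("<trained_ensemble> %s, %d members, mean fold AUC %.3f\n",
              x$arch$label, length(x$members), mean(x$fold_auc, na.rm = TRUE)))
  invisible(x)
}

#' Predict with the majority-voting ensemble
#'
#' Each member votes with its thresholded probability (>= 0.5 is PCNSL); the
#' label is the modal vote, a tie resolving to PCNSL when the mean PCNSL
#' probability is >= 0.5. The continuous score (for AUC) is the mean member
#' probability.
#'
#' @param ens a `trained_ensemble`.
#' @param features matrix with the training feature dimension.
#' @return list with `label` (character), `score` (mean PCNSL probability),
#'   `votes` (member x row matrix of 0/1 votes).
#' @export
predict_ensemble <- function(ens, features) {
  probs <- vapply(ens$members, mlp_predict_prob, numeric(nrow(features)),
                  newx = features)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  votes <- probs >= 0.5
  n_pcnsl <- rowSums(votes)
  n_memb <- length(ens$members)
  score <- rowMeans(probs)
  label <- ifelse(n_pcnsl > n_memb / 2, ens$levels[2],
                  ifelse(n_pcnsl < n_memb / 2, ens$levels[1],
                         ifelse(score >= 0.5, ens$levels[2], ens$levels[1])))
  list(label = label, score = score, votes = t(votes))
}

#' Ridge-stabilized logistic baseline with the ensemble CV protocol
#'
#' The comparison model: a (minimally ridge-penalized) logistic regression
#' trained with the same 10-fold protocol as the MLP ensemble; returns the
#' per-fold held-out AUCs and a final fit on all rows.
#'
#' @inheritParams train_mlp_ensemble
#' @param lambda ridge penalty (default 1e-3).
#' @return list with `fit` (a `fitted_classifier`), `fold_auc`.
#' @export
train_logistic_baseline <- function(features, labels,
                                    cv = cv_scheme(n_repeats = 1),
                                    lambda = 1e-3) {
  spec <- classifier_spec("logistic", lambda = lambda)
  folds <- make_folds(labels, cv$n_folds, derive_seed(cv$seed, 78))
  fold_auc <- numeric(cv$n_folds)
  for (f in seq_len(cv$n_folds)) {
    tr <- setdiff(seq_along(labels), folds[[f]])
    fit <- fit_classifier(spec, features[tr, , drop = FALSE], labels[tr])
    fold_auc[f] <- if (length(unique(labels[folds[[f]]])) < 2) NA_real_ else {
      compute_auc(
        score_classifier(fit, features[folds[[f]], , drop = FALSE]),
        labels[folds[[f]]])
    }
  }
  list(fit = fit_classifier(spec, features, labels), fold_auc = fold_auc)
}
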