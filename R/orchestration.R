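#' Experiment configuration
#'
#' Drives the end-to-end synthetic study: a training cohort, an internal
#' hold-out from the same (simulated) site, and an external cohort acquired
#' through a protocol shift. Cohort sizes default to the 73/50, 18/12 and
#' 28/14 glioblastoma/PCNSL layout of the two-center design.
#'
#' @param n_train,n_internal,n_external length-2 integer vectors
#'   `c(gbm, pcnsl)`.
#' @param channels feature channels: `"ce+adc"`, `"ce"` or `"adc"`.
#' @param selectors Metric-1 selector ids.
#' @param classifiers named list of [classifier_spec()]s.
#' @param mlp_archs character vector of architecture dash strings.
#' @param mlp_cfg a [training_config()].
#' @param cv a [cv_scheme()] for the Metric-1 grid.
#' @param external_shift a [protocol_shift()] applied to the external cohort.
#' @param phantom a [phantom_spec()] template for the generator.
#' @param nested nested (leakage-safe) selection inside each CV fold.
#' @param use_truth_masks use generator truth masks (default) instead of
#'   region growing, so classification is not confounded by segmentation.
#' @param n_boot bootstrap resamples for CIs.
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @export
experiment_config <- function(n_train = c(73, 50), n_internal = c(18, 12),
                              n_external = c(28, 14), channels = "ce+adc",
                              selectors = c("mrmr", "cfs",
                                            "backward_elimination"),
                              classifiers = default_classifier_grid(),
                              mlp_archs = default_mlp_architectures(),
                              mlp_cfg = training_config(),
                              cv = cv_scheme(n_folds = 10, n_repeats = 10),
                              external_shift = default_external_shift(),
                              phantom = phantom_spec(),
                              nested = TRUE, use_truth_masks = TRUE,
                              n_boot = 2000, seed = 1L) {
  cfg <- list(n_train = n_train, n_internal = n_internal,
              n_external = n_external, channels = channels,
              selectors = selectors, classifiers = classifiers,
              mlp_archs = mlp_archs, mlp_cfg = mlp_cfg, cv = cv,
              external_shift = external_shift, phantom = phantom,
              nested = nested, use_truth_masks = use_truth_masks,
              n_boot = n_boot, seed = as.integer(seed))
  class(cfg) <- "experiment_config"
  cfg
}

# FNV-1a over the deparsed config: cheap reproducible fingerprint
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

evaluate_scores <- function(scores, labels, n_boot, seed) {
  roc_result(scores, labels, n_boot = n_boot, seed = seed,
             positive = "pcnsl")
}

#' Run the full synthetic classification experiment
#'
#' Simulates the three cohorts, preprocesses and extracts features, fits the
#' Metric-1 selector x classifier grid with repeated CV, trains the MLP
#' ensemble sweep and the logistic baseline, and evaluates everything on the
#' internal hold-out and the protocol-shifted external cohort. A rerun with
#' the same config reproduces the report.
#'
#' @param cfg an [experiment_config()].
#' @param progress print per-stage progress lines.
#' @return an `evaluation_report` list.
#' @export
run_experiment <- function(cfg = experiment_config(), progress = interactive()) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- Sys.time()
  say <- function(...) if (progress) {
    message(sprintf("[%6.1fs] ", as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs"))),
            sprintf(...))
  }

  say("simulating cohorts (%d/%d/%d subjects)...",
      sum(cfg$n_train), sum(cfg$n_internal), sum(cfg$n_external))
  train <- generate_cohort(cfg$n_train[1], cfg$n_train[2], cfg$phantom,
                           seed = derive_seed(cfg$seed, 101))
  internal <- generate_cohort(cfg$n_internal[1], cfg$n_internal[2],
                              cfg$phantom, seed = derive_seed(cfg$seed, 102))
  external <- generate_cohort(cfg$n_external[1], cfg$n_external[2],
                              cfg$phantom, seed = derive_seed(cfg$seed, 103))
  external <- lapply(seq_along(external), function(i) {
    apply_protocol_shift(external[[i]], cfg$external_shift,
                         seed = derive_seed(cfg$seed, 104, i))
  })

  if (!cfg$use_truth_masks) {
    refine <- function(subj) {
      band_lo <- 0.5 * max(subj$ce_t1w$values)
      m <- region_grow(subj$ce_t1w, subj$seed_point, band_lo)
      subj$mask_truth <- largest_component(m)
      subj
    }
    train <- lapply(train, refine)
    internal <- lapply(internal, refine)
    external <- lapply(external, refine)
  }

  say("extracting %s features...", cfg$channels)
  manifest <- feature_manifest()
  ft_train <- cohort_feature_table(train, cfg$channels, manifest)
  ft_internal <- cohort_feature_table(internal, cfg$channels, manifest)
  ft_external <- cohort_feature_table(external, cfg$channels, manifest)

  all_feats <- rbind(ft_train$features, ft_internal$features,
                     ft_external$features)
  n_tr <- nrow(ft_train$features)
  n_in <- nrow(ft_internal$features)
  zt <- suppressWarnings(z_transform_features(all_feats, seq_len(n_tr)))
  x_train <- zt$table[seq_len(n_tr), , drop = FALSE]
  x_internal <- zt$table[n_tr + seq_len(n_in), , drop = FALSE]
  x_external <- zt$table[(n_tr + n_in + 1):nrow(all_feats), , drop = FALSE]
  y_train <- ft_train$labels
  y_internal <- ft_internal$labels
  y_external <- ft_external$labels

  say("Metric 1: %d-model grid, %d x %d CV...",
      length(cfg$selectors) * length(cfg$classifiers),
      cfg$cv$n_repeats, cfg$cv$n_folds)
  cv1 <- cfg$cv
  cv1$seed <- derive_seed(cfg$seed, 201)
  grid_fit <- train_classifier_grid(x_train, y_train, cfg$selectors,
                                    cfg$classifiers, cv = cv1,
                                    nested = cfg$nested)
  metric1 <- list(grid = grid_fit$grid, auc_runs = grid_fit$auc_runs,
                  models = list())
  for (id in names(grid_fit$final_models)) {
    fit <- grid_fit$final_models[[id]]
    metric1$models[[id]] <- list(
      internal = evaluate_scores(score_classifier(fit, x_internal),
                                 y_internal, cfg$n_boot,
                                 derive_seed(cfg$seed, 202)),
      external = evaluate_scores(score_classifier(fit, x_external),
                                 y_external, cfg$n_boot,
                                 derive_seed(cfg$seed, 203)))
  }
  best_id <- with(grid_fit$grid,
                  paste(selector, classifier, sep = "|")[which.max(mean_auc)])
  metric1$best_model <- best_id

  say("Metric 2: MLP sweep (%s)...", paste(cfg$mlp_archs, collapse = ", "))
  metric2 <- list()
  for (arch in cfg$mlp_archs) {
    cfg_m <- cfg$mlp_cfg
    cfg_m$seed <- derive_seed(cfg$seed, 301, match(arch, cfg$mlp_archs))
    ens <- train_mlp_ensemble(x_train, y_train, arch, cfg_m,
                              cv = cv_scheme(n_folds = 10, n_repeats = 1,
                                             seed = cfg_m$seed))
    metric2[[arch]] <- list(
      ensemble = ens,
      stability = rsd_stability(ens$fold_auc[!is.na(ens$fold_auc)]),
      internal = evaluate_scores(predict_ensemble(ens, x_internal)$score,
                                 y_internal, cfg$n_boot,
                                 derive_seed(cfg$seed, 302)),
      external = evaluate_scores(predict_ensemble(ens, x_external)$score,
                                 y_external, cfg$n_boot,
                                 derive_seed(cfg$seed, 303)))
  }

  say("logistic baseline...")
  base <- train_logistic_baseline(x_train, y_train,
                                  cv = cv_scheme(n_folds = 10, n_repeats = 1,
                                                 seed = derive_seed(cfg$seed, 401)))
  logistic <- list(
    fold_auc = base$fold_auc,
    internal = evaluate_scores(score_classifier(base$fit, x_internal),
                               y_internal, cfg$n_boot,
                               derive_seed(cfg$seed, 402)),
    external = evaluate_scores(score_classifier(base$fit, x_external),
                               y_external, cfg$n_boot,
                               derive_seed(cfg$seed, 403)))

  report <- structure(list(
    config = cfg, config_hash = config_hash(cfg),
    metric1 = metric1, metric2 = metric2, logistic = logistic,
    labels = list(train = y_train, internal = y_internal,
                  external = y_external),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "evaluation_report")
  say("done in %.1f s", report$runtime_s)
  report
}

report_table3 <- function(report) {
  rows <- list()
  add <- function(metric, model, dataset, rr) {
    rows[[length(rows) + 1]] <<- data.frame(
      metric = metric, model = model, dataset = dataset,
      auc = rr$auc, ci_low = rr$ci_low, ci_high = rr$ci_high,
      sensitivity = rr$sensitivity, specificity = rr$specificity,
      accuracy = rr$accuracy, stringsAsFactors = FALSE)
  }
  best <- report$metric1$best_model
  for (ds in c("internal", "external")) {
    add("metric1_best", best, ds, report$metric1$models[[best]][[ds]])
  }
  for (arch in names(report$metric2)) {
    for (ds in c("internal", "external")) {
      add("metric2_mlp", arch, ds, report$metric2[[arch]][[ds]])
    }
  }
  for (ds in c("internal", "external")) {
    add("logistic_baseline", "ridge_logistic", ds, report$logistic[[ds]])
  }
  do.call(rbind, rows)
}

#' Write an evaluation report to disk
#'
#' Produces `report.json` (full nested report), `table3.csv` (one row per
#' metric x dataset with AUC/CI/sensitivity/specificity/accuracy), the two
#' selector x classifier heat-map CSVs, and `run.log`.
#'
#' @param report an `evaluation_report` from [run_experiment()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the output directory.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "evaluation_report"))
  if (is.null(report$metric1$models) || length(report$metric1$models) == 0) {
    stop("incomplete report: metric1 models missing")
  }
  if (length(report$metric2) == 0) stop("incomplete report: metric2 missing")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  strip <- function(x) {
    if (inherits(x, "trained_ensemble")) {
      return(list(arch = x$arch$label, n_members = length(x$members),
                  fold_auc = x$fold_auc))
    }
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  json <- list(config_hash = report$config_hash,
               seed = report$config$seed,
               runtime_s = report$runtime_s,
               metric1 = list(grid = report$metric1$grid,
                              best_model = report$metric1$best_model,
                              models = strip(report$metric1$models)),
               metric2 = strip(report$metric2),
               logistic = strip(report$logistic))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(report_table3(report), file.path(out_dir, "table3.csv"),
            row.names = FALSE)
  grid_heatmap_export(report$metric1$grid, out_dir)
  writeLines(c(sprintf("config_hash: %s", report$config_hash),
               sprintf("seed: %d", report$config$seed),
               sprintf("runtime_s: %.1f", report$runtime_s)),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Read an experiment config from a YAML file
#'
#' Scalar fields override the defaults of [experiment_config()]; nested
#' objects (`cv`, `mlp_cfg`, `external_shift`, `phantom`) take their fields
#' as key/value maps.
#'
#' @param path YAML file.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- experiment_config()
  for (k in c("n_train", "n_internal", "n_external")) {
    if (!is.null(y[[k]])) cfg[[k]] <- as.integer(unlist(y[[k]]))
  }
  for (k in c("channels", "selectors", "mlp_archs")) {
    if (!is.null(y[[k]])) cfg[[k]] <- unlist(y[[k]])
  }
  for (k in c("nested", "use_truth_masks")) {
    if (!is.null(y[[k]])) cfg[[k]] <- isTRUE(y[[k]])
  }
  if (!is.null(y$n_boot)) cfg$n_boot <- as.integer(y$n_boot)
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  if (!is.null(y$cv)) {
    cfg$cv <- do.call(cv_scheme, y$cv)
  }
  if (!is.null(y$mlp_cfg)) cfg$mlp_cfg <- do.call(training_config, y$mlp_cfg)
  if (!is.null(y$external_shift)) {
    cfg$external_shift <- do.call(protocol_shift, y$external_shift)
  }
  if (!is.null(y$phantom)) cfg$phantom <- do.call(phantom_spec, y$phantom)
  cfg
}
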