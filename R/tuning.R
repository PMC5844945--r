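#' Default hyperparameter search space
#'
#' Each entry is a sampling rule: `log_uniform(lo, hi)`, `uniform(lo, hi)`
#' or `integer(lo, hi)`. Classifier spaces: penalty strength `lambda`
#' log-uniform 1e-3..1e3 (logistic family), elastic-net mixing `alpha`
#' uniform 0..1, `k` 1..30 (kNN), SVM `cost`/`gamma` log-uniform, tree
#' ensembles 50..500 trees of depth 2..8 with log-uniform learning rate
#' 0.01..0.3 (GTB). Selector spaces: `n_features` 1..min(15, d) for
#' UFS/RFE, `importance_threshold` uniform 0.5..1.5 for MB selectors.
#'
#' @param classifier one of [classifier_names()].
#' @param selector one of [selector_names()].
#' @param n_features_max cap for the selector size (the feature count `d`).
#' @return named list of sampling rules.
#' @export
hyperparameter_space <- function(classifier, selector = "none",
                                 n_features_max = 15) {
  cls <- switch(classifier,
    "LR-L1" = , "LR-L2" = list(lambda = hp_log_uniform(1e-3, 1e3)),
    "LR-EN" = list(lambda = hp_log_uniform(1e-3, 1e3),
                   alpha = hp_uniform(0, 1)),
    "kNN" = list(k = hp_integer(1, 30)),
    "SVM" = list(cost = hp_log_uniform(1e-3, 1e3),
                 gamma = hp_log_uniform(1e-4, 1e1)),
    "ET" = list(num_trees = hp_integer(50, 500),
                max_depth = hp_integer(2, 8)),
    "GTB" = list(num_trees = hp_integer(50, 500),
                 max_depth = hp_integer(2, 8),
                 learning_rate = hp_log_uniform(0.01, 0.3)))
  sel <- if (selector %in% c("UFS-F", "UFS-MI", "RFE-LR", "RFE-ET")) {
    list(n_features = hp_integer(1, max(1, min(15, n_features_max))))
  } else if (selector %in% c("MB-LR", "MB-ET")) {
    list(importance_threshold = hp_uniform(0.5, 1.5))
  } else list()
  c(cls, sel)
}

hp_log_uniform <- function(lo, hi)
  structure(list(kind = "log_uniform", lo = lo, hi = hi), class = "hp_rule")
hp_uniform <- function(lo, hi)
  structure(list(kind = "uniform", lo = lo, hi = hi), class = "hp_rule")
hp_integer <- function(lo, hi)
  structure(list(kind = "integer", lo = lo, hi = hi), class = "hp_rule")

#' Draw one hyperparameter sample from a space
#' @param space a [hyperparameter_space()].
#' @return named list of values.
#' @export
sample_hyperparameters <- function(space) {
  lapply(space, function(rule) {
    switch(rule$kind,
      log_uniform = exp(stats::runif(1, log(rule$lo), log(rule$hi))),
      uniform = stats::runif(1, rule$lo, rule$hi),
      integer = sample(seq(rule$lo, rule$hi), 1))
  })
}

#' Random-search hyperparameter tuning
#'
#' Draws `n_iter` hyperparameter samples, evaluates each by cross-validated
#' AUC under the scheme (all preprocessing fold-local), keeps the best
#' (first-sampled wins ties), and refits the winning configuration on all
#' data. The tuning AUC's confidence interval is a BCa bootstrap over the
#' per-split scores.
#'
#' @param config a [model_config()] (its `hyperparameters` are overridden by
#'   the search).
#' @param features,labels full tuning data.
#' @param scheme a [mccv_scheme()] or [lpocv_scheme()].
#' @param n_iter number of random hyperparameter samples.
#' @param patient_ids required for LPOCV.
#' @param seed integer seed.
#' @param space optional custom [hyperparameter_space()].
#' @param ci_B bootstrap replicates for the tuning-AUC interval (0 skips it).
#' @return object of class `"tuning_result"`: `best_config`, `tuning_auc`,
#'   `ci`, `per_split`, `model` (refit on all data), `searched` (per-iter
#'   AUCs).
#' @export
random_search <- function(config, features, labels, scheme, n_iter = 300,
                          patient_ids = NULL, seed = 1L, space = NULL,
                          ci_B = 0) {
  X <- as.matrix(features)
  cols <- select_group_columns(colnames(X), config$feature_groups)
  if (is.null(space))
    space <- hyperparameter_space(config$classifier, config$selector,
                                  n_features_max = length(cols))
  set.seed(seed)
  draws <- lapply(seq_len(n_iter), function(i) sample_hyperparameters(space))
  evals <- vector("list", n_iter)
  failures <- character(0)
  for (i in seq_len(n_iter)) {
    cfg <- config
    cfg$hyperparameters <- utils::modifyList(config$hyperparameters, draws[[i]])
    evals[[i]] <- tryCatch(
      cross_validate_config(cfg, X, labels, scheme,
                            patient_ids = patient_ids, seed = seed),
      error = function(e) conditionMessage(e))
    if (is.character(evals[[i]]))
      failures <- c(failures, sprintf("iter %d: %s", i, evals[[i]]))
  }
  ok <- !vapply(evals, is.character, logical(1))
  if (!any(ok))
    stop("all candidate configurations failed:\n",
         paste(utils::head(failures, 5), collapse = "\n"))
  aucs <- rep(-Inf, n_iter)
  aucs[ok] <- vapply(evals[ok], function(e) e$auc, numeric(1))
  best <- which.max(aucs)  # first maximum wins ties
  best_cfg <- config
  best_cfg$hyperparameters <- utils::modifyList(config$hyperparameters,
                                                draws[[best]])
  per_split <- evals[[best]]$per_split
  ci <- c(NA_real_, NA_real_)
  if (ci_B > 0 && length(per_split) >= 10) {
    ci <- suppressWarnings(
      bca_interval(per_split, function(d, idx) mean(d[idx]), B = ci_B))
  }
  model <- fit_workflow(best_cfg, X, labels, seed = seed)
  structure(list(best_config = best_cfg, tuning_auc = aucs[best], ci = ci,
                 per_split = per_split, model = model,
                 searched = aucs, failures = failures),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %s: tuning AUC %.3f",
              x$best_config$classifier, x$tuning_auc))
  if (!anyNA(x$ci)) cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci[1], x$ci[2]))
  cat(sprintf(", %d candidates searched\n", length(x$searched)))
  invisible(x)
}

#' Nested cross-validation
#'
#' Estimates generalization performance: for each outer split, the random
#' search (inner loop) runs on the outer-training portion only, and the
#' refit winner is scored on the untouched outer test fold. Outer test
#' scores aggregate to the generalization AUC with a BCa bootstrap interval
#' over the per-split scores.
#'
#' @param config a [model_config()].
#' @param features,labels full data.
#' @param outer_scheme,inner_scheme split schemes for the two loops.
#' @param n_iter inner random-search budget.
#' @param patient_ids required when either scheme is LPOCV.
#' @param seed integer seed.
#' @param space optional custom hyperparameter space.
#' @param ci_B bootstrap replicates for the generalization interval.
#' @return object of class `"nested_cv_result"`: `generalization_auc`, `ci`,
#'   `mean_tuning_auc`, `per_outer` (per-split outer scores), `configs`
#'   (winning hyperparameters per outer split).
#' @export
nested_cv <- function(config, features, labels, outer_scheme, inner_scheme,
                      n_iter = 300, patient_ids = NULL, seed = 1L,
                      space = NULL, ci_B = 2000) {
  X <- as.matrix(features)
  labels <- as.integer(labels)
  outer <- if (outer_scheme$kind == "MCCV") {
    mccv_splits(labels, outer_scheme$n_splits, outer_scheme$test_fraction,
                seed = seed)
  } else {
    if (is.null(patient_ids)) stop("LPOCV requires patient_ids")
    lpocv_splits(patient_ids, labels, outer_scheme$n_pairs, seed = seed)
  }
  per_outer <- numeric(length(outer))
  tuning_aucs <- numeric(length(outer))
  configs <- vector("list", length(outer))
  for (i in seq_along(outer)) {
    sp <- outer[[i]]
    tr_ids <- if (is.null(patient_ids)) NULL else patient_ids[sp$train]
    ts <- random_search(config, X[sp$train, , drop = FALSE],
                        labels[sp$train], inner_scheme, n_iter = n_iter,
                        patient_ids = tr_ids, seed = seed + i, space = space,
                        ci_B = 0)
    scores <- predict(ts$model, X[sp$test, , drop = FALSE])
    per_outer[i] <- if (outer_scheme$kind == "MCCV") {
      mwu_auc(scores, labels[sp$test])$auc
    } else {
      (scores[1] > scores[2]) + 0.5 * (scores[1] == scores[2])
    }
    tuning_aucs[i] <- ts$tuning_auc
    configs[[i]] <- ts$best_config
  }
  ci <- c(NA_real_, NA_real_)
  if (ci_B > 0 && length(per_outer) >= 10) {
    ci <- suppressWarnings(
      bca_interval(per_outer, function(d, idx) mean(d[idx]), B = ci_B))
  }
  structure(list(generalization_auc = mean(per_outer), ci = ci,
                 mean_tuning_auc = mean(tuning_aucs),
                 per_outer = per_outer, configs = configs,
                 outer_scheme = outer_scheme),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("<nested_cv_result> generalization AUC %.3f",
              x$generalization_auc))
  if (!anyNA(x$ci)) cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci[1], x$ci[2]))
  cat(sprintf("; mean inner tuning AUC %.3f over %d outer splits\n",
              x$mean_tuning_auc, length(x$per_outer)))
  invisible(x)
}
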