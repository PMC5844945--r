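#' Endpoint vocabulary
#' @return character vector of the four modeled endpoints.
#' @export
endpoint_names <- function() c("early", "late", "long_term", "longitudinal")

#' Construct a model configuration
#'
#' A configuration fixes one choice in the model space: the feature groups
#' admitted, the sampler, the selector, the classifier, optional
#' hyperparameters and the endpoint.
#'
#' @param feature_groups nonempty subset of [feature_group_names()].
#' @param sampler one of [sampler_names()].
#' @param selector one of [selector_names()].
#' @param classifier one of [classifier_names()].
#' @param hyperparameters named list (classifier and selector settings).
#' @param endpoint one of [endpoint_names()].
#' @return object of class `"model_config"`.
#' @export
model_config <- function(feature_groups = feature_group_names(),
                         sampler = "none", selector = "none",
                         classifier = "LR-L2", hyperparameters = list(),
                         endpoint = "long_term") {
  if (!length(feature_groups)) stop("feature_groups must be nonempty")
  bad <- setdiff(feature_groups, feature_group_names())
  if (length(bad)) stop("unknown feature group(s): ", paste(bad, collapse = ", "))
  structure(list(
    feature_groups = feature_groups,
    sampler = match.arg(sampler, sampler_names()),
    selector = match.arg(selector, selector_names()),
    classifier = match.arg(classifier, classifier_names()),
    hyperparameters = hyperparameters,
    endpoint = match.arg(endpoint, endpoint_names())),
    class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s | sampler=%s selector=%s classifier=%s | %d group(s)\n",
              x$endpoint, x$sampler, x$selector, x$classifier,
              length(x$feature_groups)))
  invisible(x)
}

#' Bernoulli feature-group selection
#'
#' Keeps each feature group independently with probability `p`; when the
#' draw selects no group at all, the whole draw is repeated until nonempty.
#'
#' @param groups candidate group names.
#' @param p per-group success probability in (0, 1\].
#' @return nonempty character subset of `groups`.
#' @export
bernoulli_group_selection <- function(groups = feature_group_names(),
                                      p = 0.5) {
  if (!length(groups)) stop("at least one group required")
  if (!is.numeric(p) || p <= 0 || p > 1) stop("p must lie in (0, 1]")
  repeat {
    keep <- stats::runif(length(groups)) < p
    if (any(keep)) return(groups[keep])
  }
}

# Restrict a feature table to the columns in the configured groups; the
# longitudinal time covariate rides along with demographics.
select_group_columns <- function(feature_names, groups) {
  ann <- annotate_features(feature_names)
  feature_names[ann$group %in% groups]
}

# Fold-local z-scaling (population SD); constant columns map to 0.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2, mu)^2))
  list(mu = mu, sd = sd)
}

apply_scaler <- function(X, sc) {
  Z <- sweep(X, 2, sc$mu)
  ok <- sc$sd > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, sc$sd[ok], "/")
  Z[, !ok] <- 0
  Z
}

#' Fit the five-step workflow on a training set
#'
#' Applies, in order: feature-group restriction, Z-score scaling (statistics
#' from this training set only), the configured sampler, the configured
#' selector, and classifier training. The returned model carries the scaler
#' and the selected columns so `predict()` can replay the exact
#' transformation on new data.
#'
#' @param config a [model_config()].
#' @param features numeric matrix with column names (training rows only).
#' @param labels 0/1 training labels.
#' @param seed integer seed for the stochastic stages.
#' @return object of class `"workflow_model"`.
#' @export
fit_workflow <- function(config, features, labels, seed = 1L) {
  X <- as.matrix(features)
  cols <- select_group_columns(colnames(X), config$feature_groups)
  if (!length(cols)) stop("no feature columns left after group restriction")
  X <- X[, cols, drop = FALSE]
  sc <- fit_scaler(X)
  Z <- apply_scaler(X, sc)
  set.seed(seed)
  s <- apply_sampler(config$sampler, Z, labels)
  hp <- config$hyperparameters
  sel <- apply_selector(config$selector, s$features, s$labels,
                        k = if (is.null(hp$n_features)) 10 else hp$n_features,
                        threshold = if (is.null(hp$importance_threshold)) 1
                                    else hp$importance_threshold,
                        seed = seed)
  scorer <- train_classifier(config$classifier, hp,
                             s$features[, sel, drop = FALSE], s$labels,
                             seed = seed)
  structure(list(config = config, scaler = sc, columns = cols,
                 selected = cols[sel], scorer = scorer),
            class = "workflow_model")
}

#' @export
predict.workflow_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$columns, drop = FALSE]
  Z <- apply_scaler(X, object$scaler)
  predict(object$scorer, Z[, match(object$selected, object$columns),
                           drop = FALSE])
}

#' @export
print.workflow_model <- function(x, ...) {
  cat(sprintf("<workflow_model> %s, %d/%d features selected\n",
              x$config$classifier, length(x$selected), length(x$columns)))
  invisible(x)
}

#' Cross-validate one configuration
#'
#' Evaluates a fixed configuration under a split scheme. Scaling, sampling
#' and selection are fitted inside each training fold only. Under MCCV the
#' score is the mean of per-split test AUCs; under LPOCV it is the fraction
#' of correctly ranked held-out pairs.
#'
#' @param config a [model_config()].
#' @param features,labels full data.
#' @param scheme a [mccv_scheme()] or [lpocv_scheme()].
#' @param patient_ids required for LPOCV.
#' @param seed integer seed.
#' @return list with `auc`, `per_split` (per-split AUCs for MCCV; pair
#'   indicator scores for LPOCV), and `splits`.
#' @export
cross_validate_config <- function(config, features, labels, scheme,
                                  patient_ids = NULL, seed = 1L) {
  X <- as.matrix(features)
  labels <- as.integer(labels)
  splits <- if (scheme$kind == "MCCV") {
    mccv_splits(labels, scheme$n_splits, scheme$test_fraction, seed = seed)
  } else {
    if (is.null(patient_ids)) stop("LPOCV requires patient_ids")
    lpocv_splits(patient_ids, labels, scheme$n_pairs, seed = seed)
  }
  per_split <- vapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    m <- fit_workflow(config, X[sp$train, , drop = FALSE], labels[sp$train],
                      seed = seed + i)
    scores <- predict(m, X[sp$test, , drop = FALSE])
    if (scheme$kind == "MCCV") {
      mwu_auc(scores, labels[sp$test])$auc
    } else {
      (scores[1] > scores[2]) + 0.5 * (scores[1] == scores[2])
    }
  }, numeric(1))
  list(auc = mean(per_split), per_split = per_split, splits = splits)
}

#' Enumerate the model space
#'
#' Builds the full cross product of classifiers, selector options and
#' sampler options for each endpoint, and tallies totals and per-algorithm
#' involvement counts by enumeration.
#'
#' @param endpoints endpoints to enumerate.
#' @return list with `configs` (data.frame of endpoint/sampler/selector/
#'   classifier), `per_endpoint`, `total`, `per_classifier`, `per_selector`,
#'   `per_sampler` (each split into time-specific and longitudinal counts).
#' @export
enumerate_model_space <- function(endpoints = endpoint_names()) {
  grid <- expand.grid(endpoint = endpoints,
                      sampler = sampler_names(),
                      selector = selector_names(),
                      classifier = classifier_names(),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ts <- grid$endpoint != "longitudinal"
  count_by <- function(col) {
    lv <- unique(grid[[col]])
    out <- t(vapply(lv, function(v) {
      c(time_specific = sum(ts & grid[[col]] == v),
        longitudinal = sum(!ts & grid[[col]] == v))
    }, numeric(2)))
    rownames(out) <- lv
    out
  }
  list(configs = grid,
       per_endpoint = table(grid$endpoint),
       total = nrow(grid),
       per_classifier = count_by("classifier"),
       per_selector = count_by("selector"),
       per_sampler = count_by("sampler"))
}

#' Reference mean-dose and morphological model configurations
#'
#' The classical NTCP baselines expressed as fixed logistic configurations:
#' univariate logistic models on the ipsilateral mean dose, the
#' contralateral mean dose, and the pooled-gland mean dose; a bivariate
#' model on both mean doses; and the morphological model on the four
#' dose-moment covariates of [morphological_features()].
#'
#' @return named list of lists with `label` and `features` (column names of
#'   the wide feature table; `mean_b` denotes the mean of `mean_i` and
#'   `mean_c`, and must be added by [reference_model_columns()]).
#' @export
reference_model_configs <- function() {
  list(
    mean_ipsi = list(label = "Mean (ipsi)", features = "mean_i"),
    mean_contra = list(label = "Mean (contra)", features = "mean_c"),
    mean_both = list(label = "Mean (both glands)", features = "mean_b"),
    mean_pair = list(label = "Mean (ipsi + contra)",
                     features = c("mean_i", "mean_c")),
    morphological = list(label = "Morphological",
                         features = c("eta111_i", "eta002_c", "eta300_c",
                                      "eta110i_eta110c")))
}

#' Augment a feature table with reference-model covariates
#'
#' Adds `mean_b` (average of the two gland mean doses) and the morphological
#' product term `eta110i_eta110c` when the needed columns are present.
#'
#' @param table wide feature table.
#' @return the augmented table.
#' @export
reference_model_columns <- function(table) {
  if (all(c("mean_i", "mean_c") %in% names(table)))
    table$mean_b <- (table$mean_i + table$mean_c) / 2
  if (all(c("eta110_i", "eta110_c") %in% names(table)))
    table$eta110i_eta110c <- table$eta110_i * table$eta110_c
  table
}
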