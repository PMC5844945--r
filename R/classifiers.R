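#' Classifier vocabulary
#'
#' The seven classification algorithms compared by the pipeline.
#' @return character vector.
#' @export
classifier_names <- function() {
  c("LR-L1", "LR-L2", "LR-EN", "kNN", "SVM", "ET", "GTB")
}

#' Train a classifier returning a continuous risk scorer
#'
#' Fits the named algorithm and wraps it as a `"risk_scorer"`: `predict()`
#' returns a continuous score, higher meaning more likely positive. All
#' learners are deterministic given `seed`.
#'
#' Hyperparameters by algorithm (defaults in parentheses):
#' * `LR-L1`, `LR-L2`: `lambda` (0.01) — penalty strength.
#' * `LR-EN`: `lambda` (0.01), `alpha` (0.5) — elastic-net mixing.
#' * `kNN`: `k` (5) — neighbor count; score is the positive fraction among
#'   the k nearest training points.
#' * `SVM`: `cost` (1), `gamma` (1/d) — RBF kernel; the decision value is
#'   oriented so that higher means positive.
#' * `ET`: `num_trees` (200), `max_depth` (0 = unlimited) — extra-trees;
#'   score is the positive-class vote fraction.
#' * `GTB`: `num_trees` (100), `max_depth` (3), `learning_rate` (0.1),
#'   `subsample` (1).
#'
#' @param name one of [classifier_names()].
#' @param hyperparameters named list (missing entries take defaults).
#' @param features numeric matrix.
#' @param labels 0/1 labels, both classes present.
#' @param seed integer seed.
#' @return an object of class `"risk_scorer"`.
#' @export
train_classifier <- function(name, hyperparameters = list(), features,
                             labels, seed = 1L) {
  name <- match.arg(name, classifier_names())
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  hp <- hyperparameters
  def <- function(key, val) if (is.null(hp[[key]])) val else hp[[key]]
  fit <- tryCatch(switch(name,
    "LR-L1" = , "LR-L2" = , "LR-EN" = {
      alpha <- switch(name, "LR-L1" = 1, "LR-L2" = 0, "LR-EN" = def("alpha", 0.5))
      list(kind = "glmnet",
           model = glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                                  lambda = def("lambda", 0.01),
                                  standardize = FALSE))
    },
    "kNN" = list(kind = "knn", X = X, y = y,
                 k = min(def("k", 5), nrow(X))),
    "SVM" = {
      set.seed(seed)
      m <- e1071::svm(X, factor(y), kernel = "radial",
                      cost = def("cost", 1),
                      gamma = def("gamma", 1 / ncol(X)), scale = FALSE)
      # orient decision values: positive direction = class "1"
      dv <- attr(stats::predict(m, X, decision.values = TRUE),
                 "decision.values")
      orient <- if (grepl("^1", colnames(dv)[1])) 1 else -1
      list(kind = "svm", model = m, orient = orient)
    },
    "ET" = {
      df <- data.frame(X, .y = factor(y, levels = c(0, 1)))
      list(kind = "ranger",
           model = ranger::ranger(.y ~ ., data = df,
                                  num.trees = def("num_trees", 200),
                                  max.depth = def("max_depth", 0),
                                  splitrule = "extratrees",
                                  num.random.splits = 1,
                                  probability = TRUE, seed = seed))
    },
    "GTB" = {
      set.seed(seed)
      dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      list(kind = "xgb",
           model = xgboost::xgb.train(
             params = list(objective = "binary:logistic",
                           max_depth = def("max_depth", 3),
                           eta = def("learning_rate", 0.1),
                           subsample = def("subsample", 1),
                           nthread = 1, seed = seed),
             data = dm, nrounds = def("num_trees", 100), verbose = 0))
    }),
    error = function(e) stop("training failed for ", name, ": ",
                             conditionMessage(e)))
  structure(list(name = name, fit = fit, hyperparameters = hp,
                 columns = colnames(X)),
            class = "risk_scorer")
}

#' Predict continuous risk scores
#'
#' @param object a `"risk_scorer"` from [train_classifier()].
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of scores (higher = more likely positive).
#' @export
predict.risk_scorer <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  fit <- object$fit
  switch(fit$kind,
    glmnet = as.numeric(stats::predict(fit$model, X, type = "link")),
    knn = {
      tr <- fit$X
      apply(X, 1, function(p) {
        d <- sqrt(colSums((t(tr) - p)^2))
        mean(fit$y[order(d)[seq_len(fit$k)]])
      })
    },
    svm = {
      dv <- attr(stats::predict(fit$model, X, decision.values = TRUE),
                 "decision.values")
      fit$orient * as.numeric(dv)
    },
    ranger = {
      df <- data.frame(X)
      colnames(df) <- object$columns
      stats::predict(fit$model, data = df)$predictions[, "1"]
    },
    xgb = as.numeric(stats::predict(fit$model,
                                    xgboost::xgb.DMatrix(X, nthread = 1))))
}

#' @export
print.risk_scorer <- function(x, ...) {
  cat(sprintf("<risk_scorer> %s on %d features\n", x$name,
              length(x$columns)))
  invisible(x)
}
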