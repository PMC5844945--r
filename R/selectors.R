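#' Feature-selector vocabulary
#'
#' Six selection algorithms plus explicit no-selection.
#' @return character vector.
#' @export
selector_names <- function() {
  c("none", "UFS-F", "UFS-MI", "RFE-LR", "RFE-ET", "MB-LR", "MB-ET")
}

#' Apply a feature selector
#'
#' Univariate filters (`UFS-F` by ANOVA F-score, `UFS-MI` by mutual
#' information) keep the `k` top-ranked features; recursive feature
#' elimination (`RFE-LR`, `RFE-ET`) repeatedly drops the feature with the
#' smallest weight of the named model until `k` remain; model-based selection
#' (`MB-LR` via L1-logistic coefficients, `MB-ET` via extra-trees impurity
#' importance) keeps features whose importance exceeds `threshold` times the
#' mean importance; `"none"` keeps everything.
#'
#' @param name one of [selector_names()].
#' @param features numeric matrix with column names.
#' @param labels 0/1 labels.
#' @param k target number of features for UFS/RFE (capped at the feature
#'   count with a warning).
#' @param threshold importance multiplier for MB selectors.
#' @param seed integer seed controlling the stochastic learners.
#' @return integer vector of selected column indices (increasing).
#' @export
apply_selector <- function(name, features, labels, k = 10, threshold = 1,
                           seed = 1L) {
  name <- match.arg(name, selector_names())
  X <- as.matrix(features)
  y <- as.integer(labels)
  d <- ncol(X)
  if (d < 1) stop("need at least one feature")
  if (name == "none") return(seq_len(d))
  if (name %in% c("UFS-F", "UFS-MI", "RFE-LR", "RFE-ET") && k > d) {
    warning("k exceeds feature count: keeping all ", d, " features")
    k <- d
  }
  k <- max(1L, as.integer(k))
  sel <- switch(name,
    "UFS-F" = order(apply(X, 2, f_score, y = y), decreasing = TRUE)[seq_len(k)],
    "UFS-MI" = order(apply(X, 2, mutual_information, y = y),
                     decreasing = TRUE)[seq_len(k)],
    "RFE-LR" = rfe(X, y, k, weight_fn = lr_weights),
    "RFE-ET" = rfe(X, y, k, weight_fn = function(X, y) et_importance(X, y, seed)),
    "MB-LR" = {
      w <- lr_l1_weights(X, y, seed)
      keep_above(w, threshold)
    },
    "MB-ET" = keep_above(et_importance(X, y, seed), threshold))
  sort(sel)
}

keep_above <- function(w, threshold) {
  keep <- which(w > threshold * mean(w))
  if (!length(keep)) keep <- which.max(w)
  keep
}

# One-way ANOVA F-score of a feature against the binary label.
f_score <- function(x, y) {
  g0 <- x[y == 0]; g1 <- x[y == 1]
  n0 <- length(g0); n1 <- length(g1); n <- n0 + n1
  mb <- mean(x)
  ssb <- n0 * (mean(g0) - mb)^2 + n1 * (mean(g1) - mb)^2
  ssw <- sum((g0 - mean(g0))^2) + sum((g1 - mean(g1))^2)
  if (ssw == 0) return(Inf)
  (ssb / 1) / (ssw / (n - 2))
}

# Mutual information between a feature (equal-frequency discretized) and the
# binary label, in nats.
mutual_information <- function(x, y, n_bins = 10) {
  n <- length(x)
  n_bins <- min(n_bins, max(2, floor(n / 5)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) br <- c(-Inf, stats::median(x), Inf)
  xb <- cut(x, breaks = br, include.lowest = TRUE)
  tab <- table(xb, y) / n
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- tab[i, j]
    if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
  }
  mi
}

# |coefficient| of an (unpenalized, mildly ridge-stabilized) logistic fit on
# standardized features.
lr_weights <- function(X, y) {
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                        lambda = 1e-4, standardize = FALSE)
  abs(as.numeric(fit$beta))
}

lr_l1_weights <- function(X, y, seed) {
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 1,
                        lambda = 0.01, standardize = FALSE)
  abs(as.numeric(fit$beta))
}

et_importance <- function(X, y, seed) {
  df <- data.frame(X, .y = factor(y))
  fit <- ranger::ranger(.y ~ ., data = df, num.trees = 100,
                        splitrule = "extratrees", num.random.splits = 1,
                        importance = "impurity", seed = seed,
                        respect.unordered.factors = TRUE)
  imp <- fit$variable.importance[colnames(X)]
  pmax(as.numeric(imp), 0)
}

rfe <- function(X, y, k, weight_fn) {
  remaining <- seq_len(ncol(X))
  while (length(remaining) > k) {
    w <- weight_fn(X[, remaining, drop = FALSE], y)
    remaining <- remaining[-which.min(w)]
  }
  remaining
}
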