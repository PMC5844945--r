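#' Sampler vocabulary
#'
#' The ten sampling options of the model-building workflow: nine data
#' cleaning / class balancing algorithms plus explicit no-sampling.
#' @return character vector.
#' @export
sampler_names <- function() {
  c("none", "ROS", "SMOTE", "ADASYN", "OSS", "TL", "ENN", "NCL",
    "SMOTE+ENN", "SMOTE+TL")
}

#' Apply a class-imbalance sampler
#'
#' Resamples a two-class training set. Oversamplers (`ROS`, `SMOTE`,
#' `ADASYN`) bring the minority class to parity with the majority; cleaning
#' rules (`TL`, `ENN`, `OSS`, `NCL`) remove majority-class points near the
#' class boundary; combinations apply left-to-right; `"none"` is the
#' identity. Distances are Euclidean in the given feature space (scale
#' features first).
#'
#' @param name one of [sampler_names()].
#' @param features numeric matrix (rows = observations).
#' @param labels 0/1 labels.
#' @param k neighbor count for SMOTE/ADASYN (reduced with a warning when the
#'   minority class is too small).
#' @param k_enn neighbor count for the edited nearest-neighbor rule.
#' @return list with resampled `features` and `labels`.
#' @export
apply_sampler <- function(name, features, labels, k = 5, k_enn = 3) {
  name <- match.arg(name, sampler_names())
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (name != "none" && length(unique(labels)) < 2)
    stop("sampler requires both classes present")
  switch(name,
    "none" = list(features = features, labels = labels),
    "ROS" = sampler_ros(features, labels),
    "SMOTE" = sampler_smote(features, labels, k),
    "ADASYN" = sampler_adasyn(features, labels, k),
    "TL" = sampler_tomek(features, labels),
    "ENN" = sampler_enn(features, labels, k_enn),
    "OSS" = sampler_oss(features, labels),
    "NCL" = sampler_ncl(features, labels, k_enn),
    "SMOTE+ENN" = {
      s <- sampler_smote(features, labels, k)
      sampler_enn(s$features, s$labels, k_enn)
    },
    "SMOTE+TL" = {
      s <- sampler_smote(features, labels, k)
      sampler_tomek(s$features, s$labels)
    })
}

minority_class <- function(labels) {
  tab <- table(factor(labels, levels = c(0, 1)))
  if (tab[["1"]] <= tab[["0"]]) 1L else 0L
}

sampler_ros <- function(X, y) {
  mc <- minority_class(y)
  n_min <- sum(y == mc); n_maj <- sum(y != mc)
  extra <- n_maj - n_min
  if (extra <= 0) return(list(features = X, labels = y))
  idx <- which(y == mc)[sample.int(n_min, extra, replace = TRUE)]
  list(features = rbind(X, X[idx, , drop = FALSE]), labels = c(y, y[idx]))
}

# k nearest minority neighbors of each minority point (excluding itself)
knn_within <- function(X, idx, k) {
  D <- as.matrix(stats::dist(X[idx, , drop = FALSE]))
  diag(D) <- Inf
  t(apply(D, 1, function(r) idx[order(r)[seq_len(k)]]))
}

effective_k <- function(k, n_min) {
  if (n_min - 1 < k) {
    warning("minority class smaller than k+1: reducing k to ", n_min - 1)
    n_min - 1L
  } else k
}

smote_points <- function(X, min_idx, counts, k) {
  # counts: number of synthetic points to seed from each minority point
  nb <- knn_within(X, min_idx, k)
  rows <- lapply(seq_along(min_idx), function(i) {
    ni <- counts[i]
    if (ni <= 0) return(NULL)
    base <- X[min_idx[i], , drop = FALSE][rep(1, ni), , drop = FALSE]
    nbr <- X[nb[i, sample.int(k, ni, replace = TRUE)], , drop = FALSE]
    gap <- stats::runif(ni)
    base + gap * (nbr - base)
  })
  do.call(rbind, rows)
}

sampler_smote <- function(X, y, k = 5) {
  mc <- minority_class(y)
  min_idx <- which(y == mc)
  n_min <- length(min_idx); n_maj <- sum(y != mc)
  n_syn <- n_maj - n_min
  if (n_syn <= 0 || n_min < 2) return(list(features = X, labels = y))
  k <- effective_k(k, n_min)
  counts <- tabulate(sample(rep_len(seq_len(n_min), n_syn)), nbins = n_min)
  syn <- smote_points(X, min_idx, counts, k)
  list(features = rbind(X, syn), labels = c(y, rep(mc, nrow(syn))))
}

sampler_adasyn <- function(X, y, k = 5) {
  mc <- minority_class(y)
  min_idx <- which(y == mc)
  n_min <- length(min_idx); n_maj <- sum(y != mc)
  n_syn <- n_maj - n_min
  if (n_syn <= 0 || n_min < 2) return(list(features = X, labels = y))
  k <- effective_k(k, n_min)
  # density weights: fraction of majority points among the k nearest
  # neighbors (any class) of each minority point
  D <- as.matrix(stats::dist(X))
  r <- vapply(min_idx, function(i) {
    nb <- order(D[i, -i])[seq_len(min(k, nrow(X) - 1))]
    nb <- seq_len(nrow(X))[-i][nb]
    mean(y[nb] != mc)
  }, numeric(1))
  w <- if (sum(r) == 0) rep(1 / n_min, n_min) else r / sum(r)
  counts <- stats::rmultinom(1, n_syn, w)[, 1]
  syn <- smote_points(X, min_idx, counts, k)
  list(features = rbind(X, syn), labels = c(y, rep(mc, nrow(syn))))
}

# Tomek pairs: mutual nearest neighbors from opposite classes.
tomek_majority_members <- function(X, y) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  mc <- minority_class(y)
  drop <- integer(0)
  for (i in seq_len(n)) {
    j <- nn[i]
    if (y[i] != y[j] && nn[j] == i) {
      maj <- if (y[i] == mc) j else i
      drop <- c(drop, maj)
    }
  }
  unique(drop)
}

sampler_tomek <- function(X, y) {
  drop <- tomek_majority_members(X, y)
  if (length(drop)) {
    X <- X[-drop, , drop = FALSE]; y <- y[-drop]
  }
  list(features = X, labels = y)
}

# Wilson's rule: drop majority points misclassified by their k nearest
# neighbors.
enn_majority_misclassified <- function(X, y, k = 3) {
  mc <- minority_class(y)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  which(vapply(seq_len(nrow(X)), function(i) {
    if (y[i] == mc) return(FALSE)
    nb <- order(D[i, ])[seq_len(min(k, nrow(X) - 1))]
    mean(y[nb] == y[i]) < 0.5
  }, logical(1)))
}

sampler_enn <- function(X, y, k = 3) {
  drop <- enn_majority_misclassified(X, y, k)
  if (length(drop)) {
    X <- X[-drop, , drop = FALSE]; y <- y[-drop]
  }
  list(features = X, labels = y)
}

# One-sided selection: 1-NN condensing (keep all minority + one random
# majority point, then add majority points misclassified by 1-NN on the kept
# set), followed by Tomek-link removal.
sampler_oss <- function(X, y) {
  mc <- minority_class(y)
  maj_idx <- which(y != mc)
  keep <- c(which(y == mc), maj_idx[sample.int(length(maj_idx), 1)])
  for (i in setdiff(maj_idx, keep)) {
    D <- sqrt(colSums((t(X[keep, , drop = FALSE]) - X[i, ])^2))
    if (y[keep[which.min(D)]] != y[i]) keep <- c(keep, i)
  }
  keep <- sort(keep)
  X2 <- X[keep, , drop = FALSE]; y2 <- y[keep]
  sampler_tomek(X2, y2)
}

# Neighborhood cleaning rule: ENN on the majority class, plus removal of
# majority neighbors that misclassify minority points.
sampler_ncl <- function(X, y, k = 3) {
  mc <- minority_class(y)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  drop <- enn_majority_misclassified(X, y, k)
  for (i in which(y == mc)) {
    nb <- order(D[i, ])[seq_len(min(k, nrow(X) - 1))]
    if (mean(y[nb] == mc) < 0.5) drop <- c(drop, nb[y[nb] != mc])
  }
  drop <- unique(drop)
  if (length(drop)) {
    X <- X[-drop, , drop = FALSE]; y <- y[-drop]
  }
  list(features = X, labels = y)
}
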