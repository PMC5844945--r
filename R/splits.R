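#' Split-scheme constructors
#'
#' `mccv_scheme()` describes stratified Monte Carlo cross-validation: at each
#' split a stratified fraction of observations is held out for testing.
#' `lpocv_scheme()` describes the modified leave-pair-out scheme for
#' longitudinal data: each split holds out one positive and one negative
#' observation from distinct patients, and every training observation sharing
#' a patient id with the test pair is removed.
#'
#' @param n_splits,n_pairs number of random splits / sampled pairs.
#' @param test_fraction held-out fraction for MCCV.
#' @return a list of class `"split_scheme"`.
#' @export
mccv_scheme <- function(n_splits = 300, test_fraction = 0.1) {
  stopifnot(n_splits >= 1, test_fraction > 0, test_fraction < 1)
  structure(list(kind = "MCCV", n_splits = n_splits,
                 test_fraction = test_fraction, stratified = TRUE),
            class = "split_scheme")
}

#' @rdname mccv_scheme
#' @export
lpocv_scheme <- function(n_pairs = 300) {
  stopifnot(n_pairs >= 1)
  structure(list(kind = "LPOCV", n_pairs = n_pairs), class = "split_scheme")
}

#' Stratified Monte Carlo cross-validation splits
#'
#' Each split holds out a stratified `test_fraction` sample (at least one
#' observation per class), so the test-fold class ratio stays within one
#' observation of the cohort ratio.
#'
#' @param labels 0/1 labels.
#' @param n_splits number of splits.
#' @param test_fraction held-out fraction.
#' @param seed integer seed.
#' @return list of `list(train, test)` index vectors.
#' @export
mccv_splits <- function(labels, n_splits = 300, test_fraction = 0.1,
                        seed = 1L) {
  labels <- as.integer(labels)
  idx0 <- which(labels == 0); idx1 <- which(labels == 1)
  if (length(idx0) < 2 || length(idx1) < 2)
    stop("both classes need >= 2 observations to stratify")
  k0 <- max(1L, round(length(idx0) * test_fraction))
  k1 <- max(1L, round(length(idx1) * test_fraction))
  set.seed(seed)
  lapply(seq_len(n_splits), function(s) {
    test <- sort(c(idx0[sample.int(length(idx0), k0)],
                   idx1[sample.int(length(idx1), k1)]))
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

#' Modified leave-pair-out cross-validation splits
#'
#' Samples positive-negative observation pairs from distinct patients. Each
#' split's test fold is one such pair; the training fold excludes every
#' observation sharing a patient id with either test observation. If fewer
#' distinct pairs exist than requested, all are used.
#'
#' @param patient_ids patient identifier per observation.
#' @param labels 0/1 labels per observation.
#' @param n_pairs number of pairs to sample.
#' @param seed integer seed.
#' @return list of `list(train, test)`; `test` is `c(pos_index, neg_index)`.
#' @export
lpocv_splits <- function(patient_ids, labels, n_pairs = 300, seed = 1L) {
  labels <- as.integer(labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  pairs <- expand.grid(pos = pos, neg = neg, KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[patient_ids[pairs$pos] != patient_ids[pairs$neg], ,
                 drop = FALSE]
  if (nrow(pairs) == 0)
    stop("no cross-patient positive-negative pair exists")
  set.seed(seed)
  if (nrow(pairs) > n_pairs)
    pairs <- pairs[sample.int(nrow(pairs), n_pairs), , drop = FALSE]
  lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs$pos[i]; n <- pairs$neg[i]
    test_pids <- patient_ids[c(p, n)]
    train <- which(!(patient_ids %in% test_pids))
    list(train = train, test = c(p, n))
  })
}

#' Leave-pair-out AUC from per-split scores
#'
#' The LPOCV AUC estimator: the fraction of held-out pairs where the positive
#' observation's score exceeds the negative's, ties counting 0.5.
#'
#' @param pos_scores,neg_scores score of the positive / negative test
#'   observation at each split.
#' @return AUC in \[0, 1\].
#' @export
lpocv_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) != length(neg_scores))
    stop("score vectors must have equal length")
  mean((pos_scores > neg_scores) + 0.5 * (pos_scores == neg_scores))
}
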