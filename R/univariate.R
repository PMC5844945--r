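#' Mann-Whitney U statistic and AUC
#'
#' `U` counts (negative, positive) pairs where the positive observation has
#' the larger value, with 0.5 per tie (midrank convention), and
#' `AUC = U / (n_neg * n_pos)`.
#'
#' @param values numeric feature values.
#' @param labels 0/1 outcome labels; both classes nonempty.
#' @return list with `U`, `auc`, `n_neg`, `n_pos`.
#' @export
mwu_auc <- function(values, labels) {
  labels <- as.integer(labels)
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be nonempty")
  r <- rank(values)  # midranks
  U <- sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2
  list(U = U, auc = U / (n_neg * n_pos), n_neg = n_neg, n_pos = n_pos)
}

# Two-sided MWU p-value: normal approximation with tie and continuity
# correction (stable for cohort-scale n).
mwu_pvalue <- function(values, labels) {
  res <- mwu_auc(values, labels)
  n1 <- res$n_pos; n0 <- res$n_neg; n <- n0 + n1
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n0 * n1 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  mu <- n0 * n1 / 2
  z <- (abs(res$U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  2 * stats::pnorm(-z)
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Nonparametric BCa interval: the bias correction `z0` is the normal
#' quantile of the fraction of bootstrap replicates below the point estimate,
#' and the acceleration `a` comes from the skewness of the jackknife
#' distribution. With `strata` supplied (e.g. class labels), resampling is
#' stratified so every replicate preserves the class counts.
#'
#' @param data vector, or data.frame/matrix resampled by rows.
#' @param statistic function `(data, indices) -> numeric scalar`.
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @param strata optional stratification factor, same length as rows of
#'   `data`.
#' @return `c(lo, hi)`.
#' @export
bca_interval <- function(data, statistic, B = 2000, level = 0.95,
                         strata = NULL) {
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 10) stop("BCa interval needs n >= 10")
  idx_all <- seq_len(n)
  theta <- statistic(data, idx_all)
  groups <- if (is.null(strata)) list(idx_all) else split(idx_all, strata)
  boot_stats <- vapply(seq_len(B), function(b) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), replace = TRUE)]), use.names = FALSE)
    statistic(data, idx)
  }, numeric(1))
  if (all(boot_stats == boot_stats[1])) {
    warning("degenerate bootstrap distribution: zero-width interval")
    return(c(boot_stats[1], boot_stats[1]))
  }
  prop <- (sum(boot_stats < theta) + 0.5 * sum(boot_stats == theta)) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  jack <- vapply(idx_all, function(i) statistic(data, idx_all[-i]), numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
  alpha <- (1 - level) / 2
  adj <- function(p) {
    z <- z0 + stats::qnorm(p)
    stats::pnorm(z0 + z / (1 - a * z))
  }
  stats::quantile(boot_stats, probs = c(adj(alpha), adj(1 - alpha)),
                  names = FALSE, type = 7)
}

#' Adaptive FDR step-down procedure
#'
#' Step-down multiple-testing procedure bounding the false discovery rate at
#' `q`, with critical constants `c_i = i q / (m + 1 - i (1 - q))`: the sorted
#' p-values are rejected up to the largest prefix satisfying `p_(i) <= c_i`
#' throughout.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param q FDR bound.
#' @return logical rejection flags in the input order.
#' @export
gbs_stepdown <- function(pvalues, q = 0.05) {
  m <- length(pvalues)
  if (m == 0) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  ord <- order(pvalues)
  i <- seq_len(m)
  crit <- i * q / (m + 1 - i * (1 - q))
  ok <- pvalues[ord] <= crit
  k <- if (all(ok)) m else which.min(ok) - 1L  # largest all-pass prefix
  flags <- logical(m)
  if (k > 0) flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Logistic tolerance values
#'
#' Fits the univariate logistic model `P(event) = logistic(b0 + b1 x)` and
#' inverts it: `TVp = (logit(p) - b0) / b1`, the feature value at which the
#' predicted complication probability equals `p`.
#'
#' @param values feature values (original units).
#' @param labels 0/1 outcomes.
#' @param probs complication probabilities (default 20%, 10%, 5%).
#' @return named numeric vector (`TV20`, `TV10`, `TV5` for the defaults), in
#'   the feature's units.
#' @export
tolerance_values <- function(values, labels, probs = c(0.20, 0.10, 0.05)) {
  fit <- suppressWarnings(
    stats::glm(labels ~ values, family = stats::binomial()))
  if (!fit$converged) stop("univariate logistic fit did not converge")
  b <- stats::coef(fit)
  scale <- stats::sd(values)
  if (!is.finite(b[2]) || abs(b[2]) * max(scale, 1) < 1e-8)
    stop("non-informative feature: logistic slope is ~0, tolerance values undefined")
  tv <- (stats::qlogis(probs) - b[1]) / b[2]
  names(tv) <- paste0("TV", round(probs * 100))
  tv
}

#' Lower bounds on the truth of FDR-significant discoveries
#'
#' Treating each of `R` discoveries as independently false with probability
#' `q` (the FDR level), returns the probability that all are true,
#' `(1-q)^R`, and that at most one is false,
#' `(1-q)^R + R q (1-q)^(R-1)`.
#'
#' @param n_rejections number of discoveries `R` (>= 1).
#' @param q FDR level.
#' @return named numeric vector `c(all_true, at_most_one_false)`.
#' @export
fdr_truth_bounds <- function(n_rejections, q) {
  if (n_rejections < 1) stop("n_rejections must be >= 1")
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  R <- n_rejections
  c(all_true = (1 - q)^R,
    at_most_one_false = (1 - q)^R + R * q * (1 - q)^(R - 1))
}

#' Univariate feature screen
#'
#' For every feature: Z-score normalization (population SD), Mann-Whitney
#' AUC with a stratified BCa bootstrap confidence interval, a two-sided MWU
#' p-value, adaptive FDR step-down significance flags across all screened
#' features, and logistic tolerance values in the feature's original units.
#' Constant features are skipped with a warning; features whose logistic
#' slope vanishes get `NA` tolerance values.
#'
#' @param table wide feature table (data.frame; optional `patient_id` column
#'   ignored for statistics), no missing values.
#' @param labels 0/1 outcome labels, one per row.
#' @param B bootstrap replicates for the BCa interval.
#' @param q FDR bound for the significance flags.
#' @param level confidence level of the AUC interval.
#' @return data.frame of class `"univariate_screen"` with one row per
#'   feature: `feature`, `group`, `side`, `n_neg`, `n_pos`, `direction`
#'   (+1 harmful, -1 protective), `U`, `auc`, `ci_lo`, `ci_hi`, `p_value`,
#'   `significant`, `TV20`, `TV10`, `TV5`. The reported AUC is that of the
#'   univariate logistic model: protective features (higher value, lower
#'   risk) are orientation-flipped so AUC >= 0.5 describes discrimination in
#'   either direction, with `U` flipped consistently so
#'   `auc = U / (n_neg n_pos)` always holds.
#' @export
univariate_screen <- function(table, labels, B = 2000, q = 0.05,
                              level = 0.95) {
  feats <- setdiff(names(table), "patient_id")
  labels <- as.integer(labels)
  keep <- vapply(feats, function(f) {
    if (stats::sd(table[[f]]) == 0) {
      warning("constant feature skipped: ", f)
      FALSE
    } else TRUE
  }, logical(1))
  feats <- feats[keep]
  if (!length(feats)) stop("no non-constant features to screen")
  ann <- annotate_features(feats)
  auc_stat <- function(d, idx) mwu_auc(d$value[idx], d$label[idx])$auc
  rows <- lapply(feats, function(f) {
    x <- table[[f]]
    z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    res <- mwu_auc(z, labels)
    # orient protective features so the reported AUC is the discrimination
    # of the univariate logistic model (monotone in risk, not in the raw
    # feature); U is flipped consistently so auc = U / (n- n+) still holds
    direction <- if (res$auc < 0.5) -1L else 1L
    zo <- direction * z
    res <- mwu_auc(zo, labels)
    ci <- bca_interval(data.frame(value = zo, label = labels), auc_stat,
                       B = B, level = level, strata = labels)
    tv <- tryCatch(tolerance_values(x, labels),
                   error = function(e) c(TV20 = NA_real_, TV10 = NA_real_,
                                         TV5 = NA_real_))
    data.frame(feature = f, n_neg = res$n_neg, n_pos = res$n_pos,
               direction = direction,
               U = res$U, auc = res$auc, ci_lo = ci[1], ci_hi = ci[2],
               p_value = mwu_pvalue(z, labels),
               TV20 = tv[["TV20"]], TV10 = tv[["TV10"]], TV5 = tv[["TV5"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- gbs_stepdown(out$p_value, q = q)
  out <- cbind(out[, "feature", drop = FALSE],
               group = ann$group, side = ann$side,
               out[, setdiff(names(out), "feature")])
  rownames(out) <- NULL
  class(out) <- c("univariate_screen", "data.frame")
  attr(out, "q") <- q
  out
}

#' @export
print.univariate_screen <- function(x, digits = 3, ...) {
  cat(sprintf("<univariate_screen> %d features, %d significant at FDR <= %g\n",
              nrow(x), sum(x$significant), attr(x, "q")))
  df <- as.data.frame(x)
  df <- df[order(-df$auc), c("feature", "group", "auc", "ci_lo", "ci_hi",
                             "p_value", "significant")]
  print(utils::head(df, 15), digits = digits, row.names = FALSE)
  if (nrow(df) > 15) cat("... (", nrow(df) - 15, " more)\n", sep = "")
  invisible(x)
}

#' Write the univariate screen report
#'
#' Delimited table of the screen: feature, group, AUC with confidence
#' interval, significance flag and tolerance values.
#'
#' @param screen a [univariate_screen()] result.
#' @param path output CSV path.
#' @export
write_screen_report <- function(screen, path) {
  utils::write.csv(as.data.frame(screen), path, row.names = FALSE)
  invisible(path)
}
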