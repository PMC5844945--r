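#' Friedman rank test
#'
#' Ranks the algorithms within each context (midranks for ties; rank 1 =
#' best, i.e. highest score) and tests whether all algorithms have the same
#' influence on performance:
#' `chi2_F = 12 N / (k (k + 1)) * (sum_j Rbar_j^2 - k (k + 1)^2 / 4)`,
#' referred to a chi-square with `k - 1` degrees of freedom.
#'
#' @param scores numeric matrix, contexts (rows) x algorithms (columns).
#' @return list with `statistic`, `df`, `p_value`, `avg_ranks`, `k`, `N`.
#' @export
friedman_rank_test <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores); N <- nrow(scores)
  if (k < 3) stop("need at least 3 algorithms")
  if (N < 2) stop("need at least 2 contexts")
  ranks <- t(apply(-scores, 1, rank))  # rank 1 = best score
  rbar <- colMeans(ranks)
  stat <- 12 * N / (k * (k + 1)) * (sum(rbar^2) - k * (k + 1)^2 / 4)
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
       avg_ranks = rbar, k = k, N = N)
}

#' Nemenyi critical difference
#'
#' The minimum difference in Friedman average ranks at which two algorithms
#' differ significantly:
#' `CD = q_alpha,k sqrt(k (k + 1) / (6 N))`, with `q` the studentized-range
#' quantile (infinite df) divided by sqrt(2), computed numerically.
#'
#' @param k number of algorithms (2..20).
#' @param N number of contexts.
#' @param alpha significance level.
#' @return the critical difference.
#' @export
nemenyi_cd <- function(k, N, alpha = 0.05) {
  if (k < 2 || k > 20) stop("k must lie in 2..20")
  if (N < 2) stop("N must be >= 2")
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * N))
}

#' Holm-Bonferroni step-down FWER control
#'
#' Sorts the p-values ascending and rejects while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param alpha family-wise error level.
#' @return logical rejection flags in input order.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  ord <- order(pvalues)
  flags <- logical(m)
  for (i in seq_len(m)) {
    if (pvalues[ord[i]] <= alpha / (m - i + 1)) flags[ord[i]] <- TRUE
    else break
  }
  flags
}

#' Pairwise win-proportion matrix
#'
#' Entry `(a, b)` is the fraction of contexts in which algorithm `a`'s best
#' score strictly exceeds `b`'s, ties counting 0.5, so
#' `M[a, b] + M[b, a] = 1` off the diagonal.
#'
#' @param scores matrix, contexts x algorithms (best score per context and
#'   algorithm). Rows with missing values are dropped with a warning.
#' @return k x k matrix with dimnames from the columns; diagonal 0.5.
#' @export
win_proportion_matrix <- function(scores) {
  scores <- as.matrix(scores)
  bad <- apply(scores, 1, anyNA)
  if (any(bad)) {
    warning(sum(bad), " context(s) with missing algorithm scores dropped")
    scores <- scores[!bad, , drop = FALSE]
  }
  k <- ncol(scores)
  M <- matrix(0.5, k, k, dimnames = list(colnames(scores), colnames(scores)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    M[a, b] <- mean((scores[, a] > scores[, b]) +
                    0.5 * (scores[, a] == scores[, b]))
  }
  M
}

#' Compare algorithm families with Friedman/Nemenyi under one Holm correction
#'
#' Runs a Friedman test per family (e.g. classifiers, selectors, samplers,
#' each in time-specific and longitudinal models), applies one
#' Holm-Bonferroni correction across the whole family set, and attaches the
#' Nemenyi critical difference for each family.
#'
#' @param families named list of score matrices (contexts x algorithms).
#' @param alpha FWER level.
#' @return object of class `"algorithm_comparison"`: data.frame `summary`
#'   plus per-family `tests` (with `avg_ranks` and `cd`).
#' @export
compare_algorithms <- function(families, alpha = 0.05) {
  tests <- lapply(families, friedman_rank_test)
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  rej <- holm_bonferroni(p, alpha)
  for (i in seq_along(tests)) {
    tests[[i]]$rejected <- rej[i]
    tests[[i]]$cd <- nemenyi_cd(tests[[i]]$k, tests[[i]]$N, alpha)
  }
  summary <- data.frame(
    family = names(families),
    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p_value = p, rejected = rej,
    cd = vapply(tests, `[[`, numeric(1), "cd"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary, tests = tests, alpha = alpha),
            class = "algorithm_comparison")
}

#' @export
print.algorithm_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("<algorithm_comparison> %d families, FWER <= %g (Holm)\n",
              nrow(x$summary), x$alpha))
  print(x$summary, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Critical-difference diagram
#'
#' Plots average ranks on a horizontal axis (rank 1 = best, left) and
#' connects groups of algorithms whose ranks differ by less than the
#' critical difference.
#'
#' @param avg_ranks named numeric vector of average ranks.
#' @param cd the critical difference.
#' @param main plot title.
#' @export
plot_cd_diagram <- function(avg_ranks, cd, main = "Critical difference") {
  k <- length(avg_ranks)
  ord <- order(avg_ranks)
  r <- avg_ranks[ord]
  graphics::plot(NULL, xlim = range(1, k, r), ylim = c(0, k + 2),
                 axes = FALSE, xlab = "average rank", ylab = "", main = main)
  graphics::axis(1, at = pretty(c(1, k)))
  graphics::segments(min(r), k + 1.2, min(r) + cd, k + 1.2, lwd = 3)
  graphics::text(min(r) + cd / 2, k + 1.7, sprintf("CD = %.2f", cd))
  for (i in seq_len(k)) {
    graphics::points(r[i], k + 1 - i, pch = 19)
    graphics::text(r[i], k + 1 - i, names(r)[i], pos = 4, cex = 0.9)
  }
  # bars joining algorithms within one CD
  level <- 0.4
  i <- 1
  while (i <= k) {
    j <- max(which(r - r[i] < cd))
    if (j > i) {
      graphics::segments(r[i], level, r[j], level, lwd = 3)
      level <- level + 0.3
    }
    i <- i + 1
  }
  invisible(NULL)
}
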