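# Classical tests used downstream: Fisher's exact (2x2), Pearson chi-square
# (2x2), Mann-Whitney U. Thin tidy wrappers so results slot into pipelines.

.as_2x2 <- function(table) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
    m <- table
  } else if (is.numeric(table) && length(table) == 4) {
    # row-major: a b / c d
    m <- matrix(table, nrow = 2, byrow = TRUE)
  } else {
    stop("supply a 2x2 matrix or a length-4 vector (a, b, c, d)", call. = FALSE)
  }
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers", call. = FALSE)
  if (sum(m) == 0) stop("empty table", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value: the sum of hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed one.
#' A table with a zero margin carries no information and returns p = 1.
#'
#' @param table 2x2 matrix or length-4 vector `c(a, b, c, d)` in row-major
#'   order.
#' @return One-row tibble: `p_value`, `odds_ratio` (conditional MLE), `method`.
#' @examples
#' fisher_exact(c(308, 132, 129, 83))
#' @export
fisher_exact <- function(table) {
  m <- .as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble(p_value = 1, odds_ratio = NA_real_, method = "fisher_exact"))
  }
  ht <- stats::fisher.test(m, alternative = "two.sided")
  tibble(p_value = ht$p.value, odds_ratio = unname(ht$estimate),
         method = "fisher_exact")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson statistic sum((O-E)^2/E) on 1 df, without Yates continuity
#' correction by default (set `correct = TRUE` for the corrected version).
#'
#' @inheritParams fisher_exact
#' @param correct apply Yates continuity correction.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  m <- .as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin: expected counts are not all positive", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, method = "chi_square_2x2")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. Uses exact enumeration
#' when `n1 * n2 <= exact_max` and the pooled data are tie-free, otherwise
#' the normal approximation with tie correction (and continuity correction).
#' `U` is the number of (x, y) pairs with x > y (+ half the ties), i.e. the
#' W statistic of [stats::wilcox.test()] with x first.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max exact enumeration cutoff on `n1 * n2`.
#' @return One-row tibble: `u`, `p_value`, `n1`, `n2`, `exact`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 400) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) * length(y) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)
  )
  tibble(u = unname(ht$statistic), p_value = ht$p.value,
         n1 = length(x), n2 = length(y), exact = use_exact,
         method = "mann_whitney_u")
}
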