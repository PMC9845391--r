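# Shared two-group and correlation machinery: the Mann-Whitney engine with a
# tie-safe exact branch, the Shapiro normality gate, and gated test selection
# used by both the NMD and phenotype modules.

#' Two-sided Mann-Whitney U test
#'
#' Exact when both groups have at most 20 observations: via the exact
#' rank-sum distribution when there are no ties, or by full enumeration of
#' group assignments (two-sided permutation p-value on the rank-sum
#' deviation, midranks for ties) when there are. Larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (nonempty, no NAs).
#' @param exact_max largest per-group size for the exact branch; default 20.
#' @return list `statistic` (U for group `a`), `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 20L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L, !anyNA(a), !anyNA(b))
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  w <- sum(ranks[seq_len(n1)])                  # rank sum of group a
  u <- w - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  small <- n1 <= exact_max && n2 <= exact_max
  if (small && !ties) {
    p <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    method <- "exact"
  } else if (small && choose(n1 + n2, n1) <= 2e5) {
    # enumerate all assignments of the pooled ranks to group a
    combos <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(ranks[combos], nrow = n1))
    center <- n1 * (n1 + n2 + 1) / 2
    p <- mean(abs(sums - center) >= abs(w - center) - 1e-9)
    method <- "exact (permutation, ties)"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  list(statistic = u, p_value = min(p, 1), method = paste("Mann-Whitney U,", method))
}

#' Shapiro-Wilk normality gate
#'
#' @param x numeric vector.
#' @param alpha gate level; default 0.05.
#' @return `TRUE` when normality is not rejected (Shapiro-Wilk p > alpha).
#'   Vectors too short for the test (n < 3) or constant vectors fail the
#'   gate, routing callers to the nonparametric branch.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) return(FALSE)
  if (stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

#' Normality-gated correlation
#'
#' Pearson's correlation when both vectors pass the Shapiro-Wilk gate,
#' Spearman's rank correlation otherwise; the result records which branch
#' ran. Pairs with a missing value are dropped first.
#'
#' @param x,y numeric vectors of equal length.
#' @param alpha_gate Shapiro-Wilk gate level; default 0.05.
#' @return list `method` ("pearson" or "spearman"), `estimate`, `p_value`,
#'   `n`.
#' @export
gated_correlation <- function(x, y, alpha_gate = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  method <- if (normality_gate(x, alpha_gate) && normality_gate(y, alpha_gate)) {
    "pearson"
  } else {
    "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(method = method, estimate = unname(ct$estimate),
       p_value = ct$p.value, n = n)
}

#' Normality-gated two-group comparison of a continuous variable
#'
#' The two-sample t-test when both groups pass the Shapiro-Wilk gate,
#' otherwise the Mann-Whitney U test ([mann_whitney()]). Summaries are
#' medians with interquartile ranges (linear-interpolation quantiles),
#' regardless of which test ran.
#'
#' @param a,b numeric vectors; NAs dropped.
#' @param alpha_gate Shapiro-Wilk gate level; default 0.05.
#' @param welch use the Welch unequal-variance t-test instead of the classic
#'   equal-variance test; default `FALSE`.
#' @return list `n` (c(a, b) non-missing sizes), `median`, `q1`, `q3` (each
#'   length 2), `method`, `p_value` (`NA` with method "insufficient data"
#'   when either group has fewer than 2 values).
#' @export
compare_continuous <- function(a, b, alpha_gate = 0.05, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  summ <- list(n = c(length(a), length(b)),
               median = c(if (length(a)) qs(a)[2L] else NA_real_,
                          if (length(b)) qs(b)[2L] else NA_real_),
               q1 = c(if (length(a)) qs(a)[1L] else NA_real_,
                      if (length(b)) qs(b)[1L] else NA_real_),
               q3 = c(if (length(a)) qs(a)[3L] else NA_real_,
                      if (length(b)) qs(b)[3L] else NA_real_))
  if (length(a) < 2L || length(b) < 2L) {
    return(c(summ, list(method = "insufficient data", p_value = NA_real_)))
  }
  if (normality_gate(a, alpha_gate) && normality_gate(b, alpha_gate)) {
    tt <- stats::t.test(a, b, var.equal = !welch)
    c(summ, list(method = if (welch) "Welch t-test" else "t-test",
                 p_value = tt$p.value))
  } else {
    mw <- mann_whitney(a, b)
    c(summ, list(method = mw$method, p_value = mw$p_value))
  }
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided by the minimum-likelihood convention: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one ([stats::fisher.test()]).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list `p_value`, `odds_ratio` (conditional MLE).
#' @export
compare_categorical <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("empty margin: a row or column of the 2x2 table is all zero")
  }
  ft <- stats::fisher.test(table, alternative = "two.sided")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}
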