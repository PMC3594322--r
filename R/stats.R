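test_result <- function(statistic, p_value, method, exact, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = statistic, p_value = min(p_value, 1),
                 method = method, exact = exact, ...),
            class = "cer_test_result")
}

#' @export
print.cer_test_result <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g, p-value = %.6g%s\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for independence in a 2x2 contingency table
#' (rows = constructs, columns = positive calls vs the rest): with all
#' margins fixed, the table count follows a hypergeometric distribution, and
#' the two-sided p sums the probabilities of every admissible table whose
#' probability does not exceed that of the observed table (equality judged
#' with relative tolerance 1e-12). When a margin is empty only one table is
#' admissible and p = 1, with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A test result with `statistic` (the [1,1] count), `p_value`,
#'   `method`, `exact = TRUE`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) ||
      any(table != round(table)) || any(!is.finite(table))) {
    stop("table must be a 2x2 matrix of non-negative integer counts")
  }
  if (sum(table) < 1) stop("table total must be >= 1")
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); c2 <- sum(table[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("empty margin: only one admissible table; p = 1")
    return(test_result(a, 1, "Fisher's exact test (two-sided)", TRUE,
                       table = table))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  test_result(a, p, "Fisher's exact test (two-sided)", TRUE, table = table)
}

# Exact distribution of the (doubled) rank sum over all C(N, n) subsets of
# size n, by the shift algorithm: dynamic programme over (subset size,
# subset sum) counting subsets of the doubled mid-rank multiset. Doubling
# makes tied mid-ranks (x.5) integral so sums index an array exactly.
rank_sum_counts <- function(dr, n) {
  S <- sum(dr)
  counts <- matrix(0, nrow = n + 1L, ncol = S + 1L)  # [k+1, s+1]
  counts[1L, 1L] <- 1
  for (j in seq_along(dr)) {
    v <- dr[j]
    kmax <- min(j, n)
    for (k in kmax:1) {
      src <- counts[k, 1:(S + 1L - v)]
      counts[k + 1L, (v + 1L):(S + 1L)] <-
        counts[k + 1L, (v + 1L):(S + 1L)] + src
    }
  }
  counts[n + 1L, ]  # index s+1 holds the number of subsets with sum s
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Exact permutation distribution of the rank sum of `x` within the pooled
#' sample, computed over all `choose(n + m, n)` group assignments with a
#' shift-algorithm dynamic programme (no normal approximation at any sample
#' size). Ties receive mid-ranks, and the permutation distribution is
#' computed over the observed tied configuration. The two-sided p-value
#' doubles the smaller tail (each tail including the observed value), capped
#' at 1.
#'
#' @param x,y Numeric samples (length >= 1 each).
#' @return A test result with `statistic` (rank sum of `x`), `p_value`,
#'   `exact = TRUE`.
#' @export
wilcoxon_exact <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))  # mid-ranks for ties
  W <- sum(r[seq_len(n)])
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across both samples; p = 1")
    return(test_result(W, 1, "Wilcoxon exact rank-sum test (two-sided)", TRUE))
  }
  dr <- as.integer(round(2 * r))
  counts <- rank_sum_counts(dr, n)
  total <- choose(N, n)
  sums <- seq_along(counts) - 1L
  W2 <- as.integer(round(2 * W))
  p_le <- sum(counts[sums <= W2]) / total
  p_ge <- sum(counts[sums >= W2]) / total
  p <- min(1, 2 * min(p_le, p_ge))
  test_result(W, p, "Wilcoxon exact rank-sum test (two-sided)", TRUE,
              n_x = n, n_y = m)
}

#' Anderson-Darling test of normality
#'
#' Case-3 Anderson-Darling test (mean and variance estimated from the
#' sample): computes
#' \deqn{A^2 = -n - \frac{1}{n}\sum_i (2i-1)[\ln \Phi(z_{(i)}) + \ln(1 - \Phi(z_{(n+1-i)}))]}
#' with the small-sample adjustment
#' \eqn{A^{2*} = A^2 (1 + 0.75/n + 2.25/n^2)}. The null of normality is
#' rejected at alpha = 0.05 when \eqn{A^{2*} > 0.752}; the p-value uses the
#' standard piecewise-exponential approximation for the adjusted statistic.
#'
#' @param x Numeric sample, n >= 8, non-degenerate.
#' @return A test result with `statistic` (the adjusted \eqn{A^{2*}}),
#'   `p_value`, `reject_normal` (decision at alpha = 0.05), `exact = FALSE`.
#' @export
anderson_darling_normal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n < 8L) stop("Anderson-Darling normality test requires n >= 8")
  if (sd(x) == 0) stop("zero variance: constant sample")
  z <- sort((x - mean(x)) / sd(x))
  logF <- pnorm(z, log.p = TRUE)
  logS <- pnorm(-z, log.p = TRUE)  # log(1 - Phi(z)) computed stably
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (logF + rev(logS)))
  A <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (A < 0.2) {
    1 - exp(-13.436 + 101.14 * A - 223.73 * A^2)
  } else if (A < 0.34) {
    1 - exp(-8.318 + 42.796 * A - 59.938 * A^2)
  } else if (A < 0.6) {
    exp(0.9177 - 4.279 * A - 1.38 * A^2)
  } else {
    exp(1.2937 - 5.709 * A + 0.0186 * A^2)
  }
  p <- min(max(p, 0), 1)
  test_result(A, p, "Anderson-Darling normality test (adjusted)", FALSE,
              A2 = A2, n = n, reject_normal = A > 0.752)
}
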