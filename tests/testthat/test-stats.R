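test_that("Fisher's exact test matches enumeration on reference tables", {
  # perfectly balanced table carries no evidence
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1.0)
  # diagonal and near-diagonal tables against the brute-force oracle
  for (tab in list(c(10, 0, 0, 10), c(3, 1, 1, 3), c(7, 2, 1, 9),
                   c(0, 5, 5, 0), c(2, 8, 6, 4))) {
    m <- matrix(tab, 2, byrow = TRUE)
    expect_equal(fisher_exact(m)$p_value,
                 oracle_fisher(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-12)
  }
  expect_warning(res <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "empty margin")
  expect_equal(res$p_value, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Fisher p is invariant under row and column swaps", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rpois(4, 6), 2)
    if (sum(m) == 0) next
    p <- fisher_exact(m)$p_value
    expect_equal(suppressWarnings(fisher_exact(m[2:1, ]))$p_value, p,
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(fisher_exact(m[, 2:1]))$p_value, p,
                 tolerance = 1e-12)
  }
})

test_that("Fisher agrees with the stats package cross-check", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(fisher_exact(m)$p_value, stats::fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Wilcoxon exact p-values match full enumeration", {
  # 2 vs 2, fully separated: 2 tables of 6 are as extreme
  expect_equal(wilcoxon_exact(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  # identical multisets are perfectly symmetric
  expect_equal(wilcoxon_exact(c(1, 5, 9), c(9, 1, 5))$p_value, 1)
  set.seed(19)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8, 0.8)
    expect_equal(wilcoxon_exact(x, y)$p_value, oracle_wilcoxon(x, y),
                 tolerance = 1e-12)
  }
  # unequal sizes
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(9)
    expect_equal(wilcoxon_exact(x, y)$p_value, oracle_wilcoxon(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles ties by mid-ranks over the observed pattern", {
  for (case in list(list(x = c(1, 2, 2), y = c(2, 3, 4)),
                    list(x = c(5, 5, 7, 8), y = c(5, 6, 7)),
                    list(x = c(0, 0, 1), y = c(0, 1, 1, 2)))) {
    expect_equal(wilcoxon_exact(case$x, case$y)$p_value,
                 oracle_wilcoxon(case$x, case$y), tolerance = 1e-12)
  }
  expect_warning(res <- wilcoxon_exact(c(3, 3, 3), c(3, 3)), "tied")
  expect_equal(res$p_value, 1)
})

test_that("Wilcoxon p is invariant under monotone transforms of the data", {
  set.seed(23)
  x <- rlnorm(7); y <- rlnorm(9, 0.5)
  p <- wilcoxon_exact(x, y)$p_value
  for (f in list(log, sqrt, function(v) 3 * v - 100, function(v) v^3)) {
    expect_equal(wilcoxon_exact(f(x), f(y))$p_value, p, tolerance = 1e-12)
  }
})

test_that("Wilcoxon agrees with the stats package exact cross-check", {
  set.seed(29)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(7, 0.5)
    expect_equal(wilcoxon_exact(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Anderson-Darling statistic matches the nortest cross-check", {
  skip_if_not_installed("nortest")
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(40 + 10 * i, 5, 2)
    ours <- anderson_darling_normal(x)
    ref <- nortest::ad.test(x)
    expect_equal(ours$statistic, unname(ref$statistic) *
                   (1 + 0.75 / length(x) + 2.25 / length(x)^2),
                 tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("Anderson-Darling screens normal vs skewed samples", {
  set.seed(37)
  # type-I error near the nominal 5% on normal data
  rej <- mean(vapply(1:200, function(i) {
    anderson_darling_normal(rnorm(200))$reject_normal
  }, logical(1)))
  expect_gt(rej, 0.05 - 2.576 * sqrt(0.05 * 0.95 / 200))
  expect_lt(rej, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 200))
  # strong power against exponential data
  power <- mean(vapply(1:100, function(i) {
    anderson_darling_normal(rexp(50))$reject_normal
  }, logical(1)))
  expect_gte(power, 0.95)
  expect_error(anderson_darling_normal(rep(2, 20)), "zero variance")
  expect_error(anderson_darling_normal(rnorm(5)), "n >= 8")
})

test_that("exact tests match brute force for all small configurations", {
  # Fisher: every 2x2 table with total <= 9 (the full sweep to 16 runs in
  # the acceptance suite)
  for (N in 1:9) {
    for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b)) {
      d <- N - a - b - c
      m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
      expect_equal(suppressWarnings(fisher_exact(m))$p_value,
                   oracle_fisher(a, b, c, d), tolerance = 1e-12)
    }
  }
  # rank-sum: every untied configuration with n + m <= 10
  for (n in 1:5) for (m in n:(10 - n)) {
    N <- n + m
    oracle <- oracle_wilcoxon_table(n, m)
    Ws <- sort(unique(colSums(matrix((1:N)[utils::combn(N, n)], nrow = n))))
    for (k in seq_along(Ws)) {
      x <- seq_len(N)[seq_len(n)]  # any sample with rank sum Ws[k]
      # construct a sample achieving rank sum Ws[k]: use combn indexing
      idx <- utils::combn(N, n)
      hit <- which(colSums(matrix((1:N)[idx], nrow = n)) == Ws[k])[1]
      x <- idx[, hit]
      y <- setdiff(seq_len(N), x)
      expect_equal(wilcoxon_exact(x, y)$p_value, oracle[k],
                   tolerance = 1e-12)
    }
  }
})
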