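# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops, full enumeration, closed forms.

# Mean over a mask by an explicit per-pixel loop.
oracle_mask_mean <- function(image, mask) {
  total <- 0; n <- 0
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (mask[i, j]) { total <- total + image[i, j]; n <- n + 1 }
    }
  }
  total / n
}

# CER by per-pixel sums over masks of a noise-free image.
oracle_cer <- function(image, chrom_mask, cell_mask, bg) {
  (oracle_mask_mean(image, chrom_mask) - bg) /
    (oracle_mask_mean(image, cell_mask) - bg)
}

# Two-sided Fisher p by exhaustive enumeration of tables with fixed margins,
# probabilities from log-binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (N - c1) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(N, c1)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# Two-sided exact rank-sum p by enumerating every subset of size n of the
# pooled mid-ranks (doubled smaller tail, capped at 1).
oracle_wilcoxon <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  idx <- utils::combn(N, n)
  sums <- colSums(matrix(r[idx], nrow = n))
  p_le <- mean(sums <= W + 1e-9)
  p_ge <- mean(sums >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# All rank-sum p-values for samples of sizes (n, m) without ties, keyed by
# the integer rank sum W: enumeration over subsets of 1..N.
oracle_wilcoxon_table <- function(n, m) {
  N <- n + m
  idx <- utils::combn(N, n)
  sums <- colSums(matrix((1:N)[idx], nrow = n))
  vapply(sort(unique(sums)), function(W) {
    min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
  }, numeric(1))
}
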