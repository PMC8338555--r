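# Independent oracles, written against definitions (not the package paths
# they check).

# One-sided (greater) Fisher exact p for [[a, n1-a], [b, n2-b]] by direct
# enumeration of the conditional hypergeometric distribution with
# log-binomial coefficients.
oracle_fisher_greater <- function(a, n1, b, n2) {
  K <- a + b
  ks <- max(0L, K - n2):min(n1, K)
  logp <- lchoose(n1, ks) + lchoose(n2, K - ks) - lchoose(n1 + n2, K)
  sum(exp(logp[ks >= a]))
}

# Exact two-sided rank-sum p by enumeration over all group assignments of
# the pooled observations (no ties assumed). Uses the doubled-tail
# convention of the exact Wilcoxon test.
oracle_ranksum_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= w_obs), mean(u_all >= w_obs))
  min(1, p)
}

# Analytic minimum of a two-component Gaussian mixture density between the
# component means, by fine-grid evaluation.
oracle_mixture_trough <- function(w1, m1, s1, w2, m2, s2, n_grid = 100000L) {
  grid <- seq(min(m1, m2), max(m1, m2), length.out = n_grid)
  dens <- w1 * stats::dnorm(grid, m1, s1) + w2 * stats::dnorm(grid, m2, s2)
  grid[which.min(dens)]
}

# Bayes misclassification error of the same mixture: classify "component 2"
# above the optimal boundary.
oracle_mixture_bayes_error <- function(w1, m1, s1, w2, m2, s2) {
  cut <- oracle_mixture_trough(w1, m1, s1, w2, m2, s2)
  w1 * stats::pnorm(cut, m1, s1, lower.tail = FALSE) +
    w2 * stats::pnorm(cut, m2, s2)
}
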