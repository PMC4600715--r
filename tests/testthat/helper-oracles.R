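# Independent oracles used to cross-check the package implementations.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j,
# capped at 1, original order restored. Written as a literal double loop so
# it shares no code path with the implementation under test.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n, n_a) assignments of the observed ranks to group A. No ties
# assumed. U = number of (a, b) pairs with a > b.
wilcoxon_enumeration_oracle <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n_a + n_b, n_a)
  all_ranks <- seq_len(n_a + n_b)
  u_all <- apply(combos, 2, function(idx)
    sum(all_ranks[idx]) - n_a * (n_a + 1) / 2)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_low, p_high)))
}

# Closed-form two-way means estimator for a complete balanced design:
# alpha_p = plate-mean deviation, beta_s = screen-mean deviation. Equals the
# least-squares solution only under balance, which is what the toy fixtures
# guarantee.
balanced_two_way_oracle <- function(y, plate, screen) {
  mu <- mean(y)
  alpha <- tapply(y, plate, mean) - mu
  beta <- tapply(y, screen, mean) - mu
  list(mu = mu, alpha = alpha, beta = beta)
}

# Grid + bisection solver for the variance-prior moment equations, sharing
# no code with estimate_prior(). Solves trigamma(d0/2) = var(z) -
# mean(trigamma(d/2)) by bisection on a bracket found by doubling.
prior_moment_oracle <- function(s2, d) {
  if (length(d) == 1L) d <- rep(d, length(s2))
  z <- log(s2)
  target <- var(z) - mean(trigamma(d / 2))
  if (!is.finite(target) || target <= 0)
    return(list(d0 = Inf, s0sq = exp(mean(z - digamma(d / 2) + log(d / 2)))))
  lo <- 1e-6
  hi <- 1
  while (trigamma(hi / 2) > target) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (trigamma(mid / 2) > target) lo <- mid else hi <- mid
  }
  d0 <- (lo + hi) / 2
  s0sq <- exp(mean(z) - mean(digamma(d / 2)) + digamma(d0 / 2) -
                log(d0) + mean(log(d)))
  list(d0 = d0, s0sq = s0sq)
}
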