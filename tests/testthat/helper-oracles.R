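# Independent oracles, deliberately coded from the textbook definitions
# rather than shared with the implementation.

o_ror <- function(a, b, c, d, z = 1.96) {
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(est = est, lo = exp(log(est) - z * se), hi = exp(log(est) + z * se))
}

o_chi2 <- function(a, b, c, d, yates = TRUE) {
  n <- a + b + c + d
  det <- abs(a * d - b * c)
  if (yates) det <- max(0, det - n / 2)
  n * det^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# closest-rank linear interpolation quantile (the type-7 rule written out)
o_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# exact Mann-Whitney by direct pair counting over all group assignments
o_mwu_exact <- function(x, y) {
  u_pairs <- function(xx, yy) {
    u <- 0
    for (xi in xx) u <- u + sum(xi > yy) + 0.5 * sum(xi == yy)
    u
  }
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  mu <- n1 * n2 / 2
  u_obs <- u_pairs(x, y)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(ix) u_pairs(pooled[ix], pooled[-ix]))
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# posterior density of the relative reporting ratio under a two-gamma
# mixture prior, for quadrature oracles
o_posterior_density <- function(prior) {
  function(l, a, e) {
    lw1 <- log(prior$mix_p) +
      dnbinom(a, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + e),
              log = TRUE)
    lw2 <- log1p(-prior$mix_p) +
      dnbinom(a, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + e),
              log = TRUE)
    w1 <- exp(lw1) / (exp(lw1) + exp(lw2))
    w1 * dgamma(l, prior$alpha1 + a, rate = prior$beta1 + e) +
      (1 - w1) * dgamma(l, prior$alpha2 + a, rate = prior$beta2 + e)
  }
}

# marginal log-likelihood of pair counts under a mixture prior
o_mgps_loglik <- function(pairs, alpha1, beta1, alpha2, beta2, p) {
  l1 <- p * dnbinom(pairs$a, size = alpha1,
                    prob = beta1 / (beta1 + pairs$e))
  l2 <- (1 - p) * dnbinom(pairs$a, size = alpha2,
                          prob = beta2 / (beta2 + pairs$e))
  sum(log(l1 + l2))
}
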