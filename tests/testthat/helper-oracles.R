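# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (linear-space enumeration, stats::lm
# likelihoods, finite differences, band-conditional Dirichlet draws).

# Brute-force mixture log-likelihood: enumerate the three components per
# sample in linear space.
oracle_loglik <- function(probs, y, z, beta0, beta1, gamma, sigma2) {
  mu0 <- beta0 + if (length(gamma)) drop(z %*% gamma) else 0
  comp <- sapply(0:2, function(g)
    probs[, g + 1] * dnorm(y, mu0 + beta1 * g, sqrt(sigma2)))
  sum(log(rowSums(matrix(comp, ncol = 3))))
}

# Gaussian-regression LRT via stats::lm log-likelihoods.
oracle_lm_lrt <- function(x, y, z = NULL) {
  d1 <- if (is.null(z)) data.frame(y = y, x = x)
        else data.frame(y = y, x = x, z)
  f1 <- lm(y ~ ., data = d1)
  f0 <- if (is.null(z)) lm(y ~ 1, data = d1)
        else lm(y ~ . - x, data = d1)
  lrs <- max(0, 2 * (as.numeric(logLik(f1)) - as.numeric(logLik(f0))))
  list(lrs = lrs, pvalue = pchisq(lrs, 1, lower.tail = FALSE))
}

# Expected complete-data log-likelihood for fixed posterior moments
# (the function the M-step is supposed to maximize).
oracle_q_fun <- function(w, y, z, beta0, beta1, gamma, sigma2) {
  mu0 <- beta0 + if (length(gamma)) drop(z %*% gamma) else 0
  q <- 0
  for (g in 0:2) {
    r <- y - mu0 - beta1 * g
    q <- q + sum(w[, g + 1] * (-0.5 * log(2 * pi * sigma2) -
                                 r^2 / (2 * sigma2)))
  }
  q
}

num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Exact independent sampler for f1 | dosage: the conditional kernel is
# p^(a1-1) (s-p)^(gam-1) x g(p) with g bounded and monotone on the
# support, so a scaled stats::rbeta proposal with accept-reject on
# g(p)/max(g) is exact. Shares no code with the package's
# incomplete-Beta grid sampler.
oracle_f1_beta_reject <- function(marker, d, n) {
  a <- marker$alpha
  if (d < 1) {
    s <- d; a1 <- a[2]; gam <- a[3]
    gfun <- function(p) ((2 - d - p) / 2)^(a[1] - 1)
  } else {
    s <- 2 - d; a1 <- a[2]; gam <- a[1]
    gfun <- function(p) ((d - p) / 2)^(a[3] - 1)
  }
  gmax <- max(gfun(0), gfun(s * (1 - 1e-12)))
  out <- numeric(0)
  while (length(out) < n) {
    p <- s * rbeta(2 * n, a1, gam)
    keep <- runif(2 * n) < gfun(p) / gmax
    out <- c(out, p[keep])
  }
  out[seq_len(n)]
}

expect_within_3se <- function(est, truth, se, label = "") {
  expect_lt(abs(est - truth), 3 * se,
            label = paste0(label, " |", signif(est, 5), " - ",
                           signif(truth, 5), "|"))
}
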