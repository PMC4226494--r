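#' @title Baseline association tests
#' @description
#' The standard Dosage regression test (OLS of trait on imputed dosage),
#' the Mixture method (the same observed-data mixture likelihood as the
#' EM, maximized by Nelder-Mead simplex search), and the gold-standard
#' regression on true genotypes (available in simulations only). All are
#' likelihood-ratio tests with 1 df against the covariate-only null, so
#' the methods are directly comparable.
#' @name baselines-module
NULL

# Gaussian-regression LRT of y ~ (1, x, Z) against y ~ (1, Z).
# LRS = N log(RSS0 / RSS1); exact OLS likelihood ratio.
gaussian_lrt <- function(x, cohort, method) {
  cohort <- as_cohort(cohort)
  y <- cohort$y
  n <- length(y)
  if (length(x) != n) stop(method, ": predictor length mismatch")
  if (sd(x) == 0) {
    return(assoc_result(0, 0, method,
                        diagnostics = list(monomorphic = TRUE)))
  }
  null <- lm.fit(cbind(1, cohort$z), y)
  alt <- lm.fit(cbind(1, x, cohort$z), y)
  rss0 <- max(sum(null$residuals^2), 1e-12 * n)
  rss1 <- max(sum(alt$residuals^2), 1e-12 * n)
  assoc_result(n * log(rss0 / rss1), alt$coefficients[2], method,
               diagnostics = list(rss0 = rss0, rss1 = rss1))
}

#' Dosage association test (standard post-imputation method)
#'
#' OLS regression of the trait on imputed dosage (plus covariates) with a
#' 1-df likelihood-ratio test on the dosage coefficient.
#'
#' @param dosages numeric vector in `[0, 2]`.
#' @param cohort a [cohort_data()].
#' @return An `assoc_result` with method tag `"dosage"`.
#' @export
dosage_test <- function(dosages, cohort) {
  gaussian_lrt(dosages, cohort, "dosage")
}

#' Gold-standard test on true genotypes
#'
#' OLS LRT of the trait on the true minor-allele count; only available in
#' simulations where the truth is retained.
#'
#' @param g integer genotype vector in `{0, 1, 2}`.
#' @inheritParams dosage_test
#' @return An `assoc_result` with method tag `"truth"`.
#' @export
truth_test <- function(g, cohort) {
  gaussian_lrt(as.numeric(g), cohort, "truth")
}

#' Optimizer settings for the Mixture method
#'
#' @param max_evals function-evaluation cap for one simplex run.
#' @param reltol relative convergence tolerance passed to [stats::optim()].
#' @param restarts extra simplex runs restarted from the previous optimum
#'   (standard Nelder-Mead practice to polish convergence).
#' @return A list of class `optimizer_settings`.
#' @export
optimizer_settings <- function(max_evals = 2000L, reltol = 1e-12,
                               restarts = 1L) {
  stopifnot(max_evals > 0, reltol > 0, restarts >= 0)
  structure(list(method = "simplex", max_evals = as.integer(max_evals),
                 reltol = reltol, restarts = as.integer(restarts)),
            class = "optimizer_settings")
}

#' Mixture association test (direct likelihood maximization)
#'
#' Maximizes the same observed-data mixture log-likelihood as
#' [em_fit()] by Nelder-Mead simplex search over
#' \eqn{(\beta_0, \beta_1, \gamma, \log\sigma)}, started at the
#' dosage-regression estimates, then forms the 1-df LRT against the null.
#' Serves both as a user-facing method and as an independent oracle for
#' the EM fit.
#'
#' @inheritParams emlrt_prob_test
#' @param opt an [optimizer_settings()].
#' @return An `assoc_result` with method tag `"mixture"`; diagnostics
#'   carry the maximized log-likelihood and optimizer convergence code.
#' @export
mixture_test <- function(probs, cohort, opt = optimizer_settings()) {
  cohort <- as_cohort(cohort)
  if (monomorphic_probs(probs)) {
    return(assoc_result(0, 0, "mixture",
                        diagnostics = list(monomorphic = TRUE)))
  }
  y <- cohort$y; z <- cohort$z
  start <- dosage_start(probs, cohort)
  par <- c(start$beta0, start$beta1, start$gamma,
           0.5 * log(max(start$sigma2, 1e-12)))
  K <- ncol(z)
  negll <- function(p) {
    -obs_loglik_cpp(y, probs, z, p[1], p[2],
                    if (K > 0) p[3:(2 + K)] else numeric(0),
                    exp(2 * p[3 + K]))
  }
  fit <- optim(par, negll, method = "Nelder-Mead",
               control = list(maxit = opt$max_evals, reltol = opt$reltol))
  for (r in seq_len(opt$restarts)) {
    fit <- optim(fit$par, negll, method = "Nelder-Mead",
                 control = list(maxit = opt$max_evals,
                                reltol = opt$reltol))
  }
  null <- fit_null(cohort)
  assoc_result(2 * (-fit$value - null$loglik), fit$par[2], "mixture",
               diagnostics = list(loglik = -fit$value,
                                  convergence = fit$convergence,
                                  null_loglik = null$loglik))
}

# Lean mixture-method p-value for Monte-Carlo drivers (no covariates):
# same likelihood and optimizer as mixture_test, minus S3 packaging and
# with economical simplex settings.
mixture_pvalue <- function(y, probs, max_evals = 500L, reltol = 1e-8,
                           restarts = 0L) {
  n <- length(y)
  d <- probs[, 2L] + 2 * probs[, 3L]
  if (sd(d) == 0) return(1)
  Z <- matrix(numeric(0), n, 0)
  b1 <- cov(d, y) / var(d)
  b0 <- mean(y) - b1 * mean(d)
  s2 <- max(mean((y - b0 - b1 * d)^2), 1e-12)
  negll <- function(p) -obs_loglik_cpp(y, probs, Z, p[1], p[2],
                                       numeric(0), exp(2 * p[3]))
  fit <- optim(c(b0, b1, 0.5 * log(s2)), negll, method = "Nelder-Mead",
               control = list(maxit = max_evals, reltol = reltol))
  for (r in seq_len(restarts))
    fit <- optim(fit$par, negll, method = "Nelder-Mead",
                 control = list(maxit = max_evals, reltol = reltol))
  vy <- max(mean((y - mean(y))^2), 1e-12)
  l0 <- -n / 2 * (log(2 * pi * vy) + 1)
  pchisq(max(0, 2 * (-fit$value - l0)), 1L, lower.tail = FALSE)
}
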