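#' @title EM fitting of the mixture-of-regressions model
#' @description
#' With posterior genotype probabilities \eqn{f_i = (f_{i0}, f_{i1},
#' f_{i2})} and trait \eqn{y_i}, the observed-data likelihood treats the
#' true genotype as latent:
#' \deqn{L(\theta) = \prod_i \sum_{g=0}^{2} f_{ig}\,
#'   \phi(y_i;\ \beta_0 + \beta_1 g + \gamma' z_i,\ \sigma^2).}
#' The EM algorithm alternates posterior genotype moments (E-step) with
#' closed-form weighted-regression updates (M-step); each iteration cannot
#' decrease the observed-data log-likelihood. The likelihood-ratio test of
#' \eqn{\beta_1 = 0} refers \eqn{2(l_1 - l_0)} to \eqn{\chi^2_1}.
#' @name em-module
NULL

#' Phenotype and covariates for one analysis
#'
#' @param y numeric quantitative trait, no missing values.
#' @param z optional covariate matrix (`n` x K) or vector.
#' @return A list of class `cohort_data` with `y` and `z` (always a
#'   matrix, possibly with 0 columns).
#' @export
cohort_data <- function(y, z = NULL) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(is.finite(y))) stop("cohort_data: y must be finite")
  if (is.null(z)) z <- matrix(numeric(0), length(y), 0)
  if (!is.matrix(z)) z <- cbind(z)
  if (nrow(z) != length(y)) stop("cohort_data: y and z lengths differ")
  if (ncol(z) > 0 && (anyNA(z) || !all(is.finite(z))))
    stop("cohort_data: covariates must be finite")
  if (length(y) < ncol(z) + 1) stop("cohort_data: need N >= K + 1")
  structure(list(y = y, z = z), class = "cohort_data")
}

as_cohort <- function(cohort) {
  if (inherits(cohort, "cohort_data")) cohort else cohort_data(cohort$y, cohort$z)
}

#' Regression parameters of the mixture model
#'
#' @param beta0 intercept; @param beta1 per-minor-allele effect;
#' @param gamma covariate effects (length K); @param sigma2 residual
#'   variance (floored at 1e-12).
#' @return A list of class `reg_params`.
#' @export
reg_params <- function(beta0, beta1, gamma = numeric(0), sigma2) {
  structure(list(beta0 = unname(beta0), beta1 = unname(beta1),
                 gamma = as.numeric(gamma),
                 sigma2 = max(unname(sigma2), 1e-12)),
            class = "reg_params")
}

#' Observed-data log-likelihood of the mixture model
#'
#' \eqn{\sum_i \log \sum_g f_{ig} \phi(y_i; \beta_0 + \beta_1 g +
#' \gamma' z_i, \sigma^2)}, computed in log space with per-sample max
#' subtraction.
#'
#' @param probs `n` x 3 posterior probability matrix.
#' @param cohort a [cohort_data()].
#' @param params a [reg_params()].
#' @return Scalar log-likelihood.
#' @export
obs_loglik <- function(probs, cohort, params) {
  cohort <- as_cohort(cohort)
  stopifnot(is.matrix(probs), ncol(probs) == 3L,
            nrow(probs) == length(cohort$y))
  if (!all(is.finite(probs))) stop("obs_loglik: non-finite probabilities")
  obs_loglik_cpp(cohort$y, probs, cohort$z, params$beta0, params$beta1,
                 params$gamma, params$sigma2)
}

#' E-step: posterior genotype moments given current parameters
#'
#' Posterior weights \eqn{w_{ig} \propto f_{ig} \phi(y_i; \beta_0 +
#' \beta_1 g + \gamma' z_i, \sigma^2)} normalized per sample, and the
#' conditional moments \eqn{E[G_i|\cdot] = \sum_g g\, w_{ig}},
#' \eqn{E[G_i^2|\cdot] = \sum_g g^2 w_{ig}}.
#'
#' @inheritParams obs_loglik
#' @return List with `w` (n x 3), `eg`, `eg2`, and `loglik` (the
#'   observed-data log-likelihood at `params`, a by-product).
#' @export
e_step <- function(probs, cohort, params) {
  cohort <- as_cohort(cohort)
  y <- cohort$y
  mu0 <- params$beta0 +
    (if (ncol(cohort$z) > 0) drop(cohort$z %*% params$gamma) else 0)
  s2 <- max(params$sigma2, 1e-12)
  lw <- vapply(0:2, function(g)
    log(probs[, g + 1L]) + dnorm(y, mu0 + params$beta1 * g, sqrt(s2),
                                 log = TRUE),
    numeric(length(y)))
  lw <- matrix(lw, ncol = 3L)
  m <- pmax(lw[, 1L], lw[, 2L], lw[, 3L])  # per-sample max; never -Inf/Inf mix
  w <- exp(lw - m)
  w[is.na(w)] <- 0  # f = 0 components: log(0) - (-Inf) guards
  s <- rowSums(w)
  w <- w / s
  list(w = w, eg = w[, 2L] + 2 * w[, 3L], eg2 = w[, 2L] + 4 * w[, 3L],
       loglik = sum(m + log(s)))
}

#' M-step: maximize the expected complete-data log-likelihood
#'
#' Solves the expected-complete-data normal equations for
#' \eqn{(\beta_0, \beta_1, \gamma)}, substituting \eqn{E[G_i]} in the
#' design and \eqn{E[G_i^2]} in the Gram matrix, then updates
#' \deqn{\sigma^2 = \frac{1}{N}\sum_i\left[(y_i - \beta_0 - \beta_1 E[G_i]
#'  - \gamma' z_i)^2 + \beta_1^2 (E[G_i^2] - E[G_i]^2)\right].}
#'
#' @inheritParams obs_loglik
#' @param moments an [e_step()] result (fields `eg`, `eg2`).
#' @return A [reg_params()]; attribute `degenerate` set `TRUE` when the
#'   Gram matrix is singular (e.g. `eg` constant).
#' @export
m_step <- function(probs, cohort, moments) {
  cohort <- as_cohort(cohort)
  y <- cohort$y; z <- cohort$z
  n <- length(y); K <- ncol(z)
  eg <- moments$eg; eg2 <- moments$eg2
  A <- matrix(0, 2 + K, 2 + K)
  A[1, 1] <- n
  A[1, 2] <- A[2, 1] <- sum(eg)
  A[2, 2] <- sum(eg2)
  b <- c(sum(y), sum(y * eg))
  if (K > 0) {
    A[1, 3:(2 + K)] <- A[3:(2 + K), 1] <- colSums(z)
    A[2, 3:(2 + K)] <- A[3:(2 + K), 2] <- drop(crossprod(z, eg))
    A[3:(2 + K), 3:(2 + K)] <- crossprod(z)
    b <- c(b, drop(crossprod(z, y)))
  }
  coef <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(coef)) {
    out <- reg_params(mean(y), 0, rep(0, K), var(y) * (n - 1) / n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  beta0 <- coef[1]; beta1 <- coef[2]; gamma <- coef[-(1:2)]
  resid <- y - beta0 - beta1 * eg - (if (K > 0) drop(z %*% gamma) else 0)
  s2 <- mean(resid^2 + beta1^2 * (eg2 - eg^2))
  out <- reg_params(beta0, beta1, gamma, s2)
  attr(out, "degenerate") <- FALSE
  out
}

#' Fit the mixture model by EM
#'
#' Alternates [e_step()] and [m_step()] until the absolute change in
#' observed-data log-likelihood falls below `tol` or `max_iter` is
#' reached. The default start is the dosage-regression (OLS of `y` on
#' `(1, D, Z)`) estimate, which the EM then refines.
#'
#' @inheritParams obs_loglik
#' @param start optional [reg_params()] starting value.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param engine `"C"` (compiled, default) or `"R"` (reference
#'   implementation built from [e_step()]/[m_step()]); both produce the
#'   same fit to numerical precision.
#' @param keep_trace record the per-iteration log-likelihood trace.
#' @return A list of class `em_fit` with `params`, `loglik`, `n_iter`,
#'   `converged`, `degenerate` and optionally `trace` (non-decreasing).
#' @export
em_fit <- function(probs, cohort, start = NULL, tol = 1e-6,
                   max_iter = 1000L, engine = c("C", "R"),
                   keep_trace = FALSE) {
  engine <- match.arg(engine)
  cohort <- as_cohort(cohort)
  stopifnot(tol > 0, is.matrix(probs), nrow(probs) == length(cohort$y))
  if (is.null(start)) start <- dosage_start(probs, cohort)
  if (engine == "C") {
    fit <- em_fit_cpp(cohort$y, probs, cohort$z,
                      c(start$beta0, start$beta1, start$gamma),
                      start$sigma2, tol, as.integer(max_iter), keep_trace)
    out <- list(params = reg_params(fit$beta0, fit$beta1, fit$gamma,
                                    fit$sigma2),
                loglik = fit$loglik, n_iter = fit$n_iter,
                converged = fit$converged, degenerate = fit$degenerate)
    if (keep_trace) out$trace <- fit$trace
  } else {
    params <- start
    prev <- -Inf; ll <- -Inf
    trace <- numeric(0)
    converged <- FALSE; degenerate <- FALSE
    it <- 0L
    for (it in seq_len(max_iter)) {
      es <- e_step(probs, cohort, params)
      ll <- es$loglik
      if (keep_trace) trace <- c(trace, ll)
      if (it > 1L && abs(ll - prev) < tol) { converged <- TRUE; break }
      prev <- ll
      params <- m_step(probs, cohort, es)
      if (isTRUE(attr(params, "degenerate"))) { degenerate <- TRUE; break }
    }
    out <- list(params = params, loglik = ll, n_iter = it,
                converged = converged, degenerate = degenerate)
    if (keep_trace) out$trace <- trace
  }
  class(out) <- "em_fit"
  out
}

# Dosage-regression (naive) estimates: the suggested EM starting values.
dosage_start <- function(probs, cohort) {
  d <- dosage_from_probs(probs)
  ols_params(d, cohort)
}

# OLS of y on (1, x, Z) with MLE sigma^2 = RSS / N.
ols_params <- function(x, cohort) {
  y <- cohort$y
  X <- cbind(1, x, cohort$z)
  fit <- lm.fit(X, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  reg_params(coefs[1], coefs[2], coefs[-(1:2)], mean(fit$residuals^2))
}

#' Null-model fit (no genetic effect)
#'
#' Closed-form Gaussian ML fit of `y` on `(1, Z)`:
#' \eqn{\hat\sigma^2 = RSS/N} and
#' \eqn{l_0 = -\frac{N}{2}(\log(2\pi\hat\sigma^2) + 1)}. This equals the
#' mixture log-likelihood at \eqn{\beta_1 = 0} for any probability matrix.
#'
#' @param cohort a [cohort_data()].
#' @return An `em_fit`-shaped list (`params`, `loglik`, `converged = TRUE`).
#' @export
fit_null <- function(cohort) {
  cohort <- as_cohort(cohort)
  y <- cohort$y; z <- cohort$z
  n <- length(y)
  X <- cbind(1, z)
  fit <- lm.fit(X, y)
  if (ncol(z) > 0 && any(is.na(fit$coefficients)))
    stop("fit_null: collinear covariates")
  s2 <- max(mean(fit$residuals^2), 1e-12)
  params <- reg_params(fit$coefficients[1], 0,
                       if (ncol(z) > 0) fit$coefficients[-1] else numeric(0),
                       s2)
  structure(list(params = params,
                 loglik = -n / 2 * (log(2 * pi * s2) + 1),
                 n_iter = 0L, converged = TRUE, degenerate = FALSE),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat("Mixture-of-regressions EM fit\n")
  cat(sprintf("  beta0 = %.6g, beta1 = %.6g, sigma2 = %.6g\n",
              x$params$beta0, x$params$beta1, x$params$sigma2))
  if (length(x$params$gamma))
    cat("  gamma =", paste(signif(x$params$gamma, 6), collapse = ", "), "\n")
  cat(sprintf("  loglik = %.6f after %d iterations (%s)\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Shared association-result constructor.
assoc_result <- function(lrs, beta1_hat, method, df = 1L,
                         diagnostics = list()) {
  lrs <- max(0, lrs)
  structure(list(lrs = lrs, df = df,
                 pvalue = pchisq(lrs, df, lower.tail = FALSE),
                 beta1_hat = beta1_hat, method = method,
                 diagnostics = diagnostics),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s association test: LRS = %.4f (df = %d), p = %.4g, beta1 = %.4g\n",
              x$method, x$lrs, x$df, x$pvalue, x$beta1_hat))
  invisible(x)
}

#' EM-LRT on posterior genotype probabilities (scenario I)
#'
#' Fits the mixture model by EM ([em_fit()]), fits the covariate-only null
#' ([fit_null()]), and refers \eqn{LRS = \max(0, 2(l_1 - l_0))} to
#' \eqn{\chi^2_1}.
#'
#' @inheritParams em_fit
#' @param settings optional list overriding `tol`, `max_iter`, `engine`.
#' @return An `assoc_result` with method tag `"emlrt_prob"`.
#' @examples
#' sim <- simulate_marker_data(sim_config(n = 500, q = 0.2, rsq = 0.5,
#'                                        beta1 = 0.4, seed = 11))
#' emlrt_prob_test(sim$probs, cohort_data(sim$y))
#' @export
emlrt_prob_test <- function(probs, cohort, settings = list()) {
  cohort <- as_cohort(cohort)
  s <- modifyList(list(tol = 1e-6, max_iter = 1000L, engine = "C"), settings)
  if (monomorphic_probs(probs)) {
    return(assoc_result(0, 0, "emlrt_prob",
                        diagnostics = list(monomorphic = TRUE)))
  }
  null <- fit_null(cohort)
  fit <- em_fit(probs, cohort, tol = s$tol, max_iter = s$max_iter,
                engine = s$engine)
  assoc_result(2 * (fit$loglik - null$loglik), fit$params$beta1,
               "emlrt_prob",
               diagnostics = list(n_iter = fit$n_iter,
                                  converged = fit$converged,
                                  loglik = fit$loglik,
                                  null_loglik = null$loglik))
}

monomorphic_probs <- function(probs) {
  any(vapply(1:3, function(j) all(probs[, j] >= 1 - 1e-12), logical(1)))
}
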