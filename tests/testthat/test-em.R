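# EM machinery: observed-data likelihood, E/M steps against independent
# oracles, ascent property, engine agreement, and the LRT reductions.

make_instance <- function(n = 50, K = 0, q = 0.2, rsq = 0.4, beta1 = 0.5,
                          seed = 1) {
  set.seed(seed)
  F <- sample_probs(make_marker(q, rsq), n)
  g <- sample_genotypes(F)
  z <- if (K > 0) matrix(rnorm(n * K), n, K) else NULL
  y <- beta1 * g + (if (K > 0) drop(z %*% rep(0.5, K)) else 0) + rnorm(n)
  list(F = F, g = g, cohort = cohort_data(y, z))
}

test_that("obs_loglik matches a brute-force linear-space oracle", {
  inst <- make_instance(n = 6, K = 1, seed = 3)
  p <- reg_params(0.3, -0.2, 0.7, 1.3)
  expect_equal(obs_loglik(inst$F, inst$cohort, p),
               oracle_loglik(inst$F, inst$cohort$y, inst$cohort$z,
                             0.3, -0.2, 0.7, 1.3),
               tolerance = 1e-10)
})

test_that("obs_loglik collapses when the genetic effect is zero", {
  inst <- make_instance(n = 40, K = 1, seed = 4)
  null <- fit_null(inst$cohort)
  p0 <- null$params
  # independent of the probability matrix
  expect_equal(obs_loglik(inst$F, inst$cohort, p0), null$loglik,
               tolerance = 1e-10)
  F2 <- sample_probs(make_marker(0.4, 0.9), 40, seed = 99)
  expect_equal(obs_loglik(F2, inst$cohort, p0), null$loglik,
               tolerance = 1e-10)
})

test_that("obs_loglik with degenerate probs equals the fixed-G likelihood", {
  inst <- make_instance(n = 30, seed = 5)
  Fd <- matrix(0, 30, 3)
  Fd[cbind(1:30, inst$g + 1)] <- 1
  p <- reg_params(0.1, 0.4, numeric(0), 0.9)
  expect_equal(obs_loglik(Fd, inst$cohort, p),
               sum(dnorm(inst$cohort$y, 0.1 + 0.4 * inst$g, sqrt(0.9),
                         log = TRUE)),
               tolerance = 1e-10)
})

test_that("e_step produces the posterior moments of the latent genotype", {
  co <- cohort_data(2)
  es <- e_step(matrix(c(0.25, 0.5, 0.25), 1), co,
               reg_params(0, 1, numeric(0), 1))
  w_raw <- c(0.25 * dnorm(2, 0, 1), 0.5 * dnorm(2, 1, 1),
             0.25 * dnorm(2, 2, 1))
  w <- w_raw / sum(w_raw)
  expect_equal(drop(es$w), w, tolerance = 1e-12)
  expect_equal(es$eg, sum(0:2 * w), tolerance = 1e-12)
  expect_equal(es$eg2, sum((0:2)^2 * w), tolerance = 1e-12)

  # degenerate prior pins the posterior
  es2 <- e_step(matrix(c(0, 1, 0), 1), co, reg_params(0, 1, numeric(0), 1))
  expect_equal(drop(es2$w), c(0, 1, 0))
  expect_equal(es2$eg, 1)
  expect_equal(es2$eg2, 1)

  # beta1 = 0: weights equal the prior, E[G] equals the dosage
  inst <- make_instance(n = 25, seed = 6)
  es3 <- e_step(inst$F, inst$cohort, reg_params(0.2, 0, numeric(0), 1))
  expect_equal(es3$w, inst$F, tolerance = 1e-12)
  expect_equal(es3$eg, dosage_from_probs(inst$F), tolerance = 1e-12)
})

test_that("e_step weights survive extreme standardized residuals", {
  co <- cohort_data(300)  # |residual| up to 300 standard deviations
  es <- e_step(matrix(c(0.3, 0.4, 0.3), 1), co,
               reg_params(0, 1, numeric(0), 1))
  expect_equal(sum(es$w), 1, tolerance = 1e-12)
  expect_equal(drop(es$w), c(0, 0, 1), tolerance = 1e-10)
})

test_that("m_step solves the expected-complete-data normal equations", {
  # no uncertainty: reduces to OLS on E[G]
  inst <- make_instance(n = 20, K = 1, seed = 7)
  eg <- dosage_from_probs(inst$F)
  mom <- list(eg = eg, eg2 = eg^2)
  p <- m_step(inst$F, inst$cohort, mom)
  fit <- lm(inst$cohort$y ~ eg + inst$cohort$z)
  expect_equal(p$beta0, unname(coef(fit)[1]), tolerance = 1e-9)
  expect_equal(p$beta1, unname(coef(fit)[2]), tolerance = 1e-9)
  expect_equal(p$sigma2, mean(residuals(fit)^2), tolerance = 1e-9)

  # perfect fit floors sigma2
  co <- cohort_data(c(0, 1, 1, 2))
  mom2 <- list(eg = c(0, 1, 1, 2), eg2 = c(0, 1, 1, 4))
  p2 <- m_step(matrix(1 / 3, 4, 3), co, mom2)
  expect_equal(p2$beta0, 0, tolerance = 1e-9)
  expect_equal(p2$beta1, 1, tolerance = 1e-9)
  expect_equal(p2$sigma2, 1e-12)

  # stationarity: numerical gradient of the Q-function vanishes
  inst3 <- make_instance(n = 8, seed = 8)
  es <- e_step(inst3$F, inst3$cohort, reg_params(0.1, 0.3, numeric(0), 1))
  p3 <- m_step(inst3$F, inst3$cohort, es)
  gr <- num_grad(function(th)
    oracle_q_fun(es$w, inst3$cohort$y, inst3$cohort$z, th[1], th[2],
                 numeric(0), exp(th[3])),
    c(p3$beta0, p3$beta1, log(p3$sigma2)))
  expect_lt(max(abs(gr)), 1e-5)
})

test_that("m_step flags a singular Gram matrix", {
  co <- cohort_data(rnorm(10))
  mom <- list(eg = rep(1, 10), eg2 = rep(1, 10))  # E[G] constant
  p <- m_step(matrix(1 / 3, 10, 3), co, mom)
  expect_true(attr(p, "degenerate"))
})

test_that("EM ascends and both engines agree", {
  for (s in 1:5) {
    inst <- make_instance(n = 120, K = (s %% 2), q = 0.15, rsq = 0.3,
                          seed = 20 + s)
    fr <- em_fit(inst$F, inst$cohort, engine = "R", keep_trace = TRUE)
    fc <- em_fit(inst$F, inst$cohort, engine = "C", keep_trace = TRUE)
    expect_true(all(diff(fr$trace) >= -1e-10), label = "R trace ascent")
    expect_true(all(diff(fc$trace) >= -1e-10), label = "C trace ascent")
    expect_equal(fr$loglik, fc$loglik, tolerance = 1e-8)
    expect_equal(fr$params$beta1, fc$params$beta1, tolerance = 1e-5)
    expect_true(fr$converged && fc$converged)
  }
})

test_that("EM with vertex probabilities reaches the OLS fit immediately", {
  inst <- make_instance(n = 60, seed = 30)
  Fd <- matrix(0, 60, 3)
  Fd[cbind(1:60, inst$g + 1)] <- 1
  fit <- em_fit(Fd, inst$cohort)
  expect_lte(fit$n_iter, 2)
  ols <- lm(inst$cohort$y ~ inst$g)
  expect_equal(fit$params$beta1, unname(coef(ols)[2]), tolerance = 1e-9)
})

test_that("fit_null gives the closed-form Gaussian ML fit", {
  f <- fit_null(cohort_data(c(0, 2)))
  expect_equal(f$params$beta0, 1)
  expect_equal(f$params$sigma2, 1)
  expect_equal(f$loglik, -2 * (0.5 * log(2 * pi) + 0.5), tolerance = 1e-12)

  yc <- cohort_data(rep(3, 10))
  fc <- fit_null(yc)
  expect_equal(fc$params$beta0, 3)
  expect_equal(fc$params$sigma2, 1e-12)
})

test_that("emlrt_prob_test reduces to the classical LRT on true genotypes", {
  inst <- make_instance(n = 150, q = 0.3, beta1 = 0.4, seed = 31)
  Fd <- matrix(0, 150, 3)
  Fd[cbind(1:150, inst$g + 1)] <- 1
  res <- emlrt_prob_test(Fd, inst$cohort)
  orc <- oracle_lm_lrt(inst$g, inst$cohort$y)
  expect_equal(res$lrs, orc$lrs, tolerance = 1e-8)
  expect_equal(res$pvalue, orc$pvalue, tolerance = 1e-8)
})

test_that("monomorphic markers return p = 1 with a diagnostic", {
  F <- matrix(rep(c(1, 0, 0), each = 20), 20)
  res <- emlrt_prob_test(F, cohort_data(rnorm(20)))
  expect_equal(res$pvalue, 1)
  expect_true(res$diagnostics$monomorphic)
})

test_that("the batch kernel reproduces the reference EM test", {
  set.seed(40)
  for (s in 1:8) {
    inst <- make_instance(n = 300, q = runif(1, 0.05, 0.4),
                          rsq = runif(1, 0.1, 0.9),
                          beta1 = rnorm(1, 0, 0.4), seed = 40 + s)
    b <- emlrt:::em_lrt_batch_cpp(inst$cohort$y, inst$F, 300L, 1e-6, 1000L)
    r <- emlrt_prob_test(inst$F, inst$cohort, settings = list(tol = 1e-8))
    expect_equal(unname(b[1, "pvalue"]), r$pvalue,
                 tolerance = 1e-4 * max(r$pvalue, 1e-8))
  }
})
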