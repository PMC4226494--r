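# Monte-Carlo drivers: reproducibility, cell independence, and report
# structure. (The paper-scale rejection-rate comparisons live in
# test-acceptance.R.)

test_that("mc_pvalues is deterministic and cell-order independent", {
  for (eng in c("R", "C")) {
    P1 <- mc_pvalues(200, 0.2, 0.5, 0, 30, c("dosage", "emlrt_prob"),
                     seed = 5, engine = eng)
    P2 <- mc_pvalues(200, 0.2, 0.5, 0, 30, c("dosage", "emlrt_prob"),
                     seed = 5, engine = eng)
    expect_identical(P1, P2)
    expect_true(all(P1 > 0 & P1 <= 1))
  }
  # per-cell child seeds: the same cell gives the same rates regardless of
  # which other cells run alongside it
  cells_a <- data.frame(rsq = c(0.5, 0.3), maf = c(0.2, 0.1))
  cells_b <- data.frame(rsq = c(0.3, 0.5), maf = c(0.1, 0.2))
  ra <- run_type1(cells_a, n = 200, reps = 200, methods = "dosage", seed = 3)
  rb <- run_type1(cells_b, n = 200, reps = 200, methods = "dosage", seed = 3)
  expect_equal(ra$rate[ra$rsq == 0.5], rb$rate[rb$rsq == 0.5])
  expect_equal(ra$rate[ra$rsq == 0.3], rb$rate[rb$rsq == 0.3])
})

test_that("the two engines draw from the same sampling distribution", {
  # same cell, disjoint streams: compare rejection rates at a loose level
  PR <- mc_pvalues(300, 0.2, 0.5, 0.5, 400, "emlrt_prob", seed = 6,
                   engine = "R")
  PC <- mc_pvalues(300, 0.2, 0.5, 0.5, 400, "emlrt_prob", seed = 6,
                   engine = "C")
  rr <- mean(PR < 0.05); rc <- mean(PC < 0.05)
  se <- sqrt(rr * (1 - rr) / 400 + rc * (1 - rc) / 400)
  expect_lt(abs(rr - rc), 4 * se + 0.01)
})

test_that("rate tables carry Monte-Carlo standard errors", {
  out <- run_type1(data.frame(rsq = 0.5, maf = 0.2), n = 200, reps = 400,
                   alpha = c(0.05, 0.2), methods = c("dosage", "truth"),
                   seed = 7)
  expect_setequal(names(out),
                  c("rsq", "maf", "method", "alpha", "rate", "se", "reps"))
  expect_equal(nrow(out), 4)
  expect_true(all(out$se == sqrt(out$rate * (1 - out$rate) / out$reps)))
  # truth test is exactly calibrated: loose 4-SE sanity band
  tr <- out[out$method == "truth", ]
  expect_true(all(abs(tr$rate - tr$alpha) <
                    4 * sqrt(tr$alpha * (1 - tr$alpha) / tr$reps) + 0.01))
})

test_that("run_power rejects null configurations and reports power", {
  expect_error(run_power(data.frame(rsq = 0.5, maf = 0.2), beta1 = 0))
  out <- run_power(data.frame(rsq = 0.9, maf = 0.3), n = 500, beta1 = 1,
                   reps = 200, alpha = 1e-4, methods = "dosage", seed = 8)
  expect_gt(out$rate, 0.9)  # enormous effect, high quality: near-certain
})

test_that("spearman concordance is perfect for self and degenerate cells", {
  out <- spearman_concordance(data.frame(rsq = 1, maf = 0.3), n = 300,
                              beta1 = 0.3, reps = 150,
                              methods = c("truth", "emlrt_prob"), seed = 9,
                              engine = "C")
  expect_equal(out$rho[out$method == "truth"], 1)
  expect_equal(out$rho[out$method == "emlrt_prob"], 1, tolerance = 1e-6)
})

test_that("reconstruction error vanishes as imputation quality approaches 1", {
  out <- mse_calibration(c(0.98, 0.3), 0.05, n = 2000, seed = 10)
  expect_lt(out$mse_rejection[out$rsq == 0.98],
            out$mse_rejection[out$rsq == 0.3])
  expect_lt(out$mse_rejection[out$rsq == 0.98], 0.01)
  expect_lt(out$mse_approximation[out$rsq == 0.98], 0.02)
  # quadrature prediction agrees with the sampled MSE
  outq <- mse_calibration(0.5, 0.25, n = 2000, seed = 11, quadrature = TRUE)
  expect_equal(outq$mse_rejection, outq$mse_quadrature, tolerance = 0.25)
})

test_that("inflation t-test controls its own error on calibrated methods", {
  # dosage is calibrated; at any scale the one-sided flag fires with
  # probability <= 5e-4 under the null of no inflation
  out <- inflation_ttest(0.5, 0.2, A = 10L, B = 100L, n = 200,
                         methods = "dosage", seed = 12)
  expect_false(any(out$flagged))
  expect_setequal(names(out), c("rsq", "maf", "method", "mean_rate",
                                "tstat", "pvalue", "flagged"))
})
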