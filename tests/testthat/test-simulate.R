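# Three-stage hierarchical simulator: Dirichlet parameterization, moment
# identities, and reproducibility.

test_that("make_marker encodes HWE-proportional Dirichlet parameters", {
  m <- make_marker(q = 0.5, rsq = 0.5)
  expect_equal(m$c, 1)
  expect_equal(m$alpha, c(0.25, 0.5, 0.25))

  m2 <- make_marker(q = 0.2, rsq = 0.3)
  expect_equal(sum(m2$alpha), m2$c)
  expect_equal(m2$alpha / m2$c, c(0.64, 0.32, 0.04))

  expect_true(make_marker(0.2, 1)$degenerate)
  expect_error(make_marker(0, 0.5), "MAF")
  expect_error(make_marker(0.6, 0.5), "MAF")
  expect_error(make_marker(0.2, 0), "R\\^2")
  expect_error(make_marker(0.2, 1.2), "R\\^2")
})

test_that("sampled probability rows live on the simplex", {
  for (q in c(0.02, 0.2, 0.5)) {
    for (rsq in c(0.1, 0.5, 0.95)) {
      F <- sample_probs(make_marker(q, rsq), 2000, seed = 42)
      expect_true(all(F >= 0 & F <= 1))
      expect_lt(max(abs(rowSums(F) - 1)), 1e-9)
    }
  }
})

test_that("degenerate markers (rsq = 1) sample simplex vertices at HWE rates", {
  F <- sample_probs(make_marker(0.2, 1), 1e4, seed = 7)
  expect_true(all(F %in% c(0, 1)))
  expect_lt(max(abs(rowSums(F) - 1)), 1e-12)
  # fraction of homozygous-minor rows ~ q^2 = 0.04
  expect_within_3se(mean(F[, 3] == 1), 0.04, sqrt(0.04 * 0.96 / 1e4))
})

test_that("probability moments match the Dirichlet model", {
  n <- 2e5
  for (cell in list(c(0.05, 0.1), c(0.2, 0.3), c(0.3, 0.8))) {
    q <- cell[1]; rsq <- cell[2]
    F <- sample_probs(make_marker(q, rsq), n, seed = 11)
    hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    for (j in 1:3) {
      se <- sd(F[, j]) / sqrt(n)
      expect_within_3se(mean(F[, j]), hwe[j], se, "col mean")
    }
    # Var(f1) = R^2 * m(1-m), m = 2q(1-q)
    m <- 2 * q * (1 - q)
    v <- var(F[, 2])
    se_v <- sd((F[, 2] - mean(F[, 2]))^2) / sqrt(n)
    expect_within_3se(v, rsq * m * (1 - m), se_v, "Var(f1)")
  }
})

test_that("squared dosage-genotype correlation converges to target rsq", {
  n <- 2e5
  for (cell in list(c(0.2, 0.1), c(0.2, 0.3), c(0.1, 0.5), c(0.2, 0.95))) {
    q <- cell[1]; rsq <- cell[2]
    F <- sample_probs(make_marker(q, rsq), n, seed = 13)
    g <- sample_genotypes(F, seed = 14)
    d <- F[, 2] + 2 * F[, 3]
    r2 <- cor(d, g)^2
    # batch-based SE (the delta-method normal formula understates the
    # sampling noise for this skewed, discrete pair)
    bat <- rep(1:20, length.out = n)
    r2b <- vapply(1:20, function(b) cor(d[bat == b], g[bat == b])^2,
                  numeric(1))
    se <- sd(r2b) / sqrt(20)
    expect_within_3se(r2, rsq, se, "corr^2(D,G)")
    # marginal allele frequency
    expect_within_3se(mean(g) / 2, q, sd(g) / (2 * sqrt(n)), "MAF")
  }
})

test_that("genotype sampling respects degenerate rows", {
  F <- matrix(rep(c(1, 0, 0), each = 50), 50)
  expect_true(all(sample_genotypes(F, seed = 3) == 0))
})

test_that("trait stage follows the linear model", {
  cfg <- sim_config(n = 5e4, q = 0.05, rsq = 0.5, beta0 = 0, beta1 = 1,
                    sigma2 = 1, seed = 21)
  sim <- simulate_marker_data(cfg)
  # var(y) = sigma2 + beta1^2 * 2q(1-q)
  expect_within_3se(var(sim$y), 1.095, sd((sim$y - mean(sim$y))^2) /
                      sqrt(cfg$n), "var(y)")
  # noiseless limit: y = G exactly
  g <- sample_genotypes(sample_probs(make_marker(0.3, 0.5), 100, seed = 1),
                        seed = 2)
  tr <- sample_trait(g, sim_config(n = 100, beta0 = 0, beta1 = 1,
                                   sigma2 = 1e-28, seed = 3), seed = 4)
  expect_equal(tr$y, as.numeric(g), tolerance = 1e-10)
  # null model: y independent of g
  expect_error(sample_trait(g, list(n = 100, gamma = numeric(0),
                                    beta0 = 0, beta1 = 0, sigma2 = -1)),
               "sigma2")
})

test_that("covariates enter the trait with the requested effects", {
  cfg <- sim_config(n = 3e4, q = 0.2, rsq = 0.5, beta1 = 0.5,
                    gamma = c(2, -1), sigma2 = 0.5, seed = 31)
  sim <- simulate_marker_data(cfg)
  fit <- lm(sim$y ~ sim$g + sim$z)
  expect_equal(unname(coef(fit)[-1]), c(0.5, 2, -1), tolerance = 0.05)
})

test_that("samplers are reproducible from seeds, per stage", {
  m <- make_marker(0.2, 0.3)
  expect_identical(sample_probs(m, 50, seed = 5), sample_probs(m, 50, seed = 5))
  F <- sample_probs(m, 50, seed = 5)
  expect_identical(sample_genotypes(F, seed = 6), sample_genotypes(F, seed = 6))
  s1 <- simulate_marker_data(sim_config(n = 50, seed = 9))
  s2 <- simulate_marker_data(sim_config(n = 50, seed = 9))
  expect_identical(s1$y, s2$y)
  expect_identical(s1$probs, s2$probs)
  # probability stage unchanged when only the trait stage would differ
  expect_identical(s1$probs,
                   sample_probs(make_marker(s1$marker$q, s1$marker$rsq), 50,
                                seed = emlrt:::child_seed(9L, 1L)))
})
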