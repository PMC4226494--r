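# Conditional distribution of f1 given dosage, the two reconstruction
# modes, and the MAF-threshold policy.

test_that("boundary dosages give point masses at the simplex vertices", {
  m <- make_marker(0.2, 0.5)
  expect_true(conditional_density(m, 0)$point_mass)
  expect_true(conditional_density(m, 2)$point_mass)
  expect_identical(rejection_sample(conditional_density(m, 0), 5, seed = 1),
                   rep(0, 5))
  sp <- sample_probs_from_dosage(c(0, 2), m, mode = "rejection", seed = 1)
  expect_equal(sp$probs, rbind(c(1, 0, 0), c(0, 0, 1)))
  expect_equal(sp$mode_used, c("boundary", "boundary"))
})

test_that("conditional density input checks", {
  m <- make_marker(0.2, 0.5)
  expect_error(conditional_density(m, 2.5), "outside")
  expect_error(conditional_density(make_marker(0.2, 1), 0.5), "degenerate")
})

test_that("the conditional density is normalized", {
  # mild cells: direct adaptive quadrature on the raw density succeeds
  # and must give exactly 1 for the normalized density
  for (cell in list(c(0.2, 0.2, 0.3), c(0.35, 0.2, 0.9),
                    c(0.2, 0.2, 1.5), c(0.05, 0.2, 1.5))) {
    dens <- conditional_density(make_marker(cell[1], cell[2]), cell[3])
    I <- integrate(dcond_f1, 0, dens$support, dens = dens,
                   rel.tol = 1e-9, subdivisions = 1000L)$value
    expect_equal(I, 1, tolerance = 1e-6,
                 label = sprintf("integral q=%g rsq=%g d=%g",
                                 cell[1], cell[2], cell[3]))
  }
  # strongly singular cells (endpoint exponents near -1): check the
  # normalizer against an independent incomplete-Beta piecewise sum
  for (cell in list(c(0.05, 0.8, 0.3), c(0.35, 0.8, 0.9))) {
    m <- make_marker(cell[1], cell[2])
    d <- cell[3]
    a <- m$alpha
    s <- min(d, 2 - d)
    gam <- if (d < 1) a[3] else a[1]
    u <- sin(pi / 2 * seq(0, 1, length.out = 4097))^2
    mid <- s * (u[-1] + u[-4097]) / 2
    g <- if (d < 1) ((2 - d - mid) / 2)^(a[1] - 1)
         else ((d - mid) / 2)^(a[3] - 1)
    Z_alt <- sum(g * diff(pbeta(u, a[2], gam))) *
      s^(a[2] + gam - 1) * 2^(1 - gam) * beta(a[2], gam)
    dens <- conditional_density(m, d)
    expect_equal(dens$lognorm, log(Z_alt), tolerance = 1e-5)
  }
})

test_that("conditional draws match an exact independent sampler", {
  set.seed(77)
  for (cell in list(c(0.2, 0.5, 0.6), c(0.05, 0.1, 0.08),
                    c(0.35, 0.8, 1.2))) {
    m <- make_marker(cell[1], cell[2])
    dens <- conditional_density(m, cell[3])
    draws <- rejection_sample(dens, 5000, seed = 78)
    orc <- oracle_f1_beta_reject(m, cell[3], 5000)
    ks <- suppressWarnings(ks.test(draws, orc))
    expect_gt(ks$p.value, 1e-3)
    mom <- conditional_moments(dens)
    expect_within_3se(mean(draws), mom$mean, sd(draws) / sqrt(5000),
                      "cond mean")
  }
  # empirical CDF tracks the quadrature CDF pointwise
  m <- make_marker(0.2, 0.5)
  dens <- conditional_density(m, 0.6)
  draws <- rejection_sample(dens, 2e4, seed = 79)
  for (x in c(0.05, 0.2, 0.45, 0.59)) {
    ci <- integrate(dcond_f1, 0, x, dens = dens, rel.tol = 1e-9)$value
    expect_lt(abs(mean(draws <= x) - ci), 0.015)
  }
})

test_that("a flat conditional density is sampled uniformly", {
  # alpha = (1,1,1) makes the restricted density constant on the support
  m <- structure(list(q = 1 / 3, rsq = 0.25, c = 3, alpha = c(1, 1, 1),
                      hwe = rep(1 / 3, 3), degenerate = FALSE),
                 class = "marker_info")
  dens <- conditional_density(m, 0.8)
  draws <- rejection_sample(dens, 5000, seed = 5)
  ks <- suppressWarnings(ks.test(draws, "punif", 0, 0.8))
  expect_gt(ks$p.value, 1e-3)
})

test_that("d = 1 uses the exact Beta reduction", {
  m <- make_marker(0.3, 0.3)
  dens <- conditional_density(m, 1)
  expect_true(dens$beta_exact)
  draws <- rejection_sample(dens, 5000, seed = 9)
  ks <- suppressWarnings(
    ks.test(draws, "pbeta", m$alpha[2], m$alpha[1] + m$alpha[3] - 1))
  expect_gt(ks$p.value, 1e-3)
})

test_that("reconstructed rows satisfy the simplex and dosage constraints", {
  m <- make_marker(0.25, 0.4)
  set.seed(10)
  d <- dosage_from_probs(sample_probs(m, 500))
  for (mode in c("rejection", "approximation")) {
    sp <- sample_probs_from_dosage(d, m, mode = mode, seed = 11)
    expect_true(all(sp$probs >= -1e-12))
    expect_lt(max(abs(rowSums(sp$probs) - 1)), 1e-9)
    expect_lt(max(abs(dosage_from_probs(sp$probs) - d)), 1e-9)
  }
})

test_that("dosage approximation follows the low-MAF rule and its extension", {
  expect_equal(dosage_approximation(0.3), cbind(0.7, 0.3, 0))
  expect_equal(dosage_approximation(0), cbind(1, 0, 0))
  expect_equal(dosage_approximation(1.4), cbind(0, 0.6, 0.4))
  expect_error(dosage_approximation(2.1))
})

test_that("choose_mode applies the tabulated MAF cutoffs", {
  expect_equal(choose_mode(make_marker(0.15, 0.95)), "approximation")
  expect_equal(choose_mode(make_marker(0.30, 0.20)), "rejection")
  expect_equal(choose_mode(make_marker(0.30, 0.50)), "approximation")
  expect_equal(choose_mode(make_marker(0.25, 0.10)), "rejection")
  # off-bin rsq maps to the nearest tabulated bin
  expect_equal(choose_mode(make_marker(0.22, 0.12)), "rejection")
  expect_equal(choose_mode(make_marker(0.28, 0.93)), "rejection")
  expect_equal(choose_mode(make_marker(0.18, 0.93)), "approximation")
})

test_that("emlrt_dose_test with integer dosages equals the regression on D", {
  set.seed(12)
  g <- sample_genotypes(sample_probs(make_marker(0.3, 1), 200))
  y <- 0.4 * g + rnorm(200)
  co <- cohort_data(y)
  res <- emlrt_dose_test(as.numeric(g), co, marker = make_marker(0.3, 1),
                         seed = 13)
  orc <- oracle_lm_lrt(g, y)
  expect_equal(res$pvalue, orc$pvalue, tolerance = 1e-8)
  expect_equal(res$method, "emlrt_dose")
})

test_that("emlrt_dose_test requires imputation quality and handles MAF", {
  d <- runif(50, 0, 0.5)
  co <- cohort_data(rnorm(50))
  expect_error(emlrt_dose_test(d, co), "imputation quality")
  expect_warning(emlrt_dose_test(d, co, rsq = 0.5, seed = 1),
                 "MAF estimated")
})

test_that("one conditional draw has MSE 2 E[Var(f1|D)] against the truth", {
  m <- make_marker(0.25, 0.5)
  set.seed(14)
  F <- sample_probs(m, 3000)
  d <- dosage_from_probs(F)
  p1 <- emlrt:::sample_f1_cond(m$alpha, d)
  sqerr <- (p1 - F[, 2])^2
  vs <- vapply(d[1:400], function(di)
    conditional_moments(conditional_density(m, di))$var, numeric(1))
  expect_within_3se(mean(sqerr), 2 * mean(vs),
                    sd(sqerr) / sqrt(length(sqerr)) + 2 * sd(vs) / 20,
                    "reconstruction MSE")
})
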