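#' @title Monte-Carlo benchmark drivers
#' @description
#' Replicated-simulation studies of the association tests under the
#' hierarchical model: empirical type I error and power across
#' (R-squared, MAF) cells, Spearman concordance with gold-standard
#' p-values, reconstruction-error calibration of the two
#' dosage-to-probability modes, and a grouped one-sample t-test that
#' detects type-I-error inflation. Every rejection-rate estimate is
#' reported with its Monte-Carlo standard error sqrt(r(1-r)/reps).
#' Results are bit-reproducible: each (seed, cell) pair derives an
#' independent child seed, so cells can be run in any order.
#' @name experiments-module
NULL

# Vectorized 1-df Gaussian-regression LRT p-values, one per column of
# the n x m trait matrix Y against the matching column of X.
batch_lrt_p <- function(Y, X) {
  n <- nrow(Y)
  my <- colMeans(Y); mx <- colMeans(X)
  syy <- colSums(Y * Y) - n * my^2
  sxx <- colSums(X * X) - n * mx^2
  sxy <- colSums(X * Y) - n * mx * my
  r2 <- sxy^2 / (sxx * syy)
  r2[!is.finite(r2)] <- 0
  r2 <- pmin(r2, 1 - 1e-15)
  pchisq(-n * log(1 - r2), 1L, lower.tail = FALSE)
}

#' Replicated p-values for one simulation cell
#'
#' Simulates `reps` independent data sets from the three-stage model at
#' one (MAF, R-squared) cell and returns each requested method's p-value
#' per replicate. All methods see the same simulated data, so paired
#' comparisons (and Spearman concordance against `"truth"`) are valid.
#'
#' @param n samples per replicate.
#' @param q,rsq marker MAF and imputation quality.
#' @param beta1 genetic effect (0 for null simulations).
#' @param reps replicate count.
#' @param methods subset of `c("dosage", "truth", "emlrt_prob",
#'   "emlrt_dose", "mixture")`.
#' @param seed integer seed (the whole run is deterministic given it).
#' @param beta0,sigma2 trait-stage intercept and residual variance.
#' @param mixture_reps cap on the (slower) simplex-maximized Mixture
#'   method; its column is `NA` beyond this row.
#' @param dose_mode reconstruction mode for `"emlrt_dose"` (`"auto"`
#'   applies the MAF-threshold policy).
#' @param engine `"C"` (default): the whole replicate loop, including
#'   simulation, runs in the compiled kernel with its own seeded
#'   generator — required for paper-scale replicate counts.  `"R"`: the
#'   simulator's R implementation generates the data (R RNG) and the EM
#'   core is applied per replicate; supports every `dose_mode`. Both are
#'   deterministic given `seed` but produce distinct streams.
#' @param chunk replicates simulated per block under `engine = "R"`
#'   (fixed by default so results are independent of memory
#'   considerations).
#' @param tol,max_iter EM convergence settings.
#' @return `reps` x `length(methods)` matrix of p-values.
#' @export
mc_pvalues <- function(n, q, rsq, beta1, reps, methods, seed,
                       beta0 = 0, sigma2 = 1, mixture_reps = reps,
                       dose_mode = "auto", engine = c("C", "R"),
                       chunk = 500L, tol = 1e-6, max_iter = 1000L) {
  methods <- match.arg(methods,
                       c("dosage", "truth", "emlrt_prob", "emlrt_dose",
                         "mixture"), several.ok = TRUE)
  engine <- match.arg(engine)
  set.seed(seed)
  marker <- make_marker(q, rsq)
  if (dose_mode == "auto") dose_mode <- choose_mode(marker)
  if (engine == "C") {
    if ("emlrt_dose" %in% methods && dose_mode != "approximation")
      stop("mc_pvalues: the compiled kernel implements the ",
           "dosage-approximation reconstruction only; use engine = \"R\" ",
           "for conditional-sampling cells")
    order_all <- c("dosage", "truth", "emlrt_prob", "emlrt_dose",
                   "mixture")
    mask <- order_all %in% methods
    P <- mc_kernel_cpp(as.integer(n), as.integer(reps), marker$alpha,
                       marker$hwe, marker$degenerate, beta0, beta1,
                       sigma2, as.double(seed %% 2^31), mask, tol,
                       as.integer(max_iter), as.integer(mixture_reps),
                       1e-8, 500L)
    colnames(P) <- order_all[mask]
    return(P[, methods, drop = FALSE])
  }
  P <- matrix(NA_real_, reps, length(methods),
              dimnames = list(NULL, methods))
  done <- 0L
  while (done < reps) {
    m <- min(chunk, reps - done)
    nm <- n * m
    if (marker$degenerate) {
      g0 <- sample_vertex(marker$hwe, nm)
      F <- matrix(0, nm, 3L)
      F[cbind(seq_len(nm), g0 + 1L)] <- 1
    } else {
      F <- matrix(rgamma(3L * nm, shape = rep(marker$alpha, each = nm)),
                  nm, 3L)
      rs <- rowSums(F)
      zero <- which(rs == 0)
      if (length(zero)) {
        F[zero, which.max(marker$alpha)] <- 1
        rs[zero] <- 1
      }
      F <- F / rs
    }
    u <- runif(nm)
    G <- (u > F[, 1L]) + (u > F[, 1L] + F[, 2L])
    y <- beta0 + beta1 * G + rnorm(nm, sd = sqrt(sigma2))
    D <- F[, 2L] + 2 * F[, 3L]
    rows <- done + seq_len(m)
    if ("dosage" %in% methods)
      P[rows, "dosage"] <- batch_lrt_p(matrix(y, n, m), matrix(D, n, m))
    if ("truth" %in% methods)
      P[rows, "truth"] <- batch_lrt_p(matrix(y, n, m), matrix(G, n, m))
    if ("emlrt_prob" %in% methods)
      P[rows, "emlrt_prob"] <-
        em_lrt_batch_cpp(y, F, n, tol, max_iter)[, "pvalue"]
    if ("emlrt_dose" %in% methods) {
      Fd <- if (dose_mode == "approximation") dosage_approximation(D)
      else {
        p1 <- sample_f1_cond(marker$alpha, D)
        f2 <- (D - p1) / 2
        unname(cbind(pmax(1 - p1 - f2, 0), p1, f2))
      }
      P[rows, "emlrt_dose"] <-
        em_lrt_batch_cpp(y, Fd, n, tol, max_iter)[, "pvalue"]
    }
    if ("mixture" %in% methods && done < mixture_reps) {
      for (j in seq_len(min(m, mixture_reps - done))) {
        idx <- ((j - 1L) * n + 1L):(j * n)
        P[done + j, "mixture"] <- mixture_pvalue(y[idx], F[idx, ])
      }
    }
    done <- done + m
  }
  P
}

rate_table <- function(P, alpha, rsq, maf) {
  do.call(rbind, lapply(colnames(P), function(meth) {
    p <- P[, meth]
    p <- p[!is.na(p)]
    do.call(rbind, lapply(alpha, function(a) {
      r <- mean(p < a)
      data.frame(rsq = rsq, maf = maf, method = meth, alpha = a,
                 rate = r, se = sqrt(r * (1 - r) / length(p)),
                 reps = length(p))
    }))
  }))
}

# Seed derived from the cell's own coordinates (not its position in the
# grid), so results are independent of execution order.
cell_seed <- function(seed, rsq, maf, offset = 0L) {
  child_seed(seed, (round(rsq * 1e4) * 20011 + round(maf * 1e4) * 13 +
                      offset) %% 1e9)
}

run_cells <- function(cells, n, beta1, reps, alpha, methods, seed, ...) {
  out <- lapply(seq_len(nrow(cells)), function(i) {
    P <- mc_pvalues(n, cells$maf[i], cells$rsq[i], beta1, reps, methods,
                    seed = cell_seed(seed, cells$rsq[i], cells$maf[i]), ...)
    rate_table(P, alpha, cells$rsq[i], cells$maf[i])
  })
  do.call(rbind, out)
}

#' Empirical type I error across simulation cells
#'
#' Null simulations (`beta1 = 0`) per (R-squared, MAF) cell; rejection
#' rate at each nominal level with its Monte-Carlo standard error.
#'
#' @param cells data frame with columns `rsq` and `maf`.
#' @param n samples per replicate.
#' @param reps replicates per cell.
#' @param alpha nominal significance level(s).
#' @param methods see [mc_pvalues()].
#' @param seed root seed; cell `i` uses a derived child seed.
#' @param ... passed to [mc_pvalues()] (e.g. `mixture_reps`).
#' @return Data frame: `rsq, maf, method, alpha, rate, se, reps`.
#' @export
run_type1 <- function(cells, n = 2000L, reps = 1e5, alpha = 0.05,
                      methods = c("dosage", "emlrt_dose", "emlrt_prob",
                                  "truth"),
                      seed = 1L, ...) {
  stopifnot(reps >= 100, all(alpha > 0 & alpha < 1))
  run_cells(cells, n, beta1 = 0, reps = reps, alpha = alpha,
            methods = methods, seed = seed, ...)
}

#' Empirical power across simulation cells
#'
#' As [run_type1()] but with a nonzero genetic effect. The default
#' power-study significance threshold is 1e-4, calibrated so that the
#' closed-form power of the dosage test (noncentral chi-square with
#' noncentrality n beta1^2 Var(D) / (sigma^2 + beta1^2 (Var(G) - Var(D))))
#' reproduces the reference power benchmarks; see the methods vignette.
#'
#' @inheritParams run_type1
#' @param beta1 genetic effect size (nonzero).
#' @export
run_power <- function(cells, n = 2000L, beta1 = 1, reps = 2e4,
                      alpha = 1e-4,
                      methods = c("dosage", "emlrt_dose", "emlrt_prob"),
                      seed = 1L, ...) {
  stopifnot(beta1 != 0, reps >= 100)
  run_cells(cells, n, beta1 = beta1, reps = reps, alpha = alpha,
            methods = methods, seed = seed, ...)
}

#' Spearman concordance with gold-standard p-values
#'
#' Per cell and method, the Spearman rank correlation between the
#' method's p-values and the true-genotype regression p-values over
#' shared replicates.
#'
#' @inheritParams run_type1
#' @param beta1 genetic effect (0 reproduces the null-simulation design).
#' @return Data frame: `rsq, maf, method, rho, se, reps` (`se` is the
#'   Fisher-transform large-sample standard error mapped back).
#' @export
spearman_concordance <- function(cells, n = 2000L, beta1 = 0, reps = 2000,
                                 methods = c("dosage", "emlrt_dose",
                                             "emlrt_prob"),
                                 seed = 1L, ...) {
  out <- lapply(seq_len(nrow(cells)), function(i) {
    P <- mc_pvalues(n, cells$maf[i], cells$rsq[i], beta1, reps,
                    unique(c(methods, "truth")),
                    seed = cell_seed(seed, cells$rsq[i], cells$maf[i],
                                     1L), ...)
    do.call(rbind, lapply(methods, function(meth) {
      keep <- !is.na(P[, meth])
      rho <- cor(P[keep, meth], P[keep, "truth"], method = "spearman")
      data.frame(rsq = cells$rsq[i], maf = cells$maf[i], method = meth,
                 rho = rho,
                 se = (1 - rho^2) * 1.06 / sqrt(sum(keep) - 3),
                 reps = sum(keep))
    }))
  })
  do.call(rbind, out)
}

#' Reconstruction-error calibration of the two sampling modes
#'
#' For each (R-squared, MAF) point, simulates probabilities and dosages,
#' estimates the heterozygote probability by conditional sampling and by
#' the literal dosage rule \eqn{\hat f_1 = D} (the low-MAF approximation
#' whose breakdown beyond MAF cutoffs this calibration quantifies; the
#' reconstruction code in [dosage_approximation()] additionally folds
#' dosages above 1 back onto the simplex), and reports each mode's mean
#' squared error against the true \eqn{f_1}, plus the quadrature
#' prediction \eqn{2 E[Var(f_1|D)]} for the conditional-sampling MSE.
#'
#' @param rsq_list,maf_grid grids of imputation quality and MAF values.
#' @param n samples per point.
#' @param reps independent marker replicates averaged per point.
#' @param seed root seed.
#' @param quadrature also compute the quadrature prediction (slower).
#' @return Data frame: `rsq, maf, mse_rejection, mse_approximation,
#'   mse_quadrature, n_total`.
#' @export
mse_calibration <- function(rsq_list, maf_grid, n = 2000L, reps = 1L,
                            seed = 1L, quadrature = FALSE) {
  grid <- expand.grid(maf = maf_grid, rsq = rsq_list)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    q <- grid$maf[i]; rsq <- grid$rsq[i]
    marker <- make_marker(q, rsq)
    set.seed(cell_seed(seed, rsq, q, 2L))
    se_rej <- se_app <- 0
    mse_quad <- NA_real_
    for (r in seq_len(reps)) {
      F <- sample_probs(marker, n)
      D <- dosage_from_probs(F)
      p_rej <- sample_f1_cond(marker$alpha, D)
      p_app <- D
      se_rej <- se_rej + sum((p_rej - F[, 2L])^2)
      se_app <- se_app + sum((p_app - F[, 2L])^2)
      if (quadrature && r == 1L) {
        vs <- vapply(D, function(d) {
          conditional_moments(conditional_density(marker, d))$var
        }, numeric(1))
        mse_quad <- 2 * mean(vs)
      }
    }
    data.frame(rsq = rsq, maf = q, mse_rejection = se_rej / (n * reps),
               mse_approximation = se_app / (n * reps),
               mse_quadrature = mse_quad, n_total = n * reps)
  })
  do.call(rbind, out)
}

#' Grouped one-sample t-test for type-I-error inflation
#'
#' For each cell and method, simulates `A` exchangeable groups of `B`
#' null replicates, computes the group-wise type I error at level
#' `alpha`, and runs the one-sided one-sample t-test of H0: type I error
#' <= `alpha` against inflation. Cells with p below `flag_at` are
#' flagged.
#'
#' @param rsq_list,maf_list cell grids.
#' @param A,B number of groups and replicates per group.
#' @param n samples per replicate.
#' @param alpha nominal level for the group-wise type I error.
#' @param methods see [mc_pvalues()].
#' @param flag_at t-test significance threshold for flagging.
#' @param seed root seed.
#' @param ... passed to [mc_pvalues()].
#' @return Data frame: `rsq, maf, method, mean_rate, tstat, pvalue,
#'   flagged`.
#' @export
inflation_ttest <- function(rsq_list, maf_list, A = 100L, B = 2000L,
                            n = 2000L, alpha = 0.05,
                            methods = c("dosage", "emlrt_dose",
                                        "emlrt_prob"),
                            flag_at = 5e-4, seed = 1L, ...) {
  grid <- expand.grid(maf = maf_list, rsq = rsq_list)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    P <- mc_pvalues(n, grid$maf[i], grid$rsq[i], beta1 = 0,
                    reps = A * B, methods = methods,
                    seed = cell_seed(seed, grid$rsq[i], grid$maf[i], 3L),
                    ...)
    grp <- rep(seq_len(A), each = B)
    do.call(rbind, lapply(methods, function(meth) {
      rates <- tapply(P[, meth] < alpha, grp, mean)
      tt <- t.test(rates, mu = alpha, alternative = "greater")
      data.frame(rsq = grid$rsq[i], maf = grid$maf[i], method = meth,
                 mean_rate = mean(rates),
                 tstat = unname(tt$statistic), pvalue = tt$p.value,
                 flagged = tt$p.value < flag_at)
    }))
  })
  do.call(rbind, out)
}
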