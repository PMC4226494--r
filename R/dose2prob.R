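#' @title Recovering genotype probabilities from dosages (scenario II)
#' @description
#' When only imputed dosages \eqn{D = f_1 + 2 f_2} are retained, the
#' posterior probability triple can be re-sampled from its conditional
#' distribution given the dosage under the Dirichlet model. Restricting
#' the Dirichlet density to the line \eqn{f_1 + 2 f_2 = d} and writing
#' \eqn{p = f_1} gives the (unnormalized) conditional density
#' \deqn{h(p) = \left(\frac{2-d-p}{2}\right)^{\alpha_0-1} p^{\alpha_1-1}
#'   \left(\frac{d-p}{2}\right)^{\alpha_2-1}, \quad
#'   p \in [0, \min(d, 2-d)].}
#' Sampling from \eqn{h} plus the back-transformation
#' \eqn{f_2 = (d-p)/2}, \eqn{f_0 = 1 - p - f_2} reconstructs a
#' simplex-consistent probability row with exactly the observed dosage.
#' For low-MAF markers the cheap dosage approximation \eqn{(1-d, d, 0)}
#' is used instead, per the tabulated MAF cutoffs ([threshold_table()]).
#' @name dose2prob-module
NULL

# ---- conditional density -------------------------------------------------

# Branch bookkeeping shared by the density, quadrature and samplers.
# For d < 1 the support is (0, d): kernel p^(a1-1) * ((s-p)/2)^(alpha2-1),
# bounded factor ((2-d-p)/2)^(alpha0-1) (its base >= 1-d > 0).
# For d > 1 the support is (0, 2-d): kernel upper exponent alpha0, bounded
# factor ((d-p)/2)^(alpha2-1) (its base >= d-1 > 0).
cond_branch <- function(alpha, d) {
  if (d < 1) list(s = d, gam = alpha[3], aG = alpha[1],
                  gbase = function(p) (2 - d - p) / 2)
  else list(s = 2 - d, gam = alpha[1], aG = alpha[3],
            gbase = function(p) (d - p) / 2)
}

# integral of fun(p) * h(p) over the support, by splitting at s/2 and
# substituting out the endpoint power singularities (t = (p/s)^a1 below,
# u = ((s-p)/s)^gam above), so integrate() sees bounded smooth integrands.
cond_integral <- function(alpha, d, fun = function(p) rep(1, length(p)),
                          rel.tol = 1e-10) {
  br <- cond_branch(alpha, d)
  s <- br$s; a1 <- alpha[2]; gam <- br$gam; aG <- br$aG
  f_lo <- function(t) {
    p <- s * t^(1 / a1)
    br$gbase(p)^(aG - 1) * ((s - p) / 2)^(gam - 1) * fun(p)
  }
  f_hi <- function(u) {
    w <- s * u^(1 / gam)
    p <- s - w
    br$gbase(p)^(aG - 1) * p^(a1 - 1) * 2^(1 - gam) * fun(p)
  }
  I_lo <- integrate(f_lo, 0, 0.5^a1, rel.tol = rel.tol,
                    subdivisions = 400L)$value * s^a1 / a1
  I_hi <- integrate(f_hi, 0, 0.5^gam, rel.tol = rel.tol,
                    subdivisions = 400L)$value * s^gam / gam
  I_lo + I_hi
}

#' Conditional density of the heterozygote probability given dosage
#'
#' Builds the normalized density of \eqn{p = f_1} given dosage `d` under
#' the marker's Dirichlet model (see the module description for the
#' kernel). `d = 0` or `d = 2` give a degenerate point mass at the
#' corresponding simplex vertex. When `d` is 1 (within 1e-8) the density
#' is exactly \eqn{Beta(\alpha_1, \alpha_0 + \alpha_2 - 1)}.
#'
#' @param marker a [make_marker()] object with `rsq < 1`.
#' @param d dosage value in `[0, 2]`.
#' @return An object of class `cond_dose_density` with fields `alpha`,
#'   `d`, `support` (upper end of the support interval), `lognorm` (log
#'   normalizing constant of the kernel) and `point_mass` (for boundary
#'   `d`). Evaluate it with [dcond_f1()].
#' @examples
#' dens <- conditional_density(make_marker(0.2, 0.5), d = 0.6)
#' integrate(dcond_f1, 0, dens$support, dens = dens)$value  # ~1
#' @export
conditional_density <- function(marker, d) {
  stopifnot(inherits(marker, "marker_info"))
  if (marker$degenerate)
    stop("conditional_density: undefined for rsq = 1 (degenerate marker)")
  if (!is.finite(d) || d < 0 || d > 2)
    stop("conditional_density: dosage d = ", d, " outside [0, 2]")
  alpha <- marker$alpha
  out <- list(marker = marker, alpha = alpha, d = d,
              support = min(d, 2 - d), point_mass = FALSE,
              beta_exact = FALSE, lognorm = NA_real_)
  if (min(d, 2 - d) < 1e-9) {
    out$point_mass <- TRUE
    out$support <- 0
  } else if (abs(d - 1) < 1e-8 && alpha[1] + alpha[3] > 1) {
    out$beta_exact <- TRUE
    out$d <- 1
    out$support <- 1
    # kernel p^(a1-1) ((1-p)/2)^(a0+a2-2): Z = 2^(2-a0-a2) B(a1, a0+a2-1)
    out$lognorm <- (2 - alpha[1] - alpha[3]) * log(2) +
      lbeta(alpha[2], alpha[1] + alpha[3] - 1)
  } else {
    if (abs(d - 1) < 1e-8) {  # non-integrable knife-edge; nudge off d = 1
      d <- 1 - 1e-8
      out$d <- d
      out$support <- min(d, 2 - d)
    }
    out$lognorm <- log(cond_integral(alpha, d))
  }
  class(out) <- "cond_dose_density"
  out
}

#' Evaluate a conditional dosage density
#'
#' @param p evaluation points (vector).
#' @param dens a [conditional_density()] object.
#' @param log return the log density.
#' @return Density values; 0 outside the support (infinite at an endpoint
#'   when the corresponding Dirichlet parameter is below 1).
#' @export
dcond_f1 <- function(p, dens, log = FALSE) {
  stopifnot(inherits(dens, "cond_dose_density"))
  if (dens$point_mass)
    stop("dcond_f1: density is a point mass at p = 0 (boundary dosage)")
  alpha <- dens$alpha; d <- dens$d
  br <- cond_branch(alpha, d)
  s <- br$s
  inside <- p >= 0 & p <= s
  lf <- rep(-Inf, length(p))
  pi_ <- p[inside]
  lf[inside] <- (alpha[1] - 1) * log((2 - d - pi_) / 2) +
    (alpha[2] - 1) * log(pi_) +
    (alpha[3] - 1) * log((d - pi_) / 2) - dens$lognorm
  if (log) lf else exp(lf)
}

#' Conditional mean and variance of f1 given dosage
#'
#' Quadrature moments of a [conditional_density()]; used for
#' reconstruction-error calibration (the mean-squared error of one
#' conditional draw against the true \eqn{f_1} is \eqn{2 E[Var(f_1|D)]}).
#'
#' @param dens a [conditional_density()] object.
#' @return List with `mean` and `var`.
#' @export
conditional_moments <- function(dens) {
  stopifnot(inherits(dens, "cond_dose_density"))
  if (dens$point_mass) return(list(mean = 0, var = 0))
  alpha <- dens$alpha
  if (dens$beta_exact) {
    a <- alpha[2]; b <- alpha[1] + alpha[3] - 1
    return(list(mean = a / (a + b),
                var = a * b / ((a + b)^2 * (a + b + 1))))
  }
  Z <- exp(dens$lognorm)
  m1 <- cond_integral(alpha, dens$d, function(p) p) / Z
  m2 <- cond_integral(alpha, dens$d, function(p) p^2) / Z
  list(mean = m1, var = max(m2 - m1^2, 0))
}

# ---- samplers ------------------------------------------------------------

# Piecewise inverse-CDF draw (one per sample) for a group of dosages
# sharing a support branch. Within each grid interval the kernel
# p^(a1-1) ((s-p)/2)^(gam-1) is integrated exactly (incomplete Beta) and
# the bounded factor is frozen at the interval midpoint, so the endpoint
# singularities are represented analytically. Grid fractions are
# clustered at both endpoints.
icdf_group <- function(a1, gam, aG, gbase_mat, s, n, m = 160L) {
  u <- sin(pi / 2 * seq(0, 1, length.out = m + 1L))^2
  pb <- pbeta(u, a1, gam)
  dB <- diff(pb)
  mid <- (u[-1L] + u[-(m + 1L)]) / 2
  P <- outer(s, mid)                       # n x m midpoints in p-space
  G <- gbase_mat(P)^(aG - 1)               # bounded factor
  W <- G * rep(dB, each = n)
  CDF <- t(apply(W, 1L, cumsum))
  if (n == 1L) CDF <- matrix(CDF, 1L)
  tot <- CDF[, m]
  U <- runif(n) * tot
  k <- rowSums(CDF < U) + 1L
  k[k > m] <- m
  prev <- ifelse(k == 1L, 0, CDF[cbind(seq_len(n), pmax(k - 1L, 1L))])
  frac <- pmin(pmax((U - prev) / W[cbind(seq_len(n), k)], 0), 1)
  # invert within the interval by the local power-law form of the kernel
  # (t^(a1-1) near 0, (1-t)^(gam-1) near 1) -- analytic, and robust where
  # qbeta loses accuracy for very small shape parameters
  t <- numeric(n)
  lo <- u[k + 1L] <= 0.5
  if (any(lo)) {
    A <- u[k[lo]]^a1; B <- u[k[lo] + 1L]^a1
    t[lo] <- (A + frac[lo] * (B - A))^(1 / a1)
  }
  if (any(!lo)) {
    A <- (1 - u[k[!lo]])^gam; B <- (1 - u[k[!lo] + 1L])^gam
    t[!lo] <- 1 - ((1 - frac[!lo]) * A + frac[!lo] * B)^(1 / gam)
  }
  s * t
}

# Uniform-proposal rejection draw for a group whose density is bounded
# (both endpoint exponents >= 0): envelope = 1.01 x grid max of h.
# Unaccepted stragglers (envelope misses are possible only through the
# 1% safety margin; rate guard at 1e-4) fall back to the inverse CDF.
reject_group <- function(a1, gam, aG, gbase_mat, s, max_rounds = 200L) {
  n <- length(s)
  grid <- seq(0, 1, length.out = 129L)[-c(1L, 129L)]
  P <- outer(s, grid)
  H <- gbase_mat(P)^(aG - 1) * P^(a1 - 1) * ((s - P) / 2)^(gam - 1)
  M <- 1.01 * apply(H, 1L, max)
  out <- numeric(n)
  active <- seq_len(n)
  h1 <- function(p, i) {
    gbase_mat(matrix(p, length(p), 1L), rows = i)^(aG - 1) *
      p^(a1 - 1) * ((s[i] - p) / 2)^(gam - 1)
  }
  for (round in seq_len(max_rounds)) {
    if (!length(active)) break
    p_prop <- s[active] * runif(length(active))
    u <- runif(length(active)) * M[active]
    acc <- u <= h1(p_prop, active)
    out[active[acc]] <- p_prop[acc]
    active <- active[!acc]
  }
  if (length(active)) {
    out[active] <- icdf_group(a1, gam, aG,
                              function(P) gbase_mat(P, rows = active),
                              s[active], length(active))
  }
  out
}

# One conditional draw of p = f1 per dosage (vectorized over samples).
# Assumes the RNG is already seeded by the caller.
sample_f1_cond <- function(alpha, d) {
  n <- length(d)
  out <- numeric(n)
  s_all <- pmin(d, 2 - d)
  boundary <- s_all < 1e-9
  near1 <- !boundary & abs(d - 1) < 1e-8
  if (any(near1)) {
    if (alpha[1] + alpha[3] > 1) {
      out[near1] <- rbeta(sum(near1), alpha[2], alpha[1] + alpha[3] - 1)
    } else {
      d[near1] <- 1 - 1e-8
      s_all[near1] <- pmin(d[near1], 2 - d[near1])
      near1[] <- FALSE
    }
  }
  for (lower in c(TRUE, FALSE)) {
    idx <- which(!boundary & !near1 & (if (lower) d < 1 else d >= 1))
    if (!length(idx)) next
    di <- d[idx]; si <- s_all[idx]
    if (lower) {
      a1 <- alpha[2]; gam <- alpha[3]; aG <- alpha[1]
      gb <- function(P, rows = NULL) {
        dd <- if (is.null(rows)) di else di[rows]
        (2 - dd - P) / 2
      }
    } else {
      a1 <- alpha[2]; gam <- alpha[1]; aG <- alpha[3]
      gb <- function(P, rows = NULL) {
        dd <- if (is.null(rows)) di else di[rows]
        (dd - P) / 2
      }
    }
    out[idx] <- if (a1 >= 1 && gam >= 1)
      reject_group(a1, gam, aG, gb, si)
    else
      icdf_group(a1, gam, aG, gb, si, length(idx))
  }
  out
}

#' Draw the heterozygote probability from a conditional dosage density
#'
#' Accept-reject sampling with a uniform proposal on the support and a
#' grid-max envelope when the density is bounded; when an endpoint
#' Dirichlet parameter is below 1 the density is unbounded there, a
#' finite envelope does not exist, and an inverse-CDF sampler on an
#' endpoint-clustered grid (with the singular kernel integrated
#' analytically per interval) is used instead.
#'
#' @param dens a [conditional_density()] object.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` draws of \eqn{p = f_1}.
#' @export
rejection_sample <- function(dens, n = 1L, seed = NULL) {
  stopifnot(inherits(dens, "cond_dose_density"))
  if (!is.null(seed)) set.seed(seed)
  if (dens$point_mass) return(rep(0, n))
  sample_f1_cond(dens$alpha, rep(dens$d, n))
}

# ---- dosage approximation and the MAF-threshold policy -------------------

#' Dosage approximation of a probability row
#'
#' Low-MAF shortcut: for `d <= 1` the row is `(1-d, d, 0)`; for `d > 1`
#' the unique simplex-consistent completion `(0, 2-d, d-1)` is used.
#'
#' @param d dosage vector in `[0, 2]`.
#' @return `length(d)` x 3 probability matrix with `f1 + 2 f2 = d`.
#' @examples
#' dosage_approximation(c(0.3, 1.4))
#' @export
dosage_approximation <- function(d) {
  stopifnot(all(d >= 0 & d <= 2))
  lo <- d <= 1
  cbind(ifelse(lo, 1 - d, 0),
        ifelse(lo, d, 2 - d),
        ifelse(lo, 0, d - 1))
}

#' MAF cutoffs for dosage approximation vs conditional sampling
#'
#' Per imputation-quality bin, the MAF at or below which the dosage
#' approximation matches conditional sampling in reconstruction error and
#' is preferred for speed.
#'
#' @return Data frame with columns `rsq_bin` and `maf_cutoff`.
#' @export
threshold_table <- function() {
  data.frame(rsq_bin = c(0.95, 0.75, 0.50, 0.30, 0.25, 0.20, 0.10),
             maf_cutoff = c(0.20, 0.30, 0.30, 0.30, 0.30, 0.25, 0.20))
}

#' Choose the probability-reconstruction mode for a marker
#'
#' Maps the marker's `rsq` to the nearest tabulated bin (ties resolved
#' toward the smaller cutoff, i.e. the conditional-sampling path) and
#' returns `"approximation"` iff the MAF is at or below that bin's
#' cutoff, else `"rejection"`.
#'
#' @param marker a [make_marker()] object.
#' @return `"approximation"` or `"rejection"`.
#' @examples
#' choose_mode(make_marker(0.15, 0.95))  # "approximation"
#' choose_mode(make_marker(0.30, 0.20))  # "rejection"
#' @export
choose_mode <- function(marker) {
  stopifnot(inherits(marker, "marker_info"))
  tab <- threshold_table()
  dist <- abs(tab$rsq_bin - marker$rsq)
  cand <- which(dist == min(dist))
  row <- cand[which.min(tab$maf_cutoff[cand])]
  if (marker$q <= tab$maf_cutoff[row]) "approximation" else "rejection"
}

#' Reconstruct genotype probabilities from dosages
#'
#' @param dosages dosage vector in `[0, 2]`.
#' @param marker a [make_marker()] object carrying the MAF and `rsq` that
#'   parameterize the conditional distribution.
#' @param mode `"auto"` (apply [choose_mode()]), `"rejection"`
#'   (conditional sampling) or `"approximation"`.
#' @param seed optional integer seed (conditional sampling is stochastic).
#' @return A list of class `sampled_probs` with `probs` (n x 3, rows on
#'   the simplex with `f1 + 2 f2` equal to the dosage) and `mode_used`
#'   (per-sample tag: `rejection`, `approximation` or `boundary`).
#' @export
sample_probs_from_dosage <- function(dosages, marker,
                                     mode = c("auto", "rejection",
                                              "approximation"),
                                     seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(marker, "marker_info"))
  if (any(dosages < 0 | dosages > 2))
    stop("sample_probs_from_dosage: dosages outside [0, 2]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(dosages)
  if (marker$degenerate) {
    g <- as.integer(round(dosages))
    probs <- matrix(0, n, 3L)
    probs[cbind(seq_len(n), g + 1L)] <- 1
    return(structure(list(probs = probs,
                          mode_used = rep("boundary", n)),
                     class = "sampled_probs"))
  }
  if (mode == "auto") mode <- choose_mode(marker)
  tag <- rep(mode, n)
  tag[pmin(dosages, 2 - dosages) < 1e-9] <- "boundary"
  if (mode == "approximation") {
    probs <- dosage_approximation(dosages)
  } else {
    p1 <- sample_f1_cond(marker$alpha, dosages)
    f2 <- (dosages - p1) / 2
    probs <- unname(cbind(pmax(1 - p1 - f2, 0), p1, f2))
  }
  structure(list(probs = probs, mode_used = tag), class = "sampled_probs")
}

#' EM-LRT on dosages via conditional probability sampling (scenario II)
#'
#' Reconstructs one posterior-probability row per sample from its dosage
#' ([sample_probs_from_dosage()]) and applies the EM likelihood-ratio
#' test to the reconstructed matrix.
#'
#' @param dosages dosage vector in `[0, 2]`.
#' @param cohort a [cohort_data()].
#' @param marker optional [make_marker()]; when `NULL` it is built from
#'   `rsq` and `maf` (MAF estimated as `mean(dosages)/2` if missing,
#'   with a warning).
#' @param rsq,maf marker information used when `marker` is `NULL`.
#' @param settings EM settings as in [emlrt_prob_test()].
#' @param mode reconstruction mode, see [sample_probs_from_dosage()].
#' @param seed integer seed for the conditional draw (recorded in the
#'   diagnostics for reproducibility).
#' @return An `assoc_result` with method tag `"emlrt_dose"`.
#' @export
emlrt_dose_test <- function(dosages, cohort, marker = NULL, rsq = NULL,
                            maf = NULL, settings = list(), mode = "auto",
                            seed = NULL) {
  if (is.null(marker)) {
    if (is.null(rsq) || !is.numeric(rsq) || rsq <= 0)
      stop("emlrt_dose_test: supply the marker's imputation quality ",
           "(marker= or rsq=); dosage-only testing requires it")
    if (is.null(maf)) {
      maf <- mean(dosages) / 2
      warning("emlrt_dose_test: MAF estimated from dosages as mean(D)/2 = ",
              signif(maf, 4))
    }
    if (maf > 0.5) stop("emlrt_dose_test: dosages must be minor-allele coded")
    marker <- make_marker(maf, min(rsq, 1))
  }
  sp <- sample_probs_from_dosage(dosages, marker, mode = mode, seed = seed)
  res <- emlrt_prob_test(sp$probs, cohort, settings)
  res$method <- "emlrt_dose"
  res$diagnostics$mode <- sp$mode_used[1]
  res$diagnostics$seed <- seed
  res
}
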