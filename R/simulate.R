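#' @title Hierarchical simulator of imputed genotype data
#' @description
#' Three-stage generative model for per-marker imputed data at a target
#' minor allele frequency (MAF) \eqn{q} and imputation quality \eqn{R^2}:
#' (1) posterior genotype probabilities drawn from a Dirichlet distribution
#' whose parameters encode \eqn{q} and \eqn{R^2}; (2) true allele counts
#' drawn per sample from a multinomial with those probabilities; (3) a
#' quantitative trait from a linear model on the true genotype. Under this
#' model the expected probabilities follow Hardy-Weinberg equilibrium (HWE)
#' and the squared correlation between imputed dosage and true genotype
#' converges to the target \eqn{R^2}.
#' @name simulate-module
NULL

# Deterministic child seed so probability / genotype / trait stages are
# independently reproducible from one root seed. Kept below 2^31 - 1.
child_seed <- function(seed, stage) {
  as.integer((as.double(seed %% 2147483647L) * 69069 + stage) %% 2147483629)
}

#' Marker information for the Dirichlet model of imputation uncertainty
#'
#' Builds the per-marker description used by the simulator and by the
#' dosage-to-probability sampler. The Dirichlet parameters are
#' \eqn{\alpha_j = c \, p_j^{HWE}} with concentration \eqn{c = (1-R^2)/R^2}
#' and \eqn{p^{HWE} = ((1-q)^2, 2q(1-q), q^2)}. This is the unique
#' symmetric-concentration choice with \eqn{E[f_j] = p_j^{HWE}} and
#' \eqn{Var(f_1) = R^2 \, m(1-m)}, \eqn{m = 2q(1-q)}; it also implies
#' \eqn{cor^2(D, G) = R^2} for dosage \eqn{D = f_1 + 2 f_2}.
#'
#' @param q minor allele frequency, in (0, 0.5].
#' @param rsq imputation quality \eqn{R^2}, in (0, 1]. `rsq = 1` gives a
#'   degenerate marker: sampled probability rows are exact simplex vertices.
#' @return An object of class `marker_info` with fields `q`, `rsq`, `c`,
#'   `alpha` (length-3), `hwe` (length-3) and `degenerate`.
#' @examples
#' m <- make_marker(q = 0.2, rsq = 0.3)
#' m$alpha / sum(m$alpha)  # HWE probabilities
#' @export
make_marker <- function(q, rsq) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q > 0.5)
    stop("make_marker: MAF q = ", q, " outside (0, 0.5]")
  if (!is.numeric(rsq) || length(rsq) != 1L || !is.finite(rsq) ||
      rsq <= 0 || rsq > 1)
    stop("make_marker: imputation R^2 = ", rsq, " outside (0, 1]")
  hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  degenerate <- (rsq == 1)
  cc <- if (degenerate) 0 else (1 - rsq) / rsq
  structure(list(q = q, rsq = rsq, c = cc, alpha = cc * hwe, hwe = hwe,
                 degenerate = degenerate),
            class = "marker_info")
}

#' @export
print.marker_info <- function(x, ...) {
  cat("Imputed marker: MAF =", x$q, ", R^2 =", x$rsq, "\n")
  if (x$degenerate) {
    cat("  degenerate (no imputation uncertainty)\n")
  } else {
    cat("  Dirichlet alpha = (", paste(signif(x$alpha, 4), collapse = ", "),
        "), concentration c =", signif(x$c, 4), "\n")
  }
  invisible(x)
}

#' Sample posterior genotype probabilities for a marker
#'
#' Draws `n` independent rows from the marker's Dirichlet distribution
#' (via normalized Gamma variates). For a degenerate marker (`rsq = 1`)
#' rows are simplex vertices drawn with HWE frequencies.
#'
#' @param marker a [make_marker()] object.
#' @param n number of samples.
#' @param seed optional integer seed (set before drawing when supplied).
#' @return An `n` x 3 matrix; rows sum to 1.
#' @examples
#' p <- sample_probs(make_marker(0.2, 0.3), 5, seed = 1)
#' rowSums(p)
#' @export
sample_probs <- function(marker, n, seed = NULL) {
  stopifnot(inherits(marker, "marker_info"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (marker$degenerate) {
    g <- sample_vertex(marker$hwe, n)
    F <- matrix(0, n, 3)
    F[cbind(seq_len(n), g + 1L)] <- 1
  } else {
    F <- matrix(rgamma(3L * n, shape = rep(marker$alpha, each = n)), n, 3)
    # Gamma(shape) underflows to 0 for very small shapes; a whole zero row
    # is then resolved to the vertex with the largest alpha.
    s <- rowSums(F)
    bad <- which(s == 0)
    if (length(bad)) {
      F[bad, which.max(marker$alpha)] <- 1
      s[bad] <- 1
    }
    F <- F / s
  }
  F
}

# One multinomial(1, p) index in {0,1,2} per row of a probability matrix.
sample_vertex <- function(p, n) {
  if (is.matrix(p)) {
    u <- runif(nrow(p))
    as.integer((u > p[, 1L]) + (u > p[, 1L] + p[, 2L]))
  } else {
    u <- runif(n)
    as.integer((u > p[1L]) + (u > p[1L] + p[2L]))
  }
}

#' Sample true genotypes given posterior probabilities
#'
#' One multinomial trial per sample: \eqn{P(G_i = j) = f_{ij}}. As the
#' sample grows, \eqn{cor^2(D, G)} converges to the marker's \eqn{R^2}.
#'
#' @param probs `n` x 3 probability matrix (rows sum to 1).
#' @param seed optional integer seed.
#' @return Integer vector of minor-allele counts in `{0, 1, 2}`.
#' @export
sample_genotypes <- function(probs, seed = NULL) {
  stopifnot(is.matrix(probs), ncol(probs) == 3L)
  if (!is.null(seed)) set.seed(seed)
  sample_vertex(probs, nrow(probs))
}

#' Simulation configuration for the trait stage
#'
#' @param n sample count (>= 10).
#' @param q,rsq marker MAF and imputation quality (see [make_marker()]).
#' @param beta0 intercept (trait units).
#' @param beta1 per-minor-allele genetic effect (trait units).
#' @param gamma covariate effects (length K; empty for no covariates).
#' @param sigma2 residual variance (> 0).
#' @param seed root RNG seed; the three stages use derived child seeds.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 2000, q = 0.05, rsq = 0.1, beta0 = 0, beta1 = 0,
                       gamma = numeric(0), sigma2 = 1, seed = 1L) {
  if (sigma2 <= 0) stop("sim_config: sigma2 must be > 0, got ", sigma2)
  if (n < 10) stop("sim_config: n must be >= 10, got ", n)
  structure(list(n = as.integer(n), q = q, rsq = rsq, beta0 = beta0,
                 beta1 = beta1, gamma = as.numeric(gamma), sigma2 = sigma2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a quantitative trait from true genotypes
#'
#' \eqn{y_i = \beta_0 + \beta_1 G_i + \gamma' z_i + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0, \sigma^2)} iid. Covariates (when
#' `length(cfg$gamma) > 0`) are generated iid standard normal.
#'
#' @param g integer genotype vector (length `cfg$n`).
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return A list with `y` (length-n trait) and `z` (n x K covariate
#'   matrix, K possibly 0).
#' @export
sample_trait <- function(g, cfg, seed = NULL) {
  stopifnot(length(g) == cfg$n)
  if (cfg$sigma2 <= 0) stop("sample_trait: sigma2 must be > 0")
  if (!is.null(seed)) set.seed(seed)
  K <- length(cfg$gamma)
  z <- matrix(rnorm(cfg$n * K), cfg$n, K)
  mu <- cfg$beta0 + cfg$beta1 * g
  if (K > 0) mu <- mu + drop(z %*% cfg$gamma)
  list(y = mu + rnorm(cfg$n, sd = sqrt(cfg$sigma2)), z = z)
}

#' Run the full three-stage simulator for one marker
#'
#' @param cfg a [sim_config()].
#' @return A list with `marker`, `probs` (n x 3), `dosage` (length n),
#'   `g` (true genotypes), `y`, `z`.
#' @examples
#' sim <- simulate_marker_data(sim_config(n = 500, q = 0.2, rsq = 0.5,
#'                                        beta1 = 0.3, seed = 7))
#' cor(sim$dosage, sim$g)^2  # near 0.5 for large n
#' @export
simulate_marker_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  marker <- make_marker(cfg$q, cfg$rsq)
  probs <- sample_probs(marker, cfg$n, seed = child_seed(cfg$seed, 1L))
  g <- sample_genotypes(probs, seed = child_seed(cfg$seed, 2L))
  tr <- sample_trait(g, cfg, seed = child_seed(cfg$seed, 3L))
  list(marker = marker, probs = probs, dosage = dosage_from_probs(probs),
       g = g, y = tr$y, z = tr$z)
}

#' Imputed dosage from posterior probabilities
#'
#' @param probs `n` x 3 probability matrix.
#' @return Length-n vector \eqn{D_i = f_{i1} + 2 f_{i2}} in `[0, 2]`.
#' @export
dosage_from_probs <- function(probs) {
  probs[, 2L] + 2 * probs[, 3L]
}
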