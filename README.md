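# emlrt

Quantitative-trait association testing at **imputed** genetic variants,
with imputation uncertainty modelled explicitly.

Imputation software reports, per sample, posterior probabilities
(f₀, f₁, f₂) of carrying 0/1/2 copies of the minor allele, usually
summarized into the dosage D = f₁ + 2f₂ ∈ [0, 2]. The standard
post-imputation test regresses the trait on D and loses power at rare or
poorly imputed variants. `emlrt` instead fits the mixture of regressions

  y_i = β₀ + β₁ G_i + γ′z_i + ε_i,  ε_i ~ N(0, σ²),  G_i ∈ {0, 1, 2} latent,

with observed-data likelihood L(θ) = Π_i Σ_g f_ig φ(y_i; β₀ + β₁g + γ′z_i, σ²),
maximized by an expectation–maximization algorithm, and tests β₁ = 0 by a
1-df likelihood-ratio test (LRS = 2(ℓ₁ − ℓ₀) referred to χ²₁). Two input
scenarios are supported:

* **EM-LRT-Prob** — posterior probabilities available (`emlrt_prob_test()`);
* **EM-LRT-Dose** — dosages only (`emlrt_dose_test()`): genotype
  probabilities are first re-sampled from their conditional distribution
  given the dosage under a Dirichlet model of imputation uncertainty
  (with a fast dosage-approximation path below tabulated MAF cutoffs),
  then tested by the same EM-LRT.

Baselines with the same null model: the standard dosage regression
(`dosage_test()`), the simplex-maximized mixture fit (`mixture_test()`,
numerically identical to the EM fit but slower), and the true-genotype
regression (`truth_test()`, simulations only). A hierarchical simulator
(`simulate_marker_data()`) generates probabilities, genotypes, dosages
and traits calibrated to any target minor allele frequency and
imputation quality R² (squared dosage–genotype correlation), and
Monte-Carlo drivers (`run_type1()`, `run_power()`, `inflation_ttest()`,
`mse_calibration()`, `spearman_concordance()`) reproduce the method's
benchmark studies. Readers ingest VCF (DS/GP FORMAT fields), MaCH-style
dosage/probability text files and phenotype tables; a post-imputation
quality filter (`apply_quality_filter()`, default R² > 0.1) implements
the recommended usage policy. Intended users: statistical geneticists
analysing imputed GWAS data, especially low-frequency or low-quality
variants.

## Worked example

Simulate one poorly imputed rare marker (n = 2000, MAF 0.05, R² 0.3)
with a genuine effect β₁ = 0.4, and test it four ways:

```r
library(emlrt)
sim <- simulate_marker_data(sim_config(n = 2000, q = 0.05, rsq = 0.3,
                                       beta1 = 0.4, seed = 42))
co <- cohort_data(sim$y)
emlrt_prob_test(sim$probs, co)
#> emlrt_prob association test: LRS = 4.7693 (df = 1), p = 0.02897, beta1 = 0.2967
emlrt_dose_test(sim$dosage, co, marker = sim$marker, seed = 7)
#> emlrt_dose association test: LRS = 4.6004 (df = 1), p = 0.03196, beta1 = 0.2865
dosage_test(sim$dosage, co)
#> dosage association test: LRS = 4.6659 (df = 1), p = 0.03077, beta1 = 0.2913
truth_test(sim$g, co)
#> truth association test: LRS = 24.3309 (df = 1), p = 8.113e-07, beta1 = 0.3676
```

The effect estimates from the imputed-data tests are attenuated toward
zero (≈0.29 vs the true-genotype 0.37) and their evidence is far weaker
than the truth-based test — the information genuinely lost to
imputation error at R² = 0.3. The EM-LRT's advantage over the dosage
test grows as R² drops; at R² = 0.1 and a genome-wide-style threshold
the power gap is ~20 percentage points (see the benchmark below).

File-based analysis mirrors the same calls: `read_vcf()` /
`read_mach_dose()` / `read_pheno()` feed `emlrt_scan()`, which emits one
row per marker (`marker, n, maf, method, beta1_hat, lrs, df, pvalue,
n_iter, converged, flipped`). A command-line wrapper with subcommands
`simulate`, `sample-probs`, `test` and `benchmark` is installed at
`inst/cli/emlrt.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/emlrt.R", package="emlrt"))')" \
  test --vcf chr16.vcf --pheno pheno.tsv --trait TRAIT \
  --method emlrt-prob --rsq-min 0.1 --out results.tsv
```

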