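# trivarmix

Trivariate causal mixture models for polygenic overlap from GWAS summary
statistics.

## What it does

Many complex traits and diseases share causal genetic variants, often with
mixed effect directions that leave the genetic correlation near zero.
Causal mixture models quantify this *polygenic overlap* directly.  For a
**triad** of phenotypes, pairwise analyses cannot determine how the overlap
is organized: the same three pairwise overlaps are compatible with a common
"core" shared by all three phenotypes, a "ring" of pairwise-only sharing,
and everything in between.  `trivarmix` is for statistical geneticists who
want to resolve the full seven-region overlap pattern of three phenotypes
from GWAS summary statistics plus an LD reference panel.

The model: direct effects of each variant follow an eight-component
Gaussian mixture (null; phenotype-specific with weights π₁, π₂, π₃;
pair-specific π₁₂, π₁₃, π₂₃; triple π₁₂₃), with per-phenotype effect-size
variances σᵢ² and correlations ρᵢⱼ inside pairwise overlaps.  Observed
z-scores are LD-weighted sums of effects,

    z_ij = Σ_k √(N_i h_k) · r_jk · β_ik + ε_j,   ε ~ N(0, Σ0),

with heterozygosity h_k = 2p(1−p), allelic correlation r_jk and a residual
covariance Σ0 (variances σ₀ᵢ², correlations ρ₀ᵢⱼ).  Per-variant densities
are computed by numerically inverting the characteristic function
(trapezoidal rule, with an exact closed form for the all-null term and for
far-tail variants), and the 19 free parameters are estimated stepwise —
univariate, then bivariate with univariate parameters frozen, then a
bounded one-dimensional fit of π₁₂₃ — by maximizing a composite likelihood
over an LD-pruned template of variants.  The package also computes the
**naive expectation**: the maximum-entropy pattern consistent with the
univariate and bivariate quantities alone, the natural null against which
a fitted trivariate pattern is compared.

Everything needed to exercise the method without real data is included:
block-LD genotype simulation, scenario-based causal-set designs ("core",
"ring", "equilibrium"), phenotype + association-statistic generation, and a
direct model-level z-score sampler.

## Worked example

Feasibility bounds and the naive expectation from six numbers:

```r
library(trivarmix)
tri_overlap_bounds(pi_u = c(0.002, 0.002, 0.002),
                   pi_b = c(0.001, 0.001, 0.001))
#> $lower [1] 0        $upper [1] 0.001
max_entropy_tri_overlap(c(0.002, 0.002, 0.002),
                        c(0.001, 0.001, 0.001))$pi123_naive
#> [1] 0.0005
```

A reduced-scale stepwise fit on data simulated from the model under a
"core" design (20,000-variant block-LD panel, polygenicity 0.01 per
phenotype with the full overlap in the triple region, h² = 0.4,
N = 100,000; a few minutes on one CPU):

```r
ref  <- simulate_block_reference(20000, block_size = 10,
                                 within_block_r = 0.7, seed = 1)
sig2 <- discoverability_for_h2(h2 = 0.4, pi_u = 0.01, ref)
uni   <- replicate(3, univariate_params(0.01, sig2, 1), simplify = FALSE)
pairs <- replicate(3, pair_params(0.005, 0, 0), simplify = FALSE)
truth <- trivariate_params(uni, pairs, 0.005)  # core: triple overlap only
z <- simulate_z_from_model(ref, truth, n = 1e5, seed = 2)

harm <- structure(list(idx = 1:20000, z = z, n = matrix(1e5, 20000, 3),
                       info = NULL), class = "harmonized_sumstats")
cfg  <- qc_config(n_random = 2500, rand_prune_seed = 1)
filt <- qc_filter(harm, cfg, ref)
tpl  <- build_template(ref, filt, prune_and_subset(filt, ref, cfg))
run  <- fit_triad(tpl, options = fit_options(maxit = 100, restarts = 1,
                                             tri_max_variants = 800))
print(run)
#> Stepwise mixture fit (seed NA)
#> Trivariate overlap pattern (fractions of panel variants):
#>          pi1          pi2          pi3         pi12         pi13         pi23
#> 0.0047301658 0.0054729188 0.0056991805 0.0003912653 0.0003374074 0.0000000000
#>        pi123          pi0
#> 0.0048424465 0.9785266156
```

The fit recovers the core structure: phenotype-specific masses near the
generative 0.005, pairwise-only regions near zero, and π̂₁₂₃ ≈ 0.0048.
The naive maximum-entropy expectation for the *same* fitted univariate and
bivariate quantities puts only 0.0024 in the triple overlap —
under-estimating the core by half, which is exactly why the trivariate step
is needed:

```r
naive <- max_entropy_tri_overlap(
  vapply(run$params$uni, `[[`, 0, "pi_u"),
  vapply(run$params$pairs, `[[`, 0, "pi_b"))
c(fitted = run$params$pi123, naive = naive$pi123_naive)
#>      fitted       naive
#> 0.004842446 0.002393698
pattern_percentages(run$pattern)   # Euler-diagram percentages
#>   pi1   pi2   pi3  pi12  pi13  pi23 pi123
#>    22    25    27     2     2     0    23
```

For real data the entry point is a JSON configuration (three summary-
statistics files, an LD reference built with `compute_ld_from_genotypes()` /
`parse_plink_ld_text()` + `build_reference()`, QC thresholds, seeds) run
through `run_pipeline()`, or the CLI at `inst/cli/trivarmix.R` with verbs
`fit`, `simulate`, `naive` and `ld`.  Multi-seed runs (`multi_run()`) are
summarized by `select_representative()` and exported — per-run parameter
JSON, a summary JSON with model/naive percentage tables, and an Euler
area specification — via `export_results()`.

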