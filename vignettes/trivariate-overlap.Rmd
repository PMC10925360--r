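---
title: "Quantifying polygenic overlap among three phenotypes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polygenic overlap among three phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trivarmix)
```

## The problem

Two complex phenotypes can share a large fraction of their causal genetic
variants even when their genetic correlation is near zero, because shared
variants may act with mixed effect directions.  Causal mixture models
quantify this *polygenic overlap* from GWAS summary statistics.  For a
triad of phenotypes, pairwise analyses are not enough: many different
three-way configurations (a common "core" of variants shared by all three,
a "ring" of pairwise-only sharing, or anything in between) are compatible
with the same three pairwise overlaps.  `trivarmix` fits a trivariate
causal mixture model that resolves the full seven-region overlap pattern,
and contrasts it with the *naive expectation* — the maximum-entropy pattern
consistent with the univariate and bivariate quantities alone.

## The model

Direct (per-allele) effects of variant $j$ on the three standardized
phenotypes follow an eight-component Gaussian mixture: with probability
$\pi_0$ the variant affects nothing; with probabilities
$\pi_1,\pi_2,\pi_3$ it affects exactly one phenotype; with
$\pi_{12},\pi_{13},\pi_{23}$ exactly one pair; with $\pi_{123}$ all three.
Effect sizes in each component are zero-mean Gaussian with per-phenotype
variances $\sigma_i^2$ (the *discoverability*, assumed not to depend on
which other phenotypes a variant affects), and correlations
$\rho_{ij}$ inside each pairwise overlap.  The covariance blocks therefore
have zero rows/columns for unaffected phenotypes and off-diagonal entries
$\rho_{ij}\sigma_i\sigma_j$ where both $i$ and $j$ are affected
(`build_mixture_components()`).

Observed z-scores arise through linkage disequilibrium (LD):

$$ z_{ij} \;=\; \sum_{k \in \mathrm{LD}(j)} \sqrt{N_{ij}\,h_k}\; r_{jk}\,
   \beta_{ik} \;+\; \epsilon_{j}, \qquad
   \epsilon \sim \mathcal{N}(0, \Sigma_0), $$

where $N_{ij}$ is the GWAS sample size, $h_k = 2p_k(1-p_k)$ the
heterozygosity of variant $k$, $r_{jk}$ the allelic correlation, and
$\Sigma_0$ a residual covariance with variances $\sigma_{0i}^2$ and
correlations $\rho_{0ij}$ capturing uncontrolled inflation and sample
overlap between studies.  Only $r_{jk}^2$ enters the distribution of $z$
(effects are independent and symmetric across variants), which is why the
LD reference stores squared correlations.

The nineteen free parameters are estimated stepwise by maximizing a
composite likelihood — the sum of per-variant log densities over an LD-pruned
template of variants treated as independent:

1. three univariate fits over $(\pi_i^u, \sigma_i^2, \sigma_{0i}^2)$;
2. three bivariate fits over $(\pi_{ij}^b, \rho_{ij}, \rho_{0ij})$ with the
   univariate parameters frozen;
3. one bounded one-dimensional fit of $\pi_{123}$ with everything else
   frozen.

The seven region masses follow by subtraction
($\pi_{12} = \pi_{12}^b - \pi_{123}$,
$\pi_1 = \pi_1^u - \pi_{12} - \pi_{13} - \pi_{123}$, and permutations), so
the univariate marginals and pairwise overlaps implied by the final pattern
equal the stage estimates exactly.

The implied SNP-heritability of a univariate fit is
$\hat h^2 = \hat\pi^u \hat\sigma^2 \sum_k h_k$ over the panel
(`implied_heritability()`).

## Feasibility and the naive expectation

Given marginals $\pi_i^u$ and pairwise overlaps $\pi_{ij}^b$, the triple
overlap is constrained to
$[\max(0, \pi_{12}^b + \pi_{13}^b - \pi_1^u, \ldots),\;
\min(\pi_{12}^b, \pi_{13}^b, \pi_{23}^b)]$ (`tri_overlap_bounds()`).
The naive expectation picks the $\pi_{123}$ in this interval that
maximizes the Shannon entropy of the seven masses
(`max_entropy_tri_overlap()`).

One definitional point is genuinely open: the entropy could be evaluated on
the seven raw masses (which do not sum to one) or on the masses normalized
by their total.  We normalize.  Only the normalized reading makes the
balanced design — all seven regions equal — the entropy maximizer, which is
the defining property of a "naive" reconstruction (the unnormalized
objective peaks at a different $\pi_{123}$).  With this choice the
identities $\pi_{12}^{naive} + \pi_{123}^{naive} = \pi_{12}^b$ and the
univariate marginals hold exactly.  The search uses golden sections
(absolute tolerance $10^{-9}$), cross-checked against a grid oracle in the
tests; $0\log 0$ is taken as $0$.

## The numerical engine

Each variant's density is the inverse Fourier transform of its
characteristic function

$$ \mathrm{CF}_j(t) = e^{-\tfrac12 t'\Sigma_0 t} \prod_{k}
   \sum_c w_c\, e^{-\tfrac12 r^2_{jk} h_k\, t' D \Sigma_c D t}, \qquad
   D = \mathrm{diag}(\sqrt{N_i}), $$

evaluated by the trapezoidal rule on a fixed symmetric grid
(`z_density()`, `grid_spec()`).  The CF is real and even, so the integral
reduces to a cosine transform over a half grid.  Defaults: one dimension,
step 0.05 and half-width 12 in scaled units; two dimensions, $65^2$ points;
three dimensions, $33^3$ points.

Numerical design choices that matter:

* **Closed-form null term.**  The all-null assignment contributes
  $w_0^{M} \mathcal{N}(z; \Sigma_0)$ — a narrow density whose CF decays
  slowest of all terms and would dominate the truncation error.  It is
  evaluated exactly and subtracted from the CF before inversion, so the
  grid only needs to resolve terms containing at least one causal factor.
* **Grid scaling.**  Per-trait scales $\sqrt{\Sigma_{0,aa}}$ put the
  residual width at one scaled unit; a per-variant scalar
  $s_j \ge 1$ then widens the grid spacing just enough to keep the
  trapezoid rule's aliasing images (spaced $2\pi/\mathrm{step}$ in scaled
  z-units) beyond the evaluation point, capped so the truncation stays
  controlled.  We initially scaled the grid by each variant's *predicted
  total* z standard deviation; that design truncates the null component
  badly whenever causal variance dominates (errors up to ~30% against the
  enumeration oracle) and was replaced by the scheme above, which matches
  the oracle to machine precision.
* **Quantized neighbor terms.**  Inside optimization loops the per-neighbor
  log-mixture factor is tabulated on log-spaced LD-weight levels
  (1024–2048 for one and two dimensions, 128–256 for three) and linearly
  interpolated; `quantize = 0` evaluates exponentials exactly and is the
  default for `z_density()`.
* **Exact tail handling (`tail_z`).**  A grid coarse enough to be
  affordable in three dimensions cannot represent densities at
  $|z| \gtrsim 8$ residual standard deviations, where rare large-effect
  assignments dominate — and those variants carry most of the information
  about $\rho$ and $\pi_{123}$.  For variants beyond `tail_z` (6 in the
  fitting grids) the density is instead computed by exact enumeration over
  assignments with at most two causal neighbors, each a closed-form
  Gaussian.  The omitted $\ge 3$-causal mass is $O((M\bar\pi)^3/6)$,
  negligible at the per-neighbor causal rates where this package operates;
  the hybrid agrees with full enumeration to ~$10^{-5}$ relative on test
  fixtures.  The partition depends only on the data, never on the
  parameters, so the objective stays smooth.
* Densities are floored at $10^{-300}$ before logs; with the default
  $|z| \le 32$ filter an underflow indicates grid truncation and raises an
  error naming the variant.

Per-variant, per-trait sample sizes are collapsed to per-trait scalars
(median over the template) inside the engine; the synthetic data used
throughout has constant $N$, where this is exact.

## Estimation details

Each stage uses a Nelder–Mead simplex on transformed coordinates
($\log \pi$, $\log \sigma^2$, a logistic map of $\sigma_0^2$ into
$[0.8, 2.5]$, a scaled logistic for $\pi^b \in [0, \min \pi^u]$, and
$0.999\tanh$ for correlations), with deterministic perturbed restarts
(`fit_options()`; three restarts by default, fewer in the reduced-scale
validation runs).  Starting points: $\pi = 10^{-3}$, $\sigma^2$ from a
method-of-moments match of the mean $\chi^2$, $\rho = 0$, $\rho_0$ from
the empirical z-score correlation.  The $\pi_{123}$ stage is a bounded
one-dimensional search whose interior optimum is compared against both
boundary values, since the truth frequently sits on a bound.

Two situations need explicit handling:

* **Jointly invalid correlations.**  The three pairwise fits are
  independent, so the fitted $(\rho_{12},\rho_{13},\rho_{23})$ (or the
  $\rho_0$ triplet) need not form a positive semidefinite $3\times 3$
  matrix, in which case the triple-overlap covariance block is invalid.
  The trivariate stage shrinks each triplet minimally toward the identity
  until jointly PSD, leaves the frozen polygenicities untouched, and flags
  the adjustment in the run diagnostics.
* **Unidentifiable $\rho$.**  When the fitted pairwise overlap is zero the
  effect-size correlation is undefined; it is reported as 0 with a
  diagnostic flag.

Multiple independent runs (`multi_run()`) re-derive the optimization
template under different pruning/subsetting seeds; `select_representative()`
reports component-wise medians of the seven masses and the run closest to
that median vector (Euclidean metric by default, ties broken by lowest
seed).  The median vector itself need not be feasible and is flagged
accordingly.

## Quality control and the template

Defaults mirror conventional practice for this model family: variants with
reference-panel MAF below 0.05 are excluded (frequencies always come from
the LD-reference genotypes; the summary-statistic column is only a
fallback), INFO below 0.8 (skipped when absent), $|z| > 32$ in any study,
and the MHC (chr6:25,000,000–34,000,000, 1-based inclusive, hg19).  Random
pruning visits surviving variants in a seed-determined order, keeping each
visited variant unless already removed and removing its neighbors at
$r^2 \ge 0.8$; a random subset of up to 500,000 survivors forms the
template.  One pseudo-random stream, seeded by `rand_prune_seed`, drives
both steps, so a seed fully determines the template.

## Synthetic data

The generator reproduces the validation design at configurable scale:

* `scenario_spec()` encodes the three canonical designs at polygenicity
  0.002 and SNP-heritability 0.4 per phenotype — "core" (triple overlap
  only; half of each phenotype's causal set shared with both others),
  "ring" (pairwise overlaps only), and "equilibrium" (all seven regions
  equal).
* `assign_causal_sets()` sizes regions by rounding (half away from zero),
  giving per-phenotype totals `round(panel * pi_u)` priority so the
  printed causal-set counts are met exactly; residual rounding is absorbed
  into the phenotype-specific regions.
* `generate_block_genotypes()` draws hard-call dosages in Hardy–Weinberg
  proportions with block LD from a shared latent haplotype factor, with the
  loading calibrated by root finding on the Gaussian-copula binary
  correlation so the mean within-block dosage correlation matches the
  target (0.7 by default; with heterogeneous allele frequencies the
  attainable correlation saturates and the maximum loading is used).
* `simulate_phenotypes_and_gwas()` adds standard-normal effects on causal
  variants, scales the genetic score to the target $h^2$, adds Gaussian
  noise of variance $\mathrm{var_g}(1-h^2)/h^2$ (orthogonalized against
  the genetic score so the realized ratio equals $h^2$ exactly), and runs
  per-variant simple linear regression.  Covariates are omitted: synthetic
  phenotypes have no confounding structure.
* `simulate_z_from_model()` draws z-scores directly from the mixture model
  over an LD reference — the exact generative counterpart of the
  likelihood, used as the fast oracle for recovery tests.

What the generator does *not* emulate: realistic MAF–LD coupling,
population stratification, long-range LD beyond blocks, case-control
ascertainment, and annotation-dependent effect sizes.  Passing recovery
tests on these data therefore validates the estimator under the model's
own assumptions, not robustness to their violation.

## Problem sizes in the validation suite

The full-scale design (12.9M variants, 500k-variant templates, 16 runs)
is far beyond a desktop; the test-suite and the acceptance script run the
same procedures at reduced scale, chosen so the whole suite completes on
one CPU in tens of minutes:

* recovery of polygenicity and heritability: 100,000-variant block panel
  (blocks of 10 at within-block correlation 0.7), $N = 10^5$, eight
  replicates, 10,000-variant templates, one-dimensional grid of half-width
  9;
* scenario discrimination: the same panel, eight seeds per scenario,
  1,800-variant templates (500 in the three-dimensional stage), the
  $33^3$ grid with `tail_z = 6`;
* individual-level end-to-end checks: 12,000 variants by 3,000
  individuals at polygenicity 0.005.

The generative parameters themselves ($\pi = 0.002$, $h^2 = 0.4$,
$N = 10^5$, equal across phenotypes) follow the validation design.  At
these reduced panel sizes each causal variant carries far more variance
than at full scale, which is precisely the regime that motivated the
closed-form null term and the exact tail handling above.

## Known limitations

* The composite likelihood ignores residual dependence between template
  variants; random pruning at $r^2 < 0.8$ keeps this mild but not zero.
* Pairwise parameters from small templates are noisy, and the triple
  overlap inherits their bounds; representative-run selection across seeds
  is the intended stabilizer.
* The stepwise procedure conditions on earlier stages; errors in the
  univariate step propagate, and $\rho$ can be weakly identified when
  overlaps are small.
* No standard errors are reported for the trivariate step.
* The model assumes effects independent of allele frequency, LD and
  genomic location, and a single discoverability per phenotype.
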