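# Shared simulation fixtures for the heavier tests.  The large block-LD
# reference is built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 100k-variant block-LD panel mirroring the study's scaled simulation design
scaled_panel <- function() {
  cached("panel100k", simulate_block_reference(
    1e5, block_size = 10, within_block_r = 0.7,
    freq_range = c(0.05, 0.5), seed = 99))
}

# generative parameters for a scenario on a given panel: polygenicity 0.002,
# SNP-heritability 0.4 per phenotype, independent effects (rho = rho0 = 0)
scenario_params <- function(scenario, reference, polygenicity = 0.002,
                            h2 = 0.4) {
  m <- unclass(scenario_spec(scenario, polygenicity, h2)$pattern)
  sig2 <- discoverability_for_h2(h2, polygenicity, reference)
  uni <- replicate(3, univariate_params(polygenicity, sig2, 1.0),
                   simplify = FALSE)
  prs <- list(pair_params(m[["pi12"]] + m[["pi123"]], 0, 0),
              pair_params(m[["pi13"]] + m[["pi123"]], 0, 0),
              pair_params(m[["pi23"]] + m[["pi123"]], 0, 0))
  trivariate_params(uni, prs, m[["pi123"]])
}

# model-level z-scores -> QC'd template, mirroring the analysis defaults
simulated_template <- function(reference, params, sim_seed, prune_seed,
                               n_template, n_gwas = 1e5) {
  z <- simulate_z_from_model(reference, params, n_gwas, seed = sim_seed)
  V <- nrow(reference$variants)
  harm <- structure(list(idx = seq_len(V), z = z,
                         n = matrix(n_gwas, V, 3), info = NULL),
                    class = "harmonized_sumstats")
  qc <- qc_config(n_random = n_template, rand_prune_seed = prune_seed)
  filt <- suppressMessages(qc_filter(harm, qc, reference))
  idx <- suppressMessages(prune_and_subset(filt, reference, qc))
  build_template(reference, filt, idx)
}

# reduced integration grids and optimizer budgets used by the scaled
# recovery and scenario tests (problem sizes documented in the vignette)
scaled_grids <- function() {
  list(grid_spec(1, half_width = 9, quantize = 2048),
       grid_spec(2, step = 0.6, half_width = 9, quantize = 1024,
                 tail_z = 6),
       grid_spec(3, quantize = 128, tail_z = 6))
}

scaled_options <- function(tri_max = 600) {
  fit_options(maxit = 80, restarts = 0, tri_rel_tol = 0.02,
              tri_max_variants = tri_max)
}
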