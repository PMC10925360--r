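# Scenario designs, causal-set assignment, block-LD genotypes, phenotype
# and GWAS generation, and the model-level z-score simulator.

test_that("causal sets honor the scenario designs and totals", {
  core <- scenario_spec("core", 0.002, 0.4)
  sets <- assign_causal_sets(core, 1e6, seed = 2)
  # per-phenotype totals and the exact half split on a divisible panel
  for (ph in sets$phenotypes) expect_length(ph, 2000L)
  expect_length(sets$regions$pi123, 1000L)
  expect_equal(length(sets$regions$pi123) / length(sets$phenotypes[[1]]),
               0.5)
  # regions are disjoint and unions are correct
  all_idx <- unlist(sets$regions)
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_setequal(sets$phenotypes[[1]],
                  c(sets$regions$pi1, sets$regions$pi123))
  # ring: empty triple, pairwise regions disjoint, each phenotype is the
  # union of its two pairwise regions
  ring <- scenario_spec("ring", 0.002, 0.4)
  rs <- assign_causal_sets(ring, 1e6, seed = 3)
  expect_length(rs$regions$pi123, 0L)
  expect_length(rs$regions$pi1, 0L)
  expect_setequal(rs$phenotypes[[2]], c(rs$regions$pi12, rs$regions$pi23))
  # equilibrium: seven equal regions
  eq <- scenario_spec("equilibrium", 0.002, 0.4)
  es <- assign_causal_sets(eq, 1e6, seed = 4)
  expect_true(all(lengths(es$regions) == 500L))
  # per-region rounding that exceeds the panel is rejected
  big <- scenario_spec("custom", pattern = overlap_pattern(
    0.14, 0.14, 0.14, 0.14, 0.14, 0.14, 0.14))
  expect_error(assign_causal_sets(big, 3, seed = 1), "above 1")
})

test_that("block genotypes have the calibrated LD and HWE structure", {
  g <- generate_block_genotypes(4000, 300, block_size = 10,
                                within_block_r = 0.7, seed = 8)
  G <- g$genotypes
  expect_true(all(G %in% 0:2))
  expect_equal(dim(G), c(4000L, 300L))
  # realized frequencies near the drawn range
  expect_true(all(g$variants$freq > 0.01 & g$variants$freq < 0.6))
  # mean within-block dosage correlation near the target
  cors <- c()
  for (b in 1:30) {
    cols <- ((b - 1) * 10 + 1):(b * 10)
    cc <- cor(G[, cols])
    cors <- c(cors, cc[upper.tri(cc)])
  }
  expect_gt(mean(cors), 0.6)
  expect_lt(mean(cors), 0.8)
  # across blocks: independent
  off <- cor(G[, 10], G[, 11])
  expect_lt(abs(off), 0.06)
  # within_block_r = 0: r2 at the 1/n noise level
  g0 <- generate_block_genotypes(4000, 60, block_size = 10,
                                 within_block_r = 0, seed = 9)
  cc0 <- cor(g0$genotypes[, 1:10])
  expect_lt(mean(cc0[upper.tri(cc0)]^2), 3 / 4000)
})

test_that("phenotype simulation hits the target heritability and GWAS
           statistics behave", {
  set.seed(10)
  g <- cached("geno_sim", generate_block_genotypes(
    3000, 2000, block_size = 10, within_block_r = 0.7, seed = 12))
  spec <- scenario_spec("equilibrium", polygenicity = 0.02, h2 = 0.4)
  sets <- assign_causal_sets(spec, 2000, seed = 13)
  ss <- simulate_phenotypes_and_gwas(g$genotypes, sets$phenotypes, spec,
                                     g$variants, seed = 14)
  expect_equal(attr(ss, "realized_h2"), rep(0.4, 3), tolerance = 0.01)
  expect_equal(ss[[1]]$n[1], 3000)
  # causal variants carry inflated chi-square
  cs <- sets$phenotypes[[1]]
  expect_gt(mean(ss[[1]]$z[cs]^2), 3)
  # null phenotype: mean chi-square near 1
  spec0 <- scenario_spec("custom", h2 = 0,
                         pattern = overlap_pattern(0, 0, 0, 0, 0, 0, 0))
  ss0 <- simulate_phenotypes_and_gwas(g$genotypes,
                                      list(integer(0), integer(0),
                                           integer(0)),
                                      spec0, g$variants, seed = 15)
  m2 <- mean(ss0[[1]]$z^2)
  expect_lt(abs(m2 - 1), 3 * sqrt(2 / 2000) * sqrt(5))  # LD-clustered SE
  # doubling n roughly doubles causal mean chi-square minus one
  g_half <- g$genotypes[1:1500, ]
  vars_half <- g$variants
  vars_half$freq <- colMeans(g_half) / 2
  ss_half <- simulate_phenotypes_and_gwas(g_half, sets$phenotypes, spec,
                                          vars_half, seed = 14)
  ratio <- (mean(ss[[1]]$z[cs]^2) - 1) / (mean(ss_half[[1]]$z[cs]^2) - 1)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})

test_that("model-level z simulator matches its moments and the CF", {
  # all-null: sample covariance of z is Sigma0
  ref <- simulate_block_reference(2e4, block_size = 5,
                                  within_block_r = 0.6, seed = 21)
  uni0 <- replicate(3, univariate_params(0, 1e-4, 1), simplify = FALSE)
  p0 <- trivariate_params(uni0, replicate(3, pair_params(0, 0, 0.3),
                                          simplify = FALSE), 0)
  z0 <- simulate_z_from_model(ref, p0, 1e5, seed = 22)
  S <- cov(z0)
  expect_equal(unname(diag(S)), rep(1, 3), tolerance = 0.05)
  expect_equal(S[1, 2], 0.3, tolerance = 0.05)
  # single trait, no LD: fourth moment matches the two-component mixture
  ref1 <- simulate_block_reference(2e5, block_size = 1, seed = 23)
  sig2 <- 4e-5
  uni <- replicate(3, univariate_params(0.01, sig2, 1), simplify = FALSE)
  p1 <- trivariate_params(uni, replicate(3, pair_params(0, 0, 0),
                                         simplify = FALSE), 0)
  z1 <- simulate_z_from_model(ref1, p1, 5e4, seed = 24)[, 1]
  # z = sqrt(n h) beta + e with beta a scale mixture:
  # E[z^4] = 3 + 6 pi a2 + 3 pi a2^2 per variant, a2 = n h sigma2
  a2 <- 5e4 * ref1$variants$het * sig2
  ez4 <- mean(3 + 6 * 0.01 * a2 + 3 * 0.01 * a2^2)
  expect_equal(mean(z1^4), ez4, tolerance = 0.1 * ez4)
  # empirical E[cos(t z)] matches the analytic CF at a matching context
  ref2 <- simulate_block_reference(3e5, block_size = 1, seed = 31)
  ref2$variants$freq[] <- 0.3
  ref2$variants$het[] <- heterozygosity_from_freq(0.3)
  uni2 <- replicate(3, univariate_params(0.05, sig2, 1), simplify = FALSE)
  p2 <- trivariate_params(uni2, replicate(3, pair_params(0.02, 0, 0),
                                          simplify = FALSE), 0.01)
  z2 <- simulate_z_from_model(ref2, p2, 5e4, seed = 32)[, 1]
  ctx <- variant_context(1, heterozygosity_from_freq(0.3), 5e4)
  comps1 <- build_mixture_components(p2, 1)
  r1 <- residual_covariance(1)
  for (t in c(0.5, 1.2)) {
    mc <- mean(cos(t * z2))
    se <- sd(cos(t * z2)) / sqrt(length(z2))
    expect_lt(abs(characteristic_function(t, ctx, comps1, r1) - mc),
              4 * se)
  }
})

test_that("regression GWAS and the model simulator agree in distribution
           on an LD-free panel", {
  # matching conditions: no LD, shared frequencies, same n, same per-variant
  # causal variance
  set.seed(40)
  n_ind <- 2000; V <- 4000; pi_u <- 0.01; h2 <- 0.08
  g <- generate_block_genotypes(n_ind, V, block_size = 1, seed = 41,
                                freq_range = c(0.2, 0.4))
  spec <- scenario_spec("custom", h2 = h2, pattern = overlap_pattern(
    pi_u, pi_u, pi_u, 0, 0, 0, 0))
  sets <- assign_causal_sets(spec, V, seed = 42)
  ss <- simulate_phenotypes_and_gwas(g$genotypes, sets$phenotypes, spec,
                                     g$variants, seed = 43)
  # model z with the same causal variance: sigma2 from h2 over causal count
  vars <- g$variants
  rec <- data.frame(id_a = character(0), id_b = character(0),
                    r2 = numeric(0))
  ref <- build_reference(rec, vars)
  sig2 <- discoverability_for_h2(h2, pi_u, ref)
  uni <- replicate(3, univariate_params(pi_u, sig2, 1), simplify = FALSE)
  pm <- trivariate_params(uni, replicate(3, pair_params(0, 0, 0),
                                         simplify = FALSE), 0)
  zm <- simulate_z_from_model(ref, pm, n_ind, seed = 44)[, 1]
  ks <- suppressWarnings(ks.test(ss[[1]]$z, zm))
  expect_gt(ks$p.value, 0.01)
})

test_that("implied heritability inverts the discoverability formula", {
  ref <- simulate_block_reference(5000, seed = 50)
  sig2 <- discoverability_for_h2(0.4, 0.002, ref)
  expect_equal(implied_heritability(univariate_params(0.002, sig2, 1), ref),
               0.4, tolerance = 1e-12)
})
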