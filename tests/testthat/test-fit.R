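# Stepwise estimation: stage-level recoveries on model-simulated data,
# freezing identities, representative-run selection and multi-seed runs.

small_ref <- function() {
  cached("ref_fit_small", simulate_block_reference(
    2e4, block_size = 10, within_block_r = 0.7, seed = 301))
}

tpl_from <- function(ref, params, sim_seed, prune_seed = 1,
                     n_template = 1500) {
  simulated_template(ref, params, sim_seed, prune_seed, n_template)
}

test_that("univariate fit recovers null data and residual variance", {
  ref <- small_ref()
  # null model: z ~ N(0, 1)
  uni0 <- replicate(3, univariate_params(0, 1e-4, 1), simplify = FALSE)
  p0 <- trivariate_params(uni0, replicate(3, pair_params(0, 0, 0),
                                          simplify = FALSE), 0)
  tpl <- tpl_from(ref, p0, sim_seed = 71)
  f <- suppressWarnings(fit_univariate(tpl, 1,
                                       grid_spec(1, half_width = 9,
                                                 quantize = 2048),
                                       scaled_options()))
  h2hat <- implied_heritability(f$params, ref)
  expect_true(f$params$pi_u < 1e-5 || h2hat < 0.02)
  expect_equal(f$params$sigma0_sq, 1, tolerance = 0.1)
  # objective never worse than the start
  expect_lte(f$value, f$diagnostics$start_value)
  # sigma0 recovery on signal data, median over 3 replicates
  sig2 <- discoverability_for_h2(0.3, 0.002, ref)
  uni <- replicate(3, univariate_params(0.002, sig2, 1), simplify = FALSE)
  p <- trivariate_params(uni, replicate(3, pair_params(0.001, 0, 0),
                                        simplify = FALSE), 5e-4)
  s0 <- vapply(1:3, function(r) {
    tplr <- tpl_from(ref, p, sim_seed = 80 + r, prune_seed = r)
    fit_univariate(tplr, 1, grid_spec(1, half_width = 9, quantize = 2048),
                   scaled_options())$params$sigma0_sq
  }, 0)
  expect_gte(median(s0), 0.9)
  expect_lte(median(s0), 1.1)
})

test_that("bivariate fit separates genetic overlap from residual
           correlation", {
  ref <- small_ref()
  g2 <- grid_spec(2, step = 0.6, half_width = 9, quantize = 1024,
                  tail_z = 6)
  g1 <- grid_spec(1, half_width = 9, quantize = 2048)
  opt <- fit_options(maxit = 150, restarts = 1, restart_maxit = 60)
  # polygenicity 0.01 here: enough causal variants on this small panel for
  # the pair parameters to be identifiable
  sig2 <- discoverability_for_h2(0.4, 0.01, ref)
  # independent traits, shared samples: pi_b = 0, rho0 = 0.3
  uni <- replicate(3, univariate_params(0.01, sig2, 1), simplify = FALSE)
  p_ind <- trivariate_params(uni, replicate(3, pair_params(0, 0, 0.3),
                                            simplify = FALSE), 0)
  tpl <- tpl_from(ref, p_ind, sim_seed = 91, n_template = 2500)
  uf <- lapply(1:2, function(i) fit_univariate(tpl, i, g1, opt)$params)
  bf <- fit_bivariate_pair(tpl, c(1, 2), uf, g2, opt)
  expect_lt(bf$params$pi_b, 0.35 * min(uf[[1]]$pi_u, uf[[2]]$pi_u))
  expect_lt(abs(bf$params$rho0 - 0.3), 0.1)
  # complete overlap with positive effect correlation
  p_full <- trivariate_params(
    uni, replicate(3, pair_params(0.01, 0.5, 0), simplify = FALSE), 0.01)
  tpl2 <- tpl_from(ref, p_full, sim_seed = 92, n_template = 2500)
  uf2 <- lapply(1:2, function(i) fit_univariate(tpl2, i, g1, opt)$params)
  bf2 <- fit_bivariate_pair(tpl2, c(1, 2), uf2, g2, opt)
  upper2 <- min(uf2[[1]]$pi_u, uf2[[2]]$pi_u)
  expect_gt(bf2$params$pi_b, 0.5 * upper2)
  expect_gt(bf2$params$rho, 0)
  expect_true(bf2$diagnostics$rho_defined)
  # empty upper bound: rho flagged undefined
  uf3 <- list(univariate_params(0, 1e-4, 1), uf2[[2]])
  bf3 <- fit_bivariate_pair(tpl2, c(1, 2), uf3, g2,
                            fit_options(maxit = 30, restarts = 0))
  expect_false(bf3$diagnostics$rho_defined)
  expect_equal(bf3$params$rho, 0)
})

test_that("trivariate step respects bounds and degenerate cases", {
  ref <- small_ref()
  sig2 <- discoverability_for_h2(0.4, 0.002, ref)
  uni <- replicate(3, univariate_params(0.002, sig2, 1), simplify = FALSE)
  p <- trivariate_params(uni, replicate(3, pair_params(0.001, 0, 0),
                                        simplify = FALSE), 5e-4)
  tpl <- tpl_from(ref, p, sim_seed = 93, n_template = 800)
  # degenerate bounds force the value without optimization
  uni_d <- list(univariate_params(0.005, sig2, 1),
                univariate_params(0.006, sig2, 1),
                univariate_params(0.004, sig2, 1))
  pairs_d <- list(pair_params(0.004, 0, 0), pair_params(0.003, 0, 0),
                  pair_params(0.002, 0, 0))
  tf <- suppressMessages(fit_tri_overlap(tpl, uni_d, pairs_d,
                                         grid_spec(3, quantize = 128, tail_z = 6),
                                         scaled_options()))
  expect_equal(tf$pi123, 0.002)
  expect_equal(tf$bounds$lower, tf$bounds$upper)
  # fitted value stays inside the bounds on ordinary inputs
  uni_f <- replicate(3, univariate_params(0.002, sig2, 1),
                     simplify = FALSE)
  pairs_f <- replicate(3, pair_params(8e-4, 0.1, 0), simplify = FALSE)
  tf2 <- fit_tri_overlap(tpl, uni_f, pairs_f, grid_spec(3, quantize = 128, tail_z = 6),
                         scaled_options())
  expect_gte(tf2$pi123, tf2$bounds$lower)
  expect_lte(tf2$pi123, tf2$bounds$upper)
})

test_that("stepwise freezing keeps marginals and overlaps exact", {
  ref <- small_ref()
  sig2 <- discoverability_for_h2(0.4, 0.002, ref)
  uni <- replicate(3, univariate_params(0.002, sig2, 1), simplify = FALSE)
  p <- trivariate_params(uni, replicate(3, pair_params(0.001, 0, 0),
                                        simplify = FALSE), 5e-4)
  tpl <- tpl_from(ref, p, sim_seed = 94, n_template = 1000)
  run <- suppressMessages(fit_triad(tpl, scaled_grids(),
                                    scaled_options(tri_max = 500),
                                    seed = 1L))
  m <- unclass(run$pattern)
  # univariate marginals implied by the final pattern equal the univariate
  # stage estimates exactly; pairwise overlaps equal the bivariate stage
  for (k in 1:3) {
    pairkey <- c("pi12", "pi13", "pi23")[k]
    expect_equal(unname(m[[pairkey]] + m[["pi123"]]),
                 run$params$pairs[[k]]$pi_b, tolerance = 1e-15)
  }
  pu_back <- c(m[["pi1"]] + m[["pi12"]] + m[["pi13"]] + m[["pi123"]],
               m[["pi2"]] + m[["pi12"]] + m[["pi23"]] + m[["pi123"]],
               m[["pi3"]] + m[["pi13"]] + m[["pi23"]] + m[["pi123"]])
  expect_equal(unname(pu_back), vapply(run$params$uni, `[[`, 0, "pi_u"),
               tolerance = 1e-15)
})

test_that("representative selection takes medians and breaks ties by
           seed", {
  mk_run <- function(seed, pi123) {
    structure(list(seed = seed,
                   pattern = derive_pattern(c(0.002, 0.002, 0.002),
                                            c(0.001, 0.001, 0.001), pi123)),
              class = "mix_run")
  }
  # single run: itself, deviation zero
  one <- select_representative(list(mk_run(4, 5e-4)))
  expect_equal(one$representative$seed, 4)
  expect_equal(one$deviations, 0)
  # three runs differing in one component: median is the middle run
  runs <- list(mk_run(1, 1e-4), mk_run(2, 2e-4), mk_run(3, 3e-4))
  sel <- select_representative(runs)
  expect_equal(sel$representative$seed, 2)
  expect_equal(unname(sel$median_pattern[["pi123"]]), 2e-4)
  # identical runs: deterministic tie-break by lowest seed
  same <- list(mk_run(9, 2e-4), mk_run(2, 2e-4), mk_run(5, 2e-4))
  expect_equal(select_representative(same)$representative$seed, 2)
  expect_error(select_representative(list()), "no successful")
  # an infeasible median is reported as such
  bad <- list(mk_run(1, 0), mk_run(2, 0))
  bad[[1]]$pattern <- structure(c(pi1 = 0.001, pi2 = 0.001, pi3 = 0.002,
                                  pi12 = 0.001, pi13 = 0, pi23 = 0,
                                  pi123 = 0, pi0 = 0.995),
                                class = "overlap_pattern")
  sel2 <- select_representative(bad)
  expect_type(sel2$median_feasible, "logical")
})

test_that("multi-seed runs are deterministic and independent", {
  ref <- small_ref()
  sig2 <- discoverability_for_h2(0.4, 0.002, ref)
  uni <- replicate(3, univariate_params(0.002, sig2, 1), simplify = FALSE)
  p <- trivariate_params(uni, replicate(3, pair_params(0.001, 0, 0),
                                        simplify = FALSE), 5e-4)
  z <- simulate_z_from_model(ref, p, 1e5, seed = 95)
  harm <- structure(list(idx = seq_len(2e4), z = z,
                         n = matrix(1e5, 2e4, 3), info = NULL),
                    class = "harmonized_sumstats")
  cfg <- qc_config(n_random = 800, rand_prune_seed = c(1, 2))
  opts <- fit_options(maxit = 40, restarts = 0, tri_rel_tol = 0.05,
                      tri_max_variants = 400)
  runs <- suppressMessages(multi_run(harm, ref, cfg, grids = scaled_grids(),
                                     options = opts))
  expect_length(runs, 2L)
  expect_equal(vapply(runs, `[[`, 0L, "seed"), c(1L, 2L))
  # same seed twice: bitwise-identical pattern
  again <- suppressMessages(multi_run(harm, ref, cfg, seeds = 1,
                                      grids = scaled_grids(),
                                      options = opts))
  expect_identical(unclass(again[[1]]$pattern), unclass(runs[[1]]$pattern))
  # different seeds use different templates
  expect_false(identical(unclass(runs[[1]]$pattern),
                         unclass(runs[[2]]$pattern)))
})
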