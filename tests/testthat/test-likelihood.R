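# The numerical engine: characteristic function, CF-inverted densities
# against closed forms, Monte-Carlo and enumeration oracles, and the
# composite log likelihood.

test_that("characteristic function has the analytic structure", {
  p <- test_params()
  comps <- build_mixture_components(p, 1:3)
  resid <- residual_covariance(c(1.1, 0.95, 1.0), c(0.1, -0.05, 0.15))
  ctx <- variant_context(r2 = c(1, 0.5, 0.2), het = c(0.4, 0.3, 0.25),
                         n = c(9e4, 1.1e5, 1e5))
  # CF(0) = 1
  expect_equal(characteristic_function(c(0, 0, 0), ctx, comps, resid), 1)
  # real, positive, <= 1, even in t
  for (i in 1:5) {
    set.seed(i)
    t <- rnorm(3, 0, 0.5)
    v <- characteristic_function(t, ctx, comps, resid)
    expect_true(v > 0 && v <= 1)
    expect_equal(characteristic_function(-t, ctx, comps, resid), v)
  }
  # all-null mixture: CF reduces to the Gaussian CF of Sigma0
  p0 <- trivariate_params(
    replicate(3, univariate_params(0, 0, 1), simplify = FALSE),
    replicate(3, pair_params(0, 0, 0.1), simplify = FALSE), 0)
  c0 <- build_mixture_components(p0, 1:3)
  r0 <- residual_covariance(rep(1, 3), rep(0.1, 3))
  t <- c(0.4, -0.2, 0.7)
  expect_equal(characteristic_function(t, ctx, c0, r0),
               exp(-0.5 * as.numeric(t %*% r0$matrix %*% t)),
               tolerance = 1e-12)
})

test_that("characteristic function matches a Monte-Carlo oracle", {
  # d = 1, M = 3 neighbors: E[cos(t z)] over model draws
  sigma2 <- 2e-5
  n <- 5e4
  uni <- replicate(3, univariate_params(0.05, sigma2, 1), simplify = FALSE)
  p <- trivariate_params(uni, replicate(3, pair_params(0.02, 0, 0),
                                        simplify = FALSE), 0.01)
  comps1 <- build_mixture_components(p, 1)
  resid1 <- residual_covariance(1)
  r2 <- c(1, 0.6, 0.3); het <- c(0.4, 0.3, 0.2)
  ctx <- variant_context(r2, het, n)
  set.seed(404)
  B <- 1e6
  pi1u <- comps1[[2]]$weight
  z <- rnorm(B)  # residual
  for (k in 1:3) {
    beta <- ifelse(runif(B) < pi1u, rnorm(B, 0, sqrt(sigma2)), 0)
    z <- z + sqrt(n * het[k]) * sqrt(r2[k]) * beta
  }
  for (t in c(0.3, 0.8, 1.6)) {
    mc <- mean(cos(t * z))
    se <- sd(cos(t * z)) / sqrt(B)
    cf <- characteristic_function(t, ctx, comps1, resid1)
    expect_lt(abs(cf - mc), 3 * se + 1e-12)
  }
})

test_that("CF-inverted density matches closed forms", {
  # d = 1, always-causal single self neighbor: N(0, n h sigma^2 + sigma0^2)
  uni <- list(univariate_params(1, 5e-3, 1.2),
              univariate_params(1, 5e-3, 1), univariate_params(1, 5e-3, 1))
  p1 <- trivariate_params(uni, replicate(3, pair_params(1, 0, 0),
                                         simplify = FALSE), 1)
  c1 <- build_mixture_components(p1, 1)
  ctx1 <- variant_context(1, 0.4, 1e4)
  v <- 1e4 * 0.4 * 5e-3 + 1.2
  for (z in c(0, 2.5, 8)) {
    expect_equal(z_density(z, ctx1, c1, residual_covariance(1.2)),
                 dnorm(z, 0, sqrt(v)), tolerance = 1e-6)
  }
  # d = 3 all-null: trivariate Gaussian Sigma0
  p0 <- trivariate_params(
    replicate(3, univariate_params(0, 0, 1), simplify = FALSE),
    replicate(3, pair_params(0, 0, 0.2), simplify = FALSE), 0)
  c3 <- build_mixture_components(p0, 1:3)
  r3 <- residual_covariance(rep(1, 3), rep(0.2, 3))
  ctx3 <- variant_context(c(1, 0.5), c(0.4, 0.3), rep(1e5, 3))
  z3 <- c(0.5, -1, 2)
  expect_equal(z_density(z3, ctx3, c3, r3), dmvn(z3, r3$matrix),
               tolerance = 1e-6)
})

test_that("density matches finite-mixture enumeration (d = 2, M = 4)", {
  p <- test_params(pi_scale = 40)  # appreciable mixture weights
  comps <- build_mixture_components(p, c(1, 2))
  resid <- residual_covariance(c(1.1, 0.95), 0.1)
  set.seed(12)
  r2 <- c(1, 0.7, 0.35, 0.1); het <- c(0.45, 0.3, 0.2, 0.38)
  n <- c(4e4, 5e4)
  ctx <- variant_context(r2, het, n)
  u <- r2 * het
  g <- grid_spec(2, step = 0.05)
  for (i in 1:4) {
    z <- rnorm(2, 0, 2)
    expect_equal(z_density(z, ctx, comps, resid, g),
                 enum_density(z, u, n, comps, resid$matrix),
                 tolerance = 1e-6)
  }
})

test_that("only r^2 enters the density (sign of LD r is irrelevant)", {
  # the likelihood consumes r2 from the reference; build two references
  # from genotype columns differing by negation and compare end to end
  set.seed(31)
  n <- 500
  a <- rbinom(n, 2, 0.4)
  b <- ifelse(runif(n) < 0.85, a, rbinom(n, 2, 0.4))
  vars <- data.frame(id = c("a", "b"), chr = 1L, bp = c(100, 200),
                     a1 = "A", a2 = "G", freq = c(mean(a) / 2, mean(b) / 2),
                     stringsAsFactors = FALSE)
  rec_pos <- compute_ld_from_genotypes(cbind(a, b), vars)
  rec_neg <- compute_ld_from_genotypes(cbind(a, 2 - b), vars)
  expect_equal(rec_pos$r2, rec_neg$r2, tolerance = 1e-12)
  ref1 <- build_reference(rec_pos, vars)
  ref2 <- build_reference(rec_neg, vars)
  harm <- structure(list(idx = 1:2, z = matrix(c(1.2, -0.4, 0.3, 0.8, 1.1,
                                                 -0.6), 2, 3),
                         n = matrix(5e4, 2, 3), info = NULL),
                    class = "harmonized_sumstats")
  t1 <- build_template(ref1, harm, 1:2)
  t2 <- build_template(ref2, harm, 1:2)
  p <- test_params()
  expect_identical(neg_log_likelihood(p, t1, 1:3),
                   neg_log_likelihood(p, t2, 1:3))
})

test_that("one-dimensional density integrates to one", {
  p <- test_params(pi_scale = 5)
  comps <- build_mixture_components(p, 1)
  resid <- residual_covariance(1.1)
  ctx <- variant_context(c(1, 0.5, 0.3), c(0.4, 0.35, 0.2), 8e4)
  zs <- seq(-40, 40, by = 0.1)
  dens <- vapply(zs, function(z) z_density(z, ctx, comps, resid), 0)
  expect_equal(sum(dens) * 0.1, 1, tolerance = 1e-3)
})

test_that("log likelihood is additive, order-invariant and grid-stable", {
  ref <- simulate_block_reference(400, block_size = 5,
                                  within_block_r = 0.6, seed = 5)
  p <- test_params()
  z <- simulate_z_from_model(ref, p, 5e4, seed = 6)
  harm <- structure(list(idx = 1:400, z = z, n = matrix(5e4, 400, 3),
                         info = NULL), class = "harmonized_sumstats")
  tpl_all <- build_template(ref, harm, 1:400)
  tpl_a <- build_template(ref, harm, 1:150)
  tpl_b <- build_template(ref, harm, 151:400)
  g <- grid_spec(1)
  nll <- function(t) neg_log_likelihood(p, t, dims = 1, grid = g)
  expect_equal(nll(tpl_all), nll(tpl_a) + nll(tpl_b), tolerance = 1e-9)
  # permuting template order leaves the value unchanged
  perm <- sample(1:400)
  tpl_p <- build_template(ref, harm, perm)
  expect_equal(nll(tpl_p), nll(tpl_all), tolerance = 1e-9)
  # halving the grid step changes the value by < 1e-4 per variant
  g_half <- grid_spec(1, step = 0.025)
  expect_lt(abs(neg_log_likelihood(p, tpl_all, 1, g_half) - nll(tpl_all)),
            1e-4 * 400)
  # 20-variant toy matches the enumeration oracle variant by variant
  small <- build_template(ref, harm, 1:20)
  comps <- build_mixture_components(p, 1)
  resid <- residual_covariance(p$uni[[1]]$sigma0_sq)
  tot <- 0
  for (j in 1:20) {
    sel <- (small$ptr[j] + 1):small$ptr[j + 1]
    tot <- tot - log(enum_density(small$z[j, 1], small$u[sel], small$n[1],
                                  comps, resid$matrix))
  }
  expect_equal(neg_log_likelihood(p, small, 1), tot, tolerance = 1e-5)
})

test_that("true parameters beat perturbed ones on model-simulated data", {
  ref <- cached("ref_lik_order", simulate_block_reference(
    3000, block_size = 5, within_block_r = 0.6, seed = 77))
  sig2 <- 1.5e-3
  uni <- replicate(3, univariate_params(0.04, sig2, 1), simplify = FALSE)
  p <- trivariate_params(uni, replicate(3, pair_params(0.02, 0, 0),
                                        simplify = FALSE), 0.01)
  g <- grid_spec(1, quantize = 2048)
  wins <- matrix(0, 100, 3)
  for (rep in 1:100) {
    z <- simulate_z_from_model(ref, p, 2e5, seed = 9000 + rep)
    harm <- structure(list(idx = 1:3000, z = z, n = matrix(2e5, 3000, 3),
                           info = NULL), class = "harmonized_sumstats")
    sub <- seq(1 + (rep %% 6), 3000, by = 6)[1:500]
    tpl <- build_template(ref, harm, sub)
    base <- neg_log_likelihood(p, tpl, 1, g)
    pert <- list(
      trivariate_params(replace(uni, 1, list(univariate_params(
        0.08, sig2, 1))), p$pairs, 0.01),
      trivariate_params(replace(uni, 1, list(univariate_params(
        0.04, sig2 * 2, 1))), p$pairs, 0.01),
      trivariate_params(replace(uni, 1, list(univariate_params(
        0.04, sig2, 2))), p$pairs, 0.01))
    for (k in 1:3) {
      wins[rep, k] <- neg_log_likelihood(pert[[k]], tpl, 1, g) >= base
    }
  }
  expect_gte(mean(wins), 0.95)
})
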