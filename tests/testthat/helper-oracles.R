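# Independent oracles used across tests.

# Multivariate normal density for d <= 3 via Cholesky (no dependency).
dmvn <- function(z, S) {
  L <- chol(S)
  q <- sum(backsolve(L, z, transpose = TRUE)^2)
  exp(-0.5 * q) / ((2 * pi)^(length(z) / 2) * prod(diag(L)))
}

# Brute-force density of the LD-convolved mixture: enumerate all component
# assignments over the M neighbors (C^M terms), each a closed-form Gaussian.
enum_density <- function(z, u, n, comps, Sigma0) {
  d <- length(z)
  C <- length(comps)
  M <- length(u)
  B <- lapply(comps, function(cp) {
    diag(sqrt(n), d) %*% cp$covariance %*% diag(sqrt(n), d)
  })
  w <- vapply(comps, `[[`, 0, "weight")
  grid <- as.matrix(expand.grid(rep(list(seq_len(C)), M)))
  dens <- 0
  for (r in seq_len(nrow(grid))) {
    wt <- prod(w[grid[r, ]])
    if (wt == 0) next
    S <- Sigma0
    for (k in seq_len(M)) S <- S + u[k] * B[[grid[r, k]]]
    dens <- dens + wt * dmvn(z, S)
  }
  dens
}

# Grid-search oracle for the maximum-entropy triple overlap: coarse pass
# plus two refinements around the best point.
grid_entropy_argmax <- function(pi_u, pi_b) {
  b <- tri_overlap_bounds(pi_u, pi_b)
  if (b$upper - b$lower < 1e-12) return(b$lower)
  ent <- function(x) {
    m <- unclass(derive_pattern(pi_u, pi_b, x, tol = 1e-9))
    m <- m[c("pi1", "pi2", "pi3", "pi12", "pi13", "pi23", "pi123")]
    p <- m / sum(m)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  lo <- b$lower; hi <- b$upper
  for (pass in 1:3) {
    xs <- seq(lo, hi, length.out = 201)
    es <- vapply(xs, ent, 0)
    i <- which.max(es)
    st <- xs[2] - xs[1]
    lo <- max(b$lower, xs[i] - st)
    hi <- min(b$upper, xs[i] + st)
  }
  xs[i]
}

# Random feasible (pi_u, pi_b) draws for property tests.
random_feasible_inputs <- function(n, seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  i <- 0
  while (i < n) {
    m <- runif(7, 0, 5e-3)  # seven region masses -> always feasible
    pat <- overlap_pattern(m[1], m[2], m[3], m[4], m[5], m[6], m[7])
    pu <- c(m[1] + m[4] + m[5] + m[7], m[2] + m[4] + m[6] + m[7],
            m[3] + m[5] + m[6] + m[7])
    pb <- c(m[4] + m[7], m[5] + m[7], m[6] + m[7])
    i <- i + 1
    out[[i]] <- list(pi_u = pu, pi_b = pb, pattern = pat)
  }
  out
}

# Shared small fixtures -------------------------------------------------

# A valid parameter set with nonzero correlations for engine tests.
test_params <- function(pi_scale = 1) {
  uni <- list(univariate_params(2e-3 * pi_scale, 6e-3, 1.1),
              univariate_params(3e-3 * pi_scale, 4e-3, 0.95),
              univariate_params(2.5e-3 * pi_scale, 5e-3, 1.0))
  pairs <- list(pair_params(1e-3 * pi_scale, 0.4, 0.1),
                pair_params(0.8e-3 * pi_scale, -0.3, -0.05),
                pair_params(1.2e-3 * pi_scale, 0.2, 0.15))
  trivariate_params(uni, pairs, 0.5e-3 * pi_scale)
}
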