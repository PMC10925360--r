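# Composite likelihood of observed z-scores under the causal mixture with LD
# convolution: characteristic function, density by numerical CF inversion
# (trapezoidal rule), and the negative log composite likelihood over an
# optimization template.

#' Integration grid specification
#'
#' The CF-inversion grid lives in scaled t-units: each variant's grid is the
#' shared symmetric grid divided by that variant's predicted z standard
#' deviation, which keeps the integrand resolved across heterogeneous
#' `N * h`.  Defaults: one-dimensional step 0.05 with half-width 12;
#' three-dimensional 33^3 points over the same half-width; two-dimensional
#' 65^2.
#'
#' @param dims Number of phenotypes integrated over (1, 2 or 3).
#' @param step Grid spacing in scaled t-units.
#' @param half_width Truncation bound in scaled t-units (must be at least
#'   `8 * step`).
#' @param quantize Number of log-spaced interpolation levels for the
#'   neighbor mixture term; `0` (default) evaluates exponentials exactly.
#'   Fits use a quantized grid for speed.
#' @param density_floor Minimum density substituted before taking logs.
#' @param tail_z Threshold (in residual standard deviations) beyond which a
#'   variant's density is evaluated by exact truncated enumeration over
#'   causal-neighbor assignments instead of CF inversion.  Coarse grids
#'   cannot resolve the far tail where rare large-effect assignments
#'   dominate; the enumeration (at most two causal neighbors, exact Gaussian
#'   terms) is accurate there whenever per-neighbor causal rates are small.
#'   `Inf` (default) disables the hybrid; fits on coarse grids set it to 6.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(dims, step = NULL, half_width = 12,
                      quantize = 0, density_floor = 1e-300, tail_z = Inf) {
  stopifnot(dims %in% 1:3)
  if (is.null(step)) step <- switch(dims, 0.05, 2 * 12 / 64, 2 * 12 / 32)
  if (step <= 0) stop("step must be > 0")
  if (half_width < 8 * step) stop("half_width must be >= 8 * step")
  n_half <- max(4L, as.integer(round(half_width / step)))
  structure(list(dims = as.integer(dims), step = step,
                 half_width = n_half * step,
                 grid1 = step * seq.int(-n_half, n_half),
                 quantize = as.integer(quantize),
                 density_floor = density_floor, tail_z = tail_z),
            class = "grid_spec")
}

#' Per-variant context of the z-score model
#'
#' The neighborhood information entering one variant's z-score: LD r2 and
#' heterozygosity of each variant in LD (the variant itself included at
#' r2 = 1) and the per-phenotype GWAS sample sizes.
#'
#' @param r2 Numeric vector of squared correlations with the neighbors.
#' @param het Heterozygosities of the neighbors (same length).
#' @param n Per-phenotype sample sizes (length = number of phenotypes).
#' @return Object of class `variant_context`.
#' @export
variant_context <- function(r2, het, n) {
  stopifnot(length(r2) == length(het), all(r2 > 0), all(r2 <= 1),
            all(het >= 0), all(het <= 0.5), all(n > 0))
  if (!any(r2 == 1)) stop("the self-pair (r2 = 1) must be present")
  structure(list(r2 = as.numeric(r2), het = as.numeric(het),
                 n = as.numeric(n)),
            class = "variant_context")
}

#' Residual covariance of the z-scores
#'
#' @param sigma0_sq Residual variances per phenotype (length d).
#' @param rho0 Residual correlations; for d = 3 in pair order 12, 13, 23,
#'   for d = 2 a single value, empty for d = 1.
#' @return Object of class `residual_covariance` holding the d x d matrix.
#' @export
residual_covariance <- function(sigma0_sq, rho0 = numeric(0)) {
  d <- length(sigma0_sq)
  stopifnot(d %in% 1:3, all(sigma0_sq > 0))
  need <- c(0L, 1L, 3L)[d]
  if (length(rho0) != need) {
    stop("rho0 must have length ", need, " for d = ", d)
  }
  if (any(abs(rho0) > 1)) stop("|rho0| must be <= 1")
  s <- sqrt(sigma0_sq)
  S <- diag(sigma0_sq, d)
  if (d >= 2) S[1, 2] <- S[2, 1] <- rho0[1] * s[1] * s[2]
  if (d == 3) {
    S[1, 3] <- S[3, 1] <- rho0[2] * s[1] * s[3]
    S[2, 3] <- S[3, 2] <- rho0[3] * s[2] * s[3]
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) stop("residual covariance is not PSD")
  structure(list(matrix = S), class = "residual_covariance")
}

#' Characteristic function of the modeled z-score
#'
#' `CF(t) = exp(-t'S0 t/2) prod_k sum_c w_c exp(-r2_k t' D_k Sigma_c D_k
#' t/2)` with `D_k = diag(sqrt(n_i h_k))`: the exact CF of the LD-weighted
#' sum of mixture effects plus Gaussian residuals.  Real, positive, at most
#' 1 and even in `t`.
#'
#' @param t Numeric vector (length d).
#' @param ctx A [variant_context()].
#' @param components Mixture components from [build_mixture_components()]
#'   for the same d.
#' @param residual A [residual_covariance()].
#' @return Scalar CF value.
#' @export
characteristic_function <- function(t, ctx, components, residual) {
  d <- length(t)
  stopifnot(inherits(ctx, "variant_context"), length(ctx$n) == d)
  sqn <- sqrt(ctx$n)
  q_c <- vapply(components, function(cp) {
    td <- t * sqn
    as.numeric(td %*% cp$covariance %*% td)
  }, 0)
  w <- vapply(components, `[[`, 0, "weight")
  u <- ctx$r2 * ctx$het
  log_prod <- sum(vapply(u, function(uk) log(sum(w * exp(-0.5 * uk * q_c))),
                         0))
  exp(-0.5 * as.numeric(t %*% residual$matrix %*% t) + log_prod)
}

# Internal: vectorized zero-mean Gaussian densities for many covariance
# matrices given one evaluation point.  Covariance entries come as equal
# length vectors (upper triangle); d <= 3 closed forms.
.dnorm_many <- function(z, s11, s22 = NULL, s33 = NULL, s12 = NULL,
                        s13 = NULL, s23 = NULL) {
  d <- length(z)
  if (d == 1) {
    return(exp(-0.5 * z[1]^2 / s11) / sqrt(2 * pi * s11))
  }
  if (d == 2) {
    det <- s11 * s22 - s12^2
    q <- (z[1]^2 * s22 - 2 * z[1] * z[2] * s12 + z[2]^2 * s11) / det
    return(exp(-0.5 * q) / (2 * pi * sqrt(det)))
  }
  # d == 3: adjugate-based inverse
  c11 <- s22 * s33 - s23^2
  c12 <- s13 * s23 - s12 * s33
  c13 <- s12 * s23 - s13 * s22
  c22 <- s11 * s33 - s13^2
  c23 <- s12 * s13 - s11 * s23
  c33 <- s11 * s22 - s12^2
  det <- s11 * c11 + s12 * c12 + s13 * c13
  q <- (z[1]^2 * c11 + z[2]^2 * c22 + z[3]^2 * c33 +
          2 * (z[1] * z[2] * c12 + z[1] * z[3] * c13 +
                 z[2] * z[3] * c23)) / det
  exp(-0.5 * q) / ((2 * pi)^1.5 * sqrt(det))
}

# Internal: exact truncated-enumeration density for tail variants.  Sums the
# closed-form Gaussian terms over assignments with at most two causal
# neighbors (weights w0^(M-k) prod w_c); the omitted >= 3-causal mass is
# O((M pi)^3 / 6), negligible at small per-neighbor causal rates.
.tail_density <- function(z, ptr, u, n, w, covs, Sigma0) {
  d <- ncol(z)
  nullc <- vapply(covs, function(S) all(S == 0), TRUE)
  w0 <- sum(w[nullc])
  act <- which(!nullc)
  wc <- w[act]
  sqn <- diag(sqrt(n), d)
  Bc <- lapply(covs[act], function(S) sqn %*% S %*% sqn)
  ut <- function(S) { # upper-triangle entries in .dnorm_many order
    if (d == 1) list(S[1, 1]) else if (d == 2) {
      list(S[1, 1], S[2, 2], NULL, S[1, 2])
    } else {
      list(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3])
    }
  }
  e0 <- ut(Sigma0)
  eB <- lapply(Bc, ut)
  nC <- length(act)
  out <- numeric(nrow(z))
  for (j in seq_len(nrow(z))) {
    sel <- (ptr[j] + 1L):ptr[j + 1L]
    uj <- u[sel]
    uj <- uj[uj > 0]
    M <- length(uj)
    zj <- z[j, ]
    tot <- if (M == 0) dmvnS(zj, e0) else w0^M * dmvnS(zj, e0)
    if (M >= 1 && nC) {
      # one causal neighbor: M x nC terms
      um <- rep(uj, times = nC)
      ci <- rep(seq_len(nC), each = M)
      ent <- lapply(seq_along(e0), function(k) {
        if (is.null(e0[[k]])) return(NULL)
        e0[[k]] + um * vapply(eB, function(e) e[[k]], 0)[ci]
      })
      dens1 <- do.call(.dnorm_many, c(list(zj), ent))
      tot <- tot + w0^(M - 1) * sum(wc[ci] * dens1)
    }
    if (M >= 2 && nC) {
      pr <- utils::combn(M, 2)
      nP <- ncol(pr)
      ua <- rep(uj[pr[1, ]], times = nC * nC)
      ub <- rep(uj[pr[2, ]], times = nC * nC)
      c1 <- rep(rep(seq_len(nC), each = nP), times = nC)
      c2 <- rep(seq_len(nC), each = nP * nC)
      ent <- lapply(seq_along(e0), function(k) {
        if (is.null(e0[[k]])) return(NULL)
        bk <- vapply(eB, function(e) e[[k]], 0)
        e0[[k]] + ua * bk[c1] + ub * bk[c2]
      })
      dens2 <- do.call(.dnorm_many, c(list(zj), ent))
      tot <- tot + w0^(M - 2) * sum(wc[c1] * wc[c2] * dens2)
    }
    out[j] <- tot
  }
  out
}

# scalar Gaussian density from upper-triangle entry list
dmvnS <- function(z, e) do.call(.dnorm_many, c(list(z), e))

# Internal: per-variant log densities via the C++ engine.
#
# The all-null mixture term (a pure Gaussian with covariance Sigma0, the
# narrowest density component and hence the slowest-decaying CF term) is
# computed in closed form here; the engine integrates only the remainder.
# The shared grid lives in scaled t-units: per-trait scales
# c_a = sqrt(Sigma0_aa) put the residual width at one scaled unit (fixing
# CF truncation at the grid half-width), and a per-variant scalar s_j >= 1
# widens the effective grid just enough to push the trapezoid rule's
# aliasing images (spaced 2*pi/step in scaled z-units) past the evaluation
# point, capped so truncation stays controlled.  Per-variant per-trait
# sample sizes are collapsed to per-trait scalars (median over template).
.engine_logdensity <- function(z, ptr, u, n, components, Sigma0, grid) {
  d <- ncol(z)
  V <- nrow(z)
  w <- vapply(components, `[[`, 0, "weight")
  covs <- lapply(components, `[[`, "covariance")
  c2 <- pmax(diag(Sigma0), 1e-12)
  cs <- sqrt(c2)
  zsc <- abs(z) / matrix(cs, V, d, byrow = TRUE)
  z_inf <- if (d == 1) zsc[, 1] else apply(zsc, 1, max)
  s_cap <- max(1, grid$half_width / 6)
  s2 <- pmin(pmax(1, (z_inf + 8) * grid$step / (2 * pi)), s_cap)^2
  Ssc <- Sigma0 / outer(cs, cs)
  A <- vapply(covs, function(S) {
    as.numeric(S * outer(sqrt(n) / cs, sqrt(n) / cs))
  }, numeric(d * d))
  A <- matrix(A, nrow = d * d)
  zs <- z / outer(sqrt(s2), cs)
  rest <- .cpp_z_rest_density(zs, as.integer(ptr), as.numeric(u),
                              as.numeric(s2), A, as.numeric(w), Ssc,
                              grid$grid1, grid$step, grid$quantize)
  rest <- rest * exp(-0.5 * d * log(s2) - sum(log(cs)))
  # closed-form all-null term: w0^M * N_d(z; Sigma0)
  null_c <- vapply(covs, function(S) all(S == 0), TRUE)
  w0 <- sum(w[null_c])
  dens <- rest
  if (w0 > 0) {
    L <- chol(Sigma0)
    q <- colSums(forwardsolve(t(L), t(z))^2)
    logn <- -0.5 * q - sum(log(diag(L))) - 0.5 * d * log(2 * pi)
    if (length(u)) {
      grp <- rep.int(seq_len(V), diff(ptr))
      m_pos <- as.numeric(rowsum((u > 0) + 0, grp))
    } else {
      m_pos <- numeric(V)
    }
    dens <- rest + exp(m_pos * log(w0) + logn)
  }
  # hybrid tail handling: beyond tail_z residual sds the coarse shared grid
  # cannot resolve the density; use exact truncated enumeration instead
  if (is.finite(grid$tail_z) && w0 >= 0.5) {
    tail <- which(z_inf > grid$tail_z)
    if (length(tail)) {
      dens[tail] <- .tail_density(z[tail, , drop = FALSE],
                                  ptr = c(0L, cumsum(diff(ptr)[tail])),
                                  u = u[sequence(diff(ptr)[tail]) +
                                          rep.int(ptr[tail],
                                                  diff(ptr)[tail])],
                                  n, w, covs, Sigma0)
    }
  }
  if (any(!is.finite(dens))) {
    stop("non-finite z-score density for template variant row ",
         which(!is.finite(dens))[1], " (invalid parameters or grid)")
  }
  dens <- pmax(dens, grid$density_floor)
  if (any(dens <= 0)) {
    stop("non-positive z-score density for template variant row ",
         which(dens <= 0)[1], " (grid too narrow or invalid parameters)")
  }
  log(dens)
}

#' Density of an observed z-score vector under the causal mixture
#'
#' Inverse-Fourier integral `(2pi)^-d int CF(t) cos(t'z) dt` approximated by
#' the trapezoidal rule on the symmetric grid (the cosine form is valid
#' because the CF is real and even).
#'
#' @param z Numeric vector (length d) of observed z-scores.
#' @param ctx A [variant_context()].
#' @param components Mixture components for the same d.
#' @param residual A [residual_covariance()].
#' @param grid A [grid_spec()] with matching `dims`.
#' @return Scalar density (strictly positive; floored at
#'   `grid$density_floor`).
#' @export
z_density <- function(z, ctx, components, residual, grid = NULL) {
  d <- length(z)
  if (is.null(grid)) grid <- grid_spec(d)
  stopifnot(grid$dims == d, length(ctx$n) == d)
  u <- ctx$r2 * ctx$het
  ld <- .engine_logdensity(matrix(z, 1, d), c(0L, length(u)), u, ctx$n,
                           components, residual$matrix, grid)
  exp(ld[1])
}

#' Optimization template for the composite likelihood
#'
#' Packs z-scores, sample sizes and per-variant neighbor weights
#' (`u = het * r2`, self-pair included) for a set of template variants into
#' the flat arrays consumed by the likelihood engine.
#'
#' @param reference An `ld_reference`.
#' @param harmonized A `harmonized_sumstats` (or any list with `idx`, `z`,
#'   `n` aligned to reference indices).
#' @param template_idx Reference variant indices forming the template (e.g.
#'   from [prune_and_subset()]).
#' @return Object of class `mix_template` with fields `z` (V x d), `n`
#'   (per-trait medians), `ptr`, `u`, `ids`.
#' @export
build_template <- function(reference, harmonized, template_idx) {
  slot <- match(template_idx, harmonized$idx)
  if (anyNA(slot)) stop("template contains variants absent from the data")
  V <- length(template_idx)
  lens <- reference$ptr[template_idx + 1L] - reference$ptr[template_idx]
  sel <- sequence(lens) + rep.int(reference$ptr[template_idx], lens)
  nbr <- reference$nbr_idx[sel]
  u <- reference$nbr_r2[sel] * reference$variants$het[nbr]
  nmat <- harmonized$n[slot, , drop = FALSE]
  structure(list(z = harmonized$z[slot, , drop = FALSE],
                 n = apply(nmat, 2, median),
                 ptr = as.integer(c(0L, cumsum(lens))),
                 u = u,
                 ids = reference$variants$id[template_idx]),
            class = "mix_template")
}

#' @export
print.mix_template <- function(x, ...) {
  cat(sprintf("mix_template: %d variants x %d traits, %.1f LD neighbors/variant\n",
              nrow(x$z), ncol(x$z), length(x$u) / max(1, nrow(x$z))))
  invisible(x)
}

# Internal: restrict a template to a subset of traits (columns).
.template_dims <- function(template, dims) {
  structure(list(z = template$z[, dims, drop = FALSE],
                 n = template$n[dims], ptr = template$ptr, u = template$u,
                 ids = template$ids),
            class = "mix_template")
}

# Internal: negative log composite likelihood from raw pieces.
.nll_engine <- function(template, weights, covs, Sigma0, grid) {
  comps <- mapply(function(wt, S) list(weight = wt, covariance = S),
                  weights, covs, SIMPLIFY = FALSE)
  ld <- .engine_logdensity(template$z, template$ptr, template$u, template$n,
                           comps, Sigma0, grid)
  -sum(ld)
}

#' Negative log composite likelihood over a template
#'
#' Sums `-log z_density` over template variants, treating them as
#' independent (random pruning at `r2 < 0.8` is what justifies the composite
#' approximation).
#'
#' @param params A [trivariate_params()].
#' @param template A `mix_template` built over the traits in `dims`.
#' @param dims Subset of `1:3`: which traits the likelihood covers.
#' @param grid A [grid_spec()] (defaults to the dims-appropriate default).
#' @return Scalar negative log likelihood.
#' @export
neg_log_likelihood <- function(params, template, dims = 1:3, grid = NULL) {
  dims <- sort(unique(as.integer(dims)))
  d <- length(dims)
  if (is.null(grid)) grid <- grid_spec(d)
  stopifnot(grid$dims == d)
  comps <- build_mixture_components(params, dims)
  s0 <- vapply(params$uni, `[[`, 0, "sigma0_sq")[dims]
  r0 <- vapply(params$pairs, `[[`, 0, "rho0")
  rho0 <- if (d == 3) r0 else if (d == 2) {
    pair_of <- c("12" = 1, "13" = 2, "23" = 3)
    r0[pair_of[paste0(dims[1], dims[2])]]
  } else numeric(0)
  resid <- residual_covariance(s0, rho0)
  tpl <- if (ncol(template$z) == d) template else .template_dims(template, dims)
  ld <- .engine_logdensity(tpl$z, tpl$ptr, tpl$u, tpl$n, comps,
                           resid$matrix, grid)
  -sum(ld)
}
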