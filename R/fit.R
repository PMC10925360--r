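# Stepwise maximum composite-likelihood estimation: univariate ->
# bivariate (univariate parameters frozen) -> trivariate (one-dimensional
# search for the triple overlap), multi-seed runs and representative-run
# selection.

#' Optimizer options for the stepwise fit
#'
#' Each stage uses a derivative-free simplex (Nelder-Mead) on transformed
#' coordinates, followed by short restarts from deterministically perturbed
#' best points.
#'
#' @param maxit Iteration budget of the first simplex run.
#' @param restarts Number of perturbed restarts (deterministic offsets).
#' @param restart_maxit Iteration budget per restart.
#' @param reltol Relative convergence tolerance of the simplex.
#' @param tri_rel_tol Tolerance of the one-dimensional triple-overlap search,
#'   as a fraction of the feasible interval length.
#' @param tri_max_variants Cap on the number of template variants used in
#'   the three-dimensional stage (the costliest integration); when the
#'   template is larger, an evenly spaced deterministic subset is used.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(maxit = 200, restarts = 3, restart_maxit = 75,
                        reltol = 1e-8, tri_rel_tol = 5e-3,
                        tri_max_variants = Inf) {
  structure(list(maxit = maxit, restarts = restarts,
                 restart_maxit = restart_maxit, reltol = reltol,
                 tri_rel_tol = tri_rel_tol,
                 tri_max_variants = tri_max_variants),
            class = "fit_options")
}

# deterministic evenly spaced subset of a template's variants
.subsample_template <- function(template, n_max) {
  V <- nrow(template$z)
  if (V <= n_max) return(template)
  keep <- unique(round(seq(1, V, length.out = n_max)))
  lens <- diff(template$ptr)
  sel <- sequence(lens[keep]) +
    rep.int(template$ptr[keep], lens[keep])
  structure(list(z = template$z[keep, , drop = FALSE], n = template$n,
                 ptr = as.integer(c(0L, cumsum(lens[keep]))),
                 u = template$u[sel], ids = template$ids[keep]),
            class = "mix_template")
}

# deterministic perturbation offsets applied to the incumbent before each
# restart (transformed coordinates)
.RESTART_OFFSETS <- list(c(0.5, -0.5, 0.15), c(-0.5, 0.5, -0.15),
                         c(0.3, 0.3, 0.3), c(-0.3, -0.3, -0.3))

# simplex with deterministic perturbed restarts; never returns a point worse
# than the best evaluated
.simplex_multistart <- function(par0, fn, options) {
  best <- optim(par0, fn, method = "Nelder-Mead",
                control = list(maxit = options$maxit,
                               reltol = options$reltol))
  evals <- best$counts[1]
  n_restart <- min(options$restarts, length(.RESTART_OFFSETS))
  for (r in seq_len(n_restart)) {
    start <- best$par + .RESTART_OFFSETS[[r]][seq_along(par0)]
    cand <- optim(start, fn, method = "Nelder-Mead",
                  control = list(maxit = options$restart_maxit,
                                 reltol = options$reltol))
    evals <- evals + cand$counts[1]
    if (cand$value < best$value) best <- cand
  }
  best$evals <- as.integer(evals)
  best
}

.template_usum <- function(template) {
  lens <- diff(template$ptr)
  grp <- rep.int(seq_along(lens), lens)
  as.numeric(rowsum(template$u, grp))
}

#' Univariate mixture fit for one trait
#'
#' Maximizes the composite likelihood over `(pi_u, sigma_beta_sq,
#' sigma0_sq)`.  Polygenicity and discoverability are optimized on the log
#' scale (`pi_u` in `[1e-7, 1]`), the residual variance inside `[0.8, 2.5]`
#' through a logistic transform.  Starts from `pi_u = 1e-3`, a
#' method-of-moments match of the mean chi-square for `sigma_beta_sq`, and
#' `sigma0_sq = 1`.
#'
#' @param template A `mix_template` (see [build_template()]).
#' @param trait Column of the template to fit (1-3).
#' @param grid A [grid_spec()] for `dims = 1`; default uses quantized
#'   evaluation for speed.
#' @param options A [fit_options()].
#' @return List of class `uni_fit`: `params` ([univariate_params()]),
#'   `value` (negative log likelihood), `diagnostics`.
#' @export
fit_univariate <- function(template, trait = 1, grid = NULL,
                           options = fit_options()) {
  if (is.null(grid)) grid <- grid_spec(1, quantize = 2048)
  tpl <- .template_dims(template, trait)
  V <- nrow(tpl$z)
  if (V < 100) warning("univariate fit on fewer than 100 template variants")
  n <- tpl$n
  wbar <- mean(.template_usum(tpl))
  m2 <- mean(tpl$z^2)
  pi0 <- 1e-3
  s2_start <- max(m2 - 1, 0.05) / (n * pi0 * wbar)
  obj <- function(par) {
    lp <- par[1]; ls <- par[2]
    if (lp > 0 || lp < log(1e-7) || ls > log(1e3) || ls < log(1e-12)) {
      return(1e10 + abs(lp) + abs(ls))
    }
    s0 <- 0.8 + 1.7 * stats::plogis(par[3])
    val <- try(.nll_engine(tpl, c(1 - exp(lp), exp(lp)),
                           list(matrix(0, 1, 1), matrix(exp(ls), 1, 1)),
                           matrix(s0, 1, 1), grid),
               silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) 1e10 else val
  }
  par0 <- c(log(pi0), log(s2_start), stats::qlogis((1 - 0.8) / 1.7))
  best <- .simplex_multistart(par0, obj, options)
  params <- univariate_params(exp(best$par[1]), exp(best$par[2]),
                              0.8 + 1.7 * stats::plogis(best$par[3]))
  structure(list(params = params, value = best$value,
                 diagnostics = list(evals = best$evals,
                                    convergence = best$convergence,
                                    start_value = obj(par0))),
            class = "uni_fit")
}

#' Bivariate fit for one pair of traits
#'
#' With the two univariate parameter triplets frozen, maximizes the pair's
#' composite likelihood over `(pi_b, rho, rho0)`: the shared polygenicity is
#' constrained to `[0, min(pi_1u, pi_2u)]` through a logistic transform, the
#' two correlations to `(-1, 1)` through `tanh`.  When the fitted overlap is
#' essentially zero, `rho` is unidentifiable and flagged in the diagnostics.
#'
#' @param template A `mix_template`.
#' @param pair The two trait indices, e.g. `c(1, 2)`.
#' @param uni List of two [univariate_params()] in pair order (frozen).
#' @param grid A [grid_spec()] for `dims = 2`.
#' @param options A [fit_options()].
#' @return List of class `pair_fit`: `params` ([pair_params()]), `value`,
#'   `diagnostics` (including `rho_defined`).
#' @export
fit_bivariate_pair <- function(template, pair, uni, grid = NULL,
                               options = fit_options()) {
  if (is.null(grid)) grid <- grid_spec(2, quantize = 1024, tail_z = 6)
  stopifnot(length(pair) == 2L, length(uni) == 2L)
  tpl <- .template_dims(template, pair)
  p1 <- uni[[1]]$pi_u; p2 <- uni[[2]]$pi_u
  upper <- min(p1, p2)
  s1 <- uni[[1]]$sigma_beta_sq; s2 <- uni[[2]]$sigma_beta_sq
  s0 <- c(uni[[1]]$sigma0_sq, uni[[2]]$sigma0_sq)
  covs <- function(rho) list(
    matrix(0, 2, 2), diag(c(s1, 0)), diag(c(0, s2)),
    matrix(c(s1, rho * sqrt(s1 * s2), rho * sqrt(s1 * s2), s2), 2))
  obj <- function(par) {
    pb <- upper * stats::plogis(par[1])
    rho <- 0.999 * tanh(par[2]); rho0 <- 0.999 * tanh(par[3])
    w <- c(1 - p1 - p2 + pb, p1 - pb, p2 - pb, pb)
    S0 <- matrix(c(s0[1], rho0 * sqrt(prod(s0)), rho0 * sqrt(prod(s0)),
                   s0[2]), 2)
    val <- try(.nll_engine(tpl, w, covs(rho), S0, grid), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) 1e10 else val
  }
  r0_start <- min(max(cor(tpl$z[, 1], tpl$z[, 2]), -0.9), 0.9)
  par0 <- c(0, 0, atanh(r0_start))
  best <- .simplex_multistart(par0, obj, options)
  pb <- upper * stats::plogis(best$par[1])
  rho <- 0.999 * tanh(best$par[2])
  rho_defined <- pb > 1e-7 * max(upper, 1e-7) && upper > 0
  params <- pair_params(pb, if (rho_defined) rho else 0,
                        0.999 * tanh(best$par[3]))
  structure(list(params = params, value = best$value,
                 diagnostics = list(evals = best$evals,
                                    convergence = best$convergence,
                                    rho_defined = rho_defined,
                                    start_value = obj(par0))),
            class = "pair_fit")
}

#' Trivariate step: fit the triple-overlap polygenicity
#'
#' With all univariate and bivariate parameters frozen, maximizes the
#' trivariate composite likelihood over `pi123` inside its feasibility
#' bounds by a bounded one-dimensional search.  Degenerate bounds return the
#' forced value without optimization.
#'
#' @param template A `mix_template` over all three traits.
#' @param uni List of three [univariate_params()] (frozen).
#' @param pairs List of three [pair_params()] in order 12, 13, 23 (frozen).
#' @param grid A [grid_spec()] for `dims = 3`.
#' @param options A [fit_options()].
#' @return List of class `tri_fit`: `pi123`, `params`
#'   ([trivariate_params()]), `pattern`, `value`, `bounds`.
#' @export
# Minimal shrinkage of a correlation matrix toward the identity so its
# smallest eigenvalue reaches eps.  Pairwise-fitted correlations need not be
# jointly PSD; the trivariate stage requires a valid joint matrix.
.shrink_to_psd <- function(R, eps = 1e-6) {
  emin <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (emin >= eps) return(R)
  lam <- (eps - 1) / (emin - 1)
  lam * R + (1 - lam) * diag(nrow(R))
}

fit_tri_overlap <- function(template, uni, pairs, grid = NULL,
                            options = fit_options()) {
  if (is.null(grid)) grid <- grid_spec(3, quantize = 256, tail_z = 6)
  template <- .subsample_template(template, options$tri_max_variants)
  # project the two pairwise-estimated correlation triplets onto jointly
  # valid (PSD) matrices; the frozen polygenicities are untouched
  corr3 <- function(r) {
    matrix(c(1, r[1], r[2], r[1], 1, r[3], r[2], r[3], 1), 3)
  }
  rho <- vapply(pairs, `[[`, 0, "rho")
  rho0 <- vapply(pairs, `[[`, 0, "rho0")
  Rg <- .shrink_to_psd(corr3(rho))
  R0 <- .shrink_to_psd(corr3(rho0))
  adj <- c(Rg[1, 2], Rg[1, 3], Rg[2, 3]) != rho |
    c(R0[1, 2], R0[1, 3], R0[2, 3]) != rho0
  if (any(adj)) {
    message("pairwise correlations shrunk to a jointly PSD matrix for the ",
            "trivariate stage")
    pairs <- lapply(1:3, function(k) {
      pair_params(pairs[[k]]$pi_b, c(Rg[1, 2], Rg[1, 3], Rg[2, 3])[k],
                  c(R0[1, 2], R0[1, 3], R0[2, 3])[k])
    })
  }
  pu <- vapply(uni, `[[`, 0, "pi_u")
  pb <- vapply(pairs, `[[`, 0, "pi_b")
  b <- tri_overlap_bounds(pu, pb)
  nll_at <- function(x) {
    pr <- trivariate_params(uni, pairs, min(max(x, b$lower), b$upper))
    neg_log_likelihood(pr, template, 1:3, grid)
  }
  if (b$upper - b$lower < 1e-12) {
    message(sprintf("degenerate pi123 bounds [%g, %g]: value forced",
                    b$lower, b$upper))
    x <- b$lower
    value <- nll_at(x)
  } else {
    tol <- max(1e-9, options$tri_rel_tol * (b$upper - b$lower))
    o <- optimize(nll_at, c(b$lower, b$upper), tol = tol)
    # compare interior optimum against the boundary values: the likelihood
    # is often monotone in pi123 (truth at a bound in core/ring designs)
    cands <- c(o$minimum, b$lower, b$upper)
    vals <- c(o$objective, nll_at(b$lower), nll_at(b$upper))
    x <- cands[which.min(vals)]
    value <- min(vals)
  }
  params <- trivariate_params(uni, pairs, x)
  structure(list(pi123 = x, params = params,
                 pattern = derive_pattern(pu, pb, x), value = value,
                 bounds = b, rho_adjusted = any(adj)),
            class = "tri_fit")
}

#' Full stepwise fit of a triad
#'
#' Runs the three univariate fits, the three bivariate fits (univariate
#' parameters frozen) and the trivariate step (everything else frozen), and
#' assembles the fitted parameters and overlap pattern.  The stepwise
#' freezing guarantees that the univariate marginals and pairwise overlaps
#' implied by the final parameters equal the stage estimates exactly.
#'
#' @param template A `mix_template` over three traits.
#' @param grids List with grids for dims 1, 2, 3 (defaults quantized).
#' @param options A [fit_options()].
#' @param seed Identifier recorded in the result (the template's seed).
#' @return Object of class `mix_run`: `seed`, `params`, `pattern`,
#'   `objectives` (per-stage values), `diagnostics`.
#' @export
fit_triad <- function(template, grids = NULL, options = fit_options(),
                      seed = NA_integer_) {
  if (is.null(grids)) {
    grids <- list(grid_spec(1, quantize = 2048),
                  grid_spec(2, quantize = 1024),
                  grid_spec(3, quantize = 256))
  }
  ufits <- lapply(1:3, function(i) {
    fit_univariate(template, i, grids[[1]], options)
  })
  uni <- lapply(ufits, `[[`, "params")
  pairs_idx <- list(c(1, 2), c(1, 3), c(2, 3))
  bfits <- lapply(pairs_idx, function(pr) {
    fit_bivariate_pair(template, pr, uni[pr], grids[[2]], options)
  })
  pairs <- lapply(bfits, `[[`, "params")
  tfit <- fit_tri_overlap(template, uni, pairs, grids[[3]], options)
  structure(list(
    seed = seed, params = tfit$params, pattern = tfit$pattern,
    objectives = list(
      univariate = vapply(ufits, `[[`, 0, "value"),
      bivariate = vapply(bfits, `[[`, 0, "value"),
      trivariate = tfit$value),
    diagnostics = list(uni = lapply(ufits, `[[`, "diagnostics"),
                       pairs = lapply(bfits, `[[`, "diagnostics"),
                       bounds = tfit$bounds,
                       rho_adjusted = tfit$rho_adjusted)),
    class = "mix_run")
}

#' @export
print.mix_run <- function(x, ...) {
  cat(sprintf("Stepwise mixture fit (seed %s)\n", x$seed))
  print(x$pattern)
  invisible(x)
}

#' Multi-seed stepwise runs
#'
#' For each seed, re-derives the optimization template (random pruning and
#' random subsetting under that seed) and executes the full stepwise fit.
#' Individual run failures are recorded, not fatal, provided at least one
#' run succeeds.
#'
#' @param harmonized A QC-filtered `harmonized_sumstats`.
#' @param reference The `ld_reference`.
#' @param config A [qc_config()]; its `rand_prune_seed` may be a vector.
#' @param seeds Seeds to run (default: `config$rand_prune_seed`).
#' @param grids,options Passed to [fit_triad()].
#' @return List of `mix_run` objects (class `mix_runs`), with failed seeds
#'   in attribute `failures`.
#' @export
multi_run <- function(harmonized, reference, config,
                      seeds = config$rand_prune_seed, grids = NULL,
                      options = fit_options()) {
  stopifnot(length(seeds) >= 1L)
  runs <- list()
  failures <- list()
  for (s in seeds) {
    cfg <- config
    cfg$rand_prune_seed <- s
    res <- tryCatch({
      idx <- prune_and_subset(harmonized, reference, cfg)
      tpl <- build_template(reference, harmonized, idx)
      fit_triad(tpl, grids, options, seed = as.integer(s))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("run with seed ", s, " failed: ", conditionMessage(res))
      failures[[as.character(s)]] <- conditionMessage(res)
    } else {
      runs[[length(runs) + 1L]] <- res
    }
  }
  if (!length(runs)) stop("all runs failed")
  structure(runs, failures = failures, class = "mix_runs")
}

#' Median pattern and representative run
#'
#' Computes component-wise medians of the seven overlap masses across runs
#' and returns the run minimizing the deviation from that median vector
#' (Euclidean metric by default; ties broken by lowest seed).  The median
#' vector itself is reported but is not guaranteed to be feasible.
#'
#' @param runs A list of `mix_run` objects (e.g. from [multi_run()]).
#' @param metric `"euclidean"` or `"manhattan"` deviation over the seven
#'   masses.
#' @return List with `median_pattern` (named 7-vector), `representative`
#'   (a `mix_run`), `deviations`, and `median_feasible`.
#' @export
select_representative <- function(runs, metric = c("euclidean",
                                                   "manhattan")) {
  metric <- match.arg(metric)
  if (!length(runs)) stop("no successful runs to select from")
  keys <- c("pi1", "pi2", "pi3", "pi12", "pi13", "pi23", "pi123")
  M <- t(vapply(runs, function(r) unclass(r$pattern)[keys], numeric(7)))
  med <- apply(M, 2, median)
  names(med) <- keys
  dev <- apply(M, 1, function(row) {
    if (metric == "euclidean") sqrt(sum((row - med)^2)) else
      sum(abs(row - med))
  })
  seeds <- vapply(runs, function(r) as.numeric(r$seed), 0)
  ord <- order(dev, seeds)
  med_pat <- c(med, pi0 = 1 - sum(med))
  feas <- check_feasibility(structure(med_pat, class = "overlap_pattern"))
  list(median_pattern = med, representative = runs[[ord[1]]],
       deviations = dev, median_feasible = feas$feasible)
}
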