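# Synthetic-data generation: scenario-based causal-set designs, block-LD
# genotypes, additive phenotypes with target SNP-heritability and per-variant
# linear-regression association statistics, plus a direct model-level
# z-score simulator used as a fast oracle for the likelihood.

#' Scenario specification for simulated triads
#'
#' The three canonical designs share equal polygenicity and SNP-heritability
#' across phenotypes and differ only in how causal sets overlap:
#' * `"core"`: only triple overlap -- half of each phenotype's causal
#'   variants influence both other phenotypes
#'   (`pi1 = pi2 = pi3 = pi123 = pi/2`, pairwise regions empty);
#' * `"ring"`: no triple overlap -- each phenotype shares half its causal
#'   set with each of the other two (`pi12 = pi13 = pi23 = pi/2`,
#'   specific and triple regions empty);
#' * `"equilibrium"`: balanced mixture, all seven regions equal (`pi/4`).
#'
#' @param name One of `"core"`, `"ring"`, `"equilibrium"`, or `"custom"`.
#' @param polygenicity Per-phenotype univariate polygenicity (fraction of
#'   panel variants influencing each phenotype).
#' @param h2 Target SNP-heritability per phenotype (scalar or length 3).
#' @param pattern For `"custom"`: an [overlap_pattern()] of causal-set
#'   masses.
#' @return Object of class `scenario_spec` with the causal-set pattern,
#'   per-phenotype polygenicities and heritabilities.
#' @export
scenario_spec <- function(name = c("core", "ring", "equilibrium", "custom"),
                          polygenicity = 0.002, h2 = 0.4, pattern = NULL) {
  name <- match.arg(name)
  p <- polygenicity
  pat <- switch(name,
    core = overlap_pattern(p / 2, p / 2, p / 2, 0, 0, 0, p / 2),
    ring = overlap_pattern(0, 0, 0, p / 2, p / 2, p / 2, 0),
    equilibrium = overlap_pattern(p / 4, p / 4, p / 4, p / 4, p / 4, p / 4,
                                  p / 4),
    custom = {
      if (is.null(pattern)) stop("custom scenario requires a pattern")
      pattern
    })
  m <- unclass(pat)
  pi_u <- c(m["pi1"] + m["pi12"] + m["pi13"] + m["pi123"],
            m["pi2"] + m["pi12"] + m["pi23"] + m["pi123"],
            m["pi3"] + m["pi13"] + m["pi23"] + m["pi123"])
  h2 <- rep(h2, length.out = 3)
  if (any(h2 < 0 | h2 >= 1)) stop("h2 must lie in [0, 1)")
  structure(list(name = name, pattern = pat,
                 pi_u = unname(pi_u), h2 = h2),
            class = "scenario_spec")
}

#' Assign causal-variant sets honoring a scenario's overlap design
#'
#' Draws seven disjoint region sets uniformly without replacement.  Shared
#' regions get `round(panel_size * mass)` variants (half away from zero);
#' each phenotype-specific region is then sized so the phenotype's total
#' causal count equals `round(panel_size * pi_u)` exactly (residual rounding
#' is absorbed into the specific regions, or equivalently the null region).
#'
#' @param spec A [scenario_spec()].
#' @param panel_size Number of variants in the panel.
#' @param seed Integer seed.
#' @return List with `regions` (list of 7 integer index vectors named
#'   `pi1..pi123`) and `phenotypes` (list of 3 index vectors, the unions).
#' @export
assign_causal_sets <- function(spec, panel_size, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"), panel_size >= 1)
  m <- unclass(spec$pattern)
  shared <- c("pi12", "pi13", "pi23", "pi123")
  cnt <- round_half_away(panel_size * m[c("pi1", "pi2", "pi3", shared)])
  totals <- round_half_away(panel_size * spec$pi_u)
  in_pheno <- list(pi1 = 1, pi2 = 2, pi3 = 3, pi12 = c(1, 2),
                   pi13 = c(1, 3), pi23 = c(2, 3), pi123 = 1:3)
  for (i in 1:3) {
    sh <- sum(cnt[shared][vapply(in_pheno[shared],
                                 function(ph) i %in% ph, TRUE)])
    cnt[paste0("pi", i)] <- totals[i] - sh
    if (cnt[paste0("pi", i)] < 0) {
      stop("region masses inconsistent with phenotype ", i, " polygenicity")
    }
  }
  if (sum(cnt) > panel_size) stop("region masses sum above 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  pool <- sample.int(panel_size, sum(cnt))
  grp <- factor(rep.int(seq_along(cnt), cnt), levels = seq_along(cnt))
  regions <- split(pool, grp)
  names(regions) <- names(cnt)
  regions <- lapply(regions, sort)
  phen <- lapply(1:3, function(i) {
    sort(unlist(regions[vapply(in_pheno, function(ph) i %in% ph, TRUE)],
                use.names = FALSE))
  })
  list(regions = regions, phenotypes = phen)
}

# bivariate normal orthant probability P(X < a, Y < b) for correlation rho,
# by 1-D quadrature (used only to calibrate the genotype copula)
.pnorm2 <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a) * pnorm(b))
  f <- function(x) pnorm((b - rho * x) / sqrt(1 - rho^2)) * dnorm(x)
  integrate(f, -8, a, rel.tol = 1e-8)$value
}

# expected dosage correlation between two variants with allele frequencies
# p1, p2 whose haplotype alleles share a Gaussian factor with correlation rho
.copula_dosage_cor <- function(rho, p1, p2) {
  q1 <- qnorm(p1); q2 <- qnorm(p2)
  (.pnorm2(q1, q2, rho) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

#' Block-LD genotypes from a shared latent haplotype factor
#'
#' Variants come in consecutive blocks; within a block, each haplotype's
#' alleles share a Gaussian latent factor whose loading is calibrated (by
#' root finding on the Gaussian-copula binary correlation, averaged over the
#' frequency distribution) so the expected pairwise dosage correlation is
#' approximately `within_block_r`.  Blocks are mutually independent; allele
#' frequencies are drawn uniformly from `freq_range`; dosages are hard calls
#' in Hardy-Weinberg proportions.
#'
#' @param n_individuals,n_variants Dimensions of the dosage matrix.
#' @param block_size Number of variants per LD block.
#' @param within_block_r Target within-block dosage correlation in `[0, 1)`.
#' @param freq_range Range of population allele frequencies.
#' @param seed Integer seed.
#' @param bp_spacing Physical spacing between adjacent variants (bp).
#' @return List with `genotypes` (individuals x variants, dosages 0/1/2) and
#'   `variants` (data frame `id, chr, bp, a1, a2, freq` -- `freq` is the
#'   realized sample frequency of allele `a1`).
#' @export
generate_block_genotypes <- function(n_individuals, n_variants,
                                     block_size = 10, within_block_r = 0.7,
                                     freq_range = c(0.05, 0.5), seed = 1L,
                                     bp_spacing = 5000) {
  stopifnot(within_block_r >= 0, within_block_r < 1, block_size >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  freq <- runif(n_variants, freq_range[1], freq_range[2])
  rho <- 0
  if (within_block_r > 0 && block_size > 1) {
    pp <- matrix(runif(100, freq_range[1], freq_range[2]), ncol = 2)
    mean_cor <- function(r) {
      mean(apply(pp, 1, function(q) .copula_dosage_cor(r, q[1], q[2])))
    }
    attain <- mean_cor(0.9995)
    if (attain < within_block_r) {
      # frequency mismatch between variants caps the binary correlation;
      # fall back to the maximum loading (warn only on a large shortfall)
      rho <- 0.9995
      if (attain < within_block_r - 0.05) {
        warning(sprintf(paste0("target within-block correlation %.2f ",
                               "unattainable for this frequency range ",
                               "(max ~%.2f); using the maximum loading"),
                        within_block_r, attain))
      }
    } else {
      rho <- uniroot(function(r) mean_cor(r) - within_block_r,
                     c(1e-6, 0.9995), tol = 1e-4)$root
    }
  }
  G <- matrix(0, n_individuals, n_variants)
  n_blocks <- ceiling(n_variants / block_size)
  thr <- qnorm(freq)
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1) * block_size + 1):min(b * block_size, n_variants)
    for (hap in 1:2) {
      f <- rnorm(n_individuals)
      lat <- sqrt(rho) * f +
        sqrt(1 - rho) * matrix(rnorm(n_individuals * length(cols)),
                               n_individuals)
      G[, cols] <- G[, cols] +
        (lat < matrix(thr[cols], n_individuals, length(cols), byrow = TRUE))
    }
  }
  realized <- colMeans(G) / 2
  variants <- data.frame(
    id = sprintf("v%07d", seq_len(n_variants)), chr = 1L,
    bp = bp_spacing * seq_len(n_variants), a1 = "A", a2 = "G",
    freq = realized, stringsAsFactors = FALSE)
  list(genotypes = G, variants = variants)
}

#' Simulate quantitative phenotypes and per-variant GWAS statistics
#'
#' Per phenotype: standard-normal effect sizes on the causal variants, a
#' genetic score from the dosages scaled so the genetic variance equals the
#' target SNP-heritability, Gaussian environmental noise with variance
#' `var_genetic * (1 - h2) / h2` making `var(genetic) / var(total) = h2`,
#' and per-variant simple linear regression of the phenotype on dosage
#' giving `beta`, `se`, `z = beta / se` and `n = n_individuals`.
#'
#' @param genotypes Individuals x variants dosage matrix.
#' @param causal_sets List of three causal index vectors (e.g.
#'   `assign_causal_sets(...)$phenotypes`).
#' @param spec A [scenario_spec()] (its `h2` is used).
#' @param variants Variant index data frame (as from
#'   [generate_block_genotypes()]).
#' @param seed Integer seed.
#' @return List of three summary-statistics data frames (`id, chr, bp, a1,
#'   a2, z, n, freq`), plus attribute `realized_h2`.
#' @export
simulate_phenotypes_and_gwas <- function(genotypes, causal_sets, spec,
                                         variants, seed = 1L) {
  stopifnot(length(causal_sets) == 3L)
  if (any(unlist(causal_sets) > ncol(genotypes))) {
    stop("causal sets exceed the panel")
  }
  h2 <- spec$h2
  if (any(h2 < 0 | h2 >= 1)) stop("h2 must lie in [0, 1)")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  n <- nrow(genotypes)
  V <- ncol(genotypes)
  sdg <- apply(genotypes, 2, sd)
  mg <- colMeans(genotypes)
  out <- vector("list", 3)
  realized <- numeric(3)
  for (ph in 1:3) {
    cs <- causal_sets[[ph]]
    if (length(cs) && h2[ph] > 0) {
      beta <- rnorm(length(cs))
      g <- as.numeric(genotypes[, cs, drop = FALSE] %*% beta)
      g <- g - mean(g)
      g <- g * sqrt(h2[ph]) / sd(g)
    } else {
      g <- numeric(n)
    }
    noise <- rnorm(n)
    if (var(g) > 0) {
      noise <- noise - g * (cov(noise, g) / var(g))  # orthogonal to g
    }
    noise <- (noise - mean(noise)) / sd(noise) * sqrt(1 - h2[ph])
    y <- g + noise
    realized[ph] <- var(g) / var(y)
    # per-variant simple regression via correlations
    ys <- (y - mean(y)) / sd(y)
    r <- as.numeric(crossprod(genotypes, ys)) / (n - 1)
    r <- r / ifelse(sdg > 0, sdg, Inf)
    r <- pmin(pmax(r, -0.999999), 0.999999)
    z <- r * sqrt(n - 2) / sqrt(1 - r^2)
    out[[ph]] <- data.frame(
      id = variants$id, chr = variants$chr, bp = variants$bp,
      a1 = variants$a1, a2 = variants$a2, z = z, n = n,
      freq = variants$freq, stringsAsFactors = FALSE)
  }
  attr(out, "realized_h2") <- realized
  out
}

#' Write a summary-statistics table in the package text format
#'
#' @param sumstats Data frame with canonical columns (`id, chr, bp, a1, a2,
#'   z, n, freq`, optionally `info`).
#' @param path Output path.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$id, CHR = sumstats$chr, BP = sumstats$bp,
                    A1 = sumstats$a1, A2 = sumstats$a2, Z = sumstats$z,
                    N = sumstats$n)
  if (!is.null(sumstats$freq)) out$FRQ <- sumstats$freq
  if (!is.null(sumstats$info)) out$INFO <- sumstats$info
  write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Synthetic block-structured LD reference
#'
#' Builds an `ld_reference` directly: variants in consecutive blocks of
#' `block_size` with constant pairwise `r2 = within_block_r^2` inside each
#' block, heterozygosities from frequencies drawn uniformly in `freq_range`.
#' Useful for model-level simulations where genotypes are not needed.
#'
#' @inheritParams generate_block_genotypes
#' @return An `ld_reference`.
#' @export
simulate_block_reference <- function(n_variants, block_size = 10,
                                     within_block_r = 0.7,
                                     freq_range = c(0.05, 0.5), seed = 1L,
                                     bp_spacing = 5000) {
  stopifnot(within_block_r >= 0, within_block_r < 1, block_size >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  freq <- runif(n_variants, freq_range[1], freq_range[2])
  variants <- data.frame(
    id = sprintf("v%07d", seq_len(n_variants)), chr = 1L,
    bp = bp_spacing * seq_len(n_variants), a1 = "A", a2 = "G",
    freq = freq, stringsAsFactors = FALSE)
  variants$het <- heterozygosity_from_freq(freq)
  block <- (seq_len(n_variants) - 1L) %/% block_size
  r2 <- within_block_r^2
  if (r2 < 1e-12 || block_size == 1) {
    ptr <- 0:n_variants
    nbr_idx <- seq_len(n_variants)
    nbr_r2 <- rep(1, n_variants)
  } else {
    sizes <- tabulate(block + 1L)
    lens <- sizes[block + 1L]
    ptr <- c(0L, cumsum(lens))
    starts <- c(0L, cumsum(sizes))[block + 1L]
    nbr_idx <- sequence(lens) + rep.int(starts, lens)
    nbr_r2 <- rep(r2, length(nbr_idx))
    nbr_r2[nbr_idx == rep.int(seq_len(n_variants), lens)] <- 1
  }
  structure(list(variants = variants, ptr = as.integer(ptr),
                 nbr_idx = as.integer(nbr_idx), nbr_r2 = nbr_r2),
            class = "ld_reference")
}

#' Draw z-scores directly from the causal-mixture model
#'
#' Samples each panel variant's component label from the eight-component
#' mixture and its direct effects from the component's Gaussian, then forms
#' `z_ij = sum_k sqrt(N_i h_k) r_jk beta_ik + eps_j` over the reference
#' neighbor lists with `eps ~ N(0, Sigma0)` -- exact samples from the
#' likelihood's generative model (the oracle for CF and recovery tests).
#'
#' @param reference An `ld_reference`.
#' @param params A [trivariate_params()].
#' @param n GWAS sample size per phenotype (scalar or length 3).
#' @param seed Integer seed.
#' @return V x 3 matrix of z-scores.
#' @export
simulate_z_from_model <- function(reference, params, n, seed = 1L) {
  stopifnot(inherits(reference, "ld_reference"),
            inherits(params, "trivariate_params"))
  n <- rep(n, length.out = 3)
  V <- nrow(reference$variants)
  comps <- build_mixture_components(params, 1:3)
  w <- vapply(comps, `[[`, 0, "weight")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  lab <- sample.int(length(comps), V, replace = TRUE, prob = w)
  beta <- matrix(0, V, 3)
  for (c in seq_along(comps)) {
    aff <- comps[[c]]$affected
    if (!any(aff)) next
    rows <- which(lab == c)
    if (!length(rows)) next
    S <- comps[[c]]$covariance[aff, aff, drop = FALSE]
    L <- chol(S + diag(1e-14, nrow(S)))
    beta[rows, aff] <- matrix(rnorm(length(rows) * sum(aff)),
                              length(rows)) %*% L
  }
  # LD-weighted sums over neighbor lists (signs of r are irrelevant for the
  # model distribution; +sqrt(r2) is used throughout)
  lens <- diff(reference$ptr)
  src <- rep.int(seq_len(V), lens)
  dst <- reference$nbr_idx
  amp <- sqrt(reference$nbr_r2) * sqrt(reference$variants$het[dst])
  s0 <- vapply(params$uni, `[[`, 0, "sigma0_sq")
  r0 <- vapply(params$pairs, `[[`, 0, "rho0")
  S0 <- residual_covariance(s0, r0)$matrix
  z <- matrix(rnorm(V * 3), V, 3) %*% chol(S0)
  for (a in 1:3) {
    nz <- which(beta[dst, a] != 0)
    if (length(nz)) {
      contrib <- amp[nz] * beta[dst[nz], a]
      agg <- rowsum(contrib, src[nz])
      z[as.integer(rownames(agg)), a] <-
        z[as.integer(rownames(agg)), a] + sqrt(n[a]) * agg[, 1]
    }
  }
  colnames(z) <- paste0("z", 1:3)
  z
}

#' Implied SNP-heritability of a univariate mixture fit
#'
#' On the per-allele effect scale the variance explained is
#' `sum_k pi_u * h_k * sigma_beta_sq` over the panel variants.
#'
#' @param uni A [univariate_params()].
#' @param reference The `ld_reference` whose panel defines the sum.
#' @return Scalar implied heritability.
#' @export
implied_heritability <- function(uni, reference) {
  uni$pi_u * uni$sigma_beta_sq * sum(reference$variants$het)
}

#' Discoverability needed for a target SNP-heritability
#'
#' Inverse of [implied_heritability()]: the per-allele effect-size variance
#' such that `pi_u * sigma^2 * sum(h_k) = h2` on the given panel.
#'
#' @param h2 Target heritability.
#' @param pi_u Polygenicity.
#' @param reference The `ld_reference`.
#' @return Scalar `sigma_beta_sq`.
#' @export
discoverability_for_h2 <- function(h2, pi_u, reference) {
  h2 / (pi_u * sum(reference$variants$het))
}
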