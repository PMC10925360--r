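# Parameter containers and pattern algebra for the trivariate causal mixture.
#
# Conventions: polygenicities are fractions of panel variants; discoverability
# sigma_beta_sq is the variance of per-allele direct effect sizes (variances,
# not standard deviations, are stored -- the likelihood consumes sigma^2
# directly); sigma0_sq is the residual z-score variance.

#' Feasibility tolerance for overlap masses
#'
#' Optimization returns boundary values with floating-point noise, so masses
#' are allowed to undershoot zero by this much.
#' @keywords internal
.FEAS_TOL <- 1e-10

#' Univariate mixture parameters
#'
#' @param pi_u Fraction of variants influencing the phenotype, in `[0, 1]`.
#' @param sigma_beta_sq Variance of direct (per-allele) effect sizes, `>= 0`.
#' @param sigma0_sq Residual z-score variance, `> 0`.
#' @return An object of class `univariate_params`.
#' @examples
#' univariate_params(2e-3, 5e-3, 1.0)
#' @export
univariate_params <- function(pi_u, sigma_beta_sq, sigma0_sq) {
  stopifnot(is.numeric(pi_u), length(pi_u) == 1L, is.finite(pi_u))
  if (pi_u < 0 || pi_u > 1) stop("pi_u must lie in [0, 1]")
  if (!is.finite(sigma_beta_sq) || sigma_beta_sq < 0) {
    stop("sigma_beta_sq must be >= 0")
  }
  if (!is.finite(sigma0_sq) || sigma0_sq <= 0) stop("sigma0_sq must be > 0")
  structure(list(pi_u = pi_u, sigma_beta_sq = sigma_beta_sq,
                 sigma0_sq = sigma0_sq),
            class = "univariate_params")
}

#' Pairwise overlap parameters
#'
#' @param pi_b Shared polygenicity of the pair (fraction of variants
#'   influencing both phenotypes).
#' @param rho Correlation of effect sizes within the pairwise overlap.
#' @param rho0 Correlation between the two studies' residuals (e.g. from
#'   sample overlap).
#' @return An object of class `pair_params`.
#' @export
pair_params <- function(pi_b, rho = 0, rho0 = 0) {
  stopifnot(is.numeric(pi_b), length(pi_b) == 1L, is.finite(pi_b))
  if (pi_b < 0 || pi_b > 1) stop("pi_b must lie in [0, 1]")
  if (!is.finite(rho) || abs(rho) > 1) stop("|rho| must be <= 1")
  if (!is.finite(rho0) || abs(rho0) > 1) stop("|rho0| must be <= 1")
  structure(list(pi_b = pi_b, rho = rho, rho0 = rho0), class = "pair_params")
}

#' Full trivariate model parameters
#'
#' Bundles the nineteen free scalars of the model: three univariate triplets
#' (`pi_u`, `sigma_beta_sq`, `sigma0_sq`), three pairwise triplets (`pi_b`,
#' `rho`, `rho0`) for pairs (1,2), (1,3), (2,3), and the triple-overlap
#' polygenicity `pi123`.
#'
#' @param uni List of three [univariate_params()] (phenotypes 1, 2, 3).
#' @param pairs List of three [pair_params()] in the order 12, 13, 23.
#' @param pi123 Triple-overlap polygenicity; must lie within the feasibility
#'   bounds implied by `uni` and `pairs` (see [tri_overlap_bounds()]).
#' @return An object of class `trivariate_params`.
#' @export
trivariate_params <- function(uni, pairs, pi123) {
  stopifnot(length(uni) == 3L, length(pairs) == 3L)
  if (!all(vapply(uni, inherits, TRUE, "univariate_params")) ||
      !all(vapply(pairs, inherits, TRUE, "pair_params"))) {
    stop("uni must hold univariate_params and pairs must hold pair_params")
  }
  pu <- vapply(uni, `[[`, 0, "pi_u")
  pb <- vapply(pairs, `[[`, 0, "pi_b")
  mins <- c(min(pu[1], pu[2]), min(pu[1], pu[3]), min(pu[2], pu[3]))
  bad <- which(pb > mins + .FEAS_TOL)
  if (length(bad)) {
    stop("pi_b exceeds the smaller marginal pi_u for pair(s) ",
         paste(c("12", "13", "23")[bad], collapse = ", "))
  }
  b <- tri_overlap_bounds(pu, pb)
  if (pi123 < b$lower - .FEAS_TOL || pi123 > b$upper + .FEAS_TOL) {
    stop(sprintf("pi123 = %g outside feasibility bounds [%g, %g]",
                 pi123, b$lower, b$upper))
  }
  structure(list(uni = uni, pairs = pairs, pi123 = pi123),
            class = "trivariate_params")
}

#' Number of free parameters of the trivariate model
#'
#' @param params A [trivariate_params()] object.
#' @return Integer count of free scalars (3x3 univariate + 3x3 pairwise + 1).
#' @export
n_free_parameters <- function(params) {
  stopifnot(inherits(params, "trivariate_params"))
  3L * length(params$uni[[1]]) + 3L * length(params$pairs[[1]]) + 1L
}

#' Seven-region overlap pattern
#'
#' The seven non-null mixture masses of the trivariate model plus the null
#' fraction `pi0 = 1 - sum(other seven)`.
#'
#' @param pi1,pi2,pi3 Phenotype-specific polygenicities.
#' @param pi12,pi13,pi23 Phenotype pair-specific polygenicities.
#' @param pi123 Triple-overlap polygenicity.
#' @param check If `TRUE` (default) error when the pattern is infeasible.
#' @return An object of class `overlap_pattern`: a named numeric vector with
#'   components `pi1, pi2, pi3, pi12, pi13, pi23, pi123, pi0`.
#' @export
overlap_pattern <- function(pi1, pi2, pi3, pi12, pi13, pi23, pi123,
                            check = TRUE) {
  m <- c(pi1 = unname(pi1), pi2 = unname(pi2), pi3 = unname(pi3),
         pi12 = unname(pi12), pi13 = unname(pi13), pi23 = unname(pi23),
         pi123 = unname(pi123))
  p <- structure(c(m, pi0 = 1 - sum(m)), class = "overlap_pattern")
  if (check) {
    f <- check_feasibility(p)
    if (!f$feasible) {
      stop("infeasible overlap pattern: ",
           paste(f$violations, collapse = "; "))
    }
  }
  p
}

#' @export
print.overlap_pattern <- function(x, ...) {
  cat("Trivariate overlap pattern (fractions of panel variants):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Derive the seven-region pattern from marginal quantities
#'
#' Applies the subtraction formulas `pi12 = pi12b - pi123`,
#' `pi1 = pi1u - pi12 - pi13 - pi123` (and permutations) to turn univariate
#' polygenicities, pairwise overlaps and the triple overlap into the seven
#' disjoint region masses, with `pi0` as the complement.
#'
#' @param pi_u Numeric vector of three univariate polygenicities.
#' @param pi_b Numeric vector of three pairwise overlaps (order 12, 13, 23).
#' @param pi123 Triple-overlap polygenicity.
#' @param tol Feasibility tolerance on derived masses.
#' @return An [overlap_pattern()].
#' @examples
#' derive_pattern(c(0.002, 0.002, 0.002), c(0.001, 0.001, 0.001), 0.001)
#' @export
derive_pattern <- function(pi_u, pi_b, pi123, tol = .FEAS_TOL) {
  stopifnot(length(pi_u) == 3L, length(pi_b) == 3L, length(pi123) == 1L)
  if (any(!is.finite(c(pi_u, pi_b, pi123))) ||
      any(c(pi_u, pi_b, pi123) < -tol) || any(c(pi_u, pi_b, pi123) > 1)) {
    stop("pi_u, pi_b, pi123 must lie in [0, 1]")
  }
  pi12 <- pi_b[1] - pi123
  pi13 <- pi_b[2] - pi123
  pi23 <- pi_b[3] - pi123
  pi1 <- pi_u[1] - pi12 - pi13 - pi123
  pi2 <- pi_u[2] - pi12 - pi23 - pi123
  pi3 <- pi_u[3] - pi13 - pi23 - pi123
  m <- c(pi1 = pi1, pi2 = pi2, pi3 = pi3, pi12 = pi12, pi13 = pi13,
         pi23 = pi23, pi123 = pi123)
  if (any(m < -tol)) {
    bad <- names(m)[m < -tol]
    stop("infeasible overlap: negative mass in region(s) ",
         paste(bad, collapse = ", "))
  }
  m <- pmax(m, 0)  # clip floating-point noise at the boundary
  overlap_pattern(m["pi1"], m["pi2"], m["pi3"], m["pi12"], m["pi13"],
                  m["pi23"], m["pi123"], check = FALSE)
}

#' Check feasibility of an overlap pattern
#'
#' @param pattern An [overlap_pattern()] (or named vector with its fields).
#' @param tol Absolute tolerance on masses and on the sum-to-one constraint.
#' @return A list with `feasible` (logical) and `violations` (character).
#' @export
check_feasibility <- function(pattern, tol = .FEAS_TOL) {
  m <- unclass(pattern)
  viol <- character(0)
  neg <- names(m)[m < -tol]
  if (length(neg)) {
    viol <- c(viol, paste0("negative mass in ", paste(neg, collapse = ", ")))
  }
  if (abs(sum(m) - 1) > tol) {
    viol <- c(viol, sprintf("masses sum to %.15g, not 1", sum(m)))
  }
  list(feasible = length(viol) == 0L, violations = viol)
}

# round() half-to-even is not what reporting conventions use; percentages are
# rounded half away from zero.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer percentages of the seven overlap regions
#'
#' Each non-null mass is expressed as a percentage of `reference_total` and
#' rounded to the nearest integer (half away from zero).  With
#' `reference_total = "self"` the reference is the pattern's own combined
#' total (sum of the seven non-null masses), so the percentages add up to
#' approximately 100; with a foreign total (e.g. another pattern's combined
#' total, the convention used when comparing a naive expectation against a
#' fitted pattern) the sum can differ from 100.
#'
#' @param pattern An [overlap_pattern()].
#' @param reference_total `"self"` or a positive scalar.
#' @return Named integer vector of seven percentages.
#' @export
pattern_percentages <- function(pattern, reference_total = "self") {
  m <- unclass(pattern)[c("pi1", "pi2", "pi3", "pi12", "pi13", "pi23",
                          "pi123")]
  total <- if (identical(reference_total, "self")) sum(m) else reference_total
  if (!is.numeric(total) || length(total) != 1L || !is.finite(total) ||
      total <= 0) {
    stop("reference_total must be \"self\" or a positive scalar")
  }
  p <- round_half_away(100 * m / total)
  storage.mode(p) <- "integer"
  p
}

#' Combined total of a pattern's non-null regions
#' @param pattern An [overlap_pattern()].
#' @return Sum of the seven non-null masses.
#' @export
pattern_total <- function(pattern) {
  sum(unclass(pattern)[c("pi1", "pi2", "pi3", "pi12", "pi13", "pi23",
                         "pi123")])
}

#' Serialize / deserialize an overlap pattern as flat JSON
#'
#' Keys `pi1, pi2, pi3, pi12, pi13, pi23, pi123, pi0`, values as fractions.
#' @param pattern An [overlap_pattern()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `pattern_to_json()`: JSON string (invisibly when written to file);
#'   `pattern_from_json()`: an [overlap_pattern()].
#' @export
pattern_to_json <- function(pattern, path = NULL) {
  x <- as.list(unclass(pattern))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @rdname pattern_to_json
#' @param json JSON string or path to a JSON file.
#' @export
pattern_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  need <- c("pi1", "pi2", "pi3", "pi12", "pi13", "pi23", "pi123")
  if (!all(need %in% names(x))) {
    stop("pattern JSON must contain keys ", paste(need, collapse = ", "))
  }
  overlap_pattern(x$pi1, x$pi2, x$pi3, x$pi12, x$pi13, x$pi23, x$pi123,
                  check = FALSE)
}

# Internal: covariance block of the full trivariate model for the component
# affecting the phenotype set `affected` (logical length 3).  Off-diagonals
# use rho of the corresponding pair whenever both phenotypes are affected.
.component_cov3 <- function(affected, sigma, rho) {
  S <- matrix(0, 3, 3)
  pair_idx <- rbind(c(1, 2), c(1, 3), c(2, 3))
  for (i in 1:3) if (affected[i]) S[i, i] <- sigma[i]^2
  for (p in 1:3) {
    i <- pair_idx[p, 1]; j <- pair_idx[p, 2]
    if (affected[i] && affected[j]) {
      S[i, j] <- S[j, i] <- rho[p] * sigma[i] * sigma[j]
    }
  }
  S
}

#' Build the Gaussian mixture components of the causal model
#'
#' For three phenotypes the direct effects follow an eight-component mixture:
#' a null component plus one component per non-empty subset of phenotypes,
#' with covariance blocks that have zero rows/columns for unaffected
#' phenotypes and off-diagonals `rho_ij sigma_i sigma_j` inside overlaps.
#' For a subset of the phenotypes (`dims`) the mixture is marginalized: the
#' weight of each reduced component sums the trivariate weights over the
#' affect-status of the dropped phenotypes (e.g. in `dims = c(1, 2)` the
#' weight of "affects phenotype 1 only" is `pi1 + pi13`).
#'
#' @param params A [trivariate_params()].
#' @param dims Integer subset of `1:3`, the phenotypes modeled.
#' @return List of components, each a list with `weight`, `covariance`
#'   (`length(dims)` square matrix) and `affected` (logical over `dims`).
#' @examples
#' p <- example_params()
#' length(build_mixture_components(p, 1:3))  # 8
#' @export
build_mixture_components <- function(params, dims = 1:3) {
  stopifnot(inherits(params, "trivariate_params"))
  dims <- sort(unique(as.integer(dims)))
  if (length(dims) < 1L || !all(dims %in% 1:3)) {
    stop("dims must be a nonempty subset of 1:3")
  }
  sigma <- sqrt(vapply(params$uni, `[[`, 0, "sigma_beta_sq"))
  rho <- vapply(params$pairs, `[[`, 0, "rho")
  if (any(abs(rho) > 1)) stop("invalid parameters: |rho| > 1")
  pat <- derive_pattern(vapply(params$uni, `[[`, 0, "pi_u"),
                        vapply(params$pairs, `[[`, 0, "pi_b"),
                        params$pi123)
  # weight of each of the 8 affect-status cells, in subset order
  subsets <- list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                  c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
                  c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
                  c(FALSE, TRUE, TRUE), c(TRUE, TRUE, TRUE))
  w8 <- unname(unclass(pat)[c("pi0", "pi1", "pi2", "pi3", "pi12", "pi13",
                              "pi23", "pi123")])
  # marginalize over dropped phenotypes: group cells by affect-status on dims
  key <- vapply(subsets, function(s) paste(as.integer(s[dims]),
                                           collapse = ""), "")
  comps <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    affected <- subsets[[idx[1]]][dims]
    S3 <- .component_cov3(c(FALSE, FALSE, FALSE) | replace(
      logical(3), dims[affected], TRUE), sigma, rho)
    S <- S3[dims, dims, drop = FALSE]
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-12) stop("invalid parameters: non-PSD covariance block")
    comps[[length(comps) + 1L]] <- list(weight = sum(w8[idx]),
                                        covariance = S, affected = affected)
  }
  # deterministic order: null, singles 1..3, pairs 12,13,23, triple
  ord <- order(vapply(comps, function(cp) sum(cp$affected), 0),
               vapply(comps, function(cp) paste(1L - as.integer(cp$affected),
                                                collapse = ""), ""))
  comps[ord]
}

#' Example trivariate parameters (balanced "equilibrium" design)
#'
#' All seven overlap masses equal to 5e-4 (univariate polygenicity 0.002),
#' discoverability 5e-3, unit residual variance, zero correlations.
#' @param mass Per-region mass.
#' @return A [trivariate_params()].
#' @export
example_params <- function(mass = 5e-4) {
  uni <- replicate(3, univariate_params(4 * mass, 5e-3, 1.0),
                   simplify = FALSE)
  pairs <- replicate(3, pair_params(2 * mass, 0, 0), simplify = FALSE)
  trivariate_params(uni, pairs, mass)
}
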