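# Feasibility bounds on the triple overlap and the maximum-entropy "naive
# expectation" reconstructed from univariate and pairwise polygenicities.

#' Feasibility bounds for the triple-overlap polygenicity
#'
#' Given univariate polygenicities and pairwise overlaps, the triple overlap
#' is constrained to
#' `lower = max(0, pi12b + pi13b - pi1u, pi12b + pi23b - pi2u,
#'              pi13b + pi23b - pi3u)` and
#' `upper = min(pi12b, pi13b, pi23b)`.
#'
#' @param pi_u Numeric vector of three univariate polygenicities.
#' @param pi_b Numeric vector of three pairwise overlaps (order 12, 13, 23).
#' @return List with `lower` and `upper`.
#' @examples
#' tri_overlap_bounds(c(0.002, 0.002, 0.002), c(0.001, 0.001, 0.001))
#' @export
tri_overlap_bounds <- function(pi_u, pi_b) {
  stopifnot(length(pi_u) == 3L, length(pi_b) == 3L,
            all(is.finite(c(pi_u, pi_b))))
  mins <- c(min(pi_u[1], pi_u[2]), min(pi_u[1], pi_u[3]),
            min(pi_u[2], pi_u[3]))
  if (any(pi_b > mins + .FEAS_TOL)) {
    stop("each pi_b must not exceed the smaller of its two marginals")
  }
  lower <- max(0,
               pi_b[1] + pi_b[2] - pi_u[1],
               pi_b[1] + pi_b[3] - pi_u[2],
               pi_b[2] + pi_b[3] - pi_u[3])
  upper <- min(pi_b)
  if (lower > upper + .FEAS_TOL) {
    stop(sprintf(paste0("inconsistent inputs: pi123 lower bound %g exceeds ",
                        "upper bound %g (bivariate fits mutually ",
                        "incompatible)"), lower, upper))
  }
  list(lower = min(lower, upper), upper = upper)  # clamp fp noise overlap
}

# Shannon entropy of the seven masses normalized to sum one; 0 log 0 := 0.
.pattern_entropy <- function(pi_u, pi_b, pi123) {
  m <- unclass(derive_pattern(pi_u, pi_b, pi123, tol = 1e-9))
  m <- m[c("pi1", "pi2", "pi3", "pi12", "pi13", "pi23", "pi123")]
  tot <- sum(m)
  if (tot <= 0) return(0)
  p <- m / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

# Golden-section maximization of a unimodal function on [lo, hi].
golden_section_max <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Maximum-entropy naive expectation of the triple overlap
#'
#' Selects the `pi123` within its feasibility bounds that maximizes the
#' Shannon entropy of the seven overlap masses (normalized to sum one before
#' the entropy is evaluated), and returns the corresponding naive pattern.
#' This is the pattern one would "naively" expect for a triad given only the
#' three univariate and three bivariate analyses.  The identities
#' `pi12_naive + pi123_naive = pi12b` (and permutations) hold exactly, as do
#' the univariate marginals.
#'
#' @inheritParams tri_overlap_bounds
#' @param tol Absolute tolerance of the golden-section search on `pi123`.
#' @return List with `pi123_naive` and `pattern` (an [overlap_pattern()]).
#' @examples
#' max_entropy_tri_overlap(c(0.002, 0.002, 0.002), c(0.001, 0.001, 0.001))
#' @export
max_entropy_tri_overlap <- function(pi_u, pi_b, tol = 1e-9) {
  b <- tri_overlap_bounds(pi_u, pi_b)
  if (b$upper - b$lower <= tol) {
    x <- (b$lower + b$upper) / 2  # degenerate bounds: single feasible point
  } else {
    x <- golden_section_max(function(v) .pattern_entropy(pi_u, pi_b, v),
                            b$lower, b$upper, tol = tol)
  }
  list(pi123_naive = x,
       pattern = derive_pattern(pi_u, pi_b, x, tol = 1e-9))
}
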