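#' Joint normal law of the stage-wise statistics
#'
#' Distribution of the pair (T1, T1+2) — the interim z-statistic and the
#' inverse normal combination statistic — under a given true standardized
#' effect.  Both components have unit variance; their correlation is induced
#' by the combination weights and equals sqrt(n1/n) for the default
#' square-root-of-stage-size weights.
#'
#' @param design a [gs_design] object.
#' @param delta_true true standardized effect under which the law is taken.
#' @return an object of class `"joint_law"`: a list with components `mean`
#'   (length-2 numeric, `E[T1]` and `E[T1+2]`) and `rho` (scalar correlation).
#' @examples
#' d <- gs_design(delta = 0.5, alpha = 0.025, n_per_group = 94)
#' joint_law(d, delta_true = 0.5)
#' @export
joint_law <- function(design, delta_true) {
  stopifnot(inherits(design, "gs_design"))
  if (!is.numeric(delta_true) || length(delta_true) != 1L || !is.finite(delta_true))
    stop("'delta_true' must be a single finite number")
  n1 <- design$n1_per_group
  n2 <- design$n_per_group - n1
  w <- design$weights
  m1 <- delta_true * sqrt(n1 / 2)
  m2 <- delta_true * sqrt(n2 / 2)
  # E[T1+2] = (w1 E[T1] + w2 E[T2]) / ||w||; reduces to delta*sqrt(n/2) for
  # default weights
  m12 <- (w[1] * m1 + w[2] * m2) / sqrt(sum(w^2))
  structure(list(mean = c(m1, m12), rho = design$rho), class = "joint_law")
}

#' @export
print.joint_law <- function(x, ...) {
  cat(sprintf("Joint law of (T1, T1+2): mean = (%.4f, %.4f), correlation = %.4f\n",
              x$mean[1], x$mean[2], x$rho))
  invisible(x)
}

#' Bivariate normal rectangle probability
#'
#' P(lower1 < Z1 <= upper1, lower2 < Z2 <= upper2) for a bivariate normal
#' vector with the mean and correlation of `law` and unit variances.  This is
#' the numerical kernel behind every stopping and rejection probability of the
#' two-stage design.
#'
#' Computed by inclusion-exclusion over upper-orthant probabilities evaluated
#' with the deterministic TVPACK algorithm of \pkg{mvtnorm} (absolute accuracy
#' well below 1e-8 in two dimensions).
#'
#' @param lower1,upper1 bounds for the first coordinate (`-Inf`/`Inf` allowed).
#' @param lower2,upper2 bounds for the second coordinate.
#' @param law a [joint_law] object (or any list with `mean` and `rho`).
#' @return a single probability in \[0, 1\].
#' @examples
#' law <- joint_law(gs_design(0.5, 0.025, n_per_group = 94), 0)
#' bvn_rectangle(-Inf, 0, -Inf, 0, law)  # 3/8 at rho = sqrt(1/2)
#' @export
bvn_rectangle <- function(lower1, upper1, lower2, upper2, law) {
  mean <- law$mean
  rho <- law$rho
  if (length(mean) != 2L || any(!is.finite(mean)))
    stop("joint law mean must be two finite numbers")
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("joint law correlation must satisfy |rho| < 1")
  if (lower1 > upper1 || lower2 > upper2)
    stop("lower bounds must not exceed upper bounds")
  p <- .bvn_orthant(lower1, lower2, mean, rho) -
    .bvn_orthant(upper1, lower2, mean, rho) -
    .bvn_orthant(lower1, upper2, mean, rho) +
    .bvn_orthant(upper1, upper2, mean, rho)
  min(max(p, 0), 1)
}

# P(Z1 > l1, Z2 > l2); TVPACK only accepts orthants, hence the
# inclusion-exclusion in bvn_rectangle()
.bvn_orthant <- function(l1, l2, mean, rho) {
  if (l1 == Inf || l2 == Inf) return(0)
  if (l1 == -Inf && l2 == -Inf) return(1)
  if (l1 == -Inf) return(stats::pnorm(l2 - mean[2], lower.tail = FALSE))
  if (l2 == -Inf) return(stats::pnorm(l1 - mean[1], lower.tail = FALSE))
  as.numeric(mvtnorm::pmvnorm(
    lower = c(l1, l2), upper = c(Inf, Inf), mean = mean,
    corr = matrix(c(1, rho, rho, 1), 2L), algorithm = mvtnorm::TVPACK()))
}

# strictly increasing scalar root by bisection; f(lo) < 0 < f(hi) required
.bisect_increasing <- function(f, lo, hi, tol = 1e-10) {
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo > 0 || fhi < 0)
    stop("root not bracketed")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
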