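#' Specify a two-stage group sequential superiority design
#'
#' Constructs the design object for a randomized two-arm trial with a
#' continuous endpoint, one interim analysis, and the inverse normal
#' combination test at the final analysis.  The trial tests the one-sided
#' superiority hypothesis `H0: mu_I - mu_C <= 0` for a standardized effect
#' `delta = (mu_I - mu_C) / sigma`.  At the interim the trial stops for
#' efficacy when the one-sided p-value satisfies `p1 <= alpha1`, and may stop
#' (non-bindingly) for futility when `p1 > alpha0` for a futility boundary
#' chosen later (see [optimal_futility]).
#'
#' Exactly one of `n_per_group` and `power` must be given.  When `power` is
#' given, the per-group size is the fixed-design two-sample t-test sample size
#' ([fixed_design_sample_size]), mirroring the common practice of carrying the
#' fixed-design size into the group sequential plan.
#'
#' Local significance levels default to Pocock levels (`alpha1 == alpha12`)
#' solved from the global level by [pocock_local_levels]; both can be
#' overridden to plug in other boundary families.  Combination weights default
#' to `w1 = sqrt(n1)`, `w2 = sqrt(n2)`, under which the correlation between
#' the interim statistic `T1` and the combination statistic `T1+2` is
#' `sqrt(n1/n)`.
#'
#' @param delta anticipated standardized effect (minimal clinically relevant
#'   effect), `> 0`.
#' @param alpha one-sided global significance level, in (0, 0.5).
#' @param n_per_group per-group sample size at the final analysis.
#' @param power target power of the fixed-design t-test used to derive
#'   `n_per_group` (alternative to giving `n_per_group`).
#' @param info_fraction interim information fraction `n1/n`; the implied
#'   interim per-group size must be a whole number.  Default 0.5.
#' @param n1_per_group per-group interim sample size; overrides
#'   `info_fraction`.
#' @param alpha1 local one-sided level at the interim analysis; default:
#'   Pocock.
#' @param alpha12 local one-sided level at the final analysis; default:
#'   equal to `alpha1`.
#' @param weights length-2 positive weights `(w1, w2)` of the inverse normal
#'   combination.
#' @return an object of class `"gs_design"`, a list with components `delta`,
#'   `alpha`, `n_per_group`, `n1_per_group`, `n2_per_group`, `n_total`,
#'   `alpha1`, `alpha12`, `weights`, `rho` (implied correlation of
#'   `(T1, T1+2)`), and `target_power` (NULL unless derived from `power`).
#' @examples
#' # ChroPac-type planning: delta = 0.5, one-sided 2.5%, interim at 50%
#' d <- gs_design(delta = 0.5, alpha = 0.025, power = 0.90)
#' d
#' overall_power(d, alpha0 = "none", delta_true = 0.5)
#' @seealso [optimal_futility], [overall_power], [simulate_trials]
#' @export
gs_design <- function(delta, alpha = 0.025, n_per_group = NULL, power = NULL,
                      info_fraction = 0.5, n1_per_group = NULL,
                      alpha1 = NULL, alpha12 = NULL, weights = NULL) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("'delta' must be a single positive number")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must lie in (0, 0.5)")
  if (is.null(n_per_group) == is.null(power))
    stop("exactly one of 'n_per_group' and 'power' must be given")
  target_power <- NULL
  if (is.null(n_per_group)) {
    n_per_group <- fixed_design_sample_size(delta, alpha, power)
    target_power <- power
  }
  if (n_per_group != round(n_per_group) || n_per_group < 2)
    stop("'n_per_group' must be an integer >= 2")
  n_per_group <- as.integer(round(n_per_group))
  if (is.null(n1_per_group)) {
    if (!is.numeric(info_fraction) || info_fraction <= 0 || info_fraction >= 1)
      stop("'info_fraction' must lie in (0, 1)")
    n1 <- info_fraction * n_per_group
    if (abs(n1 - round(n1)) > 1e-8)
      stop("interim size n1 = info_fraction * n must be a whole number per group; ",
           "choose a compatible sample size or give 'n1_per_group'")
    n1_per_group <- as.integer(round(n1))
  }
  if (n1_per_group != round(n1_per_group) ||
      n1_per_group < 1 || n1_per_group >= n_per_group)
    stop("'n1_per_group' must be an integer with 0 < n1 < n")
  n1_per_group <- as.integer(round(n1_per_group))
  n2_per_group <- n_per_group - n1_per_group

  if (is.null(alpha1)) {
    levels <- pocock_local_levels(n1_per_group / n_per_group, alpha)
    alpha1 <- levels[["alpha1"]]
    alpha12 <- levels[["alpha12"]]
  } else if (is.null(alpha12)) {
    alpha12 <- alpha1
  }
  if (alpha1 <= 0 || alpha1 > alpha) stop("'alpha1' must lie in (0, alpha]")
  if (alpha12 <= 0 || alpha12 >= 0.5) stop("'alpha12' must lie in (0, 0.5)")

  if (is.null(weights)) weights <- c(sqrt(n1_per_group), sqrt(n2_per_group))
  if (length(weights) != 2L || any(!is.finite(weights)) || any(weights <= 0))
    stop("'weights' must be two positive numbers")
  rho <- weights[1] / sqrt(sum(weights^2))

  structure(list(delta = delta, alpha = alpha,
                 n_per_group = n_per_group, n1_per_group = n1_per_group,
                 n2_per_group = n2_per_group, n_total = 2L * n_per_group,
                 alpha1 = alpha1, alpha12 = alpha12,
                 weights = weights, rho = rho,
                 target_power = target_power),
            class = "gs_design")
}

#' @export
print.gs_design <- function(x, digits = 4, ...) {
  cat("Two-stage group sequential superiority design (continuous endpoint)\n")
  cat(sprintf("  standardized effect delta = %s, one-sided alpha = %s\n",
              format(x$delta), format(x$alpha)))
  cat(sprintf("  N = %d (%d per group), interim at n1 = %d per group (t = %.3g)\n",
              x$n_total, x$n_per_group, x$n1_per_group,
              x$n1_per_group / x$n_per_group))
  cat(sprintf("  local levels: alpha1 = %.*f, alpha1+2 = %.*f%s\n",
              digits, x$alpha1, digits, x$alpha12,
              if (isTRUE(all.equal(x$alpha1, x$alpha12))) "  (Pocock)" else ""))
  cat(sprintf("  corr(T1, T1+2) = %.*f\n", digits, x$rho))
  invisible(x)
}

#' @export
summary.gs_design <- function(object, ...) {
  out <- list(design = object,
              power_no_futility = overall_power(object, "none", object$delta),
              type_one_error = overall_power(object, "none", 0),
              efficacy_stop_at_delta =
                efficacy_stop_probability(object, object$delta))
  class(out) <- "summary.gs_design"
  out
}

#' @export
print.summary.gs_design <- function(x, digits = 4, ...) {
  print(x$design, digits = digits)
  if (!is.null(x$design$target_power))
    cat(sprintf("  nominal fixed-design planning power: %.*f\n",
                digits, x$design$target_power))
  cat(sprintf("  power without futility stopping (at delta): %.*f\n",
              digits, x$power_no_futility))
  cat(sprintf("  global type I error (check): %.*f\n", digits, x$type_one_error))
  cat(sprintf("  P(early efficacy stop at delta): %.*f\n",
              digits, x$efficacy_stop_at_delta))
  invisible(x)
}

#' Pocock local significance levels for a two-stage design
#'
#' Solves for the common local one-sided level `c = alpha1 = alpha1+2` such
#' that the global one-sided type I error of the two-stage inverse normal
#' design equals `alpha`:
#' `P_H0(p1 <= c) + P_H0(p1 > c, p1+2 <= c) = alpha`,
#' using the null joint law of `(T1, T1+2)` with correlation
#' `sqrt(info_fraction)`.
#'
#' @param info_fraction interim information fraction `n1/n`, in (0, 1).
#' @param alpha global one-sided significance level, in (0, 0.5).
#' @return named numeric vector `c(alpha1 = c, alpha12 = c)`.
#' @examples
#' pocock_local_levels(0.5, 0.025)  # 0.0147 to four decimals
#' @export
pocock_local_levels <- function(info_fraction, alpha) {
  if (!is.numeric(info_fraction) || length(info_fraction) != 1L ||
      info_fraction <= 0 || info_fraction >= 1)
    stop("'info_fraction' must lie in (0, 1)")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must lie in (0, 0.5)")
  law0 <- structure(list(mean = c(0, 0), rho = sqrt(info_fraction)),
                    class = "joint_law")
  # type I error is increasing in the common level c; c < alpha always since
  # the second stage spends additional error
  f <- function(c) {
    z <- stats::qnorm(1 - c)
    c + bvn_rectangle(-Inf, z, z, Inf, law0) - alpha
  }
  c <- .bisect_increasing(f, 1e-12, alpha - 1e-12, tol = 1e-12)
  c(alpha1 = c, alpha12 = c)
}

#' Fixed-design sample size for the two-sample t-test
#'
#' Smallest per-group size `n` for which the one-sided equal-variance
#' two-sample t-test (equal group sizes) attains the target power for a
#' standardized effect `delta`, computed from the noncentral t distribution
#' with `2n - 2` degrees of freedom and noncentrality `delta * sqrt(n/2)`.
#'
#' @param delta standardized effect, `> 0`.
#' @param alpha one-sided significance level, in (0, 0.5).
#' @param power target power, in (alpha, 1).
#' @return integer per-group sample size (total size is twice this).
#' @examples
#' fixed_design_sample_size(0.5, 0.025, 0.90)  # 86 per group, 172 total
#' @export
fixed_design_sample_size <- function(delta, alpha, power) {
  if (!is.numeric(delta) || delta <= 0) stop("'delta' must be positive")
  if (alpha <= 0 || alpha >= 0.5) stop("'alpha' must lie in (0, 0.5)")
  if (power <= alpha || power >= 1)
    stop("'power' must lie in (alpha, 1)")
  pow <- function(n) {
    df <- 2 * n - 2
    stats::pt(stats::qt(1 - alpha, df), df, ncp = delta * sqrt(n / 2),
              lower.tail = FALSE)
  }
  # normal-approximation start, then walk to the smallest adequate n
  n <- max(2, ceiling(2 * (stats::qnorm(1 - alpha) + stats::qnorm(power))^2 /
                        delta^2))
  while (n > 2 && pow(n - 1) >= power) n <- n - 1
  while (pow(n) < power) {
    n <- n + 1
    if (n > 1e7) stop("required sample size exceeds 1e7 per group")
  }
  as.integer(n)
}
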