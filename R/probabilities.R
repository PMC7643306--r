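#' Interim stopping probabilities and overall power
#'
#' Analytic operating characteristics of the two-stage design under an
#' arbitrary true standardized effect, from the joint normal law of
#' `(T1, T1+2)`.
#'
#' `futility_stop_probability()` is `P(p1 > alpha0)`, the chance of a
#' (non-binding) futility stop at the interim; under the null it equals
#' `1 - alpha0` because `p1` is uniform.  `efficacy_stop_probability()` is
#' `P(p1 <= alpha1)`.  `overall_power()` is the global rejection probability
#' when the futility rule is observed:
#' `P(p1 <= alpha1) + P(alpha1 < p1 <= alpha0, p1+2 <= alpha12)`,
#' the continuation term being the rectangle probability
#' `P(z_{1-alpha0} < T1 <= z_{1-alpha1}, T1+2 > z_{1-alpha12})`.
#'
#' @param design a [gs_design] object.
#' @param alpha0 futility boundary for the interim one-sided p-value, in
#'   `(alpha1, 1]`; `"none"` (or `NULL`) means no futility rule, which is
#'   equivalent to `alpha0 = 1`.  For `futility_stop_probability`, any value
#'   in (0, 1].
#' @param delta_true true standardized effect.
#' @return a single probability.
#' @examples
#' d <- gs_design(delta = 0.5, alpha = 0.025, n_per_group = 94)
#' futility_stop_probability(d, alpha0 = 0.22, delta_true = 0.5)  # wrong stop
#' futility_stop_probability(d, alpha0 = 0.22, delta_true = 0)    # correct stop
#' overall_power(d, alpha0 = 0.22, delta_true = 0.5)
#' overall_power(d, alpha0 = "none", delta_true = 0.5)
#' @name stopping-probabilities
NULL

#' @rdname stopping-probabilities
#' @export
futility_stop_probability <- function(design, alpha0, delta_true) {
  stopifnot(inherits(design, "gs_design"))
  if (!is.numeric(alpha0) || length(alpha0) != 1L || alpha0 <= 0 || alpha0 > 1)
    stop("'alpha0' must lie in (0, 1]")
  law <- joint_law(design, delta_true)
  # P(p1 > alpha0) = P(T1 < z_{1-alpha0})
  stats::pnorm(stats::qnorm(1 - alpha0) - law$mean[1])
}

#' @rdname stopping-probabilities
#' @export
efficacy_stop_probability <- function(design, delta_true) {
  stopifnot(inherits(design, "gs_design"))
  law <- joint_law(design, delta_true)
  stats::pnorm(stats::qnorm(1 - design$alpha1) - law$mean[1],
               lower.tail = FALSE)
}

#' @rdname stopping-probabilities
#' @export
overall_power <- function(design, alpha0 = "none", delta_true) {
  stopifnot(inherits(design, "gs_design"))
  alpha0 <- .check_alpha0(design, alpha0)
  law <- joint_law(design, delta_true)
  u1 <- stats::qnorm(1 - design$alpha1)
  u12 <- stats::qnorm(1 - design$alpha12)
  u0 <- stats::qnorm(1 - alpha0)   # -Inf when alpha0 = 1
  efficacy_stop_probability(design, delta_true) +
    bvn_rectangle(u0, u1, u12, Inf, law)
}

# normalizes "none"/NULL to 1 and enforces alpha1 < alpha0 <= 1
.check_alpha0 <- function(design, alpha0) {
  if (is.null(alpha0) || identical(alpha0, "none")) return(1)
  if (!is.numeric(alpha0) || length(alpha0) != 1L || !is.finite(alpha0))
    stop("'alpha0' must be a single number, \"none\", or NULL")
  if (alpha0 <= design$alpha1)
    stop("futility boundary below efficacy boundary: need alpha0 > alpha1 = ",
         format(design$alpha1))
  if (alpha0 > 1) stop("'alpha0' must not exceed 1")
  alpha0
}
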