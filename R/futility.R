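#' Lower bounds on admissible futility boundaries
#'
#' The futility boundary `alpha0` is *admissible* for given `(pow_loss,
#' pi_wrong)` when (i) the probability of wrongly stopping for futility under
#' the relevant effect `delta` is at most `pi_wrong`, and (ii) the global
#' power lost by observing the futility rule is at most `pow_loss`.  Each
#' condition translates into a lower bound on `alpha0`.
#'
#' `pi_wrong_bound()` is the closed form
#' `1 - Phi(z_{pi_wrong} + delta * sqrt(n1/2))`.
#' `pow_loss_bound()` is the smallest `alpha0` with
#' `overall_power(design, alpha0, delta) >= overall_power(design, "none",
#' delta) - pow_loss`, found by bisection (power is non-decreasing in
#' `alpha0`); the reference power is the group sequential design's power
#' *without* a futility rule at the same sample size.
#'
#' @param design a [gs_design] object.
#' @param pi_wrong admissible probability of wrongly stopping for futility
#'   under `delta`, in \[0, 1\].  The degenerate values 0 and 1 return the
#'   limits 1 and 0 with a warning.
#' @param pow_loss admissible global power loss, in (0, 1).
#' @return a lower bound for the futility boundary `alpha0`.
#' @examples
#' d <- gs_design(delta = 0.5, alpha = 0.025, n_per_group = 94)
#' pi_wrong_bound(d, 0.05)   # 0.22 (2 dp)
#' pow_loss_bound(d, 0.01)   # 0.29 (2 dp)
#' @name admissible-bounds
NULL

#' @rdname admissible-bounds
#' @export
pi_wrong_bound <- function(design, pi_wrong) {
  stopifnot(inherits(design, "gs_design"))
  if (!is.numeric(pi_wrong) || length(pi_wrong) != 1L ||
      pi_wrong < 0 || pi_wrong > 1)
    stop("'pi_wrong' must lie in [0, 1]")
  if (pi_wrong == 0 || pi_wrong == 1) {
    warning("degenerate pi_wrong = ", pi_wrong,
            ": boundary bound degenerates to ", 1 - pi_wrong)
    return(1 - pi_wrong)
  }
  m1 <- design$delta * sqrt(design$n1_per_group / 2)
  1 - stats::pnorm(stats::qnorm(pi_wrong) + m1)
}

#' @rdname admissible-bounds
#' @export
pow_loss_bound <- function(design, pow_loss) {
  stopifnot(inherits(design, "gs_design"))
  if (!is.numeric(pow_loss) || length(pow_loss) != 1L ||
      pow_loss <= 0 || pow_loss >= 1)
    stop("'pow_loss' must lie in (0, 1)")
  target <- overall_power(design, "none", design$delta) - pow_loss
  a1 <- design$alpha1
  f <- function(a0) overall_power(design, a0, design$delta) - target
  if (f(a1 + 1e-12) >= 0) return(a1)  # constraint slack for every boundary
  .bisect_increasing(f, a1 + 1e-12, 1, tol = 1e-10)
}

#' Derive the optimal futility boundary of a two-stage design
#'
#' The central planning function: among all futility boundaries satisfying
#' the two admissible conditions — bounded probability of wrongly stopping
#' for futility under the relevant effect, and bounded global power loss —
#' the probability of *correctly* stopping for futility (under the null or a
#' non-relevant effect) increases as the boundary decreases, so the optimal
#' boundary is the minimum admissible one:
#' `alpha0_opt = max(pi_wrong_bound, pow_loss_bound, alpha1)`.
#'
#' @param design a [gs_design] object.
#' @param pow_loss admissible global power loss (see [pow_loss_bound]).
#' @param pi_wrong admissible probability of wrongly stopping for futility
#'   (see [pi_wrong_bound]).
#' @param effects true standardized effects at which correct-stopping
#'   probabilities are reported; default `c(delta/2, 0)` (a non-relevant
#'   effect of half the anticipated size, and no effect).
#' @return an object of class `"gs_futility"` with components
#'   `alpha0_opt`, `bound_pi`, `bound_pow`, `binding` (one of `"pi_wrong"`,
#'   `"pow_loss"`, `"efficacy_floor"`; ties labelled `"pi_wrong"`),
#'   `pow_loss`, `pi_wrong`, `design`, `power_no_futility`, and `oc`
#'   (the [performance_profile] at the optimal boundary).
#' @examples
#' d188 <- gs_design(delta = 0.5, alpha = 0.025, n_per_group = 94)
#' fb <- optimal_futility(d188, pow_loss = 0.05, pi_wrong = 0.05)
#' fb          # alpha0_opt = 0.22, actual power 0.89
#' summary(fb)
#' coef(fb)
#' @seealso [performance_profile], [sensitivity_grid], [simulate.gs_futility]
#' @export
optimal_futility <- function(design, pow_loss, pi_wrong, effects = NULL) {
  stopifnot(inherits(design, "gs_design"))
  if (is.null(effects)) effects <- c(design$delta / 2, 0)
  bound_pi <- pi_wrong_bound(design, pi_wrong)
  bound_pow <- pow_loss_bound(design, pow_loss)
  a1 <- design$alpha1
  alpha0_opt <- max(bound_pi, bound_pow, a1)
  tol <- 1e-8
  binding <- if (bound_pi >= alpha0_opt - tol) "pi_wrong"
    else if (bound_pow >= alpha0_opt - tol) "pow_loss"
    else "efficacy_floor"
  oc <- if (alpha0_opt > a1)
    performance_profile(design, alpha0_opt, effects) else NULL
  structure(list(alpha0_opt = alpha0_opt, bound_pi = bound_pi,
                 bound_pow = bound_pow, binding = binding,
                 pow_loss = pow_loss, pi_wrong = pi_wrong,
                 design = design,
                 power_no_futility = overall_power(design, "none", design$delta),
                 effects = effects, oc = oc),
            class = "gs_futility")
}

#' @export
print.gs_futility <- function(x, digits = 2, ...) {
  cat(sprintf("Optimal futility boundary: alpha0_opt = %.*f  (binding: %s)\n",
              digits, x$alpha0_opt, x$binding))
  cat(sprintf("  admissible parameters: pow_loss = %s, pi_wrong = %s\n",
              format(x$pow_loss), format(x$pi_wrong)))
  if (!is.null(x$oc)) print(x$oc, digits = digits)
  invisible(x)
}

#' @export
summary.gs_futility <- function(object, ...) {
  structure(list(fit = object), class = "summary.gs_futility")
}

#' @export
print.summary.gs_futility <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f$design, digits = digits)
  cat(sprintf("Admissible parameters: pow_loss = %s, pi_wrong = %s\n",
              format(f$pow_loss), format(f$pi_wrong)))
  cat(sprintf("  bound from pi_wrong condition:  %.*f\n", digits, f$bound_pi))
  cat(sprintf("  bound from pow_loss condition:  %.*f\n", digits, f$bound_pow))
  cat(sprintf("Optimal futility boundary: %.*f  (binding: %s)\n",
              digits, f$alpha0_opt, f$binding))
  cat(sprintf("Power without futility rule: %.*f\n",
              digits, f$power_no_futility))
  if (!is.null(f$oc)) print(f$oc, digits = digits)
  invisible(x)
}

#' @export
coef.gs_futility <- function(object, ...) {
  c(alpha0_opt = object$alpha0_opt,
    bound_pi = object$bound_pi, bound_pow = object$bound_pow)
}

#' Operating characteristics at a given futility boundary
#'
#' Actual power (including the effect of the futility rule) at the design's
#' anticipated effect, the probability of wrongly stopping for futility at
#' that effect, and the probability of stopping for futility at each
#' requested true effect.
#'
#' @param design a [gs_design] object.
#' @param alpha0 futility boundary in `(alpha1, 1]`.
#' @param true_effects standardized effects at which futility-stop
#'   probabilities are evaluated; default `c(delta/2, 0)`.
#' @return object of class `"gs_oc"`: list with `alpha0`, `actual_power`,
#'   `p_wrong_stop`, and `p_correct_stop` (named numeric, one entry per
#'   requested effect).
#' @examples
#' d <- gs_design(0.5, 0.025, n_per_group = 94)
#' performance_profile(d, alpha0 = 0.22)
#' @export
performance_profile <- function(design, alpha0, true_effects = NULL) {
  stopifnot(inherits(design, "gs_design"))
  alpha0 <- .check_alpha0(design, alpha0)
  if (is.null(true_effects)) true_effects <- c(design$delta / 2, 0)
  p_stop <- vapply(true_effects,
                   function(dt) futility_stop_probability(design, alpha0, dt),
                   numeric(1))
  names(p_stop) <- format(true_effects, trim = TRUE)
  structure(list(alpha0 = alpha0,
                 actual_power = overall_power(design, alpha0, design$delta),
                 p_wrong_stop =
                   futility_stop_probability(design, alpha0, design$delta),
                 p_correct_stop = p_stop),
            class = "gs_oc")
}

#' @export
print.gs_oc <- function(x, digits = 2, ...) {
  cat(sprintf("Operating characteristics at alpha0 = %.*f:\n",
              max(digits, 2), x$alpha0))
  cat(sprintf("  actual power (at delta):        %.*f\n", digits,
              x$actual_power))
  cat(sprintf("  P(wrongly stop for futility):   %.*f\n", digits,
              x$p_wrong_stop))
  for (nm in names(x$p_correct_stop))
    cat(sprintf("  P(stop | delta_true = %s):%s%.*f\n", nm,
                strrep(" ", max(1, 9 - nchar(nm))), digits,
                x$p_correct_stop[[nm]]))
  invisible(x)
}

#' Admissible parameters implied by a given futility boundary
#'
#' Inverts the admissible conditions: for an arbitrary boundary `alpha0`
#' (e.g. the conventional 0.5), returns the probability of wrongly stopping
#' for futility and the global power loss it actually incurs.  Feeding the
#' result back into [optimal_futility] reproduces `alpha0`.
#'
#' @inheritParams performance_profile
#' @return list with components `pow_loss` and `pi_wrong`.
#' @examples
#' d <- gs_design(0.5, 0.025, n_per_group = 94)
#' implied_admissible_params(d, 0.5)  # pow_loss 0.0013, pi_wrong 0.008
#' @export
implied_admissible_params <- function(design, alpha0) {
  stopifnot(inherits(design, "gs_design"))
  alpha0 <- .check_alpha0(design, alpha0)
  list(pow_loss = overall_power(design, "none", design$delta) -
         overall_power(design, alpha0, design$delta),
       pi_wrong = futility_stop_probability(design, alpha0, design$delta))
}

#' Sensitivity of the optimal boundary to the admissible parameters
#'
#' Tabulates the optimal futility boundary and its operating characteristics
#' over a grid of admissible parameter values, for one or several designs.
#' Rows are ordered with `pi_wrong` varying slowest and `pow_loss` fastest
#' within each design.
#'
#' @param design a [gs_design] object, or a list of them (e.g. competing
#'   sample sizes).
#' @param pow_loss_values,pi_wrong_values admissible parameter values to
#'   cross.
#' @param true_effects effects for the correct-stopping columns; default
#'   `c(delta/2, 0)`.
#' @return a `data.frame` with columns `n_total`, `pow_loss`, `pi_wrong`,
#'   `alpha0_opt`, `binding`, `actual_power`, `p_wrong_stop`, and one
#'   `p_stop_<effect>` column per requested effect.
#' @examples
#' d <- gs_design(0.5, 0.025, n_per_group = 94)
#' sensitivity_grid(d, c(0.01, 0.05), c(0.01, 0.05, 0.10))
#' @export
sensitivity_grid <- function(design, pow_loss_values, pi_wrong_values,
                             true_effects = NULL) {
  designs <- if (inherits(design, "gs_design")) list(design) else design
  stopifnot(length(designs) >= 1L,
            all(vapply(designs, inherits, logical(1), "gs_design")),
            length(pow_loss_values) >= 1L, length(pi_wrong_values) >= 1L)
  rows <- list()
  for (d in designs) {
    eff <- if (is.null(true_effects)) c(d$delta / 2, 0) else true_effects
    for (pw in pi_wrong_values) {
      for (pl in pow_loss_values) {
        fit <- optimal_futility(d, pow_loss = pl, pi_wrong = pw, effects = eff)
        oc <- fit$oc
        stops <- as.list(oc$p_correct_stop)
        names(stops) <- paste0("p_stop_", names(oc$p_correct_stop))
        rows[[length(rows) + 1L]] <- data.frame(
          n_total = d$n_total, pow_loss = pl, pi_wrong = pw,
          alpha0_opt = fit$alpha0_opt, binding = fit$binding,
          actual_power = oc$actual_power, p_wrong_stop = oc$p_wrong_stop,
          stops, check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot the optimal boundary against the admissible parameters
#'
#' Draws `alpha0_opt` as a function of `pi_wrong`, one curve per `pow_loss`
#' value, for the fitted design — the planning plot used to pick admissible
#' parameters.
#'
#' @param x a `"gs_futility"` object.
#' @param pi_wrong_values grid for the x-axis.
#' @param pow_loss_values one curve per value; defaults to the fitted value.
#' @param ... passed to [graphics::matplot].
#' @return the grid `data.frame`, invisibly.
#' @export
plot.gs_futility <- function(x, pi_wrong_values = seq(0.01, 0.30, by = 0.01),
                             pow_loss_values = NULL, ...) {
  if (is.null(pow_loss_values)) pow_loss_values <- x$pow_loss
  g <- sensitivity_grid(x$design, pow_loss_values, pi_wrong_values)
  m <- matrix(g$alpha0_opt, nrow = length(pow_loss_values))
  graphics::matplot(pi_wrong_values, t(m), type = "b", pch = 19,
                    xlab = expression(pi["wrong"]),
                    ylab = expression(alpha["0,opt"]), ...)
  graphics::legend("topright", bty = "n", pch = 19,
                   col = seq_along(pow_loss_values),
                   legend = paste("pow_loss =", pow_loss_values))
  graphics::points(x$pi_wrong, x$alpha0_opt, pch = 15, cex = 1.4)
  invisible(g)
}
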