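#' Monte-Carlo simulation of the two-stage trial
#'
#' Independent stochastic oracle for the analytic operating characteristics.
#' Two generation modes:
#' \describe{
#'   \item{`"z_scale"`}{draws the stage-wise statistics directly:
#'     `T1 ~ N(delta_true * sqrt(n1/2), 1)` and independently
#'     `T2 ~ N(delta_true * sqrt(n2/2), 1)`, combined into the inverse
#'     normal statistic `T1+2 = (w1 T1 + w2 T2) / sqrt(w1^2 + w2^2)`.}
#'   \item{`"patient_level"`}{draws individual normal observations per arm
#'     and stage, forms the interim statistic from the observed mean
#'     difference over the pooled standard deviation, and the incremental
#'     second-stage statistic from second-stage data only, then combines.}
#' }
#' Stage-wise p-values use the normal approximation `p_i = 1 - Phi(T_i)`.
#' The trial stops for efficacy when `p1 <= alpha1`, for futility when
#' `p1 > alpha0`; otherwise it continues and rejects when `p1+2 <= alpha12`.
#'
#' @param design a [gs_design] object.
#' @param alpha0 futility boundary in `(alpha1, 1]`; 1 disables the rule.
#' @param delta_true true standardized effect used for generation.
#' @param n_reps number of replicated trials.
#' @param seed integer seed; identical seeds give identical results.
#' @param mode `"z_scale"` (default) or `"patient_level"`.
#' @param mu_C,sigma control-arm mean and common SD for patient-level
#'   generation; the intervention mean is `mu_C + delta_true * sigma`.
#' @param mu_I optional explicit intervention mean; must satisfy
#'   `(mu_I - mu_C)/sigma == delta_true` to within 1e-12.
#' @param keep_statistics if `TRUE`, the per-replicate statistics and
#'   p-values are returned in component `paths`.
#' @return an object of class `"gs_sim"`: a list with `prob` (named vector of
#'   estimated probabilities: `reject`, `efficacy_stop`, `futility_stop`,
#'   `continuation`, `continue_reject`), `se` (matching binomial standard
#'   errors `sqrt(p(1-p)/n_reps)`), `corr_all` (empirical correlation of
#'   `(T1, T1+2)` over all replicates, stopping ignored), `corr_continue`
#'   (same among continuing replicates), plus the generation settings.
#' @examples
#' d <- gs_design(0.5, 0.025, n_per_group = 94)
#' simulate_trials(d, alpha0 = 0.22, delta_true = 0.5,
#'                 n_reps = 10000, seed = 1)
#' @seealso [estimate_operating_characteristics], [simulate.gs_futility]
#' @export
simulate_trials <- function(design, alpha0 = 1, delta_true = design$delta,
                            n_reps = 1e5, seed = NULL,
                            mode = c("z_scale", "patient_level"),
                            mu_C = 0, sigma = 1, mu_I = NULL,
                            keep_statistics = FALSE) {
  stopifnot(inherits(design, "gs_design"))
  mode <- match.arg(mode)
  alpha0 <- .check_alpha0(design, alpha0)
  if (!is.numeric(n_reps) || n_reps < 1) stop("'n_reps' must be >= 1")
  n_reps <- as.integer(n_reps)
  if (!is.null(seed)) set.seed(seed)

  n1 <- design$n1_per_group
  n2 <- design$n2_per_group
  w <- design$weights
  wn <- sqrt(sum(w^2))

  if (mode == "z_scale") {
    t1 <- stats::rnorm(n_reps, mean = delta_true * sqrt(n1 / 2))
    t2 <- stats::rnorm(n_reps, mean = delta_true * sqrt(n2 / 2))
  } else {
    if (n1 < 2) stop("patient_level mode needs n1 >= 2 per group (pooled SD)")
    if (sigma <= 0) stop("'sigma' must be positive")
    if (is.null(mu_I)) mu_I <- mu_C + delta_true * sigma
    if (abs((mu_I - mu_C) / sigma - delta_true) > 1e-12)
      stop("(mu_I - mu_C)/sigma must equal delta_true")
    t1 <- numeric(n_reps)
    t2 <- numeric(n_reps)
    # chunked so that 1e6 replicates do not allocate n * n_reps doubles at once
    chunk <- 5000L
    done <- 0L
    while (done < n_reps) {
      k <- min(chunk, n_reps - done)
      idx <- done + seq_len(k)
      t1[idx] <- .stage_statistic(k, n1, mu_I, mu_C, sigma)
      t2[idx] <- .stage_statistic(k, n2, mu_I, mu_C, sigma)
      done <- done + k
    }
  }
  t12 <- (w[1] * t1 + w[2] * t2) / wn
  p1 <- stats::pnorm(t1, lower.tail = FALSE)
  p12 <- stats::pnorm(t12, lower.tail = FALSE)

  eff <- p1 <= design$alpha1
  fut <- !eff & p1 > alpha0
  cont <- !eff & !fut
  cont_rej <- cont & p12 <= design$alpha12
  prob <- c(reject = mean(eff | cont_rej),
            efficacy_stop = mean(eff),
            futility_stop = mean(fut),
            continuation = mean(cont),
            continue_reject = mean(cont_rej))
  structure(list(prob = prob,
                 se = sqrt(prob * (1 - prob) / n_reps),
                 corr_all = stats::cor(t1, t12),
                 corr_continue = if (sum(cont) >= 2L)
                   stats::cor(t1[cont], t12[cont]) else NA_real_,
                 n_reps = n_reps, seed = seed, mode = mode,
                 delta_true = delta_true, alpha0 = alpha0,
                 paths = if (keep_statistics)
                   data.frame(t1 = t1, t12 = t12, p1 = p1, p12 = p12)),
            class = "gs_sim")
}

# interim/incremental z-type statistic for k replicated trials of size n/arm:
# mean difference over pooled SD times sqrt(n/2), vectorized across replicates
.stage_statistic <- function(k, n, mu_I, mu_C, sigma) {
  xi <- matrix(stats::rnorm(n * k, mu_I, sigma), nrow = n)
  xc <- matrix(stats::rnorm(n * k, mu_C, sigma), nrow = n)
  mi <- colMeans(xi)
  mc <- colMeans(xc)
  # pooled variance with equal group sizes
  s2 <- (colSums(xi^2) - n * mi^2 + colSums(xc^2) - n * mc^2) / (2 * n - 2)
  (mi - mc) / sqrt(s2) * sqrt(n / 2)
}

#' @export
print.gs_sim <- function(x, digits = 4, ...) {
  cat(sprintf("Monte-Carlo trial simulation (%s, %d replicates, delta_true = %s, alpha0 = %s)\n",
              x$mode, x$n_reps, format(x$delta_true), format(x$alpha0)))
  tab <- rbind(estimate = x$prob, se = x$se)
  print(round(tab, digits))
  cat(sprintf("corr(T1, T1+2): %.4f (all), %s (continuing)\n", x$corr_all,
              ifelse(is.na(x$corr_continue), "NA",
                     sprintf("%.4f", x$corr_continue))))
  invisible(x)
}

#' Monte-Carlo operating characteristics over a set of true effects
#'
#' Batch driver over [simulate_trials]: one simulation per requested effect,
#' with per-effect seeds derived as `seed + index - 1` so adding effects never
#' perturbs earlier streams.
#'
#' @inheritParams simulate_trials
#' @param effects vector of true standardized effects.
#' @return a `data.frame` with one row per effect: `delta_true`, `power`
#'   (overall rejection), `p_efficacy_stop`, `p_futility_stop`, their
#'   standard errors, and `n_reps`.  Empty `effects` gives an empty frame.
#' @examples
#' d <- gs_design(0.5, 0.025, n_per_group = 94)
#' estimate_operating_characteristics(d, 0.22, c(0.5, 0.25, 0),
#'                                    n_reps = 5000, seed = 7)
#' @export
estimate_operating_characteristics <- function(design, alpha0, effects,
                                               n_reps = 1e5, seed = NULL,
                                               mode = "z_scale") {
  out <- data.frame(delta_true = numeric(0), power = numeric(0),
                    se_power = numeric(0), p_efficacy_stop = numeric(0),
                    p_futility_stop = numeric(0), se_futility_stop = numeric(0),
                    n_reps = integer(0))
  for (i in seq_along(effects)) {
    s <- simulate_trials(design, alpha0 = alpha0, delta_true = effects[i],
                         n_reps = n_reps,
                         seed = if (is.null(seed)) NULL else seed + i - 1L,
                         mode = mode)
    out[i, ] <- list(effects[i], s$prob[["reject"]], s$se[["reject"]],
                     s$prob[["efficacy_stop"]], s$prob[["futility_stop"]],
                     s$se[["futility_stop"]], s$n_reps)
  }
  out
}

#' Simulate the fitted design at its optimal boundary
#'
#' [stats::simulate] method for `"gs_futility"` objects: Monte-Carlo
#' cross-check of the analytic operating characteristics at `alpha0_opt`,
#' evaluated at the anticipated effect and the fitted correct-stopping
#' effects.
#'
#' @param object a `"gs_futility"` fit.
#' @param nsim replicates per effect.
#' @param seed integer seed (per-effect streams derived from it).
#' @param mode passed to [simulate_trials].
#' @param ... unused.
#' @return the `data.frame` from [estimate_operating_characteristics].
#' @export
simulate.gs_futility <- function(object, nsim = 1e5, seed = NULL,
                                 mode = "z_scale", ...) {
  estimate_operating_characteristics(
    object$design, object$alpha0_opt,
    effects = c(object$design$delta, object$effects),
    n_reps = nsim, seed = seed, mode = mode)
}
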