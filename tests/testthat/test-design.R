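test_that("bivariate rectangle probabilities match trivial cases and the quadrature oracle", {
  law0 <- structure(list(mean = c(0, 0), rho = 0), class = "joint_law")
  expect_equal(bvn_rectangle(-Inf, Inf, -Inf, Inf, law0), 1)
  expect_equal(bvn_rectangle(-Inf, 0, -Inf, 0, law0), 0.25)

  lawr <- structure(list(mean = c(0, 0), rho = sqrt(0.5)), class = "joint_law")
  # closed form for the quadrant at correlation rho: 1/4 + asin(rho)/(2*pi)
  expect_equal(bvn_rectangle(-Inf, 0, -Inf, 0, lawr),
               0.25 + asin(sqrt(0.5)) / (2 * pi), tolerance = 1e-10)
  expect_equal(bvn_rectangle(-Inf, 0, -Inf, 0, lawr),
               bvn_quad(-Inf, 0, -Inf, 0, c(0, 0), sqrt(0.5)),
               tolerance = 1e-6)

  # general rectangles with shifted means against the quadrature oracle
  set.seed(11)
  for (i in 1:6) {
    m <- stats::rnorm(2)
    rho <- stats::runif(1, -0.9, 0.9)
    b1 <- sort(stats::rnorm(2, sd = 2))
    b2 <- sort(stats::rnorm(2, sd = 2))
    law <- structure(list(mean = m, rho = rho), class = "joint_law")
    expect_equal(bvn_rectangle(b1[1], b1[2], b2[1], b2[2], law),
                 bvn_quad(b1[1], b1[2], b2[1], b2[2], m, rho),
                 tolerance = 1e-6)
  }
})

test_that("invalid joint laws and bounds are rejected", {
  bad <- structure(list(mean = c(0, 0), rho = 1), class = "joint_law")
  expect_error(bvn_rectangle(-Inf, 0, -Inf, 0, bad), "rho")
  nf <- structure(list(mean = c(NA, 0), rho = 0.5), class = "joint_law")
  expect_error(bvn_rectangle(-Inf, 0, -Inf, 0, nf), "finite")
  ok <- structure(list(mean = c(0, 0), rho = 0.5), class = "joint_law")
  expect_error(bvn_rectangle(1, 0, -Inf, 0, ok), "lower")
})

test_that("Pocock local levels solve the global type I error equation", {
  lv <- pocock_local_levels(0.5, 0.025)
  expect_equal(unname(lv[1]), unname(lv[2]))
  expect_equal(round(unname(lv[1]), 4), 0.0147)
  expect_lt(unname(lv[1]), 0.025)

  # solved level satisfies the defining equation: global rejection under the
  # null equals alpha (design built with these levels)
  d <- d188()
  expect_equal(overall_power(d, "none", 0), 0.025, tolerance = 1e-6)

  # at near-full interim information the interim test is almost the final
  # test and the common local level climbs towards the global level
  cs <- vapply(c(0.5, 0.9, 0.99, 0.9999),
               function(t) pocock_local_levels(t, 0.025)[[1]], numeric(1))
  expect_true(all(diff(cs) > 0))
  expect_lt(0.025 - cs[4], 5e-4)

  expect_error(pocock_local_levels(1.2, 0.025), "info_fraction")
  expect_error(pocock_local_levels(0.5, 0.7), "alpha")
})

test_that("joint law of (T1, T1+2) has the stated mean and correlation", {
  d <- d188()
  law <- joint_law(d, 0.5)
  expect_equal(law$mean, c(0.5 * sqrt(47 / 2), 0.5 * sqrt(94 / 2)),
               tolerance = 1e-12)
  expect_equal(law$mean, c(2.4238399, 3.4278273), tolerance = 1e-6)
  expect_equal(law$rho, sqrt(47 / 94), tolerance = 1e-12)
  expect_equal(joint_law(d, 0)$mean, c(0, 0))

  # correlation implied by non-default weights: w1 / sqrt(w1^2 + w2^2)
  dw <- gs_design(0.5, 0.025, n_per_group = 94, weights = c(1, 2))
  expect_equal(dw$rho, 1 / sqrt(5))
})

test_that("interim stopping probabilities match closed forms and the worked example", {
  d <- d188()
  # p1 is uniform under the null: P(p1 > a0) = 1 - a0
  for (a0 in c(0.1, 0.22, 0.5, 0.9))
    expect_equal(futility_stop_probability(d, a0, 0), 1 - a0,
                 tolerance = 1e-12)
  # wrong stop / correct stop at the published boundary
  expect_equal(round2(futility_stop_probability(d, 0.22, 0.5), 2), 0.05)
  expect_equal(round2(futility_stop_probability(d, 0.22, 0.25), 2), 0.33)

  expect_equal(efficacy_stop_probability(d, 0), d$alpha1, tolerance = 1e-12)
  expect_equal(efficacy_stop_probability(d, 0.5),
               1 - pnorm(qnorm(1 - d$alpha1) - 0.5 * sqrt(47 / 2)),
               tolerance = 1e-10)
  expect_equal(efficacy_stop_probability(d, 50), 1, tolerance = 1e-10)

  expect_error(futility_stop_probability(d, 0, 0.5), "alpha0")
  expect_error(futility_stop_probability(d, 1.2, 0.5), "alpha0")
})

test_that("overall power reproduces the planning example and decomposes over outcomes", {
  expect_equal(round2(overall_power(d172(), "none", 0.5), 2), 0.88)
  expect_equal(round2(overall_power(d140(), "none", 0.5), 2), 0.80)
  expect_equal(round2(overall_power(d188(), 0.22, 0.5), 2), 0.89)

  d <- d188()
  # empty continuation region: power collapses to the efficacy-stop term
  expect_equal(overall_power(d, d$alpha1 + 1e-10, 0.5),
               efficacy_stop_probability(d, 0.5), tolerance = 1e-8)
  expect_error(overall_power(d, d$alpha1 / 2, 0.5), "below efficacy")
  expect_error(overall_power(d, 1.5, 0.5), "exceed")

  # exhaustive outcomes: reject + futility stop + (continue & accept) = 1
  for (dt in c(0, 0.25, 0.5)) {
    law <- joint_law(d, dt)
    u1 <- qnorm(1 - d$alpha1); u12 <- qnorm(1 - d$alpha12)
    for (a0 in seq(0.05, 1, length.out = 12)) {
      cont_accept <- bvn_rectangle(qnorm(1 - a0), u1, -Inf, u12, law)
      expect_equal(overall_power(d, a0, dt) +
                     futility_stop_probability(d, a0, dt) + cont_accept,
                   1, tolerance = 1e-8)
    }
  }
})

test_that("power is non-decreasing and futility stop strictly decreasing in alpha0", {
  d <- d140()
  a0 <- seq(d$alpha1 + 1e-3, 1, length.out = 60)
  pow <- vapply(a0, function(a) overall_power(d, a, 0.5), numeric(1))
  fut <- vapply(a0, function(a) futility_stop_probability(d, a, 0.5),
                numeric(1))
  expect_true(all(diff(pow) >= -1e-12))
  expect_true(all(diff(fut) < 0))
})

test_that("fixed-design t-test sample size matches the noncentral-t solution", {
  n <- fixed_design_sample_size(0.5, 0.025, 0.90)
  expect_identical(n, 86L)
  # minimality: one patient fewer per group undershoots the target power
  pow_t <- function(n) pt(qt(0.975, 2 * n - 2), 2 * n - 2,
                          ncp = 0.5 * sqrt(n / 2), lower.tail = FALSE)
  expect_lt(pow_t(85), 0.90)
  expect_gte(pow_t(86), 0.90)

  # independent oracle: stats::power.t.test
  ptt <- stats::power.t.test(delta = 0.5, sd = 1, sig.level = 0.025,
                             power = 0.90, type = "two.sample",
                             alternative = "one.sided")
  expect_identical(n, as.integer(ceiling(ptt$n)))
  expect_identical(fixed_design_sample_size(0.5, 0.025, 0.80),
                   as.integer(ceiling(stats::power.t.test(
                     delta = 0.5, sd = 1, sig.level = 0.025, power = 0.80,
                     type = "two.sample",
                     alternative = "one.sided")$n)))

  # degenerate large effect: bounded below by 2 per group
  expect_gte(fixed_design_sample_size(50, 0.025, 0.90), 2L)
  expect_error(fixed_design_sample_size(-1, 0.025, 0.9), "delta")
  expect_error(fixed_design_sample_size(0.5, 0.025, 1.1), "power")
})

test_that("design constructor enforces its invariants", {
  expect_error(gs_design(0.5, 0.025), "exactly one")
  expect_error(gs_design(0.5, 0.025, n_per_group = 90, power = 0.9),
               "exactly one")
  expect_error(gs_design(0.5, 0.025, n_per_group = 93, info_fraction = 0.5),
               "whole number")
  expect_error(gs_design(-0.5, 0.025, n_per_group = 94), "delta")
  expect_error(gs_design(0.5, 0.6, n_per_group = 94), "alpha")
  d <- gs_design(0.5, 0.025, power = 0.90)
  expect_identical(d$n_per_group, 86L)
  expect_identical(d$n1_per_group, 43L)
  expect_equal(d$weights, c(sqrt(43), sqrt(43)))
  expect_equal(d$rho, sqrt(0.5))
})
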