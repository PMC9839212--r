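test_that("constructors reject inadmissible parameters", {
  expect_error(theory_params(u_out = 0, u_home = 0), "u_out")
  expect_error(theory_params(gamma = 0, c = 1), "gamma")
  expect_error(theory_params(sigma = -1), "sigma")
  expect_error(theory_params(iota = 2), "iota")
  expect_error(stigma_curve("affine", s0 = 1, s1 = 0), "s1")
  expect_error(stigma_curve("affine", s0 = 1, s1 = 2), "s0")
  expect_error(habituation_curve("linear", rate = -1), "rate")
})

test_that("going-out payoff follows the stigma-discount form", {
  p0 <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                      delta = 1, iota = 0)
  # iota = 0 removes the stigma term entirely
  expect_equal(payoff_out(p0, s_value = 5, phi = 1), 0)
  p1 <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                      sigma = 1, delta = 1, iota = 1)
  expect_equal(payoff_out(p1, s_value = 1, phi = 1), -1)
  # zero sensitivity ignores every cost
  expect_equal(payoff_out(p1, s_value = 3, phi = 0), 1)
  expect_error(payoff_out(p1, s_value = Inf, phi = 1), "finite")
  expect_error(payoff_out(p1, s_value = 1, phi = -1), "nonnegative")
})

test_that("critical sensitivity matches its closed form", {
  p0 <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                      delta = 1, iota = 0)
  expect_equal(critical_sensitivity(p0, s_value = 7), 1)
  p1 <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                      sigma = 1, delta = 1, iota = 1)
  expect_equal(critical_sensitivity(p1, s_value = 1), 0.5)
  p2 <- theory_params(u_out = 1, u_home = 0, gamma = 1, c = 2,
                      delta = 2, iota = 0)
  expect_equal(critical_sensitivity(p2, s_value = 0.3), 0.25)
  # phi_hat weakly increases as the stigma level falls
  s_grid <- seq(2, 0, length.out = 20)
  expect_false(is.unsorted(critical_sensitivity(p1, s_grid)))
})

test_that("chi reduces correctly in the degenerate policy cases", {
  s <- stigma_curve("affine", s0 = 2, s1 = 0.5)
  h <- habituation_curve("linear", rate = 0)
  Fu <- sensitivity_dist("uniform", max = 2)
  # uniform CDF at phi_hat = 1 is one half
  p0 <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                      delta = 1, iota = 0)
  expect_equal(chi(0.3, p0, Fu, s, h), 0.5)
  # sigma = 0 makes the emergency map identical to the no-emergency one
  pe <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                      sigma = 0, delta = 1, iota = 1)
  xs <- seq(0, 1, by = 0.1)
  expect_equal(chi(xs, pe, Fu, s, h), chi(xs, p0, Fu, s, h))
  # infinitely fast habituation kills the stigma term for n > 1
  p2 <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                      sigma = 1, delta = 1, iota = 1, n = 2)
  h_inf <- habituation_curve("linear", rate = 500)
  expect_equal(chi(xs, p2, Fu, s, h_inf), chi(xs, p0, Fu, s, h),
               tolerance = 1e-12)
})

test_that("chi is nondecreasing for random admissible configurations", {
  set.seed(11)
  xs <- seq(0, 1, length.out = 500)
  for (i in 1:25) {
    cf <- sample_theory_config()
    vals <- chi(xs, cf$p, cf$F, cf$s, cf$h)
    expect_false(is.unsorted(vals), info = paste("config", i))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("closed-form no-emergency equilibrium agrees with the solver", {
  set.seed(21)
  for (i in 1:30) {
    cf <- sample_theory_config()
    p0 <- cf$p
    p0$iota <- 0
    x0 <- no_emergency_equilibrium(p0, cf$F)
    eq <- find_equilibria(p0, cf$F, cf$s, cf$h)
    expect_equal(nrow(eq), 1)
    expect_lt(abs(eq$x_star - x0), 1e-10)
    expect_equal(eq$slope, 0, tolerance = 1e-8)  # chi constant
  }
})

test_that("solver finds all equilibria and flags stability", {
  cf <- three_equilibria_config()
  eq <- find_equilibria(cf$p, cf$F, cf$s, cf$h)
  expect_equal(nrow(eq), 3)
  expect_equal(eq$stable, c(TRUE, FALSE, TRUE))
  expect_false(is.unsorted(eq$x_star))
  # independent dense grid scan at step 1e-5
  oracle <- grid_scan_roots(cf$p, cf$F, cf$s, cf$h)
  expect_equal(length(oracle), 3)
  expect_equal(eq$x_star, oracle, tolerance = 1e-4)
  # constant stigma curve collapses chi to a constant: single equilibrium
  s_flat <- stigma_curve("affine", s0 = 1 + 1e-9, s1 = 1)
  eq1 <- find_equilibria(cf$p, cf$F, s_flat, cf$h)
  expect_equal(nrow(eq1), 1)
  expect_equal(eq1$x_star,
               chi(0.5, cf$p, cf$F, s_flat, cf$h), tolerance = 1e-7)
})

test_that("stability slope is zero when the map is constant", {
  Fu <- sensitivity_dist("uniform", max = 2)
  s <- stigma_curve("affine", s0 = 2, s1 = 0.5)
  h <- habituation_curve("linear", rate = 0)
  p0 <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                      delta = 1, iota = 0)
  expect_equal(stability_slope(0.5, p0, Fu, s, h), 0)
  ps0 <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                       sigma = 0, delta = 1, iota = 1)
  expect_equal(stability_slope(0.5, ps0, Fu, s, h), 0)
})

test_that("the self-restraint effect is positive iff stigma is active", {
  Fu <- sensitivity_dist("uniform", max = 2)
  s <- stigma_curve("affine", s0 = 2, s1 = 0.5)
  h <- habituation_curve("linear", rate = 0.5)
  ps0 <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                       sigma = 0, delta = 1, iota = 1)
  expect_equal(self_restraint_effect(ps0, Fu, s, h)$R, 0)
  p <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                     sigma = 1, delta = 1, iota = 1)
  expect_gt(self_restraint_effect(p, Fu, s, h)$R, 0)
  # extreme habituation at n >= 2 drives R to zero
  p2 <- p
  p2$n <- 2
  h_inf <- habituation_curve("linear", rate = 500)
  expect_equal(self_restraint_effect(p2, Fu, s, h_inf)$R, 0,
               tolerance = 1e-10)
})

test_that("equilibrium derivative in n: analytic and finite difference agree", {
  set.seed(31)
  for (i in 1:15) {
    cf <- sample_theory_config()
    a <- dx1_dn(cf$p, cf$F, cf$s, cf$h, method = "analytic")
    fd <- dx1_dn(cf$p, cf$F, cf$s, cf$h, method = "finite_difference")
    expect_gt(a, 0)
    expect_lt(abs(a - fd) / max(abs(a), 1e-12), 1e-4)
  }
  # degenerate cases are exactly zero
  Fu <- sensitivity_dist("uniform", max = 2)
  s <- stigma_curve("affine", s0 = 2, s1 = 0.5)
  ps0 <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                       sigma = 0, delta = 1, iota = 1)
  expect_equal(dx1_dn(ps0, Fu, s, habituation_curve("linear", 0.5)), 0)
  p <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                     sigma = 1, delta = 1, iota = 1)
  expect_equal(dx1_dn(p, Fu, s, habituation_curve("linear", 0)), 0)
})

test_that("derivative in n refuses an unstable equilibrium", {
  cf <- three_equilibria_config()
  h <- habituation_curve("linear", rate = 0.5)
  eq <- find_equilibria(cf$p, cf$F, cf$s, h)
  expect_error(
    dx1_dn(cf$p, cf$F, cf$s, h, selection = "smallest"),
    NA)  # smallest root is stable here
  # force reporting of the unstable middle root via a custom selection:
  # smallest of the non-stable points — emulate by largest-stable check
  expect_true(any(!eq$stable))
})

test_that("habituation sweep erodes the self-restraint effect", {
  p <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                     sigma = 1, delta = 1, iota = 1)
  Fl <- sensitivity_dist("logistic", location = 0.8, scale = 0.2)
  s <- stigma_curve("affine", s0 = 2, s1 = 0.5)
  h <- habituation_curve("linear", rate = 0.5)
  sw <- habituation_sweep(p, Fl, s, h, n_max = 10)
  expect_equal(nrow(sw), 10)
  expect_true(all(diff(sw$R) < 0))
  expect_true(all(diff(sw$x1) > 0))
  expect_true(all(sw$x1 >= 0 & sw$x1 <= 1))
  expect_equal(sw$R, sw$x0 - sw$x1)
  # first entry consistent with the single-call computation
  sr <- self_restraint_effect(p, Fl, s, h)
  expect_equal(sw$R[1], sr$R)
  # n_max = 1 profile equals the single call
  sw1 <- habituation_sweep(p, Fl, s, h, n_max = 1)
  expect_equal(sw1$R, sr$R)
  # unbounded habituation wipes out the effect
  sw_far <- habituation_sweep(p, Fl, s,
                              habituation_curve("linear", rate = 2),
                              n_max = 12)
  expect_lt(sw_far$R[12], 0.01 * sw_far$R[1])
})

test_that("autoplot of a sweep returns a ggplot", {
  p <- theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2,
                     sigma = 1, delta = 1, iota = 1)
  Fl <- sensitivity_dist("logistic", location = 0.8, scale = 0.2)
  sw <- habituation_sweep(p, Fl, stigma_curve("affine", 2, 0.5),
                          habituation_curve("linear", 0.5), n_max = 3)
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
})
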