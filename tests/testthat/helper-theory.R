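# Random admissible theory configurations for the property suites.
#
# Admissibility: all constructor invariants, plus (i) for a uniform
# sensitivity distribution the support reaches beyond the no-emergency
# threshold (so the no-emergency equilibrium is interior), and (ii) the
# emergency equilibrium is numerically interior (chi(0) >= 1e-6 at n = 1) —
# strict monotonicity of R(n) is unobservable in double precision when the
# equilibrium share underflows toward 0.
sample_theory_config <- function() {
  repeat {
    u_out <- runif(1, 0.5, 2)
    u_home <- u_out - runif(1, 0.2, 1)
    gamma <- runif(1, 0.2, 0.8)
    cc <- runif(1, 0.5, 3)
    sigma <- runif(1, 0.2, 2)
    delta <- runif(1, 0.5, 2)
    s0 <- runif(1, 1, 3)
    s1 <- s0 * runif(1, 0.2, 0.8)
    phi0 <- (u_out - u_home) / (gamma * cc)^delta
    fam <- sample(c("uniform", "logistic", "lognormal"), 1)
    Fd <- switch(fam,
      uniform = sensitivity_dist("uniform", max = phi0 * runif(1, 1.1, 3)),
      logistic = sensitivity_dist("logistic",
                                  location = phi0 * runif(1, 0.6, 1.4),
                                  scale = phi0 * runif(1, 0.1, 0.4)),
      lognormal = sensitivity_dist("lognormal",
                                   meanlog = log(phi0) + runif(1, -0.5, 0.5),
                                   sdlog = runif(1, 0.3, 1)))
    cfg <- list(
      p = theory_params(u_out, u_home, gamma, cc, sigma, delta,
                        iota = 1, n = 1),
      F = Fd,
      s = stigma_curve(sample(c("affine", "power"), 1), s0, s1,
                       kappa = runif(1, 1, 3)),
      h = habituation_curve(sample(c("linear", "log"), 1),
                            rate = runif(1, 0.2, 1)))
    if (chi(0, cfg$p, cfg$F, cfg$s, cfg$h) >= 1e-6) return(cfg)
  }
}

# A configuration with three fixed points (steep truncated-logistic F and
# a wide-range affine stigma curve): outer roots stable, middle unstable.
three_equilibria_config <- function() {
  list(p = theory_params(u_out = 1, u_home = 0, gamma = 0.1, c = 2,
                         sigma = 1, delta = 1, iota = 1, n = 1),
       F = sensitivity_dist("logistic", location = 2, scale = 0.1),
       s = stigma_curve("affine", s0 = 2, s1 = 0.05),
       h = habituation_curve("linear", rate = 0))
}

# Independent oracle: count and locate fixed points by a dense grid scan.
grid_scan_roots <- function(params, F, s, h, step = 1e-5) {
  xs <- seq(0, 1, by = step)
  g <- chi(xs, params, F, s, h) - xs
  sgn <- sign(g)
  idx <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  roots <- (xs[idx] + xs[idx + 1]) / 2
  exact <- xs[g == 0]
  sort(c(roots, exact))
}
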