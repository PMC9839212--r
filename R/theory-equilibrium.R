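#' Payoff from going out
#'
#' `u_out - phi * (gamma c + iota sigma exp(-h(n)) s)^delta`: going out
#' yields its utility minus a psychological cost scaled by the individual
#' sensitivity `phi`. Without an emergency (`iota = 0`) the stigma term
#' vanishes and only infection risk `gamma * c` remains.
#'
#' @param params A [theory_params()] object.
#' @param s_value Stigma cost level `s >= 0`.
#' @param phi Sensitivity to psychological costs, `>= 0` (vectorized).
#' @param h A [habituation_curve()]; defaults to no habituation.
#' @return Payoff value(s), one per `phi`.
#' @export
payoff_out <- function(params, s_value, phi,
                       h = habituation_curve("linear", rate = 0)) {
  stopifnot(inherits(params, "theory_params"))
  if (!all(is.finite(s_value)) || !all(is.finite(phi))) {
    stop("`s_value` and `phi` must be finite", call. = FALSE)
  }
  if (any(s_value < 0) || any(phi < 0)) {
    stop("`s_value` and `phi` must be nonnegative", call. = FALSE)
  }
  cost_base <- params$gamma * params$c +
    params$iota * params$sigma * exp(-h$value(params$n)) * s_value
  params$u_out - phi * cost_base^params$delta
}

#' Critical sensitivity to psychological costs
#'
#' The sensitivity level at which an individual is indifferent between
#' going out and staying home:
#' `phi_hat = (u_out - u_home) / (gamma c + iota sigma exp(-h(n)) s)^delta`.
#' Individuals with `phi <= phi_hat` go out.
#'
#' @inheritParams payoff_out
#' @return The threshold `phi_hat > 0`.
#' @export
critical_sensitivity <- function(params, s_value,
                                 h = habituation_curve("linear", rate = 0)) {
  stopifnot(inherits(params, "theory_params"))
  denom_base <- params$gamma * params$c +
    params$iota * params$sigma * exp(-h$value(params$n)) * s_value
  if (any(denom_base <= 0)) {
    stop("psychological cost base is not positive; check gamma*c and sigma*s",
         call. = FALSE)
  }
  (params$u_out - params$u_home) / denom_base^params$delta
}

#' Equilibrium map of the going-out share
#'
#' One round of best responses: if a share `x` currently goes out, the
#' stigma cost is `s(x)`, the critical sensitivity is `phi_hat(s(x))`, and
#' the share preferring to go out is `chi(x) = F(phi_hat(s(x)))`. Fixed
#' points of `chi` are the equilibria. Because `s` is decreasing and `F`
#' nondecreasing, `chi` is nondecreasing on `[0, 1]`.
#'
#' @inheritParams payoff_out
#' @param x Going-out share(s) in `[0, 1]` (vectorized).
#' @param F A [sensitivity_dist()].
#' @param s A [stigma_curve()].
#' @return `chi(x)`, in `[0, 1]`.
#' @export
chi <- function(x, params, F, s, h = habituation_curve("linear", rate = 0)) {
  stopifnot(inherits(F, "sensitivity_dist"), inherits(s, "stigma_curve"),
            inherits(h, "habituation_curve"))
  if (any(x < 0 | x > 1)) stop("`x` must lie in [0, 1]", call. = FALSE)
  F$cdf(critical_sensitivity(params, s$value(x), h))
}

#' Closed-form equilibrium without a state of emergency
#'
#' With `iota = 0` the stigma term drops out, `chi` is the constant
#' `F((u_out - u_home) / (gamma c)^delta)`, and the unique equilibrium is
#' that constant itself.
#'
#' @inheritParams chi
#' @return The share `x0*` in `[0, 1]`.
#' @export
no_emergency_equilibrium <- function(params, F) {
  stopifnot(inherits(params, "theory_params"),
            inherits(F, "sensitivity_dist"))
  F$cdf((params$u_out - params$u_home) / (params$gamma * params$c)^params$delta)
}

#' Find all equilibria of the going-out share
#'
#' Scans `chi(x) - x` for sign changes on a uniform grid over `[0, 1]` and
#' refines each bracket by bisection ([stats::uniroot()]). Because `chi`
#' maps `[0, 1]` into itself and is nondecreasing, at least one fixed point
#' always exists. Each root is flagged stable when the local slope of `chi`
#' is below 1.
#'
#' @inheritParams chi
#' @param grid_step Grid spacing for the sign scan (default `1e-3`).
#' @param tol Root tolerance for the bisection refinement.
#' @return A tibble of class `"equilibrium_set"` with columns `x_star`
#'   (ascending), `slope` and `stable`.
#' @export
find_equilibria <- function(params, F, s,
                            h = habituation_curve("linear", rate = 0),
                            grid_step = 1e-3, tol = 1e-12) {
  stopifnot(grid_step > 0, grid_step <= 1e-3, tol > 0)
  g <- function(x) chi(x, params, F, s, h) - x
  xs <- seq(0, 1, by = grid_step)
  if (xs[length(xs)] < 1) xs <- c(xs, 1)
  gs <- g(xs)
  roots <- numeric(0)
  # exact hits on the grid (incl. boundaries) and sign-change brackets
  hit <- which(gs == 0)
  roots <- c(roots, xs[hit])
  sgn <- sign(gs)
  idx <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  for (i in idx) {
    r <- stats::uniroot(g, lower = xs[i], upper = xs[i + 1],
                        f.lower = gs[i], f.upper = gs[i + 1],
                        tol = tol)$root
    roots <- c(roots, r)
  }
  # chi(0) >= 0 and chi(1) <= 1, so absence of any root violates existence
  if (length(roots) == 0) {
    stop("no fixed point bracketed; chi should always cross the diagonal",
         call. = FALSE)
  }
  roots <- sort(unique(roots))
  # drop near-duplicates from an exact grid hit adjacent to a bracket
  if (length(roots) > 1) {
    roots <- roots[c(TRUE, diff(roots) > 2 * grid_step * 1e-3 + 1e-12)]
  }
  slopes <- purrr::map_dbl(roots, function(r) {
    stability_slope(r, params, F, s, h)
  })
  out <- tibble::tibble(x_star = roots, slope = slopes, stable = slopes < 1)
  class(out) <- c("equilibrium_set", class(out))
  out
}

#' Local slope of the equilibrium map at a fixed point
#'
#' Central finite difference of `chi` at `x_star` (one-sided at the
#' boundaries of `[0, 1]`). A fixed point is stable under best-response
#' dynamics when this slope is below 1.
#'
#' @inheritParams chi
#' @param x_star A fixed point of `chi` (to tolerance).
#' @param eps Finite-difference step.
#' @return The slope estimate.
#' @export
stability_slope <- function(x_star, params, F, s,
                            h = habituation_curve("linear", rate = 0),
                            eps = 1e-6) {
  lo <- max(0, x_star - eps)
  hi <- min(1, x_star + eps)
  (chi(hi, params, F, s, h) - chi(lo, params, F, s, h)) / (hi - lo)
}

#' Select a reporting equilibrium from an equilibrium set
#'
#' Under multiplicity the default reports the smallest stable fixed point
#' (the most restrained outcome). The smallest crossing of a nondecreasing
#' `chi` comes from above the diagonal, so it is stable except at
#' tangencies.
#'
#' @param eq An `"equilibrium_set"` tibble from [find_equilibria()].
#' @param selection One of `"smallest-stable"`, `"largest-stable"`,
#'   `"smallest"`, `"largest"`.
#' @return A single share `x*`.
#' @export
select_equilibrium <- function(eq,
                               selection = c("smallest-stable", "largest-stable",
                                             "smallest", "largest")) {
  selection <- match.arg(selection)
  pts <- eq$x_star
  if (grepl("stable", selection)) {
    stable_pts <- pts[eq$stable]
    if (length(stable_pts) == 0) {
      warning("no stable equilibrium; falling back to all fixed points")
      stable_pts <- pts
    }
    pts <- stable_pts
  }
  if (grepl("smallest", selection)) min(pts) else max(pts)
}

# Polish a fixed point by damped Newton on chi(x) - x, using the analytic
# slope when available. Brings bisection output to ~machine precision so
# finite differences in n are clean.
polish_fixed_point <- function(x0, params, F, s, h) {
  x <- x0
  for (i in 1:8) {
    gx <- chi(x, params, F, s, h) - x
    sl <- stability_slope(x, params, F, s, h)
    if (abs(sl - 1) < 1e-6) break
    step <- gx / (1 - sl)
    x_new <- min(1, max(0, x + step))
    if (abs(x_new - x) < 1e-15) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x
}

equilibrium_under_emergency <- function(params, F, s, h, selection, n = NULL) {
  p1 <- params
  p1$iota <- 1
  if (!is.null(n)) p1$n <- n
  eq <- find_equilibria(p1, F, s, h)
  x1 <- select_equilibrium(eq, selection)
  list(x1 = polish_fixed_point(x1, p1, F, s, h), eq = eq, params = p1)
}

#' Self-restraint effect of a state of emergency
#'
#' `R = x0* - x1*`: the equilibrium going-out share without an emergency
#' minus the share under one. `R > 0` whenever the stigma channel is active
#' (`sigma > 0`, finite habituation), because the emergency strictly raises
#' the psychological cost of going out at every share.
#'
#' @inheritParams chi
#' @param selection Equilibrium selection rule, see [select_equilibrium()].
#' @return A list with `R`, `x0`, `x1` and the `"equilibrium_set"` under
#'   the emergency.
#' @export
self_restraint_effect <- function(params, F, s,
                                  h = habituation_curve("linear", rate = 0),
                                  selection = "smallest-stable") {
  stopifnot(inherits(params, "theory_params"))
  x0 <- no_emergency_equilibrium(params, F)
  em <- equilibrium_under_emergency(params, F, s, h, selection)
  list(R = x0 - em$x1, x0 = x0, x1 = em$x1, equilibria = em$eq)
}

#' Derivative of the emergency equilibrium share in the declaration count
#'
#' Treating `n` as continuous, the implicit-function derivative of the
#' selected equilibrium `x1*(n)` is
#' `(d chi / d n) / (1 - d chi / d x)` evaluated at the fixed point, with
#' `d chi / d n = f(phi_hat) * delta * (u_out - u_home) / D^(delta+1) *
#' h'(n) * sigma * exp(-h(n)) * s(x1*)` where
#' `D = gamma c + sigma exp(-h(n)) s(x1*)`. It is positive when the stigma
#' channel is active and habituation strictly increasing, so the
#' self-restraint effect `R(n)` declines with `n` (`dR/dn = -dx1/dn < 0`).
#'
#' @inheritParams self_restraint_effect
#' @param method `"analytic"` (the closed-form implicit derivative) or
#'   `"finite_difference"` (recompute the equilibrium at `n - eps` and
#'   `n + eps` and difference).
#' @param eps Step for the finite-difference method.
#' @return The derivative `d x1* / d n` (a number).
#' @export
dx1_dn <- function(params, F, s,
                   h = habituation_curve("linear", rate = 0),
                   method = c("analytic", "finite_difference"),
                   selection = "smallest-stable", eps = 1e-5) {
  method <- match.arg(method)
  em <- equilibrium_under_emergency(params, F, s, h, selection)
  p1 <- em$params
  slope <- stability_slope(em$x1, p1, F, s, h)
  if (slope >= 1) {
    stop(sprintf(paste0("selected equilibrium x1* = %.6f is unstable ",
                        "(slope %.4f >= 1); the implicit derivative in n ",
                        "is undefined there"), em$x1, slope), call. = FALSE)
  }
  if (method == "analytic") {
    x1 <- em$x1
    hn <- h$value(p1$n)
    sx <- s$value(x1)
    D <- p1$gamma * p1$c + p1$sigma * exp(-hn) * sx
    phihat <- (p1$u_out - p1$u_home) / D^p1$delta
    common <- F$pdf(phihat) * p1$delta * (p1$u_out - p1$u_home) / D^(p1$delta + 1)
    dchi_dn <- common * h$deriv(p1$n) * p1$sigma * exp(-hn) * sx
    dchi_dx <- common * (-s$deriv(x1)) * p1$sigma * exp(-hn)
    dchi_dn / (1 - dchi_dx)
  } else {
    lo <- equilibrium_under_emergency(params, F, s, h, selection,
                                      n = max(1, p1$n - eps))
    hi <- equilibrium_under_emergency(params, F, s, h, selection,
                                      n = p1$n + eps)
    (hi$x1 - lo$x1) / (hi$params$n - lo$params$n)
  }
}

#' Self-restraint effect across repeated declarations
#'
#' Recomputes the emergency equilibrium for `n = 1, ..., n_max` with all
#' other parameters fixed, tracing how habituation erodes the
#' self-restraint effect: `x1*(n)` rises toward the no-emergency share and
#' `R(n)` shrinks.
#'
#' @inheritParams self_restraint_effect
#' @param n_max Largest declaration count to evaluate (`>= 1`).
#' @return A tibble of class `"habituation_sweep"` with columns `n`, `x0`,
#'   `x1`, `R`, `k` (number of fixed points) and `n_stable`.
#' @examples
#' p <- theory_params(gamma = 0.5, c = 2, sigma = 1)
#' F <- sensitivity_dist("logistic", location = 0.6, scale = 0.2)
#' s <- stigma_curve("affine", s0 = 2, s1 = 0.5)
#' h <- habituation_curve("linear", rate = 0.5)
#' habituation_sweep(p, F, s, h, n_max = 4)
#' @export
habituation_sweep <- function(params, F, s, h, n_max = 4,
                              selection = "smallest-stable") {
  stopifnot(n_max >= 1)
  x0 <- no_emergency_equilibrium(params, F)
  rows <- purrr::map(seq_len(n_max), function(n) {
    em <- equilibrium_under_emergency(params, F, s, h, selection, n = n)
    tibble::tibble(n = n, x0 = x0, x1 = em$x1, R = x0 - em$x1,
                   k = nrow(em$eq), n_stable = sum(em$eq$stable))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("habituation_sweep", class(out))
  out
}

#' @rdname habituation_sweep
#' @param object,... Passed to the autoplot method.
#' @method autoplot habituation_sweep
#' @export
autoplot.habituation_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("x0", "x1", "R"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$n) +
    ggplot2::labs(x = "declaration number n", y = NULL, colour = NULL,
                  title = "Habituation erodes the self-restraint effect",
                  subtitle = "x0: no-emergency share; x1: share under emergency; R = x0 - x1")
}
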