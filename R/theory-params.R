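#' Parameters of the stigma-habituation going-out model
#'
#' Bundles the primitive parameters of the going-out/stay-home decision
#' model. An individual with psychological-cost sensitivity `phi` receives
#' `u_out - phi * (gamma * c + iota * sigma * exp(-h(n)) * s(x))^delta`
#' from going out and `u_home` from staying home, where `s(x)` is the
#' stigma cost at going-out share `x` and `h(n)` the habituation exponent
#' after `n` emergency declarations.
#'
#' @param u_out,u_home Utility from going out / staying home; `u_out` must
#'   exceed `u_home` or no one would ever go out.
#' @param gamma Infection probability, in `[0, 1]`.
#' @param c Infection cost, positive; `gamma * c` must be positive so the
#'   psychological cost is positive even without an emergency.
#' @param sigma Relative impact of stigma, nonnegative.
#' @param delta Cost scale exponent, positive.
#' @param iota Policy indicator: 1 under a state of emergency, 0 otherwise.
#' @param n Number of emergency declarations experienced, `>= 1`. Real
#'   valued so comparative statics can differentiate in `n`.
#'
#' @return An object of class `"theory_params"` (a named list).
#' @examples
#' theory_params(u_out = 1, u_home = 0, gamma = 0.5, c = 2)
#' @export
theory_params <- function(u_out = 1, u_home = 0, gamma = 0.3, c = 2,
                          sigma = 1, delta = 1, iota = 1, n = 1) {
  vals <- c(u_out = u_out, u_home = u_home, gamma = gamma, c = c,
            sigma = sigma, delta = delta, iota = iota, n = n)
  if (!all(is.finite(vals))) {
    stop("all theory parameters must be finite", call. = FALSE)
  }
  if (u_out <= u_home) stop("`u_out` must exceed `u_home`", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]", call. = FALSE)
  if (c <= 0) stop("`c` must be positive", call. = FALSE)
  if (gamma * c <= 0) stop("`gamma * c` must be positive", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (!iota %in% c(0, 1)) stop("`iota` must be 0 or 1", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  structure(as.list(vals), class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat("<theory_params>\n")
  cat(sprintf("  u_out = %g, u_home = %g, gamma = %g, c = %g\n",
              x$u_out, x$u_home, x$gamma, x$c))
  cat(sprintf("  sigma = %g, delta = %g, iota = %d, n = %g\n",
              x$sigma, x$delta, as.integer(x$iota), x$n))
  invisible(x)
}

#' Distribution of the sensitivity to psychological costs
#'
#' The population share going out at critical sensitivity `phi_hat` is
#' `F(phi_hat)`, where `F` is the distribution of the sensitivity `phi`
#' over `[0, Inf)`. Three continuous families are provided; all have a
#' density, which the comparative statics require.
#'
#' @param family `"uniform"` on `[0, max]`; `"logistic"`, a location-scale
#'   logistic truncated to the positive half-line; or `"lognormal"`.
#' @param max Upper endpoint of the uniform family (positive).
#' @param location,scale Location and scale of the logistic family
#'   (`scale > 0`).
#' @param meanlog,sdlog Log-scale mean and standard deviation of the
#'   lognormal family (`sdlog > 0`).
#'
#' @return An object of class `"sensitivity_dist"` with elements `cdf` and
#'   `pdf` (vectorized functions on `[0, Inf)`), `family` and `params`.
#' @examples
#' F <- sensitivity_dist("uniform", max = 2)
#' F$cdf(1)   # 0.5
#' @export
sensitivity_dist <- function(family = c("uniform", "logistic", "lognormal"),
                             max = 2, location = 1, scale = 0.25,
                             meanlog = 0, sdlog = 0.5) {
  family <- match.arg(family)
  obj <- switch(family,
    uniform = {
      stopifnot(max > 0)
      list(cdf = function(q) stats::punif(pmax(q, 0), 0, max),
           pdf = function(q) stats::dunif(pmax(q, 0), 0, max),
           params = c(max = max))
    },
    logistic = {
      stopifnot(scale > 0)
      p0 <- stats::plogis(0, location, scale)
      list(cdf = function(q) {
             (stats::plogis(pmax(q, 0), location, scale) - p0) / (1 - p0)
           },
           pdf = function(q) stats::dlogis(pmax(q, 0), location, scale) / (1 - p0),
           params = c(location = location, scale = scale))
    },
    lognormal = {
      stopifnot(sdlog > 0)
      list(cdf = function(q) stats::plnorm(pmax(q, 0), meanlog, sdlog),
           pdf = function(q) stats::dlnorm(pmax(q, 0), meanlog, sdlog),
           params = c(meanlog = meanlog, sdlog = sdlog))
    })
  structure(c(obj, list(family = family)), class = "sensitivity_dist")
}

#' @export
print.sensitivity_dist <- function(x, ...) {
  cat(sprintf("<sensitivity_dist: %s (%s)>\n", x$family,
              paste(names(x$params), signif(x$params, 4),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Stigma cost as a function of the going-out share
#'
#' The stigma cost `s(x)` of going out is strictly decreasing in the share
#' `x` of the population going out: the fewer people outside, the stronger
#' the social sanction. Both families satisfy `s(x) > 0` on `[0, 1]` and in
#' particular `s(1) > 0`.
#'
#' @param family `"affine"`, `s(x) = s0 - (s0 - s1) x`; or `"power"`,
#'   `s(x) = s1 + (s0 - s1) (1 - x)^kappa`.
#' @param s0 Stigma cost when nobody goes out, `s(0)`.
#' @param s1 Stigma cost when everybody goes out, `s(1)`; `0 < s1 < s0`.
#' @param kappa Curvature of the power family, positive.
#'
#' @return An object of class `"stigma_curve"` with vectorized `value` and
#'   `deriv` functions on `[0, 1]`.
#' @examples
#' s <- stigma_curve("affine", s0 = 2, s1 = 0.5)
#' s$value(c(0, 1))  # 2.0 0.5
#' @export
stigma_curve <- function(family = c("affine", "power"),
                         s0 = 2, s1 = 0.5, kappa = 2) {
  family <- match.arg(family)
  if (s1 <= 0) stop("`s1` = s(1) must be positive", call. = FALSE)
  if (s0 <= s1) stop("`s0` must exceed `s1` (s strictly decreasing)", call. = FALSE)
  obj <- switch(family,
    affine = list(
      value = function(x) s0 - (s0 - s1) * x,
      deriv = function(x) rep(-(s0 - s1), length(x)),
      params = c(s0 = s0, s1 = s1)),
    power = {
      stopifnot(kappa > 0)
      list(
        value = function(x) s1 + (s0 - s1) * (1 - x)^kappa,
        deriv = function(x) -kappa * (s0 - s1) * (1 - x)^(kappa - 1),
        params = c(s0 = s0, s1 = s1, kappa = kappa))
    })
  structure(c(obj, list(family = family)), class = "stigma_curve")
}

#' @export
print.stigma_curve <- function(x, ...) {
  cat(sprintf("<stigma_curve: %s (%s)>\n", x$family,
              paste(names(x$params), signif(x$params, 4),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Habituation of the stigma cost to repeated declarations
#'
#' Repeated declarations blunt the stigma term through the discount
#' `exp(-h(n))`, with `h` nondecreasing in the declaration count `n` and
#' `h(1) = 0`: the first declaration carries the full stigma cost.
#'
#' @param family `"linear"`, `h(n) = rate * (n - 1)`; or `"log"`,
#'   `h(n) = rate * log(n)`.
#' @param rate Habituation rate, nonnegative. `rate = 0` switches
#'   habituation off (the discount is 1 for every `n`).
#'
#' @return An object of class `"habituation_curve"` with vectorized `value`
#'   and `deriv` functions of `n >= 1`.
#' @examples
#' h <- habituation_curve("linear", rate = 0.5)
#' exp(-h$value(1:4))
#' @export
habituation_curve <- function(family = c("linear", "log"), rate = 0.5) {
  family <- match.arg(family)
  if (rate < 0) stop("`rate` must be nonnegative", call. = FALSE)
  obj <- switch(family,
    linear = list(value = function(n) rate * (n - 1),
                  deriv = function(n) rep(rate, length(n))),
    log = list(value = function(n) rate * log(n),
               deriv = function(n) rate / n))
  structure(c(obj, list(family = family, rate = rate)),
            class = "habituation_curve")
}

#' @export
print.habituation_curve <- function(x, ...) {
  cat(sprintf("<habituation_curve: %s (rate = %g)>\n", x$family, x$rate))
  invisible(x)
}
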