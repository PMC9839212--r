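#' Configuration of the synthetic mobility panel generator
#'
#' Collects the dimensions, true coefficients and disturbance parameters of
#' the synthetic prefecture-by-day panel. The disturbance of each mobility
#' category follows the error-component process with spatial and serial
#' correlation: a unit effect `alpha_i ~ N(0, sigma_alpha^2)`, a spatial
#' term `nu_t = (I - rho W)^{-1} eta_t`, and an AR(1) core
#' `eta_t = psi eta_{t-1} + e_t`, `e_t ~ N(0, sigma_e^2 I)`.
#'
#' Defaults emulate the Japanese study window (47 prefectures, 1 April 2020
#' to 31 August 2021) with true emergency effects taken from the
#' habituation pattern of the fitted going-out regressions: for the retail
#' category, strictly shrinking negative effects over the four declarations.
#'
#' @param n_units Number of prefectures.
#' @param start,end First and last date of the window (inclusive).
#' @param beta Named list: one named coefficient vector per mobility
#'   category. Names refer to regressor columns of the assembled panel.
#' @param rho Spatial autocorrelation of the disturbance, `|rho| < 1`.
#' @param psi Temporal AR(1) autocorrelation, `|psi| < 1`.
#' @param sigma_alpha,sigma_e Standard deviations of the unit effect and of
#'   the innovation, on the mobility-fraction scale.
#' @param seed Integer seed; mandatory, every draw flows from it.
#' @param ar_init `"stationary"` starts the AR(1) from its stationary
#'   distribution; `"burnin"` starts at zero and discards 200 presample
#'   steps.
#' @param innovations `"gaussian"` or `"t"` (scaled Student-t with
#'   `t_df` degrees of freedom, for robustness experiments only).
#' @param t_df Degrees of freedom for `innovations = "t"`.
#' @return A list of class `"panel_config"`.
#' @export
panel_config <- function(n_units = 47,
                         start = as.Date("2020-04-01"),
                         end = as.Date("2021-08-31"),
                         beta = default_true_beta(),
                         rho = 0.3, psi = 0.5,
                         sigma_alpha = 0.05, sigma_e = 0.02,
                         seed = NULL,
                         ar_init = c("stationary", "burnin"),
                         innovations = c("gaussian", "t"),
                         t_df = 5) {
  if (is.null(seed)) stop("`seed` is mandatory in panel_config()", call. = FALSE)
  start <- as.Date(start)
  end <- as.Date(end)
  stopifnot(n_units >= 1, end >= start, abs(rho) < 1, abs(psi) < 1,
            sigma_alpha >= 0, sigma_e >= 0)
  structure(list(n_units = as.integer(n_units), start = start, end = end,
                 dates = seq(start, end, by = "day"),
                 beta = beta, rho = rho, psi = psi,
                 sigma_alpha = sigma_alpha, sigma_e = sigma_e,
                 seed = as.integer(seed),
                 ar_init = match.arg(ar_init),
                 innovations = match.arg(innovations), t_df = t_df),
            class = "panel_config")
}

#' Default true coefficients of the synthetic panel
#'
#' Per-category effects of the four declaration dummies, matched to the
#' habituation pattern of the fitted going-out regressions (retail shows
#' strictly shrinking negative effects with the declaration number),
#' together with modest covariate effects on the mobility-fraction scale.
#'
#' @return A named list of named numeric vectors, one per category.
#' @export
default_true_beta <- function() {
  covar <- function(prec, temp, wind, pos, nat, unoff) {
    c(precipitation_adj = prec, temperature_z = temp, windspeed_adj = wind,
      positive_per1000_l1 = pos, national_holiday = nat,
      unofficial_holiday = unoff)
  }
  list(
    retail = c(emergency_1st = -0.2009, emergency_2nd = -0.0644,
               emergency_3rd = -0.0605, emergency_4th = -0.0088,
               covar(-0.02, 0.01, -0.01, -0.5, 0.04, 0.03)),
    grocery = c(emergency_1st = -0.0314, emergency_2nd = -0.0195,
                emergency_3rd = 0.0080, emergency_4th = -0.0182,
                covar(-0.01, 0.005, -0.005, -0.1, 0.02, 0.01)),
    workplaces = c(emergency_1st = -0.1316, emergency_2nd = 0.0048,
                   emergency_3rd = 0.0063, emergency_4th = 0.0428,
                   covar(-0.005, 0.0, -0.005, -0.2, -0.25, -0.15)),
    residential = c(emergency_1st = 0.0765, emergency_2nd = 0.0072,
                    emergency_3rd = 0.0084, emergency_4th = -0.0129,
                    covar(0.01, -0.005, 0.005, 0.2, 0.05, 0.03))
  )
}

#' Simulate error-component disturbances with spatial and AR(1) structure
#'
#' Draws one disturbance surface `epsilon_it = alpha_i + nu_it` where
#' `alpha ~ N(0, sigma_alpha^2)` per unit, `eta_t = psi eta_{t-1} + e_t`
#' with a stationary start `eta_0 ~ N(0, sigma_e^2 / (1 - psi^2))`, and
#' `nu_t = (I - rho W)^{-1} eta_t`. Reproducible: all draws flow from
#' `config$seed` (offset by `stream` so independent surfaces can be drawn
#' from one config).
#'
#' @param config A [panel_config()].
#' @param W Spatial weight matrix from [make_weight_matrix()] (or any
#'   `n x n` matrix making `I - rho W` invertible).
#' @param stream Integer stream offset for independent replicate surfaces.
#' @return An `n_units x n_dates` matrix of disturbances.
#' @export
simulate_disturbances <- function(config, W, stream = 0L) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_units
  Tn <- length(config$dates)
  W <- as.matrix(W)
  stopifnot(nrow(W) == n, ncol(W) == n)
  B <- diag(n) - config$rho * W
  if (rcond(B) < 1e-12) {
    stop("I - rho * W is (numerically) singular; pick |rho| inside the ",
         "spectral bounds of W", call. = FALSE)
  }
  with_seed(child_seed(config$seed, 1000L + stream), {
    rinnov <- switch(config$innovations,
      gaussian = function(m) rnorm(m),
      t = function(m) stats::rt(m, df = config$t_df) /
            sqrt(config$t_df / (config$t_df - 2)))
    alpha <- config$sigma_alpha * rinnov(n)
    burn <- if (config$ar_init == "burnin") 200L else 0L
    E <- matrix(config$sigma_e * rinnov(n * (Tn + burn)), n, Tn + burn)
    eta <- matrix(0, n, Tn + burn)
    eta0 <- if (config$ar_init == "stationary") {
      config$sigma_e / sqrt(1 - config$psi^2) * rinnov(n)
    } else {
      numeric(n)
    }
    eta[, 1] <- config$psi * eta0 + E[, 1]
    for (t in seq_len(Tn + burn)[-1]) {
      eta[, t] <- config$psi * eta[, t - 1] + E[, t]
    }
    if (burn > 0) eta <- eta[, -seq_len(burn), drop = FALSE]
    nu <- solve(B, eta)
    eps <- sweep(nu, 1, alpha, `+`)
    dimnames(eps) <- list(NULL, as.character(config$dates))
    eps
  })
}

#' Simulate weather, infection and holiday covariates
#'
#' Emulates the covariates of the mobility regressions: zero-inflated
#' lognormal daily precipitation (mm), a seasonal sinusoid plus unit offset
#' for temperature (deg C), lognormal wind speed (m/s), a nonnegative
#' log-AR(1) wave process with seasonal forcing for daily positive cases,
#' a synthetic prefecture population, and national/unofficial holiday flags
#' from the packaged Japanese calendar. Deterministic under `seed`.
#'
#' @param units Character vector of unit (prefecture) names.
#' @param dates `Date` vector (daily).
#' @param seed Integer seed.
#' @param holidays Holiday calendar, by default [jp_holidays()]; dates
#'   outside the calendar get flag 0.
#' @return A tibble with one row per unit-date: `prefecture`, `date`,
#'   `precipitation`, `temperature`, `windspeed`, `positives`,
#'   `population`, `national_holiday`, `unofficial_holiday`.
#' @export
simulate_covariates <- function(units, dates, seed, holidays = jp_holidays()) {
  n <- length(units)
  Tn <- length(dates)
  with_seed(child_seed(seed, 2000L), {
    pop <- round(stats::rlnorm(n, log(1.5e6), 0.8))
    temp_offset <- rnorm(n, 0, 2)
    doy <- as.integer(format(dates, "%j"))
    season <- -cos(2 * pi * (doy - 15) / 365.25)
    grid <- tidyr::expand_grid(prefecture = units, date = dates)
    N <- nrow(grid)
    precipitation <- stats::rbinom(N, 1, 0.3) * stats::rlnorm(N, 1.0, 1.0)
    # grid is unit-major (each unit's dates contiguous)
    temperature <- 15 + 10 * rep(season, times = n) +
      rep(temp_offset, each = Tn) + rnorm(N, 0, 2)
    windspeed <- stats::rlnorm(N, 1.0, 0.4)
    # positives: log-AR(1) around a population-scaled seasonal mean
    z <- matrix(0, n, Tn)
    mu <- log(pop * 2e-6) + matrix(rep(0.8 * sin(2 * pi * doy / 180), each = n),
                                   n, Tn)
    innov <- matrix(rnorm(n * Tn, 0, 0.3), n, Tn)
    z[, 1] <- mu[, 1] + innov[, 1] / sqrt(1 - 0.9^2)
    for (t in seq_len(Tn)[-1]) {
      z[, t] <- mu[, t] + 0.9 * (z[, t - 1] - mu[, t - 1]) + innov[, t]
    }
    positives <- exp(as.vector(t(z)))  # unit-major vector
    nat <- holidays$date[holidays$type == "national"]
    unoff <- holidays$date[holidays$type == "unofficial"]
    dplyr::mutate(grid,
      precipitation = precipitation,
      temperature = temperature,
      windspeed = windspeed,
      positives = positives,
      population = rep(pop, each = Tn),
      national_holiday = as.integer(.data$date %in% nat),
      unofficial_holiday = as.integer(.data$date %in% unoff))
  })
}

#' Synthetic emergency schedule for an arbitrary window
#'
#' Compresses the four-round declaration pattern into a given date window
#' so short panels still contain every declaration number: the window is
#' split into one block per round, each unit that reaches round `k` gets an
#' episode with a random start and duration inside block `k`. The share of
#' units reaching rounds 1-4 mirrors the real schedule (all units saw the
#' first declaration; about 21/47 a second, 19/47 a third, 8/47 a fourth).
#'
#' @param units Character vector of unit names.
#' @param dates Daily `Date` vector of the window.
#' @param seed Integer seed.
#' @param n_rounds Number of declaration rounds (default 4).
#' @param p_reach Probabilities that a unit reaches round 1, 2, ... (first
#'   must be 1; nonincreasing).
#' @return An `"emergency_schedule"` tibble (see [emergency_schedule()]).
#' @export
make_synthetic_schedule <- function(units, dates, seed, n_rounds = 4,
                                    p_reach = c(1, 21 / 47, 19 / 47, 8 / 47)) {
  stopifnot(length(p_reach) >= n_rounds, p_reach[1] == 1,
            !is.unsorted(rev(p_reach[seq_len(n_rounds)])))
  Tn <- length(dates)
  stopifnot(Tn >= 8 * n_rounds)
  block <- floor(Tn / n_rounds)
  with_seed(child_seed(seed, 3000L), {
    u <- runif(length(units))
    reach <- vapply(u, function(ui) sum(ui <= p_reach[seq_len(n_rounds)]),
                    integer(1))
    rows <- purrr::map(seq_along(units), function(i) {
      k <- reach[i]
      purrr::map(seq_len(k), function(r) {
        lo <- (r - 1) * block + 1
        start_off <- sample.int(max(1, floor(block * 0.3)), 1)
        dur <- sample(seq(floor(block * 0.3), floor(block * 0.6)), 1)
        s <- lo + start_off - 1
        e <- min(lo + block - 1, s + dur - 1)
        tibble::tibble(prefecture_en = units[i],
                       emergency_start = dates[s],
                       emergency_end = dates[e],
                       times = r)
      })
    })
    out <- dplyr::bind_rows(rows)
    out <- dplyr::arrange(out, .data$prefecture_en, .data$emergency_start)
    out$truncated <- FALSE
    class(out) <- c("emergency_schedule", class(out))
    out
  })
}

#' Assemble a synthetic mobility panel
#'
#' Builds the long prefecture-by-date panel: declaration dummies from the
#' schedule (inclusive of both the declaration and the lift date, clipped
#' to the window), regression-ready covariates, and one mobility outcome
#' per category generated as `y = x' beta + epsilon` with an independent
#' disturbance surface per category. With the default 47 units over
#' 2020-04-01..2021-08-31 the panel has `47 * 518 = 24,346` rows.
#'
#' The lagged-positives regressor uses a left-edge partial moving-average
#' window and carries the first value into the lag slot, keeping the
#' generated panel rectangular; the stricter missing-value marking used on
#' raw data lives in the preprocessing step (see [prepare_panel()]).
#'
#' @param config A [panel_config()].
#' @param schedule An `"emergency_schedule"`; defaults to the packaged
#'   Japanese schedule when the window fits it, otherwise supply one (e.g.
#'   [make_synthetic_schedule()]).
#' @param covariates Covariate table from [simulate_covariates()];
#'   simulated from `config$seed` when `NULL`.
#' @param disturbances Named list of `n x T` matrices (one per category) or
#'   a single matrix reused for every category; simulated when `NULL`.
#' @param W Spatial weight matrix; default ring over `n_units`.
#' @return A tibble of class `"mobility_panel"`: `prefecture`, `date`, the
#'   mobility categories, dummies `emergency`, `emergency_1st` ...,
#'   covariates (raw and regression-ready).
#' @examples
#' cfg <- panel_config(n_units = 5, start = "2020-04-01", end = "2020-05-31",
#'                     seed = 1)
#' sched <- make_synthetic_schedule(paste0("u", 1:5), cfg$dates, seed = 1,
#'                                  n_rounds = 2)
#' panel <- assemble_panel(cfg, schedule = sched)
#' @export
assemble_panel <- function(config, schedule = emergency_schedule(),
                           covariates = NULL, disturbances = NULL, W = NULL) {
  stopifnot(inherits(config, "panel_config"),
            inherits(schedule, "emergency_schedule"))
  units <- sort(unique(schedule$prefecture_en))
  if (length(units) < config$n_units) {
    stop("schedule has fewer prefectures than `n_units`", call. = FALSE)
  }
  units <- units[seq_len(config$n_units)]
  dates <- config$dates
  if (is.null(W)) W <- make_weight_matrix("ring", config$n_units)
  if (is.null(covariates)) {
    covariates <- simulate_covariates(units, dates, config$seed)
  }
  covariates <- dplyr::arrange(covariates, .data$prefecture, .data$date)
  if (nrow(covariates) != length(units) * length(dates)) {
    stop("covariate table is not rectangular over units x dates",
         call. = FALSE)
  }

  dummies <- purrr::map(units, function(u) {
    dplyr::mutate(build_emergency_dummies(schedule, u, dates),
                  prefecture = u, .before = 1)
  })
  dummies <- dplyr::bind_rows(dummies)

  panel <- dplyr::inner_join(dummies, covariates,
                             by = c("prefecture", "date"))
  if (nrow(panel) != length(units) * length(dates)) {
    stop("date misalignment between dummies and covariates", call. = FALSE)
  }

  # regression-ready covariates (generator variant: no missing edges)
  panel <- dplyr::mutate(panel,
    precipitation_adj = log_mean_adjust(.data$precipitation,
                                        mean(.data$precipitation)),
    windspeed_adj = log_mean_adjust(.data$windspeed, mean(.data$windspeed)),
    temperature_z = zscore(.data$temperature))
  panel <- dplyr::mutate(panel,
    positive_per1000 = per_1000(.data$positives, .data$population[1]),
    positive_per1000_l1 = {
      ma <- zoo::rollapplyr(.data$positive_per1000, 7, mean, partial = TRUE)
      dplyr::lag(ma, 1, default = ma[1])
    },
    .by = "prefecture")

  categories <- names(config$beta)
  X_names <- lapply(config$beta, names)
  for (ci in seq_along(categories)) {
    cat_name <- categories[ci]
    b <- config$beta[[cat_name]]
    miss <- setdiff(names(b), names(panel))
    if (length(miss) > 0) {
      stop("true beta refers to absent columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    Xb <- as.matrix(panel[names(b)]) %*% b
    eps <- if (is.null(disturbances)) {
      simulate_disturbances(config, W, stream = ci)
    } else if (is.list(disturbances)) {
      disturbances[[cat_name]]
    } else {
      disturbances
    }
    # panel is unit-major; eps is units x dates
    panel[[cat_name]] <- as.vector(Xb) + as.vector(t(eps))
  }
  panel <- dplyr::relocate(panel, dplyr::all_of(categories),
                           .after = "date")
  class(panel) <- c("mobility_panel", class(panel))
  panel
}
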