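#' Trailing moving average
#'
#' The value at day `t` is the mean of the `window` values ending at `t`;
#' the leading `window - 1` entries are missing. A 7-day trailing window
#' removes the day-of-week trend of daily mobility and case series.
#'
#' @param x Numeric vector, one value per consecutive day.
#' @param window Window length (`>= 1`); `window = 1` is the identity.
#' @return Numeric vector of the same length, `NA` for the first
#'   `window - 1` entries.
#' @examples
#' trailing_moving_average(1:7)  # last entry 4
#' @export
trailing_moving_average <- function(x, window = 7) {
  stopifnot(window >= 1)
  zoo::rollapplyr(as.numeric(x), window, mean, fill = NA)
}

#' Lag a daily series
#'
#' @param x Numeric vector, one value per consecutive day.
#' @param k Lag length (`>= 0`); leading `k` entries become `NA`.
#' @return Lagged vector of the same length.
#' @export
lag_series <- function(x, k = 1) {
  stopifnot(k >= 0)
  dplyr::lag(x, k)
}

#' Counts per 1,000 people
#'
#' @param x Count series.
#' @param population Positive population size.
#' @return `x * 1000 / population`.
#' @export
per_1000 <- function(x, population) {
  if (population <= 0) stop("`population` must be positive", call. = FALSE)
  x * 1000 / population
}

#' Log conversion adjusted by the pooled mean
#'
#' Damps disaster-driven anomalies of precipitation and wind speed:
#' `log((x + offset) / (pooled_mean + offset))`. The default `offset = 1`
#' keeps zero-rain and zero-wind days finite; a value equal to the pooled
#' mean maps to 0. `offset = 0` gives the plain log-ratio.
#'
#' @param x Nonnegative series.
#' @param pooled_mean Mean over all units and dates (nonnegative; positive
#'   when `offset = 0`).
#' @param offset Additive offset before the log (default 1).
#' @return Transformed series.
#' @export
log_mean_adjust <- function(x, pooled_mean, offset = 1) {
  if (any(x < 0, na.rm = TRUE)) stop("`x` must be nonnegative", call. = FALSE)
  if (pooled_mean + offset <= 0) {
    stop("`pooled_mean + offset` must be positive", call. = FALSE)
  }
  log((x + offset) / (pooled_mean + offset))
}

#' Normalize a series to zero mean and unit standard deviation
#'
#' @param x Numeric series.
#' @param center,scale Pooled mean and standard deviation; computed from
#'   `x` when omitted. `scale` must be positive (a constant series has no
#'   z-score).
#' @return `(x - center) / scale`.
#' @export
zscore <- function(x, center = mean(x, na.rm = TRUE),
                   scale = stats::sd(x, na.rm = TRUE)) {
  if (!is.finite(scale) || scale <= 0) {
    stop("standard deviation must be positive; cannot z-score a constant ",
         "series", call. = FALSE)
  }
  (x - center) / scale
}

#' Declaration dummies for one prefecture
#'
#' `emergency` is 1 on every date the prefecture is under a declared state
#' of emergency — both the declaration date and the lift date count as
#' under declaration (inclusive bounds) — and `emergency_kth` marks the
#' span of the k-th episode only, so `emergency` equals the sum of the
#' per-number dummies at every date.
#'
#' @param schedule An `"emergency_schedule"` tibble.
#' @param unit Prefecture name; a unit absent from the schedule gets all
#'   zeros.
#' @param dates Daily `Date` vector.
#' @param inclusive_end Count the lift date as under declaration (default
#'   `TRUE`, the reading of the printed declared/lifted dates).
#' @return A tibble: `date`, `emergency`, `emergency_1st` ...
#'   `emergency_4th` (and beyond if the schedule has more rounds).
#' @export
build_emergency_dummies <- function(schedule, unit, dates,
                                    inclusive_end = TRUE) {
  stopifnot(inherits(schedule, "emergency_schedule"))
  eps <- dplyr::filter(schedule, .data$prefecture_en == unit)
  k_max <- max(4L, schedule$times)
  out <- tibble::tibble(date = dates)
  labels <- paste0("emergency_",
                   c("1st", "2nd", "3rd", "4th",
                     if (k_max > 4) paste0(5:k_max, "th")))[seq_len(k_max)]
  for (k in seq_len(k_max)) {
    ep <- eps[eps$times == k, ]
    flag <- rep(0L, length(dates))
    if (nrow(ep) == 1) {
      last <- if (inclusive_end) ep$emergency_end else ep$emergency_end - 1
      flag <- as.integer(dates >= ep$emergency_start & dates <= last)
    }
    out[[labels[k]]] <- flag
  }
  per_number <- as.matrix(out[labels])
  if (any(rowSums(per_number) > 1)) {
    stop("overlapping episodes for ", unit, call. = FALSE)
  }
  dplyr::mutate(out, emergency = as.integer(rowSums(per_number)),
                .after = "date")
}

#' Turn raw daily series into regression-ready variables
#'
#' Applies the variable-construction recipe to a raw panel (one row per
#' prefecture-date with mobility categories, `precipitation`,
#' `temperature`, `windspeed`, `positives`, `population`): 7-day trailing
#' moving average of each mobility category; precipitation and wind speed
#' log-converted against their all-prefecture means; temperature
#' normalized; positives scaled per 1,000 people, smoothed over 7 days and
#' lagged one day; declaration dummies joined from the schedule. All
#' transforms operate within each prefecture and never leak across units.
#'
#' @param data Raw panel tibble; must contain `prefecture`, `date`, the
#'   columns named in `mobility_cols`, and the covariate columns above.
#' @param schedule An `"emergency_schedule"` for the dummies (skipped when
#'   `NULL`).
#' @param mobility_cols Mobility category columns to smooth.
#' @param trim `"mark"` leaves the moving-average/lag edges as `NA`;
#'   `"drop"` removes rows with any missing regression variable (listwise).
#' @return A tibble with the regression-ready columns appended
#'   (`<cat>` smoothed in place, `precipitation_adj`, `windspeed_adj`,
#'   `temperature_z`, `positive_per1000_l1`, dummies).
#' @export
prepare_panel <- function(data, schedule = NULL,
                          mobility_cols = c("retail", "grocery",
                                            "workplaces", "residential"),
                          trim = c("mark", "drop")) {
  trim <- match.arg(trim)
  stopifnot(all(c("prefecture", "date") %in% names(data)))
  data <- dplyr::arrange(data, .data$prefecture, .data$date)
  gaps <- dplyr::summarise(data,
    daily = all(diff(as.integer(.data$date)) == 1), .by = "prefecture")
  if (!all(gaps$daily)) {
    stop("series must be daily without gaps: ",
         paste(gaps$prefecture[!gaps$daily], collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(data, dplyr::across(
    dplyr::all_of(intersect(mobility_cols, names(data))),
    trailing_moving_average), .by = "prefecture")
  if (all(c("precipitation", "windspeed") %in% names(out))) {
    out <- dplyr::mutate(out,
      precipitation_adj = log_mean_adjust(.data$precipitation,
                                          mean(.data$precipitation)),
      windspeed_adj = log_mean_adjust(.data$windspeed,
                                      mean(.data$windspeed)))
  }
  if ("temperature" %in% names(out)) {
    out <- dplyr::mutate(out, temperature_z = zscore(.data$temperature))
  }
  if (all(c("positives", "population") %in% names(out))) {
    out <- dplyr::mutate(out,
      positive_per1000_l1 = lag_series(
        trailing_moving_average(per_1000(.data$positives,
                                         .data$population[1])), 1),
      .by = "prefecture")
  }
  if (!is.null(schedule)) {
    units <- unique(out$prefecture)
    dts <- sort(unique(out$date))
    dummies <- dplyr::bind_rows(purrr::map(units, function(u) {
      dplyr::mutate(build_emergency_dummies(schedule, u, dts),
                    prefecture = u, .before = 1)
    }))
    out <- dplyr::left_join(out, dummies, by = c("prefecture", "date"))
  }
  if (trim == "drop") out <- stats::na.omit(out)
  tibble::as_tibble(out)
}
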