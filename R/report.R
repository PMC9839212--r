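#' Fit the declaration models for every mobility category
#'
#' Runs the going-out regressions for the four mobility categories with
#' the declaration dummies as target variables, either pooled (a single
#' `emergency` dummy that ignores the declaration number) or split by
#' number (`emergency_1st` ... `emergency_4th`), using the within
#' fixed-effects estimator or the spatial-error AR(1) ML estimator. The
#' result mirrors the printed regression-table layout: one row per
#' (dependent, explanatory) pair with estimate, cluster-robust (FE) or
#' ML (spatial) standard error and two-sided normal p-value, plus `rho`
#' and `psi` rows for the spatial model.
#'
#' @param panel A regression-ready panel (e.g. from [assemble_panel()]).
#' @param mode `"pooled"` or `"by_number"`.
#' @param estimator `"fe"` or `"spatial"`.
#' @param outcomes Outcome columns to fit.
#' @param covariates Covariate columns included alongside the dummies;
#'   set to `character()` for the no-covariate sensitivity variant.
#' @param W Spatial weight matrix (spatial estimator only); defaults to a
#'   ring over the panel's units.
#' @param unit,time Unit and time column names.
#' @return A tibble: `dependent`, `explanatory`, `estimate`, `std.error`,
#'   `p.value`, `covariates` (`"Yes"`/`"No"`).
#' @export
run_declaration_models <- function(panel,
                                   mode = c("pooled", "by_number"),
                                   estimator = c("fe", "spatial"),
                                   outcomes = c("retail", "grocery",
                                                "workplaces", "residential"),
                                   covariates = c("precipitation_adj",
                                                  "temperature_z",
                                                  "windspeed_adj",
                                                  "positive_per1000_l1",
                                                  "national_holiday",
                                                  "unofficial_holiday"),
                                   W = NULL,
                                   unit = "prefecture", time = "date") {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  targets <- if (mode == "pooled") "emergency" else {
    grep("^emergency_", names(panel), value = TRUE)
  }
  if (length(targets) == 0 || !all(targets %in% names(panel))) {
    stop("declaration dummies not found in the panel", call. = FALSE)
  }
  miss_out <- setdiff(outcomes, names(panel))
  if (length(miss_out) > 0) {
    stop("missing outcome column(s): ", paste(miss_out, collapse = ", "),
         call. = FALSE)
  }
  covariates <- intersect(covariates, names(panel))
  regressors <- c(targets, covariates)
  if (estimator == "spatial" && is.null(W)) {
    W <- make_weight_matrix("ring", length(unique(panel[[unit]])))
  }
  cov_flag <- if (length(covariates) > 0) "Yes" else "No"
  rows <- purrr::map(outcomes, function(out) {
    fit <- if (estimator == "fe") {
      fit_within_fe(panel, out, regressors, unit = unit)
    } else {
      fit_spatial_ar(panel, out, regressors, W, unit = unit, time = time)
    }
    td <- tidy(fit)
    td <- td[td$term %in% c(targets, "rho", "psi"), ]
    tibble::tibble(dependent = out, explanatory = td$term,
                   estimate = td$estimate, std.error = td$std.error,
                   p.value = td$p.value, covariates = cov_flag)
  })
  dplyr::bind_rows(rows)
}

#' Plot a declaration-model coefficient table
#'
#' Point-range plot of the estimated declaration effects by mobility
#' category; for by-number tables the habituation pattern (shrinking
#' magnitudes across declarations) is visible directly.
#'
#' @param results Output of [run_declaration_models()].
#' @return A ggplot object.
#' @export
plot_declaration_effects <- function(results) {
  df <- dplyr::filter(results, !.data$explanatory %in% c("rho", "psi"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$explanatory,
                                   y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$std.error,
      ymax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::facet_wrap(~dependent, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "estimated effect on mobility (fraction)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
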