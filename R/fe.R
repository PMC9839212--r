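#' Within (fixed-effects) panel regression with cluster-robust errors
#'
#' Estimates the one-way error-component model
#' `y_it = x'_it beta + alpha_i + e_it` by the within estimator: all
#' variables are demeaned within each unit, absorbing the unit effects
#' `alpha_i`, and the slopes are obtained by least squares on the demeaned
#' data — numerically identical to least squares with a full set of unit
#' dummies. Covariance is the cluster-robust sandwich with clusters at the
#' unit level (see [cluster_robust_vcov()]); p-values use the normal
#' reference distribution, two-sided.
#'
#' @param data Long panel tibble.
#' @param outcome Name of the outcome column.
#' @param regressors Character vector of regressor column names (numeric).
#' @param unit Name of the unit (fixed-effect) column.
#' @param cluster Name of the cluster column; defaults to `unit`.
#' @return An object of class `"fe_fit"`: coefficients, cluster-robust
#'   vcov, `se`, `p`, `nobs`, `n_clusters`, residuals and the within R^2.
#'   Supports [tidy()] and [glance()].
#' @examples
#' df <- tibble::tibble(unit = rep(c("A", "B"), each = 2),
#'                      x = c(0, 1, 0, 1), y = c(0, 1, 1, 2))
#' tidy(fit_within_fe(df, "y", "x", unit = "unit"))
#' @export
fit_within_fe <- function(data, outcome, regressors, unit = "prefecture",
                          cluster = unit) {
  stopifnot(outcome %in% names(data), unit %in% names(data),
            cluster %in% names(data))
  miss <- setdiff(regressors, names(data))
  if (length(miss) > 0) {
    stop("missing regressor columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[c(outcome, regressors, unit, cluster)])
  data <- data[keep, , drop = FALSE]
  g <- as.factor(data[[unit]])
  if (min(table(g)) < 2) {
    stop("every unit needs at least 2 observations for the within transform",
         call. = FALSE)
  }
  y <- as.numeric(data[[outcome]])
  X <- as.matrix(data[regressors])
  storage.mode(X) <- "double"
  y_dm <- y - stats::ave(y, g)
  X_dm <- apply(X, 2, function(col) col - stats::ave(col, g))
  wvar <- apply(X_dm, 2, function(col) sum(col^2))
  if (any(wvar < 1e-12 * nrow(X_dm))) {
    stop("time-invariant regressor(s) absorbed by the unit effects: ",
         paste(regressors[wvar < 1e-12 * nrow(X_dm)], collapse = ", "),
         call. = FALSE)
  }
  qrX <- qr(X_dm)
  if (qrX$rank < ncol(X_dm)) {
    dropped <- regressors[qrX$pivot[(qrX$rank + 1):ncol(X_dm)]]
    stop("rank-deficient design after the within transform; collinear: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y_dm)
  resid <- y_dm - X_dm %*% beta
  V <- cluster_robust_vcov(resid, X_dm, data[[cluster]])
  se <- sqrt(diag(V))
  z <- beta / se
  structure(list(
    coefficients = setNames(as.numeric(beta), regressors),
    vcov = V,
    se = setNames(se, regressors),
    p = setNames(2 * stats::pnorm(-abs(z)), regressors),
    nobs = length(y),
    n_clusters = length(unique(data[[cluster]])),
    n_units = nlevels(g),
    r_squared_within = 1 - sum(resid^2) / sum(y_dm^2),
    residuals = as.numeric(resid),
    outcome = outcome
  ), class = "fe_fit")
}

#' Cluster-robust sandwich covariance
#'
#' `(X'X)^{-1} (sum_g X_g' u_g u_g' X_g) (X'X)^{-1}` scaled by the
#' small-sample factor `G/(G-1) * (N-1)/(N-K)`, allowing arbitrary
#' correlation of the residuals within each cluster. `K` is the column
#' count of `design`; effects absorbed before the regression are not
#' counted.
#'
#' @param residuals Residual vector.
#' @param design Design matrix (`N x K`).
#' @param clusters Cluster id per observation; at least 2 distinct
#'   clusters.
#' @return A `K x K` covariance matrix.
#' @export
cluster_robust_vcov <- function(residuals, design, clusters) {
  design <- as.matrix(design)
  u <- as.numeric(residuals)
  N <- nrow(design)
  K <- ncol(design)
  stopifnot(length(u) == N, length(clusters) == N)
  G <- length(unique(clusters))
  if (G < 2) stop("cluster-robust covariance needs at least 2 clusters",
                  call. = FALSE)
  bread <- solve(crossprod(design))
  scores <- rowsum(design * u, clusters)
  meat <- crossprod(scores)
  adj <- G / (G - 1) * (N - 1) / (N - K)
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(design), colnames(design))
  V
}

#' @export
print.fe_fit <- function(x, ...) {
  cat(sprintf("<fe_fit: %s ~ %d regressors, N = %d, %d clusters>\n",
              x$outcome, length(x$coefficients), x$nobs, x$n_clusters))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_within_fe
#' @param x,object An `"fe_fit"` object.
#' @param ... Unused.
#' @method tidy fe_fit
#' @export
tidy.fe_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients),
                 std.error = as.numeric(x$se),
                 statistic = as.numeric(x$coefficients / x$se),
                 p.value = as.numeric(x$p))
}

#' @rdname fit_within_fe
#' @method glance fe_fit
#' @export
glance.fe_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared_within, nobs = x$nobs,
                 n_clusters = x$n_clusters, n_units = x$n_units)
}
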