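# Small random panels and brute-force estimator oracles.

random_panel <- function(n_units = 10, n_times = 20, seed = 1, K = 3,
                         alpha_sd = 1, e_sd = 1) {
  set.seed(seed)
  units <- sprintf("u%02d", seq_len(n_units))
  dates <- as.Date("2020-01-01") + seq_len(n_times) - 1
  df <- tidyr::expand_grid(prefecture = units, date = dates)
  X <- matrix(rnorm(nrow(df) * K), ncol = K)
  colnames(X) <- paste0("x", seq_len(K))
  beta <- seq_len(K) / 2
  alpha <- rep(rnorm(n_units, sd = alpha_sd), each = n_times)
  df <- dplyr::bind_cols(df, tibble::as_tibble(X))
  df$y <- as.vector(X %*% beta) + alpha + rnorm(nrow(df), sd = e_sd)
  df
}

# Dense triple-product cluster sandwich with the CR1-type factor.
dense_cluster_vcov <- function(residuals, design, clusters) {
  design <- as.matrix(design)
  N <- nrow(design)
  K <- ncol(design)
  G <- length(unique(clusters))
  bread <- solve(t(design) %*% design)
  meat <- matrix(0, K, K)
  for (g in unique(clusters)) {
    i <- clusters == g
    sg <- t(design[i, , drop = FALSE]) %*% residuals[i]
    meat <- meat + sg %*% t(sg)
  }
  G / (G - 1) * (N - 1) / (N - K) * bread %*% meat %*% bread
}

# Dense-matrix log-likelihood of the spatial-error AR(1) random-effects
# model, by explicit nT x nT covariance assembly (tiny instances only).
dense_spatial_loglik <- function(data, outcome, regressors, W, beta, rho,
                                 psi, sigma_alpha2, sigma_e2,
                                 unit = "prefecture", time = "date") {
  units <- sort(unique(data[[unit]]))
  times <- sort(unique(data[[time]]))
  n <- length(units)
  Tn <- length(times)
  data <- data[order(match(data[[time]], times),
                     match(data[[unit]], units)), ]
  r <- as.numeric(data[[outcome]]) -
    as.matrix(data[regressors]) %*% beta
  B <- diag(n) - rho * as.matrix(W)
  V <- solve(t(B) %*% B)
  P <- psi^abs(outer(seq_len(Tn), seq_len(Tn), "-"))
  Sig <- sigma_alpha2 * (matrix(1, Tn, Tn) %x% diag(n)) +
    sigma_e2 / (1 - psi^2) * (P %x% V)
  -0.5 * (n * Tn * log(2 * pi) +
            as.numeric(determinant(Sig, TRUE)$modulus) +
            as.numeric(t(r) %*% solve(Sig, r)))
}

# Regression-ready covariate + dummy column sets used across tests.
panel_covariate_cols <- function() {
  c("precipitation_adj", "temperature_z", "windspeed_adj",
    "positive_per1000_l1", "national_holiday", "unofficial_holiday")
}

panel_dummy_cols <- function() {
  paste0("emergency_", c("1st", "2nd", "3rd", "4th"))
}
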