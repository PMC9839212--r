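test_that("weight matrices have the requested topology", {
  W4 <- make_weight_matrix("ring", 4)
  expect_true(all(rowSums(W4 > 0) == 2))
  expect_true(all(W4[W4 > 0] == 0.5))
  expect_equal(rowSums(W4), rep(1, 4))
  W2 <- make_weight_matrix("ring", 2)
  expect_equal(unname(W2), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  # custom adjacency with an isolate row-normalizes without error
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  Wc <- make_weight_matrix("custom", adjacency = A)
  expect_equal(Wc[3, ], rep(0, 3))
  expect_equal(rowSums(Wc), c(1, 1, 0))
  Wl <- make_weight_matrix("lattice", 9, normalize = FALSE)
  expect_true(isSymmetric(unname(Wl)))
  expect_equal(sum(Wl), 2 * 12)  # 3x3 rook grid has 12 edges
  expect_error(make_weight_matrix("custom", adjacency = diag(2)), "diagonal")
})

test_that("panel config validates its invariants", {
  expect_error(panel_config(seed = NULL), "seed")
  expect_error(panel_config(psi = 1, seed = 1))
  expect_error(panel_config(rho = -1.2, seed = 1))
  cfg <- panel_config(seed = 5)
  expect_equal(length(cfg$dates), 518)
})

test_that("disturbances are reproducible and respect degenerate cases", {
  cfg <- panel_config(n_units = 6, start = "2020-01-01", end = "2020-03-01",
                      seed = 42)
  W <- make_weight_matrix("ring", 6)
  e1 <- simulate_disturbances(cfg, W)
  e2 <- simulate_disturbances(cfg, W)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(6, length(cfg$dates)))
  # all-zero W short-circuits the spatial filter: nu == eta for any rho
  cfg9 <- panel_config(n_units = 6, start = "2020-01-01", end = "2020-03-01",
                       rho = 0.9, psi = cfg$psi, sigma_alpha = cfg$sigma_alpha,
                       sigma_e = cfg$sigma_e, seed = 42)
  expect_equal(simulate_disturbances(cfg9, matrix(0, 6, 6)),
               simulate_disturbances(cfg, matrix(0, 6, 6)))
  # singular spatial filter is refused (unnormalized W, exact singularity)
  cfg_r <- panel_config(n_units = 2, start = "2020-01-01", end = "2020-01-10",
                        rho = 0.5, seed = 1)
  W_sing <- make_weight_matrix("custom", adjacency = matrix(c(0, 2, 2, 0), 2),
                               normalize = FALSE)
  expect_error(simulate_disturbances(cfg_r, W_sing), "singular")
})

test_that("disturbance moments match the error-component theory", {
  # iid case: sample variance near sigma_e^2 at nT = 1e5
  cfg <- panel_config(n_units = 10, start = "2000-01-01",
                      end = as.Date("2000-01-01") + 9999,
                      rho = 0, psi = 0, sigma_alpha = 0, sigma_e = 1,
                      seed = 7)
  eps <- simulate_disturbances(cfg, matrix(0, 10, 10))
  mc_se <- sqrt(2 / (length(eps) - 1))
  expect_lt(abs(stats::var(as.vector(eps)) - 1), 3 * mc_se)
  # AR(1) case: pooled lag-1 autocorrelation of nu near psi
  cfg_ar <- panel_config(n_units = 2, start = "2000-01-01",
                         end = as.Date("2000-01-01") + 9999,
                         rho = 0, psi = 0.8, sigma_alpha = 0, sigma_e = 1,
                         seed = 8)
  nu <- simulate_disturbances(cfg_ar, matrix(0, 2, 2))
  ac <- stats::cor(as.vector(nu[, -1]), as.vector(nu[, -ncol(nu)]))
  expect_lt(abs(ac - 0.8), 0.02)
  # spatial case: ring neighbours positively correlated when rho > 0
  cfg_sp <- panel_config(n_units = 8, start = "2000-01-01",
                         end = as.Date("2000-01-01") + 4999,
                         rho = 0.6, psi = 0, sigma_alpha = 0, sigma_e = 1,
                         seed = 9)
  Wr <- make_weight_matrix("ring", 8)
  nu_sp <- simulate_disturbances(cfg_sp, Wr)
  neigh_cor <- stats::cor(nu_sp[1, ], nu_sp[2, ])
  expect_gt(neigh_cor, 0.2)
  # variance decomposition: Var(eps) = sigma_alpha^2 + Var(nu)
  cfg_full <- panel_config(n_units = 40, start = "2000-01-01",
                           end = as.Date("2000-01-01") + 1999,
                           rho = 0, psi = 0.5, sigma_alpha = 0.5,
                           sigma_e = 1, seed = 10)
  eps_f <- simulate_disturbances(cfg_full, matrix(0, 40, 40))
  v_theory <- 0.5^2 + 1 / (1 - 0.5^2)
  expect_equal(stats::var(as.vector(eps_f)), v_theory, tolerance = 0.1)
})

test_that("covariates are deterministic, nonnegative where they must be", {
  units <- paste0("u", 1:3)
  dates <- seq(as.Date("2020-04-01"), as.Date("2020-06-30"), by = "day")
  c1 <- simulate_covariates(units, dates, seed = 3)
  c2 <- simulate_covariates(units, dates, seed = 3)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 3 * length(dates))
  expect_true(all(c1$precipitation >= 0))
  expect_true(all(c1$windspeed > 0))
  expect_true(all(c1$positives >= 0))
  expect_true(all(c1$population > 0))
  # a known national holiday in the window is flagged
  expect_true(all(c1$national_holiday[c1$date == as.Date("2020-05-04")] == 1))
  expect_true(all(c1$national_holiday[c1$date == as.Date("2020-05-07")] == 0))
})

test_that("assembled panel has the study dimensions and dummy structure", {
  cfg <- panel_config(seed = 1)
  panel <- assemble_panel(cfg)
  expect_equal(nrow(panel), 24346)
  expect_equal(length(unique(panel$prefecture)), 47)
  expect_equal(length(unique(panel$date)), 518)
  # rectangular: every unit-date pair exactly once
  expect_equal(nrow(dplyr::distinct(panel, prefecture, date)), nrow(panel))
  # Tokyo under the first declaration on its start date
  tok <- dplyr::filter(panel, prefecture == "Tokyo",
                       date == as.Date("2020-04-07"))
  expect_equal(tok$emergency, 1L)
  expect_equal(tok$emergency_1st, 1L)
  expect_equal(tok$emergency_2nd, 0L)
  # pooled dummy is the pointwise sum of the per-number dummies
  expect_equal(panel$emergency,
               as.integer(rowSums(panel[panel_dummy_cols()])))
})

test_that("noise-free panel reproduces the linear signal exactly", {
  beta <- list(retail = c(emergency_1st = -0.2, national_holiday = 0.1))
  cfg <- panel_config(n_units = 4, start = "2020-04-01", end = "2020-06-30",
                      beta = beta, sigma_alpha = 0, sigma_e = 0,
                      rho = 0, psi = 0, seed = 2)
  units <- paste0("p", 1:4)
  sched <- make_synthetic_schedule(units, cfg$dates, seed = 2, n_rounds = 1)
  panel <- assemble_panel(cfg, schedule = sched)
  manual <- -0.2 * panel$emergency_1st + 0.1 * panel$national_holiday
  expect_equal(panel$retail, manual, tolerance = 1e-12)
})

test_that("synthetic schedules compress the declaration rounds", {
  units <- sprintf("u%02d", 1:47)
  dates <- seq(as.Date("2020-04-01"), by = "day", length.out = 200)
  sched <- make_synthetic_schedule(units, dates, seed = 5)
  expect_s3_class(sched, "emergency_schedule")
  expect_equal(sum(sched$times == 1), 47)
  expect_gt(sum(sched$times == 4), 0)
  expect_true(all(sched$emergency_start >= min(dates)))
  expect_true(all(sched$emergency_end <= max(dates)))
  # numbering consecutive within each unit
  by_u <- split(sched, sched$prefecture_en)
  expect_true(all(vapply(by_u, function(b) all(b$times == seq_len(nrow(b))),
                         logical(1))))
})
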