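# Synthetic-data generator: covariate design, pair sampler, study presets.

test_that("study presets encode the documented designs", {
  c1 <- sim_config(study = 1, n = 100, theta0 = -5)
  expect_equal(c1$beta_u, c(0, 0.4, -0.4, 0.2, -0.2))
  expect_equal(c1$beta_v, c(0, -0.2, 0.2, -0.4, 0.4))
  expect_equal(c(c1$shape_u, c1$shape_v), c(2, 6))
  expect_equal(c1$theta_mode, "constant")
  c2 <- sim_config(study = 2, n = 100, theta0 = 10)
  expect_equal(c2$beta_v, c(0, 0.2, -0.2, 0.4, -0.4))
  expect_equal(c(c2$shape_u, c2$shape_v), c(2, 2))
  c3 <- sim_config(study = 3, n = 100)
  expect_equal(c3$beta_theta, c(0, 1, -1, 0.5, -0.5))
  expect_equal(c3$theta_mode, "covariate")
  expect_error(sim_config(study = 1, n = 100), "theta0")
  expect_error(sim_config(study = "custom", n = 50), "custom")
})

test_that("covariate design has the stated marginals and latent correlation", {
  X <- gen_covariates(1e5, seed = 2024)
  expect_equal(cor(X[, 1], X[, 2]), 0.4, tolerance = 0.02)
  expect_equal(mean(X[, 3]), 0.5, tolerance = 0.01)
  expect_equal(mean(X[, 4]), 0.5, tolerance = 0.01)
  expect_equal(sd(X[, 1]), 1, tolerance = 0.02)
  # attenuated mixed-pair correlation: 2 * 0.4 / sqrt(2 * pi)
  expect_equal(cor(X[, 1], X[, 3]), 2 * 0.4 / sqrt(2 * pi),
               tolerance = 0.02)
  # attenuated binary-binary correlation: 2 * asin(0.4) / pi
  expect_equal(cor(X[, 3], X[, 4]), 2 * asin(0.4) / pi, tolerance = 0.02)
})

test_that("pair sampler hits the analytic rank correlation at strong dependence", {
  s <- sample_frank_gamma_pair(50000, gamma_marginal(1, 2),
                               gamma_marginal(1, 2), theta = 10, seed = 1)
  expect_equal(emp_tau(s$u, s$v), 0.67, tolerance = 0.03)
})

test_that("simulate_dataset is seed-deterministic with a faithful truth sidecar", {
  cfg <- sim_config(study = 1, n = 400, theta0 = -1)
  d1 <- simulate_dataset(cfg, seed = 10)
  d2 <- simulate_dataset(cfg, seed = 10)
  d3 <- simulate_dataset(cfg, seed = 11)
  expect_identical(d1$u, d2$u)
  expect_identical(d1$x, d2$x)
  expect_false(identical(d1$u, d3$u))
  tr <- attr(d1, "truth")
  expect_equal(tr$lambda_u, exp(drop(cbind(1, d1$x) %*% cfg$beta_u)))
  expect_true(all(tr$theta == -1))
  # conditional dependence at fixed covariates matches the configured tau
  cfg0 <- sim_config(study = "custom", n = 40000, beta_u = 0, beta_v = 0,
                     theta0 = -1, shape_u = 2, shape_v = 6)
  d0 <- simulate_dataset(cfg0, seed = 4)
  expect_equal(emp_tau(d0$u, d0$v), kendall_tau(-1), tolerance = 0.03)
})

test_that("covariate-dependent association spans the documented tau range", {
  cfg <- sim_config(study = 3, n = 5000)
  d <- simulate_dataset(cfg, seed = 21)
  th <- attr(d, "truth")$theta
  taus <- ifelse(abs(th) < 1e-6, 0, kendall_tau(pmax(abs(th), 1e-6)) * sign(th))
  # realised row-wise rank correlations comparable to roughly (-0.48, 0.46)
  expect_lt(min(taus), -0.4)
  expect_gt(max(taus), 0.4)
  expect_true(all(abs(taus) < 0.75))
})

test_that("true conditional medians are exact against Monte Carlo", {
  cfg <- sim_config(study = "custom", n = 10, beta_u = c(0.2, 0.5),
                    beta_v = c(-0.1, -0.3), theta0 = -5,
                    shape_u = 2, shape_v = 6)
  x <- 0.7
  med <- true_conditional_median(x, cfg)
  lam_u <- exp(0.2 + 0.5 * x); lam_v <- exp(-0.1 - 0.3 * x)
  s <- sample_frank_gamma_pair(4e5, gamma_marginal(lam_u, 2),
                               gamma_marginal(lam_v, 6), theta = -5,
                               seed = 33)
  expect_equal(med, median(s$u / s$v), tolerance = 0.01)
  # intercept-only exchangeable configuration has median exactly 1
  cfg1 <- sim_config(study = "custom", n = 10, beta_u = 0, beta_v = 0,
                     theta0 = 2, shape_u = 3, shape_v = 3)
  expect_equal(true_conditional_median(numeric(0), cfg1), 1,
               tolerance = 1e-7)
  # median decreases in a covariate that increases eta_U - eta_V
  meds <- true_conditional_median(matrix(c(-1, 0, 1)), cfg)
  expect_true(all(diff(meds) < 0))
})
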