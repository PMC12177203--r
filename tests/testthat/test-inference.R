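# Posterior approximation, credible intervals and prediction.

fit_once <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) fit <<- fcgam_fit(make_test_data(n = 500, seed = 99))
    fit
  }
})

test_that("posterior draws are reproducible and match the Laplace moments", {
  fit <- fit_once()
  d1 <- sample_posterior(fit, n_draws = 2000, seed = 5)
  d2 <- sample_posterior(fit, n_draws = 2000, seed = 5)
  expect_identical(unclass(d1), unclass(d2))
  big <- sample_posterior(fit, n_draws = 1e5, seed = 6)
  Sigma <- chol2inv(chol(fit$hessian))
  se <- sqrt(diag(Sigma))
  # draw means converge to the estimates (4 MC standard errors each)
  bu <- grep("^beta_u", colnames(big))
  expect_true(all(abs(colMeans(big[, bu]) - fit$par[bu]) <
                    4 * se[bu] / sqrt(1e5)))
  # draw covariance converges to the inverse information (coefficients
  # are untransformed, so compare those blocks directly)
  S_hat <- stats::cov(big[, bu])
  expect_lt(norm(S_hat - Sigma[bu, bu], "F") / norm(Sigma[bu, bu], "F"),
            0.05)
  expect_error(sample_posterior(fit, n_draws = 10), "at least 1000")
})

test_that("credible intervals are percentile-based, including derived quantities", {
  fit <- fit_once()
  dr <- sample_posterior(fit, n_draws = 4000, seed = 8)
  ci <- credible_intervals(dr, level = 0.95)
  M <- unclass(dr)
  # raw coefficient rows equal the empirical percentiles of the draws
  expect_equal(ci$lower[ci$parameter == "beta_u.x1"],
               unname(quantile(M[, "beta_u.x1"], 0.025)))
  # rate-ratio rows are percentiles of the differenced draws, not
  # differences of percentiles
  dif <- M[, "beta_u.x1"] - M[, "beta_v.x1"]
  row <- ci[ci$parameter == "lambda.x1", ]
  expect_equal(row$lower, unname(quantile(dif, 0.025)))
  expect_equal(row$upper, unname(quantile(dif, 0.975)))
  naive_lower <- quantile(M[, "beta_u.x1"], 0.025) -
    quantile(M[, "beta_v.x1"], 0.025)
  expect_false(isTRUE(all.equal(row$lower, unname(naive_lower))))
  # user-supplied transform: implied Kendall tau of the association draws
  ci2 <- credible_intervals(dr, transform = function(m)
    matrix(kendall_tau(m[, "beta_theta.(Intercept)"]),
           dimnames = list(NULL, "tau")))
  expect_true("tau" %in% ci2$parameter)
  expect_true(with(ci2[ci2$parameter == "tau", ], lower < upper))
  expect_error(credible_intervals(dr, level = 1.2), "\\(0, 1\\)")
})

test_that("widening the level widens the intervals towards full coverage", {
  fit <- fit_once()
  dr <- sample_posterior(fit, n_draws = 4000, seed = 9)
  ci95 <- credible_intervals(dr, 0.95)
  ci999 <- credible_intervals(dr, 0.999)
  expect_true(all(ci999$lower <= ci95$lower & ci999$upper >= ci95$upper))
  M <- unclass(dr)
  j <- match("beta_u.x1", ci999$parameter)
  expect_gte(mean(M[, "beta_u.x1"] >= ci999$lower[j] &
                    M[, "beta_u.x1"] <= ci999$upper[j]), 0.999)
})

test_that("predicted ratio law reduces correctly at reference profiles", {
  fit <- fit_once()
  cf <- coef(fit)
  law0 <- predict_ratio_law(fit, rep(0, 4))
  expect_equal(law0$lambda_ratio,
               exp(cf$beta_u[["(Intercept)"]] - cf$beta_v[["(Intercept)"]]))
  expect_equal(law0$shape_u, cf$shape_u)
  # constant-association fits give the same theta at every profile
  law1 <- predict_ratio_law(fit, c(1, -1, 1, 0))
  expect_equal(law0$theta, law1$theta)
  expect_error(predict_ratio_law(fit, c(1, 2)), "length 4")
})

test_that("fast median prediction equals direct quantile inversion", {
  fit <- fit_once()
  X <- gen_covariates(5, seed = 3)
  fast <- predict(fit, X, what = "median")
  slow <- vapply(1:5, function(i)
    ratio_quantile(0.5, predict_ratio_law(fit, X[i, ])), numeric(1))
  expect_equal(fast, slow, tolerance = 1e-6)
  q9 <- predict(fit, X, what = "quantile", q = 0.9)
  expect_true(all(q9 > fast))
  m <- predict(fit, X[1:2, ], what = "mean")
  expect_true(all(is.finite(m) & m > 0))
})
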