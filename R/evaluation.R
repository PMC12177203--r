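# Replication harnesses: credible-interval coverage, RMSE of conditional
# medians on held-out data, out-of-sample predictive log-likelihood, and
# CRPS utilities.  Every experiment is a pure function of
# (configuration, n_reps, seed); replicates whose optimisation fails are
# dropped and counted (attribute "n_failed").

#' Credible-interval coverage experiment
#'
#' For each replicate: simulate a dataset from the configuration, fit the
#' copula ratio regression, draw from the posterior approximation, build
#' percentile intervals, and record whether each slope coefficient's
#' interval contains its true value.  Returns per-coefficient coverage
#' proportions with binomial Monte-Carlo standard errors.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates (at least 50).
#' @param level Interval level (default 0.95).
#' @param n_draws Posterior draws per replicate (default 10000).
#' @param seed Master seed; spawns all per-replicate streams.
#' @return Data frame with columns `parameter`, `truth`, `coverage`, `se`;
#'   attributes `n_used` and `n_failed`.
#' @export
coverage_experiment <- function(config, n_reps, level = 0.95,
                                n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 50L) stop("'n_reps' must be at least 50")
  seeds <- .seed_streams(seed, n_reps, 2L)
  p <- config$p
  pars <- c(paste0("beta_u.x", seq_len(p)), paste0("beta_v.x", seq_len(p)))
  truth <- c(config$beta_u[-1], config$beta_v[-1])
  hits <- matrix(NA, n_reps, length(pars), dimnames = list(NULL, pars))
  failed <- 0L
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      d <- simulate_dataset(config, seed = seeds[i, 1])
      fit <- fcgam_fit(d, theta_mode = config$theta_mode)
      dr <- sample_posterior(fit, n_draws = n_draws, seed = seeds[i, 2])
      ci <- credible_intervals(dr, level = level)
      idx <- match(pars, ci$parameter)
      ci$lower[idx] <= truth & truth <= ci$upper[idx]
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else hits[i, ] <- res
  }
  ok <- stats::complete.cases(hits)
  cov <- colMeans(hits[ok, , drop = FALSE])
  out <- data.frame(parameter = pars, truth = truth, coverage = cov,
                    se = sqrt(cov * (1 - cov) / sum(ok)), row.names = NULL)
  attr(out, "n_used") <- sum(ok)
  attr(out, "n_failed") <- failed
  out
}

#' RMSE of estimated conditional medians on held-out data
#'
#' For each replicate: fit the model on a training set, predict conditional
#' medians for an independently simulated test set of the same size by
#' inverting the fitted ratio CDF, and compute the root-mean-squared error
#' against the true conditional medians (inverted true CDF).
#'
#' @inheritParams coverage_experiment
#' @return List with `mean`, `sd`, the per-replicate `rmse` vector, and
#'   counts `n_used`, `n_failed`.
#' @export
rmse_median_experiment <- function(config, n_reps, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 50L) stop("'n_reps' must be at least 50")
  seeds <- .seed_streams(seed, n_reps, 2L)
  rmse <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      train <- simulate_dataset(config, seed = seeds[i, 1])
      test <- simulate_dataset(config, seed = seeds[i, 2])
      fit <- fcgam_fit(train, theta_mode = config$theta_mode)
      pred <- predict(fit, test$x, what = "median")
      truth <- true_conditional_median(test$x, config)
      sqrt(mean((pred - truth)^2))
    }, error = function(e) NULL)
    if (!is.null(res)) rmse[i] <- res
  }
  ok <- !is.na(rmse)
  list(mean = mean(rmse[ok]), sd = stats::sd(rmse[ok]), rmse = rmse[ok],
       n_used = sum(ok), n_failed = sum(!ok))
}

.PLL_MODELS <- c("FCGAM.modeled", "FCGAM.const", "GB2", "LN", "LN.LSS",
                 "GA", "GA.LSS")

#' Out-of-sample predictive log-likelihood experiment
#'
#' For each replicate: simulate a training and an independent test set from
#' the configuration, fit every requested model on the training set, and
#' evaluate each fit's summed log predictive density of the test ratios.
#' `"FCGAM.modeled"` relates the association parameter to the covariates,
#' `"FCGAM.const"` keeps it constant; the remaining names are the benchmark
#' families of [fit_benchmark()].
#'
#' @inheritParams coverage_experiment
#' @param models Character vector of model labels (see Details).
#' @return Matrix of per-replicate predictive log-likelihoods
#'   (`n_used` rows, one column per model), with attribute `n_failed`.
#'   A replicate is dropped entirely if any requested model fails on it, so
#'   columns remain paired.
#' @export
predictive_ll_experiment <- function(config, models = c("FCGAM.const", "LN", "GA"),
                                     n_reps, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  models <- match.arg(models, .PLL_MODELS, several.ok = TRUE)
  seeds <- .seed_streams(seed, n_reps, 2L)
  out <- matrix(NA_real_, n_reps, length(models),
                dimnames = list(NULL, models))
  for (i in seq_len(n_reps)) {
    row <- tryCatch({
      train <- simulate_dataset(config, seed = seeds[i, 1])
      test <- simulate_dataset(config, seed = seeds[i, 2])
      vapply(models, function(m) {
        fit <- switch(m,
          "FCGAM.modeled" = fcgam_fit(train, theta_mode = "covariate"),
          "FCGAM.const" = fcgam_fit(train, theta_mode = "constant"),
          fit_benchmark(m, train))
        predictive_log_density(fit, test)
      }, numeric(1))
    }, error = function(e) NULL)
    if (!is.null(row)) out[i, ] <- row
  }
  ok <- stats::complete.cases(out)
  res <- out[ok, , drop = FALSE]
  attr(res, "n_failed") <- sum(!ok)
  res
}

#' Sample-based continuous ranked probability score
#'
#' Monte-Carlo estimator of the CRPS of a predictive distribution
#' represented by draws \eqn{X_1, \dots, X_m} against an observation
#' \eqn{r}: \eqn{\mathrm{mean}_i |X_i - r| -
#' \tfrac12 \mathrm{mean}_{i,j} |X_i - X_j|}.  Lower is better under the
#' default orientation; `orientation = "skill"` negates the score for use
#' where larger values are to indicate better fit.
#'
#' @param draws Numeric vector of at least 2 forecast draws.
#' @param observed The observed value.
#' @param orientation `"loss"` (default, lower is better) or `"skill"`.
#' @return Scalar score.
#' @export
crps_from_samples <- function(draws, observed,
                              orientation = c("loss", "skill")) {
  orientation <- match.arg(orientation)
  m <- length(draws)
  if (m < 2L) stop("need at least 2 draws")
  if (length(observed) != 1L) stop("'observed' must be a single value")
  x <- sort(draws)
  # mean over all ordered pairs of |Xi - Xj|, via the sorted-sample identity
  mad2 <- 2 * sum((2 * seq_len(m) - m - 1) * x) / m^2
  s <- mean(abs(x - observed)) - mad2 / 2
  if (orientation == "skill") -s else s
}

#' Quantile (pinball) decomposition of the CRPS
#'
#' Quantile scores \eqn{QS_\alpha = (1\{r \le q_\alpha\} - \alpha)
#' (q_\alpha - r)} of the forecast quantiles \eqn{q_\alpha} at each level of
#' `alphas`, such that \eqn{\mathrm{CRPS} = 2\int_0^1 QS_\alpha\,d\alpha}.
#' The curve localises the fit: levels where the score is large are the
#' quantiles the forecast gets wrong.
#'
#' @inheritParams crps_from_samples
#' @param alphas Grid of levels in \eqn{(0, 1)}.
#' @return Data frame with columns `alpha` and `score` (nonnegative;
#'   negated under `orientation = "skill"`).
#' @export
crps_quantile_decomposition <- function(draws, observed,
                                        alphas = seq(0.01, 0.99, by = 0.01),
                                        orientation = c("loss", "skill")) {
  orientation <- match.arg(orientation)
  if (any(alphas <= 0 | alphas >= 1)) stop("'alphas' must lie in (0, 1)")
  if (length(observed) != 1L) stop("'observed' must be a single value")
  q <- stats::quantile(draws, probs = alphas, names = FALSE, type = 7)
  s <- ((observed <= q) - alphas) * (q - observed)
  if (orientation == "skill") s <- -s
  data.frame(alpha = alphas, score = s)
}
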