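# Posterior-approximation inference and conditional-distribution prediction.

#' Draw from the normal posterior approximation of the fitted coefficients
#'
#' Under flat priors the posterior of the coefficient vector is approximated
#' by \eqn{N(\hat\gamma, J^{-1}(\hat\gamma))}, where \eqn{J} is the observed
#' information (Hessian of the negative log-likelihood) at the optimum.  The
#' approximation is applied on the optimisation scale (unconstrained
#' \eqn{\psi} for the shapes); draws are returned on the natural scale,
#' which leaves percentile intervals unchanged (percentiles are equivariant
#' under the monotone shape transform).
#'
#' @param fit A converged [fcgam_fit()].
#' @param n_draws Number of draws; at least 1000 (default 10000, the sample
#'   size used for all reported intervals).
#' @param seed Seed making the draws reproducible.
#' @return An `n_draws` x k matrix of class `"fcgam_draws"` with named
#'   columns (`beta_u.*`, `beta_v.*`, `beta_theta.*`, `shape_u`, `shape_v`).
#' @export
sample_posterior <- function(fit, n_draws = 10000L, seed = NULL) {
  stopifnot(inherits(fit, "fcgam_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (n_draws < 1000L) stop("'n_draws' must be at least 1000 for interval construction")
  k <- length(fit$par)
  ev <- eigen(fit$hessian, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("observed information is not positive definite (eigenvalues: ",
         paste(signif(ev, 3), collapse = ", "),
         "); the likelihood surface is flat or the fit is degenerate")
  Sigma <- chol2inv(chol(fit$hessian))
  R <- chol(Sigma)
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(n_draws * k), n_draws, k)
  draws <- sweep(Z %*% R, 2, fit$par, "+")
  colnames(draws) <- names(fit$par)
  # natural scale for the shapes
  iu <- match("psi_u", colnames(draws)); iv <- match("psi_v", colnames(draws))
  draws[, iu] <- 1 + exp(draws[, iu])
  draws[, iv] <- 1 + exp(draws[, iv])
  colnames(draws)[c(iu, iv)] <- c("shape_u", "shape_v")
  structure(draws, class = c("fcgam_draws", "matrix", "array"),
            theta_mode = fit$theta_mode, covnames = fit$covnames,
            estimate = fit$par, seed = seed)
}

#' Percentile credible intervals from posterior draws
#'
#' Equal-tailed percentile intervals at level `level` for every raw
#' coefficient and for the derived rate-ratio coefficients
#' \eqn{\beta_{\Lambda j} = \beta_{Uj} - \beta_{Vj}} (including the
#' intercept).  The interval for a derived quantity is the percentile range
#' of the transformed draws (e.g. of the differenced draws), never the
#' difference of interval endpoints.  Empirical percentiles use the default
#' (type 7) quantile convention.
#'
#' @param draws A [sample_posterior()] result.
#' @param level Interval level in \eqn{(0, 1)}; default 0.95.
#' @param transform Optional function mapping the draw matrix to a vector or
#'   matrix of derived quantities; their percentile intervals are appended.
#' @return A data frame with columns `parameter`, `estimate` (posterior
#'   median of the draws), `lower`, `upper`.
#' @export
credible_intervals <- function(draws, level = 0.95, transform = NULL) {
  stopifnot(inherits(draws, "fcgam_draws"))
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)")
  a <- (1 - level) / 2
  M <- unclass(draws)
  # derived rate-ratio coefficients
  bu <- grep("^beta_u\\.", colnames(M)); bv <- grep("^beta_v\\.", colnames(M))
  L <- M[, bu, drop = FALSE] - M[, bv, drop = FALSE]
  colnames(L) <- sub("^beta_u\\.", "lambda.", colnames(M)[bu])
  M <- cbind(M, L)
  if (!is.null(transform)) {
    Tr <- transform(unclass(draws))
    if (is.null(dim(Tr))) Tr <- matrix(Tr, ncol = 1,
                                       dimnames = list(NULL, "transform"))
    M <- cbind(M, Tr)
  }
  data.frame(
    parameter = colnames(M),
    estimate = apply(M, 2, stats::median),
    lower = apply(M, 2, stats::quantile, probs = a, names = FALSE),
    upper = apply(M, 2, stats::quantile, probs = 1 - a, names = FALSE),
    row.names = NULL)
}

#' Conditional ratio law at a covariate profile
#'
#' Plugs the fitted coefficients into the ratio distribution for a new
#' covariate profile: \eqn{\hat\Lambda = \exp\{\tilde x'(\hat\beta_U -
#' \hat\beta_V)\}}, \eqn{\hat\theta = \tilde x'\hat\beta_\theta} (or the
#' fitted constant), with the fitted shapes.
#'
#' @param fit A [fcgam_fit()], or a coefficient list in the same layout.
#' @param x_new Numeric covariate vector of length \eqn{p} (no intercept
#'   entry), or a named vector matching the fitted covariate names.
#' @param theta_mode Only needed when `fit` is a bare coefficient list.
#' @return A [ratio_law()].
#' @export
predict_ratio_law <- function(fit, x_new,
                              theta_mode = c("constant", "covariate")) {
  if (inherits(fit, "fcgam_fit")) {
    cf <- fit$coefficients; theta_mode <- fit$theta_mode
    covn <- fit$covnames
  } else {
    cf <- fit; theta_mode <- match.arg(theta_mode)
    covn <- names(cf$beta_u)[-1]
  }
  p <- length(cf$beta_u) - 1L
  if (!is.null(names(x_new)) && !is.null(covn) && p > 0L) {
    if (!all(covn %in% names(x_new)))
      stop("'x_new' is missing covariate(s): ",
           paste(setdiff(covn, names(x_new)), collapse = ", "))
    x_new <- x_new[covn]
  }
  if (length(x_new) != p)
    stop("'x_new' must have length ", p, " (one value per covariate)")
  xd <- c(1, as.numeric(x_new))
  lam <- exp(sum(xd * (cf$beta_u - cf$beta_v)))
  th <- if (theta_mode == "covariate") sum(xd * cf$beta_theta) else
    unname(cf$beta_theta[1])
  ratio_law(lam, cf$shape_u, cf$shape_v, th)
}

#' Predict conditional distributional summaries of the ratio
#'
#' Computes, for each row of `newdata`, the conditional median, quantile or
#' mean of the ratio under the fitted model, by inverting (or integrating)
#' the fitted ratio CDF.  With a constant association parameter the exact
#' scale relation \eqn{q(\alpha; \Lambda) = q(\alpha; 1)/\Lambda} reduces
#' the work to a single quantile inversion shared by all rows.
#'
#' @param object A [fcgam_fit()].
#' @param newdata Covariate matrix or data frame with the fitted covariate
#'   columns (one row per profile).
#' @param what `"median"`, `"quantile"` or `"mean"`.
#' @param q Probability level when `what = "quantile"`.
#' @param ... Unused.
#' @return Numeric vector with one prediction per row of `newdata`.
#' @export
predict.fcgam_fit <- function(object, newdata,
                              what = c("median", "quantile", "mean"),
                              q = 0.5, ...) {
  what <- match.arg(what)
  if (what == "median") q <- 0.5
  X <- .resolve_newdata(newdata, object$covnames)
  cf <- object$coefficients
  Xd <- cbind(1, X)
  lam <- exp(drop(Xd %*% (cf$beta_u - cf$beta_v)))
  th <- if (object$theta_mode == "covariate")
    drop(Xd %*% cf$beta_theta) else rep(cf$beta_theta[1], nrow(X))
  if (what %in% c("median", "quantile")) {
    if (object$theta_mode == "constant") {
      base <- ratio_quantile(q, ratio_law(1, cf$shape_u, cf$shape_v, th[1]))
      return(base / lam)
    }
    vapply(seq_len(nrow(X)), function(i)
      ratio_quantile(q, ratio_law(lam[i], cf$shape_u, cf$shape_v, th[i])),
      numeric(1))
  } else {
    vapply(seq_len(nrow(X)), function(i)
      .ratio_mean(ratio_law(lam[i], cf$shape_u, cf$shape_v, th[i])),
      numeric(1))
  }
}

# E[R] by quadrature of r f_R(r); finite for shape_v > 1.
.ratio_mean <- function(law) {
  # mean scales like the quantiles: E[R(Lambda)] = E[R(1)] / Lambda
  base <- ratio_law(1, law$shape_u, law$shape_v, law$theta)
  up <- ratio_quantile(1 - 1e-7, base)
  stats::integrate(function(r) r * ratio_pdf(r, base), 0, up,
                   rel.tol = 1e-7)$value / law$lambda_ratio
}

.resolve_newdata <- function(newdata, covnames) {
  X <- as.matrix(as.data.frame(newdata))
  storage.mode(X) <- "double"
  if (!is.null(colnames(X)) && length(covnames) &&
      all(covnames %in% colnames(X)))
    X <- X[, covnames, drop = FALSE]
  if (ncol(X) != length(covnames))
    stop("'newdata' must provide ", length(covnames), " covariate column(s)")
  if (anyNA(X)) stop("'newdata' contains missing values")
  X
}
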