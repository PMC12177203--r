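# Maximum-likelihood fitting of the Frank-copula gamma ratio regression.
#
# Linear predictors (all with intercept):
#   log lambda_U = x' beta_u,  log lambda_V = x' beta_v,
#   theta        = x' beta_theta          (or a constant intercept).
# The shapes delta_U, delta_V are covariate-free nuisance parameters with
# the constraint delta > 1, handled by the smooth reparameterisation
# delta = 1 + exp(psi) so that quasi-Newton optimisation and the observed
# information stay unconstrained and well-defined.

# ---- parameter bookkeeping ----------------------------------------------

.par_dim <- function(p, theta_mode) {
  2L * (p + 1L) + (if (theta_mode == "covariate") p + 1L else 1L) + 2L
}

.par_unpack <- function(par, p, theta_mode) {
  i <- 0L
  bu <- par[i + seq_len(p + 1L)]; i <- i + p + 1L
  bv <- par[i + seq_len(p + 1L)]; i <- i + p + 1L
  nt <- if (theta_mode == "covariate") p + 1L else 1L
  bt <- par[i + seq_len(nt)]; i <- i + nt
  list(beta_u = bu, beta_v = bv, beta_theta = bt,
       psi_u = par[i + 1L], psi_v = par[i + 2L],
       shape_u = 1 + exp(par[i + 1L]), shape_v = 1 + exp(par[i + 2L]))
}

.par_names <- function(covnames, theta_mode) {
  cn <- c("(Intercept)", covnames)
  tn <- if (theta_mode == "covariate") paste0("beta_theta.", cn) else
    "beta_theta.(Intercept)"
  c(paste0("beta_u.", cn), paste0("beta_v.", cn), tn, "psi_u", "psi_v")
}

# negative log-likelihood on the optimisation scale; sentinel instead of
# NaN/Inf so BFGS line searches can recover from overflow regions.
.fcgam_negll <- function(par, Xd, u, v, theta_mode) {
  p <- ncol(Xd) - 1L
  cf <- .par_unpack(par, p, theta_mode)
  lu <- exp(drop(Xd %*% cf$beta_u))
  lv <- exp(drop(Xd %*% cf$beta_v))
  th <- if (theta_mode == "covariate") drop(Xd %*% cf$beta_theta) else
    rep(cf$beta_theta, length(u))
  # extreme line-search steps can push the rates to Inf; the sentinel
  # covers those, so the NaN warnings carry no information
  ll <- suppressWarnings(
    sum(.joint_log_pdf(u, v, lu, cf$shape_u, lv, cf$shape_v, th)))
  if (!is.finite(ll)) 1e10 else -ll
}

# Gradient of the negative log-likelihood on the optimisation scale.
# The rate and association coefficients have closed-form scores; the two
# shape parameters involve the derivative of the regularised incomplete
# gamma function with respect to its shape, which has no closed form, so
# those two entries use central finite differences.  Near-zero theta rows
# are evaluated at a clamped |theta| = 1e-5 (the copula score is continuous
# through 0 and the clamp error is below the optimiser's tolerance).
.fcgam_negll_grad <- function(par, Xd, u, v, theta_mode) {
  p <- ncol(Xd) - 1L
  cf <- .par_unpack(par, p, theta_mode)
  lu <- exp(drop(Xd %*% cf$beta_u))
  lv <- exp(drop(Xd %*% cf$beta_v))
  th <- if (theta_mode == "covariate") drop(Xd %*% cf$beta_theta) else
    rep(cf$beta_theta, length(u))
  du <- cf$shape_u; dv <- cf$shape_v
  a <- suppressWarnings(stats::pgamma(u, shape = du, rate = lu))
  b <- suppressWarnings(stats::pgamma(v, shape = dv, rate = lv))
  fu <- suppressWarnings(stats::dgamma(u, shape = du, rate = lu))
  fv <- suppressWarnings(stats::dgamma(v, shape = dv, rate = lv))

  tc <- pmax(abs(th), 1e-5) * ifelse(th >= 0, 1, -1)
  E <- expm1(-tc); Ea <- expm1(-tc * a); Eb <- expm1(-tc * b)
  D <- E + Ea * Eb
  ea <- exp(-tc * a); eb <- exp(-tc * b)
  dlc_da <- -tc + 2 * tc * ea * Eb / D
  dlc_db <- -tc + 2 * tc * eb * Ea / D
  Dth <- -exp(-tc) - a * ea * Eb - b * eb * Ea
  dlc_dth <- 1 / tc - exp(-tc) / E - (a + b) - 2 * Dth / D

  su_b <- dlc_da * u * fu + du - lu * u     # d ll / d eta_U per row
  sv_b <- dlc_db * v * fv + dv - lv * v
  g_bu <- -drop(crossprod(Xd, su_b))
  g_bv <- -drop(crossprod(Xd, sv_b))
  g_bt <- if (theta_mode == "covariate") -drop(crossprod(Xd, dlc_dth)) else
    -sum(dlc_dth)
  # shapes: central differences on the psi scale
  k <- length(par)
  g_psi <- numeric(2)
  for (j in 1:2) {
    hj <- 1e-6 * max(1, abs(par[k - 2L + j]))
    ej <- replace(numeric(k), k - 2L + j, hj)
    g_psi[j] <- (.fcgam_negll(par + ej, Xd, u, v, theta_mode) -
                   .fcgam_negll(par - ej, Xd, u, v, theta_mode)) / (2 * hj)
  }
  out <- c(g_bu, g_bv, g_bt, g_psi)
  if (any(!is.finite(out))) rep(0, k) else out
}

#' Log-likelihood of the Frank-copula gamma ratio regression
#'
#' Evaluates the joint log-likelihood
#' \eqn{\sum_i \log f_{U,V}(u_i, v_i \mid x_i)} at a given coefficient set,
#' with covariate-dependent rates \eqn{\lambda_U, \lambda_V} (log link) and
#' association \eqn{\theta} (identity link).
#'
#' @param coef List with elements `beta_u`, `beta_v` (numeric, length
#'   \eqn{p + 1}, intercept first), `beta_theta` (length \eqn{p + 1}, or 1
#'   for a constant association), and `shape_u`, `shape_v` (both \eqn{> 1}).
#' @param data A [paired_dataset()].
#' @param theta_mode `"constant"` or `"covariate"`.
#' @return The log-likelihood (scalar).  Parameter regions that overflow the
#'   density evaluate to a large negative sentinel rather than `NaN`.
#' @export
fcgam_loglik <- function(coef, data, theta_mode = c("constant", "covariate")) {
  stopifnot(inherits(data, "paired_dataset"))
  theta_mode <- match.arg(theta_mode)
  p <- ncol(data$x)
  nt <- if (theta_mode == "covariate") p + 1L else 1L
  if (length(coef$beta_u) != p + 1L || length(coef$beta_v) != p + 1L ||
      length(coef$beta_theta) != nt)
    stop("coefficient dimensions do not match the data/theta_mode")
  if (coef$shape_u <= 1 || coef$shape_v <= 1)
    stop("'shape_u' and 'shape_v' must exceed 1")
  par <- c(coef$beta_u, coef$beta_v, coef$beta_theta,
           log(coef$shape_u - 1), log(coef$shape_v - 1))
  -.fcgam_negll(par, cbind(1, data$x), data$u, data$v, theta_mode)
}

# ---- initialisation ------------------------------------------------------

# Deterministic, cheap starting values: marginal gamma log-link regressions
# for the rate predictors (rate = shape/mean), method-of-moments shapes, and
# the empirical Kendall tau mapped through the copula for theta.
.fcgam_init <- function(data, theta_mode) {
  p <- ncol(data$x)
  mom_shape <- function(z) max(mean(z)^2 / stats::var(z), 1.05)
  fit_marg <- function(z) {
    sh <- mom_shape(z)
    if (p > 0L) {
      g <- stats::glm.fit(cbind(1, data$x), z,
                          family = stats::Gamma(link = "log"))
      b <- g$coefficients
    } else b <- log(mean(z))
    # mean = exp(x'b) and rate = shape/mean => log rate = log(shape) - x'b
    beta <- -b; beta[1] <- log(sh) - b[1]
    list(beta = beta, psi = log(sh - 1))
  }
  mu <- fit_marg(data$u); mv <- fit_marg(data$v)
  tau <- stats::cor(data$u, data$v, method = "kendall")
  tau <- min(max(tau, -0.95), 0.95)
  th0 <- if (abs(tau) < 0.02) sign(tau + (tau == 0)) * 0.05 else
    theta_from_tau(tau, tol = 1e-6)
  th0 <- sign(th0) * max(abs(th0), 0.05)
  bt <- if (theta_mode == "covariate") c(th0, rep(0, p)) else th0
  c(mu$beta, mv$beta, bt, mu$psi, mv$psi)
}

# ---- observed information ------------------------------------------------

# Central finite-difference Hessian of the negative log-likelihood on the
# optimisation scale, step h_j = 1e-4 * max(1, |par_j|), computed as the
# symmetrised Jacobian of the (mostly analytic) gradient.
.fd_hessian <- function(gr, par, ...) {
  k <- length(par)
  h <- 1e-4 * pmax(1, abs(par))
  J <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    J[i, ] <- (gr(par + ei, ...) - gr(par - ei, ...)) / (2 * h[i])
  }
  (J + t(J)) / 2
}

# ---- fitting -------------------------------------------------------------

#' Fit the Frank-copula gamma ratio regression by maximum likelihood
#'
#' Maximises the joint log-likelihood of the paired outcomes over the rate
#' coefficients, association coefficients and shape parameters using the
#' BFGS quasi-Newton algorithm, with the shape constraint
#' \eqn{\delta_U, \delta_V > 1} enforced through the smooth
#' reparameterisation \eqn{\delta = 1 + e^\psi}.  On non-convergence the
#' optimisation is restarted up to `n_restarts` times from jittered starting
#' values.
#'
#' @param data A [paired_dataset()].
#' @param theta_mode `"constant"` for an intercept-only association
#'   parameter, `"covariate"` to relate \eqn{\theta} linearly to the
#'   covariates.
#' @param init Optional starting values as a coefficient list (see
#'   [fcgam_loglik()]); defaults to moment/GLM-based values.
#' @param n_restarts Maximum number of jittered restarts on non-convergence.
#' @param seed Seed for the restart jitter (only used if restarts happen).
#' @param control Passed to [stats::optim()] after the defaults
#'   `maxit = 500`, `reltol = 1e-10`.
#' @return An object of class `"fcgam_fit"`: coefficient list
#'   (`coefficients`, natural scale), `par` and `hessian` (optimisation
#'   scale; the Hessian is the observed information of the negative
#'   log-likelihood), `loglik`, `bic`, `converged`, `n_obs`, `theta_mode`,
#'   `covnames`.
#' @examples
#' cfg <- sim_config(study = 1, n = 300, theta0 = -5)
#' d <- simulate_dataset(cfg, seed = 7)
#' fit <- fcgam_fit(d)
#' coef(fit)$beta_u
#' @export
fcgam_fit <- function(data, theta_mode = c("constant", "covariate"),
                      init = NULL, n_restarts = 3L, seed = NULL,
                      control = list()) {
  stopifnot(inherits(data, "paired_dataset"))
  theta_mode <- match.arg(theta_mode)
  p <- ncol(data$x)
  Xd <- cbind(1, data$x)
  if (qr(Xd)$rank < ncol(Xd))
    stop("degenerate design: covariate columns are collinear")
  k <- .par_dim(p, theta_mode)
  n <- length(data$u)
  if (n < k + 5L)
    stop("too few observations (", n, ") for ", k, " parameters")
  par0 <- if (is.null(init)) .fcgam_init(data, theta_mode) else {
    if (init$shape_u <= 1 || init$shape_v <= 1)
      stop("initial shapes must exceed 1")
    c(init$beta_u, init$beta_v, init$beta_theta,
      log(init$shape_u - 1), log(init$shape_v - 1))
  }
  if (length(par0) != k) stop("'init' has the wrong dimension")
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)

  attempt <- function(p0) {
    stats::optim(p0, .fcgam_negll, gr = .fcgam_negll_grad, method = "BFGS",
                 control = ctl,
                 Xd = Xd, u = data$u, v = data$v, theta_mode = theta_mode)
  }
  opt <- attempt(par0)
  tries <- 0L
  trace <- opt$convergence
  while (opt$convergence != 0L && tries < n_restarts) {
    tries <- tries + 1L
    if (!is.null(seed)) set.seed(seed + tries)
    opt2 <- attempt(par0 + stats::rnorm(k, sd = 0.1))
    trace <- c(trace, opt2$convergence)
    if (opt2$value < opt$value || opt2$convergence == 0L) opt <- opt2
    if (opt$convergence == 0L) break
  }
  if (opt$convergence != 0L)
    stop("optimizer failed to converge (codes: ",
         paste(trace, collapse = ", "), ")")

  H <- .fd_hessian(.fcgam_negll_grad, opt$par, Xd = Xd, u = data$u,
                   v = data$v, theta_mode = theta_mode)
  cf <- .par_unpack(opt$par, p, theta_mode)
  cn <- c("(Intercept)", colnames(data$x))
  names(cf$beta_u) <- names(cf$beta_v) <- cn
  names(cf$beta_theta) <- if (theta_mode == "covariate") cn else "(Intercept)"
  ll <- -opt$value
  structure(list(
    coefficients = cf[c("beta_u", "beta_v", "beta_theta",
                        "shape_u", "shape_v")],
    par = stats::setNames(opt$par, .par_names(colnames(data$x), theta_mode)),
    hessian = H,
    loglik = ll,
    bic = k * log(n) - 2 * ll,
    converged = TRUE,
    n_obs = n,
    n_par = k,
    theta_mode = theta_mode,
    covnames = colnames(data$x)),
    class = "fcgam_fit")
}

#' @export
coef.fcgam_fit <- function(object, ...) object$coefficients

#' @export
logLik.fcgam_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")
}

#' @export
BIC.fcgam_fit <- function(object, ...) object$bic

#' @export
print.fcgam_fit <- function(x, ...) {
  cat("Frank-copula gamma ratio regression (",
      x$theta_mode, " association)\n", sep = "")
  cat(sprintf("  n = %d, log-likelihood = %.3f, BIC = %.3f\n",
              x$n_obs, x$loglik, x$bic))
  cat("  rate-ratio coefficients (beta_u - beta_v):\n")
  print(round(x$coefficients$beta_u - x$coefficients$beta_v, 4))
  th <- x$coefficients$beta_theta
  if (x$theta_mode == "constant")
    cat(sprintf("  theta = %.4f (Kendall tau %.3f)\n", th,
                if (abs(th) < .FRANK_THETA_EPS) 0 else kendall_tau(th)))
  else {
    cat("  association coefficients:\n"); print(round(th, 4))
  }
  cat(sprintf("  shapes: delta_u = %.4f, delta_v = %.4f\n",
              x$coefficients$shape_u, x$coefficients$shape_v))
  invisible(x)
}
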