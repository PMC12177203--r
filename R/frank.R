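# Frank copula kernel: CDF, density, conditional distribution (h-function)
# and the theta <-> Kendall's tau mapping.

# Below this |theta| the copula is numerically indistinguishable from the
# independence copula and all routines switch to the exact independence
# formulas (the expm1 ratios in the Frank formulas lose all precision there).
.FRANK_THETA_EPS <- 1e-6

#' Frank copula distribution function
#'
#' Evaluates \eqn{C_\theta(u, v) = -\theta^{-1}\log\{1 +
#' [e^{-\theta u} - 1][e^{-\theta v} - 1] / [e^{-\theta} - 1]\}},
#' the Frank copula, which supports the full range of positive and negative
#' dependence as \eqn{\theta} ranges over \eqn{(-\infty, 0) \cup (0, \infty)}.
#'
#' @param u,v Numeric vectors with values in \eqn{[0, 1]}; recycled to a
#'   common length.
#' @param theta Association parameter (any real). Values with
#'   \eqn{|\theta| < 10^{-6}} are treated as the independence limit
#'   \eqn{C(u,v) = uv}.
#' @return Numeric vector of copula values in \eqn{[0, 1]}.
#' @seealso [frank_density()], [kendall_tau()]
#' @examples
#' frank_cdf(0.5, 0.5, 1)    # mild positive dependence
#' frank_cdf(0.5, 0.5, 0)    # 0.25, independence
#' @export
frank_cdf <- function(u, v, theta) {
  stopifnot(length(theta) == 1L, is.finite(theta))
  if (any(u < 0 | u > 1, na.rm = TRUE) || any(v < 0 | v > 1, na.rm = TRUE))
    stop("'u' and 'v' must lie in [0, 1]")
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  if (abs(theta) < .FRANK_THETA_EPS) return(u * v)
  -log1p(expm1(-theta * u) * expm1(-theta * v) / expm1(-theta)) / theta
}

#' Frank copula density
#'
#' Density \eqn{c_\theta(u, v) = \partial^2 C_\theta / \partial u \partial v}
#' of the Frank copula, evaluated in log space so that strongly dependent
#' configurations (large \eqn{|\theta|}) do not overflow.
#'
#' @inheritParams frank_cdf
#' @param log If `TRUE`, return the log density.
#' @return Numeric vector of (log) density values.
#' @export
frank_density <- function(u, v, theta, log = FALSE) {
  stopifnot(length(theta) == 1L, is.finite(theta))
  if (any(u < 0 | u > 1, na.rm = TRUE) || any(v < 0 | v > 1, na.rm = TRUE))
    stop("'u' and 'v' must lie in (0, 1)")
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  ld <- .frank_log_density(u, v, theta)
  if (log) ld else exp(ld)
}

# log c_theta(u, v), vectorised over u, v and theta (recycled).
# c = -theta e^{-theta(u+v)} E / D^2 with E = expm1(-theta),
# D = E + expm1(-theta u) expm1(-theta v); -theta E > 0 and D^2 > 0 for all
# theta != 0, so the log is taken of |theta E| and |D|.
.frank_log_density <- function(u, v, theta) {
  n <- max(length(u), length(v), length(theta))
  u <- rep_len(u, n); v <- rep_len(v, n); theta <- rep_len(theta, n)
  # strongly positive theta: expm1(-theta) saturates at -1 and the
  # denominator cancels catastrophically; the 90-degree rotation identity
  # c_theta(u, v) = c_{-theta}(u, 1 - v) maps those rows to the stable
  # negative branch
  flip <- theta > 35
  if (any(flip)) {
    v[flip] <- 1 - v[flip]
    theta[flip] <- -theta[flip]
  }
  out <- numeric(n)
  ind <- abs(theta) < .FRANK_THETA_EPS
  if (any(!ind)) {
    th <- theta[!ind]
    E <- expm1(-th)
    D <- E + expm1(-th * u[!ind]) * expm1(-th * v[!ind])
    out[!ind] <- log(abs(th) * abs(E)) - th * (u[!ind] + v[!ind]) -
      2 * log(abs(D))
  }
  out
}

# Conditional distribution ("h-function") of the second coordinate given the
# first: h(v | u) = P(V <= v | U = u) = e^{-theta u} expm1(-theta v) /
# [expm1(-theta) + expm1(-theta u) expm1(-theta v)].  Vectorised; theta may
# be a vector (covariate-dependent association).
.frank_hfun <- function(v, u, theta) {
  n <- max(length(u), length(v), length(theta))
  u <- rep_len(u, n); v <- rep_len(v, n); theta <- rep_len(theta, n)
  out <- v
  dep <- abs(theta) >= .FRANK_THETA_EPS
  if (any(dep)) {
    th <- theta[dep]
    out[dep] <- exp(-th * u[dep]) * expm1(-th * v[dep]) /
      (expm1(-th) + expm1(-th * u[dep]) * expm1(-th * v[dep]))
  }
  out
}

# Inverse of .frank_hfun in its first argument: given u and a probability t,
# the v with h(v | u) = t.  Closed form; used by the pair sampler.
.frank_hinv <- function(t, u, theta) {
  n <- max(length(u), length(t), length(theta))
  u <- rep_len(u, n); t <- rep_len(t, n); theta <- rep_len(theta, n)
  out <- t
  dep <- abs(theta) >= .FRANK_THETA_EPS
  if (any(dep)) {
    th <- theta[dep]
    Ev <- t[dep] * expm1(-th) /
      (exp(-th * u[dep]) - t[dep] * expm1(-th * u[dep]))
    out[dep] <- -log1p(Ev) / th
  }
  out
}

#' Kendall's tau of the Frank copula
#'
#' Computes the rank correlation implied by the Frank association parameter,
#' \deqn{\tau(\theta) = 1 + \frac{4}{\theta}\left(\frac{1}{\theta}
#'   \int_0^\theta \frac{t}{e^t - 1}\,dt - 1\right),}
#' a strictly increasing, antisymmetric map from
#' \eqn{\theta \in R \setminus \{0\}} onto \eqn{(-1, 1)}.  The Debye-type
#' integral is evaluated by adaptive quadrature with the integrand patched to
#' its limit 1 at \eqn{t = 0}.
#'
#' @param theta Numeric vector of nonzero association parameters.
#' @return Numeric vector of rank correlations in \eqn{(-1, 1)}.
#' @examples
#' kendall_tau(c(1, 5, 10))    # 0.11, 0.46, 0.67 (2 d.p.)
#' kendall_tau(-5)             # -0.46
#' @export
kendall_tau <- function(theta) {
  if (any(theta == 0)) stop("'theta' must be nonzero; tau(0) is the independence limit 0")
  vapply(theta, function(th) {
    f <- function(t) ifelse(t == 0, 1, t / expm1(t))
    I <- stats::integrate(f, 0, th, rel.tol = 1e-12, abs.tol = 0)$value
    1 + (4 / th) * (I / th - 1)
  }, numeric(1))
}

#' Invert the Kendall's tau mapping of the Frank copula
#'
#' Finds the \eqn{\theta} whose Frank copula has rank correlation `tau`,
#' by root finding on [kendall_tau()] with a geometrically expanded bracket.
#'
#' @param tau Numeric vector of rank correlations with \eqn{0 < |\tau| < 1}.
#' @param tol Absolute tolerance on the fitted tau.
#' @return Numeric vector of association parameters.
#' @export
theta_from_tau <- function(tau, tol = 1e-10) {
  if (any(tau == 0)) stop("tau = 0 corresponds to the independence limit theta -> 0")
  if (any(abs(tau) >= 1)) stop("'tau' must satisfy |tau| < 1")
  vapply(tau, function(tt) {
    sgn <- sign(tt); at <- abs(tt)
    hi <- 1
    while (kendall_tau(hi) < at) hi <- hi * 2
    r <- stats::uniroot(function(th) kendall_tau(th) - at,
                        lower = .FRANK_THETA_EPS * 2, upper = hi,
                        tol = tol)
    sgn * r$root
  }, numeric(1))
}
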