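# Frank copula kernel: CDF, density, conditional inversion and the
# theta <-> Kendall's tau mapping.

test_that("Kendall's tau mapping reproduces reference values and the small-theta limit", {
  # rank correlations implied by commonly used association strengths
  expect_equal(round(kendall_tau(1), 2), 0.11)
  expect_equal(round(kendall_tau(-5), 2), -0.46)
  expect_equal(round(kendall_tau(10), 2), 0.67)
  expect_equal(round(kendall_tau(5), 2), 0.46)
  # linearisation tau(theta) ~ theta/9 near 0 (high-precision quadrature)
  expect_equal(kendall_tau(0.01), 0.01 / 9, tolerance = 1e-3)
})

test_that("Kendall's tau is strictly increasing, antisymmetric and bounded", {
  grid <- c(-30, -10, -5, -2, -0.5, -0.1, 0.1, 0.5, 2, 5, 10, 30)
  tau <- kendall_tau(grid)
  expect_true(all(diff(tau) > 0))
  expect_true(all(abs(tau) < 1))
  expect_equal(kendall_tau(-grid), -tau, tolerance = 1e-10)
  expect_error(kendall_tau(0), "nonzero")
})

test_that("theta_from_tau inverts the tau mapping", {
  expect_equal(kendall_tau(theta_from_tau(0.3)), 0.3, tolerance = 1e-8)
  expect_equal(kendall_tau(theta_from_tau(-0.67)), -0.67, tolerance = 1e-8)
  # printed tau = 0.67 corresponds to theta = 10 at printed rounding
  expect_equal(theta_from_tau(kendall_tau(10)), 10, tolerance = 1e-6)
  # antisymmetry of the inverse
  expect_equal(theta_from_tau(-0.3), -theta_from_tau(0.3), tolerance = 1e-8)
  expect_error(theta_from_tau(0), "independence")
  expect_error(theta_from_tau(1), "< 1")
})

test_that("frank_cdf has uniform margins, grounding, and known central value", {
  for (th in c(-7, 1, 12)) {
    u <- c(0.1, 0.35, 0.8)
    expect_equal(frank_cdf(u, 1, th), u, tolerance = 1e-12)
    expect_equal(frank_cdf(1, u, th), u, tolerance = 1e-12)
    expect_equal(frank_cdf(u, 0, th), rep(0, 3), tolerance = 1e-12)
  }
  # direct high-precision evaluation of the closed form at (0.5, 0.5, 1)
  expect_equal(frank_cdf(0.5, 0.5, 1), 0.2809298, tolerance = 1e-6)
  expect_equal(frank_cdf(0.5, 0.5, 1e-9), 0.25)   # independence guard
  expect_error(frank_cdf(1.2, 0.5, 1), "\\[0, 1\\]")
})

test_that("frank_density matches finite differences of frank_cdf and normalises", {
  for (th in c(-10, 1, 10)) {
    g <- seq(0.15, 0.85, by = 0.1)
    h <- 1e-4
    for (u in g) for (v in g) {
      fd <- (frank_cdf(u + h, v + h, th) - frank_cdf(u + h, v - h, th) -
               frank_cdf(u - h, v + h, th) + frank_cdf(u - h, v - h, th)) /
        (4 * h^2)
      expect_equal(frank_density(u, v, th), fd, tolerance = 1e-5)
    }
    # 2-d product quadrature of the copula density
    gl <- pracma::gaussLegendre(80, 0, 1)
    cmat <- outer(gl$x, gl$x, function(a, b) frank_density(a, b, th))
    expect_equal(drop(gl$w %*% cmat %*% gl$w), 1, tolerance = 1e-6)
  }
  expect_equal(frank_density(c(0.2, 0.9), c(0.5, 0.1), 1e-9), c(1, 1))
})

test_that("log-space density evaluation survives strong dependence", {
  expect_true(all(is.finite(
    frank_density(c(0.001, 0.999), c(0.001, 0.999), 300, log = TRUE))))
  expect_true(all(is.finite(
    frank_density(c(0.001, 0.999), c(0.999, 0.001), -300, log = TRUE))))
})

test_that("conditional h-function and its inverse are consistent", {
  set.seed(11)
  for (th in c(-8, -1, 2, 15)) {
    w <- runif(20); t <- runif(20)
    s <- fcgam:::.frank_hinv(t, w, th)
    expect_true(all(s > 0 & s < 1))
    expect_equal(fcgam:::.frank_hfun(s, w, th), t, tolerance = 1e-10)
  }
})
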