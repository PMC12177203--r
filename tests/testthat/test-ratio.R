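# Distribution of the ratio of two Frank-coupled gamma components.

test_that("ratio_pdf normalises and both integral forms agree", {
  law <- ratio_law(1, 2, 6, theta = -5)
  expect_equal(integrate(function(r) ratio_pdf(r, law), 0, Inf,
                         rel.tol = 1e-6)$value, 1, tolerance = 1e-4)
  r <- exp(seq(log(0.02), log(20), length.out = 50))
  for (law in list(ratio_law(1, 2, 6, -5), ratio_law(0.7, 3, 2, 8))) {
    prod <- ratio_pdf(r, law)
    ref <- ratio_pdf(r, law, method = "reference", rate_v = 2.3)
    expect_equal(prod, ref, tolerance = 1e-6)
  }
  expect_error(ratio_pdf(-1, law), "positive")
})

test_that("independence limit of the ratio law is the closed-form GB2", {
  r <- exp(seq(log(0.05), log(10), length.out = 50))
  law0 <- ratio_law(1.3, 2, 6, theta = 0)
  expect_equal(ratio_pdf(r, law0), gb2_pdf(r, 1.3, 2, 6), tolerance = 1e-6)
  expect_equal(ratio_cdf(c(0.5, 1, 3), law0),
               pf(c(0.5, 1, 3) * 1.3 * 6 / 2, 4, 12), tolerance = 1e-8)
})

test_that("ratio_cdf is a proper CDF consistent with ratio_pdf", {
  law <- ratio_law(1, 2, 6, theta = -5)
  r <- c(0.05, 0.2, 0.5, 1, 2, 5)
  Fr <- ratio_cdf(r, law)
  expect_true(all(diff(Fr) > 0))
  expect_true(all(Fr >= 0 & Fr <= 1))
  expect_lt(ratio_cdf(1e-4, law), 1e-5)
  expect_gt(ratio_cdf(1e4, law), 1 - 1e-5)
  h <- 1e-4
  fd <- (ratio_cdf(r + h, law) - ratio_cdf(r - h, law)) / (2 * h)
  expect_equal(fd, ratio_pdf(r, law), tolerance = 1e-4)
})

test_that("simulated ratios match the analytic CDF (Kolmogorov-Smirnov)", {
  n <- 20000
  for (th in c(-5, 1, 10)) {
    mu <- gamma_marginal(1.4, 2); mv <- gamma_marginal(0.7, 6)
    s <- sample_frank_gamma_pair(n, mu, mv, theta = th, seed = 5 + th)
    law <- ratio_law(1.4 / 0.7, 2, 6, theta = th)
    grid <- quantile(s$u / s$v, probs = seq(0.02, 0.98, by = 0.02))
    Fhat <- ecdf(s$u / s$v)(grid)
    ks <- max(abs(Fhat - ratio_cdf(as.numeric(grid), law)))
    expect_lt(ks, 3 / sqrt(n))
  }
})

test_that("exchangeable case has median exactly 1 and quantiles round-trip", {
  for (th in c(-6, 0.5, 9)) {
    expect_equal(ratio_cdf(1, ratio_law(1, 2.5, 2.5, th)), 0.5,
                 tolerance = 1e-8)
  }
  law <- ratio_law(1, 2, 6, theta = -5)
  for (q in c(0.1, 0.5, 0.9)) {
    expect_equal(ratio_cdf(ratio_quantile(q, law), law), q,
                 tolerance = 1e-6)
  }
  expect_error(ratio_quantile(1.2, law), "\\(0, 1\\)")
})

test_that("conditional median decreases monotonically in the rate ratio", {
  lams <- c(0.1, 0.25, 0.5, 1, 2, 4)
  med <- vapply(lams, function(L)
    ratio_quantile(0.5, ratio_law(L, 2, 3, theta = 1)), numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("median is (approximately) invariant to the association strength", {
  # observed empirically: equal medians across theta in the illustrative
  # settings; asserted with a loose tolerance since no formal proof exists
  for (sh in list(c(2, 3), c(3, 2), c(2, 2))) {
    meds <- vapply(c(-10, 1, 10), function(th)
      ratio_quantile(0.5, ratio_law(1.5, sh[1], sh[2], th)), numeric(1))
    expect_lt(diff(range(meds)) / mean(meds), 0.02)
  }
})

test_that("mode of the ratio density is nondecreasing in theta", {
  settings <- expand.grid(lam = c(1, 2, 0.5), sh_u = c(2, 3), sh_v = c(2, 3))
  for (i in seq_len(nrow(settings))) {
    s <- settings[i, ]
    modes <- vapply(c(-10, 1, 10), function(th) {
      law <- ratio_law(s$lam, s$sh_u, s$sh_v, th)
      stats::optimize(function(r) ratio_pdf(r, law),
                      interval = c(1e-3, 10 / s$lam), maximum = TRUE)$maximum
    }, numeric(1))
    expect_true(all(diff(modes) > -1e-4))
  }
})

test_that("GB2 density normalises, matches simulation, peaks at the analytic mode", {
  expect_equal(integrate(function(r) gb2_pdf(r, 1.7, 2.5, 4), 0, Inf,
                         rel.tol = 1e-12)$value, 1, tolerance = 1e-10)
  set.seed(31)
  rr <- rgamma(2e5, 2.5, rate = 1.7) / rgamma(2e5, 4, rate = 1)
  # closed-form CDF via the scaled F representation
  expect_gt(suppressWarnings(
    ks.test(rr, function(q) pf(q * 1.7 * 4 / 2.5, 5, 8))$p.value), 0.01)
  mode_hat <- stats::optimize(function(r) gb2_pdf(r, 1.7, 2.5, 4),
                              c(1e-3, 5), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(mode_hat, (2.5 - 1) / (1.7 * (4 + 1)), tolerance = 1e-5)
  expect_error(gb2_pdf(1, -1, 2, 2), "positive")
})

test_that("ratio_law rejects inadmissible parameters", {
  expect_error(ratio_law(0, 2, 2), "positive")
  expect_error(ratio_law(1, 1, 2), "exceed 1")
  expect_error(ratio_law(1, 2, 0.5), "exceed 1")
})
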