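# Shared fixtures: all test data is generated in code.

# a small deterministic dataset for fitting tests
make_test_data <- function(n = 300, study = 1, theta0 = -5, seed = 421) {
  cfg <- sim_config(study = study, n = n, theta0 = theta0)
  simulate_dataset(cfg, seed = seed)
}

# empirical Kendall tau on a subsample (cor(method = "kendall") is O(n^2))
emp_tau <- function(u, v, cap = 4000L) {
  if (length(u) > cap) {
    idx <- seq(1L, length(u), length.out = cap)
    u <- u[idx]; v <- v[idx]
  }
  stats::cor(u, v, method = "kendall")
}

# two-sided exact binomial band: range of proportions not rejected at
# level 'conf' when the true proportion is p0
binom_band <- function(p0, n, conf = 0.99) {
  a <- (1 - conf) / 2
  c(stats::qbinom(a, n, p0), stats::qbinom(1 - a, n, p0)) / n
}

# write a small CSV fixture in a temp file, return the path
write_fixture_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
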