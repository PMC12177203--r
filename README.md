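# fcgam — copula regression for ratios of correlated gamma biomarkers

Ratios of paired biomarkers are everyday clinical endpoints: LDL/HDL
cholesterol, CD4/CD8 cell counts, amyloid-beta 42 over total tau in
dementia diagnostics. Both components are positive and right-skewed, and
they are *dependent* — sometimes negatively (amyloid-beta and tau),
sometimes positively. Common practice regresses the ratio directly with
a log-normal or gamma model, or assumes the components are independent
gammas (the GB2 ratio model); both choices discard or misstate the
dependence structure of the pair.

`fcgam` fits a distributional regression for the ratio `R = U/V` where
the components have gamma marginals

```
f_U(u) = λ_U^δ_U / Γ(δ_U) · u^(δ_U−1) · exp(−λ_U u)      (and likewise f_V)
```

joined by a Frank copula `C_θ`, which covers the full range of negative
and positive dependence and maps one-to-one onto Kendall's rank
correlation τ(θ). Covariates enter through three linear predictors

```
log λ_U = x'β_U,    log λ_V = x'β_V,    θ = x'β_θ  (or a constant),
```

with the shapes `δ_U, δ_V > 1` as nuisance parameters. Only the rate
ratio `Λ = λ_U/λ_V` is identifiable from the ratio, so covariate effects
on the ratio distribution are read from `β_Λj = β_Uj − β_Vj`: a positive
`β_Λj` shifts the conditional distribution of `R` downward. The full
conditional density, CDF, quantiles and mean of `R` follow from a
one-dimensional integral that the package evaluates by adaptive
quadrature.

The package provides:

- the exact ratio law (`ratio_law`, `ratio_pdf`, `ratio_cdf`,
  `ratio_quantile`, `gb2_pdf`, `kendall_tau`, `theta_from_tau`);
- maximum-likelihood fitting with BFGS and the `δ > 1` constraint handled
  smoothly (`fcgam_fit`), credible intervals from a normal posterior
  approximation with percentile intervals on 10,000 draws
  (`sample_posterior`, `credible_intervals`), and conditional prediction
  (`predict`, `predict_ratio_law`);
- a synthetic-data generator for equicorrelated mixed normal/binary
  covariate designs with Frank-coupled gamma outcomes (`sim_config`,
  `simulate_dataset`, `gen_covariates`, `sample_frank_gamma_pair`);
- benchmark ratio regressions (GB2, log-normal, gamma, and
  location-scale variants; `fit_benchmark`) scored by out-of-sample
  predictive log-likelihood on a common scale
  (`predictive_log_density`), plus CRPS utilities (`crps_from_samples`,
  `crps_quantile_decomposition`);
- replication harnesses for interval coverage, conditional-median RMSE
  and predictive log-likelihood (`coverage_experiment`,
  `rmse_median_experiment`, `predictive_ll_experiment`);
- a command-line interface (`run_cli`; thin wrapper in
  `inst/cli/fcgam.R`) with `simulate`, `fit`, `predict` and `evaluate`
  subcommands.

## Worked example

Simulate a cohort of n = 500 with four covariates (two standard normal,
two binary, latently equicorrelated at 0.4) and strongly negatively
dependent components (θ = −5, Kendall's τ ≈ −0.46), then fit and
summarise:

```r
library(fcgam)

cfg <- sim_config(study = 1, n = 500, theta0 = -5)
d   <- simulate_dataset(cfg, seed = 1)
fit <- fcgam_fit(d)
fit
#> Frank-copula gamma ratio regression (constant association)
#>   n = 500, log-likelihood = -1788.429, BIC = 3657.647
#>   rate-ratio coefficients (beta_u - beta_v):
#> (Intercept)          x1          x2          x3          x4
#>     -0.0739      0.5755     -0.5494      0.8289     -0.6798
#>   theta = -5.2347 (Kendall tau -0.471)
#>   shapes: delta_u = 1.9204, delta_v = 5.9284
```

The generating values are `β_Λ = (0, 0.6, −0.6, 0.6, −0.6)`, `θ = −5`,
shapes (2, 6); every estimate is close to its target, and the fitted
association correctly recovers the strong negative rank correlation.
Credible intervals for the rate-ratio coefficients come from percentiles
of differenced posterior draws:

```r
dr <- sample_posterior(fit, n_draws = 10000, seed = 1)
ci <- credible_intervals(dr, level = 0.95)
ci[grep("lambda|theta", ci$parameter), ]
#>                 parameter    estimate      lower      upper
#> 11 beta_theta.(Intercept) -5.23603592 -5.9140604 -4.5663233
#> 14     lambda.(Intercept) -0.07400689 -0.2784319  0.1297070
#> 15              lambda.x1  0.57486877  0.4832528  0.6720406
#> 16              lambda.x2 -0.54884267 -0.6400548 -0.4593214
#> 17              lambda.x3  0.82848664  0.6496307  1.0115994
#> 18              lambda.x4 -0.67964013 -0.8682549 -0.4976054
```

All four covariate intervals exclude 0 (effects present by
construction); the intercept interval covers 0 (its true value). Any
conditional summary of the ratio distribution follows by inverting the
fitted CDF at a covariate profile:

```r
x0 <- c(x1 = 0.5, x2 = -0.5, x3 = 1, x4 = 0)
predict(fit, t(x0), what = "median")
#> [1] 0.07651498
predict(fit, t(x0), what = "quantile", q = c(0.9))
#> [1] 0.2930323
```

For this profile the predicted conditional median ratio is 0.077 with
an 80% predictive range of roughly (0.016, 0.29) — the covariates push
`Λ` up and hence the ratio down.

The same workflow is available from a shell:

```sh
Rscript inst/cli/fcgam.R simulate --study 1 --theta0 -5 --n 500 --seed 1 --out d.csv
Rscript inst/cli/fcgam.R fit --data d.csv --u-col u --v-col v \
    --covariates x1,x2,x3,x4 --seed 1 --out fit.json
```

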