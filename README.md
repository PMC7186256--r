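# resindex

**A robust, model-agnostic effect size index from M-estimators and
sandwich covariances.**

## The problem

Effect size indices are unitless measures of association strength, central
to study design (power analysis), meta-analysis, and reporting. The
classical ones are each welded to one parametric model — Cohen's *d* to a
two-group mean difference with equal variances, *R²* to homoskedastic
linear regression, the standardized log odds ratio to logistic regression —
and their estimators become asymptotically *biased* as soon as the variance
model is wrong (unequal group variances with unequal sampling,
heteroskedasticity, overdispersion). They also do not share a scale, which
makes effect sizes hard to compare across models.

`resindex` implements a single index defined for any parameter that solves
an estimating equation. For an M-estimator with parameter
θ = (α, β) — an m₀-dimensional nuisance block and an m₁-dimensional target
block — and sandwich (robust) covariance Σ, the index is

    S = sqrt( (β − β₀)' Σ_β⁻¹ (β − β₀) ),

the standardized distance of the target parameter β from its reference
value β₀ (zero by default), where Σ_β is the target block of the
asymptotic covariance of √n(θ̂ − θ). S is the per-observation noncentrality
root of the robust Wald statistic T² = n(β̂ − β₀)'Σ̂_β⁻¹(β̂ − β₀), so it is
unitless, comparable across models, and remains meaningful under variance
misspecification because the sandwich covariance does. It is estimated by
the truncated form

    Ŝ = sqrt( max{0, (T² − m) / (n − m)} ),   m = m₀ + m₁.

The package provides, for this index:

* a generic M-estimation engine (built-in least-squares, logistic, and
  two-group-means families; custom score functions through the same
  contract) with empirical bread/meat matrices and the HC0-equivalent
  sandwich covariance;
* closed-form special cases (`two_sample_s`, `linreg_s`, `logistic_s`);
* conversions linking S to Cohen's d, f², and partial R², plus the
  conventional qualitative bands on the S scale (`classify_effect_size`);
* asymptotic bias diagnostics for the classical indices under
  heteroskedasticity (`cohens_d_bias_ratio`, `r2_bias_ratio`,
  `bias_surface`);
* model-free power/sample-size/effect-size solving via the noncentral
  chi-squared distribution (`power_from_s`, `n_from_power`,
  `s_from_power`, `power_curve`);
* a synthetic-data simulation engine measuring finite-sample bias and SE
  of Ŝ over grids of n, S, and covariate correlation (`simulation_config`,
  `run_grid`).

## Worked example

A 400-subject study of a treatment effect on a clinical score, adjusting
for age, where the treated arm happens to be noisier (heteroskedastic — the
setting where classical d/R² estimates go wrong):

```r
library(resindex)
set.seed(2024)
n <- 400
clinic <- data.frame(age = rnorm(n, 50, 10), treated = rbinom(n, 1, 0.5))
clinic$score <- 0.04 * clinic$age + 0.35 * clinic$treated +
  rnorm(n, sd = 0.8 + 0.4 * clinic$treated)

prob <- estimating_problem(clinic, outcome = "score",
                           nuisance = "age", target = "treated")
fit <- estimate_from_data(prob)
fit
#> Robust effect size index: S_hat = 0.1407 (small-medium)
#>   T2 = 10.8623 on 1 df, n = 400, m = 3
fit$sandwich
#> Sandwich estimate (linear family): n = 400, m = 3 (m1 = 1 target)
#> theta_hat:
#> (Intercept)         age     treated
#> -0.05259910  0.04064041  0.33466171
#> Sigma_beta (asymptotic covariance of sqrt(n) * beta_hat):
#>          treated
#> treated 4.124309
```

The adjusted treatment effect is 0.335 score units; standardized by its
robust variability it is Ŝ = 0.141 — a small-to-medium effect on the common
S scale (the thresholds 0.1/0.25/0.4 correspond to d = 0.2/0.5/0.8 for
balanced groups). Downstream, on the same scale:

```r
d_from_s(fit$S)                                        # robust d analogue
#> 0.281455
power_from_s(0.05, df = 1, s = fit$S, n = 400)         # power of this design
#> 0.8036106
n_from_power(0.05, df = 1, s = fit$S, power = 0.9, ceiling = TRUE)
#> 531
cohens_d_bias_ratio(0.25, sigma1_sq = 2, sigma0_sq = 1) # classical d bias
#> 1.183216
```

So a replication would need about 531 subjects for 90% power at this effect
size; and in a design with 25% sampling in the noisier group, the classical
pooled-SD Cohen's d would overstate the effect by ~18% asymptotically.

A thin command-line wrapper over the same functions is installed at
`exec/resindex` inside the package library, with subcommands `estimate`,
`convert`, `power`, `bias`, and `simulate`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/resindex", package="resindex"))')" \
  convert --from d --to S --value 0.5
#> S = 0.25
#> band: small-medium
```

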