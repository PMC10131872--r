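# mtpcost

Marginalized two-part models for longitudinal medical-cost panels, with a
segmented interrupted-time-series design centred on a diagnosis event.

## The problem

Monthly medical costs from insurance claims are *semicontinuous*: a
sizeable share of subject-months have zero spending, and the positive
amounts are strongly right-skewed. Conventional two-part (hurdle) models
split the outcome into a usage indicator and a conditional-on-positive
mean, but the regression coefficients of the positive part then describe
only the users, not the population. The *marginalized two-part (MTP)
model* reparameterizes the positive part so the coefficients act directly
on the **overall mean including the zeros**, which is the quantity health
policy cares about.

`mtpcost` implements the MTP model for diagnosis-centred cost panels, as
used to study whether patients with chronic kidney disease (CKD) living in
medically vulnerable regions of South Korea (regional healthcare-level
index PARC below -0.33) accumulate higher costs after diagnosis than
patients in better-served regions. Since the underlying national claims
cohort is access-restricted, the package ships a calibrated synthetic
cohort generator with known ground truth, so the entire pipeline is
reproducible and testable without data access.

## The model

For subject *i* in month *j* of a 49-month window (24 months before the
diagnosis, the diagnosis month, 24 months after), with correlated random
intercepts (a_i, d_i) ~ N2(0, Sigma):

    P(Y_ij > 0 | a_i)  = pi_ij = logistic(x1_ij' alpha + a_i)
    E(Y_ij | a_i, d_i) = nu_ij = exp(x2_ij' beta + d_i)
    Y_ij | Y_ij > 0    ~ Gamma(shape kappa, mean mu_ij = nu_ij / pi_ij)

so `exp(beta_k)` is the multiplicative change in the overall mean per unit
of covariate *k*. Both parts share a segmented-regression design:
intercept, post-diagnosis level shift, region, month index (time), their
products, the post-diagnosis slope change (after-time = months since
diagnosis), a region slope term (region x time) and the three-way
difference-in-differences term (diagnosis x region x after-time), plus
age, sex and comorbidity adjustments. The marginal likelihood integrates
the bivariate random intercept with adaptive Gauss-Hermite quadrature
(Laplace-centred per subject); estimation is maximum likelihood with
analytic gradients and Wald inference from the observed information.

Key post-fit quantities:

- the 3 x 3 grid of monthly log-mean slopes (region x before/after/change),
- the projected region difference in overall mean cost, 100 x
  (beta7 + beta8) x years, in percent per years since diagnosis,
- model-implied log-mean trajectories with pointwise confidence bands.

## Worked example

```r
library(mtpcost)

# 1. simulate a cohort from the packaged, calibrated configuration
cfg   <- default_params(n_subjects = 500, seed = 11)
panel <- generate_cohort(cfg)
mean(panel$cost == 0)          # ~0.29 zero-cost subject-months
region_split(panel)            # ~12.2% vulnerable subjects

# 2. fit the marginalized two-part model
fit <- mtp_fit(build_design(panel), quadrature_spec(nodes_per_dim = 3))
summary(fit)

# 3. published-coefficient worked example: the region gap over time
ref <- mtp_reference_fit()
predict_region_difference(ref, 1:5)
```

The final call prints the projected vulnerable-minus-nonvulnerable
difference in overall mean expenditure:

```
  years difference_pct        se        lower     upper
1     1           0.26 0.1370947 -0.008700577 0.5287006
2     2           0.52 0.2741893 -0.017401154 1.0574012
3     3           0.78 0.4112840 -0.026101731 1.5861017
4     4           1.04 0.5483786 -0.034802307 2.1148023
5     5           1.30 0.6854733 -0.043502884 2.6435029
```

i.e. the cost gap between regions grows by about 0.26 percentage points
per year after diagnosis (the `se` column uses the diagonal covariance
recoverable from the printed confidence limits; refitting supplies the
full covariance). A fitted cohort can be pushed through the same
machinery: `named_slope_contrasts(fit)`, `predict_trajectory(fit, ...)`,
`plot_trajectories(fit)`.

A thin command-line pipeline is included:

```sh
Rscript inst/cli/mtpcost.R simulate --output-prefix out/sim --seed 1 --n-subjects 500
Rscript inst/cli/mtpcost.R fit      --input out/sim_panel.csv --output-prefix out/fit --quad-nodes 3
Rscript inst/cli/mtpcost.R report   --input out/fit_fit.json --output-prefix out/rep
```

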