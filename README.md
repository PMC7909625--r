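# menarcheMR

Mendelian randomization of age at menarche (AAM) on young-adult body-mass
index, with generation standardization for populations where menarcheal age
has fallen by several years across birth cohorts.

## The problem

Earlier menarche is observationally associated with higher BMI in young
women. But where modernization was rapid, mean AAM declined steeply by birth
year while education expanded and body habitus changed, so AAM, BMI and
their social determinants are all confounded by generation. `menarcheMR`
addresses this two ways:

* **Generation standardization** — AAM becomes the within-birth-year z-score
  **gsAAM** = (AAM − μ_year)/σ_year against a reference population; education
  becomes a cohort-relative "highly educated" indicator; birth cohorts are
  segmented data-adaptively so that the AAM distribution is homogeneous
  within each (pooled early-menarche proportion held in a 5–6% band, cohorts
  closed at >2% year-on-year jumps).
* **Mendelian randomization** — an unweighted genetic risk score (GRS)
  counting AAM-decreasing alleles across 14 menarche-timing SNPs serves as an
  instrumental variable. The estimator suite covers two-stage least squares
  (2SLS, pairs bootstrap SEs), the inverse-variance-weighted estimator
  (β̂ = Σβ_Xj β_Yj/se²_Yj ÷ Σβ²_Xj/se²_Yj), the weighted median, MR-Egger
  regression (slope = causal effect, intercept = average directional
  pleiotropy), MR-PRESSO, Cochran's Q and leave-one-out diagnostics — all
  implemented from first principles and checked against closed-form oracles.

Because the cohort data such analyses run on are access-restricted, the
package includes a synthetic-cohort generator with known causal structure
(secular AAM trend 16.5 → 12.4 years over birth years 1927–2003, generational
education expansion, 14 Hardy–Weinberg SNPs shifting AAM, optional
directional pleiotropy, configurable true causal effect), so every stage is
testable end to end with ground truth.

## Worked example

```r
library(menarcheMR)

cfg <- sim_config(n_individuals = 4093, beta_causal = -0.5,
                  snp_effects_on_aam = seq(-0.1, -0.4, length.out = 14),
                  seed = 42)
sim <- simulate_cohort(cfg)                       # phenotypes + genotypes + SNP panel
ref <- simulate_reference_population(cfg)         # birth-year AAM reference
dat <- standardize_cohort(sim$phenotypes, ref)    # adds gsaam, cohort, highly_educated
dat$grs <- build_grs(sim$genotypes, sim$panel)    # AAM-decreasing allele count

first_stage_diagnostics(dat, dat$grs)
#>   coding       estimate conf.low conf.high  p.value     F r.squared     n
#> 1 per_unit       -0.248   -0.277    -0.219 5.53e-62  286.    0.0653  4093
#> 2 per_quartile   -0.453   -0.513    -0.393 6.71e-48  217.    0.0504  4093
```

Each added risk allele lowers AAM by ~0.25 years; F = 286 ≫ 10, so the score
is a strong instrument. The full model grid (four covariate specifications ×
observational/2SLS, plus the summary-data MR block per exposure form):

```r
report <- run_models(dat, sim$genotypes, sim$panel, n_boot = 1000, seed = 42)
report
#> <mr_report> n = 4093 participants, 14 instrument SNPs, seed 42
#>
#> Observational and 2SLS estimates:
#>         method model exposure estimate conf.low conf.high  p.value
#>  observational     1      aam   -0.499   -0.544    -0.453 8.21e-97
#>           2sls     1      aam   -0.474   -0.632    -0.308 2.05e-08
#>  observational     2      aam   -0.492   -0.538    -0.447 5.76e-96
#>           2sls     2      aam   -0.462   -0.618    -0.303 1.73e-08
#>  ...
#>
#> Summary-data MR (aam):
#>           method              term estimate std.error conf.low conf.high
#>              ivw     causal_effect  -0.5302    0.0705  -0.6684    -0.392
#>  weighted_median     causal_effect  -0.4977    0.0959  -0.6857    -0.310
#>            egger             slope  -0.6317    0.1707  -1.0035    -0.260
#>            egger         intercept   0.0305    0.0470  -0.0719     0.133
#>           presso outlier_corrected  -0.5302    0.0705  -0.6684    -0.392
```

The cohort was simulated with a true effect of **−0.5 kg/m² per year** of
menarcheal age: every estimator brackets the truth, the 2SLS and IVW
estimates agree (as they should with independent SNPs), and the Egger
intercept's CI covers 0 — no evidence of directional pleiotropy, which is
correct since none was simulated. The gsAAM rows sit near −0.9 because one
gsAAM unit is one within-year SD of AAM (~1.9 years), so the per-SD effect is
≈ −0.5 × 1.9.

Results are tidy throughout: `tidy(report)`/`forest_table(report)` give a
plot-ready long table, `glance(report)` the run metadata, and
`autoplot(report)` the observational-versus-MR forest plot. Every estimator
(`mr_ivw()`, `mr_weighted_median()`, `mr_egger()`, `mr_presso()`) returns an
object with `tidy()` and `glance()` methods.

A file-to-file CLI covering the same stages
(`simulate`/`standardize`/`instrument`/`analyze`/`report`) ships in
`inst/cli/genmr.R`.

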