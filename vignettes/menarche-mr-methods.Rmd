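---
title: "Methods: generation-standardized Mendelian randomization of age at menarche on young-adult BMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generation-standardized Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Earlier menarche is observationally associated with higher body-mass index in
young adulthood. But in populations that modernized rapidly, mean age at
menarche (AAM) fell by roughly four years across twentieth-century birth
cohorts while education expanded and body habitus changed, so the
exposure, the outcome and major social determinants are all strongly
patterned by birth year. A naive regression of young-adult BMI on AAM then
mixes a within-generation signal with a between-generation secular trend.

`menarcheMR` implements two complementary answers:

1. **Generation standardization.** AAM is converted to a within-birth-year
   z-score (gsAAM) against a reference population, and education is converted
   to a generation-relative "highly educated" indicator, so comparisons are
   made within, not across, generations.
2. **Mendelian randomization (MR).** A genetic risk score (GRS) built from
   menarche-timing SNPs serves as an instrumental variable. Because alleles
   are assigned at meiosis, the GRS is independent of social confounders and
   immune to reverse causation, so the instrumented estimate isolates the
   causal effect of AAM on young-adult BMI.

## The generative model behind the synthetic cohorts

No individual-level cohort with menarche phenotypes and genotypes is publicly
deposited, so the package ships a synthetic-cohort generator whose parameters
are the ground truth every estimator is validated against:

$$AAM_i = T(y_i) + \textstyle\sum_j \beta_j G_{ij} + \gamma_A E_i + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma_A^2)$$
$$BMI_i = \beta_{causal}\,AAM_i + \textstyle\sum_j \alpha_j G_{ij} +
\gamma_B E_i + S(y_i) + \eta_i, \qquad \eta_i \sim N(0, \sigma_B^2)$$

with $y_i$ the birth year, $T(\cdot)$ the secular AAM trend, $S(\cdot)$ a
birth-year BMI offset, $E_i$ the 5-level education code (sampled from an
ordered-probit model whose latent mean rises across birth years, so later
cohorts are more educated), and $G_{ij} \in \{0,1,2\}$ independent
Hardy–Weinberg dosages. Non-zero $\alpha_j$ inject directional pleiotropy —
the classic violation of the MR exclusion restriction.

Default settings emulate the study population the method targets: 4,093
women born 1927–2003, mean AAM declining linearly 16.5 → 12.4 years, AAM
residual SD 1.8 years, young-adult BMI offset declining mildly 21.8 → 20.5
kg/m², BMI residual SD 2.8 kg/m², 14 SNPs with effect-allele frequencies
0.15–0.45 and per-allele AAM effects averaging −0.08 years (the scale at
which an unweighted 14-SNP score shifts AAM about −0.08 years per unit, and
first-stage F-statistics land in the tens), education lowering both AAM
(−0.1 yr/level) and BMI (−0.2 kg/m²/level), and `beta_causal = 0` — the
substantive finding the method was built to test. Noise is Gaussian because
every analysis stage is a linear model; genotypes are independent across SNPs
(the instrument panel spans distinct loci, and linkage disequilibrium
modelling is out of scope). Missing genotype calls are generated only when a
missingness rate is configured.

What the generator does *not* emulate: family/twin structure, recall error in
self-reported AAM and early-adult weight, genotyping-array batch effects,
linkage disequilibrium, and assortative mating. Passing the validation suite
therefore demonstrates correctness of the estimators under the stated model,
not robustness to those real-data complications.

## Birth-cohort segmentation

Cohorts are defined so that the AAM distribution is homogeneous within each:
the algorithm tracks the proportion of women with early menarche (strictly
AAM < 14) per birth year, opens a cohort at the earliest unassigned year, and

* extends it while the pooled (participant-weighted) early-menarche
  proportion of the open cohort stays within a band (default 5–6%), provided
  the opening year itself lies in the band;
* closes it whenever the per-year proportion changes by more than a jump
  threshold (default 2%) from one year to the next, whichever rule triggers
  first.

Two readings of the stopping rule were possible: the band could constrain the
pooled proportion of the open cohort or each successive year's marginal
proportion. The pooled reading is the default (`band = "pooled"`) because
"expanding as far as the cumulative proportion is maintained" describes a
running pooled constraint; the marginal variant is available behind the
`band` switch. Years that *open* outside the band (recent cohorts where early
menarche exceeds 40%) cannot satisfy a 5–6% band at all, so they are governed
by the jump rule alone — without this, the modern end of any realistic
reference could never form a multi-year cohort. The final cohort always runs
to the last reference year. Correctness is established against an exhaustive
enumeration oracle: on randomized references (≤ 15 years, so all $2^{K-1}$
boundary sets can be checked) exactly one partition satisfies the rules, and
the greedy construction returns it.

Reference years with fewer than `min_n = 30` participants are pooled with the
adjacent year before means and SDs are computed (`build_reference()`), so no
year's standardization rests on a handful of observations.

## gsAAM and generation-relative education

`compute_gsaam()` is the plain within-year z-score
$(AAM - \mu_y)/\sigma_y$ with $\mu_y, \sigma_y$ from the reference table. It
errors on years absent from the reference or with zero SD rather than
guessing. When the reference is built from the analysis cohort itself, the
within-year mean and SD of gsAAM are 0 and 1 to machine precision, and the
transform is invariant to affine recoding of the AAM scale applied jointly to
data and reference — both properties are tested.

"Highly educated" is relative to the generation: the attainment that
distinguishes the top half of women born in the 1930s (elementary school) is
not the one that does for the 1980s (university). When thresholds are not
supplied, `derive_education_map()` picks, per cohort, the education level
whose at-or-above share is closest to one half — a majority split, matching
the 51–63% "highly educated" shares that motivate the indicator. Explicit
threshold maps are accepted wherever a map is consumed.

## Instruments

Genotype QC follows array-era conventions: per-SNP call rate > 0.95, MAF >
0.01, Hardy–Weinberg equilibrium p > 1e-6 (1-df χ² by default, conditional
exact test behind an option), after dropping samples with call rate ≤ 0.9.
Replication requires each candidate SNP to associate with AAM at p < 0.05
*with the published direction*; the replication regressions are unadjusted
(exposure on dosage only), as no covariate set is defined for that step.
Known pleiotropic loci are removed via a user-supplied exclusion list, since
pleiotropy evidence comes from external reports, not from this data.

The GRS is an **unweighted** count of AAM-decreasing alleles: coefficients
are reported "per 1-unit increase" of the score, which is only interpretable
for a count; an effect-size-weighted variant sits behind `weighted = TRUE`.
Dosages of SNPs whose effect allele increases AAM are flipped ($2 - G$) so
a higher score always predicts earlier menarche — the orientation test
asserts that regressing simulated AAM on the score gives a negative slope
whenever all configured effects are AAM-decreasing. Missing dosages are
mean-imputed per SNP for scoring only; high missingness is QC's job.
Quartile coding is rank-based with ties assigned to the lower quartile.

## Estimators

* **Observational OLS** per four covariate specifications: Model 1 (AAM +
  birth-year dummies + 5-level education), Model 2 (AAM + data-driven cohort
  dummies + highly-educated), Model 3 (gsAAM + education), Model 4 (gsAAM +
  highly-educated). Rank-deficient designs error with the aliased columns
  named; estimation is complete-case per model.
* **2SLS** with the GRS quartile-coded in the first stage by default (the
  per-quartile coefficient is the interpretable scale), continuous score
  optional. Standard errors from a seeded nonparametric pairs bootstrap with
  percentile CIs (1000 replications by default); `n_boot = 0` switches to
  the analytic 2SLS standard error (structural residuals evaluated at the
  observed exposure), used where thousands of repeated fits are needed.
* **Per-SNP summaries** by Frisch–Waugh–Lovell residualization — numerically
  identical to the full per-SNP regressions, but one QR of the covariate
  block serves all SNPs. Inside `run_models()` the summaries are adjusted
  with Model 2's covariates for AAM and Model 4's for gsAAM (the
  cohort-relative sets); unadjusted summaries are an option.
* **IVW**, fixed-effect: the precision-weighted mean of Wald ratios with
  weights $\beta_{Xj}^2/se_{Yj}^2$; Cochran's Q against the IVW estimate.
* **Weighted median** by the standardized-cumulative-weight interpolation
  rule; SE from a seeded parametric bootstrap redrawing each summary from
  $N(\hat\beta_j, se_j)$.
* **MR-Egger**: summaries oriented so all exposure betas are non-negative
  (flipping both betas jointly — required for the intercept to mean "average
  directional pleiotropy"), then weighted regression with intercept, weights
  $1/se_{Yj}^2$. Inference is classical weighted-LS t on $K-2$ df with the
  residual dispersion estimated from the fit: exactly calibrated under
  homogeneity, conservative under overdispersion. (A dispersion floor at 1
  was tried and rejected: it pushed null coverage to 0.972.)
* **MR-PRESSO**: the observed weighted RSS of outcome betas about their
  leave-one-out IVW predictions is compared to a parametric null (redrawing
  both betas, outcome centred on the leave-one-out prediction); per-SNP
  outlier p-values are Bonferroni-adjusted and tested at 0.05 regardless of
  the global result; flagged outliers are removed and IVW recomputed; the
  distortion p compares the observed before/after shift against shifts from
  removing random same-size subsets. All simulation counts default to 1000.
* **Leave-one-out** IVW with per-row Q, to localize heterogeneity to single
  SNPs.

No multiplicity correction is applied across models or estimators — raw CIs
and p-values are reported, as is conventional for MR sensitivity suites.

## Numerical choices and degenerate inputs

All linear algebra goes through one QR path; rank deficiency raises an error
naming the aliased columns instead of silently dropping them. Single-level
factors contribute no columns (adjusting for a constant is a no-op), which
keeps Model 2 usable when a partition yields one cohort. A degenerate first
stage (fitted exposure with zero variance) errors. The Wald ratio errors on
zero exposure betas; monomorphic SNPs are dropped from summaries with a
warning. Monomorphic genotype counts are in Hardy–Weinberg equilibrium by
convention (p = 1). Weighted-median cumulative weights hitting 0.5 exactly
return the boundary ratio. Seeds: a single master seed in `run_models()`
fixes the 2SLS bootstrap, weighted-median bootstrap and PRESSO draws, and
reruns are byte-identical.

## Validation scenarios and their settings

The acceptance-style tests simulate at sizes chosen to make Monte-Carlo error
small relative to the tolerances while keeping the suite inside a desktop
run: estimator recovery uses 200 cohorts of n = 10,000; null-CI coverage
1,000 cohorts of n = 5,000; the IVW–2SLS equivalence one cohort of
n = 50,000; weighted-median robustness 40 cohorts of n = 50,000; Egger
intercept recovery 200 cohorts of n = 20,000.

Two scenario settings deserve justification, decided by power analysis
before the tests were run:

* **Instrument strength.** Validation scenarios use per-allele AAM effects
  of −0.10 to −0.40 years rather than the default −0.08 average. MR-Egger is
  identified only when the spread of the per-SNP exposure associations
  dominates their estimation error (the NOME condition, $I^2_{GX}$ near 1);
  at the default effect scale $I^2_{GX} \approx 0.55$ at n = 10,000 and the
  Egger slope is attenuated by regression dilution far beyond any usable
  tolerance. The defaults stay at the realistic scale; only the
  estimator-validation scenarios strengthen the instruments.
* **Pleiotropy magnitudes.** The robustness scenario gives 6 of 14 SNPs a
  direct +0.2 kg/m² per-allele BMI effect (ratio-scale offset
  $\alpha/\beta_X \approx -0.67$), enough to displace IVW by well over 0.1
  while the invalid weight share (~35%) stays below the weighted median's
  50% breakdown. The intercept-recovery scenario uses a constant +0.05
  kg/m² per-allele effect with AAM-increasing orientation, so no Egger flip
  occurs and the recovered intercept equals +0.05 directly.

## Known limitations

* One-sample MR only: no two-sample analysis against external GWAS summary
  databases, no LD-aware IVW for correlated instruments.
* The exclusion list for pleiotropic SNPs is an input, not a computed step.
* The segmentation reproduces the *rules*, not any particular historical
  partition, which would require the original reference survey.
* Weak-instrument behaviour is inherited, not corrected: with a one-sample
  design, weak scores bias 2SLS toward the observational estimate. The
  first-stage F is reported so users can see when they are in that regime.
* gsAAM relies on the reference covering every analysis birth year; there is
  deliberately no extrapolation outside the reference range.
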