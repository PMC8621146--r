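# frimeta

Diagnostic-test-accuracy (DTA) meta-analysis of automatic facial-recognition
studies, with a phenotype-intensity index linking how strongly a disease
marks the face to how accurately a classifier can detect it.

Many genetic and endocrine diseases — Down syndrome, acromegaly, Cornelia de
Lange syndrome, Turner syndrome and others — show characteristic facial
phenotypes, and a growing literature trains image classifiers to recognise
them from photographs. Each such study reports a 2x2 table (TP/FP/FN/TN)
against a reference diagnosis. frimeta is for the analyst synthesising this
literature: it pools the tables, quantifies each disease's facial
distinctiveness, and answers the question *how distinctive must a disease's
face be before automatic recognition can reach a target sensitivity and
specificity?*

## What it computes

**Bivariate pooling.** Study sensitivities and specificities are pooled
jointly with the binomial-normal bivariate random-effects model: per study
*k*, tp<sub>k</sub> ~ Bin(n<sub>1k</sub>, logit⁻¹ θ<sub>k1</sub>),
tn<sub>k</sub> ~ Bin(n<sub>2k</sub>, logit⁻¹ θ<sub>k2</sub>), with
(θ<sub>k1</sub>, θ<sub>k2</sub>) ~ N(μ, Σ). The exact marginal likelihood
is maximised by adaptive Gauss–Hermite product quadrature
(`fit_bivariate()`); `pooled_summary()` derives pooled Se, Sp, likelihood
ratios and the diagnostic odds ratio with delta-method intervals, and
`sroc()` traces the summary ROC curve with Wald confidence and prediction
regions.

**The FRI index.** Facial recognition intensity is
FRI = N<sub>f</sub> × P<sub>max</sub>: the number of independent facial
phenotypes of a disease (correlated phenotypes counted once) times the
maximum penetrance among them (`compute_fri()`). A reference table of seven
benchmark diseases ships with the package.

**Meta-regression and thresholds.** `fit_metareg()` regresses study
ln(OR) on FRI with a random-effects meta-regression (REML τ²; the engine is
metafor). Inverting the fitted line, ln(OR) = β₁·FRI + β₀, gives the FRI a
disease must reach for target accuracy: `required_fri(se, sp)` returns
(ln[Se·Sp/((1−Se)(1−Sp))] − β₀)/β₁.

**Simulation.** `simulate_studies()` / `simulate_fri_cohort()` generate
seeded synthetic study sets from exactly the assumed data-generating
process, so every stage is testable without external data.

**Orchestration.** `run_full_analysis()` runs the whole pipeline (pooling,
SROC, meta-regression, thresholds, subgroups, stratified summaries,
sensitivity refits) from a studies CSV and writes CSV/JSON artifacts; a
command-line wrapper ships at `inst/cli/frimeta-report.R`.

## Worked example

```r
library(frimeta)

studies <- read_studies(system.file("extdata", "synthetic_studies_20.csv",
                                    package = "frimeta"))
fit <- fit_bivariate(studies, seed = 1)
pooled_summary(fit)
#> Pooled diagnostic accuracy
#>   Se    91.9%  (95% CI 87.1% to 95.0%)
#>   Sp    91.4%  (95% CI 90.1% to 92.6%)
#>   PLR   10.73  (95% CI 9.28 to 12.40)
#>   NLR    0.09  (95% CI 0.05 to 0.14)
#>   DOR  121.06  (95% CI 71.24 to 205.72)
```

The pooled operating point says this (synthetic) study set detects disease
from face photographs with 91.9% sensitivity at 91.4% specificity; a
positive call raises the odds of disease about 11-fold (PLR), and the DOR of
~121 summarises both axes in one number. The packaged phenotype table gives
each disease's FRI (the Angelman row carries a documented warning about
conflicting published values):

```r
fri_table(fri_reference_profiles())
#>                            disease nf  pmax   fri
#> 1                    Down syndrome  9 1.000 9.000
#> 2                       Acromegaly  8 1.000 8.000
#> 3       Cornelia de Lange syndrome  9 0.827 7.443
#> 4                Angelman syndrome  6 1.000 6.000
#> 5               Cushing's syndrome  5 1.000 5.000
#> 6 Fetal alcohol spectrum disorders  4 1.000 4.000
#> 7                  Turner syndrome  6 0.560 3.360
```

Inverting the reference FRI/ln(OR) link (slope 0.4960, intercept 1.459)
shows the facial distinctiveness needed for a target accuracy — e.g. a
disease needs FRI ≈ 4.05 for 85%/85% but ≈ 8.93 for 95%/95%:

```r
format_fri_thresholds(required_fri_table(
  list(c(0.85, 0.85), c(0.90, 0.90), c(0.95, 0.95))))
#>     se   sp     or ln_or  fri
#> 1 0.85 0.85  32.11  3.47 4.05
#> 2 0.90 0.90  81.00  4.39 5.92
#> 3 0.95 0.95 361.00  5.89 8.93
```

And the meta-regression stage estimates that link from data (here the
synthetic fixture, generated with a true slope of 0.496):

```r
studies <- attach_fri(studies, fri_reference_profiles())
fit_metareg(studies[!is.na(studies$fri), ], "fri")
#> Random-effects meta-regression of ln(OR) (REML), 16 studies, tau2 = 0.0000
#>   (intercept)    1.0333  [95% CI 0.2771, 1.7895]  p = 0.007404
#>   fri            0.5652  [95% CI 0.4437, 0.6868]  p = 8.032e-20
```

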