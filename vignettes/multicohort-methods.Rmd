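---
title: "Multi-cohort risk modeling and cohort-level internal validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cohort risk modeling and cohort-level internal validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortrisk)
```

## The problem

Online clinical risk calculators are increasingly built on patient-level data
pooled from many institutions. The institutions differ — in outcome
prevalence, in the mix of risk factors, sometimes dramatically (one cohort may
have no patients of African ancestry, another more than 60%) — and the
modeling question is how to respect that clustering when the tool will be used
by individual patients anywhere. `cohortrisk` implements a complete strategy
for this setting, profiled on multi-center prostate biopsy consortia: a binary
high-grade-cancer outcome, PSA, age and four binary risk factors, ten-ish
cohorts of a few hundred to a couple of thousand biopsies each.

The package's pieces are: (1) data ingestion and a fixed covariate encoding;
(2) five fitting/prediction strategies for clustered binary data; (3) three
out-of-sample performance metrics with interval estimates; (4) an exhaustive
cohort-level cross-validation engine with cohort-influence analyses; (5) a
synthetic multi-cohort generator with known ground truth; and (6)
heterogeneity graphics. Real consortium data are typically restricted, so the
generator is a first-class module: every pipeline stage is testable against a
known truth.

## Covariate encoding

PSA is modeled on the log-base-2 scale and standardized (subtract mean, divide
by standard deviation); age is standardized the same way. The design matrix
has exactly nine terms in a fixed order: standardized log2 PSA, standardized
age, abnormal DRE, African ancestry, first-degree family history, prior
negative biopsy, and the interactions log2PSA:DRE, age:DRE and age:African
ancestry. The covariate set is fixed; feature selection is deliberately out of
scope.

Two preprocessing conventions matter:

* **Standardization provenance.** For a final model the constants are computed
  across all sites (`fit_preprocessing(..., "all_data")`). Inside
  cross-validation the package fits them on the *training* cohorts only and
  freezes them for the test side (`"training_only"`), avoiding test-set
  leakage. The `source` field records which convention produced the constants.
* **Missing data.** Rows missing age, PSA or the outcome are excluded and
  reported by reason (`apply_exclusions()`); missing binary factors are
  imputed to the low-risk reference — normal DRE, non-African, no family
  history, no prior negative biopsy (`impute_binary_missing()`). PSA is
  continuous, so a reference-value imputation is undefined; missing PSA shares
  the fate of missing age. Multiple imputation is not implemented.

## The five modeling strategies

Write $y_{ic}$ for the outcome of individual $i$ in cohort $c$ and $x_{ic}$
for the 9-vector of covariates. All five strategies report an intercept
$\beta_0$ and slope vector $\beta$, and predict via the inverse logit
$\operatorname{expit}(\beta_0 + \beta'x)$ unless noted.

1. **Pooled** — one logistic regression on all individuals, cohort ignored.
2. **Random intercept, median prediction** — the one-stage meta-analysis
   $\operatorname{logit} P(y_{ic}=1) = \beta_0 + \beta_{0c} + \beta'x_{ic}$,
   $\beta_{0c} \sim N(0, d)$, fitted by maximizing the marginal likelihood
   with the random intercept integrated out by adaptive Gauss–Hermite
   quadrature. A new individual's cohort effect is set to its prior median, 0.
3. **Random intercept, mean prediction** — the same fit, but the prediction
   integrates the inverse logit over $N(0, d)$:
   $\int \operatorname{expit}(\beta_0 + u + \beta'x)\,\varphi(u; 0, d)\,du$.
4. **Fixed-effects meta-analysis** — the two-stage strategy: separate
   logistic regressions per center, then each coefficient $k = 0, \dots, 9$
   combined as the inverse-variance weighted mean with weights
   $w_{kc} = 1/\widehat{\mathrm{var}}(\beta_{kc})$.
5. **Random-effects meta-analysis** — as 4, with weights
   $w_{kc} = 1/\{\widehat{\mathrm{var}}(\beta_{kc}) + b_k\}$ and $b_k$ the
   between-center variance from the DerSimonian–Laird method of moments,
   truncated at zero.

The two-stage strategies matter operationally: they need only per-center
coefficients and standard errors, never the patient-level data, so they scale
to consortia that cannot centralize records.

### Numerical choices

* **GLMM estimator**: adaptive Gauss–Hermite quadrature with 15 nodes
  (`lme4::glmer`, `nAGQ = 15`), the standard high-accuracy choice for a
  scalar random intercept; if quadrature fails the fit falls back to the
  Laplace approximation with a warning. A variance estimate at the boundary
  ($d \approx 0$) is allowed with a warning.
* **Mean-prediction integral**: 50-node Gauss–Hermite. Doubling the node
  count moves predictions by less than $10^{-8}$ over $|\eta| \le 10$,
  $d \le 4$ (asserted in the test suite). The integral collapses *exactly* to
  the median rule at $d = 0$.
* **DerSimonian–Laird**: per-coefficient, ignoring cross-coefficient
  covariance — this matches the scalar per-$k$ weighting of the two-stage
  strategy, and is how coefficient-level meta-analysis is done in practice.
  $b_k = \max\{0, (Q_k - (C_k - 1))/(S_1 - S_2/S_1)\}$ with fixed-weight
  heterogeneity statistic $Q_k$, $S_1 = \sum w$, $S_2 = \sum w^2$.
* **Inestimable center terms**: a covariate with zero variation within a
  center (e.g. African ancestry in an all-European cohort) is dropped from
  that center's regression and flagged; the center simply does not contribute
  to that coefficient's combination. A per-center coefficient that diverges
  (quasi-separation in a small center) is likewise flagged rather than
  allowed to enter with a meaningless value; its huge variance would have
  given it near-zero weight anyway. Each combined coefficient requires at
  least two contributing centers.
* **Separation**: pooled and per-center fits error (or flag, per-center) when
  coefficients diverge beyond ±15 on the standardized scale or the IRLS loop
  fails to converge. No penalized fallback is attempted — a separated fit is
  a data problem the user should see.

## Out-of-sample metrics

* **AUC** — the Mann–Whitney estimator (ties counted half), with analytic
  DeLong confidence intervals from placement values; the paired DeLong
  variance serves differences between two models evaluated on the same test
  rows.
* **Hosmer–Lemeshow statistic (HLS)** — individuals sorted by predicted risk
  and cut at the sample deciles of risk into ten groups (tied risks stay
  together, so groups can be unequal); then
  $\sum_g (O_g - E_g)^2 / \{E_g (1 - E_g/n_g)\}$ on observed and expected
  event counts. This count-scale form is the one that is asymptotically
  chi-square with $g - 2 = 8$ degrees of freedom for an in-sample fit of a
  correctly specified model — the property the test suite checks by
  simulation. A risk-scale variant (squared difference of observed and
  expected mean risks over expected) is available via `form = "risk"` for
  users who prefer that reading; it lacks the chi-square reference. Because
  lower HLS is better while higher AUC is better, validation reports carry
  the negated statistic (−HLS) so that "higher is better" holds everywhere.
* **Net benefit** — decision-curve utility at risk threshold $t$:
  $TP/n - (FP/n)\,t/(1-t)$ calling risk $\ge t$ positive, reported alongside
  the treat-all benchmark $\pi - (1-\pi)\,t/(1-t)$. The default threshold is
  0.15, the operating point used for biopsy-referral decisions in this
  application. Bootstrap 2.5–97.5 percentile intervals (default
  $B = 1000$, seeded, single-class resamples redrawn) serve HLS and net
  benefit, whose analytic intervals are awkward.

## The validation engine

Cross-validation is split **by cohort, not by patient**: the question is how a
tool built on some centers performs at other centers. Three designs:

1. **Exhaustive 5/5 splits** (`run_split_validation()`): all
   $\binom{10}{5} = 252$ ways to hold out five of ten cohorts for testing.
   Metrics are computed on the pooled test rows (not averaged per cohort).
   Per-split differences between each ordered pair of methods are summarized
   by the median and 2.5/97.5 percentiles of this permutation distribution
   (`compare_methods_pairwise()`); positive differences favor the
   first-listed method.
2. **Leave-one-cohort-out** (`leave_one_cohort_out()`): the split validation
   repeated with each cohort removed, to see whether any cohort's exclusion
   improves the distribution.
3. **Designated-cohort influence** (`cohort_exclusion_influence()`): each
   remaining cohort serves as sole test set; models trained with and without
   the designated cohort are compared on it. The AUC difference carries a
   paired DeLong interval; −HLS and net-benefit differences carry bootstrap
   percentile intervals on resamples of test individuals shared between the
   two models. Sign convention: positive = including the designated cohort
   helps.

Split-level fitting failures (e.g. a meta term inestimable in a small
training half) are recorded per split and dropped pairwise-listwise from
comparisons; the run aborts only if more than 10% of fits fail. Repeat
biopsies from the same patient, where present, are treated as independent
rows; a `patient_id` column is carried but not used for clustering.

## The synthetic generator

`generate_cohorts()` draws, per cohort: log2 PSA from a normal (so PSA is
log-normal base 2), age from a normal truncated to [40, 90] years (PSA to
[0.1, 50] ng/ml), four independent Bernoulli binary factors, and the outcome
from the random-intercept logistic model itself — $\beta_0 + \beta_{0c} +
\beta'x$ with $\beta_{0c} \sim N(0, d)$ or fixed per-cohort offsets.
Missingness in the binary factors is applied after outcome generation,
independently of everything (MCAR by construction). The linear predictor uses
*population* standardization constants (the cohort-size-weighted mixture
moments implied by the configuration), so fitted models that standardize by
sample moments are estimating the same coefficients.

`pbcg_like_preset()` encodes the published marginal facts of a ten-cohort
prostate biopsy consortium as the default study conditions: cohort sizes
spanning 299–1863 (total 8492), outcome prevalence spanning 18–39%, one
cohort with 63% African ancestry, one with 51% abnormal DRE, and one large
low-prevalence cohort with no African-ancestry patients, 2.8% family history
and 40% prior negative biopsies. True coefficients follow the published sign
structure (risk up with PSA, age, DRE, ancestry, family history; down with a
prior negative biopsy; DRE magnifies the PSA effect, age's effect attenuated
under abnormal DRE or African ancestry). Only two cohort prevalences are
printed facts (18% and 39%, with the rest "27% and higher"); the remaining
targets are spread over 0.27–0.35 in the published prevalence ordering, and
the six unpublished cohort sizes were chosen within the printed range to hit
the printed total. Per-cohort intercepts are then *solved*, not tuned: for
each cohort, `solve_cohort_intercepts()` finds the intercept whose expected
prevalence under the cohort's covariate mix equals the target, by exact
enumeration of the 16 binary-factor combinations and two-dimensional
Gauss–Hermite quadrature over the standardized continuous covariates. The
preset is deterministic and involves no random search.

**What the generator does not emulate**: within-cohort covariate correlations
(e.g. PSA–age) — only marginals are published, so covariates are independent
within cohort; non-logistic outcome mechanisms; informative missingness;
patient-level repeat-biopsy correlation. Tests passing on this generator
demonstrate the *machinery* — estimator correctness, calibration of the
metrics, the validation bookkeeping — under the stated heterogeneity, not
that any conclusion transfers to a particular real consortium.

## Problem sizes used by the test suite

The suite exercises the full 252-split × 5-method grid on the preset at a
quarter of the study scale (total n ≈ 2100) — the method-comparison check is
qualitative (intervals covering zero) and scale-stable, and a quarter-scale
grid keeps the run pleasant. Parameter-recovery checks run 50 replicates at
full preset scale for the pooled fit and at 10 cohorts × 300 for the
random-intercept variance; metric calibration uses 200 replicates of n = 5000
for the HLS null and 500 replicates of n = 1000 for the AUC null. Interval
checks under a null construction allow the nominal ~5% false-exclusion rate
(asserting a ≤ 20% bound) rather than demanding every interval cover zero,
which a 95% interval does not promise.

## Known limitations

* Patient-level clustering (repeat biopsies) is ignored, matching the
  analysis the package profiles; a `patient_id` column is carried for users
  who want to handle it upstream.
* The multinomial three-outcome variant used by some online tools is out of
  scope; the outcome here is binary high-grade vs rest.
* No recalibration-to-a-new-population utilities; the influence analyses tell
  you *whether* a cohort is problematic, not how to repair calibration for it.
* Random slopes, penalized/Firth fitting and bootstrap-over-cohorts
  resampling are not implemented.
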