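---
title: "Methods: trial-based cost-effectiveness analysis of depression-care strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis of depression-care strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depcea)
```

## The analysis depcea implements

depcea re-implements, as a tested and reusable pipeline, the economic
evaluation of a four-arm randomized trial of depression care in primary
care: standard care (SC), treatment as usual (TAU), treatment as usual
plus online CBT (ICBT), and a stepped-care pathway (SCP). Participants
were screened with the PHQ-9 (0–27; above 10 indicates
moderate-to-severe depression) and completed the EQ-5D-5L, whose
responses map to a utility between 0 (worst) and 1 (full health), at
baseline and 12 weeks. Costs come from administrative data for three
sectors — physician, outpatient, and inpatient services — over three
windows: 12 weeks pre-randomization, 12 weeks post, and 12 weeks to one
year. All costs are expressed in 2017 Canadian dollars; a multiplicative
`price_factor` lets users re-express them under a different price year
(the consumer-price-index ratio is supplied by the user, not bundled).

Because the trial's patient-level data are not publicly available, the
package has two complementary modes:

* **table-reproduction mode** (`reproduce_reference_analysis()`): the
  published arm-level summaries bundled in `ref_service_counts()`,
  `ref_sector_costs()`, `ref_outcome_summary()` and `ref_ce_summary()`
  drive the decision tree, the QALY construction and the probabilistic
  sensitivity analysis (PSA) directly;
* **patient-level mode** (`run_full_analysis()` on a cohort from
  `generate_cohort()` or `read_cohort()`): the full pipeline —
  classification, trimming, imputation, regression adjustment, QALYs,
  decision tree, PSA — runs on one row per participant.

## Model components

### Service-mix decision tree

Health-care use in the year after randomization is represented by five
mutually exclusive combinations: no services, physician only,
physician + outpatient, physician + inpatient, and all three sectors
(`service_mix`). With sector mean costs among users $C_p, C_o, C_i$ the
expected annual cost per participant is

$$E[\text{cost}] = p_{phys}C_p + p_{p+o}(C_p+C_o) + p_{p+i}(C_p+C_i) +
  p_{all}(C_p+C_o+C_i),$$

the no-service branch contributing zero. Branch probabilities are
estimated from classified counts (they then sum to exactly 1); the
published count tables contain a handful of internal inconsistencies
between counts, percentages, and totals, and the package always
normalizes by the sum of the counts. Cells printed as "na" are treated
as structural zeros. The identical-service-mix sensitivity analysis
(`pooled_mix = TRUE`) gives every arm the pooled mix.

### Cost cleaning and adjustment

Administrative cost data contain implausibly expensive observations.
Physician and outpatient costs are trimmed per arm × period × sector
with the classic boxplot rule: values outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ are excluded,
quartiles computed by linear interpolation between order statistics
(quantile type 7; the convention is recorded in the `TrimReport` so the
fences are auditable). Fences are computed among *users* (positive
costs): a zero means no service use, not cheap use. Inpatient costs are
never trimmed — admissions are few and genuinely expensive. Trimming
removes observations, not participants: a record trimmed in one sector
stays in the analysis for the others.

Among users, sector costs are right-skewed; they are adjusted for age,
sex, and baseline PHQ-9 with a gamma GLM with **identity** link (a
linear cost–predictor relation with gamma noise). The identity link can
propose non-positive means during fitting, so the in-package IRLS
step-halves each update until fitted means stay above a 1e-6 floor,
declares convergence when the relative deviance change falls below
1e-8, and errors with its deviance trace after 100 iterations. Arm
estimates are predictions at the pooled covariate means
(recycled-population standardization) so arms are compared on a common
population; strata with fewer than 10 users per arm fall back to the
flagged raw mean. Zero-cost non-users are excluded from the GLM by
design — use versus non-use is the decision tree's job, giving the
familiar two-part structure (use probabilities × user means).

### Outcomes and QALYs

Twelve-week PHQ-9 and EQ-5D are adjusted for their baseline values by
OLS on arm indicators plus the baseline score, again predicted at the
pooled baseline mean. QALYs are the area under the piecewise-linear
utility path over 52 weeks with the 12-week measurement at 12/52. The
trial did not measure utilities after 12 weeks, so the base case carries
the 12-week utility forward; two persistence scenarios bound that
assumption (`linear_return`: the effect decays linearly back to
baseline by one year; `immediate_return`: it vanishes at 12 weeks).
All three share the linear 0–12-week segment, so for weights
$w = (w_0, w_{12})$ the QALY is $w_0 u_0 + w_{12} u_{12}$ with
$w = (6/52, 46/52)$, $(26/52, 26/52)$, $(46/52, 6/52)$ respectively.
No discounting is applied on the one-year horizon.

### Missing outcomes

Twelve-week outcomes are missing for some participants; baselines never
are. `impute_missing()` performs chained-equation imputation with
predictive-mean-matching draws (posterior-drawn coefficients, donor
pool of 5, 5 cycles), conditioning on arm, age, sex, both baselines,
and the other 12-week outcome, producing `m = 20` completed datasets by
default. Downstream estimates are pooled with Rubin's rules: the point
estimate is the mean of the per-imputation estimates and the total
variance adds $(1 + 1/m)$ times the between-imputation variance to the
mean within-imputation variance.

### Probabilistic sensitivity analysis

The PSA samples, independently per arm, 10,000 (cost, QALY) pairs —
gamma for costs (parameterized by mean and s.d.:
shape $= \mu^2/\sigma^2$, scale $= \sigma^2/\mu$), normal truncated to
$[0,1]$ for QALYs. The published "(s.d.)" columns of the
cost-effectiveness table are interpreted as the sampling spread of the
arm *means* (the distributions the original Monte Carlo redrew), an
interpretation that reproduces the published 55% below-line scatter
fraction; a patient-level-s.d. reading would not. An arm-correlation
knob exists but defaults to 0 (nothing is published about it). From the
draws the package computes ICERs with quadrant classification (dominant
/ dominated / trade-off; no ratio when the QALY difference is zero),
per-iteration net monetary benefit
$\mathrm{NMB} = \lambda\,\Delta\mathrm{QALY} - \Delta\mathrm{cost}$,
cost-effectiveness acceptability curves (probability of attaining the
maximum NMB among all arms, ties split equally, on a $0$–$200{,}000$
grid in $1{,}000$ steps), and the incremental cost-effectiveness
scatter, whose below-the-line fraction at a willingness-to-pay equals
the pairwise CEAC value on the same draws by construction. Excluding
dominated arms from scatterplots is a reporting choice, not an
estimation step. Four-way max-NMB CEACs are the default; pairwise
curves are available by subsetting the draws to two arms.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without any
data download; its defaults are calibrated once to the published
arm-level tables and are not tuning knobs.

* **PHQ-9 margins.** Scores are a latent normal, rounded and *censored*
  (clamped) at the instrument bounds 0 and 27. Censoring, not
  rejection-truncation, is deliberate: screening populations pile up at
  0, and a left-truncated normal cannot be simultaneously as
  overdispersed (s.d. 5.01 at mean 4.61) and as heavy above 10 (14.6%)
  as the published cohort, whereas the censored margin reproduces the
  mean and either the s.d. or the depressed fraction. When an arm
  profile carries a `depressed_fraction` target (the default, from the
  published per-arm depressed counts), mean and tail are matched and
  the s.d. is emergent (5.12 against the printed 5.01 for the pooled
  row); without it, mean and s.d. are matched.
* **EQ-5D margins.** Latent normal censored to $[0,1]$,
  moment-matched to the published mean and s.d.; the ceiling mass at 1
  mirrors the instrument's full-health ceiling.
* **Copula.** The four outcome margins are linked by a Gaussian copula:
  baseline–12-week stability 0.6 within each instrument, PHQ-9↔EQ-5D
  cross-correlation −0.5 (worse depression, lower utility), cross-lag
  the product of the two. The trial publishes only marginals; these are
  plausible field values, exposed as `cor_stability` / `cor_cross`.
* **Service use and costs.** Each participant draws one of the five
  combinations from the arm's published mix; sector costs among users
  are gamma with the published one-year (mean, s.d.), split across
  periods proportional to length (12/52 pre and post, 40/52 late) at
  constant coefficient of variation, exact zeros for unused sectors.
  The stored combination governs the post-randomization year; the
  pre-randomization window draws its own combination from the same mix.
  A cost–outcome correlation knob (`cor_cost_outcome`, default 0)
  exists because the trial reports none.
* **Contamination and missingness.** High-cost outliers multiply a 3%
  fraction of physician/outpatient observations by 6; 15% of 12-week
  outcomes go missing, by default MAR with probability increasing in
  baseline PHQ-9 (the intercept is solved so the expected rate is
  exact). Both rates are unpublished; these are realistic defaults for
  administrative trial data, set once.

What the generator does **not** emulate: clinic-level clustering (the
trial notes it only as a limitation), individual billing events or
drug-level costs, week-6 assessments, and any cost–outcome dependence
beyond the optional knob. Passing tests therefore demonstrate that the
estimators recover the generating structure under these assumptions,
not that they would be unbiased under, say, informative clustering.

## Numerical and design choices

* Quantile convention for trimming: type 7, recorded in every report.
* The strict "greater than 10" depressed rule is implemented as
  printed; the common elsewhere "≥ 10" reading would move 10-scorers
  into the subgroup.
* Gamma GLM: OLS start, step-halving, 1e-6 floor on fitted means,
  deviance tolerance 1e-8, 100-iteration cap; dispersion by the Pearson
  estimator; `stats::glm` with the same family/link is used in the test
  suite as an independent cross-check, never as the implementation.
* Degenerate inputs: constant covariates are dropped from cost models
  (they carry no information and break the design); a constant cost
  vector trims nothing (IQR 0 puts every point on the fences); `sd = 0`
  PSA inputs collapse to point masses, where the equal-split tie rule
  for CEACs matters and is tested.
* Arm-level PSA input s.d. for generated cohorts combines, by the delta
  method, multinomial service-mix uncertainty and the sector-mean
  standard errors.
* Every random stage (generation, imputation, bootstrap, PSA) derives
  its seed deterministically from one master seed; identical
  configuration and seed give byte-identical results.

## Problem sizes used in the checks

The test suite exercises moment recovery at 40,000–50,000 records per
profile, regression-coefficient recovery at 20,000 records, imputation
recovery at 5,000, and an end-to-end parameter-recovery run at 50,000
per arm, comparing pipeline output against closed-form decision-tree
totals and a latent-quadrature oracle for the adjusted-utility QALYs at
three Monte-Carlo standard errors. The end-to-end recovery run disables
outlier injection and trimming: trimming a genuine gamma tail biases
user means by a percent or two by design (robustness against
contamination, at the price of a small bias on clean data), which would
otherwise swamp the Monte-Carlo tolerance; trimming's behaviour under
contamination is tested separately (an injected 5%-at-×10 contamination
moves raw means visibly while trimmed means stay within 1%).

## Known limitations

* The published trial tables are the only calibration source; where
  they are internally inconsistent (count sums versus printed totals)
  the counts win, and reproduced totals consequently differ from the
  published ones by up to ~7% in the smallest subgroup cells.
* Whether the original analysis fed raw or GLM-adjusted sector means to
  its decision tree, and whether its published QALYs used adjusted or
  raw utilities, is not fully specified; the package uses adjusted
  values in patient-level mode and raw published values in
  table-reproduction mode, and the reproduction tolerances absorb the
  difference.
* The published confidence intervals for cost and QALY differences are
  much narrower than the spread implied by the published scatter
  fractions; the two cannot both follow from one sampling model. The
  package follows the scatter-consistent interpretation of the
  published s.d. columns.
* Periods are fixed 12/12/40-week totals; there are no dated events,
  no Markov extension, and no societal-cost perspective.
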