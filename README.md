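# depcea

Trial-based cost-effectiveness analysis of four primary-care
depression-care strategies: standard care (SC), treatment as usual
(TAU), treatment as usual plus online CBT (ICBT), and a stepped-care
pathway (SCP).

The package is for health economists and biostatisticians who want the
whole evaluation as a reproducible, tested pipeline rather than a
one-off script: cost cleaning and covariate adjustment, QALY
construction from EQ-5D-5L utilities, a service-mix decision-tree cost
model, and Monte Carlo probabilistic sensitivity analysis (PSA)
producing ICERs, cost-effectiveness acceptability curves (CEACs), and
incremental cost-effectiveness scatterplots. Because the underlying
trial's patient-level administrative data are not public, the package
also ships a calibrated synthetic cohort generator, so every stage runs
and is testable end to end from the published arm-level tables alone.

## The model in brief

**Costs.** Participants fall into one of five service-use combinations
over the year after randomization (none, physician only,
physician + outpatient, physician + inpatient, all three). With branch
probabilities *p* and sector mean costs among users
*C<sub>p</sub>, C<sub>o</sub>, C<sub>i</sub>* (2017 CAD), the
decision-tree expected annual cost per participant is

> E[cost] = p<sub>phys</sub>·C<sub>p</sub> +
> p<sub>p+o</sub>·(C<sub>p</sub>+C<sub>o</sub>) +
> p<sub>p+i</sub>·(C<sub>p</sub>+C<sub>i</sub>) +
> p<sub>all</sub>·(C<sub>p</sub>+C<sub>o</sub>+C<sub>i</sub>).

Physician/outpatient costs are IQR-trimmed (1.5 × IQR boxplot rule,
never inpatient) and user means are adjusted for age, sex, and baseline
PHQ-9 with an identity-link gamma GLM.

**Effects.** QALYs are the area under the piecewise-linear EQ-5D
utility path over 52 weeks, carrying the 12-week utility forward in the
base case (two persistence scenarios relax this), with 12-week
utilities baseline-adjusted by OLS. Missing 12-week outcomes are
multiply imputed (chained equations with predictive-mean-matching
draws) and estimates pooled by Rubin's rules.

**Uncertainty.** The PSA draws 10,000 (cost, QALY) pairs per arm (gamma
costs, truncated-normal QALYs), classifies ICER quadrants
(dominant/dominated/trade-off), and builds CEACs from the probability
of attaining the maximum net monetary benefit
λ·ΔQALY − Δcost across arms.

## Worked example

Reproduce the published analysis directly from the bundled arm-level
tables:

```r
library(depcea)
rep <- reproduce_reference_analysis("all", n_iter = 10000, seed = 1)
dplyr::select(rep$expected_costs, arm, total)
#> # A tibble: 4 × 2
#>   arm   total
#>   <fct> <dbl>
#> 1 SC    2392.
#> 2 TAU   2770.
#> 3 ICBT  2487.
#> 4 SCP   2198.
rep$icers
#> # A tibble: 3 × 7
#>   arm_a arm_b delta_cost delta_qaly  icer classification degenerate
#>   <chr> <chr>      <dbl>      <dbl> <dbl> <chr>          <lgl>
#> 1 SCP   SC         -166.   0.000981    NA dominant       FALSE
#> 2 SCP   TAU        -579.   0.0120      NA dominant       FALSE
#> 3 SCP   ICBT       -168.   0.00105     NA dominant       FALSE
rep$scatter_fraction
#> [1] 0.5768
```

The expected-cost column says the stepped-care pathway is the cheapest
strategy (about $2,198 per participant-year against $2,770 for
treatment as usual); the ICER table classifies SCP as *dominant* —
cheaper and at least as effective — against all three alternatives; and
57.7% of the 10,000 simulated SCP-vs-ICBT differences fall below the
$50,000-per-QALY line, i.e. the decision between those two arms remains
genuinely uncertain. `plot_ceac(rep$ceac)` and
`plot_ce_plane(rep$scatter)` draw the corresponding figures.

The same pipeline runs on patient-level data (synthetic or your own CSV
in the documented cohort dialect):

```r
cfg <- cohort_config(profiles = arm_profiles("all"))
report <- run_full_analysis(cfg, seed = 1)      # generate → classify →
report                                          # trim → impute → adjust →
                                                # QALY → tree → PSA
```

See the methods vignette (`vignettes/cost-effectiveness-methods.Rmd`)
for the model assumptions, the generator's calibration, and every
numerical choice.

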