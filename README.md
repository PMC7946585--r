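# uuscore

Composite patient-engagement scoring and longitudinal analysis for mobile
diabetes coaching.

Mobile coaching systems for type 2 diabetes log, day by day, whether a
patient uploaded a self-monitored blood glucose (SMBG) reading, a dietary
record or an exercise record, and whether the coaching messages sent by care
managers were read. `uuscore` turns that usage trail into the **User Utility
Score (UUS)** — a 0–8 composite measuring engagement over the first three
months — and runs the longitudinal analysis linking it to glycemic control
over a twelve-month follow-up. It is aimed at biostatisticians evaluating
digital-health engagement measures and at anyone who wants a fully
reproducible, simulation-validated reference implementation of this class of
analysis.

## The score and the analysis

For participant *i* and component *c* ∈ {SMBG days, diet days, exercise
days, message reading rate}, each component value over days 1–91 is cut at
the cohort's empirical tertiles (inverted-ECDF quantiles, ties to the lower
tertile) and scored s<sub>ic</sub> ∈ {0, 1, 2}; the composite is

> UUS<sub>i</sub> = Σ<sub>c</sub> s<sub>ic</sub> ∈ {0, …, 8},

and the cohort is dichotomized at its median UUS (low vs high engagement).
The analysis battery then mirrors standard longitudinal trial practice:
last-observation-carried-forward (LOCF) completion of missing follow-ups;
Student t / Pearson chi-square group contrasts; mixed between–within
repeated-measures ANOVA (group × visit, Type III); ordinary least squares of
the HbA1c change Δ<sub>M</sub> = HbA1c<sub>M</sub> − HbA1c<sub>0</sub> at
months M ∈ {3, 6, 12} on the continuous UUS under nested covariate sets
(crude; + age, sex; + BMI, SBP, LDL, baseline HbA1c, diabetes duration;
+ smoking, alcohol, ADS score); the reduction-rate regression
100·Δ<sub>M</sub>/HbA1c<sub>0</sub> ~ UUS; and Bonferroni correction across
the three time points (0.05/3, reported as .016).

Because the motivating trial's raw data are private, the package includes a
first-class synthetic cohort generator (`sim_scenario()`,
`simulate_cohort()`) whose calibrated defaults encode the study conditions —
n = 72, beta-binomial engagement counts whose tertile boundaries sit near
33/75, 3/30, 37/81 days and 73%/97%, true HbA1c effects of
−0.113/−0.143/−0.136 % per UUS point at months 3/6/12, and
group-differential month-12 dropout (39% vs 9%) — so every stage of the
pipeline can be validated by parameter recovery. See the methods vignette
(`vignettes/uus-methods.Rmd`) for the full model and its assumptions.

## Worked example

```r
library(uuscore)

b <- run_pipeline(pipeline_config(scenario = "calibrated", seed = 7))

b$sizes
#>  low high
#>   47   25

b$table3[b$table3$model == "model3", c("visit_month", "estimate", "se", "p_value", "n")]
#>   visit_month estimate     se p_value  n
#> 1           3   -0.197 0.0793  0.0157 72
#> 2           6   -0.150 0.0875  0.0911 72
#> 3          12   -0.123 0.0746  0.1044 72
```

This simulates one 72-participant cohort under the calibrated scenario,
scores it (here the median split lands at UUS ≤ 4 vs ≥ 5, 47 vs 25
participants), and fits the fully adjusted (model 3) regressions: each row
is the estimated change in HbA1c (% points) per additional UUS point at that
visit, with its standard error and two-sided p-value on all 72 participants
after LOCF. At n = 72 a single simulated cohort is deliberately noisy — the
point estimates scatter around the generative truths (−0.113/−0.143/−0.136)
with SEs near 0.08; the test suite averages over many large cohorts to check
the pipeline recovers them. `run_pipeline()` also returns the baseline
comparison (`table1`), per-group change contrasts (`table2`, `table5`), the
reduction-rate fits (`table4`) and the mixed ANOVA (`anova`), and, given
`output_dir`, writes the whole bundle (CSV/JSON, config-stamped) to disk.
A thin command-line front end with `simulate` / `score` / `analyze` / `run`
subcommands ships in `inst/cli/uus.R`.

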