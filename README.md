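# ctgobs

Observer-performance and interobserver-agreement analysis for
cardiotocography (CTG) interpretation studies.

## The problem

During labor, obstetricians, residents and midwives read the CTG trace
(fetal heart rate + uterine contractions) to judge whether the fetus is
becoming hypoxic. The ground truth only arrives at delivery, as the
umbilical cord blood pH: a pH below 7.15 is taken as moderate fetal
hypoxia. Multi-reader studies of this task collect thousands of
case-level predictions from readers of different professions and
experience levels, then ask two questions:

1. **Accuracy** — how often do readers predict the outcome correctly,
   overall and by stratum, and how does difficulty vary with pH?
2. **Agreement and reliability** — do readers (or professions) say the
   same thing, beyond what chance would produce?

`ctgobs` implements the full analysis for such studies, plus a synthetic
annotator-cohort generator so every stage is testable without access to
any clinical data.

## What it computes

* **Diagnostic accuracy.** For pooled annotations and per stratum
  (profession, experience band): success rate, sensitivity Se and
  specificity Sp, each with a **Wilson score interval**

  $$\frac{\hat p + z^2/2n}{1 + z^2/n} \;\pm\; \frac{z}{1 + z^2/n}
    \sqrt{\frac{\hat p(1-\hat p)}{n} + \frac{z^2}{4n^2}}$$

  Also: per-participant TPR/FPR operating points (readers with more than
  10 annotations), and the success-rate profile across pH ranges.

* **Agreement and reliability.** Per profession, a majority-vote
  consensus label per case; then, for each pair of professions on their
  overlapping cases, the proportion of agreement PA (with Wilson CI and
  the Altman verbal scale) and Cohen's kappa
  $\kappa = (p_o - p_e)/(1 - p_e)$ (large-sample CI, Landis–Koch scale).
  Overall PA and kappa are overlap-weighted means of the pairwise
  values; their CIs come from a seeded case-level bootstrap.

* **Design.** Batched balanced case assignment (shared batches of 10
  with 5 hypoxic + 5 normal cases, privately shuffled within batch per
  reader) and the Buderer-type sample-size calculation
  $n = z^2\,Se(1-Se) / (d^2\,\text{prev})$ (and the Sp analogue).

* **Simulation.** A generator producing case sets, cohorts and
  annotations from a latent two-parameter logistic rater model:
  each rater calls "hypoxia" with probability
  $\sigma(a + b(\tau - \mathrm{pH}))$, which makes accuracy dip toward
  chance for cases near the 7.15 threshold, as observed in practice.

## Worked example

```r
library(ctgobs)
study <- simulate_study(generator_config(seed = 2024))
study
#> CTG annotation study
#>   cases:        100 (50 hypoxia / 50 normal at pH < 7.15)
#>   participants: 120 (midwife 23, obstetrician_gynecologist 58, resident 39)
#>   annotations:  3125

summarize_performance(study, grouping = "profession")
#> Accuracy summary (grouping: profession, 95% Wilson CIs)
#>                      group    n           success       sensitivity       specificity
#>                   resident  927 0.64 (0.61, 0.67) 0.59 (0.54, 0.63) 0.69 (0.65, 0.73)
#>                    midwife  636 0.64 (0.61, 0.68) 0.65 (0.60, 0.70) 0.64 (0.58, 0.69)
#>  obstetrician_gynecologist 1562 0.63 (0.61, 0.66) 0.63 (0.59, 0.66) 0.64 (0.61, 0.67)
#>                      total 3125 0.64 (0.62, 0.66) 0.62 (0.60, 0.64) 0.66 (0.63, 0.68)

agreement_analysis(study, seed = 2024)
#> Interobserver agreement (95% CIs; overall CIs: case bootstrap, 2000 resamples)
#>                                   pair  n                PA             kappa
#>                    resident vs midwife 76 0.75 (0.64, 0.83) 0.51 (0.32, 0.70)
#>  resident vs obstetrician_gynecologist 89 0.67 (0.57, 0.76) 0.36 (0.16, 0.55)
#>   midwife vs obstetrician_gynecologist 77 0.75 (0.65, 0.84) 0.51 (0.31, 0.70)
#> overall: PA 0.72 (0.65, 0.79) [good], kappa 0.45 (0.31, 0.59) [moderate]

sample_size_sens_spec(se = 0.45, sp = 0.67, precision = 0.14, prevalence = 0.5)
#> [1] 97
```

Reading the output: each row pools that profession's annotations; a
success rate of 0.64 means 64% of predictions matched the pH-derived
outcome, and the Wilson bounds quantify the binomial uncertainty at that
denominator. In the agreement table, `n` is the number of cases the two
professions' consensus vectors share; PA is raw concordance on those
cases, while kappa discounts the concordance expected by chance (with a
50/50 case mix the two are directly comparable). The verbal labels in
brackets are the Altman (PA) and Landis–Koch (kappa) categories. The
final number is the case count needed so a 95% CI on an anticipated
sensitivity of 0.45 (at 50% prevalence) has half-width at most 0.14.

One call runs everything and writes report tables (CSV + JSON mirrors)
and a run manifest:

```r
run_pipeline(pipeline_config(out_dir = "reports", seed = 1))
```

To analyse real data instead of a simulation, point
`pipeline_config(study_dir = ...)` at a directory containing
`cases.csv` (case_id, ph), `participants.csv` (participant_id,
profession, years_experience, setting, country) and `annotations.csv`
(participant_id, case_id, predicted_outcome, presentation_index).

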